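#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# canonical genotype codes used throughout the package
GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

CONSEQUENCE_LEVELS <- c(
  "missense", "utr5", "utr3", "upstream", "downstream",
  "intronic", "intergenic", "other"
)

IMPACT_LEVELS <- c("deleterious", "tolerated", "none")

TIE_LEVELS <- c("both_sides", "one_side", "none", "is_founder")

assert_gt <- function(x, arg = "genotype") {
  bad <- setdiff(unique(x[!is.na(x)]), GT_LEVELS)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s contains values outside {%s}: %s",
      arg, paste(GT_LEVELS, collapse = ", "), paste(bad, collapse = ", ")
    ))
  }
  invisible(x)
}

# genotype columns in a variant table are prefixed gt_<sample_id>
gt_cols <- function(sites) grep("^gt_", names(sites), value = TRUE)

gt_samples <- function(sites) sub("^gt_", "", gt_cols(sites))

#' Extract the genotype matrix of a variant table
#'
#' Variant tables store one column per sequenced sample, named
#' `gt_<sample_id>`, holding calls in `hom_ref` / `het` / `hom_alt` /
#' `missing`. This helper returns them as a sites-by-samples character
#' matrix with sample ids as column names.
#'
#' @param sites A variant table as returned by [read_variants()] or
#'   [simulate_variants()].
#' @return Character matrix, one row per site, one column per sample.
#' @export
gt_matrix <- function(sites) {
  cols <- gt_cols(sites)
  m <- as.matrix(sites[, cols, drop = FALSE])
  colnames(m) <- sub("^gt_", "", cols)
  m
}

site_key <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

signif_or_zero <- function(x, digits) ifelse(x == 0, 0, signif(x, digits))
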