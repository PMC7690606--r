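#' Call genotypes from per-locus pileup read counts
#'
#' Implements threshold genotype calling on targeted pileups: a sample
#' needs at least `min_depth` informative reads (reference + alternate) at
#' the locus, otherwise the call is `missing`; with sufficient depth the
#' alternate-read fraction `f = alt / (ref + alt)` is called `hom_ref`
#' when `f <= hom_threshold`, `hom_alt` when `f >= 1 - hom_threshold`, and
#' `het` in between.
#'
#' @param pileup Tibble with columns `chrom`, `pos`, `sample_id`,
#'   `ref_reads`, `alt_reads` (and optionally `other_reads`, ignored for
#'   calling).
#' @param min_depth Minimum informative depth (default 10).
#' @param hom_threshold Alternate-fraction cutoff for homozygous calls
#'   (default 0.15; the homozygous-alternate cutoff is its complement).
#' @return Tibble of assay calls: `sample_id`, `chrom`, `pos`, `call`,
#'   `depth`, `method = "pileup"`.
#' @export
genotype_from_pileup <- function(pileup, min_depth = 10, hom_threshold = 0.15) {
  pileup <- as_tibble(pileup)
  if (any(pileup$ref_reads < 0 | pileup$alt_reads < 0)) {
    abort("read counts must be non-negative")
  }
  d <- pileup$ref_reads + pileup$alt_reads
  f <- ifelse(d > 0, pileup$alt_reads / d, NA_real_)
  call <- dplyr::case_when(
    d < min_depth ~ "missing",
    f <= hom_threshold ~ "hom_ref",
    f >= 1 - hom_threshold ~ "hom_alt",
    TRUE ~ "het"
  )
  tibble(
    sample_id = pileup$sample_id, chrom = pileup$chrom, pos = pileup$pos,
    call = call, depth = d, method = "pileup"
  )
}

#' Resolve duplicate assay calls
#'
#' Genotyping assays run in duplicate are accepted only when both
#' reactions yield the same non-missing call; anything else (a discordant
#' pair, or one or both reactions failing) raises a failure flag that
#' signals re-genotyping by an orthogonal method.
#'
#' @param call_a,call_b Tibbles of assay calls with columns `sample_id`,
#'   `chrom`, `pos`, `call`, matched row-by-row (same sample and site per
#'   row; a mismatch is an error).
#' @return Tibble with `sample_id`, `chrom`, `pos`, `call` (NA where the
#'   pair failed) and logical `failed`.
#' @export
duplicate_concordance <- function(call_a, call_b) {
  call_a <- as_tibble(call_a); call_b <- as_tibble(call_b)
  if (nrow(call_a) != nrow(call_b)) abort("duplicate call tables differ in length")
  same <- call_a$sample_id == call_b$sample_id &
    call_a$chrom == call_b$chrom & call_a$pos == call_b$pos
  if (!all(same)) {
    abort("duplicate calls are not matched by sample and site")
  }
  assert_gt(call_a$call); assert_gt(call_b$call)
  ok <- call_a$call == call_b$call & call_a$call != "missing"
  tibble(
    sample_id = call_a$sample_id, chrom = call_a$chrom, pos = call_a$pos,
    call = ifelse(ok, call_a$call, NA_character_),
    failed = !ok
  )
}

pool_droplets <- function(droplets) {
  droplets <- as_tibble(droplets)
  need <- c("variant_positive", "wildtype_positive", "double_positive", "negative")
  missing_cols <- setdiff(need, names(droplets))
  if (length(missing_cols) > 0) {
    abort(paste0("droplet table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(as.matrix(droplets[, need]) < 0)) abort("droplet counts must be non-negative")
  lapply(stats::setNames(need, need), function(col) sum(droplets[[col]]))
}

#' Variant allele fraction from droplet digital PCR counts
#'
#' Estimates the variant allele fraction from droplet counts of a duplexed
#' assay. Because a positive droplet may contain several template copies,
#' channel occupancies are converted to per-droplet concentrations by
#' Poisson inversion, `lambda = -log(1 - positives/total)`, and the
#' fraction is `lambda_v / (lambda_v + lambda_w)`. Replicate wells are
#' pooled by summing counts (preserving the Poisson statistics) before
#' inversion.
#'
#' @param droplets Tibble of droplet counts with columns
#'   `variant_positive`, `wildtype_positive` (single-positive counts),
#'   `double_positive`, `negative`; one row per well/replicate.
#' @param raw If `TRUE`, skip the Poisson correction and return the raw
#'   positive-droplet ratio.
#' @return The estimated variant allele fraction (scalar).
#' @export
ddpcr_allele_fraction <- function(droplets, raw = FALSE) {
  cc <- pool_droplets(droplets)
  total <- cc$variant_positive + cc$wildtype_positive + cc$double_positive + cc$negative
  pos_v <- cc$variant_positive + cc$double_positive
  pos_w <- cc$wildtype_positive + cc$double_positive
  if (pos_v + pos_w == 0) {
    abort("no positive droplets in either channel")
  }
  if (raw) return(pos_v / (pos_v + pos_w))
  if (pos_v >= total || pos_w >= total) {
    abort("a channel is saturated (every droplet positive); concentration unresolvable")
  }
  lambda_v <- -log(1 - pos_v / total)
  lambda_w <- -log(1 - pos_w / total)
  lambda_v / (lambda_v + lambda_w)
}

#' Delta-method standard error of the ddPCR allele fraction
#'
#' @inheritParams ddpcr_allele_fraction
#' @return Approximate standard error of [ddpcr_allele_fraction()] for the
#'   pooled counts, by the delta method on the two channel occupancies.
#' @export
ddpcr_fraction_se <- function(droplets) {
  cc <- pool_droplets(droplets)
  total <- cc$variant_positive + cc$wildtype_positive + cc$double_positive + cc$negative
  p_v <- (cc$variant_positive + cc$double_positive) / total
  p_w <- (cc$wildtype_positive + cc$double_positive) / total
  lambda_v <- -log(1 - p_v)
  lambda_w <- -log(1 - p_w)
  var_lv <- p_v / ((1 - p_v) * total)
  var_lw <- p_w / ((1 - p_w) * total)
  lt <- lambda_v + lambda_w
  sqrt(lambda_w^2 * var_lv + lambda_v^2 * var_lw) / lt^2
}

#' Allele-detection power of a ddPCR assay from a single-allele control
#'
#' When a control well contains template of only one allele, every
#' positive droplet in the opposite channel is a false call, and the
#' assay's power to detect the loaded allele is
#' `1 - opposite-channel positives / total positives`. Double-positive
#' droplets count as opposite-channel signal.
#'
#' @param control Tibble of droplet counts for the control well(s);
#'   replicates pooled by summing.
#' @param allele Which allele the control template represents
#'   (`"variant"` or `"wildtype"`): the power reported is for detecting
#'   that allele.
#' @return Power in `[0, 1]`; 1 exactly when the opposite channel has no
#'   positives. Zero total positives is an error.
#' @export
ddpcr_power <- function(control, allele = c("variant", "wildtype")) {
  allele <- match.arg(allele)
  cc <- pool_droplets(control)
  total_pos <- cc$variant_positive + cc$wildtype_positive + cc$double_positive
  if (total_pos == 0) abort("control well has no positive droplets")
  opposite <- switch(allele,
    variant = cc$wildtype_positive + cc$double_positive,
    wildtype = cc$variant_positive + cc$double_positive
  )
  1 - opposite / total_pos
}

#' Assess germline mosaicism against wildtype controls
#'
#' Compares the ddPCR variant allele fraction of each test animal (its
#' replicate wells pooled) with the largest fraction observed among
#' wildtype control animals. A mosaic origin is supported only when the
#' test fraction strictly exceeds every control fraction; a tie or lower
#' value is indistinguishable from assay background.
#'
#' @param test Tibble of droplet counts for test wells, with a
#'   `sample_id` column (replicates share the id).
#' @param wildtype_controls Tibble of droplet counts for wildtype control
#'   wells (must be non-empty).
#' @return Tibble with one row per test animal: `sample_id`, `fraction`,
#'   `control_max`, and `verdict` (`mosaic_supported` / `not_supported`).
#' @export
mosaicism_assessment <- function(test, wildtype_controls) {
  if (is.null(wildtype_controls) || nrow(wildtype_controls) == 0) {
    abort("at least one wildtype control well is required")
  }
  if (is.null(test) || nrow(test) == 0) abort("at least one test well is required")
  frac_by_sample <- function(d) {
    d <- as_tibble(d)
    if (!"sample_id" %in% names(d)) d$sample_id <- "pooled"
    d |>
      group_by(.data$sample_id) |>
      group_modify(~ tibble(fraction = ddpcr_allele_fraction(.x))) |>
      ungroup()
  }
  control_max <- max(frac_by_sample(wildtype_controls)$fraction)
  res <- frac_by_sample(test)
  res$control_max <- control_max
  res$verdict <- ifelse(res$fraction > control_max, "mosaic_supported", "not_supported")
  res
}
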