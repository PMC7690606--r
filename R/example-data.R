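md_extdata <- function(file) {
  system.file("extdata", file, package = "recessivescan", mustWork = TRUE)
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = "NA", ...)
}

#' Worked-example data: Hereford mandibulofacial dysostosis candidates
#'
#' Small bundled tables for the package's worked example, drawn from the
#' published candidate set of a Hereford mandibulofacial dysostosis (MD)
#' discovery cohort: the eight candidate variants that survived recessive
#' segregation filtering of the sequenced cohort, external-cohort genotype
#' summaries at those sites, and the validation-genotyping tallies of the
#' causal *CYP26C1* missense variant by founder-tie class and by data
#' source.
#'
#' `md_example_summaries()` reconstructs per-breed rows from published
#' aggregate counts (6 heterozygotes among 1018 samples at one site; 7
#' heterozygotes and 1 homozygote among 1083 at another, all in
#' non-Hereford breeds); the split across breeds is synthetic, as the
#' file name notes, but the totals and the breeds involved are as
#' reported.
#'
#' @return A tibble: candidate variants (`md_example_candidates()`),
#'   per-breed cohort summaries (`md_example_summaries()`), genotype
#'   counts by cohort and founder-tie class
#'   (`md_example_genotype_counts()`), or genotype tallies by source
#'   (`md_example_genotype_sources()`).
#' @name md_example
NULL

#' @rdname md_example
#' @export
md_example_candidates <- function() {
  read_tsv_quiet(md_extdata("md_candidates.tsv"))
}

#' @rdname md_example
#' @export
md_example_summaries <- function() {
  read_tsv_quiet(md_extdata("sra_cohort_summaries_synthetic.tsv"))
}

#' @rdname md_example
#' @export
md_example_genotype_counts <- function() {
  read_tsv_quiet(md_extdata("cyp26c1_genotypes_by_tie.tsv"))
}

#' @rdname md_example
#' @export
md_example_genotype_sources <- function() {
  read_tsv_quiet(md_extdata("cyp26c1_genotype_sources.tsv"))
}

#' Expand per-cell genotype counts into one row per animal
#'
#' Utility for rebuilding a validation report from published count tables:
#' converts a table of genotype counts per (cohort, tie-class) cell into
#' per-animal call rows suitable for [build_genotype_report()].
#'
#' @param counts Tibble with columns `cohort`, `tie_class`, and one column
#'   per genotype class (`hom_ref`, `het`, `hom_alt`, optionally
#'   `missing`).
#' @return List with `calls` (`sample_id`, `call`), `cohort_labels`, and
#'   `tie_classes` tibbles.
#' @export
expand_genotype_counts <- function(counts) {
  counts <- as_tibble(counts)
  gt_present <- intersect(GT_LEVELS, names(counts))
  long <- tidyr::pivot_longer(counts, cols = all_of(gt_present),
                              names_to = "call", values_to = "n")
  long <- long[long$n > 0, ]
  rows <- long[rep(seq_len(nrow(long)), long$n), ]
  rows$sample_id <- sprintf("animal_%04d", seq_len(nrow(rows)))
  list(
    calls = tibble(sample_id = rows$sample_id, call = rows$call),
    cohort_labels = tibble(sample_id = rows$sample_id, cohort = rows$cohort),
    tie_classes = tibble(sample_id = rows$sample_id, tie_class = rows$tie_class)
  )
}
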