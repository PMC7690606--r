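check_summaries <- function(summaries) {
  summaries <- as_tibble(summaries)
  need <- c("chrom", "pos", "ref", "alt", "n_samples", "n_het", "n_hom_alt")
  missing_cols <- setdiff(need, names(summaries))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort summaries missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"breed" %in% names(summaries)) summaries$breed <- NA_character_
  key <- paste(site_key(summaries), summaries$breed)
  if (anyDuplicated(key) > 0) {
    abort("duplicate cohort summary rows for the same site and breed")
  }
  summaries
}

#' Exclude candidates homozygous-alternate in external cohorts
#'
#' A variant cannot cause a fully penetrant recessive defect if an
#' unaffected external individual is homozygous for its alternate allele.
#' Drops every candidate whose matched cohort summary reports at least one
#' homozygous-alternate sample; candidates with no summary pass through
#' (absence of evidence does not exclude). Matching is exact on
#' (chrom, pos, ref, alt).
#'
#' @param candidates Variant table.
#' @param summaries Cohort summary tibble with columns `chrom`, `pos`,
#'   `ref`, `alt`, `breed` (optional), `n_samples`, `n_het`, `n_hom_alt`;
#'   one row per breed per site.
#' @return The retained subset of `candidates`.
#' @export
homalt_exclusion <- function(candidates, summaries) {
  summaries <- check_summaries(summaries)
  if (nrow(candidates) == 0 || nrow(summaries) == 0) return(candidates)
  hom_sites <- unique(site_key(summaries[summaries$n_hom_alt >= 1, ]))
  candidates[!site_key(candidates) %in% hom_sites, , drop = FALSE]
}

#' Exclude candidates whose alternate allele occurs in other breeds
#'
#' A defect restricted to one breed cannot be caused by an allele
#' segregating in unrelated breeds. Drops every candidate whose alternate
#' allele is observed (heterozygous or homozygous) in at least one sample
#' of a breed other than `defect_breed`.
#'
#' @inheritParams homalt_exclusion
#' @param defect_breed Name of the breed in which the defect segregates.
#' @return The retained subset of `candidates`.
#' @export
breed_exclusion <- function(candidates, summaries, defect_breed) {
  summaries <- check_summaries(summaries)
  if (nrow(candidates) == 0 || nrow(summaries) == 0) return(candidates)
  other <- summaries[
    !is.na(summaries$breed) & summaries$breed != defect_breed &
      (summaries$n_het + summaries$n_hom_alt) >= 1, ]
  candidates[!site_key(candidates) %in% unique(site_key(other)), , drop = FALSE]
}

#' Cohort frequency of an alternate allele
#'
#' The screening statistic used when tabulating external-cohort genotypes:
#' alternate-allele copies per genotyped sample,
#' `(n_het + 2 * n_hom_alt) / n_samples`. Note this is per sample, not per
#' chromosome; the conventional allele frequency (per `2 * n_samples`) is
#' available via `allele_frequency()`.
#'
#' @param n_het Number of heterozygous samples.
#' @param n_hom_alt Number of homozygous-alternate samples.
#' @param n_samples Number of genotyped samples (must be positive).
#' @return Numeric vector of frequencies (0 when no alternate alleles,
#'   2 when every sample is homozygous alternate).
#' @export
cohort_frequency <- function(n_het, n_hom_alt, n_samples) {
  if (any(n_samples <= 0)) abort("n_samples must be positive")
  if (any(n_het + n_hom_alt > n_samples)) {
    abort("n_het + n_hom_alt cannot exceed n_samples")
  }
  (n_het + 2 * n_hom_alt) / n_samples
}

#' Conventional allele frequency from genotype tallies
#'
#' @inheritParams cohort_frequency
#' @return `(n_het + 2 * n_hom_alt) / (2 * n_samples)`.
#' @export
allele_frequency <- function(n_het, n_hom_alt, n_samples) {
  cohort_frequency(n_het, n_hom_alt, n_samples) / 2
}

#' Eliminate candidates using targeted confirmation genotypes
#'
#' Applies the logic of follow-up genotyping assays (Sanger/KASP) on
#' selected animals: a candidate is dropped if any unaffected animal
#' genotypes homozygous alternate, or any affected animal genotypes
#' something other than homozygous alternate. Missing confirmation calls
#' are uninformative and never eliminate a candidate.
#'
#' @param candidates Variant table.
#' @param confirm_genotypes Tibble with columns `chrom`, `pos`, `ref`,
#'   `alt`, `sample_id`, `gt` (canonical genotype codes).
#' @param roles Tibble with columns `sample_id` and `status`
#'   (`affected` / `unaffected`).
#' @return The retained subset of `candidates`. Confirmation rows for
#'   sites absent from `candidates` are ignored with a warning.
#' @export
confirmation_genotype_elimination <- function(candidates, confirm_genotypes, roles) {
  if (is.null(confirm_genotypes) || nrow(confirm_genotypes) == 0) return(candidates)
  confirm_genotypes <- as_tibble(confirm_genotypes)
  assert_gt(confirm_genotypes$gt, "confirmation genotypes")
  cand_keys <- site_key(candidates)
  unknown <- !site_key(confirm_genotypes) %in% cand_keys
  if (any(unknown)) {
    warn(sprintf("%d confirmation genotype(s) at sites not in the candidate list; ignored",
                 sum(unknown)))
    confirm_genotypes <- confirm_genotypes[!unknown, , drop = FALSE]
  }
  status <- stats::setNames(roles$status, roles$sample_id)
  cg <- confirm_genotypes
  cg$status <- unname(status[cg$sample_id])
  bad <- cg[
    (cg$status == "unaffected" & cg$gt == "hom_alt") |
      (cg$status == "affected" & !cg$gt %in% c("hom_alt", "missing")), ]
  candidates[!cand_keys %in% unique(site_key(bad)), , drop = FALSE]
}
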