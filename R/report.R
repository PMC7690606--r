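#' Cross-tabulate validation genotypes by cohort and founder tie
#'
#' Builds the reporting table of a validation genotyping campaign: counts
#' of animals by genotype class within each (cohort, founder-tie) cell,
#' with per-cohort subtotals and a grand total, plus a per-source tally
#' when the calls carry a `source` column. Tie classes are computed from
#' the pedigree against `founder_id`, or supplied directly via
#' `tie_classes` for animals whose ties were classified elsewhere.
#'
#' @param calls Tibble with `sample_id` and `call` (canonical genotype
#'   codes); optional `source` column.
#' @param ped Optional validated pedigree tibble.
#' @param founder_id Founder id (required with `ped`).
#' @param cohort_labels Optional tibble (`sample_id`, `cohort`); samples
#'   without a label fall into cohort `"all"`.
#' @param tie_classes Optional tibble (`sample_id`, `tie_class`)
#'   overriding pedigree classification. Samples found in neither source
#'   are reported under tie class `"no_pedigree"` with a warning.
#' @return An object of class `genotype_report`: list with `cells`
#'   (cohort x tie-class genotype counts), `cohort_totals`, `totals`
#'   (named genotype counts plus `n`), and `by_source` (or `NULL`).
#'   Marginal sums are checked on every build.
#' @export
build_genotype_report <- function(calls, ped = NULL, founder_id = NULL,
                                  cohort_labels = NULL, tie_classes = NULL) {
  calls <- as_tibble(calls)
  assert_gt(calls$call, "calls")
  if (anyDuplicated(calls$sample_id) > 0) {
    abort("one call per animal expected; duplicate sample_id in calls")
  }
  tie <- stats::setNames(rep(NA_character_, nrow(calls)), calls$sample_id)
  if (!is.null(tie_classes)) {
    m <- match(calls$sample_id, tie_classes$sample_id)
    tie[!is.na(m)] <- tie_classes$tie_class[m[!is.na(m)]]
  }
  if (!is.null(ped)) {
    if (is.null(founder_id)) abort("founder_id is required with a pedigree")
    in_ped <- calls$sample_id %in% ped$animal_id & is.na(tie)
    if (any(in_ped)) {
      ct <- classify_founder_ties(ped, calls$sample_id[in_ped], founder_id)
      tie[calls$sample_id[in_ped]] <- ct$tie_class
    }
  }
  if (any(is.na(tie))) {
    warn(sprintf("%d animal(s) without pedigree ties; reported as no_pedigree",
                 sum(is.na(tie))))
    tie[is.na(tie)] <- "no_pedigree"
  }
  cohort <- rep("all", nrow(calls))
  if (!is.null(cohort_labels)) {
    m <- match(calls$sample_id, cohort_labels$sample_id)
    cohort[!is.na(m)] <- cohort_labels$cohort[m[!is.na(m)]]
  }
  df <- tibble(cohort = cohort, tie_class = unname(tie), call = calls$call)
  cells <- df |>
    count(.data$cohort, .data$tie_class, .data$call) |>
    tidyr::pivot_wider(names_from = "call", values_from = "n", values_fill = 0L)
  for (g in GT_LEVELS) if (!g %in% names(cells)) cells[[g]] <- 0L
  cells <- cells[, c("cohort", "tie_class", GT_LEVELS)]
  cells$total <- rowSums(cells[, GT_LEVELS])
  cohort_totals <- cells |>
    group_by(.data$cohort) |>
    summarise(across(all_of(c(GT_LEVELS, "total")), sum), .groups = "drop")
  totals <- colSums(cells[, c(GT_LEVELS, "total")])
  totals <- c(totals, n = unname(totals[["total"]]))

  stopifnot(
    sum(cells$total) == nrow(calls),
    all(rowSums(cells[, GT_LEVELS]) == cells$total),
    sum(cohort_totals$total) == totals[["n"]]
  )

  by_source <- NULL
  if ("source" %in% names(calls)) {
    by_source <- count(calls, source = .data$source, name = "n_animals")
    stopifnot(sum(by_source$n_animals) == nrow(calls))
  }
  structure(
    list(cells = cells, cohort_totals = cohort_totals, totals = totals,
         by_source = by_source),
    class = "genotype_report"
  )
}

#' @exportS3Method base::print
print.genotype_report <- function(x, ...) {
  cat("Validation genotyping report\n")
  print(as.data.frame(x$cells), row.names = FALSE)
  cat(sprintf(
    "totals: %d hom_ref / %d het / %d hom_alt / %d missing (%d animals)\n",
    x$totals[["hom_ref"]], x$totals[["het"]], x$totals[["hom_alt"]],
    x$totals[["missing"]], x$totals[["n"]]
  ))
  if (!is.null(x$by_source)) {
    cat(sprintf("genotypes by source: %d total\n", sum(x$by_source$n_animals)))
  }
  invisible(x)
}

#' Tidy a genotype report
#'
#' @param x A `genotype_report`.
#' @param ... Unused.
#' @return The cohort x tie-class count table as a tibble.
#' @export
tidy.genotype_report <- function(x, ...) x$cells

#' One-row summary of a genotype report
#'
#' @param x A `genotype_report`.
#' @param ... Unused.
#' @return Tibble of overall genotype counts and animal total.
#' @export
glance.genotype_report <- function(x, ...) {
  tibble(
    hom_ref = x$totals[["hom_ref"]], het = x$totals[["het"]],
    hom_alt = x$totals[["hom_alt"]], missing = x$totals[["missing"]],
    n_animals = x$totals[["n"]],
    n_sources = if (is.null(x$by_source)) NA_integer_ else nrow(x$by_source)
  )
}

#' Check calls for Mendelian consistency and carrier-mating segregation
#'
#' Flags genotype calls impossible under biallelic Mendelian
#' transmission given the called parental genotypes (e.g., a
#' homozygous-alternate calf of a homozygous-reference parent), and
#' summarizes matings between two heterozygous (carrier) parents:
#' observed offspring genotype counts next to the expected 1:2:1
#' proportions at that family size.
#'
#' @param calls Tibble with `sample_id` and `call` at one locus.
#' @param ped Validated pedigree tibble.
#' @return List of class `mendel_check`: `inconsistencies` (one row per
#'   flagged animal with its parents' calls and the reason) and
#'   `carrier_matings` (observed and expected counts for het x het
#'   matings with genotyped offspring).
#' @export
mendelian_check <- function(calls, ped) {
  calls <- as_tibble(calls)
  assert_gt(calls$call, "calls")
  g <- stats::setNames(calls$call, calls$sample_id)
  gt_of <- function(id) {
    out <- unname(g[id])
    out[is.na(id) | !id %in% names(g)] <- NA_character_
    ifelse(out == "missing", NA_character_, out)
  }
  kids <- ped[ped$animal_id %in% names(g), ]
  child <- gt_of(kids$animal_id)
  sire <- gt_of(kids$sire_id)
  dam <- gt_of(kids$dam_id)

  viol_single <- function(child, parent) {
    !is.na(child) & !is.na(parent) &
      ((child == "hom_alt" & parent == "hom_ref") |
         (child == "hom_ref" & parent == "hom_alt"))
  }
  # pair-level: alleles a child can draw from each called parent
  viol_pair <- !is.na(child) & !is.na(sire) & !is.na(dam) &
    ((child == "het" & sire == "hom_ref" & dam == "hom_ref") |
       (child == "het" & sire == "hom_alt" & dam == "hom_alt"))
  bad <- viol_single(child, sire) | viol_single(child, dam) | viol_pair
  inconsistencies <- tibble(
    animal_id = kids$animal_id[bad], call = child[bad],
    sire_id = kids$sire_id[bad], sire_call = sire[bad],
    dam_id = kids$dam_id[bad], dam_call = dam[bad],
    reason = "impossible transmission"
  )

  hh <- !is.na(sire) & !is.na(dam) & sire == "het" & dam == "het" & !is.na(child)
  obs <- c(
    hom_ref = sum(child[hh] == "hom_ref"),
    het = sum(child[hh] == "het"),
    hom_alt = sum(child[hh] == "hom_alt")
  )
  n <- sum(obs)
  carrier_matings <- tibble(
    n_offspring = n,
    obs_hom_ref = obs[["hom_ref"]], obs_het = obs[["het"]],
    obs_hom_alt = obs[["hom_alt"]],
    exp_hom_ref = n / 4, exp_het = n / 2, exp_hom_alt = n / 4
  )
  structure(list(inconsistencies = inconsistencies,
                 carrier_matings = carrier_matings),
            class = "mendel_check")
}

#' @exportS3Method base::print
print.mendel_check <- function(x, ...) {
  cat(sprintf("Mendelian check: %d inconsistent call(s)\n",
              nrow(x$inconsistencies)))
  cm <- x$carrier_matings
  if (cm$n_offspring > 0) {
    cat(sprintf(
      "carrier x carrier offspring (n=%d): observed %d/%d/%d vs expected %.1f/%.1f/%.1f (hom_ref/het/hom_alt)\n",
      cm$n_offspring, cm$obs_hom_ref, cm$obs_het, cm$obs_hom_alt,
      cm$exp_hom_ref, cm$exp_het, cm$exp_hom_alt
    ))
  }
  invisible(x)
}
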