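#' Run the discovery pipeline end-to-end
#'
#' Deterministic composition of the discovery stages: site-quality
#' filtering, recessive segregation filtering, external-cohort
#' homozygous-alternate exclusion, cross-breed exclusion, and
#' annotation-based prioritization, with shared-homozygosity mapping of
#' the affected samples computed alongside from the quality-passing sites.
#' Every input variant is accounted for in the provenance log with the
#' stage that eliminated it (or `retained`).
#'
#' @param variants A VCF path or an in-memory variant table (see
#'   [read_variants()]).
#' @param roles Role tibble (`sample_id`, `role`) for the sequenced cohort.
#' @param summaries Optional external cohort summaries (see
#'   [homalt_exclusion()]).
#' @param defect_breed Optional breed name enabling [breed_exclusion()].
#' @param confirm_genotypes,confirm_roles Optional targeted confirmation
#'   genotypes and their affected/unaffected status map (see
#'   [confirmation_genotype_elimination()]).
#' @param min_qual Site quality cutoff (default 30).
#' @param missing_policy Passed to [segregation_filter()].
#' @param roh_min_sites,roh_max_exceptions Passed to
#'   [shared_homozygosity_regions()].
#' @return An object of class `discovery_run` with elements `candidates`
#'   (ranked variant table), `regions` (shared-homozygosity regions),
#'   `stages` (per-stage counts), `log` (per-variant provenance), and
#'   `params`.
#' @export
run_discovery <- function(variants, roles, summaries = NULL,
                          defect_breed = NULL,
                          confirm_genotypes = NULL, confirm_roles = NULL,
                          min_qual = 30,
                          missing_policy = "compatible",
                          roh_min_sites = 20, roh_max_exceptions = 1) {
  sites <- if (is.character(variants)) {
    read_variants(variants, min_qual = 0)
  } else {
    as_tibble(variants)
  }
  log <- tibble(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    stage_eliminated = NA_character_
  )
  mark <- function(log, before, after, stage) {
    gone <- setdiff(site_key(before), site_key(after))
    hit <- site_key(log) %in% gone & is.na(log$stage_eliminated)
    log$stage_eliminated[hit] <- stage
    log
  }
  stages <- list()
  note <- function(stage, n_in, n_out) {
    tibble(stage = stage, n_in = n_in, n_removed = n_in - n_out, n_out = n_out)
  }
  # errors surface with the stage they arose in
  in_stage <- function(stage, expr) {
    withCallingHandlers(expr, error = function(e) {
      abort(paste0("discovery stage '", stage, "' failed: ",
                   conditionMessage(e)), parent = e)
    })
  }

  s0 <- sites
  s1 <- s0[!is.na(s0$qual) & s0$qual >= min_qual, , drop = FALSE]
  log <- mark(log, s0, s1, "qual")
  stages[[1]] <- note("qual", nrow(s0), nrow(s1))

  regions <- if (nrow(s1) > 0 && any(roles$role == "affected")) {
    in_stage("roh", shared_homozygosity_regions(
      s1, roles$sample_id[roles$role == "affected"],
      min_sites = roh_min_sites, max_exceptions = roh_max_exceptions
    ))
  } else {
    empty_region_table()
  }

  s2 <- in_stage("segregation",
                 segregation_filter(s1, roles, missing_policy = missing_policy))
  log <- mark(log, s1, s2, "segregation")
  stages[[2]] <- note("segregation", nrow(s1), nrow(s2))

  s3 <- s2
  if (!is.null(summaries)) {
    s3 <- in_stage("homalt_external", homalt_exclusion(s2, summaries))
    log <- mark(log, s2, s3, "homalt_external")
    stages[[length(stages) + 1]] <- note("homalt_external", nrow(s2), nrow(s3))
    if (!is.null(defect_breed)) {
      s4 <- in_stage("breed", breed_exclusion(s3, summaries, defect_breed))
      log <- mark(log, s3, s4, "breed")
      stages[[length(stages) + 1]] <- note("breed", nrow(s3), nrow(s4))
      s3 <- s4
    }
  }
  if (!is.null(confirm_genotypes)) {
    s5 <- confirmation_genotype_elimination(s3, confirm_genotypes, confirm_roles)
    log <- mark(log, s3, s5, "confirmation")
    stages[[length(stages) + 1]] <- note("confirmation", nrow(s3), nrow(s5))
    s3 <- s5
  }
  log$stage_eliminated[is.na(log$stage_eliminated)] <- "retained"
  candidates <- prioritize_candidates(s3)
  res <- list(
    candidates = candidates, regions = regions,
    stages = bind_rows(stages), log = log,
    params = list(min_qual = min_qual, missing_policy = missing_policy,
                  roh_min_sites = roh_min_sites,
                  roh_max_exceptions = roh_max_exceptions,
                  defect_breed = defect_breed)
  )
  class(res) <- "discovery_run"
  res
}

#' @exportS3Method base::print
print.discovery_run <- function(x, ...) {
  cat("Recessive-defect discovery run\n")
  for (i in seq_len(nrow(x$stages))) {
    s <- x$stages[i, ]
    cat(sprintf("  %-16s %5d -> %5d (removed %d)\n",
                s$stage, s$n_in, s$n_out, s$n_removed))
  }
  cat(sprintf("  candidates: %d; shared-homozygosity regions: %d\n",
              nrow(x$candidates), nrow(x$regions)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the ranked candidate table of a discovery run
#'
#' @param x A `discovery_run`.
#' @param ... Unused.
#' @return The ranked candidate tibble with a `rank` column.
#' @export
tidy.discovery_run <- function(x, ...) {
  out <- x$candidates
  if (nrow(out) > 0) out <- mutate(out, rank = dplyr::row_number(), .before = 1)
  out
}

#' One-row summary of a discovery run
#'
#' @param x A `discovery_run`.
#' @param ... Unused.
#' @return Tibble with input/retained counts per stage and region tally.
#' @export
glance.discovery_run <- function(x, ...) {
  tibble(
    n_input = x$stages$n_in[1],
    n_pass_qual = x$stages$n_out[x$stages$stage == "qual"],
    n_segregating = x$stages$n_out[x$stages$stage == "segregation"],
    n_candidates = nrow(x$candidates),
    n_roh_regions = nrow(x$regions)
  )
}
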