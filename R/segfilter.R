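#' Filter variants by recessive segregation pattern
#'
#' Retains exactly the sites whose genotypes match a fully penetrant
#' recessive model across the sequenced cohort: every affected sample is
#' homozygous for the alternate allele, every obligate carrier (parent of
#' an affected) is heterozygous, and every other related individual is
#' heterozygous or homozygous reference.
#'
#' @param sites Variant table (see [read_variants()]).
#' @param roles Tibble with columns `sample_id` and `role`, role one of
#'   `affected`, `obligate_carrier`, `relative`. At least one affected is
#'   required, and every listed sample must have a genotype column.
#' @param missing_policy How a `missing` genotype counts against the
#'   pattern: `"compatible"` (default; a missing call never disqualifies a
#'   site) or `"incompatible"` (a missing call fails its constraint).
#' @return The retained subset of `sites`, in input order.
#' @export
segregation_filter <- function(sites, roles,
                               missing_policy = c("compatible", "incompatible")) {
  missing_policy <- match.arg(missing_policy)
  roles <- as_tibble(roles)
  if (!all(c("sample_id", "role") %in% names(roles))) {
    abort("roles must have columns sample_id and role")
  }
  bad_role <- setdiff(roles$role, c("affected", "obligate_carrier", "relative"))
  if (length(bad_role) > 0) {
    abort(paste0("unknown role(s): ", paste(bad_role, collapse = ", ")))
  }
  if (!any(roles$role == "affected")) {
    abort("segregation filtering requires at least one affected sample")
  }
  absent <- setdiff(roles$sample_id, gt_samples(sites))
  if (length(absent) > 0 && nrow(sites) > 0) {
    abort(paste0("role map references sample(s) absent from the variant table: ",
                 paste(absent, collapse = ", ")))
  }
  if (nrow(sites) == 0) return(sites)
  gm <- gt_matrix(sites)
  ok_call <- function(g, allowed) {
    if (missing_policy == "compatible") {
      g == "missing" | g %in% allowed
    } else {
      g %in% allowed
    }
  }
  keep <- rep(TRUE, nrow(sites))
  for (i in seq_len(nrow(roles))) {
    g <- gm[, roles$sample_id[i]]
    allowed <- switch(roles$role[i],
      affected = "hom_alt",
      obligate_carrier = "het",
      relative = c("het", "hom_ref")
    )
    keep <- keep & ok_call(g, allowed)
  }
  sites[keep, , drop = FALSE]
}

#' Detect runs of homozygosity shared by all affected samples
#'
#' Scans each chromosome for maximal runs of consecutive sites at which
#' every affected sample is homozygous (either class; a missing call is
#' allowed), permitting up to `max_exceptions` non-conforming sites inside
#' a run. Under autozygosity around a recessive causal locus the affecteds
#' share an extended homozygous segment, so such runs localize the defect.
#'
#' @param sites Variant table sorted by (chrom, pos); unsorted input is an
#'   error.
#' @param affected_ids Sample ids of the affected individuals.
#' @param min_sites Minimum number of conforming sites for a run to be
#'   reported (default 20).
#' @param max_exceptions Maximum non-conforming sites tolerated inside a
#'   run (default 1), guarding against an isolated genotyping error.
#' @return Tibble with columns `chrom`, `start`, `end` (1-based inclusive,
#'   positions of the first/last conforming site), `n_sites` (conforming
#'   sites in the run), `samples` (list column of the affected ids).
#' @export
shared_homozygosity_regions <- function(sites, affected_ids,
                                        min_sites = 20, max_exceptions = 1) {
  if (min_sites < 2) abort("min_sites must be at least 2")
  if (nrow(sites) == 0) return(empty_region_table())
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    abort("sites must be sorted by (chrom, pos)")
  }
  absent <- setdiff(affected_ids, gt_samples(sites))
  if (length(absent) > 0) {
    abort(paste0("affected sample(s) absent from the variant table: ",
                 paste(absent, collapse = ", ")))
  }
  gm <- gt_matrix(sites)[, affected_ids, drop = FALSE]
  conforming <- apply(gm, 1, function(g) all(g %in% c("hom_ref", "hom_alt", "missing")))

  out <- list()
  for (chr in unique(sites$chrom)) {
    idx <- which(sites$chrom == chr)
    conf <- conforming[idx]
    pos <- sites$pos[idx]
    for (w in max_windows_with_exceptions(conf, max_exceptions)) {
      span <- w[1]:w[2]
      conf_in <- span[conf[span]]
      if (length(conf_in) < min_sites) next
      out[[length(out) + 1]] <- tibble(
        chrom = chr,
        start = pos[conf_in[1]],
        end = pos[conf_in[length(conf_in)]],
        n_sites = length(conf_in)
      )
    }
  }
  if (length(out) == 0) return(empty_region_table())
  regions <- distinct(bind_rows(out))
  regions$samples <- rep(list(affected_ids), nrow(regions))
  regions
}

empty_region_table <- function() {
  tibble(chrom = character(0), start = integer(0), end = integer(0),
         n_sites = integer(0), samples = list())
}

# maximal windows of a logical vector containing at most k FALSE entries;
# two-pointer sweep, windows contained in a longer one are dropped
max_windows_with_exceptions <- function(conf, k) {
  n <- length(conf)
  if (n == 0) return(list())
  windows <- list()
  left <- 1L
  bad <- 0L
  last_left <- 0L
  for (right in seq_len(n)) {
    if (!conf[right]) bad <- bad + 1L
    while (bad > k) {
      if (!conf[left]) bad <- bad - 1L
      left <- left + 1L
    }
    if (right == n || (!conf[right + 1L] && bad == k)) {
      # window [left, right] is maximal to the right; record once per left
      if (left > last_left || right == n) {
        windows[[length(windows) + 1]] <- c(left, right)
        last_left <- left
      }
    }
  }
  # drop windows nested inside another
  if (length(windows) <= 1) return(windows)
  keep <- vapply(seq_along(windows), function(i) {
    wi <- windows[[i]]
    !any(vapply(seq_along(windows), function(j) {
      if (i == j) return(FALSE)
      wj <- windows[[j]]
      wj[1] <= wi[1] && wj[2] >= wi[2] && (wj[1] < wi[1] || wj[2] > wi[2])
    }, logical(1)))
  }, logical(1))
  windows[keep]
}

#' Rank candidate variants by predicted functional impact
#'
#' Stable sort of a candidate table by (1) consequence-class severity
#' (missense, then 5'/3' UTR, then upstream/downstream, then intronic,
#' then intergenic, then other), (2) impact label (deleterious before
#' tolerated before unannotated), and (3) ascending deleteriousness score
#' (0 is maximally deleterious, so smaller ranks higher; missing scores
#' last). Ties preserve input order.
#'
#' @param sites Variant table.
#' @return `sites` reordered by priority.
#' @export
prioritize_candidates <- function(sites) {
  severity <- c(missense = 1, utr5 = 2, utr3 = 2, upstream = 3,
                downstream = 3, intronic = 4, intergenic = 5, other = 6)
  label_rank <- c(deleterious = 1, tolerated = 2, none = 3)
  s <- unname(severity[sites$consequence])
  l <- unname(label_rank[sites$impact_label])
  l[is.na(l)] <- 3
  sc <- sites$impact_score
  sc[is.na(sc)] <- Inf
  sites[order(s, l, sc), , drop = FALSE]
}
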