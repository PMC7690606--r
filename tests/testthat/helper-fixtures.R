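# in-code fixtures shared across test files

site_key_str <- function(x) paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")

trio_pedigree <- function() {
  as_pedigree(tibble::tibble(
    animal_id = c("C", "S", "D"),
    sire_id = c("S", NA, NA),
    dam_id = c("D", NA, NA),
    sex = c("male", "male", "female"),
    phenotype = c("affected", "unaffected", "unaffected")
  ))
}

# random sex-consistent pedigree for property tests: animal i draws each
# parent (when available) from earlier animals of the right sex
random_pedigree <- function(n, seed, p_parent = 0.7) {
  set.seed(seed)
  sex <- rep(c("male", "female"), length.out = n)
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  ids <- sprintf("A%03d", seq_len(n))
  for (i in seq_len(n)) {
    males <- which(sex[seq_len(i - 1)] == "male")
    females <- which(sex[seq_len(i - 1)] == "female")
    if (length(males) > 0 && runif(1) < p_parent) {
      sire[i] <- ids[males[sample.int(length(males), 1)]]
    }
    if (length(females) > 0 && runif(1) < p_parent) {
      dam[i] <- ids[females[sample.int(length(females), 1)]]
    }
  }
  as_pedigree(tibble::tibble(
    animal_id = ids, sire_id = sire, dam_id = dam, sex = sex
  ))
}

# independent ancestor oracle: igraph reachability over parent edges
igraph_ancestors <- function(ped, id) {
  edges <- rbind(
    cbind(ped$sire_id, ped$animal_id),
    cbind(ped$dam_id, ped$animal_id)
  )
  edges <- edges[!is.na(edges[, 1]), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges), vertices = ped$animal_id
  )
  anc <- names(igraph::subcomponent(g, id, mode = "in"))
  setdiff(anc, id)
}

# build a variant table from a genotype matrix (sites x samples)
make_sites <- function(gt, chrom = "1", pos = NULL, qual = 100,
                       consequence = "intergenic", gene = NA_character_,
                       impact_label = "none", impact_score = NA_real_) {
  n <- nrow(gt)
  sites <- tibble::tibble(
    chrom = rep(chrom, length.out = n),
    pos = if (is.null(pos)) seq_len(n) * 100L else as.integer(pos),
    ref = rep("A", n), alt = rep("G", n),
    qual = rep(qual, length.out = n),
    consequence = rep(consequence, length.out = n),
    gene = rep(gene, length.out = n),
    impact_label = rep(impact_label, length.out = n),
    impact_score = rep(impact_score, length.out = n)
  )
  for (s in colnames(gt)) sites[[paste0("gt_", s)]] <- gt[, s]
  sites
}

# random genotype matrix for role-based panels
random_gt_matrix <- function(n_sites, samples, seed,
                             levels = c("hom_ref", "het", "hom_alt", "missing"),
                             prob = c(0.4, 0.3, 0.2, 0.1)) {
  set.seed(seed)
  matrix(
    sample(levels, n_sites * length(samples), replace = TRUE, prob = prob),
    nrow = n_sites, dimnames = list(NULL, samples)
  )
}

# brute-force per-site recheck of the recessive segregation pattern
brute_segregation_keep <- function(sites, roles, missing_policy = "compatible") {
  gm <- gt_matrix(sites)
  vapply(seq_len(nrow(sites)), function(i) {
    all(vapply(seq_len(nrow(roles)), function(r) {
      g <- gm[i, roles$sample_id[r]]
      allowed <- switch(roles$role[r],
        affected = "hom_alt",
        obligate_carrier = "het",
        relative = c("het", "hom_ref")
      )
      if (g == "missing") missing_policy == "compatible" else g %in% allowed
    }, logical(1)))
  }, logical(1))
}

# exhaustive homozygosity-run oracle: all maximal windows with <= k
# non-conforming sites, trimmed to conforming bounds
brute_roh <- function(conf, pos, min_sites, k) {
  n <- length(conf)
  bad <- function(i, j) sum(!conf[i:j])
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (bad(i, j) > k) next
      maximal <- (i == 1 || bad(i - 1, j) > k) && (j == n || bad(i, j + 1) > k)
      if (!maximal) next
      confIdx <- (i:j)[conf[i:j]]
      if (length(confIdx) < min_sites) next
      out[[length(out) + 1]] <- c(pos[confIdx[1]], pos[confIdx[length(confIdx)]],
                                  length(confIdx))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(0), end = integer(0),
                          n_sites = integer(0)))
  }
  m <- unique(do.call(rbind, out))
  tibble::tibble(start = m[, 1], end = m[, 2], n_sites = m[, 3]) |>
    dplyr::arrange(start, end)
}
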