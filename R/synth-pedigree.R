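#' Monte-Carlo gene dropping through a pedigree
#'
#' Drops a single mutant allele carried (heterozygously) by one founder
#' through the pedigree: at every meiosis each parental allele is
#' transmitted with probability 1/2, independently across meioses and
#' replicates. Returns per-animal carrier/homozygote frequencies across
#' replicates together with the per-replicate allele counts.
#'
#' @param ped A validated pedigree tibble.
#' @param founder_id Animal in whom the mutation arises.
#' @param n_replicates Number of independent drops.
#' @param seed Integer seed.
#' @return A list of class `gene_drop`: `freq`, a tibble with
#'   `animal_id`, `p_het`, `p_hom`, `p_carrier` (= P(at least one copy));
#'   and `genotypes`, an animals-by-replicates integer matrix of mutant
#'   allele counts (0/1/2).
#' @export
gene_drop <- function(ped, founder_id, n_replicates = 1000L, seed = 1L) {
  if (!founder_id %in% ped$animal_id) {
    abort(paste0("unknown founder id: ", founder_id))
  }
  set.seed(seed)
  ids <- ped$animal_id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  ord <- pedigree_topo_order(ped)
  sire_i <- idx[ped$sire_id]
  dam_i <- idx[ped$dam_id]

  R <- n_replicates
  H1 <- matrix(FALSE, n, R) # slot-1 haplotype carries the mutation
  H2 <- matrix(FALSE, n, R)
  H1[idx[[founder_id]], ] <- TRUE
  for (i in ord) {
    s <- sire_i[i]; d <- dam_i[i]
    if (is.na(s) && is.na(d)) next
    if (!is.na(s)) {
      pick1 <- stats::runif(R) < 0.5
      H1[i, ] <- ifelse(pick1, H1[s, ], H2[s, ])
    }
    if (!is.na(d)) {
      pick2 <- stats::runif(R) < 0.5
      H2[i, ] <- ifelse(pick2, H1[d, ], H2[d, ])
    }
  }
  copies <- H1 + H2
  rownames(copies) <- ids
  freq <- tibble(
    animal_id = ids,
    p_het = rowMeans(copies == 1L),
    p_hom = rowMeans(copies == 2L)
  )
  freq$p_carrier <- freq$p_het + freq$p_hom
  structure(list(freq = freq, genotypes = copies), class = "gene_drop")
}

# topological order (parents before offspring) by Kahn's algorithm;
# assumes the pedigree is already validated acyclic
pedigree_topo_order <- function(ped) {
  ids <- ped$animal_id
  idx <- stats::setNames(seq_along(ids), ids)
  sire_i <- idx[ped$sire_id]
  dam_i <- idx[ped$dam_id]
  indeg <- (!is.na(sire_i)) + (!is.na(dam_i))
  children <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    for (p in c(sire_i[i], dam_i[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  ord <- integer(0)
  queue <- which(indeg == 0)
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  ord
}

# Build the fixed mating structure: one founder sire used heavily, his
# descendants outcrossed, then case matings that carry the founder on both
# the sire and the dam side.
build_pedigree_structure <- function(cfg) {
  w <- cfg$founder_matings_per_generation
  rows <- list(tibble(animal_id = "FOUNDER", sire_id = NA_character_,
                      dam_id = NA_character_, sex = "male"))
  pad <- function(prefix, i) sprintf("%s%03d", prefix, i)

  g1_dams <- vapply(seq_len(w), function(i) pad("FD", i), "")
  rows[[length(rows) + 1]] <- tibble(animal_id = g1_dams, sire_id = NA_character_,
                                     dam_id = NA_character_, sex = "female")
  g1 <- vapply(seq_len(w), function(i) pad("G1_", i), "")
  g1_sex <- rep(c("male", "female"), length.out = w)
  rows[[length(rows) + 1]] <- tibble(animal_id = g1, sire_id = "FOUNDER",
                                     dam_id = g1_dams, sex = g1_sex)

  g2 <- character(0); g2_sex <- character(0)
  g2_family <- integer(0)
  if (cfg$n_generations >= 4) {
    mates <- vapply(seq_len(w), function(i) {
      pad(if (g1_sex[i] == "male") "UD" else "US", i)
    }, "")
    rows[[length(rows) + 1]] <- tibble(
      animal_id = mates, sire_id = NA_character_, dam_id = NA_character_,
      sex = ifelse(g1_sex == "male", "female", "male")
    )
    for (i in seq_len(w)) {
      kids <- c(pad(sprintf("G2_%03d_", i), 1), pad(sprintf("G2_%03d_", i), 2))
      ks <- c("male", "female")
      sire <- if (g1_sex[i] == "male") g1[i] else mates[i]
      dam <- if (g1_sex[i] == "male") mates[i] else g1[i]
      rows[[length(rows) + 1]] <- tibble(animal_id = kids, sire_id = sire,
                                         dam_id = dam, sex = ks)
      g2 <- c(g2, kids); g2_sex <- c(g2_sex, ks); g2_family <- c(g2_family, i, i)
    }
  }

  # case matings: founder reachable through both parents, no animal reused
  if (cfg$n_generations == 3) {
    sires <- g1[g1_sex == "male"]
    dams <- g1[g1_sex == "female"]
    k <- min(length(sires), length(dams))
    matings <- tibble(sire = sires[seq_len(k)], dam = rev(dams)[seq_len(k)])
  } else {
    g1_m <- which(g1_sex == "male")
    g2_f <- which(g2_sex == "female")
    g1_f <- which(g1_sex == "female")
    g2_m <- which(g2_sex == "male")
    pair_up <- function(p1, fam1, p2, fam2) {
      # rotate the second list by one family so parents come from
      # different founder lines
      used2 <- logical(length(p2))
      out <- list()
      for (a in seq_along(p1)) {
        j <- which(!used2 & fam2 != fam1[a])[1]
        if (is.na(j)) next
        used2[j] <- TRUE
        out[[length(out) + 1]] <- tibble(sire = p1[a], dam = p2[j])
      }
      bind_rows(out)
    }
    m1 <- pair_up(g1[g1_m], g1_m, g2[g2_f], g2_family[g2_f])
    m2 <- pair_up(g2[g2_m], g2_family[g2_m], g1[g1_f], g1_f)
    m2 <- tibble(sire = m2$sire, dam = m2$dam)
    matings <- bind_rows(m1, m2)
  }
  kid_rows <- list()
  for (k in seq_len(nrow(matings))) {
    kids <- sprintf("CASE_%03d_%d", k, 1:2)
    kid_rows[[k]] <- tibble(animal_id = kids, sire_id = matings$sire[k],
                            dam_id = matings$dam[k],
                            sex = c("male", "female"))
  }
  ped <- bind_rows(c(rows, kid_rows))
  ped$phenotype <- "unknown"
  ped$breed <- cfg$defect_breed
  ped$herd <- NA_character_
  ped$birth_year <- NA_integer_
  list(pedigree = ped, matings = matings,
       case_offspring = lapply(seq_len(nrow(matings)),
                               function(k) sprintf("CASE_%03d_%d", k, 1:2)))
}

# one gene drop that records, per animal, which parental slot each
# haplotype came from, so linked loci can be transmitted identically later
drop_with_slots <- function(ped, founder_id) {
  ids <- ped$animal_id
  idx <- stats::setNames(seq_along(ids), ids)
  ord <- pedigree_topo_order(ped)
  sire_i <- idx[ped$sire_id]; dam_i <- idx[ped$dam_id]
  n <- length(ids)
  o1 <- logical(n); o2 <- logical(n)        # founder-haplotype origin
  s_choice <- rep(NA_integer_, n); d_choice <- rep(NA_integer_, n)
  o1[idx[[founder_id]]] <- TRUE
  for (i in ord) {
    s <- sire_i[i]; d <- dam_i[i]
    if (!is.na(s)) {
      s_choice[i] <- sample.int(2L, 1L)
      o1[i] <- if (s_choice[i] == 1L) o1[s] else o2[s]
    }
    if (!is.na(d)) {
      d_choice[i] <- sample.int(2L, 1L)
      o2[i] <- if (d_choice[i] == 1L) o1[d] else o2[d]
    }
  }
  list(o1 = o1, o2 = o2, s_choice = s_choice, d_choice = d_choice,
       copies = stats::setNames(o1 + o2, ids))
}

#' Simulate a pedigree segregating a founder recessive defect
#'
#' Builds a multi-generation pedigree in which one founder sire is mated
#' widely (emulating artificial insemination), his descendants are
#' outcrossed, and a generation of case matings joins two different
#' founder lines, so case offspring carry the founder on both the sire and
#' the dam side. A single mutant allele seeded in the founder is
#' gene-dropped through the structure; the drop is repeated until at least
#' `n_affected_matings` case matings produce an affected (homozygous,
#' penetrant) calf — the ascertainment that triggers such a study in the
#' first place. Phenotypes follow genotype and penetrance.
#'
#' @param cfg A [sim_config()].
#' @return List with `pedigree` (validated pedigree tibble) and `truth`, a
#'   list carrying the founder id, the causal-site coordinates, true
#'   mutant-allele counts per animal, the true homozygous-haplotype
#'   interval, the sequenced-cohort `roles` tibble (affected / obligate
#'   carrier / relative), and internal transmission records used by
#'   [simulate_variants()].
#' @export
simulate_pedigree <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  st <- build_pedigree_structure(cfg)
  ped <- suppressMessages(as_pedigree(st$pedigree))
  # as_pedigree may append auto-created rows; structure above is complete
  drop <- NULL
  affected_ids <- character(0)
  affected_matings <- integer(0)
  for (attempt in seq_len(cfg$max_attempts)) {
    cand <- drop_with_slots(ped, "FOUNDER")
    hom <- names(cand$copies)[cand$copies == 2L]
    aff <- hom[stats::runif(length(hom)) < cfg$penetrance]
    m_aff <- which(vapply(st$case_offspring,
                          function(kids) any(kids %in% aff), logical(1)))
    if (length(m_aff) >= cfg$n_affected_matings) {
      drop <- cand
      affected_ids <- aff
      affected_matings <- m_aff
      break
    }
  }
  if (is.null(drop)) {
    abort(paste0(
      "no gene drop with at least ", cfg$n_affected_matings,
      " affected case matings in ", cfg$max_attempts,
      " attempts; increase founder_matings_per_generation or n_generations"
    ))
  }
  ped$phenotype <- ifelse(ped$animal_id %in% affected_ids, "affected", "unaffected")

  # sequenced cohort: affected calves, parents of affected calves
  # (obligate carriers), and other relatives from the affected lines
  m_used <- affected_matings[seq_len(cfg$n_affected_matings)]
  aff_in <- function(k) intersect(st$case_offspring[[k]], affected_ids)
  seq_affected <- vapply(m_used[seq_len(cfg$n_sequenced_affected)],
                         function(k) aff_in(k)[1], "")
  carriers <- unique(unlist(lapply(m_used, function(k) {
    c(st$matings$sire[k], st$matings$dam[k])
  })))
  carriers <- utils::head(carriers, cfg$n_obligate_carriers)
  rel_pool <- setdiff(
    c(unlist(st$case_offspring[m_used]),
      unique(c(ped$sire_id[ped$animal_id %in% carriers],
               ped$dam_id[ped$animal_id %in% carriers]))),
    c(affected_ids, carriers, "FOUNDER", NA)
  )
  relatives <- utils::head(rel_pool, cfg$n_relatives)

  roles <- bind_rows(
    tibble(sample_id = seq_affected, role = "affected"),
    tibble(sample_id = carriers, role = "obligate_carrier"),
    tibble(sample_id = relatives, role = "relative")
  )
  half <- cfg$haplotype_block_bp / 2
  truth <- list(
    founder_id = "FOUNDER",
    causal = list(chrom = cfg$chrom, pos = cfg$causal_pos, ref = "T", alt = "C"),
    copies = drop$copies,
    block_interval = c(
      start = max(1, floor(cfg$causal_pos - half)),
      end = min(cfg$chrom_length_bp, ceiling(cfg$causal_pos + half))
    ),
    affected_ids = affected_ids,
    roles = roles,
    transmission = drop
  )
  list(pedigree = ped, truth = truth)
}
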