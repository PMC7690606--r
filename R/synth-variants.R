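# consequence classes assigned to neutral background variants, with
# realistic genome-wide proportions
BACKGROUND_CONSEQ <- c(
  intergenic = 0.45, intronic = 0.35, upstream = 0.07, downstream = 0.07,
  utr5 = 0.01, utr3 = 0.01, missense = 0.04
)

#' Simulate the sequenced cohort's multi-sample variant table
#'
#' Generates the causal site plus neutral background variants for the
#' sequenced cohort of a simulated pedigree. Background alleles are drawn
#' for pedigree founders at uniform(0.05, 0.95) population frequencies and
#' transmitted by Mendelian descent through the full pedigree. Variants
#' inside the haplotype block around the causal position are transmitted
#' with the same meiotic choices as the causal allele (complete linkage),
#' so every affected animal is homozygous across the block — the shared
#' homozygosity signal. The causal site is annotated as a deleterious
#' missense (score 0); background variants receive neutral annotations.
#' Genotype errors, missing calls, and sub-threshold site qualities are
#' injected at the configured rates (artifact sites get the low quality;
#' the causal site, a well-supported true variant, does not).
#'
#' @param ped Validated pedigree tibble from [simulate_pedigree()].
#' @param truth Truth record from [simulate_pedigree()].
#' @param cfg The same [sim_config()].
#' @return List with `sites` (variant table over the sequenced cohort,
#'   sorted by position, monomorphic background sites dropped) and
#'   `summaries` (external-cohort genotype tallies per breed; the causal
#'   allele is absent from all external cohorts by construction).
#' @export
simulate_variants <- function(ped, truth, cfg = sim_config()) {
  set.seed(cfg$seed + 1L)
  ids <- ped$animal_id
  idx <- stats::setNames(seq_along(ids), ids)
  ord <- pedigree_topo_order(ped)
  sire_i <- idx[ped$sire_id]; dam_i <- idx[ped$dam_id]
  tr <- truth$transmission

  V <- cfg$n_background_variants
  draw <- unique(ceiling(stats::runif(V * 2) * cfg$chrom_length_bp))
  draw <- setdiff(draw, truth$causal$pos)
  if (length(draw) < V) abort("chromosome too short for n_background_variants")
  pos <- sort(draw[seq_len(V)])
  freq <- stats::runif(V, 0.05, 0.95)
  in_block <- pos >= truth$block_interval[["start"]] &
    pos <= truth$block_interval[["end"]]

  # add the causal site
  pos <- c(pos, truth$causal$pos)
  freq <- c(freq, 0)               # absent from the general population
  in_block <- c(in_block, TRUE)
  causal_j <- length(pos)
  o <- order(pos)
  pos <- pos[o]; freq <- freq[o]; in_block <- in_block[o]
  causal_j <- which(o == causal_j)
  nv <- length(pos)

  # founder haplotype allele at linked loci (drawn at population frequency;
  # alt at the causal locus itself)
  fh_allele <- integer(nv)
  fh_allele[in_block] <- stats::rbinom(sum(in_block), 1, freq[in_block])
  fh_allele[causal_j] <- 1L

  n <- length(ids)
  A1 <- matrix(0L, n, nv); A2 <- matrix(0L, n, nv)
  founder_row <- idx[[truth$founder_id]]
  for (i in seq_len(n)) {
    if (is.na(sire_i[i])) A1[i, ] <- stats::rbinom(nv, 1, freq)
    if (is.na(dam_i[i])) A2[i, ] <- stats::rbinom(nv, 1, freq)
  }
  A1[founder_row, ] <- stats::rbinom(nv, 1, freq)
  A1[founder_row, in_block] <- fh_allele[in_block]   # slot 1 = mutant haplotype
  blk <- which(in_block); out <- which(!in_block)
  for (i in ord) {
    s <- sire_i[i]; d <- dam_i[i]
    if (!is.na(s)) {
      pick <- stats::runif(length(out)) < 0.5
      A1[i, out] <- ifelse(pick, A1[s, out], A2[s, out])
      A1[i, blk] <- if (tr$s_choice[i] == 1L) A1[s, blk] else A2[s, blk]
    }
    if (!is.na(d)) {
      pick <- stats::runif(length(out)) < 0.5
      A2[i, out] <- ifelse(pick, A1[d, out], A2[d, out])
      A2[i, blk] <- if (tr$d_choice[i] == 1L) A1[d, blk] else A2[d, blk]
    }
  }

  samples <- truth$roles$sample_id
  G <- A1[idx[samples], , drop = FALSE] + A2[idx[samples], , drop = FALSE]
  gt <- matrix(GT_LEVELS[G + 1L], nrow = length(samples))

  # inject genotype errors
  n_s <- length(samples)
  wrong_call <- function(g) {
    vapply(g, function(x) sample(setdiff(c("hom_ref", "het", "hom_alt"), x), 1),
           "", USE.NAMES = FALSE)
  }
  if (cfg$genotype_error_rate > 0) {
    if (cfg$error_model == "per_site") {
      hit <- which(stats::runif(nv) < cfg$genotype_error_rate)
      for (j in hit) {
        i <- sample.int(n_s, 1L)
        gt[i, j] <- wrong_call(gt[i, j])
      }
    } else {
      hit <- which(matrix(stats::runif(n_s * nv) < cfg$genotype_error_rate,
                          n_s, nv))
      gt[hit] <- wrong_call(gt[hit])
    }
  }
  if (cfg$missing_rate > 0) {
    gt[matrix(stats::runif(n_s * nv) < cfg$missing_rate, n_s, nv)] <- "missing"
  }

  # site quality: a configurable share of background sites are artifacts
  # below the QUAL 30 cutoff; the causal site is a well-supported variant
  qual <- round(stats::runif(nv, 31, 2000), 1)
  low <- stats::runif(nv) < cfg$low_qual_rate
  low[causal_j] <- FALSE
  qual[low] <- round(stats::runif(sum(low), 5, 29.9), 1)

  conseq <- sample(names(BACKGROUND_CONSEQ), nv, replace = TRUE,
                   prob = BACKGROUND_CONSEQ)
  impact_label <- ifelse(conseq == "missense", "tolerated", "none")
  impact_score <- ifelse(conseq == "missense",
                         round(stats::runif(nv, 0.2, 1), 2), NA_real_)
  gene <- ifelse(conseq %in% c("intergenic", "other"), NA_character_,
                 sprintf("GENE%04d", pmin(floor(pos / 5e4) + 1, 9999)))
  conseq[causal_j] <- "missense"
  impact_label[causal_j] <- "deleterious"
  impact_score[causal_j] <- 0
  gene[causal_j] <- "GENE_CAUSAL"

  ref_alt <- matrix(
    replicate(nv, sample(c("A", "C", "G", "T"), 2)), nrow = 2
  )
  ref_alt[, causal_j] <- c(truth$causal$ref, truth$causal$alt)

  sites <- tibble(
    chrom = cfg$chrom, pos = as.integer(pos),
    ref = ref_alt[1, ], alt = ref_alt[2, ], qual = qual,
    consequence = conseq, gene = gene,
    impact_label = impact_label, impact_score = impact_score
  )
  for (k in seq_along(samples)) {
    sites[[paste0("gt_", samples[k])]] <- gt[k, ]
  }

  # a variant caller only reports sites with alternate evidence in the cohort
  has_alt <- colSums(matrix(gt %in% c("het", "hom_alt"), n_s, nv)) > 0
  keep <- has_alt
  keep[causal_j] <- TRUE
  summaries <- simulate_cohort_summaries(sites[keep, ], freq[keep],
                                         pos[keep] == truth$causal$pos, cfg)
  list(sites = sites[keep, ], summaries = summaries)
}

# external-population genotype tallies per breed at each simulated site;
# Hardy-Weinberg draws at the site's population frequency, zero alternate
# alleles everywhere for the causal site (a de novo allele private to the
# founder line)
simulate_cohort_summaries <- function(sites, freq, is_causal, cfg) {
  breeds <- c(cfg$defect_breed, cfg$other_breeds)
  n <- cfg$cohort_n_per_breed
  out <- vector("list", length(breeds))
  for (b in seq_along(breeds)) {
    p <- ifelse(is_causal, 0, pmin(pmax(freq + stats::rnorm(length(freq), 0, 0.03),
                                        0), 1))
    counts <- vapply(p, function(pi) {
      stats::rmultinom(1, n, c((1 - pi)^2, 2 * pi * (1 - pi), pi^2))[, 1]
    }, numeric(3))
    out[[b]] <- tibble(
      chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
      breed = breeds[b], n_samples = n,
      n_het = as.integer(counts[2, ]), n_hom_alt = as.integer(counts[3, ])
    )
  }
  bind_rows(out)
}

#' Simulate pileup read counts at candidate loci
#'
#' Per sample and locus, total depth is drawn from a negative binomial
#' (overdispersed relative to Poisson, as real short-read coverage is)
#' with the configured mean, and alternate reads are binomial with success
#' probability set by the true genotype (`read_error_rate`, 0.5, or
#' `1 - read_error_rate`).
#'
#' @param truth Truth record from [simulate_pedigree()].
#' @param cfg A [sim_config()].
#' @param sample_ids Samples to simulate (default: the sequenced cohort).
#' @return Tibble with `chrom`, `pos`, `sample_id`, `ref_reads`,
#'   `alt_reads`, `other_reads`, `true_gt`.
#' @export
simulate_pileup <- function(truth, cfg = sim_config(),
                            sample_ids = truth$roles$sample_id) {
  set.seed(cfg$seed + 2L)
  copies <- truth$copies[sample_ids]
  depth <- stats::rnbinom(length(sample_ids), mu = cfg$mean_depth,
                          size = cfg$depth_dispersion)
  p_alt <- c(cfg$read_error_rate, 0.5, 1 - cfg$read_error_rate)[copies + 1L]
  alt <- stats::rbinom(length(depth), depth, p_alt)
  tibble(
    chrom = truth$causal$chrom, pos = truth$causal$pos,
    sample_id = sample_ids,
    ref_reads = depth - alt, alt_reads = alt, other_reads = 0L,
    true_gt = GT_LEVELS[copies + 1L]
  )
}

#' Simulate droplet digital PCR wells
#'
#' Template copies seed droplets as independent Poisson counts per
#' channel, at concentrations proportional to the allele amounts; a
#' droplet is called positive in a channel when it holds at least one
#' copy of that allele or false-fires at the configured per-droplet rate.
#'
#' @param true_fraction True variant allele fraction in `[0, 1]`.
#' @param cfg A [sim_config()].
#' @param n_wells Number of replicate wells.
#' @param sample_id Sample label for the wells.
#' @param seed Seed (default derived from the config).
#' @return Droplet-count tibble: `well_id`, `sample_id`, `replicate`,
#'   `variant_positive`, `wildtype_positive`, `double_positive`,
#'   `negative`.
#' @export
simulate_droplets <- function(true_fraction, cfg = sim_config(), n_wells = 2L,
                              sample_id = "sample", seed = cfg$seed + 3L) {
  if (true_fraction < 0 || true_fraction > 1) {
    abort("true_fraction must lie in [0, 1]")
  }
  set.seed(seed)
  lam <- cfg$droplet_mean_copies
  fp <- cfg$droplet_false_positive_rate
  p_v <- 1 - (1 - fp) * exp(-lam * true_fraction)
  p_w <- 1 - (1 - fp) * exp(-lam * (1 - true_fraction))
  probs <- c(
    p_v * (1 - p_w),        # variant only
    (1 - p_v) * p_w,        # wildtype only
    p_v * p_w,              # double positive
    (1 - p_v) * (1 - p_w)   # negative
  )
  counts <- stats::rmultinom(n_wells, cfg$droplet_total, probs)
  tibble(
    well_id = sprintf("%s_w%02d", sample_id, seq_len(n_wells)),
    sample_id = sample_id,
    replicate = seq_len(n_wells),
    variant_positive = counts[1, ],
    wildtype_positive = counts[2, ],
    double_positive = counts[3, ],
    negative = counts[4, ]
  )
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generator — pedigree, gene drop, variant table, external
#' cohort summaries, pileups at the causal locus, and ddPCR wells (one
#' carrier-level sample plus wildtype controls) — and optionally writes
#' every artifact as plain-text files (VCF, TSVs, and a JSON truth
#' manifest).
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed); `NULL` to skip writing.
#' @return List with `pedigree`, `truth`, `sites`, `roles`, `summaries`,
#'   `pileup`, `droplets`, and (if written) `paths`.
#' @export
simulate_cohort <- function(cfg = sim_config(), dir = NULL) {
  sim <- simulate_pedigree(cfg)
  vs <- simulate_variants(sim$pedigree, sim$truth, cfg)
  pileup <- simulate_pileup(sim$truth, cfg)
  droplets <- bind_rows(
    simulate_droplets(0.5, cfg, n_wells = 2, sample_id = "carrier",
                      seed = cfg$seed + 3L),
    simulate_droplets(0, cfg, n_wells = 2, sample_id = "wt_control",
                      seed = cfg$seed + 4L)
  )
  out <- list(
    pedigree = sim$pedigree, truth = sim$truth, sites = vs$sites,
    roles = sim$truth$roles, summaries = vs$summaries,
    pileup = pileup, droplets = droplets
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      vcf = file.path(dir, "cohort.vcf"),
      pedigree = file.path(dir, "pedigree.tsv"),
      roles = file.path(dir, "roles.tsv"),
      summaries = file.path(dir, "cohort_summaries.tsv"),
      pileup = file.path(dir, "pileup.tsv"),
      droplets = file.path(dir, "droplets.tsv"),
      truth = file.path(dir, "truth.json")
    )
    write_variant_vcf(out$sites, paths$vcf)
    readr::write_tsv(out$pedigree, paths$pedigree, progress = FALSE)
    readr::write_tsv(out$roles, paths$roles, progress = FALSE)
    readr::write_tsv(out$summaries, paths$summaries, progress = FALSE)
    readr::write_tsv(out$pileup, paths$pileup, progress = FALSE)
    readr::write_tsv(out$droplets, paths$droplets, progress = FALSE)
    manifest <- list(
      founder_id = out$truth$founder_id,
      causal = out$truth$causal,
      block_interval = as.list(out$truth$block_interval),
      affected_ids = out$truth$affected_ids,
      copies = as.list(out$truth$copies)
    )
    jsonlite::write_json(manifest, paths$truth, auto_unbox = TRUE, pretty = TRUE)
    out$paths <- paths
  }
  out
}
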