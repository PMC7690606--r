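small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_background_variants = 150L, ...)
}

test_that("simulated pedigrees put the founder on both sides of every case", {
  sim <- simulate_pedigree(small_cfg(seed = 21))
  ped <- sim$pedigree
  aff <- sim$truth$affected_ids
  expect_gte(length(aff), 3)
  for (a in aff) {
    s <- ped$sire_id[ped$animal_id == a]
    d <- ped$dam_id[ped$animal_id == a]
    expect_true(sim$truth$founder_id %in% ancestors_of(ped, s))
    expect_true(sim$truth$founder_id %in% ancestors_of(ped, d))
  }
  expect_true(sim$truth$founder_id %in%
                shared_ancestor_across_cases(ped, aff))
  # cohort composition matches the study design being emulated
  expect_equal(as.integer(table(sim$truth$roles$role)[c(
    "affected", "obligate_carrier", "relative")]), c(3L, 10L, 7L))
})

test_that("full penetrance equates affection with homozygosity", {
  sim <- simulate_pedigree(small_cfg(seed = 33))
  hom <- names(sim$truth$copies)[sim$truth$copies == 2]
  expect_setequal(sim$truth$affected_ids, hom)
  expect_setequal(sim$pedigree$animal_id[sim$pedigree$phenotype == "affected"], hom)
})

test_that("identical seeds reproduce the cohort byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(small_cfg(seed = 5), dir = d1)
  simulate_cohort(small_cfg(seed = 5), dir = d2)
  f1 <- readLines(file.path(d1, "cohort.vcf"))
  f2 <- readLines(file.path(d2, "cohort.vcf"))
  expect_identical(f1, f2)
  sim_a <- simulate_pedigree(small_cfg(seed = 5))
  sim_b <- simulate_pedigree(small_cfg(seed = 5))
  expect_identical(sim_a$pedigree, sim_b$pedigree)
  expect_identical(sim_a$truth$copies, sim_b$truth$copies)
})

test_that("gene dropping reproduces Mendelian transmission frequencies", {
  # direct offspring of the founder carry with probability one half
  ped <- as_pedigree(tibble::tibble(
    animal_id = c("F", "D", "kid", "D2", "kid2", "gkid_dam", "gkid"),
    sire_id = c(NA, NA, "F", NA, "F", NA, "kid"),
    dam_id = c(NA, NA, "D", NA, "D2", NA, "gkid_dam"),
    sex = c("male", "female", "male", "female", "male", "female", "male")
  ))
  gd <- gene_drop(ped, "F", n_replicates = 10000, seed = 42)
  freq <- tibble::deframe(gd$freq[, c("animal_id", "p_carrier")])
  mc3 <- 3 * sqrt(0.25 / 10000)
  expect_lt(abs(freq[["kid"]] - 0.5), mc3)
  expect_lt(abs(freq[["kid2"]] - 0.5), mc3)
  # grandchild through one carrier line: exact recursion gives 1/4
  expect_lt(abs(freq[["gkid"]] - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  expect_equal(freq[["F"]], 1)
  expect_equal(freq[["D"]], 0)
})

test_that("carrier-by-carrier matings segregate 1:2:1", {
  ped <- as_pedigree(tibble::tibble(
    animal_id = c("F", "M1", "M2", "S", "D", "kid"),
    sire_id = c(NA, NA, NA, "F", "F", "S"),
    dam_id = c(NA, NA, NA, "M1", "M2", "D"),
    sex = c("male", "female", "female", "male", "female", "male")
  ))
  gd <- gene_drop(ped, "F", n_replicates = 10000, seed = 9)
  g <- gd$genotypes
  both_het <- g["S", ] == 1 & g["D", ] == 1
  kid <- g["kid", both_het]
  n <- length(kid)
  obs <- c(mean(kid == 0), mean(kid == 1), mean(kid == 2))
  exp_p <- c(0.25, 0.5, 0.25)
  expect_true(all(abs(obs - exp_p) < 3 * sqrt(exp_p * (1 - exp_p) / n)))
})

test_that("no offspring receives the allele a parent could not transmit", {
  sim <- simulate_pedigree(small_cfg(seed = 2))
  ped <- sim$pedigree
  gd <- gene_drop(ped, "FOUNDER", n_replicates = 200, seed = 17)
  g <- gd$genotypes
  kids <- ped[!is.na(ped$sire_id) & !is.na(ped$dam_id), ]
  for (r in sample(200, 25)) {
    possible <- (g[kids$sire_id, r] > 0) + (g[kids$dam_id, r] > 0)
    expect_true(all(g[kids$animal_id, r] <= possible))
  }
})

test_that("error-free cohorts always retain the causal variant", {
  for (seed in c(4, 14)) {
    cfg <- small_cfg(seed = seed, genotype_error_rate = 0, missing_rate = 0)
    sim <- simulate_pedigree(cfg)
    vs <- simulate_variants(sim$pedigree, sim$truth, cfg)
    kept <- segregation_filter(
      vs$sites[vs$sites$qual >= 30, ], sim$truth$roles
    )
    expect_true(cfg$causal_pos %in% kept$pos)
    # genotypes at the causal site match the gene-drop truth exactly
    causal <- vs$sites[vs$sites$pos == cfg$causal_pos, ]
    gm <- gt_matrix(causal)[1, ]
    truth_gt <- c("hom_ref", "het", "hom_alt")[
      sim$truth$copies[names(gm)] + 1]
    expect_equal(unname(gm), unname(truth_gt))
  }
})

test_that("affecteds are homozygous across the seeded haplotype block", {
  cfg <- small_cfg(seed = 6, genotype_error_rate = 0, missing_rate = 0)
  sim <- simulate_pedigree(cfg)
  vs <- simulate_variants(sim$pedigree, sim$truth, cfg)
  aff <- sim$truth$roles$sample_id[sim$truth$roles$role == "affected"]
  blk <- vs$sites$pos >= sim$truth$block_interval[["start"]] &
    vs$sites$pos <= sim$truth$block_interval[["end"]]
  gm <- gt_matrix(vs$sites[blk, ])[, aff, drop = FALSE]
  expect_true(all(gm %in% c("hom_ref", "hom_alt")))
  # and the scan reports a region overlapping the truth interval
  # (min_sites scaled to this deliberately small 150-variant panel)
  r <- shared_homozygosity_regions(vs$sites[vs$sites$qual >= 30, ], aff,
                                   min_sites = 5)
  expect_true(any(r$start <= sim$truth$block_interval[["end"]] &
                    r$end >= sim$truth$block_interval[["start"]]))
})

test_that("simulated pileups track genotype and the depth distribution", {
  cfg <- sim_config(seed = 12)
  # a large synthetic panel of known genotypes exercises the count model
  ids <- sprintf("s%04d", 1:2000)
  truth <- list(
    causal = list(chrom = "26", pos = 14404993L, ref = "T", alt = "C"),
    copies = stats::setNames(rep(c(0L, 1L, 2L), length.out = 2000), ids),
    roles = tibble::tibble(sample_id = ids, role = "relative")
  )
  p <- simulate_pileup(truth, cfg, sample_ids = ids)
  d <- p$ref_reads + p$alt_reads

  # depth below the genotyping floor occurs at the negative-binomial rate
  expect_lt(
    abs(mean(d < 10) - pnbinom(9, mu = cfg$mean_depth, size = cfg$depth_dispersion)),
    3 * sqrt(0.25 / 2000)
  )
  # hom_ref truth with zero read error yields zero alternate reads
  cfg0 <- sim_config(seed = 12, read_error_rate = 0)
  p0 <- simulate_pileup(truth, cfg0, sample_ids = ids)
  expect_true(all(p0$alt_reads[p0$true_gt == "hom_ref"] == 0))
  # het truth at high depth sits near one half
  big <- p[p$true_gt == "het" & d >= 15, ]
  reads <- sum(big$ref_reads + big$alt_reads)
  f <- sum(big$alt_reads) / reads
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / reads))
})

test_that("simulated droplets recover the loaded allele fraction", {
  cfg <- sim_config(seed = 10)
  # pure wildtype with no false positives leaves the variant channel dark
  cfg0 <- sim_config(seed = 10, droplet_false_positive_rate = 0)
  w0 <- simulate_droplets(0, cfg0, n_wells = 3)
  expect_true(all(w0$variant_positive == 0 & w0$double_positive == 0))

  w5 <- simulate_droplets(0.5, cfg, n_wells = 4)
  est <- ddpcr_allele_fraction(w5)
  se <- ddpcr_fraction_se(w5)
  expect_lt(abs(est - 0.5), 3 * se)

  # wildtype-only control: power reflects the false-positive share
  wt <- simulate_droplets(0, cfg, n_wells = 2)
  expect_gt(ddpcr_power(wt, "wildtype"), 0.99)
})
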