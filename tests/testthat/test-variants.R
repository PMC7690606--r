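vcf_lines <- function(records, samples = c("s1", "s2")) {
  c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  )
}

test_that("VCF reading applies the strict quality cutoff and parses annotation", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(c(
    "1\t100\t.\tA\tG\t29.9\tPASS\tCSQ=missense|GENEA|deleterious(0)\tGT\t0/1\t0/0",
    "1\t200\t.\tA\tG\t30\tPASS\tCSQ=intron_variant|GENEA|\tGT\t1/1\t0|1",
    "1\t300\t.\tC\tT\t55\tPASS\t.\tGT\t./.\t0/0"
  )), path)
  sites <- read_variants(path, min_qual = 30)
  # qual 29.9 excluded, 30 retained (strictly-lower-than rule)
  expect_equal(sites$pos, c(200L, 300L))
  expect_equal(sites$consequence, c("intronic", "other"))
  expect_equal(sites$gt_s1, c("hom_alt", "missing"))
  expect_equal(sites$gt_s2, c("het", "hom_ref"))
})

test_that("multi-allelic records split into biallelic sites with recoded genotypes", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines(
    "2\t500\t.\tA\tG,T\t90\tPASS\t.\tGT\t1/2\t2/2"
  ), path)
  sites <- read_variants(path)
  expect_equal(nrow(sites), 2)
  expect_equal(sites$alt, c("G", "T"))
  # 1/2 holds one copy of each alternate; 2/2 is hom for the second
  expect_equal(sites$gt_s1, c("het", "het"))
  expect_equal(sites$gt_s2, c("hom_ref", "hom_alt"))
})

test_that("malformed records error with their line number", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_lines("1\t100\tbroken"), path)
  expect_error(read_variants(path), "line 5")
})

test_that("written VCFs round-trip through read_variants", {
  gt <- matrix(c("hom_alt", "het", "hom_ref", "missing"), 2,
               dimnames = list(NULL, c("a", "b")))
  sites <- make_sites(gt, chrom = "26", qual = c(45.5, 100),
                      consequence = c("missense", "intergenic"),
                      gene = c("G1", NA),
                      impact_label = c("deleterious", "none"),
                      impact_score = c(0, NA))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(sites, path)
  back <- read_variants(path, min_qual = 0)
  expect_equal(back[names(sites)], sites)
})

test_that("a generated panel with known sub-threshold sites filters to the rest", {
  set.seed(99)
  gt <- random_gt_matrix(100, c("x", "y"), seed = 99)
  qual <- c(rep(10, 10), runif(90, 30, 500))[sample(100)]
  sites <- make_sites(gt, qual = qual)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(sites, path)
  expect_equal(nrow(read_variants(path, min_qual = 30)), 90)
})

test_that("segregation filter retains exactly the pattern-matching sites", {
  samples <- c("aff1", "aff2", "car1", "car2", "rel1")
  roles <- tibble::tibble(
    sample_id = samples,
    role = c("affected", "affected", "obligate_carrier", "obligate_carrier",
             "relative")
  )
  gt <- rbind(
    c("hom_alt", "hom_alt", "het", "het", "hom_ref"),  # matches
    c("hom_alt", "hom_alt", "het", "het", "hom_alt"),  # relative hom_alt
    c("hom_alt", "het",     "het", "het", "het"),      # affected het
    c("hom_alt", "hom_alt", "hom_ref", "het", "het")   # carrier hom_ref
  )
  colnames(gt) <- samples
  sites <- make_sites(gt)
  kept <- segregation_filter(sites, roles)
  expect_equal(kept$pos, sites$pos[1])

  expect_error(
    segregation_filter(sites, tibble::tibble(sample_id = "zz", role = "affected")),
    "absent"
  )
  expect_error(
    segregation_filter(sites, dplyr::filter(roles, role != "affected")),
    "at least one affected"
  )
})

test_that("missing calls follow the chosen policy", {
  samples <- c("aff1", "car1")
  roles <- tibble::tibble(sample_id = samples,
                          role = c("affected", "obligate_carrier"))
  gt <- rbind(c("hom_alt", "missing"), c("missing", "het"))
  colnames(gt) <- samples
  sites <- make_sites(gt)
  expect_equal(nrow(segregation_filter(sites, roles, "compatible")), 2)
  expect_equal(nrow(segregation_filter(sites, roles, "incompatible")), 0)
})

test_that("segregation filter equals a per-site brute-force oracle", {
  samples <- c("a1", "a2", "a3", "c1", "c2", "r1", "r2")
  roles <- tibble::tibble(
    sample_id = samples,
    role = c(rep("affected", 3), rep("obligate_carrier", 2), rep("relative", 2))
  )
  for (seed in c(1, 7, 23)) {
    gt <- random_gt_matrix(200, samples, seed = seed,
                           prob = c(0.25, 0.35, 0.3, 0.1))
    sites <- make_sites(gt)
    for (policy in c("compatible", "incompatible")) {
      kept <- segregation_filter(sites, roles, policy)
      expect_equal(site_key_str(kept),
                   site_key_str(sites[brute_segregation_keep(sites, roles, policy), ]))
    }
  }
})

test_that("adding an informative sample never adds a retained site", {
  samples <- c("a1", "c1", "r1", "r2")
  base_roles <- tibble::tibble(
    sample_id = samples[1:3],
    role = c("affected", "obligate_carrier", "relative")
  )
  wider <- dplyr::bind_rows(base_roles,
                            tibble::tibble(sample_id = "r2", role = "relative"))
  for (seed in 1:5) {
    gt <- random_gt_matrix(80, samples, seed = 100 + seed)
    sites <- make_sites(gt)
    kept_small <- segregation_filter(sites, base_roles, "incompatible")
    kept_big <- segregation_filter(sites, wider, "incompatible")
    expect_true(all(site_key_str(kept_big) %in% site_key_str(kept_small)))
  }
})

test_that("full-span and degenerate homozygosity runs are handled", {
  samples <- c("a1", "a2")
  gt <- matrix("hom_alt", 25, 2, dimnames = list(NULL, samples))
  gt[10, ] <- "hom_ref"      # homozygous either way still conforms
  sites <- make_sites(gt)
  r <- shared_homozygosity_regions(sites, samples, min_sites = 20,
                                   max_exceptions = 0)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(sites$pos[1], sites$pos[25]))
  expect_equal(r$n_sites, 25)

  # alternating hets leave nothing once runs must have >= 2 sites
  gt2 <- matrix(rep(c("het", "hom_ref"), 20), ncol = 2,
                dimnames = list(NULL, samples))
  r2 <- shared_homozygosity_regions(make_sites(gt2), samples,
                                    min_sites = 2, max_exceptions = 0)
  expect_true(all(r2$n_sites >= 2))
  expect_true(nrow(r2) == 0 || all(r2$end > r2$start))

  expect_error(
    shared_homozygosity_regions(make_sites(gt)[c(2, 1, 3:25), ], samples),
    "sorted"
  )
})

test_that("homozygosity scan equals the exhaustive window oracle", {
  samples <- c("a1", "a2", "a3")
  for (seed in c(2, 13, 31)) {
    set.seed(seed)
    n <- 200
    gt <- matrix(
      sample(c("hom_ref", "hom_alt", "het"), n * 3, replace = TRUE,
             prob = c(0.45, 0.4, 0.15)),
      ncol = 3, dimnames = list(NULL, samples)
    )
    sites <- make_sites(gt)
    conf <- apply(gt, 1, function(g) all(g != "het"))
    for (k in 0:1) {
      got <- shared_homozygosity_regions(sites, samples, min_sites = 3,
                                         max_exceptions = k) |>
        dplyr::select(start, end, n_sites) |>
        dplyr::arrange(start, end)
      want <- brute_roh(conf, sites$pos, min_sites = 3, k = k)
      expect_equal(as.data.frame(got), as.data.frame(want))
    }
  }
})

test_that("prioritization ranks by consequence, impact label, then score", {
  cand <- md_example_candidates()
  ranked <- prioritize_candidates(cand)
  expect_equal(ranked$gene[1], "CYP26C1")
  expect_equal(ranked$consequence[1], "missense")

  # total ties preserve input order
  gt <- random_gt_matrix(5, "s", seed = 1)
  flat <- make_sites(gt, consequence = "intergenic")
  expect_equal(prioritize_candidates(flat)$pos, flat$pos)

  # shuffled panel equals a brute-force sort on the explicit key
  set.seed(5)
  n <- 20
  panel <- make_sites(
    random_gt_matrix(n, "s", seed = 5),
    consequence = sample(c("missense", "utr5", "utr3", "upstream",
                           "downstream", "intronic", "intergenic", "other"),
                         n, replace = TRUE),
    impact_label = sample(c("deleterious", "tolerated", "none"), n, TRUE),
    impact_score = round(runif(n), 2)
  )
  sev <- c(missense = 1, utr5 = 2, utr3 = 2, upstream = 3, downstream = 3,
           intronic = 4, intergenic = 5, other = 6)
  lab <- c(deleterious = 1, tolerated = 2, none = 3)
  want <- panel[order(sev[panel$consequence], lab[panel$impact_label],
                      panel$impact_score), ]
  expect_equal(prioritize_candidates(panel)$pos, want$pos)
})
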