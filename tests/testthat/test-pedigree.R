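test_that("pedigree files load with missing-parent normalization and stubs", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "animal_id,sire_id,dam_id,sex,phenotype",
    "C,S,D,male,affected",
    "S,0,,male,unaffected",
    "D,NA,0,female,unaffected"
  ), path)
  ped <- read_pedigree(path)
  expect_equal(nrow(ped), 3)
  expect_true(all(is.na(ped$sire_id[ped$animal_id %in% c("S", "D")])))
  expect_equal(sum(!is.na(ped$sire_id)) + sum(!is.na(ped$dam_id)), 2)

  # a parent without its own row is auto-created
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("animal_id\tsire_id\tdam_id", "X\tP\tQ"), path2)
  expect_message(ped2 <- read_pedigree(path2), "auto-created")
  expect_setequal(ped2$animal_id, c("X", "P", "Q"))
})

test_that("pedigree validation rejects cycles, duplicates, and sex conflicts", {
  cyc <- tibble::tibble(
    animal_id = c("A", "B"), sire_id = c("B", "A"),
    dam_id = c(NA, NA), sex = c("male", "male")
  )
  expect_error(as_pedigree(cyc), "cycle")

  dup <- tibble::tibble(animal_id = c("A", "A"), sire_id = NA, dam_id = NA)
  expect_error(as_pedigree(dup), "duplicate")

  herm <- tibble::tibble(
    animal_id = c("K1", "K2", "P", "M"),
    sire_id = c("P", "M", NA, NA),
    dam_id = c("M", "P", NA, NA)
  )
  expect_error(as_pedigree(herm), "both sire and dam")
})

test_that("generated pedigree edge count equals its non-missing parent fields", {
  ped <- random_pedigree(10, seed = 42)
  n_edges <- sum(!is.na(ped$sire_id)) + sum(!is.na(ped$dam_id))
  # edges reconstructed from the graph match the parent fields exactly
  edges <- sum(vapply(ped$animal_id, function(a) {
    r <- ped[ped$animal_id == a, ]
    sum(!is.na(c(r$sire_id, r$dam_id)))
  }, numeric(1)))
  expect_equal(edges, n_edges)
})

test_that("ancestors_of matches an independent graph-reachability oracle", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    ped <- random_pedigree(50, seed = seed)
    for (a in sample(ped$animal_id, 10)) {
      expect_setequal(ancestors_of(ped, a), igraph_ancestors(ped, a))
    }
  }
  # trivial cases
  ped <- trio_pedigree()
  expect_setequal(ancestors_of(ped, "C"), c("S", "D"))
  expect_equal(ancestors_of(ped, "S"), character(0))
  expect_error(ancestors_of(ped, "nope"), "unknown")
})

test_that("shared ancestors across cases behave as an intersection", {
  # parents are full sibs with parents (P, Q) -> grandparents shared
  ped <- as_pedigree(tibble::tibble(
    animal_id = c("kid", "S", "D", "P", "Q"),
    sire_id = c("S", "P", "P", NA, NA),
    dam_id = c("D", "Q", "Q", NA, NA),
    sex = c("male", "male", "female", "male", "female"),
    phenotype = c("affected", rep("unaffected", 4))
  ))
  expect_setequal(shared_ancestor_across_cases(ped, "kid"), c("P", "Q"))

  # disjoint ancestries give the empty set
  ped2 <- as_pedigree(tibble::tibble(
    animal_id = c("a1", "a2", "s1", "d1", "s2", "d2"),
    sire_id = c("s1", "s2", NA, NA, NA, NA),
    dam_id = c("d1", "d2", NA, NA, NA, NA),
    sex = c("male", "male", "male", "female", "male", "female"),
    phenotype = c("affected", "affected", rep("unaffected", 4))
  ))
  expect_length(shared_ancestor_across_cases(ped2, c("a1", "a2")), 0)

  # a case with an unknown parent is skipped with a warning
  expect_warning(
    res <- shared_ancestor_across_cases(
      as_pedigree(tibble::tibble(
        animal_id = c("x"), sire_id = NA_character_, dam_id = NA_character_,
        phenotype = "affected"
      )), "x"
    ),
    "unrecorded parent"
  )
  expect_length(res, 0)
})

test_that("more cases can only shrink the candidate-founder set", {
  sim <- simulate_pedigree(sim_config(seed = 11, n_background_variants = 10L))
  aff <- sim$truth$roles$sample_id[sim$truth$roles$role == "affected"]
  full <- shared_ancestor_across_cases(sim$pedigree, aff)
  expect_true(sim$truth$founder_id %in% full)
  for (k in seq_along(aff)) {
    sub <- shared_ancestor_across_cases(sim$pedigree, aff[seq_len(k)])
    expect_true(all(full %in% sub))
  }
})

test_that("founder ties classify by parental route", {
  sim <- simulate_pedigree(sim_config(seed = 3, n_background_variants = 10L))
  ped <- sim$pedigree
  f <- sim$truth$founder_id
  aff <- sim$truth$roles$sample_id[sim$truth$roles$role == "affected"]

  ties <- classify_founder_ties(ped, c(aff[1], f), f)
  expect_equal(ties$tie_class[1], "both_sides")
  expect_equal(ties$tie_class[2], "is_founder")

  # an unrelated outside animal has no tie
  outsider <- setdiff(
    ped$animal_id[is.na(ped$sire_id) & is.na(ped$dam_id)], f
  )[1]
  expect_equal(classify_founder_ties(ped, outsider, f)$tie_class, "none")

  # both_sides implies membership in that single animal's shared-ancestor set
  both <- classify_founder_ties(ped, aff, f)
  for (a in both$animal_id[both$tie_class == "both_sides"]) {
    ped_a <- ped
    expect_true(f %in% shared_ancestor_across_cases(ped_a, a))
  }
})

test_that("obligate carriers are the union of affected animals' parents", {
  ped <- as_pedigree(tibble::tibble(
    animal_id = c("a1", "a2", "a3", "s1", "d1", "s2", "d2", "s3", "d3"),
    sire_id = c("s1", "s2", "s3", rep(NA, 6)),
    dam_id = c("d1", "d2", "d3", rep(NA, 6)),
    sex = c(rep("male", 3), rep(c("male", "female"), 3)),
    phenotype = c(rep("affected", 3), rep("unaffected", 6))
  ))
  expect_setequal(infer_obligate_carriers(ped),
                  c("s1", "d1", "s2", "d2", "s3", "d3"))

  # unknown dam contributes nothing; no affecteds gives the empty set
  ped2 <- as_pedigree(tibble::tibble(
    animal_id = c("a", "s"), sire_id = c("s", NA), dam_id = c(NA, NA),
    sex = c("male", "male"), phenotype = c("affected", "unaffected")
  ))
  expect_equal(infer_obligate_carriers(ped2), "s")
  ped2$phenotype <- "unaffected"
  expect_length(infer_obligate_carriers(ped2), 0)
})
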