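#' Read and validate a pedigree file
#'
#' Reads a comma- or tab-separated pedigree with header columns
#' `animal_id`, `sire_id`, `dam_id`, and optionally `sex`, `phenotype`,
#' `breed`, `herd`, `birth_year`. Missing parents may be encoded as an
#' empty field, `"0"`, or `"NA"`; all are normalized to `NA`. Animals
#' referenced as a parent but lacking their own row are auto-created with
#' unknown sex and phenotype (a message reports how many).
#'
#' @param path Path to the pedigree file. The delimiter is sniffed from the
#'   header line (tab wins over comma).
#' @return A validated pedigree tibble with columns `animal_id`, `sire_id`,
#'   `dam_id`, `sex` (`male`/`female`/`unknown`), `phenotype`
#'   (`affected`/`unaffected`/`unknown`), `breed`, `herd`, `birth_year`.
#' @details Validation rejects duplicate animal ids, an id used both as a
#'   sire and as a dam, a sire recorded as female (or dam as male), and any
#'   cycle in the parent-offspring graph (an animal its own ancestor); the
#'   cycle error names one animal on the cycle.
#' @seealso [as_pedigree()] to validate an existing data frame.
#' @export
read_pedigree <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  as_pedigree(df)
}

#' Validate a pedigree data frame
#'
#' @param df Data frame with at least `animal_id`, `sire_id`, `dam_id`.
#' @return A validated, normalized pedigree tibble (see [read_pedigree()]).
#' @export
as_pedigree <- function(df) {
  df <- as_tibble(df)
  need <- c("animal_id", "sire_id", "dam_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("pedigree is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  norm_id <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x %in% c("", "0", "NA")] <- NA_character_
    x
  }
  ped <- tibble(
    animal_id = as.character(df$animal_id),
    sire_id = norm_id(df$sire_id),
    dam_id = norm_id(df$dam_id),
    sex = if ("sex" %in% names(df)) tolower(as.character(df$sex)) else NA_character_,
    phenotype = if ("phenotype" %in% names(df)) tolower(as.character(df$phenotype)) else NA_character_,
    breed = if ("breed" %in% names(df)) as.character(df$breed) else NA_character_,
    herd = if ("herd" %in% names(df)) as.character(df$herd) else NA_character_,
    birth_year = if ("birth_year" %in% names(df)) as.integer(df$birth_year) else NA_integer_
  )
  ped$sex[is.na(ped$sex) | !ped$sex %in% c("male", "female")] <- "unknown"
  ped$phenotype[is.na(ped$phenotype) | !ped$phenotype %in% c("affected", "unaffected")] <- "unknown"

  if (any(is.na(ped$animal_id) | ped$animal_id == "")) {
    abort("pedigree contains an empty animal_id")
  }
  dup <- ped$animal_id[duplicated(ped$animal_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate animal_id in pedigree: ", paste(unique(dup), collapse = ", ")))
  }

  # registry extracts are routinely truncated: create stub rows for parents
  # that have no row of their own
  referenced <- unique(stats::na.omit(c(ped$sire_id, ped$dam_id)))
  orphans <- setdiff(referenced, ped$animal_id)
  if (length(orphans) > 0) {
    inform(sprintf("auto-created %d parent(s) without their own pedigree row", length(orphans)))
    ped <- bind_rows(ped, tibble(
      animal_id = orphans, sire_id = NA_character_, dam_id = NA_character_,
      sex = "unknown", phenotype = "unknown",
      breed = NA_character_, herd = NA_character_, birth_year = NA_integer_
    ))
  }

  sires <- unique(stats::na.omit(ped$sire_id))
  dams <- unique(stats::na.omit(ped$dam_id))
  both <- intersect(sires, dams)
  if (length(both) > 0) {
    abort(paste0("animal(s) recorded as both sire and dam: ", paste(both, collapse = ", ")))
  }
  sex_of <- stats::setNames(ped$sex, ped$animal_id)
  bad_sire <- sires[sex_of[sires] == "female"]
  bad_dam <- dams[sex_of[dams] == "male"]
  if (length(bad_sire) > 0 || length(bad_dam) > 0) {
    abort(paste0("parent sex inconsistency for: ",
                 paste(c(bad_sire, bad_dam), collapse = ", ")))
  }

  cyc <- find_cycle_animal(ped)
  if (!is.na(cyc)) {
    abort(paste0("pedigree contains a cycle: animal ", cyc, " is its own ancestor"))
  }
  class(ped) <- c("pedigree_tbl", class(ped))
  ped
}

# Kahn's algorithm over parent -> offspring edges; any node never freed
# sits on (or downstream of) a cycle. Returns one animal on a cycle or NA.
find_cycle_animal <- function(ped) {
  ids <- ped$animal_id
  idx <- stats::setNames(seq_along(ids), ids)
  parents <- cbind(idx[ped$sire_id], idx[ped$dam_id])
  indeg <- rowSums(!is.na(parents))
  children <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    for (p in parents[i, ]) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0)
  seen <- 0L
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(ids)) return(NA_character_)
  # nodes with unresolved in-degree include the cycle members; pick one that
  # is an ancestor of itself by walking parent links
  leftover <- ids[indeg > 0]
  leftover[[1]]
}

#' Ancestors of an animal
#'
#' Transitive closure over sire/dam links, excluding the animal itself.
#'
#' @param ped A validated pedigree tibble.
#' @param animal_id Single animal id present in `ped`.
#' @return Character vector of ancestor ids (possibly empty).
#' @export
ancestors_of <- function(ped, animal_id) {
  if (length(animal_id) != 1 || !animal_id %in% ped$animal_id) {
    abort(paste0("unknown animal_id: ", paste(animal_id, collapse = ", ")))
  }
  sire <- stats::setNames(ped$sire_id, ped$animal_id)
  dam <- stats::setNames(ped$dam_id, ped$animal_id)
  out <- character(0)
  frontier <- animal_id
  while (length(frontier) > 0) {
    par <- unique(stats::na.omit(c(sire[frontier], dam[frontier])))
    par <- setdiff(par, out)
    out <- c(out, par)
    frontier <- par
  }
  unname(setdiff(out, animal_id))
}

#' Candidate founders shared across affected cases
#'
#' For each affected animal, intersects the ancestries of its sire and dam;
#' the returned set contains animals found in that intersection for every
#' usable case. Under a rare recessive model, the individual in whom the
#' mutation arose must appear on both the sire side and the dam side of
#' every affected animal, so this set is the candidate-founder set.
#'
#' @param ped A validated pedigree tibble.
#' @param affected_ids Animal ids of the affected cases; defaults to all
#'   animals with `phenotype == "affected"`.
#' @return Character vector of candidate founder ids (possibly empty).
#'   Cases with an unrecorded sire or dam contribute no constraint and are
#'   skipped with a warning.
#' @export
shared_ancestor_across_cases <- function(ped, affected_ids = NULL) {
  if (is.null(affected_ids)) {
    affected_ids <- ped$animal_id[ped$phenotype == "affected"]
  }
  unknown <- setdiff(affected_ids, ped$animal_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown affected id(s): ", paste(unknown, collapse = ", ")))
  }
  sire <- stats::setNames(ped$sire_id, ped$animal_id)
  dam <- stats::setNames(ped$dam_id, ped$animal_id)
  result <- NULL
  n_used <- 0L
  for (a in affected_ids) {
    s <- sire[[a]]; d <- dam[[a]]
    if (is.na(s) || is.na(d)) {
      warn(paste0("affected ", a, " has an unrecorded parent; case skipped"))
      next
    }
    shared <- intersect(ancestors_of(ped, s), ancestors_of(ped, d))
    result <- if (n_used == 0L) shared else intersect(result, shared)
    n_used <- n_used + 1L
    if (length(result) == 0) break
  }
  if (n_used == 0L) return(character(0))
  result
}

#' Classify pedigree ties of animals to a founder
#'
#' For each animal, reports whether the founder appears in the paternal
#' pedigree, the maternal pedigree, both, or neither — the classification
#' used when tabulating carrier genotypes against pedigree ties. A parent
#' itself counts as its side's pedigree.
#'
#' @param ped A validated pedigree tibble.
#' @param animal_ids One or more animal ids in `ped`.
#' @param founder_id The founder's animal id.
#' @return Tibble with columns `animal_id` and `tie_class`
#'   (`both_sides`, `one_side`, `none`, `is_founder`).
#' @export
classify_founder_ties <- function(ped, animal_ids, founder_id) {
  unknown <- setdiff(c(animal_ids, founder_id), ped$animal_id)
  if (length(unknown) > 0) {
    abort(paste0("unknown animal id(s): ", paste(unknown, collapse = ", ")))
  }
  sire <- stats::setNames(ped$sire_id, ped$animal_id)
  dam <- stats::setNames(ped$dam_id, ped$animal_id)
  via_side <- function(parent) {
    !is.na(parent) &&
      (parent == founder_id || founder_id %in% ancestors_of(ped, parent))
  }
  cls <- vapply(animal_ids, function(a) {
    if (a == founder_id) return("is_founder")
    p <- via_side(sire[[a]])
    m <- via_side(dam[[a]])
    if (p && m) "both_sides" else if (p || m) "one_side" else "none"
  }, character(1))
  tibble(animal_id = animal_ids, tie_class = unname(cls))
}

#' Infer obligate carriers from phenotypes
#'
#' Under a fully penetrant recessive model every parent of an affected
#' animal must carry one copy of the causal allele. Returns the union of
#' recorded sires and dams of affected animals.
#'
#' @param ped A validated pedigree tibble.
#' @return Character vector of obligate-carrier animal ids.
#' @export
infer_obligate_carriers <- function(ped) {
  aff <- ped[ped$phenotype == "affected", ]
  unique(stats::na.omit(c(aff$sire_id, aff$dam_id)))
}
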