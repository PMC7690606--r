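CONSEQUENCE_MAP <- c(
  "missense" = "missense", "missense_variant" = "missense",
  "utr5" = "utr5", "5_prime_utr_variant" = "utr5",
  "utr3" = "utr3", "3_prime_utr_variant" = "utr3",
  "upstream" = "upstream", "upstream_gene_variant" = "upstream",
  "downstream" = "downstream", "downstream_gene_variant" = "downstream",
  "intronic" = "intronic", "intron_variant" = "intronic",
  "intergenic" = "intergenic", "intergenic_variant" = "intergenic",
  "intergenic_region" = "intergenic"
)

normalize_consequence <- function(x) {
  key <- tolower(gsub("[ -]", "_", trimws(x)))
  out <- unname(CONSEQUENCE_MAP[key])
  out[is.na(out)] <- "other"
  out[is.na(x) | x == ""] <- "other"
  out
}

# parse "deleterious(0)" / "tolerated(0.42)" / "" into label + score
parse_sift <- function(x) {
  label <- rep("none", length(x))
  score <- rep(NA_real_, length(x))
  hit <- !is.na(x) & grepl("^(deleterious|tolerated)", x)
  label[hit] <- sub("^(deleterious|tolerated).*", "\\1", x[hit])
  num <- suppressWarnings(as.numeric(sub("^[a-z_]+\\(([^)]*)\\).*", "\\1", x[hit])))
  score[hit] <- num
  bare <- !is.na(x) & grepl("^[0-9.]+$", x)
  score[bare] <- suppressWarnings(as.numeric(x[bare]))
  label[bare & !is.na(score) & score <= 0.05] <- "deleterious"
  label[bare & !is.na(score) & score > 0.05] <- "tolerated"
  list(label = label, score = score)
}

info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(g) if (length(g) == 2) g[[2]] else NA_character_, character(1))
}

#' Read a multi-sample VCF into a variant table
#'
#' Parses a VCF 4.x file with per-sample GT fields into a tidy variant
#' table: one row per biallelic site, one `gt_<sample>` column per sample.
#' Multi-allelic records are split into one biallelic site per alternate
#' allele — never dropped — with genotypes recoded as the copy number of
#' that alternate (other alternates fold into the reference class).
#' Sites whose QUAL is strictly below `min_qual` are removed, mirroring
#' variant-caller quality pre-filtering; a QUAL of exactly `min_qual` is
#' retained. A missing QUAL (`.`) is treated as failing.
#'
#' Annotation is read from INFO when present: the key named by
#' `csq_key` may hold either a bare consequence term or a pipe-separated
#' `consequence|gene|sift` triplet (SIFT as `deleterious(0)` style);
#' unannotated sites get consequence class `other`.
#'
#' @param path Path to a VCF file.
#' @param min_qual Minimum site quality (default 30).
#' @param csq_key INFO key holding the consequence annotation (default `"CSQ"`).
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `consequence`, `gene`, `impact_label`, `impact_score`, then one
#'   `gt_<sample>` column per sample with values `hom_ref`, `het`,
#'   `hom_alt`, `missing`.
#' @export
read_variants <- function(path, min_qual = 30, csq_key = "CSQ") {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  nf <- lengths(regmatches(lines[body], gregexpr("\t", lines[body]))) + 1L
  if (any(nf < 8L)) {
    abort(sprintf("malformed VCF record at line %d (fewer than 8 fields)",
                  body[which(nf < 8L)[1]]))
  }
  if (length(body) == 0) {
    return(empty_variant_table(character(0)))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  has_gt <- ncol(v@gt) > 1
  samples <- if (has_gt) colnames(v@gt)[-1] else character(0)
  gt_raw <- if (has_gt) {
    fmt <- strsplit(v@gt[, 1], ":", fixed = TRUE)
    gt_i <- vapply(fmt, function(f) match("GT", f), integer(1))
    apply_cols <- function(j) {
      vapply(seq_len(nrow(v@gt)), function(i) {
        val <- v@gt[i, j + 1]
        if (is.na(val) || is.na(gt_i[i])) return(NA_character_)
        strsplit(val, ":", fixed = TRUE)[[1]][gt_i[i]]
      }, character(1))
    }
    do.call(cbind, lapply(seq_along(samples), apply_cols))
  } else {
    matrix(character(0), nrow = nrow(fix), ncol = 0)
  }

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    qual <- suppressWarnings(as.numeric(fix$QUAL[i]))
    info <- fix$INFO[i] %||% NA_character_
    csq <- if (!is.na(info)) info_field(info, csq_key) else NA_character_
    ann <- parse_csq_value(csq)
    per_alt <- lapply(seq_along(alts), function(k) {
      gts <- recode_gt_vs_alt(gt_raw[i, ], k)
      c(list(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], qual = qual,
        consequence = ann$consequence, gene = ann$gene,
        impact_label = ann$impact_label, impact_score = ann$impact_score
      ), stats::setNames(as.list(gts), paste0("gt_", samples)))
    })
    rows[[i]] <- per_alt
  }
  out <- bind_rows(lapply(unlist(rows, recursive = FALSE), as_tibble))
  out <- out[!is.na(out$qual) & out$qual >= min_qual, , drop = FALSE]
  out
}

parse_csq_value <- function(csq) {
  if (is.na(csq)) {
    return(list(consequence = "other", gene = NA_character_,
                impact_label = "none", impact_score = NA_real_))
  }
  parts <- strsplit(csq, "|", fixed = TRUE)[[1]]
  cons <- normalize_consequence(parts[1])
  gene <- if (length(parts) >= 2 && nzchar(parts[2])) parts[2] else NA_character_
  sift <- parse_sift(if (length(parts) >= 3) parts[3] else NA_character_)
  list(consequence = cons, gene = gene,
       impact_label = sift$label, impact_score = sift$score)
}

# genotype of one sample against alternate allele k of a (possibly
# multi-allelic) record: copies of k -> hom_alt/het; other alleles fold to ref
recode_gt_vs_alt <- function(gt_strings, k) {
  vapply(gt_strings, function(g) {
    if (is.na(g)) return("missing")
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".") || length(alleles) == 0) return("missing")
    n_alt <- sum(alleles == as.character(k))
    c("hom_ref", "het", "hom_alt")[n_alt + 1L]
  }, character(1), USE.NAMES = FALSE)
}

empty_variant_table <- function(samples) {
  base <- tibble(
    chrom = character(0), pos = integer(0), ref = character(0),
    alt = character(0), qual = numeric(0), consequence = character(0),
    gene = character(0), impact_label = character(0), impact_score = numeric(0)
  )
  for (s in samples) base[[paste0("gt_", s)]] <- character(0)
  base
}

#' Write a variant table as a VCF file
#'
#' Serializes a variant table (see [read_variants()]) to a plain-text
#' VCF 4.2 file with GT fields and the package's `CSQ`-style annotation
#' (`consequence|gene|sift`) in INFO. Round-trips with [read_variants()].
#'
#' @param sites Variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(sites, path) {
  samples <- gt_samples(sites)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Annotation: consequence|gene|sift\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  sift_str <- ifelse(
    sites$impact_label %in% c("deleterious", "tolerated"),
    sprintf("%s(%s)", sites$impact_label,
            ifelse(is.na(sites$impact_score), "", format(sites$impact_score))),
    ""
  )
  info <- sprintf("CSQ=%s|%s|%s", sites$consequence,
                  ifelse(is.na(sites$gene), "", sites$gene), sift_str)
  gm <- gt_matrix(sites)
  gt_txt <- if (length(samples) > 0) {
    apply(gm, 1, function(r) paste(gt_code[r], collapse = "\t"))
  } else {
    character(nrow(sites))
  }
  rec <- paste(
    sites$chrom, sites$pos, ".", sites$ref, sites$alt,
    format(sites$qual, trim = TRUE, scientific = FALSE), "PASS", info, "GT",
    sep = "\t"
  )
  if (length(samples) > 0) rec <- paste(rec, gt_txt, sep = "\t")
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Write candidate variants as a tab-separated table
#'
#' @param candidates Variant table (typically after filtering/ranking).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  out <- candidates[, c("chrom", "pos", "ref", "alt", "consequence",
                        "gene", "impact_label", "impact_score")]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write homozygosity regions as BED
#'
#' Regions are stored 1-based inclusive internally; BED output uses the
#' format's 0-based half-open convention (the one coordinate conversion in
#' the package).
#'
#' @param regions Region tibble from [shared_homozygosity_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roh_bed <- function(regions, path) {
  bed <- tibble(
    chrom = regions$chrom,
    start = regions$start - 1L,
    end = regions$end,
    name = sprintf("roh_%d_sites", regions$n_sites)
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
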