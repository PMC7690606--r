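#' Configuration for the synthetic cohort generator
#'
#' Collects every tunable of the gene-dropping simulator. Defaults emulate
#' the discovery setting the package targets: a de novo recessive allele
#' arising in one widely used founder sire, a sequenced cohort of 3
#' affected calves, 10 obligate carriers, and 7 other relatives at ~13X
#' coverage, a ~5 Mb completely linked haplotype around the causal locus
#' on a ~52 Mb chromosome, and duplexed ddPCR wells of ~20,000 droplets.
#'
#' @param seed Integer seed; every simulation function derives its random
#'   stream from it, so identical configs give byte-identical outputs.
#' @param n_generations Pedigree depth including the founder generation
#'   (3-4 supported; default 4: founder, his offspring, grand-offspring,
#'   and the case generation).
#' @param founder_matings_per_generation Number of founder matings (and of
#'   case matings); controls pedigree width (default 40, emulating heavy
#'   artificial-insemination use of one sire line).
#' @param chrom,chrom_length_bp Chromosome name and length of the single
#'   simulated chromosome.
#' @param n_background_variants Number of neutral background variants.
#' @param causal_pos 1-based position of the causal variant.
#' @param haplotype_block_bp Width of the completely linked haplotype
#'   carrying the causal allele (no recombination inside; hard edges).
#' @param genotype_error_rate Probability that a site's emitted genotype
#'   matrix contains a miscall (see `error_model`).
#' @param error_model `"per_site"` (default): with probability
#'   `genotype_error_rate` a site receives one miscalled genotype in one
#'   randomly chosen sample, modelling locus-level artifacts;
#'   `"per_call"`: each genotype call is independently miscalled with that
#'   probability.
#' @param missing_rate Per-call no-call probability.
#' @param mean_depth,depth_dispersion Mean and negative-binomial size of
#'   per-sample read depth at a pileup locus (mean 13 matches low-pass
#'   whole-genome sequencing).
#' @param read_error_rate Per-read miscall probability in simulated pileups.
#' @param low_qual_rate Fraction of background sites emitted with VCF site
#'   quality below 30 (artifact sites removed by quality pre-filtering).
#' @param penetrance Probability that a homozygous-alternate animal shows
#'   the phenotype (default 1: fully penetrant).
#' @param droplet_total Droplets per ddPCR well (default 20000).
#' @param droplet_false_positive_rate Per-droplet false-positive rate per
#'   channel (default 5e-4, giving single-allele-control powers around
#'   0.999 at typical loading).
#' @param droplet_mean_copies Mean template copies per droplet.
#' @param n_sequenced_affected,n_obligate_carriers,n_relatives Composition
#'   of the sequenced cohort (defaults 3 / 10 / 7).
#' @param n_affected_matings Ascertainment target: gene drops are repeated
#'   until at least this many case matings produce an affected calf
#'   (default 5, so the parents of affected calves number
#'   `n_obligate_carriers`).
#' @param max_attempts Maximum gene-drop attempts before giving up.
#' @param defect_breed,other_breeds,cohort_n_per_breed External-cohort
#'   emulation: breed of the defect and breeds/sample sizes of the
#'   external genotype summaries.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_generations = 4L,
                       founder_matings_per_generation = 40L,
                       chrom = "26",
                       chrom_length_bp = 52e6,
                       n_background_variants = 800L,
                       causal_pos = 14404993L,
                       haplotype_block_bp = 5e6,
                       genotype_error_rate = 0.01,
                       error_model = c("per_site", "per_call"),
                       missing_rate = 0.03,
                       mean_depth = 13,
                       depth_dispersion = 20,
                       read_error_rate = 0.01,
                       low_qual_rate = 0.1,
                       penetrance = 1.0,
                       droplet_total = 20000L,
                       droplet_false_positive_rate = 5e-4,
                       droplet_mean_copies = 0.8,
                       n_sequenced_affected = 3L,
                       n_obligate_carriers = 10L,
                       n_relatives = 7L,
                       n_affected_matings = 5L,
                       max_attempts = 500L,
                       defect_breed = "Hereford",
                       other_breeds = c("Angus", "Simmental", "Romagnola",
                                        "Original Braunvieh"),
                       cohort_n_per_breed = 200L) {
  error_model <- match.arg(error_model)
  cfg <- as.list(environment())
  rates <- c(genotype_error_rate, missing_rate, low_qual_rate, penetrance,
             droplet_false_positive_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (causal_pos > chrom_length_bp) abort("causal_pos exceeds chrom_length_bp")
  if (!n_generations %in% 3:4) abort("n_generations must be 3 or 4")
  class(cfg) <- "sim_config"
  cfg
}
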