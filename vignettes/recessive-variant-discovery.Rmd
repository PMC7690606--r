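---
title: "Mapping a recessive defect: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive defect: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recessivescan)
```

# The problem and the model

`recessivescan` implements the analysis used to map rare, fully penetrant
recessive defects in pedigreed populations — the setting typified by a
congenital syndrome appearing suddenly in one livestock breed. The model has
three ingredients:

1. **A founder mutation.** A de novo allele arises in one ancestor. Because
   an affected individual needs two copies, the founder must appear in
   *both* the sire-side and dam-side pedigree of every case. The
   candidate-founder set is therefore
   `intersect(ancestors(sire), ancestors(dam))`, intersected across cases
   (`shared_ancestor_across_cases()`). The package returns the full set:
   when several ancestors satisfy the constraint (e.g., a bull and his own
   sire), pedigree data alone cannot separate them, and designating "the"
   founder is left to the analyst.

2. **Recessive segregation in a sequenced cohort.** With phenotypes assigned
   (affected calves, their parents as obligate carriers, and other
   relatives), a causal variant must be homozygous-alternate in every
   affected, heterozygous in every obligate carrier, and anything but
   homozygous-alternate in unaffected relatives. `segregation_filter()`
   applies this pattern literally, per site.

3. **Autozygosity.** The two causal haplotypes of an affected descend from
   one founder chromosome, so affecteds share an extended run of
   homozygosity (ROH) around the locus. `shared_homozygosity_regions()`
   scans consecutive sites for runs homozygous in all affecteds.

Candidates surviving segregation are then screened against external
populations (`homalt_exclusion()`, `breed_exclusion()`,
`confirmation_genotype_elimination()`) and ranked by predicted impact
(`prioritize_candidates()`). `run_discovery()` composes the stages and logs
the fate of every input variant; the attrition trace *is* the result of a
campaign like this, so it is first-class output.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_qual` | 30 | phred-scaled site quality | strict `< 30` elimination; a site at exactly 30 is kept |
| `missing_policy` | `"compatible"` | — | at ~13X coverage sporadic no-calls are inevitable; a missing call should not disqualify a site. `"incompatible"` is available for stringent reruns |
| `roh_min_sites` | 20 | sites | a run shorter than this is uninformative at whole-genome marker density |
| `roh_max_exceptions` | 1 | sites | tolerates a single genotyping error inside a long run without splitting it |
| `min_depth` (pileup) | 10 | reads | genotypes are only called from pileups with at least 10 informative reads |
| `hom_threshold` (pileup) | 0.15 | alt fraction | conventional low-coverage cutoffs: `f <= 0.15` hom-ref, `f >= 0.85` hom-alt, het between |

The cohort screening statistic `cohort_frequency()` is alternate-allele
copies **per genotyped sample**, `(n_het + 2 n_hom_alt) / n_samples`. This
is the convention such screening reports actually print (6 heterozygotes in
1018 samples → 0.006; 7 heterozygotes plus 1 homozygote in 1083 → 0.0083);
the conventional per-chromosome allele frequency is exposed separately as
`allele_frequency()` to avoid ambiguity.

# ddPCR analytics

A duplexed droplet assay partitions a reaction into ~20,000 droplets read in
two fluorescence channels. Because one droplet can hold several template
copies, raw positive-droplet ratios understate concentrated targets;
`ddpcr_allele_fraction()` therefore inverts Poisson occupancy,
$\lambda = -\log(1 - p_{pos})$ per channel, and reports
$\lambda_v / (\lambda_v + \lambda_w)$. A `raw = TRUE` mode skips the
correction for comparison. Replicate wells are pooled by **summing counts**,
not averaging fractions, which preserves the Poisson statistics; the
pooling-equivalence property is tested.

Assay power is estimated from single-allele control wells as
`1 - opposite-channel positives / total positives`; double-positive droplets
count as opposite-channel signal since the channel did fire.
`mosaicism_assessment()` calls germline mosaicism supported only when a test
animal's pooled fraction **strictly** exceeds every wildtype control — a tie
is indistinguishable from assay background, and no formal significance test
is invented beyond that exceedance rule.

# What the synthetic cohort emulates

`simulate_cohort()` generates every input the pipeline consumes, with known
truth. Design choices, made once:

* **Pedigree topology.** One founder sire is mated to
  `founder_matings_per_generation` (default 40) unrelated dams, emulating
  artificial insemination; his offspring are outcrossed; a final generation
  of case matings joins two different founder lines (a son of the founder
  with a granddaughter from another line, and vice versa), so every case
  mating structurally carries the founder on both sides.
* **Ascertainment.** The gene drop is repeated until at least
  `n_affected_matings` (default 5) case matings segregate an affected calf —
  the situation that triggers such a study. The sequenced cohort is then 3
  affected calves, the 10 parents of affected calves (obligate carriers,
  truly heterozygous by descent), and 7 other relatives, matching the
  default study design. The public `gene_drop()` operation is
  unconditioned; only the cohort construction ascertains.
* **Linkage.** Variants within `haplotype_block_bp` (default 5 Mb) of the
  causal position are transmitted with the *same* meiotic choices as the
  causal allele — complete linkage with hard edges, the simplest structure
  that produces the shared-ROH signal and the cluster of co-segregating
  candidates that external cohorts must then eliminate. Outside the block,
  loci recombine freely. Background founder alleles are drawn at
  uniform(0.05, 0.95) population frequencies and transmitted by proper
  Mendelian descent, so trio genotypes are Mendelian-consistent everywhere.
* **Noise.** `missing_rate` (default 0.03) produces per-call no-calls.
  `genotype_error_rate` (default 0.01) is, by default, a **per-site**
  corruption probability: with probability 0.01 a site's genotype vector
  contains one miscall in one randomly chosen sample, modelling the
  locus-level artifacts (local misassembly, paralogy) that dominate
  residual error in quality-filtered multi-sample calls. An
  `error_model = "per_call"` mode applies the rate to every call
  independently instead; note that per-call corruption at rate $e$ removes
  the causal site from a strict 20-sample segregation filter with
  probability $\approx 1 - (1-e)^{13}(1-e/2)^{7}$ (≈15% at $e = 0.01$), so
  strict-filter recovery studies should interpret that mode accordingly.
* **Site quality.** A `low_qual_rate` share (default 0.1) of background
  sites is emitted below the QUAL-30 cutoff, modelling artifact calls. The
  causal site is always emitted above it: a true variant homozygous in
  three ~13X genomes does not fall below a site-quality of 30, and a cohort
  in which it did would never have reached candidate filtering.
* **External cohorts.** Per-breed genotype tallies are Hardy–Weinberg draws
  at each background variant's population frequency (default 200 samples in
  each of five breeds); the causal allele is absent from all of them, being
  private to the founder line.
* **Assays.** Pileup depth is negative-binomial (mean 13, matching low-pass
  sequencing; dispersion 20) with a 1% per-read error; droplets use Poisson
  seeding at `droplet_mean_copies` (0.8) with a per-droplet, per-channel
  false-positive rate of 5e-4, which yields single-allele-control powers
  around 0.999 at default loading.

What the generator does **not** model: recombination inside the block,
phenotype misclassification (the case definition being emulated is
unambiguous), breed substructure beyond an independent frequency jitter,
read-level sequence context, and KASP fluorescence clustering (the assay
module starts from per-reaction calls). Passing the recovery tests therefore
demonstrates the pipeline's logic and its robustness to the modelled noise —
not robustness to misalignment artifacts, segmental duplications, or
pedigree errors in real registries.

# Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout, as in VCF; the single
  conversion is BED export of ROH regions (0-based half-open), documented at
  `write_roh_bed()`.
* Multi-allelic records are split, never dropped; genotypes are recoded as
  copy number of the focal alternate, other alternates folding into the
  reference class.
* A missing QUAL (`.`) fails the quality filter: a site whose quality
  cannot be certified is not certified.
* The ROH scan enumerates *maximal* windows containing at most
  `max_exceptions` non-conforming sites by a two-pointer sweep (verified
  against an exhaustive window oracle in the tests); region bounds are
  trimmed to the first/last conforming site, and `n_sites` counts conforming
  sites only.
* Prioritization is a stable sort: severity class, then impact label, then
  ascending deleteriousness score (0 = most deleterious), ties preserving
  input order. The severity order below missense (UTR > up/downstream >
  intronic > intergenic) is a package decision; published reports only
  distinguish coarser classes.
* `cohort_frequency()` errors on zero samples rather than returning NaN;
  saturated ddPCR channels (every droplet positive) error rather than
  returning infinite concentration.
* Test and recovery-study problem sizes — 800-variant chromosomes, 100
  replicates for end-to-end recovery, 10,000 gene-drop replicates, 1,000
  droplet wells — were chosen so Monte-Carlo error is well below every
  asserted margin while the whole suite runs in minutes on a laptop.

# Worked example

```{r example}
cand <- md_example_candidates()
kept <- breed_exclusion(cand, md_example_summaries(), defect_breed = "Hereford")
nrow(kept)                         # 6 of 8 candidates survive breed screening
prioritize_candidates(kept)[1, c("chrom", "pos", "gene", "consequence")]

signif(cohort_frequency(6, 0, 1018), 1)
signif(cohort_frequency(7, 1, 1083), 2)
```

# Known limitations

Pedigree inference stops at reachability: kinship and inbreeding
coefficients are out of scope, as is pedigree drawing. The variant reader
handles VCF 4.x with GT fields and one annotation key; it is not a general
VEP parser. External-cohort matching is exact on (chrom, pos, ref, alt) by
design — no normalization or liftover — so inputs must share a genome build.
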