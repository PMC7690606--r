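# recessivescan

Tidyverse-native R toolkit for mapping rare, fully penetrant **recessive
defects** in pedigreed populations — the workflow used when a congenital
syndrome surfaces in a livestock breed and has to be traced from pedigrees
and whole-genome sequence to a single causal variant.

## What it does

For whom: geneticists working from a multi-sample VCF, a registry pedigree,
and validation genotyping assays. The package covers the whole campaign:

1. **Pedigree analysis** — validate registry extracts, find the common
   ancestor present on *both* the sire and dam side of every affected
   individual (the candidate founder), classify every animal's pedigree tie
   to that founder, and infer obligate carriers
   (`read_pedigree()`, `shared_ancestor_across_cases()`,
   `classify_founder_ties()`, `infer_obligate_carriers()`).
2. **Segregation filtering** — read a multi-sample VCF (QUAL ≥ 30,
   multi-allelics split) and keep sites where every affected is hom-alt,
   every obligate carrier het, and every relative non-hom-alt
   (`read_variants()`, `segregation_filter()`).
3. **Shared homozygosity** — scan for runs of homozygosity common to all
   affecteds, localizing the autozygous segment around the causal locus
   (`shared_homozygosity_regions()`).
4. **Population screening** — eliminate candidates seen homozygous-alternate
   in external cohorts, or segregating in other breeds; the screening
   statistic is alternate copies per genotyped sample,
   `(n_het + 2·n_hom_alt) / n_samples`
   (`homalt_exclusion()`, `breed_exclusion()`, `cohort_frequency()`).
5. **Prioritization** — stable ranking by consequence severity, impact
   label, and deleteriousness score (`prioritize_candidates()`).
6. **Validation assays** — pileup genotype calling with a ≥10-read floor,
   duplicate-assay concordance, droplet digital PCR allele fractions with
   Poisson occupancy correction, assay power from single-allele controls,
   and control-referenced germline-mosaicism assessment
   (`genotype_from_pileup()`, `ddpcr_allele_fraction()`, `ddpcr_power()`,
   `mosaicism_assessment()`).
7. **Synthetic cohorts** — a gene-dropping generator that emits pedigrees,
   VCFs, cohort summaries, pileups, and droplet tables with known ground
   truth, so the entire pipeline can be exercised at desk scale
   (`sim_config()`, `simulate_cohort()`, `gene_drop()`).

`run_discovery()` composes stages 2–5 and logs the fate of every input
variant; results carry `tidy()`, `glance()`, and `autoplot()` methods.
A thin CLI (`exec/recessivescan`) wraps discovery, founder analysis,
Mendelian checks, and cohort generation.

## Worked example

The bundled example data are the eight candidate variants of a Hereford
mandibulofacial dysostosis discovery cohort, with external-cohort genotype
summaries (per-breed split reconstructed from published aggregate counts —
see `?md_example`):

```r
library(recessivescan)

cand <- md_example_candidates()
kept <- breed_exclusion(cand, md_example_summaries(), defect_breed = "Hereford")
nrow(kept)
#> [1] 6
prioritize_candidates(kept)[1, c("chrom", "pos", "ref", "alt", "gene")]
#> # A tibble: 1 × 5
#>   chrom      pos ref   alt   gene
#>   <chr>    <dbl> <chr> <chr> <chr>
#> 1 26    14404993 T     C     CYP26C1
```

Two of the eight candidates are dropped because their alternate allele
segregates in breeds the defect has never appeared in (screening
frequencies 0.006 and 0.0083 alternate copies per genotyped sample); the
lone deleterious missense variant — the *CYP26C1* exon-3 substitution —
ranks first among the survivors.

A fully synthetic campaign, end to end:

```r
coh <- simulate_cohort(sim_config(seed = 4))
run <- run_discovery(coh$sites, coh$roles, coh$summaries,
                     defect_breed = "Hereford")
run
#> Recessive-defect discovery run
#>   qual               774 ->   692 (removed 82)
#>   segregation        692 ->     1 (removed 691)
#>   homalt_external      1 ->     1 (removed 0)
#>   breed                1 ->     1 (removed 0)
#>   candidates: 1; shared-homozygosity regions: 2
tidy(run)$pos[1] == coh$truth$causal$pos
#> [1] TRUE
```

The stage trace reads: 774 simulated sites, 82 removed below QUAL 30, 691
incompatible with recessive segregation, and the single survivor is the
seeded causal variant, inside a shared-homozygosity region overlapping the
seeded haplotype block.

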