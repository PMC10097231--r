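# plumprint

SSR fingerprinting and genetic diversity analysis for dominant-scored
polyploid germplasm, built around the hexaploid European plum
(*Prunus domestica*, 2n = 6x = 48).

In polyploids, capillary electrophoresis of microsatellite (SSR) amplicons
shows up to six distinct fragment sizes per locus per accession, and peak
heights cannot be phased into genotypes. The data are therefore
dominant-scored: each accession carries a *set* of alleles per locus, with
unknown dosage. `plumprint` implements the complete analysis pipeline for
such data:

- **Per-locus diversity statistics.** Carrier frequencies
  p<sub>i</sub> = 100 · (carriers) / (scored accessions); observed
  heterozygosity H<sub>o</sub> as the fraction of accessions showing ≥ 2
  distinct alleles (the only observable form when dosage is unknown); and the
  dominant-marker polymorphism information content
  PIC = mean over bands of 2f(1 − f), bounded by 0.5.
- **Allele classification.** Common vs group-unique alleles between two
  accession groups, with rare alleles defined by p<sub>i</sub> ≤ 10 % in every
  carrying group.
- **Minimal discriminating marker sets.** The greedy procedure used for
  cultivar fingerprinting — add loci in decreasing PIC order until every pair
  of genotypes is distinguishable — plus an exhaustive subset-enumeration
  oracle for verification.
- **UPGMA dendrograms with bootstrap support** on the binary band matrix
  (Dice distance by default; Jaccard and simple matching available), with
  Newick export.
- **Bayesian admixture clustering** (STRUCTURE-style Gibbs sampler for
  ploidy-6 data with -9 missing-slot coding, implemented in C++) over a grid
  of K, with the **Evanno ΔK** estimator
  ΔK = mean|L″(K)| / sd(L(K)) for selecting the number of genetic groups.
- **A synthetic hexaploid genotype generator** — group-structured allele
  frequencies, pedigree crosses under a balanced hexaploid gamete model, and
  fragment-size jitter with integer re-binning — so the whole pipeline is
  testable end to end without external data.

The package bundles transcriptions of a published nine-locus ECPGR plum
marker panel and its per-locus summary tables, usable both as reference
fixtures and as worked inputs (`load_fixture("table1")` … `"table4"`).

## Worked example

```r
library(plumprint)

# classify the bundled published allele table
cls <- classify_alleles(load_fixture("table2"))
cls
#> Allele classification: 157 alleles, rare threshold p_i <= 10 %
#>    category  n  pct
#>      common 79 50.3
#>   unique_lt 62 39.5
#>  unique_ref 16 10.2
#> rare: 74 alleles
```

Of the 157 polymorphic alleles, 79 (50.3 %) are shared between the
Lithuanian-origin and reference cultivar groups, 62 (39.5 %) are unique to
the Lithuanian-origin material and 16 (10.2 %) to the reference cultivars;
74 alleles are rare under the p<sub>i</sub> ≤ 10 % rule.

```r
# simulate a structured hexaploid data set and analyze it end to end
cfg <- sim_config(accessions_per_group = c(15, 15, 15),
                  concentration = 0.1, seed = 1001)
prof <- simulate_groups(cfg)

locus_summary_means(locus_summary_table(prof, c("G1", "G2", "G3")))
#>   group allele_number   ho   pic max_alleles
#> 1    G1          4.89 0.86 0.234        3.67
#> 2    G2          5.33 0.79 0.256        3.67
#> 3    G3          5.56 0.86 0.226        3.78

greedy_minimal_set(prof)$selected      # loci that fingerprint all accessions
#> [1] "SIM006" "SIM001" "SIM007" "SIM003"

runs <- run_grid(structure_data(prof), k_range = 1:6, runs_per_k = 5,
                 burn_in = 2000, iterations = 5000, seed_base = 1)
attr(evanno_delta_k(runs), "best_k")[1]
#> [1] 3
```

The ΔK maximum recovers the three simulated populations. `run_pipeline()`
chains all stages (summaries, classification, minimal set, bootstrapped
tree, admixture grid) into an output directory with a plain-text report.

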