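---
title: "Methods: dominant-scored SSR analysis for hexaploid germplasm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant-scored SSR analysis for hexaploid germplasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumprint)
```

## The data model

European plum is hexaploid (2n = 6x = 48), so a single SSR locus can show up
to six distinct fragment sizes in one accession, and electropherogram peak
heights cannot be resolved into allele copy numbers. `plumprint` therefore
treats a genotype as *dominant-scored*: per locus, the set of distinct
allele sizes (1–6 members), never a dosage. Every statistic in the package
is defined on that basis:

- **Carrier frequency** p<sub>i</sub>: the percentage of accessions in a
  group carrying an allele, among those scored at the locus. This is not an
  allele-copy frequency; the two are related (under random copy sampling at
  copy frequency f, the carrier probability is 1 − (1 − f)<sup>6</sup>), and
  the synthetic generator documents which one it reports.
- **Observed heterozygosity** H<sub>o</sub>: the fraction of accessions
  displaying two or more distinct alleles. An accession with a single band
  may carry one to six copies of it; "homozygous" here can only mean "single
  distinct allele". This definition is the one consistent with published
  per-cultivar homozygosity statements for this marker system.
- **PIC** (dominant form): each band with carrier fraction f contributes
  2f(1 − f); the locus PIC is the band mean. It is bounded by 0.5 (attained
  at f = 0.5) and symmetric in f ↔ 1 − f. Codominant PIC is undefined
  without dosage, so the dominant-marker form is used throughout.

## Allele classification

Given two accession groups, an allele is *common* (carried in both),
*unique* (carried in exactly one — the genetic individuality of that group),
and *rare* when every nonzero group frequency is at most 10 % (the
configurable `rare_threshold`). Percentages are reported to one decimal;
printed-table style outputs round half-up, since published tables do not use
banker's rounding.

The bundled fixtures transcribe a published nine-locus plum study verbatim,
including its typographic quirks: one allele is printed in both the common
and the unique column, and the printed bold (rare) flags disagree with the
frequency rule in four places. The fixture keeps the printed categories and
an independent `printed_rare` flag; `classify_alleles()` on the fixture
preserves the printed partition and recomputes rare flags from the rule, so
the two can be compared. On ordinary frequency slices the partition is
computed by set membership over distinct (locus, size) pairs.

## Fragment-size binning

Capillary sizing returns fractional base pairs with run-to-run jitter
(shifts of a few bp between instruments are routine). `bin_fragment_sizes()`
clusters raw sizes by *constrained single linkage*: neighbours merge when
their gap is below `min_step / 2`, but never into a cluster spanning
`min_step` or more. The rationale: true alleles sit at least `min_step`
apart (default 2 bp, the dinucleotide repeat unit), so half the spacing is
the natural decision boundary, and the span cap prevents jitter clouds of
*adjacent* alleles from chaining into one bin. Labels are rounded cluster
medians, so pooling observations per locus across accessions — the standard
way allele bins are defined across sequencer runs, and what
`rebin_profiles()` does — centres each label on the true size. With 0.2 bp
jitter on a 2 bp grid this recovers the true integer alleles; recovery
degrades by design once jitter approaches the bin half-width (the package's
stress tests exercise 2.0 bp jitter).

## Minimal discriminating marker sets

The fingerprinting procedure adds loci in decreasing PIC order (ties broken
alphabetically, for determinism) until all genotype pairs are
distinguishable. "Separated" is formalized as pairwise profile inequality —
two accessions are resolved when some selected locus shows them different
allele sets — rather than as dendrogram topology, which is the testable
reading of the procedure. A missing call compares as a wildcard: a locus an
accession lacks cannot prove it distinct, which is conservative for
fingerprinting. `exhaustive_minimal_set()` enumerates subsets by size and
lexicographic order (up to 15 loci) and serves as the optimality oracle:
greedy never returns a smaller set than the optimum and always discriminates
when discrimination is possible.

## UPGMA and bootstrap

Distances are computed on the binary band matrix. Dice
(1 − 2a/(2a + b + c)) is the default, as the standard coefficient for
dominant marker data; Jaccard and simple matching are selectable. A
nucleotide-substitution distance (as reported in some published workflows
driven by sequence-analysis software) is not computable from fragment-size
band data, and this replacement is deliberate and documented. Missing loci
are pairwise-deleted; a pair with no comparable columns is an error.

UPGMA is size-weighted average linkage (delegated to `stats::hclust`, which
implements exactly that) with node height at half the merge distance, so
trees are ultrametric; ties are broken toward the lexicographically lowest
leaf pair by pre-sorting labels. Bootstrap support resamples matrix
*columns* (alleles — the character unit of dominant data) with replacement,
1000 replicates by default; locus-block resampling is available via
`unit = "locus"`. Support of a reference clade is the percentage of
replicate trees containing it; all values are retained, with 30 % recorded
as the conventional display threshold. Trees serialize to Newick via `ape`.

## The admixture model

`gibbs_fit()` implements the standard Bayesian admixture model for the
ploidy-6, -9-padded layout: each non-missing allele slot is an independent
allele copy whose cluster origin z follows the accession's admixture vector
Q, and whose allele follows the cluster's locus frequencies P. Priors are
Dirichlet(1) on every P block and a fixed symmetric Dirichlet(1) on Q (no
alpha updating) — a deliberate simplification of full STRUCTURE that is
adequate for ΔK behaviour. Missing slots are skipped everywhere. Because
each distinct allele occupies exactly one slot, nothing is double-counted;
dosage is ignored, the same approximation the dominant scoring itself makes.

The per-run model evidence `lnP` is estimated as mean − var/2 of the
post-burn-in data log-likelihood trace — the estimator the established
STRUCTURE/Harvester toolchain feeds to the Evanno method. The raw posterior
mean is kept as `lnP_mean`. The variance correction matters: with cleanly
separated populations the raw mean makes ΔK at K = 2 and at the true K
nearly indistinguishable, while the corrected estimator penalizes
over-fitted K through their inflated likelihood variance.

Evanno's ΔK(K) = |L(K+1) − 2L(K) + L(K−1)| / sd(L(K)) is computed over
replicate runs at consecutive K; it is defined only for interior K with at
least two runs, is invariant to shifting all lnP by a constant, and reports
+Inf with a warning when replicate runs have zero variance. Run grids derive
seeds deterministically (`seed_base`·1000 + K·100 + run), so every result is
bit-reproducible. Q matrices from replicate runs are aligned by greedy
column matching on correlation before averaging.

Published protocols use burn-in 200,000 with 500,000 iterations, ten runs,
K = 1–20; that is the `preset = "full"` configuration. Desk-scale analyses
and the package's own validation use burn-in 2,000 with 5,000 iterations,
K ≤ 6, five runs, which the C++ sampler completes in seconds per fit on a
45-accession data set.

## The synthetic generator

`sim_config()` defaults emulate the targeted study design: nine loci with
8–21 alleles each on a 2-bp grid (allele sizes in the ~100–260 bp range),
two groups of 14 and 6 accessions, ploidy 6. Group allele frequencies are
drawn from a symmetric Dirichlet whose concentration controls
differentiation; 0.5 (the default) gives moderately differentiated breeding
pools, while the three-population recovery experiments use 0.1 for strongly
disjoint-leaning frequencies. Each accession receives six i.i.d. allele
copies and is stored as the distinct set.

Pedigree crosses use a balanced hexaploid gamete model: each parent's
distinct-allele set is cycled to six copies, three copies are drawn without
replacement from each parent, and the union collapses to a set. Real
*P. domestica* meiosis is more complex, but the downstream analyses only
require offspring alleles to be a subset of the parental union, which this
model guarantees.

What the generator does *not* emulate: mutation, linkage between loci,
null alleles, and realistic coalescent history. Passing recovery tests on
these simulations therefore shows the pipeline's statistical machinery is
sound, not that any particular real germplasm will show the same
separability.

## Validation scale and limitations

The package's own experiments run at sizes chosen for tight feedback loops:
50 seeded panels (≤ 12 loci, ≤ 20 accessions) for the marker-selection
oracle; 1000-replicate bootstraps on ~20–45 accession matrices; ten
repetitions of the K = 1..6 × 5-run grid at desk scale for the Evanno
recovery experiment; ten seeded runs of three 4-offspring crosses for the
pedigree check. Known limitations: ΔK cannot select the boundary values of
the tested K range; Evanno selection on *symmetric* equally sized
populations is intrinsically close between K = 2 and the true K, which is
why the variance-corrected evidence estimator is the default; and the
greedy marker set is only guaranteed minimal when the top-PIC locus ordering
happens to be optimal — the exhaustive oracle exists precisely to audit
that.
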