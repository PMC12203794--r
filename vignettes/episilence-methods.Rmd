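---
title: "Methods: discovering epigenetically silenced tumour suppressors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering epigenetically silenced tumour suppressors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episilence)
```

## The scientific problem

Tumour cells can silence a tumour suppressor gene in two largely independent
ways: genetically, through loss-of-function (LOF) mutations or deep copy-number
deletions, or epigenetically, through aberrant DNA methylation of the gene's
promoter. When a *de novo* DNA methyltransferase such as DNMT3B is ectopically
activated in a tumour, it can hypermethylate CpG-rich promoter regions of
genes that are normally expressed in the healthy tissue, switching them off
without touching their DNA sequence.

`episilence` implements a complete discovery cascade for such epigenetically
silenced genes, designed around breast-cancer-style multi-omic data:

1. **Driver split.** Samples are dichotomised at the median expression of the
   driver gene (driver-high vs driver-low).
2. **EWAS.** Every methylation probe is tested for association between its
   β value and the driver group.
3. **DMR calling.** Per-probe p-values are aggregated into differentially
   methylated regions with a native combined-p caller (details below).
4. **Gene assignment.** Regions are assigned to genes through
   promoter-proximal probe classes (TSS200 / TSS1500 / 5′UTR), keeping only
   hypermethylated regions below a stringent Šidák-corrected threshold.
5. **Differential expression.** Genes down-regulated in driver-high samples
   (|fold change| above 1.5, Benjamini–Hochberg adjusted p < 0.05) are
   intersected with the hypermethylated genes to give candidate silenced
   genes.
6. **Survival consensus.** Each candidate is screened in every cohort with a
   Cox proportional-hazards model on standardised continuous expression *and*
   a log-rank test on the gene's own median split; a candidate is prognostic
   when both p-values fall below 0.05 with hazard ratio < 1 (higher
   expression protective) in at least 3 cohorts.
7. **Alteration ranking and stratification.** LOF mutation and deep-deletion
   frequencies rank the candidates; the top target is stratified into
   mutually exclusive METH / LOFDEL / CTRL sample groups.
8. **Pre-ranked GSEA.** Both inactivation groups are contrasted against the
   controls by fold-change-ranked gene set enrichment with gene-label
   permutation significance.

Because real tumour methylomes with matched clinical follow-up are
controlled-access, the package ships a synthetic multi-cohort generator with
planted ground truth; every stage is validated against what was planted.

## The combined-p DMR caller

The region caller re-implements the combined-p approach natively rather than
shelling out to an external tool, with every internal choice pinned and
testable:

**Per-probe test.** For probe $j$, the β values are regressed on the 0/1
group indicator by ordinary least squares — numerically identical to the
equal-variance two-sample t-test — giving a two-sided p-value $p_j$ on
$n - 2$ degrees of freedom. Missing β values are dropped pairwise; a probe
with fewer than two usable samples in a group is reported with $p = 1$ and an
`insufficient_data` flag rather than silently dropped, and a constant probe
returns $\Delta\beta = 0$, $p = 1$.

**Autocorrelation (ACF).** Nearby probes are correlated, so naive
combination would be anticonservative. We estimate the correlation of probit
scores $z_j = \Phi^{-1}(1 - p_j)$ as a function of genomic distance, in 50 bp
bins up to the window width (1000 bp by default): for each bin, the Pearson
correlation over all same-chromosome probe pairs whose separation falls in
the bin, clipped to $[0, 0.99]$. Bins with fewer than 10 pairs inherit the
nearest populated bin's estimate; a degenerate bin (zero score variance, e.g.
identical p-values everywhere) falls back to 0.99 and is flagged. Lag 0 is
defined as 1, and pairs farther apart than the maximum lag are treated as
uncorrelated — region members can be farther apart than the window, and
extrapolating the ACF beyond where it was estimated would be a guess. The
entire structure sits behind an `acf_estimate` object so a fixed ACF can be
injected (`constant_acf()`), which is also how the brute-force oracle tests
pin the correlation structure.

**Stouffer–Liptak combination.** Given p-values $p_1,\dots,p_k$ and a
correlation matrix $\sigma$,
$$z_{comb} = \frac{\sum_i z_i}{\sqrt{\sum_{ij}\sigma_{ij}}},\qquad
p_{comb} = 1 - \Phi(z_{comb}),$$
with p-values clamped to $[10^{-300}, 1-10^{-16}]$ before the probit so the
transform never overflows. A single p-value passes through unchanged; two
independent p-values of 0.5 combine to 0.5.

**Sliding window.** Each probe's p-value is replaced by the Stouffer–Liptak
combination over all probes within half the window width (±500 bp by
default) on the same chromosome, with $\sigma_{ij}$ looked up from the ACF
bin of the pair's separation. An isolated probe keeps its raw p.

**Region growth.** Regions are seeded at probes whose adjusted p falls below
`dmr_seed_p` (1e-5) and extended over consecutive probes with adjusted p
below `dmr_region_filter_p` (0.05) provided each inter-probe gap is at most
`dmr_dist` (1000 bp). Runs are maximal, so overlapping grown regions merge
automatically. Regions with fewer than `dmr_region_filter_n` (2) probes are
discarded. Direction is the sign of the members' mean $\Delta\beta$, with
ties resolved conservatively to hypo. Probes at equal positions are processed
in manifest order, making the grower deterministic.

**Region scoring.** The region's combined p uses the *raw* member p-values
(the windowed values would double-count the neighbourhood). The
multiple-testing correction is Šidák over the effective number of
same-width tests genome-wide:
$$p_{sidak} = 1 - (1 - p_{comb})^{B/w},$$
where $w$ is the region span in bp (minimum 1) and $B$ is the total span of
tested probes summed over chromosomes; the exponent is floored at 1. The
identity $1-(1-p)^k = -\mathrm{expm1}(k\,\mathrm{log1p}(-p))$ is used so the
correction does not underflow for very small $p_{comb}$. By construction
$p_{sidak} \ge p_{comb}$.

**Gene assignment.** A gene is called hypermethylated iff some region is
hyper-directional, has $p_{sidak}$ below `gene_dmr_p` (1e-5), and contains a
member probe annotated to the gene with a promoter-proximal class. A probe
annotated to several genes fans out to each of them, each judged against its
own region class — the array's annotation does not say which gene a
multi-gene CpG regulates, so the promoter-class filter does the
discrimination. The promoter is operationalised through the Infinium classes
TSS200/TSS1500/5′UTR rather than a fixed bp window around the TSS, because
the probe manifest carries exactly these classes; the class set is an
argument. Whether the gene threshold should apply to the corrected or
uncorrected region p is genuinely open; the default is the Šidák-corrected
value (the conservative choice) and the uncorrected value is retained on
every region.

## Survival screening

Kaplan–Meier estimation, the log-rank test, and Cox fitting are delegated to
the `survival` package (Breslow tie handling, Newton–Raphson with a 1e-9
coefficient tolerance and at most 50 iterations); the package's own tests
verify them against hand oracles (the product-limit calculation, an O−E/V
log-rank tabulation, and a one-dimensional grid search of the Breslow
partial likelihood). A non-converged or separated fit is returned flagged
with `p = NA` and counted non-significant, never thrown.

Two deliberate conventions:

* The Cox model uses *continuous standardised* expression (so hazard ratios
  are per SD and comparable across genes and cohorts), while the log-rank
  test uses the gene's own *median split*. Requiring both p-values below α
  combines the stronger power of the continuous model with the
  assumption-lean rank test.
* No cross-gene multiplicity correction is applied at this stage. The
  replication requirement — significance in at least `consensus_min_cohorts`
  of the cohorts, with HR < 1 each time — is the guard against false
  positives, and it is monotone: adding a significant cohort can never turn
  a passing gene into a failing one.

## Stratification and mutual exclusivity

The METH / LOFDEL / CTRL strata contrast the two silencing routes:

* **LOFDEL**: any sample with a retained-vocabulary LOF mutation
  (stop gained, start lost, frameshift, in-frame insertion/deletion,
  protein-altering; missense is deliberately excluded as functionally
  ambiguous) or a deep deletion (copy-number category −2; single-copy losses
  are excluded because one copy usually preserves expression — the category
  set is configurable).
* **METH**: driver-high samples whose target promoter mean β exceeds the
  90th percentile of the driver-low population *and* whose target expression
  is below the cohort median, minus any LOFDEL sample. The sample-level
  methylation rule is an operational construction (group-level
  hypermethylation does not dictate a per-sample cut-off); the quantile is a
  parameter so its influence can be examined.
* **CTRL**: driver-low samples with no genetic alteration of the target.

Genetic evidence takes precedence when both are present, which makes the
strata disjoint *by construction*; the code still asserts disjointness on
every input rather than assuming it, and the combined inactivation
percentage is checked to equal the sum of the two stratum percentages.

## Pre-ranked GSEA

Genes are ranked by the difference in mean log2(1+x) expression between the
two contrasted strata, ties broken deterministically (metric descending,
then symbol). The enrichment score is the classic weighted
Kolmogorov–Smirnov running-sum extremum with weight 1 by default (weight 0
gives the unweighted KS statistic used by the oracle tests). Significance
uses gene-label permutation — size-matched random sets drawn from the ranked
universe — because the ranking arrives pre-computed and phenotype
permutation is therefore unavailable. NES is ES divided by the mean
matching-sign permutation |ES|; the nominal p is add-one corrected; the FDR
q follows the NES-ratio procedure of the original GSEA method over the
pooled observed and permuted NES. Permutation pools are shared across sets
of the same size, which changes nothing statistically and makes the
permutation cost independent of collection size. A set is significant at
nominal p < 0.05 and FDR q < 0.25. Genes missing from the ranked universe
are dropped before scoring, and the intersected size is reported.

## The synthetic cohort generator

`simulate_multicohort()` generates the study conditions every test is run
under. Defaults: 8 cohorts of 300 samples over a 1000-gene universe (plus
the driver), 10 planted target genes, 5 promoter probes per gene spaced
200 bp apart, β shift `delta_beta = 0.3` in driver-high samples, expression
knock-down `expr_log2fc = 1` log2 unit with residual sd 0.3, hazard
coefficient −0.7 per SD of target activity, baseline hazard 0.1, 30%
censoring, and LOF lesions in 15% of driver-low samples.

Generative choices worth knowing:

* **β noise** is `Beta(mu*kappa, (1-mu)*kappa)` with concentration
  `kappa = 50`, so values respect $[0,1]$ without clipping artefacts and the
  group mean difference equals `delta_beta` exactly in expectation. Baseline
  probe means are uniform on $[0.15, 0.35]$, typical of unmethylated CpG
  island promoters; the configuration is rejected before sampling if the
  planted shift could push a mean out of range.
* **Expression noise sd 0.3** (log2 scale) reflects within-group variability
  of a moderately-to-highly expressed transcript after normalisation; with
  the planted 1 log2-unit knock-down this gives a clear but not trivial
  separation.
* **Survival** follows an exponential proportional-hazards model on the
  *functional activity* of the designated target (the first planted gene):
  genetic lesions leave the transcript level unchanged — a mutated mRNA is
  still expressed — so their survival effect is planted by discounting the
  carrier's activity by `expr_log2fc` before standardisation. The other
  targets share the driver-driven knock-down and therefore carry an
  attenuated, recoverable hazard association. Because the truth is an
  exponential PH model, the Cox coefficient has a known value for recovery
  tests.
* **Censoring** is independent uniform: censoring times are drawn from
  $U(0,\tau)$ with $\tau$ solved numerically so the expected censored
  fraction equals `censor_rate`. Independence from the covariates keeps the
  Cox estimand unbiased.
* **Mutual exclusivity is planted exactly**: lesions are placed only in
  driver-low samples, outside the methylation-silenced set, in every
  realisation.
* **Determinism**: every (cohort, table) pair draws from its own
  counter-derived RNG stream, so adding or regenerating one table never
  perturbs another, and identical configurations reproduce byte-identical
  bundles.
* **Subtype composition** skews driver-high samples towards basal-like and
  HER2-enriched labels and driver-low samples towards luminal labels, so the
  stratum composition tables have realistic structure.

What the generator does *not* emulate: batch effects, microarray-vs-RNA-seq
platform differences, segment-level copy-number structure,
subtype-specific expression programs, or enhancer methylation. Passing tests
therefore demonstrate that the pipeline's logic and statistics are correct
under a faithful generative model of the claimed mechanism — not that the
pipeline is robust to every artefact of real cohorts.

## Problem sizes used by the test suite

The suite exercises the pipeline at the scale the statistics need, kept
deliberately moderate: DMR oracle equivalence on 200 random instances of up
to 30 probes; null calibration on 40 global-null cohorts of 20,000 probes ×
200 samples (expecting uniform EWAS p-values and zero gene-level calls at
the 1e-5 threshold in ≥95% of seeds); end-to-end planted recovery on 20
seeds of the default 8-cohort, 300-sample design (expecting ≥90% recall of
planted genes and ≥0.9 stratum Jaccard in ≥90% of seeds); Cox recovery over
100 seeds at n = 500; GSEA null calibration over 200 random sets at 1000
permutations.

## Known limitations

* The ACF is assumed zero beyond the window width; comb-p-style tools
  sometimes extrapolate instead. Both choices are defensible; ours is
  isolated behind the `acf_estimate` seam.
* The sample-level METH rule (90th-percentile β threshold plus below-median
  expression) is one reasonable operationalisation of "hypermethylated and
  down-regulated"; cohorts with a weak driver split will blur it.
* The consensus filter treats cohorts symmetrically; no weighting by cohort
  size or event count is attempted.
* Fold changes are computed as differences of mean log2(1+x) values
  (pseudocount-free and reproducible), not ratios of linear-scale means;
  with strong outliers the two differ.
* The Methods-level choice between a t-test and a Mann–Whitney test for
  differential expression is data-dependent in practice; both are
  implemented (`de_test`), Welch t is the default, and the choice is echoed
  in output headers.
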