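---
title: "Methods: ABO blood-type inference and downstream association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ABO blood-type inference and downstream association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abostroke)
```

## The problem

ABO blood type is determined by the *ABO* glycosyltransferase locus on
9q34.2. O alleles are loss-of-function, so an individual is blood type O
exactly when both chromosomes carry an O allele. Two variants tag
essentially all O alleles: the single-base deletion c.261G>del
(rs8176719), which frameshifts the enzyme ("deletional" O), and the
missense c.802G>A ("nondeletional" O). Given diploid sequencing genotypes
at these two sites, the package infers each person's O/non-O type and
feeds the calls into stroke-subtype association, plasma-proteome
comparison, and cholesterol-handling assay calculations.

## Genotype quality control

A genotype call at either site is accepted when read depth DP >= 9 and
genotype quality GQ >= 20; heterozygous calls additionally need allele
depth AD >= 3 supporting reads. The AD rule is stated for "an allele"
without saying which; we require **both** observed alleles to reach 3
reads, the conservative reading — a heterozygote supported by 2 reads on
one side is exactly the kind of call the filter exists to remove. Missing
FORMAT subfields fail QC rather than defaulting, and in multiallelic
records only the configured REF/ALT pair is interpreted (any other ALT in
a genotype makes it missing): the typing model is defined over exactly two
biallelic sites, and re-normalising indel representations is out of scope
— the VCF representation of the c.261 deletion is matched as declared in
the locus configuration.

QC failure is a state, not an error: `apply_qc()` only sets a flag, which
makes it idempotent and monotone in the thresholds (both properties are
tested). A sample failing QC at either site receives a **missing**
blood-type call rather than a default of non-O; the source cohort design
excluded un-sequenceable samples, and silently defaulting them would bias
the O fraction downward.

## Haplotype phasing: exact two-locus EM

With two biallelic sites there are four haplotypes,
$h \in \{rr, ra, ar, aa\}$ at (c261, c802), with frequencies $f_h$. Under
Hardy–Weinberg equilibrium the nine two-locus genotype classes are
multinomial, and the only phase-ambiguous class is the double
heterozygote, which is either *cis* $(rr, aa)$ or *trans* $(ra, ar)$. The
EM algorithm iterates

$$w = \frac{f_{rr} f_{aa}}{f_{rr} f_{aa} + f_{ra} f_{ar}}, \qquad
  f_h \leftarrow \frac{e_h + n_{dh} \cdot w_h}{2n},$$

where $e_h$ counts haplotypes fixed by the eight unambiguous classes,
$n_{dh}$ is the double-heterozygote count and $w_h$ splits it between the
cis and trans pair. This is the exact maximum-likelihood solution for the
two-site problem — population-scale HMM phasing adds machinery (reference
panels, recombination maps, switch-error modelling) that a two-locus
diplotype does not need, and replacing it removes an external binary from
the pipeline. The trade-off is deliberate and visible: the package phases
two sites and nothing else.

Numerical choices:

* **Initialisation** is the product of observed allele frequencies
  (linkage-equilibrium start); no randomness anywhere, fixed iteration
  order. If that start puts zero mass on an observed class (possible when
  an allele is absent from one stratum), it is nudged off the simplex
  face by mixing 0.1% of the uniform.
* **Convergence** when the largest per-haplotype change is below `tol`
  (default 1e-8), capped at 1000 iterations. The log-likelihood trace is
  kept and tested to be non-decreasing.
* **Unidentifiable corner**: a cohort consisting solely of double
  heterozygotes cannot distinguish cis from trans; from a uniform start
  the EM stays at the symmetric stationary point (0.25 each). This is
  reported, not resolved.
* **Degenerate posteriors**: if both cis and trans products are zero for
  a double heterozygote, the diplotype posterior falls back to 0.5/0.5
  with a warning.

An independent check matters for an estimator like this, so the package
also ships `grid_search_haplotype_frequencies()`: an exhaustive scan of
the multinomial likelihood over the frequency simplex at step 0.001
(~1.7e8 points, compiled; the likelihood reduces to four table lookups
plus one logarithm per point). The test suite and the acceptance script
verify the EM lands within 0.005 per haplotype of the grid optimum on a
200-sample cohort.

## Blood-type calling

Per haplotype: any c.261 deletion makes the allele `O_deletional`
(the frameshift truncates the enzyme regardless of downstream variants —
the rare del+802A haplotype is classified deletional for that reason);
c.802A on an intact c.261 background is `O_nondeletional`; neither
variant means a functional (non-O) allele. Per sample, each diplotype
configuration is classified (O iff both alleles are O alleles), the
reported type is that of the maximum-probability configuration, and the
posterior is the summed probability of configurations sharing that type.
Calls are hard by default (`min_posterior = 0`); the posterior column
lets downstream tables filter if desired.

## Association machinery

* **Contingency tables**: counts of blood type by category with
  within-row percents rounded half-up to 2 decimals (table convention),
  and the uncorrected Pearson chi-square of independence,
  $\sum (O - E)^2 / E$ with $(r-1)(c-1)$ degrees of freedom. No
  continuity correction by default — the primary use is the df = 4
  omnibus test over five stroke subtypes; a Yates flag exists for 2x2
  tables. A zero expected cell is an error instructing category collapse.
* **Odds ratios**: $ad/bc$ with Woolf's log-normal 95% CI; any zero cell
  triggers the Haldane–Anscombe +0.5 correction.
* **Wilcoxon rank-sum** for continuous baselines: midranks for ties. For
  `min(n) < 20` the null distribution is computed *exactly* by dynamic
  programming over doubled midranks — identical to enumerating all
  $\binom{N}{n_1}$ assignments (tested against literal enumeration up to
  group size 8) but polynomial-time, so exactness does not collapse under
  ties. Above that, the normal approximation with tie-corrected variance
  and 0.5 continuity correction (cross-checked against
  `stats::wilcox.test`). The exact branch additionally caps total N at
  200, beyond which the DP table stops being worthwhile and the normal
  approximation is already excellent. The two-sided p-value is the null
  probability of a rank sum at least as far from its mean as observed,
  which makes it symmetric under group relabelling.
* **Multiple testing**: none by default across baseline variables (raw
  p-values are reported, matching the source analysis); missing biomarker
  values are dropped pairwise per variable.

## Proteomics

Per protein, a two-sample t-test on log2 intensities — Welch by default,
since equal group variances are an assumption nothing here guarantees; a
Student flag exists. The effect is `log2fc = mean(log2 O) − mean(log2
non-O)`. A protein is `up` when `p < 0.05` and `log2fc > 1.2`, `down`
symmetrically. The published threshold phrase "log2-fold change exceeding
1.2" is ambiguous between the log2 scale (|log2FC| > 1.2, fold change
2.3x) and the linear scale (fold change > 1.2x, |log2FC| > 0.26); the
literal log2 reading is the default and `fc_scale = "linear"` switches.
Zeros and missing intensities are imputed with half the per-protein
minimum positive value before the log — a standard floor that keeps the
transform defined without inventing signal. Proteins constant in both
groups are flagged and excluded from classification rather than producing
NaN statistics.

Enrichment is a hypergeometric upper-tail test of the significant set
against each GMT term, with all detected proteins as background, terms
intersected with the background first, and terms below 3 in-background
members skipped. Q-values are Benjamini–Hochberg: deterministic and
parameter-free, where a Storey-type FDR estimate would add a tuning
parameter for no benefit at these term counts (the reports name the
method). Both the hypergeometric tail and the BH step-up are tested
against enumeration/brute-force oracles.

## Assay calculators

Efflux percentage is `100 * FI(medium) / (FI(medium) + FI(lysate))`;
replicates are aggregated as the mean of per-replicate percentages, not
the percentage of summed fluorescence (the former is the plate-assay
convention and weights replicates equally). Background subtraction is
available via a `blank` argument but off by default since no blank values
are modelled. Relative expression is the standard $2^{-\Delta\Delta
C_t}$ with GAPDH as reference; uptake reduction is
`100 * (control − treated) / control`, negative when treatment increases
uptake.

## What the simulator emulates — and what it does not

`gen_genotypes()` draws haplotype pairs iid from the configured
frequencies, then simulates reads: depth Poisson(60), allele reads
binomial with a 0.5% per-read error, genotypes called by maximum
likelihood with GQ as the capped phred likelihood ratio. Defaults were
chosen once to mirror the target population: O-genotype fraction 29.5%
(O-allele frequency 0.543), with the nondeletional O allele rare
(`ra = 0.005`) as in East-Asian populations. At depth 60 miscalls are
below 0.1%, so QC behaviour is probed by lowering depth, not by tuning
error rates. `gen_cohort_labels()` draws CCS subtypes from
blood-type-conditional multinomials (defaults: the published row
percents) and log-normal biomarkers — LDL-C with a small non-O location
shift (medians 2.3 vs 2.4 mmol/L, sdlog 0.42 from the printed IQRs), CRP
as a null biomarker. `gen_proteome()` plants 17 up / 42 down proteins
out of 974 at |log2FC| = 2 with residual SD 0.5 over 30 samples per
group, and builds a GMT whose planted term contains true-DE proteins at
three times the background rate.

The simulator does **not** model linkage with flanking markers, real
read alignment artefacts (indel realignment error at the c.261 deletion,
strand bias), batch structure in the proteome, or the correlation
structure of real clinical biomarkers. Passing tests therefore
demonstrate that the *algorithms* are correct under their stated
assumptions, not that real cohort data would be this clean. In
particular, the published cohort's specific numbers that depend on raw
data that was never released — the 17-up/42-down protein identity, the
baseline biomarker p-values, the healthy-control blood-type split, the
figure-level uptake/efflux percentages — are not reproduction targets;
the property-based suites cover the machinery instead.

## Problem sizes used in the checks

The repeated-simulation checks use: 200 samples for the EM-vs-grid
comparison (grid step 0.001); 20 seeds x 1,000 samples for typing
recovery; 2,000 null cohorts of 500 for test calibration; 50 cohorts of
9,542 for association power; 10 seeds for differential-expression
recovery and 100 seeds for enrichment ranking. These sizes put the Monte
Carlo error comfortably inside each criterion's band while keeping a
full run in tens of seconds.

One power figure deserves a note: resampling the published joint
blood-type x subtype distribution at n = 9,542 makes the Pearson
statistic noncentral chi-square with noncentrality equal to the table's
own statistic (27.15), so the exact rejection probability at
alpha = 1e-4 is 0.746 — the calibration test checks the empirical rate
against that closed form rather than against an arbitrary high bar, and
verifies near-certain rejection (0.994) at alpha = 0.05.

## Known limitations

* Only O vs non-O: A/B/AB subtyping would need additional *ABO* variants
  and is out of scope.
* The EM assumes Hardy–Weinberg; strong inbreeding or population
  stratification would bias the diplotype posteriors (though hard calls
  for the 94%+ of samples that are phase-unambiguous are unaffected).
* Exact Wilcoxon p-values are limited to total N <= 200; larger
  unbalanced designs fall back to the normal approximation.
* GO-style term relationships (parent propagation) are not modelled; the
  enrichment treats terms as flat sets.
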