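# abostroke

ABO blood-type inference from sequencing genotypes, with the downstream
analyses that connect blood type to ischaemic-stroke subtype and
cholesterol metabolism: contingency-table association against CCS stroke
subtypes, thresholded differential proteomics with term enrichment, and
calculators for cholesterol-uptake/efflux and qPCR assays. It is written
for population-genetics / clinical-epidemiology analysts who have VCF
genotype calls at the two *ABO* typing sites and want reproducible O/non-O
calls plus the standard battery of comparisons, all testable end to end on
synthetic data with known truth.

## The model

Two variants tag the O alleles of *ABO* (9q34.2): the frameshift deletion
c.261G>del (rs8176719, "deletional" O) and the missense c.802G>A
("nondeletional" O). With four possible two-locus haplotypes
*h* ∈ {rr, ra, ar, aa} and frequencies *f_h*, Hardy–Weinberg makes the
nine observable genotype classes multinomial; the only phase-ambiguous
class is the double heterozygote (cis (rr,aa) vs trans (ra,ar)). The
package estimates *f* by the exact two-locus EM

> w = f_rr·f_aa / (f_rr·f_aa + f_ra·f_ar),  f_h ← (e_h + n_dh·w_h) / 2n

assigns each sample a diplotype posterior, classifies alleles
(del ⇒ O_deletional; 802A on intact 261 ⇒ O_nondeletional; else non-O),
and calls type O exactly when both alleles are O alleles. Genotypes first
pass the calling filters DP ≥ 9, GQ ≥ 20, and AD ≥ 3 on both alleles for
heterozygotes; samples failing either locus are reported missing, not
defaulted.

Downstream: Pearson chi-square (uncorrected, df = (r−1)(c−1)) for
blood-type × subtype tables; Wilcoxon rank-sum with exact
enumeration-equivalent p-values for small groups and tie-corrected normal
approximation otherwise; odds ratios ad/bc with Woolf CIs; per-protein
Welch t-tests on log2 intensities with volcano thresholds (p < 0.05,
|log2FC| > 1.2); hypergeometric over-representation with
Benjamini–Hochberg q-values; and the deterministic assay formulas
(efflux % = 100·FI_medium/(FI_medium+FI_lysate), 2^−ΔΔCt, percent
reduction).

## Worked example

```r
library(abostroke)

# simulate a 2,000-sample cohort with truth, then type it from the VCF
cfg <- sim_config(n_samples = 2000, seed = 20260921)
sim <- gen_genotypes(cfg, "cohort.vcf")
res <- blood_type_pipeline("cohort.vcf")

round(res$freqs, 4)
#>     rr     ra     ar     aa
#> 0.4723 0.0037 0.5225 0.0015
mean(res$calls$blood_type == sim$truth$blood_type)
#> [1] 0.9985

# the published blood-type x CCS-subtype counts ship as a fixture
tab <- ccs_table1_counts()
round_half_up(100 * tab / rowSums(tab), 2)
#>           subtype
#> blood_type   LAA   CE   SAO   OE    UE
#>      O     25.12 6.85 28.59 0.74 38.70
#>      non_O 30.19 7.07 26.33 0.82 35.59
chi_square_test(tab)$p_value
#> [1] 1.850721e-05
```

The haplotype frequencies recover the simulator's truth (0.457, 0.005,
0.535, 0.003) within sampling error; typing accuracy is 99.9% at mean
depth 60, with the residual errors being double heterozygotes whose
maximum-posterior phase is the rarer configuration. The row percents and
omnibus p reproduce the published table: non-O patients are
over-represented in large-artery-atherosclerosis stroke (30.19% vs
25.12%).

The `analysis/` directory chains the stages as numbered drivers
(`01_simulate_cohort.R` → `05_assays.R`), each writing its tables under
`results/`.

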