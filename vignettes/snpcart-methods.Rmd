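---
title: "Methods: pathway SNP association, cumulative risk and CART in snpcart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway SNP association, cumulative risk and CART in snpcart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(snpcart)
```

## The analysis model

`snpcart` implements a candidate-gene case-control analysis for SNP panels
of a few hundred markers. Genotypes are stored as variant-allele counts
$g \in \{0, 1, 2\}$ (the variant allele is fixed by annotation, not by
which allele happens to be minor in a given stratum, so the coding cannot
flip between cases and controls). Disease association for SNP $j$ is
modelled by unconditional logistic regression

$$\operatorname{logit} P(Y = 1) = \beta_0 + \beta_j\, c_m(g_j)
  + \boldsymbol{\gamma}^\top \mathbf{z},$$

where $\mathbf{z}$ holds age (continuous), ethnicity indicators (reference
White) and smoking indicators (reference Never), and $c_m$ is one of three
genetic codings: dominant $c(g) = \mathbf 1[g > 0]$, recessive
$c(g) = \mathbf 1[g = 2]$, additive $c(g) = g$. The reported OR is
$e^{\beta_j}$ with a Wald 95% CI; for the additive coding this is a
per-allele OR. The *best-fitting model* is the coding with the smallest
Wald p; ties (measure-zero with continuous p) break toward additive, then
dominant, then recessive, preferring the codings with more power and fewer
degenerate-cell pathologies.

Unconditional (not conditional) regression is appropriate because the
emulated design frequency-matches controls in aggregate rather than
pairing them individually.

### The rare-homozygote rule

When the homozygous variant genotype is carried by fewer than
`min_homozygote = 5` subjects in cases *or* in controls, only the dominant
model is fitted (`note = "dominant_only"`). This rule is conventionally
stated as a "less than five" floor that can read as either a count or a
percentage; the count reading is
the default because five *subjects* is the conventional sparse-cell floor
for a Wald test, and a `hom_rule = "percent"` option preserves the other
reading.

## Quality control

Hardy-Weinberg equilibrium is tested in **controls only** with a 1-df
Pearson goodness-of-fit chi-square against $(\hat p^2, 2\hat p\hat q,
\hat q^2)$, no continuity correction ($\hat p$ estimated from the same
counts, hence one df). Departure in controls flags genotyping artefacts;
cases are excluded because true associations distort case genotype
frequencies. SNPs with control HWE $p < 0.01$ are removed. MAF and
call-rate floors exist but default to 0 (pass-through), since the emulated
study applied those filters at array design time, not at analysis time.
Monomorphic SNPs get $\chi^2 = 0$, $p = 1$ and a flag rather than an
error.

## Multiplicity

Pairwise LD is the squared Pearson correlation of genotype dosage vectors
(composite LD; phase is unknown, and at candidate-gene scale the dosage
$r^2$ is an adequate redundancy measure). Pruning is greedy by
significance: SNPs are visited in ascending p order and dropped if
$r^2 > 0.8$ with any retained SNP, so the more significant member of a
correlated pair survives; the output is invariant to input order for
distinct p-values. Pruning precedes adjustment.

q-values are Benjamini-Hochberg step-up values,
$q_{(i)} = \min_{j \ge i} m\, p_{(j)} / j$ clipped to 1. A Storey-type
option (fixed $\lambda = 0.5$) exists, but BH is the reference behaviour:
$\pi_0$ estimation is unstable at the $m \approx 50$ scale this pipeline
sees after restriction to significant SNPs.

## Bootstrap internal validation

Each selected association is refit on `B = 100` resamples of whole
subjects (cases and controls pooled, original size, with replacement), and
the counts of resamples with $p < 0.05 / 0.01 / 0.001$ are reported.
Resamples with a monomorphic SNP or a separated fit count as *not*
significant (conservative). A master seed spawns a per-SNP substream
keyed on the SNP id, so results do not depend on panel order.

One calibration fact worth knowing: for a **null** SNP the expected
fraction of significant resamples is *not* 5%. The bootstrap Wald z is
approximately $N(z_{\text{obs}}, 1)$ and $z_{\text{obs}} \sim N(0,1)$
across null SNPs, so the expected fraction is
$2\Phi(-1.96/\sqrt 2) \approx 0.166$. The test suite asserts this band
rather than the naive binomial one.

Group-level ORs (cumulative and CART stages) get percentile bootstrap CIs
(2.5/97.5) from `ci_B = 10000` resamples; resamples with an empty
reference group are redrawn with a retry cap. On the bundled cumulative
fixture the percentile CI agrees with the printed Wald CI within ~10% on
both endpoints (the upper endpoint sits ~6% high — percentile intervals
are right-skewed when the reference arm is small).

## Cumulative unfavorable-genotype analysis

For each significant SNP the *unfavorable* group is the side of its
best-model dichotomy with the higher case odds: the variant-carrying group
if OR > 1, its complement if OR < 1; additive SNPs use the carrier split
oriented the same way; OR exactly 1 excludes the SNP. Subjects are scored
by the number of unfavorable genotypes they carry (missing genotypes
contribute 0), grouped at nearest-rank 25/50/75 percentiles of the pooled
score with tied cuts collapsed upward, and each group's adjusted OR versus
the lowest group is estimated; the trend test is the Wald test on a
0-based ordinal group index in an adjusted logistic fit (not
Cochran-Armitage, so covariate adjustment is uniform across stages).

The SNP panel entering this stage defaults to the q-significant set, with
a `rule = "p"` option; the emulated study's Table-3 score range (3-12 over
12 SNPs) pins the default. One honest caveat: the published group sizes
are *not* exact quartiles of any count distribution (the reference group
holds 12% of subjects), so the printed boundaries cannot be recovered by
quartile arithmetic from the printed sizes alone; `group_or_trend()`
accepts explicit boundaries for exactly this situation.

## CART

Candidate splits are the two carrier collapses per SNP (WW vs WV+VV,
WW+WV vs VV) — the only split shapes the emulated analysis exhibits —
scored by the 1-df Pearson chi-square p on the dichotomy-by-status table
within the node. Growth is deterministic: the minimum-p split is applied
while $p < 0.05$, both children hold at least `min_node_size = 20`
subjects, and depth is under `max_depth = 10`; ties break by panel order
then dichotomy order. The proprietary reference implementation's exact
stopping rule is unpublished; p < 0.05 plus a size floor of 20 (just below
the smallest published terminal node, 24) is the assumed contract. Missing
genotypes follow the majority child. Terminal nodes are numbered by
ascending case fraction, node 1 serving as reference; node ORs come from
the same adjusted logistic machinery as every other stage, and a node with
zero controls is flagged infinite rather than fitted.

Decreasing the growth alpha can only remove splits, so terminal-node
counts are monotone in alpha — a property the suite checks, along with
exact child-count additivity and oracle equivalence of every reported
split p.

## The synthetic cohort: what it does and does not emulate

`simulate_cohort()` draws a large source population (default sized
$2.5\,n_{\text{cases}}/\text{prevalence}$), assigns disease by a logistic
model with intercept `qlogis(0.1)` by default and the configured per-SNP
effects under their stated codings, samples cases from the affected pool,
and frequency-matches controls on ethnicity (exact) and age (±5 years) by
rejection sampling; when a particular case has no remaining compatible
control, another case is substituted (frequency matching constrains
distributions, not pairs), and the generator errors only when no
compatible control exists at all.

Defaults state the emulated world: 417/417 subjects, 587 SNPs in 65
genes, MAF uniform on [0.05, 0.5] (the array design floor), ages around
60.5 ± 10.5 years, ethnicity ~82% White / 11.5% Hispanic / 4.5% Black / 2%
Other and smoking ~68.5% never / 23% former / 8.5% current (control-arm
frequencies of the emulated cohort), no covariate effects on disease
(matching removes the confounding the covariates would otherwise need to
carry).

LD blocks use a latent-Gaussian haplotype construction: two equicorrelated
standard-normal draws per subject, thresholded at $\Phi^{-1}(\text{MAF})$,
summed to a dosage. The latent correlation is calibrated by solving the
bivariate-normal orthant equation so the *indicator* correlation hits
$\sqrt{r^2_{\text{target}}}$ at the block's mean MAF — approximate when
MAFs vary within a block, which is why `ld_block_r2_check()` exists and
the calibration test requires the achieved mean $r^2$ within ±0.05 at
n = 10,000.

Not emulated: population stratification, genotyping error, missingness
mechanisms (missing calls exist only in hand-built fixtures), haplotype
phase. A green synthetic test therefore establishes estimator correctness
and pipeline plumbing under the stated generative model — not robustness
to the artefacts real arrays produce.

## Numerical choices

* Logistic fits use `stats::glm.fit`; separation is declared when any
  $|\beta| > 15$ or a fitted probability reaches 0/1 within $10^{-10}$,
  and flagged results carry NA estimates instead of raising.
* Crude 2×2 ORs apply the Haldane-Anscombe +0.5 to **all four cells only
  when some cell is zero**; a still-empty denominator yields an
  infinite-OR flag, not an exception.
* Chi-square statistics are computed in double precision from the margin
  formula (the printed-table counts overflow 32-bit integer arithmetic in
  $(ad-bc)^2$).
* All randomness descends from one master seed through named substreams
  (`genotypes`, `covariates`, `status`, `matching`, per-SNP bootstrap), so
  stages are individually reproducible; derived seeds stay below $2^{31}$.

## Scaling of the test suite

The replication-heavy checks (parameter recovery, global-null calibration,
CART interaction recovery) run at 60 cohorts / 4,000 null SNPs / 60
replications instead of the 200 / 10,000 / 200 a full study would use, to
keep the default suite within a single-CPU budget; acceptance thresholds
are identical. The deterministic estimator checks against the bundled
published contingency tables are exact and cheap.
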