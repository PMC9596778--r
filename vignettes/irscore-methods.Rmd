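---
title: "Immune-related signature scoring: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune-related signature scoring: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Tumor cohorts differ widely in how strongly the immune compartment shapes
outcome. `irscore` implements a stratification pipeline built on that idea:
score every sample for a collection of immune-related transcriptional
signatures, keep the signatures whose enrichment is reproducibly associated
with recurrence-free survival across several independent cohorts, and
combine the survivors into a single per-sample score — the immune-related
signature score (IRScore) — that splits each cohort into a high and a low
group at its median.

The package implements every statistical step itself (single-sample
enrichment, the two-group Cox model, the log-rank test, the Kaplan-Meier
estimator, inverse-variance meta-analysis) and validates each against
independent oracles and, where available, reference implementations
(`survival`, `metafor`) in the test suite.

# Single-sample enrichment

Two per-sample enrichment algorithms are provided.

**ssGSEA.** Within one sample, genes are ranked by expression. Walking the
ranked list top-down, the score accumulates the difference between the
weighted cumulative distribution of signature genes ("hits", weighted by
rank value to the power $\alpha$, default $\alpha = 0.25$) and the uniform
cumulative distribution of the remaining genes:
$$ES = \sum_{i=1}^{N}\left[P^w_{hit}(i) - P_{miss}(i)\right].$$
Only within-sample ranks matter, so any strictly increasing per-sample
transform of the expression values leaves scores unchanged — the practical
reason bulk arrays, RNA-seq log-TPM and counts can all be scored. Ties take
average rank values; walk order among tied values falls back to
lexicographic gene ID, making results deterministic.

**GSVA.** Per gene, the sample-level expression distribution is estimated by
a Gaussian kernel CDF with bandwidth $s_g/4$; per sample, genes are ranked
by that estimate and converted to the symmetric statistic $|N/2 - r|$; a
weighted Kolmogorov–Smirnov walk down the ranked list yields the score as
maximum positive deviation plus maximum negative deviation (the `mx.diff`
convention). Because the kernel CDF is cross-sample, GSVA requires at least
three samples and is *not* a pure single-sample statistic; with fewer
samples the package directs you to ssGSEA.

The pipeline default is GSVA, matching the default of the enrichment tooling
this design descends from; the large simulation experiments in this package
run with ssGSEA, which admits a closed-form per-signature score (the running
sum telescopes to a weighted mean of "steps remaining") and is orders of
magnitude cheaper at hundreds of replicated cohorts. Both are exposed and
interchangeable; the choice is recorded in the run manifest.

**NES.** Raw scores are z-scaled per signature *within one cohort* (sample
standard deviation, ddof = 1). Zero-variance rows become all-zero and are
flagged rather than dropped. Scaling is never pooled across cohorts — each
cohort is scored and dichotomized on its own scale, and the same rule
applies when a frozen signature list is transferred to a validation cohort.
Whether scaling pooled or per-cohort data in the original design is not
determinable; per-cohort is the package's documented choice, consistent
with per-cohort Cox screening.

# Survival machinery

All survival statistics operate on a median split: samples with values
strictly above the cohort median are "high", ties at the median go "low"
(deterministic, and consistent with "higher than the median" defining the
high group).

The two-group Cox model maximizes the partial likelihood by Newton–Raphson
with the Efron tie correction (Breslow selectable), converging at
$|\Delta\beta| < 10^{-8}$ with at most 50 iterations, standard errors from
the observed information. A monotone likelihood (all events drifting to one
arm) is detected by divergence of the estimate; the fit is flagged, the log
hazard ratio reported as signed infinity, and the p-value falls back to the
score test at $\beta = 0$ — which, on tie-free data, is exactly the log-rank
chi-square (an identity the tests verify to $10^{-8}$). Non-converged fits
are excluded from meta-analysis rather than imputed.

The Wilcoxon comparison of two independent groups is implemented as the
rank-sum (Mann–Whitney) test with normal approximation and tie correction;
a signed-rank variant exists for genuinely paired inputs. (A signed-rank
test requires pairing, which independent high/low groups lack; the package
documents this rather than resolving it silently.)

# Meta-analytic selection

Per signature, converged per-cohort log hazard ratios are pooled by inverse
variance. The default is the DerSimonian–Laird random-effects model:
$$\tau^2 = \max\!\left\{0,\; \frac{Q - (k-1)}{\sum w - \sum w^2 / \sum w}\right\},
\qquad w_i = 1/se_i^2,$$
with $I^2 = \max(0, (Q - (k-1))/Q)\cdot 100$. The fixed-effect estimate is
always reported alongside; selection uses the default model's p-value.
Random effects is the package default because cohort heterogeneity
(platforms, populations) is the norm in multi-cohort transcriptomics; with
homogeneous cohorts $\tau^2$ truncates to zero and the two models coincide.

Selection keeps signatures with pooled $p < 0.05$ (raw, no multiplicity
correction — mirroring the screening rule the score descends from; a
Benjamini–Hochberg switch exists but is off by default) and classifies them
as prognostically *good* (pooled HR < 1) or *bad* (HR > 1).

# IRScore

For each sample,
$$IRScore = \sum_{i=1}^{M} NES_i - \sum_{j=1}^{N} NES_j,$$
summing NES over the $M$ good signatures and subtracting the $N$ bad ones —
algebraically a dot product of the NES column with a $\pm 1$ direction
vector, which is how the test suite verifies it. Stratification is again a
per-cohort median split. When a frozen verdict list is applied to a new
cohort (the immunotherapy-validation use-case), NES is recomputed within
the new cohort and the same signed sum applied; the verdict list travels in
the run manifest so scoring is reproducible.

# Cell-level scoring and DP/DN analysis

Cluster- and patient-level scores average expression within labels
(clustering itself is consumed as input, never computed here). Per-cell
scores use ssGSEA over each cell's *nonzero* genes by default: with
zero-inflated counts, ranking the full gene universe makes the tied zero
block dominate the walk; restricting to detected genes preserves contrast.
A rank-all-genes mode is available for comparison. Signatures with fewer
than two matched genes among a cell's detected transcripts contribute a
raw score of zero and are counted in a flag.

Cells are classified by the CD103 (ITGAE) / CD39 (ENTPD1) markers: DP if
both exceed the positivity threshold, DN if neither, SP otherwise. The gate
defaults to zero on counts (any detected transcript counts as expressing);
no quantified gate is available from the score's provenance, so the
threshold is a recorded configuration field, not a claimed constant.
Cluster-level enrichment of DP over DN membership uses the odds ratio with
the Haldane–Anscombe +0.5 correction applied only when a zero cell exists,
and a two-sided Fisher exact p computed from the conditional hypergeometric
distribution (verified against full enumeration for every table with total
at most 40).

# Cytometry preprocessing

Ion intensities are arcsinh-transformed with cofactor 5
($x \mapsto \mathrm{asinh}(x/5)$), then rescaled per marker to $[0, 1]$
using the 99th percentile (linear-interpolation convention, "type 7") as
the maximum and the observed minimum as the floor. The observed minimum —
rather than zero — is the floor because post-arcsinh intensities can be
negative. Markers whose cap equals their floor are zeroed and flagged.
Subsampling draws a fixed number of events per sample (default 1000)
uniformly without replacement under a seed. Cluster frequencies are
per-sample proportions within the declared parent population; unions of
clusters (e.g. all CD103+CD39+ T-cell clusters) are supported as composite
populations whose frequency is the member sum, and groups are compared by
the rank-sum test.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; it is first-class, tested code.

**Bulk cohorts.** Per cohort and planted signature $s$, a latent activity
$a_{s,j} \sim N(0,1)$ per sample $j$; signature genes follow
$x_{g,j} = \mu_g + \lambda a_{s,j} + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$, background genes $\mu_g + \varepsilon$,
with baselines $\mu_g \sim N(6, 1)$ on a log2-array-like scale. Survival is
exponential proportional hazards by inverse-transform sampling,
$T_j = -\log U / (h_0 e^{\eta_j})$ with
$\eta_j = \sum_s d_s \beta a_{s,j}$, $d_s = -1$ for good and $+1$ for bad
signatures, and independent exponential censoring. Good signatures are
coded $-1$ so that a *high* planted activity lowers the hazard — the
pipeline must then produce pooled HR < 1 for them through its own Cox and
meta-analysis steps, rather than having the direction asserted. Defaults
are the headline conditions: 7 cohorts of 200 samples; 20 good, 20 bad and
60 null signatures of 10 genes each plus 200 background genes;
$\beta = 0.8$, $\lambda = 1$, $\sigma = 1$, $h_0 = 0.1$, censoring rate
0.05. Each cohort runs on substream seed `seed + k`, so adding a held-out
cohort never perturbs the discovery cohorts.

With 40 planted effects of $\beta = 0.8$ the latent linear predictor has a
standard deviation of about 5 — any single signature explains a small slice
of a very heterogeneous hazard, so each marginal median-split Cox fit is
heavily attenuated by the unmodeled remainder. That is deliberate: it makes
recovery a meaningfully hard multi-cohort problem rather than a
single-cohort power calculation.

**Single cells.** Negative-binomial counts (size 2) with cluster-specific
gamma-distributed means; DP/DN/SP fractions default to 0.462 / 0.133 (the
remainder SP), matching the composition scale of the T-cell data this
module mirrors. The two marker genes are noiseless by default — exactly the
shift value where positive, zero where negative — so classification can be
validated against ground truth exactly; a noisy-marker mode exists. DP
cells receive an up-shift on a designated cytotoxic/exhausted signature
block, so per-cell scores should separate DP from DN through the full
scoring path.

**Cytometry.** Per-sample cluster compositions are Dirichlet draws
(concentration 50) around group-level bases; the high group's target
cluster is raised by $\Delta$ (default 0.15), taken proportionally from the
others; intensities are log-normal around cluster centers on the raw
nonnegative scale. Defaults (6 vs 7 samples, 8 clusters, 500 events per
sample) keep the rank-sum comparison honestly small-sample.

**What the generator does not emulate:** microarray probe effects and batch
structure, informative censoring, correlated or overlapping signature gene
sets, doublets and ambient RNA in the single-cell model, and spillover or
bead-normalization artifacts in cytometry. Passing the recovery experiments
therefore demonstrates internal statistical correctness and calibration of
the pipeline under its stated model — not robustness to those real-data
pathologies.

# Problem sizes and numerical choices

The validation suite runs the full discovery pipeline on 50 replicated
seven-cohort studies (ssGSEA path) plus 50 null-calibration replicates at
three cohorts of 120 samples with 60 inert signatures, 2000 log-rank
null simulations at $n = 60$, exhaustive Fisher enumeration to table total
40, 500-cell scoring runs, and 200 cytometry replicates; the acceptance
script reproduces the same quantities at 25 replicates. These sizes were
chosen so the whole suite completes in minutes on one core while leaving
Monte Carlo error well inside the asserted bands.

Numerical conventions worth knowing: enrichment tie-breaks are average rank
then lexicographic gene ID; NES uses ddof = 1 and flags zero-variance rows;
Cox convergence is $10^{-8}$ on the coefficient with a divergence guard at
$|\beta| > 15$; DL $\tau^2$ truncates at zero; the Fisher two-sided p sums
hypergeometric probabilities not exceeding the observed one with the
customary $1 + 10^{-7}$ relative tolerance; percentile rescaling uses
quantile type 7. Exact-median ties always stratify low.

# Known limitations

* Probe-to-gene collapsing, batch correction and cross-platform
  normalization are out of scope; the loaders accept pre-collapsed,
  pre-normalized matrices only.
* Gene matching is exact-string and case-sensitive; the per-signature
  overlap report is always emitted so silent mapping loss cannot occur,
  but no symbol aliasing is attempted.
* The meta-analysis assumes per-cohort estimates are independent and
  normal on the log-HR scale; very small cohorts (few events) strain that
  approximation, and non-converged fits are dropped, not shrunk.
* Selection controls the per-signature error rate at raw
  $\alpha$ — by design it does not control FDR unless the optional
  switch is enabled.
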