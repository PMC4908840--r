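---
title: "tssmeth: models, choices and limits of the targeted promoter methylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tssmeth: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tssmeth)
```

# Scope

`tssmeth` implements a targeted epigenomic analysis for liver disease: does
non-alcoholic fatty liver disease (NAFLD) shift CpG methylation near the
transcription start sites (TSS) of genes controlling bile-acid homeostasis
and drug metabolism, and do those shifts track transcription? The package
covers the whole chain — promoter probe selection, a discovery disease scan,
a fibrosis-staged validation scan, direction-consistent site validation,
gene-level enrichment and categorization, and robust methylation–expression
association — plus a synthetic three-cohort generator that makes every stage
testable without array downloads. Raw array preprocessing (IDAT handling,
normalization, batch or cell-type correction) is out of scope: inputs are
preprocessed β matrices, expression intensities and sample metadata.

# The analysis model, stage by stage

## Probe selection

A gene's analysis set is its CpG probes with |signed distance to the nearest
TSS| ≤ 1500 bp and no known SNP under the probe. The boundary is inclusive,
matching the array vendor's "TSS1500" naming; SNP-overlapping probes are
removed because a polymorphism changes probe hybridization independently of
methylation. Probes annotated to several genes contribute to each gene's set
independently. Gene symbols are upper-cased; the packaged cluster table
keeps common aliases (OSTα, FXR, PXR, …) as metadata. The drug-metabolism
cluster ships with NAT2 as an *optional* member (off by default): published
descriptions of the cluster disagree about whether it has 40 or 41 members,
and the canonical table enumerates 40.

## Discovery and validation scans

Both scans are per-CpG ordinary least squares on the β scale with age, sex
and BMI as covariates (listwise deletion per probe, with the per-probe n
reported). Discovery regresses on binary disease (control = 0, simple
steatosis or NASH = 1; the two NAFLD forms are pooled). Validation, run in
a NAFLD-only cohort, regresses on an ordinal stage — fibrosis stage 0–2 by
default, steatosis grade 0–3 as a companion scan. Stages enter as numeric
ordinals because the analysis reports a single coefficient per stage
variable. Covariates absent from a cohort's metadata are dropped and the
used set is recorded on the result (`attr(x, "covariates")`).

Multiple testing: Benjamini–Hochberg step-up across the scanned probes of
one cluster (the default family; a single global family across clusters is
available via `fdr_family = "global"`). Duplicated probes (multi-gene
annotations) enter the family once. Ties share the min-over-tail adjusted
value, the standard step-up convention. The validation scan is a targeted
confirmation of pre-selected hits, so it uses raw p < 0.05 by design.

A CpG is *validated* when it is FDR-significant in discovery, raw-significant
in the fibrosis validation scan, and the two coefficients agree in sign;
the sign defines hyper- versus hypomethylation. Requiring the fibrosis
predictor specifically (rather than fibrosis *or* steatosis) is the default
because steatosis severity barely moves promoter methylation in this
setting; `validation_requires = "either"` relaxes it.

## Gene level

Validated sites are split by direction; a gene can legitimately appear on
both sides (a predominantly hypermethylated promoter with one discordant
site). Per gene × direction the package reports:

* the **binomial overrepresentation tail** P(X ≥ k), X ~ Binomial(n, p₀)
  with n the gene's total TSS1500 probes, k its validated sites of that
  direction, and p₀ = 0.05 the per-site null rate. It is computed through
  the complementary binomial CDF, which is numerically stable far into the
  tail (~1e-20), and reported without further multiple-testing adjustment;
* the **percent changed**, rounded half away from zero (printed-table
  convention, 85.7 → 86);
* the **category** (1 strong / 2 medium / 3 weak) from CpG density and the
  *combined* changed fraction: ≥ 7 sites with ≥ 50 % changed → 1; 3–6 sites
  with ≥ 50 %, or ≥ 7 sites with 30–50 % → 2; otherwise 3. Two edge policies
  are deliberate: exactly 50 % goes to the higher tier, exactly 30 % counts
  as the 30–50 % band; and 3–6 sites with 30–50 % changed — a combination
  the published tier wording leaves unassigned — goes conservatively to
  category 3. The category uses the combined hyper+hypo count, while the
  binomial test is per direction, because the tiers describe how much of a
  promoter changed at all, whereas enrichment is directional.

## Methylation–expression association

Per gene × direction, the β-values of the validated sites (only those, by
default; `average_all_sites = TRUE` switches to the full TSS1500 set) are
averaged per sample *first* and the mean is then transformed to an M-value,
M = log₂(β̄/(1−β̄)) — averaging before transforming is the published order.
β̄ at 0 or 1 is clamped to [1e-6, 1−1e-6] so M stays finite.

The association model is a robust linear regression, by default with the
M-value as response and expression plus fibrosis stage as predictors; a
variant adds an expression×fibrosis interaction, for which the reported
coefficient and p remain those of the expression main effect (the
interaction term is returned alongside, since which term the original
analysis reported is not stated). The orientation is configurable
(`orientation = "expr_on_m"`), which matters when one wants the slope on the
"expression change per unit promoter M" scale — the scale on which the
synthetic generator defines its coupling γ; sign and significance are
orientation-invariant for practical purposes, and the orientation is
recorded on the result.

The robust estimator is written in the package: iteratively reweighted least
squares with a Huber start (k = 1.345, scale = MAD, both iterated), followed
by redescending Tukey-bisquare weights (c = 4.685, 95 % Gaussian efficiency)
at fixed scale; convergence when the maximum relative coefficient change
falls below 1e-9 (cap 200 iterations; hitting the cap is an error carrying
the iteration diagnostics). Standard errors use the classical M-estimation
variance (Σψ²/(n−p)) / (mean ψ′)² · s² · (XᵀX)⁻¹ with a t reference on n−p
degrees of freedom. The original analysis used an MM-type "high breakdown,
high efficiency" fit; the bisquare-with-Huber-start estimator shares the
redescending ψ and efficiency target but not the S-estimation start, so
coefficients can differ in pathological contamination patterns — the
package's tests therefore anchor the estimator to synthetic-data recovery
and to an independent MM implementation on clean-plus-outlier data, not to
published real-data coefficients. With constant weights (`psi = "ols"`)
the fit reduces exactly to least squares, which the tests exploit as an
oracle. Exactly collinear designs and constant expression are errors, as is
a subgroup below 3 samples for the accompanying uncorrected Pearson
correlations (computed within the NAFLD and control subgroups separately).

Expression matrices with several transcript rows per gene are collapsed by
mean with a logged per-gene count — multi-transcript probesets are a known
source of unspecific signal, and the collapse makes that explicit rather
than silent.

The neighbor scan reruns the fibrosis-adjusted robust model against the
expression of up to k = 5 genes upstream and downstream (by TSS position,
same chromosome), flagging each row with the source gene. Neighbors without
expression are skipped with a log message, never an error.

## Reporting

`render_summary()` emits one row per gene × direction with ≥ 1 validated
site: category, direction, and an association label derived from the robust
fibrosis-adjusted model — `inverse` when the methylation–expression slope is
significantly negative, `parallel` when significantly positive, `none`
otherwise. The label follows the sign of the measured association itself:
a hypomethylated gene whose methylation correlates *positively* with
expression is a parallel association. (An alternative reading — comparing
the slope sign against the disease direction of methylation — was
considered and rejected because it relabels exactly those published examples
that are described as positive correlations.)

# The synthetic generator: what it emulates, what it does not

The generator emits three cohorts shaped like the study design: discovery
(n = 74: 45 controls, 14 SS, 15 NASH), validation (n = 54, NAFLD-only, only
mild/advanced fibrosis at roughly 59/41 %), and a matched
methylation+expression cohort (n = 50: 30 controls, 13 SS, 7 NASH), with a
shared ground truth of planted effects.

Methylation is logit-normal. For probe j of gene g in sample i:

logit βᵢⱼ = aⱼ + bⱼ·disease + fⱼ·fibrosis + c₁·age_z + c₂·sex + c₃·BMI_z +
u_gi + εᵢⱼ

* aⱼ ~ N(−1.4, 0.8²): baseline promoters mostly in the β ≈ 0.1–0.4 band.
* bⱼ = ±0.25 logits on a random `fraction_affected` = 0.5 of each gene's
  probes (0 elsewhere): a 0.25-logit shift is ≈ 3–6 β-percentage points at
  those baselines, the reported magnitude of NAFLD-dependent promoter
  changes. Each gene draws a dominant direction (hypermethylation with
  probability 0.75, reflecting the predominance of hypermethylated targets),
  and individual affected probes flip with probability 0.1 — producing the
  occasional single discordant site that the direction split must handle.
* fⱼ = bⱼ per stage by default (`fibrosis_effect_scale = 1`): published
  validation per-stage coefficients have the same magnitude as the discovery
  disease coefficients. The steatosis multiplier defaults to 0 — steatosis
  severity hardly moves promoter methylation — which is exactly what makes
  the fibrosis/steatosis contrast in the validation scan testable.
* u_gi ~ N(0, 0.3²): a promoter-level regional effect shared by a gene's
  probes within an individual. Real promoter CpGs are co-methylated, so the
  gene-level methylation summary varies between individuals; without this
  term that summary would be nearly constant and the association stage would
  have no signal to find. 0.3 logits is ≈ 5 β-percentage points of
  inter-individual promoter spread.
* εᵢⱼ ~ N(0, 0.35²): independent probe noise (≈ 0.05–0.08 β SD at typical
  baselines). Demographics: age ~ N(50, 12²) years, BMI ~ N(40, 10²) kg/m²,
  70 % female, with small default covariate effects (0.05 logits per SD or
  for female sex). Discovery samples carry latent fibrosis/steatosis that
  drive β but are reported as missing — mirroring a cohort whose staging
  was never published. β is clamped to [1e-6, 1−1e-6].

Expression couples to the same summary statistic the analysis computes —
the M-value of the per-sample mean β over the gene's affected probes:
x_gi = μ_g + γ_g·M̄_gi + δ·fibrosis + η, with γ = −0.5 for genes carrying
planted effects (inverse coupling dominates in this system), δ = 0.2,
η ~ N(0, 0.5²), μ_g ~ N(8, 1²) on the log-intensity scale. Coupling to the
analysis-side summary makes a planted γ the exact estimand of the
association stage (in the `expr_on_m` orientation), so parameter-recovery
tests measure estimator quality rather than a generator/analysis mismatch.
An optional `neighbor_coupling` feeds one gene's methylation into another
gene's expression to exercise the neighbor scan. Decoy probes (outside the
window, or SNP-flagged) are always generated so the annotation filter is
exercised end to end. Everything is reproducible from (config, seed), and a
separate `truth_seed` lets sample draws vary while planted effects stay
fixed.

Not emulated: array chemistry (detection p-values, Infinium I/II probe-type
differences, dye bias, batch), cell-type composition, genuine genomic probe
spacing (synthetic genes sit on one chromosome at uniform 100 kb spacing),
missing-not-at-random patterns (only uniform missingness is available), and
any real correlation between demographics and disease. A green test on
synthetic data therefore establishes that the statistics do what they claim
under the stated model — calibrated nulls, recovered planted effects — not
that the pipeline is robust to array artifacts a normalization pipeline
must remove upstream.

# Numerical and interface choices

* β→M clamp ε = 1e-6; M-values are base-2 logits, generator internals use
  natural-log logits (they differ by the constant log₂e only).
* Percent columns round half away from zero; base R's half-to-even would
  print 12.5 % as 12.
* BH is delegated to `stats::p.adjust(method = "BH")` behind the module
  surface; the test suite keeps an independent brute-force step-up oracle.
  The binomial tail is `stats::pbinom(lower.tail = FALSE)` against a
  direct-summation oracle; per-probe fits use least squares via QR with a
  normal-equations oracle. Rank-deficient designs fail naming the collinear
  columns; a stage variable without variation, an empty averaging set, and
  a missing β matrix are all immediate, named errors. Pipeline stages wrap
  their errors with the stage name.
* Scans are invariant to sample order (matching by sample id) and probe
  order; results are sorted by gene and probe id.
* Files are plain TSV/CSV with a configurable annotation column dialect;
  positions 1-based; a JSON manifest (config, seeds, stage counts)
  accompanies every written cohort and result bundle. There is no shell
  entry point: the exported functions are the interface, in the style of
  the field's analysis packages.

# Known limitations

* The robust estimator is an M-estimator with Huber start, not a true
  S-start MM-estimator; its breakdown point is lower in extreme-leverage
  contamination. For the n ≈ 50 matched-cohort use case the tests show
  agreement with an MM reference within 0.05 on contaminated data.
* The binomial test treats a promoter's CpGs as independent Bernoulli
  trials; co-methylation makes it anti-conservative as a literal null test.
  It is used, as intended, as a ranking/enrichment statistic.
* Validation covariates may be partly unavailable in real metadata; the
  scan adjusts for what exists and records it, so two cohorts' results are
  only comparable conditional on that record.
* The EC-cohort fibrosis adjustment treats missing stages as 0 when the
  metadata omit them; with fully staged metadata this is a no-op.
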