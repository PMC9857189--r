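---
title: "Methods: depth Z-scores, Gi instability scoring, and survival integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth Z-scores, Gi instability scoring, and survival integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(giscan)
```

# The model

Shallow WGS of plasma cfDNA measures, per genomic feature $f$ (a 100 kb bin
or a gene body), a mean read depth $d_f$. Three systematic effects sit
between $d_f$ and the underlying copy number: total sequencing yield, a
smooth dependence on the local GC fraction, and the dilution of the tumor
signal by normal cfDNA. `giscan` models them in sequence:

1. **GC correction.** Per sample, $d_f \approx \beta(gc_f)\,c_f$ with
   $\beta$ a smooth library-specific efficiency and $c_f$ the copy-number
   signal. $\beta$ is estimated by LOESS regression of raw depth on GC over
   the sample's bins and removed as
   $\tilde d_f = (d_f / \hat\beta(gc_f)) \cdot s$, with $s$ chosen so the
   median over the bins used in the fit is exactly preserved. The
   correction is multiplicative because coverage bias acts as a per-locus
   sampling efficiency; an additive (`subtract`) mode is kept for
   comparison only.
2. **Control reference.** Healthy controls (n = 20 by default) provide
   per-feature $\mu_f, \sigma_f$ of normalized depth. The patient score is
   $z_f = (\tilde d_f - \mu_f)/\sigma_f$. Because both the sample and the
   reference are normalized the same way, $z$ is invariant to rescaling all
   depths by a constant — sequencing yield cancels.
3. **Calls and grouping.** $z_f > 2$ is an amplification, $z_f < -2$ a
   deletion, strictly (a score of exactly ±2 is neutral, reading
   "exceeding" literally). For survival analysis each panel gene carries an
   expected direction (AMP or DEL, the dominant alteration in TCGA ovarian
   tumors), and a patient is an event for that gene (group 1) only when the
   Z-score crosses the threshold *in the panel direction*; a strong
   deletion of an AMP gene stays group 0.
4. **Instability score.** $Gi = \sum_f |z_f|$ over autosomal bins. Under
   the null a control has $E|z| \approx \sqrt{2/\pi}$ per feature, so Gi
   concentrates near $0.8\,n$; focal and arm-level events push it up.
   Cohorts are compared with the two-sided Wilcoxon rank-sum test (exact
   null for combined $n \le 20$ without ties, normal approximation with
   continuity correction otherwise).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| bin size | 100,000 | bp | the genome-wide window size used for segment-level Z profiles |
| LOESS span / degree | 0.75 / 2 | — | standard smoother defaults; the source method names LOESS but no parameters, so these are exposed in `norm_config()` |
| GC window | [0.28, 0.68] | fraction | extreme-GC bins are unreliable at shallow depth; outside bins are flagged missing, never zeroed |
| `depth_floor` | 0 | fold-coverage | bins at/below it are excluded from the GC fit |
| σ floor | max(1e−6, 0.05 µ) | depth | counting noise implies a CV floor; prevents infinite Z at zero-variance features |
| call thresholds | +2 / −2 | Z | strict inequalities |
| reference SD | n−1 sample SD | — | unbiased default; the source is silent |

Gene bodies are normalized with the **bin-fitted** LOESS curve evaluated at
the gene's GC: 33 genes are far too few points to support their own smooth,
while the bins come from the same library and share its bias.

# Numerical and convention choices

* **Degenerate GC fit.** If all eligible bins share one GC value, no bias
  is estimable; the profile is returned unchanged with a warning rather
  than an error.
* **Median preservation.** The rescale factor is chosen so the median
  normalized depth over the bins used in the fit equals the median raw
  depth to numerical precision (checked at 1e−6 relative) — GC correction
  reshapes a profile, it does not change its depth scale.
* **Missing propagation.** Flagged features (extreme GC, unstable fit,
  absent reference) carry `NA` Z-scores, are skipped by Gi, map to group 0
  in directional grouping, and are marked in the call table.
* **Survival ties.** At tied times events precede censoring (standard
  risk-set convention). Recurrence at exactly 6 months counts as
  progression ("within six months" read inclusively); CA125 exactly at the
  median goes to the low arm ("≤ median").
* **Log-rank degeneracies.** With no events the test is vacuous (χ² = 0,
  p = 1, warning). If the variance matrix is singular (risk sets collapse),
  the χ² is computed from the O−E vector with a Moore–Penrose inverse
  instead of failing.
* **Eligibility rules.** A gene screen is flagged ineligible for DFS with
  ≤ 1 carrier and for OS when no carrier died — mirroring the exclusions
  applied in the motivating study — but statistics are still reported when
  computable. Patients without OS follow-up are dropped from OS analyses
  (not censored at zero).
* **No multiplicity correction** is applied to the 33 univariate screens,
  matching the screening design; a Benjamini–Hochberg column is emitted for
  information only.

# Open design decisions

* **Gi feature set.** Whether the instability sum runs over genome-wide
  bins or the 33 panel genes is ambiguous in the source; both are provided
  (`gi_score(..., features = "bin"/"gene")`) with bins as the default,
  since "genome-wide Z-scores" most naturally means the window profile.
* **Sex chromosomes.** Excluded from Gi by default: all subjects in the
  motivating design are female, but X-depth still tracks cohort and
  normalization artifacts more than somatic instability; a flag restores
  them.
* **Downsampling.** The in-silico comparison of deep vs shallow profiles is
  implemented as binomial thinning of per-feature read counts (the
  depth-level equivalent of read subsampling), followed by rescaling to the
  original coverage, re-normalization, and re-scoring against the same
  reference.
* **Depth regime.** The generator defaults to 5× fold-coverage — the
  per-sample coverage the motivating study actually measured — rather than
  its nominal 0.27× design depth; both regimes are supported through
  `mean_depth`, and the pipeline itself is depth-agnostic.

# What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws per-feature read counts from a negative binomial
with mean $\bar d \cdot \beta(gc) \cdot (1 + tf\,(cs - 2)/2)$:

* $\beta$ is a quadratic GC-efficiency curve (amplitude 0.3 by default),
  peaking at GC 0.45 — the shape seen in real libraries;
* the negative-binomial overdispersion (default 0.005, ~7% extra-Poisson
  CV) represents the residual bin-to-bin noise of GC-corrected shallow WGS,
  chosen a priori as mid-range of the 5–10% typically reported;
* $tf$ is the tumor fraction (Uniform(0.2, 0.8) per patient by default) and
  $cs$ the planted copy state (4 for amplifications, 0 for deletions), the
  standard ctDNA mixture dilution;
* each patient alters each panel gene independently with the gene's
  published occurrence frequency; altered genes become padded segments, and
  background instability segments are planted on a reserved chromosome so
  gene-level truth stays unambiguous;
* DFS/OS are exponential with a multiplicative hazard (default 6) per
  planted risk-gene event, administratively censored in a 36–72 month
  window; CA125 is log-normal around the published median 575.5 U/mL,
  shifted upward with event burden.

`make_fixture_cohort()` is the deterministic counterpart: carrier counts
are exactly `round(freq × n)` and the clinical table reproduces the
published cohort composition (stages 9/2/26/3, histology 23/3/5/4/5, 20
recurrences, 6 BRCA-pathogenic, 3 patients lost to OS follow-up, CA125
median pinned at 575.5).

The generator does **not** emulate: mappability and replication-timing
bias, fragment-length (fragmentomics) signal, subclonal mixtures of
different copy states, correlated GC structure along the genome, germline
CNVs in controls, or read-level artifacts (duplicates, chimeras) — the
pipeline starts from aligned depth by design. A green recovery test
therefore establishes that the statistical machinery recovers planted
signal under the stated noise model, not that the thresholds are clinically
validated.

# Known limitations

* Threshold calling per gene/bin, no segmentation (CBS/HMM) and no
  tumor-fraction estimation: borderline events at low tf are missed by
  design, and the recovery tests quantify this only under the simulator's
  noise model.
* With very small carrier arms (2–3 of 40) the χ² approximation of the
  log-rank runs anti-conservative: in null simulations the per-gene
  rejection rate at nominal 0.05 reaches ~0.15 for 2-carrier genes while
  the cohort-wide average stays near 0.05–0.08. Survival conclusions for
  genes with so few carriers should rest on the Kaplan–Meier curves, not
  the p-value alone — one reason the screening rules exclude single-carrier
  genes outright.
* The 33-gene panel and its directions are frozen from TCGA ovarian data;
  no liftover from hg19 is provided.
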