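---
title: "Dyadic analysis of the developing social brain: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyadic analysis of the developing social brain: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dyadsync)
```

# The analysis problem

When a child and their mother watch the same animated movie in the scanner,
three questions can be asked of the resulting BOLD timecourses in the social
brain:

1. **Which moments of the movie drive the social networks?** Reverse
   correlation finds time points at which the group-average response of a
   network reliably exceeds baseline, and reads events off the runs of
   consecutive significant time points.
2. **How adult-like is a child's network organization?** Each subject's
   ROI-by-ROI correlation matrix summarizes the functional coupling of the
   networks; *neural maturity* is the similarity of a child's matrix to the
   adults' matrices.
3. **Are child and mother synchronized, and does the relationship matter?**
   Inter-subject synchronization (ISS) is the temporal correlation between
   the child's and a partner's network-level timecourses, compared between
   the own mother and an average stranger, and related to relationship
   quality (conflict) controlling for age.

`dyadsync` implements all three stages over a fixed 13-ROI atlas: a 6-ROI
Theory-of-Mind (ToM) network (bilateral TPJ, precuneus, three medial
prefrontal subdivisions) and a 7-ROI Social Pain Matrix (SPM: bilateral S2,
insula and middle frontal gyrus, anterior middle cingulate). ROIs are 9 mm
radius spheres around published MNI peaks; the atlas row order fixes the
row/column order of every matrix in the package.

# Signal conditioning

The package operates on ROI timecourses. When starting from volumes,
`extract_sphere_timecourses()` averages voxels whose centers fall within
the sphere radius (inclusive boundary). The conditioning chain
(`prep_timecourse()`) mirrors standard naturalistic-fMRI practice, in this
fixed order:

discard initial volumes (default 5) → linear detrend → confound regression
(typically 24 motion regressors + WM + CSF) → zero-phase band-pass →
motion scrubbing → per-ROI z-scoring.

Choices worth making explicit:

* **Framewise displacement** is the Power formulation — the sum of absolute
  backward differences, rotations converted to arc length on a 50 mm
  sphere — because the displacement formula is a convention rather than a
  derived quantity; both radius and threshold (0.5 mm) are arguments.
* **Scrubbing** flags FD > 0.5 mm, dilates by 1 TR back and 2 TRs forward,
  and replaces flagged samples by a cubic interpolating spline fitted to
  the clean samples (`stats::spline`, FMM end conditions, which reproduce a
  global cubic exactly). Clean samples are returned bit-identical. We scrub
  *after* filtering; the alternative ordering is a one-line change in user
  code since every step is exposed as a function.
* **Band-pass** (0.01–0.15 Hz) is a fourth-order Butterworth run
  forward-backward (`signal::filtfilt`) for zero phase: phase distortion
  would shift detected event boundaries. On pure sinusoids the passband is
  preserved within 5% and stopband frequencies past the transition are
  attenuated by more than 90% (tested).
* **Motion exclusion** uses strict inequalities at 3 mm translation and
  3° rotation, with rotations stored in radians and converted only at this
  boundary.
* The run length is always taken from the data, never hard-coded: the
  acquisition nominally yields 155 volumes of which 5 are discarded, and
  downstream code must not care whether 145 or 150 remain.

# Reverse-correlation event detection

At every TR the across-subject network-mean response is tested against 0
with a one-sample, one-tailed *t* test (df = n − 1). Events are maximal
runs of at least `min_len_tr = 2` consecutive TRs with p < α. The
significance threshold is a genuine free parameter of the method; we
default to α = 0.05, one-tailed and uncorrected, and expose it, so an event
inventory can be re-derived under any other choice.

Conventions: half-open `[onset, offset)` intervals in 0-based TRs; the peak
TR of an event is the argmax of the group-mean response with ties broken by
the earliest TR; rank 1 is the largest peak response and labels are
`T01`, `P01`, … accordingly. A TR with zero across-subject variance is
degenerate but defined (p decided by the sign of the mean, with a warning):
it arises in noise-free simulation, not in real data.

The ToM/SP-vs-other mask is the union of both networks' event TRs;
TRs claimed by both networks are reported (in natural stimuli this overlap
is expected to be nearly empty). Child "replication" of an adult event
defaults to at least one shared TR, configurable to a required overlap
fraction, because replication counts are conventionally reported without
the matching rule.

# Connectivity and neural maturity

Per subject, all pairwise Pearson correlations between ROI timecourses are
clipped to |r| ≤ 1 − 1e-7 (keeping the Fisher transform finite in
degenerate cases) and mapped to Fisher z. Summaries never touch the
diagonal (stored as `NaN`). Block means average the unique unordered pairs
within each network (15 ToM, 21 SPM pairs) and all 42 across-network pairs.

Neural maturity vectorizes the strictly-lower triangle (78 entries) of the
z matrix and averages the Pearson correlations between the child's vector
and each adult's vector, on the r scale — the plain mean matches the
natural reading of "average correlation"; a Fisher-mean alternative is a
flag. The joint 13×13 matrix is the default similarity target; per-network
restriction is available by sub-setting the atlas. Condition-restricted
maturity recomputes the matrices of *both* children and adults over the
masked TRs, with a floor of 10 TRs per condition (below which correlation
matrices are too unstable to interpret).

Age groups can be formed by the published bands (Pre-junior 3.3–4.8,
Junior 5.0–5.8, Senior 6.0–8.0 years) or by an equal-count tertile split;
for arbitrary simulated cohorts the tertile split is the right choice and
is the pipeline default.

# Inter-subject synchronization

ISS operates on the grand network mean (all 13 ROIs of z-scored data; the
equal-weight mean implies the 6·ToM + 7·SPM recombination identity tested
in the suite). The mother partner is the dyad's own adult; the stranger
partner is the unweighted average of all *other* adults' series
(leave-own-mother-out). The alternative reading — averaging pairwise
child–stranger correlations on the Fisher scale — is implemented behind
`method = "mean_pairwise"` since published wording is ambiguous; the
average-series form is the default because it is the direct reading of the
methods convention. Conflict–ISS associations are assessed by partial
correlation controlling age. The mother-vs-stranger contrast is reported
both as the conventional two-sample *t* test and as the paired test that
the dyadic design actually warrants.

# The synthetic cohort

`generate_dyads()` builds a cohort with the statistical structure the
analysis assumes, so every stage is testable without any download. For ROI
*i* of subject *j* in dyad *d*:

y_ij(t) = w_j · s_N(t) − λ · w_j · s_N′(t) + G_j(t) + ε_ij(t)

* **Stimulus trains** `s_ToM`, `s_SPM`: 7 ToM and 8 social-pain boxcar
  events of 2–7 TRs, non-overlapping with ≥1 TR spacing, convolved with a
  canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6 — the
  analysis itself never models the HRF, so these are generator-only
  parameters), then centered and scaled to unit sample variance.
* **Loadings**: adults at `w_adult = 1`; children ramp linearly from 0.3 at
  age 3 to the adult value at age 8 (ages uniform on [3, 8]). The
  cross-network suppression λ = 0.2 plants the across-network
  anticorrelation as a generative knob.
* **Dyad coupling**: each subject carries a network-wide AR(1) latent
  (ρ = 0.3) of total variance c0² = 0.25, split between a component shared
  with the dyad partner (weight `c_d = c0·(1 − conflict_norm)`) and a
  private component (weight `sqrt(c0² − c_d²)`). This variance-preserving
  split is a deliberate design decision: if coupling simply *added*
  variance, per-ROI z-scoring would make the stimulus share of every series
  depend on conflict and leak relationship quality into child–stranger
  synchronization, which must stay null by construction. Synchrony, in this
  model, reallocates idiosyncratic network fluctuation into shared
  fluctuation — it does not create extra signal.
* **Noise**: i.i.d. Gaussian, SD 1 per ROI. Conflict scores are uniform on
  36–50 (a realistic questionnaire range) and normalized internally.
* **Behavior**: the planted ToM score is
  `round(clip(9.9 + 2·age_std − 1·conflict_std + N(0, 2²), 0, 14))`; the
  other questionnaire columns are drawn around realistic means and, for the
  social-responsiveness total, tied negatively to the ToM score.

With the default configuration the analytic anchor holds: under zero
coupling, a single child ROI and the paired mother ROI are two noisy copies
of the same unit-variance signal, so their expected correlation is
w²/(w² + σ²); the acceptance suite verifies the empirical mean against this
closed form. What the generator does **not** emulate: spatial structure
within ROIs, physiological noise spectra, motion artifacts, hemodynamic
variability across subjects, and any non-stationarity of coupling — so
passing tests demonstrate the correctness and calibration of the
*analysis*, not realism of the data model.

# Numerical and testing choices

* Sample (n − 1) standard deviations everywhere; z-scoring requires
  non-constant rows and errors otherwise naming the ROI.
* Correlation clipping margin 1e-7, shared by every module.
* All statistics route through the standard R machinery (`cor.test`,
  `t.test`, `p.adjust(method = "BH")`, `car::Anova` type II); the package's
  own contributions — event detection, maturity, ISS, the generator — are
  tested against independent brute-force oracles and closed forms at
  1e-12 tolerances.
* FDR families are explicit (`family_id`) because printed "FDR-corrected"
  values in the literature rarely state family composition; the pipeline
  defaults to one family for maturity correlations and one for ISS
  correlations.
* Monte-Carlo problem sizes used by the validation suite — 20,000 null
  replicates for detector calibration, 200 cohort replicates for the
  maturity and ISS recovery checks, 500 for the ISS anchor — were chosen so
  that three Monte-Carlo standard errors resolve the tested effects; they
  run in about two minutes total.
* Determinism: a configuration plus one integer seed reproduces every
  fixture byte-for-byte and every pipeline report hash exactly.

# Known limitations

* The 2×3 maturity ANOVA and the 2×2 ISS ANOVA are fixed-effects
  between-cell analyses even though one factor is within-subject; the
  paired contrasts are emitted alongside as the statistically preferable
  view.
* Event-restricted correlation matrices concatenate non-contiguous TR
  segments, which ignores autocorrelation across the seams; with a 10-TR
  floor this is conventional but approximate.
* The stranger average grows cleaner as the adult pool grows, so
  mother-vs-stranger differences shrink with cohort size for a fixed
  coupling strength; interpret the contrast jointly with the
  conflict-modulated partial correlation.
* Sphere extraction assumes the image is already in the atlas space; no
  registration is attempted.
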