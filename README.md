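# dyadsync

Analysis pipeline for **naturalistic movie-viewing fMRI in child–mother
dyads**, built around three questions developmental social neuroscientists
ask of such data:

1. **Reverse correlation** — which moments of the stimulus reliably drive
   the Theory-of-Mind (ToM) and Social Pain Matrix (SPM) networks? At each
   TR the across-subject network-mean response x̄(t) is tested against
   baseline with a one-tailed one-sample *t* test,
   t(t) = x̄(t) / (s(t)/√n), and events are maximal runs of ≥ 2
   consecutive TRs with p < α, ranked by peak response (`T01`, `P01`, …).
2. **Neural maturity** — how adult-like is a child's network organization?
   Per subject, all pairwise ROI correlations r_ij over a 13-ROI atlas
   (6 ToM + 7 SPM spheres) are Fisher-transformed, z = atanh(r); a child's
   maturity is the mean over adults *a* of
   corr(vec(Z_child), vec(Z_a)) on the 78 lower-triangle entries —
   whole-run, and restricted to event vs non-event TRs.
3. **Inter-subject synchronization (ISS)** — is the child synchronized
   with their own mother more than with an average stranger?
   ISS = atanh(corr(g_child, g_partner)) on grand network-mean
   timecourses, with the stranger partner the leave-own-mother-out adult
   average; conflict–ISS associations use partial correlation controlling
   age, with Benjamini–Hochberg FDR within declared families.

The package also provides the timecourse-level signal conditioning used
upstream (volume discard, linear detrend, confound regression, 0.01–0.15 Hz
zero-phase band-pass, FD > 0.5 mm scrubbing with cubic-spline
interpolation, motion exclusion at 3 mm / 3°), sphere extraction from NIfTI
volumes, and a **synthetic dyadic-BOLD generator** that plants stimulus
events, age-scaled loadings, and conflict-modulated dyad coupling so that
the whole pipeline is testable end-to-end without any data download. See
`vignette("dyadic-social-brain")` for the model and design decisions.

## Worked example

A full synthetic cohort (34 dyads, 145 TRs of 2 s) analyzed end-to-end:

```r
library(dyadsync)
report <- run_pipeline(list(seed = 1, simulate = list()))

ev <- report$events
cat(sprintf("ToM events: %d (total %g s)\n",
            sum(ev$network == "ToM"), report$event_summary$ToM$total_duration_s))
#> ToM events: 7 (total 84 s)
head(ev[, c("label", "onset_tr", "offset_tr", "peak_tr", "peak_mean_response")], 3)
#>   label onset_tr offset_tr peak_tr peak_mean_response
#> 1   T07        4         8       5          0.8399069
#> 2   T04       10        17      13          1.4764493
#> 3   T02       61        69      64          1.6344874

s <- report$stats
s[s$name %in% c("maturity_vs_age", "conflict_vs_mother_iss",
                "conflict_vs_stranger_iss"),
  c("name", "estimate", "p_raw", "p_fdr")]
#>                      name    estimate        p_raw        p_fdr
#>           maturity_vs_age  0.80303400 1.098439e-08 4.393756e-08
#>    conflict_vs_mother_iss -0.89656629 1.709165e-12 3.418330e-12
#>  conflict_vs_stranger_iss  0.09092587 6.147999e-01 6.147999e-01
```

Reading the output: the detector recovers the planted event inventory
(7 ToM events; labels encode peak-response rank, so `T01` is the strongest
ToM event). Neural maturity rises with age (r = 0.80) because child
network loadings ramp linearly toward the adult value by construction;
mother–child synchronization falls with relationship conflict
(partial r = −0.90 controlling age) because coupling is planted as
`c0·(1 − conflict)`, while the child–stranger control association is null
(r = 0.09, p = 0.61), as it must be when coupling is dyad-specific.

Individual stages are plain functions — `detect_events()`,
`interregion_matrix()`, `neural_maturity()`, `dyad_iss()`,
`generate_dyads()` — and a thin CLI wrapper lives at
`inst/scripts/dyadsync-pipeline.R`.

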