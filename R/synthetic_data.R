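# Synthetic dyadic-BOLD generator. Emulates the statistical structure the
# analysis assumes: stimulus-locked events shared by all subjects (boxcars
# convolved with a canonical HRF), network loadings that rise linearly with
# child age toward the adult value, a dyad-specific shared AR(1) signal
# whose strength falls with relationship conflict, i.i.d. Gaussian noise,
# and a behavioral table with planted age and conflict effects on ToM
# performance. Every draw is governed by a single seed.

#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = g(t; a1, b) - ratio * g(t; a2, b)` with gamma-density lobes
#' peaking at `peak_s` and `undershoot_s` seconds (shape = peak since the
#' rate is 1/s).
#'
#' @param t_s time points in seconds.
#' @param peak_s positive-lobe peak (default 6 s).
#' @param undershoot_s undershoot peak (default 16 s).
#' @param ratio undershoot amplitude ratio (default 1/6).
#' @return HRF values at `t_s`.
#' @export
hrf_double_gamma <- function(t_s, peak_s = 6, undershoot_s = 16, ratio = 1/6) {
  g <- function(t, shape) ifelse(t <= 0, 0, stats::dgamma(t, shape = shape, rate = 1))
  g(t_s, peak_s) - ratio * g(t_s, undershoot_s)
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the acquisition and cohort the pipeline targets: 34
#' dyads, 145 TRs of 2 s, 7 ToM and 8 social-pain events of 2-7 TRs, child
#' ages uniform on 3-8 years with network loading rising linearly from
#' `w_min` at age 3 to `w_adult` at age 8, a cross-network suppression
#' `lambda` producing the across-network anticorrelation, and dyad coupling
#' `c0 * (1 - normalized conflict)` shared between the two members of a
#' dyad.
#'
#' @param n_dyads number of child-mother dyads (default 34).
#' @param n_tr time points per run (default 145).
#' @param tr_seconds repetition time (default 2).
#' @param n_tom_events,n_pain_events event counts (defaults 7 and 8).
#' @param event_len_range event duration range in TRs (default 2-7).
#' @param w_adult adult network loading (default 1).
#' @param w_min child loading at age 3 (default 0.3).
#' @param age_range child age range in years (default 3-8).
#' @param lambda cross-network suppression (default 0.2).
#' @param c0 maximum dyad coupling (default 0.5).
#' @param noise_sd i.i.d. noise SD per ROI (default 1).
#' @param ar_rho AR(1) coefficient of the dyad latent signal (default 0.3).
#' @param conflict_range CPRS-conflict-like score range (default 36-50).
#' @param hrf_peak_s,hrf_undershoot_s,hrf_ratio HRF parameters.
#' @param tom_beta0,tom_beta_age,tom_beta_conflict,tom_noise_sd coefficients
#'   of the planted ToM-score model (intercept, age slope, conflict slope on
#'   standardized predictors, residual SD).
#' @param seed integer RNG seed; mandatory.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_dyads = 34, n_tr = 145, tr_seconds = 2,
                         n_tom_events = 7, n_pain_events = 8,
                         event_len_range = c(2, 7),
                         w_adult = 1.0, w_min = 0.3, age_range = c(3, 8),
                         lambda = 0.2, c0 = 0.5, noise_sd = 1.0,
                         ar_rho = 0.3, conflict_range = c(36, 50),
                         hrf_peak_s = 6, hrf_undershoot_s = 16,
                         hrf_ratio = 1/6,
                         tom_beta0 = 9.9, tom_beta_age = 2.0,
                         tom_beta_conflict = 1.0, tom_noise_sd = 2.0,
                         seed) {
  .check(!missing(seed) && is.finite(seed), "a seed is mandatory")
  .check(noise_sd >= 0 && c0 >= 0 && tom_noise_sd >= 0,
         "variances must be nonnegative")
  .check(abs(ar_rho) < 1, "ar_rho must be in (-1, 1)")
  cfg <- list(n_dyads = n_dyads, n_tr = n_tr, tr_seconds = tr_seconds,
              n_tom_events = n_tom_events, n_pain_events = n_pain_events,
              event_len_range = event_len_range, w_adult = w_adult,
              w_min = w_min, age_range = age_range, lambda = lambda,
              c0 = c0, noise_sd = noise_sd, ar_rho = ar_rho,
              conflict_range = conflict_range, hrf_peak_s = hrf_peak_s,
              hrf_undershoot_s = hrf_undershoot_s, hrf_ratio = hrf_ratio,
              tom_beta0 = tom_beta0, tom_beta_age = tom_beta_age,
              tom_beta_conflict = tom_beta_conflict,
              tom_noise_sd = tom_noise_sd, seed = as.integer(seed))
  n_events <- n_tom_events + n_pain_events
  min_need <- sum(rep(event_len_range[1], n_events)) + (n_events - 1)
  .check(min_need <= n_tr,
         "event schedule cannot fit: %d events need >= %d of %d TRs",
         n_events, min_need, n_tr)
  class(cfg) <- "synth_config"
  cfg
}

# Random non-overlapping event schedule: durations uniform in range, at
# least one TR between events, network labels interleaved at random.
.make_schedule <- function(cfg) {
  n_events <- cfg$n_tom_events + cfg$n_pain_events
  repeat {
    dur <- sample(seq(cfg$event_len_range[1], cfg$event_len_range[2]),
                  n_events, replace = TRUE)
    slack <- cfg$n_tr - sum(dur) - (n_events - 1)
    if (slack >= 0) break
  }
  # distribute the slack over the n_events + 1 gaps
  gap_extra <- if (slack > 0) {
    tabulate(sample.int(n_events + 1, slack, replace = TRUE), n_events + 1)
  } else rep(0L, n_events + 1)
  gaps <- gap_extra + c(0L, rep(1L, n_events - 1), 0L)
  onset <- cumsum(gaps[seq_len(n_events)]) +
    c(0L, cumsum(dur[-n_events]))
  network <- sample(c(rep("ToM", cfg$n_tom_events),
                      rep("SPM", cfg$n_pain_events)))
  data.frame(network = network, onset_tr = as.integer(onset),
             offset_tr = as.integer(onset + dur), stringsAsFactors = FALSE)
}

# boxcar train -> HRF convolution -> centered, unit-sample-variance series
.stimulus_series <- function(schedule, network, cfg) {
  box <- numeric(cfg$n_tr)
  ev <- schedule[schedule$network == network, , drop = FALSE]
  for (i in seq_len(nrow(ev))) box[(ev$onset_tr[i] + 1):ev$offset_tr[i]] <- 1
  kernel_t <- seq(0, 32, by = cfg$tr_seconds)
  kernel <- hrf_double_gamma(kernel_t, cfg$hrf_peak_s, cfg$hrf_undershoot_s,
                             cfg$hrf_ratio)
  s <- stats::convolve(box, rev(kernel), type = "open")[seq_len(cfg$n_tr)]
  (s - mean(s)) / stats::sd(s)
}

# unit-variance AR(1) latent signal
.ar1 <- function(n, rho) {
  innov <- stats::rnorm(n, sd = sqrt(1 - rho^2))
  innov[1] <- stats::rnorm(1)
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Generate a synthetic dyadic cohort
#'
#' ROI `i` of subject `j` (network `N(i)`, dyad `d`) is
#' `y_ij(t) = w_j s_N(t) - lambda w_j s_N'(t) + G_j(t) + eps_ij(t)`,
#' where `s_ToM`, `s_SPM` are unit-variance HRF-convolved boxcar trains on
#' the planted event schedule and `eps` is i.i.d. Gaussian noise
#' (`noise_sd`). `G_j` is the subject's network-wide latent fluctuation,
#' `G_j = c_d g_d + sqrt(c0^2 - c_d^2) h_j`, built from unit-variance AR(1)
#' signals: `g_d` is shared by the two members of dyad `d`, `h_j` is
#' private, and `c_d = c0 (1 - conflict_norm_d)`. Coupling thus reallocates
#' latent variance from the private to the shared channel while every
#' subject's total latent variance stays `c0^2` (otherwise per-ROI
#' z-scoring would couple relationship quality to the stimulus share of
#' every series). `w_j` is the adult loading for mothers and the age-linear
#' ramp for children. All rows are then z-scored. The planted ToM behavior score is
#' `round(clip(b0 + b_age age_std - b_conf conflict_std + noise, 0, 14))`.
#'
#' @param config a `synth_config`.
#' @return a `synth_dataset`: lists `children` and `mothers` of z-scored
#'   `subject_timecourse`s, a `behavior` data frame, and `truth` (event
#'   schedule, stimulus series, boxcar event mask, true loadings and
#'   couplings, the config).
#' @export
generate_dyads <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  atlas <- load_default_atlas()
  schedule <- .make_schedule(cfg)
  s_tom <- .stimulus_series(schedule, "ToM", cfg)
  s_spm <- .stimulus_series(schedule, "SPM", cfg)

  age <- stats::runif(cfg$n_dyads, cfg$age_range[1], cfg$age_range[2])
  conflict <- stats::runif(cfg$n_dyads, cfg$conflict_range[1],
                           cfg$conflict_range[2])
  conflict_norm <- (conflict - cfg$conflict_range[1]) /
    diff(cfg$conflict_range)
  w_child <- cfg$w_min + (age - cfg$age_range[1]) / diff(cfg$age_range) *
    (cfg$w_adult - cfg$w_min)
  coupling <- cfg$c0 * (1 - conflict_norm)

  roi_net <- atlas$network
  # Coupling is variance-preserving: every subject carries a network-wide
  # latent of total variance c0^2, split between a dyad-shared component
  # (weight c_d) and a private one (weight sqrt(c0^2 - c_d^2)). Synchrony
  # therefore reallocates fluctuation from the private to the shared channel
  # without changing any series' variance; otherwise per-ROI z-scoring would
  # make the stimulus share of a series depend on conflict and leak
  # relationship quality into child-stranger synchronization.
  make_subject <- function(w, latent) {
    signal <- rbind(
      matrix(rep(s_tom - cfg$lambda * s_spm, sum(roi_net == "ToM")),
             nrow = sum(roi_net == "ToM"), byrow = TRUE),
      matrix(rep(s_spm - cfg$lambda * s_tom, sum(roi_net == "SPM")),
             nrow = sum(roi_net == "SPM"), byrow = TRUE)
    )
    noise <- matrix(stats::rnorm(nrow(atlas) * cfg$n_tr, sd = cfg$noise_sd),
                    nrow = nrow(atlas))
    y <- w * signal + matrix(rep(latent, nrow(atlas)),
                             nrow = nrow(atlas), byrow = TRUE) + noise
    rownames(y) <- atlas$name
    y
  }

  children <- vector("list", cfg$n_dyads)
  mothers <- vector("list", cfg$n_dyads)
  for (d in seq_len(cfg$n_dyads)) {
    g_shared <- .ar1(cfg$n_tr, cfg$ar_rho)
    w_priv <- sqrt(max(cfg$c0^2 - coupling[d]^2, 0))
    latent_child <- coupling[d] * g_shared + w_priv * .ar1(cfg$n_tr, cfg$ar_rho)
    latent_mother <- coupling[d] * g_shared + w_priv * .ar1(cfg$n_tr, cfg$ar_rho)
    did <- sprintf("dyad_%02d", d)
    cid <- sprintf("child_%02d", d)
    mid <- sprintf("mother_%02d", d)
    children[[d]] <- znormalize(subject_timecourse(
      cid, "child", make_subject(w_child[d], latent_child),
      cfg$tr_seconds, dyad_id = did))
    mothers[[d]] <- znormalize(subject_timecourse(
      mid, "adult", make_subject(cfg$w_adult, latent_mother),
      cfg$tr_seconds, dyad_id = did))
  }
  names(children) <- vapply(children, function(x) x$subject_id, character(1))
  names(mothers) <- vapply(mothers, function(x) x$subject_id, character(1))

  age_std <- as.numeric(scale(age))
  conf_std <- as.numeric(scale(conflict))
  tom_score <- round(pmin(pmax(
    cfg$tom_beta0 + cfg$tom_beta_age * age_std -
      cfg$tom_beta_conflict * conf_std +
      stats::rnorm(cfg$n_dyads, sd = cfg$tom_noise_sd), 0), 14))
  behavior <- data.frame(
    dyad_id = sprintf("dyad_%02d", seq_len(cfg$n_dyads)),
    child_id = names(children), mother_id = names(mothers),
    age = age, sex = sample(c("F", "M"), cfg$n_dyads, replace = TRUE),
    conflict = conflict,
    closeness = stats::rnorm(cfg$n_dyads, 25.5, 8.7),
    rejection = stats::rnorm(cfg$n_dyads, 18.1, 3.7),
    warmth = stats::rnorm(cfg$n_dyads, 57.4, 7.0),
    control = stats::rnorm(cfg$n_dyads, 42.0, 4.8),
    srs_total = round(pmin(pmax(
      58 - 2.8 * tom_score + stats::rnorm(cfg$n_dyads, sd = 10), 0), 195)),
    tom_score = tom_score,
    ppvt = round(120 + 4.6 * age + stats::rnorm(cfg$n_dyads, sd = 10)),
    stringsAsFactors = FALSE
  )

  event_mask_true <- logical(cfg$n_tr)
  for (i in seq_len(nrow(schedule))) {
    event_mask_true[(schedule$onset_tr[i] + 1):schedule$offset_tr[i]] <- TRUE
  }

  structure(
    list(children = children, mothers = mothers, behavior = behavior,
         truth = list(schedule = schedule,
                      stimulus = list(ToM = s_tom, SPM = s_spm),
                      event_mask = event_mask_true,
                      w_child = w_child, coupling = coupling,
                      conflict_norm = conflict_norm, config = cfg)),
    class = "synth_dataset"
  )
}

#' Write a synthetic dataset as a fixture directory
#'
#' Emits one TSV + JSON-sidecar timecourse per subject, `behavior.tsv`, the
#' ground truth as `truth.json`, and a `manifest.json` recording the
#' configuration (including the seed).
#'
#' @param ds a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tc in c(ds$children, ds$mothers)) {
    write_timecourse(tc, file.path(dir, tc$subject_id))
  }
  .write_tsv(ds$behavior, file.path(dir, "behavior.tsv"))
  truth <- ds$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  jsonlite::write_json(unclass(ds$truth$config), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return a `synth_dataset` (ground truth restored from `truth.json`).
#' @export
read_fixture <- function(dir) {
  behavior <- .read_tsv(file.path(dir, "behavior.tsv"))
  children <- lapply(behavior$child_id, function(id)
    read_timecourse(file.path(dir, id)))
  mothers <- lapply(behavior$mother_id, function(id)
    read_timecourse(file.path(dir, id)))
  names(children) <- behavior$child_id
  names(mothers) <- behavior$mother_id
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$schedule <- as.data.frame(truth$schedule)
  structure(
    list(children = children, mothers = mothers, behavior = behavior,
         truth = truth),
    class = "synth_dataset"
  )
}
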