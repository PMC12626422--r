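# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately avoid the package's own code paths.

# run-scan event detector: explicit loop over every TR
bf_detect <- function(p, alpha, min_len) {
  sig <- p < alpha
  out <- list()
  t <- 1L
  while (t <= length(sig)) {
    if (sig[t]) {
      start <- t
      while (t <= length(sig) && sig[t]) t <- t + 1L
      if (t - start >= min_len) {
        out[[length(out) + 1]] <- c(onset = start - 1L, offset = t - 1L)
      }
    } else t <- t + 1L
  }
  if (length(out) == 0) {
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("onset", "offset")))
  } else do.call(rbind, out)
}

# textbook Pearson correlation from sums
bf_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# z-scored subject timecourse with given data matrix
make_tc <- function(data, subject_id = "s1", group = "adult",
                    tr_seconds = 2, zscore = TRUE) {
  tc <- subject_timecourse(subject_id, group, data, tr_seconds)
  if (zscore) znormalize(tc) else tc
}

# random z-scored timecourse on the default 13-ROI atlas
random_tc <- function(n_tr = 40, subject_id = "s1", group = "adult") {
  data <- matrix(rnorm(13 * n_tr), nrow = 13,
                 dimnames = list(load_default_atlas()$name, NULL))
  make_tc(data, subject_id, group)
}

# deterministic group stack: strong positive group response at `event_trs`,
# ~zero elsewhere; across-subject spread from fixed subject offsets
det_stack <- function(n_subj, n_tr, event_trs, amplitude = 1,
                      tr_seconds = 2) {
  offsets <- seq(-0.1, 0.1, length.out = n_subj)
  signal <- rep(0, n_tr)
  signal[event_trs + 1L] <- amplitude
  structure(
    list(network = "ToM",
         data = outer(offsets, rep(1, n_tr)) +
           matrix(rep(signal, n_subj), nrow = n_subj, byrow = TRUE),
         subject_ids = paste0("s", seq_len(n_subj)),
         tr_seconds = tr_seconds),
    class = "group_stack"
  )
}
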