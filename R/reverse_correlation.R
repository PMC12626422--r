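# Reverse-correlation event detection. Stimulus moments that reliably drive
# a network are found by testing, at every TR, whether the group-mean
# network response exceeds baseline (0), then keeping runs of consecutive
# significant TRs as "events".

#' Stack network-mean timecourses across subjects
#'
#' @param tcs list of z-scored `subject_timecourse` objects on a common TR
#'   grid.
#' @param which network selector passed to [network_mean_timecourse()].
#' @param atlas atlas defining network membership.
#' @return a `group_stack`: list with `network`, `data` (subjects x TR
#'   matrix), `subject_ids`, `tr_seconds`.
#' @export
group_stack <- function(tcs, which = c("ToM", "SPM", "all"),
                        atlas = load_default_atlas()) {
  which <- match.arg(which)
  .check(length(tcs) >= 3, "need at least 3 subjects, got %d", length(tcs))
  rows <- lapply(tcs, network_mean_timecourse, which = which, atlas = atlas)
  n_tr <- unique(lengths(rows))
  .check(length(n_tr) == 1L, "subjects have unequal TR counts")
  structure(
    list(network = which,
         data = do.call(rbind, rows),
         subject_ids = vapply(tcs, function(x) x$subject_id, character(1)),
         tr_seconds = tcs[[1]]$tr_seconds),
    class = "group_stack"
  )
}

#' Per-TR one-tailed t-test of the group response against baseline
#'
#' One-sample t-test of the across-subject values at each TR against 0 with
#' alternative "greater" (df = n - 1). A TR with zero across-subject
#' variance is degenerate but defined: p = 0 if the mean is positive, 0.5 if
#' exactly zero, 1 if negative, with a warning.
#'
#' @param stack a `group_stack` (or a subjects x TR matrix).
#' @return data frame with columns `tr` (0-based), `t`, `p`.
#' @export
per_tr_ttest <- function(stack) {
  data <- if (inherits(stack, "group_stack")) stack$data else stack
  n <- nrow(data)
  .check(n >= 3, "need at least 3 subjects, got %d", n)
  m <- colMeans(data)
  sds <- apply(data, 2L, stats::sd)
  tval <- m / (sds / sqrt(n))
  p <- stats::pt(tval, df = n - 1, lower.tail = FALSE)
  degen <- which(sds == 0)
  if (length(degen) > 0) {
    warning(sprintf("zero across-subject variance at %d TR(s); p set by sign of mean",
                    length(degen)), call. = FALSE)
    tval[degen] <- sign(m[degen]) * Inf
    tval[degen][m[degen] == 0] <- 0
    p[degen] <- ifelse(m[degen] > 0, 0, ifelse(m[degen] < 0, 1, 0.5))
  }
  data.frame(tr = seq_along(m) - 1L, t = tval, p = p)
}

#' Detect events as runs of consecutive significant TRs
#'
#' Maximal runs of TRs with `p < alpha` are kept when at least
#' `min_len_tr` TRs long. Intervals are half-open `[onset, offset)` in
#' 0-based TRs.
#'
#' @param pvals per-TR p-values (vector, or the data frame from
#'   [per_tr_ttest()]).
#' @param alpha significance threshold in (0, 1); default 0.05, one-tailed,
#'   uncorrected.
#' @param min_len_tr minimum run length in TRs (default 2).
#' @param tr_seconds TR duration used for `duration_s`.
#' @return an `event_table` data frame: `onset_tr`, `offset_tr`,
#'   `duration_s` (unranked; see [rank_and_label()]).
#' @export
detect_events <- function(pvals, alpha = 0.05, min_len_tr = 2,
                          tr_seconds = 2.0) {
  if (is.data.frame(pvals)) pvals <- pvals$p
  .check(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  .check(min_len_tr >= 1, "min_len_tr must be >= 1")
  sig <- pvals < alpha
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_len_tr
  tbl <- data.frame(
    onset_tr = starts[keep] - 1L,
    offset_tr = ends[keep],            # exclusive
    duration_s = runs$lengths[keep] * tr_seconds
  )
  class(tbl) <- c("event_table", "data.frame")
  attr(tbl, "tr_seconds") <- tr_seconds
  tbl
}

#' Rank events by peak response magnitude and label them
#'
#' The peak TR of an event is the argmax of the group-mean response inside
#' `[onset, offset)` (ties broken by the earliest TR). Rank 1 is the event
#' with the largest peak mean response; labels are the prefix plus the
#' zero-padded rank (e.g. `T01`, `P03`).
#'
#' @param events an `event_table` with non-overlapping events.
#' @param group_mean per-TR group-mean response vector.
#' @param prefix single character label prefix (`"T"` for ToM, `"P"` for
#'   social pain).
#' @return the event table with `peak_tr`, `peak_mean_response`, `rank` and
#'   `label` columns added, sorted by onset.
#' @export
rank_and_label <- function(events, group_mean, prefix = "T") {
  if (nrow(events) == 0) {
    events$peak_tr <- integer(0); events$peak_mean_response <- numeric(0)
    events$rank <- integer(0); events$label <- character(0)
    return(events)
  }
  .check(max(events$offset_tr) <= length(group_mean),
         "event extends beyond the group-mean series")
  peaks <- mapply(function(a, b) {
    seg <- group_mean[(a + 1):b]          # 0-based [a, b) -> 1-based a+1..b
    a + which.max(seg) - 1L               # which.max takes the earliest tie
  }, events$onset_tr, events$offset_tr)
  events$peak_tr <- as.integer(peaks)
  events$peak_mean_response <- group_mean[peaks + 1L]
  ord <- order(-events$peak_mean_response, events$onset_tr)
  events$rank[ord] <- seq_len(nrow(events))
  events$label <- sprintf("%s%02d", prefix, events$rank)
  events[order(events$onset_tr), , drop = FALSE]
}

#' Summarize an event table
#'
#' @param events an `event_table`.
#' @param tr_seconds TR duration in seconds.
#' @return list with `count`, `total_duration_s`, `mean_length_s`,
#'   `sd_length_s` (sample SD; `NaN` for fewer than 2 events).
#' @export
summarize_events <- function(events, tr_seconds = 2.0) {
  dur <- (events$offset_tr - events$onset_tr) * tr_seconds
  list(
    count = nrow(events),
    total_duration_s = sum(dur),
    mean_length_s = if (length(dur) == 0) NaN else mean(dur),
    sd_length_s = if (length(dur) < 2) NaN else stats::sd(dur)
  )
}

#' Build the ToM/SP-vs-other event mask
#'
#' Partitions the TR grid into `tom_sp` (inside any ToM or social-pain
#' event) and `other` TRs, and reports TRs claimed by both networks.
#'
#' @param tom_events,pain_events `event_table`s on the same TR grid.
#' @param n_tr total number of TRs.
#' @param tr_seconds TR duration, used for the seconds-based counts.
#' @return an `event_mask`: list with `tom_sp` (logical per TR), `overlap_trs`
#'   (0-based TRs flagged by both networks), and TR/second counts.
#' @export
build_event_mask <- function(tom_events, pain_events, n_tr, tr_seconds = 2.0) {
  in_events <- function(ev) {
    .check(nrow(ev) == 0 || (min(ev$onset_tr) >= 0 && max(ev$offset_tr) <= n_tr),
           "event exceeds the TR grid (n_tr = %d)", n_tr)
    flag <- logical(n_tr)
    for (i in seq_len(nrow(ev))) {
      flag[(ev$onset_tr[i] + 1):ev$offset_tr[i]] <- TRUE
    }
    flag
  }
  tom <- in_events(tom_events)
  pain <- in_events(pain_events)
  mask <- tom | pain
  structure(
    list(tom_sp = mask,
         overlap_trs = which(tom & pain) - 1L,
         n_tom_sp = sum(mask), n_other = sum(!mask),
         tom_sp_s = sum(mask) * tr_seconds,
         other_s = sum(!mask) * tr_seconds),
    class = "event_mask"
  )
}

#' Which adult events replicate in children?
#'
#' Runs event detection on the child stack and marks each adult event as
#' replicated when a child event overlaps it by at least `min_overlap_tr`
#' TRs (default 1; the matching rule is configurable because only the counts,
#' not the rule, are conventionally reported).
#'
#' @param child_stack a `group_stack` of child network timecourses.
#' @param adult_events adult `event_table` on the same TR grid.
#' @param alpha,min_len_tr detection parameters for the child pass.
#' @param min_overlap_tr minimum shared TRs to count as replicated; values
#'   in (0, 1) are read as a required fraction of the adult event's length.
#' @return logical vector, one entry per adult event; attribute
#'   `"child_events"` carries the child event table.
#' @export
child_event_replication <- function(child_stack, adult_events, alpha = 0.05,
                                    min_len_tr = 2, min_overlap_tr = 1) {
  child_ev <- detect_events(per_tr_ttest(child_stack), alpha = alpha,
                            min_len_tr = min_len_tr,
                            tr_seconds = child_stack$tr_seconds)
  rep_flag <- vapply(seq_len(nrow(adult_events)), function(i) {
    a0 <- adult_events$onset_tr[i]; a1 <- adult_events$offset_tr[i]
    need <- if (min_overlap_tr < 1) min_overlap_tr * (a1 - a0) else min_overlap_tr
    any(pmin(child_ev$offset_tr, a1) - pmax(child_ev$onset_tr, a0) >= need)
  }, logical(1))
  attr(rep_flag, "child_events") <- child_ev
  rep_flag
}
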