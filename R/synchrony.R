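# Inter-subject synchronization (ISS): temporal correlation between the
# grand social-network timecourses of a child and a partner (own mother, or
# the average of all non-mother adults), whole-run or event-restricted.

# select TRs for a condition given an optional event mask
.select_trs <- function(n_tr, mask, condition) {
  switch(condition,
    all = rep(TRUE, n_tr),
    tom_sp = { .check(!is.null(mask), "condition 'tom_sp' needs an event mask")
               mask$tom_sp },
    other = { .check(!is.null(mask), "condition 'other' needs an event mask")
              !mask$tom_sp })
}

#' Dyadic inter-subject synchronization
#'
#' Pearson correlation between a child's and a partner's network-mean
#' timecourses over the selected TRs, with the Fisher r-to-z transform
#' (r clipped to `|r| <= 1 - 1e-7`).
#'
#' @param child_series,partner_series numeric vectors of equal length
#'   (grand network means of z-scored data; see
#'   [network_mean_timecourse()]).
#' @param mask optional `event_mask`.
#' @param condition `"all"`, `"tom_sp"` or `"other"`.
#' @param min_tr minimum selected TRs (default 10).
#' @param child_id,partner identifiers recorded in the result.
#' @return an `iss_record`: list with `child_id`, `partner`, `condition`,
#'   `r`, `z`, `n_tr_used`.
#' @export
dyad_iss <- function(child_series, partner_series, mask = NULL,
                     condition = c("all", "tom_sp", "other"), min_tr = 10,
                     child_id = "child", partner = "mother") {
  condition <- match.arg(condition)
  .check(length(child_series) == length(partner_series),
         "series lengths differ: %d vs %d",
         length(child_series), length(partner_series))
  sel <- .select_trs(length(child_series), mask, condition)
  .check(length(sel) == length(child_series), "mask does not match TR grid")
  .check(sum(sel) >= min_tr, "only %d TRs selected; need at least %d",
         sum(sel), min_tr)
  a <- child_series[sel]; b <- partner_series[sel]
  .check(stats::sd(a) > 0 && stats::sd(b) > 0,
         "zero variance over selected TRs")
  r <- stats::cor(a, b)
  structure(
    list(child_id = child_id, partner = partner, condition = condition,
         r = r, z = fisher_z(r), n_tr_used = sum(sel)),
    class = "iss_record"
  )
}

#' Child-stranger inter-subject synchronization
#'
#' The stranger partner series is the unweighted TR-wise mean of all adult
#' series except the child's own mother (`method = "average_series"`, the
#' default). The alternative reading — the mean of the pairwise
#' child-adult correlations, Fisher-averaged — is available as
#' `method = "mean_pairwise"`.
#'
#' @param child_series numeric grand-network series of the child.
#' @param adult_series_by_id named list of adult grand-network series.
#' @param own_mother_id name of the child's mother in that list.
#' @param method `"average_series"` or `"mean_pairwise"`.
#' @param ... passed to [dyad_iss()] (`mask`, `condition`, `min_tr`).
#' @param child_id identifier recorded in the result.
#' @return an `iss_record` with `partner = "stranger"`.
#' @export
stranger_iss <- function(child_series, adult_series_by_id, own_mother_id,
                         method = c("average_series", "mean_pairwise"),
                         ..., child_id = "child") {
  method <- match.arg(method)
  .check(own_mother_id %in% names(adult_series_by_id),
         "own mother '%s' not found in the adult set", own_mother_id)
  others <- adult_series_by_id[names(adult_series_by_id) != own_mother_id]
  .check(length(others) >= 1, "need at least 2 adults for a stranger average")
  if (method == "average_series") {
    partner <- Reduce(`+`, others) / length(others)
    rec <- dyad_iss(child_series, partner, ..., child_id = child_id,
                    partner = "stranger")
  } else {
    recs <- lapply(others, function(s)
      dyad_iss(child_series, s, ..., child_id = child_id, partner = "stranger"))
    zs <- vapply(recs, function(r) r$z, numeric(1))
    rec <- recs[[1]]
    rec$z <- mean(zs)
    rec$r <- tanh(rec$z)
  }
  rec
}

#' Long ISS table for all children, partners and conditions
#'
#' One row per child x partner (mother, stranger) x condition (whole run
#' plus, when a mask is given, event and non-event TRs), in deterministic
#' (child, partner, condition) order.
#'
#' @param child_series_by_id named list of child grand-network series.
#' @param adult_series_by_id named list of adult grand-network series.
#' @param mother_of named character vector mapping child id to mother id.
#' @param mask optional `event_mask`; `NULL` emits only `all` rows.
#' @param ... passed to [dyad_iss()] / [stranger_iss()].
#' @return data frame: `child_id`, `partner`, `condition`, `r`, `z`,
#'   `n_tr_used`.
#' @export
iss_contrast_table <- function(child_series_by_id, adult_series_by_id,
                               mother_of, mask = NULL, ...) {
  conditions <- if (is.null(mask)) "all" else c("all", "tom_sp", "other")
  rows <- list()
  for (cid in sort(names(child_series_by_id))) {
    mid <- mother_of[[cid]]
    .check(!is.null(mid) && mid %in% names(adult_series_by_id),
           "no mother series for child '%s'", cid)
    for (partner in c("mother", "stranger")) {
      for (cond in conditions) {
        rec <- if (partner == "mother") {
          dyad_iss(child_series_by_id[[cid]], adult_series_by_id[[mid]],
                   mask = mask, condition = cond, child_id = cid,
                   partner = "mother", ...)
        } else {
          stranger_iss(child_series_by_id[[cid]], adult_series_by_id, mid,
                       mask = mask, condition = cond, child_id = cid, ...)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          child_id = rec$child_id, partner = rec$partner,
          condition = rec$condition, r = rec$r, z = rec$z,
          n_tr_used = rec$n_tr_used, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
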