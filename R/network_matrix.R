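# Inter-region correlation matrices and the neural-maturity score: how
# similar is a child's ROI-by-ROI connectivity pattern to the adult pattern,
# over the whole run or restricted to event/non-event TRs.

#' Per-subject inter-region correlation matrix
#'
#' Pairwise Pearson correlation between every pair of ROI timecourses over
#' the selected TRs, clipped to `|r| <= 1 - 1e-7` and Fisher z-transformed.
#' The diagonal is stored as `NaN` and excluded from every summary.
#'
#' @param tc a z-scored `subject_timecourse`.
#' @param mask optional `event_mask` (from [build_event_mask()]); with
#'   `condition = "tom_sp"` only event TRs are used, with `"other"` only
#'   non-event TRs.
#' @param condition `"all"`, `"tom_sp"` or `"other"`.
#' @param min_tr minimum number of selected TRs (default 10); fewer is an
#'   error because the correlations become unstable.
#' @return a `conn_matrix`: list with `subject_id`, `condition`, `z`
#'   (ROI x ROI Fisher-z matrix in atlas order), `n_tr_used`.
#' @export
interregion_matrix <- function(tc, mask = NULL,
                               condition = c("all", "tom_sp", "other"),
                               min_tr = 10) {
  condition <- match.arg(condition)
  .check(tc$zscored, "timecourse must be z-scored")
  sel <- switch(condition,
    all = rep(TRUE, ncol(tc$data)),
    tom_sp = { .check(!is.null(mask), "condition '%s' needs an event mask",
                      condition); mask$tom_sp },
    other = { .check(!is.null(mask), "condition '%s' needs an event mask",
                     condition); !mask$tom_sp })
  .check(length(sel) == ncol(tc$data),
         "mask length %d does not match %d TRs", length(sel), ncol(tc$data))
  .check(sum(sel) >= min_tr, "only %d TRs selected; need at least %d",
         sum(sel), min_tr)
  sub <- tc$data[, sel, drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    nm <- rownames(sub)
    bad <- if (is.null(nm)) paste("row", which(sds == 0)) else nm[sds == 0]
    stop(sprintf("zero-variance ROI over selected TRs: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  z <- fisher_z(stats::cor(t(sub)))
  diag(z) <- NaN
  structure(
    list(subject_id = tc$subject_id, condition = condition, z = z,
         n_tr_used = sum(sel)),
    class = "conn_matrix"
  )
}

#' Within- and across-network block means
#'
#' Means over the unique unordered ROI pairs inside each network block
#' (6*5/2 = 15 ToM pairs, 7*6/2 = 21 SPM pairs with the default atlas) and
#' over all ToM-by-SPM pairs (6*7 = 42).
#'
#' @param cm a `conn_matrix` (or a bare ROI x ROI matrix in atlas order).
#' @param atlas the `network_atlas` defining block membership.
#' @param scale `"z"` (default) averages the stored Fisher-z entries;
#'   `"r"` back-transforms entries with `tanh` first.
#' @return named list: `within_tom`, `within_spm`, `across`.
#' @export
block_means <- function(cm, atlas = load_default_atlas(),
                        scale = c("z", "r")) {
  scale <- match.arg(scale)
  z <- if (inherits(cm, "conn_matrix")) cm$z else cm
  .check(nrow(z) == nrow(atlas), "matrix order %d != atlas size %d",
         nrow(z), nrow(atlas))
  if (scale == "r") z <- tanh(z)
  tom <- atlas_indices(atlas, "ToM")
  spm <- atlas_indices(atlas, "SPM")
  upper_mean <- function(idx) {
    block <- z[idx, idx, drop = FALSE]
    mean(block[upper.tri(block)])
  }
  list(
    within_tom = upper_mean(tom),
    within_spm = upper_mean(spm),
    across = mean(z[tom, spm])
  )
}

#' Entrywise mean connectivity matrix for a group of subjects
#'
#' @param matrices list of `conn_matrix` objects sharing atlas order and
#'   condition.
#' @return a `conn_matrix` with `subject_id = "group_mean"`; the diagonal
#'   stays `NaN`.
#' @export
group_mean_matrix <- function(matrices) {
  .check(length(matrices) >= 1, "empty group: no matrices to average")
  conds <- unique(vapply(matrices, function(m) m$condition, character(1)))
  .check(length(conds) == 1L, "matrices mix conditions: %s",
         paste(conds, collapse = ", "))
  z <- Reduce(`+`, lapply(matrices, function(m) m$z)) / length(matrices)
  structure(
    list(subject_id = "group_mean", condition = conds, z = z,
         n_tr_used = NA_integer_),
    class = "conn_matrix"
  )
}

# strictly-lower-triangle vectorization of a conn matrix (78 entries for 13
# ROIs); the similarity vector used by neural_maturity
conn_vector <- function(cm, scale = c("z", "r")) {
  scale <- match.arg(scale)
  z <- cm$z
  v <- z[lower.tri(z)]
  if (scale == "r") tanh(v) else v
}

#' Neural maturity of a child
#'
#' The child's Fisher-z connectivity matrix is vectorized (strictly lower
#' triangle, 78 entries for the default 13-ROI atlas) and Pearson-correlated
#' with each adult's vector; the maturity score is the plain arithmetic mean
#' of the per-adult correlations (r scale). A Fisher-z mean of the
#' per-adult similarities is available via `average`.
#'
#' @param child a `conn_matrix`.
#' @param adults list of `conn_matrix` objects with the same atlas order and
#'   condition as the child.
#' @param scale vectorize the `"z"` (default) or back-transformed `"r"`
#'   entries.
#' @param average `"r"` (plain mean of per-adult correlations, default) or
#'   `"fisher"` (mean on the z scale, back-transformed).
#' @return a `maturity_score`: list with `subject_id`, `condition`, `value`,
#'   `n_adults`, and the `per_adult` correlation vector.
#' @export
neural_maturity <- function(child, adults, scale = c("z", "r"),
                            average = c("r", "fisher")) {
  scale <- match.arg(scale)
  average <- match.arg(average)
  .check(length(adults) >= 1, "need at least one adult matrix")
  conds <- vapply(adults, function(m) m$condition, character(1))
  .check(all(conds == child$condition),
         "condition mismatch: child '%s' vs adults '%s'",
         child$condition, paste(unique(conds), collapse = ", "))
  cv <- conn_vector(child, scale)
  .check(stats::sd(cv) > 0, "child connectivity vector has zero variance")
  per_adult <- vapply(adults, function(a) {
    av <- conn_vector(a, scale)
    .check(stats::sd(av) > 0,
           "adult %s connectivity vector has zero variance", a$subject_id)
    stats::cor(cv, av)
  }, numeric(1))
  value <- if (average == "r") mean(per_adult) else tanh(mean(atanh(clip_r(per_adult))))
  structure(
    list(subject_id = child$subject_id, condition = child$condition,
         value = value, n_adults = length(adults), per_adult = per_adult),
    class = "maturity_score"
  )
}

#' Neural maturity restricted to event conditions
#'
#' Computes condition-restricted connectivity matrices (event TRs and
#' non-event TRs) for every child and adult, then the child-to-adult
#' maturity score within matching conditions.
#'
#' @param child_tcs,adult_tcs lists of z-scored `subject_timecourse`s.
#' @param mask an `event_mask` on the common TR grid.
#' @param conditions conditions to compute (default both restricted ones).
#' @param ... passed to [interregion_matrix()] and [neural_maturity()].
#' @return data frame with one row per child x condition: `subject_id`,
#'   `condition`, `value`, `n_adults`.
#' @export
maturity_by_condition <- function(child_tcs, adult_tcs, mask,
                                  conditions = c("tom_sp", "other"), ...) {
  rows <- lapply(conditions, function(cond) {
    adult_ms <- lapply(adult_tcs, interregion_matrix, mask = mask,
                       condition = cond)
    vals <- lapply(child_tcs, function(tc) {
      ms <- neural_maturity(interregion_matrix(tc, mask = mask,
                                               condition = cond), adult_ms)
      data.frame(subject_id = ms$subject_id, condition = cond,
                 value = ms$value, n_adults = ms$n_adults,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, vals)
  })
  do.call(rbind, rows)
}

#' Assign children to age groups
#'
#' Either by explicit ranges (the default three bands: Pre-junior 3.3-4.8,
#' Junior 5.0-5.8, Senior 6.0-8.0 years; ages falling in a gap or outside
#' all bands are an error) or by an equal-count tertile split on age rank
#' with ties broken by stable input order — the right choice for an
#' arbitrary cohort.
#'
#' @param behavior data frame with columns `child_id` (or `subject_id`) and
#'   `age` (years).
#' @param spec `"default"`, `"tertile"`, or a data frame with columns
#'   `group`, `min_age`, `max_age` (inclusive).
#' @return the behavior table with an `age_group` factor column added;
#'   attribute `"group_sizes"` records the counts.
#' @export
assign_age_groups <- function(behavior, spec = "default") {
  .check("age" %in% names(behavior), "behavior table needs an 'age' column")
  age <- behavior$age
  .check(all(is.finite(age) & age > 0), "ages must be present and positive")
  id_col <- intersect(c("child_id", "subject_id"), names(behavior))[1]
  ids <- if (is.na(id_col)) as.character(seq_along(age)) else behavior[[id_col]]

  lev <- c("Pre-junior", "Junior", "Senior")
  if (identical(spec, "tertile")) {
    n <- length(age)
    sizes <- rep(n %/% 3, 3) + c(rep(1, n %% 3), rep(0, 3 - n %% 3))
    ord <- order(age)            # stable: ties keep input order
    grp <- character(n)
    grp[ord] <- rep(lev, times = sizes)
  } else {
    if (identical(spec, "default")) {
      spec <- data.frame(group = lev,
                         min_age = c(3.3, 5.0, 6.0),
                         max_age = c(4.8, 5.8, 8.0))
    }
    grp <- vapply(seq_along(age), function(i) {
      hit <- which(age[i] >= spec$min_age & age[i] <= spec$max_age)
      .check(length(hit) >= 1, "child %s (age %g) falls outside all age ranges",
             ids[i], age[i])
      spec$group[hit[1]]
    }, character(1))
    lev <- spec$group
  }
  behavior$age_group <- factor(grp, levels = lev)
  attr(behavior, "group_sizes") <- table(behavior$age_group)
  behavior
}
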