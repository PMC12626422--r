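# Inferential layer: correlation and partial-correlation tests,
# Benjamini-Hochberg FDR, two-sample/paired t-tests, and two-way ANOVA,
# all returned in a common tidy "stat_result" row.

stat_result <- function(name, estimate, df, p_raw, n, statistic = NA_real_,
                        family_id = NA_character_) {
  data.frame(name = name, estimate = estimate, statistic = statistic,
             df = df, p_raw = p_raw, p_fdr = NA_real_,
             family_id = family_id, n = n, stringsAsFactors = FALSE)
}

#' Pearson correlation test
#'
#' @param x,y numeric vectors, length >= 3, nonzero variance.
#' @param name label for the result row.
#' @return one-row data frame: `name`, `estimate` (r), `statistic` (t),
#'   `df` (n - 2), `p_raw` (two-tailed), `n`.
#' @export
pearson_test <- function(x, y, name = "pearson") {
  .check(length(x) == length(y), "x and y lengths differ")
  n <- length(x)
  .check(n >= 3, "need n >= 3, got %d", n)
  .check(all(is.finite(x)) && all(is.finite(y)), "non-finite input")
  .check(stats::sd(x) > 0 && stats::sd(y) > 0, "zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  stat_result(name, estimate = unname(ct$estimate),
              statistic = unname(ct$statistic), df = unname(ct$parameter),
              p_raw = ct$p.value, n = n)
}

#' Partial correlation controlling for covariates
#'
#' Correlates the OLS residuals of `x` and `y` on `[intercept | covariates]`.
#' With a single covariate this equals the textbook closed form
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`. The test statistic
#' is `t = r sqrt(df / (1 - r^2))` with `df = n - 2 - k`.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector, matrix or data frame (k columns).
#' @param name label for the result row.
#' @return one-row data frame as in [pearson_test()] with `df = n - 2 - k`.
#' @export
partial_correlation <- function(x, y, covariates, name = "partial") {
  z <- as.matrix(covariates)
  n <- length(x)
  k <- ncol(z)
  .check(length(y) == n && nrow(z) == n, "input lengths differ")
  .check(n > k + 2, "need n > k + 2 (n = %d, k = %d)", n, k)
  X <- cbind(1, z)
  qx <- qr(X)
  .check(qx$rank == ncol(X), "covariate design is rank deficient")
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  .check(stats::sd(rx) > 1e-10 * stats::sd(x) &&
           stats::sd(ry) > 1e-10 * stats::sd(y),
         "residual variance is zero (covariate explains x or y exactly)")
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- clip_r(r) * sqrt(df / (1 - clip_r(r)^2))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  stat_result(name, estimate = r, statistic = tval, df = df, p_raw = p, n = n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity; ties are stable
#' (adjusted values follow their raw p-values under any input permutation).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param family_id optional family label, recorded as an attribute.
#' @return adjusted p-values in input order.
#' @export
fdr_bh <- function(pvals, family_id = NULL) {
  .check(all(is.finite(pvals)) && all(pvals >= 0 & pvals <= 1),
         "p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  if (!is.null(family_id)) attr(adj, "family_id") <- family_id
  adj
}

#' Apply BH-FDR within named families of a results table
#'
#' @param results data frame of stacked stat-result rows.
#' @return the table with `p_fdr` filled per `family_id` (rows with
#'   `NA` family are left unadjusted).
#' @export
adjust_families <- function(results) {
  for (fam in unique(stats::na.omit(results$family_id))) {
    idx <- which(results$family_id == fam)
    results$p_fdr[idx] <- fdr_bh(results$p_raw[idx])
  }
  results
}

#' Two-sample t-test (pooled variance by default)
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param welch use the Welch unequal-variance form instead of the classic
#'   pooled-variance Student test.
#' @param name label.
#' @return one-row stat-result data frame (two-tailed).
#' @export
two_sample_t <- function(a, b, welch = FALSE, name = "two_sample_t") {
  .check(length(a) >= 2 && length(b) >= 2, "each group needs n >= 2")
  tt <- stats::t.test(a, b, var.equal = !welch)
  stat_result(name, estimate = unname(diff(rev(tt$estimate))),
              statistic = unname(tt$statistic), df = unname(tt$parameter),
              p_raw = tt$p.value, n = length(a) + length(b))
}

#' Paired t-test
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @param name label.
#' @return one-row stat-result data frame (two-tailed).
#' @export
paired_t <- function(a, b, name = "paired_t") {
  .check(length(a) == length(b), "paired samples must have equal length")
  .check(length(a) >= 2, "need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    # identical pairwise differences: t defined by the sign of the shift
    tval <- sign(mean(d)) * if (mean(d) == 0) 0 else Inf
    return(stat_result(name, estimate = mean(d), statistic = tval,
                       df = length(a) - 1,
                       p_raw = if (mean(d) == 0) 1 else 0, n = length(a)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  stat_result(name, estimate = unname(tt$estimate),
              statistic = unname(tt$statistic), df = unname(tt$parameter),
              p_raw = tt$p.value, n = length(a))
}

#' Two-way fixed-effects ANOVA with interaction
#'
#' Fits `y ~ A * B` and reports Type-II sums-of-squares F tests for the two
#' main effects and the interaction (Type II matches the sequential table on
#' balanced designs and is robust to mild imbalance).
#'
#' @param data data frame.
#' @param y,factor_a,factor_b column names (response, two factors).
#' @return data frame with one stat-result row per effect; `estimate` holds
#'   F, `df` the numerator df; attribute `"df_residual"` the denominator df.
#' @export
anova_twoway <- function(data, y, factor_a, factor_b) {
  fa <- factor(data[[factor_a]])
  fb <- factor(data[[factor_b]])
  .check(nlevels(fa) >= 2, "factor '%s' has fewer than 2 levels", factor_a)
  .check(nlevels(fb) >= 2, "factor '%s' has fewer than 2 levels", factor_b)
  cells <- table(fa, fb)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop(sprintf("empty design cell(s): %s",
                 paste(sprintf("%s x %s", rownames(cells)[empty[, 1]],
                               colnames(cells)[empty[, 2]]), collapse = ", ")),
         call. = FALSE)
  }
  d <- data.frame(.y = data[[y]], .a = fa, .b = fb)
  fit <- stats::lm(.y ~ .a * .b, data = d)
  tab <- car::Anova(fit, type = 2)
  effects <- c(.a = factor_a, .b = factor_b, `.a:.b` =
                 paste0(factor_a, ":", factor_b))
  rows <- lapply(names(effects), function(term) {
    stat_result(effects[[term]], estimate = tab[term, "F value"],
                statistic = tab[term, "F value"], df = tab[term, "Df"],
                p_raw = tab[term, "Pr(>F)"], n = nrow(d))
  })
  out <- do.call(rbind, rows)
  attr(out, "df_residual") <- tab["Residuals", "Df"]
  out
}
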