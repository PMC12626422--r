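test_that("inter-region matrices match brute-force Pearson with clipping", {
  tc <- make_tc(rbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(3, 2, 1)),
                zscore = TRUE)
  # identical rows correlate 1 -> clipped before atanh
  expect_warning(cm <- interregion_matrix(tc, min_tr = 3), NA)
  expect_equal(cm$z[1, 2], atanh(1 - 1e-7))
  expect_equal(cm$z[1, 3], atanh(-(1 - 1e-7)))
  expect_equal(cm$z, t(cm$z))
  expect_true(all(is.nan(diag(cm$z))))
  expect_equal(cm$n_tr_used, 3)

  set.seed(31)
  tc2 <- random_tc(40)
  cm2 <- interregion_matrix(tc2)
  for (i in 1:5) {
    a <- sample(13, 1); b <- sample(setdiff(1:13, a), 1)
    expect_equal(cm2$z[a, b],
                 atanh(bf_pearson(tc2$data[a, ], tc2$data[b, ])),
                 tolerance = 1e-12)
  }
})

test_that("condition restriction enforces the TR floor and names flat ROIs", {
  set.seed(32)
  tc <- random_tc(20)
  mask <- build_event_mask(data.frame(onset_tr = 0L, offset_tr = 2L),
                           data.frame(onset_tr = integer(0),
                                      offset_tr = integer(0)), 20)
  expect_error(interregion_matrix(tc, mask, condition = "tom_sp"),
               "need at least 10")
  ok <- interregion_matrix(tc, mask, condition = "other")
  expect_equal(ok$n_tr_used, 18)
  expect_equal(ok$condition, "other")

  flat <- tc
  flat$data["PC", 3:20] <- flat$data["PC", 3]  # constant over "other" TRs
  expect_error(interregion_matrix(flat, mask, condition = "other"), "PC")
})

test_that("block means equal explicit pair enumeration", {
  atlas <- load_default_atlas()
  tom <- which(atlas$network == "ToM"); spm <- which(atlas$network == "SPM")

  # constant blocks
  z <- matrix(NA_real_, 13, 13)
  z[tom, tom] <- 0.5; z[spm, spm] <- 0.3
  z[tom, spm] <- -0.1; z[spm, tom] <- -0.1
  diag(z) <- NaN
  bm <- block_means(z, atlas)
  expect_equal(unlist(bm), c(within_tom = 0.5, within_spm = 0.3,
                             across = -0.1))

  # random symmetric matrix vs a brute-force loop over unordered pairs
  set.seed(33)
  r <- matrix(rnorm(169), 13); r <- (r + t(r)) / 2; diag(r) <- NaN
  bm2 <- block_means(r, atlas)
  pair_mean <- function(idx) {
    acc <- c()
    for (i in idx) for (j in idx) if (i < j) acc <- c(acc, r[i, j])
    mean(acc)
  }
  cross <- c(); for (i in tom) for (j in spm) cross <- c(cross, r[i, j])
  expect_equal(bm2$within_tom, pair_mean(tom), tolerance = 1e-12)
  expect_equal(bm2$within_spm, pair_mean(spm), tolerance = 1e-12)
  expect_equal(bm2$across, mean(cross), tolerance = 1e-12)
})

test_that("group-mean matrices average entrywise and keep the NaN diagonal", {
  set.seed(34)
  cms <- lapply(1:3, function(i) interregion_matrix(random_tc(30)))
  gm <- group_mean_matrix(cms)
  expect_equal(gm$z[2, 5],
               mean(sapply(cms, function(m) m$z[2, 5])), tolerance = 1e-12)
  expect_true(all(is.nan(diag(gm$z))))

  same <- group_mean_matrix(cms[c(1, 1)])
  expect_equal(same$z, cms[[1]]$z)

  neg <- cms[[1]]; neg$z <- -neg$z; diag(neg$z) <- NaN
  zero <- group_mean_matrix(list(cms[[1]], neg))
  expect_equal(zero$z[lower.tri(zero$z)],
               rep(0, 78), tolerance = 1e-12)
  expect_error(group_mean_matrix(list()), "empty")
})

test_that("neural maturity averages per-adult similarities on the r scale", {
  set.seed(35)
  child <- interregion_matrix(random_tc(40, "c1", "child"))
  # identical matrices -> perfect similarity
  expect_equal(neural_maturity(child, list(child, child))$value, 1.0,
               tolerance = 1e-9)

  # exact anti-correlation with a single adult
  anti <- child
  v <- child$z[lower.tri(child$z)]
  anti$z[lower.tri(anti$z)] <- -v + 2 * mean(v)  # reflect around the mean
  anti$z <- t(anti$z); anti$z[lower.tri(anti$z)] <- -v + 2 * mean(v)
  diag(anti$z) <- NaN
  expect_equal(neural_maturity(child, list(anti))$value, -1.0,
               tolerance = 1e-9)

  adults <- lapply(1:3, function(i)
    interregion_matrix(random_tc(40, paste0("a", i))))
  ms <- neural_maturity(child, adults)
  hand <- sapply(adults, function(a)
    bf_pearson(child$z[lower.tri(child$z)], a$z[lower.tri(a$z)]))
  expect_equal(ms$value, mean(hand), tolerance = 1e-12)
  expect_equal(ms$n_adults, 3)

  # invariant to a common ROI relabeling of child and adults
  perm <- sample(13)
  permute <- function(cm) { cm$z <- cm$z[perm, perm]; cm }
  ms_p <- neural_maturity(permute(child), lapply(adults, permute))
  expect_equal(ms_p$value, ms$value, tolerance = 1e-12)

  bad <- adults[[1]]; bad$condition <- "tom_sp"
  expect_error(neural_maturity(child, list(bad)), "condition mismatch")
})

test_that("maturity never decreases as child loading approaches the adult", {
  # noise-free construction: shared stimulus plus fixed per-ROI signatures
  set.seed(36)
  n_tr <- 60
  atlas <- load_default_atlas()
  s <- sin(2 * pi * seq_len(n_tr) / 20)
  sig <- matrix(rnorm(13 * n_tr), nrow = 13, dimnames = list(atlas$name, NULL))
  build <- function(w) {
    net_s <- outer(ifelse(atlas$network == "ToM", 1, -1), s)
    make_tc(w * net_s + sig, zscore = TRUE)
  }
  adult_cm <- list(interregion_matrix(build(1.0)))
  vals <- sapply(seq(0.2, 1.0, by = 0.1), function(w)
    neural_maturity(interregion_matrix(build(w)), adult_cm)$value)
  expect_true(all(diff(vals) >= -1e-12))
  expect_equal(vals[length(vals)], 1.0, tolerance = 1e-9)
})

test_that("condition-restricted maturity matches the whole run on a full mask", {
  set.seed(37)
  children <- lapply(1:3, function(i) random_tc(30, paste0("c", i), "child"))
  adults <- lapply(1:3, function(i) random_tc(30, paste0("a", i)))
  full_mask <- build_event_mask(data.frame(onset_tr = 0L, offset_tr = 30L),
                                data.frame(onset_tr = integer(0),
                                           offset_tr = integer(0)), 30)
  bycond <- maturity_by_condition(children, adults, full_mask,
                                  conditions = "tom_sp")
  whole <- sapply(children, function(tc)
    neural_maturity(interregion_matrix(tc),
                    lapply(adults, interregion_matrix))$value)
  expect_equal(bycond$value, unname(whole), tolerance = 1e-12)
})

test_that("age groups follow the published bands or an equal tertile split", {
  b <- data.frame(child_id = c("a", "b", "c"), age = c(4.1, 5.5, 6.7))
  g <- assign_age_groups(b)
  expect_equal(as.character(g$age_group),
               c("Pre-junior", "Junior", "Senior"))

  set.seed(38)
  b34 <- data.frame(child_id = sprintf("c%02d", 1:34), age = runif(34, 3, 8))
  g34 <- assign_age_groups(b34, "tertile")
  expect_equal(as.numeric(table(g34$age_group)), c(12, 11, 11))
  expect_true(all(g34$age[g34$age_group == "Pre-junior"] <=
                    min(g34$age[g34$age_group == "Senior"])))

  expect_error(assign_age_groups(data.frame(child_id = "x", age = 2.0)),
               "x.*outside|outside")
})
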