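test_that("per-TR t-test matches the closed form and handles degenerate TRs", {
  vals <- c(0.5, -0.5, 0.1, -0.1)
  stack <- matrix(vals, ncol = 1)
  res <- per_tr_ttest(stack)
  t_hand <- mean(vals) / (sd(vals) / sqrt(4))
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$p, pt(t_hand, df = 3, lower.tail = FALSE),
               tolerance = 1e-12)

  # zero across-subject variance: p decided by the sign of the mean
  degen <- cbind(rep(1, 4), rep(0, 4), rep(-2, 4), vals)
  expect_warning(res2 <- per_tr_ttest(degen), "zero across-subject variance")
  expect_equal(res2$p[1:3], c(0, 0.5, 1))
  expect_equal(res2$t[2], 0)

  expect_error(per_tr_ttest(matrix(1:4, nrow = 2)), "at least 3")
})

test_that("event detection matches the printed examples", {
  ev <- detect_events(c(0.01, 0.01, 0.20, 0.04), alpha = 0.05,
                      min_len_tr = 2, tr_seconds = 2)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_tr, 0L)
  expect_equal(ev$offset_tr, 2L)
  expect_equal(ev$duration_s, 4)

  expect_equal(nrow(detect_events(rep(0.5, 20))), 0)

  all_sig <- detect_events(rep(0.001, 10), tr_seconds = 2)
  expect_equal(all_sig$onset_tr, 0L)
  expect_equal(all_sig$offset_tr, 10L)
  expect_equal(all_sig$duration_s, 20)

  expect_error(detect_events(runif(5), alpha = 1.5), "alpha")
})

test_that("event detection equals the brute-force run scan on random inputs", {
  set.seed(101)
  for (i in 1:300) {
    p <- runif(sample(10:60, 1))
    alpha <- runif(1, 0.05, 0.6)
    min_len <- sample(1:3, 1)
    ev <- detect_events(p, alpha = alpha, min_len_tr = min_len)
    bf <- bf_detect(p, alpha, min_len)
    expect_identical(cbind(onset = ev$onset_tr, offset = ev$offset_tr),
                     rbind(bf[, , drop = FALSE]))
  }
})

test_that("events are ranked by peak magnitude with deterministic tie-breaks", {
  gm <- c(0.2, 0.8, 0.8, 0.1, 1.2, 0.9, 0.0, 0.0)
  ev <- detect_events(c(0.01, 0.01, 0.01, 0.5, 0.01, 0.01, 0.9, 0.9),
                      tr_seconds = 2)
  lab <- rank_and_label(ev, gm, prefix = "T")
  # event [0,3) peaks 0.8 (tie at TRs 1 and 2 -> earliest, TR 1)
  expect_equal(lab$peak_tr, c(1L, 4L))
  expect_equal(lab$label, c("T02", "T01"))
  expect_equal(lab$rank, c(2L, 1L))
  expect_equal(lab$peak_mean_response, c(0.8, 1.2))

  labp <- rank_and_label(ev, gm, prefix = "P")
  expect_equal(labp$label, c("P02", "P01"))
})

test_that("event summaries use sample SD and survive empty tables", {
  ev <- data.frame(onset_tr = seq(0, 70, by = 10)[1:8],
                   offset_tr = seq(0, 70, by = 10)[1:8] + 1L)
  s <- summarize_events(ev, tr_seconds = 6.5)
  expect_equal(s$count, 8)
  expect_equal(s$total_duration_s, 52)
  expect_equal(s$mean_length_s, 6.5)
  expect_equal(s$sd_length_s, 0)

  one <- summarize_events(ev[1, ], tr_seconds = 2)
  expect_true(is.nan(one$sd_length_s))

  none <- summarize_events(ev[0, ], tr_seconds = 2)
  expect_equal(none$count, 0)
  expect_equal(none$total_duration_s, 0)
  expect_true(is.nan(none$mean_length_s) && is.nan(none$sd_length_s))
})

test_that("the event mask partitions the grid and reports overlaps", {
  tom <- data.frame(onset_tr = 2L, offset_tr = 4L)
  pain <- data.frame(onset_tr = 3L, offset_tr = 6L)
  mask <- build_event_mask(tom, pain, n_tr = 8, tr_seconds = 2)
  expect_equal(which(mask$tom_sp) - 1L, 2:5)
  expect_equal(mask$overlap_trs, 3L)
  expect_equal(mask$n_tom_sp, 4)
  expect_equal(mask$n_other, 4)
  expect_equal(mask$tom_sp_s, 8)

  disj <- build_event_mask(tom, data.frame(onset_tr = 5L, offset_tr = 7L), 8)
  expect_length(disj$overlap_trs, 0)

  empty <- build_event_mask(tom[0, ], pain[0, ], 8)
  expect_equal(empty$n_other, 8)

  expect_error(build_event_mask(data.frame(onset_tr = 5L, offset_tr = 10L),
                                pain[0, ], 8), "exceeds")
})

test_that("child replication flags adult events by shared-TR overlap", {
  stack <- det_stack(10, 40, event_trs = c(5:8, 20:23))
  adult_ev <- detect_events(per_tr_ttest(stack), tr_seconds = 2)
  expect_equal(nrow(adult_ev), 2)

  # identical child stack -> everything replicates
  expect_true(all(child_event_replication(stack, adult_ev)))

  # child events abutting (no shared TR) the adult events -> no replication
  shifted <- det_stack(10, 40, event_trs = c(9:12, 24:27))
  expect_false(any(child_event_replication(shifted, adult_ev)))

  # fractional overlap rule: child covering half an event
  half <- det_stack(10, 40, event_trs = c(7:8, 22:23))
  expect_true(all(child_event_replication(stack, adult_ev,
                                          min_overlap_tr = 0.5)))
  expect_true(all(child_event_replication(half, adult_ev,
                                          min_overlap_tr = 0.5)))
})
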