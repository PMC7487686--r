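test_that("Miller units evaluate the printed formula literally", {
  # 1000 * 0.5 / (2 * 10 * 0.2) = 125
  expect_equal(miller_units(od420 = 0.5, od550 = 0, od600 = 0.2, t_min = 10),
               125)
  # numerator vanishes when OD420 = 1.75 * OD550
  expect_equal(miller_units(0.35, 0.2, 0.5, 5), 0)
  # linear in OD420 at OD550 = 0; doubling the time halves the value
  expect_equal(miller_units(1.0, 0, 0.2, 10),
               2 * miller_units(0.5, 0, 0.2, 10))
  expect_equal(miller_units(0.5, 0, 0.2, 20),
               miller_units(0.5, 0, 0.2, 10) / 2)
  expect_error(miller_units(0.5, 0, 0.2, 0), "time")
  expect_equal(normalize_to_wt(c(250, 125), 125), c(200, 100))
})

test_that("ER-GFP normalization cancels protein level and anchors WT at 100%", {
  wt <- ergfp_ratio(1000, 50, 10)
  expect_equal(normalized_ergfp(1000, 50, 10, wt_ratio = wt), 100)
  expect_equal(normalized_ergfp(2000, 50, 10, wt_ratio = wt), 200)
  expect_equal(normalized_ergfp(2000, 100, 10, wt_ratio = wt), 100)
})

test_that("pulse-chase summaries recover percent remaining and the half-life", {
  clean <- simulate_decay(30, c(0, 15, 30, 60), noise_sd = 0,
                          n_replicates = 3, seed = 1)
  res <- pulse_chase_turnover(clean)
  expect_equal(res$curve$mean_percent[res$curve$time_min == 0], 100)
  expect_equal(res$curve$mean_percent[res$curve$time_min == 30], 50)
  expect_equal(res$half_life_min, 30)
  expect_equal(res$curve$sd_percent[res$curve$time_min == 30], 0)

  # noisy recovery within 20% of the true half-life
  hl <- vapply(1:10, function(s) {
    pulse_chase_turnover(simulate_decay(30, c(0, 10, 20, 30, 45, 60),
                                        noise_sd = 5, n_replicates = 3,
                                        seed = 100 + s))$half_life_min
  }, numeric(1))
  expect_true(all(abs(hl - 30) / 30 < 0.2))
})

test_that("the final-timepoint Student test matches the textbook pooled formula", {
  a <- c(10, 12, 14); b <- c(20, 22, 24)
  # independent hand evaluation of the pooled-variance t statistic
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  df_hand <- length(a) + length(b) - 2
  p_hand <- 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE)
  expect_equal(t_hand, -6.123724, tolerance = 1e-6)
  expect_equal(p_hand, 0.0036022, tolerance = 1e-4)

  got <- compare_final(a, b)
  expect_equal(got$t, t_hand, tolerance = 1e-9)
  expect_equal(got$df, df_hand)
  expect_equal(got$p, p_hand, tolerance = 1e-9)
  expect_equal(got$stars, "**")

  ident <- compare_final(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_equal(ident$stars, "")
  # symmetric up to the sign of t
  rev_ <- compare_final(b, a)
  expect_equal(rev_$t, -got$t)
  expect_equal(rev_$p, got$p)
})

test_that("Welch's test matches the Satterthwaite formula evaluated by hand", {
  x <- c(1, 2, 3); y <- c(1, 2, 3, 4, 5, 6)
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t_hand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 /
    (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p_hand <- 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE)

  got <- welch_t(x, y)
  expect_equal(got$t, t_hand, tolerance = 1e-9)
  expect_equal(got$df, df_hand, tolerance = 1e-9)
  expect_equal(got$p, p_hand, tolerance = 1e-9)

  eq <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  # with equal variances and sizes Welch converges to Student
  a <- c(10, 12, 14); b <- c(20, 22, 24)
  expect_equal(welch_t(a, b)$p, compare_final(a, b)$p, tolerance = 1e-9)
})

test_that("HAC1 splice fractions are control-invariant ratios in [0, 1]", {
  expect_equal(hac1_splice_fraction(10, 0), 1)
  expect_equal(hac1_splice_fraction(5, 5), 0.5)
  expect_equal(hac1_splice_fraction(30, 90), 0.25)
  expect_equal(hac1_splice_fraction(30, 90, act1_intensity = 7),
               hac1_splice_fraction(30, 90, act1_intensity = 1))
  expect_error(hac1_splice_fraction(0, 0), "zero")
})

test_that("doubling time and the ORF-burden correlation follow their definitions", {
  t <- seq(0, 10, by = 1)
  od <- 0.1 * 2^(t / 2)                 # exact doubling every 2 h
  expect_equal(doubling_time(t, od), 2)
  expect_error(doubling_time(t[1:2], od[1:2]), "at least 3")
  expect_error(doubling_time(t, rev(od) * 0 + c(3:1, rep(1, 8))), "no growth")

  expect_equal(orf_burden_correlation(1:5, 2 * (1:5) + 3), 1)
  # hand evaluation of the product-moment formula on {(1,2),(2,1),(3,3)}
  expect_equal(orf_burden_correlation(c(1, 2, 3), c(2, 1, 3)), 0.5)
  # invariant to affine rescaling of either variable
  expect_equal(orf_burden_correlation(c(1, 2, 3) * 7 + 1, c(2, 1, 3)), 0.5)
})
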