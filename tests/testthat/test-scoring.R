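# Fisher's discriminant, Sickle Score and the spillover-calibrated gate.

test_that("Fisher's discriminant matches hand arithmetic and conventions", {
  expect_equal(fishers_discriminant(c(1, 2, 3), c(4, 6, 8)), 4 / 3)
  expect_identical(fishers_discriminant(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(fishers_discriminant(c(2, 2), c(5, 5)), Inf)
  expect_identical(fishers_discriminant(c(2, 2), c(2, 2)), 0)
  expect_error(fishers_discriminant(1, c(1, 2)), "at least 2")

  a <- c(1.2, 3.4, 2.2, 5.1)
  b <- c(0.3, 0.9, 2.5)
  expect_equal(fishers_discriminant(a, b), fishers_discriminant(b, a))
  expect_equal(fishers_discriminant(3 * a + 2, 3 * b + 2),
               fishers_discriminant(a, b))

  set.seed(4)
  expect_lt(abs(fishers_discriminant(rnorm(1e5), rnorm(1e5, 1)) - 0.5), 0.01)
})

test_that("metric ranking sorts, self-compares to zero, names missing metrics", {
  fx <- data.frame(shape_ratio = rnorm(30, 0.9, 0.02),
                   symmetry2 = rnorm(30, 0.02, 0.005),
                   flag = FALSE)
  rk <- rank_metrics(fx, fx, metrics = c("shape_ratio", "symmetry2"))
  expect_true(all(rk$fd == 0))
  expect_false(is.unsorted(rev(rk$fd)))
  expect_error(rank_metrics(fx, fx, metrics = c("shape_ratio", "h_contrast")),
               "h_contrast")
})

test_that("Sickle Score divides symmetry by shape ratio with flag handling", {
  fx <- data.frame(symmetry2 = c(0.8, 0.01, 0.5, 0.3),
                   shape_ratio = c(0.2, 0.95, 0, 0.5),
                   flag = c(FALSE, FALSE, FALSE, TRUE))
  sc <- sickle_score(fx)
  expect_equal(sc[1], 4)
  expect_lt(sc[2], 0.02)
  expect_true(is.na(sc[3]) && is.na(sc[4]))
})

test_that("score rises monotonically with crescent elongation", {
  meds <- vapply(c(1.5, 2, 2.5, 3, 3.5, 4), function(el) {
    sc <- vapply(1:50, function(s)
      featurize(render_cell(shape_params("crescent", size_um = 6.2,
                                         elongation = el),
                            seed = 1000 + s))$sickle_score, numeric(1))
    median(sc, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("sickle gate calibration hits the requested spillover", {
  g <- calibrate_sickle_gate(1:100, spillover = 0.10)
  expect_equal(g$threshold, 90.1)
  expect_false(g$degenerate)

  const <- calibrate_sickle_gate(rep(2.5, 200))
  expect_true(const$degenerate)
  expect_identical(percent_sickled(rep(2.5, 200), const), 0)

  set.seed(8)
  cal <- rlnorm(5000, 0, 0.6)
  held <- rlnorm(1e4, 0, 0.6)
  g2 <- calibrate_sickle_gate(cal, 0.10)
  expect_lt(abs(percent_sickled(cal, g2) - 0.10), 0.02)
  expect_lt(abs(percent_sickled(held, g2) - 0.10), 0.01)
  expect_error(calibrate_sickle_gate(1:50), "at least 100")
})

test_that("percent sickled counts strict exceedances of finite scores", {
  g <- structure(list(threshold = 1, spillover = 0.1, degenerate = FALSE),
                 class = "sickle_gate")
  expect_equal(percent_sickled(c(0.2, 0.5, 1, 1.5, 2, 3, 0.4, 0.6, 0.1, 0.9),
                               g), 0.3)
  # flagged (NA) scores leave both numerator and denominator
  expect_equal(percent_sickled(c(2, 0.5, NA, NA), g), 0.5)
  expect_error(percent_sickled(c(NA_real_, NA_real_), g), "no finite")
})

test_that("group t test matches closed form and calibrates under the null", {
  res <- compare_groups_t(c(34, 35, 36), c(29, 30, 31))
  expect_lt(res$p.value, 0.05)
  expect_equal(res$mean_a - res$mean_b, 5)
  same <- compare_groups_t(c(1, 2, 3), c(1, 2, 3))
  expect_lt(abs(same$p.value - 1), 1e-9)

  set.seed(12)
  rej <- mean(replicate(2000, {
    compare_groups_t(rnorm(5, 30, 3), rnorm(5, 30, 3))$p.value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("induced mixtures score far above uninduced at the same gate", {
  # induced-like mature set: 35% crescents; uninduced: none
  render_set <- function(frac_crescent, seed, n = 60) {
    k_cres <- round(n * frac_crescent)
    evs <- c(
      lapply(seq_len(k_cres), function(i)
        render_cell(shape_params("crescent", size_um = 8, elongation = 3),
                    seed = seed + i)),
      lapply(seq_len(n - k_cres), function(i)
        render_cell(shape_params("disc", size_um = 8), seed = 5000 + seed + i)))
    sickle_score(featurize_events(evs))
  }
  uninduced <- render_set(0, seed = 1, n = 120)
  induced <- render_set(0.35, seed = 2, n = 60)
  gate <- calibrate_sickle_gate(uninduced, 0.10)
  expect_gt(percent_sickled(induced, gate),
            percent_sickled(uninduced, gate) + 0.15)
})
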