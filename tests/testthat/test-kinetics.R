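# Sickling-time simulation, sparse video rendering, event detection and
# the kinetic endpoints / group tests.

test_that("sampled frame indices follow the fixed stride", {
  idx <- sample_frame_indices(7200, 256)
  expect_length(idx, 29)
  expect_identical(idx[1], 0L)
  expect_identical(idx[29], 7168L)
  expect_identical(sample_frame_indices(5, 1), 0:4)
  expect_error(sample_frame_indices(100, 256), "smaller")
})

test_that("simulated times follow the delay + exponential model", {
  none <- simulate_sickling_times(kinetics_config(200, 0, seed = 1))
  expect_false(any(none$susceptible))
  expect_false(any(none$sickles_in_window))

  fast <- simulate_sickling_times(
    kinetics_config(500, 1, delay_min = 4, hazard_per_min = 1000, seed = 2))
  expect_gte(mean(abs(fast$true_time_min - 4) < 0.01), 0.99)

  cfg <- kinetics_config(1e4, 0.5, delay_min = 4, hazard_per_min = 0.2,
                         duration_min = 30, seed = 3)
  tr <- simulate_sickling_times(cfg)
  p_expected <- 0.5 * (1 - exp(-0.2 * 26))
  se <- sqrt(p_expected * (1 - p_expected) / 1e4)
  expect_lt(abs(mean(tr$sickles_in_window) - p_expected), 3 * se)
})

test_that("video rendering is sparse-consistent and morphs on schedule", {
  cfg <- kinetics_config(9, 1, delay_min = 0.5, hazard_per_min = 2,
                         duration_min = 2, fps = 1, transition_sec = 3,
                         seed = 6)
  truth <- data.frame(cell_id = 1:9, susceptible = TRUE,
                      true_time_min = c(0.7, 1.1, NA, 0.9, NA, 1.5, 0.8,
                                        NA, 1.3),
                      sickles_in_window = c(TRUE, TRUE, FALSE, TRUE, FALSE,
                                            TRUE, TRUE, FALSE, TRUE))
  dense <- render_video(truth, cfg)
  sparse <- render_video(truth, cfg, frames = c(0L, 50L, 100L))
  expect_identical(sparse$frames[["50"]], dense$frames[["50"]])
  expect_identical(sparse$frames[["100"]], dense$frames[["100"]])

  # a cell with true time 0.7 min is a disc at 0.5 min, crescent at 1.0 min
  sp <- dense$layout$spacing_px
  tile <- function(f, k) {
    tr <- dense$centers$tile_row[k]; tc <- dense$centers$tile_col[k]
    dense$frames[[as.character(f)]][((tr - 1) * sp + 1):(tr * sp),
                                    ((tc - 1) * sp + 1):(tc * sp)]
  }
  m_before <- tile(30, 1) < 0.675   # 0.5 min
  m_after <- tile(60, 1) < 0.675    # 1.0 min
  expect_gt(1 - sum(m_before & m_after) / sum(m_before | m_after), 0.25)

  # censored cell keeps its morphology from first to last frame
  m0 <- tile(0, 3) < 0.675
  m1 <- tile(119, 3) < 0.675
  expect_gt(sum(m0 & m1) / sum(m0 | m1), 0.95)
})

test_that("detection assigns the first sampled frame at or after the event", {
  cfg <- kinetics_config(4, 1, delay_min = 4, hazard_per_min = 0.3, seed = 8)
  truth <- data.frame(cell_id = 1:4, susceptible = TRUE,
                      true_time_min = c(8.4, 20.0, NA, 5.0),
                      sickles_in_window = c(TRUE, TRUE, FALSE, TRUE))
  idx <- sample_frame_indices(7200, 256)
  field <- render_video(truth, cfg, frames = idx)
  tl <- detect_events(field)
  expect_equal(tl$time_min[1], 8.5333, tolerance = 1e-4)
  expect_equal(tl$time_min[4], 5.3333, tolerance = 1e-4)
  expect_true(tl$censored[3])
  expect_equal(tl$time_min[3], 30)
  expect_true(all(!tl$censored[c(1, 2, 4)]))
  # detected times are multiples of the sampling interval and never precede
  # the true transition
  grid_min <- 256 / 4 / 60
  expect_true(all(abs(tl$time_min[!tl$censored] / grid_min -
                        round(tl$time_min[!tl$censored] / grid_min)) < 1e-9))
  expect_true(all(tl$time_min[!tl$censored] >=
                    truth$true_time_min[!tl$censored]))
})

test_that("noise alone rarely triggers events in censored cells", {
  cfg <- kinetics_config(500, 0, seed = 12)
  tr <- run_kinetics_trial(cfg)
  expect_lt(mean(!tr$timelines$censored), 0.02)
})

test_that("cumulative curve steps to the final sickled fraction", {
  tl <- data.frame(time_min = c(5, 6, 7, 30, 30, 30),
                   censored = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  crv <- cumulative_curve(tl)
  expect_identical(crv$fraction[1], 0)
  expect_true(all(diff(crv$fraction) >= 0))
  expect_equal(crv$fraction[crv$time_min == 6], 2 / 6)
  expect_equal(crv$fraction[nrow(crv)], 0.5)

  flat <- cumulative_curve(data.frame(time_min = rep(30, 4),
                                      censored = TRUE))
  expect_true(all(flat$fraction == 0))
})

test_that("kinetics summary reproduces the hand-worked endpoints", {
  tl <- data.frame(time_min = c(5.333, 6.4, 7.467, 30, 30, 30),
                   censored = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  ks <- kinetics_summary(tl, interval_sec = 64)
  expect_equal(ks$pct_sickled, 0.5)
  expect_equal(ks$median_time_min, 6.4)
  expect_equal(ks$delay_min, 5.333)
  expect_equal(ks$max_rate_per_sec, (1 / 6) / 64)
  expect_gte(ks$max_rate_per_sec, ks$pct_sickled / (30 * 60))

  single <- kinetics_summary(data.frame(time_min = 10, censored = FALSE),
                             interval_sec = 64)
  expect_equal(single$pct_sickled, 1)
  expect_equal(single$median_time_min, 10)
  expect_equal(single$delay_min, 10)
  expect_error(kinetics_summary(data.frame()), "empty")
})

test_that("the final curve value equals the summary percent sickled", {
  cfg <- kinetics_config(80, 0.6, seed = 31)
  truth <- simulate_sickling_times(cfg)
  tl <- grid_detect_times(truth, cfg)
  expect_equal(cumulative_curve(tl)$fraction[nrow(cumulative_curve(tl))],
               kinetics_summary(tl, 64)$pct_sickled)
})

test_that("Gehan-Breslow-Wilcoxon matches the hand-worked example", {
  a <- data.frame(time_min = c(1, 2), censored = FALSE)
  b <- data.frame(time_min = c(3, 4), censored = FALSE)
  res <- gehan_breslow_wilcoxon(a, b)
  # weights 4,3,2,1; U = 4*(1/2) + 3*(2/3) = 4; Var = 4 + 2 = 6
  expect_equal(res$statistic, 16 / 6)
  expect_equal(res$p.value, pchisq(16 / 6, 1, lower.tail = FALSE))

  same <- gehan_breslow_wilcoxon(a, a)
  expect_identical(same$statistic, 0)
  expect_identical(same$p.value, 1)

  cens <- data.frame(time_min = c(30, 30), censored = TRUE)
  none <- gehan_breslow_wilcoxon(cens, cens)
  expect_identical(none$p.value, 1)
})

test_that("rank-sum comparison handles exact small samples and grid ties", {
  expect_equal(wilcoxon_times(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  expect_equal(wilcoxon_times(c(1, 2, 3), c(1, 2, 3))$p.value, 1)

  # shift alternative: control-model detected times vs the same times two
  # grid steps later; high power at n = 150
  step <- 256 / 4 / 60
  set.seed(21)
  hits <- mean(replicate(200, {
    tt <- 4.3 + rexp(400, 0.165)
    a <- sample(ceiling(tt[tt <= 28] / step) * step, 150)
    b <- a + 2 * step
    wilcoxon_times(a, b)$p.value < 0.001
  }))
  expect_gte(hits, 0.95)
})
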