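# Event renderer and population sampler.

test_that("rendered disc mask matches the requested circle", {
  ev <- render_cell(shape_params("disc", size_um = 8), seed = 1)
  msk <- segment_event(ev)
  expect_false(msk$degenerate)
  r_px <- 8 / 2 / ev$pixel_size_um
  expect_lt(abs(msk$area_px - pi * r_px^2) / (pi * r_px^2), 0.05)
})

test_that("rendered crescent is elongated as measured by the morphometry", {
  fx <- featurize(render_cell(shape_params("crescent", size_um = 8,
                                           elongation = 3), seed = 1))
  expect_false(fx$flag)
  expect_gte(fx$length_um / fx$thickness_min_um, 2.5)
})

test_that("DNA channel lights up only for nucleated classes", {
  gains <- c(BF = 1, DNA = 1, CD235 = 1)
  nuc <- render_cell(shape_params("nucleated", size_um = 9.5), seed = 1,
                     channel_gains = gains)
  disc <- render_cell(shape_params("disc", size_um = 8), seed = 1,
                      channel_gains = gains)
  dna_sum <- function(e) {
    m <- segment_event(e)$mask
    sum(e$channels$DNA[m])
  }
  expect_gte(dna_sum(nuc), 10 * dna_sum(disc))
})

test_that("rendering is a pure function of params and seed", {
  p <- shape_params("spiculated", size_um = 8, elongation = 2.5,
                    n_spicules = 5)
  a <- render_cell(p, seed = 7)
  b <- render_cell(p, seed = 7)
  expect_identical(a$channels, b$channels)
  c2 <- render_cell(p, seed = 8)
  expect_false(identical(a$channels$BF, c2$channels$BF))
})

test_that("invalid shape requests are rejected with informative errors", {
  expect_error(shape_params("blob"), "unknown shape_class")
  expect_error(render_cell(shape_params("crescent", size_um = 10,
                                        elongation = 4), crop_px = 40),
               "crop too small.*px")
  expect_error(render_cell(shape_params("nucleated"), channels = c("BF")),
               "DNA")
  expect_error(render_cell(shape_params("disc"), channels = c("DNA")),
               "brightfield")
})

test_that("largest-remainder apportionment is exact and near-proportional", {
  expect_identical(apportion_counts(100, c(disc = 0.5, crescent = 0.5)),
                   c(disc = 50L, crescent = 50L))
  fr <- c(disc = 0.31, sideways = 0.17, crescent = 0.13, star = 0.11,
          wrinkled = 0.09, nucleated = 0.13, debris = 0.06)
  cts <- apportion_counts(1e4, fr)
  expect_identical(sum(cts), 10000L)
  expect_true(all(abs(cts - 1e4 * fr) <= 1))
  expect_error(apportion_counts(10, c(a = 0.6, b = 0.5)), "sum to 1")
})

test_that("population class counts follow the apportionment and shuffle", {
  cfg <- population_config(120, class_fractions = c(disc = 0.5, crescent = 0.3,
                                                    nucleated = 0.2),
                           seed = 5)
  pop <- sample_population(cfg)
  expect_length(pop$events, 120)
  expect_equal(as.vector(table(pop$truth$class)[c("disc", "crescent",
                                                  "nucleated")]),
               c(60, 36, 24))
  # shuffled, not blocked by class
  expect_false(all(pop$truth$class[1:60] == "disc"))
  expect_identical(nrow(pop$truth), 120L)
})

test_that("identical configs give byte-identical manifests", {
  cfg <- population_config(25, seed = 42)
  d1 <- withr_local_tempdir()
  d2 <- withr_local_tempdir()
  m1 <- write_events(sample_population(cfg)$events, d1,
                     truth = sample_population(cfg)$truth)
  m2 <- write_events(sample_population(cfg)$events, d2,
                     truth = sample_population(cfg)$truth)
  expect_identical(readLines(m1), readLines(m2))
  expect_identical(unname(tools::md5sum(file.path(d1, "event_00001.tif"))),
                   unname(tools::md5sum(file.path(d2, "event_00001.tif"))))
})
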