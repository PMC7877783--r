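test_that("E:S ratio scales inversely with uPA concentration from the benign anchor", {
  expect_equal(es_ratio(8), 25)            # tumor level
  expect_equal(es_ratio(1), 200)           # the anchor itself
  expect_equal(es_ratio(4), 50)            # intermediate, infiltrating tissue
  # exact inverse proportionality: level x ratio is constant
  levels <- c(0.5, 1, 2, 3.7, 8, 12.25)
  expect_true(all(abs(levels * es_ratio(levels) - 200) < 1e-12))
  expect_error(es_ratio(0), "positive")
  expect_error(es_ratio(-3), "positive")
})

test_that("fluorescence trace starts at baseline and saturates at 1/(1-q)", {
  p <- kinetics_params(quench_efficiency = 0.9, t_max = 1e7)
  tr <- fluorescence_trace(p, c(0, 1, 10, 1e6))
  expect_equal(tr$fluorescence[1], 1)
  expect_equal(tr$fluorescence[4], 10)     # tenfold increase on full cleavage
  expect_true(all(diff(tr$fluorescence) >= 0))
  # k = 0 keeps the probe quenched forever
  p0 <- kinetics_params(rate = 0)
  expect_true(all(fluorescence_trace(p0, c(0, 1, 5))$fluorescence == 1))
  # hand evaluation: q = 0.9, k chosen so half the substrate is cleaved at
  # 1 min for E:S 1:25 -> F(1) = (0.5*0.1 + 0.5)/0.1 = 5.5
  k_half <- 25 * log(2)
  ph <- kinetics_params(quench_efficiency = 0.9, es = 25, rate = k_half)
  expect_equal(fluorescence_trace(ph, c(0, 1))$fluorescence[2], 5.5)
  expect_error(fluorescence_trace(p, c(1, 0.5)), "increasing")
  expect_error(kinetics_params(quench_efficiency = 1), "quench")
})

test_that("trace is monotone in time, enzyme concentration and quenching", {
  for (s in 1:5) {
    set.seed(s)
    q <- runif(1, 0.5, 0.95); k <- runif(1, 5, 100)
    t <- sort(runif(6, 0, 5))
    f_lo <- fluorescence_trace(kinetics_params(q, es = 200, rate = k), t)$fluorescence
    f_hi <- fluorescence_trace(kinetics_params(q, es = 25, rate = k), t)$fluorescence
    expect_true(all(diff(f_lo) >= 0))
    expect_true(all(f_hi >= f_lo))          # more enzyme, more signal
    f_q <- fluorescence_trace(kinetics_params(min(q + 0.04, 0.99), es = 25,
                                              rate = k), t)$fluorescence
    expect_true(all(f_q >= f_hi))           # deeper quenching, larger release
  }
})

test_that("tumor-vs-benign contrast behaves as first-order kinetics predicts", {
  a <- kinetics_params(es = 25); b <- kinetics_params(es = 200)
  expect_equal(contrast_ratio(a, a, 1), 1)
  # baseline-subtracted ratio tends to the enzyme ratio (8) as t -> 0+
  expect_equal(contrast_ratio(a, b, 1e-7, background_subtracted = TRUE), 8,
               tolerance = 1e-4)
  # default rate is calibrated to the observed optimum: 4.5 at one minute
  expect_equal(contrast_ratio(a, b, 1, background_subtracted = TRUE), 4.5,
               tolerance = 1e-6)
  expect_equal(calibrate_cleavage_rate(), a$rate, tolerance = 1e-6)
  expect_error(contrast_ratio(a, b, a$t_max + 1), "range")
  expect_error(contrast_ratio(a, kinetics_params(quench_efficiency = 0.5), 1),
               "share")
})

test_that("fluorescence ROI detection returns exact bounding boxes", {
  img <- matrix(0.1, 40, 40)
  expect_equal(nrow(fl_threshold_rois(img, threshold = 0.5, absolute = TRUE)), 0)
  img[5:10, 7:14] <- 1           # 6 x 8 = 48 px
  img[25:32, 30:33] <- 0.8       # 8 x 4 = 32 px
  rois <- fl_threshold_rois(img, threshold = 0.5, absolute = TRUE, min_area = 9)
  expect_equal(nrow(rois), 2)
  expect_equal(unname(unlist(rois[1, 1:4])), c(5, 10, 7, 14))   # brighter first
  expect_equal(unname(unlist(rois[2, 1:4])), c(25, 32, 30, 33))
  expect_equal(rois$area_px, c(48L, 32L))
  # min-area filter removes the small component
  rois2 <- fl_threshold_rois(img, threshold = 0.5, absolute = TRUE, min_area = 40)
  expect_equal(nrow(rois2), 1)
  expect_error(fl_threshold_rois(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("phantom fluorescence channel highlights the tumor footprint", {
  lay <- build_layout("infiltrating_boundary", c(64, 64), seed = 3)
  # zero incubation: uniform quenched baseline everywhere
  fl0 <- render_fl(lay, incubation_min = 0, psf_sigma_px = 0, noise_sd = 0)
  expect_true(all(abs(fl0 - 1) < 1e-12))
  # positive incubation, noiseless: tumor outshines benign
  fl <- render_fl(lay, incubation_min = 2, psf_sigma_px = 0, noise_sd = 0)
  expect_gt(mean(fl[lay == 1]) / mean(fl[lay == 3]), 1)
  # seeded call is reproducible
  f1 <- render_fl(lay, seed = 9); f2 <- render_fl(lay, seed = 9)
  expect_identical(f1, f2)
  expect_error(render_fl(lay, incubation_min = -1), "non-negative")
  # the dominant detected ROI covers most of the tumor footprint
  ph <- specimen_phantom(phantom_spec(layout_pattern = "deep_focus", seed = 6,
                                      grid_shape = c(64, 64, 40)),
                         with_rcm = FALSE)
  focus <- attr(ph$layout, "focus_mask")
  rois <- fl_threshold_rois(ph$fl, threshold = 0.6)
  box <- matrix(FALSE, 64, 64)
  box[rois$row1[1]:rois$row2[1], rois$col1[1]:rois$col2[1]] <- TRUE
  expect_gte(sum(box & focus) / sum(focus), 0.9)
})
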