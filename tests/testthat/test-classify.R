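make_feats <- function(slope, rsd, class) {
  data.frame(slope_mean = slope, roughness_sd_mean = rsd, class = class)
}

test_that("threshold training matches the exhaustive-search oracle", {
  # tumor roughness {4,5,6} vs benign {1,2,3}: gap midpoint 3.5
  tr <- make_feats(slope = c(1, 1, 1, 1, 1, 1, 9, 9),
                   rsd = c(4, 5, 6, 1, 2, 3, 2, 2),
                   class = c(rep("tumor", 3), rep("benign", 3), rep("adipose", 2)))
  m <- tissue_classifier(tr)
  expect_equal(unname(coef(m)["roughness_sd"]), 3.5)
  expect_equal(unname(coef(m)["slope"]), 5)
  expect_equal(m$training_error, 0)
  # oracle agreement on random separable and overlapping data
  for (s in 1:10) {
    set.seed(s)
    n <- 15
    f <- make_feats(slope = c(runif(n, 0, 1), runif(n, 0.4, 1.6), runif(n, 0, 1)),
                    rsd = c(runif(n, 1, 3), runif(n, 0, 4), runif(n, 0, 2.2)),
                    class = rep(c("tumor", "adipose", "benign"), each = n))
    m2 <- tissue_classifier(f)
    expect_equal(unname(coef(m2)["slope"]),
                 oracle_threshold(f$slope_mean, f$class == "adipose"))
    rest <- f$class != "adipose"
    expect_equal(unname(coef(m2)["roughness_sd"]),
                 oracle_threshold(f$roughness_sd_mean[rest],
                                  f$class[rest] == "tumor"))
  }
})

test_that("training rejects degenerate inputs with informative errors", {
  expect_error(tissue_classifier(make_feats(1:3, 1:3, rep("tumor", 3))),
               "two classes")
  bad <- make_feats(slope = rep(2, 6), rsd = c(1, 2, 3, 4, 5, 6),
                    class = rep(c("adipose", "benign"), 3))
  expect_error(tissue_classifier(bad), "slope_mean")
  expect_error(tissue_classifier(make_feats(1, 1, "stroma")), "among")
})

test_that("classifier methods expose rule, thresholds and predictions", {
  tr <- make_feats(slope = c(0.1, 0.1, 0.9, 0.9, 0.1, 0.1),
                   rsd = c(3, 3.2, 1, 1, 0.5, 0.6),
                   class = c("tumor", "tumor", "adipose", "adipose",
                             "benign", "benign"))
  m <- tissue_classifier(tr)
  expect_s3_class(m, "tissue_classifier")
  expect_named(coef(m), c("slope", "roughness_sd"))
  expect_output(print(m), "adipose if slope_mean")
  expect_output(print(summary(m)), "training statistics")
  pred <- predict(m, data.frame(slope_mean = c(0.95, 0.1, 0.1),
                                roughness_sd_mean = c(0.2, 4, 0.1)))
  expect_equal(pred, c("adipose", "tumor", "benign"))
  expect_error(predict(m, data.frame(a = 1)), "feature columns")
})

test_that("PCA report standardizes, decomposes and orders variance", {
  # all nine features affine copies of one variable: rank one
  set.seed(2)
  base <- rnorm(30)
  tab <- sapply(1:9, function(i) i * base + i)
  colnames(tab) <- feature_names()
  rep1 <- suppressWarnings(pca_report(tab))
  expect_equal(rep1$explained[1], 1, tolerance = 1e-9)
  # i.i.d. noise: every component explains about 1/9
  set.seed(3)
  noise <- matrix(rnorm(500 * 9), 500, 9, dimnames = list(NULL, feature_names()))
  rep2 <- pca_report(noise)
  expect_true(all(abs(rep2$explained - 1 / 9) < 0.05))
  expect_true(all(diff(rep2$cumulative) >= 0))
  expect_equal(rep2$cumulative[9], 1)
  # independent oracle: prcomp on the same table
  pr <- stats::prcomp(noise, center = TRUE, scale. = TRUE)
  expect_equal(rep2$explained, unname(pr$sdev^2 / sum(pr$sdev^2)),
               tolerance = 1e-9)
  expect_error(pca_report(noise[1, , drop = FALSE]), "two ROIs")
  # zero-variance feature dropped with a warning
  noise[, 4] <- 1
  expect_warning(pca_report(noise), "zero-variance")
})

test_that("phantom ROI feature table needs few components and separates classes", {
  cfg <- margin_config()
  cfg$training$rois_per_class <- 8
  m <- train_reference_classifier(cfg, grid_shape = c(64, 64, 120))
  feats <- attr(m, "features")
  rep_ <- pca_report(feats[, feature_names()])
  expect_gt(rep_$cumulative[min(5, length(rep_$cumulative))],
            rep_$cumulative[2])
  expect_gt(rep_$cumulative[min(5, length(rep_$cumulative))], 0.9)
})

test_that("voxel classification recovers phantom tissue layouts", {
  cfg <- margin_config()
  model <- train_reference_classifier(cfg)
  pp <- process_phantom("uniform_tumor", seed = 55)
  labs <- classify_voxels(remove_surface_echo(pp$ph$oct, pp$sf$top_map), model,
                          pp$sf$mask, depth_gain = pp$dg)
  tissue <- labs != 0L
  expect_gte(mean(labs[tissue] == 1L), 0.95)
  # outside the mask everything stays background
  expect_true(all(labs[!pp$sf$mask] == 0L))
  # deterministic: same model and volume give identical labels
  labs2 <- classify_voxels(remove_surface_echo(pp$ph$oct, pp$sf$top_map), model,
                           pp$sf$mask, depth_gain = pp$dg)
  expect_identical(labs, labs2)
  expect_error(classify_voxels(pp$ph$oct, model, pp$sf$mask[, , 1]))
})

test_that("margin projection respects depth, area filter and monotonicity", {
  # hand-built label volume: nz 100 (5 um voxels), flat top at 1
  lab <- array(3L, dim = c(100, 30, 30))
  top <- matrix(1L, 30, 30)
  # tumor focus footprint at rows 10..19, cols 10..19, depth 0.25-0.35 mm
  lab[51:70, 10:19, 10:19] <- 1L
  m1 <- project_margin(lab, top, depth_mm = 1, axial_voxel_um = 5,
                       lateral_voxel_um = 10, min_area_mm2 = 0.005)
  expect_equal(sum(m1$mask), 100)
  expect_true(all(which(m1$mask, arr.ind = TRUE)[, 1] %in% 10:19))
  m2 <- project_margin(lab, top, depth_mm = 0.2, axial_voxel_um = 5,
                       lateral_voxel_um = 10, min_area_mm2 = 0.005)
  expect_equal(sum(m2$mask), 0)                  # focus below the shallow band
  # monotonicity: deeper projection never shrinks the mask
  m3 <- project_margin(lab, top, depth_mm = 0.3, axial_voxel_um = 5,
                       lateral_voxel_um = 10, min_area_mm2 = 0.005)
  expect_true(all(m1$mask[m3$mask]))
  # empty label volume: empty mask, negative call
  none <- project_margin(array(3L, dim = c(10, 8, 8)), matrix(1L, 8, 8))
  expect_equal(sum(none$mask), 0)
  expect_equal(specimen_call(none), "negative")
  # one isolated pixel falls to the area filter
  lab1 <- array(3L, dim = c(10, 20, 20)); lab1[2, 5, 5] <- 1L
  mm <- project_margin(lab1, matrix(1L, 20, 20), min_area_mm2 = 0.01)
  expect_equal(sum(mm$mask), 0)
  expect_equal(specimen_call(mm), "negative")
  expect_error(project_margin(lab, NULL), "top surface")
})
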