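test_that("evaluation reports both metric conventions from confusion counts", {
  # the study cohort: 8 histology-positive, 12 negative; 8 TP, 2 FP, 0 FN
  calls <- c(rep("positive", 8), rep("positive", 2), rep("negative", 10))
  truth <- c(rep("positive", 8), rep("negative", 12))
  ev <- evaluate_margins(calls, truth)
  expect_equal(c(ev$tp, ev$fp, ev$tn, ev$fn), c(8, 2, 10, 0))
  expect_equal(ev$ppv_paper, 1.0)
  expect_equal(ev$npv_paper, 10 / 12)
  expect_equal(ev$ppv_paper, ev$sensitivity)       # documented identity
  expect_equal(ev$npv_paper, ev$specificity)
  expect_equal(ev$ppv_std, 0.8)
  # counts round-trip from the reported fractions at these cohort sizes
  expect_equal(ev$ppv_paper * (ev$tp + ev$fn), ev$tp)
  # all-correct predictions give every metric 1
  ev2 <- evaluate_margins(truth, truth)
  expect_true(all(unlist(ev2[c("ppv_paper", "npv_paper", "ppv_std", "npv_std",
                               "sensitivity", "specificity")]) == 1))
  # hand-computed contingency: TP=3 FP=1 FN=2 TN=4
  ev3 <- evaluate_margins(c(rep("positive", 4), rep("negative", 6)),
                          c(rep("positive", 3), "negative",
                            rep("positive", 2), rep("negative", 4)))
  expect_equal(ev3$ppv_std, 0.75)
  expect_equal(ev3$npv_std, 4 / 6, tolerance = 1e-12)
  expect_equal(ev3$sensitivity, 0.6)
  expect_error(evaluate_margins("positive", c("positive", "negative")), "length")
  expect_error(evaluate_margins("yes", "positive"), "positive")
})

test_that("margin overlay tints exactly the mask at the requested opacity", {
  photo <- array(runif(20 * 20 * 3), dim = c(20, 20, 3))
  empty <- matrix(FALSE, 20, 20)
  out <- overlay_margin(photo, empty, alpha = 0.5)
  expect_equal(out[, , 1:3], photo)                 # untouched
  expect_true(all(out[, , 4] == 1))
  full <- matrix(TRUE, 20, 20)
  red <- overlay_margin(photo, full, alpha = 1)
  expect_true(all(red[, , 1] == 1) && all(red[, , 2] == 0) && all(red[, , 3] == 0))
  half <- matrix(FALSE, 20, 20); half[3:7, 3:7] <- TRUE
  mixed <- overlay_margin(photo, half, alpha = 0.45)
  changed <- abs(mixed[, , 1] - photo[, , 1]) > 1e-12 |
    abs(mixed[, , 2] - photo[, , 2]) > 1e-12
  expect_identical(unname(changed), unname(half))   # red pixel set == mask
  expect_error(overlay_margin(photo, matrix(FALSE, 5, 5)), "differ")
})

test_that("configuration carries every default and accepts YAML overrides", {
  cfg <- margin_config()
  expect_s3_class(cfg, "margin_config")
  expect_equal(cfg$margin$depth_mm, 1.0)
  expect_equal(cfg$margin$min_area_mm2, 0.01)
  expect_equal(cfg$strips$fov_mm, 2.2)
  expect_equal(cfg$strips$overlap_fraction, 0.1)
  expect_equal(cfg$texture$sd_window, 9)
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("specimen_id: from-yaml", "margin:", "  depth_mm: 0.5",
               "  min_area_mm2: 0.02"), yml)
  cfg2 <- margin_config(yaml_path = yml)
  expect_equal(cfg2$specimen_id, "from-yaml")
  expect_equal(cfg2$margin$depth_mm, 0.5)
  cfg3 <- margin_config(specimen_id = "dots-win", yaml_path = yml)
  expect_equal(cfg3$specimen_id, "dots-win")
  unlink(yml)
})

test_that("end-to-end pipeline calls phantoms by their layout truth", {
  model <- shared_model()
  base <- margin_config()
  base$training$classifier <- model
  cfg_neg <- base; cfg_neg$phantom <- list(pattern = "adipose_only", seed = 64)
  r_neg <- run_pipeline(cfg_neg)
  expect_equal(r_neg$call, "negative")
  expect_equal(sum(r_neg$class_fractions), 1, tolerance = 1e-9)
  cfg_pos <- base; cfg_pos$phantom <- list(pattern = "uniform_tumor", seed = 64)
  r_pos <- run_pipeline(cfg_pos)
  expect_equal(r_pos$call, "positive")
  # uniform tumor: margin covers essentially the whole footprint
  footprint <- prod(dim(r_pos$phantom$oct)[2:3])
  expect_gte(sum(r_pos$margin$mask) / footprint, 0.99)
  expect_true(any(grepl("classify", r_pos$log)))
  # stage errors carry the stage name
  cfg_bad <- base; cfg_bad$fl$threshold <- 2
  expect_error(run_pipeline(cfg_bad), "fl_rois")
})

test_that("pipeline reports are reproducible under a fixed configuration", {
  model <- shared_model()
  cfg <- margin_config()
  cfg$training$classifier <- model
  cfg$phantom <- list(pattern = "infiltrating_boundary", seed = 19,
                      grid_shape = c(48, 48, 120))
  r1 <- run_pipeline(cfg); r2 <- run_pipeline(cfg)
  expect_identical(r1$call, r2$call)
  expect_identical(r1$margin$mask, r2$margin$mask)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$class_fractions, r2$class_fractions)
})

test_that("phantom and report artifacts round-trip through disk", {
  ph <- specimen_phantom(phantom_spec(grid_shape = c(24, 24, 30), seed = 8),
                         with_rcm = TRUE)
  d <- file.path(tempdir(), "phantom-io")
  write_phantom(ph, d)
  expect_true(all(file.exists(file.path(d, c("oct.ome.tif", "labels.ome.tif",
                                             "fl.tif", "photo.tif", "rcm.tif",
                                             "phantom.json")))))
  oct2 <- read_oct_volume(file.path(d, "oct.ome.tif"))
  expect_identical(dim(oct2), dim(ph$oct))
  expect_lt(max(abs(oct2 - ph$oct)) / max(ph$oct), 1e-6)   # 32-bit float
  lab2 <- read_oct_volume(file.path(d, "labels.ome.tif"))
  expect_identical(as.integer(lab2), as.integer(ph$labels))
  meta <- jsonlite::read_json(file.path(d, "phantom.json"))
  expect_equal(meta$spec$seed, 8)
  # margin report artifacts
  model <- shared_model()
  cfg <- margin_config()
  cfg$training$classifier <- model
  cfg$phantom <- list(pattern = "adipose_only", seed = 5)
  cfg$out_dir <- file.path(tempdir(), "report-io")
  r <- run_pipeline(cfg)
  expect_true(all(file.exists(file.path(cfg$out_dir,
    c("margin_mask.png", "overlay.png", "margin_components.csv",
      "class_fractions.csv", "pipeline.log", "report.json")))))
  rj <- jsonlite::read_json(cfg$out_dir |> file.path("report.json"))
  expect_equal(rj$call, r$call)
  unlink(d, recursive = TRUE); unlink(cfg$out_dir, recursive = TRUE)
})

test_that("trace CSV export lists one column per condition", {
  tr <- lapply(c(25, 50, 200), function(es) {
    fluorescence_trace(kinetics_params(es = es), seq(0, 2, by = 0.5))
  })
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  df <- read.csv(f)
  expect_equal(names(df), c("time_min", "es_1_25", "es_1_50", "es_1_200"))
  expect_equal(nrow(df), 5)
  unlink(f)
})
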