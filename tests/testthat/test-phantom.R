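test_that("layout templates produce the intended class geometry", {
  expect_true(all(build_layout("uniform_tumor", c(64, 64), 1) == 1L))
  expect_true(all(build_layout("adipose_only", c(64, 64), 1) == 2L))
  lay <- build_layout("infiltrating_boundary", c(128, 128), seed = 7,
                      tumor_fraction = 0.4)
  expect_equal(mean(lay == 1L), 0.4, tolerance = 0.05 / 0.4)  # within +-5% area
  expect_true(all(lay %in% c(1L, 3L)))
  df <- build_layout("deep_focus", c(64, 64), seed = 2, focus_depth_um = 500)
  expect_equal(attr(df, "depth_offset_um"), 500)
  expect_true(any(attr(df, "focus_mask")))
  expect_identical(df == 1L, attr(df, "focus_mask"))
  li <- build_layout("lobule_insert", c(64, 64), seed = 2)
  expect_true(any(attr(li, "lobule_mask")))
  expect_true(all(li[attr(li, "lobule_mask")] == 3L))   # lobule is benign truth
  expect_error(build_layout("no_such_template", c(8, 8), 1), "unknown")
})

test_that("rendering is deterministic under a fixed spec and seed", {
  spec <- phantom_spec(grid_shape = c(32, 32, 60), seed = 77)
  p1 <- specimen_phantom(spec, with_rcm = FALSE)
  p2 <- specimen_phantom(spec, with_rcm = FALSE)
  expect_identical(p1$oct, p2$oct)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$fl, p2$fl)
  expect_identical(p1$photo, p2$photo)
  expect_error(render_oct(build_layout("uniform_tumor", c(16, 16), 1),
                          phantom_spec(grid_shape = c(32, 32, 60))), "match")
})

test_that("labels and geometry are consistent with the spec", {
  spec <- phantom_spec(grid_shape = c(32, 32, 120), seed = 5,
                       layout_pattern = "deep_focus", focus_depth_um = 300)
  ph <- specimen_phantom(spec, with_rcm = FALSE)
  expect_identical(dim(ph$oct), dim(ph$labels))
  expect_true(all(ph$labels %in% 0:3))
  # deep focus: no tumor voxel above the configured offset below the surface
  tum <- which(ph$labels == 1L, arr.ind = TRUE)
  expect_gt(nrow(tum), 0)
  depths_um <- (tum[, 1] - ph$truth_top[cbind(tum[, 2], tum[, 3])]) * 5
  expect_true(all(depths_um >= 300))
  # co-registration: lateral extents shared by all channels
  expect_identical(dim(ph$fl), dim(ph$oct)[2:3])
  expect_identical(dim(ph$photo)[1:2], dim(ph$oct)[2:3])
})

test_that("noiseless single-class phantom recovers the configured attenuation", {
  spec <- phantom_spec(grid_shape = c(24, 24, 160), layout_pattern = "uniform_tumor",
                       speckle_shape = 0, noise_sd = 0, surface_amp_vox = 0,
                       seed = 3)
  spec$class_params$tumor$mu <- 1.0
  ph <- specimen_phantom(spec, with_rcm = FALSE)
  mask <- ph$labels == 1L
  dg <- depth_compensate(ph$oct, mask, 5)   # surface voxel excluded by default
  expect_equal(dg$rate_per_mm, 2, tolerance = 0.02)   # 2 mu within 2%
})

test_that("tumor texture is rougher than benign stroma and fat lumens", {
  # reduced-size rendition of the separability sweep; the acceptance suite
  # and vignette document the full study conditions
  ok <- 0; n <- 8
  for (s in 1:n) {
    pa <- process_phantom("adipose_only", seed = 520 + s)
    pr <- adipose_lumen_probes(pa$ph, 3)
    lum <- mean(vapply(seq_len(nrow(pr)), function(i) {
      fs <- plane_features(pa, pr$z[i])
      fs$roughness_sd[pr$x[i], pr$y[i]]
    }, numeric(1)))
    pi_ <- process_phantom("infiltrating_boundary", seed = 620 + s)
    z <- min(max(pi_$sf$top_map) + 2L, dim(pi_$ph$oct)[1])
    fs <- plane_features(pi_, z)
    lab <- pi_$ph$labels[z, , ]
    ok <- ok + (mean(fs$roughness_sd[lab == 1]) > mean(fs$roughness_sd[lab == 3]) &&
                  mean(fs$roughness_sd[lab == 3]) > lum)
  }
  expect_gte(ok, n - 1)
})

test_that("tumor regions have higher windowed intensity SD than fat lumens", {
  pt <- specimen_phantom(phantom_spec(grid_shape = c(48, 48, 120),
                                      layout_pattern = "uniform_tumor", seed = 31),
                         with_rcm = FALSE)
  pa <- specimen_phantom(phantom_spec(grid_shape = c(48, 48, 120),
                                      layout_pattern = "adipose_only", seed = 32),
                         with_rcm = FALSE)
  z <- 30
  sd_t <- mean(roughness_sd_filter(pt$oct[z, , ], 9))
  pr <- adipose_lumen_probes(pa, 3, margin_px = 8)
  sd_lum <- mean(vapply(seq_len(nrow(pr)), function(i) {
    roughness_sd_filter(pa$oct[pr$z[i], , ], 9)[pr$x[i], pr$y[i]]
  }, numeric(1)))
  expect_gt(sd_t, sd_lum)
})
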