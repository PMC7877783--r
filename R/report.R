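#' Specimen-level evaluation against histology
#'
#' Builds the confusion counts of per-specimen margin calls against
#' histology truth and reports two metric conventions side by side. The
#' headline predictive values follow the convention of the source study,
#' where `PPV = TP/(TP+FN)` and `NPV = TN/(TN+FP)` — algebraically identical
#' to sensitivity and specificity — while the standard epidemiological
#' `PPV = TP/(TP+FP)` and `NPV = TN/(TN+FN)` are reported alongside to avoid
#' silent ambiguity.
#'
#' @param calls character vector of predictions (`"positive"`/`"negative"`).
#' @param truth character vector of histology labels, same length.
#' @return object of class `eval_table` with counts `tp, fp, tn, fn` and
#'   metrics `ppv_paper, npv_paper, ppv_std, npv_std, sensitivity,
#'   specificity`.
#' @export
evaluate_margins <- function(calls, truth) {
  if (length(calls) != length(truth)) stop("calls and truth differ in length")
  ok <- c("positive", "negative")
  if (!all(calls %in% ok) || !all(truth %in% ok)) {
    stop('labels must be "positive" or "negative"')
  }
  tp <- sum(calls == "positive" & truth == "positive")
  fp <- sum(calls == "positive" & truth == "negative")
  tn <- sum(calls == "negative" & truth == "negative")
  fn <- sum(calls == "negative" & truth == "positive")
  safe <- function(a, b) if (b > 0) a / b else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 ppv_paper = safe(tp, tp + fn),
                 npv_paper = safe(tn, tn + fp),
                 ppv_std = safe(tp, tp + fp),
                 npv_std = safe(tn, tn + fn),
                 sensitivity = safe(tp, tp + fn),
                 specificity = safe(tn, tn + fp)),
            class = "eval_table")
}

#' @export
print.eval_table <- function(x, ...) {
  cat(sprintf("Specimen evaluation: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  headline convention: PPV = %.3g, NPV = %.3g (= sensitivity/specificity)\n",
              x$ppv_paper, x$npv_paper))
  cat(sprintf("  standard convention: PPV = %.3g, NPV = %.3g\n", x$ppv_std, x$npv_std))
  invisible(x)
}

#' Overlay the margin mask on the specimen photograph
#'
#' Tints margin-positive pixels red at the given opacity; with an empty mask
#' the photo is returned unchanged (plus an opaque alpha channel).
#'
#' @param photo array `nx x ny x 3` (RGB in `[0, 1]`) or a grayscale matrix.
#' @param mask a `margin_mask` or logical matrix on the same lateral grid.
#' @param alpha tint opacity in `[0, 1]` (default 0.45).
#' @return RGBA array `nx x ny x 4`.
#' @export
overlay_margin <- function(photo, mask, alpha = 0.45) {
  m <- if (inherits(mask, "margin_mask")) mask$mask else mask
  if (is.matrix(photo)) {
    photo <- array(rep(photo, 3), dim = c(dim(photo), 3))
  }
  stopifnot(length(dim(photo)) == 3, dim(photo)[3] >= 3,
            alpha >= 0, alpha <= 1)
  if (!identical(dim(photo)[1:2], dim(m))) stop("photo and mask shapes differ")
  red <- c(1, 0, 0)
  out <- array(0, dim = c(dim(photo)[1:2], 4))
  for (ch in 1:3) {
    pl <- photo[, , ch]
    pl[m] <- (1 - alpha) * pl[m] + alpha * red[ch]
    out[, , ch] <- pl
  }
  out[, , 4] <- 1
  out
}

#' Default pipeline configuration
#'
#' A single document holding every tunable of the margin-assessment
#' pipeline, overridable by name (or from a YAML file via `yaml_path`).
#'
#' @param ... named overrides of top-level entries (nested lists are
#'   replaced wholesale).
#' @param yaml_path optional YAML file whose entries override the defaults.
#' @return nested list of class `margin_config`.
#' @export
margin_config <- function(..., yaml_path = NULL) {
  cfg <- list(
    specimen_id = "phantom-1",
    phantom = list(pattern = "infiltrating_boundary", seed = 1,
                   grid_shape = c(64, 64, 220), with_rcm = FALSE),
    fl = list(threshold = 0.5, min_area_px = 9),
    strips = list(fov_mm = 2.2, overlap_fraction = 0.1, jitter_px = 2),
    surfaces = list(rel_threshold = 0.5, smooth_span = 7, histogram_bins = 64),
    texture = list(sigma_smooth = 2, sigma_waviness = 16, sd_window = 9),
    training = list(rois_per_class = 5, roi_px = 28, classifier = NULL,
                    training_seed = 424243),
    margin = list(depth_mm = 1.0, min_area_mm2 = 0.01),
    overlay_alpha = 0.45,
    out_dir = NULL)
  if (!is.null(yaml_path)) {
    y <- yaml::read_yaml(yaml_path)
    cfg[names(y)] <- y
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "margin_config")
}

pipeline_stage <- function(name, log_env, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  log_env$log <- c(log_env$log,
                   sprintf("[%s] done in %.2fs", name,
                           as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

# Sample rectangular training ROIs fully inside each class region of an
# en-face plane, seeded; returns a feature data.frame with a class column.
# The plane is normalized to unit foreground mean first, matching the
# per-image depth adjustment used during voxel classification.
sample_training_rois <- function(phantom, compensated, z_ref, params,
                                 n_per_class = 5, roi_px = 16, seed = 424243) {
  cls <- tissue_classes()
  lab <- phantom$labels[z_ref, , ]
  img <- compensated[z_ref, , ]
  fg <- lab != cls[["background"]]
  if (any(fg) && mean(img[fg]) > 0) {
    img <- img / mean(img[fg])
    img[!fg] <- 1
  }
  fs <- feature_stack(img, params)
  half <- roi_px %/% 2L
  rows <- list()
  with_seed(seed, {
    for (cn in c("tumor", "adipose", "benign")) {
      ind <- lab == cls[[cn]]
      if (!any(ind)) next
      # positions whose full ROI square is inside the class region
      frac <- box_mean(ind + 0, odd_below(roi_px))
      ok <- which(frac > 0.999 &
                    row(ind) > half & row(ind) <= nrow(ind) - half &
                    col(ind) > half & col(ind) <= ncol(ind) - half,
                  arr.ind = TRUE)
      if (nrow(ok) == 0) next
      pick <- ok[sample.int(nrow(ok), min(n_per_class, nrow(ok))), , drop = FALSE]
      for (i in seq_len(nrow(pick))) {
        roi <- c(pick[i, 1] - half, pick[i, 1] + half,
                 pick[i, 2] - half, pick[i, 2] + half)
        f <- as.list(roi_features(fs, roi))
        f$class <- cn
        rows[[length(rows) + 1L]] <- as.data.frame(f)
      }
    }
  })
  if (!length(rows)) stop("no training ROI fits inside any class region")
  do.call(rbind, rows)
}

#' Run the end-to-end margin assessment pipeline
#'
#' Executes the full workflow on a synthetic specimen: phantom generation,
#' fluorescence ROI detection, strip planning and cross-correlation
#' stitching of the guidance plane, per-B-scan surface segmentation, depth
#' compensation, texture feature extraction, classifier training from
#' labelled ROIs (or an externally supplied model), 3-D voxel
#' classification, margin projection and the specimen-level call. Stage
#' errors are re-raised with the stage name; artifacts are written when
#' `out_dir` is configured.
#'
#' @param config a [margin_config()].
#' @return object of class `margin_report`.
#' @export
run_pipeline <- function(config = margin_config()) {
  stopifnot(inherits(config, "margin_config"))
  le <- new.env(); le$log <- character()
  cls <- tissue_classes()

  phantom <- pipeline_stage("phantom", le, {
    pc <- config$phantom
    if (inherits(pc, "specimen_phantom")) pc else {
      spec <- phantom_spec(grid_shape = pc$grid_shape %||% c(64, 64, 220),
                           layout_pattern = pc$pattern, seed = pc$seed)
      specimen_phantom(spec, with_rcm = isTRUE(pc$with_rcm))
    }
  })
  spec <- phantom$spec
  lat_um <- spec$lateral_voxel; ax_um <- spec$axial_voxel

  rois <- pipeline_stage("fl_rois", le, {
    fl_threshold_rois(phantom$fl, threshold = config$fl$threshold,
                      min_area = config$fl$min_area_px)
  })
  roi_extent_mm <- if (nrow(rois)) {
    max(rois$row2[1] - rois$row1[1] + 1, rois$col2[1] - rois$col1[1] + 1) *
      lat_um / 1000
  } else dim(phantom$oct)[2] * lat_um / 1000

  layout <- pipeline_stage("strips", le, {
    plan_strips(roi_extent_mm, fov_mm = config$strips$fov_mm,
                overlap_fraction = config$strips$overlap_fraction)
  })
  stitch_err <- pipeline_stage("stitch", le, {
    z_ref0 <- stats::median(phantom$truth_top) + 2L
    plane <- phantom$oct[min(z_ref0, dim(phantom$oct)[1]), , ]
    fov_px <- max(8L, min(ncol(plane), as.integer(round(
      config$strips$fov_mm * 1000 / lat_um))))
    ov_px <- max(4L, as.integer(round(fov_px * config$strips$overlap_fraction)))
    if (ncol(plane) - fov_px < 1) {
      le$log <- c(le$log, "[stitch] ROI fits a single field of view")
      0
    } else {
      cut <- cut_strips(plane, fov_px, ov_px,
                        jitter_px = config$strips$jitter_px, seed = spec$seed + 3L)
      offs <- vector("list", length(cut$strips) - 1L)
      err <- 0
      for (i in seq_along(offs)) {
        reg <- register_pair(cut$strips[[i]], cut$strips[[i + 1]],
                             nominal_overlap = ov_px,
                             search_radius = max(config$strips$jitter_px + 1L,
                                                 ov_px %/% 4L))
        offs[[i]] <- reg$absolute
        err <- max(err, max(abs(reg$absolute -
          (cut$true_offsets[[i]] + c(0, 0)))))
      }
      invisible(stitch(cut$strips, offs))
      err
    }
  })

  surf <- pipeline_stage("surfaces", le, {
    volume_surfaces(phantom$oct, config$surfaces$rel_threshold,
                    config$surfaces$smooth_span, config$surfaces$histogram_bins)
  })

  oct_clean <- pipeline_stage("surface_echo", le, {
    remove_surface_echo(phantom$oct, surf$top_map)
  })

  gain <- pipeline_stage("depth", le, {
    depth_compensate(oct_clean, surf$mask, ax_um)
  })

  params <- texture_params(config$texture$sigma_smooth,
                           config$texture$sigma_waviness,
                           config$texture$sd_window,
                           lateral_voxel_um = lat_um)

  model <- pipeline_stage("training", le, {
    if (!is.null(config$training$classifier)) {
      le$log <- c(le$log, "[training] using externally supplied classifier")
      config$training$classifier
    } else {
      le$log <- c(le$log,
                  "[training] fitting thresholds from labelled reference training images")
      train_reference_classifier(config, params,
                                 grid_shape = spec$grid_shape,
                                 lateral_voxel = spec$lateral_voxel,
                                 axial_voxel = spec$axial_voxel)
    }
  })

  labels <- pipeline_stage("classify", le, {
    classify_voxels(oct_clean, model, surf$mask, depth_gain = gain,
                    params = params, axial_voxel_um = ax_um)
  })

  margin <- pipeline_stage("margin", le, {
    project_margin(labels, surf$top_map, depth_mm = config$margin$depth_mm,
                   axial_voxel_um = ax_um, lateral_voxel_um = lat_um,
                   min_area_mm2 = config$margin$min_area_mm2)
  })
  call <- specimen_call(margin, config$margin$min_area_mm2)

  fractions <- pipeline_stage("fractions", le, {
    surf_lab <- surface_labels(labels, surf$top_map)
    fg <- surf_lab != cls[["background"]]
    f <- vapply(c("tumor", "adipose", "benign"), function(cn) {
      sum(surf_lab[fg] == cls[[cn]]) / max(1L, sum(fg))
    }, numeric(1))
    f
  })

  overlay <- overlay_margin(phantom$photo, margin, config$overlay_alpha)

  report <- structure(list(specimen_id = config$specimen_id,
                           call = call, margin = margin, overlay = overlay,
                           class_fractions = fractions,
                           classifier = model, labels = labels,
                           strip_layout = layout,
                           stitch_error_px = stitch_err,
                           depth_gain = gain, fl_rois = rois,
                           phantom = phantom,
                           config = config, log = le$log),
                      class = "margin_report")
  if (!is.null(config$out_dir)) write_margin_report(report, config$out_dir)
  report
}

#' Train the tissue classifier from reference training images
#'
#' Mirrors the study workflow of building the threshold model from labelled
#' training image sets: generates one seeded reference phantom per tissue
#' type (uniform tumor, adipose, and an infiltrating specimen supplying
#' clean benign stroma), samples labelled ROIs from a surface-adjacent
#' en-face plane of each after surface-echo removal and depth compensation,
#' and fits [tissue_classifier()] on the pooled features.
#'
#' @param config a [margin_config()] (uses its `training`, `surfaces` and
#'   `texture` entries).
#' @param params a [texture_params()]; defaults to the config's texture
#'   entry.
#' @param grid_shape,lateral_voxel,axial_voxel geometry of the reference
#'   phantoms.
#' @return a fitted `tissue_classifier`, with the pooled training features
#'   attached as attribute `features`.
#' @export
train_reference_classifier <- function(config = margin_config(), params = NULL,
                                       grid_shape = c(64, 64, 220),
                                       lateral_voxel = 10, axial_voxel = 5) {
  if (is.null(params)) {
    params <- texture_params(config$texture$sigma_smooth,
                             config$texture$sigma_waviness,
                             config$texture$sd_window,
                             lateral_voxel_um = lateral_voxel)
  }
  base_seed <- config$training$training_seed
  sources <- list(tumor = "uniform_tumor", adipose = "adipose_only",
                  benign = "infiltrating_boundary")
  feats <- NULL
  for (i in seq_along(sources)) {
    rspec <- phantom_spec(grid_shape = grid_shape,
                          lateral_voxel = lateral_voxel,
                          axial_voxel = axial_voxel,
                          layout_pattern = sources[[i]],
                          seed = base_seed + i)
    ref <- specimen_phantom(rspec, with_rcm = FALSE)
    surf <- volume_surfaces(ref$oct, config$surfaces$rel_threshold,
                            config$surfaces$smooth_span,
                            config$surfaces$histogram_bins)
    clean <- remove_surface_echo(ref$oct, surf$top_map)
    gain <- depth_compensate(clean, surf$mask, axial_voxel)
    z_ref <- min(max(surf$top_map) + 2L, dim(ref$oct)[1])
    f <- sample_training_rois(ref, gain$compensated, z_ref, params,
                              config$training$rois_per_class,
                              config$training$roi_px,
                              seed = base_seed + 10L * i)
    feats <- rbind(feats, f[f$class == names(sources)[i], , drop = FALSE])
  }
  model <- tissue_classifier(feats)
  attr(model, "features") <- feats
  model
}

# en-face label map read just below the top surface
surface_labels <- function(labels, top_map, offset = 1L) {
  d <- dim(labels)
  out <- matrix(tissue_classes()[["background"]], d[2], d[3])
  z <- pmin(pmax(top_map + offset, 1L), d[1])
  for (j in seq_len(d[3])) {
    out[, j] <- labels[cbind(z[, j], seq_len(d[2]), j)]
  }
  out
}

#' @export
print.margin_report <- function(x, ...) {
  cat(sprintf("Margin report for %s: %s\n", x$specimen_id, toupper(x$call)))
  cat(sprintf("  margin area %.3f mm^2 within %g mm of the surface\n",
              sum(x$margin$component_areas_mm2), x$margin$depth_mm))
  cat(sprintf("  surface fractions: tumor %.2f, adipose %.2f, benign %.2f\n",
              x$class_fractions[["tumor"]], x$class_fractions[["adipose"]],
              x$class_fractions[["benign"]]))
  invisible(x)
}

#' Run a seeded cohort of phantoms through the pipeline
#'
#' Generates `n_pos` positive-layout and `n_neg` negative-layout specimens
#' (cycling through the positive templates uniform_tumor,
#' infiltrating_boundary, deep_focus and the negative templates
#' adipose_only, lobule_insert), applies one shared classifier trained on a
#' reference multi-class phantom, and evaluates the specimen calls against
#' the layout truth.
#'
#' @param n_pos,n_neg cohort sizes (defaults 8 and 12, the study structure).
#' @param seed base seed; specimen `i` uses `seed * 1000 + i`.
#' @param config base [margin_config()] applied to every specimen.
#' @return list with `reports`, `calls`, `truth` and `eval` (an
#'   [evaluate_margins()] table).
#' @export
run_cohort <- function(n_pos = 8, n_neg = 12, seed = 1,
                       config = margin_config()) {
  pos_templates <- c("uniform_tumor", "infiltrating_boundary", "deep_focus")
  neg_templates <- c("adipose_only", "lobule_insert")
  patterns <- c(rep_len(pos_templates, n_pos), rep_len(neg_templates, n_neg))
  truth <- c(rep("positive", n_pos), rep("negative", n_neg))
  shared <- config$training$classifier %||%
    train_reference_classifier(config,
                               grid_shape = config$phantom$grid_shape %||% c(64, 64, 220))
  reports <- vector("list", length(patterns))
  calls <- character(length(patterns))
  for (i in seq_along(patterns)) {
    cfg_i <- config
    cfg_i$specimen_id <- sprintf("phantom-%02d-%s", i, patterns[i])
    cfg_i$phantom <- utils::modifyList(config$phantom %||% list(),
                                       list(pattern = patterns[i],
                                            seed = seed * 1000L + i))
    cfg_i$training$classifier <- shared
    reports[[i]] <- run_pipeline(cfg_i)
    calls[i] <- reports[[i]]$call
  }
  list(reports = reports, calls = calls, truth = truth,
       eval = evaluate_margins(calls, truth),
       patterns = patterns, classifier = shared)
}
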