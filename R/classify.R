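#' Fit the threshold tissue classifier from labelled ROI features
#'
#' Tissue-type assignment uses the two most discriminating texture features:
#' the mean sliding-window standard deviation of roughness and the mean
#' Prewitt slope. For each feature a one-dimensional decision threshold is
#' chosen by exhaustive search over the midpoints of consecutive sorted
#' training values, minimizing training misclassification. The fitted
#' decision list is: assign adipose if the slope exceeds its threshold (fat
#' cell membranes dominate image gradients), otherwise tumor if the
#' roughness SD exceeds its threshold, otherwise benign.
#'
#' @param features data.frame of ROI feature vectors (see [roi_features()]
#'   and [feature_names()]) with one row per training ROI.
#' @param class character vector (or factor) of tissue classes per row;
#'   taken from `features$class` when present. At least two classes must be
#'   represented.
#' @param slope_feature,roughness_feature column names of the two decision
#'   features.
#' @return object of class `tissue_classifier` with per-class training
#'   statistics, the two thresholds, training error and provenance counts.
#' @seealso [predict.tissue_classifier()], [classify_voxels()]
#' @export
tissue_classifier <- function(features, class = features$class,
                              slope_feature = "slope_mean",
                              roughness_feature = "roughness_sd_mean") {
  features <- as.data.frame(features)
  if (is.null(class)) stop("training classes are required")
  class <- as.character(class)
  stopifnot(nrow(features) == length(class),
            all(c(slope_feature, roughness_feature) %in% names(features)))
  known <- c("tumor", "adipose", "benign")
  if (!all(class %in% known)) {
    stop("classes must be among: ", paste(known, collapse = ", "))
  }
  if (length(unique(class)) < 2) {
    stop("training set must represent at least two classes")
  }
  slope_vals <- features[[slope_feature]]
  rough_vals <- features[[roughness_feature]]
  stopifnot(all(is.finite(slope_vals)), all(is.finite(rough_vals)))

  if (any(class == "adipose")) {
    sl <- best_threshold(slope_vals, class == "adipose", slope_feature)
  } else {
    sl <- list(threshold = Inf, errors = 0L)
  }
  rest <- class != "adipose"
  if (any(class[rest] == "tumor") && any(class[rest] == "benign")) {
    rg <- best_threshold(rough_vals[rest], class[rest] == "tumor",
                         roughness_feature)
  } else if (any(class[rest] == "tumor")) {
    rg <- list(threshold = -Inf, errors = 0L)
  } else {
    rg <- list(threshold = Inf, errors = 0L)
  }

  stats_tab <- do.call(rbind, lapply(intersect(known, unique(class)), function(cn) {
    sel <- class == cn
    data.frame(class = cn, n = sum(sel),
               slope_mean = mean(slope_vals[sel]),
               slope_sd = stats::sd(slope_vals[sel]),
               roughness_sd_mean = mean(rough_vals[sel]),
               roughness_sd_sd = stats::sd(rough_vals[sel]))
  }))
  model <- structure(list(
    thresholds = c(slope = sl$threshold, roughness_sd = rg$threshold),
    features = c(slope = slope_feature, roughness_sd = roughness_feature),
    stats = stats_tab,
    n_train = table(class),
    call = match.call()),
    class = "tissue_classifier")
  pred <- predict(model, features)
  model$training_error <- mean(pred != class)
  model
}

# Exhaustive 1-D threshold search over midpoints of consecutive sorted values;
# positive cases lie above the threshold.
best_threshold <- function(values, positive, feature_name) {
  u <- sort(unique(values))
  if (length(u) < 2) {
    stop(sprintf("feature '%s' is identical across classes: threshold degenerate",
                 feature_name))
  }
  cand <- (u[-1] + u[-length(u)]) / 2
  errs <- vapply(cand, function(th) {
    sum((values > th) != positive)
  }, numeric(1))
  best <- which.min(errs)
  list(threshold = cand[best], errors = errs[best])
}

#' @export
print.tissue_classifier <- function(x, ...) {
  cat("Threshold tissue classifier\n")
  cat(sprintf("  rule: adipose if %s > %.4g; else tumor if %s > %.4g; else benign\n",
              x$features[["slope"]], x$thresholds[["slope"]],
              x$features[["roughness_sd"]], x$thresholds[["roughness_sd"]]))
  cat(sprintf("  training ROIs: %s; training error %.3f\n",
              paste(sprintf("%s=%d", names(x$n_train), x$n_train), collapse = ", "),
              x$training_error))
  invisible(x)
}

#' @export
summary.tissue_classifier <- function(object, ...) {
  structure(list(model = object), class = "summary.tissue_classifier")
}

#' @export
print.summary.tissue_classifier <- function(x, ...) {
  print(x$model)
  cat("\nPer-class training statistics:\n")
  print(x$model$stats, row.names = FALSE)
  invisible(x)
}

#' @export
coef.tissue_classifier <- function(object, ...) {
  object$thresholds
}

#' Predict tissue classes for ROI feature rows
#'
#' Applies the fitted decision list to a data.frame of ROI features.
#'
#' @param object a [tissue_classifier()].
#' @param newdata data.frame containing the model's two feature columns.
#' @param ... unused.
#' @return character vector of classes (`"tumor"`, `"adipose"`, `"benign"`).
#' @export
predict.tissue_classifier <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  sv <- newdata[[object$features[["slope"]]]]
  rv <- newdata[[object$features[["roughness_sd"]]]]
  if (is.null(sv) || is.null(rv)) stop("newdata lacks the model's feature columns")
  ifelse(sv > object$thresholds[["slope"]], "adipose",
         ifelse(rv > object$thresholds[["roughness_sd"]], "tumor", "benign"))
}

#' Principal component analysis of the nine-feature table
#'
#' Standardizes the ROI-by-feature table (zero mean, unit SD per feature;
#' zero-variance features are dropped with a warning) and decomposes it by
#' singular value decomposition, reporting component loadings, the
#' explained-variance fractions and their cumulative stair.
#'
#' @param feature_table numeric matrix or data.frame, ROIs in rows, features
#'   in columns (at least 2 rows).
#' @return object of class `pca_report`: `loadings`, `explained`,
#'   `cumulative`, `dropped`.
#' @export
pca_report <- function(feature_table) {
  x <- as.matrix(as.data.frame(feature_table)[,
         setdiff(colnames(as.data.frame(feature_table)), "class"), drop = FALSE])
  storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("at least two ROIs are required")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warning("dropping zero-variance feature(s): ", paste(dropped, collapse = ", "))
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
    sds <- sds[!(names(sds) %in% dropped)]
  }
  if (ncol(x) == 0) stop("no informative features remain")
  xs <- scale(x, center = TRUE, scale = TRUE)
  s <- svd(xs)
  expl <- s$d^2 / sum(s$d^2)
  loadings <- s$v
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  structure(list(loadings = loadings, explained = expl,
                 cumulative = cumsum(expl), dropped = dropped,
                 scores = xs %*% loadings),
            class = "pca_report")
}

#' @export
print.pca_report <- function(x, ...) {
  cat(sprintf("PCA of %d features: explained variance %s\n",
              nrow(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained[seq_len(min(5, length(x$explained)))]),
                    collapse = ", ")))
  cat(sprintf("  cumulative after 2: %.1f%%, after 5: %.1f%%\n",
              100 * x$cumulative[min(2, length(x$cumulative))],
              100 * x$cumulative[min(5, length(x$cumulative))]))
  invisible(x)
}

#' Assign tissue classes to every voxel of an OCT volume
#'
#' Applies the fitted decision list per voxel with depth-adjusted
#' processing: the volume is depth-compensated, and every en-face plane is
#' additionally normalized to unit foreground mean before feature
#' extraction — the same convention used when the training features were
#' computed — so the signal drop of each image is accounted for regardless
#' of its cause (attenuation or structure). Both feature maps are
#' window-averaged (over the SD window) before thresholding so their scale
#' matches the ROI-mean statistics the thresholds were trained on. Voxels
#' outside the foreground mask are background. An optional 3x3x3 majority
#' vote smooths the label volume.
#'
#' @param volume OCT array `(nz, nx, ny)`.
#' @param model a [tissue_classifier()].
#' @param mask logical foreground array, same shape.
#' @param depth_gain optional `depth_gain` from [depth_compensate()]; when
#'   NULL it is fitted here.
#' @param params a [texture_params()].
#' @param axial_voxel_um axial voxel size (used only when fitting the gain).
#' @param smooth apply the 3x3x3 majority filter (default TRUE).
#' @param decision_window odd window (px) over which the feature maps are
#'   aggregated before thresholding; wider than the SD window so the
#'   per-voxel decision statistics approach the ROI-mean statistics the
#'   thresholds were trained on. The slope map is window-averaged (sparse
#'   bright septa must be able to pull a window towards adipose); the
#'   roughness-SD map is window-medianed, so an isolated bright membrane
#'   cannot masquerade as diffuse tumor texture in its neighbourhood.
#'   Default 21.
#' @param tumor_intensity_floor minimum window-averaged intensity (in units
#'   of the plane's foreground mean) for a tumor call. Tumor is the
#'   strongest scatterer of the three tissue types, so regions near the
#'   noise floor — deep fat lumens in particular — are never assigned to it
#'   however rough their neighbourhood looks. Default 0.5; 0 disables.
#' @param context_min minimum fraction of in-mask pixels within the
#'   decision window for a voxel to be classified; windows dominated by
#'   out-of-mask fill carry no usable texture and are left as background
#'   (indeterminate). Default 0.7.
#' @return integer label array (codes of [tissue_classes()]).
#' @export
classify_voxels <- function(volume, model, mask, depth_gain = NULL,
                            params = texture_params(), axial_voxel_um = 5,
                            smooth = TRUE, decision_window = 21,
                            tumor_intensity_floor = 0.5, context_min = 0.7) {
  stopifnot(inherits(model, "tissue_classifier"),
            length(dim(volume)) == 3, identical(dim(volume), dim(mask)))
  if (is.null(depth_gain)) {
    depth_gain <- depth_compensate(volume, mask, axial_voxel_um)
  }
  comp <- depth_gain$compensated
  if (is.null(comp) || !identical(dim(comp), dim(volume))) {
    comp <- volume * depth_gain$gain[slicewise_index(dim(volume))]
  }
  cls <- tissue_classes()
  d <- dim(volume)
  labels <- array(cls[["background"]], dim = d)
  th_s <- model$thresholds[["slope"]]
  th_r <- model$thresholds[["roughness_sd"]]
  for (z in seq_len(d[1])) {
    mk <- mask[z, , ]
    if (!any(mk)) next
    sl <- comp[z, , ]
    # per-image depth adjustment: unit foreground mean; fill out-of-mask
    # pixels with that mean so windows never straddle the tissue border
    fg_mean <- mean(sl[mk])
    if (fg_mean <= 0) next
    sl <- sl / fg_mean
    sl[!mk] <- 1
    fs <- feature_stack(sl, params)
    w <- as.integer(decision_window)
    if (w %% 2L == 0L) w <- w + 1L
    slope_loc <- box_mean(fs$slope, w)
    r_max <- max(fs$roughness_sd)
    rsd_loc <- if (r_max > 0) {
      EBImage::medianFilter(fs$roughness_sd / r_max, w %/% 2L) * r_max
    } else fs$roughness_sd
    int_loc <- box_mean(sl, w)
    ctx <- box_mean(mk + 0, w)
    lab <- matrix(cls[["background"]], d[2], d[3])
    lab[mk] <- ifelse(ctx[mk] < context_min, cls[["background"]],
                      ifelse(slope_loc[mk] > th_s, cls[["adipose"]],
                             ifelse(rsd_loc[mk] > th_r &
                                      int_loc[mk] > tumor_intensity_floor,
                                    cls[["tumor"]], cls[["benign"]])))
    labels[z, , ] <- lab
  }
  if (smooth) labels <- majority_smooth(labels, mask)
  labels
}

# 3x3x3 majority vote among tissue classes; background and mask are immutable.
majority_smooth <- function(labels, mask) {
  d <- dim(labels)
  cls <- setdiff(unname(tissue_classes()), 0L)
  votes <- lapply(cls, function(v) array(0L, dim = d))
  names(votes) <- as.character(cls)
  shifts <- expand.grid(dz = -1:1, dx = -1:1, dy = -1:1)
  for (s in seq_len(nrow(shifts))) {
    dz <- shifts$dz[s]; dx <- shifts$dx[s]; dy <- shifts$dy[s]
    zi <- pmin(pmax(seq_len(d[1]) + dz, 1L), d[1])
    xi <- pmin(pmax(seq_len(d[2]) + dx, 1L), d[2])
    yi <- pmin(pmax(seq_len(d[3]) + dy, 1L), d[3])
    shifted <- labels[zi, xi, yi, drop = FALSE]
    for (v in cls) {
      votes[[as.character(v)]] <- votes[[as.character(v)]] + (shifted == v)
    }
  }
  best <- array(cls[1], dim = d)
  best_count <- votes[[as.character(cls[1])]]
  for (v in cls[-1]) {
    better <- votes[[as.character(v)]] > best_count
    best[better] <- v
    best_count[better] <- votes[[as.character(v)]][better]
  }
  out <- labels
  tissue <- mask & labels != tissue_classes()[["background"]] & best_count > 0L
  out[tissue] <- best[tissue]
  out[!mask] <- tissue_classes()[["background"]]
  out
}

#' Project tumor labels within a depth band onto the surface
#'
#' A lateral pixel is margin-positive when any voxel labelled tumor lies
#' within `depth_mm` below the local top surface (the clinically relevant
#' band: no tumor within about 1 mm of the cut surface). Connected
#' components smaller than `min_area_mm2` are removed.
#'
#' @param labels integer label array `(nz, nx, ny)`.
#' @param top_map integer `nx x ny` matrix of top-surface depths (voxels).
#' @param depth_mm projection depth below the surface (default 1).
#' @param axial_voxel_um,lateral_voxel_um voxel sizes.
#' @param min_area_mm2 minimum surviving component area (default 0.01).
#' @return object of class `margin_mask`: `mask` (`nx x ny` logical),
#'   `component_areas_mm2`, and the projection parameters.
#' @export
project_margin <- function(labels, top_map, depth_mm = 1.0,
                           axial_voxel_um = 5, lateral_voxel_um = 10,
                           min_area_mm2 = 0.01) {
  stopifnot(length(dim(labels)) == 3, depth_mm > 0)
  if (is.null(top_map)) stop("top surface map is required")
  d <- dim(labels)
  stopifnot(nrow(top_map) == d[2], ncol(top_map) == d[3])
  tumor <- tissue_classes()[["tumor"]]
  depth_vox <- depth_mm * 1000 / axial_voxel_um
  acc <- matrix(FALSE, d[2], d[3])
  for (z in seq_len(d[1])) {
    hit <- (labels[z, , ] == tumor) & (z >= top_map) &
      ((z - top_map) <= depth_vox)
    acc <- acc | hit
  }
  px_mm2 <- (lateral_voxel_um / 1000)^2
  areas <- numeric(0)
  if (any(acc)) {
    lab <- EBImage::bwlabel(acc)
    ids <- setdiff(sort(unique(as.vector(lab))), 0)
    areas <- vapply(ids, function(id) sum(lab == id) * px_mm2, numeric(1))
    keep <- ids[areas >= min_area_mm2]
    acc <- matrix(lab %in% keep, d[2], d[3])
    areas <- areas[areas >= min_area_mm2]
  }
  structure(list(mask = acc, component_areas_mm2 = areas,
                 depth_mm = depth_mm, min_area_mm2 = min_area_mm2,
                 lateral_voxel_um = lateral_voxel_um),
            class = "margin_mask")
}

#' @export
print.margin_mask <- function(x, ...) {
  cat(sprintf("Margin mask: %.3f mm^2 over %d component(s), projection depth %g mm\n",
              sum(x$component_areas_mm2), length(x$component_areas_mm2), x$depth_mm))
  invisible(x)
}

#' Specimen-level margin call
#'
#' The specimen is called positive when the surviving margin-mask area
#' reaches `min_area_mm2` (default 0.01 mm^2).
#'
#' @param mask a [project_margin()] result.
#' @param min_area_mm2 minimum total area for a positive call.
#' @return `"positive"` or `"negative"`.
#' @export
specimen_call <- function(mask, min_area_mm2 = 0.01) {
  stopifnot(inherits(mask, "margin_mask"))
  total <- sum(mask$mask) * (mask$lateral_voxel_um / 1000)^2
  if (total >= min_area_mm2) "positive" else "negative"
}
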