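#' Texture filter parameters
#'
#' Kernel sizes for the roughness/waviness decomposition and the
#' sliding-window standard-deviation filter. Sizes are in pixels of the
#' lateral grid; the defaults correspond to a 10 um lateral voxel and may be
#' rescaled through `lateral_voxel_um` (a 5 um grid doubles every size).
#'
#' @param sigma_smooth Gaussian sigma (px) of the high-frequency smoothing.
#' @param sigma_waviness Gaussian sigma (px) of the large-scale waviness
#'   estimate; must exceed `sigma_smooth`.
#' @param sd_window odd window width (px) of the standard-deviation filter.
#' @param lateral_voxel_um lateral voxel size the pixel defaults refer to.
#' @return list of class `texture_params`.
#' @export
texture_params <- function(sigma_smooth = 2, sigma_waviness = 16, sd_window = 9,
                           lateral_voxel_um = 10) {
  scale <- 10 / lateral_voxel_um
  sigma_smooth <- sigma_smooth * scale
  sigma_waviness <- sigma_waviness * scale
  sd_window <- as.integer(round(sd_window * scale))
  if (sd_window %% 2L == 0L) sd_window <- sd_window + 1L
  stopifnot(sigma_smooth > 0, sigma_waviness > sigma_smooth, sd_window >= 3L)
  structure(list(sigma_smooth = sigma_smooth, sigma_waviness = sigma_waviness,
                 sd_window = sd_window, lateral_voxel_um = lateral_voxel_um),
            class = "texture_params")
}

#' Gaussian smoothing with reflective borders
#'
#' Separable convolution with a normalized discrete Gaussian truncated at
#' three sigma; borders are handled by symmetric (edge-inclusive) reflection,
#' so a constant image is reproduced exactly.
#'
#' @param image numeric matrix.
#' @param sigma kernel standard deviation in pixels (> 0).
#' @return smoothed matrix of the same shape.
#' @export
gaussian_smooth <- function(image, sigma) {
  stopifnot(is.matrix(image))
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive number")
  }
  conv_sep2(image, gaussian_kernel(sigma))
}

#' Waviness/roughness decomposition
#'
#' The smoothed image (high-frequency noise removed at `sigma_smooth`) is
#' split into a large-scale waviness profile (a second Gaussian at
#' `sigma_waviness`) and the roughness residual. By construction
#' `smoothed = waviness + roughness` exactly, and the roughness has
#' approximately zero mean away from borders.
#'
#' @param image numeric matrix.
#' @param sigma_smooth,sigma_waviness Gaussian sigmas in px, with
#'   `sigma_waviness > sigma_smooth`.
#' @return list with `smoothed`, `waviness`, `roughness` matrices.
#' @export
roughness_decompose <- function(image, sigma_smooth = 2, sigma_waviness = 16) {
  if (sigma_waviness <= sigma_smooth) {
    stop("`sigma_waviness` must exceed `sigma_smooth`")
  }
  smoothed <- gaussian_smooth(image, sigma_smooth)
  waviness <- gaussian_smooth(smoothed, sigma_waviness)
  list(smoothed = smoothed, waviness = waviness,
       roughness = smoothed - waviness)
}

#' Sliding-window standard deviation
#'
#' Per-pixel population standard deviation (divisor `n`, not `n - 1`) over a
#' `w x w` neighbourhood with reflective borders, computed from box-filtered
#' first and second moments.
#'
#' @param roughness numeric matrix (typically the roughness residual).
#' @param window odd window width `>= 3`.
#' @return matrix of non-negative standard deviations, same shape.
#' @export
roughness_sd_filter <- function(roughness, window = 9) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 3")
  }
  m1 <- box_mean(roughness, window)
  m2 <- box_mean(roughness^2, window)
  sqrt(pmax(m2 - m1^2, 0))
}

#' Prewitt gradient magnitude (tissue slope)
#'
#' Gradient magnitude `sqrt(gx^2 + gy^2)` from 3x3 Prewitt kernels divided by
#' 6, so a ramp of `s` intensity units per pixel yields slope `s` at interior
#' pixels. Borders are reflective.
#'
#' @param image numeric matrix, at least 3x3.
#' @return non-negative slope map in intensity units per pixel.
#' @export
prewitt_slope <- function(image) {
  stopifnot(is.matrix(image))
  if (nrow(image) < 3 || ncol(image) < 3) stop("image must be at least 3x3")
  kx <- outer(rep(1, 3), c(-1, 0, 1)) / 6   # d/dcol
  gx <- conv_2d(image, kx)
  gy <- conv_2d(image, t(kx))               # d/drow
  sqrt(gx^2 + gy^2)
}

#' Fit and remove the depth-dependent signal decay
#'
#' OCT signal decays roughly exponentially with depth through scattering
#' tissue. The mean foreground intensity is computed per depth, a linear
#' model is fitted to its logarithm, and the fitted decay is removed by a
#' multiplicative gain `exp(rate * z)` normalized to 1 at the surface, so
#' tissue-type thresholds trained near the surface remain valid at depth.
#'
#' @param volume 3-D array `(nz, nx, ny)` (or a single B-scan matrix
#'   `nz x nx`).
#' @param mask logical array of the same shape marking foreground tissue;
#'   depths with no foreground are excluded from the fit.
#' @param axial_voxel_um axial voxel size in um.
#' @param exclude_surface number of shallowest foreground voxels per A-line
#'   excluded from the decay fit (the specular window reflection is not
#'   scattering signal); the gain is still applied everywhere. Default 1.
#' @return list of class `depth_gain`: `gain` (per-depth multiplier, first
#'   element 1), `rate_per_mm` (fitted decay rate), `z_um`, and `compensated`
#'   (the gain-corrected volume).
#' @export
depth_compensate <- function(volume, mask, axial_voxel_um = 5,
                             exclude_surface = 1L) {
  if (is.matrix(volume)) {
    volume <- array(volume, dim = c(dim(volume), 1L))
    mask <- array(mask, dim = dim(volume))
  }
  stopifnot(length(dim(volume)) == 3, identical(dim(volume), dim(mask)),
            axial_voxel_um > 0)
  nz <- dim(volume)[1]
  fit_mask <- mask
  if (exclude_surface > 0L) {
    cs <- apply(mask, c(2, 3), cumsum)
    fit_mask <- mask & (cs > exclude_surface)
  }
  mu <- vapply(seq_len(nz), function(z) {
    sl <- volume[z, , ]; mk <- fit_mask[z, , ]
    if (!any(mk)) return(NA_real_)
    mean(sl[mk])
  }, numeric(1))
  used <- which(is.finite(mu) & mu > 0)
  if (length(used) < 3) stop("foreground mask covers too few depths for a fit")
  z_um <- (seq_len(nz) - 1) * axial_voxel_um
  fit <- stats::lm(log(mu[used]) ~ z_um[used])
  slope <- unname(stats::coef(fit)[2])          # 1/um, negative for decay
  if (!is.finite(slope)) stop("depth fit did not converge to a finite rate")
  rate_per_mm <- -slope * 1000
  gain <- exp(-slope * z_um)                    # gain(0) = 1, grows with depth
  compensated <- volume * gain[slicewise_index(dim(volume))]
  structure(list(gain = gain, rate_per_mm = rate_per_mm, z_um = z_um,
                 compensated = compensated),
            class = "depth_gain")
}

# index vector replicating a per-depth quantity across an (nz, nx, ny) array
slicewise_index <- function(d) {
  rep.int(seq_len(d[1]), d[2] * d[3])
}

#' @export
print.depth_gain <- function(x, ...) {
  cat(sprintf("Depth gain: fitted decay %.3f /mm over %d depths, max gain %.3g\n",
              x$rate_per_mm, length(x$gain), max(x$gain)))
  invisible(x)
}

#' Per-pixel texture feature maps
#'
#' Computes the full map stack used by the tissue classifier: smoothed image,
#' waviness, roughness, sliding-window roughness SD and Prewitt slope (the
#' slope of the smoothed image).
#'
#' @param image numeric matrix (an en-face OCT plane or B-scan).
#' @param params a [texture_params()] object.
#' @return object of class `feature_stack` holding `image`, `smoothed`,
#'   `waviness`, `roughness`, `roughness_sd`, `slope` and `params`.
#' @export
feature_stack <- function(image, params = texture_params()) {
  stopifnot(is.matrix(image), inherits(params, "texture_params"))
  dec <- roughness_decompose(image, params$sigma_smooth, params$sigma_waviness)
  structure(c(list(image = image), dec,
              list(roughness_sd = roughness_sd_filter(dec$roughness, params$sd_window),
                   slope = prewitt_slope(dec$smoothed),
                   params = params)),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("Feature stack %d x %d (sigma %g/%g px, SD window %d px)\n",
              nrow(x$image), ncol(x$image), x$params$sigma_smooth,
              x$params$sigma_waviness, x$params$sd_window))
  invisible(x)
}

#' Names of the nine ROI texture features
#' @return character vector of length 9.
#' @export
feature_names <- function() {
  c("intensity_mean", "intensity_sd", "waviness_mean",
    "roughness_sd_mean", "roughness_sd_max", "slope_mean", "slope_sd",
    "intensity_entropy", "local_contrast")
}

#' Nine-feature summary of a rectangular ROI
#'
#' Aggregates the feature maps over a rectangular region, excluding a border
#' of half the SD window so every retained pixel has a fully interior
#' neighbourhood. The nine features are: mean and SD of intensity, mean
#' waviness, mean and max of the roughness SD map, mean and SD of the slope
#' map, 16-bin intensity entropy (bits, 0 for a constant region) and local
#' contrast (mean absolute difference between the image and its smoothed
#' version).
#'
#' @param stack a [feature_stack()].
#' @param roi integer vector `c(row1, row2, col1, col2)` (inclusive bounds,
#'   1-based); each side must span at least `sd_window` pixels.
#' @return named numeric vector of length 9 (see [feature_names()]).
#' @export
roi_features <- function(stack, roi) {
  stopifnot(inherits(stack, "feature_stack"), length(roi) == 4)
  roi <- as.integer(roi)
  w <- stack$params$sd_window
  if (roi[1] < 1 || roi[3] < 1 || roi[2] > nrow(stack$image) ||
      roi[4] > ncol(stack$image)) {
    stop("ROI out of image bounds")
  }
  if (roi[2] - roi[1] + 1L < w || roi[4] - roi[3] + 1L < w) {
    stop(sprintf("ROI must span at least the SD window (%d px) in each dimension", w))
  }
  b <- w %/% 2L
  rows <- (roi[1] + b):(roi[2] - b)
  cols <- (roi[3] + b):(roi[4] - b)
  img <- stack$image[rows, cols]
  rsd <- stack$roughness_sd[rows, cols]
  slp <- stack$slope[rows, cols]
  c(intensity_mean = mean(img),
    intensity_sd = stats::sd(img),
    waviness_mean = mean(stack$waviness[rows, cols]),
    roughness_sd_mean = mean(rsd),
    roughness_sd_max = max(rsd),
    slope_mean = mean(slp),
    slope_sd = stats::sd(slp),
    intensity_entropy = histogram_entropy(img, 16L),
    local_contrast = mean(abs(img - stack$smoothed[rows, cols])))
}

# Shannon entropy (bits) of an equal-width histogram over the value range.
histogram_entropy <- function(x, bins = 16L) {
  r <- range(x)
  if (r[2] <= r[1]) return(0)
  idx <- pmin(bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * bins))
  p <- tabulate(idx, bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Write a feature stack as a multi-page TIFF
#'
#' Pages in order: image, smoothed, waviness, roughness, roughness SD, slope;
#' each page is min-max normalized to `[0, 1]` (32-bit float).
#'
#' @param stack a [feature_stack()].
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
write_feature_stack <- function(stack, path) {
  pages <- stack[c("image", "smoothed", "waviness", "roughness",
                   "roughness_sd", "slope")]
  norm <- lapply(pages, function(m) {
    r <- range(m)
    if (r[2] > r[1]) (m - r[1]) / (r[2] - r[1]) else m * 0
  })
  tiff::writeTIFF(norm, path, bits.per.sample = 32L)
  invisible(path)
}
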