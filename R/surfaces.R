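#' @name surfaces
#' @title Tissue surface segmentation in B-scans
#' @description
#' Cross-sectional OCT frames of a specimen pressed against the imaging
#' window show a highly reflective top surface and a gradual loss of signal
#' with depth. Tissue-type assignment needs both boundaries: the top surface
#' is found per A-line by peak finding, and the bottom (maximum usable signal
#' depth) by a histogram-threshold run analysis. Profiles are median-smoothed
#' across columns; smoothing is iterated to a median-filter root so it is
#' idempotent.
NULL

surface_profile <- function(depth, valid) {
  depth[!valid] <- NA_integer_
  structure(list(depth = as.integer(depth), valid = valid), class = "surface_profile")
}

#' @export
print.surface_profile <- function(x, ...) {
  cat(sprintf("Surface profile: %d columns, %d valid, depth range [%s, %s]\n",
              length(x$depth), sum(x$valid),
              if (any(x$valid)) min(x$depth[x$valid]) else "-",
              if (any(x$valid)) max(x$depth[x$valid]) else "-"))
  invisible(x)
}

# Median-smooth a profile to a median-filter root (idempotent by construction).
# Invalid entries are bridged by nearest-valid values during smoothing and
# restored to invalid afterwards.
smooth_profile <- function(depth, valid, span) {
  span <- as.integer(span)
  if (span %% 2L == 0L) span <- span + 1L
  if (!any(valid) || span < 3L || sum(valid) < 2L) return(depth)
  filled <- fill_nearest(depth, valid)
  for (i in 1:25) {
    sm <- as.numeric(stats::runmed(filled, k = min(span, odd_below(length(filled)))))
    if (all(sm == filled)) break
    filled <- sm
  }
  out <- as.integer(round(filled))
  out[!valid] <- depth[!valid]
  out
}

odd_below <- function(n) if (n %% 2L == 0L) n - 1L else n

# Replace entries where valid is FALSE by the nearest valid value.
fill_nearest <- function(x, valid) {
  if (all(valid)) return(x)
  idx <- which(valid)
  pos <- seq_along(x)
  nearest <- idx[pmax(1L, findInterval(pos, idx))]
  # findInterval gives the last valid index <= pos; compare with the next one
  nxt <- idx[pmin(length(idx), findInterval(pos, idx) + 1L)]
  take_next <- abs(nxt - pos) < abs(nearest - pos)
  out <- x
  out[!valid] <- ifelse(take_next, x[nxt], x[nearest])[!valid]
  out
}

#' Segment the top tissue surface of a B-scan
#'
#' Per lateral column, the surface is the first axial local maximum whose
#' intensity reaches `rel_threshold` times the column maximum; the resulting
#' profile is median-smoothed over `smooth_span` columns. Columns with no
#' signal (non-finite or non-positive maximum) are flagged invalid.
#'
#' @param bscan matrix `nz x ncol` (rows = depth, columns = lateral).
#' @param rel_threshold fraction of the column maximum in `(0, 1)`.
#' @param smooth_span odd median window in columns.
#' @param lateral_sigma Gaussian sigma (columns) of a lateral-only
#'   pre-smoothing that damps speckle outliers without moving axial
#'   boundaries; 0 disables. Default 2.
#' @return a `surface_profile` with integer depths (1-based voxel index) and
#'   per-column validity.
#' @export
top_surface <- function(bscan, rel_threshold = 0.5, smooth_span = 7,
                        lateral_sigma = 2) {
  stopifnot(is.matrix(bscan), rel_threshold > 0, rel_threshold < 1)
  nz <- nrow(bscan); nc <- ncol(bscan)
  if (lateral_sigma > 0 && nc > 1) {
    k <- gaussian_kernel(lateral_sigma)
    bscan <- t(conv_rows_padded(pad_rows(t(bscan), (length(k) - 1L) %/% 2L), k, nc))
  }
  depth <- integer(nc); valid <- logical(nc)
  for (j in seq_len(nc)) {
    v <- bscan[, j]
    mx <- max(v)
    if (!is.finite(mx) || mx <= 0) next
    thr <- rel_threshold * mx
    lmax <- local_maxima(v)
    hit <- lmax[v[lmax] >= thr]
    if (length(hit)) {
      depth[j] <- hit[1]
      valid[j] <- TRUE
    }
  }
  if (!any(valid)) stop("no column contains a qualifying surface peak")
  depth <- smooth_profile(depth, valid, smooth_span)
  surface_profile(depth, valid)
}

local_maxima <- function(v) {
  n <- length(v)
  if (n == 1L) return(1L)
  left <- c(TRUE, v[-1] >= v[-n])
  right <- c(v[-n] >= v[-1], TRUE)
  which(left & right)
}

# Between-class variance maximization (Otsu) on an equal-width histogram.
otsu_threshold <- function(values, bins = 64L) {
  bins <- as.integer(bins)
  stopifnot(bins >= 8L)
  r <- range(values)
  if (r[2] <= r[1]) stop("constant image: histogram threshold undefined")
  edges <- seq(r[1], r[2], length.out = bins + 1L)
  idx <- pmin(bins, 1L + floor((values - r[1]) / (r[2] - r[1]) * bins))
  p <- tabulate(idx, bins) / length(values)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[bins]
  sb <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  t_bin <- which.max(sb[-bins])   # threshold between bins t and t+1
  edges[t_bin + 1L]
}

#' Segment the bottom (maximum-signal) depth of a B-scan
#'
#' A global intensity threshold is chosen by between-class variance
#' maximization on a `histogram_bins`-bin histogram of log intensity (OCT
#' intensities are multiplicative — speckle times exponential decay — so the
#' tissue/background histogram is bimodal in the log domain; a noiseless
#' two-valued slab reduces to the same split). Per column, the bottom is the
#' deepest voxel of the largest above-threshold connected run, and the
#' profile is median-smoothed. The B-scan is first smoothed laterally
#' (columns only, so axial boundaries are untouched and noiseless slabs stay
#' exact) to bridge signal-poor structures such as fat lumens. If the
#' above-threshold runs are short (median largest run below `nz / 6`), the
#' frame carries no coherent tissue band — e.g. pure noise — and every
#' column is flagged invalid rather than reporting a spurious surface.
#'
#' @param bscan matrix `nz x ncol`.
#' @param histogram_bins number of histogram bins (>= 8, default 64).
#' @param smooth_span odd median window in columns.
#' @param lateral_sigma Gaussian sigma (columns) of the lateral
#'   pre-smoothing; 0 disables. Default 2.
#' @return a `surface_profile`.
#' @export
bottom_depth <- function(bscan, histogram_bins = 64, smooth_span = 7,
                         lateral_sigma = 2) {
  stopifnot(is.matrix(bscan))
  nz <- nrow(bscan); nc <- ncol(bscan)
  sm <- bscan
  if (lateral_sigma > 0 && nc > 1) {
    k <- gaussian_kernel(lateral_sigma)
    sm <- t(conv_rows_padded(pad_rows(t(bscan), (length(k) - 1L) %/% 2L), k, nc))
  }
  lv <- log(pmax(sm, 0) + 1e-6 * max(sm))
  thr <- otsu_threshold(as.vector(lv), histogram_bins)
  above <- lv > thr
  if (!any(above)) stop("no voxels above the histogram threshold")
  depth <- integer(nc); valid <- logical(nc); runlen <- integer(nc)
  for (j in seq_len(nc)) {
    r <- rle(above[, j])
    ends <- cumsum(r$lengths)
    runs <- which(r$values)
    if (!length(runs)) next
    best <- runs[which.max(r$lengths[runs])]
    depth[j] <- ends[best]
    runlen[j] <- r$lengths[best]
    valid[j] <- TRUE
  }
  if (!any(valid)) stop("no column contains an above-threshold run")
  # a tissue frame always carries a sizable population of columns whose
  # above-threshold run spans a good part of the depth (septa, stroma);
  # noise-only frames have uniformly short runs
  if (stats::quantile(runlen[valid], 0.75) < max(3, nz / 6)) {
    return(surface_profile(rep(0L, nc), rep(FALSE, nc)))
  }
  valid <- valid & (runlen >= max(3, nz / 8))
  depth <- smooth_profile(depth, valid, smooth_span)
  surface_profile(depth, valid)
}

#' Foreground mask between two surface profiles
#'
#' Marks voxels with `top <= z <= bottom` in columns where both profiles are
#' usable. Columns invalid in either profile are bridged by nearest-valid
#' interpolation for masking; columns whose (bridged) top exceeds the bottom
#' are excluded entirely.
#'
#' @param top,bottom `surface_profile` objects over the same columns.
#' @param shape `c(nz, ncol)` of the output mask.
#' @return logical matrix `nz x ncol`.
#' @export
mask_between <- function(top, bottom, shape) {
  stopifnot(inherits(top, "surface_profile"), inherits(bottom, "surface_profile"),
            length(top$depth) == length(bottom$depth),
            length(shape) == 2, shape[2] == length(top$depth))
  nz <- shape[1]; nc <- shape[2]
  if (!any(top$valid) || !any(bottom$valid)) {
    stop("profiles share no valid columns")
  }
  t_f <- fill_nearest(top$depth, top$valid)
  b_f <- fill_nearest(bottom$depth, bottom$valid)
  mask <- matrix(FALSE, nz, nc)
  for (j in seq_len(nc)) {
    if (t_f[j] > b_f[j]) next
    z1 <- max(1L, t_f[j]); z2 <- min(nz, b_f[j])
    if (z1 <= z2) mask[z1:z2, j] <- TRUE
  }
  mask
}

#' Surfaces and foreground of a full OCT volume
#'
#' Runs [top_surface()] and [bottom_depth()] on every B-scan of a volume and
#' assembles the lateral top/bottom depth maps and the 3-D foreground mask.
#'
#' @param volume array `(nz, nx, ny)`.
#' @param rel_threshold,smooth_span,histogram_bins passed to the per-B-scan
#'   segmenters.
#' @details The per-B-scan bottom profiles are additionally median-smoothed
#'   across the second lateral dimension so the foreground mask is a
#'   laterally coherent slab: isolated columns whose maximum-signal depth
#'   ends early (for instance under a deep fat lumen) would otherwise
#'   perforate the mask and every texture window near such a hole would see
#'   an artificial boundary.
#' @return list with `top_map`, `bottom_map` (`nx x ny` integer matrices),
#'   `mask` (logical array like `volume`) and the per-B-scan profiles.
#' @export
volume_surfaces <- function(volume, rel_threshold = 0.5, smooth_span = 7,
                            histogram_bins = 64) {
  stopifnot(length(dim(volume)) == 3)
  d <- dim(volume)
  top_map <- matrix(NA_integer_, d[2], d[3])
  bottom_map <- matrix(NA_integer_, d[2], d[3])
  tops <- vector("list", d[3]); bottoms <- vector("list", d[3])
  for (y in seq_len(d[3])) {
    bs <- volume[, , y]
    tp <- top_surface(bs, rel_threshold, smooth_span)
    bt <- bottom_depth(bs, histogram_bins, smooth_span)
    tops[[y]] <- tp; bottoms[[y]] <- bt
    top_map[, y] <- fill_nearest(tp$depth, tp$valid)
    bottom_map[, y] <- fill_nearest(bt$depth, bt$valid)
  }
  bottom_map <- median_smooth_map(bottom_map, smooth_span)
  mask <- array(FALSE, dim = d)
  for (y in seq_len(d[3])) {
    for (x in seq_len(d[2])) {
      if (top_map[x, y] <= bottom_map[x, y]) {
        mask[top_map[x, y]:bottom_map[x, y], x, y] <- TRUE
      }
    }
  }
  list(top_map = top_map, bottom_map = bottom_map, mask = mask,
       top_profiles = tops, bottom_profiles = bottoms)
}

# separable (row-then-column) running-median smoothing of an integer map
median_smooth_map <- function(m, span) {
  span <- max(3L, as.integer(span))
  if (span %% 2L == 0L) span <- span + 1L
  sm <- apply(m, 2, function(v) stats::runmed(v, k = min(span, odd_below(length(v)))))
  sm <- t(apply(sm, 1, function(v) stats::runmed(v, k = min(span, odd_below(length(v))))))
  matrix(as.integer(round(sm)), nrow(m), ncol(m))
}

#' Remove the specular surface echo from a volume
#'
#' The bright window-tissue interface reflection carries no tissue texture;
#' left in place it contaminates any texture map computed on planes near the
#' surface. Each A-line's surface voxel (per the segmented top map) is
#' replaced by the voxel immediately below it.
#'
#' @param volume array `(nz, nx, ny)`.
#' @param top_map integer `nx x ny` matrix of surface depths (voxels).
#' @return the volume with surface voxels replaced.
#' @export
remove_surface_echo <- function(volume, top_map) {
  d <- dim(volume)
  stopifnot(length(d) == 3, nrow(top_map) == d[2], ncol(top_map) == d[3])
  out <- volume
  for (y in seq_len(d[3])) {
    tz <- pmin(pmax(top_map[, y], 1L), d[1])
    below <- pmin(tz + 1L, d[1])
    xs <- seq_len(d[2])
    out[cbind(tz, xs, y)] <- volume[cbind(below, xs, y)]
  }
  out
}

#' Export top/bottom profiles as CSV
#'
#' @param top,bottom `surface_profile` objects for one B-scan.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_surface_profiles <- function(top, bottom, path) {
  df <- data.frame(column = seq_along(top$depth),
                   top = top$depth, bottom = bottom$depth,
                   valid = top$valid & bottom$valid)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
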