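#' Plan line-strip coverage of a region of interest
#'
#' When the fluorescence-selected region exceeds the instantaneous field of
#' view (2.2 mm for OCT), it is covered by parallel strips with a
#' user-defined overlap that later drives cross-correlation stitching. The
#' strip count is `ceiling((roi - overlap) / (fov - overlap))`, the minimum
#' number of strips whose union (with the configured overlap) covers the ROI.
#'
#' @param roi_extent_mm lateral ROI extent to cover, in mm (> 0).
#' @param fov_mm instantaneous field of view in mm (default 2.2).
#' @param overlap_fraction overlap between adjacent strips as a fraction of
#'   the field of view, in `(0, 0.5]` (default 0.1).
#' @return object of class `strip_layout` with `n_strips`, `strip_length_mm`,
#'   `step_mm`, `overlap_mm`, `fov_mm`.
#' @export
plan_strips <- function(roi_extent_mm, fov_mm = 2.2, overlap_fraction = 0.1) {
  stopifnot(roi_extent_mm > 0, fov_mm > 0,
            overlap_fraction > 0, overlap_fraction <= 0.5)
  overlap <- overlap_fraction * fov_mm
  step <- fov_mm - overlap
  n <- max(1L, as.integer(ceiling((roi_extent_mm - overlap) / step - 1e-9)))
  layout <- structure(list(n_strips = n, strip_length_mm = roi_extent_mm,
                           step_mm = step, overlap_mm = overlap, fov_mm = fov_mm),
                      class = "strip_layout")
  stopifnot(n * fov_mm - (n - 1) * overlap >= roi_extent_mm - 1e-9)
  layout
}

#' @export
print.strip_layout <- function(x, ...) {
  cat(sprintf("Strip layout: %d strip(s) of %.2f mm FOV, %.2f mm overlap, covering %.2f mm\n",
              x$n_strips, x$fov_mm, x$overlap_mm, x$strip_length_mm))
  invisible(x)
}

#' Register two adjacent strips by normalized cross-correlation
#'
#' Strip `b` nominally continues strip `a` to the right (along columns) with
#' `nominal_overlap` shared columns. The integer offset maximizing the
#' Pearson correlation of the shared band is searched within
#' `search_radius` pixels of the nominal placement in both axes.
#'
#' @param strip_a,strip_b image matrices (equal row counts expected at the
#'   nominal offset; small deviations are handled by the search).
#' @param nominal_overlap nominal overlap in columns (pixels).
#' @param search_radius search half-width in pixels; must be smaller than
#'   the overlap.
#' @return list with `offset = c(row, col)` (deviation from nominal),
#'   `absolute = c(row, col)` (displacement of `b`'s origin relative to
#'   `a`'s, for [stitch()]), and `score` (correlation at the optimum).
#' @export
register_pair <- function(strip_a, strip_b, nominal_overlap, search_radius) {
  stopifnot(is.matrix(strip_a), is.matrix(strip_b))
  nominal_overlap <- as.integer(nominal_overlap)
  search_radius <- as.integer(search_radius)
  if (nominal_overlap < 2 || nominal_overlap > ncol(strip_a) ||
      nominal_overlap > ncol(strip_b)) {
    stop("`nominal_overlap` must give a non-empty band inside both strips")
  }
  if (search_radius < 0 || search_radius >= nominal_overlap) {
    stop("`search_radius` must be non-negative and smaller than the overlap")
  }
  nominal_col <- ncol(strip_a) - nominal_overlap   # b origin col - 1 in a frame
  best <- list(score = -Inf, offset = c(0L, 0L))
  any_defined <- FALSE
  for (u in (-search_radius):search_radius) {
    for (v in (-search_radius):search_radius) {
      or_ <- u                 # row of b's first row, relative to a's first (0-based)
      oc <- nominal_col + v    # col of b's first col - 1 in a's frame
      r1 <- max(1L, 1L + or_); r2 <- min(nrow(strip_a), or_ + nrow(strip_b))
      c1 <- max(1L, 1L + oc);  c2 <- min(ncol(strip_a), oc + ncol(strip_b))
      if (r2 < r1 || c2 < c1) next
      a_sub <- strip_a[r1:r2, c1:c2]
      b_sub <- strip_b[(r1 - or_):(r2 - or_), (c1 - oc):(c2 - oc)]
      sa <- stats::sd(a_sub); sb <- stats::sd(b_sub)
      if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) next
      any_defined <- TRUE
      score <- stats::cor(as.vector(a_sub), as.vector(b_sub))
      better <- score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
           abs(u) + abs(v) < sum(abs(best$offset)))
      if (better) best <- list(score = score, offset = c(row = u, col = v))
    }
  }
  if (!any_defined) stop("constant overlap band: normalized correlation undefined")
  list(offset = best$offset,
       absolute = c(row = unname(best$offset[1]),
                    col = nominal_col + unname(best$offset[2])),
       score = best$score)
}

#' Stitch an ordered list of strips into a mosaic
#'
#' Strips are placed at cumulative displacements and blended by linear
#' feathering across the shared bands: each strip's weight ramps from 0 to 1
#' over the width of the overlap on sides that have a neighbour, and the
#' weighted sum is normalized, so constant content is preserved exactly and
#' regions covered by a single strip are copied losslessly.
#'
#' @param strips list of image matrices, left to right.
#' @param offsets list of `c(row, col)` displacements of each strip's origin
#'   relative to its left neighbour (the `absolute` element of
#'   [register_pair()]); length `length(strips) - 1`.
#' @return the mosaic matrix (bounding box of all placements).
#' @export
stitch <- function(strips, offsets) {
  stopifnot(length(strips) >= 1, length(offsets) == length(strips) - 1)
  n <- length(strips)
  if (n == 1) return(strips[[1]])
  orig <- matrix(0L, n, 2)          # 0-based origin of each strip
  for (i in 2:n) {
    off <- as.integer(round(offsets[[i - 1]]))
    stopifnot(length(off) == 2)
    orig[i, ] <- orig[i - 1, ] + off
  }
  # realized overlap (columns) with each neighbour; must be positive
  ov <- integer(n - 1)
  for (i in seq_len(n - 1)) {
    ov[i] <- ncol(strips[[i]]) - (orig[i + 1, 2] - orig[i, 2])
    if (ov[i] < 1) stop(sprintf("strips %d and %d are disjoint after placement", i, i + 1))
  }
  r1 <- min(orig[, 1]) + 1L
  c1 <- min(orig[, 2]) + 1L
  r2 <- max(orig[, 1] + vapply(strips, nrow, integer(1)))
  c2 <- max(orig[, 2] + vapply(strips, ncol, integer(1)))
  num <- matrix(0, r2 - r1 + 1L, c2 - c1 + 1L)
  den <- matrix(0, r2 - r1 + 1L, c2 - c1 + 1L)
  for (i in seq_len(n)) {
    s <- strips[[i]]
    ramp_l <- if (i > 1) ov[i - 1] else 0L
    ramp_r <- if (i < n) ov[i] else 0L
    wc <- rep(1, ncol(s))
    if (ramp_l > 0) wc <- pmin(wc, seq_len(ncol(s)) / (ramp_l + 1))
    if (ramp_r > 0) wc <- pmin(wc, rev(seq_len(ncol(s))) / (ramp_r + 1))
    w <- matrix(wc, nrow(s), ncol(s), byrow = TRUE)
    rr <- (orig[i, 1] + 1L):(orig[i, 1] + nrow(s)) - r1 + 1L
    cc <- (orig[i, 2] + 1L):(orig[i, 2] + ncol(s)) - c1 + 1L
    num[rr, cc] <- num[rr, cc] + s * w
    den[rr, cc] <- den[rr, cc] + w
  }
  out <- num / den
  out[den == 0] <- 0
  out
}

#' Cut an image into overlapping strips (for simulation and round-trips)
#'
#' Splits an image into `n_strips` column bands of width `fov_px` spaced by
#' `fov_px - overlap_px`, optionally with a seeded integer placement jitter
#' on every strip after the first (emulating stage positioning error).
#'
#' @param image source matrix.
#' @param fov_px strip width in pixels.
#' @param overlap_px nominal overlap in pixels.
#' @param jitter_px maximum absolute integer jitter applied to each cut
#'   position (rows and columns); 0 disables. Row jitter requires
#'   `strip_rows < nrow(image)`.
#' @param seed RNG seed for the jitter.
#' @param strip_rows strip height in pixels (default: full image height).
#' @return list with `strips`, `true_offsets` (list of `c(row, col)`
#'   displacements between consecutive origins) and `layout` geometry.
#' @export
cut_strips <- function(image, fov_px, overlap_px, jitter_px = 0, seed = 1,
                       strip_rows = nrow(image)) {
  stopifnot(is.matrix(image), fov_px > overlap_px, overlap_px >= 1,
            strip_rows >= 1, strip_rows <= nrow(image))
  step <- fov_px - overlap_px
  n <- max(1L, as.integer(ceiling((ncol(image) - overlap_px) / step)))
  r_slack <- nrow(image) - strip_rows
  with_seed(seed, {
    strips <- vector("list", n)
    true <- vector("list", max(0L, n - 1L))
    prev_c <- 0L; prev_r <- 0L
    for (i in seq_len(n)) {
      jc <- if (i > 1 && jitter_px > 0) sample(-jitter_px:jitter_px, 1) else 0L
      jr <- if (i > 1 && jitter_px > 0) sample(-jitter_px:jitter_px, 1) else 0L
      c0 <- max(0L, min(ncol(image) - fov_px, (i - 1L) * step + jc))
      r0 <- max(0L, min(r_slack, (r_slack %/% 2L) + jr))
      strips[[i]] <- image[(r0 + 1L):(r0 + strip_rows),
                           (c0 + 1L):(c0 + fov_px), drop = FALSE]
      if (i > 1) true[[i - 1L]] <- c(row = r0 - prev_r, col = c0 - prev_c)
      prev_c <- c0; prev_r <- r0
    }
    list(strips = strips, true_offsets = true,
         layout = list(n_strips = n, fov_px = fov_px, overlap_px = overlap_px,
                       step_px = step))
  })
}
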