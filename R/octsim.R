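#' Gaussian source spectrum for spectral-domain OCT
#'
#' The imaging source is modelled as a Gaussian spectral envelope described by
#' its center wavelength and full-width-at-half-maximum bandwidth, truncated
#' at three standard deviations on either side. The system this emulates uses
#' a superluminescent diode at 1310 nm with roughly 100 nm of bandwidth.
#'
#' @param center_wavelength center wavelength in nm (> 0).
#' @param fwhm_bandwidth FWHM bandwidth in nm (> 0).
#' @param n_samples number of spectral samples (default 2048).
#' @return object of class `source_spectrum` with the wavelength grid (nm,
#'   strictly increasing) and envelope parameters.
#' @export
source_spectrum <- function(center_wavelength = 1310, fwhm_bandwidth = 100,
                            n_samples = 2048) {
  stopifnot(center_wavelength > 0, fwhm_bandwidth > 0, n_samples >= 16)
  sigma <- fwhm_bandwidth / (2 * sqrt(2 * log(2)))
  grid <- seq(center_wavelength - 3 * sigma, center_wavelength + 3 * sigma,
              length.out = n_samples)
  structure(list(center_wavelength = center_wavelength,
                 fwhm_bandwidth = fwhm_bandwidth,
                 sigma = sigma,
                 n_samples = as.integer(n_samples),
                 wavelength_nm = grid),
            class = "source_spectrum")
}

#' @export
print.source_spectrum <- function(x, ...) {
  cat(sprintf("Source spectrum: %g nm center, %g nm FWHM, %d samples [%0.1f, %0.1f] nm\n",
              x$center_wavelength, x$fwhm_bandwidth, x$n_samples,
              min(x$wavelength_nm), max(x$wavelength_nm)))
  cat(sprintf("Theoretical axial resolution (air): %.2f um\n", axial_resolution(x)))
  invisible(x)
}

spectral_envelope <- function(spectrum, wavelength_nm = spectrum$wavelength_nm) {
  exp(-(wavelength_nm - spectrum$center_wavelength)^2 / (2 * spectrum$sigma^2))
}

#' Theoretical axial resolution of a Gaussian source
#'
#' Round-trip coherence length in air,
#' `(2 ln 2 / pi) * lambda0^2 / delta_lambda`, returned in micrometres. For a
#' 1310 nm / 100 nm source this evaluates to about 7.6 um ("about 8 um").
#'
#' @param spectrum a [source_spectrum()] object.
#' @return axial resolution in um (in air).
#' @export
axial_resolution <- function(spectrum) {
  stopifnot(inherits(spectrum, "source_spectrum"))
  (2 * log(2) / pi) * spectrum$center_wavelength^2 /
    spectrum$fwhm_bandwidth / 1000
}

#' Simulate spectral-domain interference fringes
#'
#' For each reflector at depth `z` (um) with intensity reflectivity `R`, the
#' detected spectrum carries a fringe term `2 sqrt(R) cos(2 k z + phi(k))`
#' under the source envelope, where `k = 2 pi / lambda` is the wavenumber in
#' rad/um and `phi(k) = dispersion_coeff (k - k0)^2` models unbalanced
#' second-order dispersion. The spectrum is sampled on the source wavelength
#' grid, optionally warped quadratically (`k_nonlinearity`) to emulate a
#' non-linear spectrometer axis.
#'
#' @param reflectors data.frame (or list coercible to one) with columns
#'   `depth_um` (>= 0) and `reflectivity` (in `[0, 1]`).
#' @param spectrum a [source_spectrum()] object.
#' @param dispersion_coeff second-order dispersion coefficient in
#'   rad/(rad/um)^2; 0 disables.
#' @param k_nonlinearity unitless quadratic warp of the sampling grid; 0
#'   keeps the grid uniform in wavelength.
#' @return object of class `interferogram`: `fringes`, `wavelength_nm`
#'   (actual sampling grid), `spectrum`, `dispersion_coeff`.
#' @export
simulate_interferogram <- function(reflectors, spectrum, dispersion_coeff = 0,
                                   k_nonlinearity = 0) {
  stopifnot(inherits(spectrum, "source_spectrum"))
  reflectors <- as.data.frame(reflectors)
  if (nrow(reflectors) == 0) stop("reflector list must not be empty")
  stopifnot(all(c("depth_um", "reflectivity") %in% names(reflectors)),
            all(reflectors$depth_um >= 0),
            all(reflectors$reflectivity >= 0),
            all(reflectors$reflectivity <= 1))
  lam <- spectrum$wavelength_nm
  if (k_nonlinearity != 0) {
    span <- diff(range(lam))
    lam <- lam + k_nonlinearity * (lam - spectrum$center_wavelength)^2 / span
    if (any(diff(lam) <= 0)) stop("`k_nonlinearity` too large: grid not increasing")
  }
  k <- 2000 * pi / lam                               # rad/um
  k0 <- 2000 * pi / spectrum$center_wavelength
  env <- spectral_envelope(spectrum, lam)
  fringe <- rep(0, length(lam))
  phi <- dispersion_coeff * (k - k0)^2
  for (i in seq_len(nrow(reflectors))) {
    r <- reflectors$reflectivity[i]
    if (r == 0) next
    fringe <- fringe + 2 * sqrt(r) *
      cos(2 * k * reflectors$depth_um[i] + phi)
  }
  structure(list(fringes = env * (1 + fringe),
                 wavelength_nm = lam,
                 spectrum = spectrum,
                 dispersion_coeff = dispersion_coeff),
            class = "interferogram")
}

# Analytic signal of a real vector via the FFT half-spectrum method.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Reconstruct an A-line from spectral fringes
#'
#' Standard spectral-domain processing: subtract the source envelope (DC),
#' resample the fringes onto a uniform wavenumber grid, form the analytic
#' signal, optionally multiply by the conjugate dispersion phase, and Fourier
#' transform. The depth axis is calibrated as `z_m = pi m / (N dk)` in air.
#'
#' @param interf an `interferogram` from [simulate_interferogram()].
#' @param compensate_dispersion multiply by `exp(-i phi(k))` using the
#'   interferogram's dispersion coefficient before the transform.
#' @param pad_factor zero-padding factor for a finer depth sampling of the
#'   peak (default 8).
#' @return object of class `aline`: `depth_um` (uniform) and `magnitude`
#'   (one-sided, >= 0).
#' @export
reconstruct_aline <- function(interf, compensate_dispersion = FALSE,
                              pad_factor = 8) {
  stopifnot(inherits(interf, "interferogram"))
  lam <- interf$wavelength_nm
  if (length(lam) != length(interf$fringes)) {
    stop("fringes and wavelength grid lengths differ")
  }
  env <- spectral_envelope(interf$spectrum, lam)
  x <- interf$fringes - env                     # remove envelope / DC
  k <- 2000 * pi / lam                          # decreasing in lambda
  ord <- order(k)
  k <- k[ord]; x <- x[ord]
  n <- length(k)
  ku <- seq(min(k), max(k), length.out = n)
  xu <- stats::spline(k, x, xout = ku)$y
  a <- analytic_signal(xu)
  if (compensate_dispersion && interf$dispersion_coeff != 0) {
    k0 <- 2000 * pi / interf$spectrum$center_wavelength
    a <- a * exp(-1i * interf$dispersion_coeff * (ku - k0)^2)
  }
  np <- n * pad_factor
  a <- c(a, rep(0 + 0i, np - n))
  dk <- ku[2] - ku[1]
  mag <- Mod(stats::fft(a))
  depth <- pi * (0:(np - 1)) / (np * dk)
  keep <- seq_len(np %/% 2)                     # one-sided
  structure(list(depth_um = depth[keep], magnitude = mag[keep]),
            class = "aline")
}

#' @export
print.aline <- function(x, ...) {
  pk <- which.max(x$magnitude)
  cat(sprintf("A-line: %d samples, dz = %.3f um, peak at %.1f um\n",
              length(x$depth_um), x$depth_um[2] - x$depth_um[1],
              x$depth_um[pk]))
  invisible(x)
}

#' Full width at half maximum of an A-line peak
#'
#' Width of the global peak at half its magnitude, with linear interpolation
#' between samples on both flanks.
#'
#' @param aline an `aline` object (or list with `depth_um`, `magnitude`).
#' @return FWHM in um.
#' @export
psf_fwhm <- function(aline) {
  z <- aline$depth_um
  m <- aline$magnitude
  stopifnot(length(z) == length(m), length(m) >= 3)
  if (max(m) - min(m) <= 0) stop("flat A-line: no peak")
  p <- which.max(m)
  half <- m[p] / 2
  # left crossing
  i <- p
  while (i > 1 && m[i - 1] >= half) i <- i - 1
  zl <- if (i == 1) z[1] else {
    f <- (half - m[i - 1]) / (m[i] - m[i - 1])
    z[i - 1] + f * (z[i] - z[i - 1])
  }
  # right crossing
  j <- p
  while (j < length(m) && m[j + 1] >= half) j <- j + 1
  zr <- if (j == length(m)) z[j] else {
    f <- (m[j] - half) / (m[j] - m[j + 1])
    z[j] + f * (z[j + 1] - z[j])
  }
  zr - zl
}
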