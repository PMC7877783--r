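#' Enzyme-to-substrate ratio from a uPA concentration
#'
#' The activatable contrast agent is cleaved by urokinase plasminogen
#' activator (uPA), which is overexpressed roughly eightfold in malignant
#' breast tissue (about 8 ng/mg protein versus 1 ng/mg in benign tissue).
#' Given a benign anchor condition (uPA level mapped to a substrate-per-enzyme
#' ratio), the ratio for any other uPA level follows by exact inverse
#' proportionality: doubling the enzyme concentration halves the number of
#' substrate molecules available per enzyme.
#'
#' @param upa_level uPA concentration in ng per mg protein; must be positive.
#' @param anchor named numeric vector `c(level = , ratio = )` giving the
#'   reference condition. The default maps the benign level of 1 ng/mg to an
#'   E:S ratio of 1:200 (i.e. 200 substrate molecules per enzyme).
#' @return Substrate molecules per enzyme (the `N` of a `1:N` E:S ratio).
#' @examples
#' es_ratio(8)   # tumor level -> 25, i.e. 1:25
#' es_ratio(4)   # intermediate -> 1:50
#' @export
es_ratio <- function(upa_level, anchor = c(level = 1, ratio = 200)) {
  if (!is.numeric(upa_level) || any(!is.finite(upa_level)) || any(upa_level <= 0)) {
    stop("`upa_level` must be a positive finite number (ng/mg protein)")
  }
  stopifnot(all(c("level", "ratio") %in% names(anchor)),
            anchor[["level"]] > 0, anchor[["ratio"]] > 0)
  unname(anchor[["ratio"]] * anchor[["level"]] / upa_level)
}

#' Calibrate the pseudo-first-order cleavage rate
#'
#' Solves for the rate constant `k` such that the baseline-subtracted
#' fluorescence contrast between two E:S conditions at time `t` equals
#' `target`. With cleaved fraction `c(t) = 1 - exp(-k t / es)` the contrast is
#' `(1 - exp(-k t / es1)) / (1 - exp(-k t / es2))`, which decreases
#' monotonically from `es2/es1` (at t -> 0) towards 1, so a unique root exists
#' for any target strictly between those limits.
#'
#' @param target desired baseline-subtracted contrast (default 4.5, the best
#'   tumor-vs-benign contrast observed at one minute of incubation).
#' @param t incubation time in minutes at which the contrast is evaluated.
#' @param es_pair the two substrate-per-enzyme ratios being contrasted
#'   (default tumor 25 vs benign 200).
#' @return rate constant in 1/(relative enzyme concentration x minute).
#' @export
calibrate_cleavage_rate <- function(target = 4.5, t = 1, es_pair = c(25, 200)) {
  stopifnot(length(es_pair) == 2, all(es_pair > 0), t > 0)
  lim <- max(es_pair) / min(es_pair)
  if (target <= 1 || target >= lim) {
    stop(sprintf("target contrast must lie in (1, %g) for this E:S pair", lim))
  }
  f <- function(k) {
    (1 - exp(-k * t / min(es_pair))) - target * (1 - exp(-k * t / max(es_pair)))
  }
  stats::uniroot(f, c(1e-9, 1e6), tol = 1e-12)$root
}

# Default rate frozen from calibrate_cleavage_rate(4.5, 1, c(25, 200)).
.default_cleavage_rate <- 38.2632710380

#' Kinetic parameters of the quenched activatable probe
#'
#' The intact probe carries two internally quenched near-infrared
#' fluorophores; enzymatic cleavage releases the quenching, so full cleavage
#' multiplies fluorescence by `1/(1 - q)` (tenfold for the measured 90%
#' quenching efficiency). Cleavage is modelled as pseudo-first-order in the
#' relative enzyme concentration `1/es`.
#'
#' @param quench_efficiency fraction of emission suppressed in the intact
#'   probe, in `[0, 1)`. Default 0.9.
#' @param substrate_um substrate concentration in micromolar (scale only;
#'   traces are normalized to the intact baseline). Default 1.
#' @param es substrate molecules per enzyme (the `N` of `1:N`). Default 200
#'   (benign tissue).
#' @param rate pseudo-first-order rate constant per (relative enzyme x
#'   minute). The default is calibrated so the baseline-subtracted 1:25 vs
#'   1:200 contrast at one minute equals 4.5.
#' @param t_max incubation limit in minutes for trace evaluation. Default 10.
#' @return object of class `kinetics_params`.
#' @export
kinetics_params <- function(quench_efficiency = 0.9, substrate_um = 1,
                            es = 200, rate = .default_cleavage_rate,
                            t_max = 10) {
  stopifnot(quench_efficiency >= 0, quench_efficiency < 1,
            substrate_um > 0, es > 0, rate >= 0, t_max > 0)
  structure(list(quench_efficiency = quench_efficiency,
                 substrate_um = substrate_um, es = es,
                 rate = rate, t_max = t_max),
            class = "kinetics_params")
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat(sprintf(
    "Probe kinetics: q = %.2f (fold increase %.3g), E:S = 1:%g, k = %.4g /(E_rel*min), t_max = %g min\n",
    x$quench_efficiency, 1 / (1 - x$quench_efficiency), x$es, x$rate, x$t_max))
  invisible(x)
}

#' Fluorescence activation trace
#'
#' Cleaved fraction `c(t) = 1 - exp(-k t / es)`; fluorescence relative to the
#' intact (quenched) baseline is
#' `F(t) = ((1 - c(t)) (1 - q) + c(t)) / (1 - q)`,
#' so `F(0) = 1` and `F` saturates at the fold increase `1/(1 - q)`.
#'
#' @param params a [kinetics_params()] object.
#' @param times non-negative, strictly increasing vector of minutes.
#' @return object of class `fluorescence_trace` with fields `time_min`,
#'   `fluorescence` and `params`.
#' @export
fluorescence_trace <- function(params, times = seq(0, params$t_max, length.out = 121)) {
  stopifnot(inherits(params, "kinetics_params"))
  if (any(times < 0) || any(diff(times) <= 0)) {
    stop("`times` must be non-negative and strictly increasing")
  }
  f <- .trace_at(params, times)
  structure(list(time_min = times, fluorescence = f, params = params),
            class = "fluorescence_trace")
}

.trace_at <- function(params, t) {
  q <- params$quench_efficiency
  cleaved <- 1 - exp(-params$rate * t / params$es)
  ((1 - cleaved) * (1 - q) + cleaved) / (1 - q)
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace: E:S = 1:%g, %d samples over [%g, %g] min, F range [%.3g, %.3g]\n",
              x$params$es, length(x$time_min), min(x$time_min), max(x$time_min),
              min(x$fluorescence), max(x$fluorescence)))
  invisible(x)
}

#' Fluorescence contrast between two probe conditions
#'
#' Ratio of the activation traces of two parameter sets at time `t`,
#' optionally after subtracting the common quenched baseline (value 1).
#' Baseline subtraction isolates the cleavage-driven signal; for small `k t`
#' the subtracted ratio tends to the enzyme concentration ratio itself.
#'
#' @param params_a,params_b [kinetics_params()] sharing quenching efficiency
#'   and substrate concentration.
#' @param t time in minutes, within `[0, t_max]`.
#' @param background_subtracted subtract the baseline before taking the ratio.
#' @return unitless contrast (may be `NaN` at `t = 0` when subtracted).
#' @export
contrast_ratio <- function(params_a, params_b, t, background_subtracted = FALSE) {
  stopifnot(inherits(params_a, "kinetics_params"),
            inherits(params_b, "kinetics_params"))
  if (params_a$quench_efficiency != params_b$quench_efficiency ||
      params_a$substrate_um != params_b$substrate_um) {
    stop("conditions must share quenching efficiency and substrate concentration")
  }
  if (any(t < 0) || any(t > min(params_a$t_max, params_b$t_max))) {
    stop("`t` outside the simulated incubation range")
  }
  fa <- .trace_at(params_a, t)
  fb <- .trace_at(params_b, t)
  if (background_subtracted) (fa - 1) / (fb - 1) else fa / fb
}

#' Detect bright fluorescence regions of interest
#'
#' Automated surrogate for the operator's selection of the imaging region on
#' the fluorescence channel: thresholds the image, labels connected
#' components (8-connectivity), drops components smaller than `min_area`, and
#' returns their bounding rectangles ordered by integrated signal.
#'
#' @param fl 2-D fluorescence image (matrix).
#' @param threshold fraction of the image maximum in `(0, 1)` when
#'   `absolute = FALSE` (default 0.5), otherwise an absolute intensity.
#' @param absolute interpret `threshold` as an absolute intensity.
#' @param min_area minimum component area in pixels.
#' @return data.frame with one row per ROI: `row1, row2, col1, col2`
#'   (inclusive bounds), `area_px`, `signal` (integrated intensity), sorted by
#'   decreasing `signal`. Zero rows when nothing exceeds the threshold.
#' @export
fl_threshold_rois <- function(fl, threshold = 0.5, absolute = FALSE, min_area = 9) {
  if (!is.matrix(fl) || length(fl) == 0) stop("`fl` must be a non-empty matrix")
  thr <- if (absolute) threshold else {
    stopifnot(threshold > 0, threshold < 1)
    threshold * max(fl)
  }
  mask <- fl > thr
  empty <- data.frame(row1 = integer(), row2 = integer(),
                      col1 = integer(), col2 = integer(),
                      area_px = integer(), signal = numeric())
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask)
  ids <- setdiff(sort(unique(as.vector(lab))), 0)
  rois <- lapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    if (nrow(idx) < min_area) return(NULL)
    data.frame(row1 = min(idx[, 1]), row2 = max(idx[, 1]),
               col1 = min(idx[, 2]), col2 = max(idx[, 2]),
               area_px = nrow(idx),
               signal = sum(fl[idx]))
  })
  rois <- do.call(rbind, rois[!vapply(rois, is.null, logical(1))])
  if (is.null(rois)) return(empty)
  rois[order(-rois$signal), , drop = FALSE]
}

#' Write activation traces to CSV
#'
#' One column of time in minutes followed by one fluorescence column per
#' E:S condition.
#'
#' @param traces list of [fluorescence_trace()] objects sharing a time grid.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  stopifnot(length(traces) >= 1)
  tg <- traces[[1]]$time_min
  for (tr in traces) stopifnot(identical(tr$time_min, tg))
  df <- data.frame(time_min = tg)
  for (tr in traces) {
    df[[sprintf("es_1_%g", tr$params$es)]] <- tr$fluorescence
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
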