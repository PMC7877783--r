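# Independent brute-force oracles, written against the documented
# conventions (symmetric edge-inclusive reflection, population SD) and kept
# free of the package's convolution code path.

# symmetric reflection of an out-of-range index onto 1..n
oracle_reflect <- function(i, n) {
  period <- 2 * n
  j <- (i - 1) %% period
  ifelse(j < n, j, period - 1 - j) + 1
}

# sliding-window population SD by explicit double loop
oracle_sd_filter <- function(img, w) {
  h <- (w - 1) / 2
  out <- matrix(0, nrow(img), ncol(img))
  for (a in seq_len(nrow(img))) {
    for (b in seq_len(ncol(img))) {
      vals <- img[oracle_reflect((a - h):(a + h), nrow(img)),
                  oracle_reflect((b - h):(b + h), ncol(img))]
      out[a, b] <- sqrt(mean((vals - mean(vals))^2))
    }
  }
  out
}

# full 2-D convolution by explicit loops with reflected borders
oracle_conv <- function(img, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  hr <- (kr - 1) / 2; hc <- (kc - 1) / 2
  out <- matrix(0, nrow(img), ncol(img))
  for (a in seq_len(nrow(img))) {
    for (b in seq_len(ncol(img))) {
      acc <- 0
      for (i in seq_len(kr)) {
        for (j in seq_len(kc)) {
          acc <- acc + kernel[i, j] *
            img[oracle_reflect(a + i - 1 - hr, nrow(img)),
                oracle_reflect(b + j - 1 - hc, ncol(img))]
        }
      }
      out[a, b] <- acc
    }
  }
  out
}

# exhaustive 1-D threshold search (midpoints of consecutive sorted values)
oracle_threshold <- function(values, positive) {
  u <- sort(unique(values))
  cand <- (u[-1] + u[-length(u)]) / 2
  errs <- sapply(cand, function(th) sum((values > th) != positive))
  cand[which.min(errs)]
}

# Shannon entropy (bits) of an equal-width histogram
oracle_entropy <- function(x, bins = 16) {
  r <- range(x)
  if (r[2] <= r[1]) return(0)
  idx <- pmin(bins, 1 + floor((x - r[1]) / (r[2] - r[1]) * bins))
  p <- as.vector(table(factor(idx, levels = 1:bins))) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# reference classifier trained once per test run (default study conditions)
shared_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- train_reference_classifier(margin_config())
    m
  }
})

# small default-parameter phantom processed up to normalized feature planes
process_phantom <- function(pattern, seed, grid = c(64, 64, 220)) {
  ph <- specimen_phantom(phantom_spec(grid_shape = grid, layout_pattern = pattern,
                                      seed = seed), with_rcm = FALSE)
  sf <- volume_surfaces(ph$oct)
  dg <- depth_compensate(remove_surface_echo(ph$oct, sf$top_map), sf$mask,
                         ph$spec$axial_voxel)
  list(ph = ph, sf = sf, dg = dg)
}

# feature stack of a normalized en-face plane (same convention as training)
plane_features <- function(pp, z, params = texture_params()) {
  mk <- pp$ph$labels[z, , ] != 0L
  sl <- pp$dg$compensated[z, , ]
  if (any(mk) && mean(sl[mk]) > 0) {
    sl <- sl / mean(sl[mk]); sl[!mk] <- 1
  }
  feature_stack(sl, params)
}
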