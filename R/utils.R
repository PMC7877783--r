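# Internal helpers: seeded RNG scoping and reflect-padded separable convolution.
# All image filters in the package use symmetric (edge-inclusive) reflection at
# the borders; the brute-force oracles in the test suite use the same mapping.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Map arbitrary integer indices onto 1..n by symmetric reflection:
# ... 2, 1 | 1, 2, ..., n | n, n-1, ...
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- (as.integer(i) - 1L) %% period
  ifelse(j < n, j, period - 1L - j) + 1L
}

# Pad only the rows of a matrix by symmetric reflection.
pad_rows <- function(m, p) {
  if (p == 0L) return(m)
  m[reflect_index((1L - p):(nrow(m) + p), nrow(m)), , drop = FALSE]
}

# Pad a matrix by `p` pixels on every side using symmetric reflection.
pad_reflect <- function(m, p) {
  if (p == 0L) return(m)
  ri <- reflect_index((1L - p):(nrow(m) + p), nrow(m))
  ci <- reflect_index((1L - p):(ncol(m) + p), ncol(m))
  m[ri, ci, drop = FALSE]
}

# 1-D convolution along rows of a matrix already padded by (k-1)/2 rows.
conv_rows_padded <- function(padded, kernel, n_out) {
  out <- matrix(0, n_out, ncol(padded))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * padded[j:(j + n_out - 1L), , drop = FALSE]
  }
  out
}

# Separable 2-D convolution with a symmetric odd-length kernel, reflective borders.
conv_sep2 <- function(m, kernel) {
  k <- length(kernel)
  stopifnot(k %% 2L == 1L)
  p <- (k - 1L) %/% 2L
  padded <- pad_reflect(m, p)                                   # (n+2p) x (m+2p)
  rowpass <- conv_rows_padded(padded, kernel, nrow(m))          # n x (m+2p)
  t(conv_rows_padded(t(rowpass), kernel, ncol(m)))              # n x m
}

# Full (non-separable) 2-D correlation with a small odd-sized kernel,
# reflective borders. kernel[i, j] weights the neighbour at row offset
# i - (nrow+1)/2 and column offset j - (ncol+1)/2.
conv_2d <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2L == 1L, kc %% 2L == 1L)
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  p <- max(pr, pc)
  padded <- pad_reflect(m, p)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      if (kernel[i, j] == 0) next
      ro <- p - pr + i - 1L
      co <- p - pc + j - 1L
      out <- out + kernel[i, j] *
        padded[(1L + ro):(nrow(m) + ro), (1L + co):(ncol(m) + co), drop = FALSE]
    }
  }
  out
}

# Normalized discrete Gaussian kernel truncated at ceiling(3 sigma).
gaussian_kernel <- function(sigma) {
  stopifnot(is.finite(sigma), sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Sliding-window box mean with reflective borders (odd window).
box_mean <- function(m, w) {
  conv_sep2(m, rep(1 / w, w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
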