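# Internal numerical helpers shared across the pipeline.

# Cumulative trapezoidal integral of x sampled at constant dt, anchored at 0.
cumtrapz <- function(x, dt) {
  n <- length(x)
  c(0, cumsum((x[-1] + x[-n]) / 2)) * dt
}

# Remove the least-squares line from x (constant sampling assumed).
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2) return(x - mean(x))
  i <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, i), x)
  x - fit$fitted.values
}

# Remove the line through the first and last sample (phase-neutral for
# series that return to a like phase at both ends).
detrend_endpoint <- function(x) {
  n <- length(x)
  if (n < 2) return(x - mean(x))
  x - seq(x[1], x[n], length.out = n)
}

# Derivative-of-Gaussian kernel; sigma in samples, support +/- 4 sigma.
dgauss_kernel <- function(sigma) {
  half <- ceiling(4 * sigma)
  i <- seq(-half, half)
  -(i / sigma^2) * exp(-i^2 / (2 * sigma^2)) / sqrt(2 * pi * sigma^2)
}

#' Gaussian-derivative wavelet differentiation
#'
#' Convolves a series with a first-derivative-of-Gaussian kernel, producing a
#' smoothed derivative. The sign is oriented so that, applied to the
#' time-integral of gravity-aligned vertical acceleration, local minima of the
#' output mark initial contacts (and a second application yields maxima at
#' final contacts). Values within the kernel half-width of either end are
#' zeroed (edge region; callers discard events there).
#'
#' @param x Numeric series.
#' @param scale Wavelet scale in samples; the Gaussian standard deviation is
#'   `scale / 4`.
#' @return Numeric series of the same length.
#' @export
wavelet_differentiate <- function(x, scale) {
  if (!is.numeric(x) || length(x) < 8) {
    abort("`x` must be a numeric series of at least 8 samples.")
  }
  if (scale <= 0) abort("`scale` must be positive.")
  k <- dgauss_kernel(scale / 4)
  if (length(k) >= length(x)) {
    abort("wavelet scale too large for series length")
  }
  y <- stats::filter(x, rev(k), sides = 2)
  y[is.na(y)] <- 0
  -as.numeric(y)
}

# Local maxima (or minima) with a topographic-prominence floor and a minimum
# separation, keeping larger peaks first. Returns sorted indices.
find_extrema <- function(x, minima = FALSE, min_sep = 1, prominence_frac = 0.2) {
  if (minima) x <- -x
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    lh <- which(x[seq_len(i - 1)] > x[i])
    l <- if (length(lh)) max(lh) else 1L
    rh <- which(x[seq(i + 1, n)] > x[i])
    r <- if (length(rh)) i + min(rh) else n
    x[i] - max(min(x[l:i]), min(x[i:r]))
  }, numeric(1))
  scale <- stats::mad(x)
  if (scale > 0) cand <- cand[prom >= prominence_frac * scale]
  if (!length(cand)) return(integer(0))
  ord <- order(x[cand], decreasing = TRUE)
  taken <- integer(0)
  keep <- logical(length(cand))
  for (j in ord) {
    if (all(abs(cand[j] - taken) >= min_sep)) {
      keep[j] <- TRUE
      taken <- c(taken, cand[j])
    }
  }
  sort(cand[keep])
}

# Run code with a local RNG seed, restoring the caller's RNG state after.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic hash of a configuration list (for artifact provenance).
config_hash <- function(x) rlang::hash(x)

stopifnot_finite <- function(x, name) {
  if (any(!is.finite(x[!is.na(x)]))) {
    abort(sprintf("`%s` contains non-finite values.", name))
  }
  invisible(x)
}
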