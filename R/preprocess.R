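#' Low-pass filter specification
#'
#' Order and normalized critical frequency of a Butterworth low-pass filter.
#' `wn` is a fraction of the Nyquist frequency (wn = 2 * cutoff / sampling
#' rate), so it must lie strictly inside (0, 1). The pipeline defaults are
#' (N = 2, wn = 0.002) for the smoothing pass and (N = 2, wn = 0.03) for the
#' second pass over the difference signal.
#'
#' @param N filter order, a positive integer.
#' @param wn normalized critical frequency in (0, 1).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(N, wn) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("filter order N must be a positive integer")
  if (!is.numeric(wn) || length(wn) != 1L || wn <= 0 || wn >= 1)
    stop("normalized frequency wn must lie in the open interval (0, 1)")
  structure(list(N = as.integer(N), wn = as.numeric(wn)),
            class = "filter_spec")
}

#' Design Butterworth low-pass coefficients
#'
#' Wraps [signal::butter()] and validates the result: `b` and `a` each have
#' `N + 1` coefficients, `a[1]` is normalized to 1, and the DC gain
#' `sum(b)/sum(a)` equals 1 to within 1e-9.
#'
#' @param spec a [filter_spec()].
#' @return object of class `filter_coefficients` with fields `b` and `a`.
#' @export
design_lowpass <- function(spec) {
  stopifnot(inherits(spec, "filter_spec"))
  ba <- signal::butter(spec$N, spec$wn, type = "low")
  b <- as.numeric(ba$b) / ba$a[1L]
  a <- as.numeric(ba$a) / ba$a[1L]
  if (length(b) != spec$N + 1L || length(a) != spec$N + 1L)
    stop("unexpected coefficient count from filter design")
  if (abs(sum(b) / sum(a) - 1) >= 1e-9)
    stop("designed filter DC gain deviates from 1 by more than 1e-9")
  structure(list(b = b, a = a), class = "filter_coefficients")
}

# Steady-state initial filter state for a unit step (matches the standard
# lfilter_zi construction: solve (I - A^T) zi = B with A the companion
# matrix of a and B = b[-1] - a[-1]*b[1]).
lfilter_zi <- function(b, a) {
  n <- length(a)
  m <- n - 1L
  A <- matrix(0, m, m)
  A[1L, ] <- -a[2:n]
  if (m > 1L) A[2:m, 1:(m - 1L)] <- diag(m - 1L)
  B <- b[2:n] - a[2:n] * b[1L]
  solve(diag(m) - t(A), B)
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the recursive filter once forward and once backward so the output
#' has no phase lag. Ends are stabilized by odd-reflection padding of length
#' `3 * (N + 1)` on each side together with steady-state initial conditions,
#' so a constant input is returned unchanged and even-symmetric inputs stay
#' even-symmetric.
#'
#' @param x numeric signal; must be longer than `3 * (N + 1)`.
#' @param coeffs a `filter_coefficients` object from [design_lowpass()].
#' @return filtered signal, same length as `x`.
#' @export
zero_phase_filter <- function(x, coeffs) {
  stopifnot(inherits(coeffs, "filter_coefficients"))
  b <- coeffs$b
  a <- coeffs$a
  pad <- 3L * length(b)
  n <- length(x)
  if (n <= pad)
    stop("signal of length ", n,
         " is too short for zero-phase filtering (needs > ", pad, " points)")
  ext <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  zi <- lfilter_zi(b, a)
  y <- cpp_lfilter(b, a, ext, zi * ext[1L])
  y <- rev(y)
  y <- cpp_lfilter(b, a, y, zi * y[1L])
  rev(y)[(pad + 1L):(pad + n)]
}

#' Min-max normalization to [0, 1]
#'
#' Removes the arbitrary intensity scale of a spectrum: the minimum maps to
#' 0 and the maximum to 1. A constant signal has no range and is rejected.
#'
#' @param x numeric signal with at least two distinct values.
#' @return normalized signal in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  r <- range(x)
  if (r[1L] == r[2L])
    stop("cannot min-max normalize a constant signal (degenerate range)")
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Filter-difference crest extraction
#'
#' The baseline-removal scheme at the heart of the preprocessing: the
#' (normalized) intensity trace is smoothed by a very-low-cutoff zero-phase
#' Butterworth pass so the smooth output `y1` tracks the baseline, the
#' difference `X = x_norm - y1` isolates the crests, and a second, wider
#' zero-phase pass removes small clutter from `X`.
#'
#' @param spectrum a [raman_spectrum()].
#' @param first [filter_spec()] of the baseline-tracking pass
#'   (default N = 2, wn = 0.002).
#' @param second [filter_spec()] of the clutter-removal pass
#'   (default N = 2, wn = 0.03).
#' @param normalize logical; min-max normalize before filtering (default
#'   TRUE).
#' @return object of class `processed_signal` with fields `shifts`, `x`
#'   (raw intensities), `x_norm` (filter input), `y1` (first-pass output),
#'   `X` (difference signal, exactly `x_norm - y1`) and `Xs` (second-pass
#'   output, the signal crest windows are cut from).
#' @export
peak_signal <- function(spectrum,
                        first = filter_spec(2, 0.002),
                        second = filter_spec(2, 0.03),
                        normalize = TRUE) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  x <- spectrum$intensities
  xn <- if (normalize) minmax_normalize(x) else x
  y1 <- zero_phase_filter(xn, design_lowpass(first))
  X <- xn - y1
  Xs <- zero_phase_filter(X, design_lowpass(second))
  structure(list(shifts = spectrum$shifts, x = x, x_norm = xn,
                 y1 = y1, X = X, Xs = Xs,
                 sample_id = spectrum$sample_id),
            class = "processed_signal")
}

# Topographic prominence of a local maximum at index p: height minus the
# higher of the two bases, where each base is the minimum between the peak
# and the nearest sample on that side exceeding the peak height (or the
# signal edge).
peak_prominence <- function(x, p) {
  h <- x[p]
  left <- h
  if (p > 1L) {
    i <- p - 1L
    left <- x[i]
    while (i >= 1L && x[i] <= h) {
      if (x[i] < left) left <- x[i]
      i <- i - 1L
    }
  }
  right <- h
  n <- length(x)
  if (p < n) {
    i <- p + 1L
    right <- x[i]
    while (i <= n && x[i] <= h) {
      if (x[i] < right) right <- x[i]
      i <- i + 1L
    }
  }
  h - max(left, right)
}

#' Detect prominent local maxima
#'
#' Diagnostic peak finder used to confirm that the filter-difference signal
#' exposes the expected crests; the production pipeline always cuts windows
#' at the fixed reference shifts instead. A local maximum is kept when its
#' topographic prominence reaches `min_prominence_frac * max(x)`.
#'
#' @param x numeric, non-constant signal.
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   signal maximum (default 0.05).
#' @return integer indices of detected peaks, sorted.
#' @export
detect_peaks <- function(x, min_prominence_frac = 0.05) {
  if (length(unique(x)) == 1L) stop("cannot detect peaks in a constant signal")
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                x[2:(n - 1L)] > x[3:n]) + 1L
  thr <- min_prominence_frac * max(x)
  cand[vapply(cand, function(p) peak_prominence(x, p) >= thr, logical(1))]
}
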