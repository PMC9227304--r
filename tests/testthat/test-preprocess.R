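test_that("Butterworth design yields unit-DC-gain coefficients", {
  for (wn in c(0.002, 0.03)) {
    cf <- design_lowpass(filter_spec(2, wn))
    expect_length(cf$b, 3L)
    expect_length(cf$a, 3L)
    expect_equal(cf$a[1], 1)
    expect_lt(abs(sum(cf$b) / sum(cf$a) - 1), 1e-9)
  }
  expect_error(filter_spec(2, 1.5), "open interval")
  expect_error(filter_spec(2, 0), "open interval")
  expect_error(filter_spec(0, 0.5), "positive integer")
})

test_that("zero-phase filtering preserves constants and handles edges", {
  cf <- design_lowpass(filter_spec(2, 0.03))
  x <- rep(3.7, 50)
  expect_lt(max(abs(zero_phase_filter(x, cf) - 3.7)), 1e-8 * 3.7)
  expect_equal(zero_phase_filter(rep(0, 50), cf), rep(0, 50))
  expect_error(zero_phase_filter(rep(1, 9), cf), "too short")
})

test_that("zero-phase output matches an independent filtfilt reference", {
  # frozen reference computed with an independent implementation of
  # forward-backward Butterworth filtering (order 2, wn = 0.03, odd padding)
  n <- 0:199
  x <- sin(0.05 * n) + 0.3 * cos(0.21 * n)
  y <- zero_phase_filter(x, design_lowpass(filter_spec(2, 0.03)))
  idx <- c(1, 2, 3, 51, 100, 101, 151, 198, 199, 200)
  ref <- c(0.349617323654465, 0.363327041626738, 0.377917255669407,
           0.538375393346704, -0.90425130512238, -0.894390163383183,
           0.871158263036867, -0.17175262322766, -0.188725836009703,
           -0.203259493718418)
  expect_equal(y[idx], ref, tolerance = 1e-12)
})

test_that("zero-phase filtering is symmetric and linear away from edges", {
  # Edge transients decay with the filter's time constant, so symmetry is
  # checked on signals whose features sit far from the boundaries.
  sym_case <- function(wn, len) {
    cf <- design_lowpass(filter_spec(2, wn))
    mid <- (len + 1) / 2
    s <- exp(-((1:len) - mid)^2 / (2 * 9^2))
    y <- zero_phase_filter(s, cf)
    max(abs(y - rev(y)))
  }
  expect_lt(sym_case(0.03, 2287), 1e-8)
  expect_lt(sym_case(0.002, 8001), 1e-8)

  # reversal commutation for centrally supported random signals
  set.seed(42)
  cf <- design_lowpass(filter_spec(2, 0.03))
  for (k in 1:3) {
    x <- numeric(2000)
    x[800:1200] <- cumsum(rnorm(401)) * 0.05
    x[800:1200] <- x[800:1200] * sin(seq(0, pi, length.out = 401))^2
    d <- max(abs(rev(zero_phase_filter(x, cf)) -
                   zero_phase_filter(rev(x), cf)))
    expect_lt(d, 1e-8)
  }

  # linearity holds exactly for arbitrary signals
  set.seed(43)
  s <- rnorm(300)
  t <- rnorm(300)
  lhs <- zero_phase_filter(2.5 * s - 1.3 * t, cf)
  rhs <- 2.5 * zero_phase_filter(s, cf) - 1.3 * zero_phase_filter(t, cf)
  expect_lt(max(abs(lhs - rhs)), 1e-8)
})

test_that("sinusoid attenuation is monotone above the cutoff", {
  cf <- design_lowpass(filter_spec(2, 0.03))
  freqs <- c(0.05, 0.08, 0.12, 0.2, 0.3, 0.45)  # fractions of Nyquist
  amp <- vapply(freqs, function(f) {
    x <- sin(pi * f * (0:3999))
    y <- zero_phase_filter(x, cf)
    max(abs(y[1000:3000]))
  }, numeric(1))
  expect_true(all(diff(amp) <= 1e-10))
})

test_that("min-max normalization maps onto [0, 1] and rejects constants", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.25, 0.9, 1)
  expect_equal(minmax_normalize(x), x)
  expect_error(minmax_normalize(c(5, 5, 5)), "degenerate")
})

test_that("the filter-difference signal conserves x_norm = X + y1 exactly", {
  sp <- bumpy_spectrum(c(480, 941, 2910))
  sig <- peak_signal(sp)
  expect_identical(sig$X, sig$x_norm - sig$y1)
  expect_lt(max(abs(sig$x_norm - (sig$X + sig$y1))), 1e-15)
})

test_that("baseline removal localizes a narrow peak", {
  # slow baseline (wavelength far above the first filter's cutoff) plus one
  # narrow Gaussian: the difference signal must peak at the Gaussian center
  axis <- default_axis()
  center <- 1339
  x <- 0.8 + 0.4 * sin(2 * pi * (axis - 200) / 3200) +
    1.0 * exp(-(axis - center)^2 / (2 * 10^2))
  sig <- peak_signal(raman_spectrum(axis, x))
  ci <- which.min(abs(axis - center))
  expect_lte(abs(which.max(abs(sig$Xs)) - ci), 3L)
})

test_that("a constant spectrum is rejected by normalization", {
  sp <- raman_spectrum(default_axis(), rep(2, length(default_axis())))
  expect_error(peak_signal(sp), "degenerate")
})

test_that("peak detection finds constructed crests and nothing else", {
  expect_equal(detect_peaks(1:100), integer(0))
  expect_error(detect_peaks(rep(1, 10)), "constant")

  # three well-separated unit Gaussians on a zero baseline
  y <- rep(0, 400)
  for (c0 in c(80, 200, 320)) y <- y + exp(-((1:400) - c0)^2 / 18)
  pk <- detect_peaks(y, 0.05)
  expect_length(pk, 3L)
  expect_true(all(abs(pk - c(80, 200, 320)) <= 1))

  # ten constructed crests survive the full preprocessing chain
  ten <- c(480, 865, 941, 1129, 1339, 1461, 1780, 2140, 2330, 2910)
  sig <- peak_signal(bumpy_spectrum(ten))
  pk <- detect_peaks(sig$Xs, 0.05)
  expect_length(pk, length(ten))
  centers <- vapply(ten, function(s) which.min(abs(default_axis() - s)),
                    integer(1))
  expect_true(all(vapply(pk, function(p) min(abs(p - centers)) <= 2,
                         logical(1))))
})
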