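#' Class peak-signature profile for synthetic spectra
#'
#' Describes the statistical structure the classifier is meant to exploit:
#' Gaussian crest amplitudes at the seven reference shifts, lognormal
#' between-sample amplitude jitter, a smooth baseline, and white noise.
#'
#' @param label class label in `{0, 1, 2}`.
#' @param peak_amplitudes 7 positive amplitudes, one per reference shift.
#' @param peak_width_sigma Gaussian crest width (sd, cm^-1; default 12).
#' @param amplitude_cv between-sample coefficient of variation of the
#'   crest amplitudes (default 0.08).
#' @param baseline_scale overall baseline height (default 0.4).
#' @param noise_sigma white-noise sd (default 0.02).
#' @return object of class `class_profile`.
#' @export
class_profile <- function(label, peak_amplitudes, peak_width_sigma = 12,
                          amplitude_cv = 0.08, baseline_scale = 0.4,
                          noise_sigma = 0.02) {
  stopifnot(label %in% 0:2, length(peak_amplitudes) == 7L,
            all(peak_amplitudes > 0), peak_width_sigma > 0,
            amplitude_cv >= 0, baseline_scale >= 0, noise_sigma >= 0)
  structure(list(label = as.integer(label),
                 peak_amplitudes = as.numeric(peak_amplitudes),
                 peak_width_sigma = peak_width_sigma,
                 amplitude_cv = amplitude_cv,
                 baseline_scale = baseline_scale,
                 noise_sigma = noise_sigma),
            class = "class_profile")
}

#' Default class profiles
#'
#' Shared base amplitudes with the CH-stretch crest (2910 cm^-1) the
#' largest band; the classes differ by multiplicative gaps of about 20% on
#' the starch/sugar crests at 480, 941 and 1129 cm^-1 (the bands that carry
#' the growth-duration signal), ordered class 0 < class 2 < class 1.
#'
#' @param gap multiplicative gap between adjacent classes (default 0.2;
#'   0 gives identical classes, the negative-control condition).
#' @return named list of three [class_profile()]s keyed "0", "1", "2".
#' @export
default_class_profiles <- function(gap = 0.2) {
  base <- c(1.0, 0.4, 0.9, 0.7, 0.5, 0.6, 1.6)
  starch <- c(1L, 3L, 4L)  # 480, 941, 1129 cm^-1
  make <- function(label, mult) {
    amps <- base
    amps[starch] <- amps[starch] * mult
    class_profile(label, amps)
  }
  list(`0` = make(0L, 1), `1` = make(1L, (1 + gap)^2), `2` = make(2L, 1 + gap))
}

#' Synthetic dataset configuration
#'
#' Defaults emulate the reference material: seven varieties of 35 grains
#' each (245 spectra) on the 200-3400 cm^-1 axis at 1.4 cm^-1 (2286
#' points), labels following the variety-to-zone map, and class-distinct
#' starch/sugar crest amplitudes.
#'
#' @param varieties list of entries `list(name, profile, n_samples, seed)`
#'   (`seed` optional; derived from `master_seed` when absent).
#' @param axis_start,axis_stop,axis_step shift axis in cm^-1.
#' @param master_seed integer master seed.
#' @param reference_shifts crest centers (cm^-1).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(varieties = NULL,
                         axis_start = 200, axis_stop = 3400,
                         axis_step = 1.4, master_seed = 7L,
                         reference_shifts = crest_config()$reference_shifts) {
  if (is.null(varieties)) {
    profiles <- default_class_profiles()
    labmap <- variety_labels()
    varieties <- lapply(names(labmap), function(nm)
      list(name = nm, profile = profiles[[as.character(labmap[[nm]])]],
           n_samples = 35L))
  }
  axis <- seq(axis_start, axis_stop, by = axis_step)
  margin <- 60 * axis_step
  if (any(reference_shifts < axis_start + margin) ||
      any(reference_shifts > axis_stop - margin))
    stop("axis must cover every reference shift with at least 60 grid ",
         "points of margin on each side")
  structure(list(varieties = varieties, axis = axis,
                 axis_step = axis_step, master_seed = as.integer(master_seed),
                 reference_shifts = as.numeric(reference_shifts)),
            class = "synth_config")
}

#' Generate one synthetic Raman spectrum
#'
#' Intensity = smooth baseline (low-order polynomial plus a broad sinusoid
#' whose wavelength far exceeds the baseline filter's cutoff wavelength,
#' scaled by `baseline_scale`) + Gaussian crests at the reference shifts
#' with lognormal amplitude jitter + white noise, clipped at zero.
#'
#' @param profile a [class_profile()].
#' @param axis numeric shift axis (cm^-1).
#' @param seed integer seed; the same seed reproduces the spectrum exactly.
#' @param centers crest centers (cm^-1), by default the seven reference
#'   shifts.
#' @param sample_id,variety metadata for the resulting spectrum.
#' @return a [raman_spectrum()] labeled with the profile's class.
#' @export
generate_spectrum <- function(profile, axis, seed,
                              centers = crest_config()$reference_shifts,
                              sample_id = "synthetic", variety = "SYN") {
  stopifnot(inherits(profile, "class_profile"))
  with_preserved_seed(seed, {
    t <- (axis - axis[1L]) / (axis[length(axis)] - axis[1L])
    phase <- runif(1, 0, 2 * pi)
    height <- exp(rnorm(1, 0, 0.1))
    baseline <- profile$baseline_scale * height *
      (0.6 + 0.3 * t - 0.25 * t^2 + 0.25 * sin(2 * pi * 1.25 * t + phase))
    if (profile$amplitude_cv > 0) {
      sl <- sqrt(log(1 + profile$amplitude_cv^2))
      amps <- profile$peak_amplitudes *
        rlnorm(length(centers), -sl^2 / 2, sl)
    } else {
      amps <- profile$peak_amplitudes
    }
    y <- baseline
    for (k in seq_along(centers))
      y <- y + amps[k] *
        exp(-(axis - centers[k])^2 / (2 * profile$peak_width_sigma^2))
    if (profile$noise_sigma > 0)
      y <- y + rnorm(length(axis), 0, profile$noise_sigma)
    raman_spectrum(axis, pmax(y, 0), sample_id = sample_id,
                   variety = variety, label = profile$label, n_scans = 4L)
  })
}

#' Generate a full synthetic dataset
#'
#' Per-variety seeds are derived deterministically from the master seed (or
#' taken from the variety entry when given), and per-sample seeds from the
#' variety seed, so changing one variety's seed changes only that variety's
#' spectra.
#'
#' @param cfg a [synth_config()].
#' @return a [sample_set()]; the default configuration yields 245 spectra
#'   with label counts 140/35/70 for classes 0/1/2.
#' @export
generate_dataset <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  spectra <- list()
  for (vi in seq_along(cfg$varieties)) {
    v <- cfg$varieties[[vi]]
    vseed <- v$seed %||% derive_seed(cfg$master_seed, vi)
    for (s in seq_len(v$n_samples)) {
      spectra[[length(spectra) + 1L]] <- generate_spectrum(
        v$profile, cfg$axis, seed = derive_seed(vseed, s),
        centers = cfg$reference_shifts,
        sample_id = sprintf("%s_%02d", v$name, s), variety = v$name)
    }
  }
  sample_set(spectra)
}
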