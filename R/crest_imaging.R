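#' Crest-window configuration
#'
#' The seven fixed reference crests (starch/sugar vibrational bands, cm^-1)
#' and the window geometry: 56 points before + the center + 55 points after
#' = 112 points per window, divided into 4 segments of 28 that become four
#' adjacent image columns. Seven crests x 4 segments give the 28-column
#' pseudo-image.
#'
#' @param reference_shifts ordered crest positions in cm^-1.
#' @param points_before,points_after window extent around the center.
#' @param segment_length points per segment (image rows).
#' @param segments_per_window segments (image columns) per crest.
#' @return object of class `crest_config`.
#' @export
crest_config <- function(reference_shifts = c(480, 865, 941, 1129,
                                              1339, 1461, 2910),
                         points_before = 56L, points_after = 55L,
                         segment_length = 28L, segments_per_window = 4L) {
  cfg <- structure(list(reference_shifts = as.numeric(reference_shifts),
                        points_before = as.integer(points_before),
                        points_after = as.integer(points_after),
                        segment_length = as.integer(segment_length),
                        segments_per_window = as.integer(segments_per_window)),
                   class = "crest_config")
  wl <- cfg$points_before + cfg$points_after + 1L
  if (wl != cfg$segment_length * cfg$segments_per_window)
    stop("window length ", wl, " does not equal segment_length * ",
         "segments_per_window = ",
         cfg$segment_length * cfg$segments_per_window)
  if (length(cfg$reference_shifts) * cfg$segments_per_window !=
      cfg$segment_length)
    stop("crest count x segments_per_window must equal segment_length ",
         "(square image)")
  cfg
}

window_length <- function(cfg) cfg$points_before + cfg$points_after + 1L

#' Map a Raman shift to the nearest grid index
#'
#' Returns the 1-based index of the axis value nearest to `target`; ties
#' break to the lower index. Targets outside the axis range are an error.
#'
#' @param shifts increasing shift axis.
#' @param target shift in cm^-1.
#' @return integer index into `shifts`.
#' @export
shift_to_index <- function(shifts, target) {
  if (target < shifts[1L] || target > shifts[length(shifts)])
    stop("target shift ", target, " cm^-1 lies outside the axis range [",
         shifts[1L], ", ", shifts[length(shifts)], "]")
  which.min(abs(shifts - target))
}

#' Extract a crest window from a processed signal
#'
#' Slices `points_before` values before the center, the center, and
#' `points_after` after it from the second-pass filtered difference signal
#' `Xs`.
#'
#' @param signal a `processed_signal` from [peak_signal()].
#' @param center_index 1-based grid index of the crest center.
#' @param cfg a [crest_config()].
#' @return object of class `peak_window` with fields `center_shift`,
#'   `center_index`, `values`.
#' @export
extract_window <- function(signal, center_index, cfg = crest_config()) {
  stopifnot(inherits(signal, "processed_signal"))
  lo <- center_index - cfg$points_before
  hi <- center_index + cfg$points_after
  if (lo < 1L || hi > length(signal$Xs))
    stop(sprintf(
      "crest at %.6g cm^-1 (index %d) has insufficient margin for a %d-point window",
      signal$shifts[min(max(center_index, 1L), length(signal$shifts))],
      center_index, window_length(cfg)))
  structure(list(center_shift = signal$shifts[center_index],
                 center_index = as.integer(center_index),
                 values = signal$Xs[lo:hi]),
            class = "peak_window")
}

#' Fold seven crest windows into a 28 x 28 sample image
#'
#' Each 112-point window is cut into 4 consecutive 28-point segments which
#' are aligned side by side: window w occupies columns
#' `(w-1)*4 + 1 ... (w-1)*4 + 4`, and within a segment the 28 points run
#' down the rows. The folding is a pure rearrangement: no value is altered.
#'
#' @param windows list of exactly 7 `peak_window` objects, in crest order.
#' @param cfg a [crest_config()].
#' @param sample_id,label,variety metadata carried on the image.
#' @return object of class `sample_image` with a `segment_length` x
#'   `segment_length` `pixels` matrix.
#' @export
fold_sample <- function(windows, cfg = crest_config(), sample_id = "sample",
                        label = NA_integer_, variety = NA_character_) {
  if (length(windows) != length(cfg$reference_shifts))
    stop("expected ", length(cfg$reference_shifts), " windows, got ",
         length(windows))
  wl <- window_length(cfg)
  cols <- lapply(windows, function(w) {
    if (length(w$values) != wl)
      stop("window at ", w$center_shift, " cm^-1 has ", length(w$values),
           " values, expected ", wl)
    matrix(w$values, nrow = cfg$segment_length)
  })
  px <- do.call(cbind, cols)
  if (!all(is.finite(px))) stop("non-finite pixel values in sample image")
  structure(list(pixels = px, sample_id = as.character(sample_id),
                 label = if (is.na(label)) NA_integer_ else as.integer(label),
                 variety = as.character(variety)),
            class = "sample_image")
}

#' Recover the seven crest windows from a sample image
#'
#' Exact inverse of [fold_sample()] (folding is lossless).
#'
#' @param image a `sample_image`.
#' @param cfg a [crest_config()].
#' @return list of 7 numeric vectors of 112 values each.
#' @export
unfold_image <- function(image, cfg = crest_config()) {
  s <- cfg$segments_per_window
  lapply(seq_along(cfg$reference_shifts), function(w)
    as.vector(image$pixels[, ((w - 1L) * s + 1L):(w * s)]))
}

#' Build the pseudo-image of one spectrum
#'
#' Full composition: preprocess with [peak_signal()], cut the seven crest
#' windows from `Xs`, and fold them into the 28 x 28 image. Exactly
#' 7 x 112 = 784 signal values contribute.
#'
#' @param spectrum a [raman_spectrum()].
#' @param cfg a [crest_config()].
#' @param first,second,normalize forwarded to [peak_signal()].
#' @return a `sample_image` carrying the spectrum's id, label and variety.
#' @export
image_from_spectrum <- function(spectrum, cfg = crest_config(),
                                first = filter_spec(2, 0.002),
                                second = filter_spec(2, 0.03),
                                normalize = TRUE) {
  sig <- peak_signal(spectrum, first = first, second = second,
                     normalize = normalize)
  windows <- lapply(cfg$reference_shifts, function(rs) {
    ok <- rs >= sig$shifts[1L] && rs <= sig$shifts[length(sig$shifts)]
    if (!ok)
      stop("cannot place a window for the crest at ", rs,
           " cm^-1: outside the spectrum's axis range")
    extract_window(sig, shift_to_index(sig$shifts, rs), cfg)
  })
  fold_sample(windows, cfg, sample_id = spectrum$sample_id,
              label = spectrum$label, variety = spectrum$variety)
}

#' Build pseudo-images for every spectrum in a sample set
#'
#' @param set a [sample_set()].
#' @param ... forwarded to [image_from_spectrum()].
#' @return list of `sample_image` objects.
#' @export
images_from_sampleset <- function(set, ...) {
  lapply(set$spectra, image_from_spectrum, ...)
}

#' Write a sample image as delimited text
#'
#' 28 rows x 28 tab-separated columns at 9 significant digits; reading the
#' file back reproduces those 9-digit values bit-exactly.
#'
#' @param image a `sample_image`.
#' @param path destination file.
#' @export
write_image <- function(image, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#sample_id\t%s", image$sample_id), con)
  writeLines(sprintf("#label\t%s", image$label), con)
  writeLines(sprintf("#variety\t%s", image$variety), con)
  writeLines(apply(image$pixels, 1L, function(r)
    paste(sprintf("%.9g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read a sample image written by [write_image()]
#'
#' @param path image text file.
#' @return a `sample_image`.
#' @export
read_image <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  grab <- function(key) {
    ln <- meta[startsWith(meta, paste0("#", key, "\t"))]
    if (length(ln) == 1L) strsplit(ln, "\t")[[1L]][2L] else NA_character_
  }
  px <- do.call(rbind, lapply(body, function(ln)
    as.numeric(strsplit(ln, "\t")[[1L]])))
  lab <- suppressWarnings(as.integer(grab("label")))
  structure(list(pixels = px, sample_id = grab("sample_id"),
                 label = lab, variety = grab("variety")),
            class = "sample_image")
}

#' Pseudocolor rendering of a sample image
#'
#' Writes (or displays) the 28 x 28 image with a viridis color map, the way
#' folded crest images are usually inspected.
#'
#' @param image a `sample_image`.
#' @param file optional PNG path; when `NULL` the current device is used.
#' @export
plot_sample_image <- function(image, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 480, height = 480)
    on.exit(grDevices::dev.off())
  }
  px <- image$pixels
  graphics::image(t(px[nrow(px):1, ]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE,
                  main = sprintf("%s (class %s)", image$sample_id,
                                 format(image$label)))
  invisible(image)
}
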