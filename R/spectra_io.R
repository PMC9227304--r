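#' Raman spectrum container
#'
#' A single grain's Raman spectrum: a strictly increasing shift axis in
#' cm^-1 with non-negative intensities (arbitrary units), plus identity
#' metadata. The shift spacing must be approximately constant (maximum
#' deviation from the median spacing below 10%), matching data acquired on a
#' regular grid such as 200-3400 cm^-1 at 1.4 cm^-1.
#'
#' @param shifts numeric, strictly increasing Raman shifts (cm^-1).
#' @param intensities numeric, same length, non-negative intensities (a.u.).
#' @param sample_id character scalar identifying the grain.
#' @param variety character scalar, rice variety name.
#' @param label integer class in `{0, 1, 2}` (accumulated-temperature zone),
#'   or `NA` when unknown.
#' @param n_scans positive integer, number of co-added scans.
#' @return an object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(shifts, intensities, sample_id = "sample",
                           variety = NA_character_, label = NA_integer_,
                           n_scans = 1L) {
  x <- structure(
    list(sample_id = as.character(sample_id),
         variety = as.character(variety),
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         shifts = as.numeric(shifts),
         intensities = as.numeric(intensities),
         n_scans = as.integer(n_scans)),
    class = "raman_spectrum")
  validate_spectrum(x)
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s (variety %s, label %s): %d points, %.6g-%.6g cm^-1, %d scan(s)\n",
              x$sample_id, x$variety, format(x$label), length(x$shifts),
              min(x$shifts), max(x$shifts), x$n_scans))
  invisible(x)
}

validate_spectrum <- function(x) {
  if (length(x$shifts) != length(x$intensities))
    stop("shifts and intensities differ in length for sample '",
         x$sample_id, "'")
  if (length(x$shifts) < 2L)
    stop("spectrum '", x$sample_id, "' has fewer than 2 points")
  d <- diff(x$shifts)
  if (any(d <= 0))
    stop("shift axis of '", x$sample_id,
         "' is not strictly increasing (duplicate or unordered shifts)")
  md <- stats::median(d)
  if (max(abs(d - md)) >= 0.1 * md)
    stop("shift spacing of '", x$sample_id,
         "' deviates more than 10% from the median spacing")
  if (any(x$intensities < 0))
    stop("negative intensities in spectrum '", x$sample_id, "'")
  if (is.na(x$n_scans) || x$n_scans < 1L)
    stop("n_scans must be a positive integer")
  x
}

#' Default class-label descriptions
#'
#' Labels follow the accumulated-temperature-zone coding: class 0 is the
#' third zone (short growth duration), class 1 the first zone (long), class 2
#' the second zone (medium).
#'
#' @return named character vector keyed by label.
#' @export
default_class_names <- function() {
  c(`0` = "third accumulated-temperature zone (short GD)",
    `1` = "first accumulated-temperature zone (long GD)",
    `2` = "second accumulated-temperature zone (medium GD)")
}

#' Variety-to-label map for the seven japonica varieties
#'
#' @return named integer vector mapping variety name to class label.
#' @export
variety_labels <- function() {
  c(LJ47 = 0L, KY131 = 0L, LJ11 = 0L, HH311 = 0L,
    QJ1 = 1L, SJ13 = 2L, HJ313 = 2L)
}

#' Collection of spectra on a shared axis
#'
#' @param spectra list of [raman_spectrum()] objects.
#' @param class_names named character vector mapping label to description.
#' @return object of class `sample_set`.
#' @export
sample_set <- function(spectra, class_names = default_class_names()) {
  x <- structure(list(spectra = spectra, class_names = class_names),
                 class = "sample_set")
  validate_sample_set(x)
}

validate_sample_set <- function(x) {
  if (length(x$spectra) == 0L) return(x)
  ref <- x$spectra[[1L]]$shifts
  for (sp in x$spectra) {
    stopifnot(inherits(sp, "raman_spectrum"))
    if (length(sp$shifts) != length(ref) || any(sp$shifts != ref))
      stop("spectrum '", sp$sample_id,
           "' is not on the shared shift axis of the sample set")
    if (!is.na(sp$label) && !(as.character(sp$label) %in% names(x$class_names)))
      stop("label ", sp$label, " of '", sp$sample_id,
           "' is not in the class-name map")
  }
  x
}

#' @export
print.sample_set <- function(x, ...) {
  labs <- vapply(x$spectra, function(s) s$label, integer(1))
  cat(sprintf("<sample_set> %d spectra; label counts: %s\n",
              length(x$spectra),
              paste(sprintf("%s=%d", names(table(labs)), table(labs)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.sample_set <- function(x) length(x$spectra)

parse_numeric_rows <- function(lines, path, skip_first = FALSE) {
  rows <- list()
  ncol_seen <- NA_integer_
  header_done <- FALSE
  for (i in seq_along(lines)) {
    if (skip_first && i == 1L) next
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    toks <- strsplit(ln, "[,;[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      if (!header_done) next  # leading header line(s): skip
      stop("cannot parse line ", i, " of '", path, "': '", lines[[i]], "'")
    }
    if (length(vals) < 2L)
      stop("line ", i, " of '", path, "' has fewer than 2 columns")
    if (is.na(ncol_seen)) ncol_seen <- length(vals)
    if (length(vals) != ncol_seen)
      stop("line ", i, " of '", path, "' has ", length(vals),
           " columns, expected ", ncol_seen)
    header_done <- TRUE
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) == 0L)
    stop("no numeric data rows found in '", path, "'")
  do.call(rbind, rows)
}

#' Read a spectrum from PRN-style delimited text
#'
#' PRN files are treated as whitespace- or comma-delimited numeric text:
#' the first column is the Raman shift, remaining column(s) are intensity
#' traces. Leading non-numeric header lines are skipped; a non-numeric row
#' inside the data block is a parse error naming the line. When several
#' intensity columns are present (one per scan) they are averaged and
#' `n_scans` records how many were combined. Rows are sorted by shift before
#' validation.
#'
#' @param path file path.
#' @param dialect `"two-column-text"` (default; header lines auto-detected)
#'   or `"delimited-with-header"` (first line always treated as a header).
#' @param sample_id,variety,label metadata attached to the result.
#' @return a [raman_spectrum()].
#' @export
read_spectrum <- function(path,
                          dialect = c("two-column-text",
                                      "delimited-with-header"),
                          sample_id = NULL, variety = NA_character_,
                          label = NA_integer_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("spectrum file not found: '", path, "'")
  m <- parse_numeric_rows(readLines(path, warn = FALSE), path,
                          skip_first = dialect == "delimited-with-header")
  ord <- order(m[, 1L])
  m <- m[ord, , drop = FALSE]
  if (anyDuplicated(m[, 1L]))
    stop("duplicate Raman shifts in '", path, "' after sorting")
  inten <- if (ncol(m) == 2L) m[, 2L] else rowMeans(m[, -1L, drop = FALSE])
  raman_spectrum(m[, 1L], inten,
                 sample_id = sample_id %||%
                   tools::file_path_sans_ext(basename(path)),
                 variety = variety, label = label,
                 n_scans = ncol(m) - 1L)
}

#' Write a spectrum as two-column text
#'
#' Values are written with 17 significant digits so a read round-trips to
#' full double precision.
#'
#' @param spectrum a [raman_spectrum()].
#' @param path destination file.
#' @export
write_spectrum <- function(spectrum, path) {
  writeLines(sprintf("%.17g %.17g", spectrum$shifts, spectrum$intensities),
             path)
  invisible(path)
}

#' Read a sample manifest and all referenced spectra
#'
#' The manifest is delimited text (comma or whitespace) with a header and
#' columns `sample_id`, `variety`, `label`, `path`; paths are resolved
#' relative to the manifest's directory. All spectra are validated against a
#' shared shift axis and labels against `{0, 1, 2}`.
#'
#' @param path manifest file.
#' @return a [sample_set()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: '", path, "'")
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (nrow(df) == 0L) {
    warning("manifest '", path, "' lists no samples; returning an empty set")
    return(sample_set(list()))
  }
  need <- c("sample_id", "variety", "label", "path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  bad <- !df$label %in% 0:2
  if (any(bad))
    stop("manifest label(s) outside {0,1,2}: ",
         paste(unique(df$label[bad]), collapse = ", "))
  base <- dirname(normalizePath(path))
  spectra <- lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(base, df$path[i])
    if (!file.exists(p))
      stop("spectrum file for sample '", df$sample_id[i],
           "' not found: '", df$path[i], "'")
    read_spectrum(p, sample_id = df$sample_id[i], variety = df$variety[i],
                  label = as.integer(df$label[i]))
  })
  sample_set(spectra)
}

#' Write a sample set as PRN files plus a manifest
#'
#' Produces the same on-disk layout [read_manifest()] consumes: one
#' two-column PRN file per spectrum under `dir/spectra/` and a
#' `manifest.csv`.
#'
#' @param set a [sample_set()].
#' @param dir destination directory (created if needed).
#' @return path of the written manifest.
#' @export
write_manifest <- function(set, dir) {
  spdir <- file.path(dir, "spectra")
  dir.create(spdir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(set$spectra, function(sp) {
    f <- file.path("spectra", paste0(sp$sample_id, ".prn"))
    write_spectrum(sp, file.path(dir, f))
    data.frame(sample_id = sp$sample_id, variety = sp$variety,
               label = sp$label, path = f, stringsAsFactors = FALSE)
  })
  man <- file.path(dir, "manifest.csv")
  utils::write.table(do.call(rbind, rows), man, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(man)
}

#' Write a consolidated dataset file
#'
#' One delimited text file: metadata lines prefixed `#` (sample ids,
#' varieties, labels, column-aligned), then a header and a matrix whose
#' first column is the shift axis and remaining columns are the spectra.
#' Round-trips through [read_dataset()] at full double precision.
#'
#' @param set a [sample_set()].
#' @param path destination file.
#' @export
write_dataset <- function(set, path) {
  ids <- vapply(set$spectra, function(s) s$sample_id, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#sample_id\t", paste(ids, collapse = "\t")),
               paste0("#variety\t", paste(vapply(set$spectra,
                 function(s) s$variety, character(1)), collapse = "\t")),
               paste0("#label\t", paste(vapply(set$spectra,
                 function(s) s$label, integer(1)), collapse = "\t")),
               paste0("#n_scans\t", paste(vapply(set$spectra,
                 function(s) s$n_scans, integer(1)), collapse = "\t"))), con)
  m <- cbind(set$spectra[[1L]]$shifts,
             do.call(cbind, lapply(set$spectra, function(s) s$intensities)))
  writeLines(apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' Read a consolidated dataset file written by [write_dataset()]
#'
#' @param path dataset file.
#' @return a [sample_set()].
#' @export
read_dataset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_meta <- function(key) {
    ln <- meta[startsWith(meta, paste0("#", key, "\t"))]
    if (length(ln) != 1L) stop("dataset file lacks #", key, " metadata")
    strsplit(sub(paste0("^#", key, "\t"), "", ln), "\t")[[1L]]
  }
  ids <- get_meta("sample_id")
  vars <- get_meta("variety")
  labs <- as.integer(get_meta("label"))
  scans <- as.integer(get_meta("n_scans"))
  m <- do.call(rbind, lapply(body, function(ln)
    as.numeric(strsplit(ln, "\t")[[1L]])))
  if (ncol(m) != length(ids) + 1L)
    stop("dataset matrix has ", ncol(m) - 1L, " spectra but ",
         length(ids), " sample ids")
  sample_set(lapply(seq_along(ids), function(i)
    raman_spectrum(m[, 1L], m[, i + 1L], sample_id = ids[i],
                   variety = vars[i], label = labs[i], n_scans = scans[i])))
}
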