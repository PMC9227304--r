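test_that("two-column text parses, sorts, and reports bad lines", {
  f <- withr::local_tempfile()
  writeLines(c("200 1.0", "201.4 2.0", "202.8 1.5"), f)
  sp <- read_spectrum(f)
  expect_length(sp$shifts, 3L)
  expect_equal(sp$shifts, c(200, 201.4, 202.8))
  expect_equal(sp$intensities, c(1.0, 2.0, 1.5))
  expect_equal(sp$n_scans, 1L)

  # rows out of order give the same spectrum as sorted input
  f2 <- withr::local_tempfile()
  writeLines(c("202.8 1.5", "200 1.0", "201.4 2.0"), f2)
  sp2 <- read_spectrum(f2, sample_id = sp$sample_id)
  expect_equal(sp2$shifts, sp$shifts)
  expect_equal(sp2$intensities, sp$intensities)

  # malformed row inside the data block names its line
  f3 <- withr::local_tempfile()
  writeLines(c("200 1.0", "abc def", "202.8 1.5"), f3)
  expect_error(read_spectrum(f3), "line 2")

  # leading non-numeric header lines are skipped
  f4 <- withr::local_tempfile()
  writeLines(c("Raman shift, intensity", "200, 1.0", "201.4, 2.0",
               "202.8, 0.5"), f4)
  expect_equal(read_spectrum(f4)$intensities, c(1, 2, 0.5))

  # duplicate shifts after sorting are rejected
  f5 <- withr::local_tempfile()
  writeLines(c("200 1", "200 2", "201.4 1"), f5)
  expect_error(read_spectrum(f5), "duplicate")
})

test_that("multi-column scans are averaged into one trace", {
  f <- withr::local_tempfile()
  writeLines(c("200 1 3 5 7", "201.4 2 2 2 2", "202.8 0 4 0 4"), f)
  sp <- read_spectrum(f)
  expect_equal(sp$n_scans, 4L)
  expect_equal(sp$intensities, c(4, 2, 2))
})

test_that("spectrum invariants reject irregular axes", {
  expect_error(raman_spectrum(c(200, 201.4, 210), c(1, 1, 1)), "spacing")
  expect_error(raman_spectrum(c(200, 200, 201.4), c(1, 1, 1)),
               "strictly increasing")
  expect_error(raman_spectrum(c(200, 201.4), c(1, -1)), "negative")
})

test_that("manifest round trip preserves values and metadata", {
  dir <- withr::local_tempdir()
  axis <- seq(200, 340, by = 1.4)
  set.seed(3)
  labmap <- variety_labels()
  spectra <- lapply(names(labmap), function(nm)
    raman_spectrum(axis, runif(length(axis)), sample_id = paste0(nm, "_01"),
                   variety = nm, label = labmap[[nm]]))
  man <- write_manifest(sample_set(spectra), dir)
  back <- read_manifest(man)
  expect_length(back, 7L)
  # Label map: four third-zone, one first-zone, two second-zone varieties
  labs <- vapply(back$spectra, function(s) s$label, integer(1))
  vars <- vapply(back$spectra, function(s) s$variety, character(1))
  expect_equal(labs, unname(labmap[vars]))
  # full stored precision round trip
  for (i in seq_along(spectra)) {
    orig <- spectra[[which(names(labmap) ==
                             back$spectra[[i]]$variety)]]
    expect_identical(back$spectra[[i]]$shifts, orig$shifts)
    expect_identical(back$spectra[[i]]$intensities, orig$intensities)
  }
})

test_that("manifest validation catches bad labels, files, and emptiness", {
  dir <- withr::local_tempdir()
  man <- file.path(dir, "manifest.csv")
  writeLines("sample_id,variety,label,path", man)
  expect_warning(s <- read_manifest(man), "no samples")
  expect_length(s, 0L)

  writeLines(c("sample_id,variety,label,path", "a,V,5,a.prn"), man)
  expect_error(read_manifest(man), "outside \\{0,1,2\\}")

  writeLines(c("sample_id,variety,label,path", "a,V,1,missing.prn"), man)
  expect_error(read_manifest(man), "not found")
})

test_that("a sample set rejects spectra on differing shift grids", {
  a <- raman_spectrum(seq(200, 220, 1.4), rep(1, 15), sample_id = "a",
                      label = 0L)
  b <- raman_spectrum(seq(201, 221, 1.4), rep(1, 15), sample_id = "b",
                      label = 0L)
  expect_error(sample_set(list(a, b)), "shared shift axis")
})

test_that("consolidated dataset file round-trips exactly", {
  axis <- seq(200, 300, by = 1.4)
  set.seed(9)
  spectra <- lapply(1:3, function(i)
    raman_spectrum(axis, runif(length(axis)), sample_id = paste0("s", i),
                   variety = "V", label = 2L, n_scans = 4L))
  f <- withr::local_tempfile()
  write_dataset(sample_set(spectra), f)
  back <- read_dataset(f)
  for (i in 1:3) {
    expect_identical(back$spectra[[i]]$intensities,
                     spectra[[i]]$intensities)
    expect_identical(back$spectra[[i]]$shifts, spectra[[i]]$shifts)
    expect_equal(back$spectra[[i]]$n_scans, 4L)
  }
})
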