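test_that("generated spectra live on the right axis, reproducibly", {
  prof <- default_class_profiles()[["0"]]
  axis <- default_axis()
  sp <- generate_spectrum(prof, axis, seed = 101)
  expect_length(sp$intensities, 2286L)  # floor((3400-200)/1.4) + 1
  expect_true(all(sp$intensities >= 0))
  expect_equal(sp$n_scans, 4L)
  sp2 <- generate_spectrum(prof, axis, seed = 101)
  expect_identical(sp$intensities, sp2$intensities)
  expect_false(identical(sp$intensities,
                         generate_spectrum(prof, axis, 102)$intensities))
})

test_that("a noise-free single crest peaks at its grid point", {
  prof <- class_profile(0L, c(1, rep(1e-9, 6)), amplitude_cv = 0,
                        baseline_scale = 0, noise_sigma = 0)
  axis <- default_axis()
  sp <- generate_spectrum(prof, axis, seed = 1)
  expect_equal(which.max(sp$intensities), which.min(abs(axis - 480)))
})

test_that("the default dataset reproduces the study's composition", {
  ds <- generate_dataset(synth_config(master_seed = 7))
  expect_length(ds, 245L)
  labs <- vapply(ds$spectra, function(s) s$label, integer(1))
  expect_equal(as.vector(table(labs)), c(140L, 35L, 70L))
  expect_equal(length(unique(vapply(ds$spectra, function(s) s$variety,
                                    character(1)))), 7L)
  # determinism per master seed
  ds2 <- generate_dataset(synth_config(master_seed = 7))
  expect_identical(ds$spectra[[100]]$intensities,
                   ds2$spectra[[100]]$intensities)
})

test_that("changing one variety's seed perturbs only that variety", {
  cfgA <- synth_config(master_seed = 7)
  cfgB <- synth_config(master_seed = 7)
  cfgB$varieties[[3]]$seed <- 999L
  a <- generate_dataset(cfgA)
  b <- generate_dataset(cfgB)
  va <- vapply(a$spectra, function(s) s$variety, character(1))
  target <- cfgA$varieties[[3]]$name
  for (i in seq_along(a$spectra)) {
    same <- identical(a$spectra[[i]]$intensities, b$spectra[[i]]$intensities)
    expect_identical(same, va[i] != target)
  }
})

test_that("class means at the 941 cm^-1 crest order as the amplitudes", {
  ds <- generate_dataset(synth_config(master_seed = 7))
  idx <- which.min(abs(default_axis() - 941))
  labs <- vapply(ds$spectra, function(s) s$label, integer(1))
  at941 <- vapply(ds$spectra, function(s) s$intensities[idx], numeric(1))
  means <- tapply(at941, labs, mean)
  # profile multipliers order class 0 < class 2 < class 1
  expect_true(means[["0"]] < means[["2"]])
  expect_true(means[["2"]] < means[["1"]])
})

test_that("synthetic data exercises the real on-disk I/O path", {
  profiles <- default_class_profiles()
  varieties <- list(
    list(name = "LJ47", profile = profiles[["0"]], n_samples = 2L),
    list(name = "QJ1", profile = profiles[["1"]], n_samples = 2L))
  ds <- generate_dataset(synth_config(varieties = varieties,
                                      master_seed = 3))
  dir <- withr::local_tempdir()
  back <- read_manifest(write_manifest(ds, dir))
  expect_length(back, 4L)
  for (i in seq_along(ds$spectra)) {
    expect_identical(back$spectra[[i]]$intensities,
                     ds$spectra[[i]]$intensities)
    expect_equal(back$spectra[[i]]$label, ds$spectra[[i]]$label)
  }
})

test_that("widening the class gap raises held-out accuracy", {
  run <- function(gap, sd) {
    imgs <- small_synth_images(gap, sd, n_samples = 12L)
    sp <- split_dataset(imgs, split_spec(3L, seed = sd))
    tr <- train_capsnet(sp$train, sp$test,
                        capsnet_config(conv1_channels = 16L,
                                       primary_channels = 32L),
                        train_config(epochs = 30L, eval_every = 5L),
                        seed = sd)
    tr$best_test_acc
  }
  low <- mean(vapply(1:3, function(sd) run(0, sd), numeric(1)))
  high <- mean(vapply(1:3, function(sd) run(0.2, sd), numeric(1)))
  # monotone on average; ties within noise would still satisfy >=
  expect_gte(high, low)
  expect_gt(high, low + 5)
})
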