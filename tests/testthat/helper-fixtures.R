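# Shared fixture builders; everything is generated in code at test time.

default_axis <- function() seq(200, 3400, by = 1.4)

# Smooth baseline plus Gaussian bumps at the given centers.
bumpy_spectrum <- function(centers, amp = 0.8, width = 12,
                           axis = default_axis(), id = "fix") {
  t <- (axis - axis[1]) / diff(range(axis))
  x <- 0.5 * (0.6 + 0.3 * t - 0.2 * t^2 + 0.2 * sin(2 * pi * t + 1))
  for (ck in centers)
    x <- x + amp * exp(-(axis - ck)^2 / (2 * width^2))
  raman_spectrum(axis, x, sample_id = id)
}

# A processed_signal with a prescribed Xs, for window-slicing tests.
fake_processed <- function(Xs, axis = default_axis()[seq_along(Xs)]) {
  structure(list(shifts = axis, x = Xs, x_norm = Xs, y1 = 0 * Xs,
                 X = Xs, Xs = Xs, sample_id = "fake"),
            class = "processed_signal")
}

# Small network configuration used wherever the full widths are not the
# point (keeps the suite fast while exercising identical code paths).
tiny_net_cfg <- function(...) {
  capsnet_config(conv1_channels = 8L, primary_channels = 16L,
                 primary_caps_dim = 8L, class_caps_dim = 8L, ...)
}

# Linearly separable image set: each class lights up a disjoint block.
constant_images <- function(n_per_class = 10L, noise = 0) {
  imgs <- list()
  for (cl in 0:2) {
    for (i in seq_len(n_per_class)) {
      px <- matrix(0.05, 28, 28)
      px[, (cl * 9 + 1):(cl * 9 + 9)] <- 1
      if (noise > 0) px <- px + matrix(rnorm(784, 0, noise), 28, 28)
      imgs[[length(imgs) + 1L]] <-
        structure(list(pixels = px,
                       sample_id = sprintf("c%d_%02d", cl, i),
                       label = cl, variety = sprintf("V%d", cl)),
                  class = "sample_image")
    }
  }
  imgs
}

# Straight-line reference implementation of agreement routing, written as
# bare nested loops directly from the update equations; used as the oracle
# for dynamic_routing.
routing_oracle <- function(u_hat, iterations) {
  I <- dim(u_hat)[1]; D <- dim(u_hat)[2]; J <- dim(u_hat)[3]
  b <- matrix(0, I, J)
  v <- matrix(0, J, D)
  cc <- matrix(0, I, J)
  for (t in seq_len(iterations)) {
    for (i in seq_len(I)) {
      ex <- exp(b[i, ])
      cc[i, ] <- ex / sum(ex)
    }
    for (j in seq_len(J)) {
      s <- rep(0, D)
      for (i in seq_len(I)) s <- s + cc[i, j] * u_hat[i, , j]
      n2 <- sum(s^2)
      v[j, ] <- if (n2 == 0) s else (n2 / (1 + n2)) * s / sqrt(n2)
    }
    if (t < iterations) {
      for (i in seq_len(I))
        for (j in seq_len(J))
          b[i, j] <- b[i, j] + sum(v[j, ] * u_hat[i, , j])
    }
  }
  list(v = v, c = cc, b = b)
}

# Synthetic dataset scaled down for fast training checks.
small_synth_images <- function(gap, master_seed, n_samples = 10L) {
  profiles <- default_class_profiles(gap = gap)
  labmap <- variety_labels()
  varieties <- lapply(names(labmap), function(nm)
    list(name = nm, profile = profiles[[as.character(labmap[[nm]])]],
         n_samples = n_samples))
  images_from_sampleset(
    generate_dataset(synth_config(varieties = varieties,
                                  master_seed = master_seed)))
}
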