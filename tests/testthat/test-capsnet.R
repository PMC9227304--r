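test_that("architecture arithmetic matches the stated geometry", {
  cfg <- capsnet_config()
  expect_equal(cfg$conv1_grid, 20L)
  expect_equal(cfg$primary_grid, 6L)
  expect_equal(cfg$primary_caps_types, 32L)
  expect_equal(cfg$n_primary_caps, 1152L)
  expect_error(capsnet_config(primary_channels = 30L), "multiple")
})

test_that("squashing bounds, scales, and preserves direction", {
  expect_identical(squash(c(0, 0, 0)), c(0, 0, 0))
  u <- c(1, 0, 0)
  expect_lt(abs(sqrt(sum(squash(u)^2)) - 0.5), 1e-12)
  expect_lt(max(abs(squash(c(3, 0, 0)) - c(0.9, 0, 0))), 1e-12)
  # norm strictly increasing in input norm, always in [0, 1), direction kept
  set.seed(2)
  dirv <- rnorm(5); dirv <- dirv / sqrt(sum(dirv^2))
  norms <- vapply(seq(0.1, 20, length.out = 30), function(m) {
    v <- squash(m * dirv)
    cosang <- sum(v * dirv) / sqrt(sum(v^2))
    expect_lt(abs(cosang - 1), 1e-12)
    sqrt(sum(v^2))
  }, numeric(1))
  expect_true(all(norms >= 0 & norms < 1))
  expect_true(all(diff(norms) > 0))
})

test_that("prediction vectors are the W_ij u_i products", {
  # identity and zero transforms (square case)
  I <- 4L; Dk <- 3L; J <- 2L
  Wid <- array(0, c(Dk, Dk, J, I))
  for (i in 1:I) for (j in 1:J) Wid[, , j, i] <- diag(Dk)
  set.seed(1)
  u <- matrix(rnorm(I * Dk), I, Dk)
  uh <- predict_uhat(u, Wid)
  for (j in 1:J) expect_equal(uh[, , j], u, tolerance = 1e-14)
  expect_true(all(predict_uhat(u, 0 * Wid) == 0))

  # hand-computed rectangular case against plain matrix products
  W <- array(rnorm(2 * 2 * 1 * 2), c(2, 2, 1, 2))
  u2 <- matrix(rnorm(4), 2, 2)
  uh2 <- predict_uhat(u2, W)
  for (i in 1:2)
    expect_equal(uh2[i, , 1], as.vector(W[, , 1, i] %*% u2[i, ]),
                 tolerance = 1e-14)
  expect_error(predict_uhat(matrix(0, 3, 2), W), "conform")
})

test_that("routing starts uniform and matches a straight-line oracle", {
  set.seed(8)
  # uniform couplings at initialization (softmax of zeros)
  uh <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  rs <- dynamic_routing(uh, iterations = 1L)
  expect_equal(rs$c, matrix(1 / 3, 5, 3))

  # zero predictions: outputs zero, couplings stay uniform
  rs0 <- dynamic_routing(array(0, c(5, 4, 3)), iterations = 4L)
  expect_true(all(rs0$v == 0))
  expect_equal(rs0$c, matrix(1 / 3, 5, 3))

  # oracle equivalence on small instances, several shapes and iteration
  # counts
  for (case in list(c(2, 2, 2, 2), c(3, 2, 3, 3), c(3, 3, 2, 5),
                    c(1, 4, 3, 2))) {
    I <- case[1]; D <- case[2]; J <- case[3]; iters <- case[4]
    uh <- array(rnorm(I * D * J), c(I, D, J))
    got <- dynamic_routing(uh, iterations = iters)
    ref <- routing_oracle(uh, iters)
    expect_lt(max(abs(got$v - ref$v)), 1e-10)
    expect_lt(max(abs(got$c - ref$c)), 1e-10)
  }
})

test_that("couplings sum to one at every routing iteration", {
  set.seed(12)
  uh <- array(rnorm(40 * 6 * 3, sd = 2), c(40, 6, 3))
  rs <- dynamic_routing(uh, iterations = 5L, keep_history = TRUE)
  for (h in rs$history)
    expect_lt(max(abs(rowSums(h$c) - 1)), 1e-9)
})

test_that("one uniform iteration equals squashing the uniform mixture", {
  set.seed(13)
  I <- 10L
  uh <- array(rnorm(I * 4 * 3), c(I, 4, 3))
  v1 <- dynamic_routing(uh, iterations = 1L)$v
  for (j in 1:3)
    expect_equal(v1[j, ], squash(colSums(uh[, , j]) / 3),
                 tolerance = 1e-12)
})

test_that("margin loss is zero exactly on the satisfied-margin set", {
  cfg <- capsnet_config()
  expect_equal(margin_loss(c(0.95, 0.05, 0.02), 0, cfg), 0)
  expect_equal(margin_loss(c(0, 0, 0), 1, cfg), 0.81)
  expect_equal(margin_loss(c(1, 1, 1), 2, cfg), 0.81)
  expect_error(margin_loss(c(0.1, 0.1, 0.1), 5, cfg), "label")
  set.seed(4)
  for (k in 1:50) {
    l <- runif(3)
    lab <- sample(0:2, 1)
    loss <- margin_loss(l, lab, cfg)
    expect_gte(loss, 0)
    sat <- l[lab + 1] >= cfg$m_plus && all(l[-(lab + 1)] <= cfg$m_minus)
    expect_identical(loss == 0, sat)
  }
})

test_that("initialization is seeded and correctly shaped", {
  cfg <- capsnet_config()
  p1 <- init_params(cfg, 42)
  p2 <- init_params(cfg, 42)
  expect_identical(p1$tensors, p2$tensors)
  expect_false(identical(p1$tensors$W, init_params(cfg, 43)$tensors$W))
  expect_equal(dim(p1$tensors$W), c(16L, 8L, 3L, 1152L))
  expect_equal(dim(p1$tensors$conv1_w), c(81L, 256L))
  expect_equal(length(p1$tensors$conv1_w), 9L * 9L * 256L)
})

test_that("the forward pass yields bounded, deterministic class lengths", {
  cfg <- tiny_net_cfg()
  p <- init_params(cfg, 7)
  set.seed(21)
  img <- matrix(runif(784), 28, 28)
  out <- capsnet_forward(img, p)
  expect_length(out$lengths, 3L)
  expect_true(all(out$lengths >= 0 & out$lengths < 1))
  expect_true(out$predicted %in% 0:2)
  out2 <- capsnet_forward(img, p)
  expect_identical(out$lengths, out2$lengths)
  expect_error(capsnet_forward(matrix(0, 20, 20), p), "28 x 28")
})

test_that("checkpoints round-trip and reject mismatched shapes", {
  p <- init_params(tiny_net_cfg(), 3)
  f <- withr::local_tempfile()
  save_params(p, f)
  q <- load_params(f)
  expect_identical(q$tensors, p$tensors)
  bad <- p
  bad$tensors$W <- bad$tensors$W[, , , 1:10]
  save_params(bad, f)
  expect_error(load_params(f), "shapes")
})
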