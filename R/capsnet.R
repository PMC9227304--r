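#' Capsule-network configuration
#'
#' Architecture of the three-layer network: a plain convolution (Conv1, 9x9,
#' stride 1, ReLU), a convolutional capsule layer (9x9, stride 2) whose
#' channels are regrouped into capsule vectors, and one output capsule per
#' class coupled to every primary capsule by dynamic (agreement) routing.
#' With the default 28x28 input the Conv1 grid is 20x20, the primary grid is
#' 6x6, and 6*6*32 = 1152 primary capsules feed 3 class capsules.
#'
#' @param conv1_channels,conv1_kernel,conv1_stride Conv1 geometry
#'   (defaults 256, 9, 1).
#' @param primary_channels,primary_kernel,primary_stride primary capsule
#'   convolution geometry (defaults 256, 9, 2).
#' @param primary_caps_dim dimensionality of a primary capsule (default 8);
#'   `primary_channels` must be a multiple of it.
#' @param n_classes number of class capsules (default 3).
#' @param class_caps_dim dimensionality of a class capsule (default 16).
#' @param routing_iterations agreement-routing iterations (default 3).
#' @param m_plus,m_minus,lambda margin-loss constants (defaults 0.9, 0.1,
#'   0.5).
#' @param image_side input image side length (default 28).
#' @return object of class `capsnet_config` with derived fields
#'   `conv1_grid`, `primary_grid`, `primary_caps_types`, `n_primary_caps`.
#' @export
capsnet_config <- function(conv1_channels = 256L, conv1_kernel = 9L,
                           conv1_stride = 1L,
                           primary_channels = 256L, primary_kernel = 9L,
                           primary_stride = 2L, primary_caps_dim = 8L,
                           n_classes = 3L, class_caps_dim = 16L,
                           routing_iterations = 3L,
                           m_plus = 0.9, m_minus = 0.1, lambda = 0.5,
                           image_side = 28L) {
  cfg <- list(conv1_channels = as.integer(conv1_channels),
              conv1_kernel = as.integer(conv1_kernel),
              conv1_stride = as.integer(conv1_stride),
              primary_channels = as.integer(primary_channels),
              primary_kernel = as.integer(primary_kernel),
              primary_stride = as.integer(primary_stride),
              primary_caps_dim = as.integer(primary_caps_dim),
              n_classes = as.integer(n_classes),
              class_caps_dim = as.integer(class_caps_dim),
              routing_iterations = as.integer(routing_iterations),
              m_plus = m_plus, m_minus = m_minus, lambda = lambda,
              image_side = as.integer(image_side))
  if (cfg$routing_iterations < 1L) stop("routing_iterations must be >= 1")
  if (cfg$primary_channels %% cfg$primary_caps_dim != 0L)
    stop("primary_channels must be a multiple of primary_caps_dim")
  cfg$conv1_grid <- (cfg$image_side - cfg$conv1_kernel) %/% cfg$conv1_stride + 1L
  cfg$primary_grid <- (cfg$conv1_grid - cfg$primary_kernel) %/%
    cfg$primary_stride + 1L
  if (cfg$conv1_grid < 1L || cfg$primary_grid < 1L)
    stop("kernel/stride combination leaves no valid output positions")
  cfg$primary_caps_types <- cfg$primary_channels %/% cfg$primary_caps_dim
  cfg$n_primary_caps <- as.integer(cfg$primary_grid^2 *
                                     cfg$primary_caps_types)
  structure(cfg, class = "capsnet_config")
}

#' Initialize capsule-network parameters
#'
#' Seeded initialization: convolution weights are He-scaled normal draws
#' (sd = sqrt(2 / fan_in)), biases start at zero, and the per-pair
#' transformation matrices `W_ij` (one `class_caps_dim x primary_caps_dim`
#' matrix for every primary capsule i and class capsule j) are normal with
#' sd 0.1. The same seed always reproduces the same parameters bit for bit.
#'
#' @param cfg a [capsnet_config()].
#' @param seed integer RNG seed.
#' @return object of class `capsnet_params`: matrices `conv1_w`
#'   (`kernel^2*in_channels` x `out_channels`), `prim_w`, bias vectors, and
#'   `W` as an array of dim `c(class_caps_dim, primary_caps_dim, n_classes,
#'   n_primary_caps)`.
#' @export
init_params <- function(cfg, seed) {
  stopifnot(inherits(cfg, "capsnet_config"))
  with_preserved_seed(seed, {
    k1 <- cfg$conv1_kernel^2 * 1L
    k2 <- cfg$primary_kernel^2 * cfg$conv1_channels
    p <- list(
      conv1_w = matrix(rnorm(k1 * cfg$conv1_channels, sd = sqrt(2 / k1)),
                       k1, cfg$conv1_channels),
      conv1_b = numeric(cfg$conv1_channels),
      prim_w = matrix(rnorm(k2 * cfg$primary_channels, sd = sqrt(2 / k2)),
                      k2, cfg$primary_channels),
      prim_b = numeric(cfg$primary_channels),
      W = array(rnorm(cfg$class_caps_dim * cfg$primary_caps_dim *
                        cfg$n_classes * cfg$n_primary_caps, sd = 0.1),
                dim = c(cfg$class_caps_dim, cfg$primary_caps_dim,
                        cfg$n_classes, cfg$n_primary_caps)))
    structure(list(tensors = p, config = cfg, seed = as.integer(seed)),
              class = "capsnet_params")
  })
}

#' Capsule squashing nonlinearity
#'
#' `v = (||s||^2 / (1 + ||s||^2)) * s / ||s||`: the direction of `s` is kept
#' and its length is mapped monotonically into `[0, 1)`. The zero vector
#' maps to zero (continuity limit).
#'
#' @param s numeric vector.
#' @return squashed vector of the same length.
#' @export
squash <- function(s) {
  n2 <- sum(s * s)
  if (n2 == 0) return(s)
  (n2 / (1 + n2)) * s / sqrt(n2)
}

# Row-wise squash of a matrix (each row one capsule input).
squash_rows <- function(S) {
  n2 <- rowSums(S * S)
  f <- ifelse(n2 == 0, 0, n2 / ((1 + n2) * sqrt(pmax(n2, .Machine$double.xmin))))
  S * f
}

# VJP of squash_rows: rows of dv pulled back to rows of ds.
# d squash / ds = k(n) I + (k'(n)/n) s s^T with k(n) = n / (1 + n^2).
squash_rows_bwd <- function(dv, S) {
  n2 <- rowSums(S * S)
  n <- sqrt(n2)
  safe <- pmax(n, .Machine$double.xmin)
  kf <- n / (1 + n2)
  kp <- (1 - n2) / (1 + n2)^2
  dots <- rowSums(S * dv)
  dv * kf + S * (kp / safe * dots)
}

#' Prediction vectors from primary capsules
#'
#' Computes `u_hat[i, , j] = W[, , j, i] %*% u[i, ]` for every primary
#' capsule i and class capsule j.
#'
#' @param u matrix of primary capsule outputs, `n_primary_caps x
#'   primary_caps_dim` (rows already squashed).
#' @param W transformation array of dim `c(class_caps_dim,
#'   primary_caps_dim, n_classes, n_primary_caps)`.
#' @return array of dim `c(n_primary_caps, class_caps_dim, n_classes)`.
#' @export
predict_uhat <- function(u, W) {
  d <- dim(W)
  if (length(d) != 4L) stop("W must be a 4-d array (D, Dk, J, I)")
  D <- d[1L]; Dk <- d[2L]; J <- d[3L]; I <- d[4L]
  if (!is.matrix(u) || nrow(u) != I || ncol(u) != Dk)
    stop("u must be a ", I, " x ", Dk, " matrix to conform with W")
  row <- cpp_caps_fwd(matrix(as.vector(t(u)), nrow = 1L), as.vector(W),
                      I, J, D, Dk)
  array(row[1L, ], dim = c(I, D, J))
}

#' Dynamic (agreement) routing between capsule layers
#'
#' Full-link routing: every primary capsule routes to every class capsule.
#' Log-prior couplings `b` start at zero; each iteration computes coupling
#' coefficients `c` as the row-wise softmax of `b` over classes, the
#' weighted sums `s_j = sum_i c_ij u_hat[i, , j]`, the squashed outputs
#' `v_j`, and agreements `a_ij = v_j . u_hat[i, , j]` which are added to
#' `b`. After the final iteration `b` is not updated further and the last
#' `v` is returned.
#'
#' @param u_hat array of prediction vectors, dim `c(I, D, J)` as produced
#'   by [predict_uhat()].
#' @param iterations number of routing iterations (>= 1).
#' @param keep_history record per-iteration `(c, s, v)` (used for
#'   backpropagation through the unrolled loop).
#' @return object of class `routing_state` with fields `b`, `c`, `u_hat`,
#'   `s`, `v`, `a`, and `lengths` (the class capsule norms).
#' @export
dynamic_routing <- function(u_hat, iterations = 3L, keep_history = FALSE) {
  if (iterations < 1L) stop("iterations must be >= 1")
  if (!all(is.finite(u_hat))) stop("non-finite prediction vectors")
  dm <- dim(u_hat)
  I <- dm[1L]; D <- dm[2L]; J <- dm[3L]
  b <- matrix(0, I, J)
  cc <- s <- v <- a <- NULL
  history <- if (keep_history) vector("list", iterations) else NULL
  uj <- lapply(seq_len(J), function(j) matrix(u_hat[, , j], I, D))
  for (t in seq_len(iterations)) {
    cc <- softmax_rows(b)
    s <- matrix(0, J, D)
    for (j in seq_len(J)) s[j, ] <- crossprod(uj[[j]], cc[, j])
    v <- squash_rows(s)
    a <- matrix(0, I, J)
    for (j in seq_len(J)) a[, j] <- uj[[j]] %*% v[j, ]
    if (keep_history) history[[t]] <- list(c = cc, s = s, v = v)
    if (t < iterations) b <- b + a
  }
  structure(list(b = b, c = cc, u_hat = u_hat, s = s, v = v, a = a,
                 lengths = sqrt(rowSums(v * v)), history = history),
            class = "routing_state")
}

# Pull the gradient at the final class outputs v back through the unrolled
# routing loop (including the agreement updates of b), yielding d u_hat.
routing_backward <- function(u_hat, history, dv) {
  dm <- dim(u_hat)
  I <- dm[1L]; D <- dm[2L]; J <- dm[3L]
  T <- length(history)
  duhat <- vector("list", J)
  uj <- lapply(seq_len(J), function(j) matrix(u_hat[, , j], I, D))
  for (j in seq_len(J)) duhat[[j]] <- matrix(0, I, D)
  # gb accumulates d loss / d b_{t} across iterations: b_t feeds both the
  # next softmax and, by the additive update, every earlier b state.
  gb <- matrix(0, I, J)
  for (t in rev(seq_len(T))) {
    st <- history[[t]]
    ds <- squash_rows_bwd(dv, st$s)
    dc <- matrix(0, I, J)
    for (j in seq_len(J)) {
      dc[, j] <- uj[[j]] %*% ds[j, ]
      duhat[[j]] <- duhat[[j]] + tcrossprod(st$c[, j], ds[j, ])
    }
    gb <- gb + st$c * (dc - rowSums(st$c * dc))
    if (t > 1L) {
      # b_{t-1} = b_{t-2} + a_{t-1} with a_{t-1,ij} = v_{t-1,j} . u_hat_ij
      vp <- history[[t - 1L]]$v
      dv <- matrix(0, J, D)
      for (j in seq_len(J)) {
        dv[j, ] <- crossprod(uj[[j]], gb[, j])
        duhat[[j]] <- duhat[[j]] + tcrossprod(gb[, j], vp[j, ])
      }
    }
  }
  array(unlist(duhat), dim = dm)
}

# Permutation taking a primary-conv activation row (index pos + P*(channel))
# to the capsule row layout (index k + Dk*(pos + P*type), capsule
# components contiguous), where channel = k + Dk*type. Returns 1-based
# source indices for each destination position.
primary_perm <- function(cfg) {
  P <- cfg$primary_grid^2
  Dk <- cfg$primary_caps_dim
  ty <- cfg$primary_caps_types
  g <- expand.grid(k = 0:(Dk - 1L), pos = 0:(P - 1L), type = 0:(ty - 1L))
  as.integer(g$pos + P * (g$k + Dk * g$type)) + 1L
}

# Batched forward pass. X: B x image_side^2 matrix (images in R column-major
# pixel order). Returns activations needed for the backward pass when
# keep = TRUE.
caps_forward <- function(X, params, keep = FALSE) {
  cfg <- params$config
  p <- params$tensors
  side <- cfg$image_side
  B <- nrow(X)
  h1 <- cpp_conv2d_fwd(X, p$conv1_w, p$conv1_b, side, side, 1L,
                       cfg$conv1_kernel, cfg$conv1_stride)
  r1 <- h1 * (h1 > 0)
  h2 <- cpp_conv2d_fwd(r1, p$prim_w, p$prim_b, cfg$conv1_grid,
                       cfg$conv1_grid, cfg$conv1_channels,
                       cfg$primary_kernel, cfg$primary_stride)
  perm <- primary_perm(cfg)
  u_raw <- h2[, perm, drop = FALSE]
  I <- cfg$n_primary_caps
  Dk <- cfg$primary_caps_dim
  D <- cfg$class_caps_dim
  J <- cfg$n_classes
  # capsule-wise squash, vectorized over the batch
  u2 <- u_raw * u_raw
  n2 <- colSums(aperm(array(u2, c(B, Dk, I)), c(2L, 1L, 3L)))  # B x I
  if (B == 1L) n2 <- matrix(n2, 1L, I)
  f <- ifelse(n2 == 0, 0,
              n2 / ((1 + n2) * sqrt(pmax(n2, .Machine$double.xmin))))
  u_sq <- u_raw * f[, rep(seq_len(I), each = Dk), drop = FALSE]
  uhat_all <- cpp_caps_fwd(u_sq, as.vector(p$W), I, J, D, Dk)
  lengths <- matrix(0, B, J)
  routes <- vector("list", B)
  for (b in seq_len(B)) {
    rs <- dynamic_routing(array(uhat_all[b, ], c(I, D, J)),
                          iterations = cfg$routing_iterations,
                          keep_history = keep)
    lengths[b, ] <- rs$lengths
    routes[[b]] <- if (keep) rs else list(v = rs$v)
  }
  out <- list(lengths = lengths, routes = routes)
  if (keep)
    out <- c(out, list(X = X, h1 = h1, r1 = r1, u_raw = u_raw, n2 = n2,
                       u_sq = u_sq, uhat_all = uhat_all, perm = perm))
  out
}

# Batched backward pass from d loss / d lengths. Returns gradients for every
# parameter tensor.
caps_backward <- function(fw, params, dlengths) {
  cfg <- params$config
  p <- params$tensors
  B <- nrow(fw$lengths)
  I <- cfg$n_primary_caps
  Dk <- cfg$primary_caps_dim
  D <- cfg$class_caps_dim
  J <- cfg$n_classes
  duhat_all <- matrix(0, B, I * D * J)
  for (b in seq_len(B)) {
    rs <- fw$routes[[b]]
    len <- pmax(rs$lengths, .Machine$double.xmin)
    dv <- rs$v * (dlengths[b, ] / len)
    uh <- array(fw$uhat_all[b, ], c(I, D, J))
    duhat_all[b, ] <- as.vector(routing_backward(uh, rs$history, dv))
  }
  cb <- cpp_caps_bwd(fw$u_sq, as.vector(p$W), duhat_all, I, J, D, Dk)
  dW <- array(cb$dW, dim = dim(p$W))
  # back through the primary-capsule squash
  du_sq <- cb$du
  n2 <- fw$n2
  n <- sqrt(n2)
  safe <- pmax(n, .Machine$double.xmin)
  kf <- n / (1 + n2)
  kp <- (1 - n2) / (1 + n2)^2
  dots <- colSums(aperm(array(fw$u_raw * du_sq, c(B, Dk, I)), c(2L, 1L, 3L)))
  if (B == 1L) dots <- matrix(dots, 1L, I)
  expand <- function(m) m[, rep(seq_len(I), each = Dk), drop = FALSE]
  du_raw <- du_sq * expand(kf) + fw$u_raw * expand(kp / safe * dots)
  dh2 <- matrix(0, B, ncol(du_raw))
  dh2[, fw$perm] <- du_raw
  side <- cfg$image_side
  g2 <- cpp_conv2d_bwd(fw$r1, p$prim_w, dh2, cfg$conv1_grid, cfg$conv1_grid,
                       cfg$conv1_channels, cfg$primary_kernel,
                       cfg$primary_stride)
  dh1 <- g2$dx * (fw$h1 > 0)
  g1 <- cpp_conv2d_bwd(fw$X, p$conv1_w, dh1, side, side, 1L,
                       cfg$conv1_kernel, cfg$conv1_stride)
  list(conv1_w = g1$dw, conv1_b = as.numeric(g1$db),
       prim_w = g2$dw, prim_b = as.numeric(g2$db), W = dW)
}

#' Forward pass of the capsule network on one image
#'
#' Conv1 (valid convolution, ReLU) -> primary capsule convolution ->
#' capsule regrouping and squash -> prediction vectors -> dynamic routing.
#' The length of each class capsule's output vector is the network's
#' evidence that the image belongs to that class; the predicted class is
#' the one with the longest vector.
#'
#' @param image a `sample_image` (or bare matrix of the configured side).
#' @param params a [init_params()] result (or loaded checkpoint).
#' @return list with `lengths` (one value per class, each in `[0, 1)`),
#'   `predicted` (0-based class), and `routing` (the final
#'   [dynamic_routing()] state).
#' @export
capsnet_forward <- function(image, params) {
  cfg <- params$config
  px <- if (inherits(image, "sample_image")) image$pixels else image
  if (!is.matrix(px) || any(dim(px) != cfg$image_side))
    stop("image must be ", cfg$image_side, " x ", cfg$image_side)
  fw <- caps_forward(matrix(as.vector(px), nrow = 1L), params, keep = TRUE)
  rs <- fw$routes[[1L]]
  list(lengths = as.numeric(fw$lengths[1L, ]),
       predicted = which.max(fw$lengths[1L, ]) - 1L,
       routing = rs)
}

#' Margin loss on class-capsule lengths
#'
#' Separation margin loss
#' `sum_j T_j max(0, m+ - l_j)^2 + lambda (1 - T_j) max(0, l_j - m-)^2`
#' with `T_j = 1` for the true class: zero exactly when the true class
#' length reaches `m_plus` and every other length is at most `m_minus`.
#'
#' @param lengths numeric vector of class capsule lengths in `[0, 1]`.
#' @param label true class, 0-based, in `{0, ..., n_classes - 1}`.
#' @param cfg a [capsnet_config()] supplying `m_plus`, `m_minus`, `lambda`.
#' @return non-negative scalar loss.
#' @export
margin_loss <- function(lengths, label, cfg = capsnet_config()) {
  J <- length(lengths)
  if (!is.numeric(label) || length(label) != 1L || is.na(label) ||
      label < 0 || label > J - 1 || label != round(label))
    stop("label must be an integer class in {0, ..., ", J - 1, "}")
  Tj <- as.numeric(seq_len(J) - 1L == label)
  sum(Tj * pmax(0, cfg$m_plus - lengths)^2 +
        cfg$lambda * (1 - Tj) * pmax(0, lengths - cfg$m_minus)^2)
}

# Batch margin loss and its gradient wrt lengths. labels 0-based.
margin_loss_batch <- function(lengths, labels, cfg) {
  B <- nrow(lengths)
  J <- ncol(lengths)
  Tj <- matrix(0, B, J)
  Tj[cbind(seq_len(B), labels + 1L)] <- 1
  pos <- pmax(0, cfg$m_plus - lengths)
  neg <- pmax(0, lengths - cfg$m_minus)
  loss <- rowSums(Tj * pos^2 + cfg$lambda * (1 - Tj) * neg^2)
  dl <- -2 * Tj * pos + 2 * cfg$lambda * (1 - Tj) * neg
  list(loss = loss, dlengths = dl)
}

#' Save network parameters to a checkpoint file
#'
#' Single archive holding every tensor plus the configuration and
#' initialization seed.
#'
#' @param params a `capsnet_params`.
#' @param path destination file.
#' @export
save_params <- function(params, path) {
  stopifnot(inherits(params, "capsnet_params"))
  saveRDS(params, path)
  invisible(path)
}

#' Load a parameter checkpoint
#'
#' Shapes are re-derived from the stored configuration and the load is
#' rejected on any mismatch.
#'
#' @param path checkpoint file written by [save_params()].
#' @return a `capsnet_params`.
#' @export
load_params <- function(path) {
  params <- readRDS(path)
  if (!inherits(params, "capsnet_params"))
    stop("'", path, "' is not a capsule-network checkpoint")
  cfg <- params$config
  p <- params$tensors
  k1 <- as.integer(cfg$conv1_kernel^2)
  k2 <- as.integer(cfg$primary_kernel^2 * cfg$conv1_channels)
  ok <- identical(dim(p$conv1_w), c(k1, cfg$conv1_channels)) &&
    length(p$conv1_b) == cfg$conv1_channels &&
    identical(dim(p$prim_w), c(k2, cfg$primary_channels)) &&
    length(p$prim_b) == cfg$primary_channels &&
    identical(dim(p$W), c(cfg$class_caps_dim, cfg$primary_caps_dim,
                          cfg$n_classes, cfg$n_primary_caps))
  if (!ok) stop("checkpoint tensor shapes do not match its configuration")
  params
}
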