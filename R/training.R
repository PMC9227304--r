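#' Stratified split specification
#'
#' @param per_variety_test test samples drawn per variety (default 8).
#' @param seed RNG seed for the draw.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(per_variety_test = 8L, seed = 1L) {
  if (per_variety_test < 1L) stop("per_variety_test must be positive")
  structure(list(per_variety_test = as.integer(per_variety_test),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Training schedule configuration
#'
#' The reference protocol trains for 160 epochs with early stopping simply
#' realized as the configured epoch budget; the optimizer is Adam.
#'
#' @param epochs training epochs (default 160).
#' @param batch_size minibatch size (default 16).
#' @param learning_rate Adam step size (default 1e-3).
#' @param optimizer_seed seed for initialization and shuffling (default 1).
#' @param eval_every evaluate train/test accuracy every this many epochs
#'   (default 1).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 160L, batch_size = 16L,
                         learning_rate = 1e-3, optimizer_seed = 1L,
                         eval_every = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 optimizer_seed = as.integer(optimizer_seed),
                 eval_every = as.integer(eval_every)),
            class = "train_config")
}

#' Screen abnormal sample images
#'
#' Optional robust outlier filter: within each variety, an image whose total
#' pixel intensity lies more than `z_threshold` robust standard deviations
#' (median/MAD) from the variety median is rejected. Disabled by default;
#' when a variety has zero spread all its images are kept.
#'
#' @param images list of `sample_image` objects.
#' @param enabled logical (default FALSE).
#' @param z_threshold robust z cutoff (default 3).
#' @return list with `retained` (images) and `rejected_ids` (character).
#' @export
screen_outliers <- function(images, enabled = FALSE, z_threshold = 3) {
  if (!enabled) return(list(retained = images, rejected_ids = character(0)))
  totals <- vapply(images, function(im) sum(im$pixels), numeric(1))
  varieties <- vapply(images, function(im) im$variety, character(1))
  keep <- rep(TRUE, length(images))
  for (v in unique(varieties)) {
    idx <- which(varieties == v)
    if (length(idx) < 2L)
      stop("variety '", v, "' has fewer than 2 images; cannot screen")
    med <- stats::median(totals[idx])
    s <- stats::mad(totals[idx])
    dev <- abs(totals[idx] - med)
    if (s == 0) {
      # zero robust spread: any deviating image is arbitrarily many robust
      # standard deviations out; identical images are all kept
      keep[idx[dev > 1e-8 * max(1, abs(med))]] <- FALSE
    } else {
      keep[idx[dev / s > z_threshold]] <- FALSE
    }
  }
  list(retained = images[keep],
       rejected_ids = vapply(images[!keep], function(im) im$sample_id,
                             character(1)))
}

#' Stratified train/test split by variety
#'
#' For every variety, exactly `per_variety_test` images are drawn uniformly
#' at random (seeded) into the test set; the remainder train. With the
#' reference per-variety counts (32, 34, 32, 34, 34, 34, 33) and 8 test
#' samples per variety this gives the 177/56 partition of 233 samples.
#'
#' @param images list of `sample_image` objects carrying `variety`.
#' @param spec a [split_spec()].
#' @return list with `train` and `test` lists of images.
#' @export
split_dataset <- function(images, spec = split_spec()) {
  varieties <- vapply(images, function(im) im$variety, character(1))
  test_idx <- integer(0)
  with_preserved_seed(spec$seed, {
    for (v in sort(unique(varieties))) {
      idx <- which(varieties == v)
      if (length(idx) <= spec$per_variety_test)
        stop("variety '", v, "' has only ", length(idx),
             " samples; cannot reserve ", spec$per_variety_test,
             " for the test set")
      test_idx <- c(test_idx, sample(idx, spec$per_variety_test))
    }
  })
  list(train = images[-test_idx], test = images[sort(test_idx)])
}

images_to_matrix <- function(images) {
  t(vapply(images, function(im) as.vector(im$pixels),
           numeric(length(images[[1L]]$pixels))))
}

image_labels <- function(images) {
  vapply(images, function(im) im$label, integer(1))
}

adam_init <- function(tensors) {
  list(m = lapply(tensors, function(x) x * 0),
       v = lapply(tensors, function(x) x * 0), t = 0L)
}

adam_step <- function(tensors, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  corr1 <- 1 - beta1^st$t
  corr2 <- 1 - beta2^st$t
  for (nm in names(tensors)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    tensors[[nm]] <- tensors[[nm]] -
      lr * (st$m[[nm]] / corr1) / (sqrt(st$v[[nm]] / corr2) + eps)
  }
  list(tensors = tensors, state = st)
}

#' Train the capsule network
#'
#' Minimizes the mean margin loss by Adam over minibatches for the
#' configured number of epochs, recording mean training loss and (every
#' `eval_every` epochs) training and test accuracy. Fully reproducible
#' given the seeds.
#'
#' @param train_images,test_images lists of labeled `sample_image` objects
#'   (disjoint).
#' @param net_cfg a [capsnet_config()].
#' @param tr_cfg a [train_config()].
#' @param seed overrides `tr_cfg$optimizer_seed` when given.
#' @param verbose print per-epoch progress (accuracies rounded to integer
#'   percent, matching the usual reporting style; stored values keep full
#'   precision).
#' @return object of class `train_report`: `report` data frame with one row
#'   per epoch (`epoch`, `loss`, `train_acc`, `test_acc`), `params`, and
#'   `best_test_epoch` / `best_test_acc`.
#' @export
train_capsnet <- function(train_images, test_images,
                          net_cfg = capsnet_config(),
                          tr_cfg = train_config(),
                          seed = NULL, verbose = FALSE) {
  if (length(train_images) == 0L) stop("empty training set")
  seed <- as.integer(seed %||% tr_cfg$optimizer_seed)
  ids_tr <- vapply(train_images, function(im) im$sample_id, character(1))
  ids_te <- vapply(test_images, function(im) im$sample_id, character(1))
  if (length(intersect(ids_tr, ids_te)) > 0L)
    stop("train and test sets share sample ids")
  params <- init_params(net_cfg, derive_seed(seed, 1L))
  Xtr <- images_to_matrix(train_images)
  ytr <- image_labels(train_images)
  Xte <- if (length(test_images)) images_to_matrix(test_images) else NULL
  yte <- if (length(test_images)) image_labels(test_images) else NULL
  n <- nrow(Xtr)
  bs <- min(tr_cfg$batch_size, n)
  opt <- adam_init(params$tensors)
  report <- data.frame(epoch = seq_len(tr_cfg$epochs), loss = NA_real_,
                       train_acc = NA_real_, test_acc = NA_real_)
  with_preserved_seed(derive_seed(seed, 2L), {
    for (ep in seq_len(tr_cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = bs)) {
        take <- ord[start:min(start + bs - 1L, n)]
        fw <- caps_forward(Xtr[take, , drop = FALSE], params, keep = TRUE)
        ml <- margin_loss_batch(fw$lengths, ytr[take], net_cfg)
        losses <- c(losses, mean(ml$loss))
        grads <- caps_backward(fw, params, ml$dlengths / length(take))
        upd <- adam_step(params$tensors, grads, opt, tr_cfg$learning_rate)
        params$tensors <- upd$tensors
        opt <- upd$state
      }
      report$loss[ep] <- mean(losses)
      if (ep %% tr_cfg$eval_every == 0L || ep == tr_cfg$epochs) {
        report$train_acc[ep] <- accuracy_of(params, Xtr, ytr)
        if (!is.null(Xte)) report$test_acc[ep] <- accuracy_of(params, Xte, yte)
        if (verbose)
          message(sprintf("epoch %3d  loss %.4f  train %d%%  test %s%%",
                          ep, report$loss[ep], round(report$train_acc[ep]),
                          if (is.null(Xte)) "-"
                          else round(report$test_acc[ep])))
      }
    }
  })
  best <- if (all(is.na(report$test_acc))) NA_integer_
          else which.max(report$test_acc)
  structure(list(report = report, params = params,
                 best_test_epoch = best,
                 best_test_acc = if (is.na(best)) NA_real_
                                 else report$test_acc[best]),
            class = "train_report")
}

predict_classes <- function(params, X, chunk = 64L) {
  n <- nrow(X)
  pred <- integer(n)
  for (start in seq(1L, n, by = chunk)) {
    take <- start:min(start + chunk - 1L, n)
    fw <- caps_forward(X[take, , drop = FALSE], params, keep = FALSE)
    pred[take] <- max.col(fw$lengths, ties.method = "first") - 1L
  }
  pred
}

accuracy_of <- function(params, X, y) {
  100 * mean(predict_classes(params, X) == y)
}

#' Evaluate a trained network on a labeled image set
#'
#' @param params a `capsnet_params`.
#' @param images non-empty list of labeled `sample_image` objects.
#' @return list with `accuracy` (percent), `confusion` (rows = true class,
#'   columns = predicted) and `n`.
#' @export
evaluate <- function(params, images) {
  if (length(images) == 0L) stop("cannot evaluate on an empty dataset")
  X <- images_to_matrix(images)
  y <- image_labels(images)
  pred <- predict_classes(params, X)
  J <- params$config$n_classes
  cm <- table(factor(y, levels = 0:(J - 1L)),
              factor(pred, levels = 0:(J - 1L)))
  list(accuracy = 100 * mean(pred == y),
       confusion = unclass(as.matrix(cm)),
       n = length(y))
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report> %d epochs; final loss %.4f; best test accuracy %s%% at epoch %s\n",
              nrow(x$report), x$report$loss[nrow(x$report)],
              format(round(x$best_test_acc, 2)), format(x$best_test_epoch)))
  invisible(x)
}
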