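#' Training configuration
#'
#' Defaults follow the reference training recipe: AdamW with initial
#' learning rate 2e-4 and weight decay 1e-4, cosine-annealed learning rate
#' (floor 0), 224x224 inputs, batch size 16, an 8:2 stratified
#' train/validation split, and channel normalization by the dataset-level
#' mean/std triples (see [pi_norm_stats()]).  The epoch count is
#' configurable (default 100).
#'
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param lr initial learning rate.
#' @param lr_floor terminal learning rate of the cosine schedule.
#' @param weight_decay decoupled AdamW weight decay.
#' @param image_size input side length (divisible by 32).
#' @param split_ratio training fraction of the stratified split, in (0, 1).
#' @param seed integer seed fixing shuffling (and any upstream split).
#' @param norm_mean,norm_std RGB normalization triples.
#' @return A list of class `wfpn_train_cfg`.
#' @export
train_config <- function(epochs = 100L, batch_size = 16L, lr = 2e-4,
                         lr_floor = 0, weight_decay = 1e-4,
                         image_size = 224L, split_ratio = 0.8, seed = 42L,
                         norm_mean = pi_norm_stats()$mean,
                         norm_std = pi_norm_stats()$std) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, lr_floor >= 0,
            weight_decay >= 0, image_size %% 32L == 0L,
            split_ratio > 0, split_ratio < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, lr_floor = lr_floor, weight_decay = weight_decay,
                 image_size = as.integer(image_size),
                 split_ratio = split_ratio, seed = as.integer(seed),
                 norm_mean = norm_mean, norm_std = norm_std),
            class = "wfpn_train_cfg")
}

#' Seed-fixed stratified train/validation split
#'
#' Per class `c` with `n_c` items, the validation set receives
#' `floor((1 - ratio) * n_c)` items and training the rest; assignment
#' within a class is a seeded random permutation.  The split is disjoint
#' and exhaustive, and the same seed always reproduces it.
#'
#' @param labels vector of class labels (any type; every class non-empty).
#' @param ratio training fraction in (0, 1), default 0.8.
#' @param seed integer seed.
#' @return A list of class `wfpn_split`: integer index vectors `train` and
#'   `validation`, plus a per-class `sizes` tibble.
#' @examples
#' s <- stratified_split(rep(1:4, c(385, 523, 318, 293)), 0.8, seed = 1)
#' s$sizes  # per-stage 308/77, 419/104, 255/63, 235/58
#' @export
stratified_split <- function(labels, ratio = 0.8, seed = 1L) {
  stopifnot(length(labels) > 0L, ratio > 0, ratio < 1)
  classes <- sort(unique(labels))
  train <- integer(0); val <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (cls in classes) {
      idx <- which(labels == cls)
      if (length(idx) == 0L) stop("empty class: ", cls)
      n_val <- floor((1 - ratio) * length(idx) + 1e-9)
      perm <- sample(idx)
      val <- c(val, perm[seq_len(n_val)])
      train <- c(train, perm[setdiff(seq_along(perm), seq_len(n_val))])
    }
  })
  sizes <- tibble::tibble(
    class = as.character(classes),
    total = vapply(seq_along(classes),
                   function(i) sum(labels == classes[i]), numeric(1))
  )
  sizes$validation <- floor((1 - ratio) * sizes$total + 1e-9)
  sizes$train <- sizes$total - sizes$validation
  structure(list(train = sort(train), validation = sort(val), sizes = sizes),
            class = "wfpn_split")
}

#' @export
print.wfpn_split <- function(x, ...) {
  cat("Stratified split:", length(x$train), "train /",
      length(x$validation), "validation\n")
  print(x$sizes)
  invisible(x)
}

batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

#' Train a weighted feature pyramid model
#'
#' Runs the training loop: shuffled minibatches, cross-entropy on the
#' ensembled prediction, AdamW updates with a cosine-annealed learning
#' rate, and a per-epoch log of learning rate, loss, and train/validation
#' accuracy.  The parameter snapshot with the best validation accuracy is
#' kept (best-by-validation checkpoint); when no validation set is given
#' the best training accuracy is tracked instead.  Inputs are normalized
#' with the config triples before entering the network.  A non-finite loss
#' aborts with diagnostics.
#'
#' @param model a [wfpn_model()].
#' @param x training images, `S x S x 3 x N` array in `[0, 1]`.
#' @param y integer class labels in `1..K`.
#' @param config a [train_config()].
#' @param x_val,y_val optional validation set, same conventions.
#' @param verbose print one line per epoch.
#' @return A `wfpn_fit`: list with the trained `model`, `log` tibble
#'   (epoch, lr, loss, train_acc, val_acc), `best` (epoch, metric,
#'   parameter snapshot) and the `config`.
#' @export
wfpn_train <- function(model, x, y, config = train_config(),
                       x_val = NULL, y_val = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "wfpn_model"), inherits(config, "wfpn_train_cfg"))
  n <- dim(x)[4]
  stopifnot(length(y) == n, all(y >= 1L),
            all(y <= model$config$num_classes))
  if (!is.null(x_val) && dim(x_val)[4] == 0L) {
    x_val <- NULL
    y_val <- NULL
  }
  xn <- normalize_images(x, config$norm_mean, config$norm_std)
  xv <- if (!is.null(x_val)) {
    normalize_images(x_val, config$norm_mean, config$norm_std)
  }
  params <- model$params
  opt <- adamw_state(params, weight_decay = config$weight_decay)
  log <- vector("list", config$epochs)
  best <- list(metric = -Inf, epoch = 0L, state = NULL)
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- cosine_lr(epoch, config$epochs, config$lr, config$lr_floor)
      perm <- sample(n)
      losses <- numeric(0)
      correct <- 0L
      for (b in batch_indices(n, config$batch_size)) {
        idx <- perm[b]
        xb <- ag_input(xn[, , , idx, drop = FALSE])
        out <- wfpn_forward(model, xb, training = TRUE)
        loss <- ag_cross_entropy(out$pred, y[idx])
        if (!is.finite(loss$value)) {
          stop("non-finite loss at epoch ", epoch, " (lr ", signif(lr, 4),
               ", batch of ", length(idx), "); last finite losses: ",
               paste(signif(utils::tail(losses, 3), 4), collapse = ", "))
        }
        ag_zero_grad(params)
        ag_backward(loss)
        opt <- adamw_step(opt, params, lr)
        losses <- c(losses, loss$value)
        correct <- correct + sum(apply(node_value(out$pred), 2L,
                                       which.max) == y[idx])
      }
      train_acc <- correct / n
      val_acc <- NA_real_
      if (!is.null(xv)) {
        val_acc <- mean(apply(wfpn_forward(model, xv)$pred, 2L,
                              which.max) == y_val)
      }
      metric <- if (is.na(val_acc)) train_acc else val_acc
      if (metric > best$metric) {
        best <- list(metric = metric, epoch = epoch,
                     state = model_state(model))
      }
      log[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                     loss = mean(losses),
                                     train_acc = train_acc,
                                     val_acc = val_acc)
      if (verbose) {
        cat(sprintf("epoch %3d  lr %.6g  loss %.4f  train %.3f  val %s\n",
                    epoch, lr, mean(losses), train_acc,
                    ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
      }
    }
  })
  structure(list(model = model, log = dplyr::bind_rows(log), best = best,
                 config = config),
            class = "wfpn_fit")
}

#' @export
print.wfpn_fit <- function(x, ...) {
  last <- utils::tail(x$log, 1)
  cat(sprintf("<wfpn_fit> %d epochs | final loss %.4f | best %s accuracy %.3f (epoch %d)\n",
              nrow(x$log), last$loss,
              ifelse(all(is.na(x$log$val_acc)), "train", "validation"),
              x$best$metric, x$best$epoch))
  invisible(x)
}

#' Restore the best-by-validation parameter snapshot into the model
#'
#' @param fit a [wfpn_train()] result.
#' @return The fit's model with the checkpointed parameters, invisibly.
#' @export
wfpn_restore_best <- function(fit) {
  stopifnot(inherits(fit, "wfpn_fit"))
  if (!is.null(fit$best$state)) {
    set_model_state(fit$model, fit$best$state)
  }
  invisible(fit$model)
}

#' Evaluate a model on labelled data
#'
#' Scores every image (deterministic: the forward pass has no stochastic
#' components), assembles the prediction records and computes the full
#' metric report.  Optionally writes all artifacts (prediction CSV, metric
#' JSON, confusion and ROC CSVs) to a directory.
#'
#' @param model a (trained) [wfpn_model()].
#' @param x images, `S x S x 3 x N` array in `[0, 1]`.
#' @param y integer true labels in `1..K`.
#' @param config a [train_config()] supplying the normalization triples.
#' @param paths optional per-image identifiers for the prediction records.
#' @param out_dir optional directory for the written artifacts.
#' @return A `wfpn_eval`: list with `predictions` (tibble: path, truth,
#'   pred, per-class scores) and `report` (a [metric_report()]).
#' @export
wfpn_evaluate <- function(model, x, y, config = train_config(),
                          paths = NULL, out_dir = NULL) {
  stopifnot(inherits(model, "wfpn_model"))
  n <- dim(x)[4]
  if (n == 0L) stop("empty evaluation set")
  if (max(y) > model$config$num_classes) {
    stop("data contain class ", max(y), " but the model has ",
         model$config$num_classes, " classes")
  }
  xn <- normalize_images(x, config$norm_mean, config$norm_std)
  scores <- wfpn_scores(model, xn)
  predictions <- dplyr::bind_cols(
    tibble::tibble(path = paths %||% sprintf("image_%04d", seq_len(n)),
                   truth = as.integer(y)),
    scores
  )
  report <- metric_report(predictions, truth, pred,
                          k = model$config$num_classes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(predictions, file.path(out_dir, "predictions.csv"),
                     progress = FALSE)
    write_metrics(report, out_dir)
  }
  structure(list(predictions = predictions, report = report),
            class = "wfpn_eval")
}

#' @export
print.wfpn_eval <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Predict classes for new images
#'
#' @param model a trained [wfpn_model()].
#' @param x an image file, a directory of images, or an `S x S x 3 x N`
#'   array in `[0, 1]`.
#' @param config a [train_config()] supplying image size and normalization.
#' @return A tibble: path (when reading files), predicted class index and
#'   name, and the per-class scores.
#' @export
wfpn_predict <- function(model, x, config = train_config()) {
  paths <- NULL
  if (is.character(x)) {
    files <- if (dir.exists(x)) {
      sort(list.files(x, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                      full.names = TRUE, recursive = TRUE))
    } else x
    if (length(files) == 0L) stop("no images found at ", x)
    s <- config$image_size
    arr <- array(0, c(s, s, 3L, length(files)))
    for (i in seq_along(files)) {
      arr[, , , i] <- resize_bilinear(read_image(files[i]), s, s)
    }
    paths <- files
    x <- arr
  }
  xn <- normalize_images(x, config$norm_mean, config$norm_std)
  out <- wfpn_scores(model, xn)
  out <- dplyr::mutate(out, class = paste0("stage", .data$pred),
                       .after = "pred")
  if (!is.null(paths)) out <- dplyr::mutate(out, path = paths, .before = 1L)
  out
}
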