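#' Surrogate model configuration
#'
#' Architecture and training settings of the multi-output feed-forward
#' surrogate: three hidden layers of 128/64/32 units (ReLU), a 4-unit
#' linear output, Adam at learning rate 0.001 on MSE loss, minibatches of
#' 32, 150 epochs, and an 80/20 train/test split.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param activation Hidden activation, `"relu"` or `"tanh"`.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param weight_decay L2 penalty coefficient on the weights (the
#'   conventional small default of standard MLP implementations; stabilizes
#'   late training near interpolation).
#' @param train_fraction Fraction of rows assigned to training by
#'   [split_dataset()].
#' @param seed Integer seed driving weight initialization and shuffling.
#' @return A `surrogate_config` list.
#' @export
surrogate_config <- function(hidden_sizes = c(128, 64, 32),
                             activation = c("relu", "tanh"),
                             learning_rate = 0.001, epochs = 150,
                             batch_size = 32, weight_decay = 1e-4,
                             train_fraction = 0.8, seed = 42L) {
  activation <- match.arg(activation)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie in (0, 1)", class = "tpmsdesign_config_error")
  }
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1,
            all(hidden_sizes >= 1), weight_decay >= 0)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 activation = activation, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "surrogate_config")
}

#' Split a dataset into training and test partitions
#'
#' Disjoint, exhaustive random split: the training set receives
#' `floor(n * train_fraction)` rows; shuffling is driven only by `seed`.
#'
#' @param dataset Non-empty tibble.
#' @param train_fraction Fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles.
#' @examples
#' # 3024 rows at 0.8 -> 2419 train / 605 test
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, seed = 42L) {
  n <- nrow(dataset)
  stopifnot(n > 0)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie in (0, 1)", class = "tpmsdesign_config_error")
  }
  idx <- with_seed(seed, sample.int(n))
  n_train <- floor(n * train_fraction)
  list(train = dataset[sort(idx[seq_len(n_train)]), ],
       test = dataset[sort(idx[seq.int(n_train + 1L, n)]), ])
}

DEFAULT_TARGETS <- c("relative_density", "sa_vr", "ultimate_stress",
                     "energy_absorption")

relu <- function(x) pmax(x, 0)

mlp_forward_layers <- function(W, b, X, activation) {
  act <- if (activation == "relu") relu else tanh
  L <- length(W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% W[[l]]
    Z <- sweep(Z, 2, b[[l]], "+")
    A[[l + 1]] <- if (l < L) act(Z) else Z
  }
  A
}

mlp_predict_scaled <- function(model, X) {
  A <- mlp_forward_layers(model$W, model$b, X, model$config$activation)
  A[[length(A)]]
}

#' Fit the feed-forward surrogate
#'
#' Trains a multi-layer perceptron mapping encoded design features (seven
#' z-scored numerics plus the surface-type one-hot) to the four targets
#' (relative density, SA/VR, ultimate stress, energy absorption). Targets
#' are z-scored internally so the MSE loss weights outputs of different
#' magnitudes comparably, and predictions are returned in natural units.
#' Weight initialization (Glorot uniform), minibatch shuffling and hence
#' the entire loss history are deterministic functions of `config$seed`.
#'
#' @param train Training tibble: design columns plus the target columns.
#' @param config A [surrogate_config()].
#' @param validation Optional tibble scored each epoch with the training
#'   target scaling (held-out loss curve).
#' @param targets Character vector of target column names.
#' @param scaler Optional pre-fitted [fit_feature_scaler()]; fitted on
#'   `train` when omitted.
#' @return A fitted `tpms_surrogate` with weights, scalers and the
#'   per-epoch loss history.
#' @export
fit_surrogate <- function(train, config = surrogate_config(),
                          validation = NULL, targets = DEFAULT_TARGETS,
                          scaler = NULL) {
  enc <- encode_features(train, scaler)
  X <- enc$features
  Y <- as.matrix(train[targets])
  if (!all(is.finite(Y))) {
    abort("non-finite target values", class = "tpmsdesign_fit_error")
  }
  t_mu <- colMeans(Y)
  t_sd <- apply(Y, 2, stats::sd)
  t_sd[t_sd == 0] <- 1
  Yz <- sweep(sweep(Y, 2, t_mu), 2, t_sd, "/")

  Xv <- Yv <- NULL
  if (!is.null(validation)) {
    Xv <- encode_features(validation, enc$scaler)$features
    Yv <- sweep(sweep(as.matrix(validation[targets]), 2, t_mu), 2, t_sd, "/")
  }

  sizes <- c(ncol(X), config$hidden_sizes, length(targets))
  L <- length(sizes) - 1L
  n <- nrow(X)
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8

  fitted <- with_seed(config$seed, {
    W <- b <- mW <- vW <- mb <- vb <- vector("list", L)
    for (l in seq_len(L)) {
      # Glorot-uniform initialization (the Keras default)
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -lim, lim),
                       sizes[l], sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
      mW[[l]] <- vW[[l]] <- matrix(0, sizes[l], sizes[l + 1])
      mb[[l]] <- vb[[l]] <- numeric(sizes[l + 1])
    }
    history <- tibble(epoch = integer(), train_loss = numeric(),
                      validation_loss = numeric())
    step <- 0L
    act <- config$activation
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        rows <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- X[rows, , drop = FALSE]
        Yb <- Yz[rows, , drop = FALSE]
        A <- mlp_forward_layers(W, b, Xb, act)
        delta <- 2 * (A[[L + 1]] - Yb) / length(Yb)
        step <- step + 1L
        wd <- config$weight_decay %||% 0
        for (l in rev(seq_len(L))) {
          gW <- crossprod(A[[l]], delta)
          if (wd > 0) gW <- gW + wd * W[[l]] / nrow(Xb)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- delta %*% t(W[[l]])
            delta <- if (act == "relu") delta * (A[[l]] > 0) else delta * (1 - A[[l]]^2)
          }
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
          vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
          c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
          W[[l]] <- W[[l]] - lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + adam_eps)
          b[[l]] <- b[[l]] - lr * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + adam_eps)
        }
      }
      A_full <- mlp_forward_layers(W, b, X, act)
      train_loss <- mean((A_full[[L + 1]] - Yz)^2)
      if (!is.finite(train_loss)) {
        abort(sprintf(paste0("training diverged (non-finite loss at epoch %d); ",
                             "learning_rate = %g, target sd range [%.3g, %.3g]"),
                      epoch, lr, min(t_sd), max(t_sd)),
              class = "tpmsdesign_fit_error")
      }
      val_loss <- NA_real_
      if (!is.null(Xv)) {
        Av <- mlp_forward_layers(W, b, Xv, act)
        val_loss <- mean((Av[[length(Av)]] - Yv)^2)
      }
      history <- dplyr::bind_rows(history,
        tibble(epoch = epoch, train_loss = train_loss,
               validation_loss = val_loss))
    }
    list(W = W, b = b, history = history)
  })

  structure(list(W = fitted$W, b = fitted$b, config = config,
                 scaler = enc$scaler, targets = targets,
                 target_mean = t_mu, target_sd = t_sd,
                 history = fitted$history,
                 n_train = n, feature_names = colnames(X)),
            class = "tpms_surrogate")
}

#' @export
print.tpms_surrogate <- function(x, ...) {
  cat(sprintf("<tpms_surrogate> %d features -> [%s] -> %d targets | %d epochs, final train MSE %.4g\n",
              length(x$feature_names),
              paste(x$config$hidden_sizes, collapse = ", "),
              length(x$targets), nrow(x$history),
              tail(x$history$train_loss, 1)))
  invisible(x)
}

#' Predict lattice properties for new designs
#'
#' @param object A fitted `tpms_surrogate`.
#' @param newdata Design tibble with the columns the stored feature scaler
#'   expects (`surface_type`, `cell_size_x/y/z`, `thickness`,
#'   `rotation_deg`, `height`, `diameter`).
#' @param ... Unused.
#' @return Tibble of predictions in natural units, one column per target.
#' @export
predict.tpms_surrogate <- function(object, newdata, ...) {
  needed <- c("surface_type", object$scaler$numeric_cols)
  missing_cols <- setdiff(needed, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("newdata lacks expected feature column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "tpmsdesign_contract_error")
  }
  X <- encode_features(newdata, object$scaler)$features
  Z <- mlp_predict_scaled(object, X)
  out <- sweep(sweep(Z, 2, object$target_sd, "*"), 2, object$target_mean, "+")
  colnames(out) <- object$targets
  as_tibble(out)
}

#' Evaluate a surrogate on a test set
#'
#' Per-target coefficient of determination `R^2 = 1 - SS_res / SS_tot` and
#' mean absolute error, with signed residuals retained for diagnostics.
#' A zero-variance target has undefined R^2 and is reported as `NA`.
#'
#' @param model A fitted `tpms_surrogate`.
#' @param test Tibble with design and target columns.
#' @return A `surrogate_eval`: list with `metrics` (tibble of `target`,
#'   `r_squared`, `mae`, `residual_mean`) and `residuals` (long tibble).
#' @export
evaluate_surrogate <- function(model, test) {
  pred <- predict(model, test)
  obs <- as.matrix(test[model$targets])
  metrics <- purrr::map_dfr(model$targets, function(tg) {
    r <- obs[, tg] - pred[[tg]]
    sstot <- sum((obs[, tg] - mean(obs[, tg]))^2)
    tibble(target = tg,
           r_squared = if (sstot == 0) NA_real_ else 1 - sum(r^2) / sstot,
           mae = mean(abs(r)), residual_mean = mean(r))
  })
  residuals <- purrr::map_dfr(model$targets, function(tg) {
    tibble(target = tg, observed = obs[, tg], predicted = pred[[tg]],
           residual = obs[, tg] - pred[[tg]])
  })
  structure(list(metrics = metrics, residuals = residuals),
            class = "surrogate_eval")
}

#' @export
print.surrogate_eval <- function(x, ...) {
  print(x$metrics)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a surrogate
#'
#' @param x A `tpms_surrogate`.
#' @param ... Unused.
#' @return Long tibble of `epoch`, `loss` (MSE on z-scored targets) and
#'   `partition` (train/validation).
#' @export
tidy.tpms_surrogate <- function(x, ...) {
  x$history %>%
    tidyr::pivot_longer(c("train_loss", "validation_loss"),
                        names_to = "partition", values_to = "loss") %>%
    dplyr::mutate(partition = sub("_loss$", "", .data$partition)) %>%
    dplyr::filter(is.finite(.data$loss))
}

#' One-row summary of a fitted surrogate
#'
#' @param x A `tpms_surrogate`.
#' @param ... Unused.
#' @return One-row tibble: feature/target counts, epochs, final losses.
#' @export
glance.tpms_surrogate <- function(x, ...) {
  tibble(n_features = length(x$feature_names), n_targets = length(x$targets),
         n_train = x$n_train, epochs = nrow(x$history),
         final_train_loss = tail(x$history$train_loss, 1),
         final_validation_loss = tail(x$history$validation_loss, 1))
}

#' @rdname tidy.tpms_surrogate
#' @export
tidy.surrogate_eval <- function(x, ...) x$metrics
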