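#' Split sample indices into train / validation / test partitions
#'
#' Sizes are `round(n * f_train)` and `round(n * f_validation)`, with the
#' remainder going to the test partition; 780 samples at 0.70/0.15/0.15
#' give 546/117/117. Partitions are disjoint, exhaustive and shuffled by
#' the seed.
#'
#' @param n number of samples (>= 3)
#' @param fractions length-3 train/validation/test fractions summing to 1
#' @param seed integer seed for the shuffle
#' @return list with integer index vectors `train`, `validation`, `test`
#' @export
split_data <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(fractions <= 0)) stop("all fractions must be positive")
  if (n < 3) stop("need at least 3 samples to form three partitions")
  n_train <- round(n * fractions[1])
  n_val <- round(n * fractions[2])
  n_test <- n - n_train - n_val
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stop("sample size too small for non-empty partitions at these fractions")
  set.seed(seed)
  idx <- sample.int(n)
  list(train = sort(idx[seq_len(n_train)]),
       validation = sort(idx[n_train + seq_len(n_val)]),
       test = sort(idx[n_train + n_val + seq_len(n_test)]))
}

#' Network architecture
#' @param n_input number of input features
#' @param n_hidden hidden layer width (tanh units)
#' @param seed weight-initialisation seed
#' @return an object of class `network_spec`
#' @export
network_spec <- function(n_input, n_hidden = 10, seed = 1L) {
  if (n_hidden < 1) stop("n_hidden must be at least 1")
  structure(list(n_input = n_input, n_hidden = n_hidden, seed = as.integer(seed)),
            class = "network_spec")
}

#' Training configuration
#' @param fractions train/validation/test split fractions
#' @param max_epochs maximum gradient-descent epochs
#' @param learning_rate step size
#' @param momentum classical momentum coefficient
#' @param patience early-stopping patience on validation MSE (epochs)
#' @param min_delta minimum validation improvement that resets patience
#' @param seed seed for the split shuffle
#' @return an object of class `train_config`
#' @export
train_config <- function(fractions = c(0.70, 0.15, 0.15), max_epochs = 2000,
                         learning_rate = 0.02, momentum = 0.9,
                         patience = 20, min_delta = 1e-6, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(c(max_epochs, learning_rate, patience) <= 0))
    stop("max_epochs, learning_rate and patience must be positive")
  structure(list(fractions = fractions, max_epochs = max_epochs,
                 learning_rate = learning_rate, momentum = momentum,
                 patience = patience, min_delta = min_delta,
                 seed = as.integer(seed)),
            class = "train_config")
}

# forward pass; returns prediction and hidden activations
nn_forward <- function(X, w) {
  H <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
  list(yhat = as.vector(H %*% w$W2 + w$b2), H = H)
}

#' Train the feedforward intensity network
#'
#' Single hidden layer of tanh units with a linear output, trained by
#' full-batch gradient descent with momentum on the training MSE
#' (error back-propagation), with early stopping on validation MSE. The
#' target is standardized internally for conditioning and predictions are
#' destandardized, so reported MSE is in squared target units (g^2/m^4).
#' Fully reproducible from the seeds in `spec` and `cfg`.
#'
#' @param table data.frame of standardized features plus a `target` column
#'   (e.g. from [select_combination()] after [standardize()])
#' @param spec a [network_spec()]; its `n_input` must match the feature count
#' @param cfg a [train_config()]
#' @return a `bpnn_fit`: weights, per-partition `r2` and `mse`, training
#'   history, split indices
#' @export
bpnn_train <- function(table, spec, cfg = train_config()) {
  feats <- setdiff(names(table), "target")
  X <- as.matrix(table[feats])
  y <- table$target
  if (spec$n_input != ncol(X))
    stop("network input size ", spec$n_input, " does not match ", ncol(X), " features")
  n <- nrow(X)
  parts <- split_data(n, cfg$fractions, seed = cfg$seed)
  ymu <- mean(y[parts$train]); ysd <- stats::sd(y[parts$train])
  if (!is.finite(ysd) || ysd == 0) ysd <- 1
  ys <- (y - ymu) / ysd
  h <- spec$n_hidden
  set.seed(spec$seed)
  w <- list(W1 = matrix(stats::rnorm(ncol(X) * h, 0, sqrt(1 / ncol(X))), ncol(X), h),
            b1 = rep(0, h),
            W2 = matrix(stats::rnorm(h, 0, sqrt(1 / h)), h, 1),
            b2 = 0)
  vel <- lapply(w, function(z) z * 0)
  Xtr <- X[parts$train, , drop = FALSE]; ytr <- ys[parts$train]
  Xva <- X[parts$validation, , drop = FALSE]; yva <- ys[parts$validation]
  ntr <- nrow(Xtr)
  best <- list(w = w, val = Inf, epoch = 0)
  wait <- 0
  history <- data.frame(epoch = integer(0), train_mse = numeric(0),
                        val_mse = numeric(0))
  for (ep in seq_len(cfg$max_epochs)) {
    fw <- nn_forward(Xtr, w)
    err <- fw$yhat - ytr
    train_mse <- mean(err^2)
    if (!is.finite(train_mse))
      stop("training diverged to non-finite loss; reduce learning_rate (",
           cfg$learning_rate, ")")
    # backprop
    dY <- matrix(2 * err / ntr, ncol = 1)
    gW2 <- t(fw$H) %*% dY
    gb2 <- sum(dY)
    dH <- (dY %*% t(w$W2)) * (1 - fw$H^2)
    gW1 <- t(Xtr) %*% dH
    gb1 <- colSums(dH)
    g <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (k in names(w)) {
      vel[[k]] <- cfg$momentum * vel[[k]] - cfg$learning_rate * g[[k]]
      w[[k]] <- w[[k]] + vel[[k]]
    }
    val_mse <- mean((nn_forward(Xva, w)$yhat - yva)^2)
    history <- rbind(history, data.frame(epoch = ep, train_mse = train_mse,
                                         val_mse = val_mse))
    if (val_mse < best$val - cfg$min_delta) {
      best <- list(w = w, val = val_mse, epoch = ep)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= cfg$patience) break
    }
  }
  w <- best$w
  predict_raw <- function(Xp) nn_forward(Xp, w)$yhat * ysd + ymu
  metrics <- lapply(parts, function(ix) {
    pred <- predict_raw(X[ix, , drop = FALSE])
    list(r2 = tryCatch(r_squared(pred, y[ix]), error = function(e) NA_real_),
         mse = mse_metric(y[ix], pred))
  })
  structure(list(weights = w, target_mean = ymu, target_sd = ysd,
                 features = feats, split = parts,
                 r2 = metrics$test$r2, mse = metrics$test$mse,
                 metrics = metrics, history = history,
                 best_epoch = best$epoch, spec = spec, cfg = cfg),
            class = "bpnn_fit")
}

#' Predict from a fitted network
#' @param object a `bpnn_fit`
#' @param newdata data.frame containing the fit's feature columns
#' @param ... unused
#' @return numeric predictions on the original target scale
#' @export
predict.bpnn_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$features])
  nn_forward(X, object$weights)$yhat * object$target_sd + object$target_mean
}

#' @export
print.bpnn_fit <- function(x, ...) {
  cat(sprintf("<bpnn_fit> %d-%d-1 tanh network, best epoch %d\n",
              x$spec$n_input, x$spec$n_hidden, x$best_epoch))
  cat(sprintf("  test R2 = %.4f, test MSE = %.6g\n", x$r2, x$mse))
  invisible(x)
}

#' Coefficient of determination with a predicted-mean denominator
#'
#' `1 - sum((pred - actual)^2) / sum((pred - mean(pred))^2)`. Note the
#' denominator centres the *predicted* values on their own mean — not the
#' conventional coefficient of determination, which centres the actual
#' values. The two agree when predictions are unbiased with matching
#' spread; [r_squared_conventional()] is provided for comparison.
#'
#' @param predicted,actual numeric vectors of equal length >= 2
#' @return unitless score, at most 1 when predictions are good
#' @export
r_squared <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (length(predicted) < 2) stop("need at least 2 values")
  den <- sum((predicted - mean(predicted))^2)
  if (den == 0) stop("constant predictions: score undefined")
  1 - sum((predicted - actual)^2) / den
}

#' Conventional coefficient of determination
#' @param predicted,actual numeric vectors of equal length
#' @return `1 - SS_res / SS_tot` with the total sum of squares about the
#'   mean of `actual`
#' @export
r_squared_conventional <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  den <- sum((actual - mean(actual))^2)
  if (den == 0) stop("constant actuals: score undefined")
  1 - sum((actual - predicted)^2) / den
}

#' Mean squared error
#' @param expected,actual numeric vectors of equal length
#' @return mean of squared differences
#' @export
mse_metric <- function(expected, actual) {
  if (length(expected) != length(actual)) stop("length mismatch")
  mean((expected - actual)^2)
}

#' Screen the nine feature combinations
#'
#' Trains one network per combination with a shared, deterministic seed
#' schedule and reports test-partition R2 and MSE in combination order.
#' The best combination is the highest R2, ties broken by lowest MSE then
#' lowest combination index.
#'
#' @param table a `feature_table` with all eight (standardized) features
#'   and `target`
#' @param combos character vector of combination ids (default all nine)
#' @param n_hidden hidden layer width
#' @param cfg a [train_config()]
#' @param aspect aspect encoding passed to [select_combination()]
#' @return a `screening_report` data.frame: `combo`, the eight 0/1 flags,
#'   `R2`, `MSE`, `best`; fitted models in attribute `"fits"`
#' @export
screen_combinations <- function(table, combos = rownames(feature_combinations()),
                                n_hidden = 10, cfg = train_config(),
                                aspect = "sincos") {
  masks <- feature_combinations()
  rows <- list(); fits <- list()
  for (id in combos) {
    sub <- select_combination(table, id, aspect = aspect)
    spec <- network_spec(n_input = ncol(sub) - 1, n_hidden = n_hidden,
                         seed = derive_seed(cfg$seed, "net", match(id, rownames(masks))))
    fit <- bpnn_train(sub, spec, cfg)
    fits[[id]] <- fit
    rows[[id]] <- data.frame(combo = id, t(masks[id, ]),
                             R2 = fit$r2, MSE = fit$mse)
  }
  rep <- do.call(rbind, rows)
  ord <- order(-rep$R2, rep$MSE, match(rep$combo, rownames(masks)))
  rep$best <- seq_len(nrow(rep)) == 0
  rep$best[ord[1]] <- TRUE
  rownames(rep) <- NULL
  class(rep) <- c("screening_report", "data.frame")
  attr(rep, "fits") <- fits
  rep
}
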