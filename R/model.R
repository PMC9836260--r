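#' Gaussian grade-mask weight
#'
#' Bell-shaped weight centered on the cohort grade mean,
#' \eqn{\exp(-(s - \mu)^2 / (2\sigma^2))}, used as a training sample weight
#' to down-weight extreme-grade outliers. Defaults \eqn{\mu = 76.4},
#' \eqn{\sigma = 5.16}.
#'
#' @param score Numeric grade(s).
#' @param mu,sigma Mask center and width (\code{sigma > 0}).
#' @return Weight(s) in (0, 1].
#' @export
gaussian_weight <- function(score, mu = 76.4, sigma = 5.16) {
  stopifnot(sigma > 0)
  exp(-(score - mu)^2 / (2 * sigma^2))
}

#' Hidden-layer sizes under the two-thirds rule
#'
#' Each of the \code{depth} hidden layers gets
#' \eqn{n_h = \lceil \tfrac{2}{3} n_x + n_y \rceil} neurons, from the input
#' width \code{n_x} and output width \code{n_y}.
#'
#' @param n_x Input feature count (>= 1).
#' @param n_y Output count (>= 1), 1 for scalar regression.
#' @param depth Number of hidden layers.
#' @return Integer vector of length \code{depth}.
#' @export
hidden_sizes <- function(n_x, n_y = 1L, depth = 25L) {
  stopifnot(n_x >= 1, n_y >= 1, depth >= 1)
  rep(as.integer(ceiling(2 / 3 * n_x + n_y)), depth)
}

#' Active neuron count under dropout
#'
#' With dropout rate \code{rate}, a layer of \code{n} neurons keeps
#' \code{round(n * (1 - rate))} active units (at least 1). Training-time
#' masks select exactly this many units on alternating layers; inference
#' uses all units with activations scaled by the kept fraction.
#'
#' @param n Neuron count.
#' @param rate Dropout rate in [0, 1).
#' @return Integer count of active neurons.
#' @export
dropout_active_count <- function(n, rate) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop("dropout rate must lie in [0, 1)")
  }
  stopifnot(n >= 1)
  max(1L, as.integer(round(n * (1 - rate))))
}

#' Confusion counts from numeric predictions
#'
#' Classifies both predictions and actual grades against the threshold
#' \code{mu} (positive class: grade >= mu). \code{rule = "band"} is a
#' tolerance-band variant in which a prediction within \code{sigma} of the
#' actual grade counts as agreeing with the actual's class.
#'
#' @param predicted,actual Equal-length numeric vectors.
#' @param mu Class threshold, default 76.
#' @param sigma Tolerance band width for \code{rule = "band"}, default 5.
#' @param rule \code{"threshold"} (default) or \code{"band"}.
#' @return Named integer vector \code{TP}, \code{TN}, \code{FP}, \code{FN};
#'   the four always sum to \code{length(actual)}.
#' @export
confusion_counts <- function(predicted, actual, mu = 76, sigma = 5,
                             rule = c("threshold", "band")) {
  rule <- match.arg(rule)
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length")
  }
  act_pos <- actual >= mu
  if (rule == "threshold") {
    pred_pos <- predicted >= mu
    agree <- pred_pos == act_pos
  } else {
    agree <- abs(predicted - actual) <= sigma
    pred_pos <- ifelse(agree, act_pos, predicted >= mu)
  }
  c(TP = sum(agree & act_pos),
    TN = sum(agree & !act_pos),
    FP = sum(!agree & pred_pos),
    FN = sum(!agree & !pred_pos))
}

#' Precision, recall and F1
#'
#' \eqn{F_1 = 2 \cdot \mathrm{precision} \cdot \mathrm{recall} /
#' (\mathrm{precision} + \mathrm{recall})}; any zero denominator yields 0.
#'
#' @param TP,FP,FN Non-negative counts.
#' @return Named list \code{precision}, \code{recall}, \code{F1}.
#' @export
f1_metrics <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, F1 = f1)
}

#' Mean absolute percentage error
#'
#' \eqn{\delta_{MAPE} = \frac{1}{N} \sum_i |E_i - Y_i| / |E_i|} between
#' expected grades \eqn{E} and predictions \eqn{Y}.
#'
#' @param expected Nonzero numeric vector of true values.
#' @param predicted Numeric vector, same length.
#' @return Non-negative numeric.
#' @export
mape <- function(expected, predicted) {
  if (length(expected) != length(predicted)) {
    stop("expected and predicted must have equal length")
  }
  if (any(expected == 0)) stop("MAPE is undefined for zero expected values")
  mean(abs(expected - predicted) / abs(expected))
}

# ---- multilayer perceptron -------------------------------------------------

relu <- function(x) pmax(x, 0)

#' Fit the MLP regressor
#'
#' Fully connected feed-forward network: \code{depth} ReLU hidden layers of
#' equal width from [hidden_sizes()], linear output, trained by minibatch
#' stochastic gradient descent with momentum on a (optionally
#' sample-weighted) squared-error loss with L2 penalty \code{alpha}. Inputs
#' and the target are standardized internally. Dropout masks deactivate a
#' fixed number of units ([dropout_active_count()]) on alternating hidden
#' layers (the first, third, ... hidden layers) during training; at
#' inference these layers' activations are scaled by the kept fraction.
#' Training stops early once the epoch loss improves by less than
#' \code{tol} on two consecutive epochs.
#'
#' @param x Numeric feature matrix (rows = observations).
#' @param y Numeric response vector.
#' @param config An [eva_config()] list (depth, alpha, max_iter, tol,
#'   dropout_rate, learning_rate, momentum, batch_size).
#' @param sample_weights Optional non-negative weights, one per row.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return Object of class \code{eva_mlp}; predict with [predict.eva_mlp()].
#' @export
mlp_fit <- function(x, y, config = eva_config(), sample_weights = NULL,
                    seed = config$seed) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- nrow(x)
  if (is.null(sample_weights)) sample_weights <- rep(1, n)
  stopifnot(length(sample_weights) == n, all(sample_weights >= 0))
  sample_weights <- sample_weights / mean(sample_weights)

  x_center <- colMeans(x)
  x_scale <- apply(x, 2, sd)
  x_scale[x_scale < 1e-12] <- 1
  y_center <- mean(y)
  y_scale <- sd(y)
  if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
  xs <- sweep(sweep(x, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale

  sizes <- c(ncol(x), hidden_sizes(ncol(x), 1L, config$depth), 1L)
  L <- length(sizes) - 1L
  set.seed(seed)
  W <- lapply(seq_len(L), function(l) {
    matrix(rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
           sizes[l], sizes[l + 1L])
  })
  b <- lapply(seq_len(L), function(l) rep(0, sizes[l + 1L]))
  vW <- lapply(W, function(w) w * 0)
  vb <- lapply(b, function(bb) bb * 0)

  # dropout applies to hidden layers 1, 3, 5, ... (alternating from input)
  drop_layer <- rep(FALSE, L)
  if (config$dropout_rate > 0 && config$depth >= 1) {
    drop_layer[seq(1L, config$depth, by = 2L)] <- TRUE
  }

  lr <- config$learning_rate
  mom <- config$momentum
  alpha <- config$alpha
  batch <- max(1L, min(as.integer(config$batch_size), n))
  prev_loss <- Inf
  stall <- 0L
  converged <- FALSE
  epochs_run <- 0L

  for (epoch in seq_len(config$max_iter)) {
    ord <- sample.int(n)
    epoch_loss <- 0
    for (start in seq(1L, n, by = batch)) {
      idx <- ord[start:min(start + batch - 1L, n)]
      a <- xs[idx, , drop = FALSE]
      m <- length(idx)
      acts <- vector("list", L + 1L)
      acts[[1L]] <- a
      masks <- vector("list", L)
      for (l in seq_len(L)) {
        zmat <- acts[[l]] %*% W[[l]] + matrix(b[[l]], m, sizes[l + 1L],
                                              byrow = TRUE)
        if (l < L) {
          h <- relu(zmat)
          if (drop_layer[l]) {
            keep <- sample.int(sizes[l + 1L],
                               dropout_active_count(sizes[l + 1L],
                                                    config$dropout_rate))
            mask <- rep(0, sizes[l + 1L]); mask[keep] <- 1
            h <- sweep(h, 2, mask, "*")
            masks[[l]] <- mask
          }
          acts[[l + 1L]] <- h
        } else {
          acts[[l + 1L]] <- zmat
        }
      }
      pred <- acts[[L + 1L]][, 1L]
      wgt <- sample_weights[idx]
      resid <- pred - ys[idx]
      epoch_loss <- epoch_loss + sum(wgt * resid^2)
      # backprop
      delta <- matrix(2 * wgt * resid / m, m, 1L)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(acts[[l]], delta) + 2 * alpha * W[[l]]
        gb <- colSums(delta)
        gnorm <- sqrt(sum(gW^2) + sum(gb^2))
        if (gnorm > 5) { gW <- gW * (5 / gnorm); gb <- gb * (5 / gnorm) }
        if (l > 1L) {
          delta <- (delta %*% t(W[[l]])) * (acts[[l]] > 0)
          if (drop_layer[l - 1L] && !is.null(masks[[l - 1L]])) {
            delta <- sweep(delta, 2, masks[[l - 1L]], "*")
          }
        }
        vW[[l]] <- mom * vW[[l]] - lr * gW
        vb[[l]] <- mom * vb[[l]] - lr * gb
        W[[l]] <- W[[l]] + vW[[l]]
        b[[l]] <- b[[l]] + vb[[l]]
      }
    }
    epochs_run <- epoch
    epoch_loss <- epoch_loss / n
    if (!is.finite(epoch_loss)) {
      warning("training diverged; reduce learning_rate")
      break
    }
    if (prev_loss - epoch_loss < config$tol) {
      stall <- stall + 1L
      if (stall >= 2L) { converged <- TRUE; break }
    } else {
      stall <- 0L
    }
    prev_loss <- epoch_loss
  }

  structure(list(W = W, b = b, sizes = sizes, drop_layer = drop_layer,
                 dropout_rate = config$dropout_rate,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 converged = converged, epochs = epochs_run,
                 loss = epoch_loss),
            class = "eva_mlp")
}

#' Predict from a fitted MLP
#'
#' @param object An \code{eva_mlp} from [mlp_fit()].
#' @param newdata Numeric matrix with the training feature columns.
#' @param ... Unused.
#' @return Numeric predictions on the original grade scale.
#' @export
predict.eva_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  a <- sweep(sweep(x, 2, object$x_center), 2, object$x_scale, "/")
  L <- length(object$W)
  for (l in seq_len(L)) {
    zmat <- a %*% object$W[[l]] +
      matrix(object$b[[l]], nrow(a), length(object$b[[l]]), byrow = TRUE)
    if (l < L) {
      a <- relu(zmat)
      if (object$drop_layer[l]) {
        width <- object$sizes[l + 1L]
        keep_frac <- dropout_active_count(width, object$dropout_rate) / width
        a <- a * keep_frac
      }
    } else {
      a <- zmat
    }
  }
  a[, 1L] * object$y_scale + object$y_center
}

#' @export
print.eva_mlp <- function(x, ...) {
  cat("<eva_mlp>", length(x$W) - 1L, "hidden layers x", x$sizes[2],
      "units | epochs:", x$epochs,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

# ---- cross-validation ------------------------------------------------------

#' K-fold cross-validated training and prediction
#'
#' Partitions the cohort into \code{K} folds (seeded), fits the MLP on each
#' training split -- with Gaussian-mask sample weights when
#' \code{config$use_gaussian_mask} -- predicts the held-out fold, and
#' reports the per-fold and mean MAPE. Deterministic for a fixed
#' \code{config$seed}.
#'
#' @param features Numeric matrix or data frame of feature columns.
#' @param grades Finite nonzero numeric grades, one per row.
#' @param config An [eva_config()] list.
#' @param K Fold count, \code{2 <= K <= n}; default \code{config$k_folds}.
#' @return Object of class \code{eva_cv}: \code{K}, \code{fold_mape},
#'   \code{mape} (their mean), \code{predictions} data frame
#'   (\code{index}, \code{fold}, \code{actual}, \code{predicted}).
#' @export
train_predict_cv <- function(features, grades, config = eva_config(),
                             K = config$k_folds) {
  x <- as.matrix(features)
  grades <- as.numeric(grades)
  n <- nrow(x)
  stopifnot(length(grades) == n, all(is.finite(grades)))
  K <- as.integer(K)
  if (K > n) stop("K (", K, ") exceeds the number of documents (", n, ")")
  if (K < 2) stop("K must be at least 2")
  set.seed(config$seed)
  fold <- sample(rep(seq_len(K), length.out = n))
  preds <- numeric(n)
  fold_mape <- numeric(K)
  unconverged <- 0L
  for (k in seq_len(K)) {
    tr <- fold != k
    wgt <- if (isTRUE(config$use_gaussian_mask)) {
      gaussian_weight(grades[tr], config$mask_mu, config$mask_sigma)
    } else NULL
    fit <- mlp_fit(x[tr, , drop = FALSE], grades[tr], config,
                   sample_weights = wgt, seed = config$seed + k)
    if (!fit$converged) unconverged <- unconverged + 1L
    preds[fold == k] <- predict(fit, x[fold == k, , drop = FALSE])
    fold_mape[k] <- mape(grades[fold == k], preds[fold == k])
  }
  if (unconverged > 0L) {
    warning(unconverged, " of ", K,
            " folds did not reach the loss tolerance within max_iter")
  }
  structure(list(K = K, fold_mape = fold_mape, mape = mean(fold_mape),
                 predictions = data.frame(index = seq_len(n), fold = fold,
                                          actual = grades,
                                          predicted = preds)),
            class = "eva_cv")
}

#' @export
print.eva_cv <- function(x, ...) {
  cat("<eva_cv> K =", x$K, "| mean MAPE =", signif(x$mape, 4), "\n")
  invisible(x)
}

#' Hold-out training and evaluation
#'
#' Single seeded 80/20-style split: fit on the training share, predict the
#' held-out share, report its MAPE.
#'
#' @inheritParams train_predict_cv
#' @param test_fraction Held-out share in (0, 1), default
#'   \code{config$holdout_fraction}.
#' @return List \code{mape}, \code{predictions} (held-out data frame),
#'   \code{fit}.
#' @export
train_predict_holdout <- function(features, grades, config = eva_config(),
                                  test_fraction = config$holdout_fraction) {
  x <- as.matrix(features)
  grades <- as.numeric(grades)
  n <- nrow(x)
  stopifnot(length(grades) == n, test_fraction > 0, test_fraction < 1)
  set.seed(config$seed)
  n_test <- max(1L, round(n * test_fraction))
  test <- sample.int(n, n_test)
  tr <- setdiff(seq_len(n), test)
  wgt <- if (isTRUE(config$use_gaussian_mask)) {
    gaussian_weight(grades[tr], config$mask_mu, config$mask_sigma)
  } else NULL
  fit <- mlp_fit(x[tr, , drop = FALSE], grades[tr], config,
                 sample_weights = wgt, seed = config$seed + 1L)
  pred <- predict(fit, x[test, , drop = FALSE])
  list(mape = mape(grades[test], pred),
       predictions = data.frame(index = test, actual = grades[test],
                                predicted = pred),
       fit = fit)
}

# ---- drop-one feature selection --------------------------------------------

lin_mae <- function(x, y) {
  x <- cbind(1, as.matrix(x))
  fit <- suppressWarnings(lm.fit(x, y))
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    warning("rank-deficient design; pseudo-solution with dropped columns used")
    coefs[is.na(coefs)] <- 0
  }
  mean(abs(y - x %*% coefs))
}

#' Drop-one feature importance and top-k selection
#'
#' Fits a linear least-squares model on all features to get a baseline mean
#' absolute error, then refits with each feature dropped in turn; the
#' importance of a feature is the MAE increase its removal causes. Features
#' are ranked by descending importance, and \code{k} is chosen in
#' \code{1..k_max} to minimize the seeded 5-fold cross-validated MAE of the
#' top-\code{k} linear model.
#'
#' @param features Numeric matrix or data frame (>= 2 columns).
#' @param targets Numeric response vector.
#' @param k_max Largest subset size scanned; default all features.
#' @param seed Integer seed for the selection folds.
#' @return List \code{ranking} (feature names, most important first),
#'   \code{importance} (named MAE deltas), \code{k} (chosen size),
#'   \code{cv_mae} (per-k), \code{baseline_mae}.
#' @export
drop_one_selection <- function(features, targets, k_max = ncol(features),
                               seed = 1L) {
  x <- as.matrix(features)
  y <- as.numeric(targets)
  p <- ncol(x)
  stopifnot(p >= 2, nrow(x) == length(y))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(p))
  baseline <- lin_mae(x, y)
  importance <- vapply(seq_len(p), function(j) {
    lin_mae(x[, -j, drop = FALSE], y) - baseline
  }, numeric(1))
  names(importance) <- colnames(x)
  ranking <- names(sort(importance, decreasing = TRUE))

  k_max <- min(k_max, p)
  set.seed(seed)
  nfold <- min(5L, nrow(x))
  fold <- sample(rep(seq_len(nfold), length.out = nrow(x)))
  cv_mae <- vapply(seq_len(k_max), function(k) {
    cols <- ranking[seq_len(k)]
    errs <- vapply(seq_len(nfold), function(f) {
      tr <- fold != f
      xtr <- cbind(1, x[tr, cols, drop = FALSE])
      fit <- suppressWarnings(lm.fit(xtr, y[tr]))
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0
      xte <- cbind(1, x[!tr, cols, drop = FALSE])
      mean(abs(y[!tr] - xte %*% coefs))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  list(ranking = ranking, importance = importance,
       k = which.min(cv_mae), cv_mae = cv_mae, baseline_mae = baseline)
}
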