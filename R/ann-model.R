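#' Network architecture and training configuration
#'
#' The defaults pin the reference configuration for the hospitalization
#' expenditure regression: a single hidden layer of 5 hyperbolic-tangent
#' nodes, L2-regularized squared-error loss, trained by L-BFGS (gradients via
#' backpropagation) for at most 1500 iterations.
#'
#' @param n_hidden Hidden-layer size (default 5, chosen by trial and error in
#'   the reference configuration).
#' @param l2_alpha L2 penalty strength on connection weights (default 1e-4).
#' @param max_iter Maximum optimizer iterations (default 1500).
#' @param tol Relative convergence tolerance on the loss (default 1e-5);
#'   the optimizer may stop earlier than `max_iter` once improvement falls
#'   below it.
#' @param seed Integer seed fixing the random weight initialization.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_hidden = 5L, l2_alpha = 1e-4, max_iter = 1500L,
                         tol = 1e-5, seed = 1L) {
  stopifnot(n_hidden >= 1, l2_alpha >= 0, max_iter >= 1, tol > 0)
  structure(
    list(n_hidden = as.integer(n_hidden), l2_alpha = l2_alpha,
         max_iter = as.integer(max_iter), tol = tol, seed = as.integer(seed)),
    class = "network_spec"
  )
}

init_params <- function(p, h, seed) {
  set.seed(seed)
  # Glorot-style uniform initialization, the convention for tanh layers
  lim_in <- sqrt(6 / (p + h))
  lim_out <- sqrt(6 / (h + 1))
  c(runif(p * h, -lim_in, lim_in), rep(0, h),
    runif(h, -lim_out, lim_out), 0)
}

#' Fit the single-hidden-layer perceptron regression
#'
#' Minimizes `0.5 * mean((yhat - y)^2) + alpha/(2n) * (||W||^2 + ||v||^2)`
#' over the connection weights with L-BFGS-B, gradients computed by
#' backpropagation. When a [make_splits()] plan is given, training uses the
#' training rows only and both train and test metrics are reported.
#'
#' @param matrix A `model_matrix` from [encode_factors()].
#' @param spec A [network_spec()].
#' @param split Optional [make_splits()] plan; default trains on all rows.
#' @return An object of class `cce_mlp`: connection weights (`W`, `b_h`,
#'   `v`, `b_o`), the spec, `feature_map`, train/test [evaluate_predictions()]
#'   metrics, and diagnostics (`converged`, `iterations`, `loss`,
#'   `loss_trace` -- the best loss seen at each objective evaluation, a
#'   non-increasing sequence).
#' @export
fit_mlp <- function(matrix, spec = network_spec(), split = NULL) {
  stopifnot(inherits(matrix, "model_matrix"), inherits(spec, "network_spec"))
  tr <- if (is.null(split)) seq_len(matrix$n) else split$train_idx
  X <- matrix$X[tr, , drop = FALSE]
  y <- matrix$y[tr]
  p <- ncol(X)
  h <- spec$n_hidden
  if (length(y) <= p) {
    warn(sprintf("Training set (n = %d) has no more rows than features (p = %d): under-determined fit.",
                 length(y), p))
  }

  trace_env <- new.env()
  trace_env$best <- Inf
  trace_env$trace <- numeric(0)
  cache <- new.env()
  eval_at <- function(par) {
    if (!identical(par, cache$par)) {
      res <- mlp_loss_grad(par, X, y, h, spec$l2_alpha)
      if (!is.finite(res$loss)) {
        abort(sprintf("Non-finite loss during training (seed %d): check for degenerate inputs or lower l2_alpha/learning scale.",
                      spec$seed),
              class = "cceann_numerical_error")
      }
      cache$par <- par
      cache$res <- res
      trace_env$best <- min(trace_env$best, res$loss)
      trace_env$trace <- c(trace_env$trace, trace_env$best)
    }
    cache$res
  }

  par0 <- init_params(p, h, spec$seed)
  opt <- stats::optim(
    par0,
    fn = function(par) eval_at(par)$loss,
    gr = function(par) eval_at(par)$grad,
    method = "L-BFGS-B",
    control = list(maxit = spec$max_iter,
                   factr = spec$tol / .Machine$double.eps)
  )

  par <- opt$par
  fit <- structure(
    list(
      W = matrix(par[seq_len(p * h)], nrow = p, ncol = h,
                 dimnames = list(colnames(matrix$X), NULL)),
      b_h = par[p * h + seq_len(h)],
      v = par[p * h + h + seq_len(h)],
      b_o = par[p * h + 2 * h + 1],
      par = par,
      spec = spec,
      feature_map = matrix$feature_map,
      converged = opt$convergence == 0,
      iterations = opt$counts[["function"]],
      loss = opt$value,
      loss_trace = trace_env$trace,
      n_train = length(y),
      p = p
    ),
    class = "cce_mlp"
  )
  fit$metrics <- mlp_metrics(fit, matrix, split)
  fit
}

mlp_metrics <- function(fit, matrix, split) {
  sets <- if (is.null(split)) {
    list(train = seq_len(matrix$n))
  } else {
    list(train = split$train_idx, test = split$test_idx)
  }
  purrr::imap_dfr(sets, function(idx, nm) {
    pred <- predict(fit, matrix$X[idx, , drop = FALSE])
    dplyr::mutate(
      evaluate_predictions(matrix$y[idx], pred, p = fit$p),
      set = nm, .before = 1
    )
  })
}

#' @export
predict.cce_mlp <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "model_matrix")) newdata$X else newdata
  as.numeric(mlp_forward(object$par, X, object$spec$n_hidden))
}

#' @export
print.cce_mlp <- function(x, ...) {
  cat(sprintf(
    "<cce_mlp> %d-%d-1 tanh perceptron, %s after %d evaluations (loss %.4g)\n",
    x$p, x$spec$n_hidden,
    if (x$converged) "converged" else "stopped at iteration cap",
    x$iterations, x$loss
  ))
  print(x$metrics)
  invisible(x)
}

#' Extract connection weights
#'
#' @param model A fitted `cce_mlp`.
#' @return A list with `W` (p x h input-to-hidden matrix), `b_h`, `v`
#'   (hidden-to-output weights) and `b_o`, as consumed by [garson()].
#' @export
perceptron_weights <- function(model) {
  stopifnot(inherits(model, "cce_mlp"))
  model[c("W", "b_h", "v", "b_o")]
}

#' @export
tidy.cce_mlp <- function(x, ...) {
  w <- x$W
  dplyr::bind_rows(
    tibble(
      term = rep(rownames(w) %||% paste0("x", seq_len(nrow(w))),
                 times = ncol(w)),
      hidden_node = rep(seq_len(ncol(w)), each = nrow(w)),
      layer = "input_hidden",
      weight = as.numeric(w)
    ),
    tibble(term = "bias", hidden_node = seq_along(x$b_h),
           layer = "input_hidden", weight = x$b_h),
    tibble(term = "output", hidden_node = seq_along(x$v),
           layer = "hidden_output", weight = x$v),
    tibble(term = "bias", hidden_node = NA_integer_,
           layer = "hidden_output", weight = x$b_o)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
glance.cce_mlp <- function(x, ...) {
  m <- x$metrics
  test <- m[m$set == "test", ]
  tibble(
    r2_train = m$r2[m$set == "train"],
    r2_test = if (nrow(test)) test$r2 else NA_real_,
    mse_train = m$mse[m$set == "train"],
    mae_train = m$mae[m$set == "train"],
    converged = x$converged,
    iterations = x$iterations,
    n_train = x$n_train,
    p = x$p
  )
}

#' Regression evaluation metrics
#'
#' `r2 = 1 - SS_res / SS_tot`; adjusted R-squared applies the
#' `1 - (1 - r2)(n - 1)/(n - p - 1)` penalty for `p` predictors.
#'
#' @param y_true,y_pred Equal-length numeric vectors, length at least 2.
#' @param p Number of predictors used by the model.
#' @return One-row tibble: `r2`, `r2_adj`, `mse`, `mae`, `n`, `p`.
#' @export
#' @examples
#' evaluate_predictions(c(0, 1, 2, 3), c(0, 1, 2, 4), p = 1)
evaluate_predictions <- function(y_true, y_pred, p) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    abort("`y_true` and `y_pred` must be equal-length vectors, length >= 2.",
          class = "cceann_validation_error")
  }
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    abort("`y_true` has zero variance; R-squared is undefined.",
          class = "cceann_validation_error")
  }
  n <- length(y_true)
  r2 <- 1 - sum((y_true - y_pred)^2) / ss_tot
  tibble(
    r2 = r2,
    # the (n-1)/(n-p-1) penalty is meaningless without residual df
    r2_adj = if (n > p + 1) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_,
    mse = mean((y_true - y_pred)^2),
    mae = mean(abs(y_true - y_pred)),
    n = n,
    p = p
  )
}

#' Cross-validation scores
#'
#' Fits the network on each training fold's complement and scores the held
#' fold, giving one row per fold.
#'
#' @param matrix A `model_matrix`.
#' @param spec A [network_spec()].
#' @param split A [make_splits()] plan (its `cv_folds` are used).
#' @return Tibble with `fold`, `n_validation`, `mse`, `r2`.
#' @export
cv_scores <- function(matrix, spec, split) {
  purrr::imap_dfr(split$cv_folds, function(hold, nm) {
    tr <- setdiff(split$train_idx, hold)
    sub <- submatrix(matrix, tr)
    fit <- fit_mlp(sub, spec)
    pred <- predict(fit, matrix$X[hold, , drop = FALSE])
    m <- evaluate_predictions(matrix$y[hold], pred, p = matrix$p)
    tibble(fold = as.integer(nm), n_validation = length(hold),
           mse = m$mse, r2 = m$r2)
  })
}

submatrix <- function(matrix, idx) {
  out <- matrix
  out$X <- matrix$X[idx, , drop = FALSE]
  out$y <- matrix$y[idx]
  out$n <- length(idx)
  out
}

#' Learning curve over training-set size
#'
#' Retrains on nested subsets of the training rows and reports training and
#' cross-validation error at each fraction, the standard diagnostic for
#' whether more data would still help.
#'
#' @param matrix A `model_matrix`.
#' @param spec A [network_spec()].
#' @param split A [make_splits()] plan.
#' @param fractions Increasing training fractions in (0, 1].
#' @return An object of class `learning_curve`: tibble with `fraction`,
#'   `n_train`, `train_mse`, `cv_mse`.
#' @export
learning_curve <- function(matrix, spec, split,
                           fractions = c(0.2, 0.4, 0.6, 0.8, 1.0)) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  rows <- purrr::map_dfr(fractions, function(f) {
    res <- purrr::map_dfr(seq_along(split$cv_folds), function(k) {
      hold <- split$cv_folds[[k]]
      tr_all <- setdiff(split$train_idx, hold)
      tr <- tr_all[seq_len(max(2, floor(f * length(tr_all))))]
      fit <- fit_mlp(submatrix(matrix, tr), spec)
      tibble(
        train_mse = fit$metrics$mse[fit$metrics$set == "train"],
        cv_mse = evaluate_predictions(
          matrix$y[hold],
          predict(fit, matrix$X[hold, , drop = FALSE]),
          p = matrix$p
        )$mse
      )
    })
    tibble(fraction = f, n_train = floor(f * length(split$train_idx)),
           train_mse = mean(res$train_mse), cv_mse = mean(res$cv_mse))
  })
  structure(rows, class = c("learning_curve", class(rows)))
}
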