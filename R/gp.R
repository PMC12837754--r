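# Gaussian Process regression with an automatic relevance determination
# (ARD) squared-exponential kernel of unit amplitude:
#   k(xi, xj) = exp(-1/2 sum_d (xi_d - xj_d)^2 / l_d^2)
# A small fixed sigma2 is added to the kernel matrix; the length scales are
# the only optimized hyperparameters (log-space evidence maximization).

#' ARD squared-exponential kernel matrix
#'
#' @param X1 n1 x D numeric matrix (or data frame of numeric columns).
#' @param X2 n2 x D matrix; defaults to `X1`.
#' @param lengthscales Positive length scale per dimension (same units as
#'   the corresponding input column).
#' @return n1 x n2 kernel matrix with entries in (0, 1].
#' @examples
#' ard_kernel(matrix(0), matrix(1), lengthscales = 1) # exp(-0.5)
#' @export
ard_kernel <- function(X1, X2 = NULL, lengthscales) {
  X1 <- as.matrix(X1)
  X2 <- if (is.null(X2)) X1 else as.matrix(X2)
  D <- ncol(X1)
  if (ncol(X2) != D) abort("X1 and X2 must have the same number of columns")
  if (length(lengthscales) == 1) lengthscales <- rep(lengthscales, D)
  if (length(lengthscales) != D) abort("lengthscales must have one entry per dimension")
  if (any(lengthscales <= 0)) abort("lengthscales must be strictly positive")
  A <- sweep(X1, 2, lengthscales, "/")
  B <- sweep(X2, 2, lengthscales, "/")
  d2 <- pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B), 0)
  exp(-0.5 * d2)
}

chol_or_abort <- function(K) {
  out <- tryCatch(chol(K), error = function(e) e)
  if (inherits(out, "error")) {
    abort(paste0(
      "Kernel matrix is not positive definite (condition estimate ",
      format(kappa(K), digits = 3), "); increase sigma2."
    ))
  }
  out
}

#' Log marginal likelihood of a GP with ARD kernel
#'
#' The Gaussian evidence of the targets under a zero-mean GP prior with the
#' ARD kernel plus `sigma2` on the diagonal:
#' `-1/2 y' K^-1 y - 1/2 log|K| - n/2 log(2 pi)`.
#'
#' @param X n x D inputs.
#' @param y Length-n targets (used as given; [fit_gp()] standardizes
#'   internally before calling this).
#' @param lengthscales Per-dimension length scales.
#' @param sigma2 Fixed noise/jitter variance added to the kernel diagonal.
#' @return Scalar log evidence.
#' @export
log_marginal_likelihood <- function(X, y, lengthscales, sigma2) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), sigma2 > 0)
  K <- ard_kernel(X, lengthscales = lengthscales)
  diag(K) <- diag(K) + sigma2
  L <- chol_or_abort(K)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  -0.5 * sum(y * alpha) - sum(log(diag(L))) - length(y) / 2 * log(2 * pi)
}

# Evidence and its gradient w.r.t. theta = log(lengthscales).
lml_with_grad <- function(X, y, theta, sigma2) {
  l <- exp(theta)
  n <- nrow(X)
  D <- ncol(X)
  K0 <- ard_kernel(X, lengthscales = l)
  K <- K0
  diag(K) <- diag(K) + sigma2
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = -Inf, grad = rep(0, D)))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  Kinv <- chol2inv(L)
  value <- -0.5 * sum(y * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi)
  W <- tcrossprod(alpha) - Kinv
  grad <- vapply(seq_len(D), function(d) {
    S2 <- outer(X[, d], X[, d], "-")^2 / l[d]^2
    0.5 * sum(W * (K0 * S2))
  }, numeric(1))
  list(value = value, grad = grad)
}

#' Fit a GP surrogate by evidence maximization
#'
#' Standardizes the targets to zero mean and unit variance (the kernel has
#' unit amplitude), leaves the inputs on their physical scales (the ARD
#' length scales absorb them), and maximizes the log marginal likelihood
#' over log length scales with L-BFGS-B from `init_lengthscales` plus two
#' deterministic restarts at half and double the init; the best evidence
#' wins. `sigma2` is held fixed throughout.
#'
#' @param data Data frame holding predictors and response.
#' @param response Name of the response column (default
#'   `"orifice_area_mm2"`).
#' @param predictors Character vector of predictor columns; default: all
#'   numeric columns except the response, in data order.
#' @param sigma2 Fixed noise variance on the standardized targets
#'   (default 1e-4).
#' @param init_lengthscales Initial length scales (default: the per-column
#'   input range).
#' @param optimize If `FALSE`, keep `init_lengthscales` (used when
#'   rebuilding a surrogate with previously selected hyperparameters and
#'   inside the cross-validation of [cv_init_lengthscale()]).
#' @param maxit Maximum L-BFGS-B iterations.
#' @return Object of class `gp_fit`.
#' @examples
#' d <- generate_dataset(60, seed = 1)
#' gp <- fit_gp(d)
#' cor(predict(gp, d), d$orifice_area_mm2)
#' @export
fit_gp <- function(data, response = "orifice_area_mm2", predictors = NULL,
                   sigma2 = 1e-4, init_lengthscales = NULL, optimize = TRUE,
                   maxit = 200) {
  data <- tibble::as_tibble(data)
  if (!response %in% names(data)) abort(paste0("Response column not found: ", response))
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], response)
  }
  X <- as.matrix(data[predictors])
  y <- data[[response]]
  n <- nrow(X)
  D <- ncol(X)
  stopifnot(n >= 2, sigma2 > 0)
  y_mu <- mean(y)
  y_sd <- sd(y)
  constant <- !is.finite(y_sd) || y_sd < 1e-12
  if (constant) {
    return(structure(
      list(
        constant = TRUE, y_mu = y_mu, y_sd = 0, predictors = predictors,
        response = response, sigma2 = sigma2, n = n,
        lengthscales = rep(NA_real_, D)
      ),
      class = "gp_fit"
    ))
  }
  ys <- (y - y_mu) / y_sd
  if (is.null(init_lengthscales)) {
    init_lengthscales <- apply(X, 2, function(col) max(diff(range(col)), 1e-3))
  }
  if (length(init_lengthscales) == 1) init_lengthscales <- rep(init_lengthscales, D)
  stopifnot(length(init_lengthscales) == D, all(init_lengthscales > 0))

  l <- init_lengthscales
  best <- NULL
  if (optimize) {
    starts <- list(init_lengthscales, init_lengthscales / 2, init_lengthscales * 2)
    for (l0 in starts) {
      fit <- tryCatch(
        optim(
          par = log(l0),
          fn = function(th) -lml_with_grad(X, ys, th, sigma2)$value,
          gr = function(th) -lml_with_grad(X, ys, th, sigma2)$grad,
          method = "L-BFGS-B", control = list(maxit = maxit)
        ),
        error = function(e) NULL
      )
      if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
    if (is.null(best)) {
      warn("Evidence optimization failed for every start; keeping the initial length scales")
    } else {
      l <- exp(best$par)
    }
  }
  K <- ard_kernel(X, lengthscales = l)
  diag(K) <- diag(K) + sigma2
  L <- chol_or_abort(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  structure(
    list(
      constant = FALSE, X_train = X, y_train = y, y_mu = y_mu, y_sd = y_sd,
      lengthscales = setNames(l, predictors), sigma2 = sigma2,
      chol_K = L, alpha = alpha,
      log_evidence = -0.5 * sum(ys * alpha) - sum(log(diag(L))) - n / 2 * log(2 * pi),
      predictors = predictors, response = response, n = n,
      optimized = optimize && !is.null(best),
      init_lengthscales = init_lengthscales
    ),
    class = "gp_fit"
  )
}

#' @export
print.gp_fit <- function(x, ...) {
  if (isTRUE(x$constant)) {
    cat("<gp_fit> degenerate constant target, mean =", x$y_mu, "\n")
    return(invisible(x))
  }
  cat("<gp_fit> n = ", x$n, ", D = ", length(x$predictors),
    ", log evidence = ", format(x$log_evidence, digits = 6), "\n",
    sep = ""
  )
  invisible(x)
}

#' GP posterior mean prediction
#'
#' `y* = k(x*, X) (K + sigma2 I)^-1 y` on the standardized targets, then
#' transformed back to the original units. Far from all training points the
#' prediction decays to the training mean. Evaluated in chunks so that
#' millions of query points stay within memory.
#'
#' @param object A `gp_fit`.
#' @param new_data Data frame containing the predictor columns.
#' @param chunk_size Rows per kernel-evaluation chunk.
#' @param ... Ignored.
#' @return Numeric vector of posterior means (original units).
#' @export
predict.gp_fit <- function(object, new_data, chunk_size = 4000L, ...) {
  if (isTRUE(object$constant)) {
    return(rep(object$y_mu, nrow(as.data.frame(new_data))))
  }
  Xs <- as.matrix(tibble::as_tibble(new_data)[object$predictors])
  if (ncol(Xs) != ncol(object$X_train)) abort("Prediction input dimension mismatch")
  n <- nrow(Xs)
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk_size)) {
    idx <- i0:min(n, i0 + chunk_size - 1L)
    Ks <- ard_kernel(Xs[idx, , drop = FALSE], object$X_train, object$lengthscales)
    out[idx] <- as.numeric(Ks %*% object$alpha)
  }
  object$y_mu + object$y_sd * out
}

#' @rdname predict.gp_fit
#' @param gp A `gp_fit`.
#' @export
predict_mean <- function(gp, new_data) predict(gp, new_data)

#' @export
tidy.gp_fit <- function(x, ...) {
  tibble::tibble(
    term = x$predictors,
    lengthscale = as.numeric(x$lengthscales),
    relevance = 1 / as.numeric(x$lengthscales)^2
  )
}

#' @export
glance.gp_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, dims = length(x$predictors), sigma2 = x$sigma2,
    log_evidence = if (isTRUE(x$constant)) NA_real_ else x$log_evidence,
    constant = isTRUE(x$constant)
  )
}

#' Ordinary least squares baseline
#'
#' Linear regression with intercept on the same predictors as the GP;
#' warns on rank deficiency.
#'
#' @inheritParams fit_gp
#' @return Object of class `linear_fit` wrapping the `lm` fit.
#' @export
fit_linear <- function(data, response = "orifice_area_mm2", predictors = NULL) {
  data <- tibble::as_tibble(data)
  if (!response %in% names(data)) abort(paste0("Response column not found: ", response))
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], response)
  }
  stopifnot(nrow(data) > length(predictors))
  fml <- stats::reformulate(sprintf("`%s`", predictors), response = sprintf("`%s`", response))
  m <- stats::lm(fml, data = data)
  if (m$rank < length(predictors) + 1) {
    warn(paste0(
      "Rank-deficient design: rank ", m$rank, " < ", length(predictors) + 1,
      " coefficients"
    ))
  }
  structure(
    list(model = m, predictors = predictors, response = response),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("<linear_fit> ", length(x$predictors), " predictors, R2 = ",
    format(summary(x$model)$r.squared, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname fit_linear
#' @param object A `linear_fit`.
#' @param new_data Data frame with predictor columns.
#' @param ... Ignored.
#' @export
predict.linear_fit <- function(object, new_data, ...) {
  as.numeric(predict(object$model, newdata = tibble::as_tibble(new_data)))
}

#' @rdname fit_linear
#' @param m A `linear_fit`.
#' @export
predict_linear <- function(m, new_data) predict(m, new_data)

#' @export
tidy.linear_fit <- function(x, ...) {
  co <- stats::coef(x$model)
  tibble::tibble(term = names(co), estimate = as.numeric(co))
}

#' @export
glance.linear_fit <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    n = length(x$model$residuals), r_squared = s$r.squared,
    sigma = s$sigma, rank = x$model$rank
  )
}

#' Coefficient of determination
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; errors when the
#' targets have zero variance (undefined).
#'
#' @param y Observed values.
#' @param yhat Predictions.
#' @return Scalar, at most 1.
#' @export
r_squared <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) > 0)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) abort("R^2 is undefined: targets have zero variance")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Mean absolute percentage error
#'
#' `MAPE = mean(|y - yhat| / |y|)`, reported as a fraction (0.15, not 15%).
#' Targets with `|y| < min_abs` are excluded from the mean (the formula
#' divides by the target); the number excluded is reported via a message.
#'
#' @inheritParams r_squared
#' @param min_abs Exclusion threshold for near-zero targets (default 1e-6).
#' @return Scalar fraction, non-negative.
#' @export
mape <- function(y, yhat, min_abs = 1e-6) {
  stopifnot(length(y) == length(yhat), length(y) > 0)
  keep <- abs(y) >= min_abs
  if (!all(keep)) {
    inform(paste0("mape: excluded ", sum(!keep), " target(s) with |y| < ", min_abs))
  }
  if (!any(keep)) abort("MAPE is undefined: all targets are (near) zero")
  mean(abs(y[keep] - yhat[keep]) / abs(y[keep]))
}

#' Evaluate a fitted model on held-out data
#'
#' @param model A `gp_fit` or `linear_fit`.
#' @param data Held-out data containing predictors and response.
#' @param label Model label for the report row.
#' @param split_id Split identifier.
#' @return One-row tibble `model, split, r2, mape`.
#' @export
evaluate_fit <- function(model, data, label = class(model)[1], split_id = NA_integer_) {
  y <- tibble::as_tibble(data)[[model$response]]
  yhat <- predict(model, data)
  tibble::tibble(
    model = label, split = split_id,
    r2 = r_squared(y, yhat),
    mape = suppressMessages(mape(y, yhat))
  )
}

#' Choose the initial length scale by k-fold cross-validation
#'
#' Candidate initial length scales are multiples of the per-dimension input
#' range (geometric grid over `[0.1, 10]` by default). Each candidate is
#' scored by k-fold cross-validated R^2 of a GP whose length scales are
#' fixed at the candidate (no inner evidence optimization); the winner is
#' returned and is meant to seed [fit_gp()]. Ties go to the smaller
#' candidate.
#'
#' @inheritParams fit_gp
#' @param multipliers Candidate multipliers of the per-dimension range.
#' @param k_folds Number of folds (default 5).
#' @param seed Seed for the fold assignment.
#' @return Named list: `init` (length-scale vector), `multiplier`,
#'   `cv_table` (tibble of candidate mean R^2).
#' @export
cv_init_lengthscale <- function(data, response = "orifice_area_mm2", predictors = NULL,
                                multipliers = 10^seq(-1, 1, by = 0.5),
                                k_folds = 5, seed = 1, sigma2 = 1e-4) {
  data <- tibble::as_tibble(data)
  if (is.null(predictors)) {
    predictors <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], response)
  }
  n <- nrow(data)
  stopifnot(n >= k_folds)
  multipliers <- sort(multipliers)
  base_l <- apply(as.matrix(data[predictors]), 2, function(col) max(diff(range(col)), 1e-3))
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  score <- vapply(multipliers, function(m) {
    r2s <- vapply(seq_len(k_folds), function(k) {
      train <- data[folds != k, ]
      test <- data[folds == k, ]
      gp <- fit_gp(train, response, predictors,
        sigma2 = sigma2,
        init_lengthscales = m * base_l, optimize = FALSE
      )
      r_squared(test[[response]], predict(gp, test))
    }, numeric(1))
    mean(r2s)
  }, numeric(1))
  best <- which(score >= max(score) - 1e-12)[1] # ties -> smallest multiplier
  list(
    init = multipliers[best] * base_l,
    multiplier = multipliers[best],
    cv_table = tibble::tibble(multiplier = multipliers, mean_r2 = score)
  )
}
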