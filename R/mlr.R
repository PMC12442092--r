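#' Autoscale (z-score) descriptor columns
#'
#' Centers each column to mean 0 and scales to sample standard deviation 1
#' (ddof = 1), the transformation under which multilinear-regression
#' coefficients become directly comparable importances.
#'
#' @param X numeric matrix or data.frame of descriptor columns.
#' @return Matrix of scaled columns with attributes `center` and `scale`.
#' @export
#' @examples
#' autoscale(cbind(a = 1:3))
autoscale <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("`X` must be numeric", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  bad <- which(scl == 0 | !is.finite(scl))
  if (length(bad))
    stop("constant column(s): ", paste(colnames(X)[bad], collapse = ", "),
         call. = FALSE)
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  attr(Z, "center") <- ctr
  attr(Z, "scale") <- scl
  Z
}

# least squares with intercept via QR; returns coefficients (intercept first)
.ols_qr <- function(X, y) {
  A <- cbind(`(Intercept)` = 1, X)
  qrA <- qr(A)
  if (qrA$rank < ncol(A))
    stop("rank-deficient descriptor matrix", call. = FALSE)
  qr.coef(qrA, y)
}

#' Fit the multilinear barrier model
#'
#' Ordinary least squares (QR factorisation) of activation barriers on
#' descriptor columns, conventionally one alkylborane-side and one
#' ketone-side descriptor. Both the raw-descriptor form and the autoscaled
#' (standardized) form are stored; they give identical predictions, and the
#' standardized intercept equals the training-response mean.
#'
#' @param X data.frame or matrix of descriptor columns (n x p, p >= 1).
#' @param y activation barriers in kcal/mol.
#' @return An object of class `barrier_mlr` with raw and standardized
#'   coefficients, training centers/scales/ranges and fit statistics.
#' @export
#' @examples
#' d <- data.frame(N_prime = runif(10, 2, 5), eps_lumo_eV = runif(10, -3, -1))
#' fit_barrier_mlr(d, 30 - d$N_prime + 9 * d$eps_lumo_eV)
fit_barrier_mlr <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (nrow(X) != n) stop("`X` and `y` sizes disagree", call. = FALSE)
  if (n <= ncol(X) + 1) stop("need n > p + 1 observations", call. = FALSE)
  Z <- autoscale(X)
  coef_raw <- .ols_qr(X, y)
  coef_std <- .ols_qr(Z, y)
  fitted <- drop(cbind(1, X) %*% coef_raw)
  model <- structure(list(
    descriptors = colnames(X),
    coef_raw = coef_raw,
    coef_std = coef_std,
    center = attr(Z, "center"),
    scale = attr(Z, "scale"),
    ranges = apply(X, 2, range),
    n = n,
    fitted = fitted,
    residuals = y - fitted,
    y_mean = mean(y)
  ), class = "barrier_mlr")
  model$stats <- evaluate_fit(model, X, y)
  model
}

#' @export
print.barrier_mlr <- function(x, ...) {
  terms <- paste(sprintf("%+.2f x %s", x$coef_std[-1L], x$descriptors),
                 collapse = " ")
  cat(sprintf("<barrier_mlr> dG^ = %.2f %s  (standardized; n = %d, R2 = %.3f)\n",
              x$coef_std[1L], terms, x$n, x$stats$R2))
  invisible(x)
}

#' Fit statistics
#'
#' `R2 = 1 - SS_res/SS_tot`, `rmse = sqrt(SS_res/n)` and `MAE` of a fitted
#' barrier model on data. The bias-corrected `rmse_np = sqrt(SS_res/(n-p-1))`
#' is reported alongside since both denominators are in circulation.
#'
#' @param model a [fit_barrier_mlr()] model.
#' @param X descriptor columns.
#' @param y observed barriers.
#' @return List of class `fit_stats`: `R2`, `rmse`, `mae`, `rmse_np`, `n`.
#' @export
evaluate_fit <- function(model, X, y) {
  stopifnot(inherits(model, "barrier_mlr"))
  n <- length(y)
  if (n == 0L) stop("no observations", call. = FALSE)
  res <- y - predict(model, X, warn_extrapolation = FALSE)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  p <- length(model$descriptors)
  structure(list(R2 = 1 - ss_res / ss_tot,
                 rmse = sqrt(ss_res / n),
                 mae = mean(abs(res)),
                 rmse_np = sqrt(ss_res / max(n - p - 1, 1)),
                 n = n),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("R2 = %.3f, rmse = %.2f, MAE = %.2f kcal/mol (n = %d)\n",
              x$R2, x$rmse, x$mae, x$n))
  invisible(x)
}

#' Predict activation barriers
#'
#' Raw-form evaluation of the fitted plane. Observations with any descriptor
#' outside the training range are flagged as extrapolations (attribute
#' `extrapolated`, with an optional warning): the model is trusted only while
#' substrates stay close to the training set.
#'
#' @param object a [fit_barrier_mlr()] model.
#' @param newdata data.frame/matrix containing the model's descriptor
#'   columns.
#' @param warn_extrapolation warn when a point falls outside the training
#'   box.
#' @param ... unused.
#' @return Numeric vector of barriers (kcal/mol) with attribute
#'   `extrapolated`.
#' @export
predict.barrier_mlr <- function(object, newdata, warn_extrapolation = TRUE,
                                ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$descriptors, names(newdata))
  if (length(miss))
    stop("missing descriptor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(newdata[object$descriptors])
  if (any(!is.finite(X))) stop("non-finite descriptor values", call. = FALSE)
  pred <- drop(cbind(1, X) %*% object$coef_raw)
  lo <- object$ranges[1L, ]; hi <- object$ranges[2L, ]
  extra <- apply(X, 1, function(r) any(r < lo | r > hi))
  if (warn_extrapolation && any(extra))
    warning(sum(extra), " point(s) outside the training descriptor range",
            call. = FALSE)
  attr(pred, "extrapolated") <- extra
  pred
}

#' Leave-one-out cross-validation
#'
#' Each point is predicted from a model refit (autoscaling included) on the
#' remaining n - 1 points. `R2` is the predictive `1 - PRESS/SS_tot`; rmse
#' and MAE are computed from the out-of-sample residuals.
#'
#' @inheritParams fit_barrier_mlr
#' @return A `fit_stats` list, plus element `press_residuals`.
#' @export
loo_cv <- function(X, y) {
  X <- as.data.frame(X)
  n <- length(y)
  if (n <= 4) stop("need n > 4 for leave-one-out", call. = FALSE)
  res <- vapply(seq_len(n), function(i) {
    m <- tryCatch(fit_barrier_mlr(X[-i, , drop = FALSE], y[-i]),
                  error = function(e)
                    stop("fold leaving out point ", i, ": ",
                         conditionMessage(e), call. = FALSE))
    y[i] - predict(m, X[i, , drop = FALSE], warn_extrapolation = FALSE)
  }, numeric(1))
  press <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  out <- structure(list(R2 = 1 - press / ss_tot,
                        rmse = sqrt(press / n),
                        mae = mean(abs(res)),
                        rmse_np = sqrt(press / max(n - ncol(X) - 1, 1)),
                        n = n),
                   class = "fit_stats")
  out$press_residuals <- res
  out
}

#' k-fold cross-validation
#'
#' Deterministic seeded shuffle into `k` near-equal folds; each fold is
#' predicted by a model (autoscaling refit) trained on the others, and the
#' pooled out-of-fold residuals are scored. `k = n` reduces to [loo_cv()].
#'
#' @inheritParams fit_barrier_mlr
#' @param k number of folds (default 4).
#' @param seed integer seed fixing the fold assignment.
#' @return A `fit_stats` list, plus the fold assignment as element `folds`.
#' @export
kfold_cv <- function(X, y, k = 4, seed = 1) {
  X <- as.data.frame(X)
  n <- length(y)
  if (k > n) stop("`k` cannot exceed the number of observations", call. = FALSE)
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  folds <- local({
    set.seed(seed)
    sample(rep_len(seq_len(k), n))
  })
  res <- numeric(n)
  for (f in seq_len(k)) {
    test <- folds == f
    m <- fit_barrier_mlr(X[!test, , drop = FALSE], y[!test])
    res[test] <- y[test] - predict(m, X[test, , drop = FALSE],
                                   warn_extrapolation = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  out <- structure(list(R2 = 1 - sum(res^2) / ss_tot,
                        rmse = sqrt(mean(res^2)),
                        mae = mean(abs(res)),
                        rmse_np = sqrt(sum(res^2) / max(n - ncol(X) - 1, 1)),
                        n = n),
                   class = "fit_stats")
  out$folds <- folds
  out
}

#' Exhaustive search for the best donor/acceptor descriptor pair
#'
#' Fits every (alkylborane descriptor, ketone descriptor) combination and
#' ranks them by training R-squared, with the leave-one-out R-squared as a
#' deterministic tiebreak.
#'
#' @param data data.frame holding one row per substrate pairing.
#' @param borane_cols,ketone_cols candidate column names for the donor and
#'   acceptor side.
#' @param y activation barriers (kcal/mol).
#' @return List with `best` (character vector of the two chosen columns),
#'   `model` (the refitted winner) and `ranking` (data.frame of all pairs).
#' @export
best_pair_search <- function(data, borane_cols, ketone_cols, y) {
  data <- as.data.frame(data)
  if (!length(borane_cols) || !length(ketone_cols))
    stop("need at least one candidate column per side", call. = FALSE)
  miss <- setdiff(c(borane_cols, ketone_cols), names(data))
  if (length(miss))
    stop("unknown column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  grid <- expand.grid(borane = borane_cols, ketone = ketone_cols,
                      stringsAsFactors = FALSE)
  score <- t(apply(grid, 1, function(pr) {
    X <- data[, pr, drop = FALSE]
    m <- fit_barrier_mlr(X, y)
    c(R2 = m$stats$R2, R2_loo = loo_cv(X, y)$R2)
  }))
  ranking <- cbind(grid, score)
  ord <- order(-ranking$R2, -ranking$R2_loo, ranking$borane, ranking$ketone)
  ranking <- ranking[ord, ]
  rownames(ranking) <- NULL
  best <- c(ranking$borane[1L], ranking$ketone[1L])
  list(best = best,
       model = fit_barrier_mlr(data[, best, drop = FALSE], y),
       ranking = ranking)
}
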