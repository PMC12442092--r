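test_that("autoscaling gives mean-0, sd-1 columns and inverts cleanly", {
  Z <- autoscale(cbind(a = c(1, 2, 3)))
  expect_equal(attr(Z, "center"), c(a = 2))
  expect_equal(attr(Z, "scale"), c(a = 1))
  expect_equal(as.vector(Z), c(-1, 0, 1))
  set.seed(8)
  X <- cbind(u = rnorm(20, 5, 3), v = runif(20, -2, 2))
  Z <- autoscale(X)
  expect_equal(colMeans(Z), c(u = 0, v = 0), tolerance = 1e-12)
  expect_equal(apply(Z, 2, sd), c(u = 1, v = 1), tolerance = 1e-12)
  # round trip
  back <- sweep(sweep(Z, 2, attr(Z, "scale"), "*"), 2, -attr(Z, "center"))
  expect_equal(back, X, tolerance = 1e-12, ignore_attr = TRUE)
  # affine transforms of a column change nothing after scaling
  X2 <- X
  X2[, "u"] <- 3.7 * X[, "u"] - 11
  expect_equal(autoscale(X2), Z, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(autoscale(cbind(c1 = rep(2, 5), ok = 1:5)), "c1")
})

test_that("least-squares fit agrees with the reference implementation", {
  set.seed(21)
  X <- data.frame(N_prime = runif(28, 2, 5), eps_lumo_eV = runif(28, -3, -0.5))
  y <- 30 - 0.9 * X$N_prime + 9 * X$eps_lumo_eV + rnorm(28)
  m <- fit_barrier_mlr(X, y)
  ref <- lm(y ~ N_prime + eps_lumo_eV, data = X)
  expect_equal(unname(m$coef_raw), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(m$fitted), unname(fitted(ref)), tolerance = 1e-8)
  # standardized and raw forms predict identically; standardized intercept
  # is the training mean
  pz <- m$coef_std[1] +
    as.matrix(sweep(sweep(X, 2, m$center), 2, m$scale, "/")) %*% m$coef_std[-1]
  expect_equal(drop(pz), predict(m, X), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unname(m$coef_std[1]), mean(y), tolerance = 1e-10)
  expect_equal(sum(m$residuals), 0, tolerance = 1e-8)
  # noiseless data: exact plane
  y0 <- 30 - 0.9 * X$N_prime + 9 * X$eps_lumo_eV
  m0 <- fit_barrier_mlr(X, y0)
  expect_lt(max(abs(m0$residuals)), 1e-10)
  expect_equal(m0$stats$R2, 1, tolerance = 1e-12)
  # rank deficiency is an error
  expect_error(fit_barrier_mlr(cbind(X, dup = X$N_prime), y), "rank")
})

test_that("fit statistics follow their definitions", {
  set.seed(3)
  X <- data.frame(a = rnorm(15), b = rnorm(15))
  y <- 1 + X$a - 2 * X$b + rnorm(15, 0, 0.5)
  m <- fit_barrier_mlr(X, y)
  st <- evaluate_fit(m, X, y)
  res <- y - predict(m, X)
  expect_equal(st$R2, 1 - sum(res^2) / sum((y - mean(y))^2))
  expect_equal(st$rmse, sqrt(mean(res^2)))
  expect_equal(st$mae, mean(abs(res)))
  expect_gte(st$rmse, st$mae)
  # constant-prediction degenerate model scores R2 = 0
  mc <- m
  mc$coef_raw[] <- c(mean(y), 0, 0)
  expect_equal(evaluate_fit(mc, X, y)$R2, 0, tolerance = 1e-10)
})

test_that("LOO residuals equal ordinary residuals over one minus leverage", {
  set.seed(13)
  X <- data.frame(a = runif(20, 2, 5), b = runif(20, -3, -1))
  y <- 28 - X$a + 8 * X$b + rnorm(20, 0, 1.2)
  cv <- loo_cv(X, y)
  ref <- lm(y ~ a + b, data = X)
  press_ref <- residuals(ref) / (1 - hatvalues(ref))
  expect_equal(unname(cv$press_residuals), unname(press_ref), tolerance = 1e-8)
  expect_equal(cv$R2, 1 - sum(press_ref^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)
  # noiseless data: LOO rmse ~ 0
  cv0 <- loo_cv(X, 28 - X$a + 8 * X$b)
  expect_lt(cv0$rmse, 1e-9)
})

test_that("LOO error is rarely below the training error on noisy data", {
  worse <- vapply(1:100, function(s) {
    set.seed(s)
    X <- data.frame(a = runif(20, 2, 5), b = runif(20, -3, -1))
    y <- 28 - X$a + 8 * X$b + rnorm(20)
    loo_cv(X, y)$rmse >= fit_barrier_mlr(X, y)$stats$rmse
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})

test_that("k-fold CV is seeded, deterministic, and reduces to LOO at k = n", {
  set.seed(17)
  X <- data.frame(a = runif(16, 2, 5), b = runif(16, -3, -1))
  y <- 28 - X$a + 8 * X$b + rnorm(16)
  k1 <- kfold_cv(X, y, k = 4, seed = 99)
  k2 <- kfold_cv(X, y, k = 4, seed = 99)
  expect_identical(k1$folds, k2$folds)
  expect_equal(k1$R2, k2$R2)
  expect_false(identical(kfold_cv(X, y, k = 4, seed = 100)$folds, k1$folds))
  kn <- kfold_cv(X, y, k = length(y), seed = 1)
  expect_equal(kn$R2, loo_cv(X, y)$R2, tolerance = 1e-10)
  expect_lt(kfold_cv(X, 28 - X$a + 8 * X$b, k = 4, seed = 1)$rmse, 1e-9)
  expect_error(kfold_cv(X, y, k = 20, seed = 1), "exceed")
})

test_that("exhaustive pair search finds the planted generating pair", {
  set.seed(31)
  n <- 28
  d <- data.frame(
    d1 = runif(n, 2, 5), d2 = rnorm(n), d3 = rnorm(n),      # borane side
    d7 = runif(n, -3, -0.5), d8 = rnorm(n), d9 = rnorm(n))  # ketone side
  y <- 30 - 2 * d$d1 + 9 * d$d7 + rnorm(n, 0, 0.3)
  res <- best_pair_search(d, borane_cols = c("d1", "d2", "d3"),
                          ketone_cols = c("d7", "d8", "d9"), y)
  expect_equal(res$best, c("d1", "d7"))
  # ranking invariant under candidate ordering
  res2 <- best_pair_search(d, borane_cols = c("d3", "d1", "d2"),
                           ketone_cols = c("d9", "d7", "d8"), y)
  expect_equal(res2$best, res$best)
  expect_equal(res2$ranking$R2, res$ranking$R2, tolerance = 1e-12)
  # single candidate pair: returned as-is
  one <- best_pair_search(d, "d2", "d8", y)
  expect_equal(one$best, c("d2", "d8"))
})

test_that("prediction flags extrapolation and honours the centering identity", {
  set.seed(41)
  X <- data.frame(a = runif(20, 2, 5), b = runif(20, -3, -1))
  y <- 28 - X$a + 8 * X$b + rnorm(20, 0, 0.5)
  m <- fit_barrier_mlr(X, y)
  # descriptors at the training means predict the training mean
  expect_equal(predict(m, data.frame(a = mean(X$a), b = mean(X$b))),
               mean(y), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(predict(m, X), m$fitted, tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(p <- predict(m, data.frame(a = 10, b = -2)), "outside")
  expect_true(attr(p, "extrapolated"))
  expect_error(predict(m, data.frame(a = 1)), "missing descriptor")
})

test_that("predictions are invariant under affine descriptor rescaling", {
  set.seed(51)
  X <- data.frame(a = runif(20, 2, 5), b = runif(20, -3, -1))
  y <- 28 - X$a + 8 * X$b + rnorm(20, 0, 0.5)
  m <- fit_barrier_mlr(X, y)
  X2 <- data.frame(a = 2 * X$a + 3, b = -0.5 * X$b + 1)
  m2 <- fit_barrier_mlr(X2, y)
  expect_equal(predict(m2, X2), predict(m, X), tolerance = 1e-8,
               ignore_attr = TRUE)
  # standardized slopes agree up to the sign flips of the transforms
  expect_equal(abs(unname(m2$coef_std[-1])), abs(unname(m$coef_std[-1])),
               tolerance = 1e-8)
})
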