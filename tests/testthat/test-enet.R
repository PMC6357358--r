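make_xy <- function(n = 60, p = 8, causal = c(f1 = 1.5, f3 = -1),
                    noise = 0.3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), p, n,
              dimnames = list(paste0("f", seq_len(p)),
                              paste0("s", seq_len(n))))
  y <- drop(crossprod(x[names(causal), , drop = FALSE], causal)) +
    rnorm(n, sd = noise)
  list(x = x, y = setNames(y, colnames(x)))
}

test_that("the hyperparameter grid is the stated Cartesian product", {
  g <- make_grid(enet_config())
  expect_equal(nrow(g), 2500L)
  expect_equal(min(g$lambda), exp(-6))
  expect_equal(max(g$lambda), exp(5))
  expect_equal(sort(unique(g$alpha)), seq(0.2, 1, length.out = 10))
  # alpha-major ordering
  expect_equal(g$alpha[1:250], rep(0.2, 250))
  g1 <- make_grid(enet_config(alpha = 1, lambda = 0.5))
  expect_equal(g1, data.frame(alpha = 1, lambda = 0.5))
  expect_error(enet_config(alpha = numeric(0)), "non-empty")
  expect_error(enet_config(lambda = c(1, -2)), "positive")
  expect_error(enet_config(alpha = 1.5), "\\[0, 1\\]")
})

test_that("the fully penalized limit is the intercept-only model", {
  d <- make_xy()
  fit <- fit_elastic_net_cv(d$x, d$y,
                            enet_config(alpha = c(0.5, 1), lambda = exp(5),
                                        n_folds = 5))
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, mean(d$y))
  expect_equal(unname(predict(fit, d$x)), rep(mean(d$y), 60))
  # held-out MSE of the null model is about the variance of y
  expect_equal(fit$min_cv_mse, var(d$y), tolerance = 0.15)
})

test_that("the vanishing-penalty fit reproduces ordinary least squares", {
  d <- make_xy(n = 20, p = 3, causal = c(f1 = 1, f2 = -2, f3 = 0.5),
               seed = 2)
  fit <- fit_elastic_net_cv(d$x, d$y,
                            enet_config(alpha = 0.5, lambda = 1e-8,
                                        n_folds = 5))
  ols <- lm(d$y ~ t(d$x))
  expect_equal(unname(fit$coefficients), unname(coef(ols)[-1]),
               tolerance = 1e-4)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-4)
  expect_equal(unname(predict(fit, d$x)), unname(fitted(ols)),
               tolerance = 1e-4)
})

test_that("minimal CV MSE never exceeds the intercept-only CV MSE", {
  d <- make_xy(seed = 3)
  cfg <- enet_config(alpha = c(0.2, 0.6, 1),
                     lambda = exp(seq(-6, 5, length.out = 40)), n_folds = 5)
  fit <- fit_elastic_net_cv(d$x, d$y, cfg)
  folds <- fit$folds
  null_mse <- mean(vapply(seq_len(cfg$n_folds), function(f) {
    mean((d$y[names(folds)[folds == f]] -
            mean(d$y[names(folds)[folds != f]]))^2)
  }, numeric(1)))
  expect_lte(fit$min_cv_mse, null_mse + 1e-8)
  expect_equal(fit$min_cv_mse, min(fit$cv_mse))
})

test_that("fits are deterministic and invariant to sample order", {
  d <- make_xy(seed = 4)
  cfg <- enet_config(alpha = c(0.4, 0.8),
                     lambda = exp(seq(-5, 3, length.out = 30)), n_folds = 5,
                     fold_seed = 11)
  f1 <- fit_elastic_net_cv(d$x, d$y, cfg)
  f2 <- fit_elastic_net_cv(d$x, d$y, cfg)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$cv_mse, f2$cv_mse)
  perm <- sample(ncol(d$x))
  f3 <- fit_elastic_net_cv(d$x[, perm], d$y[perm], cfg)
  expect_identical(f3$coefficients, f1$coefficients)
  expect_identical(f3$cv_mse, f1$cv_mse)
  expect_identical(f3$alpha, f1$alpha)
  expect_identical(f3$lambda, f1$lambda)
})

test_that("sparsity is non-increasing in lambda at fixed alpha", {
  d <- make_xy(n = 80, p = 12, causal = c(f1 = 2, f4 = -1.5, f7 = 1),
               seed = 5)
  lams <- exp(seq(-6, 2, length.out = 12))
  nnz <- vapply(lams, function(l) {
    fit <- fit_elastic_net_cv(d$x, d$y,
                              enet_config(alpha = 0.6, lambda = l,
                                          n_folds = 5))
    sum(fit$coefficients != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) <= 0))
})

test_that("samples are matched by id and missing responses dropped", {
  d <- make_xy(seed = 6)
  y <- d$y
  y[c("s3", "s10")] <- NA
  fit <- fit_elastic_net_cv(d$x, y, enet_config(alpha = 0.5,
                                                lambda = exp(seq(-4, 1,
                                                                 length.out = 10)),
                                                n_folds = 5))
  expect_equal(fit$n_samples, 58L)
  expect_false(any(c("s3", "s10") %in% fit$sample_ids))
  expect_error(fit_elastic_net_cv(d$x, d$y[1:5],
                                  enet_config(n_folds = 10)),
               "fewer usable samples")
  expect_warning(fit_elastic_net_cv(d$x, setNames(rep(2, 60), names(d$y)),
                                    enet_config(n_folds = 5)),
                 "constant response")
})

test_that("prediction applies the linear model and validates features", {
  d <- make_xy(seed = 7)
  fit <- fit_elastic_net_cv(d$x, d$y,
                            enet_config(alpha = 1,
                                        lambda = exp(seq(-4, 0,
                                                         length.out = 10)),
                                        n_folds = 5))
  manual <- drop(crossprod(d$x, fit$coefficients)) + fit$intercept
  expect_equal(predict(fit, d$x), manual)
  # single-feature arithmetic: beta = 2, intercept 1, x = 3 -> 7
  toy <- fit
  toy$feature_names <- "f"
  toy$coefficients <- c(f = 2)
  toy$intercept <- 1
  nx <- matrix(3, 1, 1, dimnames = list("f", "sNew"))
  expect_equal(unname(predict(toy, nx)), 7)
  expect_error(predict(fit, d$x[-1, , drop = FALSE]), "absent.*f1")
  # residuals are y minus fitted on the training samples
  expect_equal(residuals(fit), d$y[fit$sample_ids] - fit$fitted)
})

test_that("nonzero_features orders selected features as requested", {
  d <- make_xy(seed = 8)
  fit <- fit_elastic_net_cv(d$x, d$y,
                            enet_config(alpha = 1, lambda = 0.05,
                                        n_folds = 5))
  fit$coefficients[] <- 0
  expect_equal(nrow(nonzero_features(fit)), 0L)
  fit$coefficients[c("f1", "f2")] <- c(0.5, -0.2)
  expect_equal(nonzero_features(fit),
               data.frame(feature = c("f1", "f2"),
                          coefficient = c(0.5, -0.2),
                          stringsAsFactors = FALSE))
  fit$coefficients[] <- 0
  fit$coefficients[c("f1", "f2")] <- c(0.1, -0.3)
  expect_equal(nonzero_features(fit, "abs_desc")$feature, c("f2", "f1"))
})

test_that("fold assignment is balanced and id-driven", {
  ids <- sprintf("cell%03d", 1:57)
  f <- pathdrive:::.fold_assignment(ids, 10, 3)
  expect_true(all(table(f) %in% c(5L, 6L)))
  expect_identical(pathdrive:::.fold_assignment(rev(ids), 10, 3)[ids], f[ids])
  expect_false(identical(pathdrive:::.fold_assignment(ids, 10, 4), f))
})
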