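#' Elastic-net hyperparameter grid configuration
#'
#' Defaults reproduce a 2500-point grid: 10 mixing values alpha equally
#' spaced over `[0.2, 1]` and 250 penalty strengths lambda log-equally spaced
#' over `[exp(-6), exp(5)]`, searched by k-fold cross-validation (default 10
#' folds). The penalty follows the glmnet convention,
#' `(1/2n) * RSS + lambda * (alpha * |beta|_1 + (1 - alpha)/2 * |beta|_2^2)`,
#' with features standardized internally by default and coefficients reported
#' on the original scale.
#'
#' @param alpha numeric vector of mixing parameters in `[0, 1]`.
#' @param lambda numeric vector of positive penalty strengths.
#' @param n_folds number of CV folds (>= 2, default 10).
#' @param fold_seed integer seed for the deterministic fold assignment.
#' @param standardize standardize features inside the fit (default `TRUE`).
#' @return Object of class `enet_config`.
#' @export
enet_config <- function(alpha = seq(0.2, 1, length.out = 10),
                        lambda = exp(seq(-6, 5, length.out = 250)),
                        n_folds = 10L, fold_seed = 1L, standardize = TRUE) {
  if (length(alpha) == 0L || length(lambda) == 0L) {
    stop("alpha and lambda grids must be non-empty")
  }
  if (any(alpha < 0 | alpha > 1)) stop("alpha values must lie in [0, 1]")
  if (any(lambda <= 0)) stop("lambda values must be positive")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(list(alpha = as.numeric(alpha), lambda = as.numeric(lambda),
                 n_folds = as.integer(n_folds),
                 fold_seed = as.integer(fold_seed),
                 standardize = isTRUE(standardize)),
            class = "enet_config")
}

#' Expand a configuration into the ordered (alpha, lambda) grid
#'
#' Cartesian product in alpha-major order: all lambda values for the first
#' alpha, then the next alpha, and so on. The default configuration yields
#' exactly 2500 rows with lambda endpoints `exp(-6)` and `exp(5)` included.
#'
#' @param config an [enet_config()].
#' @return Data frame with columns `alpha` and `lambda`.
#' @export
make_grid <- function(config = enet_config()) {
  stopifnot(inherits(config, "enet_config"))
  data.frame(alpha = rep(config$alpha, each = length(config$lambda)),
             lambda = rep(config$lambda, times = length(config$alpha)))
}

# 32-bit FNV-1a-style hash of "id\rseed", kept exact in doubles (mod 2^31).
.id_hash <- function(ids, seed) {
  vapply(ids, function(id) {
    h <- 2166136261
    for (b in utf8ToInt(paste0(id, "\r", seed))) {
      h <- (bitwXor(h %% 2^31, b) * 16777619) %% 2^31
    }
    h
  }, numeric(1))
}

# Deterministic, row-order-invariant fold assignment: samples are ordered by
# (hash(id, seed), id) and folds dealt round-robin, so folds are balanced and
# depend only on the sample ids.
.fold_assignment <- function(ids, n_folds, fold_seed) {
  ord <- order(.id_hash(ids, fold_seed), ids)
  folds <- integer(length(ids))
  folds[ord] <- rep_len(seq_len(n_folds), length(ids))
  stats::setNames(folds, ids)
}

# Descending lambda path for glmnet: the requested grid, log-densified and
# extended so warm starts are stable even for single-lambda requests.
.lambda_path <- function(lambda) {
  lo <- min(lambda)
  hi <- max(lambda)
  extra <- if (hi > lo) {
    exp(seq(log(hi), log(lo), length.out = 100L))
  } else {
    hi * 10^seq(4, 0, length.out = 25L)
  }
  sort(unique(c(lambda, extra)), decreasing = TRUE)
}

#' Fit a cross-validated elastic-net drug-response model
#'
#' Fits penalized linear models of a continuous response (log-IC50) on
#' pathway-activity or gene-expression features over the full
#' (alpha, lambda) grid of `config`, selecting the grid point with minimal
#' mean cross-validated MSE and refitting on all samples there. Samples are
#' matched by id between `features` and `response`; samples with a missing
#' response are dropped. Fold assignment is a deterministic function of the
#' sample ids and `fold_seed`, and samples are processed in sorted-id order,
#' so the fit is invariant to input row order and bit-reproducible.
#'
#' Ties on the CV surface (within 1e-12 of the minimum) are broken toward
#' larger lambda (sparser), then larger alpha.
#'
#' @param features numeric matrix, features x samples, with dimnames (an
#'   `activity_matrix` or an expression matrix).
#' @param response named numeric vector of responses (names = sample ids),
#'   or a one-column samples x drugs matrix; `NA` entries are dropped.
#' @param config an [enet_config()].
#' @return Object of class `pd_enet` with elements `feature_names`,
#'   `intercept`, `coefficients` (original feature scale; exact zeros mark
#'   unselected features), `alpha`, `lambda`, `cv_mse` (alpha x lambda matrix
#'   of mean held-out MSE), `min_cv_mse`, `n_samples`, `sample_ids`, `folds`,
#'   `fitted`, `y` and `config`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(50 * 6), 6, 50,
#'             dimnames = list(paste0("f", 1:6), paste0("s", 1:50)))
#' y <- stats::setNames(2 * x[1, ] + rnorm(50, sd = 0.3), colnames(x))
#' fit <- fit_elastic_net_cv(x, y, enet_config(n_folds = 5))
#' nonzero_features(fit)
#' @export
fit_elastic_net_cv <- function(features, response, config = enet_config()) {
  stopifnot(inherits(config, "enet_config"), is.matrix(features))
  if (is.matrix(response)) {
    if (ncol(response) != 1L) stop("response matrix must have one column")
    response <- stats::setNames(response[, 1L], rownames(response))
  }
  if (is.null(names(response)) || is.null(colnames(features))) {
    stop("features and response must carry sample ids")
  }
  response <- response[!is.na(response)]
  ids <- sort(intersect(colnames(features), names(response)))
  n <- length(ids)
  if (n < config$n_folds) {
    stop("fewer usable samples (", n, ") than folds (", config$n_folds, ")")
  }
  x <- t(features[, ids, drop = FALSE])
  if (anyNA(x)) stop("missing feature values are not allowed")
  y <- as.numeric(response[ids])
  feat <- colnames(x)

  if (stats::var(y) == 0) {
    warning("constant response; returning intercept-only model")
    cv <- matrix(0, length(config$alpha), length(config$lambda),
                 dimnames = list(alpha = format(config$alpha, digits = 6),
                                 lambda = format(config$lambda, digits = 6)))
    return(structure(list(
      feature_names = feat, intercept = mean(y),
      coefficients = stats::setNames(numeric(length(feat)), feat),
      alpha = max(config$alpha), lambda = max(config$lambda),
      cv_mse = cv, min_cv_mse = 0, n_samples = n, sample_ids = ids,
      folds = .fold_assignment(ids, config$n_folds, config$fold_seed),
      fitted = stats::setNames(rep(mean(y), n), ids),
      y = stats::setNames(y, ids), config = config,
      call = match.call()), class = "pd_enet"))
  }

  folds <- .fold_assignment(ids, config$n_folds, config$fold_seed)
  path <- .lambda_path(config$lambda)
  li <- match(config$lambda, path)
  cv <- matrix(NA_real_, length(config$alpha), length(config$lambda),
               dimnames = list(alpha = format(config$alpha, digits = 6),
                               lambda = format(config$lambda, digits = 6)))
  for (a in seq_along(config$alpha)) {
    fold_mse <- matrix(NA_real_, config$n_folds, length(config$lambda))
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f
      fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr],
                            alpha = config$alpha[a], lambda = path,
                            standardize = config$standardize,
                            thresh = 1e-10, maxit = 1e6)
      pr <- stats::predict(fit, newx = x[!tr, , drop = FALSE])[, li,
                                                               drop = FALSE]
      fold_mse[f, ] <- colMeans((pr - y[!tr])^2)
    }
    cv[a, ] <- colMeans(fold_mse)
  }
  m <- min(cv)
  cand <- which(cv <= m + 1e-12, arr.ind = TRUE)
  lam_cand <- config$lambda[cand[, 2L]]
  best_lam <- max(lam_cand)
  cand <- cand[lam_cand == best_lam, , drop = FALSE]
  a_star <- max(config$alpha[cand[, 1L]])

  full <- glmnet::glmnet(x, y, alpha = a_star, lambda = path,
                         standardize = config$standardize,
                         thresh = 1e-10, maxit = 1e6)
  cf <- as.numeric(stats::coef(full)[, which.min(abs(full$lambda - best_lam))])
  coefs <- stats::setNames(cf[-1L], feat)
  intercept <- cf[1L]
  fitted <- drop(x %*% coefs) + intercept
  structure(list(feature_names = feat, intercept = intercept,
                 coefficients = coefs, alpha = a_star, lambda = best_lam,
                 cv_mse = cv, min_cv_mse = m, n_samples = n,
                 sample_ids = ids, folds = folds,
                 fitted = stats::setNames(fitted, ids),
                 y = stats::setNames(y, ids), config = config,
                 call = match.call()),
            class = "pd_enet")
}

#' Predict drug response from a fitted elastic-net model
#'
#' @param object a `pd_enet` fit.
#' @param features numeric matrix, features x samples; must contain every
#'   feature of the model (extra rows are ignored).
#' @param ... ignored.
#' @return Named numeric vector of predictions, one per sample column.
#' @export
predict.pd_enet <- function(object, features, ...) {
  stopifnot(is.matrix(features))
  missing <- setdiff(object$feature_names, rownames(features))
  if (length(missing)) {
    stop("features absent from new data: ", paste(missing, collapse = ", "))
  }
  xb <- crossprod(features[object$feature_names, , drop = FALSE],
                  object$coefficients)
  stats::setNames(drop(xb) + object$intercept, colnames(features))
}

#' @export
coef.pd_enet <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
residuals.pd_enet <- function(object, ...) {
  if (is.null(object$y)) stop("model carries no training data")
  object$y - object$fitted
}

#' @export
print.pd_enet <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("Cross-validated elastic-net model (pd_enet)\n")
  cat(sprintf("  n = %d samples, %d feature(s), %d nonzero coefficient(s)\n",
              x$n_samples, length(x$feature_names), nz))
  cat(sprintf("  selected alpha = %.4g, lambda = %.6g, min CV MSE = %.6g\n",
              x$alpha, x$lambda, x$min_cv_mse))
  invisible(x)
}

#' @export
summary.pd_enet <- function(object, ...) {
  nzf <- nonzero_features(object)
  out <- list(n_samples = object$n_samples,
              n_features = length(object$feature_names),
              n_nonzero = nrow(nzf),
              alpha = object$alpha, lambda = object$lambda,
              min_cv_mse = object$min_cv_mse,
              top_features = utils::head(nonzero_features(object, "abs_desc"),
                                         10L))
  class(out) <- "summary.pd_enet"
  out
}

#' @export
print.summary.pd_enet <- function(x, ...) {
  cat(sprintf(
    "elastic net: n = %d, p = %d, nonzero = %d\nalpha = %.4g, lambda = %.6g, min CV MSE = %.6g\n",
    x$n_samples, x$n_features, x$n_nonzero, x$alpha, x$lambda, x$min_cv_mse))
  if (nrow(x$top_features)) {
    cat("top features by |coefficient|:\n")
    print(x$top_features, row.names = FALSE)
  }
  invisible(x)
}

#' Plot the cross-validation MSE surface of a fit
#'
#' One curve of mean held-out MSE versus `log(lambda)` per alpha value, with
#' the selected grid point marked.
#'
#' @param x a `pd_enet` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pd_enet <- function(x, ...) {
  if (is.null(x$cv_mse)) stop("model carries no CV surface")
  lam <- x$config$lambda
  graphics::matplot(log(lam), t(x$cv_mse), type = "l", lty = 1,
                    xlab = "log(lambda)", ylab = "mean CV MSE",
                    main = "elastic-net CV surface (one curve per alpha)",
                    ...)
  graphics::points(log(x$lambda), x$min_cv_mse, pch = 19)
  invisible(x)
}

#' Nonzero coefficients of a fitted model
#'
#' Elastic net performs feature selection: the features with strictly nonzero
#' weights are the ones predictive of response. `signed_desc` ordering
#' (default) reproduces the waterfall layout used to rank selected pathways
#' by their model coefficient; `abs_desc` orders by magnitude.
#'
#' @param model a `pd_enet` fit.
#' @param order `"signed_desc"` or `"abs_desc"`.
#' @return Data frame with columns `feature` and `coefficient` (possibly
#'   zero rows).
#' @export
nonzero_features <- function(model, order = c("signed_desc", "abs_desc")) {
  order <- match.arg(order)
  stopifnot(inherits(model, "pd_enet"))
  nz <- model$coefficients[model$coefficients != 0]
  o <- if (order == "signed_desc") {
    base::order(nz, decreasing = TRUE)
  } else {
    base::order(abs(nz), decreasing = TRUE)
  }
  data.frame(feature = names(nz)[o], coefficient = unname(nz[o]),
             stringsAsFactors = FALSE)
}
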