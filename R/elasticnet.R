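#' Elastic-net configuration
#'
#' @param alpha L1/L2 mixing weight in (0, 1]; 1 = lasso. Default 0.50.
#' @param n_lambda number of lambda-path values.
#' @param lambda_min_ratio smallest lambda as a fraction of `lambda_max`.
#' @param train_fraction fraction of rows assigned to the training split.
#' @param cv_folds number of cross-validation folds.
#' @param standardize standardize columns to unit SD internally.
#' @param stratify_split preserve the event rate across the train/test split.
#' @param seed integer seed for split and fold assignment.
#' @return An object of class `enet_config`.
#' @export
enet_config <- function(alpha = 0.5, n_lambda = 100,
                        lambda_min_ratio = 1e-4, train_fraction = 0.70,
                        cv_folds = 10, standardize = TRUE,
                        stratify_split = FALSE, seed = NULL) {
  stopifnot(alpha > 0, alpha <= 1, train_fraction > 0, train_fraction < 1,
            cv_folds >= 2, n_lambda >= 2, lambda_min_ratio > 0,
            lambda_min_ratio < 1)
  structure(list(alpha = alpha, n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 train_fraction = train_fraction, cv_folds = cv_folds,
                 standardize = standardize, stratify_split = stratify_split,
                 seed = seed),
            class = "enet_config")
}

#' Random train/test split
#'
#' Simple random split without replacement into `round(n * f)` training and
#' `n - round(n * f)` test rows; optionally stratified on a binary outcome
#' so the training event count is within one event of proportional.
#'
#' @param n number of rows, or a data.frame.
#' @param train_fraction training fraction.
#' @param seed integer seed.
#' @param y binary outcome for stratification (required if `stratify`).
#' @param stratify preserve the event rate across the split.
#' @return A list with integer row indices `train` and `test`.
#' @export
split_train_test <- function(n, train_fraction = 0.70, seed = NULL,
                             y = NULL, stratify = FALSE) {
  if (is.data.frame(n)) n <- nrow(n)
  with_seed(seed, {
    if (stratify) {
      stopifnot(!is.null(y), length(y) == n)
      i1 <- which(y == 1); i0 <- which(y == 0)
      k1 <- round(length(i1) * train_fraction)
      k0 <- round(n * train_fraction) - k1
      train <- sort(c(sample(i1, k1), sample(i0, k0)))
    } else {
      train <- sort(sample.int(n, round(n * train_fraction)))
    }
    test <- setdiff(seq_len(n), train)
    if (!is.null(y) && (sum(y[train]) == 0 || sum(y[test]) == 0))
      stop("split left zero events in one part; consider stratify = TRUE")
    list(train = train, test = test)
  })
}

# standardize columns: center to 0, scale to unit 1/n-SD
standardize_cols <- function(X, standardize = TRUE) {
  m <- colMeans(X)
  Xc <- sweep(X, 2, m)
  s <- if (standardize) sqrt(colMeans(Xc^2)) else rep(1, ncol(X))
  if (any(s == 0)) stop("constant column in elastic-net design")
  list(X = sweep(Xc, 2, s, "/"), center = m, scale = s)
}

#' Elastic-net penalized logistic regression at one lambda
#'
#' Minimizes `deviance / (2n) + lambda * (alpha * |B|_1 +
#' (1 - alpha)/2 * |B|_2^2)` over the slopes (intercept unpenalized) by
#' cyclic coordinate descent on the IRLS quadratic approximation, with
#' covariates standardized internally to unit SD. Coefficients are returned
#' on the original covariate scale.
#'
#' @param X numeric predictor matrix (no intercept column).
#' @param y binary outcome.
#' @param alpha mixing weight in (0, 1].
#' @param lambda penalty strength (>= 0).
#' @param standardize standardize internally (default `TRUE`).
#' @param tol convergence tolerance on the maximum standardized-coefficient
#'   change.
#' @param max_iter maximum outer IRLS iterations.
#' @param init optional warm start `list(beta0, beta_std)`.
#' @return An object of class `enet_coefs`: `intercept` and `beta` on the
#'   original scale, `beta_std`/`intercept_std` on the standardized scale,
#'   the standardization constants, `deviance`, `null_deviance`, `kkt_max`
#'   (largest stationarity violation), and convergence info.
#' @export
enet_fit <- function(X, y, alpha = 0.5, lambda, standardize = TRUE,
                     tol = 1e-7, max_iter = 250, init = NULL) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)), lambda >= 0,
            alpha > 0, alpha <= 1)
  std <- standardize_cols(X, standardize)
  enet_core(std, y, alpha, lambda, tol, max_iter, init)
}

# IRLS + coordinate descent on a pre-standardized design (`std` as returned
# by standardize_cols); shared by enet_fit and the warm-started path.
enet_core <- function(std, y, alpha, lambda, tol = 1e-7, max_iter = 250,
                      init = NULL) {
  Xs <- std$X
  n <- nrow(Xs); p <- ncol(Xs)
  beta <- if (!is.null(init)) init$beta_std else rep(0, p)
  beta0 <- if (!is.null(init)) init$beta0 else stats::qlogis(mean(y))

  eta <- beta0 + drop(Xs %*% beta)
  converged <- FALSE
  for (outer in seq_len(max_iter)) {
    pr <- stats::plogis(eta)
    w <- pmax(pr * (1 - pr), 1e-10)
    z <- eta + (y - pr) / w
    r <- z - beta0 - drop(Xs %*% beta)    # working residual
    # inner cyclic coordinate descent on the weighted quadratic
    sol <- .cd_enet_inner(Xs, w, r, beta, beta0, lambda, alpha, tol, 1000L)
    beta <- sol$beta
    beta0 <- sol$beta0
    eta <- beta0 + drop(Xs %*% beta)
    if (sol$max_delta < tol) { converged <- TRUE; break }
  }
  beta[abs(beta) < 1e-10] <- 0            # snap numerically-null coefficients

  pr <- stats::plogis(eta)
  dev <- logistic_deviance(y, pr)
  null_dev <- logistic_deviance(y, rep(mean(y), n))
  # stationarity (KKT) residuals on the standardized scale
  grad <- -drop(crossprod(Xs, y - pr)) / n + lambda * (1 - alpha) * beta
  kkt <- ifelse(beta != 0, abs(grad + lambda * alpha * sign(beta)),
                pmax(abs(grad) - lambda * alpha, 0))
  if (!converged)
    stop(sprintf("elastic net did not converge in %d iterations (max KKT residual %.2e)",
                 max_iter, max(kkt)))

  b_orig <- beta / std$scale
  structure(list(
    intercept = beta0 - sum(b_orig * std$center), beta = b_orig,
    intercept_std = beta0, beta_std = beta,
    center = std$center, scale = std$scale,
    alpha = alpha, lambda = lambda,
    deviance = dev, null_deviance = null_dev,
    kkt_max = max(kkt), converged = converged, iterations = outer),
    class = "enet_coefs")
}

#' Largest lambda with an all-zero slope solution
#'
#' @inheritParams enet_fit
#' @return The smallest penalty at which the null (intercept-only) model is
#'   stationary: `max_j |x_j' (y - mean(y))| / (n * alpha)` over
#'   standardized columns.
#' @export
enet_lambda_max <- function(X, y, alpha = 0.5, standardize = TRUE) {
  std <- standardize_cols(as.matrix(X), standardize)
  max(abs(drop(crossprod(std$X, y - mean(y))))) / (length(y) * alpha)
}

enet_predict_eta <- function(fit, X) fit$intercept + drop(as.matrix(X) %*% fit$beta)

#' Lambda path, cross-validation and model selection
#'
#' Fits a warm-started descending log-spaced lambda path from `lambda_max`,
#' records per-lambda in-sample deviance, deviance ratio
#' (`1 - deviance / null deviance`), BIC (`deviance + k * log(n)` with `k`
#' counting nonzero coefficients including the intercept) and tenfold
#' cross-validated deviance, then selects lambda: restrict to the subpath
#' whose CV deviance is within one standard error of the CV minimum, take
#' the BIC minimizer there, break ties toward the larger lambda.
#'
#' @param X training predictor matrix (no intercept).
#' @param y training binary outcome.
#' @param config an [enet_config()].
#' @param X_test,y_test optional held-out rows for the test deviance ratio.
#' @return An object of class `enet_path`: `path` (a data.frame with
#'   `lambda`, `deviance`, `deviance_ratio`, `bic`, `cv_deviance`, `cv_se`,
#'   `support_size`), `fits` (per-lambda `enet_coefs`), `selected_index`,
#'   `selected_lambda`, `selected_fit`, `support` (named nonzero slopes),
#'   `odds_ratios`, `test_deviance_ratio` (when test rows are given), and
#'   the config.
#' @export
enet_path_select <- function(X, y, config = enet_config(),
                             X_test = NULL, y_test = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  lam_max <- enet_lambda_max(X, y, config$alpha, config$standardize)
  lambdas <- exp(seq(log(lam_max), log(lam_max * config$lambda_min_ratio),
                     length.out = config$n_lambda))

  fit_path <- function(Xf, yf) {
    std <- standardize_cols(Xf, config$standardize)
    fits <- vector("list", length(lambdas))
    init <- NULL
    for (i in seq_along(lambdas)) {
      fits[[i]] <- enet_core(std, yf, config$alpha, lambdas[i], init = init)
      init <- list(beta0 = fits[[i]]$intercept_std,
                   beta_std = fits[[i]]$beta_std)
    }
    fits
  }
  fits <- fit_path(X, y)

  folds <- with_seed(config$seed, sample(rep_len(seq_len(config$cv_folds), n)))
  cv_dev_fold <- matrix(NA_real_, config$cv_folds, length(lambdas))
  for (f in seq_len(config$cv_folds)) {
    hold <- folds == f
    ffits <- fit_path(X[!hold, , drop = FALSE], y[!hold])
    for (i in seq_along(lambdas)) {
      eta <- enet_predict_eta(ffits[[i]], X[hold, , drop = FALSE])
      cv_dev_fold[f, i] <-
        logistic_deviance(y[hold], stats::plogis(eta)) / sum(hold)
    }
  }
  cv_dev <- colMeans(cv_dev_fold)
  cv_se <- apply(cv_dev_fold, 2, stats::sd) / sqrt(config$cv_folds)

  dev <- vapply(fits, `[[`, numeric(1), "deviance")
  null_dev <- fits[[1]]$null_deviance
  k <- vapply(fits, function(f) 1L + sum(f$beta != 0), integer(1))
  path <- data.frame(
    lambda = lambdas, deviance = dev,
    deviance_ratio = 1 - dev / null_dev,
    bic = dev + k * log(n),
    cv_deviance = cv_dev, cv_se = cv_se, support_size = k - 1L)

  i_min <- which.min(cv_dev)
  in_band <- which(cv_dev <= cv_dev[i_min] + cv_se[i_min])
  best_bic <- min(path$bic[in_band])
  sel <- in_band[path$bic[in_band] == best_bic]
  sel <- sel[which.max(lambdas[sel])]   # ties -> larger lambda

  sfit <- fits[[sel]]
  support <- sfit$beta[sfit$beta != 0]
  names(support) <- colnames(X)[sfit$beta != 0]
  flagged <- length(support) == 0L

  test_dr <- NULL
  if (!is.null(X_test)) {
    eta_t <- enet_predict_eta(sfit, X_test)
    test_dr <- 1 - logistic_deviance(y_test, stats::plogis(eta_t)) /
      logistic_deviance(y_test, rep(mean(y_test), length(y_test)))
  }
  structure(list(path = path, fits = fits, lambda_max = lam_max,
                 selected_index = sel, selected_lambda = lambdas[sel],
                 selected_fit = sfit, support = support,
                 odds_ratios = exp(support),
                 intercept_only = flagged,
                 test_deviance_ratio = test_dr, config = config),
            class = "enet_path")
}

#' @export
print.enet_path <- function(x, ...) {
  cat(sprintf(
    "Elastic net path: alpha = %.2f, %d lambdas from %.4g\n",
    x$config$alpha, nrow(x$path), x$lambda_max))
  i <- x$selected_index
  cat(sprintf(
    "Selected lambda = %.4g: BIC = %.2f, deviance ratio = %.3f, support = %d\n",
    x$selected_lambda, x$path$bic[i], x$path$deviance_ratio[i],
    x$path$support_size[i]))
  if (length(x$support)) {
    tab <- data.frame(term = names(x$support),
                      coef = signif(unname(x$support), 3),
                      odds_ratio = signif(unname(x$odds_ratios), 3))
    print(tab, row.names = FALSE)
  } else cat("(intercept-only selection)\n")
  if (!is.null(x$test_deviance_ratio))
    cat(sprintf("Test deviance ratio = %.3f\n", x$test_deviance_ratio))
  invisible(x)
}

#' Refit the selected support by plain maximum likelihood
#'
#' Fits an unpenalized logistic regression ([fit_logistic()]) of the outcome
#' on exactly the elastic-net-selected predictors, on the full analysis
#' sample.
#'
#' @param data data.frame holding the predictors and outcome.
#' @param support predictor names (nonzero elastic-net coefficients) or an
#'   `enet_path` object.
#' @param outcome binary outcome column name.
#' @return A `pursuit_logit` plus attribute `"rows"` (complete-case rows
#'   used).
#' @export
refit_selected <- function(data, support, outcome = "case") {
  if (inherits(support, "enet_path")) support <- names(support$support)
  stopifnot(length(support) >= 1)
  dm <- build_design_matrix(domain_data(data), support, outcome = outcome)
  m <- fit_logistic(dm)
  attr(m, "rows") <- dm$rows
  m
}

#' Write the lambda path as CSV
#'
#' @param path_fit an `enet_path`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_enet_path <- function(path_fit, path) {
  utils::write.csv(path_fit$path, path, row.names = FALSE)
  invisible(path)
}
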