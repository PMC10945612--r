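#' Build a design matrix from cohort columns
#'
#' Complete-case construction: rows with any missing value among the
#' requested columns (or the outcome) are dropped and logged. Binary flags
#' are passed through as 0/1; an intercept column is prepended.
#'
#' @param data a data.frame.
#' @param vars predictor column names.
#' @param outcome outcome column name (binary 0/1), or `NULL` for a
#'   predictor-only matrix.
#' @return A list with `X` (matrix incl. `(Intercept)`), `y` (or `NULL`),
#'   `rows` (row indices kept), `dropped` (indices removed as incomplete).
#' @export
build_design_matrix <- function(data, vars, outcome = NULL) {
  stopifnot(all(vars %in% names(data)))
  cols <- c(vars, outcome)
  cc <- stats::complete.cases(data[, cols, drop = FALSE])
  X <- cbind(`(Intercept)` = rep(1, sum(cc)),
             as.matrix(data[cc, vars, drop = FALSE]))
  storage.mode(X) <- "double"
  if (nrow(X) > 0 && qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient")
  list(X = X,
       y = if (!is.null(outcome)) as.numeric(data[[outcome]][cc]) else NULL,
       rows = which(cc), dropped = which(!cc))
}

logistic_deviance <- function(y, p) {
  eps <- 1e-12
  -2 * sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

#' Maximum-likelihood logistic regression (IRLS)
#'
#' Fits a binary logistic model by iteratively reweighted least squares,
#' with Wald standard errors from the inverse Fisher information at the
#' optimum. Iteration stops when the deviance changes by less than `tol`
#' (default 1e-8) or after `max_iter` iterations; diverging coefficients
#' (|B| beyond `separation_guard`, default 15) raise a separation error.
#'
#' @param X design matrix including an intercept column (first), or a list
#'   as returned by [build_design_matrix()].
#' @param y binary outcome vector (ignored when `X` is such a list).
#' @param tol deviance-change convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @param separation_guard bound on |coefficient| beyond which perfect
#'   separation is declared.
#' @return An object of class `pursuit_logit` with `coefficients`, `se`,
#'   `z`, `p_value`, `odds_ratio`, `ci_lower`/`ci_upper` (95% Wald),
#'   `loglik`, `null_loglik`, `lr_chisq`, `df`, `lr_p`, `pseudo_r2`
#'   (McFadden), `pseudo_r2_nagelkerke`, `logits` (in-sample), `fitted`,
#'   `vcov`, `converged`, `iterations`, and the data used.
#' @export
fit_logistic <- function(X, y = NULL, tol = 1e-8, max_iter = 100,
                         separation_guard = 15) {
  if (is.list(X) && !is.null(X$X)) { y <- X$y; X <- X$X }
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one event and one non-event")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")

  beta <- rep(0, ncol(X))
  dev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    if (any(!is.finite(beta))) stop("IRLS diverged (non-finite coefficients)")
    if (max(abs(beta)) > separation_guard)
      stop("perfect separation detected (diverging coefficients)")
    new_dev <- logistic_deviance(y, stats::plogis(drop(X %*% beta)))
    if (abs(dev - new_dev) < tol) { dev <- new_dev; converged <- TRUE; break }
    dev <- new_dev
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  W <- p * (1 - p)
  info <- crossprod(X, X * W)
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  ll <- -dev / 2

  n <- length(y)
  p0 <- mean(y)
  ll0 <- sum(y) * log(p0) + (n - sum(y)) * log(1 - p0)
  df <- ncol(X) - 1L
  lr <- 2 * (ll - ll0)
  names(beta) <- names(se) <- colnames(X)

  structure(list(
    coefficients = beta, se = se, z = zval, p_value = pval,
    odds_ratio = exp(beta),
    ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
    loglik = ll, null_loglik = ll0, lr_chisq = lr, df = df,
    lr_p = stats::pchisq(lr, df, lower.tail = FALSE),
    pseudo_r2 = 1 - ll / ll0,
    pseudo_r2_nagelkerke =
      (1 - exp(2 * (ll0 - ll) / n)) / (1 - exp(2 * ll0 / n)),
    logits = eta, fitted = p, vcov = vcov,
    converged = converged, iterations = it, n = n, n_events = sum(y),
    X = X, y = y), class = "pursuit_logit")
}

#' McFadden pseudo R-squared
#'
#' `1 - loglik / null_loglik` for a fitted binary logistic model.
#'
#' @param model a `pursuit_logit`.
#' @param type `"mcfadden"` (default) or `"nagelkerke"`.
#' @return The pseudo R-squared.
#' @export
mcfadden_r2 <- function(model, type = c("mcfadden", "nagelkerke")) {
  type <- match.arg(type)
  stopifnot(inherits(model, "pursuit_logit"))
  if (model$null_loglik == 0)
    stop("degenerate outcome: null log-likelihood is zero")
  if (type == "mcfadden") model$pseudo_r2 else model$pseudo_r2_nagelkerke
}

#' Linear predictors for new data
#'
#' @param model a `pursuit_logit`.
#' @param X design matrix with the fitted model's columns (intercept first),
#'   or a [build_design_matrix()] list.
#' @return Logits `X %*% B` in input row order.
#' @export
predict_logits <- function(model, X) {
  if (is.list(X) && !is.null(X$X)) X <- X$X
  X <- as.matrix(X)
  if (!identical(colnames(X), names(model$coefficients)))
    stop("design columns do not match the fitted model")
  drop(X %*% model$coefficients)
}

#' Coefficient table of a fitted logistic model
#'
#' @param model a `pursuit_logit`.
#' @return A data.frame with columns `term`, `B`, `SE`, `p_value`,
#'   `odds_ratio`, `ci_lower`, `ci_upper` (intercept row included).
#' @export
model_table <- function(model) {
  stopifnot(inherits(model, "pursuit_logit"))
  data.frame(term = names(model$coefficients), B = unname(model$coefficients),
             SE = unname(model$se), p_value = unname(model$p_value),
             odds_ratio = unname(model$odds_ratio),
             ci_lower = unname(model$ci_lower),
             ci_upper = unname(model$ci_upper))
}

#' Serialize a fitted logistic model
#'
#' Writes the coefficient table as CSV (`B, SE, p-value, Odds ratio, 95% CI`
#' style) or the full summary as JSON.
#'
#' @param model a `pursuit_logit`.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("csv", "json")) {
  format <- match.arg(format)
  tab <- model_table(model)
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    jsonlite::write_json(list(
      coefficients = tab, loglik = model$loglik,
      null_loglik = model$null_loglik, lr_chisq = model$lr_chisq,
      df = model$df, lr_p = model$lr_p, pseudo_r2 = model$pseudo_r2,
      pseudo_r2_nagelkerke = model$pseudo_r2_nagelkerke,
      n = model$n, n_events = model$n_events),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @export
print.pursuit_logit <- function(x, ...) {
  cat(sprintf(
    "Logistic model: %d obs (%d events), chi2[%d] = %.2f, p = %.3g, pseudo R2 = %.3f\n",
    x$n, x$n_events, x$df, x$lr_chisq, x$lr_p, x$pseudo_r2))
  tab <- model_table(x)
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}
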