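test_that("train/test split follows the rounding rule, seed and stratification", {
  sp <- split_train_test(3036, 0.70, seed = 1)
  expect_length(sp$train, 2125)
  expect_length(sp$test, 911)
  expect_identical(sp, split_train_test(3036, 0.70, seed = 1))
  expect_false(identical(sp$train, split_train_test(3036, 0.70, seed = 2)$train))

  y <- rep(c(1, 0), c(60, 1940))
  st <- split_train_test(2000, 0.70, seed = 3, y = y, stratify = TRUE)
  expect_lte(abs(sum(y[st$train]) - 0.70 * 60), 1)

  yrare <- rep(c(1, 0), c(1, 99))
  expect_error(
    split_train_test(100, 0.5, seed = 101, y = yrare),
    "zero events")
})

test_that("the penalty boundary conditions hold: lambda_max nulls, lambda -> 0 is MLE", {
  d <- planted_logistic(300, c(1, -0.7, 0.5, 0, 0), seed = 2)
  lmax <- enet_lambda_max(d$X, d$y, alpha = 0.5)
  f_at_max <- enet_fit(d$X, d$y, alpha = 0.5, lambda = lmax)
  expect_identical(unname(f_at_max$beta), rep(0, 5))
  f_above <- enet_fit(d$X, d$y, alpha = 0.5, lambda = lmax * 1.5)
  expect_identical(unname(f_above$beta), rep(0, 5))

  f0 <- enet_fit(d$X, d$y, alpha = 0.5, lambda = 1e-8)
  mle <- fit_logistic(cbind(`(Intercept)` = 1, d$X), d$y)
  expect_lt(max(abs(f0$beta - mle$coefficients[-1])), 1e-4)
  expect_lt(abs(f0$intercept - mle$coefficients[1]), 1e-4)
})

test_that("coordinate descent satisfies KKT conditions and matches the penalized reference", {
  d <- planted_logistic(300, c(1, -0.7, 0.5, rep(0, 5)), seed = 3)
  for (lam in c(0.005, 0.02, 0.08)) {
    f <- enet_fit(d$X, d$y, alpha = 0.5, lambda = lam)
    expect_lt(f$kkt_max, 1e-6)
  }
  f <- enet_fit(d$X, d$y, alpha = 0.5, lambda = 0.02)
  gn <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 0.5,
                       lambda = 0.02, standardize = TRUE, thresh = 1e-12)
  expect_lt(max(abs(f$beta - as.numeric(coef(gn))[-1])), 1e-4)
  expect_lt(abs(f$intercept - as.numeric(coef(gn))[1]), 1e-4)
  # alpha = 1 reduces to the lasso
  fl <- enet_fit(d$X, d$y, alpha = 1, lambda = 0.02)
  gl <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 1,
                       lambda = 0.02, thresh = 1e-12)
  expect_lt(max(abs(fl$beta - as.numeric(coef(gl))[-1])), 1e-4)
})

test_that("warm starts, standardization invariance and path bookkeeping hold", {
  d <- planted_logistic(250, c(1, -0.8, rep(0, 6)), seed = 4)
  cfg <- enet_config(seed = 9, n_lambda = 30, cv_folds = 5)
  pf <- enet_path_select(d$X, d$y, cfg)

  # warm-started path equals cold restarts
  for (i in c(5, 15, 25)) {
    cold <- enet_fit(d$X, d$y, cfg$alpha, pf$path$lambda[i])
    expect_lt(max(abs(cold$beta - pf$fits[[i]]$beta)), 1e-6)
  }
  # deviance ratio at lambda_max is zero; BIC recomputable from the table
  expect_equal(pf$path$deviance_ratio[1], 0, tolerance = 1e-8)
  expect_equal(pf$path$bic,
               pf$path$deviance + (pf$path$support_size + 1) *
                 log(length(d$y)), tolerance = 1e-10)

  # rescaling a covariate: same support, exactly rescaled coefficient
  X2 <- d$X
  X2[, 1] <- X2[, 1] * 4
  f <- enet_fit(d$X, d$y, 0.5, 0.02)
  f2 <- enet_fit(X2, d$y, 0.5, 0.02)
  expect_identical(which(f$beta != 0), which(f2$beta != 0))
  expect_equal(f2$beta[1] * 4, f$beta[1], tolerance = 1e-7)
  expect_equal(f2$deviance, f$deviance, tolerance = 1e-6)
})

test_that("path selection recovers sparse truth and generalizes to held-out rows", {
  set.seed(5)
  beta <- c(1, -1, 0.8, rep(0, 12))
  ok <- 0; gap <- numeric(10)
  for (i in 1:10) {
    d <- planted_logistic(500, beta, intercept = -0.5)
    sp <- split_train_test(500, 0.7, seed = i, y = d$y)
    pf <- enet_path_select(d$X[sp$train, ], d$y[sp$train],
                           enet_config(seed = i, n_lambda = 40),
                           d$X[sp$test, ], d$y[sp$test])
    if (all(c("v1", "v2", "v3") %in% names(pf$support))) ok <- ok + 1
    gap[i] <- pf$test_deviance_ratio -
      pf$path$deviance_ratio[pf$selected_index]
  }
  expect_gte(ok, 9)
  expect_lt(abs(mean(gap)), 0.05)
})

test_that("a pure-noise problem is flagged as an intercept-only selection", {
  d <- planted_logistic(400, rep(0, 10), intercept = -1, seed = 6)
  pf <- enet_path_select(d$X, d$y, enet_config(seed = 6, n_lambda = 30,
                                               cv_folds = 5))
  expect_true(pf$intercept_only)
  expect_length(pf$support, 0)
})

test_that("refitting the selected support reduces to plain maximum likelihood", {
  # support of one binary exposure: the 2x2 closed form
  dat <- data.frame(x = rep(c(1, 0), each = 20),
                    case = c(rep(1, 10), rep(0, 10), rep(1, 5), rep(0, 15)))
  m <- refit_selected(dat, "x")
  expect_equal(unname(m$coefficients["x"]), log(3), tolerance = 1e-8)
  expect_identical(m$df, 1L)

  # df equals the support size on a nine-predictor refit
  d <- planted_logistic(600, c(1, -1, 0.8, -0.8, 0.6, rep(0, 4)), seed = 7)
  dat9 <- data.frame(d$X, case = d$y)
  m9 <- refit_selected(dat9, paste0("v", 1:9))
  expect_identical(m9$df, 9L)
  expect_identical(nrow(model_table(m9)), 10L)

  # subsetting consistency: train-only refit equals a direct fit on those rows
  rows <- seq_len(400)
  mt <- refit_selected(dat9[rows, ], paste0("v", 1:3))
  md <- fit_logistic(cbind(`(Intercept)` = 1, d$X[rows, 1:3]), d$y[rows])
  expect_equal(unname(mt$coefficients), unname(md$coefficients),
               tolerance = 1e-10)
})
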