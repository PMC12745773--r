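test_that("absorbed-FE slopes equal explicit dummy-variable OLS", {
  p <- toy_panel()
  spec <- model_spec(poly_order = 2, n_lags = 1, climate_interaction = FALSE,
                     controls = "rh")
  d <- build_design(p, spec)
  fit <- fit_erf(d)
  df <- data.frame(y = d$y, d$X, fe1 = d$fe1, fe2 = d$fe2,
                   check.names = FALSE)
  fml <- stats::as.formula(paste("y ~", paste(sprintf("`%s`",
                                                      colnames(d$X)),
                                              collapse = " + "),
                                 "+ fe1 + fe2"))
  lmfit <- stats::lm(fml, data = df)
  expect_equal(unname(fit$coefficients),
               unname(coef(lmfit)[names(fit$coefficients)]),
               tolerance = 1e-8)
})

test_that("a column constant within both FE group sets is flagged collinear", {
  p <- toy_panel()
  spec <- model_spec(poly_order = 1, n_lags = 0, climate_interaction = TRUE,
                     controls = character(0))
  p <- with_department_climate(p)
  d <- build_design(p, spec)
  # add a column that is a deterministic function of (department, year)
  d$X <- cbind(d$X, fe_func = as.integer(d$fe1))
  expect_warning(fit <- fit_erf(d), "collinear")
  expect_false("fe_func" %in% names(fit$coefficients))
})

test_that("an exactly linear outcome is recovered to machine precision", {
  p <- toy_panel()
  spec <- model_spec(poly_order = 1, n_lags = 0, climate_interaction = FALSE,
                     controls = character(0))
  d <- build_design(p, spec)
  d$y <- 0.037 * d$X[, "t_l0_p1"] + as.integer(d$fe1) * 0.5 -
    as.integer(d$fe2) * 0.25
  fit <- fit_erf(d)
  expect_equal(unname(fit$coefficients["t_l0_p1"]), 0.037, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_equal(unname(cluster_vcov(fit)), matrix(0, 1, 1), tolerance = 1e-16)
})

test_that("estimates are invariant to row permutation", {
  p <- small_gen_panel()
  spec <- model_spec(compounding = "previous_level")
  d <- build_design(p, spec)
  fit1 <- fit_erf(d)
  set.seed(3)
  perm <- sample(length(d$y))
  d2 <- d
  d2$y <- d$y[perm]
  d2$X <- d$X[perm, ]
  d2$fe1 <- d$fe1[perm]
  d2$fe2 <- d$fe2[perm]
  d2$cluster <- d$cluster[perm]
  d2$rows <- d$rows[perm, ]
  fit2 <- fit_erf(d2)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-8)
  expect_equal(fit1$vcov, fit2$vcov, tolerance = 1e-6)
})

test_that("clustered covariance equals the brute-force CR1 sandwich", {
  p <- toy_panel()
  spec <- model_spec(poly_order = 2, n_lags = 0, climate_interaction = FALSE,
                     controls = character(0))
  d <- build_design(p, spec)
  fit <- fit_erf(d)
  # literal formula on the demeaned design
  X <- fit$X_demeaned
  u <- fit$residuals
  bread <- solve(crossprod(X))
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in levels(fit$cluster)) {
    idx <- fit$cluster == g
    s <- t(X[idx, , drop = FALSE]) %*% u[idx]
    meat <- meat + s %*% t(s)
  }
  G <- nlevels(fit$cluster)
  N <- fit$nobs
  K <- ncol(X) + fit$df_absorbed
  V <- G / (G - 1) * (N - 1) / (N - K) * bread %*% meat %*% bread
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-10)
  expect_error(cluster_vcov(fit, cluster = rep("one", fit$nobs)),
               "2 clusters")
})

test_that("CR1 covariance matches the sandwich package on a dummy-variable fit", {
  p <- toy_panel()
  spec <- model_spec(poly_order = 2, n_lags = 1, climate_interaction = FALSE,
                     controls = character(0))
  d <- build_design(p, spec)
  fit <- fit_erf(d)
  df <- data.frame(y = d$y, d$X, fe1 = d$fe1, fe2 = d$fe2,
                   cl = d$cluster, check.names = FALSE)
  fml <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", colnames(d$X)),
                                              collapse = " + "),
                                 "+ fe1 + fe2"))
  lmfit <- stats::lm(fml, data = df)
  Vcl <- sandwich::vcovCL(lmfit, cluster = df$cl, type = "HC1",
                          cadjust = TRUE)
  nm <- names(fit$coefficients)
  expect_equal(unname(fit$vcov), unname(Vcl[nm, nm]), tolerance = 1e-6)
})

test_that("cluster-robust variances are nonnegative across random toys", {
  set.seed(99)
  for (r in 1:20) {
    n <- 60
    cl <- factor(sample(letters[1:4], n, replace = TRUE))
    fe1 <- factor(sample(1:3, n, replace = TRUE))
    fe2 <- factor(sample(1:5, n, replace = TRUE))
    X <- cbind(a = rnorm(n), b = rnorm(n))
    y <- rnorm(n)
    d <- structure(list(y = y, X = X, fe1 = fe1, fe2 = fe2, cluster = cl,
                        rows = data.frame(department_id = as.character(cl)),
                        spec = model_spec(), g_info = list(mode = "none"),
                        n_lag_excluded = 0, n_zero_excluded = 0),
                   class = "heat_design")
    fit <- fit_erf(d)
    expect_true(all(diag(fit$vcov) >= 0))
    eg <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(eg), -1e-10 * max(abs(eg)))
  }
})

test_that("clustered SEs exceed classical SEs under within-department error autocorrelation", {
  p <- small_gen_panel()
  spec <- model_spec(poly_order = 2, n_lags = 1, climate_interaction = FALSE,
                     controls = character(0))
  d <- build_design(p, spec)
  # replace the outcome: known slope plus strongly autocorrelated errors
  # within each department (the situation department clustering guards
  # against; temperatures are themselves persistent, so score correlation
  # is positive)
  set.seed(17)
  e <- numeric(length(d$y))
  for (g in levels(d$cluster)) {
    i <- which(d$cluster == g)
    e[i] <- as.numeric(stats::filter(rnorm(length(i), 0, 0.1), 0.95,
                                     method = "recursive"))
  }
  d$y <- 0.01 * d$X[, "t_l0_p1"] + e
  fit <- fit_erf(d)
  sigma2 <- sum(fit$residuals^2) / (fit$nobs - length(fit$coefficients) -
                                      fit$df_absorbed)
  se_classic <- sqrt(diag(sigma2 * fit$XtX_inv))
  # aggregate comparison across coefficients
  expect_gt(mean(fit$se / se_classic), 1)
})

test_that("coefficient sampling is reproducible, degenerate at V=0, and converges", {
  p <- toy_panel()
  spec <- model_spec(poly_order = 2, n_lags = 0, climate_interaction = FALSE,
                     controls = character(0))
  d <- build_design(p, spec)
  fit <- fit_erf(d)
  s <- sample_coefficients(fit, n = 500, seed = 4)
  expect_equal(nrow(s$draws), 500)
  s2 <- sample_coefficients(fit, n = 500, seed = 4)
  expect_identical(s$draws, s2$draws)
  # degenerate covariance: all draws equal the point estimate
  fit0 <- fit
  fit0$vcov <- matrix(0, 2, 2, dimnames = dimnames(fit$vcov))
  s0 <- sample_coefficients(fit0, n = 50, seed = 5)
  expect_equal(s0$draws, matrix(rep(fit$coefficients, each = 50), 50,
                                dimnames = list(NULL, names(fit$coefficients))),
               tolerance = 1e-12)
  # law of large numbers: empirical covariance approaches V
  sbig <- sample_coefficients(fit, n = 1e5, seed = 6)
  emp <- cov(sbig$draws)
  rel <- norm(emp - fit$vcov, "F") / norm(fit$vcov, "F")
  expect_lt(rel, 0.05)
})
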