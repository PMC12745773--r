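test_that("marginal effect is zero at the reference and matches closed form", {
  spec <- model_spec(poly_order = 4, n_lags = 5, compounding = "none",
                     climate_interaction = FALSE, controls = character(0))
  # hand-built coefficients: 0.01 on the lag-0 linear term only
  nm <- sprintf("t_l%d_p%d", rep(0:5, each = 4), rep(1:4, 6))
  beta <- setNames(rep(0, length(nm)), nm)
  beta["t_l0_p1"] <- 0.01
  s <- manual_samples(beta, spec = spec,
                      g_info = list(mode = "none"))
  me0 <- marginal_effect(s, c(25, 20), c(25, 20), tbar = 13)
  expect_equal(me0$draws, rep(0, s$n))
  expect_equal(me0$hi - me0$lo, 0)
  me <- marginal_effect(s, c(30, 20), c(20, 20), tbar = 13)
  expect_equal(me$mean, 100 * (exp(0.01 * 10) - 1), tolerance = 1e-10)
  # approximate flag uses the linear transform
  mea <- marginal_effect(s, c(30, 20), c(20, 20), tbar = 13,
                         approximate = TRUE)
  expect_equal(mea$mean, 10)
})

test_that("zero compounding coefficients make the effect independent of the previous day", {
  spec <- model_spec(compounding = "previous_level",
                     climate_interaction = FALSE, controls = character(0))
  nm <- c(sprintf("t_l%d_p%d", rep(0:5, each = 4), rep(1:4, 6)),
          sprintf("t_l%d_p%d_x_prev", rep(0:5, each = 4), rep(1:4, 6)))
  beta <- setNames(rep(0, length(nm)), nm)
  beta["t_l0_p2"] <- 0.0005
  s <- manual_samples(beta, spec = spec,
                      g_info = list(mode = "previous_level"))
  m1 <- marginal_effect(s, c(30, 20), c(20, 20), tbar = 13)
  m2 <- marginal_effect(s, c(30, 30), c(20, 20), tbar = 13)
  expect_equal(m1$mean, m2$mean)
  # and a nonzero interaction breaks the equality
  beta2 <- beta
  beta2["t_l0_p1_x_prev"] <- 1e-4
  s2 <- manual_samples(beta2, spec = spec,
                       g_info = list(mode = "previous_level"))
  expect_gt(marginal_effect(s2, c(30, 30), c(20, 20), 13)$mean,
            marginal_effect(s2, c(30, 20), c(20, 20), 13)$mean)
})

test_that("cumulative effects follow impulse-response bookkeeping", {
  spec <- model_spec(poly_order = 2, n_lags = 3, compounding = "none",
                     climate_interaction = FALSE, controls = character(0))
  nm <- sprintf("t_l%d_p%d", rep(0:3, each = 2), rep(1:2, 4))
  beta <- setNames(c(0.01, 1e-4, 0.005, 5e-5, 0.002, 2e-5, 0.001, 1e-5), nm)
  s <- manual_samples(beta, spec = spec, g_info = list(mode = "none"))
  ref <- rep(20, 4)
  expect_equal(cumulative_effect(s, ref, ref, tbar = 13)$mean, 0)
  # single-day perturbation at lag j contributes through exactly L+1 focal
  # days; check the log-scale contributions match the per-lag terms
  f <- function(path) cumulative_effect(s, path, ref, tbar = 13,
                                        approximate = TRUE)$mean / 100
  contribs <- vapply(0:3, function(j) {
    path <- ref
    path[j + 1] <- 30
    f(path)
  }, numeric(1))
  expected <- vapply(0:3, function(j) {
    beta[sprintf("t_l%d_p1", j)] * 10 + beta[sprintf("t_l%d_p2", j)] * 500
  }, numeric(1))
  expect_equal(contribs, unname(expected), tolerance = 1e-10)
  # disjoint perturbations add exactly on the log scale
  p12 <- ref
  p12[c(1, 3)] <- 30
  expect_equal(f(p12), contribs[1] + contribs[3], tolerance = 1e-12)
  expect_error(cumulative_effect(s, rep(20, 2), rep(20, 2), 13), "history")
})

test_that("fitted compounding surface reproduces the generator's ordering", {
  p <- small_gen_panel()
  des <- build_design(p, model_spec(compounding = "previous_level"))
  fit <- fit_erf(des)
  s <- sample_coefficients(fit, 200, seed = 31)
  tb <- population_weighted_tbar(p)
  supp <- support_mask(p)
  surf <- compounding_surface(s, prev_grid = seq(14, 32, 2),
                              cur_grid = seq(14, 32, 2), tbar = tb,
                              support = supp)
  # reference cell is zero
  i20 <- which(surf$prev_grid == 20)
  expect_equal(surf$mean_pct[i20, which(surf$cur_grid == 20)], 0,
               tolerance = 1e-9)
  # positive true compounding: hot-after-hot exceeds hot-after-mild
  i30 <- which(surf$prev_grid == 30)
  j30 <- which(surf$cur_grid == 30)
  if (surf$supported[i30, j30] && surf$supported[i20, j30]) {
    expect_gt(surf$mean_pct[i30, j30], surf$mean_pct[i20, j30])
  }
  # masked cells carry no value and correspond to unobserved pairs
  expect_true(all(is.na(surf$mean_pct[!surf$supported])))
  expect_error(compounding_surface(s, seq(25, 30), seq(25, 30), tb,
                                   reference = c(20, 20)), "reference")
})

test_that("percent and log scales are order-isomorphic on a surface", {
  p <- small_gen_panel()
  des <- build_design(p, model_spec(compounding = "previous_level"))
  fit <- fit_erf(des)
  # degenerate draws: the percent surface is then the pointwise transform
  # of the log surface, so cell rankings must agree exactly
  s <- sample_coefficients(fit, 50, seed = 32)
  s$draws <- matrix(rep(fit$coefficients, each = 50), 50,
                    dimnames = list(NULL, names(fit$coefficients)))
  surf <- compounding_surface(s, seq(16, 28, 3), seq(16, 28, 3),
                              tbar = 13)
  v <- as.numeric(surf$mean_pct)
  lg <- as.numeric(surf$mean_log)
  expect_equal(order(v), order(lg))
})

test_that("response curves flag extrapolation outside the conditional range", {
  p <- small_gen_panel()
  des <- build_design(p, model_spec(compounding = "previous_level"))
  fit <- fit_erf(des)
  s <- sample_coefficients(fit, 100, seed = 33)
  supp <- support_mask(p)
  cur <- seq(-20, 45, by = 5)
  rc <- response_curve(s, cur, previous = 20, tbar = 13, support = supp)
  expect_true(all(rc$extrapolated[rc$current_c < -10]))
  expect_true(any(!rc$extrapolated))
  # bands are nested around the mean
  expect_true(all(rc$lo_pct <= rc$mean_pct + 1e-9))
  expect_true(all(rc$mean_pct <= rc$hi_pct + 1e-9))
})
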