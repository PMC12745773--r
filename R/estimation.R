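#' Absorb two-way fixed effects from a design
#'
#' Residualizes the outcome and every regressor column on both
#' fixed-effect group sets by alternating within-group demeaning, iterated
#' to convergence (tolerance 1e-10 on the maximum absolute adjustment,
#' relative to column scale; cap 10,000 sweeps). Slopes estimated on the
#' demeaned design equal those from explicit dummy-variable least squares
#' (Frisch-Waugh-Lovell). Columns demeaned to (numerically) zero variance
#' are collinear with the fixed effects and are flagged.
#'
#' @param design a `heat_design`.
#' @param tol convergence tolerance.
#' @param maxit iteration cap.
#' @return list: `y` (demeaned outcome), `X` (demeaned regressors),
#'   `collinear` (names of FE-collinear columns), `iterations`.
#' @export
absorb_fixed_effects <- function(design, tol = 1e-10, maxit = 10000) {
  stopifnot(inherits(design, "heat_design"))
  M <- cbind(design$y, design$X)
  g1 <- as.integer(design$fe1) - 1L
  g2 <- as.integer(design$fe2) - 1L
  res <- demean_two_way_cpp(M, g1, g2, nlevels(design$fe1),
                            nlevels(design$fe2), tol, as.integer(maxit))
  if (!all(res$converged)) {
    bad <- which(!res$converged)
    stop("fixed-effect absorption did not converge for ", length(bad),
         " column(s); final max adjustment ",
         format(max(res$final_delta[bad]), digits = 3))
  }
  Xd <- res$X[, -1, drop = FALSE]
  colnames(Xd) <- colnames(design$X)
  v <- res$var_out[-1]
  v0 <- res$var_in[-1]
  collinear <- colnames(Xd)[v < 1e-12 * (1 + v0)]
  list(y = res$X[, 1], X = Xd, collinear = collinear,
       iterations = max(res$iterations))
}

# Number of connected components of the bipartite graph linking the two
# fixed-effect group sets (needed for absorbed degrees of freedom).
fe_components <- function(fe1, fe2) {
  n1 <- nlevels(fe1)
  n2 <- nlevels(fe2)
  parent <- seq_len(n1 + n2)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  a <- as.integer(fe1)
  b <- as.integer(fe2) + n1
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n1 + n2), find, integer(1))))
}

#' Fit an exposure-response model by absorbed least squares
#'
#' OLS on the two-way-demeaned design, with department-clustered (CR1)
#' covariance and degrees of freedom accounting for the absorbed group
#' counts (G1 + G2 minus the number of connected components of the group
#' graph). FE-collinear columns are dropped with a warning; rank deficiency
#' among the remaining substantive regressors is an error naming the
#' collinear set.
#'
#' @param design a `heat_design`.
#' @param period optional estimation-period tag (e.g. `c(1980, 2002)`),
#'   stored as metadata and propagated to coefficient samples.
#' @return a `heat_fit`: coefficients, cluster-robust `vcov`, `se`,
#'   `nobs`, `n_clusters`, `df_absorbed`, `residuals`, dropped column
#'   names, the spec and `g_info`, and the absorbed design (for the
#'   sandwich).
#' @export
fit_erf <- function(design, period = NULL) {
  ab <- absorb_fixed_effects(design)
  keep <- setdiff(colnames(ab$X), ab$collinear)
  if (length(ab$collinear) > 0) {
    warning("dropping fixed-effect-collinear column(s): ",
            paste(ab$collinear, collapse = ", "))
  }
  X <- ab$X[, keep, drop = FALSE]
  y <- ab$y
  # solve the normal equations on unit-RMS-scaled columns (Cholesky); fall
  # back to pivoted QR only to name the collinear set on rank deficiency
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  sc <- sqrt(diag(XtX) / nrow(X))
  sc[sc == 0] <- 1
  XtXs <- XtX / outer(sc, sc)
  ch <- tryCatch(chol(XtXs), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < 1e-8)) {
    qrX <- qr(t(t(X) / sc))
    bad <- colnames(X)[qrX$pivot[seq_len(ncol(X)) > qrX$rank]]
    stop("rank-deficient design; collinear regressor(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- backsolve(ch, forwardsolve(t(ch), Xty / sc)) / sc
  resid <- y - X %*% beta
  XtX_inv <- t(chol2inv(ch) / sc) / sc
  df_absorbed <- nlevels(design$fe1) + nlevels(design$fe2) -
    fe_components(design$fe1, design$fe2)
  fit <- structure(list(
    coefficients = setNames(as.numeric(beta), keep),
    nobs = length(y), n_clusters = nlevels(design$cluster),
    cluster = design$cluster, residuals = as.numeric(resid),
    X_demeaned = X, XtX_inv = XtX_inv,
    df_absorbed = df_absorbed, dropped = ab$collinear,
    spec = design$spec, g_info = design$g_info, period = period,
    absorb_iterations = ab$iterations
  ), class = "heat_fit")
  fit$vcov <- cluster_vcov(fit)
  fit$se <- sqrt(diag(fit$vcov))
  fit
}

#' Cluster-robust (CR1) covariance of a fitted model
#'
#' The sandwich (X'X)^-1 (sum_g X_g' u_g u_g' X_g) (X'X)^-1 on the
#' absorbed design, scaled by the CR1 small-sample factor
#' G/(G-1) x (N-1)/(N-K), where K counts the substantive regressors plus
#' the absorbed fixed-effect degrees of freedom. Clustering by department
#' accommodates arbitrary within-department correlation of the errors.
#'
#' @param fit a `heat_fit`.
#' @param cluster optional replacement cluster factor (defaults to the
#'   fit's department clusters).
#' @return covariance matrix (symmetric, PSD up to numerical noise).
#' @export
cluster_vcov <- function(fit, cluster = NULL) {
  stopifnot(inherits(fit, "heat_fit"))
  cl <- cluster %||% fit$cluster
  cl <- droplevels(as.factor(cl))
  G <- nlevels(cl)
  if (G < 2) stop("clustered covariance requires at least 2 clusters")
  X <- fit$X_demeaned
  u <- fit$residuals
  if (any(!is.finite(u))) stop("non-finite residuals in sandwich inputs")
  # sum_g (X_g' u_g)(X_g' u_g)'
  S <- rowsum(X * u, cl)
  meat <- crossprod(S)
  N <- fit$nobs
  K <- ncol(X) + fit$df_absorbed
  cr1 <- G / (G - 1) * (N - 1) / (N - K)
  V <- cr1 * fit$XtX_inv %*% meat %*% fit$XtX_inv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(fit$coefficients), names(fit$coefficients))
  V
}

#' Multivariate-normal coefficient samples
#'
#' Draws n samples from MVN(beta_hat, V_hat) via the symmetric eigen
#' factorization of the cluster-robust covariance, with negative
#' eigenvalues (numerical noise) clipped at zero. These draws propagate
#' coefficient uncertainty through every downstream contrast and
#' prediction; 95% intervals are the 2.5th to 97.5th percentiles across
#' draws.
#'
#' @param fit a `heat_fit`.
#' @param n number of draws (default 500).
#' @param seed RNG seed (stored for pairing checks).
#' @return a `coef_samples`: `draws` (n x K matrix), `beta`, `spec`,
#'   `g_info`, `period`, `seed`.
#' @export
sample_coefficients <- function(fit, n = 500, seed = 1L) {
  stopifnot(inherits(fit, "heat_fit"))
  V <- fit$vcov
  if (any(!is.finite(V))) stop("non-finite entries in coefficient covariance")
  eg <- eigen(V, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  set.seed(seed)
  K <- length(fit$coefficients)
  Z <- matrix(rnorm(n * K), n, K)
  draws <- Z %*% (t(eg$vectors) * sqrt(lam))
  draws <- sweep(draws, 2, fit$coefficients, `+`)
  colnames(draws) <- names(fit$coefficients)
  structure(list(draws = draws, beta = fit$coefficients,
                 spec = fit$spec, g_info = fit$g_info,
                 period = fit$period, seed = seed, n = n),
            class = "coef_samples")
}

#' @export
print.heat_fit <- function(x, ...) {
  cat("heat_fit:", length(x$coefficients), "coefficients;", x$nobs,
      "obs;", x$n_clusters, "clusters;", x$df_absorbed,
      "absorbed fixed-effect df",
      if (!is.null(x$period)) paste0("; period ",
                                     paste(x$period, collapse = "-")), "\n")
  invisible(x)
}

#' Serialize a fitted model and draws to a CSV/JSON bundle
#'
#' Writes `<stem>_coef.csv` (name, estimate, se), `<stem>_vcov.csv`, and,
#' if draws are supplied, `<stem>_draws.csv`, plus `<stem>_meta.json`.
#'
#' @param fit a `heat_fit`.
#' @param stem output path stem.
#' @param samples optional `coef_samples`.
#' @return invisibly, the written paths.
#' @export
write_fit_bundle <- function(fit, stem, samples = NULL) {
  paths <- c(coef = paste0(stem, "_coef.csv"),
             vcov = paste0(stem, "_vcov.csv"),
             meta = paste0(stem, "_meta.json"))
  write.csv(data.frame(name = names(fit$coefficients),
                       estimate = unname(fit$coefficients),
                       se = unname(fit$se)),
            paths["coef"], row.names = FALSE, quote = FALSE)
  write.csv(as.data.frame(fit$vcov), paths["vcov"], row.names = FALSE)
  meta <- list(nobs = fit$nobs, n_clusters = fit$n_clusters,
               df_absorbed = fit$df_absorbed, period = fit$period,
               spec = unclass(fit$spec))
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA)
  if (!is.null(samples)) {
    paths <- c(paths, draws = paste0(stem, "_draws.csv"))
    write.csv(as.data.frame(samples$draws), paths["draws"], row.names = FALSE)
  }
  invisible(paths)
}
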