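#' Sample covariance summary of a response matrix
#'
#' @param data Respondent x item numeric data frame or matrix.
#' @return List of class `ipv_cov`: `S` (unbiased, n-1 denominator), `n`,
#'   `means`, `sds`, `items`.
#' @export
sample_covariance <- function(data) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  if (nrow(x) < 3L) stop("need >= 3 respondents")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(x)[sds == 0], collapse = ", "))
  S <- stats::cov(x)
  S <- (S + t(S)) / 2
  structure(list(S = S, n = nrow(x), means = colMeans(x), sds = sds,
                 items = colnames(x)), class = "ipv_cov")
}

#' Specify a confirmatory factor model
#'
#' Simple structure: every item loads on exactly one factor; factor variances
#' are fixed to 1 for identification, so the solution is directly in
#' standardized metric. With `structure = "correlated"` all factor
#' correlations are free; `"orthogonal"` fixes them to 0; a single-factor
#' spec has no correlation parameters.
#'
#' @param loadings Named list `factor -> character vector of item ids`.
#' @param structure `"correlated"` or `"orthogonal"`.
#' @return Object of class `ipv_cfa_spec`.
#' @export
#' @examples
#' cfa_spec(list(g = c("a", "b", "c")))
cfa_spec <- function(loadings, structure = c("correlated", "orthogonal")) {
  structure <- match.arg(structure)
  stopifnot(is.list(loadings), length(loadings) >= 1L,
            !is.null(names(loadings)))
  items <- unlist(loadings, use.names = FALSE)
  if (anyDuplicated(items))
    stop("an item may load on exactly one factor")
  fac_of <- rep(names(loadings), lengths(loadings))
  structure(list(items = items, factors = names(loadings),
                 fac_of = fac_of, structure = structure),
            class = "ipv_cfa_spec")
}

#' Single-factor spec over a registry's items
#' @param registry An `ipv_registry`.
#' @param level `"pool"` (one factor over all items), `"facet"` (one factor
#'   per facet) or `"instrument"` (one per instrument).
#' @return An `ipv_cfa_spec`.
#' @export
registry_spec <- function(registry, level = c("pool", "facet", "instrument")) {
  level <- match.arg(level)
  key <- switch(level,
    pool = rep("general", nrow(registry)),
    facet = paste(registry$instrument, registry$facet, sep = "."),
    instrument = registry$instrument)
  cfa_spec(split(registry$item_id, factor(key, levels = unique(key))))
}

## Model-implied covariance and ML discrepancy ------------------------------

sigma_of <- function(lam, theta, Phi, spec) {
  p <- length(lam); k <- length(spec$factors)
  L <- matrix(0, p, k, dimnames = list(spec$items, spec$factors))
  L[cbind(seq_len(p), match(spec$fac_of, spec$factors))] <- lam
  Sig <- L %*% Phi %*% t(L)
  diag(Sig) <- diag(Sig) + theta
  list(Sigma = Sig, L = L)
}

phi_from_par <- function(phipar, k) {
  Phi <- diag(k)
  if (length(phipar)) Phi[upper.tri(Phi)] <- phipar
  Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
  Phi
}

# F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p, and its analytic gradient
# with respect to (lambda, log theta, phi). Returns a large penalty when the
# implied Sigma is not positive definite so the optimizer backtracks.
ml_objective <- function(par, S, logdetS, spec, grad = FALSE) {
  p <- length(spec$items); k <- length(spec$factors)
  nphi <- if (spec$structure == "correlated" && k > 1L) k * (k - 1L) / 2L else 0L
  lam <- par[seq_len(p)]
  theta <- exp(par[p + seq_len(p)])
  Phi <- phi_from_par(if (nphi) par[2L * p + seq_len(nphi)] else numeric(0), k)
  m <- sigma_of(lam, theta, Phi, spec)
  ch <- tryCatch(chol(m$Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    if (grad) return(list(value = 1e10, gradient = rep(0, length(par))))
    return(1e10)
  }
  Sinv_chol <- backsolve(ch, diag(p))          # R^-1
  Siginv <- Sinv_chol %*% t(Sinv_chol)
  val <- 2 * sum(log(diag(ch))) + sum(Siginv * S) - logdetS - p
  if (!grad) return(val)
  G <- Siginv %*% (m$Sigma - S) %*% Siginv     # dF/dSigma
  GLP <- G %*% m$L %*% Phi
  g_lam <- 2 * GLP[cbind(seq_len(p), match(spec$fac_of, spec$factors))]
  g_u <- diag(G) * theta
  g <- c(g_lam, g_u)
  if (nphi) {
    M <- t(m$L) %*% G %*% m$L
    g <- c(g, 2 * M[upper.tri(M)])
  }
  list(value = val, gradient = g)
}

cfa_start <- function(R, spec) {
  p <- length(spec$items); k <- length(spec$factors)
  fidx <- match(spec$fac_of, spec$factors)
  lam0 <- numeric(p)
  for (f in seq_len(k)) {
    sel <- which(fidx == f)
    if (length(sel) == 1L) { lam0[sel] <- 0.7; next }
    Rf <- R[sel, sel, drop = FALSE]
    # first principal component of the facet block, sign-aligned
    e <- eigen(Rf, symmetric = TRUE)
    v <- e$vectors[, 1]
    if (sum(v) < 0) v <- -v
    lam0[sel] <- pmin(0.95, pmax(0.1, sqrt(max(e$values[1], 0.2)) * abs(v)))
  }
  theta0 <- pmax(0.1, 1 - lam0^2)
  phi0 <- numeric(0)
  if (spec$structure == "correlated" && k > 1L) {
    # start factor correlations at the correlations of unit-weight composites
    Phi0 <- diag(k)
    for (f in 1:(k - 1)) for (g in (f + 1):k) {
      a <- which(fidx == f); b <- which(fidx == g)
      num <- sum(R[a, b])
      den <- sqrt(sum(R[a, a]) * sum(R[b, b]))
      Phi0[f, g] <- max(-0.9, min(0.9, num / den))
    }
    phi0 <- Phi0[upper.tri(Phi0)]
  }
  c(lam0, log(theta0), phi0)
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p`
#' over free loadings, factor correlations, and uniquenesses, using an
#' analytic gradient. Uniquenesses are log-parameterized (bounded below at
#' 1e-6; hitting the bound is flagged as a Heywood case). The model is fitted
#' on the correlation metric -- the model is scale invariant, so the
#' discrepancy, the test statistic and the completely standardized solution
#' are identical to a covariance-metric fit -- and the test statistic uses
#' the classic `(n - 1) * F_min` convention.
#'
#' Initialization is deterministic (per-facet principal components and
#' composite correlations); there is no randomness in fitting.
#'
#' @param cov An `ipv_cov` from [sample_covariance()], or a covariance/
#'   correlation matrix (then `n` must be given).
#' @param spec An `ipv_cfa_spec`.
#' @param n Sample size, only when `cov` is a bare matrix.
#' @param control List: `gtol` (gradient max-norm tolerance for the
#'   convergence flag, default 1e-6), `iter.max` (default 10000).
#' @return Object of class `ipv_cfa`: standardized loadings (`lambda`,
#'   named; `Lambda` full pattern matrix), `Phi` (factor correlations),
#'   `theta` (uniquenesses), `F_min`, `chi2`, `df`, `n`, `converged`,
#'   `n_iter`, `heywood` (item ids at the variance floor), `Sigma_hat`
#'   (implied correlation matrix), `sb_c`/`chi2_scaled` (filled by
#'   [satorra_bentler()]; initialized to `NA`).
#' @export
fit_ml <- function(cov, spec, n = NULL, control = list()) {
  if (inherits(cov, "ipv_cov")) { S <- cov$S; n <- cov$n } else {
    S <- as.matrix(cov)
    if (is.null(n)) stop("n is required when passing a bare matrix")
  }
  if (is.null(colnames(S))) stop("covariance matrix needs item names")
  absent <- setdiff(spec$items, colnames(S))
  if (length(absent)) stop("spec items not in data: ", paste(absent, collapse = ", "))
  S <- S[spec$items, spec$items, drop = FALSE]
  R <- stats::cov2cor(S)
  p <- length(spec$items); k <- length(spec$factors)
  ldS <- determinant(R, logarithm = TRUE)
  if (ldS$sign <= 0) stop("sample covariance is not positive definite")
  logdetS <- as.numeric(ldS$modulus)
  ctrl <- utils::modifyList(list(gtol = 1e-6, iter.max = 10000L), control)

  nphi <- if (spec$structure == "correlated" && k > 1L) k * (k - 1L) / 2L else 0L
  start <- cfa_start(R, spec)
  lower <- c(rep(-1.5, p), rep(log(1e-6), p), rep(-0.999, nphi))
  upper <- c(rep(1.5, p), rep(log(10), p), rep(0.999, nphi))
  fn <- function(par) ml_objective(par, R, logdetS, spec, grad = FALSE)
  gr <- function(par) ml_objective(par, R, logdetS, spec, grad = TRUE)$gradient
  proj_gnorm <- function(par) {
    gvec <- gr(par)
    at_lo <- par <= lower + 1e-10 & gvec > 0
    at_hi <- par >= upper - 1e-10 & gvec < 0
    max(abs(gvec[!(at_lo | at_hi)]), 0)
  }
  opt <- stats::nlminb(start, fn, gr, lower = lower, upper = upper,
                       control = list(iter.max = ctrl$iter.max,
                                      eval.max = 4L * ctrl$iter.max,
                                      rel.tol = 1e-12, x.tol = 1e-12))
  # nlminb can stop on relative function change with the gradient not yet
  # flat; an L-BFGS-B polish from its solution flattens it
  if (proj_gnorm(opt$par) > ctrl$gtol) {
    pol <- stats::optim(opt$par, fn, gr, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(factr = 1, maxit = ctrl$iter.max))
    if (pol$value <= opt$objective) {
      opt$par <- pol$par; opt$objective <- pol$value
      opt$iterations <- opt$iterations + pol$counts[["function"]]
      opt$convergence <- 0L
    }
  }
  par <- opt$par
  gnorm <- proj_gnorm(par)
  lam <- par[seq_len(p)]
  theta <- exp(par[p + seq_len(p)])
  Phi <- phi_from_par(if (nphi) par[2L * p + seq_len(nphi)] else numeric(0), k)
  m <- sigma_of(lam, theta, Phi, spec)
  # completely standardized solution (implied variances can drift from 1)
  dsd <- sqrt(diag(m$Sigma))
  lam_std <- lam / dsd
  theta_std <- theta / dsd^2
  # sign alignment: reflect each factor so it loads positively on its items'
  # unit-weight sum (removes sign indeterminacy)
  fidx <- match(spec$fac_of, spec$factors)
  flip <- vapply(seq_len(k), function(f) sum(lam_std[fidx == f]) < 0, logical(1))
  if (any(flip)) {
    sgn <- ifelse(flip, -1, 1)
    lam_std <- lam_std * sgn[fidx]
    Phi <- diag(sgn, k) %*% Phi %*% diag(sgn, k)
  }
  dimnames(Phi) <- list(spec$factors, spec$factors)
  q <- 2L * p + nphi
  df <- p * (p + 1L) / 2L - q
  F_min <- max(0, opt$objective)
  chi2 <- max(0, (n - 1) * F_min)
  heywood <- spec$items[theta <= 1.5e-6]
  Lstd <- matrix(0, p, k, dimnames = list(spec$items, spec$factors))
  Lstd[cbind(seq_len(p), fidx)] <- lam_std
  Sigma_hat <- Lstd %*% Phi %*% t(Lstd)
  diag(Sigma_hat) <- diag(Sigma_hat) + theta_std
  res <- list(lambda = stats::setNames(lam_std, spec$items), Lambda = Lstd,
              Phi = Phi, theta = stats::setNames(theta_std, spec$items),
              F_min = F_min, chi2 = chi2, df = df, n = n, q = q,
              converged = gnorm <= ctrl$gtol && opt$convergence %in% c(0L, 1L),
              gnorm = gnorm, n_iter = opt$iterations,
              heywood = heywood, Sigma_hat = Sigma_hat, R = R, spec = spec,
              sb_c = NA_real_, chi2_scaled = NA_real_)
  class(res) <- "ipv_cfa"
  if (length(heywood))
    warning("Heywood case: uniqueness at floor for ",
            paste(heywood, collapse = ", "))
  res
}

#' @export
print.ipv_cfa <- function(x, ...) {
  cat("<ipv_cfa> ", length(x$lambda), " items, ", length(x$spec$factors),
      " factor(s); chi2 = ", format(x$chi2, digits = 6), " on df = ", x$df,
      if (!is.na(x$chi2_scaled))
        paste0(" (scaled ", format(x$chi2_scaled, digits = 6), ")"),
      "; converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

## Satorra-Bentler scaling ---------------------------------------------------

duplication_matrix <- function(p) {
  ps <- p * (p + 1L) / 2L
  D <- matrix(0, p * p, ps)
  k <- 0L
  for (j in seq_len(p)) for (i in j:p) {
    k <- k + 1L
    D[(j - 1L) * p + i, k] <- 1
    D[(i - 1L) * p + j, k] <- 1
  }
  D
}

vech <- function(M) M[lower.tri(M, diag = TRUE)]

# Jacobian d vech(Sigma) / d theta' at the fitted solution, standardized
# metric; columns span the same space under any smooth reparameterization,
# which is all the residual projector needs.
cfa_delta <- function(fit) {
  spec <- fit$spec
  p <- length(spec$items); k <- length(spec$factors)
  fidx <- match(spec$fac_of, spec$factors)
  L <- fit$Lambda; Phi <- fit$Phi
  cols <- vector("list", fit$q)
  c0 <- 0L
  PhiLt <- Phi %*% t(L)                       # k x p
  for (i in seq_len(p)) {                     # loadings
    dS <- matrix(0, p, p)
    dS[i, ] <- PhiLt[fidx[i], ]
    dS <- dS + t(dS)
    cols[[c0 + i]] <- vech(dS)
  }
  c0 <- p
  for (i in seq_len(p)) {                     # uniquenesses
    dS <- matrix(0, p, p); dS[i, i] <- 1
    cols[[c0 + i]] <- vech(dS)
  }
  c0 <- 2L * p
  if (spec$structure == "correlated" && k > 1L) {
    ut <- which(upper.tri(diag(k)), arr.ind = TRUE)
    for (r in seq_len(nrow(ut))) {
      f <- ut[r, 1]; g <- ut[r, 2]
      dS <- tcrossprod(L[, f], L[, g])
      dS <- dS + t(dS)
      cols[[c0 + r]] <- vech(dS)
    }
  }
  do.call(cbind, cols)
}

#' Satorra-Bentler scaled test statistic
#'
#' Computes the mean-scaling factor `c = tr(U Gamma) / df` from the sample
#' fourth-order moments (`Gamma` = asymptotic covariance of `vech(S)`) and
#' the normal-theory residual weight projector
#' `U = W - W Delta (Delta' W Delta)^-1 Delta' W`, with
#' `W = 0.5 D' (Sigma^-1 x Sigma^-1) D`. The scaled statistic is
#' `chi2 / c`; under multivariate normality `c -> 1`, under excess kurtosis
#' `c > 1` so the scaled statistic is deflated accordingly.
#'
#' @param data The raw respondent x item data the model was fitted to
#'   (fourth moments are needed; a covariance matrix is not enough).
#' @param fit An `ipv_cfa` from [fit_ml()].
#' @return The fit with `sb_c` and `chi2_scaled` filled in. For a
#'   just-identified model (`df = 0`) the scaling is undefined: `sb_c = 1`
#'   with attribute `sb_undefined = TRUE`.
#' @export
satorra_bentler <- function(data, fit) {
  spec <- fit$spec
  x <- as.matrix(as.data.frame(data)[, spec$items, drop = FALSE])
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n <= length(spec$items)) stop("need n > p for fourth-order moments")
  if (fit$df == 0L) {
    fit$sb_c <- 1; fit$chi2_scaled <- fit$chi2
    attr(fit, "sb_undefined") <- TRUE
    return(fit)
  }
  # fit is in correlation metric; use standardized scores throughout
  x <- scale(x)
  p <- ncol(x)
  S <- stats::cov(x) * (n - 1) / n
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  Y <- x[, idx[, 1], drop = FALSE] * x[, idx[, 2], drop = FALSE]
  Y <- sweep(Y, 2, vech(S))
  Gamma <- crossprod(Y) / n
  Siginv <- solve(fit$Sigma_hat)
  D <- duplication_matrix(p)
  W <- 0.5 * t(D) %*% (Siginv %x% Siginv) %*% D
  Delta <- cfa_delta(fit)
  WD <- W %*% Delta
  M <- tryCatch(solve(crossprod(Delta, WD), t(WD)),
                error = function(e) stop("singular weight matrix in scaling"))
  UG <- W %*% Gamma - WD %*% (M %*% Gamma)
  fit$sb_c <- sum(diag(UG)) / fit$df
  fit$chi2_scaled <- fit$chi2 / fit$sb_c
  fit
}

## Fit indices ---------------------------------------------------------------

#' Independence (baseline) model fit
#'
#' The baseline constrains all covariances to zero; on the correlation
#' metric its ML discrepancy has the closed form `-log|R|`.
#'
#' @param cov An `ipv_cov` or correlation/covariance matrix (with `n`).
#' @param items Optional subset/order of items.
#' @param n Sample size when `cov` is a bare matrix.
#' @return List with `chi2`, `df`, `F_min`.
#' @export
baseline_fit <- function(cov, items = NULL, n = NULL) {
  if (inherits(cov, "ipv_cov")) { S <- cov$S; n <- cov$n } else S <- as.matrix(cov)
  if (!is.null(items)) S <- S[items, items, drop = FALSE]
  R <- stats::cov2cor(S)
  p <- ncol(R)
  F_b <- -as.numeric(determinant(R, logarithm = TRUE)$modulus)
  list(chi2 = max(0, (n - 1) * F_b), df = p * (p - 1L) / 2L, F_min = F_b)
}

#' RMSEA confidence interval
#'
#' Inverts the noncentral chi-square CDF in the noncentrality parameter at
#' the `(1 + level)/2` and `(1 - level)/2` tails and maps
#' `ncp -> sqrt(ncp / (df (n-1)))`. The lower bound is 0 whenever the
#' statistic is below the corresponding central quantile.
#'
#' @param chi2,df,n Test statistic, degrees of freedom, sample size.
#' @param level Confidence level (default 0.90).
#' @return Numeric `c(lo, hi)`.
#' @export
rmsea_ci <- function(chi2, df, n, level = 0.90) {
  if (df < 1L || n <= 1) return(c(0, 0))
  a_lo <- (1 + level) / 2  # e.g. 0.95: lo bound solves P(X <= chi2 | ncp) = 0.95
  a_hi <- (1 - level) / 2
  solve_ncp <- function(target) {
    f <- function(ncp) stats::pchisq(chi2, df, ncp = ncp) - target
    if (f(0) < 0) return(0)  # even ncp = 0 leaves too little mass below chi2
    up <- max(chi2 * 2, df * 2, 10)
    while (f(up) > 0 && up < 1e8) up <- up * 2
    stats::uniroot(f, c(0, up), tol = 1e-10)$root
  }
  lo <- sqrt(solve_ncp(a_lo) / (df * (n - 1)))
  hi <- sqrt(solve_ncp(a_hi) / (df * (n - 1)))
  c(lo = lo, hi = hi)
}

#' Fit indices for a fitted CFA
#'
#' Computes `chi2/df`, RMSEA with its 90% CI, SRMR (root mean square of the
#' standardized residuals over the `p(p+1)/2` unique entries), and CFI
#' against the independence baseline. When the Satorra-Bentler scaling has
#' been computed (see [satorra_bentler()]), scaled and robust
#' (population-corrected) RMSEA/CFI variants are reported alongside the
#' normal-theory ones; both conventions are reported because published
#' "robust" indices vary between the two.
#'
#' @param fit An `ipv_cfa`.
#' @param baseline Optional baseline list from [baseline_fit()] (computed
#'   from the fit's own correlation matrix when omitted). If the baseline
#'   should be scaled too, pass a baseline with an `sb_c` element.
#' @return List of class `ipv_fit_indices`.
#' @export
fit_indices <- function(fit, baseline = NULL) {
  n <- fit$n; chi2 <- fit$chi2; df <- fit$df
  if (is.null(baseline))
    baseline <- baseline_fit(fit$R, n = n)
  chi2_df <- if (df > 0) chi2 / df else NA_real_
  rmsea <- if (df > 0) sqrt(max(0, (chi2 - df) / (df * (n - 1)))) else 0
  ci <- if (df > 0) rmsea_ci(chi2, df, n) else c(lo = 0, hi = 0)
  # SRMR on the correlation metric, unique entries incl. diagonal
  resid <- stats::cov2cor(fit$Sigma_hat) - fit$R
  srmr <- sqrt(mean(vech(resid)^2))
  num_t <- max(0, chi2 - df)
  num_b <- max(chi2 - df, baseline$chi2 - baseline$df, 0)
  cfi <- if (num_b == 0) 1 else 1 - num_t / num_b
  out <- list(chi2 = chi2, df = df, chi2_df = chi2_df,
              rmsea = rmsea, rmsea_lo = unname(ci[1]), rmsea_hi = unname(ci[2]),
              srmr = srmr, cfi = cfi, n = n,
              baseline_chi2 = baseline$chi2, baseline_df = baseline$df)
  if (!is.na(fit$sb_c)) {
    c_t <- fit$sb_c
    c_b <- if (!is.null(baseline$sb_c)) baseline$sb_c else c_t
    T_sc <- fit$chi2_scaled
    Tb_sc <- baseline$chi2 / c_b
    out$sb_c <- c_t
    out$chi2_scaled <- T_sc
    out$chi2_df_scaled <- if (df > 0) T_sc / df else NA_real_
    out$rmsea_scaled <- if (df > 0) sqrt(max(0, (T_sc - df) / (df * (n - 1)))) else 0
    ci_s <- if (df > 0) rmsea_ci(T_sc, df, n) else c(0, 0)
    out$rmsea_scaled_lo <- unname(ci_s[1]); out$rmsea_scaled_hi <- unname(ci_s[2])
    # population-corrected (robust) variants: chi2 - c * df in the numerators
    out$rmsea_robust <- if (df > 0)
      sqrt(max(0, (chi2 - c_t * df) / (df * (n - 1)))) else 0
    nt <- max(0, chi2 - c_t * df)
    nb <- max(chi2 - c_t * df, baseline$chi2 - c_b * baseline$df, 0)
    out$cfi_robust <- if (nb == 0) 1 else 1 - nt / nb
  }
  class(out) <- "ipv_fit_indices"
  out
}

#' @export
print.ipv_fit_indices <- function(x, ...) {
  cat(sprintf("chi2 = %.3f, df = %d, chi2/df = %.2f\n", x$chi2, x$df,
              ifelse(is.na(x$chi2_df), NaN, x$chi2_df)))
  cat(sprintf("RMSEA = %.3f [%.3f, %.3f], SRMR = %.3f, CFI = %.3f\n",
              x$rmsea, x$rmsea_lo, x$rmsea_hi, x$srmr, x$cfi))
  if (!is.null(x$sb_c))
    cat(sprintf("scaled: c = %.3f, chi2 = %.3f; robust RMSEA = %.3f, robust CFI = %.3f\n",
                x$sb_c, x$chi2_scaled, x$rmsea_robust, x$cfi_robust))
  invisible(x)
}

#' Side-by-side model comparison
#'
#' @param fit_a,fit_b `ipv_fit_indices` for two models on the same items.
#' @param labels Character pair of model labels.
#' @return List with an index `table` (one row per model) and `delta_chi2`,
#'   `delta_df` (unscaled differences, a vs b).
#' @export
compare_models <- function(fit_a, fit_b, labels = c("model_a", "model_b")) {
  pick <- function(f) data.frame(
    chi2 = f$chi2, df = f$df, chi2_df = f$chi2_df, rmsea = f$rmsea,
    rmsea_lo = f$rmsea_lo, rmsea_hi = f$rmsea_hi, srmr = f$srmr, cfi = f$cfi)
  tab <- rbind(pick(fit_a), pick(fit_b))
  tab <- cbind(model = labels, tab)
  list(table = tab, delta_chi2 = fit_a$chi2 - fit_b$chi2,
       delta_df = fit_a$df - fit_b$df)
}

#' Per-instrument CFA fit table
#'
#' Fits each instrument's facet-structure model (correlated facets; a
#' single-facet instrument gets a one-factor model) on its own items and
#' reports the scaled test statistic and fit indices, one row per
#' instrument.
#'
#' @param data Validated response data over a registry's items.
#' @param registry An `ipv_registry`.
#' @param scaled Compute Satorra-Bentler scaling (default TRUE).
#' @return Data frame with one row per instrument: `chi2_scaled` (equal to
#'   `chi2` when `scaled = FALSE`), `df`, `chi2_df`, rmsea/srmr/cfi columns
#'   (scaled + robust variants when available) and `converged`.
#' @export
fit_instrument_cfas <- function(data, registry, scaled = TRUE) {
  rows <- list()
  for (inst in unique(registry$instrument)) {
    sub <- registry[registry$instrument == inst, ]
    spec <- registry_spec(sub, level = if (length(unique(sub$facet)) > 1L)
      "facet" else "pool")
    cv <- sample_covariance(data[, sub$item_id, drop = FALSE])
    fit <- fit_ml(cv, spec)
    base <- baseline_fit(cv)
    if (scaled && fit$df > 0L) {
      fit <- satorra_bentler(data, fit)
      base$sb_c <- baseline_sb_c(data, sub$item_id)
    }
    fi <- fit_indices(fit, base)
    rows[[inst]] <- data.frame(
      instrument = inst, n_items = nrow(sub),
      chi2 = fi$chi2, chi2_scaled = if (scaled) fi$chi2_scaled else fi$chi2,
      df = fi$df, chi2_df = if (scaled) fi$chi2_df_scaled else fi$chi2_df,
      rmsea = fi$rmsea, rmsea_lo = fi$rmsea_lo, rmsea_hi = fi$rmsea_hi,
      rmsea_robust = if (scaled) fi$rmsea_robust else NA_real_,
      srmr = fi$srmr, cfi = fi$cfi,
      cfi_robust = if (scaled) fi$cfi_robust else NA_real_,
      converged = fit$converged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Scaling factor of the independence model (diagonal Sigma): Delta spans the
# diagonal coordinates, so U projects onto off-diagonal moments.
baseline_sb_c <- function(data, items) {
  x <- scale(as.matrix(as.data.frame(data)[, items, drop = FALSE]))
  n <- nrow(x); p <- ncol(x)
  S <- stats::cov(x) * (n - 1) / n
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  Y <- x[, idx[, 1], drop = FALSE] * x[, idx[, 2], drop = FALSE]
  Y <- sweep(Y, 2, vech(S))
  Gamma <- crossprod(Y) / n
  Sigma0 <- diag(diag(S))
  Siginv <- diag(1 / diag(S))
  D <- duplication_matrix(p)
  W <- 0.5 * t(D) %*% (Siginv %x% Siginv) %*% D
  diag_cols <- which(idx[, 1] == idx[, 2])
  Delta <- matrix(0, nrow(idx), p)
  Delta[cbind(diag_cols, seq_len(p))] <- 1
  WD <- W %*% Delta
  M <- solve(crossprod(Delta, WD), t(WD))
  UG <- W %*% Gamma - WD %*% (M %*% Gamma)
  df_b <- p * (p - 1L) / 2L
  sum(diag(UG)) / df_b
}
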