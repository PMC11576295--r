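test_that("sample covariance matches hand computation", {
  # 3 x 2 toy: x = (0,1,2), y = (1,3,2); means 1, 2
  # cov_xx = 1, cov_yy = 1, cov_xy = ((-1)(-1) + 0*1 + 1*0)/2 = 0.5
  d <- data.frame(x = c(0, 1, 2), y = c(1, 3, 2))
  cv <- sample_covariance(d)
  expect_equal(unname(cv$S), matrix(c(1, 0.5, 0.5, 1), 2), tolerance = 1e-12)
  expect_equal(cv$n, 3L)
  # duplicated column: off-diagonal equals the diagonal
  d2 <- data.frame(a = rnorm(20))
  d2$b <- d2$a
  S2 <- sample_covariance(d2)$S
  expect_equal(S2["a", "b"], S2["a", "a"])
  # standardized input gives unit diagonal
  z <- scale(matrix(rnorm(60), 20, 3))
  colnames(z) <- letters[1:3]
  expect_equal(unname(diag(sample_covariance(z)$S)), rep(1, 3),
               tolerance = 1e-12)
  expect_error(sample_covariance(data.frame(a = rep(1, 10), b = rnorm(10))),
               "constant")
})

test_that("model specification enforces simple structure", {
  expect_error(cfa_spec(list(f1 = c("a", "b"), f2 = c("b", "c"))),
               "exactly one factor")
  sp <- registry_spec(default_registry(), "facet")
  expect_equal(length(sp$factors), 11L)
  expect_equal(length(sp$items), 47L)
  expect_equal(length(registry_spec(default_registry(), "instrument")$factors), 4L)
})

test_that("perfect-fit identity: fitting the implied covariance recovers it", {
  tf <- two_factor_truth(phi = 0.6)
  fit <- fit_ml(tf$Sigma, tf$spec, n = 500)
  expect_lte(fit$F_min, 1e-8)
  expect_true(fit$converged)
  expect_equal(unname(fit$lambda), tf$lambda, tolerance = 1e-4)
  expect_equal(fit$Phi["f1", "f2"], 0.6, tolerance = 1e-4)
  base <- baseline_fit(tf$Sigma, n = 500)
  fi <- fit_indices(fit, base)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$cfi, 1)
  expect_lte(fi$srmr, 1e-6)
})

test_that("just-identified single-factor model fits exactly with df = 0", {
  # closed form for 3 items: lambda_1 = sqrt(r12 r13 / r23), etc.
  R <- matrix(c(1, 0.56, 0.48, 0.56, 1, 0.42, 0.48, 0.42, 1), 3,
              dimnames = rep(list(c("a", "b", "c")), 2))
  fit <- fit_ml(R, cfa_spec(list(g = c("a", "b", "c"))), n = 200)
  expect_equal(fit$df, 0L)
  expect_lt(fit$chi2, 1e-6)
  lam_closed <- c(sqrt(0.56 * 0.48 / 0.42), sqrt(0.56 * 0.42 / 0.48),
                  sqrt(0.48 * 0.42 / 0.56))
  expect_equal(unname(fit$lambda), lam_closed, tolerance = 1e-6)
  # scaling undefined at df = 0: flagged, statistic unchanged
  set.seed(8)
  Sig0 <- tcrossprod(c(0.7, 0.6, 0.5)); diag(Sig0) <- 1
  x <- as.data.frame(matrix(rnorm(600), 200, 3) %*% chol(Sig0))
  colnames(x) <- c("a", "b", "c")
  f0 <- fit_ml(sample_covariance(x), cfa_spec(list(g = c("a", "b", "c"))))
  f0 <- satorra_bentler(x, f0)
  expect_equal(f0$sb_c, 1)
  expect_true(isTRUE(attr(f0, "sb_undefined")))
  expect_equal(f0$chi2_scaled, f0$chi2)
})

test_that("single-factor ML solutions agree with an independent ML factor
          analysis (factanal) across seeded models", {
  for (seed in 1:10) {
    set.seed(seed)
    p <- sample(5:9, 1)
    lam <- runif(p, 0.3, 0.9)
    Sig <- tcrossprod(lam)
    diag(Sig) <- 1
    n <- 400
    x <- matrix(rnorm(n * p), n, p) %*% chol(Sig)
    colnames(x) <- paste0("v", seq_len(p))
    fa <- factanal(covmat = cov(x), factors = 1, n.obs = n)
    fit <- fit_ml(sample_covariance(x), cfa_spec(list(g = colnames(x))))
    expect_equal(unname(fit$lambda), as.numeric(fa$loadings),
                 tolerance = 1e-3)
    expect_equal(fit$F_min, unname(fa$criteria["objective"]),
                 tolerance = 1e-6)
  }
})

test_that("fit is invariant to item rescaling and covariance vs correlation", {
  cc <- default_sim()
  reg <- cc$pop$registry
  sub <- reg[reg$instrument == "FS", ]
  x <- as.data.frame(cc$sim$responses)[, sub$item_id]
  spec <- registry_spec(sub, "pool")
  f1 <- fit_ml(sample_covariance(x), spec)
  x2 <- x; x2[[3]] <- x2[[3]] * 37
  f2 <- fit_ml(sample_covariance(x2), spec)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-6)
  expect_equal(f2$chi2, f1$chi2, tolerance = 1e-6)
  i1 <- fit_indices(f1); i2 <- fit_indices(f2)
  expect_equal(i2$rmsea, i1$rmsea, tolerance = 1e-6)
  expect_equal(i2$srmr, i1$srmr, tolerance = 1e-6)
  expect_equal(i2$cfi, i1$cfi, tolerance = 1e-6)
  # correlation-matrix fit equals the standardized covariance solution
  f3 <- fit_ml(cov2cor(sample_covariance(x)$S), spec, n = nrow(x))
  expect_equal(f3$lambda, f1$lambda, tolerance = 1e-5)
  expect_equal(f3$F_min, f1$F_min, tolerance = 1e-8)
})

test_that("correlated-factor recovery on continuous synthetic data", {
  tf <- two_factor_truth(phi = 0.6)
  set.seed(31)
  x <- matrix(rnorm(3000 * 6), 3000, 6) %*% chol(tf$Sigma)
  colnames(x) <- rownames(tf$Sigma)
  fit <- fit_ml(sample_covariance(x), tf$spec)
  expect_true(fit$converged)
  expect_lt(max(abs(unname(fit$lambda) - tf$lambda)), 0.05)
  expect_lt(abs(fit$Phi["f1", "f2"] - 0.6), 0.05)
  # block-diagonal truth: estimated factor correlation near zero
  tf0 <- two_factor_truth(phi = 0)
  set.seed(32)
  x0 <- matrix(rnorm(3000 * 6), 3000, 6) %*% chol(tf0$Sigma)
  colnames(x0) <- rownames(tf0$Sigma)
  fit0 <- fit_ml(sample_covariance(x0), tf0$spec)
  expect_lt(abs(fit0$Phi["f1", "f2"]), 0.05)
})

test_that("Satorra-Bentler scaling reacts to excess kurtosis", {
  tf <- two_factor_truth()
  set.seed(41)
  n <- 2000
  x <- matrix(rnorm(n * 6), n, 6) %*% chol(tf$Sigma)
  # scale mixture of normals: elliptical with heavy tails
  x_t <- x * sqrt(5 / rchisq(n, df = 5))
  colnames(x_t) <- rownames(tf$Sigma)
  x_t <- as.data.frame(x_t)
  fit <- fit_ml(sample_covariance(x_t), tf$spec)
  fit <- satorra_bentler(x_t, fit)
  expect_gt(fit$sb_c, 1.2)
  expect_equal(fit$chi2_scaled, fit$chi2 / fit$sb_c)
})

test_that("fit indices follow their closed forms", {
  mk <- function(chi2, df, n) {
    f <- list(chi2 = chi2, df = df, n = n, sb_c = NA_real_,
              Sigma_hat = diag(2), R = diag(2))
    colnames(f$Sigma_hat) <- rownames(f$Sigma_hat) <- c("a", "b")
    colnames(f$R) <- rownames(f$R) <- c("a", "b")
    f
  }
  base <- list(chi2 = 500, df = 1)
  # chi2 = df: rmsea 0, cfi 1
  fi <- fit_indices(mk(50, 50, 201), base)
  expect_equal(fi$rmsea, 0)
  expect_equal(fi$cfi, 1)
  # closed form: chi2 = 100, df = 50, n = 201 -> sqrt(50 / (50 * 200))
  fi2 <- fit_indices(mk(100, 50, 201), base)
  expect_equal(fi2$rmsea, sqrt(50 / (50 * 200)), tolerance = 1e-12)
  expect_equal(fi2$chi2_df, 2)
  # rmsea strictly increasing in chi2 at fixed df, n
  rs <- vapply(seq(60, 300, by = 20),
               function(ch) fit_indices(mk(ch, 50, 201), base)$rmsea,
               numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("rmsea confidence interval brackets the point estimate", {
  # below the central quantile: lower bound 0
  ci0 <- rmsea_ci(40, 50, 300)
  expect_equal(unname(ci0[1]), 0)
  for (chi2 in c(80, 150, 265.09)) {
    ci <- rmsea_ci(chi2, 74, 698)
    pt <- sqrt(max(0, (chi2 - 74) / (74 * 697)))
    expect_lte(ci[["lo"]], pt)
    expect_gte(ci[["hi"]], pt)
    expect_lt(ci[["hi"]], 0.10)
  }
  # degenerate inputs
  expect_equal(unname(rmsea_ci(10, 0, 100)), c(0, 0))
})

test_that("model comparison prefers the true two-factor structure", {
  fiA <- fit_indices(structure(list(chi2 = 100, df = 50, n = 201,
                                    sb_c = NA_real_,
                                    Sigma_hat = structure(diag(2), dimnames = rep(list(c("a","b")), 2)),
                                    R = structure(diag(2), dimnames = rep(list(c("a","b")), 2))),
                               class = "ipv_cfa"),
                     list(chi2 = 500, df = 1))
  cmpAA <- compare_models(fiA, fiA)
  expect_equal(cmpAA$delta_chi2, 0)
  expect_equal(cmpAA$delta_df, 0)
  # two correlated WBCF-like facets: 1-factor model fits worse than 2-factor
  tf <- two_factor_truth(phi = 0.7)
  set.seed(51)
  x <- matrix(rnorm(1500 * 6), 1500, 6) %*% chol(tf$Sigma)
  colnames(x) <- rownames(tf$Sigma)
  cv <- sample_covariance(x)
  f2 <- fit_ml(cv, tf$spec)
  f1 <- fit_ml(cv, cfa_spec(list(g = colnames(x))))
  base <- baseline_fit(cv)
  i2 <- fit_indices(f2, base); i1 <- fit_indices(f1, base)
  cmp <- compare_models(i1, i2, c("one-factor", "two-factor"))
  expect_gt(i1$rmsea, i2$rmsea)
  expect_gt(cmp$delta_chi2, 0)
  expect_equal(cmp$delta_df, 1)
  expect_error(compare_models(i1, i2, c("a", "b")), NA)
})

test_that("instrument fit table covers all four measures", {
  cc <- default_sim()
  dat <- validate_responses(cc$sim$responses, cc$pop$registry)
  ft <- fit_instrument_cfas(dat, cc$pop$registry)
  expect_equal(nrow(ft), 4L)
  expect_setequal(ft$instrument, c("MHC-SF", "PERMA", "FS", "WBCF"))
  expect_true(all(ft$converged))
  expect_equal(ft$df[ft$instrument == "MHC-SF"], 74L)
  expect_equal(ft$df[ft$instrument == "FS"], 20L)
  expect_equal(ft$df[ft$instrument == "PERMA"], 80L)
  expect_equal(ft$df[ft$instrument == "WBCF"], 34L)
  expect_true(all(ft$rmsea >= 0 & ft$srmr >= 0 & ft$cfi <= 1))
  expect_true(all(ft$chi2_scaled > 0))
})

test_that("Heywood cases are clamped and flagged", {
  # closed-form loading for item 1 is sqrt(0.8 * 0.7 / 0.3) > 1, so an
  # exact single-factor fit needs a negative uniqueness; the engine clamps
  # at the variance floor and flags it instead
  S <- matrix(c(1, 0.8, 0.7, 0.8, 1, 0.3, 0.7, 0.3, 1), 3,
              dimnames = rep(list(paste0("v", 1:3)), 2))
  expect_warning(
    fit <- fit_ml(S, cfa_spec(list(g = paste0("v", 1:3))), n = 200),
    "Heywood")
  expect_equal(fit$heywood, "v1")
})
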