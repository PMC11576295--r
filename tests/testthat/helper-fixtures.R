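# Shared fixtures, built in code.

# Small two-instrument registry: FS with 3 items (1-7), WBCF-PC with two
# items on a 0-4 scale, one reverse-keyed.
toy_registry <- function() {
  reg <- data.frame(
    item_id = c("FS-1", "FS-2", "FS-3", "WBCF-PC-1", "WBCF-PC-2"),
    instrument = c("FS", "FS", "FS", "WBCF", "WBCF"),
    facet = c("FS", "FS", "FS", "PC", "PC"),
    index = c(1L, 2L, 3L, 1L, 2L),
    min_code = c(1L, 1L, 1L, 0L, 0L),
    max_code = c(7L, 7L, 7L, 4L, 4L),
    reverse = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  class(reg) <- c("ipv_registry", "data.frame")
  reg
}

# Columns with exact sample moments: unit variance, mean zero, pairwise
# sample correlation exactly `r` (via empirical Gram-Schmidt), so
# closed-form oracles apply exactly.
exact_corr_pair <- function(n = 40, r = 0.5, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n); x <- (x - mean(x)) / stats::sd(x)
  e <- stats::rnorm(n)
  e <- stats::residuals(stats::lm(e ~ x))
  e <- e / stats::sd(e)
  y <- r * x + sqrt(1 - r^2) * e
  cbind(x = x, y = y / stats::sd(y))
}

# Population Sigma for a known two-factor model (3 + 3 items).
two_factor_truth <- function(phi = 0.6) {
  lam <- c(0.8, 0.7, 0.6, 0.75, 0.65, 0.55)
  L <- matrix(0, 6, 2, dimnames = list(paste0("it", 1:6), c("f1", "f2")))
  L[1:3, 1] <- lam[1:3]; L[4:6, 2] <- lam[4:6]
  Phi <- matrix(c(1, phi, phi, 1), 2)
  Sig <- L %*% Phi %*% t(L)
  diag(Sig) <- 1
  list(Sigma = Sig, lambda = lam, Phi = Phi,
       spec = cfa_spec(list(f1 = paste0("it", 1:3), f2 = paste0("it", 4:6))))
}

# Likert data simulated from the default flourishing population, cached per
# session so several test files can share one draw.
default_sim <- local({
  cache <- NULL
  function(n = 698, seed = 20260101) {
    key <- paste(n, seed)
    if (is.null(cache) || cache$key != key) {
      pop <- default_flourishing_population()
      sim <- simulate_responses(pop, n = n, seed = seed)
      cache <<- list(key = key, pop = pop, sim = sim)
    }
    cache
  }
})
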