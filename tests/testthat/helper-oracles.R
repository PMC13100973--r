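# Independent oracles and small fixtures used across the suite. The oracles
# are deliberately naive (explicit normal equations, plain loops) so they
# share no code with the implementation they check.

# OLS via explicit normal equations; returns coefficients and t statistics.
ols_oracle <- function(y, X) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(s2 * diag(xtx_inv))
  list(beta = beta, t = beta / se, df = nrow(X) - ncol(X))
}

# Naive per-draw subsampling loop mirroring the documented seed derivation
# and sampling order, with lm() fits unit by unit.
subsample_oracle <- function(Y, frailty, scanner, config) {
  n <- nrow(Y)
  m <- floor(config$fraction * n)
  out <- matrix(NA_real_, config$n_draws, ncol(Y),
                dimnames = list(NULL, colnames(Y)))
  for (d in seq_len(config$n_draws)) {
    set.seed(fraildex:::derive_seed(config$seed, d))
    idx <- sample.int(n, m)
    for (u in seq_len(ncol(Y))) {
      dat <- data.frame(y = Y[idx, u], frailty = frailty[idx],
                        scanner = droplevels(factor(scanner[idx])))
      fit <- if (nlevels(dat$scanner) > 1) {
        dat$scanner <- stats::relevel(dat$scanner,
                                      ref = names(which.max(table(dat$scanner))))
        lm(y ~ frailty + scanner, data = dat)
      } else lm(y ~ frailty, data = dat)
      out[d, u] <- summary(fit)$coefficients["frailty", "t value"]
    }
  }
  out
}

# Two-group cohort at the published CU/AD design scaled down for unit tests.
small_cohort_config <- function(n = c(150, 100), n_regions = 6L, seed = 11L,
                                ...) {
  cohort_config(
    group_specs = data.frame(group = c("CU", "AD"), n = n,
                             mean = c(0.14, 0.24), sd = c(0.065, 0.075)),
    n_regions = n_regions, seed = seed, ...)
}

# Deficit table with known structure for screening tests.
screening_fixture <- function(n = 400, seed = 2L) {
  set.seed(seed)
  base <- function(p) rbinom(n, 1, p)
  tab <- data.frame(
    ok_a = base(0.3), ok_b = base(0.2), ok_c = base(0.4),
    rare = c(rep(1L, 2), rep(0L, n - 2)),        # 0.5% prevalence
    common = rbinom(n, 1, 0.9),                  # ~90% prevalence
    holey = base(0.3))
  tab$holey[seq_len(ceiling(0.2 * n))] <- NA     # 20% missing
  tab$twin <- tab$ok_a                           # r = 1 with ok_a
  tab
}
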