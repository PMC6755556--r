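# Shared helpers: an independent normal-equations OLS oracle and small
# constructors used across test files.

# Brute-force OLS via the normal equations; deliberately independent of
# fit_affinity_model / lm.
ols_oracle <- function(X, y) {
  Xm <- cbind(`(Intercept)` = 1, X)
  XtX <- crossprod(Xm)
  beta <- solve(XtX, crossprod(Xm, y))
  res <- y - Xm %*% beta
  n <- nrow(Xm); k <- ncol(Xm)
  s2 <- sum(res^2) / (n - k)
  list(beta = drop(beta),
       se = sqrt(diag(solve(XtX)) * s2),
       rmse = sqrt(s2),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

rec_kd <- function(id, n_nh, kd_molar, ...) {
  compound_record(id, n_nh, affinity = kd_molar, affinity_unit = "M",
                  affinity_kind = "KD", ...)
}

ctx298 <- thermo_context(298)
RT298LN10 <- 1.987204e-3 * 298 * log(10)
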