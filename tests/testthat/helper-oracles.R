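# Independent closed-form oracles for the regression-based estimators.
# These deliberately go through stats::lm (QR decomposition on the weighted
# design) rather than the package's own normal-equation code paths.

ivw_oracle <- function(h) {
  fit <- stats::lm(beta_out ~ 0 + beta_exp, data = h, weights = 1 / h$se_out^2)
  s <- summary(fit)
  list(b = unname(coef(fit)[1]), se = unname(s$coefficients[1, 2]))
}

egger_oracle <- function(h) {
  flip <- ifelse(h$beta_exp < 0, -1, 1)
  d <- data.frame(g = h$beta_exp * flip, G = h$beta_out * flip)
  fit <- stats::lm(G ~ g, data = d, weights = 1 / h$se_out^2)
  s <- summary(fit)
  list(
    intercept = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
    intercept_se = unname(s$coefficients[1, 2]),
    se = unname(s$coefficients[2, 2])
  )
}

mvmr_oracle <- function(X, y, w) {
  fit <- stats::lm(y ~ 0 + X, weights = w)
  s <- summary(fit)
  list(
    b = unname(coef(fit)),
    se = unname(s$coefficients[, 2])
  )
}

# step-up Benjamini-Hochberg by direct enumeration of the i*alpha/m bounds
bh_keep_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) * alpha / m)
  keep <- logical(m)
  if (length(below)) keep[o[seq_len(max(below))]] <- TRUE
  keep
}
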