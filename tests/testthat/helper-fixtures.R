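# Shared fixtures: the default synthetic probe/root and the control-group
# transport parameters used throughout the tests.

default_probe <- function() probe_system(beta = 1.09e10, Ar = 1.57e-4)
default_geometry <- function() root_geometry()  # 0.1 m x 0.5 mm, 1.5 % xylem

control_params <- function() transport_params(Lpr = 8.11e-8, Psr = 2.24e-9,
                                              sigma = 0.38)

control_delta_pi <- function() vant_hoff_osmotic_pressure(60, 23)

# brute-force pairwise pooled-MSE t-test oracle, independent of
# anova_fisher_lsd's internals
oracle_pairwise_p <- function(values, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  k <- length(lev)
  ns <- tapply(values, groups, length)
  ms <- tapply(values, groups, mean)
  ss <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df <- length(values) - k
  mse <- ss / df
  p <- matrix(1, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    tt <- (ms[i] - ms[j]) / sqrt(mse * (1 / ns[i] + 1 / ns[j]))
    p[i, j] <- p[j, i] <- 2 * pt(-abs(tt), df)
  }
  p
}
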