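# Shared fixtures and independent oracles for the test suite.

default_params <- leaf_params()
default_arch <- canopy_arch()
default_schedule <- crop_schedule()

# one small shared synthetic archive; built once when the helpers load
fix_arch2 <- generate_archive(2, seed = 42)
fix_year1 <- fix_arch2[fix_arch2$year == 2001, ]

# Independent coupled-leaf oracle: bisection on ci of the supply/demand
# residual, using only the prescribed-ci leaf model and base uniroot.
oracle_solve_leaf <- function(env, params) {
  resid <- function(ci) {
    fl <- assimilation_at_ci(ci, env, params)
    gs <- max(params$bb_slope * fl$an * env$rh / env$ca + params$bb_intercept,
              params$bb_intercept)
    ci - (env$ca - 1.6 * fl$an / gs)
  }
  hi <- env$ca + 1.6 * temperature_adjust(params, env$t_leaf)$rd /
    params$bb_intercept + 10
  ci <- uniroot(resid, c(0.1, hi), tol = 1e-10)$root
  fl <- assimilation_at_ci(ci, env, params)
  gs <- max(params$bb_slope * fl$an * env$rh / env$ca + params$bb_intercept,
            params$bb_intercept)
  list(ci = ci, an = fl$an, gs = gs)
}

# Independent PRCC oracle: precision matrix of the rank-transformed
# (drivers, response) correlation matrix; partial correlation of driver
# j with y given the rest is -P[j, y] / sqrt(P[j, j] * P[y, y]).
oracle_prcc <- function(drivers, response) {
  r <- cbind(apply(as.matrix(drivers), 2, rank), y = rank(response))
  p <- solve(cor(r))
  k <- ncol(r) - 1
  vapply(seq_len(k), function(j) {
    -p[j, k + 1] / sqrt(p[j, j] * p[k + 1, k + 1])
  }, numeric(1))
}

# Arrhenius reference, written out independently of the package helper
oracle_arrhenius <- function(x25, ea, t_c) {
  tk <- t_c + 273.15
  x25 * exp(ea * (tk - 298.15) / (298.15 * 8.314 * tk))
}
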