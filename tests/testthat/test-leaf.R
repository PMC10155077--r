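test_that("temperature adjustment is the identity at 25 C and Arrhenius elsewhere", {
  p <- default_params
  at25 <- temperature_adjust(p, 25)
  expect_equal(at25$vcmax, p$vcmax25)
  expect_equal(at25$jmax, p$jmax25)
  expect_equal(at25$kc, p$kc25)
  expect_equal(at25$gamma_star, p$gamma_star25)

  expect_gt(temperature_adjust(p, 35)$kc, p$kc25)
  expect_lt(temperature_adjust(p, 15)$kc, p$kc25)

  at15 <- temperature_adjust(p, 15)
  expect_equal(at15$vcmax, oracle_arrhenius(110, p$ea_vcmax, 15),
               tolerance = 1e-12)
  expect_equal(at15$gamma_star, oracle_arrhenius(42.75, p$ea_gamma_star, 15),
               tolerance = 1e-12)

  expect_error(temperature_adjust(p, 55), "range")
  expect_error(temperature_adjust(p, -20), "range")
})

test_that("electron transport follows the non-rectangular hyperbola", {
  p <- default_params
  alpha <- p$leaf_absorb * (1 - p$f_spectral) / 2
  expect_equal(electron_transport(0, 195, p$theta, alpha), 0)
  expect_equal(electron_transport(1e7, 195, p$theta, alpha), 195,
               tolerance = 1e-3)
  # smaller quadratic root, cross-checked with a generic root finder
  q <- 1500
  i2 <- q * alpha
  roots <- Re(polyroot(c(i2 * 195, -(i2 + 195), p$theta)))
  expect_equal(electron_transport(q, 195, p$theta, alpha), min(roots),
               tolerance = 1e-9)
  # monotone in q and jmax
  qs <- seq(0, 2000, 100)
  expect_true(all(diff(electron_transport(qs, 195, p$theta, alpha)) >= 0))
  expect_true(all(electron_transport(qs, 234, p$theta, alpha) >=
                    electron_transport(qs, 195, p$theta, alpha)))
  expect_error(electron_transport(1000, 195, theta = 1.2), "theta")
})

test_that("the three candidate rates behave at their limits", {
  p <- default_params
  g <- p$gamma_star25
  km_args <- list(vcmax = 110, kc = p$kc25, ko = p$ko25, o2 = p$o2,
                  gamma_star = g)
  expect_equal(do.call(rubisco_limited, c(list(ci = g), km_args)), 0)
  expect_equal(do.call(rubisco_limited, c(list(ci = 1e9), km_args)), 110,
               tolerance = 1e-5)
  # direct formula evaluation
  expect_equal(rubisco_limited(280, 110, p$kc25, p$ko25, p$o2, g),
               110 * (280 - g) / (280 + p$kc25 * (1 + p$o2 / p$ko25)))
  expect_equal(rubp_limited(g, 171, g), 0)
  expect_equal(rubp_limited(1e9, 171, g), 171 / 4, tolerance = 1e-5)
  expect_equal(rubp_limited(400, 171, 42.75),
               171 * (400 - 42.75) / (4 * 400 + 8 * 42.75))
  expect_equal(tpu_limited(23), 69)
})

test_that("TPU only binds above a high ci threshold found by brute force", {
  p <- default_params
  env <- leaf_env(1500, 25, 0.7, 1500)
  ci <- seq(50, 1500, 10)
  fl <- assimilation_at_ci(ci, env, p)
  # default parameters: TPU never limits below ci = 1000 at q <= 2000
  expect_false(any(fl$limiting[ci <= 1000] == "tpu"))
  # brute-force argmin agrees with the labels everywhere
  brute <- apply(cbind(fl$ac, fl$aj, fl$ap), 1, which.min)
  expect_equal(fl$limiting, c("rubisco", "rubp", "tpu")[brute])
})

test_that("assimilation accounting identity holds for random states", {
  p <- default_params
  set.seed(7)
  for (i in 1:50) {
    ci <- runif(1, 60, 1400)
    env <- leaf_env(runif(1, 0, 2000), runif(1, 5, 40), runif(1, 0.2, 1),
                    1000)
    fl <- assimilation_at_ci(ci, env, p)
    expect_equal(fl$vc - fl$rp - fl$rd, fl$an, tolerance = 1e-9)
  }
  # dark: An = -Rd, RuBP-limited (J = 0 makes Aj the argmin)
  dark <- assimilation_at_ci(280, leaf_env(0, 25, 0.7, 400), p)
  expect_equal(dark$an, -dark$rd)
  expect_identical(dark$limiting, "rubp")
})

test_that("coupled solver satisfies both balance equations and matches bisection", {
  p <- default_params
  env <- leaf_env(1500, 25, 0.7, 400)
  fl <- solve_coupled(env, p)
  # both balance residuals below the contract tolerance
  gs_demand <- p$bb_slope * fl$an * env$rh / env$ca + p$bb_intercept
  expect_equal(fl$gs, gs_demand, tolerance = 1e-6)
  expect_equal(fl$ci, env$ca - 1.6 * fl$an / fl$gs, tolerance = 1e-6)
  # dark closure
  dark <- solve_coupled(leaf_env(0, 25, 0.7, 400), p)
  expect_equal(dark$an, -dark$rd)
  expect_equal(dark$gs, p$bb_intercept)
  expect_true(dark$gs_clamped)
  # oracle equivalence on random environments
  set.seed(11)
  for (i in 1:40) {
    env <- leaf_env(runif(1, 0, 2000), runif(1, 5, 40),
                    runif(1, 0.2, 0.95), runif(1, 250, 1100))
    got <- solve_coupled(env, p)
    want <- oracle_solve_leaf(env, p)
    expect_equal(got$ci, want$ci, tolerance = 1e-4)
    expect_equal(got$an, want$an, tolerance = 1e-4)
  }
})

test_that("An is monotone in ci, light and capacities", {
  p <- default_params
  set.seed(3)
  ci <- sort(runif(30, 60, 1200))
  env <- leaf_env(1200, 25, 0.7, 1200)
  expect_true(all(diff(assimilation_at_ci(ci, env, p)$an) >= -1e-12))
  for (q in c(200, 800, 1600)) {
    a1 <- assimilation_at_ci(500, leaf_env(q, 25, 0.7, 500), p)$an
    a2 <- assimilation_at_ci(500, leaf_env(q + 100, 25, 0.7, 500), p)$an
    expect_gte(a2, a1)
  }
  for (s in c(1.1, 1.3)) {
    up_v <- scale_params(p, s, 1)
    up_j <- scale_params(p, 1, s)
    # gross limited rate can only go up with either capacity
    base <- assimilation_at_ci(300, env, p)
    expect_gte(assimilation_at_ci(300, env, up_j)$an + 1e-12, base$an)
    expect_gte(assimilation_at_ci(300, env, up_v)$an + up_v$rd25 - p$rd25,
               base$an)
  }
})

test_that("transition ci separates the limitation regimes", {
  p <- default_params
  tr <- find_transition_ci(1500, 25, p)
  expect_identical(tr$regime, "crossing")
  adj <- temperature_adjust(p, 25)
  # equality of the two branches at the root
  j <- electron_transport(1500, adj$jmax, adj$theta, adj$alpha)
  ac <- rubisco_limited(tr$ci_star, adj$vcmax, adj$kc, adj$ko, adj$o2,
                        adj$gamma_star)
  aj <- rubp_limited(tr$ci_star, j, adj$gamma_star)
  expect_lt(abs(ac - aj), 1e-6 * adj$vcmax)
  env <- leaf_env(1500, 25, 0.7, 2000)
  expect_identical(assimilation_at_ci(tr$ci_star - 20, env, p)$limiting,
                   "rubisco")
  expect_identical(assimilation_at_ci(tr$ci_star + 20, env, p)$limiting,
                   "rubp")
  # low light: RuBP regeneration limits everywhere
  low <- find_transition_ci(100, 25, p)
  expect_identical(low$regime, "always_rubp")
  expect_true(is.na(low$ci_star))
})

test_that("A-Ci curves are monotone and switch limitation exactly once", {
  p <- default_params
  grid <- seq(100, 1000, 50)
  curve <- aci_curve(1500, 25, p, grid)
  expect_equal(nrow(curve), length(grid))
  expect_true(all(diff(curve$an) >= -1e-12))
  switches <- sum(diff(match(curve$limiting, c("rubisco", "rubp", "tpu"))) != 0)
  expect_identical(switches, 1L)
  ci_star <- find_transition_ci(1500, 25, p)$ci_star
  expect_identical(curve$limiting, ifelse(grid < ci_star, "rubisco", "rubp"))
  # scaling jmax alone leaves the curve unchanged where Rubisco binds
  curve_j <- aci_curve(1500, 25, scale_params(p, 1, 1.2), grid)
  rub <- curve$limiting == "rubisco" & curve_j$limiting == "rubisco"
  expect_equal(curve_j$an[rub], curve$an[rub])
  expect_error(aci_curve(1500, 25, p, numeric(0)), "empty")
})

test_that("percent An gain is zero at identity scaling and errors on negative control", {
  p <- default_params
  expect_equal(percent_gain_an(1500, 25, p, 400, 600, 1, 1), 0)
  expect_error(percent_gain_an(0, 25, p, 400, 600, 1.2, 1.2), "undefined")
})

test_that("photorespiration gain ratio equals its closed form in a single regime", {
  p <- default_params
  for (ci in c(300, 400, 500, 600, 800)) {
    got <- photoresp_gain_ratio(ci, 1500, 25, p, 1.2, 1.2)
    expect_equal(got, 100 * p$gamma_star25 / ci, tolerance = 1e-6)
  }
  expect_error(photoresp_gain_ratio(40, 1500, 25, p), "compensation")
})
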