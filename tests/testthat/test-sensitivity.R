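test_that("relative change implements the |control| convention", {
  expect_equal(relative_change(6.6, 6.6), 0)
  expect_equal(relative_change(7.0, 6.6), 100 * 0.4 / 6.6)
  expect_equal(relative_change(-2, -4), 50)
  expect_true(is.na(relative_change(1, 0)))
})

test_that("the scaling grid must contain the control", {
  g <- scaling_grid(-50, 50, 5)
  expect_equal(length(g$scales), 21)
  expect_true(any(g$scales == 1))
  expect_error(scaling_grid(-50, -5, 5), "control")
})

test_that("surface interpolation reproduces nodes, planes and quadratics", {
  xs <- seq(0.5, 1.5, 0.05)  # the 21-point axis of the full design
  quad <- outer(xs, xs, function(a, b) 3 * a^2 + b^2 - a * b)
  f <- interpolate_surface(quad, x = xs, y = xs)
  # grid nodes exact
  for (idx in list(c(1, 1), c(7, 15), c(21, 21))) {
    expect_equal(f(xs[idx[1]], xs[idx[2]]), quad[idx[1], idx[2]],
                 tolerance = 1e-12)
  }
  # midpoint error below 1% of the surface range
  rng <- diff(range(quad))
  mids <- expand.grid(x = xs[-1] - 0.025, y = xs[-1] - 0.025)
  errs <- vapply(seq_len(nrow(mids)), function(i) {
    truth <- 3 * mids$x[i]^2 + mids$y[i]^2 - mids$x[i] * mids$y[i]
    abs(f(mids$x[i], mids$y[i]) - truth)
  }, numeric(1))
  expect_lt(max(errs) / rng, 0.01)
  # planar data reproduce exactly anywhere
  plane <- interpolate_surface(outer(xs, xs, function(a, b) 2 * a - 7 * b),
                               x = xs, y = xs)
  expect_equal(plane(0.77, 1.23), 2 * 0.77 - 7 * 1.23, tolerance = 1e-10)
  expect_error(f(2, 1), "hull")
  # long-format input round-trips through the same interpolant
  df <- expand.grid(scale_v = xs[1:5], scale_j = xs[1:5])
  df$relchange <- 2 * df$scale_v - 7 * df$scale_j
  f2 <- interpolate_surface(df)
  expect_equal(f2(0.55, 0.65), 2 * 0.55 - 7 * 0.65, tolerance = 1e-10)
})

test_that("central differences are exact on lines and O(h^2) on quadratics", {
  lin <- function(x, y) x
  expect_equal(gradient(lin, 0.3, 0.9), c(1, 0), tolerance = 1e-12)
  quad <- function(x, y) x^2 + y^2
  expect_equal(gradient(quad, 1, 1, h = 0.01), c(2, 2), tolerance = 1e-10)
  # on an interpolated quadratic surface the analytic gradient survives
  xs <- seq(-1, 1, 0.1)
  f <- interpolate_surface(outer(xs, xs, function(a, b) a^2 + b^2),
                           x = xs, y = xs)
  expect_equal(gradient(f, 0.35, -0.15, h = 0.01), c(0.7, -0.3),
               tolerance = 1e-3)
})

test_that("steepest paths climb bowls and follow planes", {
  xs <- seq(-1, 1, 0.1)
  bowl <- interpolate_surface(outer(xs, xs, function(a, b) -(a^2 + b^2)),
                              x = xs, y = xs)
  path <- steepest_path(bowl, c(0.6, 0.6), alpha = 0.05,
                        direction = "ascend", stop_tol = 1e-3)
  end <- path$points[nrow(path$points), ]
  expect_identical(path$termination, "gradient_below_tol")
  expect_lt(sqrt(end$x^2 + end$y^2), 0.01)
  # consecutive step lengths equal alpha * |grad| along the way
  mid <- path$points[5, ]
  g <- gradient(bowl, mid$x, mid$y)
  step_len <- sqrt((path$points$x[6] - mid$x)^2 +
                     (path$points$y[6] - mid$y)^2)
  expect_equal(step_len, 0.05 * sqrt(sum(g^2)), tolerance = 1e-6)

  plane <- interpolate_surface(outer(xs, xs, function(a, b) a + 2 * b),
                               x = xs, y = xs)
  pp <- steepest_path(plane, c(-0.5, -0.5), alpha = 0.02,
                      direction = "ascend")
  expect_identical(pp$termination, "hull_exit")
  # straight line along the constant gradient (1, 2)
  d <- cbind(pp$points$x - pp$points$x[1], pp$points$y - pp$points$y[1])
  expect_equal(d[-1, 2] / d[-1, 1], rep(2, nrow(d) - 1), tolerance = 1e-9)

  expect_error(steepest_path(plane, c(5, 5)), "outside")
})

test_that("PRCC matches rank invariance, nulls, and planted signs", {
  set.seed(21)
  # a monotone transform of a single driver has PRCC 1
  x1 <- matrix(runif(200), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(prcc(x1, exp(3 * x1[, 1]))$coefficient, 1, tolerance = 1e-12)

  # independence: coefficients near zero for most drivers
  xn <- matrix(rnorm(1000 * 4), 1000, 4,
               dimnames = list(NULL, paste0("v", 1:4)))
  pn <- prcc(xn, rnorm(1000))
  expect_true(all(abs(pn$coefficient) < 0.1))

  # planted effects recover their signs with significance
  x <- matrix(rnorm(400 * 5), 400, 5, dimnames = list(NULL, letters[1:5]))
  y <- 2 * rank(x[, 1]) - rank(x[, 2]) + rnorm(400, 0, 50)
  pr <- prcc(x, y)
  expect_gt(pr$coefficient[1], 0.5)
  expect_lt(pr$coefficient[2], -0.3)
  expect_lt(pr$p_value[1], 1e-6)

  # collinear drivers are named
  xc <- cbind(x[, 1:2], dup = x[, 1])
  expect_error(prcc(xc, y), "dup")
})

test_that("PRCC equals the precision-matrix formulation on random instances", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(30:80, 1)
    k <- sample(2:5, 1)
    x <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("d", 1:k)))
    y <- rnorm(n) + x %*% rnorm(k)
    expect_equal(prcc(x, y)$coefficient, oracle_prcc(x, y),
                 tolerance = 1e-10)
  }
})

test_that("a control-only grid has an identically zero relative surface", {
  g <- scaling_grid(0, 0, 5, co2_levels = 400)
  surf <- run_grid(fix_year1, g)
  expect_true(all(surf$relchange == 0))
  expect_equal(sort(unique(surf$variable)),
               sort(c("pod", "shoot", "max_lai", "mean_daily_max_an",
                      "mean_daily_mean_an", "mean_wue")))
})

test_that("limiting-rate audits need traces and partition daylight hours", {
  res <- simulate_season(fix_year1, co2 = 400)
  expect_error(limiting_frequency(res), "keep_traces")
  res_tr <- simulate_season(fix_year1, co2 = 400, keep_traces = TRUE)
  lf <- limiting_frequency(res_tr)
  expect_equal(sum(lf$counts), nrow(res_tr$trace))
  expect_equal(sum(lf$ci_hist$count), nrow(res_tr$trace))
  # degenerate histogram: a single repeated hour fills one bin
  fake <- res_tr
  fake$trace <- fake$trace[rep(1, 25), ]
  lf1 <- limiting_frequency(fake)
  expect_equal(sum(lf1$ci_hist$count > 0), 1L)
})

test_that("small bootstrap ensembles split quartiles and reproduce", {
  ens <- run_bootstrap_ensemble(fix_arch2, n = 4, master_seed = 5)
  expect_equal(sum(ens$replicates$set == "set-25"), 1L)
  expect_equal(sum(ens$replicates$set == "set-75"), 1L)
  ens2 <- run_bootstrap_ensemble(fix_arch2, n = 4, master_seed = 5)
  expect_identical(ens$replicates, ens2$replicates)
  expect_error(run_bootstrap_ensemble(fix_arch2, n = 3, master_seed = 1),
               "quartile")
  one_year <- fix_arch2[fix_arch2$year == 2001, ]
  expect_error(run_bootstrap_ensemble(one_year, n = 4, master_seed = 1),
               "2 years")
})
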