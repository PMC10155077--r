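#' Leaf environment
#'
#' Bundles the environmental drivers of a single steady-state leaf
#' gas-exchange solve.
#'
#' @param q Incident photosynthetic photon flux density, umol m-2 s-1.
#' @param t_leaf Leaf temperature, degC (air temperature is used as leaf
#'   temperature throughout the package).
#' @param rh Relative humidity at the leaf surface, fraction in \[0, 1\].
#' @param ca Ambient CO2 mole fraction at the leaf surface, umol mol-1.
#' @return An object of class `leaf_env`.
#' @examples
#' leaf_env(q = 1500, t_leaf = 25, rh = 0.7, ca = 400)
#' @export
leaf_env <- function(q, t_leaf, rh, ca) {
  stopifnot(is.numeric(q), is.numeric(t_leaf), is.numeric(rh), is.numeric(ca))
  if (any(q < 0)) stop("`q` must be >= 0", call. = FALSE)
  if (any(rh < 0 | rh > 1)) stop("`rh` must lie in [0, 1]", call. = FALSE)
  if (any(ca <= 0)) stop("`ca` must be > 0", call. = FALSE)
  structure(list(q = q, t_leaf = t_leaf, rh = rh, ca = ca),
            class = "leaf_env")
}

#' Electron transport rate
#'
#' Non-rectangular hyperbola light response: `J` is the smaller root of
#' `theta * J^2 - (I2 + jmax) * J + I2 * jmax = 0` with
#' `I2 = q * alpha`, the photon flux delivered to photosystem II.
#'
#' @param q Incident PPFD, umol m-2 s-1 (vectorized).
#' @param jmax Maximum electron transport rate at the current
#'   temperature, umol m-2 s-1.
#' @param theta Curvature, strictly in (0, 1).
#' @param alpha Effective fraction of incident light delivered to PSII.
#' @return Electron transport rate J, umol m-2 s-1, in `[0, jmax]`.
#' @examples
#' electron_transport(1500, 195)
#' electron_transport(0, 195)  # 0
#' @export
electron_transport <- function(q, jmax, theta = 0.7,
                               alpha = 0.85 * (1 - 0.15) / 2) {
  if (any(theta <= 0) || any(theta >= 1)) {
    stop("`theta` must lie strictly between 0 and 1", call. = FALSE)
  }
  stopifnot(all(q >= 0), all(jmax > 0))
  i2 <- q * alpha
  b <- i2 + jmax
  disc <- pmax(b^2 - 4 * theta * i2 * jmax, 0)
  (b - sqrt(disc)) / (2 * theta)
}

#' Rubisco-limited carboxylation rate
#'
#' `Ac = vcmax * (ci - gamma_star) / (ci + kc * (1 + o2 / ko))`.
#'
#' @param ci Intercellular CO2, umol mol-1 (vectorized).
#' @param vcmax Maximum carboxylation rate, umol m-2 s-1.
#' @param kc,ko Michaelis constants for CO2 (umol mol-1) and O2
#'   (mmol mol-1).
#' @param o2 Ambient oxygen, mmol mol-1.
#' @param gamma_star CO2 compensation point without dark respiration,
#'   umol mol-1.
#' @return Ac, umol m-2 s-1.
#' @export
rubisco_limited <- function(ci, vcmax, kc, ko, o2, gamma_star) {
  stopifnot(all(ci > 0))
  vcmax * (ci - gamma_star) / (ci + kc * (1 + o2 / ko))
}

#' RuBP-regeneration-limited rate
#'
#' `Aj = J * (ci - gamma_star) / (4 * ci + 8 * gamma_star)`.
#'
#' @param ci Intercellular CO2, umol mol-1 (vectorized).
#' @param j Electron transport rate, umol m-2 s-1.
#' @param gamma_star CO2 compensation point, umol mol-1.
#' @return Aj, umol m-2 s-1.
#' @export
rubp_limited <- function(ci, j, gamma_star) {
  stopifnot(all(ci > 0), all(j >= 0))
  j * (ci - gamma_star) / (4 * ci + 8 * gamma_star)
}

#' Triose-phosphate-utilization-limited rate
#'
#' `Ap = 3 * tpu`, constant in both `ci` and light. The default TPU
#' capacity is high enough that this rate rarely binds at current or
#' near-future CO2.
#'
#' @param tpu TPU capacity at the current temperature, umol m-2 s-1.
#' @return Ap, umol m-2 s-1.
#' @export
tpu_limited <- function(tpu) {
  stopifnot(all(tpu > 0))
  3 * tpu
}

# Vectorized FvCB rates at prescribed ci. `adj` is a temperature_adjust()
# output whose elements are scalars or vectors conformable with ci/q.
leaf_rates_at_ci <- function(ci, q, adj) {
  j <- electron_transport(q, adj$jmax, adj$theta, adj$alpha)
  ac <- rubisco_limited(ci, adj$vcmax, adj$kc, adj$ko, adj$o2, adj$gamma_star)
  aj <- rubp_limited(ci, j, adj$gamma_star)
  ap <- tpu_limited(adj$tpu) + 0 * ci
  a_min <- pmin(ac, aj, ap)
  an <- a_min - adj$rd
  # tie-break order: rubisco < rubp < tpu
  limiting <- ifelse(ac <= aj & ac <= ap, "rubisco",
                     ifelse(aj <= ap, "rubp", "tpu"))
  gross <- an + adj$rd
  vc <- ifelse(ci > adj$gamma_star,
               gross / (1 - adj$gamma_star / ci),
               pmax(gross, 0))
  rp <- ifelse(ci > adj$gamma_star, vc * adj$gamma_star / ci, 0)
  list(an = an, ac = ac, aj = aj, ap = ap, rd = adj$rd + 0 * ci,
       vc = vc, rp = rp, j = j, limiting = limiting)
}

leaf_flux_tibble <- function(ci, rates, gs = NA_real_) {
  tibble::tibble(
    ci = ci, an = rates$an, ac = rates$ac, aj = rates$aj, ap = rates$ap,
    rd = rates$rd, vc = rates$vc, rp = rates$rp, gs = gs,
    limiting = rates$limiting
  )
}

#' Assimilation at prescribed intercellular CO2
#'
#' Evaluates the FvCB model at a fixed `ci`: the net rate is
#' `An = min(Ac, Aj, Ap) - Rd` with the limiting process labelled by the
#' argmin (tie-break order rubisco < rubp < tpu). Gross carboxylation
#' and photorespiratory release are recovered from the identity
#' `Vc = (An + Rd) / (1 - gamma_star / ci)`, `Rp = Vc * gamma_star / ci`,
#' so that `Vc - Rp - Rd = An` whenever `ci > gamma_star`; below the
#' compensation point `Rp` is reported as 0 and `Vc` as
#' `max(An + Rd, 0)`.
#'
#' @param ci Intercellular CO2, umol mol-1 (vectorized); must be > 0.
#' @param env A [leaf_env()] (its `ca` is ignored at prescribed ci).
#' @param params A [leaf_params()] object.
#' @return A tibble with one row per `ci`: columns `ci`, `an`, `ac`,
#'   `aj`, `ap`, `rd`, `vc`, `rp`, `gs` (NA at prescribed ci) and
#'   `limiting`.
#' @examples
#' env <- leaf_env(1500, 25, 0.7, 400)
#' assimilation_at_ci(280, env, leaf_params())
#' @export
assimilation_at_ci <- function(ci, env, params) {
  stopifnot(inherits(env, "leaf_env"), inherits(params, "leaf_params"))
  if (any(!is.finite(ci)) || any(ci <= 0)) {
    stop("`ci` must be positive and finite", call. = FALSE)
  }
  adj <- temperature_adjust(params, env$t_leaf)
  rates <- leaf_rates_at_ci(ci, env$q, adj)
  leaf_flux_tibble(ci, rates)
}

# Core coupled solver, vectorized over elements of q/t_leaf/rh/ca.
# Damped fixed point on ci with a bisection fallback; returns plain
# vectors for speed. Relative tolerance `tol` applies to the ci update
# scaled by ca. Quantities that do not depend on ci (electron transport,
# the effective Michaelis constant, the temperature-adjusted capacities)
# are computed once outside the iteration.
solve_coupled_core <- function(q, t_leaf, rh, ca, params,
                               tol = 1e-8, max_iter = 200, capacity = 1) {
  n <- max(length(q), length(t_leaf), length(rh), length(ca))
  q <- rep_len(q, n); t_leaf <- rep_len(t_leaf, n)
  rh <- rep_len(rh, n); ca <- rep_len(ca, n)
  capacity <- rep_len(capacity, n)
  adj <- temperature_adjust(params, t_leaf)
  adj$vcmax <- adj$vcmax * capacity
  adj$jmax <- adj$jmax * capacity
  adj$rd <- adj$rd * capacity
  adj$tpu <- adj$tpu * capacity
  b1 <- adj$bb_slope
  b0 <- adj$bb_intercept
  j <- electron_transport(q, adj$jmax, adj$theta, adj$alpha)
  km <- adj$kc * (1 + adj$o2 / adj$ko)
  gam <- adj$gamma_star
  vcmax <- rep_len(adj$vcmax, n)
  rd <- rep_len(adj$rd, n)
  ap <- rep_len(3 * adj$tpu, n)
  ci_hi <- ca + 1.6 * rd / b0 + 10

  an_at <- function(ci) {
    pmin(vcmax * (ci - gam) / (ci + km),
         j * (ci - gam) / (4 * ci + 8 * gam), ap) - rd
  }
  supply_ci <- function(ci) {
    an <- an_at(ci)
    gs <- pmax(b1 * an * rh / ca + b0, b0)
    pmin(pmax(ca - 1.6 * an / gs, 0.1), ci_hi)
  }

  ci <- 0.7 * ca
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ci_new <- supply_ci(ci)
    delta <- ci_new - ci
    if (all(abs(delta) <= tol * ca)) {
      converged <- TRUE
      ci <- ci_new
      break
    }
    ci <- ci + 0.5 * delta
  }

  if (!converged) {
    unconv <- which(abs(supply_ci(ci) - ci) > tol * ca)
    for (k in unconv) {
      resid <- function(x) {
        an <- pmin(vcmax[k] * (x - gam[k]) / (x + km[k]),
                   j[k] * (x - gam[k]) / (4 * x + 8 * gam[k]), ap[k]) - rd[k]
        gs <- max(b1 * an * rh[k] / ca[k] + b0, b0)
        x - min(max(ca[k] - 1.6 * an / gs, 0.1), ci_hi[k])
      }
      if (resid(0.1) * resid(ci_hi[k]) > 0) {
        stop(sprintf(paste0("leaf solver failed to converge ",
                            "(q=%.1f, t=%.1f, rh=%.2f, ca=%.1f)"),
                     q[k], t_leaf[k], rh[k], ca[k]), call. = FALSE)
      }
      ci[k] <- stats::uniroot(resid, c(0.1, ci_hi[k]),
                              tol = tol * ca[k] / 10)$root
    }
  }

  rates <- leaf_rates_at_ci(ci, q, adj)
  gs_raw <- b1 * rates$an * rh / ca + b0
  gs <- pmax(gs_raw, b0)
  list(ci = ci, gs = gs, an = rates$an, ac = rates$ac,
       aj = rates$aj, ap = rates$ap, rd = rates$rd, vc = rates$vc,
       rp = rates$rp, limiting = rates$limiting, gs_clamped = gs_raw < b0)
}

#' Coupled leaf gas exchange
#'
#' Solves the FvCB demand function simultaneously with the Ball-Berry
#' stomatal conductance model `gs = bb_slope * An * rh / ca +
#' bb_intercept` and the CO2 supply constraint
#' `ci = ca - 1.6 * An / gs`. The solver is a damped fixed point on `ci`
#' (start `0.7 * ca`, cap 200 iterations) with a bisection fallback, and
#' is deterministic. A negative Ball-Berry conductance (dark, An < 0) is
#' clamped to `bb_intercept` and flagged in the `gs_clamped` column.
#'
#' @param env A [leaf_env()] object (may hold vectors).
#' @param params A [leaf_params()] object.
#' @return A one-row-per-element tibble with columns `ci`, `an`, `ac`,
#'   `aj`, `ap`, `rd`, `vc`, `rp`, `gs`, `limiting`, `gs_clamped`.
#' @examples
#' solve_coupled(leaf_env(1500, 25, 0.7, 400), leaf_params())
#' @export
solve_coupled <- function(env, params) {
  stopifnot(inherits(env, "leaf_env"), inherits(params, "leaf_params"))
  s <- solve_coupled_core(env$q, env$t_leaf, env$rh, env$ca, params)
  out <- leaf_flux_tibble(s$ci, s, gs = s$gs)
  out$gs_clamped <- s$gs_clamped
  out
}

#' Transition intercellular CO2 between Rubisco and RuBP limitation
#'
#' Finds the `ci` at which the Rubisco-limited and
#' RuBP-regeneration-limited rates are equal, i.e. the crossover of the
#' A-Ci curve's two branches. Below the transition the leaf is
#' Rubisco-limited, above it RuBP-limited (at light high enough for a
#' crossing to exist).
#'
#' @param q Incident PPFD, umol m-2 s-1.
#' @param t_leaf Leaf temperature, degC.
#' @param params A [leaf_params()] object.
#' @param ci_max Upper search bound, umol mol-1.
#' @return A list with `ci_star` (numeric, NA when no crossing) and
#'   `regime`: `"crossing"`, `"always_rubp"` (Aj below Ac throughout)
#'   or `"always_rubisco"`.
#' @examples
#' find_transition_ci(1500, 25, leaf_params())$ci_star
#' @export
find_transition_ci <- function(q, t_leaf, params, ci_max = 2000) {
  stopifnot(inherits(params, "leaf_params"), q >= 0)
  adj <- temperature_adjust(params, t_leaf)
  gap <- function(ci) {
    rubisco_limited(ci, adj$vcmax, adj$kc, adj$ko, adj$o2, adj$gamma_star) -
      rubp_limited(ci, electron_transport(q, adj$jmax, adj$theta, adj$alpha),
                   adj$gamma_star)
  }
  lo <- adj$gamma_star * 1.001
  g_lo <- gap(lo)
  g_hi <- gap(ci_max)
  if (g_lo > 0 && g_hi > 0) {
    return(list(ci_star = NA_real_, regime = "always_rubp"))
  }
  if (g_lo < 0 && g_hi < 0) {
    return(list(ci_star = NA_real_, regime = "always_rubisco"))
  }
  root <- stats::uniroot(gap, c(lo, ci_max), tol = 1e-10)$root
  list(ci_star = root, regime = "crossing")
}

#' A-Ci curve
#'
#' Evaluates the leaf model over a grid of intercellular CO2 values at
#' fixed light and temperature.
#'
#' @param q Incident PPFD, umol m-2 s-1.
#' @param t_leaf Leaf temperature, degC.
#' @param params A [leaf_params()] object.
#' @param ci_grid Ascending vector of positive `ci` values.
#' @return A tibble as from [assimilation_at_ci()], one row per grid
#'   point.
#' @examples
#' aci_curve(1500, 25, leaf_params(), seq(100, 1000, 50))
#' @export
aci_curve <- function(q, t_leaf, params, ci_grid) {
  if (length(ci_grid) == 0) stop("`ci_grid` is empty", call. = FALSE)
  if (is.unsorted(ci_grid, strictly = FALSE)) {
    stop("`ci_grid` must be sorted ascending", call. = FALSE)
  }
  assimilation_at_ci(ci_grid, leaf_env(q, t_leaf, 0.7, max(ci_grid)), params)
}

#' Mean percent gain in leaf net assimilation under capacity scaling
#'
#' Scales `vcmax25` and `jmax25` (with `rd25` co-scaled by the Vcmax
#' factor), evaluates An over a dense `ci` grid at fixed light, and
#' returns the mean of `100 * (An_scaled - An_control) / An_control`.
#'
#' @param q Incident PPFD, umol m-2 s-1.
#' @param t_leaf Leaf temperature, degC.
#' @param params Control [leaf_params()].
#' @param ci_lo,ci_hi Bounds of the `ci` window, umol mol-1.
#' @param scale_v,scale_j Scaling factors applied to Vcmax25 / Jmax25.
#' @param n Number of grid points.
#' @return Mean percent change of An over the window.
#' @examples
#' percent_gain_an(1500, 25, leaf_params(), 400, 600, 1.2, 1.2)
#' @export
percent_gain_an <- function(q, t_leaf, params, ci_lo, ci_hi,
                            scale_v = 1, scale_j = 1, n = 201) {
  stopifnot(ci_lo < ci_hi, n >= 2)
  grid <- seq(ci_lo, ci_hi, length.out = n)
  env <- leaf_env(q, t_leaf, 0.7, ci_hi)
  an_ctl <- assimilation_at_ci(grid, env, params)$an
  if (any(an_ctl <= 0)) {
    stop("control An <= 0 on the ci grid; percent change undefined",
         call. = FALSE)
  }
  an_scl <- assimilation_at_ci(grid, env,
                               scale_params(params, scale_v, scale_j))$an
  mean(100 * (an_scl - an_ctl) / an_ctl)
}

#' Photorespiration increase relative to carboxylation increase
#'
#' For a capacity-scaling scenario, returns the increase in
#' photorespiratory CO2 release as a percentage of the increase in gross
#' carboxylation, `100 * (Rp_s - Rp_c) / (Vc_s - Vc_c)`, at fixed `ci`.
#' When both scenarios sit in the same limitation regime this equals the
#' closed form `100 * gamma_star / ci`.
#'
#' @param ci Intercellular CO2, umol mol-1; must exceed the compensation
#'   point.
#' @param q Incident PPFD, umol m-2 s-1.
#' @param t_leaf Leaf temperature, degC.
#' @param params Control [leaf_params()].
#' @param scale_v,scale_j Scaling factors.
#' @return Percent, typically ~10 at ci = 400 and ~7 at ci = 600.
#' @examples
#' photoresp_gain_ratio(400, 1500, 25, leaf_params(), 1.2, 1.2)
#' @export
photoresp_gain_ratio <- function(ci, q, t_leaf, params,
                                 scale_v = 1.2, scale_j = 1.2) {
  adj <- temperature_adjust(params, t_leaf)
  if (ci <= adj$gamma_star) {
    stop("`ci` must exceed the CO2 compensation point", call. = FALSE)
  }
  env <- leaf_env(q, t_leaf, 0.7, ci)
  ctl <- assimilation_at_ci(ci, env, params)
  scl <- assimilation_at_ci(ci, env, scale_params(params, scale_v, scale_j))
  dvc <- scl$vc - ctl$vc
  if (dvc == 0) {
    stop("carboxylation unchanged by the scaling; ratio undefined",
         call. = FALSE)
  }
  100 * (scl$rp - ctl$rp) / dvc
}
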