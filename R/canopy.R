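#' Solar zenith angle
#'
#' Standard solar geometry: declination
#' `delta = -23.45 * cos(2*pi*(doy + 10)/365)` and hour angle
#' `H = 15 * (hour - 12)` degrees, with
#' `cos(zenith) = sin(lat) sin(delta) + cos(lat) cos(delta) cos(H)`.
#' Hours are local solar time, so the minimum zenith falls at hour 12.
#'
#' @param doy Day of year (1-366), vectorized.
#' @param hour Local solar hour (0-24), vectorized.
#' @param latitude Degrees north.
#' @return Zenith angle in degrees (0-180; above 90 the sun is below
#'   the horizon).
#' @examples
#' solar_zenith(172, 12, 40.04)  # ~16.6 at summer solstice noon
#' @export
solar_zenith <- function(doy, hour, latitude) {
  stopifnot(all(doy >= 1), all(doy <= 366), all(hour >= 0), all(hour < 24))
  decl <- -23.45 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  lat <- latitude * pi / 180
  h_angle <- 15 * (hour - 12) * pi / 180
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(h_angle)
  acos(pmin(pmax(cosz, -1), 1)) * 180 / pi
}

#' Canopy architecture
#'
#' Optical and geometric constants of the multilayer sunlit/shaded
#' canopy scheme. The defaults assume a spherical leaf-angle
#' distribution, for which the beam extinction coefficient is
#' `0.5 / cos(zenith)`.
#'
#' @param n_layers Number of canopy layers (default 10).
#' @param k_diffuse Extinction coefficient for diffuse light.
#' @param scatter Leaf scattering coefficient (reflectance +
#'   transmittance).
#' @param latitude Site latitude, degrees north.
#' @param diffuse_min Minimum diffuse fraction of incident PPFD under
#'   perfectly clear sky.
#' @param k_nitrogen Exponential decay coefficient of photosynthetic
#'   capacity (Vcmax, Jmax, Rd, TPU) with cumulative leaf area, the
#'   canopy nitrogen profile; 0 gives a uniform canopy.
#' @return A list of class `canopy_arch`.
#' @export
canopy_arch <- function(n_layers = 10, k_diffuse = 0.7, scatter = 0.2,
                        latitude = 40.04, diffuse_min = 0.23,
                        k_nitrogen = 0.10) {
  stopifnot(n_layers >= 1, k_diffuse > 0, scatter >= 0, scatter < 1,
            k_nitrogen >= 0)
  structure(list(n_layers = as.integer(n_layers), k_diffuse = k_diffuse,
                 scatter = scatter, latitude = latitude,
                 diffuse_min = diffuse_min, k_nitrogen = k_nitrogen),
            class = "canopy_arch")
}

# Beam extinction coefficient for a spherical leaf-angle distribution;
# beam is dropped entirely for sun lower than cos(zenith) = 0.05.
beam_extinction <- function(cosz) {
  ifelse(cosz > 0.05, 0.5 / pmax(cosz, 0.05), Inf)
}

# Diffuse fraction from a clearness-index rule: fully diffuse for
# overcast (q near zero relative to clear sky), `diffuse_min` when clear;
# quadratic in (1 - clearness) so near-clear skies stay beam-dominated.
diffuse_fraction <- function(q_above, cosz, arch, q_clear_max = 2400) {
  q_cs <- q_clear_max * pmax(cosz, 0)
  clearness <- ifelse(q_cs > 0, pmin(q_above / q_cs, 1), 0)
  arch$diffuse_min + (1 - arch$diffuse_min) * (1 - clearness)^2
}

#' Sunlit/shaded light partitioning over canopy layers
#'
#' Splits incident PPFD into direct-beam and diffuse streams and
#' attenuates both through the canopy with Beer's law. At cumulative
#' leaf area `L` above a layer, the sunlit leaf fraction is
#' `exp(-k_beam * L)`; shaded leaves receive attenuated diffuse light
#' plus a downward-scattered beam component, and sunlit leaves receive
#' the same plus the unattenuated beam projection `k_beam * I_beam`.
#' For sun at or below the horizon the partition is all-diffuse.
#'
#' @param q_above PPFD above the canopy, umol m-2 s-1.
#' @param zenith Solar zenith angle, degrees.
#' @param arch A [canopy_arch()].
#' @param lai Total leaf area index, m2 m-2.
#' @return A tibble with one row per layer: `layer`, `cum_lai_above`
#'   (at the layer centre), `f_sunlit`, `q_sunlit`, `q_shaded`
#'   (per unit leaf area). `lai = 0` returns a single notional layer.
#' @examples
#' light_partition(1500, 30, canopy_arch(), lai = 5)
#' @export
light_partition <- function(q_above, zenith, arch, lai) {
  stopifnot(q_above >= 0, lai >= 0, inherits(arch, "canopy_arch"))
  lp <- light_partition_core(q_above, cos(zenith * pi / 180), arch,
                             max(lai, 0))
  tibble::tibble(
    layer = seq_len(ncol(lp$q_sun)),
    cum_lai_above = lp$l_mid,
    f_sunlit = as.vector(lp$f_sun),
    q_sunlit = as.vector(lp$q_sun),
    q_shaded = as.vector(lp$q_sh)
  )
}

# Vectorized over hours: cosz/q_above vectors length H; returns H x L
# matrices. lai = 0 is treated as a single notional layer of zero area.
light_partition_core <- function(q_above, cosz, arch, lai) {
  n <- if (lai > 0) arch$n_layers else 1L
  dl <- if (lai > 0) lai / n else 0
  l_mid <- (seq_len(n) - 0.5) * dl
  kd <- arch$k_diffuse
  sigma <- arch$scatter
  kb <- beam_extinction(cosz)
  has_beam <- is.finite(kb) & q_above > 0
  fd <- diffuse_fraction(q_above, cosz, arch)
  fd[!has_beam] <- 1
  i_b0 <- q_above * (1 - fd)
  i_d0 <- q_above * fd
  kb_eff <- ifelse(has_beam, kb, 0)
  kb_sc <- kb_eff * sqrt(1 - sigma)
  # H x L matrices
  att_d <- exp(-kd * outer(rep(1, length(cosz)), l_mid))
  att_b <- exp(-outer(kb_sc, l_mid))
  q_sh <- i_d0 * kd * att_d + 0.5 * sigma * (kb_eff * i_b0) * att_b
  q_sun <- q_sh + (kb_eff * i_b0) %*% t(rep(1, n))
  f_sun <- exp(-outer(kb_eff, l_mid))
  f_sun[!has_beam, ] <- 0
  list(l_mid = l_mid, f_sun = f_sun, q_sun = q_sun, q_sh = q_sh, dl = dl)
}

# Hot path: solves the sunlit and shaded leaf classes of every layer for
# a batch of hours sharing one LAI, and aggregates to ground area.
canopy_batch <- function(doy, hour, q, t_air, rh, ws, lai, co2, params,
                         arch, detail = FALSE) {
  h_n <- length(q)
  zen <- solar_zenith(doy, hour, arch$latitude)
  lp <- light_partition_core(q, cos(zen * pi / 180), arch, lai)
  n <- ncol(lp$q_sun)
  if (lai <= 0) {
    zero <- numeric(h_n)
    return(list(an_ground = zero, rd_ground = zero, gs_canopy = zero,
                e_ground = zero, wue = ifelse(zero > 0, 0, NA_real_),
                top_ci = rep(NA_real_, h_n),
                top_limiting = rep(NA_character_, h_n), layers = NULL))
  }
  # leaf classes: [hour x layer] sunlit then shaded, flattened; the
  # capacity of both classes decays with depth per the nitrogen profile
  q_leaf <- cbind(lp$q_sun, lp$q_sh)
  t_rep <- rep(t_air, 2 * n)
  rh_rep <- rep(rh, 2 * n)
  cap <- rep(rep(exp(-arch$k_nitrogen * lp$l_mid), 2), each = h_n)
  s <- solve_coupled_core(as.vector(q_leaf), t_rep, rh_rep,
                          rep(co2, length(t_rep)), params, capacity = cap)
  an <- matrix(s$an, h_n, 2 * n)
  gs <- matrix(s$gs, h_n, 2 * n)
  rd <- matrix(s$rd, h_n, 2 * n)
  f <- lp$f_sun
  w_sun <- f * lp$dl
  w_sh <- (1 - f) * lp$dl
  an_ground <- rowSums(an[, 1:n, drop = FALSE] * w_sun) +
    rowSums(an[, n + 1:n, drop = FALSE] * w_sh)
  rd_ground <- rowSums(rd[, 1:n, drop = FALSE] * w_sun) +
    rowSums(rd[, n + 1:n, drop = FALSE] * w_sh)
  gs_canopy <- rowSums(gs[, 1:n, drop = FALSE] * w_sun) +
    rowSums(gs[, n + 1:n, drop = FALSE] * w_sh)
  rn <- net_radiation(q, lai, arch)
  e_ground <- pm_et(t_air, rh, ws, gs_canopy, rn)
  wue <- ifelse(e_ground > 0, an_ground / e_ground, NA_real_)
  out <- list(an_ground = an_ground, rd_ground = rd_ground,
              gs_canopy = gs_canopy, e_ground = e_ground, wue = wue,
              top_ci = matrix(s$ci, h_n, 2 * n)[, 1],
              top_limiting = matrix(s$limiting, h_n, 2 * n)[, 1],
              layers = NULL)
  if (detail) {
    out$layers <- tibble::tibble(
      hour_index = rep(seq_len(h_n), n),
      layer = rep(seq_len(n), each = h_n),
      cum_lai_above = rep(lp$l_mid, each = h_n),
      f_sunlit = as.vector(f),
      q_sunlit = as.vector(lp$q_sun),
      q_shaded = as.vector(lp$q_sh),
      an_sunlit = as.vector(an[, 1:n]),
      an_shaded = as.vector(an[, n + 1:n]),
      gs_sunlit = as.vector(gs[, 1:n]),
      gs_shaded = as.vector(gs[, n + 1:n])
    )
  }
  out
}

# Canopy net radiation (W m-2) approximated from PPFD: shortwave
# irradiance ~ q / 2.285 (PAR is ~half of shortwave at ~4.57 umol/J),
# of which the canopy absorbs a Beer-law fraction with 0.8 net-to-
# absorbed efficiency.
net_radiation <- function(q, lai, arch) {
  0.8 * (q / 2.285) * (1 - exp(-arch$k_diffuse * lai))
}

# Penman-Monteith combination equation; gs_canopy in mol m-2 s-1
# (ground), returns mmol H2O m-2 s-1. Aerodynamic conductance from a
# log wind profile over a 1 m canopy measured at 3 m.
pm_et <- function(t_air, rh, ws, gs_canopy, rn) {
  es <- 0.6108 * exp(17.27 * t_air / (t_air + 237.3))      # kPa
  vpd <- pmax(es * (1 - rh), 0)
  slope <- 4098 * es / (t_air + 237.3)^2                    # kPa K-1
  gamma <- 0.0665                                           # kPa K-1
  rho_cp <- 1.204 * 1010                                    # J m-3 K-1
  ga <- pmax(0.0109 * ws, 0.005)                            # m s-1
  gc <- pmax(gs_canopy, 1e-4) * 0.0245                      # mol -> m s-1
  # with slope/gamma/vpd all in kPa the quotient is already W m-2
  lambda_e <- (slope * pmax(rn, 0) + rho_cp * vpd * ga) /
    (slope + gamma * (1 + ga / gc))
  pmax(lambda_e, 0) / 2.45e6 / 0.018 * 1000
}

#' Penman-Monteith canopy evapotranspiration
#'
#' Combination-equation evapotranspiration for one hour, using the
#' bulk canopy conductance (LAI-weighted sum of the per-layer stomatal
#' conductances) and an aerodynamic conductance from a logarithmic wind
#' profile over a 1 m canopy.
#'
#' @param weather_hour A list or one-row tibble with `t_air` (degC),
#'   `rh` (fraction) and `ws` (m s-1).
#' @param gs_canopy Bulk canopy stomatal conductance, mol m-2 s-1 per
#'   ground area.
#' @param net_radiation Net radiation absorbed by the canopy, W m-2.
#' @return Evapotranspiration, mmol H2O m-2 ground s-1 (non-negative;
#'   increasing in vapour-pressure deficit and net radiation).
#' @examples
#' penman_monteith_et(list(t_air = 25, rh = 0.6, ws = 3), 0.5, 400)
#' @export
penman_monteith_et <- function(weather_hour, gs_canopy, net_radiation) {
  stopifnot(all(gs_canopy >= 0))
  pm_et(weather_hour$t_air, weather_hour$rh, weather_hour$ws,
        gs_canopy, net_radiation)
}

#' Canopy water-use efficiency
#'
#' `WUE = An / E` in umol CO2 per mmol H2O. Hours without
#' evapotranspiration (night) have undefined WUE and return `NA`.
#'
#' @param an_ground Canopy net assimilation, umol m-2 ground s-1.
#' @param e_ground Canopy evapotranspiration, mmol m-2 ground s-1.
#' @return WUE, umol mmol-1; `NA_real_` where `e_ground <= 0`; 0 where
#'   `an_ground` is 0 with positive `e_ground`.
#' @examples
#' canopy_wue(5, 1)  # 5
#' @export
canopy_wue <- function(an_ground, e_ground) {
  ifelse(e_ground > 0, an_ground / e_ground, NA_real_)
}

#' Canopy assimilation for one weather hour
#'
#' Partitions light over the canopy layers, solves the coupled leaf
#' model once per layer for the sunlit and the shaded leaf class, and
#' aggregates net assimilation, dark respiration and stomatal
#' conductance to ground area with the sunlit-fraction and leaf-area
#' weights. Evapotranspiration comes from the Penman-Monteith equation
#' with the bulk canopy conductance.
#'
#' @param weather_hour A list or one-row tibble with `doy`, `hour`, `q`,
#'   `t_air`, `rh`, `ws`.
#' @param lai Leaf area index, m2 m-2.
#' @param co2 Ambient CO2, umol mol-1.
#' @param params A [leaf_params()].
#' @param arch A [canopy_arch()].
#' @return An object of class `canopy_flux`: a list with `an_ground`,
#'   `rd_ground`, `gs_canopy`, `e_ground`, `wue` and a per-layer tibble
#'   `layers` (`layer`, `f_sunlit`, `q_sunlit`, `q_shaded`, `an_sunlit`,
#'   `an_shaded`, `gs_sunlit`, `gs_shaded`).
#' @examples
#' wh <- list(doy = 180, hour = 12, q = 1800, t_air = 28, rh = 0.6, ws = 3)
#' canopy_assimilation(wh, lai = 5, co2 = 400, leaf_params(), canopy_arch())
#' @export
canopy_assimilation <- function(weather_hour, lai, co2, params, arch) {
  stopifnot(lai >= 0, co2 > 0)
  cb <- canopy_batch(weather_hour$doy, weather_hour$hour, weather_hour$q,
                     weather_hour$t_air, weather_hour$rh, weather_hour$ws,
                     lai, co2, params, arch, detail = TRUE)
  structure(list(an_ground = cb$an_ground, rd_ground = cb$rd_ground,
                 gs_canopy = cb$gs_canopy, e_ground = cb$e_ground,
                 wue = cb$wue, layers = cb$layers),
            class = "canopy_flux")
}

#' @export
print.canopy_flux <- function(x, ...) {
  cat(sprintf(paste0("<canopy_flux> An %.2f, Rd %.2f umol m-2 s-1; ",
                     "E %.2f mmol m-2 s-1; WUE %s\n"),
              x$an_ground, x$rd_ground, x$e_ground,
              ifelse(is.na(x$wue), "NA", sprintf("%.2f", x$wue))))
  invisible(x)
}
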