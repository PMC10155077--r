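#' Soybean growth schedule and partitioning configuration
#'
#' All crop-development constants live here: the photothermal clock
#' (base temperature and the thermal-time thresholds for the
#' vegetative-to-reproductive transition, senescence onset and
#' maturity), the sowing day, specific leaf area, growth-respiration
#' efficiency, and the logistic coefficients that partition assimilated
#' carbon into leaf, stem, root and pod as a function of development
#' stage `d = thermal_time / tt_mature`. Defaults describe an
#' Illinois-like soybean season: sowing on DOY 152, reproductive onset
#' near DOY 210, maturity in early October, peak LAI ~6-8 and pod
#' biomass ~5-8 Mg/ha under typical weather at 400 ppm CO2.
#'
#' @param sow_doy Sowing day of year.
#' @param t_base Base temperature for thermal time, degC.
#' @param tt_repro Thermal time at the vegetative-to-reproductive
#'   transition, degC day.
#' @param tt_sen_onset Thermal time at leaf-senescence onset, degC day.
#' @param tt_mature Thermal time at maturity, degC day.
#' @param end_doy Hard stop of the season window.
#' @param sla Specific leaf area expressed as LAI per Mg/ha of green
#'   leaf biomass (2.5 corresponds to 25 m2 per kg).
#' @param growth_efficiency Fraction of net assimilate converted to
#'   structural biomass (growth respiration takes the rest).
#' @param labile_target_frac Target size of the labile carbohydrate
#'   pool (which buffers nighttime respiration) as a fraction of green
#'   leaf biomass; positive allocation refills the pool to this target
#'   before any organ growth, mirroring the diel starch cycle of a
#'   soybean leaf.
#' @param labile_floor Minimum labile target, Mg/ha (seed reserves).
#' @param sen_rate Leaf senescence rate at full ramp, fraction of green
#'   leaf per hour.
#' @param maint_coef Maintenance-respiration coefficients for the
#'   non-leaf pools, g carbohydrate per g biomass per day at 25 degC
#'   (leaf maintenance is already carried by the FvCB dark respiration
#'   of the canopy). Named `stem`, `root`, `pod`.
#' @param maint_q10 Q10 of maintenance respiration.
#' @param carbon_per_umol Mg/ha of carbohydrate per (umol CO2 m-2 s-1
#'   over one hour): 3600 s x 30 g/mol x 1e-6 x 0.01.
#' @param partition Named list of logistic coefficient sets; see the
#'   default for the expected shape.
#' @param init Named numeric of initial pools at sowing, Mg/ha.
#' @return A list of class `crop_schedule`.
#' @export
crop_schedule <- function(sow_doy = 152, t_base = 10,
                          tt_repro = 750, tt_sen_onset = 1000,
                          tt_mature = 1600, end_doy = 310,
                          sla = 2.0, growth_efficiency = 0.7,
                          labile_target_frac = 0.15, labile_floor = 0.05,
                          sen_rate = 0.004,
                          maint_coef = c(stem = 0.008, root = 0.005,
                                         pod = 0.004),
                          maint_q10 = 2,
                          carbon_per_umol = 3600 * 30e-6 * 0.01,
                          partition = list(
                            leaf = c(a = 0.42, k = 12, d0 = 0.50),
                            stem = c(a = 0.40, k = 10, d0 = 0.60),
                            root = c(a = 0.22, k = 9, d0 = 0.40,
                                     base = 0.02),
                            pod = c(k = 12, d0 = 0.58)
                          ),
                          init = c(leaf = 0.05, stem = 0.02, root = 0.03,
                                   pod = 0, labile = 0.01)) {
  stopifnot(tt_repro < tt_sen_onset, tt_sen_onset < tt_mature,
            growth_efficiency > 0, growth_efficiency <= 1,
            sla > 0, sen_rate >= 0)
  sched <- as.list(environment())
  # fail early on malformed partition coefficients
  probe <- tryCatch(
    vapply(c(0, tt_repro, tt_mature), function(tt) {
      sum(partition_weights(tt, sched))
    }, numeric(1)),
    error = function(e) stop("malformed partition schedule: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (any(!is.finite(probe)) || any(probe <= 0)) {
    stop("partition fractions are unnormalizable", call. = FALSE)
  }
  structure(sched, class = "crop_schedule")
}

#' Thermal time increment
#'
#' Linear-above-base photothermal accumulation:
#' `max(0, t_air - t_base) * dt / 24` degC day for a `dt`-hour step.
#'
#' @param t_air Air temperature, degC (vectorized).
#' @param dt Step length, hours.
#' @param t_base Base temperature, degC.
#' @return Thermal-time increment, degC day.
#' @examples
#' thermal_time_step(34, 1, 10)  # 1 degC day
#' @export
thermal_time_step <- function(t_air, dt = 1, t_base = 10) {
  stopifnot(dt > 0)
  pmax(0, t_air - t_base) * dt / 24
}

#' Development phase from thermal time
#'
#' @param thermal_time Accumulated thermal time, degC day.
#' @param schedule A [crop_schedule()].
#' @return `"vegetative"` below `tt_repro`, `"reproductive"` at or
#'   above it (closed boundary).
#' @export
development_phase <- function(thermal_time, schedule) {
  stopifnot(all(thermal_time >= 0))
  ifelse(thermal_time >= schedule$tt_repro, "reproductive", "vegetative")
}

logistic <- function(x) 1 / (1 + exp(-x))

# Maintenance respiration of the non-leaf pools, Mg/ha of carbohydrate
# per day at the given air temperature.
maintenance_respiration <- function(state, schedule, t_air) {
  mc <- schedule$maint_coef
  (mc[["stem"]] * state$biomass_stem + mc[["root"]] * state$biomass_root +
      mc[["pod"]] * state$biomass_pod) *
    schedule$maint_q10^((t_air - 25) / 10)
}

partition_weights <- function(thermal_time, schedule) {
  d <- min(thermal_time / schedule$tt_mature, 1.2)
  p <- schedule$partition
  w_leaf <- p$leaf[["a"]] * logistic(-p$leaf[["k"]] * (d - p$leaf[["d0"]]))
  w_stem <- p$stem[["a"]] * logistic(-p$stem[["k"]] * (d - p$stem[["d0"]]))
  w_root <- p$root[["a"]] * logistic(-p$root[["k"]] * (d - p$root[["d0"]])) +
    p$root[["base"]]
  w_pod <- if (thermal_time >= schedule$tt_repro) {
    logistic(p$pod[["k"]] * (d - p$pod[["d0"]]))
  } else 0
  c(leaf = w_leaf, stem = w_stem, root = w_root, pod = w_pod)
}

#' Carbon partition fractions
#'
#' Logistic allocation weights for the four biomass pools, normalized to
#' sum to one at every development stage. The pod weight is zero before
#' the reproductive threshold and increases monotonically through the
#' reproductive phase.
#'
#' @param thermal_time Accumulated thermal time, degC day.
#' @param schedule A [crop_schedule()].
#' @return Named numeric `(leaf, stem, root, pod)` summing to 1.
#' @examples
#' partition_fractions(0, crop_schedule())
#' partition_fractions(1400, crop_schedule())
#' @export
partition_fractions <- function(thermal_time, schedule) {
  w <- partition_weights(thermal_time, schedule)
  w / sum(w)
}

#' Initial crop state
#'
#' @param schedule A [crop_schedule()].
#' @return A list of class `crop_state` with biomass pools (Mg/ha),
#'   `senesced_leaf`, `labile`, `lai`, `thermal_time` and `phase`.
#' @export
crop_state <- function(schedule = crop_schedule()) {
  ini <- schedule$init
  st <- list(biomass_leaf = ini[["leaf"]], biomass_stem = ini[["stem"]],
             biomass_root = ini[["root"]], biomass_pod = ini[["pod"]],
             labile = ini[["labile"]], senesced_leaf = 0,
             thermal_time = 0, phase = "vegetative")
  st$lai <- schedule$sla * st$biomass_leaf
  structure(st, class = "crop_state")
}

#' Advance the crop by one time step
#'
#' Converts the canopy carbon flux over the step into biomass
#' (`carbon_per_umol` stoichiometry, growth-respiration efficiency),
#' then charges Q10-scaled maintenance respiration on the stem, root
#' and pod pools (leaf maintenance is already part of the canopy's FvCB
#' dark respiration). Positive net carbohydrate first refills the
#' labile pool to its target (a fraction of green leaf biomass), then
#' grows the organ pools by the logistic partition fractions. A deficit
#' (night) is drawn from the labile pool first, then from leaf (and in
#' extremis stem, root, pod) mass. After senescence onset, green leaf is removed
#' at a stage-ramped rate and booked to `senesced_leaf`. Pool changes
#' plus senescence losses exactly balance the converted carbon; no pool
#' goes negative.
#'
#' @param state A `crop_state`.
#' @param canopy_flux A `canopy_flux` (or any list with `an_ground`).
#' @param dt Step length, hours.
#' @param schedule A [crop_schedule()].
#' @param t_air Air temperature over the step, degC (drives the
#'   thermal-time clock).
#' @return The updated `crop_state`.
#' @export
grow_step <- function(state, canopy_flux, dt = 1, schedule = crop_schedule(),
                      t_air = NULL) {
  if (!is.null(t_air)) {
    state$thermal_time <- state$thermal_time +
      thermal_time_step(t_air, dt, schedule$t_base)
  }
  c_an <- canopy_flux$an_ground * dt * schedule$carbon_per_umol
  gross <- if (c_an >= 0) schedule$growth_efficiency * c_an else c_an
  maint <- maintenance_respiration(state, schedule,
                                   if (is.null(t_air)) 25 else t_air) *
    dt / 24
  net <- gross - maint
  if (net >= 0) {
    target <- schedule$labile_target_frac * state$biomass_leaf +
      schedule$labile_floor
    refill <- min(net, max(0, target - state$labile))
    state$labile <- state$labile + refill
    fr <- partition_fractions(state$thermal_time, schedule)
    organ <- (net - refill) * fr
    state$biomass_leaf <- state$biomass_leaf + organ[["leaf"]]
    state$biomass_stem <- state$biomass_stem + organ[["stem"]]
    state$biomass_root <- state$biomass_root + organ[["root"]]
    state$biomass_pod <- state$biomass_pod + organ[["pod"]]
  } else {
    deficit <- -net
    for (pool in c("labile", "biomass_leaf", "biomass_stem",
                   "biomass_root", "biomass_pod")) {
      draw <- min(state[[pool]], deficit)
      state[[pool]] <- state[[pool]] - draw
      deficit <- deficit - draw
      if (deficit <= 0) break
    }
  }
  if (state$thermal_time > schedule$tt_sen_onset && schedule$sen_rate > 0) {
    ramp <- min((state$thermal_time - schedule$tt_sen_onset) / 200, 1)
    sen <- state$biomass_leaf * min(schedule$sen_rate * ramp * dt, 1)
    state$biomass_leaf <- state$biomass_leaf - sen
    state$senesced_leaf <- state$senesced_leaf + sen
  }
  state$lai <- schedule$sla * state$biomass_leaf
  state$phase <- development_phase(state$thermal_time, schedule)
  state
}

#' Simulate one growing season
#'
#' Runs the coupled canopy-growth model hour by hour from sowing to
#' maturity (thermal-time target) or the season window's end. The
#' canopy light environment is refreshed at the start of each day with
#' the current LAI, and all 24 hours of the day are then solved as one
#' batch; growth and development step hourly. Capacities are scaled by
#' `scale_v`/`scale_j` (dark respiration co-scales with `scale_v`).
#'
#' @param weather_year Hourly weather for one year: columns `doy`,
#'   `hour`, `q`, `t_air`, `rh`, `ws`, `precip` (e.g. one year of a
#'   [generate_archive()] result, or a [bootstrap_year()]).
#' @param co2 Ambient CO2, umol mol-1.
#' @param params A [leaf_params()].
#' @param arch A [canopy_arch()].
#' @param schedule A [crop_schedule()].
#' @param scale_v,scale_j Capacity scaling factors.
#' @param keep_traces Retain the hourly top-layer sunlit leaf record
#'   (needed by [limiting_frequency()]).
#' @return An object of class `season_result`: list with
#'   * `daily`: tibble (`doy`, `an_mean`, `an_max`, `wue_mean` over
#'     daylight hours, `lai`, `precip`, `phase`),
#'   * `summary`: tibble with `pod`, `shoot`, `max_lai`,
#'     `mean_daily_max_an`, `mean_daily_mean_an`, `mean_wue` (Mg/ha,
#'     m2/m2, umol m-2 s-1, umol mmol-1),
#'   * `phase_windows`: DOY ranges of the vegetative and reproductive
#'     phases,
#'   * `final_state`, `maturity_doy`, `co2`, `scale_v`, `scale_j`,
#'   * `trace`: hourly top-layer record when `keep_traces = TRUE`.
#' @examples
#' \donttest{
#' arch <- generate_archive(1, seed = 42)
#' res <- simulate_season(arch, co2 = 400)
#' res$summary
#' }
#' @export
simulate_season <- function(weather_year, co2 = 400, params = leaf_params(),
                            arch = canopy_arch(), schedule = crop_schedule(),
                            scale_v = 1, scale_j = 1, keep_traces = FALSE) {
  wx <- tibble::as_tibble(weather_year)[, c("doy", "hour", "q", "t_air",
                                            "rh", "ws", "precip")]
  wx <- wx[order(wx$doy, wx$hour), ]
  season <- wx[wx$doy >= schedule$sow_doy & wx$doy <= schedule$end_doy, ]
  doys <- schedule$sow_doy:min(schedule$end_doy, max(wx$doy))
  have <- paste(season$doy, season$hour)
  gaps <- setdiff(paste(rep(doys, each = 24), rep(0:23, length(doys))), have)
  if (length(gaps)) {
    stop("weather year has ", length(gaps), " missing season hour(s): ",
         paste(utils::head(gaps, 5), collapse = "; "), " (doy hour)",
         call. = FALSE)
  }

  params_s <- scale_params(params, scale_v, scale_j)
  state <- crop_state(schedule)
  n_days <- length(doys)
  daily <- list(an_mean = numeric(n_days), an_max = numeric(n_days),
                wue_mean = numeric(n_days), lai = numeric(n_days),
                precip = numeric(n_days), phase = character(n_days))
  trace <- if (keep_traces) vector("list", n_days) else NULL
  repro_doy <- NA_integer_
  maturity_doy <- NA_integer_
  last_day <- n_days

  for (i in seq_len(n_days)) {
    d <- doys[i]
    day <- season[season$doy == d, ]
    day <- day[order(day$hour), ]
    cb <- canopy_batch(d, day$hour, day$q, day$t_air, day$rh, day$ws,
                       state$lai, co2, params_s, arch)
    for (h in seq_len(24)) {
      state <- grow_step(state, list(an_ground = cb$an_ground[h]), 1,
                         schedule, t_air = day$t_air[h])
      if (is.na(repro_doy) && state$phase == "reproductive") repro_doy <- d
    }
    daylight <- day$q > 0
    daily$an_mean[i] <- mean(cb$an_ground)
    daily$an_max[i] <- max(cb$an_ground)
    wue_ok <- daylight & !is.na(cb$wue) & cb$e_ground > 0.05
    daily$wue_mean[i] <- if (any(wue_ok)) mean(cb$wue[wue_ok]) else NA_real_
    daily$lai[i] <- state$lai
    daily$precip[i] <- sum(day$precip)
    daily$phase[i] <- state$phase
    if (keep_traces) {
      live <- daylight & !is.na(cb$top_ci)  # canopy may be fully senesced
      trace[[i]] <- tibble::tibble(
        doy = d, hour = day$hour[live],
        ci = cb$top_ci[live], limiting = cb$top_limiting[live]
      )
    }
    if (state$thermal_time >= schedule$tt_mature) {
      maturity_doy <- d
      last_day <- i
      break
    }
  }

  idx <- seq_len(last_day)
  daily_tbl <- tibble::tibble(doy = doys[idx], an_mean = daily$an_mean[idx],
                              an_max = daily$an_max[idx],
                              wue_mean = daily$wue_mean[idx],
                              lai = daily$lai[idx],
                              precip = daily$precip[idx],
                              phase = daily$phase[idx])
  if (is.na(maturity_doy)) maturity_doy <- doys[last_day]
  if (is.na(repro_doy)) repro_doy <- maturity_doy
  summary_tbl <- tibble::tibble(
    pod = state$biomass_pod,
    shoot = state$biomass_pod + state$biomass_leaf + state$biomass_stem,
    max_lai = max(daily_tbl$lai),
    mean_daily_max_an = mean(daily_tbl$an_max),
    mean_daily_mean_an = mean(daily_tbl$an_mean),
    mean_wue = mean(daily_tbl$wue_mean, na.rm = TRUE)
  )
  structure(list(
    daily = daily_tbl,
    summary = summary_tbl,
    phase_windows = list(
      vegetative = c(schedule$sow_doy, max(repro_doy - 1, schedule$sow_doy)),
      reproductive = c(repro_doy, maturity_doy)
    ),
    final_state = state,
    maturity_doy = maturity_doy,
    co2 = co2, scale_v = scale_v, scale_j = scale_j,
    trace = if (keep_traces) do.call(rbind, trace[idx]) else NULL
  ), class = "season_result")
}

#' @export
print.season_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<season_result> co2 %g ppm, scales (%.2f, %.2f)\n",
                     "  pod %.2f  shoot %.2f Mg/ha; max LAI %.2f\n",
                     "  An daily-max mean %.2f, daily-mean mean %.2f ",
                     "umol m-2 s-1; WUE %.2f umol mmol-1\n",
                     "  phases: vegetative DOY %d-%d, reproductive %d-%d\n"),
              x$co2, x$scale_v, x$scale_j, s$pod, s$shoot, s$max_lai,
              s$mean_daily_max_an, s$mean_daily_mean_an, s$mean_wue,
              x$phase_windows$vegetative[1], x$phase_windows$vegetative[2],
              x$phase_windows$reproductive[1], x$phase_windows$reproductive[2]))
  invisible(x)
}
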