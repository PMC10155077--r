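#' @title Hourly weather archives
#' @description
#' Weather drives every simulation in the package as an hourly table
#' with columns `year`, `doy` (1-366), `hour` (0-23), `q` (solar PPFD,
#' umol m-2 s-1), `t_air` (degC), `rh` (fraction), `ws` (m s-1) and
#' `precip` (mm). A multi-year table of complete years is a *weather
#' archive*; [generate_archive()] builds a synthetic one,
#' [read_weather_csv()] loads a real one, and [bootstrap_year()]
#' resamples an archive day-by-day.
#' @name weather
NULL

weather_cols <- c("year", "doy", "hour", "q", "t_air", "rh", "ws", "precip")
weather_csv_cols <- c(year = "year", doy = "doy", hour = "hour",
                      q = "q_umol_m2_s", t_air = "t_c", rh = "rh_frac",
                      ws = "ws_m_s", precip = "precip_mm")

validate_weather <- function(df, what = "weather table") {
  missing_cols <- setdiff(weather_cols, names(df))
  if (length(missing_cols)) {
    stop(what, " lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$year, df$doy, df$hour)
  dup <- unique(key[duplicated(key)])
  if (length(dup)) {
    stop(what, " has duplicate (year, doy, hour) records: ",
         paste(utils::head(dup, 5), collapse = "; "), call. = FALSE)
  }
  bad <- df$q < 0 | df$q > 2600 | df$t_air < -45 | df$t_air > 55 |
    df$rh < 0 | df$rh > 1 | df$precip < 0 | df$ws < 0
  if (any(bad)) {
    off <- df[which(bad)[seq_len(min(5, sum(bad)))], c("year", "doy", "hour")]
    stop(what, " has ", sum(bad), " out-of-range value row(s), e.g. ",
         paste(sprintf("(year %d, doy %d, hour %d)", off$year, off$doy,
                       off$hour), collapse = "; "), call. = FALSE)
  }
  # every (doy, hour) present exactly once per year, days complete
  for (yr in unique(df$year)) {
    d <- df[df$year == yr, ]
    doys <- sort(unique(d$doy))
    expected <- paste(rep(doys, each = 24), rep(0:23, length(doys)))
    have <- paste(d$doy, d$hour)
    gaps <- setdiff(expected, have)
    if (length(gaps)) {
      gap1 <- strsplit(gaps[[1]], " ")[[1]]
      stop(what, sprintf(" year %s is missing %d hour(s), first gap (doy %s, hour %s)",
                         yr, length(gaps), gap1[1], gap1[2]), call. = FALSE)
    }
  }
  invisible(df)
}

as_weather_archive <- function(df) {
  df <- tibble::as_tibble(df)[weather_cols]
  df <- df[order(df$year, df$doy, df$hour), ]
  validate_weather(df, "weather archive")
  class(df) <- c("weather_archive", class(df))
  df
}

#' @export
print.weather_archive <- function(x, ...) {
  yrs <- unique(x$year)
  cat(sprintf("<weather_archive> %d year(s): %s; %d hourly records\n",
              length(yrs), paste(range(yrs), collapse = "-"), nrow(x)))
  NextMethod()
}

#' Read an hourly weather archive from CSV
#'
#' The strict column contract is
#' `year,doy,hour,q_umol_m2_s,t_c,rh_frac,ws_m_s,precip_mm` (UTF-8, no
#' missing cells). The archive is validated on load: duplicate or
#' missing (year, doy, hour) keys and out-of-range values (PPFD above
#' 2600 umol m-2 s-1, temperature outside \[-45, 55\] degC, humidity
#' outside \[0, 1\]) are reported with the offending rows.
#'
#' @param path CSV file path.
#' @return A `weather_archive` tibble.
#' @seealso [write_weather_csv()], [generate_archive()]
#' @export
read_weather_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(unname(weather_csv_cols), names(raw))
  if (length(missing_cols)) {
    stop("weather CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(stats::setNames(raw[unname(weather_csv_cols)],
                                          names(weather_csv_cols)))
  if (anyNA(df)) stop("weather CSV contains missing cells", call. = FALSE)
  as_weather_archive(df)
}

#' Write an hourly weather archive to CSV
#'
#' @param archive A `weather_archive` (or conforming tibble).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(archive, path) {
  df <- as.data.frame(archive)[weather_cols]
  names(df) <- unname(weather_csv_cols)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthetic climate generator settings
#'
#' Constants of the synthetic hourly weather generator, tuned to an
#' Illinois-like humid continental climate (the regime of the central
#' U.S. corn belt): a sinusoidal seasonal temperature cycle peaking in
#' late July, day-level cloudiness with lag-1 autocorrelation,
#' a two-state (wet/dry) precipitation occurrence chain, within-day
#' humidity anti-correlated with temperature, and year-level anomalies
#' that create interannual variability.
#'
#' @param latitude Site latitude, degrees north.
#' @param t_annual_mean Annual mean air temperature, degC.
#' @param t_annual_amplitude Seasonal half-range of the daily mean, degC.
#' @param t_peak_doy Day of year of the warmest daily mean.
#' @param q_clear_max Clear-sky PPFD scale (umol m-2 s-1 at zenith 0).
#' @param tau_mean,tau_sd,tau_ar1 Mean, innovation SD and lag-1
#'   autocorrelation of the day-level clear-sky transmission factor.
#' @param p_wet_dry,p_wet_wet Markov transition probabilities of a wet
#'   day after a dry / wet day.
#' @param rain_shape,rain_scale Gamma parameters of daily rain depth, mm.
#' @param t_day_sd,t_day_ar1 Innovation SD (degC) and autocorrelation of
#'   the day-level temperature anomaly.
#' @param year_t_sd SD of the year-level temperature anomaly, degC.
#' @param year_tau_sd SD of the year-level multiplicative radiation
#'   anomaly.
#' @return A list of class `climate_spec`.
#' @export
climate_spec <- function(latitude = 40.04,
                         t_annual_mean = 11,
                         t_annual_amplitude = 14.5,
                         t_peak_doy = 199,
                         q_clear_max = 2400,
                         tau_mean = 0.72, tau_sd = 0.13, tau_ar1 = 0.55,
                         p_wet_dry = 0.32, p_wet_wet = 0.45,
                         rain_shape = 0.9, rain_scale = 9,
                         t_day_sd = 2.0, t_day_ar1 = 0.75,
                         year_t_sd = 0.9, year_tau_sd = 0.04) {
  spec <- as.list(environment())
  structure(spec, class = "climate_spec")
}

ar1_series <- function(n, phi, sd) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
  innov <- stats::rnorm(n, 0, sd)
  for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i]
  x
}

generate_year <- function(year, spec) {
  n_days <- 365
  hours <- 0:23
  # day-level processes
  tau <- pmin(pmax(spec$tau_mean + ar1_series(n_days, spec$tau_ar1,
                                              spec$tau_sd), 0.2), 1)
  wet <- logical(n_days)
  wet[1] <- stats::runif(1) < spec$p_wet_dry
  u <- stats::runif(n_days)
  for (d in 2:n_days) {
    wet[d] <- u[d] < (if (wet[d - 1]) spec$p_wet_wet else spec$p_wet_dry)
  }
  tau[wet] <- tau[wet] * stats::runif(sum(wet), 0.45, 0.8)
  t_season <- spec$t_annual_mean + spec$t_annual_amplitude *
    cos(2 * pi * (seq_len(n_days) - spec$t_peak_doy) / 365)
  t_day <- t_season + ar1_series(n_days, spec$t_day_ar1, spec$t_day_sd) +
    1.5 * (tau - spec$tau_mean)
  rh_day <- pmin(pmax(0.72 + 0.18 * wet - 0.25 * (tau - spec$tau_mean) +
                        stats::rnorm(n_days, 0, 0.06), 0.3), 0.98)
  ws_day <- pmin(exp(stats::rnorm(n_days, 1.0, 0.4)), 18)

  # hourly fields (365 x 24 matrices)
  cosz <- outer(seq_len(n_days), hours, function(d, h) {
    cos(solar_zenith(d, h, spec$latitude) * pi / 180)
  })
  cosz[cosz < 0] <- 0
  q <- spec$q_clear_max * cosz * tau *
    matrix(exp(stats::rnorm(n_days * 24, 0, 0.06)), n_days, 24)
  q[cosz == 0] <- 0
  dtr <- 5 + 5 * tau
  diurnal <- outer(dtr / 2, cos(2 * pi * (hours - 15) / 24))
  t_air <- t_day + diurnal
  rh <- pmin(pmax(rh_day - 0.022 * (t_air - t_day), 0.15), 0.99)
  ws <- pmin(pmax(ws_day * matrix(exp(stats::rnorm(n_days * 24, 0, 0.25)),
                                  n_days, 24), 0.1), 25)
  precip <- matrix(0, n_days, 24)
  for (d in which(wet)) {
    depth <- stats::rgamma(1, spec$rain_shape, scale = spec$rain_scale)
    n_ev <- 1 + stats::rpois(1, 1.5)
    hrs <- sample.int(24, min(n_ev, 24)) - 1
    share <- stats::rexp(length(hrs))
    precip[d, hrs + 1] <- depth * share / sum(share)
  }

  tibble::tibble(
    year = year,
    doy = rep(seq_len(n_days), each = 24),
    hour = rep(hours, n_days),
    q = as.vector(t(q)),
    t_air = as.vector(t(t_air)),
    rh = as.vector(t(rh)),
    ws = as.vector(t(ws)),
    precip = as.vector(t(precip))
  )
}

#' Generate a synthetic multi-year hourly weather archive
#'
#' Produces an archive with realistic statistical structure: clear-sky
#' diurnal PPFD shaped by solar geometry and multiplied by an
#' autocorrelated day-level cloudiness factor; air temperature as a
#' seasonal sinusoid plus an autocorrelated daily anomaly and a diurnal
#' cycle lagging radiation by ~3 h; within-day relative humidity
#' anti-correlated with temperature; precipitation from a two-state
#' occurrence chain with wet days both cloudier and more humid; and
#' year-level temperature/radiation anomalies for interannual
#' variability. Nighttime PPFD is exactly zero. Years are 365 days (no
#' leap days). The result is reproducible for a fixed seed.
#'
#' @param n_years Number of years to generate (years are labelled
#'   `2001, 2002, ...` unless `start_year` is given).
#' @param seed Integer seed controlling all randomness.
#' @param spec A [climate_spec()].
#' @param start_year First year label.
#' @return A `weather_archive` tibble.
#' @examples
#' arch <- generate_archive(2, seed = 1)
#' range(arch$t_air)
#' @export
generate_archive <- function(n_years, seed = 1L, spec = climate_spec(),
                             start_year = 2001L) {
  stopifnot(n_years >= 1, inherits(spec, "climate_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  years <- lapply(seq_len(n_years), function(i) {
    yr_spec <- spec
    yr_spec$t_annual_mean <- spec$t_annual_mean +
      stats::rnorm(1, 0, spec$year_t_sd)
    yr_spec$q_clear_max <- spec$q_clear_max *
      max(stats::rnorm(1, 1, spec$year_tau_sd), 0.8)
    generate_year(start_year + i - 1L, yr_spec)
  })
  as_weather_archive(do.call(rbind, years))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Deterministic counter scheme expanding one master seed into
# per-replicate child seeds (kept below 2^31).
child_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 48271 + i * 9973) %% 2147483587)
}

#' Day-block bootstrap of a weather archive
#'
#' Builds one synthetic year by drawing, independently for every day of
#' year, that day's complete 24-hour record (all climate variables
#' together) from a uniformly random archive year. Sampling whole
#' day-blocks preserves the diurnal cycles and the within-day
#' correlations between the drivers (e.g. sunlight with temperature,
#' precipitation with humidity). Day 366 is drawn only from leap years
#' present in the archive and is dropped when there are none.
#'
#' @param archive A `weather_archive` with at least one year.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A tibble with columns `doy`, `hour`, the five drivers, and
#'   `source_year` (the archive year each day was copied from);
#'   attributes `seed`.
#' @examples
#' arch <- generate_archive(2, seed = 1)
#' by <- bootstrap_year(arch, seed = 7)
#' all(tapply(by$source_year, by$doy, function(x) length(unique(x))) == 1)
#' @export
bootstrap_year <- function(archive, seed) {
  if (nrow(archive) == 0) stop("empty weather archive", call. = FALSE)
  years <- sort(unique(archive$year))
  doys <- sort(unique(archive$doy))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  ord <- order(archive$year, archive$doy, archive$hour)
  arch <- archive[ord, ]
  key <- paste(arch$year, arch$doy)
  first_row <- match(paste(rep(years, each = length(doys)),
                           rep(doys, length(years))), key)
  names(first_row) <- paste(rep(years, each = length(doys)),
                            rep(doys, length(years)))

  picked <- integer(0)
  src <- integer(0)
  for (d in doys) {
    pool <- if (d == 366) {
      years[!is.na(first_row[paste(years, d)])]
    } else years
    if (length(pool) == 0) next  # no leap year in archive: drop doy 366
    y <- pool[sample.int(length(pool), 1)]
    r0 <- first_row[[paste(y, d)]]
    picked <- c(picked, r0:(r0 + 23))
    src <- c(src, rep(y, 24))
  }
  out <- arch[picked, c("doy", "hour", "q", "t_air", "rh", "ws", "precip")]
  out$source_year <- src
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Per-phase climate driver summaries
#'
#' Summarises the drivers over development-phase windows: arithmetic
#' means for PPFD, temperature, relative humidity and wind speed, and
#' the *total* for precipitation (seasonal rain depth, not its hourly
#' mean, is the agronomically meaningful quantity; switch with
#' `precip_total = FALSE`).
#'
#' @param weather_year A single-year hourly weather table (`doy`,
#'   `hour`, drivers).
#' @param phase_windows Named list of `c(first_doy, last_doy)` windows
#'   (inclusive), e.g. `list(vegetative = c(152, 209), reproductive =
#'   c(210, 270))`.
#' @param precip_total Report precipitation as a window total (default)
#'   rather than an hourly mean.
#' @return A tibble with one row per phase: `phase`, `q`, `t_air`,
#'   `precip`, `rh`, `ws`, `n_hours`.
#' @export
phase_driver_means <- function(weather_year, phase_windows,
                               precip_total = TRUE) {
  stopifnot(length(phase_windows) >= 1, !is.null(names(phase_windows)))
  rows <- lapply(names(phase_windows), function(ph) {
    w <- phase_windows[[ph]]
    sel <- weather_year$doy >= w[1] & weather_year$doy <= w[2]
    if (!any(sel)) {
      stop("phase window `", ph, "` contains no weather records",
           call. = FALSE)
    }
    d <- weather_year[sel, ]
    tibble::tibble(
      phase = ph,
      q = mean(d$q),
      t_air = mean(d$t_air),
      precip = if (precip_total) sum(d$precip) else mean(d$precip),
      rh = mean(d$rh),
      ws = mean(d$ws),
      n_hours = nrow(d)
    )
  })
  do.call(rbind, rows)
}
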