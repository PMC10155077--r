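#' Relative change against a control
#'
#' `100 * (value - control) / |control|` percent. The absolute-value
#' denominator keeps the sign of the numerator even for negative
#' controls. A zero control yields `NA` (undefined).
#'
#' @param value Scenario value(s).
#' @param control Control value(s).
#' @return Percent change, same length as the inputs.
#' @examples
#' relative_change(7.0, 6.6)   # +6.06
#' relative_change(-2, -4)     # +50: sign follows the numerator
#' @export
relative_change <- function(value, control) {
  ifelse(control == 0, NA_real_, 100 * (value - control) / abs(control))
}

#' Scaling-grid experiment design
#'
#' The factorial design of the sensitivity experiments: percent changes
#' applied independently to Vcmax and Jmax, crossed with ambient CO2
#' levels. The control (0%, 0%) must be part of the grid.
#'
#' @param from,to,by Percent-change range and step (defaults -50 to
#'   +50 by 5).
#' @param co2_levels CO2 levels, umol mol-1.
#' @return A list of class `scaling_grid` with `scale_pct` (percent),
#'   `scales` (multipliers, control = 1) and `co2_levels`.
#' @export
scaling_grid <- function(from = -50, to = 50, by = 5,
                         co2_levels = c(400, 600, 800, 1000)) {
  pct <- seq(from, to, by)
  if (!any(abs(pct) < 1e-9)) {
    stop("the control (0%) must be part of the scaling grid", call. = FALSE)
  }
  if (is.unsorted(pct, strictly = TRUE)) {
    stop("scales must be strictly increasing", call. = FALSE)
  }
  structure(list(scale_pct = pct, scales = 1 + pct / 100,
                 co2_levels = co2_levels),
            class = "scaling_grid")
}

season_summary_vars <- c("pod", "shoot", "max_lai", "mean_daily_max_an",
                         "mean_daily_mean_an", "mean_wue")

#' Run the scaling-grid sensitivity experiment
#'
#' Simulates one season per (year, Vcmax scale, Jmax scale, CO2 level)
#' and averages the six summary variables (pod, shoot, max LAI, mean
#' daily-max An, mean daily-mean An, mean WUE) over the archive years.
#' Every cell shares the weather with the control, so the relative
#' changes are paired by construction. With `cache_dir` set, each
#' (scale, CO2) cell is cached on disk keyed by a hash of all inputs,
#' making large grids resumable.
#'
#' @param archive A `weather_archive`.
#' @param grid A [scaling_grid()].
#' @param params,arch,schedule Model configuration (defaults used when
#'   omitted).
#' @param cache_dir Optional directory for cell-level caching.
#' @return A tibble of class `sens_surfaces` in long format:
#'   `scale_v`, `scale_j` (multipliers), `co2`, `variable`, `mean`
#'   (multi-year mean) and `relchange` (percent vs the control cell,
#'   exactly 0 at the control).
#' @export
run_grid <- function(archive, grid, params = leaf_params(),
                     arch = canopy_arch(), schedule = crop_schedule(),
                     cache_dir = NULL) {
  stopifnot(inherits(grid, "scaling_grid"))
  years <- unique(archive$year)
  cells <- expand.grid(sv = grid$scales, sj = grid$scales,
                       co2 = grid$co2_levels)
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  run_cell <- function(sv, sj, co2) {
    key <- NULL
    if (!is.null(cache_dir)) {
      key <- file.path(cache_dir, paste0(
        rlang::hash(list(archive, params, arch, schedule, sv, sj, co2)),
        ".rds"))
      if (file.exists(key)) return(readRDS(key))
    }
    per_year <- vapply(years, function(yr) {
      res <- tryCatch(
        simulate_season(archive[archive$year == yr, ], co2 = co2,
                        params = params, arch = arch, schedule = schedule,
                        scale_v = sv, scale_j = sj),
        error = function(e) {
          stop(sprintf(
            "grid cell (scale_v=%.2f, scale_j=%.2f, co2=%g, year=%s) failed: %s",
            sv, sj, co2, yr, conditionMessage(e)), call. = FALSE)
        })
      unlist(res$summary[season_summary_vars])
    }, numeric(length(season_summary_vars)))
    cell <- rowMeans(per_year)
    if (!is.null(key)) saveRDS(cell, key)
    cell
  }
  vals <- mapply(run_cell, cells$sv, cells$sj, cells$co2)
  long <- tibble::tibble(
    scale_v = rep(cells$sv, each = length(season_summary_vars)),
    scale_j = rep(cells$sj, each = length(season_summary_vars)),
    co2 = rep(cells$co2, each = length(season_summary_vars)),
    variable = rep(season_summary_vars, nrow(cells)),
    mean = as.vector(vals)
  )
  ctl <- long[abs(long$scale_v - 1) < 1e-9 & abs(long$scale_j - 1) < 1e-9, ]
  ctl_val <- ctl$mean[match(paste(long$co2, long$variable),
                            paste(ctl$co2, ctl$variable))]
  long$relchange <- relative_change(long$mean, ctl_val)
  class(long) <- c("sens_surfaces", class(long))
  long
}

#' Limiting-rate frequencies and Ci histogram
#'
#' Audits the hourly top-layer sunlit leaf record of a season: how many
#' daylight hours each FvCB process (Rubisco, RuBP regeneration, TPU)
#' was the limiting rate, and the distribution of intercellular CO2.
#'
#' @param season A `season_result` run with `keep_traces = TRUE`.
#' @param bin_width Ci histogram bin width, umol mol-1.
#' @return A list with `counts` (named: rubisco, rubp, tpu over daylight
#'   hours) and `ci_hist` (tibble `bin_lo`, `bin_hi`, `count`).
#' @export
limiting_frequency <- function(season, bin_width = 50) {
  tr <- season$trace
  if (is.null(tr)) {
    stop("season was run without trace retention; re-run simulate_season() ",
         "with keep_traces = TRUE", call. = FALSE)
  }
  counts <- c(rubisco = sum(tr$limiting == "rubisco"),
              rubp = sum(tr$limiting == "rubp"),
              tpu = sum(tr$limiting == "tpu"))
  edges <- seq(0, ceiling(max(tr$ci) / bin_width) * bin_width, bin_width)
  bins <- cut(tr$ci, edges, right = FALSE, include.lowest = TRUE)
  list(counts = counts,
       ci_hist = tibble::tibble(bin_lo = edges[-length(edges)],
                                bin_hi = edges[-1],
                                count = as.integer(table(bins))))
}

#' Bootstrap climate ensemble of paired control/scaled seasons
#'
#' Draws `n` bootstrap years from the archive (day-block resampling,
#' one child seed per replicate expanded deterministically from the
#' master seed), runs a control and a capacity-scaled season on each
#' (same weather in the pair), and collects the relative pod and
#' max-LAI changes together with the per-phase climate driver
#' summaries of each replicate (phases from the control run's own
#' predicted development windows). Replicates are split into the lower
#' and upper quartile of the pod gain (`set25`/`set75`, each exactly
#' `floor(n/4)` members), and the Pearson correlation between the LAI
#' and pod gains is reported.
#'
#' @param archive A `weather_archive` (two or more years).
#' @param n Number of bootstrap replicates (at least 4).
#' @param master_seed Integer master seed.
#' @param co2 Ambient CO2, umol mol-1.
#' @param scales Length-2 multipliers `c(scale_v, scale_j)`.
#' @param params,arch,schedule Model configuration.
#' @return An object of class `bootstrap_ensemble`: list with
#'   `replicates` (tibble: `replicate`, `seed`, `dpod`, `dlai`,
#'   `pod_ctl`, `pod_scaled`, per-phase driver columns `q_1`, `t_air_1`,
#'   `precip_1`, `rh_1`, `ws_1` and the same with suffix `_2`, and
#'   `set` membership), `cor` (list `r`, `p`), `n`, `master_seed`,
#'   `co2`, `scales`.
#' @export
run_bootstrap_ensemble <- function(archive, n = 1000, master_seed = 1,
                                   co2 = 400, scales = c(1.2, 1.2),
                                   params = leaf_params(),
                                   arch = canopy_arch(),
                                   schedule = crop_schedule()) {
  if (length(unique(archive$year)) < 2) {
    stop("bootstrap ensemble needs an archive with at least 2 years",
         call. = FALSE)
  }
  if (n < 4) stop("quartile split refused for n < 4", call. = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- child_seed(master_seed, i)
    by <- bootstrap_year(archive, seed_i)
    ctl <- simulate_season(by, co2 = co2, params = params, arch = arch,
                           schedule = schedule)
    scl <- simulate_season(by, co2 = co2, params = params, arch = arch,
                           schedule = schedule,
                           scale_v = scales[1], scale_j = scales[2])
    ph <- phase_driver_means(by, ctl$phase_windows)
    drv <- stats::setNames(
      as.vector(t(as.matrix(ph[, c("q", "t_air", "precip", "rh", "ws")]))),
      paste(rep(c("q", "t_air", "precip", "rh", "ws"), nrow(ph)),
            rep(seq_len(nrow(ph)), each = 5), sep = "_"))
    rows[[i]] <- c(replicate = i, seed = seed_i,
                   dpod = relative_change(scl$summary$pod, ctl$summary$pod),
                   dlai = relative_change(scl$summary$max_lai,
                                          ctl$summary$max_lai),
                   pod_ctl = ctl$summary$pod, pod_scaled = scl$summary$pod,
                   drv)
  }
  reps <- tibble::as_tibble(do.call(rbind, rows))
  k <- floor(n / 4)
  rk <- rank(reps$dpod, ties.method = "first")
  reps$set <- ifelse(rk <= k, "set-25",
                     ifelse(rk > n - k, "set-75", "mid"))
  ct <- stats::cor.test(reps$dlai, reps$dpod)
  structure(list(replicates = reps,
                 cor = list(r = unname(ct$estimate), p = ct$p.value),
                 n = n, master_seed = master_seed, co2 = co2,
                 scales = scales),
            class = "bootstrap_ensemble")
}

#' @export
print.bootstrap_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<bootstrap_ensemble> n %d, co2 %g ppm, scales ",
                     "(%.2f, %.2f)\n  dpod %% range [%.2f, %.2f]; ",
                     "cor(dlai, dpod) r = %.3f (p = %.3g)\n"),
              x$n, x$co2, x$scales[1], x$scales[2],
              min(x$replicates$dpod), max(x$replicates$dpod),
              x$cor$r, x$cor$p))
  invisible(x)
}

#' Partial rank correlation coefficients
#'
#' For each driver, the PRCC is the Pearson correlation between the
#' residuals of the driver's ranks and of the response's ranks, after
#' both are regressed (with intercept) on the ranks of all the other
#' drivers. P-values use the t transform with `n - (k - 1) - 2` degrees
#' of freedom, where `k` is the number of drivers.
#'
#' @param drivers A data frame or matrix of driver columns (n x k,
#'   k >= 1, full column rank after rank transform).
#' @param response Numeric response vector, length n.
#' @return A tibble of class `prcc_result`: `driver`, `coefficient`,
#'   `p_value`, `n`, `df`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' prcc(x, x[, 1] - 2 * x[, 2] + rnorm(100, 0, 0.1))
#' @export
prcc <- function(drivers, response) {
  x <- as.matrix(drivers)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  n <- nrow(x)
  k <- ncol(x)
  stopifnot(length(response) == n)
  if (n < 10) stop("PRCC needs at least 10 replicates", call. = FALSE)
  rx <- apply(x, 2, rank)
  ry <- rank(response)
  qrx <- qr(cbind(1, rx))
  if (qrx$rank < k + 1) {
    drop_idx <- qrx$pivot[(qrx$rank + 1):(k + 1)] - 1
    stop("rank-deficient drivers after rank transform: ",
         paste(colnames(x)[drop_idx[drop_idx > 0]], collapse = ", "),
         call. = FALSE)
  }
  df <- n - (k - 1) - 2
  out <- lapply(seq_len(k), function(j) {
    others <- cbind(1, rx[, -j, drop = FALSE])
    res_j <- stats::lm.fit(others, rx[, j])$residuals
    res_y <- stats::lm.fit(others, ry)$residuals
    r <- stats::cor(res_j, res_y)
    t_stat <- r * sqrt(df / (1 - r^2))
    tibble::tibble(driver = colnames(x)[j], coefficient = r,
                   p_value = 2 * stats::pt(-abs(t_stat), df),
                   n = n, df = df)
  })
  out <- do.call(rbind, out)
  class(out) <- c("prcc_result", class(out))
  out
}

#' Per-phase PRCC attribution of pod gains to climate drivers
#'
#' Runs [prcc()] of the ensemble's pod gains on the five climate
#' drivers (PPFD, temperature, precipitation total, relative humidity,
#' wind speed), separately for the vegetative (phase 1) and
#' reproductive (phase 2) windows. P-values are reported raw
#' (unadjusted).
#'
#' @param ensemble A [run_bootstrap_ensemble()] result.
#' @return A tibble: `driver`, `phase`, `coefficient`, `p_value`, `n`.
#' @export
prcc_by_phase <- function(ensemble) {
  stopifnot(inherits(ensemble, "bootstrap_ensemble"))
  reps <- ensemble$replicates
  out <- lapply(1:2, function(ph) {
    cols <- paste(c("q", "t_air", "precip", "rh", "ws"), ph, sep = "_")
    pr <- prcc(reps[cols], reps$dpod)
    pr$driver <- c("Q", "T", "P", "RH", "WS")
    pr$phase <- ph
    pr[c("driver", "phase", "coefficient", "p_value", "n")]
  })
  do.call(rbind, out)
}
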