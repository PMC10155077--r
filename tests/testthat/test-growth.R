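test_that("thermal time accumulates linearly above base", {
  expect_equal(thermal_time_step(10, 1, 10), 0)
  expect_equal(thermal_time_step(5, 1, 10), 0)
  expect_equal(thermal_time_step(34, 1, 10), 1)
  # hourly increments integrate a fixed 24-h trace exactly
  trace <- 15 + 8 * sin(2 * pi * (0:23) / 24)
  hourly <- sum(thermal_time_step(trace, 1, 10))
  expect_equal(hourly, sum(pmax(trace - 10, 0)) / 24, tolerance = 1e-12)
})

test_that("development phase is monotone with a closed boundary", {
  sched <- default_schedule
  expect_identical(development_phase(0, sched), "vegetative")
  expect_identical(development_phase(sched$tt_repro, sched), "reproductive")
  expect_identical(development_phase(sched$tt_repro - 1e-9, sched),
                   "vegetative")
  tt <- seq(0, 2000, 10)
  ph <- development_phase(tt, sched)
  expect_true(all(diff(ph == "reproductive") >= 0))
})

test_that("partition fractions are a normalized schedule with gated pod", {
  sched <- default_schedule
  for (tt in seq(0, 1800, 50)) {
    fr <- partition_fractions(tt, sched)
    expect_true(all(fr >= 0))
    expect_equal(sum(fr), 1, tolerance = 1e-9)
    if (tt < sched$tt_repro) expect_equal(fr[["pod"]], 0)
  }
  # pod share rises through the reproductive phase and dominates late
  tts <- seq(sched$tt_repro, sched$tt_mature, 25)
  pods <- vapply(tts, function(tt) partition_fractions(tt, sched)[["pod"]],
                 numeric(1))
  expect_true(all(diff(pods) > 0))
  late <- partition_fractions(1450, sched)
  expect_gt(late[["pod"]], late[["leaf"]])
})

test_that("growth steps conserve carbon exactly", {
  sched <- default_schedule
  pools <- function(s) s$biomass_leaf + s$biomass_stem + s$biomass_root +
    s$biomass_pod + s$labile + s$senesced_leaf
  maint <- function(s, t_air) {
    mc <- sched$maint_coef
    (mc[["stem"]] * s$biomass_stem + mc[["root"]] * s$biomass_root +
        mc[["pod"]] * s$biomass_pod) *
      sched$maint_q10^((t_air - 25) / 10) / 24
  }
  st <- crop_state(sched)
  st$thermal_time <- 400  # vegetative, before senescence
  # zero flux: only the maintenance bookkeeping moves carbon
  st0 <- grow_step(st, list(an_ground = 0), 1, sched, t_air = sched$t_base)
  expect_equal(pools(st0) - pools(st), -maint(st, sched$t_base),
               tolerance = 1e-12)
  # positive flux: gain = efficiency x assimilate - maintenance, exactly
  an <- 20
  st1 <- grow_step(st, list(an_ground = an), 1, sched, t_air = sched$t_base)
  expect_equal(pools(st1) - pools(st),
               sched$growth_efficiency * an * sched$carbon_per_umol -
                 maint(st, sched$t_base),
               tolerance = 1e-12)
  # negative flux: pools pay back the full deficit one to one
  st2 <- grow_step(st1, list(an_ground = -5), 1, sched, t_air = sched$t_base)
  expect_equal(pools(st2) - pools(st1),
               -5 * sched$carbon_per_umol - maint(st1, sched$t_base),
               tolerance = 1e-12)
  # senescence moves mass between pools without destroying it
  st$thermal_time <- sched$tt_sen_onset + 300
  st3 <- grow_step(st, list(an_ground = an), 1, sched, t_air = sched$t_base)
  expect_equal(pools(st3) - pools(st),
               sched$growth_efficiency * an * sched$carbon_per_umol -
                 maint(st, sched$t_base),
               tolerance = 1e-12)
  expect_gt(st3$senesced_leaf, 0)
})

test_that("repeated small steps equal one large step within a stage", {
  sched <- crop_schedule(maint_coef = c(stem = 0, root = 0, pod = 0))
  st <- crop_state(sched)
  st$thermal_time <- 500
  st$labile <- 5  # saturate the labile target so allocation is organ-only
  many <- st
  for (i in 1:10) {
    many <- grow_step(many, list(an_ground = 3), 1, sched,
                      t_air = sched$t_base)
  }
  once <- grow_step(st, list(an_ground = 30), 1, sched, t_air = sched$t_base)
  expect_equal(many$biomass_leaf, once$biomass_leaf, tolerance = 1e-10)
  expect_equal(many$biomass_pod, once$biomass_pod, tolerance = 1e-10)
})

test_that("season simulation is deterministic and rejects gappy weather", {
  r1 <- simulate_season(fix_year1, co2 = 400)
  r2 <- simulate_season(fix_year1, co2 = 400)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$daily, r2$daily)

  broken <- fix_year1[!(fix_year1$doy == 200 & fix_year1$hour == 13), ]
  expect_error(simulate_season(broken, co2 = 400), "200 13")
})

test_that("a typical synthetic season lands in the observed soybean regime", {
  r <- simulate_season(fix_year1, co2 = 400)
  s <- r$summary
  expect_gt(s$pod, 4)
  expect_lt(s$pod, 9)
  expect_gt(s$max_lai, 4)
  expect_lt(s$max_lai, 9)
  expect_lte(s$pod, s$shoot)
  expect_equal(s$max_lai, max(r$daily$lai))
  # reproductive onset in the mid-season window, pod filling afterwards
  expect_gt(r$phase_windows$reproductive[1], 180)
  expect_lt(r$phase_windows$reproductive[1], 230)
  # max LAI at or before senescence has finished
  expect_lt(r$daily$lai[nrow(r$daily)], s$max_lai)
})

test_that("CO2 enrichment and capacity scaling push the season the right way", {
  ctl <- simulate_season(fix_year1, co2 = 400)
  high <- simulate_season(fix_year1, co2 = 800)
  expect_gte(high$summary$pod, ctl$summary$pod)

  v20 <- simulate_season(fix_year1, co2 = 400, scale_v = 1.2, scale_j = 1.2)
  rel <- function(v) {
    relative_change(v20$summary[[v]], ctl$summary[[v]])
  }
  expect_gt(rel("pod"), 0)
  # attenuation chain: daily-max An gain >= daily-mean An gain >= pod gain
  expect_gte(rel("mean_daily_max_an"), rel("mean_daily_mean_an"))
  expect_gte(rel("mean_daily_mean_an"), rel("pod"))
})
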