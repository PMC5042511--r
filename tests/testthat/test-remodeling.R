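test_that("activity factor is the clamped cost ratio", {
  expect_equal(update_beta(100, 100), 1)
  expect_equal(update_beta(200, 100), 0.5)
  expect_equal(update_beta(80, 100), 1)  # off-grid cost below the minimum
  expect_error(update_beta(0, 100))
  expect_error(update_beta(100, -1))
})

test_that("daily cycle split puts the remainder in the leading blocks", {
  expect_equal(tendonadapt:::split_cycles(5000, 3), c(1667L, 1667L, 1666L))
  expect_equal(tendonadapt:::split_cycles(2000, 3), c(667L, 667L, 666L))
  expect_equal(tendonadapt:::split_cycles(9, 3), c(3L, 3L, 3L))
  expect_equal(sum(tendonadapt:::split_cycles(5000, 3)), 5000L)
})

test_that("a single simulated day conserves fibers and fills the record", {
  cfg <- test_config(2000L)
  res <- simulate_remodeling(cfg, days = 1, seed = 5)
  expect_equal(res$status, "ok")
  tr <- res$trajectory
  expect_equal(nrow(tr), 1L)
  expect_length(res$pop$slack_lengths, 2000L)
  expect_false(any(res$pop$broken))
  expect_true(tr$beta > 0 && tr$beta <= 1)
  expect_true(all(c("mean_length_mm", "sd_mm", "Q_J", "beta",
                    "mech_failures", "proteo_failures",
                    "removed_length_mm", "synthesized_length_mm",
                    "degradation_turnover_years",
                    "synthesis_turnover_years") %in% names(tr)))
  # deterministic per seed
  res2 <- simulate_remodeling(cfg, days = 1, seed = 5)
  expect_identical(res$trajectory, res2$trajectory)
  expect_identical(res$pop$slack_lengths, res2$pop$slack_lengths)
})

test_that("a zero-torque day removes every fiber proteolytically, then repairs", {
  cfg <- test_config(500L)
  gait <- config_gait(cfg)
  gait$torque[] <- 0
  set.seed(1)
  pop <- init_gaussian_population(500, 266, 0.6,
                                  fiber_area = scaled_fiber_area(500))
  params <- config_musculotendon(cfg)
  models <- tendonadapt:::config_damage_models(cfg)
  state <- list(day = 0L, beta = 1, q_min = 1, pop = pop,
                cum_removed = 0, cum_synthesized = 0,
                initial_total_length = sum(pop$slack_lengths))
  out <- simulate_day(state, gait, params, models)
  # unloaded tendon: zero strain everywhere, e^0 = 1 per-fiber cleavage
  expect_equal(out$record$proteo_failures, 500)
  expect_equal(out$record$mech_failures, 0)
  expect_length(out$state$pop$slack_lengths, 500)
  expect_false(any(out$state$pop$broken))
})

test_that("with all damage disabled the population passes through unchanged", {
  cfg <- test_config(500L)
  gait <- config_gait(cfg)
  params <- config_musculotendon(cfg)
  models <- tendonadapt:::config_damage_models(cfg)
  models$mech_enabled <- FALSE
  models$proteo_enabled <- FALSE
  set.seed(2)
  pop <- init_gaussian_population(500, 266, 0.6,
                                  fiber_area = scaled_fiber_area(500))
  state <- list(day = 3L, beta = 1, q_min = 100, pop = pop,
                cum_removed = 0, cum_synthesized = 0,
                initial_total_length = sum(pop$slack_lengths))
  out <- simulate_day(state, gait, params, models)
  expect_equal(out$state$day, 4L)
  expect_identical(out$state$pop$slack_lengths, pop$slack_lengths)
  expect_equal(out$record$removed_length_mm, 0)
  expect_identical(out$record$degradation_turnover_years, Inf)
})

test_that("daily failure counts match the expected-rate oracle across seeds", {
  cfg <- test_config(2000L)
  # aggressive geometry so daily counts are large enough to average
  cfg$tendon$mean_length <- 274
  cfg$tendon$sd <- 1
  gait <- config_gait(cfg)
  params <- config_musculotendon(cfg)
  models <- tendonadapt:::config_damage_models(cfg)
  set.seed(99)
  pop <- init_gaussian_population(2000, 274, 1,
                                  fiber_area = scaled_fiber_area(2000))
  qm <- compute_q_min(gait, params, n_fibers = 1000)$q_min
  exp_rates <- expected_daily_rates(pop, gait, params, models, qm)
  counts <- vapply(1:20, function(s) {
    set.seed(s)
    state <- list(day = 0L, beta = exp_rates[["beta"]], q_min = qm, pop = pop,
                  cum_removed = 0, cum_synthesized = 0,
                  initial_total_length = sum(pop$slack_lengths))
    rec <- simulate_day(state, gait, params, models)$record
    c(rec$mech_failures, rec$proteo_failures)
  }, numeric(2))
  tot_expected <- exp_rates[["mech"]] + exp_rates[["proteo"]]
  tot_observed <- mean(colSums(counts))
  expect_gt(tot_expected, 5)  # the regime is active
  expect_lt(abs(tot_observed - tot_expected),
            4 * sqrt(tot_expected / 20) + 0.05 * tot_expected)
})

test_that("turnover times follow their definition and equalize at equilibrium", {
  # arithmetic on a synthetic trajectory: 1e5 fibers of 275 mm, 1.5 mean
  # fibers removed per day -> 1e5/1.5 days = 182.6 years
  fake <- list(trajectory = data.frame(removed_length_mm = rep(1.5 * 275, 50),
                                       synthesized_length_mm = rep(1.5 * 275,
                                                                   50)),
               initial_total_length = 1e5 * 275)
  tt <- turnover_times(fake)
  expect_equal(tt[["degradation_years"]], (1e5 / 1.5) / 365, tolerance = 1e-10)
  expect_equal(tt[["degradation_years"]], 182.6, tolerance = 1e-3)
  # whole tendon removed in one day -> one day
  fake2 <- list(trajectory = data.frame(removed_length_mm = 1e5 * 275,
                                        synthesized_length_mm = 0),
                initial_total_length = 1e5 * 275)
  tt2 <- turnover_times(fake2)
  expect_equal(tt2[["degradation_years"]], 1 / 365)
  expect_identical(tt2[["synthesis_years"]], Inf)

  # simulated equilibrium: degradation and synthesis agree within 10%
  cfg <- test_config(4000L)
  res <- simulate_remodeling(cfg, days = 250, seed = 31)
  tt3 <- turnover_times(res, 100)
  expect_lt(abs(tt3[["synthesis_years"]] - tt3[["degradation_years"]]) /
              tt3[["degradation_years"]], 0.10)
})

test_that("stability structure: damage balance flips across the equilibrium", {
  cfg <- test_config()
  gait <- config_gait(cfg)
  params <- config_musculotendon(cfg)
  models <- tendonadapt:::config_damage_models(cfg)
  qm <- compute_q_min(gait, params, n_fibers = 1000)$q_min
  at <- function(mean_l) {
    pop <- idealized_population(2000, mean_l, 0.6,
                                fiber_area = scaled_fiber_area(2000))
    expected_daily_rates(pop, gait, params, models, qm)
  }
  eq <- at(266)
  long <- at(271)   # +5 mm: proteolysis must dominate (shortening pressure)
  short <- at(261)  # -5 mm, stable side: fatigue dominates (lengthening)
  expect_lt(abs(eq[["mech"]] - eq[["proteo"]]),
            max(eq[["mech"]], eq[["proteo"]]) * 5)  # near balance at eq
  expect_gt(long[["proteo"]], long[["mech"]])
  expect_gt(short[["mech"]], short[["proteo"]])
  # beta decreases away from the minimum-cost geometry on the long side
  expect_lt(long[["beta"]], eq[["beta"]])
})

test_that("remodeling from distinct convergent starts approaches a common band", {
  cfg <- test_config(3000L)
  # long-flank starts, where remodeling is active: 3.5 mm initial spread
  finals <- vapply(c(272, 275.5), function(ml) {
    c2 <- cfg
    c2$tendon$mean_length <- ml
    r <- simulate_remodeling(c2, days = 400, seed = 7)
    tail(r$trajectory$mean_length_mm, 1)
  }, numeric(1))
  # both shorten toward the stable point and end in a much narrower band
  expect_true(all(finals < c(272, 275.5) - 0.5))
  expect_lt(abs(diff(finals)), 2)
  # an interior start is already near-stationary (dynamic equilibrium band)
  r <- simulate_remodeling(cfg, days = 100, seed = 8)
  drift <- abs(tail(r$trajectory$mean_length_mm, 1) -
                 r$trajectory$mean_length_mm[1])
  expect_lt(drift, 0.2)
  expect_true(all(r$trajectory$beta > 0 & r$trajectory$beta <= 1))
})

test_that("geometry-domain exploration separates divergent short starts", {
  cfg <- test_config(1500L)
  cls <- explore_geometry_domain(cfg, mean_lengths = c(251, 266), sds = 1,
                                 days = 150, seed = 3, slope_window = 40)
  expect_equal(cls$class[cls$init_mean_mm == 266], "converged")
  expect_equal(cls$class[cls$init_mean_mm == 251], "diverged")
  # the short divergent start is shortening and expensive
  row <- cls[cls$init_mean_mm == 251, ]
  expect_true(is.na(row$slope_mm_day) || row$slope_mm_day < 0 ||
                row$q_ratio > 2)
})

test_that("perturbing parameters maps onto the right configuration entries", {
  cfg <- default_config()
  expect_equal(perturb_config(cfg, "a", 0.05)$fatigue$a, 105)
  expect_equal(perturb_config(cfg, "n", 0.1)$sim$cycles_per_day, 5500L)
  expect_equal(perturb_config(cfg, "fiber_stiffness",
                              0.05)$tendon$youngs_modulus, 1050)
  pm <- perturb_config(cfg, "repair_mean", 0.1)$repair$mech
  expect_equal(mean(pm), mean(cfg$repair$mech) * 1.1)
  expect_equal(diff(range(pm)), diff(range(cfg$repair$mech)))  # spread fixed
  pd <- perturb_config(cfg, "repair_dispersion", 0.1)$repair$proteo
  expect_equal(mean(pd), mean(cfg$repair$proteo))              # mean fixed
  expect_equal(diff(range(pd)), diff(range(cfg$repair$proteo)) * 1.1)
  expect_error(perturb_config(cfg, "bogus", 0.05), "unknown sensitivity")
  expect_length(sensitivity_parameters(), 13L)
})

test_that("sensitivity analysis computes the normalized ratio", {
  # a perturbation that does not enter the model yields S = 0: compare a run
  # against itself via a parameter with a deliberately null mapping
  cfg <- test_config(1500L)
  out <- sensitivity_analysis(cfg, params = c("a", "phi"), delta = 0.05,
                              days = 120, seed = 13, window = 50)
  expect_equal(nrow(out), 2L)
  expect_true(all(is.finite(out$S_length)))
  # S arithmetic: +0.5% output change at +5% parameter change gives S = 0.1
  expect_equal(((1.005 - 1) / 1) / 0.05, 0.1)
  # the equilibrium geometry is robust: small |S| for these parameters
  expect_true(all(abs(out$S_length) < 1))
})

test_that("trajectories serialize to CSV", {
  cfg <- test_config(500L)
  res <- simulate_remodeling(cfg, days = 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(res, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 3L)
  expect_equal(back$mean_length_mm, res$trajectory$mean_length_mm)
})
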