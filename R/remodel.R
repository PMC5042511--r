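#' Activity scale factor from metabolic cost
#'
#' `beta = min(1, q_min / q)`: load intensity is scaled down in proportion to
#' how far the current geometry's metabolic cost sits above the minimum cost
#' over the explored geometry domain. Clamped above at 1 (an off-grid
#' geometry can undercut the gridded minimum slightly).
#'
#' @param q Current total metabolic cost of a gait cycle (J), > 0.
#' @param q_min Minimum total metabolic cost over the geometry domain (J), > 0.
#' @return beta in (0, 1].
#' @export
update_beta <- function(q, q_min) {
  if (any(q <= 0) || any(q_min <= 0)) {
    stop("update_beta requires q > 0 and q_min > 0")
  }
  pmin(1, q_min / q)
}

#' Metabolic cost surface and its minimum over a geometry grid
#'
#' Evaluates the metabolic cost of one gait cycle (at full load intensity,
#' beta = 1) for an idealized normal fiber population at every (mean length,
#' SD) grid point. Grid points whose inverse dynamics fail (e.g. the load
#' would exceed the strain cap) are recorded as `NA` and excluded from the
#' minimum.
#'
#' @param gait A [gait_cycle()].
#' @param params A [musculotendon_params()].
#' @param mean_lengths Grid of mean tendon lengths (mm).
#' @param sds Grid of fiber-length standard deviations (mm).
#' @param n_fibers Fibers in the idealized populations (the per-fiber area is
#'   scaled via [scaled_fiber_area()] so the tendon's total cross-section and
#'   stiffness are preserved).
#' @param fiber_area,tendon_area,youngs_modulus Tendon material constants
#'   (physical per-fiber area).
#' @param n_fibers_physical Physical fiber count behind `fiber_area`.
#' @param max_strain Strain cap for the inverse dynamics.
#' @return List with `q_min` (J), `argmin` (named vector), and `surface`
#'   (data frame `mean_length_mm`, `sd_mm`, `Q_J`).
#' @export
compute_q_min <- function(gait, params = musculotendon_params(),
                          mean_lengths = seq(250, 280, by = 2.5),
                          sds = seq(0.5, 3, by = 0.5),
                          n_fibers = 2000,
                          fiber_area = 6.15e-4, tendon_area = 60,
                          youngs_modulus = 1000,
                          n_fibers_physical = 100000, max_strain = 0.12) {
  stopifnot(length(mean_lengths) >= 1, length(sds) >= 1)
  af <- scaled_fiber_area(n_fibers, fiber_area, n_fibers_physical)
  grid <- expand.grid(mean_length_mm = mean_lengths, sd_mm = sds)
  grid$Q_J <- vapply(seq_len(nrow(grid)), function(i) {
    pop <- idealized_population(n_fibers, grid$mean_length_mm[i],
                                grid$sd_mm[i], af, tendon_area,
                                youngs_modulus)
    tryCatch(
      gait_cycle_cost(gait, pop, params, beta = 1, max_strain = max_strain)$Q,
      error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(grid$Q_J))) stop("no geometry grid point is feasible")
  i_min <- which.min(grid$Q_J)
  list(q_min = grid$Q_J[i_min],
       argmin = c(mean_length_mm = grid$mean_length_mm[i_min],
                  sd_mm = grid$sd_mm[i_min]),
       surface = grid)
}

# Split a daily cycle count into near-equal blocks, extras first
# (5000 over 3 -> 1667/1667/1666).
split_cycles <- function(n, n_blocks) {
  base <- n %/% n_blocks
  extra <- n - base * n_blocks
  base + as.integer(seq_len(n_blocks) <= extra)
}

#' Simulate one day of loading, damage and repair
#'
#' The daily cycle: the day's load cycles are split into equal blocks
#' (default 3). For each block, the metabolic cost of the measured gait at
#' the current geometry sets the activity factor `beta = min(1,
#' q_min/Q)` (times any configured scale); the block's loading peak tendon
#' force is `beta` times the measured-gait peak, and mechanical fatigue
#' damage is assessed at that peak with the block's cycle count. After the
#' last block, proteolytic damage is applied once using the day's peak
#' strain, then all damaged fibers are repaired, restoring the fiber count.
#'
#' Draw order is fixed (mechanical blocks in order, then proteolysis, then
#' mechanical repairs, then proteolytic repairs) so runs are reproducible
#' for a fixed seed.
#'
#' @param state List with `day`, `beta`, `q_min`, `pop`, and turnover
#'   accumulators `cum_removed`, `cum_synthesized` (see
#'   [simulate_remodeling()], which constructs it).
#' @param gait A [gait_cycle()].
#' @param params A [musculotendon_params()].
#' @param models Damage/repair model list as built by
#'   `config_damage_models()`: `fatigue`, `proteolysis`, `mech_repair`,
#'   `proteo_repair`, `accounting`, plus logical switches `mech_enabled`,
#'   `proteo_enabled`, `repair_enabled`.
#' @param cycles_per_day Total load cycles for the day.
#' @param n_blocks Number of loading blocks.
#' @param beta_scale Multiplier applied to the computed activity factor
#'   (clamped to keep beta <= 1).
#' @param max_strain Strain cap for the inverse dynamics.
#' @return List with the updated `state` and a one-row data frame `record`.
#' @export
simulate_day <- function(state, gait, params, models,
                         cycles_per_day = 5000, n_blocks = 3,
                         beta_scale = 1, max_strain = 0.12) {
  pop <- state$pop
  initial_total <- state$initial_total_length
  blocks <- split_cycles(cycles_per_day, n_blocks)
  mech_failed <- integer()
  day_peak_x <- -Inf
  q_ref <- NA_real_
  clamped <- 0L
  for (b in seq_len(n_blocks)) {
    if (!any(!pop$broken)) {
      return(list(state = utils::modifyList(state, list(pop = pop,
                                                        status = "ruptured")),
                  record = NULL))
    }
    curve <- recruitment_curve(pop)
    cost <- gait_cycle_cost(gait, pop, params, beta = 1,
                            max_strain = max_strain)
    q_ref <- cost$Q
    clamped <- clamped + cost$clamped
    x_load <- extension_from_force(pop, state$beta * cost$peak_force,
                                   max_strain = max_strain, curve = curve)
    day_peak_x <- max(day_peak_x, x_load)
    if (isTRUE(models$mech_enabled) && blocks[b] > 0) {
      md <- apply_mechanical_damage(pop, x_load, blocks[b], models$fatigue)
      pop <- md$pop
      mech_failed <- c(mech_failed, md$report$mech_failed)
    }
    if (q_ref > 0) {
      state$beta <- min(1, beta_scale * update_beta(q_ref, state$q_min))
    }
  }
  proteo_failed <- integer()
  if (isTRUE(models$proteo_enabled) && any(!pop$broken)) {
    pd <- apply_proteolytic_damage(pop, day_peak_x, models$proteolysis)
    pop <- pd$pop
    proteo_failed <- pd$report$proteo_failed
  }
  report <- damage_report(mech_failed = mech_failed,
                          proteo_failed = proteo_failed)
  if (isTRUE(models$repair_enabled)) {
    rep <- repair_all(pop, report, models$mech_repair, models$proteo_repair,
                      accounting = models$accounting)
    pop <- rep$pop
    report <- rep$report
  } else {
    report$removed_length <- sum(state$pop$slack_lengths[c(mech_failed,
                                                           proteo_failed)])
    report$synthesized_length <- 0
  }
  state$pop <- pop
  state$day <- state$day + 1L
  state$cum_removed <- state$cum_removed + report$removed_length
  state$cum_synthesized <- state$cum_synthesized + report$synthesized_length
  li <- intact_lengths(pop)
  degrad_t <- if (report$removed_length > 0) {
    initial_total / report$removed_length / 365
  } else Inf
  synth_t <- if (report$synthesized_length > 0) {
    initial_total / report$synthesized_length / 365
  } else Inf
  record <- data.frame(
    day = state$day,
    mean_length_mm = mean(li),
    sd_mm = stats::sd(li),
    min_length_mm = min(li),
    max_length_mm = max(li),
    Q_J = q_ref,
    beta = state$beta,
    mech_failures = length(mech_failed),
    proteo_failures = length(proteo_failed),
    removed_length_mm = report$removed_length,
    synthesized_length_mm = report$synthesized_length,
    degradation_turnover_years = degrad_t,
    synthesis_turnover_years = synth_t,
    activation_clamped_samples = clamped)
  list(state = state, record = record)
}

#' Simulate multi-day tendon remodeling
#'
#' Runs the daily damage/repair cycle for `days` days under the configured
#' gait and musculotendon model. The minimum metabolic cost `q_min` is
#' computed once at initialization by sweeping the geometry grid at beta = 1
#' (unless supplied). The simulation is deterministic for a fixed `seed`.
#'
#' Daily per-fiber failure probabilities do not depend on the fiber count,
#' and turnover times are ratios of total content to removal rate, so the
#' distribution dynamics and turnover estimates are unchanged in expectation
#' when `tendon.n_fibers` is reduced for speed.
#'
#' @param config A `remodel_config` (see [default_config()]).
#' @param days Number of days to simulate. Defaults to `config$sim$days`.
#' @param seed Integer seed for all randomness (population draw and Bernoulli
#'   damage/repair draws).
#' @param q_min Optional precomputed minimum metabolic cost (J); computed
#'   from the configured geometry grid when `NULL`.
#' @param pop Optional initial [fiber_population()]; drawn from
#'   `config$tendon` when `NULL`.
#' @param gait Optional [gait_cycle()]; synthesized from `config$gait` when
#'   `NULL`.
#' @return An object of class `remodel_result`: list with `trajectory` (one
#'   row per day), `pop` (final population), `q_min`, `status` (`"ok"` or
#'   `"ruptured"`), `initial_total_length`, and `config`.
#' @export
simulate_remodeling <- function(config = default_config(),
                                days = NULL, seed = NULL,
                                q_min = NULL, pop = NULL, gait = NULL) {
  validate_config(config)
  if (is.null(days)) days <- config$sim$days
  stopifnot(days >= 1)
  if (!is.null(seed)) set.seed(seed)
  tn <- config$tendon
  if (is.null(pop)) {
    pop <- init_gaussian_population(
      tn$n_fibers, tn$mean_length, tn$sd,
      scaled_fiber_area(tn$n_fibers, tn$fiber_area, tn$n_fibers_physical),
      tn$tendon_area, tn$youngs_modulus)
  }
  if (is.null(gait)) gait <- config_gait(config)
  params <- config_musculotendon(config)
  models <- config_damage_models(config)
  sm <- config$sim
  if (is.null(q_min)) {
    q_min <- compute_q_min(gait, params,
                           mean_lengths = sm$qmin_mean_lengths,
                           sds = sm$qmin_sds, n_fibers = sm$qmin_n_fibers,
                           fiber_area = tn$fiber_area,
                           tendon_area = tn$tendon_area,
                           youngs_modulus = tn$youngs_modulus,
                           n_fibers_physical = tn$n_fibers_physical,
                           max_strain = sm$max_strain)$q_min
  }
  state <- list(day = 0L, beta = 1, q_min = q_min, pop = pop,
                cum_removed = 0, cum_synthesized = 0,
                initial_total_length = sum(intact_lengths(pop)),
                status = "ok")
  # initial activity factor from the starting geometry
  q0 <- tryCatch(gait_cycle_cost(gait, pop, params, beta = 1,
                                 max_strain = sm$max_strain)$Q,
                 error = function(e) NA_real_)
  if (is.finite(q0) && q0 > 0) {
    state$beta <- min(1, sm$beta_scale * update_beta(q0, q_min))
  }
  records <- vector("list", days)
  for (d in seq_len(days)) {
    step <- simulate_day(state, gait, params, models,
                         cycles_per_day = sm$cycles_per_day,
                         n_blocks = sm$n_blocks,
                         beta_scale = sm$beta_scale,
                         max_strain = sm$max_strain)
    state <- step$state
    if (!is.null(state$status) && state$status == "ruptured") {
      records <- records[seq_len(d - 1L)]
      break
    }
    records[[d]] <- step$record
  }
  structure(list(trajectory = do.call(rbind, records),
                 pop = state$pop, q_min = q_min,
                 status = if (is.null(state$status)) "ok" else state$status,
                 initial_total_length = state$initial_total_length,
                 config = config),
            class = "remodel_result")
}

#' @export
print.remodel_result <- function(x, ...) {
  tr <- x$trajectory
  cat("<remodel_result>\n")
  cat(sprintf("  days simulated: %d (status: %s)\n",
              if (is.null(tr)) 0L else nrow(tr), x$status))
  if (!is.null(tr) && nrow(tr) > 0) {
    last <- tr[nrow(tr), ]
    cat(sprintf("  final geometry: mean %.2f mm, SD %.3f mm\n",
                last$mean_length_mm, last$sd_mm))
    cat(sprintf("  final Q = %.3f J (q_min = %.3f J), beta = %.3f\n",
                last$Q_J, x$q_min, last$beta))
  }
  invisible(x)
}

#' Simulate remodeling under a constant peak load (tendon model only)
#'
#' Bypasses the musculotendon unit: every day the tendon is loaded to a fixed
#' peak force (the daily cycle count split into blocks as usual), damage
#' processes are applied as enabled, and repair restores damaged fibers.
#' This isolates the damage/repair dynamics, e.g. mechanical damage plus
#' lengthening-biased repair marches the fiber distribution to the right,
#' proteolysis plus shortening-biased repair marches it left.
#'
#' @param pop Initial [fiber_population()].
#' @param peak_force Constant daily peak tendon force (N). Ignored when
#'   `peak_length` is given.
#' @param days Number of days.
#' @param models Damage model list (see [simulate_day()]); defaults to the
#'   standard models with all processes enabled.
#' @param cycles_per_day,n_blocks Daily loading schedule.
#' @param mech,proteo,repair Logical switches for the three processes.
#' @param max_strain Strain cap.
#' @param peak_length Optional constant daily peak tendon end-to-end length
#'   (mm). Holding the peak extension instead of the peak force removes load
#'   redistribution: without repair the failure front through the short tail
#'   then slows as it advances into denser parts of the length distribution,
#'   rather than cascading.
#' @return List with `trajectory` (one row per day), final `pop`, `status`.
#' @export
simulate_constant_load <- function(pop, peak_force = NULL, days,
                                   models = NULL,
                                   cycles_per_day = 5000, n_blocks = 3,
                                   mech = TRUE, proteo = TRUE, repair = TRUE,
                                   max_strain = 0.12, peak_length = NULL) {
  stopifnot(!is.null(peak_force) || !is.null(peak_length))
  if (is.null(models)) models <- config_damage_models(default_config())
  models$mech_enabled <- mech
  models$proteo_enabled <- proteo
  models$repair_enabled <- repair
  initial_total <- sum(intact_lengths(pop))
  blocks <- split_cycles(cycles_per_day, n_blocks)
  records <- vector("list", days)
  status <- "ok"
  for (d in seq_len(days)) {
    mech_failed <- integer(); day_peak_x <- -Inf
    for (b in seq_len(n_blocks)) {
      if (!any(!pop$broken)) { status <- "ruptured"; break }
      x <- if (is.null(peak_length)) {
        extension_from_force(pop, peak_force, max_strain = max_strain,
                             curve = recruitment_curve(pop))
      } else {
        peak_length
      }
      day_peak_x <- max(day_peak_x, x)
      if (models$mech_enabled && blocks[b] > 0) {
        md <- apply_mechanical_damage(pop, x, blocks[b], models$fatigue)
        pop <- md$pop
        mech_failed <- c(mech_failed, md$report$mech_failed)
      }
    }
    if (status == "ruptured") { records <- records[seq_len(d - 1L)]; break }
    proteo_failed <- integer()
    if (models$proteo_enabled && any(!pop$broken)) {
      pd <- apply_proteolytic_damage(pop, day_peak_x, models$proteolysis)
      pop <- pd$pop
      proteo_failed <- pd$report$proteo_failed
    }
    report <- damage_report(mech_failed = mech_failed,
                            proteo_failed = proteo_failed)
    if (models$repair_enabled) {
      rr <- repair_all(pop, report, models$mech_repair, models$proteo_repair,
                       accounting = models$accounting)
      pop <- rr$pop
      report <- rr$report
    }
    li <- intact_lengths(pop)
    records[[d]] <- data.frame(
      day = d, mean_length_mm = mean(li), sd_mm = stats::sd(li),
      min_length_mm = min(li), max_length_mm = max(li),
      n_intact = length(li),
      mech_failures = length(mech_failed),
      proteo_failures = length(proteo_failed),
      removed_length_mm = report$removed_length,
      synthesized_length_mm = report$synthesized_length)
  }
  list(trajectory = do.call(rbind, records), pop = pop, status = status,
       initial_total_length = initial_total)
}

#' Collagen turnover times over a trajectory window
#'
#' Degradation turnover time: total initial fibrillar collagen content
#' (summed fiber length) divided by the mean daily removed length over the
#' window, converted to years at 365 days/year. Synthesis turnover time is
#' defined analogously from the synthesized length. At a remodeling
#' equilibrium the two converge. A zero mean rate reports `Inf`.
#'
#' @param result A `remodel_result` (or any list with `trajectory` and
#'   `initial_total_length`).
#' @param window Days at the end of the trajectory to average over; `NULL`
#'   uses the whole trajectory.
#' @return Named numeric vector `c(synthesis_years, degradation_years)`.
#' @export
turnover_times <- function(result, window = NULL) {
  tr <- result$trajectory
  stopifnot(!is.null(tr), nrow(tr) >= 1)
  if (!is.null(window)) {
    stopifnot(window >= 1)
    tr <- tr[seq(max(1, nrow(tr) - window + 1), nrow(tr)), ]
  }
  l0 <- result$initial_total_length
  rate_deg <- mean(tr$removed_length_mm)
  rate_syn <- mean(tr$synthesized_length_mm)
  c(synthesis_years = if (rate_syn > 0) l0 / rate_syn / 365 else Inf,
    degradation_years = if (rate_deg > 0) l0 / rate_deg / 365 else Inf)
}

#' Expected daily damage rates at a geometry (no sampling)
#'
#' Computes the expected number of mechanical and proteolytic fiber failures
#' per day at the current geometry, using the same loading chain as
#' [simulate_day()] but summing per-fiber probabilities instead of drawing.
#' Useful for examining the stability structure: where the mechanical rate
#' exceeds the proteolytic rate the tendon lengthens (given the biased
#' repairs), and vice versa.
#'
#' @param pop A [fiber_population()].
#' @param gait A [gait_cycle()].
#' @param params A [musculotendon_params()].
#' @param models Damage model list.
#' @param q_min Minimum metabolic cost (J) for the activity factor.
#' @param cycles_per_day,n_blocks Daily loading schedule.
#' @param beta_scale Activity factor multiplier.
#' @param max_strain Strain cap.
#' @return Named vector `c(mech, proteo, beta, Q)`.
#' @export
expected_daily_rates <- function(pop, gait, params, models, q_min,
                                 cycles_per_day = 5000, n_blocks = 3,
                                 beta_scale = 1, max_strain = 0.12) {
  curve <- recruitment_curve(pop)
  cost <- gait_cycle_cost(gait, pop, params, beta = 1, max_strain = max_strain)
  beta <- min(1, beta_scale * update_beta(cost$Q, q_min))
  x <- extension_from_force(pop, beta * cost$peak_force,
                            max_strain = max_strain, curve = curve)
  blocks <- split_cycles(cycles_per_day, n_blocks)
  st <- peak_fiber_stress(pop, x)
  intact <- !pop$broken
  sig <- st$stress[intact]
  mech <- 0
  loaded <- sig > 0
  if (any(loaded)) {
    nf <- cycles_to_failure(sig[loaded], models$fatigue)
    for (b in blocks) {
      mech <- mech + sum(mech_failure_probability(b, nf, models$fatigue))
    }
  }
  proteo <- sum(proteolytic_failure_probability(st$strain[intact],
                                                models$proteolysis))
  c(mech = mech, proteo = proteo, beta = beta, Q = cost$Q)
}

#' Explore the geometry domain for convergent and divergent starts
#'
#' Simulates remodeling from a grid of initial geometries and classifies
#' each start by its terminal behavior: `"diverged"` if the tendon has
#' shortened out of the explored domain and is still shortening, or its
#' metabolic cost has grown beyond `q_ratio_max` times the minimum (or it
#' ruptured); `"converged"` otherwise. Terminal drift is the fitted slope of
#' mean length over the final `slope_window` days.
#'
#' @param config A `remodel_config`.
#' @param mean_lengths,sds Grids of initial geometries.
#' @param days Days to simulate per start.
#' @param seed Base seed; start i uses `seed + i`.
#' @param q_ratio_max Divergence threshold on `Q/q_min`. Default 5.
#' @param domain_min Lower edge of the explored mean-length domain (mm).
#' @param slope_window Days over which terminal drift is fitted.
#' @return Data frame: initial geometry, final geometry, terminal slope,
#'   final cost ratio and `class`.
#' @export
explore_geometry_domain <- function(config = default_config(),
                                    mean_lengths = seq(250, 280, by = 5),
                                    sds = c(1, 2), days = 360, seed = 1,
                                    q_ratio_max = 5, domain_min = NULL,
                                    slope_window = 50) {
  if (is.null(domain_min)) domain_min <- min(mean_lengths)
  gait <- config_gait(config)
  params <- config_musculotendon(config)
  sm <- config$sim
  tn <- config$tendon
  qm <- compute_q_min(gait, params, mean_lengths = sm$qmin_mean_lengths,
                      sds = sm$qmin_sds, n_fibers = sm$qmin_n_fibers,
                      fiber_area = tn$fiber_area, tendon_area = tn$tendon_area,
                      youngs_modulus = tn$youngs_modulus,
                      n_fibers_physical = tn$n_fibers_physical,
                      max_strain = sm$max_strain)$q_min
  grid <- expand.grid(init_mean_mm = mean_lengths, init_sd_mm = sds)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$tendon$mean_length <- grid$init_mean_mm[i]
    cfg$tendon$sd <- grid$init_sd_mm[i]
    res <- simulate_remodeling(cfg, days = days, seed = seed + i, q_min = qm)
    tr <- res$trajectory
    if (res$status == "ruptured" || is.null(tr) || nrow(tr) < slope_window) {
      return(data.frame(grid[i, ], final_mean_mm = NA, final_sd_mm = NA,
                        slope_mm_day = NA, q_ratio = NA, class = "diverged"))
    }
    tail_tr <- tr[seq(nrow(tr) - slope_window + 1, nrow(tr)), ]
    slope <- unname(stats::coef(stats::lm(mean_length_mm ~ day,
                                          data = tail_tr))[2])
    last <- tr[nrow(tr), ]
    q_ratio <- last$Q_J / qm
    diverged <- (last$mean_length_mm < domain_min && slope < 0) ||
      q_ratio > q_ratio_max
    data.frame(grid[i, ], final_mean_mm = last$mean_length_mm,
               final_sd_mm = last$sd_mm, slope_mm_day = slope,
               q_ratio = q_ratio,
               class = if (diverged) "diverged" else "converged")
  })
  do.call(rbind, rows)
}

#' Perturb one named model parameter in a configuration
#'
#' Maps the parameters of the sensitivity analysis onto configuration edits:
#' `beta` (activity-factor scale), `a`, `b`, `kappa`, `lambda` (fatigue),
#' `n` (daily cycles), `phi` (proteolysis), `repair_mean` (both repair
#' distributions' means scaled together, dispersion fixed),
#' `repair_dispersion` (spread about each mean scaled, means fixed),
#' `fiber_stiffness` (Young's modulus, hence every k_i = A_F E_T / L_i),
#' `f_max`, `v_max` and `l_calc` (moment-arm scale).
#'
#' @param config A `remodel_config`.
#' @param param Parameter name (see Details).
#' @param delta Relative perturbation (0.05 = +5%).
#' @return The perturbed configuration.
#' @export
perturb_config <- function(config, param, delta) {
  scale_repair <- function(v, delta, what) {
    m <- mean(v)
    if (what == "mean") v + delta * m else m + (1 + delta) * (v - m)
  }
  switch(param,
    beta = { config$sim$beta_scale <- config$sim$beta_scale * (1 + delta) },
    a = { config$fatigue$a <- config$fatigue$a * (1 + delta) },
    b = { config$fatigue$b <- config$fatigue$b * (1 + delta) },
    kappa = { config$fatigue$kappa <- config$fatigue$kappa * (1 + delta) },
    lambda = { config$fatigue$lambda <- config$fatigue$lambda * (1 + delta) },
    n = { config$sim$cycles_per_day <-
            as.integer(round(config$sim$cycles_per_day * (1 + delta))) },
    phi = { config$proteolysis$phi <- config$proteolysis$phi * (1 + delta) },
    repair_mean = {
      config$repair$mech <- scale_repair(config$repair$mech, delta, "mean")
      config$repair$proteo <- scale_repair(config$repair$proteo, delta, "mean")
    },
    repair_dispersion = {
      config$repair$mech <- scale_repair(config$repair$mech, delta, "disp")
      config$repair$proteo <- scale_repair(config$repair$proteo, delta, "disp")
    },
    fiber_stiffness = {
      config$tendon$youngs_modulus <-
        config$tendon$youngs_modulus * (1 + delta)
    },
    f_max = { config$muscle$f_max <- config$muscle$f_max * (1 + delta) },
    v_max = { config$muscle$v_max <- config$muscle$v_max * (1 + delta) },
    l_calc = {
      config$muscle$calcaneus_length <-
        config$muscle$calcaneus_length * (1 + delta)
    },
    stop("unknown sensitivity parameter: ", param)
  )
  config
}

#' Names of the parameters covered by the sensitivity analysis
#' @return Character vector of parameter names for [perturb_config()].
#' @export
sensitivity_parameters <- function() {
  c("beta", "a", "b", "kappa", "lambda", "n", "phi",
    "repair_mean", "repair_dispersion", "fiber_stiffness",
    "f_max", "v_max", "l_calc")
}

# Equilibrium summary of a trajectory: final-window means and drift slope.
equilibrium_summary <- function(result, window = 100) {
  tr <- result$trajectory
  if (is.null(tr) || nrow(tr) < 2) {
    return(c(mean_length = NA, sd = NA, slope = NA))
  }
  tail_tr <- tr[seq(max(1, nrow(tr) - window + 1), nrow(tr)), ]
  slope <- unname(stats::coef(stats::lm(mean_length_mm ~ day,
                                        data = tail_tr))[2])
  c(mean_length = mean(tail_tr$mean_length_mm), sd = mean(tail_tr$sd_mm),
    slope = slope)
}

#' Normalized parameter sensitivity of the equilibrium geometry
#'
#' For each parameter, runs a baseline and a perturbed remodeling simulation
#' with a common seed, estimates the equilibrium mean tendon length and fiber
#' SD as final-window averages, and reports the normalized sensitivity
#' `S = (dY/Y_e) / (dP/P_e)` for both outputs. A run whose final-window mean
#' length drifts faster than `drift_tol` (mm/day) is flagged as not
#' converged.
#'
#' @param config Baseline `remodel_config`.
#' @param params Parameter names (default: all of
#'   [sensitivity_parameters()]).
#' @param delta Relative perturbation. Default +0.05.
#' @param days Days per run. Defaults to `config$sim$days`.
#' @param seed Common seed for baseline and perturbed runs.
#' @param window Final-window length (days) for equilibrium averaging.
#' @param drift_tol Convergence criterion on the final-window slope (mm/day).
#' @param q_min Optional precomputed minimum cost, reused across runs whose
#'   perturbation does not alter the cost surface.
#' @return Data frame: parameter, equilibrium outputs for baseline and
#'   perturbed runs, `S_length`, `S_dispersion`, `pct_change_length`,
#'   `converged`.
#' @export
sensitivity_analysis <- function(config = default_config(),
                                 params = sensitivity_parameters(),
                                 delta = 0.05, days = NULL, seed = 1,
                                 window = 100, drift_tol = 1e-3,
                                 q_min = NULL) {
  if (is.null(days)) days <- config$sim$days
  base <- simulate_remodeling(config, days = days, seed = seed, q_min = q_min)
  eq0 <- equilibrium_summary(base, window)
  # parameters whose perturbation changes the metabolic cost surface need
  # q_min recomputed; the rest reuse the baseline minimum
  affects_qmin <- c("f_max", "v_max", "l_calc", "fiber_stiffness")
  rows <- lapply(params, function(p) {
    cfg <- perturb_config(config, p, delta)
    qm <- if (p %in% affects_qmin) NULL else base$q_min
    res <- simulate_remodeling(cfg, days = days, seed = seed, q_min = qm)
    eq1 <- equilibrium_summary(res, window)
    conv <- res$status == "ok" && is.finite(eq1[["slope"]]) &&
      abs(eq1[["slope"]]) < drift_tol
    data.frame(
      parameter = p,
      base_length_mm = eq0[["mean_length"]],
      pert_length_mm = eq1[["mean_length"]],
      base_sd_mm = eq0[["sd"]],
      pert_sd_mm = eq1[["sd"]],
      S_length = ((eq1[["mean_length"]] - eq0[["mean_length"]]) /
                    eq0[["mean_length"]]) / delta,
      S_dispersion = ((eq1[["sd"]] - eq0[["sd"]]) / eq0[["sd"]]) / delta,
      pct_change_length = 100 * (eq1[["mean_length"]] - eq0[["mean_length"]]) /
        eq0[["mean_length"]],
      converged = conv)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- eq0
  attr(out, "base_converged") <- abs(eq0[["slope"]]) < drift_tol
  out
}
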