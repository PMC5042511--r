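#' Default run configuration
#'
#' Nested list of every model parameter, keyed by section. The tendon,
#' fatigue, proteolysis and loading defaults are the published Achilles
#' values (100,000 fibers; A_F = 6.15e-4 mm^2; A_T = 60 mm^2; E_T = 1 GPa;
#' 5,000 load cycles/day; a = 100 MPa; b = 8.25 MPa/decade; peak ankle
#' torque 165 N.m). Muscle, metabolic, repair and gait entries are
#' literature-scale defaults documented in the methods vignette.
#'
#' @return A nested named list of class `remodel_config`.
#' @export
default_config <- function() {
  structure(list(
    tendon = list(
      n_fibers = 100000L,       # fibers simulated (scaled runs use fewer)
      n_fibers_physical = 100000L,  # N_total of the physical tendon
      fiber_area = 6.15e-4,    # A_F, mm^2 (per physical fiber)
      tendon_area = 60,        # A_T, mm^2
      youngs_modulus = 1000,   # E_T, MPa (1 GPa)
      mean_length = 266,       # initial mean slack length, mm
      sd = 0.6                 # initial fiber-length SD, mm
    ),
    fatigue = list(
      a = 100,                 # ultimate tensile stress, MPa
      b = 8.25,                # fatigue slope, MPa/log10(n_fail)
      kappa = 0.0125,
      lambda = 2 * log(9)
    ),
    proteolysis = list(phi = 300),
    repair = list(
      mech = c(min = 0.0025, mode = 0.0075, max = 0.0125),
      proteo = c(min = -0.0125, mode = -0.0075, max = -0.0025),
      accounting = "whole_fiber"
    ),
    muscle = list(
      f_max = 6500,            # N (lumped plantarflexor group)
      v_max = 10,              # l_opt/s
      l_opt = 50,              # mm
      pennation_opt_deg = 25,
      torque_share = 1,
      moment_arm_coeffs = c(1, 0.1),
      calcaneus_length = 60,   # mm
      mtu_ref_length = 312,    # mm
      fl_width = 0.22,
      fv_curvature = 0.25,
      fv_ecc_plateau = 1.45,
      h_am = 60,               # W/kg
      act_frac = 0.4,
      h_sl_coeff = 200,        # W/kg at v_max
      ecc_heat_frac = 0.3,
      sigma0 = 0.25,           # MPa specific tension
      density = 1059.7         # kg/m^3
    ),
    gait = list(
      peak_torque = 165,       # N.m
      stride_duration = 1.1,   # s
      n_samples = 101L,
      angle_amplitude = 0.35,  # rad
      stance_fraction = 0.6
    ),
    sim = list(
      days = 720L,
      cycles_per_day = 5000L,
      n_blocks = 3L,
      beta_scale = 1,          # multiplier on the computed activity factor
      max_strain = 0.12,
      qmin_mean_lengths = seq(250, 280, by = 2.5),
      qmin_sds = seq(0.5, 3, by = 0.5),
      qmin_n_fibers = 2000L
    )
  ), class = "remodel_config")
}

# Recursively merge user values into defaults, erroring on unknown keys.
merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop("unknown configuration key: ", full)
    }
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]])) stop("expected a section for key: ", full)
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      val <- user[[key]]
      if (is.list(val)) val <- unlist(val)
      if (!is.null(names(base[[key]])) && is.null(names(val)) &&
          length(val) == length(base[[key]])) {
        names(val) <- names(base[[key]])
      }
      base[[key]] <- val
    }
  }
  base
}

#' Validate a run configuration
#'
#' Checks positivity/range constraints on every parameter, naming the
#' offending parameter in the error.
#'
#' @param config A configuration list (see [default_config()]).
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  chk <- function(ok, what) if (!ok) stop("invalid configuration: ", what)
  tn <- config$tendon
  chk(tn$n_fibers > 0, "tendon.n_fibers must be > 0")
  chk(tn$n_fibers_physical > 0, "tendon.n_fibers_physical must be > 0")
  chk(tn$fiber_area > 0, "tendon.fiber_area must be > 0")
  chk(tn$tendon_area > 0, "tendon.tendon_area must be > 0")
  chk(tn$youngs_modulus > 0, "tendon.youngs_modulus must be > 0")
  chk(tn$mean_length > 0, "tendon.mean_length must be > 0")
  chk(tn$sd >= 0, "tendon.sd must be >= 0")
  ft <- config$fatigue
  chk(ft$a > 0, "fatigue.a must be > 0")
  chk(ft$b > 0, "fatigue.b must be > 0")
  chk(ft$kappa > 0, "fatigue.kappa must be > 0")
  chk(ft$lambda > 0, "fatigue.lambda must be > 0")
  chk(config$proteolysis$phi >= 0, "proteolysis.phi must be >= 0")
  for (side in c("mech", "proteo")) {
    r <- config$repair[[side]]
    chk(r[["min"]] <= r[["mode"]] && r[["mode"]] <= r[["max"]],
        paste0("repair.", side, " must satisfy min <= mode <= max"))
    chk(r[["min"]] > -1, paste0("repair.", side, ".min must be > -1"))
  }
  mu <- config$muscle
  chk(mu$f_max > 0, "muscle.f_max must be > 0")
  chk(mu$v_max > 0, "muscle.v_max must be > 0")
  chk(mu$l_opt > 0, "muscle.l_opt must be > 0")
  chk(mu$torque_share > 0 && mu$torque_share <= 1,
      "muscle.torque_share must be in (0, 1]")
  ga <- config$gait
  chk(ga$peak_torque > 0, "gait.peak_torque must be > 0")
  chk(ga$stance_fraction > 0 && ga$stance_fraction < 1,
      "gait.stance_fraction must be in (0, 1)")
  chk(ga$n_samples >= 50, "gait.n_samples must be >= 50")
  sm <- config$sim
  chk(sm$days >= 1, "sim.days must be >= 1")
  chk(sm$cycles_per_day >= 0, "sim.cycles_per_day must be >= 0")
  chk(sm$n_blocks >= 1, "sim.n_blocks must be >= 1")
  chk(sm$beta_scale > 0, "sim.beta_scale must be > 0")
  invisible(config)
}

#' Load a configuration file
#'
#' Reads a YAML file of overrides, merges it onto [default_config()]
#' (unknown keys are an error, listed by name) and validates the result.
#' An empty file yields the full defaults.
#'
#' @param path Path to a YAML configuration file, or `NULL` for defaults.
#' @return A validated `remodel_config`.
#' @export
load_config <- function(path = NULL) {
  config <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) config <- merge_config(config, user)
  }
  validate_config(config)
  config
}

#' Save a configuration to YAML
#'
#' @param config A `remodel_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Effective fiber area for a scaled-down population
#'
#' Per-fiber stress and strain (which drive the damage models) depend only on
#' geometry, but the tendon's total stiffness is `sum(A_F E_T / L_i)`:
#' simulating fewer fibers than the physical count must therefore use
#' proportionally thicker fibers so the total fiber cross-section (and the
#' force-extension curve) is preserved. Returns
#' `fiber_area * n_physical / n`.
#'
#' @param n Number of simulated fibers.
#' @param fiber_area Physical per-fiber cross-sectional area (mm^2).
#' @param n_physical Physical fiber count. Default 100,000.
#' @return Effective per-fiber area (mm^2).
#' @export
scaled_fiber_area <- function(n, fiber_area = 6.15e-4, n_physical = 100000) {
  fiber_area * n_physical / n
}

#' Build model objects from a configuration
#'
#' Helpers that assemble the [musculotendon_params()], [gait_cycle()] and
#' damage/repair model list that [simulate_remodeling()] uses internally,
#' for callers who want to drive [simulate_day()] or [gait_cycle_cost()]
#' directly.
#'
#' @param config A `remodel_config` (see [default_config()]).
#' @return `config_musculotendon`: a [musculotendon_params()];
#'   `config_gait`: a [gait_cycle()]; `config_damage_models`: a list with
#'   `fatigue`, `proteolysis`, `mech_repair`, `proteo_repair`, `accounting`
#'   and the three `*_enabled` switches.
#' @export
config_musculotendon <- function(config) {
  mu <- config$muscle
  musculotendon_params(
    f_max = mu$f_max, v_max = mu$v_max, l_opt = mu$l_opt,
    pennation_opt = mu$pennation_opt_deg * pi / 180,
    torque_share = mu$torque_share,
    moment_arm_coeffs = mu$moment_arm_coeffs,
    calcaneus_length = mu$calcaneus_length,
    mtu_ref_length = mu$mtu_ref_length,
    fl_width = mu$fl_width, fv_curvature = mu$fv_curvature,
    fv_ecc_plateau = mu$fv_ecc_plateau,
    metabolic = list(h_am = mu$h_am, act_frac = mu$act_frac,
                     h_sl_coeff = mu$h_sl_coeff,
                     ecc_heat_frac = mu$ecc_heat_frac,
                     sigma0 = mu$sigma0, density = mu$density))
}

#' @rdname config_musculotendon
#' @export
config_gait <- function(config) {
  ga <- config$gait
  make_walking_cycle(peak_torque = ga$peak_torque,
                     stride_duration = ga$stride_duration,
                     n_samples = ga$n_samples,
                     angle_amplitude = ga$angle_amplitude,
                     stance_fraction = ga$stance_fraction)
}

#' @rdname config_musculotendon
#' @export
config_damage_models <- function(config) {
  r <- config$repair
  list(fatigue = fatigue_params(a = config$fatigue$a, b = config$fatigue$b,
                                kappa = config$fatigue$kappa,
                                lambda = config$fatigue$lambda),
       proteolysis = proteolysis_params(phi = config$proteolysis$phi),
       mech_repair = repair_distribution(r$mech[["min"]], r$mech[["mode"]],
                                         r$mech[["max"]]),
       proteo_repair = repair_distribution(r$proteo[["min"]],
                                           r$proteo[["mode"]],
                                           r$proteo[["max"]]),
       accounting = r$accounting,
       mech_enabled = TRUE, proteo_enabled = TRUE, repair_enabled = TRUE)
}

#' Deterministic fixture populations for tests and examples
#'
#' Presets mirroring the standard demonstration setups: `demo_narrow` and
#' `demo_wide` (mean 275 mm, SD 0.5% and 1.5% of the mean, the dispersion
#' comparison), `demo_base` (mean 275 mm, SD 2 mm, the damage/repair
#' scenario geometry) and `two_fiber_toy` (two fibers, 10 and 20 mm, with
#' A_F E_T = 1 N).
#'
#' @param preset Preset name.
#' @param n Number of fibers for the Gaussian presets. Default 10000.
#' @param seed RNG seed for the Gaussian presets.
#' @return A [fiber_population()].
#' @export
make_fixture_population <- function(preset = c("demo_base", "demo_narrow",
                                               "demo_wide", "two_fiber_toy"),
                                    n = 10000, seed = 1) {
  preset <- match.arg(preset)
  if (preset == "two_fiber_toy") {
    return(fiber_population(c(10, 20), fiber_area = 1, tendon_area = 2,
                            youngs_modulus = 1))
  }
  sd <- switch(preset, demo_base = 2, demo_narrow = 0.005 * 275,
               demo_wide = 0.015 * 275)
  set.seed(seed)
  init_gaussian_population(n, 275, sd, fiber_area = scaled_fiber_area(n))
}
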