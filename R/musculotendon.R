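#' Hill-type Achilles-soleus musculotendon parameters
#'
#' The musculotendon unit is a three-component Hill model: a contractile
#' element (soleus, constant properties) in series with the Achilles tendon
#' (the fiber-population model). Inverse dynamics runs from ankle torque and
#' angle to tendon force, muscle state, activation and metabolic cost rate.
#'
#' The moment arm is `r(theta) = L_calc * polynomial(theta)` (mm, polynomial
#' dimensionless with constant term 1 at the neutral angle), so the calcaneus
#' length scales the moment arm proportionally. The musculotendon path length
#' is `L_MTU(theta) = mtu_ref_length - L_calc * integral(polynomial)`, i.e.
#' plantarflexion (positive angle) shortens the path.
#'
#' None of these constants are measurable from the tendon model itself; they
#' are literature-scale soleus defaults and are all configuration-exposed.
#'
#' @param f_max Soleus maximum isometric force (N).
#' @param v_max Maximum shortening velocity (optimal fiber lengths per s).
#' @param l_opt Optimal muscle fiber length (mm).
#' @param pennation_opt Pennation angle at `l_opt` (rad).
#' @param torque_share Fraction of ankle plantarflexion torque carried by the
#'   modeled unit, in (0, 1]. Default 1: the Achilles tendon transmits the
#'   full plantarflexor torque (165 N.m over a 50 mm moment arm and 60 mm^2
#'   cross-section gives the ~55 MPa peak stress of normal walking).
#' @param moment_arm_coeffs Dimensionless polynomial coefficients (constant
#'   first) multiplying `calcaneus_length`.
#' @param calcaneus_length Moment-arm scale L_calc (mm).
#' @param mtu_ref_length Musculotendon path length at the neutral angle (mm).
#' @param fl_width Width of the Gaussian force-length curve. Default 0.45.
#' @param fv_curvature Hill force-velocity shape factor (concentric). Default 0.25.
#' @param fv_ecc_plateau Eccentric force plateau as a fraction of isometric.
#'   Default 1.45.
#' @param metabolic List of energetics coefficients: `h_am` activation +
#'   maintenance heat rate at full activation (W/kg), `act_frac` activation
#'   share of `h_am`, `h_sl_coeff` shortening heat at `v_max` (W/kg),
#'   `ecc_heat_frac` eccentric heat fraction, `sigma0` specific tension (MPa)
#'   and `density` muscle density (kg/m^3) used to derive muscle mass from
#'   `f_max` and `l_opt`.
#' @return An object of class `musculotendon_params`.
#' @export
musculotendon_params <- function(f_max = 6500,
                                 v_max = 10,
                                 l_opt = 50,
                                 pennation_opt = 25 * pi / 180,
                                 torque_share = 1,
                                 moment_arm_coeffs = c(1, 0.1),
                                 calcaneus_length = 60,
                                 mtu_ref_length = 312,
                                 fl_width = 0.22,
                                 fv_curvature = 0.25,
                                 fv_ecc_plateau = 1.45,
                                 metabolic = list()) {
  met <- utils::modifyList(list(h_am = 60, act_frac = 0.4, h_sl_coeff = 200,
                                ecc_heat_frac = 0.3, sigma0 = 0.25,
                                density = 1059.7), metabolic)
  stopifnot(f_max > 0, v_max > 0, l_opt > 0,
            torque_share > 0, torque_share <= 1,
            calcaneus_length > 0, mtu_ref_length > 0)
  structure(list(f_max = f_max, v_max = v_max, l_opt = l_opt,
                 pennation_opt = pennation_opt, torque_share = torque_share,
                 moment_arm_coeffs = moment_arm_coeffs,
                 calcaneus_length = calcaneus_length,
                 mtu_ref_length = mtu_ref_length,
                 fl_width = fl_width, fv_curvature = fv_curvature,
                 fv_ecc_plateau = fv_ecc_plateau, metabolic = met),
            class = "musculotendon_params")
}

# Muscle mass (kg) from max force, specific tension and optimal length.
muscle_mass <- function(params) {
  pcsa_m2 <- params$f_max / (params$metabolic$sigma0 * 1e6)
  pcsa_m2 * (params$l_opt / 1000) * params$metabolic$density
}

#' Soleus moment arm at an ankle angle
#'
#' @param angle Ankle angle(s), rad (plantarflexion positive).
#' @param params A [musculotendon_params()].
#' @return Moment arm(s), mm.
#' @export
moment_arm <- function(angle, params = musculotendon_params()) {
  if (any(abs(angle) > 1)) {
    warning("moment arm evaluated beyond +/-1 rad: outside the calibrated gait range")
  }
  co <- params$moment_arm_coeffs
  r <- params$calcaneus_length *
    Reduce(`+`, Map(function(c, p) c * angle^p, co, seq_along(co) - 1L))
  if (any(r <= 0)) stop("moment arm is non-positive at the requested angle")
  r
}

# Musculotendon path length at angle(s): analytic integral of -r(theta)
# from the neutral angle (polynomial moment arm integrates in closed form).
mtu_length <- function(angle, params) {
  co <- params$moment_arm_coeffs
  integral <- Reduce(`+`, Map(function(c, p) c * angle^(p + 1) / (p + 1),
                              co, seq_along(co) - 1L))
  params$mtu_ref_length - params$calcaneus_length * integral
}

#' Tendon force from ankle torque
#'
#' `F_T = torque_share * torque / r(theta)`, with the N.m -> N.mm conversion.
#'
#' @param torque Ankle plantarflexion torque(s), N.m, >= 0.
#' @param angle Ankle angle(s), rad.
#' @param params A [musculotendon_params()].
#' @return Tendon force(s), N.
#' @export
tendon_force_from_torque <- function(torque, angle,
                                     params = musculotendon_params()) {
  stopifnot(all(torque >= 0))
  params$torque_share * torque * 1000 / moment_arm(angle, params)
}

#' Muscle fiber state from tendon and joint kinematics
#'
#' Constant-volume (constant-thickness) pennation: the fiber's height above
#' the line of action is fixed at `l_opt sin(pennation_opt)`, so
#' `l sin(pennation) = l_opt sin(pennation_opt)` and the fiber length is the
#' hypotenuse over the projected length `L_MTU - tendon length`. The fiber
#' velocity is the time derivative of the same relation.
#'
#' @param tendon_stretched_length Tendon end-to-end length(s), mm.
#' @param angle Ankle angle(s), rad.
#' @param angle_rate Ankle angular velocity(ies), rad/s.
#' @param tendon_length_rate Tendon length rate(s), mm/s.
#' @param params A [musculotendon_params()].
#' @return List of vectors: `fiber_length` (mm), `fiber_velocity` (mm/s,
#'   positive lengthening), `pennation` (rad).
#' @export
muscle_state <- function(tendon_stretched_length, angle, angle_rate,
                         tendon_length_rate, params = musculotendon_params()) {
  lmtu <- mtu_length(angle, params)
  proj <- lmtu - tendon_stretched_length
  if (any(proj <= 0)) {
    stop("non-physiological geometry: musculotendon path shorter than tendon")
  }
  h <- params$l_opt * sin(params$pennation_opt)
  lf <- sqrt(proj^2 + h^2)
  pennation <- atan2(h, proj)
  # d(proj)/dt = dL_MTU/dt - dx/dt = -r(theta) * dtheta/dt - dx/dt
  dproj <- -moment_arm(angle, params) * angle_rate - tendon_length_rate
  vf <- proj * dproj / lf
  list(fiber_length = lf, fiber_velocity = vf, pennation = pennation)
}

#' Active force-length and force-velocity scaling factors
#'
#' `force_length` is a Gaussian bell centred on the optimal fiber length;
#' `force_velocity` is a Hill hyperbola for shortening and a saturating
#' eccentric curve with the configured plateau for lengthening. Both are
#' fractions of the maximum isometric force.
#'
#' @param fiber_length Fiber length(s), mm.
#' @param fiber_velocity Fiber velocity(ies), mm/s, positive lengthening.
#' @param params A [musculotendon_params()].
#' @return Numeric vector of dimensionless factors.
#' @export
force_length <- function(fiber_length, params = musculotendon_params()) {
  exp(-((fiber_length / params$l_opt - 1) / params$fl_width)^2)
}

#' @rdname force_length
#' @export
force_velocity <- function(fiber_velocity, params = musculotendon_params()) {
  u <- fiber_velocity / params$l_opt  # in l_opt per second
  vm <- params$v_max
  k <- params$fv_curvature
  pl <- params$fv_ecc_plateau
  fv <- ifelse(u <= 0,
               pmax(0, (vm + u) / (vm - u / k)),
               pl - (pl - 1) * exp(-7 * u / vm))
  pmin(fv, pl)
}

#' Muscle activation required to produce a force
#'
#' `M_act = F_M / (F_L F_V F_max)`, the fraction of maximal activation needed
#' given the current force-length and force-velocity capacity. Values above 1
#' mean the demanded force exceeds capacity; they are clamped to 1 and
#' counted in the `clamped` attribute.
#'
#' @param muscle_force Required muscle fiber force(s), N, >= 0.
#' @param fiber_length Fiber length(s), mm.
#' @param fiber_velocity Fiber velocity(ies), mm/s.
#' @param params A [musculotendon_params()].
#' @return Activation(s) in [0, 1]; attribute `clamped` counts samples whose
#'   raw value exceeded 1.
#' @export
activation <- function(muscle_force, fiber_length, fiber_velocity,
                       params = musculotendon_params()) {
  stopifnot(all(muscle_force >= 0))
  cap <- force_length(fiber_length, params) *
    force_velocity(fiber_velocity, params) * params$f_max
  if (any(cap <= 0 & muscle_force > 0)) {
    stop("force demanded at zero force capacity (F_L * F_V = 0)")
  }
  raw <- ifelse(muscle_force == 0, 0, muscle_force / cap)
  m <- pmin(raw, 1)
  attr(m, "clamped") <- sum(raw > 1)
  m
}

#' Metabolic cost rate of the muscle
#'
#' Sum of four terms: activation heat, maintenance heat (scaled by the
#' force-length state), shortening/lengthening heat, and mechanical work rate
#' (positive when the fiber shortens under load). The sum is rectified at
#' zero, per the usual muscle energetics convention that the muscle cannot
#' consume negative energy over a sample.
#'
#' `m_act` here is the activation *demand* `F_M/(F_L F_V F_max)` and may
#' exceed 1: when the required force exceeds the muscle's current capacity,
#' the metabolic demand of meeting it (through synergist recruitment and
#' inefficient operation) keeps growing, which is what makes
#' non-physiological tendon geometries metabolically expensive.
#'
#' @inheritParams activation
#' @param m_act Activation demand(s), >= 0 (may exceed 1).
#' @return Metabolic rate(s), W.
#' @export
metabolic_rate <- function(m_act, fiber_length, fiber_velocity, muscle_force,
                           params = musculotendon_params()) {
  stopifnot(all(m_act >= 0))
  met <- params$metabolic
  mass <- muscle_mass(params)
  fl <- force_length(fiber_length, params)
  u <- fiber_velocity / params$l_opt
  h_act <- met$act_frac * met$h_am * m_act * mass
  h_m <- (1 - met$act_frac) * met$h_am * m_act * fl * mass
  h_sl <- ifelse(u <= 0,
                 met$h_sl_coeff * (-u) / params$v_max,
                 met$ecc_heat_frac * met$h_sl_coeff * u / params$v_max) *
    m_act * mass
  w_m <- -muscle_force * fiber_velocity / 1000  # N.mm/s -> W
  pmax(0, h_act + h_m + h_sl + w_m)
}

# Central-difference gradient on a (possibly non-uniform) grid.
grid_gradient <- function(y, t) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (t[2] - t[1])
  g[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  g
}

# Trapezoidal integral.
trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Metabolic cost of one gait cycle
#'
#' Runs the inverse-dynamics chain at every time sample of the gait cycle:
#' ankle torque (scaled by the activity factor beta) -> tendon force via the
#' moment arm -> tendon stretched length by inverting the fiber-recruitment
#' force-extension curve -> muscle fiber length, velocity and pennation ->
#' activation -> metabolic cost rate, which is integrated (trapezoid) over
#' the cycle.
#'
#' @param gait A [gait_cycle()].
#' @param pop A [fiber_population()].
#' @param params A [musculotendon_params()].
#' @param beta Activity scale factor in (0, 1] multiplying the torque.
#' @param max_strain Passed to [extension_from_force()].
#' @param trace If `TRUE`, also return the per-sample `muscle_trace`
#'   data frame.
#' @param proj_floor Minimum projected fiber length (mm). Geometries that
#'   squeeze the muscle below this are evaluated at the floor rather than
#'   erroring, so a non-physiological tendon length shows up as an enormous
#'   metabolic cost (tiny force-length capacity, huge activation demand)
#'   instead of a failure; the number of floored samples is returned.
#' @return List with `Q` (J per gait cycle), `peak_force` (N),
#'   `peak_length` (mm, tendon length at peak force), `clamped` (number of
#'   samples at the activation ceiling) and, if requested, `trace`.
#' @export
gait_cycle_cost <- function(gait, pop, params = musculotendon_params(),
                            beta = 1, max_strain = 0.12, trace = FALSE,
                            proj_floor = 1) {
  stopifnot(beta > 0, beta <= 1)
  curve <- recruitment_curve(pop)
  torque <- beta * gait$torque
  f_t <- tendon_force_from_torque(torque, gait$angle, params)
  x <- extension_from_force(pop, f_t, max_strain = max_strain, curve = curve)
  dx <- grid_gradient(x, gait$time)
  dth <- grid_gradient(gait$angle, gait$time)
  lmtu <- mtu_length(gait$angle, params)
  floored <- sum(x > lmtu - proj_floor)
  x_ms <- pmin(x, lmtu - proj_floor)
  ms <- muscle_state(x_ms, gait$angle, dth, dx, params)
  f_m <- f_t / cos(ms$pennation)
  m_act <- activation(f_m, ms$fiber_length, ms$fiber_velocity, params)
  # heat scales with demanded activation (unclamped); capacity floored at 2%
  # of F_max so a fiber transiently at the force-velocity limit yields a
  # large finite demand rather than a division by zero
  cap <- pmax(force_length(ms$fiber_length, params) *
                force_velocity(ms$fiber_velocity, params), 0.02) * params$f_max
  m_demand <- ifelse(f_m == 0, 0, f_m / cap)
  qdot <- metabolic_rate(m_demand, ms$fiber_length, ms$fiber_velocity, f_m,
                         params)
  i_peak <- which.max(f_t)
  out <- list(Q = trapz(gait$time, qdot),
              peak_force = f_t[i_peak],
              peak_length = x[i_peak],
              clamped = attr(m_act, "clamped"),
              floored = floored)
  if (trace) {
    out$trace <- data.frame(
      time_s = gait$time, torque_Nm = torque, tendon_force_N = f_t,
      tendon_length_mm = x, fiber_length_mm = ms$fiber_length,
      fiber_velocity_mm_s = ms$fiber_velocity, pennation_rad = ms$pennation,
      f_l = force_length(ms$fiber_length, params),
      f_v = force_velocity(ms$fiber_velocity, params),
      activation = as.numeric(m_act), qdot_W = qdot)
  }
  out
}
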