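#' Fatigue-damage parameters
#'
#' The fatigue behavior of a collagen fiber follows a linear S-N curve,
#' `sigma_max = a - b log10(n_fail)`, with `a` the ultimate tensile stress at
#' one cycle and `b` the slope per decade of cycles. Cumulative damage over
#' `n` cycles at a given peak stress is described by an exponential failure
#' function `P = -kappa + kappa exp(lambda n / n_fail)` whose constants are
#' fixed by three boundary conditions: P = 0 at n = 0, P = 0.1 at n =
#' n_fail/2 and P = 1 at n = n_fail (see [solve_failure_constants()]).
#'
#' @param a Ultimate tensile stress (MPa), > 0. Default 100.
#' @param b Fatigue-curve slope (MPa per log10 cycle), > 0. Default 8.25.
#' @param kappa,lambda Cumulative-failure constants, > 0. Defaults are the
#'   exact boundary-condition solution kappa = 1/80, lambda = 2 ln 9.
#' @return An object of class `fatigue_params`.
#' @export
fatigue_params <- function(a = 100, b = 8.25,
                           kappa = 0.0125, lambda = 2 * log(9)) {
  stopifnot(a > 0, b > 0, kappa > 0, lambda > 0)
  structure(list(a = a, b = b, kappa = kappa, lambda = lambda),
            class = "fatigue_params")
}

#' Proteolysis parameters
#'
#' Tensile strain shields collagen from enzymatic (collagenase/MMP) cleavage;
#' the per-day probability that a fiber is proteolytically degraded decays
#' exponentially with its peak strain, `P = exp(-phi eps_max)`. The default
#' phi = 300 leaves fibers essentially fully shielded at peak strains of
#' 1.5% and above (P < 0.012).
#'
#' @param phi Dimensionless decay constant on strain, >= 0. Default 300.
#' @return An object of class `proteolysis_params`.
#' @export
proteolysis_params <- function(phi = 300) {
  stopifnot(phi >= 0)
  structure(list(phi = phi), class = "proteolysis_params")
}

#' Triangular repair distribution
#'
#' A repaired fiber's new length is `old * (1 + T)` with T drawn from a
#' triangular distribution on relative length change. Repair after mechanical
#' (fatigue) damage is biased toward lengthening; repair after proteolytic
#' damage is its mirror image, biased toward shortening.
#'
#' @param min,mode,max Signed relative length change (fraction of the
#'   pre-damage length), with min <= mode <= max and min > -1.
#' @return An object of class `repair_distribution`.
#' @export
repair_distribution <- function(min, mode, max) {
  stopifnot(min <= mode, mode <= max, min > -1)
  structure(list(min = min, mode = mode, max = max),
            class = "repair_distribution")
}

#' Default repair distributions
#'
#' Mechanical repair: symmetric triangular(+0.25%, +0.75%, +1.25%), mean
#' +0.75% (lengthening bias). Proteolytic repair: the mirror image,
#' triangular(-1.25%, -0.75%, -0.25%), mean -0.75% (shortening bias). The
#' means set how fast the fiber-length distribution marches during
#' remodeling; the spread sets the dispersion re-injected per repair and
#' hence the equilibrium fiber-length SD.
#' @return A [repair_distribution()].
#' @export
default_mech_repair <- function() repair_distribution(0.0025, 0.0075, 0.0125)

#' @rdname default_mech_repair
#' @export
default_proteo_repair <- function() {
  repair_distribution(-0.0125, -0.0075, -0.0025)
}

#' Cycles to failure at a given peak stress
#'
#' Inverts the S-N curve: `n_fail = 10^((a - sigma_max)/b)`. At
#' `sigma_max = a` a fiber fails within a single cycle; above `a`, in less
#' than one. Non-positive stress returns `Inf` (no fatigue).
#'
#' @param sigma_max Peak stress(es), MPa.
#' @param fatigue A [fatigue_params()].
#' @return Cycles to failure (same length as `sigma_max`).
#' @export
cycles_to_failure <- function(sigma_max, fatigue = fatigue_params()) {
  out <- 10^((fatigue$a - sigma_max) / fatigue$b)
  out[sigma_max <= 0] <- Inf
  out
}

#' Cumulative mechanical failure probability
#'
#' `P = clamp(-kappa + kappa exp(lambda n / n_fail), 0, 1)`: zero at n = 0,
#' 0.1 at half the fatigue life, and (after clamping, since the printed
#' constants overshoot to 1.0006) 1 at the full fatigue life.
#'
#' @param n Number of load cycles, >= 0.
#' @param n_fail Cycles to failure, > 0 (Inf allowed: probability 0).
#' @inheritParams cycles_to_failure
#' @return Failure probability in [0, 1].
#' @export
mech_failure_probability <- function(n, n_fail, fatigue = fatigue_params()) {
  stopifnot(all(n >= 0), all(n_fail > 0))
  p <- -fatigue$kappa + fatigue$kappa * exp(fatigue$lambda * n / n_fail)
  p[is.infinite(n_fail)] <- 0
  pmin(pmax(p, 0), 1)
}

#' Solve the cumulative-failure constants
#'
#' Imposes P(0) = 0 (automatic for the exponential form), P(n_fail/2) =
#' `p_half` and P(n_fail) = 1 on `P(n) = -kappa + kappa exp(lambda n /
#' n_fail)`. Substituting `x = exp(lambda/2)` reduces the pair to
#' `kappa (x^2 - 1) = 1`, `kappa (x - 1) = p_half`, giving `x = (1 -
#' p_half)/p_half` and hence a closed form. For the default p_half = 0.1:
#' kappa = 1/80 = 0.0125 and lambda = 2 ln 9 = 4.394 (to three decimals).
#'
#' @param p_half Failure probability at half the fatigue life, in (0, 1/2);
#'   p_half >= 1/2 makes x <= 1 and the system degenerate.
#' @return List with `kappa` and `lambda`.
#' @export
solve_failure_constants <- function(p_half = 0.1) {
  stopifnot(p_half > 0, p_half < 1)
  x <- (1 - p_half) / p_half
  if (x <= 1) {
    stop("p_half >= 0.5 makes exp(lambda/2) <= 1: no valid (kappa, lambda)")
  }
  list(kappa = p_half / (x - 1), lambda = 2 * log(x))
}

#' Proteolytic failure probability at a given peak strain
#'
#' `P = exp(-phi eps_max)`: a completely slack fiber (zero strain) is
#' degraded with probability 1; strain shields the fiber exponentially.
#'
#' @param eps_max Peak strain(s) during the day's loading, fraction, >= 0.
#' @param prot A [proteolysis_params()].
#' @return Probability in (0, 1].
#' @export
proteolytic_failure_probability <- function(eps_max,
                                            prot = proteolysis_params()) {
  stopifnot(all(eps_max >= 0))
  exp(-prot$phi * eps_max)
}

# Empty damage report.
damage_report <- function(mech_failed = integer(), proteo_failed = integer(),
                          removed_length = 0, synthesized_length = 0) {
  structure(list(mech_failed = mech_failed, proteo_failed = proteo_failed,
                 removed_length = removed_length,
                 synthesized_length = synthesized_length),
            class = "damage_report")
}

#' Apply one block of mechanical fatigue damage
#'
#' For every intact fiber: peak stress at the block's peak tendon length
#' (shorter fibers are stressed more), fatigue life from the S-N curve,
#' failure probability from the cumulative-failure function at the block's
#' cycle count, then an independent Bernoulli draw. Failed fibers are marked
#' broken (they carry no load until repaired). Uses the current RNG state.
#'
#' @param pop A [fiber_population()].
#' @param stretched_length_peak Peak tendon end-to-end length of the block (mm).
#' @param n_cycles Number of load cycles in the block, >= 0.
#' @param fatigue A [fatigue_params()].
#' @return List with the updated `pop` and a `report` (`damage_report`) whose
#'   `mech_failed` holds the failed fiber indices.
#' @export
apply_mechanical_damage <- function(pop, stretched_length_peak, n_cycles,
                                    fatigue = fatigue_params()) {
  stopifnot(n_cycles >= 0)
  sig <- peak_fiber_stress(pop, stretched_length_peak)$stress
  idx <- which(!pop$broken)
  p <- numeric(length(idx))
  s <- sig[idx]
  loaded <- s > 0
  if (any(loaded)) {
    nf <- cycles_to_failure(s[loaded], fatigue)
    p[loaded] <- mech_failure_probability(n_cycles, nf, fatigue)
  }
  fail <- idx[stats::runif(length(idx)) < p]
  pop$broken[fail] <- TRUE
  list(pop = pop,
       report = damage_report(mech_failed = fail,
                              removed_length = sum(pop$slack_lengths[fail])))
}

#' Apply one day's proteolytic damage
#'
#' Applied once per day after the last loading block, using each intact
#' fiber's peak strain of the day: long (slack or barely loaded) fibers are
#' poorly strain-shielded and fail with high probability, short taut fibers
#' almost never. Uses the current RNG state.
#'
#' @inheritParams apply_mechanical_damage
#' @param prot A [proteolysis_params()].
#' @return List with the updated `pop` and a `report` whose `proteo_failed`
#'   holds the failed fiber indices.
#' @export
apply_proteolytic_damage <- function(pop, stretched_length_peak,
                                     prot = proteolysis_params()) {
  eps <- peak_fiber_stress(pop, stretched_length_peak)$strain
  idx <- which(!pop$broken)
  p <- proteolytic_failure_probability(eps[idx], prot)
  fail <- idx[stats::runif(length(idx)) < p]
  pop$broken[fail] <- TRUE
  list(pop = pop,
       report = damage_report(proteo_failed = fail,
                              removed_length = sum(pop$slack_lengths[fail])))
}

#' Sample from a triangular distribution
#'
#' Inverse-CDF sampler for the triangular distribution on
#' \[min, max\] with the given mode.
#'
#' @param n Number of draws.
#' @param dist A [repair_distribution()].
#' @return Numeric vector of draws.
#' @export
rtriangular <- function(n, dist) {
  a <- dist$min; c <- dist$mode; b <- dist$max
  if (a == b) return(rep(a, n))
  u <- stats::runif(n)
  fc <- (c - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (c - a)),
         b - sqrt((1 - u) * (b - a) * (b - c)))
}

#' Sample a repaired fiber length
#'
#' `new = old * (1 + T)` with T triangular; the mean relative change
#' converges to `(min + mode + max)/3`.
#'
#' @param old_length Pre-damage fiber length(s), mm, > 0.
#' @param dist A [repair_distribution()].
#' @return Repaired length(s), mm.
#' @export
sample_repair_length <- function(old_length, dist) {
  stopifnot(all(old_length > 0))
  new_length <- old_length * (1 + rtriangular(length(old_length), dist))
  if (any(new_length <= 0)) stop("repair produced a non-positive length")
  new_length
}

#' Repair all damaged fibers
#'
#' Every broken fiber is replaced in place by a repaired fiber drawn from the
#' distribution matching its damage mode, restoring the fiber count exactly.
#' Turnover is accumulated either as whole-fiber lengths (default: removed =
#' sum of pre-damage lengths, synthesized = sum of repaired lengths) or as
#' segment lengths (only the net length change of each repair counts, split
#' into removed and synthesized portions).
#'
#' @param pop A [fiber_population()] with broken fibers marked.
#' @param report A combined `damage_report` with `mech_failed` and
#'   `proteo_failed` index sets.
#' @param mech_dist,proteo_dist [repair_distribution()]s for the two damage
#'   modes.
#' @param accounting `"whole_fiber"` or `"segment"`.
#' @return List with the repaired `pop` (no broken fibers) and the `report`
#'   updated with `removed_length` and `synthesized_length` (mm).
#' @export
repair_all <- function(pop, report,
                       mech_dist = default_mech_repair(),
                       proteo_dist = default_proteo_repair(),
                       accounting = c("whole_fiber", "segment")) {
  accounting <- match.arg(accounting)
  removed <- 0; synthesized <- 0
  for (set in list(list(idx = report$mech_failed, dist = mech_dist),
                   list(idx = report$proteo_failed, dist = proteo_dist))) {
    if (length(set$idx) == 0L) next
    old <- pop$slack_lengths[set$idx]
    new <- sample_repair_length(old, set$dist)
    pop$slack_lengths[set$idx] <- new
    pop$broken[set$idx] <- FALSE
    if (accounting == "whole_fiber") {
      removed <- removed + sum(old)
      synthesized <- synthesized + sum(new)
    } else {
      removed <- removed + sum(pmax(0, old - new))
      synthesized <- synthesized + sum(pmax(0, new - old))
    }
  }
  report$removed_length <- removed
  report$synthesized_length <- synthesized
  list(pop = pop, report = report)
}
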