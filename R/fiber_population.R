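#' Collagen fiber population
#'
#' Constructs the mechanical state of a discretized "string" tendon: a set of
#' collagen fibers that share material constants but differ in slack length.
#' A fiber carries load only once the tendon's end-to-end length exceeds the
#' fiber's slack length, so the distribution of slack lengths produces the
#' tendon's nonlinear toe region by sequential fiber recruitment.
#'
#' Units are millimetres for lengths, mm^2 for areas and MPa for moduli, so
#' that forces come out in newtons and energies in N.mm.
#'
#' @param slack_lengths Numeric vector of per-fiber slack lengths L_i (mm),
#'   all strictly positive.
#' @param fiber_area Average collagen fiber cross-sectional area A_F (mm^2).
#' @param tendon_area Whole-tendon cross-sectional area A_T (mm^2).
#' @param youngs_modulus Tendon Young's modulus E_T (MPa); 1 GPa = 1000 MPa.
#' @param broken Optional logical vector marking fibers that have failed and
#'   not yet been repaired; broken fibers carry no load.
#'
#' @return An object of class `fiber_population`.
#' @seealso [init_gaussian_population()], [tendon_force()]
#' @export
fiber_population <- function(slack_lengths,
                             fiber_area = 6.15e-4,
                             tendon_area = 60,
                             youngs_modulus = 1000,
                             broken = NULL) {
  slack_lengths <- as.numeric(slack_lengths)
  if (length(slack_lengths) == 0L) {
    stop("a fiber population needs at least one fiber")
  }
  if (any(!is.finite(slack_lengths)) || any(slack_lengths <= 0)) {
    stop("all slack lengths must be finite and > 0")
  }
  if (fiber_area <= 0 || tendon_area <= 0 || youngs_modulus < 0) {
    stop("fiber_area and tendon_area must be > 0, youngs_modulus >= 0")
  }
  if (is.null(broken)) {
    broken <- logical(length(slack_lengths))
  }
  stopifnot(length(broken) == length(slack_lengths))
  structure(
    list(
      slack_lengths = slack_lengths,
      fiber_area = fiber_area,
      tendon_area = tendon_area,
      youngs_modulus = youngs_modulus,
      broken = broken
    ),
    class = "fiber_population"
  )
}

#' @export
print.fiber_population <- function(x, ...) {
  li <- x$slack_lengths[!x$broken]
  cat("<fiber_population>\n")
  cat(sprintf("  fibers:      %d (%d intact, %d broken)\n",
              length(x$slack_lengths), length(li), sum(x$broken)))
  cat(sprintf("  mean length: %.3f mm   SD: %.4f mm\n", mean(li), stats::sd(li)))
  cat(sprintf("  range:       [%.3f, %.3f] mm\n", min(li), max(li)))
  cat(sprintf("  A_F = %g mm^2, A_T = %g mm^2, E_T = %g MPa\n",
              x$fiber_area, x$tendon_area, x$youngs_modulus))
  invisible(x)
}

#' @export
summary.fiber_population <- function(object, ...) {
  li <- object$slack_lengths[!object$broken]
  c(n_total = length(object$slack_lengths), n_intact = length(li),
    mean_mm = mean(li), sd_mm = stats::sd(li),
    min_mm = min(li), max_mm = max(li))
}

# Intact slack lengths (the load-bearing subset).
intact_lengths <- function(pop) pop$slack_lengths[!pop$broken]

#' Mean tendon length and tendon slack length
#'
#' The mean tendon length L_T is the mean of the slack lengths of all intact
#' fibers; the tendon slack length L_S is the slack length of the shortest
#' intact fiber (the length at which the tendon first bears load).
#'
#' @param pop A [fiber_population()].
#' @return Length in mm.
#' @export
mean_tendon_length <- function(pop) mean(intact_lengths(pop))

#' @rdname mean_tendon_length
#' @export
tendon_slack_length <- function(pop) min(intact_lengths(pop))

#' Estimate the number of primary collagen fibers in a tendon
#'
#' Divides the whole-tendon cross-sectional area by the cross-sectional area
#' of a single fiber of the given diameter (circular cross-section assumed).
#' With the default human Achilles values (60 mm^2, 28 um) this is about
#' 100,000 fibers.
#'
#' @param tendon_area Tendon cross-sectional area (mm^2), > 0.
#' @param fiber_diameter Average fiber diameter (micrometres), > 0.
#' @return Integer fiber count, `round(A_T / (pi (d/2)^2))`.
#' @examples
#' estimate_fiber_count(60, 28)
#' @export
estimate_fiber_count <- function(tendon_area = 60, fiber_diameter = 28) {
  if (tendon_area <= 0 || fiber_diameter <= 0) {
    stop("tendon_area and fiber_diameter must be > 0")
  }
  fiber_area <- pi * (fiber_diameter / 2000)^2  # um -> mm
  as.integer(round(tendon_area / fiber_area))
}

#' Draw an initial Gaussian fiber-length population
#'
#' The initial profile of fiber slack lengths is normal with the given mean
#' and standard deviation. Non-positive draws are resampled (not clipped) so
#' the distribution shape is preserved; resampling is vanishingly rare at
#' physiological parameters (mean ~275 mm, SD ~2 mm).
#'
#' Uses the current RNG state: call `set.seed()` beforehand for reproducible
#' populations.
#'
#' @param n Number of fibers, > 0.
#' @param mean_length Mean slack length (mm), > 0.
#' @param sd Standard deviation of slack length (mm), >= 0.
#' @inheritParams fiber_population
#' @return A [fiber_population()].
#' @export
init_gaussian_population <- function(n, mean_length, sd,
                                     fiber_area = 6.15e-4,
                                     tendon_area = 60,
                                     youngs_modulus = 1000) {
  if (n <= 0) stop("n must be > 0")
  if (mean_length <= 0) stop("mean_length must be > 0")
  if (sd < 0) stop("sd must be >= 0")
  lengths <- stats::rnorm(n, mean_length, sd)
  n_resampled <- 0L
  while (any(bad <- lengths <= 0)) {
    n_resampled <- n_resampled + sum(bad)
    lengths[bad] <- stats::rnorm(sum(bad), mean_length, sd)
  }
  if (n_resampled > 0.01 * n) {
    warning(sprintf(
      "positivity resampling affected %d of %d draws; sd is large relative to mean_length",
      n_resampled, n))
  }
  fiber_population(lengths, fiber_area, tendon_area, youngs_modulus)
}

#' Deterministic idealized normal population
#'
#' Places fiber slack lengths at the normal quantiles of evenly spaced
#' probabilities, giving a smooth, noise-free representation of a Gaussian
#' geometry. Used for metabolic cost-surface sweeps, where sampling noise
#' would roughen the surface.
#'
#' @inheritParams init_gaussian_population
#' @return A [fiber_population()].
#' @export
idealized_population <- function(n, mean_length, sd,
                                 fiber_area = 6.15e-4,
                                 tendon_area = 60,
                                 youngs_modulus = 1000) {
  q <- stats::qnorm(stats::ppoints(n))
  fiber_population(mean_length + sd * q, fiber_area, tendon_area, youngs_modulus)
}

#' Per-fiber extension at a given tendon length
#'
#' A fiber whose slack length exceeds the tendon's current end-to-end length
#' is slack and has zero extension; otherwise its extension is the difference.
#' `stretched_length` is the tendon's absolute end-to-end length (mm), not an
#' extension past slack.
#'
#' @param pop A [fiber_population()].
#' @param stretched_length Tendon end-to-end length (mm), >= 0.
#' @return Numeric vector of extensions (mm), one per fiber (broken fibers
#'   report 0).
#' @export
fiber_extensions <- function(pop, stretched_length) {
  stopifnot(length(stretched_length) == 1L, stretched_length >= 0)
  ext <- pmax(0, stretched_length - pop$slack_lengths)
  ext[pop$broken] <- 0
  ext
}

#' Per-fiber stiffness
#'
#' Uniform material along the fiber gives k_i = A_F E_T / L_i (N/mm):
#' longer fibers are more compliant.
#'
#' @param pop A [fiber_population()].
#' @return Numeric vector of stiffnesses (N/mm), one per fiber.
#' @export
fiber_stiffness <- function(pop) {
  pop$fiber_area * pop$youngs_modulus / pop$slack_lengths
}

# Piecewise-linear recruitment curve of the intact population.
# Sorting the intact slack lengths gives breakpoints; between breakpoints
# F(x) = x * cumk[j] - cumkl[j] where j fibers are recruited. force_at_break
# is the tendon force exactly at each breakpoint, used for exact inversion.
recruitment_curve <- function(pop) {
  li <- intact_lengths(pop)
  if (length(li) == 0L) stop("no intact fibers: tendon is ruptured")
  li <- sort(li)
  k <- pop$fiber_area * pop$youngs_modulus / li
  cumk <- cumsum(k)
  cumkl <- cumsum(k * li)
  force_at_break <- li * cumk - cumkl  # force when x == li[j] (j-th fiber just taut)
  list(lengths = li, cumk = cumk, cumkl = cumkl, force_at_break = force_at_break)
}

#' Tendon force at a given end-to-end length
#'
#' Sums per-fiber linear spring forces over the recruited (taut, intact)
#' fibers. The result is a non-negative, non-decreasing, convex piecewise
#' linear function of `stretched_length`, zero at and below the tendon slack
#' length.
#'
#' @param pop A [fiber_population()].
#' @param stretched_length Tendon end-to-end length(s), mm; may be a vector.
#' @param curve Optional precomputed recruitment curve (internal use).
#' @return Force(s) in N.
#' @export
tendon_force <- function(pop, stretched_length, curve = NULL) {
  stopifnot(all(stretched_length >= 0))
  if (is.null(curve)) curve <- recruitment_curve(pop)
  j <- findInterval(stretched_length, curve$lengths)
  out <- numeric(length(stretched_length))
  pos <- j > 0L
  out[pos] <- stretched_length[pos] * curve$cumk[j[pos]] - curve$cumkl[j[pos]]
  pmax(out, 0)
}

#' Tendon end-to-end length at a given force
#'
#' Exact inverse of [tendon_force()]: locates the linear segment of the
#' recruitment curve containing the target force and solves it in closed
#' form. Zero force maps to the tendon slack length (the slack convention).
#'
#' @param pop A [fiber_population()].
#' @param force Force(s) in N, >= 0.
#' @param max_strain Cap on mean tendon strain; a force requiring more than
#'   this strain (relative to the mean tendon length) is flagged as a
#'   non-physiological load and raises an error. Default 0.12.
#' @param curve Optional precomputed recruitment curve.
#' @return Stretched length(s) in mm.
#' @export
extension_from_force <- function(pop, force, max_strain = 0.12, curve = NULL) {
  stopifnot(all(is.finite(force)), all(force >= 0))
  if (is.null(curve)) curve <- recruitment_curve(pop)
  n <- length(curve$lengths)
  # segment index: number of breakpoints with breakpoint-force <= target
  j <- findInterval(force, curve$force_at_break)
  out <- numeric(length(force))
  zero <- force == 0
  out[zero] <- curve$lengths[1L]
  pos <- !zero
  jj <- pmax(j[pos], 1L)
  out[pos] <- (force[pos] + curve$cumkl[jj]) / curve$cumk[jj]
  lim <- mean(curve$lengths) * (1 + max_strain)
  if (any(out > lim)) {
    stop(sprintf(
      "non-physiological load: force requires tendon strain above %.0f%% cap",
      100 * max_strain))
  }
  out
}

#' Per-fiber peak stress and strain at a given tendon length
#'
#' sigma_i = E_T dL_i / L_i and eps_i = dL_i / L_i. At any tendon length the
#' shortest recruited fibers carry the highest stress.
#'
#' @inheritParams fiber_extensions
#' @return List with numeric vectors `stress` (MPa) and `strain` (fraction).
#' @export
peak_fiber_stress <- function(pop, stretched_length) {
  ext <- fiber_extensions(pop, stretched_length)
  strain <- ext / pop$slack_lengths
  list(stress = pop$youngs_modulus * strain, strain = strain)
}

#' Elastic strain energy stored at a given tendon length
#'
#' Sum of (1/2) k_i dL_i^2 over recruited fibers; equals the area under the
#' force-extension curve from the slack length.
#'
#' @inheritParams fiber_extensions
#' @return Energy in N.mm (1 J = 1000 N.mm).
#' @export
strain_energy <- function(pop, stretched_length) {
  stopifnot(stretched_length >= tendon_slack_length(pop))
  ext <- fiber_extensions(pop, stretched_length)
  sum(0.5 * fiber_stiffness(pop) * ext^2)
}

#' Write / read a fiber population snapshot
#'
#' Two-column delimited text (fiber index, slack length in mm) preceded by
#' `#`-prefixed header lines carrying the material constants.
#'
#' @param pop A [fiber_population()].
#' @param path File path.
#' @return `read_population` returns a [fiber_population()];
#'   `write_population` returns `path` invisibly.
#' @export
write_population <- function(pop, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fiber_area_mm2: %.10g", pop$fiber_area),
    sprintf("# tendon_area_mm2: %.10g", pop$tendon_area),
    sprintf("# youngs_modulus_MPa: %.10g", pop$youngs_modulus),
    "fiber\tslack_length_mm"
  ), con)
  utils::write.table(
    data.frame(fiber = seq_along(pop$slack_lengths),
               slack_length_mm = pop$slack_lengths),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    as.numeric(sub(".*: ", "", m))
  }
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           skip = length(hdr) + 1L)
  fiber_population(tab[[2L]],
                   fiber_area = get("fiber_area_mm2"),
                   tendon_area = get("tendon_area_mm2"),
                   youngs_modulus = get("youngs_modulus_MPa"))
}
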