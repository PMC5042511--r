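test_that("cycles to failure invert the fatigue curve", {
  ft <- fatigue_params(a = 100, b = 8.25)
  expect_equal(cycles_to_failure(100, ft), 1)
  expect_equal(cycles_to_failure(91.75, ft), 10)
  expect_equal(cycles_to_failure(55, ft), 10^(45 / 8.25))
  expect_equal(cycles_to_failure(55, ft), 2.848e5, tolerance = 1e-3)
  # strictly decreasing in stress; above the intercept fails within one cycle
  s <- seq(10, 110, by = 5)
  expect_true(all(diff(cycles_to_failure(s, ft)) < 0))
  expect_true(all(cycles_to_failure(c(100, 105), ft) <= 1))
  expect_identical(cycles_to_failure(0, ft), Inf)
})

test_that("cumulative failure probability hits its boundary conditions", {
  ft <- fatigue_params()
  expect_equal(mech_failure_probability(0, 1000, ft), 0)
  expect_equal(mech_failure_probability(500, 1000, ft), 0.1, tolerance = 1e-3)
  # the printed constants overshoot slightly at n = n_fail and are clamped
  ft_printed <- fatigue_params(kappa = 0.0125, lambda = 4.395)
  raw <- -0.0125 + 0.0125 * exp(4.395)
  expect_gt(raw, 1)
  expect_lt(raw, 1.001)
  expect_equal(mech_failure_probability(1000, 1000, ft_printed), 1)
  # monotone non-decreasing in n
  p <- mech_failure_probability(seq(0, 1000, by = 50), 1000, ft)
  expect_true(all(diff(p) >= 0))
  expect_equal(mech_failure_probability(100, Inf, ft), 0)
})

test_that("boundary-condition solve recovers the closed-form constants", {
  sol <- solve_failure_constants(0.1)
  expect_equal(sol$kappa, 1 / 80)
  expect_equal(sol$lambda, 2 * log(9))
  # self-consistency: all three boundary conditions to near machine precision
  p_at <- function(n_over_nfail) {
    -sol$kappa + sol$kappa * exp(sol$lambda * n_over_nfail)
  }
  expect_equal(p_at(0), 0, tolerance = 1e-12)
  expect_equal(p_at(0.5), 0.1, tolerance = 1e-12)
  expect_equal(p_at(1), 1, tolerance = 1e-12)
  # p_half = 0.5 makes the substitution x = exp(lambda/2) collapse to x = 1
  expect_error(solve_failure_constants(0.5), "no valid")
})

test_that("proteolytic failure probability decays exponentially with strain", {
  pr <- proteolysis_params(phi = 300)
  expect_equal(proteolytic_failure_probability(0, pr), 1)
  expect_equal(proteolytic_failure_probability(0.015, pr), exp(-4.5))
  expect_equal(proteolytic_failure_probability(0.015, pr), 0.0111,
               tolerance = 1e-2)
  eps <- seq(0, 0.05, by = 0.005)
  expect_true(all(diff(proteolytic_failure_probability(eps, pr)) < 0))
  pr0 <- proteolysis_params(phi = 0)
  expect_equal(proteolytic_failure_probability(eps, pr0), rep(1, length(eps)))
})

test_that("mechanical damage draws match the binomial expectation", {
  ft <- fatigue_params()
  pop <- fiber_population(rep(100, 10000), fiber_area = 1e-3)
  # choose the load so each fiber has P = 0.1: n = n_fail/2
  x <- 100 * 1.045  # 4.5% strain -> 45 MPa
  nf <- cycles_to_failure(45, ft)
  counts <- vapply(1:25, function(s) {
    set.seed(s)
    length(apply_mechanical_damage(pop, x, nf / 2, ft)$report$mech_failed)
  }, numeric(1))
  # binomial(10^4, 0.1): mean 1000, sd 30
  expect_lt(abs(mean(counts) - 1000), 3 * 30 / sqrt(25))
  expect_lt(abs(sd(counts) - 30), 15)

  # degenerate cases
  set.seed(1)
  expect_length(
    apply_mechanical_damage(pop, 100, 1000, ft)$report$mech_failed, 0)
  all_fail <- apply_mechanical_damage(pop, 100 * 1.10, 10, ft)  # sigma >= a
  expect_length(all_fail$report$mech_failed, 10000)
})

test_that("proteolysis spares strained fibers and removes slack ones", {
  pr <- proteolysis_params(300)
  # all fibers at >= 1.5% strain: expected failures below 1.2% of fibers
  pop <- fiber_population(rep(100, 10000), fiber_area = 1e-3)
  counts <- vapply(1:10, function(s) {
    set.seed(s)
    length(apply_proteolytic_damage(pop, 101.6, pr)$report$proteo_failed)
  }, numeric(1))
  expect_lt(mean(counts), 0.012 * 10000)
  # completely slack tendon: every fiber fails with probability 1
  set.seed(2)
  slack <- apply_proteolytic_damage(pop, 100, pr)
  expect_length(slack$report$proteo_failed, 10000)
  # one slack and one taut fiber: only the slack one is ever likely to fail
  two <- fiber_population(c(100, 120), fiber_area = 1e-3)
  res <- vapply(1:50, function(s) {
    set.seed(s)
    fails <- apply_proteolytic_damage(two, 102, pr)$report$proteo_failed
    c(1 %in% fails, 2 %in% fails)
  }, logical(2))
  expect_lt(mean(res[1, ]), 0.2)   # taut at 2%: P = e^-6 ~ 0.0025
  expect_equal(mean(res[2, ]), 1)  # slack: P = 1
})

test_that("triangular repair sampler has the textbook mean", {
  d <- repair_distribution(-0.02, 0.005, 0.02)
  set.seed(9)
  draws <- rtriangular(1e5, d)
  expect_true(all(draws >= -0.02 & draws <= 0.02))
  m <- (-0.02 + 0.005 + 0.02) / 3
  v <- (0.02^2 + 0.005^2 + 0.02^2 - (-0.02 * 0.005) - (0.005 * 0.02) -
          (-0.02 * 0.02)) / 18
  expect_lt(abs(mean(draws) - m), 3 * sqrt(v / 1e5))
  # degenerate distribution is deterministic
  dd <- repair_distribution(0.01, 0.01, 0.01)
  expect_equal(sample_repair_length(100, dd), 101)
  # defaults: mechanical repair lengthens on average, proteolytic shortens
  set.seed(4)
  mech <- mean(rtriangular(2e4, default_mech_repair()))
  prot <- mean(rtriangular(2e4, default_proteo_repair()))
  expect_gt(mech, 0)
  expect_lt(prot, 0)
  expect_error(repair_distribution(-1.5, 0, 0.5), "min > -1")
})

test_that("repair restores fiber count and accumulates turnover lengths", {
  pop <- small_pop(500)
  # break a random subset under each damage mode
  set.seed(6)
  mech_idx <- sample(500, 40)
  proteo_idx <- sample(setdiff(1:500, mech_idx), 30)
  pop$broken[c(mech_idx, proteo_idx)] <- TRUE
  rep <- structure(list(mech_failed = mech_idx, proteo_failed = proteo_idx,
                        removed_length = 0, synthesized_length = 0),
                   class = "damage_report")
  old_lengths <- pop$slack_lengths
  out <- repair_all(pop, rep)
  expect_equal(length(out$pop$slack_lengths), 500)
  expect_false(any(out$pop$broken))
  expect_equal(out$report$removed_length,
               sum(old_lengths[c(mech_idx, proteo_idx)]))
  expect_equal(out$report$synthesized_length,
               sum(out$pop$slack_lengths[c(mech_idx, proteo_idx)]))
  # untouched fibers unchanged
  keep <- setdiff(1:500, c(mech_idx, proteo_idx))
  expect_equal(out$pop$slack_lengths[keep], old_lengths[keep])

  # empty report leaves the population untouched
  out2 <- repair_all(small_pop(100), structure(
    list(mech_failed = integer(), proteo_failed = integer(),
         removed_length = 0, synthesized_length = 0),
    class = "damage_report"))
  expect_equal(out2$pop$slack_lengths, small_pop(100)$slack_lengths)

  # degenerate +1% repair shifts every damaged fiber by exactly 1%
  pop3 <- small_pop(200)
  pop3$broken[] <- TRUE
  rep3 <- structure(list(mech_failed = 1:200, proteo_failed = integer(),
                         removed_length = 0, synthesized_length = 0),
                    class = "damage_report")
  d1 <- repair_distribution(0.01, 0.01, 0.01)
  out3 <- repair_all(pop3, rep3, mech_dist = d1)
  expect_equal(out3$pop$slack_lengths, small_pop(200)$slack_lengths * 1.01)
})

test_that("segment accounting counts only net length changes", {
  pop <- fiber_population(c(100, 100))
  pop$broken[] <- TRUE
  rep <- structure(list(mech_failed = 1:2, proteo_failed = integer(),
                        removed_length = 0, synthesized_length = 0),
                   class = "damage_report")
  d1 <- repair_distribution(0.01, 0.01, 0.01)
  out <- repair_all(pop, rep, mech_dist = d1, accounting = "segment")
  expect_equal(out$report$synthesized_length, 2)   # two fibers grew 1 mm each
  expect_equal(out$report$removed_length, 0)
})

test_that("mechanical damage alone erodes the short tail of the distribution", {
  pop <- small_pop(3000, seed = 21)
  # 5.5% tendon strain held as a constant peak extension (55 MPa mean stress)
  out <- simulate_constant_load(pop, days = 15, proteo = FALSE,
                                repair = FALSE,
                                peak_length = 1.055 * mean(pop$slack_lengths))
  tr <- out$trajectory
  expect_true(all(diff(tr$min_length_mm) >= 0))
  expect_lt(tail(tr$n_intact, 1), 3000)
  expect_gt(tail(tr$min_length_mm, 1), min(pop$slack_lengths))
})

test_that("proteolysis alone erodes the long tail of the distribution", {
  pop <- small_pop(3000, seed = 22)
  # lighter load (1.5% peak-fiber strain) so the long tail is weakly shielded
  out <- simulate_constant_load(pop, days = 15, mech = FALSE,
                                repair = FALSE,
                                peak_length = 1.015 * min(pop$slack_lengths))
  tr <- out$trajectory
  expect_true(all(diff(tr$max_length_mm) <= 0))
  expect_lt(tail(tr$max_length_mm, 1), max(pop$slack_lengths))
})

test_that("damage with biased repair marches the distribution", {
  # mechanical damage + lengthening-biased repair: mean length rises and the
  # fiber count is conserved every day
  pop <- small_pop(3000, seed = 23)
  out <- simulate_constant_load(pop, days = 90, proteo = FALSE,
                                peak_length = 1.055 * mean(pop$slack_lengths))
  tr <- out$trajectory
  expect_true(all(tr$n_intact == 3000))
  expect_gt(mean(tail(tr$mean_length_mm, 10)),
            mean(head(tr$mean_length_mm, 10)))
  # proteolysis + shortening-biased repair: mean length falls
  pop2 <- small_pop(3000, seed = 24)
  out2 <- simulate_constant_load(pop2, days = 90, mech = FALSE,
                                 peak_length = 1.015 * min(pop2$slack_lengths))
  tr2 <- out2$trajectory
  expect_true(all(tr2$n_intact == 3000))
  expect_lt(mean(tail(tr2$mean_length_mm, 10)),
            mean(head(tr2$mean_length_mm, 10)))
})
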