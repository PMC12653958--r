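test_that("Weibull anchors: 63.2% at the characteristic times", {
  p <- failure_params()
  expect_equal(p_repair(5.0, p), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(p_repair(0, p), 0)
  tf <- time_to_failure(0.22, 1.71, p)
  expect_equal(p_fail(tf, 78.5, tf, p), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(p_fail(0, 78.5, tf, p), 0)
  expect_equal(p_fail(tf, 2 * 78.5, tf, p), 1 - exp(-2), tolerance = 1e-12)
})

test_that("time to failure matches an independent closed-form evaluation", {
  # frozen from a one-line evaluation of the damage law:
  # 1.0 * (1 / (2*6000/1.71)) / 365.25 * (1.03*0.22)^-12.9 = 80.9789 y
  expect_equal(time_to_failure(0.22, 1.71), 80.97890, tolerance = 1e-6)
})

test_that("time to failure scales as the power law prescribes", {
  p <- failure_params()
  t1 <- time_to_failure(0.2, 1.71, p)
  # doubling strain multiplies t_f by exactly 2^-12.9
  expect_equal(time_to_failure(0.4, 1.71, p) / t1, 2^(-12.9),
               tolerance = 1e-12)
  # halving the daily distance doubles t_f
  p_half <- failure_params(daily_distance = 3000)
  expect_equal(time_to_failure(0.2, 1.71, p_half) / t1, 2, tolerance = 1e-12)
  # strictly decreasing in strain
  tfs <- time_to_failure(seq(0.15, 0.4, by = 0.01), 1.71, p)
  expect_true(all(diff(tfs) < 0))
  # stride vs step counting differ by the factor two in cycle rate
  p_strides <- failure_params(cycle_count = "strides")
  expect_equal(time_to_failure(0.2, 1.71, p_strides) / t1, 2,
               tolerance = 1e-12)
  expect_error(time_to_failure(0, 1.71), "positive")
})

test_that("failure density is the derivative of the cumulative law", {
  p <- failure_params()
  tf <- 40
  t <- seq(0, tf, by = 0.005)
  f <- failure_density(t, 78.5, tf, p)
  expect_true(all(f >= 0))
  # quadrature over [0, t_f] with V = V_ref recovers 1 - 1/e
  expect_equal(pracma::trapz(t, f), 1 - exp(-1), tolerance = 1e-4)
  # density integrates to ~1 over a long horizon (normalisation)
  t_long <- seq(0, 12 * tf, by = 0.05)
  expect_equal(pracma::trapz(t_long, failure_density(t_long, 78.5, tf, p)), 1,
               tolerance = 1e-3)
})

test_that("repair-adjusted probability is a valid curve bounded by the unrepaired one", {
  p <- failure_params()
  res <- p_fail_with_repair(78.5, 30, p)
  expect_equal(res$p_fail[1], 0)
  expect_equal(res$p_fail_with_repair[1], 0)
  expect_true(all(diff(res$p_fail) >= 0))
  expect_true(all(diff(res$p_fail_with_repair) >= -1e-12))
  expect_true(all(res$p_fail_with_repair <= res$p_fail + 1e-12))
  expect_true(all(res$p_fail_with_repair >= 0 & res$p_fail_with_repair <= 1))
})

test_that("disabling repair collapses the adjusted curve onto the cumulative law", {
  p_off <- failure_params(repair_time = 1e9)
  res <- p_fail_with_repair(78.5, 30, p_off)
  expect_lt(max(abs(res$p_fail_with_repair - res$p_fail)), 1e-4)
})

test_that("the damage-age repair convention matches its Monte-Carlo semantics", {
  # "failed and not yet repaired at T": P(T_fail <= T and repair duration
  # since damage exceeds T - T_fail); unlike the absolute-time convention
  # this curve may legitimately decline as old damage gets repaired
  p_conv <- failure_params(repair_reference = "since_damage",
                           time_step = 0.05)
  res <- p_fail_with_repair(78.5, 30, p_conv)
  expect_true(all(res$p_fail_with_repair <= res$p_fail + 1e-9))
  expect_true(all(res$p_fail_with_repair >= 0))
  set.seed(99)
  n <- 5e5
  t_fail <- rweibull(n, shape = 14.3 / 12.9, scale = 30)
  rep_dur <- rweibull(n, shape = 5.2, scale = 5.0)
  for (tt in c(10, 25, 37)) {
    mc <- mean(t_fail <= tt & rep_dur > tt - t_fail)
    grid_val <- res$p_fail_with_repair[which.min(abs(res$time - tt))]
    expect_lt(abs(grid_val - mc), 0.005)
  }
})

test_that("terminal probability is monotone in the scientific drivers", {
  p <- failure_params()
  term <- function(eps, params = p, stride = 1.71, vol = 78.5) {
    p_fail_with_repair(vol, time_to_failure(eps, stride, params),
                       params)$p_terminal
  }
  # strain
  eps_grid <- c(0.18, 0.21, 0.24, 0.27)
  expect_true(all(diff(vapply(eps_grid, term, numeric(1))) > 0))
  # stressed volume
  expect_gt(p_fail_with_repair(2 * 78.5, 30, p)$p_terminal,
            p_fail_with_repair(78.5, 30, p)$p_terminal)
  # daily distance (more cycles, earlier failure)
  expect_gt(term(0.22, failure_params(daily_distance = 12000)), term(0.22))
  # horizon (non-decreasing; saturates once repair dominates)
  expect_gte(p_fail_with_repair(78.5, 30, failure_params(horizon = 50))$p_terminal,
             p_fail_with_repair(78.5, 30, p)$p_terminal)
  expect_gt(p_fail_with_repair(78.5, 30, failure_params(horizon = 8))$p_terminal,
            p_fail_with_repair(78.5, 30, failure_params(horizon = 4))$p_terminal)
  # more aggressive repair lowers risk
  expect_lt(p_fail_with_repair(78.5, 30, failure_params(repair_time = 2.5))$p_terminal,
            p_fail_with_repair(78.5, 30, p)$p_terminal)
})

test_that("the time grid is converged at the default step", {
  p1 <- failure_params(time_step = 0.01)
  p2 <- failure_params(time_step = 0.005)
  tf <- time_to_failure(0.24, 1.71, p1)
  expect_lt(abs(p_fail_with_repair(78.5, tf, p1)$p_terminal -
                  p_fail_with_repair(78.5, tf, p2)$p_terminal), 1e-4)
})

test_that("parameter validation rejects nonsense", {
  expect_error(failure_params(repair_time = -1), "positive")
  expect_error(failure_params(time_step = 6), "smaller than 'repair_time'")
  expect_error(p_fail(-1, 78.5, 30), "non-negative")
  expect_error(p_fail(1, 78.5, 0), "positive")
})
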