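test_that("growth-phase division and lesion curves match the closed forms", {
  tis <- fig_tissue()  # N0 = 10, r = 0.15
  mut <- fig_mut()     # lambda1 = 0.01, lambda2 = 0.001
  expect_equal(divisions_growth(0, tis), 0)
  # e^{rt} = 10 at t = log(10)/r, so d = N0 (10 - 1) = 90
  t90 <- log(10) / tis$r
  expect_equal(divisions_growth(t90, tis), 90)
  expect_equal(errors_from_divisions(90, mut), 0.9)
  expect_equal(lesions_growth(90, tis, mut), 0.6)
  expect_equal(lesions_growth(0, tis, mut), 0)
  expect_error(divisions_growth(100, tis), "growth phase")
  expect_error(lesions_growth(91, tis, mut), "growth phase")
})

test_that("stable-phase waiting time and division curve match the renewal forms", {
  tis <- fig_tissue()  # a_d = 0.16, b = 0.01, NL = 100
  wt <- stable_waiting_time(tis)
  expect_equal(wt, 1 / (0.01 * 100) + 1 / (0.16 * 99))
  expect_equal(wt, 1.0631, tolerance = 1e-4)
  # a >> b limit approaches 1/(b NL)
  fast <- tissue_params(tis$N0, tis$NL, tis$r, a_d = 1e8, b = 0.01)
  expect_equal(stable_waiting_time(fast), 1, tolerance = 1e-4)
  # doubling b halves only the removal-wait component
  tis2 <- tissue_params(tis$N0, tis$NL, tis$r, tis$a_d, b = 0.02)
  expect_equal(stable_waiting_time(tis2), 0.5 + 1 / (0.16 * 99))

  sched <- phase_schedule(tis, fig_mut())
  expect_equal(divisions_stable(sched$t_prime, tis), 90)
  expect_equal(divisions_stable(sched$t_prime + 10 * wt, tis), 100)
  expect_error(divisions_stable(0, tis), "before the growth-phase end")
  expect_error(stable_waiting_time(tissue_params(1, 1, 0, 1, 1)), "NL >= 2")
})

test_that("stable-phase lesion curve continues the growth phase", {
  tis <- fig_tissue()
  mut <- fig_mut()
  sched <- phase_schedule(tis, mut)
  expect_equal(sched$W_prime, 0.6)
  expect_equal(lesions_stable(90, tis, mut), sched$W_prime)
  # one extra division adds NL * lambda2 * (one waiting time)
  expect_equal(lesions_stable(91, tis, mut),
               0.6 + 100 * 0.001 * stable_waiting_time(tis))
  expect_error(lesions_stable(80, tis, mut), "phase boundary")
  mut0 <- mutation_params(0.01, 0)
  expect_equal(lesions_stable(c(90, 200), tis, mut0), c(0, 0))
})

test_that("inverse division-time maps round-trip in both phases", {
  set.seed(31)
  for (rep in 1:20) {
    tis <- random_tissue()
    if (tis$NL == tis$N0) next
    d_g <- runif(1, 0, tis$NL - tis$N0)
    expect_equal(divisions_growth(time_from_divisions_growth(d_g, tis), tis),
                 d_g, tolerance = 1e-9)
    t_g <- runif(1, 0, phase_schedule(tis)$t_prime)
    expect_equal(time_from_divisions_growth(divisions_growth(t_g, tis), tis),
                 t_g, tolerance = 1e-9)
    d_s <- tis$NL - tis$N0 + runif(1, 0, 500)
    expect_equal(divisions_stable(time_from_divisions_stable(d_s, tis), tis),
                 d_s, tolerance = 1e-9)
  }
})

test_that("expected totals are continuous at the phase boundary and monotone", {
  set.seed(41)
  for (rep in 1:20) {
    tis <- random_tissue()
    mut <- random_mut()
    tp <- phase_schedule(tis)$t_prime
    if (!is.finite(tp)) next
    eps <- 1e-9 * max(tp, 1)
    left <- expected_totals(max(tp - eps, 0), tis, mut)
    right <- expected_totals(tp + eps, tis, mut)
    for (col in c("N", "E", "W", "d")) {
      expect_equal(left[[col]], right[[col]], tolerance = 1e-6)
    }
    grid <- expected_totals(seq(0, tp * 2 + 10, length.out = 50), tis, mut)
    for (col in c("N", "E", "W", "d")) {
      expect_true(all(diff(grid[[col]]) >= -1e-9))
    }
  }
})

test_that("expected totals honor the lesion onset gate", {
  tis <- fig_tissue()
  tp <- phase_schedule(tis)$t_prime
  mut <- mutation_params(0.01, 0.001, lambda2_onset = tp + 5)
  before <- expected_totals(tp + 5, tis, mut)
  expect_equal(before$W, 0)
  after <- expected_totals(tp + 15, tis, mut)
  # ten exposed years at capacity: W = lambda2 * NL * 10
  expect_equal(after$W, 0.001 * 100 * 10)
  # onset inside the growth phase: accrual starts from the onset
  mut2 <- mutation_params(0.01, 0.001, lambda2_onset = 5)
  w5 <- expected_totals(10, tis, mut2)$W
  w_chronic <- expected_totals(10, tis, mutation_params(0.01, 0.001))$W
  expect_lt(w5, w_chronic)
  expect_gt(w5, 0)
  # errors and divisions are unaffected by the gate
  expect_equal(expected_totals(30, tis, mut)$d,
               expected_totals(30, tis, mutation_params(0.01, 0.001))$d)
  expect_equal(expected_totals(0, tis, mut)[, c("N", "E", "W", "d")],
               data.frame(N = 10, E = 0, W = 0, d = 0))
})

test_that("renewal waiting time overestimates the exact stable-phase pace", {
  # the stable-phase waiting-time form serialises the removal wait and the
  # refill wait, but removals keep running while a vacancy refills, so for
  # moderate a_d/b the exact process divides faster than the closed form;
  # the discrepancy vanishes as a_d/b grows
  tis <- tissue_params(2, 20, 0.5, a_d = 0.5, b = 0.1)
  mut0 <- mutation_params(0, 0)
  d_end <- 400
  times <- vapply(1:25, function(s) {
    tr <- simulate_pool(tis, mut0, t_max = Inf, seed = 500 + s, d_max = d_end)
    tr$time[nrow(tr)]
  }, numeric(1))
  t_th <- time_from_divisions_stable(d_end, tis)
  se <- sd(times) / sqrt(length(times))
  expect_lt(mean(times), t_th - 3 * se)
  # with near-instant refill the closed form is accurate
  tis_fast <- tissue_params(2, 20, 0.5, a_d = 500, b = 0.1)
  times_f <- vapply(1:25, function(s) {
    tr <- simulate_pool(tis_fast, mut0, t_max = Inf, seed = 900 + s,
                        d_max = d_end)
    tr$time[nrow(tr)]
  }, numeric(1))
  t_th_f <- time_from_divisions_stable(d_end, tis_fast)
  se_f <- sd(times_f) / sqrt(length(times_f))
  expect_lt(abs(mean(times_f) - t_th_f), 3 * se_f)
})

test_that("replicate means agree with the piecewise approximations across phases", {
  tis <- fig_tissue()
  mut <- fig_mut()
  d_grid <- c(45, 90, 120, 150)
  rs <- replicate_summary(tis, mut, d_grid = d_grid, n_reps = 30, seed = 5)
  E_th <- errors_from_divisions(d_grid, mut)
  W_th <- ifelse(d_grid <= 90, lesions_growth(pmin(d_grid, 90), tis, mut),
                 lesions_stable(pmax(d_grid, 90), tis, mut))
  se_E <- pmax(rs$se_E, sqrt(E_th / 30))
  se_W <- pmax(rs$se_W, sqrt(W_th / 30))
  expect_true(all(abs(rs$mean_E - E_th) <= 3 * se_E))
  expect_true(all(abs(rs$mean_W - W_th) <= 3 * se_W))
})
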