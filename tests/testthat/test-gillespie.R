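test_that("initial state places all founding cells at (0, 0)", {
  st <- init_state(fig_tissue(), 10, 10)
  tot <- pool_totals(st)
  expect_equal(tot$N, 10)
  expect_equal(tot$E, 0)
  expect_equal(tot$W, 0)
  expect_equal(tot$phase, "growth")
  expect_equal(unname(pool_counts(st)["0", "0"]), 10)
  expect_equal(sum(pool_counts(st)), 10)
  # pool already at capacity starts stable
  st2 <- init_state(tissue_params(5, 5, 0.1, 0.1, 0.1), 1, 1)
  expect_equal(st2$phase, "stable")
  expect_error(init_state(fig_tissue(), 0, 5), "I_cap")
})

test_that("rate table matches the phase-wise closed forms", {
  tis <- fig_tissue()
  st <- init_state(tis, 10, 10)
  rt <- compute_rates(st, tis)
  expect_equal(rt$grand_total, 10 * (0.15 + 1))  # (r + 1) N in growth
  expect_equal(rt$removal_total, 0)

  # stable at capacity: division shut off, removal b*N, lesion channel N
  tis2 <- tissue_params(100, 100, 0.15, 0.16, 0.01)
  st2 <- init_state(tis2, 5, 5)
  rt2 <- compute_rates(st2, tis2)
  expect_equal(rt2$division_total, 0)
  expect_equal(rt2$removal_total, 1.0)
  expect_equal(rt2$lesion_event_total, 100)
  expect_equal(rt2$grand_total, 101)
})

test_that("rate totals equal the per-cell sums for random scattered states", {
  set.seed(11)
  for (rep in 1:20) {
    tis <- random_tissue()
    st <- init_state(tis, 6, 6)
    # scatter the founding cells across the grid by hand
    st$counts[] <- 0
    n_cells <- sample(1:30, 1)
    idx <- sample(length(st$counts), n_cells, replace = TRUE)
    for (i in idx) st$counts[i] <- st$counts[i] + 1
    st$N <- n_cells
    st$phase <- sample(c("growth", "stable"), 1)
    rt <- compute_rates(st, tis)
    # independent oracle: accumulate each cell's own event rates
    per_cell_div <- if (st$phase == "growth") tis$r else {
      if (st$N < tis$NL) tis$a_d else 0
    }
    per_cell_rem <- if (st$phase == "growth") 0 else tis$b
    brute <- sum(st$counts * (per_cell_div + per_cell_rem + 1))
    expect_equal(rt$grand_total, brute)
    expect_equal(rt$grand_total,
                 rt$division_total + rt$lesion_event_total + rt$removal_total)
  }
})

test_that("single-step event semantics follow the transition rules", {
  # forced division with no errors: one cell becomes two at (0, 0)
  tis <- tissue_params(1, 100, 1, 0.1, 0)
  mut0 <- mutation_params(0, 0)
  set.seed(1)
  st <- init_state(tis, 3, 3)
  repeat {
    r <- sim_step(st, tis, mut0)
    if (r$event == "division") break
  }
  expect_equal(unname(pool_counts(st)["0", "0"]), 2)
  expect_equal(st$N, 2)
  expect_equal(st$E, 0)

  # daughter of a cell at the error cap stays at the cap
  tis2 <- tissue_params(1, 100, 1, 0.1, 0)
  mut_hot <- mutation_params(50, 0)  # k > 0 essentially surely
  set.seed(2)
  st2 <- init_state(tis2, 2, 2)
  st2$counts[] <- 0
  st2$counts[3, 1] <- 1  # one cell at (I = 2, j = 0)
  st2$N <- 1
  repeat {
    r <- sim_step(st2, tis2, mut_hot)
    if (r$event == "division") break
  }
  expect_equal(unname(pool_counts(st2)["2", "0"]), 2)
  expect_equal(st2$E, 0)            # clamped: no new errors enter the grid
  expect_gt(st2$n_clamped, 0)

  # stable at capacity with b = 0, lambda2 = 0: only null lesion events
  tis3 <- tissue_params(50, 50, 0.1, 0.16, 0)
  set.seed(3)
  st3 <- init_state(tis3, 2, 2)
  for (k in 1:50) {
    r <- sim_step(st3, tis3, mut0)
    expect_equal(r$event, "lesion")
    expect_equal(r$l, 0L)
  }
  expect_equal(st3$N, 50)
  expect_equal(st3$E, 0)
  expect_equal(st3$W, 0)
})

test_that("conservation and phase laws hold along random event sequences", {
  set.seed(21)
  tis <- tissue_params(5, 30, 0.5, 0.6, 0.2)
  mut <- mutation_params(0.2, 0.1)
  st <- init_state(tis, 12, 12)
  prev_phase <- st$phase
  flips <- 0L
  for (k in 1:3000) {
    before <- c(st$N, st$E, st$W, st$d, st$time)
    rec <- sim_step(st, tis, mut)
    dN <- st$N - before[1]
    expect_equal(dN, switch(rec$event, division = 1, removal = -1, lesion = 0))
    expect_gte(st$E, before[2])
    expect_gte(st$W, before[3])
    expect_gte(st$d, before[4])
    expect_gt(st$time, before[5])
    expect_lte(st$N, tis$NL)
    expect_equal(sum(st$counts), st$N)
    if (st$phase != prev_phase) {
      flips <- flips + 1L
      expect_equal(prev_phase, "growth")
      prev_phase <- st$phase
    }
    if (st$phase == "stable" && st$N == tis$NL) {
      expect_equal(compute_rates(st, tis)$division_total, 0)
    }
  }
  expect_lte(flips, 1L)
})

test_that("absorbing states are signalled, not stepped through", {
  tis <- tissue_params(1, 1, 0, 0.1, 1)  # single-slot pool
  mut <- mutation_params(0, 0)
  set.seed(5)
  st <- init_state(tis, 1, 1)
  # remove the only cell, then the grand total is 0
  repeat {
    r <- sim_step(st, tis, mut)
    if (r$event == "removal") break
  }
  expect_equal(st$N, 0)
  r <- sim_step(st, tis, mut)
  expect_equal(r$event, "absorbed")
})

test_that("trajectories are reproducible from the seed and well-formed", {
  tis <- fig_tissue()
  mut <- fig_mut()
  tr1 <- simulate_pool(tis, mut, t_max = 40, seed = 99)
  tr2 <- simulate_pool(tis, mut, t_max = 40, seed = 99)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  tr3 <- simulate_pool(tis, mut, t_max = 40, seed = 100)
  expect_false(identical(tr1$d, tr3$d))

  expect_true(all(diff(tr1$E) >= 0))
  expect_true(all(diff(tr1$W) >= 0))
  expect_true(all(diff(tr1$d) >= 0))
  expect_true(all(tr1$N <= tis$NL))
  expect_true(all(diff(tr1$N[tr1$phase == "growth"]) >= 0))
  # caps sized so that clamping never fired in this short run
  expect_equal(attr(tr1, "tallies")$n_clamped, 0)
})

test_that("mutation-free dynamics accumulate no errors or lesions", {
  tis <- fig_tissue()
  mut0 <- mutation_params(0, 0)
  tr <- simulate_pool(tis, mut0, t_max = 60, seed = 3)
  expect_true(all(tr$E == 0))
  expect_true(all(tr$W == 0))
  # N rose to capacity and then fluctuated at or below it
  expect_equal(max(tr$N), tis$NL)
})

test_that("replicate summaries align on the division grid", {
  tis <- fig_tissue()
  mut0 <- mutation_params(0, 0)
  rs <- replicate_summary(tis, mut0, d_grid = c(20, 50, 80), n_reps = 2,
                          seed = 1)
  expect_equal(rs$d, c(20, 50, 80))
  expect_equal(rs$mean_E, c(0, 0, 0))
  expect_equal(rs$se_E, c(0, 0, 0))
  expect_equal(rs$mean_W, c(0, 0, 0))
  expect_error(replicate_summary(tis, mut0, d_grid = c(10, 20), n_reps = 1,
                                 seed = 1), "n_reps")
})

test_that("growth-phase replicate means track the closed forms", {
  tis <- fig_tissue()
  mut <- fig_mut()
  d_grid <- c(30, 60, 90)  # growth phase spans 90 divisions
  rs <- replicate_summary(tis, mut, d_grid = d_grid, n_reps = 40, seed = 17)
  E_th <- errors_from_divisions(d_grid, mut)
  W_th <- lesions_growth(d_grid, tis, mut)
  expect_true(all(abs(rs$mean_E - E_th) <= 3 * pmax(rs$se_E, sqrt(E_th / 40))))
  expect_true(all(abs(rs$mean_W - W_th) <= 3 * pmax(rs$se_W, sqrt(W_th / 40))))
})
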