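#' Initialise a stem-cell pool state
#'
#' The state is an occupancy grid `n[i, j]` of stem cells carrying `i`
#' replication errors and `j` lesions (`0 <= i <= I`, `0 <= j <= J`), plus
#' the simulation clock, the phase, and cumulative tallies. The state object
#' is an environment and is updated in place by [sim_step()].
#'
#' @param tissue A [tissue_params()] object.
#' @param I_cap Maximum tracked error count per cell, `>= 1`.
#' @param J_cap Maximum tracked lesion count per cell, `>= 1`.
#' @return An object of class `stem_cell_pool`: all `N0` founding cells sit
#'   at `(0, 0)`, time is 0, and the phase is `"growth"` (or `"stable"`
#'   immediately when `N0 == NL`).
#' @examples
#' st <- init_state(tissue_params(10, 100, 0.15, 0.16, 0.01), 10, 10)
#' pool_totals(st)
#' @export
init_state <- function(tissue, I_cap, J_cap) {
  if (length(I_cap) != 1L || length(J_cap) != 1L ||
      !is.finite(I_cap) || !is.finite(J_cap) || I_cap < 1 || J_cap < 1) {
    stop("I_cap and J_cap must be finite and >= 1", call. = FALSE)
  }
  st <- new.env(parent = emptyenv())
  st$I <- as.integer(I_cap)
  st$J <- as.integer(J_cap)
  st$counts <- matrix(0, nrow = st$I + 1L, ncol = st$J + 1L)
  st$counts[1L, 1L] <- tissue$N0
  st$time <- 0
  st$phase <- if (tissue$N0 >= tissue$NL) "stable" else "growth"
  st$N <- tissue$N0
  st$E <- 0   # cumulative replication errors generated
  st$W <- 0   # cumulative lesions generated
  st$d <- 0   # cumulative divisions
  st$n_division <- 0
  st$n_removal <- 0
  st$n_lesion <- 0
  st$n_lesion_null <- 0
  st$n_clamped <- 0
  class(st) <- "stem_cell_pool"
  st
}

#' Occupancy grid of a pool state
#'
#' @param state A `stem_cell_pool` object.
#' @return A copy of the `(I+1) x (J+1)` occupancy matrix, with dimnames
#'   giving the error and lesion counts.
#' @export
pool_counts <- function(state) {
  m <- state$counts
  dimnames(m) <- list(errors = 0:state$I, lesions = 0:state$J)
  m
}

#' Scalar summaries of a pool state
#'
#' `E` and `W` are the cumulative numbers of replication errors and lesions
#' generated over the run; `grid_E` and `grid_W` are the occupancy-weighted
#' sums over the current grid (which also count mutations copied into
#' daughters at division, and drop mutations carried by removed cells).
#'
#' @param state A `stem_cell_pool` object.
#' @return A list with `time`, `phase`, `N`, `E`, `W`, `d`, `grid_E`,
#'   `grid_W` and the event tallies.
#' @export
pool_totals <- function(state) {
  iw <- 0:state$I
  jw <- 0:state$J
  list(time = state$time, phase = state$phase, N = state$N,
       E = state$E, W = state$W, d = state$d,
       grid_E = sum(rowSums(state$counts) * iw),
       grid_W = sum(colSums(state$counts) * jw),
       n_division = state$n_division, n_removal = state$n_removal,
       n_lesion = state$n_lesion, n_lesion_null = state$n_lesion_null,
       n_clamped = state$n_clamped)
}

#' @export
print.stem_cell_pool <- function(x, ...) {
  cat(sprintf("Stem-cell pool state: t = %.4g, phase = %s\n", x$time, x$phase))
  cat(sprintf("  N = %g cells, d = %g divisions, E = %g errors, W = %g lesions\n",
              x$N, x$d, x$E, x$W))
  cat(sprintf("  grid caps I = %d, J = %d\n", x$I, x$J))
  invisible(x)
}

#' Event-rate table for the current state
#'
#' Per-cell rates: division at `r` (growth) or `a_d` when `N < NL` and 0
#' when `N = NL` (stable); removal at `b` (stable only); lesion events at
#' rate 1 per cell per time unit (the Poisson masses over the lesion count,
#' including the null draw `l = 0`, sum to 1). The grand total therefore has
#' the closed forms `(r + 1) N` in growth and `(a + b + 1) N` in the stable
#' phase below capacity.
#'
#' @param state A `stem_cell_pool` object.
#' @param tissue A [tissue_params()] object.
#' @return A list of class `event_rate_table` with components
#'   `division_total`, `lesion_event_total`, `removal_total`, `grand_total`.
#' @export
compute_rates <- function(state, tissue) {
  N <- state$N
  if (state$phase == "growth") {
    division_total <- tissue$r * N
    removal_total <- 0
  } else {
    division_total <- if (N < tissue$NL) tissue$a_d * N else 0
    removal_total <- tissue$b * N
  }
  structure(list(division_total = division_total,
                 lesion_event_total = N,
                 removal_total = removal_total,
                 grand_total = division_total + N + removal_total),
            class = "event_rate_table")
}

# draw one occupied cell uniformly by occupancy; returns c(i, j)
pick_cell <- function(counts, N) {
  nz <- which(counts > 0)
  if (length(nz) == 1L) {
    cell <- nz
  } else {
    cs <- cumsum(counts[nz])
    cell <- nz[findInterval(stats::runif(1) * N, cs) + 1L]
  }
  nrow_c <- dim(counts)[1L]
  c((cell - 1L) %% nrow_c, (cell - 1L) %/% nrow_c)
}

#' Advance the pool state by one stochastic event
#'
#' One iteration of the Gillespie algorithm: the waiting time is exponential
#' with the grand total rate; the event class (division, lesion event,
#' removal) is chosen with probability proportional to its class total; the
#' affected cell is chosen uniformly by occupancy. A division of a cell at
#' `(i, j)` draws `k ~ Poisson(lambda1)` and places the daughter at
#' `(min(i + k, I), j)` with the parent entry unchanged; a lesion event
#' draws `l ~ Poisson(lambda2)` (0 before `lambda2_onset`) and moves the
#' cell to `(i, min(j + l, J))`, with `l = 0` a recorded null event; a
#' removal decrements the cell's entry. The phase flips from growth to
#' stable the instant `N` reaches `NL`. The state is modified in place.
#'
#' @param state A `stem_cell_pool` object (updated in place).
#' @param tissue A [tissue_params()] object.
#' @param mut A [mutation_params()] object.
#' @param record If `FALSE`, return only the event class (fast path).
#' @return Invisibly, the event record: a list with `event` (`"division"`,
#'   `"lesion"`, `"removal"` or `"absorbed"`), `dt`, the affected cell, and
#'   the mutation draw; or just the event class when `record = FALSE`. When
#'   no event is possible (grand total rate 0) the state is untouched and
#'   the event is `"absorbed"`.
#' @export
sim_step <- function(state, tissue, mut, record = TRUE) {
  rates <- compute_rates(state, tissue)
  gt <- rates$grand_total
  if (gt <= 0) {
    return(invisible(if (record) list(event = "absorbed", dt = NA_real_) else "absorbed"))
  }
  dt <- stats::rexp(1L, gt)
  state$time <- state$time + dt
  u <- stats::runif(1L) * gt
  if (u < rates$division_total) {
    ij <- pick_cell(state$counts, state$N)
    k <- stats::rpois(1L, mut$lambda1)
    i_dau <- min(ij[1L] + k, state$I)
    state$counts[i_dau + 1L, ij[2L] + 1L] <-
      state$counts[i_dau + 1L, ij[2L] + 1L] + 1
    state$N <- state$N + 1
    state$d <- state$d + 1
    state$E <- state$E + (i_dau - ij[1L])
    state$n_division <- state$n_division + 1
    if (k > state$I - ij[1L]) state$n_clamped <- state$n_clamped + 1
    if (state$phase == "growth" && state$N >= tissue$NL) state$phase <- "stable"
    out <- if (record) list(event = "division", dt = dt, cell = ij, k = k) else "division"
  } else if (u < rates$division_total + rates$lesion_event_total) {
    state$n_lesion <- state$n_lesion + 1
    l <- if (state$time >= mut$lambda2_onset) stats::rpois(1L, mut$lambda2) else 0L
    if (l > 0L) {
      ij <- pick_cell(state$counts, state$N)
      j_new <- min(ij[2L] + l, state$J)
      if (j_new > ij[2L]) {
        state$counts[ij[1L] + 1L, ij[2L] + 1L] <-
          state$counts[ij[1L] + 1L, ij[2L] + 1L] - 1
        state$counts[ij[1L] + 1L, j_new + 1L] <-
          state$counts[ij[1L] + 1L, j_new + 1L] + 1
        state$W <- state$W + (j_new - ij[2L])
      }
      if (l > state$J - ij[2L]) state$n_clamped <- state$n_clamped + 1
      out <- if (record) list(event = "lesion", dt = dt, cell = ij, l = l) else "lesion"
    } else {
      state$n_lesion_null <- state$n_lesion_null + 1
      out <- if (record) list(event = "lesion", dt = dt, cell = NULL, l = 0L) else "lesion"
    }
  } else {
    ij <- pick_cell(state$counts, state$N)
    state$counts[ij[1L] + 1L, ij[2L] + 1L] <-
      state$counts[ij[1L] + 1L, ij[2L] + 1L] - 1
    state$N <- state$N - 1
    state$n_removal <- state$n_removal + 1
    out <- if (record) list(event = "removal", dt = dt, cell = ij) else "removal"
  }
  invisible(out)
}

# grid caps sized so that clamping is vanishingly rare at the run horizon
default_caps <- function(tissue, mut, t_horizon, d_horizon = NULL) {
  if (is.null(d_horizon)) {
    d_horizon <- expected_totals(t_horizon, tissue, mut)$d
  }
  if (!is.finite(d_horizon)) d_horizon <- tissue$NL - tissue$N0
  W_exp <- mut$lambda2 * cumulative_cell_time(
    min(t_horizon, time_for_divisions(d_horizon, tissue) * 1.5 + 1), tissue)
  list(I = max(8, ceiling(10 * mut$lambda1 * max(d_horizon, 1))),
       J = max(8, ceiling(10 * max(W_exp, 1))))
}

#' Simulate the stem-cell pool with the Gillespie algorithm
#'
#' Repeatedly applies [sim_step()] until the clock reaches `t_max`, the
#' cumulative division count reaches `d_max`, or the state becomes
#' absorbing. The trajectory is sampled on a fixed time cadence, at the
#' growth-to-stable phase transition, at requested division counts, and at
#' the end of the run. Fully reproducible from `seed`.
#'
#' @param tissue A [tissue_params()] object.
#' @param mut A [mutation_params()] object.
#' @param t_max Time horizon (may be `Inf` if `d_max` is given).
#' @param record_every Sampling interval on the time axis; default
#'   `t_max / 200` when `t_max` is finite, otherwise no time-based sampling.
#' @param seed Integer seed; required (no silent default).
#' @param I_cap,J_cap Grid caps; defaults sized from the expected error and
#'   lesion counts at the horizon so that clamping is vanishingly rare.
#' @param d_max Optional stopping division count.
#' @param d_grid Optional division counts at which to record the state
#'   (recorded immediately after the division).
#' @return A data.frame of class `mutstage_trajectory` with columns `time`,
#'   `N`, `E`, `W`, `d`, `phase`. `E` and `W` count the mutation events
#'   generated (non-decreasing). Attributes carry the seed, caps, event
#'   tallies and an `absorbed` flag.
#' @examples
#' tissue <- tissue_params(10, 100, 0.15, 0.16, 0.01)
#' mut <- mutation_params(0.01, 0.001)
#' tr <- simulate_pool(tissue, mut, t_max = 50, seed = 1)
#' tail(tr)
#' @export
simulate_pool <- function(tissue, mut, t_max = Inf, record_every = NULL,
                          seed, I_cap = NULL, J_cap = NULL,
                          d_max = NULL, d_grid = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  if (!is.null(d_grid)) {
    d_grid <- sort(unique(round(d_grid)))
    d_max <- max(d_max, max(d_grid))
  }
  if (!is.finite(t_max) && is.null(d_max)) {
    stop("either a finite t_max or d_max must be given", call. = FALSE)
  }
  if (is.finite(t_max) && t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  if (is.null(I_cap) || is.null(J_cap)) {
    th <- if (is.finite(t_max)) t_max else time_for_divisions(d_max, tissue)
    if (!is.finite(th)) {
      stop("d_max is unreachable for these parameters (no stable-phase turnover)",
           call. = FALSE)
    }
    caps <- default_caps(tissue, mut, th, d_max)
    if (is.null(I_cap)) I_cap <- caps$I
    if (is.null(J_cap)) J_cap <- caps$J
  }
  if (is.null(record_every) && is.finite(t_max)) record_every <- t_max / 200

  set.seed(as.integer(seed))
  st <- init_state(tissue, I_cap, J_cap)

  recs <- vector("list", 256L)
  n_rec <- 0L
  push <- function(tm, N, E, W, d, phase) {
    n_rec <<- n_rec + 1L
    if (n_rec > length(recs)) length(recs) <<- 2L * length(recs)
    recs[[n_rec]] <<- c(tm, N, E, W, d, phase)
  }
  phase_code <- function(p) if (p == "growth") 1 else 2
  push(0, st$N, st$E, st$W, st$d, phase_code(st$phase))

  next_sample <- if (is.null(record_every)) Inf else record_every
  d_pending <- d_grid
  absorbed <- FALSE

  repeat {
    prev <- c(st$N, st$E, st$W, st$d, phase_code(st$phase))
    t_prev <- st$time
    evt <- sim_step(st, tissue, mut, record = FALSE)
    if (identical(evt, "absorbed")) {
      absorbed <- TRUE
      break
    }
    t_now <- st$time
    # time-cadence samples use the state that held over (t_prev, t_now)
    while (next_sample < t_now && next_sample <= t_max) {
      push(next_sample, prev[1L], prev[2L], prev[3L], prev[4L], prev[5L])
      next_sample <- next_sample + record_every
    }
    if (t_now > t_max) {
      push(t_max, prev[1L], prev[2L], prev[3L], prev[4L], prev[5L])
      break
    }
    if (evt == "division") {
      if (prev[5L] == 1 && st$phase == "stable") {
        push(t_now, st$N, st$E, st$W, st$d, 2)
      }
      if (!is.null(d_pending) && length(d_pending) > 0L && st$d >= d_pending[1L]) {
        push(t_now, st$N, st$E, st$W, st$d, phase_code(st$phase))
        d_pending <- d_pending[-1L]
      }
      if (!is.null(d_max) && st$d >= d_max) break
    }
  }
  if (!absorbed && st$time <= t_max) {
    push(st$time, st$N, st$E, st$W, st$d, phase_code(st$phase))
  }

  m <- do.call(rbind, recs[seq_len(n_rec)])
  out <- data.frame(time = m[, 1L], N = m[, 2L], E = m[, 3L], W = m[, 4L],
                    d = m[, 5L], phase = c("growth", "stable")[m[, 6L]])
  attr(out, "seed") <- as.integer(seed)
  attr(out, "I_cap") <- st$I
  attr(out, "J_cap") <- st$J
  attr(out, "absorbed") <- absorbed
  attr(out, "tallies") <- list(n_division = st$n_division,
                               n_removal = st$n_removal,
                               n_lesion = st$n_lesion,
                               n_lesion_null = st$n_lesion_null,
                               n_clamped = st$n_clamped)
  attr(out, "final_state") <- st
  class(out) <- c("mutstage_trajectory", "data.frame")
  out
}

#' Replicate simulations summarised on a common division grid
#'
#' Runs `n_reps` seeded simulations (replicate `r` uses `seed + r`), records
#' the cumulative error and lesion counts the moment the division count
#' reaches each grid value, and returns their means with standard errors.
#'
#' @param tissue A [tissue_params()] object.
#' @param mut A [mutation_params()] object.
#' @param d_grid Division counts to align on; default a 10-point grid up to
#'   the expected division count at `t_max`.
#' @param n_reps Number of replicates, `>= 2`.
#' @param seed Integer base seed.
#' @param t_max Optional time horizon used only to build the default grid
#'   (the runs themselves stop on the division grid).
#' @param I_cap,J_cap Optional grid caps, as in [simulate_pool()].
#' @return A data.frame of class `replicate_summary` with columns `d`,
#'   `mean_E`, `se_E`, `mean_W`, `se_W`, `mean_time`.
#' @examples
#' tissue <- tissue_params(10, 100, 0.15, 0.16, 0.01)
#' mut <- mutation_params(0.01, 0.001)
#' replicate_summary(tissue, mut, d_grid = c(30, 60, 90), n_reps = 5, seed = 1)
#' @export
replicate_summary <- function(tissue, mut, d_grid = NULL, n_reps, seed,
                              t_max = NULL, I_cap = NULL, J_cap = NULL) {
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  if (is.null(d_grid)) {
    if (is.null(t_max)) stop("give either d_grid or t_max", call. = FALSE)
    d_end <- floor(expected_totals(t_max, tissue, mut)$d)
    if (d_end < 10) stop("t_max too short to build a division grid", call. = FALSE)
    d_grid <- unique(round(seq(d_end / 10, d_end, length.out = 10)))
  }
  d_grid <- sort(unique(round(d_grid)))
  E_mat <- matrix(NA_real_, n_reps, length(d_grid))
  W_mat <- matrix(NA_real_, n_reps, length(d_grid))
  T_mat <- matrix(NA_real_, n_reps, length(d_grid))
  for (r in seq_len(n_reps)) {
    tr <- simulate_pool(tissue, mut, t_max = Inf, record_every = NULL,
                        seed = seed + r, I_cap = I_cap, J_cap = J_cap,
                        d_grid = d_grid)
    for (k in seq_along(d_grid)) {
      hit <- which(tr$d == d_grid[k])
      if (length(hit) > 0L) {
        E_mat[r, k] <- tr$E[hit[1L]]
        W_mat[r, k] <- tr$W[hit[1L]]
        T_mat[r, k] <- tr$time[hit[1L]]
      }
    }
    if (anyNA(E_mat[r, ])) {
      warning("replicate ", r, " ended before reaching the full division grid")
    }
  }
  se <- function(x) stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
  out <- data.frame(
    d = d_grid,
    mean_E = colMeans(E_mat, na.rm = TRUE),
    se_E = apply(E_mat, 2L, se),
    mean_W = colMeans(W_mat, na.rm = TRUE),
    se_W = apply(W_mat, 2L, se),
    mean_time = colMeans(T_mat, na.rm = TRUE)
  )
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("replicate_summary", "data.frame")
  out
}
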