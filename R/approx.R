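#' Phase schedule of the two-phase model
#'
#' The growth phase ends at `t' = log(NL/N0)/r`, after `NL - N0` divisions,
#' with `W' = (lambda2/r) (NL - N0)` lesions accrued (chronic exposure).
#'
#' @param tissue A [tissue_params()] object.
#' @param mut A [mutation_params()] object (only `lambda2` is used); may be
#'   omitted, in which case `W_prime` is `NA`.
#' @return A list with `t_prime`, `d_at_t_prime` and `W_prime`.
#' @export
phase_schedule <- function(tissue, mut = NULL) {
  if (tissue$NL == tissue$N0) {
    t_prime <- 0
  } else if (tissue$r > 0) {
    t_prime <- log(tissue$NL / tissue$N0) / tissue$r
  } else {
    t_prime <- Inf  # pool below capacity but no growth: never reaches NL
  }
  d_prime <- tissue$NL - tissue$N0
  W_prime <- if (is.null(mut)) NA_real_ else {
    if (tissue$r > 0) mut$lambda2 / tissue$r * d_prime else 0
  }
  list(t_prime = t_prime, d_at_t_prime = d_prime, W_prime = W_prime)
}

#' Expected cumulative divisions during the growth phase
#'
#' `d(t) = N0 (exp(r t) - 1)` for `0 <= t <= t'`.
#'
#' @param t Time (vectorised), within the growth phase.
#' @param tissue A [tissue_params()] object.
#' @return Expected cumulative division count.
#' @export
divisions_growth <- function(t, tissue) {
  tp <- phase_schedule(tissue)$t_prime
  if (any(t < 0 | t > tp)) {
    stop("t outside the growth phase [0, ", format(tp),
         "]; use expected_totals() for the piecewise curve", call. = FALSE)
  }
  tissue$N0 * (exp(tissue$r * t) - 1)
}

#' Inverse of [divisions_growth()]: time at a given division count
#'
#' `t = log(d/N0 + 1) / r`.
#'
#' @param d Cumulative division count in `[0, NL - N0]`.
#' @param tissue A [tissue_params()] object with a positive growth rate.
#' @return Time at which the expected division count reaches `d`.
#' @export
time_from_divisions_growth <- function(d, tissue) {
  if (any(d < 0 | d > tissue$NL - tissue$N0)) {
    stop("d outside the growth phase [0, NL - N0]", call. = FALSE)
  }
  if (tissue$r <= 0) stop("r must be > 0 to invert the growth curve", call. = FALSE)
  log(d / tissue$N0 + 1) / tissue$r
}

#' Expected total errors from the cumulative division count
#'
#' Each division contributes on average `lambda1` replication errors, in
#' both phases: `E = lambda1 d`.
#'
#' @param d Cumulative division count, `>= 0` (vectorised).
#' @param mut A [mutation_params()] object.
#' @return Expected total error count.
#' @export
errors_from_divisions <- function(d, mut) {
  if (any(d < 0)) stop("d must be >= 0", call. = FALSE)
  mut$lambda1 * d
}

#' Expected total lesions in the growth phase, by division count
#'
#' `W = (lambda2 / r) d` for `0 <= d <= NL - N0` (chronic exposure).
#'
#' @param d Cumulative division count within the growth phase.
#' @param tissue A [tissue_params()] object.
#' @param mut A [mutation_params()] object.
#' @return Expected total lesion count.
#' @export
lesions_growth <- function(d, tissue, mut) {
  if (any(d < 0 | d > tissue$NL - tissue$N0)) {
    stop("d outside the growth phase [0, NL - N0]", call. = FALSE)
  }
  if (tissue$r <= 0) {
    if (any(d > 0)) stop("r = 0: no divisions occur in the growth phase", call. = FALSE)
    return(rep(0, length(d)))
  }
  mut$lambda2 / tissue$r * d
}

#' Expected waiting time per division in the stable phase
#'
#' The wait for one stable-phase division is the wait for a removal,
#' `1/(b NL)`, plus the wait for the replacement division, `1/(a_d (NL-1))`:
#' a renewal approximation that assumes each vacancy is refilled before the
#' next removal.
#'
#' @param tissue A [tissue_params()] object with `a_d > 0`, `b > 0` and
#'   `NL >= 2`.
#' @return Expected time per stable-phase division.
#' @export
stable_waiting_time <- function(tissue) {
  if (tissue$NL < 2 || tissue$a_d <= 0 || tissue$b <= 0) {
    stop("stable_waiting_time requires NL >= 2, a_d > 0 and b > 0", call. = FALSE)
  }
  1 / (tissue$b * tissue$NL) + 1 / (tissue$a_d * (tissue$NL - 1))
}

# divisions per unit time in the stable phase; 0 when turnover is impossible
stable_division_rate <- function(tissue) {
  if (tissue$NL < 2 || tissue$a_d <= 0 || tissue$b <= 0) return(0)
  1 / stable_waiting_time(tissue)
}

#' Expected cumulative divisions at times past the growth phase
#'
#' `d(t) = NL - N0 + (t - t') a b NL (NL - 1) / (a (NL - 1) + b NL)` for
#' `t >= t'`.
#'
#' @param t Time (vectorised), at or after the growth-phase end `t'`.
#' @param tissue A [tissue_params()] object.
#' @return Expected cumulative division count.
#' @export
divisions_stable <- function(t, tissue) {
  tp <- phase_schedule(tissue)$t_prime
  if (any(t < tp)) {
    stop("t before the growth-phase end t' = ", format(tp),
         "; use expected_totals() for the piecewise curve", call. = FALSE)
  }
  tissue$NL - tissue$N0 + (t - tp) * stable_division_rate(tissue)
}

#' Inverse of [divisions_stable()]: time at a given division count
#'
#' @param d Cumulative division count, `>= NL - N0`.
#' @param tissue A [tissue_params()] object with positive stable-phase
#'   turnover.
#' @return Time at which the expected division count reaches `d`.
#' @export
time_from_divisions_stable <- function(d, tissue) {
  dp <- tissue$NL - tissue$N0
  if (any(d < dp)) stop("d below the phase boundary NL - N0", call. = FALSE)
  phase_schedule(tissue)$t_prime + (d - dp) * stable_waiting_time(tissue)
}

#' Expected total lesions in the stable phase, by division count
#'
#' `W = NL lambda2 (d - NL + N0) (a(NL-1) + b NL) / (a b NL (NL-1)) +
#' (lambda2 / r)(NL - N0)` for `d >= NL - N0` (chronic exposure).
#'
#' @param d Cumulative division count, `>= NL - N0`.
#' @param tissue A [tissue_params()] object.
#' @param mut A [mutation_params()] object.
#' @return Expected total lesion count.
#' @export
lesions_stable <- function(d, tissue, mut) {
  dp <- tissue$NL - tissue$N0
  if (any(d < dp)) stop("d below the phase boundary NL - N0", call. = FALSE)
  Wp <- phase_schedule(tissue, mut)$W_prime
  elapsed <- (d - dp) * stable_waiting_time(tissue)
  tissue$NL * mut$lambda2 * elapsed + Wp
}

# integral of N(s) ds from 0 to t under the deterministic two-phase curve
cumulative_cell_time <- function(t, tissue) {
  tp <- phase_schedule(tissue)$t_prime
  tg <- pmin(t, tp)
  growth_part <- if (tissue$r > 0) {
    tissue$N0 * (exp(tissue$r * tg) - 1) / tissue$r
  } else {
    tissue$N0 * tg
  }
  stable_part <- tissue$NL * pmax(0, t - tp)
  growth_part + stable_part
}

#' Expected cell number, errors, lesions and divisions over time
#'
#' Piecewise closed forms across both phases: `N(t) = N0 exp(rt)` capped at
#' `NL`; divisions from the growth-phase exponential and the stable-phase
#' renewal rate; `E = lambda1 d`; lesions as
#' `lambda2 * integral of N(s) ds` over the exposed interval
#' `s >= lambda2_onset`, which reduces to the phase-wise closed forms for
#' chronic exposure. All four outputs are continuous at the phase boundary.
#'
#' @param t Times, `>= 0` (vectorised).
#' @param tissue A [tissue_params()] object.
#' @param mut A [mutation_params()] object.
#' @return A data.frame with columns `time`, `N`, `E`, `W`, `d`.
#' @examples
#' tissue <- tissue_params(10, 100, 0.15, 0.16, 0.01)
#' mut <- mutation_params(0.01, 0.001)
#' expected_totals(c(0, 10, 20, 50), tissue, mut)
#' @export
expected_totals <- function(t, tissue, mut) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  tp <- phase_schedule(tissue)$t_prime
  N <- pmin(tissue$N0 * exp(tissue$r * t), tissue$NL)
  d <- ifelse(t <= tp,
              tissue$N0 * (exp(tissue$r * t) - 1),
              tissue$NL - tissue$N0 + (t - tp) * stable_division_rate(tissue))
  E <- mut$lambda1 * d
  exposed <- pmax(0, cumulative_cell_time(t, tissue) -
                       cumulative_cell_time(pmin(t, mut$lambda2_onset), tissue))
  W <- mut$lambda2 * exposed
  data.frame(time = t, N = N, E = E, W = W, d = d)
}

# time at which the expected division count reaches d, across phases
time_for_divisions <- function(d, tissue) {
  dp <- tissue$NL - tissue$N0
  if (d <= dp) {
    if (tissue$r <= 0) {
      if (d > 0) return(Inf)
      return(0)
    }
    return(time_from_divisions_growth(d, tissue))
  }
  rate <- stable_division_rate(tissue)
  if (rate <= 0) return(Inf)
  phase_schedule(tissue)$t_prime + (d - dp) / rate
}
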