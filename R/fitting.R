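#' Reference tissue parameters for registry fitting
#'
#' Stem-cell turnover rates `b` (divisions of each stem cell per year) and
#' pool sizes `NL` for nine tissues, as compiled from published stem-cell
#' estimates, together with the growth-phase division rate `log(NL) / 18`
#' implied by the registry convention.
#'
#' @return A data.frame with columns `tissue`, `b`, `NL`, `r`.
#' @examples
#' registry_tissue_table()
#' @export
registry_tissue_table <- function() {
  tab <- data.frame(
    tissue = c("esophageal", "leukemia", "liver", "lung", "thyroid",
               "pancreatic", "colon", "breast", "prostate"),
    b = c(33.2, 12, 0.91, 0.07, 0.087, 1, 73, 4.32, 2.99),
    NL = c(6.6528e6, 1.35e8, 3.01e9, 1.22e9, 6.5e7, 4.18e9, 2.00e8,
           8.7e9, 2.1e8)
  )
  tab$r <- log(tab$NL) / 18
  tab
}

#' Look up a registry tissue as a parameter object
#'
#' @param name One of the tissue names in [registry_tissue_table()].
#' @param a_over_b_ratio Ratio `a_d / b` realising the fast-refill limit.
#' @return A [tissue_params()] object (`N0 = 1`, growth rate `log(NL)/18`).
#' @examples
#' registry_tissue("colon")
#' @export
registry_tissue <- function(name, a_over_b_ratio = 1e4) {
  tab <- registry_tissue_table()
  row <- tab[tab$tissue == name, ]
  if (nrow(row) != 1L) {
    stop("unknown tissue '", name, "'; available: ",
         paste(tab$tissue, collapse = ", "), call. = FALSE)
  }
  make_tissue_from_registry(row$NL, b = row$b, a_over_b_ratio = a_over_b_ratio)
}

#' Cumulative divisions under the registry convention (fast-refill limit)
#'
#' With `N0 = 1`, growth rate `log(NL)/18` and immediate replacement of removed
#' cells (`a_d >> b`), the tissue-wide division count is
#' `d(t) = exp(r t) - 1` up to age 18 and
#' `d(t) = NL - 1 + b NL (t - 18)` afterwards.
#'
#' @param t Ages in years (vectorised).
#' @param tissue A [tissue_params()] object built under the registry
#'   convention (`N0 = 1`).
#' @return Expected cumulative tissue-wide division count.
#' @export
registry_divisions <- function(t, tissue) {
  if (tissue$N0 != 1) {
    stop("registry_divisions requires the registry convention (N0 = 1); ",
         "build the tissue with make_tissue_from_registry()", call. = FALSE)
  }
  t_end <- 18
  ifelse(t <= t_end,
         exp(tissue$r * t) - 1,
         tissue$NL - 1 + tissue$b * tissue$NL * (t - t_end))
}

# driver-mutation burden scale multiplying lambda1p, by convention:
# per_cell = divisions per stem cell, total = tissue-wide divisions
registry_error_base <- function(t, tissue, convention) {
  d <- registry_divisions(t, tissue)
  if (convention == "per_cell") {
    N <- pmin(exp(tissue$r * t), tissue$NL)
    d / N
  } else {
    d
  }
}

# burden scale multiplying lambda2p after the exposure onset
registry_lesion_base <- function(t, tissue, onset_age, convention) {
  expo <- pmax(0, t - onset_age)
  if (convention == "per_cell") expo else tissue$NL * expo
}

#' Model risk curve for registry fitting, replication errors only
#'
#' The driver-mutation burden is `lambda1p` (driver mutations per division)
#' times the division count, and the cumulative risk is the Poisson tail
#' with `g` required driver hits. Under the default `"per_cell"` convention
#' the burden is per stem cell, `lambda1p * d(t) / N(t)`
#' (`= lambda1p (1 + b (t - 18))` up to a factor `(NL-1)/NL` after age 18),
#' which is the scale on which registry cumulative risks of a few percent
#' arise; `"total"` uses the tissue-wide count `lambda1p * d(t)`.
#'
#' @param ages Ages in years.
#' @param tissue Registry-convention [tissue_params()] (see
#'   [registry_tissue()]).
#' @param g Required driver-gene mutations, positive integer.
#' @param lambda1p Driver mutations per division (`lambda1 * p`), `>= 0`.
#' @param convention `"per_cell"` (default) or `"total"`.
#' @return A `risk_curve` data.frame.
#' @examples
#' model_curve_error_only(seq(5, 85, 5), registry_tissue("colon"),
#'                        g = 5, lambda1p = 0.00041)
#' @export
model_curve_error_only <- function(ages, tissue, g, lambda1p,
                                   convention = c("per_cell", "total")) {
  convention <- match.arg(convention)
  if (lambda1p < 0) stop("lambda1p must be >= 0", call. = FALSE)
  base <- registry_error_base(ages, tissue, convention)
  out <- new_risk_curve(ages, stats::ppois(g - 1, lambda1p * base, lower.tail = FALSE),
                        label = sprintf("model g=%d", g))
  attr(out, "convention") <- convention
  attr(out, "params") <- list(g = g, lambda1p = lambda1p)
  out
}

#' Model risk curve for registry fitting, errors plus gated lesions
#'
#' Adds a mutagen term to [model_curve_error_only()]: lesions accumulate at
#' rate `lambda2` per cell per year starting at `onset_age` (at or after the
#' growth-phase end), so the per-cell driver-lesion burden is
#' `lambda2p * max(0, t - onset_age)`.
#'
#' @inheritParams model_curve_error_only
#' @param lambda2p Driver lesions per cell per year (`lambda2 * p`), `>= 0`.
#' @param onset_age Age (years) at which lesion exposure starts; `>= 18`.
#' @return A `risk_curve` data.frame.
#' @export
model_curve_with_lesions <- function(ages, tissue, g, lambda1p, lambda2p,
                                     onset_age = 20,
                                     convention = c("per_cell", "total")) {
  convention <- match.arg(convention)
  if (lambda1p < 0 || lambda2p < 0) stop("rates must be >= 0", call. = FALSE)
  if (onset_age < 18) {
    stop("onset_age must be >= 18 (after the registry growth phase)",
         call. = FALSE)
  }
  burden <- lambda1p * registry_error_base(ages, tissue, convention) +
    lambda2p * registry_lesion_base(ages, tissue, onset_age, convention)
  out <- new_risk_curve(ages, stats::ppois(g - 1, burden, lower.tail = FALSE),
                        label = sprintf("model g=%d (lesions)", g))
  attr(out, "convention") <- convention
  attr(out, "params") <- list(g = g, lambda1p = lambda1p, lambda2p = lambda2p,
                              onset_age = onset_age)
  out
}

# profile SSE over lambda1p for fixed g: coarse log grid then golden-section
profile_lambda1p <- function(y, error_base, g, extra_burden = 0, w = 1,
                             log10_range = c(-8, 2)) {
  sse <- function(l10) {
    gg <- stats::ppois(g - 1, 10^l10 * error_base + extra_burden, lower.tail = FALSE)
    sum(w * (gg - y)^2)
  }
  grid <- seq(log10_range[1L], log10_range[2L], by = 0.1)
  vals <- vapply(grid, sse, numeric(1))
  k <- which.min(vals)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-12)
  if (vals[k] < opt$objective) {
    list(lambda1p = 10^grid[k], sse = vals[k])
  } else {
    list(lambda1p = 10^opt$minimum, sse = opt$objective)
  }
}

new_fit_result <- function(g_hat, rate_hat, lesion_rate_hat, sse_profile,
                           fitted_curve, convention, onset_age = NULL) {
  structure(list(g_hat = g_hat, rate_hat = rate_hat,
                 lesion_rate_hat = lesion_rate_hat,
                 sse_profile = sse_profile,
                 sse_min = min(sse_profile$sse),
                 fitted_curve = fitted_curve,
                 convention = convention, onset_age = onset_age),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Least-squares fit of the multistage risk curve\n")
  cat(sprintf("  g_hat = %d, lambda1p_hat = %.6g", x$g_hat, x$rate_hat))
  if (!is.null(x$lesion_rate_hat) && !is.na(x$lesion_rate_hat)) {
    cat(sprintf(", lambda2p_hat = %.6g (onset %g)", x$lesion_rate_hat,
                x$onset_age))
  }
  cat(sprintf("\n  SSE = %.6g over %d candidate g\n", x$sse_min,
              nrow(x$sse_profile)))
  invisible(x)
}

#' Fit the error-only multistage model to a cumulative-risk curve
#'
#' For each integer `g` in `g_range`, the sum of squared residuals between
#' the model curve and the data is minimised over `lambda1p` (bounded search
#' on `log10(lambda1p)`: a coarse grid pass guarding against local minima,
#' then golden-section refinement). The `(g, lambda1p)` pair with the
#' global minimum is returned together with the full per-`g` SSE profile.
#' Ties in the profile resolve to the smallest `g`.
#'
#' @param data A `risk_curve` (or data.frame with columns `age`, `risk`),
#'   at least 3 points, risks in `[0, 1]`.
#' @param tissue Registry-convention [tissue_params()] object.
#' @param g_range Candidate integer driver-gene counts; default `1:20`.
#' @param convention Burden convention, see [model_curve_error_only()].
#' @param weights Optional per-point weights (default unweighted, matching
#'   ordinary least squares).
#' @return A `fit_result`: `g_hat`, `rate_hat` (fitted `lambda1p`),
#'   `sse_profile` (per-`g` minima), `sse_min`, `fitted_curve`.
#' @examples
#' tis <- registry_tissue("colon")
#' dat <- model_curve_error_only(seq(5, 85, 5), tis, g = 5, lambda1p = 4e-4)
#' fit_error_only(dat, tis, g_range = 3:7)
#' @export
fit_error_only <- function(data, tissue, g_range = 1:20,
                           convention = c("per_cell", "total"),
                           weights = NULL) {
  convention <- match.arg(convention)
  check_fit_data(data)
  w <- if (is.null(weights)) 1 else weights
  base <- registry_error_base(data$age, tissue, convention)
  profile <- do.call(rbind, lapply(g_range, function(g) {
    pr <- profile_lambda1p(data$risk, base, g, w = w)
    data.frame(g = g, lambda1p = pr$lambda1p, sse = pr$sse)
  }))
  k <- which.min(profile$sse)
  fitted <- model_curve_error_only(data$age, tissue, profile$g[k],
                                   profile$lambda1p[k], convention)
  new_fit_result(profile$g[k], profile$lambda1p[k], NA_real_, profile,
                 fitted, convention)
}

check_fit_data <- function(data) {
  if (!all(c("age", "risk") %in% names(data))) {
    stop("data needs columns 'age' and 'risk'", call. = FALSE)
  }
  if (nrow(data) < 3L) stop("need at least 3 data points", call. = FALSE)
  if (any(data$risk < 0 | data$risk > 1)) {
    stop("risks must be proportions in [0, 1]", call. = FALSE)
  }
  if (all(data$risk == 0)) {
    stop("degenerate fit: all risks are zero", call. = FALSE)
  }
  invisible(data)
}

#' Fit the multistage model with a gated lesion term
#'
#' The burden is `lambda1p * d(t) [/N(t)] + lambda2p * [NL] (t - onset)+`,
#' and the SSE is minimised jointly over `(lambda1p, lambda2p) >= 0` for
#' each candidate `g`: an outer search over `lambda2p` (a zero candidate, a
#' log grid, golden-section refinement) with the inner `lambda1p` profile
#' solved as in [fit_error_only()], then a Nelder-Mead polish of the best
#' interior point. A boundary solution `lambda2p = 0` means the lesion term
#' adds no explanatory power, and the fit coincides with the error-only fit.
#'
#' @inheritParams fit_error_only
#' @param onset_age Age (years) at which lesion exposure starts; `>= 18`.
#' @return A `fit_result` with `lesion_rate_hat` (fitted `lambda2p`) set.
#' @export
fit_with_lesions <- function(data, tissue, g_range = 1:20, onset_age = 20,
                             convention = c("per_cell", "total"),
                             weights = NULL) {
  convention <- match.arg(convention)
  check_fit_data(data)
  if (onset_age < 18) stop("onset_age must be >= 18", call. = FALSE)
  w <- if (is.null(weights)) 1 else weights
  base <- registry_error_base(data$age, tissue, convention)
  lbase <- registry_lesion_base(data$age, tissue, onset_age, convention)
  y <- data$risk

  fit_one_g <- function(g) {
    inner <- function(q) profile_lambda1p(y, base, g, extra_burden = q * lbase, w = w)
    zero <- inner(0)
    if (all(lbase == 0)) {  # onset beyond the data: lesion term vanishes
      return(data.frame(g = g, lambda1p = zero$lambda1p, lambda2p = 0,
                        sse = zero$sse))
    }
    q_grid <- 10^seq(-16, 4, by = 0.5)
    q_sse <- vapply(q_grid, function(q) inner(q)$sse, numeric(1))
    k <- which.min(q_sse)
    lo <- log10(q_grid[max(1L, k - 1L)])
    hi <- log10(q_grid[min(length(q_grid), k + 1L)])
    opt <- stats::optimize(function(lq) inner(10^lq)$sse, c(lo, hi), tol = 1e-10)
    q_best <- 10^opt$minimum
    best <- inner(q_best)
    # joint polish on the log scale
    pol <- stats::optim(
      c(log10(best$lambda1p), log10(q_best)),
      function(par) {
        gg <- stats::ppois(g - 1, 10^par[1L] * base + 10^par[2L] * lbase, lower.tail = FALSE)
        sum(w * (gg - y)^2)
      },
      method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-15)
    )
    if (pol$value < best$sse) {
      best <- list(lambda1p = 10^pol$par[1L], sse = pol$value)
      q_best <- 10^pol$par[2L]
    }
    if (zero$sse <= best$sse) {
      data.frame(g = g, lambda1p = zero$lambda1p, lambda2p = 0, sse = zero$sse)
    } else {
      data.frame(g = g, lambda1p = best$lambda1p, lambda2p = q_best,
                 sse = best$sse)
    }
  }

  profile <- do.call(rbind, lapply(g_range, fit_one_g))
  k <- which.min(profile$sse)
  fitted <- model_curve_with_lesions(data$age, tissue, profile$g[k],
                                     profile$lambda1p[k], profile$lambda2p[k],
                                     onset_age, convention)
  out <- new_fit_result(profile$g[k], profile$lambda1p[k],
                        profile$lambda2p[k], profile, fitted, convention,
                        onset_age)
  if (out$lesion_rate_hat == 0) {
    message("lambda2p fitted at the zero boundary: ",
            "the lesion term adds no explanatory power")
  }
  out
}

#' Literature calibration of the driver mutation rate per division
#'
#' Combines published per-division genome mutation rates (about 1.14 in
#' healthy haematopoiesis and 1.37 in brain development) with the driver
#' fraction of the genome (more than 1% of genes contribute to cancer, and
#' protein-coding genes are about 2% of the genome, so `p = 0.01 * 0.02`)
#' into reference values of `lambda1p`.
#'
#' @return A data.frame with columns `context`, `lambda1`, `p`, `lambda1p`.
#' @examples
#' driver_rate_reference()
#' @export
driver_rate_reference <- function() {
  p_ref <- 0.01 * 0.02
  lambda1 <- c(haematopoiesis = 1.14, brain = 1.37)
  data.frame(context = names(lambda1), lambda1 = as.numeric(lambda1),
             p = p_ref, lambda1p = as.numeric(lambda1) * p_ref,
             row.names = NULL)
}
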