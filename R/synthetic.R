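#' Specification for a synthetic registry-style risk curve
#'
#' Describes the ground truth and noise model for a synthetic age versus
#' cumulative-risk curve: the tissue, the true driver-gene count and rates,
#' the age grid (default 5, 10, ..., 85 years, the registry binning), and
#' the noise (none, binomial sampling from a finite cohort, or additive
#' gaussian).
#'
#' @param tissue A registry tissue name (see [registry_tissue_table()]) or
#'   a [tissue_params()] object.
#' @param true_g True driver-gene count, positive integer.
#' @param true_lambda1p True driver mutations per division, `> 0`.
#' @param true_lambda2p True driver lesions per cell per year (0 for an
#'   error-only curve).
#' @param onset_age Lesion exposure onset (years), `>= 18`.
#' @param ages Age grid, default `seq(5, 85, by = 5)`.
#' @param noise `"none"`, `"binomial"` or `"gaussian"`.
#' @param cohort_size Cohort size per age point for binomial noise, `>= 1`.
#' @param sd Standard deviation for gaussian noise, `>= 0`.
#' @param seed RNG seed; required when noise is not `"none"`.
#' @param convention Burden convention, see [model_curve_error_only()].
#' @param monotonize Enforce the cumulative-risk invariant on noisy curves
#'   by a running maximum (default `TRUE`); disable to stress-test fitters
#'   on raw noisy output.
#' @return An object of class `synthetic_curve_spec`.
#' @export
synthetic_curve_spec <- function(tissue, true_g, true_lambda1p,
                                 true_lambda2p = 0, onset_age = 20,
                                 ages = seq(5, 85, by = 5),
                                 noise = c("none", "binomial", "gaussian"),
                                 cohort_size = 1e6, sd = 0.01, seed = NULL,
                                 convention = c("per_cell", "total"),
                                 monotonize = TRUE) {
  noise <- match.arg(noise)
  convention <- match.arg(convention)
  if (is.character(tissue)) tissue <- registry_tissue(tissue)
  problems <- character(0)
  if (!inherits(tissue, "tissue_params")) problems <- c(problems, "invalid tissue")
  if (true_g < 1 || true_g != round(true_g)) problems <- c(problems, "true_g must be a positive integer")
  if (true_lambda1p < 0) problems <- c(problems, "true_lambda1p must be >= 0")
  if (true_lambda2p < 0) problems <- c(problems, "true_lambda2p must be >= 0")
  if (onset_age < 18) problems <- c(problems, "onset_age must be >= 18")
  if (is.unsorted(ages) || any(ages < 0)) problems <- c(problems, "ages must be sorted and >= 0")
  if (noise == "binomial" && cohort_size < 1) problems <- c(problems, "cohort_size must be >= 1")
  if (noise == "gaussian" && sd < 0) problems <- c(problems, "sd must be >= 0")
  if (noise != "none" && is.null(seed)) problems <- c(problems, "seed is required for noisy curves")
  if (length(problems) > 0L) {
    stop("invalid synthetic curve spec:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  structure(list(tissue = tissue, true_g = as.integer(true_g),
                 true_lambda1p = true_lambda1p, true_lambda2p = true_lambda2p,
                 onset_age = onset_age, ages = ages, noise = noise,
                 cohort_size = cohort_size, sd = sd, seed = seed,
                 convention = convention, monotonize = monotonize),
            class = "synthetic_curve_spec")
}

#' Generate a registry-style cumulative-risk curve with known ground truth
#'
#' Evaluates the model curve for the spec's true parameters on its age
#' grid, applies the requested noise per point (binomial: a cohort-sized
#' draw of cases; gaussian: additive, clamped to `[0, 1]`), and (by
#' default) restores the cumulative-risk invariant with a running maximum.
#' Reproducible from the spec's seed; the ground truth travels with the
#' curve as the `"truth"` attribute.
#'
#' @param spec A [synthetic_curve_spec()].
#' @return A `risk_curve` data.frame with a `"truth"` attribute.
#' @examples
#' spec <- synthetic_curve_spec("colon", true_g = 5, true_lambda1p = 4e-4,
#'                              noise = "binomial", seed = 42)
#' head(generate_registry_curve(spec))
#' @export
generate_registry_curve <- function(spec) {
  if (!inherits(spec, "synthetic_curve_spec")) {
    stop("spec must be a synthetic_curve_spec", call. = FALSE)
  }
  model <- if (spec$true_lambda2p > 0) {
    model_curve_with_lesions(spec$ages, spec$tissue, spec$true_g,
                             spec$true_lambda1p, spec$true_lambda2p,
                             spec$onset_age, spec$convention)
  } else {
    model_curve_error_only(spec$ages, spec$tissue, spec$true_g,
                           spec$true_lambda1p, spec$convention)
  }
  risk <- model$risk
  if (spec$noise != "none") {
    set.seed(as.integer(spec$seed))
    if (spec$noise == "binomial") {
      risk <- stats::rbinom(length(risk), size = round(spec$cohort_size),
                            prob = risk) / round(spec$cohort_size)
    } else {
      risk <- risk + stats::rnorm(length(risk), 0, spec$sd)
    }
    risk <- pmin(1, pmax(0, risk))
    if (spec$monotonize) risk <- cummax(risk)
  }
  out <- new_risk_curve(spec$ages, risk, label = "synthetic")
  attr(out, "truth") <- list(g = spec$true_g, lambda1p = spec$true_lambda1p,
                             lambda2p = spec$true_lambda2p,
                             onset_age = spec$onset_age,
                             convention = spec$convention,
                             noise = spec$noise, seed = spec$seed)
  out
}

#' Published figure parameter sets
#'
#' Parameter bundles used in the reference analyses: `"fig2"`/`"fig3"` is
#' the small simulated tissue (`N0 = 10, NL = 100, r = 0.15, a_d = 0.16,
#' b = 0.01, lambda1 = 0.01, lambda2 = 0.001`); `"fig5a"`, `"fig5b"` and
#' `"fig5c"` are the risk-difference scans over `lambda2`, `b` and `g`
#' around the base setting `N0 = 1, NL = 1e9, r = log(NL)/18, lambda1 =
#' 0.5, p = 0.2`. The scanned grids for the varied parameter are the
#' package's choice (one decade apart, bracketing the fixed values).
#'
#' @param name One of `"fig2"`, `"fig3"`, `"fig5a"`, `"fig5b"`, `"fig5c"`.
#' @return A named list of parameter objects and scan values.
#' @examples
#' fig_fixture("fig2")$mut
#' @export
fig_fixture <- function(name) {
  rd_tissue <- function(b) make_tissue_from_registry(1e9, b = b)
  switch(
    name,
    fig2 = ,
    fig3 = list(tissue = tissue_params(10, 100, 0.15, 0.16, 0.01),
                mut = mutation_params(0.01, 0.001)),
    fig5a = list(tissue = rd_tissue(0.1), lambda1 = 0.5, p = 0.2, g = 6,
                 b = 0.1, lambda2_values = c(0.001, 0.01, 0.1)),
    fig5b = list(lambda1 = 0.5, p = 0.2, g = 6, lambda2 = 0.01,
                 b_values = c(0.01, 0.1, 1), tissue_for_b = rd_tissue),
    fig5c = list(tissue = rd_tissue(1), lambda1 = 0.5, p = 0.2, b = 1,
                 lambda2 = 0.1, g_values = c(2, 4, 6)),
    stop("unknown fixture '", name, "'", call. = FALSE)
  )
}
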