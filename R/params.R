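#' Tissue parameters for the two-phase stem-cell pool
#'
#' A tissue is described by an initial stem-cell count `N0`, a pool capacity
#' `NL`, a growth-phase division rate `r` (per cell per time unit), a
#' stable-phase division rate `a_d` that applies while the pool is below
#' capacity, and a per-cell removal rate `b` that applies in the stable phase.
#'
#' @param N0 Initial stem-cell count (positive integer-valued).
#' @param NL Stem-cell pool capacity, `NL >= N0`.
#' @param r Growth-phase division rate per cell per time unit, `>= 0`.
#' @param a_d Stable-phase division rate per cell per time unit while
#'   `N < NL`, `>= 0`.
#' @param b Stable-phase removal rate per cell per time unit, `>= 0`.
#' @return An object of class `tissue_params`.
#' @seealso [make_tissue_from_registry()] for the registry convention
#'   (single founding cell, growth phase ending at age 18).
#' @examples
#' tissue_params(N0 = 10, NL = 100, r = 0.15, a_d = 0.16, b = 0.01)
#' @export
tissue_params <- function(N0, NL, r, a_d, b) {
  obj <- structure(
    list(N0 = as.numeric(N0), NL = as.numeric(NL), r = as.numeric(r),
         a_d = as.numeric(a_d), b = as.numeric(b)),
    class = "tissue_params"
  )
  problems <- check_tissue(obj)
  if (length(problems) > 0L) {
    stop("invalid tissue parameters:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  obj
}

check_tissue <- function(x) {
  p <- character(0)
  bad_num <- function(v) length(v) != 1L || !is.finite(v)
  if (bad_num(x$N0) || x$N0 < 1) p <- c(p, "N0 must be a finite number >= 1")
  if (bad_num(x$NL) || (is.finite(x$N0) && x$NL < x$N0))
    p <- c(p, "NL must be finite and >= N0")
  if (bad_num(x$r) || x$r < 0) p <- c(p, "r must be finite and >= 0")
  if (bad_num(x$a_d) || x$a_d < 0) p <- c(p, "a_d must be finite and >= 0")
  if (bad_num(x$b) || x$b < 0) p <- c(p, "b must be finite and >= 0")
  p
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("Tissue parameters\n")
  cat(sprintf("  N0 = %g, NL = %g (cells)\n", x$N0, x$NL))
  cat(sprintf("  r = %g (growth), a_d = %g, b = %g (stable, per cell per time)\n",
              x$r, x$a_d, x$b))
  invisible(x)
}

#' Mutation-process parameters
#'
#' Replication errors arise at cell division, Poisson-distributed with mean
#' `lambda1` per division. Lesions are mutagen-induced mutations arising
#' independently of division, Poisson-distributed with mean `lambda2` per
#' cell per time unit. `lambda2_onset` gates the lesion process: before that
#' time the effective lesion rate is 0 (e.g. exposure starting at age 20).
#'
#' @param lambda1 Mean replication errors per division, `>= 0`.
#' @param lambda2 Mean lesions per cell per time unit, `>= 0`.
#' @param lambda2_onset Time before which the effective lesion rate is 0;
#'   0 (the default) means chronic exposure from the start.
#' @return An object of class `mutation_params`.
#' @examples
#' mutation_params(lambda1 = 0.01, lambda2 = 0.001)
#' @export
mutation_params <- function(lambda1, lambda2 = 0, lambda2_onset = 0) {
  obj <- structure(
    list(lambda1 = as.numeric(lambda1), lambda2 = as.numeric(lambda2),
         lambda2_onset = as.numeric(lambda2_onset)),
    class = "mutation_params"
  )
  problems <- check_mutation(obj)
  if (length(problems) > 0L) {
    stop("invalid mutation parameters:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  obj
}

check_mutation <- function(x) {
  p <- character(0)
  bad_num <- function(v) length(v) != 1L || !is.finite(v)
  if (bad_num(x$lambda1) || x$lambda1 < 0) p <- c(p, "lambda1 must be finite and >= 0")
  if (bad_num(x$lambda2) || x$lambda2 < 0) p <- c(p, "lambda2 must be finite and >= 0")
  if (bad_num(x$lambda2_onset) || x$lambda2_onset < 0)
    p <- c(p, "lambda2_onset must be finite and >= 0")
  p
}

#' Effective lesion rate at a given time
#'
#' Step function: 0 before `lambda2_onset`, `lambda2` afterwards.
#'
#' @param mut A [mutation_params()] object.
#' @param t Time (vectorised).
#' @return Numeric vector of effective lesion rates.
#' @export
effective_lambda2 <- function(mut, t) {
  ifelse(t >= mut$lambda2_onset, mut$lambda2, 0)
}

#' @export
print.mutation_params <- function(x, ...) {
  cat("Mutation parameters\n")
  cat(sprintf("  lambda1 = %g errors per division\n", x$lambda1))
  cat(sprintf("  lambda2 = %g lesions per cell per time (onset %g)\n",
              x$lambda2, x$lambda2_onset))
  invisible(x)
}

#' Multistage carcinogenesis risk parameters
#'
#' Each accumulated mutation hits a cancer driver gene with probability `p`;
#' carcinogenesis requires mutations in `g` driver genes.
#'
#' @param p Probability that a mutation hits a driver gene, in `[0, 1]`.
#' @param g Number of driver-gene mutations required, positive integer.
#' @return An object of class `risk_params`.
#' @examples
#' risk_params(p = 0.0002, g = 5)
#' @export
risk_params <- function(p, g) {
  obj <- structure(list(p = as.numeric(p), g = as.numeric(g)),
                   class = "risk_params")
  problems <- check_risk(obj)
  if (length(problems) > 0L) {
    stop("invalid risk parameters:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  obj
}

check_risk <- function(x) {
  p <- character(0)
  bad_num <- function(v) length(v) != 1L || !is.finite(v)
  if (bad_num(x$p) || x$p < 0 || x$p > 1) p <- c(p, "p must be in [0, 1]")
  if (bad_num(x$g) || x$g < 1 || x$g != round(x$g))
    p <- c(p, "g must be a positive integer")
  p
}

#' @export
print.risk_params <- function(x, ...) {
  cat(sprintf("Risk parameters: p = %g, g = %d\n", x$p, as.integer(x$g)))
  invisible(x)
}

#' Build tissue parameters under the registry convention
#'
#' The registry convention assumes every tissue originates from a single stem
#' cell (`N0 = 1`) and that the pool reaches its capacity `NL` at age 18, so
#' the growth-phase division rate is `log(NL) / 18` per year. The
#' stable-phase division rate is taken much larger than the removal rate
#' (`a_d = a_over_b_ratio * b`), so that a removed cell is replaced
#' essentially immediately and the stable-phase per-cell division rate
#' equals `b`.
#'
#' @param NL Stem-cell pool capacity, `>= 1`.
#' @param b Per-cell removal (equivalently turnover) rate per year;
#'   defaults to 0 when only the growth-phase rate is of interest.
#' @param a_over_b_ratio Ratio `a_d / b` used to realise the fast-refill
#'   limit numerically; default `1e4`.
#' @return A [tissue_params()] object with `N0 = 1` and growth rate
#'   `log(NL)/18`.
#' @examples
#' make_tissue_from_registry(NL = 2.00e8, b = 73)  # colonic stem cells
#' @export
make_tissue_from_registry <- function(NL, b = 0, a_over_b_ratio = 1e4) {
  if (length(NL) != 1L || !is.finite(NL) || NL < 1)
    stop("NL must be a finite number >= 1", call. = FALSE)
  tissue_params(N0 = 1, NL = NL, r = log(NL) / 18,
                a_d = a_over_b_ratio * b, b = b)
}

#' Validate a full parameter bundle
#'
#' Checks all invariants of the tissue, mutation and risk parameter objects
#' and aggregates every violation into a single error report.
#'
#' @param tissue A [tissue_params()] object.
#' @param mut A [mutation_params()] object.
#' @param risk A [risk_params()] object.
#' @return Invisibly, `list(tissue, mut, risk)` unchanged, if valid.
#' @export
validate_params <- function(tissue, mut, risk) {
  problems <- character(0)
  if (!inherits(tissue, "tissue_params")) {
    problems <- c(problems, "tissue is not a tissue_params object")
  } else {
    problems <- c(problems, check_tissue(tissue))
  }
  if (!inherits(mut, "mutation_params")) {
    problems <- c(problems, "mut is not a mutation_params object")
  } else {
    problems <- c(problems, check_mutation(mut))
  }
  if (!inherits(risk, "risk_params")) {
    problems <- c(problems, "risk is not a risk_params object")
  } else {
    problems <- c(problems, check_risk(risk))
  }
  if (length(problems) > 0L) {
    stop("parameter validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(list(tissue = tissue, mut = mut, risk = risk))
}

#' Write a parameter bundle to a plain-text config file
#'
#' One `key=value` pair per line; keys are `N0, NL, r, a_d, b, lambda1,
#' lambda2, lambda2_onset, p, g, I_cap, J_cap, seed`.
#'
#' @param tissue,mut,risk Parameter objects; see [validate_params()].
#' @param path Output file path.
#' @param I_cap,J_cap Optional grid caps for simulation.
#' @param seed Optional RNG seed to record.
#' @return Invisibly, the path written.
#' @export
write_model_config <- function(tissue, mut, risk, path,
                               I_cap = NULL, J_cap = NULL, seed = NULL) {
  validate_params(tissue, mut, risk)
  kv <- c(N0 = tissue$N0, NL = tissue$NL, r = tissue$r, a_d = tissue$a_d,
          b = tissue$b, lambda1 = mut$lambda1, lambda2 = mut$lambda2,
          lambda2_onset = mut$lambda2_onset, p = risk$p, g = risk$g)
  if (!is.null(I_cap)) kv <- c(kv, I_cap = I_cap)
  if (!is.null(J_cap)) kv <- c(kv, J_cap = J_cap)
  if (!is.null(seed)) kv <- c(kv, seed = seed)
  writeLines(sprintf("%s=%.17g", names(kv), kv), path)
  invisible(path)
}

#' Read a parameter bundle from a plain-text config file
#'
#' @param path Path to a `key=value` config file written by
#'   [write_model_config()] (or by hand, same keys).
#' @return A list with elements `tissue`, `mut`, `risk`, and (when present
#'   in the file) `I_cap`, `J_cap`, `seed`.
#' @export
read_model_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(parts, function(x) length(x) != 2L, logical(1))
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(parts, `[[`, character(1), 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(parts, `[[`, character(1), 2L))))
  if (anyNA(vals)) {
    stop("non-numeric config value(s) for: ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  kv <- stats::setNames(as.list(vals), keys)
  need <- c("N0", "NL", "r", "a_d", "b", "lambda1", "lambda2", "p", "g")
  missing_keys <- setdiff(need, keys)
  if (length(missing_keys) > 0L) {
    stop("config is missing key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  onset <- if (!is.null(kv$lambda2_onset)) kv$lambda2_onset else 0
  out <- list(
    tissue = tissue_params(kv$N0, kv$NL, kv$r, kv$a_d, kv$b),
    mut = mutation_params(kv$lambda1, kv$lambda2, onset),
    risk = risk_params(kv$p, kv$g)
  )
  for (extra in c("I_cap", "J_cap", "seed")) {
    if (!is.null(kv[[extra]])) out[[extra]] <- kv[[extra]]
  }
  out
}
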