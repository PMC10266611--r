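#' Read an age versus cumulative-risk curve from CSV
#'
#' Expects a header with at least `age` and `risk` columns (risk as a
#' proportion). If several risk values exceed 1 (and none exceeds 100) the
#' whole column is taken to be in percent and divided by 100, with a
#' message; a single value above 1 is an error. Rows are sorted by age; a
#' non-monotone cumulative risk triggers a warning (real registry data can
#' wobble), an out-of-range risk an error.
#'
#' @param path Path to the CSV file.
#' @param age_col,risk_col Column names; defaults `"age"` and `"risk"`.
#' @return A `risk_curve` data.frame with columns `age`, `risk` (plus any
#'   `sex`/`site` columns carried through as the label).
#' @export
read_risk_curve_csv <- function(path, age_col = "age", risk_col = "risk") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty file: ", path, call. = FALSE)
  for (col in c(age_col, risk_col)) {
    if (!col %in% names(df)) {
      stop("missing column '", col, "' in ", path, call. = FALSE)
    }
  }
  age <- suppressWarnings(as.numeric(df[[age_col]]))
  risk <- suppressWarnings(as.numeric(df[[risk_col]]))
  bad <- which(is.na(age) | is.na(risk))
  if (length(bad) > 0L) {
    stop("unparseable numbers in ", path, " at data line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n_over <- sum(risk > 1)
  if (n_over > 0L) {
    # a consistently percent-scaled file has several values above 1;
    # a lone excursion past 1 is an out-of-range proportion
    if (n_over >= 2L && all(risk <= 100)) {
      message("risk values exceed 1; interpreting the column as percent ",
              "and dividing by 100")
      risk <- risk / 100
    } else {
      stop("risk values out of range (must be proportions or percent)",
           call. = FALSE)
    }
  }
  if (any(risk < 0)) stop("negative risk values", call. = FALSE)
  ord <- order(age)
  age <- age[ord]
  risk <- risk[ord]
  if (is.unsorted(risk)) {
    warning("cumulative risk is not monotone non-decreasing in age")
  }
  label <- NULL
  for (col in c("site", "sex")) {
    if (col %in% names(df)) label <- c(label, unique(as.character(df[[col]])))
  }
  new_risk_curve(age, risk, label = if (is.null(label)) basename(path)
                 else paste(label, collapse = "/"))
}

#' Write a risk curve to CSV
#'
#' @param curve A `risk_curve` (or data.frame with `age`, `risk`).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_risk_curve_csv <- function(curve, path) {
  df <- data.frame(age = curve$age, risk = signif(curve$risk, 12))
  lbl <- attr(curve, "label")
  if (!is.null(lbl)) df$label <- paste(lbl, collapse = "/")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

run_report_lines <- function(title, fields) {
  c(paste0("# ", title),
    paste0("package_version=", as.character(utils::packageVersion("mutstage"))),
    sprintf("%s=%s", names(fields), vapply(fields, function(x)
      paste(format(x, digits = 12), collapse = ","), character(1))))
}

#' Write analysis outputs with provenance
#'
#' Writes the CSV tables for a result object (trajectory, replicate
#' summary, risk curve, risk difference, or fit result) plus a plain-text
#' run report carrying the resolved parameters, seed and package version,
#' so the run can be reproduced exactly.
#'
#' @param result A result object produced by this package.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix; default derived from the result class.
#' @return Character vector of the paths written (the manifest).
#' @export
write_outputs <- function(result, out_dir, prefix = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  UseMethod("write_outputs")
}

#' @export
write_outputs.mutstage_trajectory <- function(result, out_dir, prefix = "trajectory") {
  csv <- file.path(out_dir, paste0(prefix, ".csv"))
  df <- as.data.frame(result)
  df[] <- lapply(df, function(x) if (is.numeric(x)) signif(x, 12) else x)
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  rpt <- file.path(out_dir, paste0(prefix, "_report.txt"))
  tl <- attr(result, "tallies")
  writeLines(run_report_lines("simulation run", c(
    list(seed = attr(result, "seed"), I_cap = attr(result, "I_cap"),
         J_cap = attr(result, "J_cap"), absorbed = attr(result, "absorbed")),
    tl)), rpt)
  c(csv, rpt)
}

#' @export
write_outputs.replicate_summary <- function(result, out_dir, prefix = "replicates") {
  csv <- file.path(out_dir, paste0(prefix, ".csv"))
  utils::write.csv(as.data.frame(result), csv, row.names = FALSE, quote = FALSE)
  rpt <- file.path(out_dir, paste0(prefix, "_report.txt"))
  writeLines(run_report_lines("replicate summary", list(
    seed = attr(result, "seed"), n_reps = attr(result, "n_reps"))), rpt)
  c(csv, rpt)
}

#' @export
write_outputs.risk_curve <- function(result, out_dir, prefix = "risk_curve") {
  csv <- file.path(out_dir, paste0(prefix, ".csv"))
  write_risk_curve_csv(result, csv)
  manifest <- csv
  truth <- attr(result, "truth")
  if (!is.null(truth)) {
    rpt <- file.path(out_dir, paste0(prefix, "_truth.txt"))
    writeLines(run_report_lines("synthetic curve ground truth", truth), rpt)
    manifest <- c(manifest, rpt)
  }
  manifest
}

#' @export
write_outputs.risk_difference <- function(result, out_dir, prefix = "risk_difference") {
  csv <- file.path(out_dir, paste0(prefix, ".csv"))
  utils::write.csv(result$curve, csv, row.names = FALSE, quote = FALSE)
  rpt <- file.path(out_dir, paste0(prefix, "_peak.txt"))
  writeLines(run_report_lines("risk difference peak", list(
    peak_time = result$peak_time, peak_rd = result$peak_rd,
    peak_resolution = result$peak_resolution,
    convention = result$convention)), rpt)
  c(csv, rpt)
}

#' @export
write_outputs.fit_result <- function(result, out_dir, prefix = "fit") {
  curve_csv <- file.path(out_dir, paste0(prefix, "_curve.csv"))
  write_risk_curve_csv(result$fitted_curve, curve_csv)
  profile_csv <- file.path(out_dir, paste0(prefix, "_sse_profile.csv"))
  utils::write.csv(result$sse_profile, profile_csv, row.names = FALSE,
                   quote = FALSE)
  rpt <- file.path(out_dir, paste0(prefix, "_report.txt"))
  fields <- list(g_hat = result$g_hat, rate_hat = result$rate_hat,
                 sse_min = result$sse_min, convention = result$convention)
  if (!is.na(result$lesion_rate_hat)) {
    fields$lesion_rate_hat <- result$lesion_rate_hat
    fields$onset_age <- result$onset_age
  }
  writeLines(run_report_lines("fit result", fields), rpt)
  c(curve_csv, profile_csv, rpt)
}
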