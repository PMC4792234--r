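#' Read and write assay-dataset tables
#'
#' Delimited text with header columns `substrate_uM`, `activator_uM`,
#' `enzyme_uM`, `replicate`, `velocity_uM_per_s`.
#'
#' @param dataset an `assay_dataset` data.frame.
#' @param path file path.
#' @param sep field separator (default tab).
#' @return `write_dataset` returns the path invisibly; `read_dataset`
#'   returns an `assay_dataset`.
#' @export
write_dataset <- function(dataset, path, sep = "\t") {
  utils::write.table(as.data.frame(dataset), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("substrate_uM", "activator_uM", "enzyme_uM", "replicate",
            "velocity_uM_per_s")
  if (!all(need %in% names(d)))
    stop("dataset table is missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  class(d) <- c("assay_dataset", "data.frame")
  d
}

#' Write a progress trace as two-column text
#'
#' Columns `time_s` and `A340`.
#'
#' @param trace a `progress_trace`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(data.frame(time_s = trace$times, A340 = trace$absorbance),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write assay designs as JSON
#'
#' @param design an [assay_design].
#' @param path file path.
#' @export
write_design <- function(design, path) {
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  assay_design(substrate_levels = d$substrate_levels,
               activator_levels = d$activator_levels,
               enzyme_conc = d$enzyme_conc, replicates = d$replicates,
               noise_cv = d$noise_cv, seed = d$seed)
}

#' Read a 1-D scattering profile from 3-column text
#'
#' Whitespace-delimited `q I sigma` (sigma optional), `#` comment lines
#' skipped — the common plain-text exchange format for small-angle
#' scattering curves.
#'
#' @param path file path.
#' @param concentration optional sample concentration, mg/mL.
#' @return A [scattering_profile].
#' @export
read_profile <- function(path, concentration = NULL) {
  d <- utils::read.table(path, header = FALSE, comment.char = "#")
  scattering_profile(q = d[[1]], intensity = d[[2]],
                     sigma = if (ncol(d) >= 3) d[[3]] else NULL,
                     concentration = concentration)
}

#' @rdname read_profile
#' @param profile a [scattering_profile].
#' @export
write_profile <- function(profile, path) {
  d <- data.frame(q = profile$q, I = profile$intensity)
  if (!is.null(profile$sigma)) d$sigma <- profile$sigma
  utils::write.table(d, path, sep = " ", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read SEC standards from 2-column text
#'
#' Delimited columns `Ve_mL`, `mass_Da`, one standard per row.
#'
#' @param path file path.
#' @return A data.frame suitable for [sec_calibration()].
#' @export
read_sec_standards <- function(path) {
  d <- utils::read.table(path, header = TRUE, comment.char = "#")
  if (!all(c("Ve_mL", "mass_Da") %in% names(d)))
    stop("standards table needs columns Ve_mL and mass_Da", call. = FALSE)
  d
}

#' Serialize fit and test results to JSON and back
#'
#' Stable field names, full double precision (no rounding), so results
#' round-trip losslessly between runs and reports.
#'
#' @param x a `fit_result` or `f_test_result`.
#' @param path file path.
#' @export
write_result_json <- function(x, path) {
  payload <- unclass(x)
  payload$result_class <- class(x)[1]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_result_json
#' @export
read_result_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- d$result_class
  d$result_class <- NULL
  if (identical(cls, "fit_result")) {
    d$estimates <- as.list(d$estimates)
    d$standard_errors <- lapply(as.list(d$standard_errors),
                                function(v) if (is.null(v)) NA_real_ else v)
  }
  structure(d, class = cls)
}

#' Full fit report for one construct's dataset
#'
#' Runs the complete inference on a replicate initial-rate dataset: the
#' per-activator apparent-constant table, both global fits (coupling factor
#' free and pinned at 1) and their extra-sum-of-squares F-test. Printing the
#' returned object gives the paper-style text layout; [write_result_json()]
#' components serialize it.
#'
#' @param dataset an `assay_dataset`.
#' @param weights optional per-row fit weights.
#' @param n_starts multi-start count for the global fits.
#' @return An object of class `fit_report` with elements `apparent_table`,
#'   `global_free`, `global_fixed`, `f_test`.
#' @export
fit_report <- function(dataset, weights = NULL, n_starts = 8) {
  tab <- apparent_constant_table(dataset)
  free <- fit_global(dataset, fix_alpha = NULL, weights = weights,
                     n_starts = n_starts)
  fixed <- fit_global(dataset, fix_alpha = 1, weights = weights,
                      n_starts = n_starts)
  ft <- tryCatch(extra_ss_f_test(fixed, free), error = function(e) NULL)
  structure(
    list(apparent_table = tab, global_free = free, global_fixed = fixed,
         f_test = ft, seed = attr(dataset, "seed")),
    class = "fit_report"
  )
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Apparent Michaelis-Menten constants by activator level\n")
  tab <- x$apparent_table
  cat(sprintf("  %-14s %-18s %-18s %s\n", "[F-actin] uM", "k_cat_app (1/s)",
              "K_M_app (uM)", "cat. power (1/s/mM)"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-14.3g %-18s %-18s %.1f\n", tab$activator_uM[i],
                sprintf("%.3g +- %.2g", tab$k_cat_app[i], tab$k_cat_app_se[i]),
                sprintf("%.3g +- %.2g", tab$K_M_app[i], tab$K_M_app_se[i]),
                tab$catalytic_power_rounded[i]))
  }
  cat("\nGlobal fit, coupling factor free:\n")
  print(x$global_free)
  cat("Global fit, coupling factor fixed at 1:\n")
  print(x$global_fixed)
  if (!is.null(x$f_test)) {
    cat("Nested-model comparison (alpha = 1 vs alpha free):\n  ")
    print(x$f_test)
  }
  invisible(x)
}
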