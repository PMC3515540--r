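# Delimited-text readers and writers for the instrument-style formats the
# pipeline consumes, and key-value serialization of fit results.

.read_delim_cols <- function(path, cols) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .stopf("%s: missing required column(s) %s", path,
           paste(missing, collapse = ", "))
  df
}

#' Read a chemical unfolding curve
#'
#' CSV with header `urea_M,signal` (decimal point, UTF-8).
#'
#' @param path file path.
#' @param temperature_K measurement temperature (default 293.15 K).
#' @param signal_kind `"raw"` or `"fraction"`.
#' @return A [chem_unfold_curve].
#' @export
read_chem_curve <- function(path, temperature_K = 293.15,
                            signal_kind = "fraction") {
  df <- .read_delim_cols(path, c("urea_M", "signal"))
  chem_unfold_curve(df$urea_M, df$signal, temperature_K = temperature_K,
                    signal_kind = signal_kind)
}

#' Write a chemical unfolding curve
#'
#' @param curve a [chem_unfold_curve].
#' @param path output CSV path (columns `urea_M,signal`).
#' @export
write_chem_curve <- function(curve, path) {
  utils::write.csv(data.frame(urea_M = curve$denaturant_M,
                              signal = curve$signal),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DSC scan
#'
#' CSV with header `temp_C,cp_kcal_mol_K`; the scan index is taken from a
#' trailing integer in the file name (e.g. `protein_scan2.csv`) unless
#' given explicitly.
#'
#' @param path file path.
#' @param scan_rate_C_per_min scan rate metadata (default 1).
#' @param scan_index explicit scan index; default parsed from the name,
#'   falling back to 1.
#' @return A [thermogram].
#' @export
read_thermogram <- function(path, scan_rate_C_per_min = 1, scan_index = NULL) {
  df <- .read_delim_cols(path, c("temp_C", "cp_kcal_mol_K"))
  if (is.null(scan_index)) {
    m <- regmatches(basename(path),
                    regexpr("[0-9]+(?=\\.[A-Za-z]+$)", basename(path),
                            perl = TRUE))
    scan_index <- if (length(m)) as.integer(m) else 1L
  }
  thermogram(df$temp_C, df$cp_kcal_mol_K,
             scan_rate_C_per_min = scan_rate_C_per_min,
             scan_index = scan_index)
}

#' Write a DSC scan
#'
#' @param t a [thermogram].
#' @param path output CSV path (columns `temp_C,cp_kcal_mol_K`).
#' @export
write_thermogram <- function(t, path) {
  utils::write.csv(data.frame(temp_C = t$temp_C, cp_kcal_mol_K = t$cp),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Kirchhoff series
#'
#' CSV with header `urea_M,Tm_C,dHcal_kcal_mol` (urea is metadata only).
#'
#' @param path file path.
#' @return Data frame with those columns.
#' @export
read_kirchhoff_series <- function(path)
  .read_delim_cols(path, c("urea_M", "Tm_C", "dHcal_kcal_mol"))

#' Read a generic two-column series
#'
#' @param path file path.
#' @param cols required column names, in order (e.g. `c("urea_M",
#'   "s0_20w_S")`, `c("quencher_M", "intensity")`).
#' @return Data frame with the requested columns.
#' @export
read_series <- function(path, cols) .read_delim_cols(path, cols)

#' Key-value records of a fit
#'
#' Serializes any of the package's fit objects as a data frame of
#' `(parameter, value, standard_error, unit)` records.
#'
#' @param fit a fitted object (`three_state_fit`, `dsc_fit`,
#'   `kirchhoff_fit`, `sigmoid_fit`, `stern_volmer_fit`).
#' @param ... passed to methods.
#' @return Data frame with columns `parameter`, `value`, `standard_error`,
#'   `unit`.
#' @export
fit_records <- function(fit, ...) UseMethod("fit_records")

.rec <- function(parameter, value, se, unit)
  data.frame(parameter = parameter, value = value, standard_error = se,
             unit = unit, stringsAsFactors = FALSE)

#' @export
fit_records.three_state_fit <- function(fit, ...) {
  p <- fit$params
  rbind(
    .rec("dG_NI", p$dG_NI, fit$se[["dG_NI"]], "kcal/mol"),
    .rec("dG_IU", p$dG_IU, fit$se[["dG_IU"]], "kcal/mol"),
    .rec("m_NI", p$m_NI, fit$se[["m_NI"]], "kcal/mol/M"),
    .rec("m_IU", p$m_IU, fit$se[["m_IU"]], "kcal/mol/M"),
    .rec("Cm_NI", fit$Cm_NI, fit$se_Cm[["Cm_NI"]], "M"),
    .rec("Cm_IU", fit$Cm_IU, fit$se_Cm[["Cm_IU"]], "M"),
    .rec("Y_N", p$Y_N, fit$se[["Y_N"]], "signal"),
    .rec("Y_I", p$Y_I, fit$se[["Y_I"]], "signal"),
    .rec("Y_U", p$Y_U, fit$se[["Y_U"]], "signal"))
}

#' @export
fit_records.dsc_fit <- function(fit, ...) {
  out <- NULL
  for (i in seq_along(fit$transitions)) {
    tr <- fit$transitions[[i]]
    out <- rbind(out,
      .rec(sprintf("Tm_%d", i), tr$Tm_C, fit$se[i, "Tm_C"], "C"),
      .rec(sprintf("dH%d_cal", i), tr$dH_cal, fit$se[i, "dH_cal"], "kcal/mol"),
      .rec(sprintf("dH%d_vH", i), tr$dH_vH, fit$se[i, "dH_vH"], "kcal/mol"))
  }
  out
}

#' @export
fit_records.kirchhoff_fit <- function(fit, ...) {
  rbind(.rec("dCp", fit$dCp, fit$se_dCp, "kcal/mol/K"),
        .rec("dH_ref", fit$dH_ref, fit$se_dH_ref, "kcal/mol"),
        .rec("Tm_ref", fit$Tm_ref_C, NA_real_, "C"))
}

#' @export
fit_records.sigmoid_fit <- function(fit, unit_x = "M", unit_y = "signal", ...) {
  rbind(.rec("midpoint", fit$midpoint, fit$se_midpoint, unit_x),
        .rec("width", fit$width, fit$se[["width"]], unit_x),
        .rec("lower", fit$lower, fit$se[["lower"]], unit_y),
        .rec("upper", fit$upper, fit$se[["upper"]], unit_y))
}

#' @export
fit_records.stern_volmer_fit <- function(fit, ...) {
  rbind(.rec("Ksv", fit$Ksv, fit$se_Ksv, "1/M"),
        .rec("intercept", fit$intercept, fit$se_intercept, ""))
}

#' Write fit records to CSV
#'
#' @param fit a fitted object with a [fit_records] method.
#' @param path output path.
#' @param ... passed to the [fit_records] method.
#' @export
write_fit_records <- function(fit, path, ...) {
  utils::write.csv(fit_records(fit, ...), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
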