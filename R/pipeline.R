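# Config-driven orchestration: run every declared analysis stage on file
# inputs and aggregate a per-protein stability report.

.report_row <- function(quantity, value, se, unit)
  data.frame(quantity = quantity, value = value, se = se, unit = unit,
             stringsAsFactors = FALSE)

# canonical report row order (summary-table layout)
.report_order <- c("dG_NI", "dG_IU", "m_NI", "m_IU", "Cm_NI", "Cm_IU",
                   "Cm_AUC", "Cm_SEC_MALLS", "Tm_1", "Tm_2",
                   "dH1_cal", "dH2_cal", "dCp_1", "dCp_2", "Tm_CD",
                   "dCp1_residue", "dCp2_residue", "Ksv")

#' Run the stability-analysis pipeline
#'
#' Reads a YAML configuration describing one protein and its per-stage
#' input files, runs every declared stage (chemical unfolding fit, thermal
#' CD sigmoid, DSC deconvolution, Kirchhoff regression, AUC and SEC-MALLS
#' transition midpoints, fluorescence quenching), writes per-stage fit
#' records and a run manifest, and returns the aggregated stability
#' report. All referenced files are checked before any computation; a
#' stage that fails afterwards leaves an explicit gap in the report
#' instead of aborting the run.
#'
#' Config layout (all stages optional):
#' \preformatted{
#' protein:
#'   name: Sis1
#'   n_residues_ctd: 235
#'   n_residues_nterm: 121
#'   monomer_mass_kDa: 39
#'   vbar_mL_g: 0.7263
#' seed: 1
#' stages:
#'   chem:       {file: chem.csv, signal_kind: fraction}
#'   thermal_cd: {file: cd.csv}
#'   dsc:        {file: dsc_scan1.csv, n_transitions: 2, excess: true,
#'                pre_range: [15, 40], post_range: [80, 90]}
#'   kirchhoff:  {files: [kirchhoff_t1.csv, kirchhoff_t2.csv]}
#'   auc:        {file: s0_series.csv}
#'   sec_malls:  {file: mm_series.csv}
#'   quench:     {file: quench.csv, force_intercept: false}
#' }
#'
#' @param config_path path to the YAML config.
#' @param out_dir output directory for per-stage records, the summary and
#'   the manifest; default a `"<config dir>/results"` directory. Created if
#'   missing.
#' @param quiet suppress progress messages (logged to standard error).
#' @return A `stability_report` (data frame `quantity`, `value`, `se`,
#'   `unit`) with attributes `protein`, `failures` (named character vector
#'   of failed stages) and `out_dir`. Invisibly.
#' @export
run_pipeline <- function(config_path, out_dir = NULL, quiet = FALSE) {
  if (!file.exists(config_path)) .stopf("config not found: %s", config_path)
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  if (is.null(out_dir)) out_dir <- file.path(base, "results")
  log <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  stages <- cfg$stages %||% list()
  if (length(stages) == 0) .stopf("config declares no stages")
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  # validate every referenced input before computing anything
  inputs <- character()
  for (nm in names(stages)) {
    fs <- c(stages[[nm]]$file, unlist(stages[[nm]]$files))
    for (f in fs) {
      fp <- resolve(f)
      if (!file.exists(fp)) .stopf("stage '%s': input file not found: %s", nm, f)
      inputs[f] <- fp
    }
  }
  protein <- cfg$protein %||% list()
  seed <- cfg$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- NULL
  failures <- character()
  add <- function(q, v, s, u) rows <<- rbind(rows, .report_row(q, v, s, u))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures[name] <<- conditionMessage(e)
      log("stage %s FAILED: %s", name, conditionMessage(e))
    })
  }

  if (!is.null(stages$chem)) run_stage("chem", {
    st <- stages$chem
    curve <- read_chem_curve(resolve(st$file),
                             temperature_K = st$temperature_K %||% 293.15,
                             signal_kind = st$signal_kind %||% "fraction")
    fit <- fit_three_state(curve,
                           fix_yi = st$fix_yi %||% NULL)
    write_fit_records(fit, file.path(out_dir, "chem_fit.csv"))
    add("dG_NI", fit$params$dG_NI, fit$se[["dG_NI"]], "kcal/mol")
    add("dG_IU", fit$params$dG_IU, fit$se[["dG_IU"]], "kcal/mol")
    add("m_NI", fit$params$m_NI, fit$se[["m_NI"]], "kcal/mol/M")
    add("m_IU", fit$params$m_IU, fit$se[["m_IU"]], "kcal/mol/M")
    add("Cm_NI", fit$Cm_NI, fit$se_Cm[["Cm_NI"]], "M")
    add("Cm_IU", fit$Cm_IU, fit$se_Cm[["Cm_IU"]], "M")
    log("stage chem: dG_NI %.2f kcal/mol, Cm_NI %.2f M", fit$params$dG_NI,
        fit$Cm_NI)
  })

  if (!is.null(stages$thermal_cd)) run_stage("thermal_cd", {
    df <- read_series(resolve(stages$thermal_cd$file), c("temp_C", "signal"))
    fit <- fit_tm_sigmoid(df)
    write_fit_records(fit, file.path(out_dir, "thermal_cd_fit.csv"),
                      unit_x = "C")
    add("Tm_CD", fit$midpoint, fit$se_midpoint, "C")
    log("stage thermal_cd: Tm_CD %.1f C", fit$midpoint)
  })

  if (!is.null(stages$dsc)) run_stage("dsc", {
    st <- stages$dsc
    scan <- read_thermogram(resolve(st$file))
    excess <- if (isTRUE(st$excess)) scan
              else subtract_baseline(scan, unlist(st$pre_range),
                                     unlist(st$post_range))
    fit <- fit_dsc(excess, n_transitions = st$n_transitions %||% 2L,
                   constrain_vh = isTRUE(st$constrain_vh))
    write_fit_records(fit, file.path(out_dir, "dsc_fit.csv"))
    for (i in seq_along(fit$transitions)) {
      tr <- fit$transitions[[i]]
      add(sprintf("Tm_%d", i), tr$Tm_C, fit$se[i, "Tm_C"], "C")
      add(sprintf("dH%d_cal", i), tr$dH_cal, fit$se[i, "dH_cal"], "kcal/mol")
    }
    log("stage dsc: %d transition(s), Tm1 %.1f C",
        length(fit$transitions), fit$transitions[[1]]$Tm_C)
  })

  if (!is.null(stages$kirchhoff)) run_stage("kirchhoff", {
    files <- stages$kirchhoff$files %||% list(stages$kirchhoff$file)
    for (i in seq_along(files)) {
      ser <- read_kirchhoff_series(resolve(files[[i]]))
      fit <- fit_kirchhoff(ser)
      write_fit_records(fit, file.path(out_dir,
                                       sprintf("kirchhoff_t%d_fit.csv", i)))
      add(sprintf("dCp_%d", i), fit$dCp, fit$se_dCp, "kcal/mol/K")
      n_res <- if (i == 1) protein$n_residues_ctd else protein$n_residues_nterm
      if (!is.null(n_res))
        add(sprintf("dCp%d_residue", i), per_residue_dcp(fit$dCp, n_res),
            per_residue_dcp(fit$se_dCp, n_res), "cal/mol/K/residue")
      log("stage kirchhoff[%d]: dCp %.2f kcal/mol/K", i, fit$dCp)
    }
  })

  if (!is.null(stages$auc)) run_stage("auc", {
    df <- read_series(resolve(stages$auc$file), c("urea_M", "s0_20w_S"))
    fit <- fit_transition_midpoint(df$urea_M, df$s0_20w_S)
    write_fit_records(fit, file.path(out_dir, "auc_fit.csv"))
    add("Cm_AUC", fit$midpoint, fit$se_midpoint, "M")
    log("stage auc: Cm_AUC %.2f M", fit$midpoint)
  })

  if (!is.null(stages$sec_malls)) run_stage("sec_malls", {
    df <- read_series(resolve(stages$sec_malls$file), c("urea_M", "mm_kDa"))
    fit <- fit_transition_midpoint(df$urea_M, df$mm_kDa)
    write_fit_records(fit, file.path(out_dir, "sec_malls_fit.csv"),
                      unit_y = "kDa")
    add("Cm_SEC_MALLS", fit$midpoint, fit$se_midpoint, "M")
    if (!is.null(protein$monomer_mass_kDa)) {
      pre <- predict(fit, min(df$urea_M))
      post <- predict(fit, max(df$urea_M))
      log("stage sec_malls: %s below, %s above the transition",
          classify_oligomer(pre, protein$monomer_mass_kDa),
          classify_oligomer(post, protein$monomer_mass_kDa))
    }
    log("stage sec_malls: Cm_SEC_MALLS %.2f M", fit$midpoint)
  })

  if (!is.null(stages$quench)) run_stage("quench", {
    st <- stages$quench
    df <- read_series(resolve(st$file), c("quencher_M", "intensity"))
    fit <- fit_stern_volmer(quench_series(df$quencher_M, df$intensity),
                            force_intercept = isTRUE(st$force_intercept))
    write_fit_records(fit, file.path(out_dir, "quench_fit.csv"))
    add("Ksv", fit$Ksv, fit$se_Ksv, "1/M")
    log("stage quench: Ksv %.2f 1/M (intercept %.3f)", fit$Ksv, fit$intercept)
  })

  if (is.null(rows)) rows <- .report_row(character(), numeric(), numeric(),
                                         character())
  ord <- order(match(rows$quantity, .report_order))
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  report <- structure(rows, class = c("stability_report", "data.frame"),
                      protein = protein$name %||% "protein",
                      failures = failures, out_dir = out_dir)

  manifest <- list(protein = protein, seed = seed,
                   package = as.character(utils::packageVersion("stabfit")),
                   inputs = lapply(names(inputs), function(f)
                     list(path = f, md5 = unname(tools::md5sum(inputs[[f]])))),
                   stages_run = names(stages),
                   failures = as.list(failures))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (nrow(report) > 0)
    write_summary(report, file.path(out_dir, "summary.csv"))
  if (length(failures))
    warning(sprintf("%d stage(s) failed: %s", length(failures),
                    paste(names(failures), collapse = ", ")))
  invisible(report)
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability report for %s\n", attr(x, "protein")))
  print(as.data.frame(x))
  f <- attr(x, "failures")
  if (length(f)) cat("failed stages:", paste(names(f), collapse = ", "), "\n")
  invisible(x)
}

# rendering precision per reported quantity (summary-table convention:
# one decimal for energies, midpoints, temperatures and per-residue dCp)
.report_digits <- function(quantity) {
  ifelse(grepl("^(dG|m)_", quantity) |
           grepl("^(Cm|Tm|dH|dCp|Ksv)", quantity), 1L, 3L)
}

#' Write an aggregated stability summary
#'
#' Deterministic serialization of a [run_pipeline] report: fixed row
#' order, fixed column order, numbers rendered at the conventional
#' precision (one decimal for free energies, m-values, midpoints,
#' temperatures, enthalpies and heat-capacity terms).
#'
#' @param report a `stability_report` with at least one row.
#' @param path output file.
#' @param format `"delimited"` (CSV, default) or `"keyvalue"`
#'   (`quantity: value se unit` lines).
#' @return The path, invisibly.
#' @export
write_summary <- function(report, path, format = c("delimited", "keyvalue")) {
  format <- match.arg(format)
  if (!is.data.frame(report) || nrow(report) == 0)
    .stopf("report is empty")
  d <- .report_digits(report$quantity)
  val <- vapply(seq_len(nrow(report)), function(i)
    formatC(report$value[i], format = "f", digits = d[i]), character(1))
  se <- vapply(seq_len(nrow(report)), function(i)
    if (is.na(report$se[i]) || !is.finite(report$se[i])) "NA"
    else formatC(report$se[i], format = "f", digits = d[i]), character(1))
  if (format == "delimited") {
    out <- paste(c("quantity,value,se,unit",
                   paste(report$quantity, val, se, report$unit, sep = ",")),
                 collapse = "\n")
  } else {
    out <- paste(sprintf("%s: %s %s %s", report$quantity, val, se,
                         report$unit), collapse = "\n")
  }
  writeLines(out, path)
  invisible(path)
}
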