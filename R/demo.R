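#' Write a complete synthetic input bundle for one protein
#'
#' Generates every input class the pipeline consumes — chemical unfolding
#' curve, excess-heat DSC scan, Kirchhoff series, thermal CD trace,
#' s20,w-vs-urea and molar-mass-vs-urea series, and a quenching series —
#' from wild-type-like ground truths (three-state dG 7.2/8.0 kcal/mol with
#' m-values 2.1/1.7; DSC transitions 59.0 C/154.0 kcal/mol and
#' 67.7 C/29.5 kcal/mol; dCp1 4.0 kcal/mol/K; Tm_CD 60.1 C; Cm_AUC 3.4 M;
#' Cm_SEC-MALLS 3.5 M with a 78 -> 39 kDa dimer-to-monomer mass change;
#' Ksv 11.1 1/M), writes them as the delimited files the analysis stages
#' read, plus a ready-to-run pipeline config.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed for all noise draws.
#' @return Path to the written `config.yaml`, invisibly usable with
#'   [run_pipeline].
#' @export
simulate_protein_bundle <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- three_state_params(7.2, 2.1, 8.0, 1.7, 0, 0.5, 1)
  write_chem_curve(gen_chem_unfold(sim_spec("chem_three_state",
    truth = list(params = p), noise_sd = 0.005, seed = seed)),
    file.path(dir, "chem.csv"))
  ex <- gen_dsc(sim_spec("dsc_two_transition",
    truth = list(transitions = list(transition_fit(59.0, 154.0),
                                    transition_fit(67.7, 29.5))),
    noise_sd = 0.02, seed = seed))$scan1
  write_thermogram(ex, file.path(dir, "dsc_scan1.csv"))
  k1 <- gen_kirchhoff_series(sim_spec("kirchhoff_line",
    truth = list(dCp = 4.0, dH_ref = 154, Tm_ref_C = 59,
                 Tm_shifts = -seq(0, 8, length.out = 8),
                 urea_M = seq(0, 2, length.out = 8)),
    noise_sd = 1, seed = seed))
  utils::write.csv(k1, file.path(dir, "kirchhoff_t1.csv"), row.names = FALSE)
  cd <- gen_logistic_series(sim_spec("logistic_series",
    truth = list(lower = 0, upper = 1, midpoint = 60.1, width = 2.5),
    grid = seq(20, 90, 0.5), noise_sd = 0.01, seed = seed),
    kind = "thermal_cd")
  utils::write.csv(cd, file.path(dir, "cd.csv"), row.names = FALSE)
  auc <- gen_logistic_series(sim_spec("logistic_series",
    truth = list(lower = 3.5, upper = 2.0, midpoint = 3.4, width = 0.3),
    grid = seq(0, 6, 0.25), noise_sd = 0.02, seed = seed), kind = "sed")
  utils::write.csv(auc, file.path(dir, "s0_series.csv"), row.names = FALSE)
  mm <- gen_logistic_series(sim_spec("logistic_series",
    truth = list(lower = 78, upper = 39, midpoint = 3.5, width = 0.3),
    grid = seq(0, 6, 0.25), noise_sd = 0.5, seed = seed), kind = "mm")
  utils::write.csv(mm, file.path(dir, "mm_series.csv"), row.names = FALSE)
  q <- gen_quench_series(sim_spec("stern_volmer",
    truth = list(F0 = 100, Ksv = 11.1), noise_sd = 0.005, seed = seed))
  utils::write.csv(q, file.path(dir, "quench.csv"), row.names = FALSE)
  cfg <- list(
    protein = list(name = "Sis1", n_residues_ctd = 235L,
                   n_residues_nterm = 121L, monomer_mass_kDa = 39),
    seed = as.integer(seed),
    stages = list(
      chem = list(file = "chem.csv"),
      thermal_cd = list(file = "cd.csv"),
      dsc = list(file = "dsc_scan1.csv", n_transitions = 2L, excess = TRUE),
      kirchhoff = list(files = list("kirchhoff_t1.csv")),
      auc = list(file = "s0_series.csv"),
      sec_malls = list(file = "mm_series.csv"),
      quench = list(file = "quench.csv")))
  cfgp <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfgp)
  invisible(cfgp)
}
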