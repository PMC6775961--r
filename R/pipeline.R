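#' Preset incubation scenarios
#'
#' Named configurations mirroring the study designs the package models:
#' \describe{
#'   \item{`sediment-SRZ`}{Sulfate-reduction-zone sediment slurry: 1 mM
#'     methanol + 10 mM bicarbonate (DIC labeled at 0.99), ambient DIC
#'     1.87 mM, slow methanogenesis over 43 d, constant `f_mix` = 0.103.}
#'   \item{`sediment-MZ`}{Methanogenic-zone slurry: stronger ambient
#'     dilution (4.3 mM), 19 d, `f_mix` = 0.034.}
#'   \item{`pure-culture`}{Batch culture in defined medium: 30 mM methanol +
#'     50 mM bicarbonate, labels at 5 atom-%, fast growth (10 d),
#'     `f_mix` = 0.025.}
#'   \item{`autoclaved-slurry`}{Killed slurry inoculated with a pure
#'     methylotroph, 20 mM methanol, ~10 atom-% DIC pool, rate-dependent
#'     `f_mix` (`f_max` = 0.12) over 14 d.}
#' }
#' Additional arguments override any [incubation_config()] field.
#'
#' @param scenario preset name.
#' @param ... overrides passed to [incubation_config()].
#' @return An [incubation_config()].
#' @export
scenario_config <- function(scenario = c("sediment-SRZ", "sediment-MZ",
                                         "pure-culture", "autoclaved-slurry"),
                            ...) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
    "sediment-SRZ" = list(meoh_mM = 1, dic_amended_mM = 10,
                          dic_ambient_mM = 1.87, label_scheme = "13C-DIC",
                          f_mix = 0.103, duration_days = 43),
    "sediment-MZ" = list(meoh_mM = 1, dic_amended_mM = 10,
                         dic_ambient_mM = 4.3, label_scheme = "13C-DIC",
                         f_mix = 0.034, duration_days = 19),
    "pure-culture" = list(meoh_mM = 30, dic_amended_mM = 50,
                          dic_ambient_mM = 0, label_scheme = "13C-DIC",
                          label_f = 0.05, f_mix = 0.025, duration_days = 10),
    "autoclaved-slurry" = list(meoh_mM = 20, dic_amended_mM = 1,
                               dic_ambient_mM = 9, label_scheme = "13C-DIC",
                               f_mix_mode = "rate", f_max = 0.12, r0 = 1,
                               duration_days = 14,
                               sampling_days = c(0, 1, 3, 5, 7, 10, 14))
  )
  overrides <- list(...)
  base[names(overrides)] <- overrides
  cfg <- do.call(incubation_config, base)
  attr(cfg, "scenario") <- scenario
  cfg
}

#' Rate-versus-f_DIC sweep across treatments
#'
#' Emulates an amendment experiment in which treatments differ in
#' methanogenesis rate (electron shuttles / conductors speed methanol
#' turnover): the autoclaved-slurry preset is run once per rate multiplier
#' with the rate-dependent `f_mix` mode, and for every replicate the
#' methanogenesis rate (two-point finite difference of methane between the
#' consecutive sampling days ending at `day`) is paired with the
#' DIC-derived methane fraction estimated from that replicate's noisy
#' measurements at `day`.
#'
#' @param seed integer seed.
#' @param k_multipliers factors applied to the preset's first-order rate
#'   constant, one treatment each (default 6 treatments spanning slow to
#'   fast).
#' @param day sampling day at which rate and fraction are evaluated
#'   (default 3).
#' @param n_replicates replicates per treatment (default 3).
#' @return List: `pairs` (data.frame treatment, replicate, rate, f_dic) and
#'   `report` (the [rate_fraction_correlation()] of the pairs).
#' @export
rate_sweep_experiment <- function(seed = 1,
                                  k_multipliers = c(0.3, 0.5, 0.7, 1, 2, 3),
                                  day = 3, n_replicates = 3) {
  base <- scenario_config("autoclaved-slurry", n_replicates = n_replicates)
  pairs <- do.call(rbind, lapply(seq_along(k_multipliers), function(i) {
    cfg <- scenario_config("autoclaved-slurry",
                           k = base$k * k_multipliers[i],
                           n_replicates = n_replicates,
                           seed = (seed + 1000L * i) %% 2147483647L)
    sim <- simulate_replicates(cfg)
    run <- sim$runs[[1]]
    days <- cfg$sampling_days
    j <- match(day, days)
    stopifnot(!is.na(j), j > 1)
    ch4 <- run$series[run$series$pool == "CH4", ]
    amt <- function(t) {
      v <- ch4$amount_mM[ch4$time_days == t]
      if (length(v)) v[1] else 0
    }
    rate <- (amt(days[j]) - amt(days[j - 1])) / (days[j] - days[j - 1])
    f_nat <- delta_to_fraction(cfg$delta_unlabeled)
    per_rep <- lapply(seq_len(n_replicates), function(rep) {
      tb <- sim$table[sim$table$replicate == rep & sim$table$time_days == day, ]
      f_ch4 <- measurement_fractions(tb[tb$pool == "CH4", ])
      f_dic <- measurement_fractions(tb[tb$pool == "DIC", ])
      est <- two_pool_source_fraction(f_ch4, f_dic, f_nat)
      data.frame(treatment = sprintf("k_x%.1f", k_multipliers[i]),
                 replicate = rep, rate = rate, f_dic = est$raw,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_rep)
  }))
  rownames(pairs) <- NULL
  list(pairs = pairs, report = rate_fraction_correlation(pairs))
}

#' Provenance predictions for the reporting stage
#'
#' Aggregate methanol-derived carbon fractions of the marker compounds of
#' both bundled pathways, plus their predicted 13C atom fractions under the
#' given pool compositions.
#'
#' @param f_meoh,f_dic 13C atom fractions of the methanol and DIC pools.
#' @return data.frame: compound, pathway, meoh_fraction, predicted F.
#' @export
provenance_predictions <- function(f_meoh = natural_abundance(),
                                   f_dic = natural_abundance()) {
  nuc <- propagate(load_pathway(pathway_file("nucleotide")))
  lip <- propagate(load_pathway(pathway_file("lipid")))
  pools <- c(MEOH = f_meoh, DIC = f_dic)
  pick <- list(
    list("ribose_5_phosphate", "nucleotide", nuc),
    list("pyrimidine_base", "nucleotide", nuc),
    list("purine_base", "nucleotide", nuc),
    list("ipp", "lipid", lip),
    list("geranylgeranyl_diphosphate", "lipid", lip),
    list("phytanyl_chain", "lipid", lip)
  )
  do.call(rbind, lapply(pick, function(p) {
    data.frame(
      compound = p[[1]], pathway = p[[2]],
      meoh_fraction = compound_source_fraction(p[[3]], p[[1]], "MEOH"),
      predicted_fraction_13c = predict_fraction_13c(p[[3]], p[[1]], pools),
      stringsAsFactors = FALSE
    )
  }))
}

#' Run the full analysis pipeline for a preset scenario
#'
#' Chains simulate -> estimate -> report: simulates replicate incubations for
#' the scenario, writes the measurement table(s), estimates the DIC-derived
#' methane fraction (and, for `pure-culture`, lipid assimilation from the
#' parallel single-label designs), writes a harvest summary shaped like a
#' SIP-incubation results table (atom fractions reported as percent with one
#' decimal), provenance predictions, a plain-text report, and a run manifest
#' with the seed and file digests. Deterministic given `seed`: rerunning
#' writes byte-identical tables (the manifest timestamp excepted).
#'
#' @param scenario preset name, see [scenario_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_mc Monte-Carlo draws for the estimator (default 10000).
#' @param ... overrides forwarded to [scenario_config()].
#' @return Invisibly, a list with the summary data.frame, estimates and the
#'   manifest path.
#' @export
run_pipeline <- function(scenario = "sediment-SRZ", out_dir, seed = 1,
                         n_mc = 10000, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- scenario_config(scenario, seed = seed, ...)
  sim <- simulate_replicates(cfg)
  tab_path <- file.path(out_dir, "measurements.tsv")
  write_measurements(sim$table, tab_path)
  files <- tab_path

  run <- sim$runs[[1]]
  est <- estimate_methane_sources(sim$table, n_mc = n_mc, seed = seed)
  fmt_pct <- function(x) sprintf("%.1f", 100 * x)
  summary <- data.frame(
    scenario = scenario,
    substrates = switch(cfg$label_scheme,
                        "13C-DIC" = "MeOH + 13C-DIC",
                        "13C-MeOH" = "DIC + 13C-MeOH",
                        "both" = "13C-MeOH + 13C-DIC",
                        "none" = "MeOH + DIC"),
    f13_dic_pct = fmt_pct(run$harvest$f13_dic),
    f_dic_ch4_pct = fmt_pct(est$f_source),
    f_dic_ch4_sd_pct = sprintf("%.2f", 100 * est$sd),
    f_dic_ch4_true_pct = fmt_pct(run$harvest$f_dic_ch4_true),
    incubation_days = cfg$duration_days,
    stringsAsFactors = FALSE
  )
  sum_path <- file.path(out_dir, "summary.tsv")
  utils::write.table(summary, sum_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, sum_path)

  prov <- provenance_predictions(f_meoh = run$harvest$f13_meoh_start,
                                 f_dic = run$harvest$f13_dic)
  prov_path <- file.path(out_dir, "provenance_predictions.tsv")
  utils::write.table(prov, prov_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, prov_path)

  lipids <- NULL
  if (identical(scenario, "pure-culture")) {
    cfg_m <- scenario_config(scenario, seed = seed + 1L,
                             label_scheme = "13C-MeOH", ...)
    sim_m <- simulate_replicates(cfg_m)
    tab_m <- file.path(out_dir, "measurements_13C-MeOH.tsv")
    write_measurements(sim_m$table, tab_m)
    files <- c(files, tab_m)
    lipids <- estimate_lipid_assimilation(sim_m$table, sim$table)
    lip_path <- file.path(out_dir, "lipid_assimilation.tsv")
    utils::write.table(lipids, lip_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, lip_path)
  }

  rpt <- c(
    sprintf("misosip pipeline report -- scenario %s (seed %d)", scenario, seed),
    "",
    sprintf("Harvest DIC composition: %s atom-%% 13C", fmt_pct(run$harvest$f13_dic)),
    sprintf("Methane from DIC: %s +/- %.2f %% (Monte-Carlo, n = %d; true %s %%)",
            fmt_pct(est$f_source), 100 * est$sd, est$n_mc,
            fmt_pct(run$harvest$f_dic_ch4_true)),
    sprintf("Incubation length: %g days", cfg$duration_days),
    "",
    "Provenance predictions (methanol-derived carbon, %):",
    sprintf("  %-28s %5.1f", prov$compound, 100 * prov$meoh_fraction)
  )
  if (!is.null(lipids)) {
    rpt <- c(rpt, "",
             "Lipid assimilation (f_DIC/lipid, %):",
             sprintf("  %-28s %5.1f", lipids$moiety, 100 * lipids$f_dic_lipid))
  }
  rpt_path <- file.path(out_dir, "report.txt")
  writeLines(rpt, rpt_path)
  files <- c(files, rpt_path)

  manifest_path <- write_manifest(out_dir, command = paste("replay", scenario),
                                  seed = seed, config = cfg, files = files)
  invisible(list(summary = summary, estimate = est, lipids = lipids,
                 provenance = prov, manifest = manifest_path))
}

# one manifest per output directory: command, seed, config hash, file digests
write_manifest <- function(out_dir, command, seed, config, files) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    command = command,
    package = "misosip",
    version = as.character(utils::packageVersion("misosip")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = lapply(c(cfg_path, files), function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             path)
  path
}
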