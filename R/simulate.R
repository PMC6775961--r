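# cache for the biomass provenance fractions used by the simulator
.misosip_cache <- new.env(parent = emptyenv())

# methanol-derived carbon fraction of the simulated biomass pools:
# lipid = phytanyl chain; RNA = carbon-weighted mean of purine and pyrimidine
# ribonucleotides (ribose + base, equal base composition)
biomass_provenance <- function() {
  if (is.null(.misosip_cache$biomass)) {
    lip <- propagate(load_pathway(pathway_file("lipid")))
    nuc <- propagate(load_pathway(pathway_file("nucleotide")))
    rna <- aggregate_macromolecule(
      nuc,
      data.frame(compound = c("ribose_5_phosphate", "purine_base",
                              "ribose_5_phosphate", "pyrimidine_base"),
                 count = 1),
      source = "MEOH"
    )
    .misosip_cache$biomass <- list(
      lipid_meoh = compound_source_fraction(lip, "phytanyl_chain", "MEOH"),
      rna_meoh = rna
    )
  }
  .misosip_cache$biomass
}

#' Configure a synthetic SIP incubation
#'
#' Defines the study conditions of a simulated methylotrophic-methanogenesis
#' SIP incubation: 1 mM methanol plus 10 mM amended bicarbonate diluting into
#' an ambient porewater DIC pool, one substrate 13C-labeled, first-order
#' methanol consumption, disproportionation stoichiometry
#' (4 CH3OH -> 3 CH4 + CO2 + 2 H2O) for the methyl-derived share of methane,
#' a mixotrophic share `f_mix` of methane carbon drawn from the DIC pool, a
#' small assimilatory flux into lipid and RNA biomass with provenance from
#' the bundled pathway models, Gaussian measurement noise on delta-13C, and
#' triplicate structure.
#'
#' @param meoh_mM methanol amendment, mmol C per litre slurry (default 1).
#' @param dic_amended_mM amended bicarbonate, mmol per litre (default 10).
#' @param dic_ambient_mM ambient (unlabeled) porewater DIC mixed into the
#'   amended pool at time zero (default 2, the order implied by the observed
#'   dilution of a 10 mM amendment to ~84 atom-%).
#' @param label_scheme which substrate carries the 13C label: `"13C-DIC"`,
#'   `"13C-MeOH"`, `"both"` or `"none"`.
#' @param label_f 13C atom fraction of a labeled substrate (default 0.99).
#' @param delta_unlabeled delta-13C (per mil) of unlabeled pools (default -30).
#' @param f_mix fraction of methane carbon drawn from the DIC pool
#'   (default 0.103); used when `f_mix_mode = "constant"`.
#' @param f_mix_mode `"constant"`, or `"rate"` for the rate-dependent form
#'   `f(t) = f_max * exp(-rate / r0)` in which slow methanogenesis favours
#'   CO2-derived methane.
#' @param f_max,r0 parameters of the rate-dependent mode (defaults 0.12 and
#'   1 mmol CH4 per litre per day).
#' @param k first-order methanol consumption rate constant (per day); default
#'   `NULL` sets `k` so that 99% of methanol is consumed by `duration_days`.
#' @param assimilation fraction of consumed methanol carbon routed to biomass
#'   (default 0.05); the rest is dissimilated.
#' @param lipid_share share of assimilated methyl carbon entering the lipid
#'   pool, the remainder entering RNA (default 0.3).
#' @param noise_sd_delta Gaussian measurement noise on exported delta-13C
#'   values, per mil (default 0.5, typical GC-IRMS precision).
#' @param n_replicates number of replicate bottles (default 3).
#' @param duration_days incubation length (default 43, the slower
#'   sulfate-reduction-zone setting).
#' @param sampling_days times at which measurements are exported; default is
#'   an early-dense grid plus the harvest day.
#' @param dt integration step in days (default 0.1).
#' @param hold_dic_f logical; if `TRUE` the DIC pool composition is pinned
#'   (infinite-reservoir approximation). Exchange with the implied reservoir
#'   is tracked explicitly so carbon and 13C budgets still close.
#' @param seed integer seed controlling all randomness (measurement noise).
#' @return An object of class `incubation_config` (a validated list).
#' @export
incubation_config <- function(meoh_mM = 1, dic_amended_mM = 10,
                              dic_ambient_mM = 2,
                              label_scheme = c("13C-DIC", "13C-MeOH",
                                               "both", "none"),
                              label_f = 0.99, delta_unlabeled = -30,
                              f_mix = 0.103,
                              f_mix_mode = c("constant", "rate"),
                              f_max = 0.12, r0 = 1,
                              k = NULL, assimilation = 0.05,
                              lipid_share = 0.3, noise_sd_delta = 0.5,
                              n_replicates = 3, duration_days = 43,
                              sampling_days = NULL, dt = 0.1,
                              hold_dic_f = FALSE, seed = 1) {
  label_scheme <- match.arg(label_scheme)
  f_mix_mode <- match.arg(f_mix_mode)
  stopifnot(meoh_mM >= 0, dic_amended_mM >= 0, dic_ambient_mM >= 0,
            f_mix >= 0, f_mix < 1, label_f >= 0, label_f < 1,
            assimilation >= 0, assimilation < 1,
            lipid_share >= 0, lipid_share <= 1,
            noise_sd_delta >= 0, n_replicates >= 1,
            duration_days > 0, dt > 0, f_max >= 0, f_max < 1, r0 > 0)
  if (is.null(k)) k <- -log(0.01) / duration_days
  stopifnot(k > 0)
  if (is.null(sampling_days)) {
    later <- if (duration_days >= 10) seq(10, duration_days, by = 10) else numeric(0)
    sampling_days <- sort(unique(c(0, 1, 3, 5, 7, later, duration_days)))
    sampling_days <- sampling_days[sampling_days <= duration_days]
  }
  sampling_days <- sort(unique(sampling_days))
  stopifnot(all(sampling_days >= 0), all(sampling_days <= duration_days))
  structure(
    list(meoh_mM = meoh_mM, dic_amended_mM = dic_amended_mM,
         dic_ambient_mM = dic_ambient_mM, label_scheme = label_scheme,
         label_f = label_f, delta_unlabeled = delta_unlabeled,
         f_mix = f_mix, f_mix_mode = f_mix_mode, f_max = f_max, r0 = r0,
         k = k, assimilation = assimilation, lipid_share = lipid_share,
         noise_sd_delta = noise_sd_delta, n_replicates = n_replicates,
         duration_days = duration_days, sampling_days = sampling_days,
         dt = dt, hold_dic_f = hold_dic_f, seed = as.integer(seed)),
    class = "incubation_config"
  )
}

#' Forward-simulate one SIP incubation
#'
#' Deterministic mass-balance integration of an [incubation_config()] (noise
#' enters only at export, see [simulate_replicates()]). Per time step, the
#' methanol consumed is split into an assimilated share (biomass, with atom
#' provenance from the bundled pathway models evaluated at the current pool
#' compositions) and a dissimilated share; of the dissimilated methyl carbon,
#' 3/4 becomes methane and 1/4 CO2 that joins the DIC pool at the methanol
#' composition, while an additional `f_mix` share of total methane carbon is
#' drawn from the DIC pool at its current composition. Total carbon and total
#' 13C are conserved at every step (to a tracked reservoir when
#' `hold_dic_f = TRUE`).
#'
#' @param config an [incubation_config()].
#' @return Object of class `incubation_run`: `series` (long data.frame of
#'   time, pool, amount, fraction_13c), `harvest` (summary list: harvest pool
#'   compositions, the realized cumulative DIC-derived methane fraction
#'   `f_dic_ch4_true`, the flux-weighted mean DIC composition feeding
#'   CO2-derived methane, totals and budget closure), and `config`.
#' @export
simulate_incubation <- function(config) {
  stopifnot(inherits(config, "incubation_config"))
  cf <- config
  f_nat <- delta_to_fraction(cf$delta_unlabeled)
  f_meoh <- if (cf$label_scheme %in% c("13C-MeOH", "both")) cf$label_f else f_nat
  f_dic_amend <- if (cf$label_scheme %in% c("13C-DIC", "both")) cf$label_f else f_nat

  # amended DIC dilutes into the ambient pool at time zero
  dic0 <- if (cf$dic_amended_mM + cf$dic_ambient_mM > 0) {
    mix_pools(carbon_pool(c("amended", "ambient"),
                          c(cf$dic_amended_mM, cf$dic_ambient_mM),
                          c(f_dic_amend, f_nat)))
  } else {
    carbon_pool("mixture", 0, f_nat)
  }

  prov <- biomass_provenance()
  p_lip <- prov$lipid_meoh
  p_rna <- prov$rna_meoh

  times <- sort(unique(c(seq(0, cf$duration_days, by = cf$dt),
                         cf$duration_days, cf$sampling_days)))
  n <- length(times)

  meoh_c <- cf$meoh_mM; meoh_c13 <- meoh_c * f_meoh
  dic_c <- dic0$concentration; dic_c13 <- dic_c * dic0$fraction_13c
  ch4_c <- 0; ch4_c13 <- 0
  lip_c <- 0; lip_c13 <- 0
  rna_c <- 0; rna_c13 <- 0
  res_c <- 0; res_c13 <- 0   # reservoir exchange ledger (hold_dic_f mode)
  cum_ch4_dic <- 0
  cum_ch4_dic_13 <- 0

  f_dic_fixed <- dic0$fraction_13c

  rec <- vector("list", n)
  frac <- function(c13, c) if (c > 0) c13 / c else NA_real_
  snapshot <- function(t) {
    data.frame(
      time_days = t,
      pool = c("MEOH", "DIC", "CH4", "LIPID", "RNA"),
      amount_mM = c(meoh_c, dic_c, ch4_c, lip_c, rna_c),
      fraction_13c = c(frac(meoh_c13, meoh_c), frac(dic_c13, dic_c),
                       frac(ch4_c13, ch4_c), frac(lip_c13, lip_c),
                       frac(rna_c13, rna_c)),
      stringsAsFactors = FALSE
    )
  }
  rec[[1]] <- snapshot(times[1])

  for (i in seq_len(n - 1)) {
    dt_i <- times[i + 1] - times[i]
    f_dic_now <- if (cf$hold_dic_f) f_dic_fixed else frac(dic_c13, dic_c)

    dM <- meoh_c * (1 - exp(-cf$k * dt_i))
    b_me <- cf$assimilation * dM
    diss <- dM - b_me
    ch4_me <- 0.75 * diss
    co2_prod <- 0.25 * diss

    f_now <- if (cf$f_mix_mode == "constant") {
      cf$f_mix
    } else {
      rate <- 0.75 * (1 - cf$assimilation) * cf$k * meoh_c  # instantaneous CH4 formation
      cf$f_max * exp(-rate / cf$r0)
    }
    ch4_dic <- if (f_now > 0) f_now / (1 - f_now) * ch4_me else 0

    m_lip <- cf$lipid_share * b_me
    m_rna <- (1 - cf$lipid_share) * b_me
    tot_lip <- m_lip / p_lip
    tot_rna <- m_rna / p_rna
    dic_lip <- tot_lip - m_lip
    dic_rna <- tot_rna - m_rna
    dic_draw <- ch4_dic + dic_lip + dic_rna

    if (!cf$hold_dic_f && dic_c + co2_prod - dic_draw < 0) {
      stop("infeasible config: DIC pool driven negative at day ",
           signif(times[i + 1], 4), call. = FALSE)
    }
    if (!is.finite(f_dic_now) && dic_draw > 0) {
      stop("infeasible config: drawing from an empty DIC pool at day ",
           signif(times[i + 1], 4), call. = FALSE)
    }

    meoh_c <- meoh_c - dM
    meoh_c13 <- meoh_c13 - dM * f_meoh
    ch4_c <- ch4_c + ch4_me + ch4_dic
    ch4_c13 <- ch4_c13 + ch4_me * f_meoh + ch4_dic * f_dic_now
    lip_c <- lip_c + tot_lip
    lip_c13 <- lip_c13 + m_lip * f_meoh + dic_lip * f_dic_now
    rna_c <- rna_c + tot_rna
    rna_c13 <- rna_c13 + m_rna * f_meoh + dic_rna * f_dic_now
    if (cf$hold_dic_f) {
      res_c <- res_c + co2_prod - dic_draw
      res_c13 <- res_c13 + co2_prod * f_meoh - dic_draw * f_dic_now
    } else {
      dic_c <- dic_c + co2_prod - dic_draw
      dic_c13 <- dic_c13 + co2_prod * f_meoh - dic_draw * f_dic_now
    }
    cum_ch4_dic <- cum_ch4_dic + ch4_dic
    cum_ch4_dic_13 <- cum_ch4_dic_13 + ch4_dic * f_dic_now

    rec[[i + 1]] <- snapshot(times[i + 1])
  }

  series <- do.call(rbind, rec)
  harvest <- list(
    f13_meoh_start = f_meoh,
    f13_dic_start = dic0$fraction_13c,
    f13_dic = if (cf$hold_dic_f) f_dic_fixed else frac(dic_c13, dic_c),
    f13_ch4 = frac(ch4_c13, ch4_c),
    f13_lipid = frac(lip_c13, lip_c),
    f13_rna = frac(rna_c13, rna_c),
    f_dic_ch4_true = if (ch4_c > 0) cum_ch4_dic / ch4_c else NA_real_,
    f13_dic_flux_weighted = if (cum_ch4_dic > 0) cum_ch4_dic_13 / cum_ch4_dic
                            else NA_real_,
    incubation_days = cf$duration_days,
    ch4_total_mM = ch4_c,
    reservoir_c = res_c, reservoir_c13 = res_c13
  )
  structure(list(series = series, harvest = harvest, config = cf),
            class = "incubation_run")
}

#' @export
print.incubation_run <- function(x, ...) {
  h <- x$harvest
  cat(sprintf(
    "SIP incubation run (%s, %g d): 13F_DIC = %.1f%%, f_DIC/CH4 true = %.1f%%, CH4 = %.3g mM\n",
    x$config$label_scheme, h$incubation_days, 100 * h$f13_dic,
    100 * h$f_dic_ch4_true, h$ch4_total_mM))
  invisible(x)
}

#' Carbon and 13C budget closure of a simulated run
#'
#' Recomputes the total carbon and total 13C across all pools (plus the
#' reservoir-exchange ledger when the DIC composition is held fixed) at each
#' recorded time and returns the maximum relative deviation from the initial
#' totals. Exactness of these budgets is the core invariant of the simulator.
#'
#' @param run a [simulate_incubation()] result.
#' @return Named numeric: `carbon` and `c13` maximum relative budget errors.
#' @export
budget_closure <- function(run) {
  stopifnot(inherits(run, "incubation_run"))
  s <- run$series
  tot <- tapply(s$amount_mM, s$time_days, sum)
  c13 <- tapply(ifelse(s$amount_mM > 0, s$amount_mM * s$fraction_13c, 0),
                s$time_days, sum)
  # reservoir exchange accrues monotonically; only the final ledger is stored,
  # so compare first vs last snapshot including the ledger
  carbon_err <- abs((tot[length(tot)] + run$harvest$reservoir_c) - tot[1]) /
    max(tot[1], 1e-12)
  c13_err <- abs((c13[length(c13)] + run$harvest$reservoir_c13) - c13[1]) /
    max(c13[1], 1e-12)
  interior <- if (!run$config$hold_dic_f) {
    max(abs(tot - tot[1]) / max(tot[1], 1e-12),
        abs(c13 - c13[1]) / max(c13[1], 1e-12))
  } else 0
  c(carbon = max(unname(carbon_err), interior),
    c13 = unname(c13_err))
}

#' Simulate replicate incubations and export a measurement table
#'
#' Runs the deterministic forward model once (replicate bottles share the
#' trajectory; there is no process noise) and exports one measurement row per
#' pool, replicate and sampling day with independent Gaussian noise on the
#' delta-13C values. Each replicate uses its own substream derived
#' deterministically from the config seed, so exports are reproducible.
#'
#' @param config an [incubation_config()].
#' @param path optional file path; if given the table is also written as TSV
#'   via [write_measurements()].
#' @return List with `runs` (list of `incubation_run`, one per replicate),
#'   `table` (the measurement data.frame) and `config`.
#' @export
simulate_replicates <- function(config, path = NULL) {
  stopifnot(inherits(config, "incubation_config"))
  run <- simulate_incubation(config)
  s <- run$series
  s <- s[s$time_days %in% config$sampling_days & s$amount_mM > 0 &
           is.finite(s$fraction_13c), , drop = FALSE]
  s$pool <- ifelse(s$pool == "LIPID", "LIPID:phytane", s$pool)

  tables <- lapply(seq_len(config$n_replicates), function(rep) {
    rep_seed <- (config$seed + 104729L * rep) %% 2147483647L
    set.seed(rep_seed)
    delta <- fraction_to_delta(s$fraction_13c)
    noisy <- delta + stats::rnorm(nrow(s), 0, config$noise_sd_delta)
    noisy <- pmax(noisy, -999.999)
    data.frame(
      sample_id = sprintf("sim_%s_r%d", gsub("[^0-9A-Za-z]+", "", config$label_scheme), rep),
      pool = s$pool,
      replicate = rep,
      time_days = s$time_days,
      value = noisy,
      value_type = "delta_permil",
      sd = config$noise_sd_delta,
      stringsAsFactors = FALSE
    )
  })
  table <- do.call(rbind, tables)
  table <- table[order(table$time_days, table$pool, table$replicate), ]
  rownames(table) <- NULL
  if (!is.null(path)) write_measurements(table, path)
  list(runs = rep(list(run), config$n_replicates), table = table,
       config = config)
}

#' Buoyant density of RNA as a function of 13C labeling
#'
#' Linear buoyant-density model for isopycnic centrifugation:
#' `BD = BD_unlabeled + k_shift * (f - f_natural)`, anchored at 1.7785 g/mL
#' (midpoint of the light gradient window) for unlabeled RNA, with the shift
#' coefficient chosen so fully labeled RNA (f = 1) bands at 1.813 g/mL,
#' inside the heavy window.
#'
#' @param f_rna_13c 13C atom fraction of the RNA, in `[0, 1)` (vectorized;
#'   f = 1 is accepted as the fully-labeled limit).
#' @param f_natural natural-abundance atom fraction anchoring the unlabeled
#'   density (default [natural_abundance()]).
#' @param bd_unlabeled unlabeled buoyant density, g/mL (default 1.7785).
#' @param k_shift density shift per unit atom fraction (default 0.035).
#' @return Buoyant density in g/mL.
#' @export
rna_density <- function(f_rna_13c, f_natural = natural_abundance(),
                        bd_unlabeled = 1.7785, k_shift = 0.035) {
  stopifnot(is.numeric(f_rna_13c))
  if (any(!is.finite(f_rna_13c)) || any(f_rna_13c < 0) || any(f_rna_13c > 1)) {
    stop("invalid isotope value: RNA atom fraction must lie in [0, 1]",
         call. = FALSE)
  }
  bd_unlabeled + k_shift * (f_rna_13c - f_natural)
}

#' Parameter-recovery experiment for the methane mixing estimator
#'
#' Closes the loop between the simulator and the two-end-member estimator:
#' simulates replicate incubations under `config` (which must label the DIC
#' pool -- the estimable design), feeds the exported measurement table to
#' [estimate_methane_sources()], and reports the estimate against the
#' realized truth.
#'
#' @param config an [incubation_config()] with `label_scheme` `"13C-DIC"` or
#'   `"both"`.
#' @param n_mc Monte-Carlo draws for the estimator (default 1000).
#' @param seed seed for both the export noise and the estimator draws;
#'   default the config seed.
#' @return List: `truth` (realized cumulative DIC-derived methane fraction),
#'   `estimate`, `bias` (= estimate - truth), `sd` (MC), and the full
#'   `mixing_estimate` object.
#' @export
recovery_experiment <- function(config, n_mc = 1000, seed = config$seed) {
  stopifnot(inherits(config, "incubation_config"))
  if (!config$label_scheme %in% c("13C-DIC", "both")) {
    stop("recovery requires a 13C-DIC labeled design", call. = FALSE)
  }
  config$seed <- as.integer(seed)
  sim <- simulate_replicates(config)
  est <- estimate_methane_sources(sim$table, n_mc = n_mc, seed = seed)
  truth <- sim$runs[[1]]$harvest$f_dic_ch4_true
  list(truth = truth, estimate = est$raw, bias = est$raw - truth,
       sd = est$sd, mixing_estimate = est)
}
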