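test_that("pure disproportionation limit: no DIC-derived methane, 3:1 CH4:CO2", {
  cfg <- incubation_config(f_mix = 0, assimilation = 0, noise_sd_delta = 0,
                           label_scheme = "13C-MeOH", duration_days = 20)
  run <- simulate_incubation(cfg)
  s <- run$series
  ch4 <- s[s$pool == "CH4" & s$amount_mM > 0, ]
  # methane carries the methanol composition at every time
  expect_lt(max(abs(ch4$fraction_13c - run$harvest$f13_meoh_start)), 1e-12)
  # produced CO2 = DIC increase; CH4 : CO2 = 3 : 1
  dic0 <- s$amount_mM[s$pool == "DIC" & s$time_days == 0]
  dic_end <- s$amount_mM[s$pool == "DIC" & s$time_days == 20]
  ch4_end <- s$amount_mM[s$pool == "CH4" & s$time_days == 20]
  expect_equal(ch4_end / (dic_end - dic0), 3, tolerance = 1e-9)
  expect_equal(run$harvest$f_dic_ch4_true, 0)
})

test_that("carbon and 13C budgets close in all simulation modes", {
  cfgs <- list(
    incubation_config(),
    incubation_config(label_scheme = "13C-MeOH"),
    incubation_config(label_scheme = "both", f_mix = 0.3),
    incubation_config(f_mix_mode = "rate", duration_days = 14),
    incubation_config(hold_dic_f = TRUE)
  )
  for (cfg in cfgs) {
    closure <- budget_closure(simulate_incubation(cfg))
    expect_lt(closure["carbon"], 1e-9)
    expect_lt(closure["c13"], 1e-9)
  }
})

test_that("a constant-composition DIC pool held from the reservoir keeps harvest values fixed", {
  cfg <- incubation_config(hold_dic_f = TRUE, noise_sd_delta = 0)
  run <- simulate_incubation(cfg)
  expect_equal(run$harvest$f13_dic, run$harvest$f13_dic_start)
  # expected methane composition from the two-pool forward model
  f_exp <- cfg$f_mix * run$harvest$f13_dic +
    (1 - cfg$f_mix) * run$harvest$f13_meoh_start
  expect_equal(run$harvest$f13_ch4, f_exp, tolerance = 1e-12)
})

test_that("infeasible stoichiometry is reported with the offending step", {
  cfg <- incubation_config(meoh_mM = 20, dic_amended_mM = 0.05,
                           dic_ambient_mM = 0, f_mix = 0.5,
                           duration_days = 10)
  expect_error(simulate_incubation(cfg), "infeasible config")
})

test_that("noiseless estimator recovery is exact across the mixing grid", {
  for (f in c(0, 0.025, 0.05, 0.10, 0.25)) {
    rec <- recovery_experiment(
      incubation_config(f_mix = f, hold_dic_f = TRUE, noise_sd_delta = 0))
    expect_equal(rec$truth, f, tolerance = 1e-12)
    expect_lt(abs(rec$bias), 1e-10)
  }
})

test_that("DIC drift biases the harvest-time estimator by a bounded amount", {
  # small DIC pool, so unlabeled CO2 from methanol dilutes the source label
  cfg <- incubation_config(meoh_mM = 1, dic_amended_mM = 2,
                           dic_ambient_mM = 0.5, noise_sd_delta = 0)
  rec <- recovery_experiment(cfg)
  run <- simulate_incubation(cfg)
  f_bg <- run$harvest$f13_meoh_start
  f_harv <- run$harvest$f13_dic
  f_bar <- run$harvest$f13_dic_flux_weighted
  # brute-force time-integrated mixing oracle for the expected estimate
  expected <- cfg$f_mix * (f_bar - f_bg) / (f_harv - f_bg)
  expect_equal(rec$estimate, expected, tolerance = 1e-6)
  expect_gt(abs(rec$bias), 0)
  # the bias is bounded by the drift between flux-weighted and harvest F_DIC
  bound <- cfg$f_mix * abs(f_bar - f_harv) / (f_harv - f_bg) + 1e-9
  expect_lte(abs(rec$bias), bound)
})

test_that("replicate export reproduces the configured measurement noise", {
  cfg0 <- incubation_config(noise_sd_delta = 0, n_replicates = 3)
  sim0 <- simulate_replicates(cfg0)
  w <- reshape(sim0$table[sim0$table$pool == "CH4", c("replicate", "time_days", "value")],
               idvar = "time_days", timevar = "replicate", direction = "wide")
  expect_equal(w$value.1, w$value.2)
  expect_equal(w$value.1, w$value.3)

  cfg <- incubation_config(noise_sd_delta = 0.5, n_replicates = 80, seed = 6)
  sim <- simulate_replicates(cfg)
  harvest <- sim$table[sim$table$pool == "CH4" &
                         sim$table$time_days == cfg$duration_days, ]
  expect_equal(stats::sd(harvest$value), 0.5, tolerance = 0.15)
  # same seed, same export
  sim_b <- simulate_replicates(cfg)
  expect_identical(sim$table$value, sim_b$table$value)
})

test_that("RNA buoyant density is anchored, monotone, and favours DIC labeling", {
  f_nat <- natural_abundance()
  expect_equal(rna_density(f_nat), 1.7785)
  expect_equal(classify_density(rna_density(f_nat)), "light")
  expect_equal(rna_density(1), 1.813, tolerance = 1e-3)
  expect_equal(classify_density(rna_density(1)), "heavy")
  grid <- seq(0, 0.99, length.out = 50)
  expect_true(all(diff(rna_density(grid)) > 0))
  expect_error(rna_density(1.2), "invalid isotope")

  # RNA is mostly DIC-derived carbon, so labeling DIC shifts RNA further
  # than labeling methanol under identical conditions
  run_m <- simulate_incubation(incubation_config(label_scheme = "13C-MeOH",
                                                 noise_sd_delta = 0))
  run_d <- simulate_incubation(incubation_config(label_scheme = "13C-DIC",
                                                 noise_sd_delta = 0))
  expect_lt(rna_density(run_m$harvest$f13_rna),
            rna_density(run_d$harvest$f13_rna))
  # methanol-only labeling is far too weak to reach the heavy window;
  # double labeling bands heaviest of all
  expect_false(classify_density(rna_density(run_m$harvest$f13_rna)) == "heavy")
  run_b <- simulate_incubation(incubation_config(label_scheme = "both",
                                                 noise_sd_delta = 0))
  expect_gt(rna_density(run_b$harvest$f13_rna),
            rna_density(run_d$harvest$f13_rna))
  expect_equal(classify_density(rna_density(run_b$harvest$f13_rna)), "heavy")
})

test_that("recovery experiments require the estimable (DIC-labeled) design", {
  expect_error(recovery_experiment(
    incubation_config(label_scheme = "13C-MeOH")), "13C-DIC")
})
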