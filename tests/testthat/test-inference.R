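test_that("the methane-source estimator inverts forward mixing exactly", {
  nat <- natural_abundance()
  f_true <- 0.25
  f_dic <- 0.836
  f_ch4 <- f_true * f_dic + (1 - f_true) * nat
  tbl <- make_mixing_table(f_ch4, f_dic, nat)
  est <- estimate_methane_sources(tbl, n_mc = 0)
  expect_equal(est$f_source, f_true, tolerance = 1e-9)

  # SRZ-style numbers: labeled DIC at 83.6 atom-%, methane at 9.6 atom-%
  tbl2 <- make_mixing_table(0.0960, 0.836, 0.0110564)
  est2 <- estimate_methane_sources(tbl2, n_mc = 0)
  expect_equal(est2$f_source, 0.1030, tolerance = 1e-3)
})

test_that("Monte-Carlo propagation is seeded, sane, and converges", {
  tbl <- make_mixing_table(0.0960, 0.836, 0.0110564, noise_sd = 0.5, seed = 4)
  p0 <- estimate_methane_sources(tbl, n_mc = 0)
  p1 <- estimate_methane_sources(tbl, n_mc = 10000, seed = 9)
  expect_equal(p0$f_source, p1$f_source)     # point estimate untouched by MC
  expect_gt(p1$sd, 0)
  expect_true(p1$ci[1] <= p1$f_source && p1$f_source <= p1$ci[2])
  # reproducible under the same seed
  p1b <- estimate_methane_sources(tbl, n_mc = 10000, seed = 9)
  expect_identical(p1$sd, p1b$sd)
  # sd -> 0 as the stated measurement sd -> 0
  tbl_tiny <- make_mixing_table(0.0960, 0.836, 0.0110564, noise_sd = 0,
                                stated_sd = 1e-6)
  p_tiny <- estimate_methane_sources(tbl_tiny, n_mc = 5000, seed = 2)
  expect_lt(p_tiny$sd, 1e-6)
  expect_equal(p_tiny$f_source, p0$f_source, tolerance = 1e-4)
})

test_that("missing pools in a measurement table are a schema error", {
  tbl <- make_mixing_table(0.096, 0.836, 0.011)
  expect_error(estimate_methane_sources(tbl[tbl$pool != "DIC", ], n_mc = 0),
               "pool 'DIC'")
  expect_error(estimate_methane_sources(tbl[, -2], n_mc = 0),
               "missing column")
})

test_that("measurement tables round-trip through the TSV dialect", {
  sim <- simulate_replicates(incubation_config(duration_days = 5, seed = 3))
  path <- tempfile(fileext = ".tsv")
  write_measurements(sim$table, path)
  back <- read_measurements(path)
  expect_equal(back$value, sim$table$value, tolerance = 1e-9)
  expect_identical(back$pool, sim$table$pool)
  expect_identical(back$replicate, sim$table$replicate)
})

test_that("lipid assimilation estimation handles symmetric and degenerate input", {
  nat <- natural_abundance()
  # symmetric enrichment per unit label strength -> f_DIC/lipid = 0.5
  f_label <- 0.05
  end_f <- nat + 0.01
  tb_m <- make_lipid_table(end_f, f_label, "MEOH")
  tb_d <- make_lipid_table(end_f, f_label, "DIC")
  res <- estimate_lipid_assimilation(tb_m, tb_d, t0 = nat)
  expect_equal(res$f_dic_lipid, 0.5, tolerance = 1e-9)

  # no enrichment in either experiment
  tb0_m <- make_lipid_table(nat, f_label, "MEOH")
  tb0_d <- make_lipid_table(nat, f_label, "DIC")
  expect_error(estimate_lipid_assimilation(tb0_m, tb0_d, t0 = nat),
               "no enrichment")

  # mismatched moiety sets
  tb_d2 <- make_lipid_table(c(end_f, end_f), f_label, "DIC",
                            moieties = c("LIPID:phytane", "LIPID:phytene_I"))
  expect_error(estimate_lipid_assimilation(tb_m, tb_d2, t0 = nat),
               "same\\s+.*set")
})

test_that("simulated single-label cultures recover the pathway's DIC share of lipids", {
  # true lipid provenance is 60% methanol, so f_DIC/lipid should come out
  # near 0.40 from the paired single-label designs
  sim_d <- simulate_replicates(scenario_config("pure-culture", seed = 21,
                                               noise_sd_delta = 0))
  sim_m <- simulate_replicates(scenario_config("pure-culture", seed = 22,
                                               label_scheme = "13C-MeOH",
                                               noise_sd_delta = 0))
  res <- estimate_lipid_assimilation(sim_m$table, sim_d$table)
  expect_equal(res$f_dic_lipid, 0.40, tolerance = 0.05)
})

test_that("rate-fraction correlation matches a hand-rolled Fisher-z oracle", {
  # perfect anticorrelation
  anti <- data.frame(rate = 1:6, f_dic = seq(0.12, 0.02, length.out = 6))
  rep <- rate_fraction_correlation(anti)
  expect_equal(rep$r, -1)
  expect_lt(rep$p_value, 1e-6)

  # degenerate input
  expect_error(rate_fraction_correlation(
    data.frame(rate = 1:5, f_dic = rep(0.1, 5))), "degenerate correlation")
  expect_error(rate_fraction_correlation(
    data.frame(rate = 1:2, f_dic = c(0.1, 0.2))), ">= 3")

  # independent oracle: r, t-test p and Fisher-z CI computed from first
  # principles on noisy data
  set.seed(31)
  x <- stats::runif(20)
  y <- -2 * x + stats::rnorm(20, 0, 0.5)
  rep2 <- rate_fraction_correlation(data.frame(rate = x, f_dic = y))
  n <- 20
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  z <- atanh(r)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3))
  expect_equal(rep2$r, r, tolerance = 1e-12)
  expect_equal(rep2$p_value, p, tolerance = 1e-12)
  expect_equal(c(rep2$ci_low, rep2$ci_high), ci, tolerance = 1e-12)

  # invariance under sign-preserving affine rescaling
  rep3 <- rate_fraction_correlation(data.frame(rate = 10 + 3 * x,
                                               f_dic = 0.2 + 0.05 * y))
  expect_equal(rep3$r, rep2$r, tolerance = 1e-12)
  expect_equal(rep3$p_value, rep2$p_value, tolerance = 1e-12)
})

test_that("gradient densities are classified into heavy/light/intermediate windows", {
  expect_equal(classify_density(1.808), "heavy")
  expect_equal(classify_density(1.778), "light")
  expect_equal(classify_density(1.790), "intermediate")
  # boundaries inclusive
  expect_equal(classify_density(c(1.803, 1.823, 1.777, 1.780)),
               c("heavy", "heavy", "light", "light"))
  expect_error(classify_density(1.95), "invalid density")
  expect_error(classify_density(1.60), "invalid density")
})
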