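#' Estimate the DIC-derived fraction of methane from a replicate table
#'
#' Applies the two-end-member mixing estimator to a replicated measurement
#' table from a methanol + 13C-DIC incubation: the point estimate uses the
#' replicate means of the harvest-time CH4 and DIC atom fractions, with the
#' methanol composition at the start as background. Uncertainty is reported
#' two ways, because they answer different questions: an across-replicate
#' standard deviation (pairing CH4 and DIC measurements by replicate, the
#' mean +/- SD convention of triplicate incubations) and, when `n_mc > 0`, a
#' seeded Monte-Carlo propagation drawing Gaussian perturbations in delta
#' space around each measured pool's replicate mean -- including the methanol
#' background when it is read off the table -- scaled by the stated
#' instrument precision (the table's `sd` column) when available, else by
#' the across-replicate SD.
#'
#' @param table measurement data.frame (see [read_measurements()]) containing
#'   `CH4` and `DIC` pools; the latest sampling time is taken as harvest.
#' @param background 13C atom fraction of methanol at the start. Default
#'   `NULL`: taken from the table's `MEOH` rows at the earliest time if
#'   present, else natural abundance at -30 per mil.
#' @param n_mc Monte-Carlo draws (default 10000; 0 disables propagation).
#' @param seed integer seed for the Monte-Carlo draws.
#' @param eps degenerate end-member tolerance, see
#'   [two_pool_source_fraction()].
#' @return A [mixing_estimate()] with `sd` (MC), `sd_replicate`, and a
#'   percentile 95% CI when `n_mc > 0`.
#' @export
estimate_methane_sources <- function(table, background = NULL, n_mc = 10000,
                                     seed = 1, eps = 1e-6) {
  table <- validate_measurements(table)
  ch4 <- pool_summary(table, "CH4")
  dic <- pool_summary(table, "DIC")
  meoh <- NULL
  if (is.null(background)) {
    if (any(table$pool == "MEOH")) {
      meoh <- pool_summary(table, "MEOH",
                           time = min(table$time_days[table$pool == "MEOH"]))
      background <- meoh$fraction
    } else {
      background <- natural_abundance()
    }
  }

  point <- two_pool_source_fraction(ch4$fraction, dic$fraction, background,
                                    eps = eps)

  # across-replicate spread: pair CH4 with DIC replicate-wise where possible
  sd_rep <- NA_real_
  if (ch4$n > 1 && ch4$n == dic$n) {
    f_rep <- (ch4$fractions - background) / (dic$fractions - background)
    sd_rep <- stats::sd(f_rep)
  }

  sd_mc <- NA_real_
  ci <- NULL
  if (n_mc > 0) {
    set.seed(as.integer(seed))
    # draw scale: the stated instrument precision when the table carries one
    # (the across-replicate sd of triplicates has only 2 df and is itself
    # noisy), otherwise the across-replicate sd
    draw <- function(p) {
      s <- if (!is.na(p$stated_sd)) p$stated_sd
           else if (!is.na(p$delta_sd)) p$delta_sd
           else 0
      pmax(stats::rnorm(n_mc, p$delta_mean, s), -999.999)
    }
    f_ch4 <- delta_to_fraction(draw(ch4))
    f_dic <- delta_to_fraction(draw(dic))
    # the background is a measured pool too: perturb it when it was read off
    # the table rather than supplied as a known constant
    f_bg <- if (is.null(meoh)) background else delta_to_fraction(draw(meoh))
    f_draws <- (f_ch4 - f_bg) / (f_dic - f_bg)
    sd_mc <- stats::sd(f_draws)
    ci <- unname(stats::quantile(f_draws, c(0.025, 0.975)))
  }

  mixing_estimate(point$raw, sd = sd_mc, n_mc = n_mc, ci = ci,
                  sd_replicate = sd_rep)
}

#' Estimate lipid carbon assimilation from parallel single-label incubations
#'
#' Computes, per lipid moiety, the 13C incorporation ratios from the
#' 13C-methanol and 13C-DIC incubations and combines them into the DIC share
#' of lipid biosynthesis (`X / label strength` per experiment, then
#' `f_DIC/lipid = X_DIC / (X_DIC + X_MeOH)`). The two tables must come from
#' parallel incubations with identical amendments, one substrate labeled in
#' each, and must cover the same lipid moieties.
#'
#' Label strengths follow the measurement convention of the mixing model:
#' the methanol label is its composition at the start, the DIC label the
#' measured DIC composition at harvest (which accounts for dilution by
#' ambient porewater DIC).
#'
#' @param table_meoh_label measurement table of the 13C-methanol incubation.
#' @param table_dic_label measurement table of the 13C-DIC incubation.
#' @param t0 13C atom fraction of the lipid pool at time zero. Default
#'   `NULL`: taken per moiety from rows at time zero when present, else
#'   natural abundance at -30 per mil.
#' @param f_meoh_label,f_dic_label optional label-strength overrides (atom
#'   fractions); by default read off the tables as described above.
#' @return data.frame with one row per lipid moiety: `moiety`, `x_meoh`,
#'   `x_dic`, `f_dic_lipid`.
#' @export
estimate_lipid_assimilation <- function(table_meoh_label, table_dic_label,
                                        t0 = NULL, f_meoh_label = NULL,
                                        f_dic_label = NULL) {
  table_meoh_label <- validate_measurements(table_meoh_label)
  table_dic_label <- validate_measurements(table_dic_label)

  moieties <- function(df) sort(unique(df$pool[startsWith(df$pool, "LIPID:")]))
  mo_m <- moieties(table_meoh_label)
  mo_d <- moieties(table_dic_label)
  if (!length(mo_m) || !identical(mo_m, mo_d)) {
    stop("measurement table schema error: the two tables must cover the same ",
         "non-empty set of LIPID:<moiety> pools", call. = FALSE)
  }

  if (is.null(f_meoh_label)) {
    f_meoh_label <- pool_summary(
      table_meoh_label, "MEOH",
      time = min(table_meoh_label$time_days[table_meoh_label$pool == "MEOH"])
    )$fraction
  }
  if (is.null(f_dic_label)) {
    f_dic_label <- pool_summary(table_dic_label, "DIC")$fraction
  }

  # time-zero lipid composition: an explicit t0 wins; otherwise rows at
  # time 0 (pre-incubation biomass) if present, else natural abundance
  start_fraction <- function(df, pool) {
    if (!is.null(t0)) return(t0)
    if (any(df$pool == pool & df$time_days == 0)) {
      return(pool_summary(df, pool, time = 0)$fraction)
    }
    natural_abundance()
  }

  rows <- lapply(mo_m, function(mo) {
    xm <- incorporation_ratio(
      pool_summary(table_meoh_label, mo)$fraction,
      start_fraction(table_meoh_label, mo),
      f_meoh_label, source = "MEOH"
    )
    xd <- incorporation_ratio(
      pool_summary(table_dic_label, mo)$fraction,
      start_fraction(table_dic_label, mo),
      f_dic_label, source = "DIC"
    )
    fdl <- dic_lipid_fraction(xd, xm)
    data.frame(moiety = sub("^LIPID:", "", mo), x_meoh = xm$x, x_dic = xd$x,
               f_dic_lipid = fdl$f_source, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "f_meoh_label") <- f_meoh_label
  attr(out, "f_dic_label") <- f_dic_label
  out
}

#' Correlation between methanogenesis rate and the DIC-derived methane share
#'
#' Pearson correlation with a two-sided t-test p-value and a 95% confidence
#' interval from the Fisher z-transform, for (rate, f_DIC/CH4) pairs across
#' treatments/replicates. A strongly negative correlation indicates that slow
#' methanogenesis favours CO2-derived methane.
#'
#' @param pairs data.frame with numeric columns `rate` (e.g. mmol CH4 per
#'   litre per day) and `f_dic` (fraction of methane from DIC).
#' @return Object of class `correlation_report` with fields `r`, `p_value`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
rate_fraction_correlation <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("rate", "f_dic") %in% names(pairs)))
  x <- pairs$rate
  y <- pairs$f_dic
  if (length(x) < 3 || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("need >= 3 finite (rate, f_dic) pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate correlation: zero variance in rate or f_dic", call. = FALSE)
  }
  n <- length(x)
  if (abs(stats::cor(x, y)) < 1 && n >= 4) {
    ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
    r <- unname(ct$estimate)
    p <- ct$p.value
    ci <- ct$conf.int
  } else {
    r <- stats::cor(x, y)
    p <- if (abs(r) >= 1) 0 else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(r = r, p_value = p, ci_low = ci[1], ci_high = ci[2], n = n),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Pearson's r = %.3f, P = %.3g, CI(0.95) = [%.3f, %.3f], n = %d\n",
              x$r, x$p_value, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Buoyant-density windows of an RNA-SIP gradient
#'
#' Labels a CsTFA gradient density as `heavy` (1.803-1.823 g/mL, the window
#' where well 13C-labeled RNA bands), `light` (1.777-1.780 g/mL, unlabeled
#' RNA) or `intermediate`; boundaries inclusive. Densities outside the
#' physically sensible gradient range (1.70, 1.90) are rejected.
#'
#' @param density buoyant density in g/mL (vectorized).
#' @return Character vector: `"heavy"`, `"light"` or `"intermediate"`.
#' @export
classify_density <- function(density) {
  stopifnot(is.numeric(density))
  if (any(!is.finite(density)) || any(density <= 1.70) || any(density >= 1.90)) {
    stop("invalid density: expected g/mL within (1.70, 1.90)", call. = FALSE)
  }
  out <- rep("intermediate", length(density))
  out[density >= 1.803 & density <= 1.823] <- "heavy"
  out[density >= 1.777 & density <= 1.780] <- "light"
  out
}
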