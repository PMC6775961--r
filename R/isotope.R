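#' VPDB carbon isotope reference ratio
#'
#' The 13C/12C amount ratio of the Vienna Pee Dee Belemnite standard used by
#' all delta-scale conversions in this package. Fixed at 0.011180, the value
#' conventionally used in SIP mixing calculations; atom fractions derived from
#' delta values are therefore bit-reproducible against that convention.
#'
#' @format A length-one numeric.
#' @export
R_VPDB <- 0.011180

#' Convert between delta-13C, isotope ratio and 13C atom fraction
#'
#' Carbon isotope compositions appear in three interchangeable forms:
#' the per-mil delta value relative to VPDB, the 13C/12C amount ratio
#' \eqn{R = (\delta/1000 + 1) \cdot R_{VPDB}}, and the fractional abundance
#' (atom fraction) \eqn{F = R/(1+R)}. Mixing mass balance is linear in
#' \eqn{F}, not in \eqn{\delta}, so all estimators in this package work on
#' atom fractions internally and convert at the boundaries.
#'
#' @param delta delta-13C in per mil vs VPDB; must be >= -1000 (a smaller
#'   value would imply a negative isotope ratio).
#' @param ratio 13C/12C amount ratio, >= 0.
#' @param f 13C atom fraction in `[0, 1)`.
#' @return Numeric vector of the requested quantity.
#' @examples
#' delta_to_ratio(0)          # the VPDB ratio, 0.011180
#' delta_to_fraction(-30)     # typical biogenic organic matter
#' fraction_to_delta(delta_to_fraction(250))
#' @name isotope-conversions
NULL

#' @rdname isotope-conversions
#' @export
delta_to_ratio <- function(delta) {
  stopifnot(is.numeric(delta))
  if (any(!is.finite(delta)) || any(delta < -1000)) {
    stop("invalid isotope value: delta-13C must be finite and >= -1000 per mil",
         call. = FALSE)
  }
  (delta / 1000 + 1) * R_VPDB
}

#' @rdname isotope-conversions
#' @export
ratio_to_delta <- function(ratio) {
  stopifnot(is.numeric(ratio))
  if (any(!is.finite(ratio)) || any(ratio < 0)) {
    stop("invalid isotope value: ratio must be finite and >= 0", call. = FALSE)
  }
  (ratio / R_VPDB - 1) * 1000
}

#' @rdname isotope-conversions
#' @export
ratio_to_fraction <- function(ratio) {
  stopifnot(is.numeric(ratio))
  if (any(!is.finite(ratio)) || any(ratio < 0)) {
    stop("invalid isotope value: ratio must be finite and >= 0", call. = FALSE)
  }
  ratio / (1 + ratio)
}

#' @rdname isotope-conversions
#' @export
fraction_to_ratio <- function(f) {
  stopifnot(is.numeric(f))
  if (any(!is.finite(f)) || any(f < 0) || any(f >= 1)) {
    stop("invalid isotope value: atom fraction must lie in [0, 1)", call. = FALSE)
  }
  f / (1 - f)
}

#' @rdname isotope-conversions
#' @export
delta_to_fraction <- function(delta) {
  ratio_to_fraction(delta_to_ratio(delta))
}

#' @rdname isotope-conversions
#' @export
fraction_to_delta <- function(f) {
  ratio_to_delta(fraction_to_ratio(f))
}

#' 13C atom fraction of unlabeled (natural abundance) carbon
#'
#' Unlabeled substrate and background pools are assumed to sit at a typical
#' biogenic delta-13C of -30 per mil unless stated otherwise; pass a
#' different delta to override. All estimators take background compositions
#' explicitly, so this default never silently drives a result.
#'
#' @param delta delta-13C in per mil vs VPDB (default -30).
#' @return 13C atom fraction.
#' @export
natural_abundance <- function(delta = -30) {
  delta_to_fraction(delta)
}

#' Construct a mixing estimate
#'
#' Container for a two-end-member source fraction. Measurement noise can push
#' the raw estimate slightly outside `[0, 1]`; the raw value is preserved in
#' `$raw` and a clamped copy in `$f_source`, with `$clamped` flagging whether
#' clamping occurred (mean +/- SD reporting needs the raw values).
#'
#' @param raw raw source fraction(s) before clamping.
#' @param sd standard deviation of the estimate (optional).
#' @param n_mc number of Monte-Carlo draws behind `sd` (0 = analytic /
#'   point estimate only).
#' @param ci optional length-2 numeric, percentile confidence bounds.
#' @param sd_replicate optional across-replicate standard deviation, reported
#'   alongside the propagated `sd` (they answer different questions).
#' @return An object of class `mixing_estimate`.
#' @export
mixing_estimate <- function(raw, sd = NA_real_, n_mc = 0L, ci = NULL,
                            sd_replicate = NA_real_) {
  stopifnot(is.numeric(raw), n_mc >= 0)
  if (!is.na(sd) && sd < 0) stop("sd must be >= 0", call. = FALSE)
  structure(
    list(
      f_source = pmin(pmax(raw, 0), 1),
      raw = raw,
      clamped = any(raw < 0 | raw > 1),
      sd = sd,
      sd_replicate = sd_replicate,
      ci = ci,
      n_mc = as.integer(n_mc)
    ),
    class = "mixing_estimate"
  )
}

#' @export
print.mixing_estimate <- function(x, ...) {
  cat(sprintf("Two-end-member mixing estimate: f_source = %.4f (%.1f%%)\n",
              x$f_source, 100 * x$f_source))
  if (x$clamped) cat(sprintf("  raw value %.4f clamped into [0, 1]\n", x$raw))
  if (!is.na(x$sd)) cat(sprintf("  propagated sd = %.3g (%d MC draws)\n", x$sd, x$n_mc))
  if (!is.na(x$sd_replicate)) cat(sprintf("  across-replicate sd = %.3g\n", x$sd_replicate))
  if (!is.null(x$ci)) cat(sprintf("  95%% CI [%.5f, %.5f]\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Two-end-member source apportionment
#'
#' Apportions a measured 13C atom fraction between two source pools under the
#' linear mixing model `f * F_source + (1 - f) * F_background = F_target`,
#' i.e. `f = (F_target - F_background) / (F_source - F_background)`. With the
#' target being methane, the source labeled DIC, and the background the
#' methanol fed at the start, `f` is the fraction of methane carbon formed
#' from the DIC pool.
#'
#' @param f_target measured 13C atom fraction of the mixed pool.
#' @param f_source 13C atom fraction of the labeled end member.
#' @param f_background 13C atom fraction of the unlabeled end member.
#' @param eps end members closer than this are considered degenerate
#'   (default 1e-6, below GC-IRMS precision).
#' @return A [mixing_estimate()].
#' @examples
#' # Sulfate-reduction-zone style numbers: 83.6% labeled DIC,
#' # methane at 9.6 atom-%, methanol near natural abundance
#' two_pool_source_fraction(0.0960, 0.836, delta_to_fraction(0))
#' @export
two_pool_source_fraction <- function(f_target, f_source, f_background,
                                     eps = 1e-6) {
  stopifnot(is.numeric(f_target), is.numeric(f_source), is.numeric(f_background))
  vals <- c(f_target, f_source, f_background)
  if (any(vals < 0) || any(vals >= 1)) {
    stop("invalid isotope value: atom fractions must lie in [0, 1)", call. = FALSE)
  }
  if (any(abs(f_source - f_background) < eps)) {
    stop("degenerate end members: |f_source - f_background| < ", eps, call. = FALSE)
  }
  mixing_estimate((f_target - f_background) / (f_source - f_background))
}

#' 13C incorporation ratio from a single-label experiment
#'
#' The increase in 13C atom fraction of a biomass pool over the incubation,
#' normalized by the label strength of the amended substrate:
#' `x = (F_end - F_start) / F_label`. Computed once per labeled substrate
#' (methanol or DIC) in parallel single-labeling incubations.
#'
#' @param f_end 13C atom fraction of the pool at harvest.
#' @param f_start 13C atom fraction at time zero.
#' @param f_label 13C atom fraction of the labeled substrate (> 0).
#' @param source which substrate carried the label, `"MEOH"` or `"DIC"`.
#' @return An object of class `incorporation_ratio` with fields `x`
#'   (clamped at 0), `raw`, `source`, `clamped`.
#' @export
incorporation_ratio <- function(f_end, f_start, f_label,
                                source = c("MEOH", "DIC")) {
  source <- match.arg(source)
  stopifnot(is.numeric(f_end), is.numeric(f_start), is.numeric(f_label))
  if (any(f_label <= 0)) {
    stop("degenerate label: f_label must be > 0", call. = FALSE)
  }
  raw <- (f_end - f_start) / f_label
  structure(
    list(x = pmax(raw, 0), raw = raw, source = source, clamped = any(raw < 0)),
    class = "incorporation_ratio"
  )
}

#' @export
print.incorporation_ratio <- function(x, ...) {
  cat(sprintf("13C incorporation ratio (label: %s): x = %.4g\n", x$source, x$x))
  invisible(x)
}

#' Fraction of lipid carbon derived from DIC
#'
#' Combines the two incorporation ratios of parallel single-label incubations
#' into the DIC share of lipid biosynthesis,
#' `f_DIC/lipid = X_DIC / (X_DIC + X_MeOH)`. Valid only when the two
#' incubations received identical (unlabeled-equivalent) amendments.
#'
#' @param x_dic [incorporation_ratio()] from the 13C-DIC incubation, or a
#'   bare non-negative number.
#' @param x_meoh [incorporation_ratio()] from the 13C-methanol incubation,
#'   or a bare non-negative number.
#' @return A [mixing_estimate()] for the DIC fraction.
#' @export
dic_lipid_fraction <- function(x_dic, x_meoh) {
  xd <- if (inherits(x_dic, "incorporation_ratio")) x_dic$x else x_dic
  xm <- if (inherits(x_meoh, "incorporation_ratio")) x_meoh$x else x_meoh
  stopifnot(is.numeric(xd), is.numeric(xm))
  if (any(xd < 0) || any(xm < 0)) {
    stop("incorporation ratios must be >= 0", call. = FALSE)
  }
  if (any(xd + xm == 0)) {
    stop("no enrichment: both incorporation ratios are zero (unlabeled sample?)",
         call. = FALSE)
  }
  mixing_estimate(xd / (xd + xm))
}

#' Construct a table of carbon pools
#'
#' A carbon pool is a named amount of carbon (mmol per litre slurry) with a
#' 13C atom fraction. Pools are plain data frames so they compose with the
#' usual tools.
#'
#' @param name pool identifier(s).
#' @param concentration mmol carbon per litre slurry (>= 0, NA allowed for
#'   unquantified pools).
#' @param fraction_13c 13C atom fraction; alternatively give `delta`.
#' @param delta delta-13C per mil, converted if `fraction_13c` is missing.
#' @return data.frame with columns `name`, `concentration`, `fraction_13c`.
#' @export
carbon_pool <- function(name, concentration = NA_real_, fraction_13c = NULL,
                        delta = NULL) {
  if (is.null(fraction_13c)) {
    if (is.null(delta)) stop("give either fraction_13c or delta", call. = FALSE)
    fraction_13c <- delta_to_fraction(delta)
  }
  if (any(fraction_13c < 0 | fraction_13c >= 1)) {
    stop("invalid isotope value: atom fraction must lie in [0, 1)", call. = FALSE)
  }
  if (any(!is.na(concentration) & concentration < 0)) {
    stop("concentration must be >= 0", call. = FALSE)
  }
  data.frame(name = name, concentration = concentration,
             fraction_13c = fraction_13c, stringsAsFactors = FALSE)
}

#' Mass-balance mixing of carbon pools
#'
#' Mixes pools conserving both total carbon and total 13C exactly:
#' the mixture concentration is the sum of concentrations and its atom
#' fraction the concentration-weighted mean of the member fractions. This is
#' the forward model of label dilution, e.g. amended 13C-bicarbonate merging
#' into the ambient sediment DIC pool.
#'
#' @param pools data.frame as returned by [carbon_pool()]; all
#'   concentrations must be present and >= 0, with at least one > 0.
#' @param name name for the mixture (default "mixture").
#' @return One-row [carbon_pool()] data frame.
#' @export
mix_pools <- function(pools, name = "mixture") {
  stopifnot(is.data.frame(pools),
            all(c("concentration", "fraction_13c") %in% names(pools)))
  conc <- pools$concentration
  if (any(is.na(conc)) || any(conc < 0)) {
    stop("all pools need a concentration >= 0 to mix", call. = FALSE)
  }
  total <- sum(conc)
  if (total == 0) stop("empty pool: all concentrations are zero", call. = FALSE)
  carbon_pool(name, total, sum(conc * pools$fraction_13c) / total)
}

#' Infer the size of an unlabeled ambient pool from label dilution
#'
#' Inverse of [mix_pools()] for two members: given the amended amount and
#' label strength, the measured atom fraction of the mixed pool, and the
#' ambient (natural abundance) composition, returns the ambient pool size
#' `c_ambient = c_amended * (F_label - F_measured) / (F_measured - F_ambient)`.
#' Used to quantify how far amended 13C-DIC was diluted by sediment porewater
#' DIC.
#'
#' @param amended_conc amended pool size, mmol per litre slurry.
#' @param f_label 13C atom fraction of the amendment.
#' @param f_measured measured atom fraction of the mixed pool.
#' @param f_ambient atom fraction of the ambient pool.
#' @return Ambient pool size in mmol per litre slurry.
#' @export
infer_ambient_pool <- function(amended_conc, f_label, f_measured, f_ambient) {
  stopifnot(is.numeric(amended_conc), amended_conc >= 0)
  if (!(f_ambient < f_measured || f_measured == f_label) || f_measured > f_label) {
    stop("inconsistent measurement: need f_ambient < f_measured <= f_label",
         call. = FALSE)
  }
  if (f_measured == f_label) return(0)
  amended_conc * (f_label - f_measured) / (f_measured - f_ambient)
}
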