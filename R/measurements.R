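MEASUREMENT_COLUMNS <- c("sample_id", "pool", "replicate", "time_days",
                         "value", "value_type", "sd")

#' Read and write SIP measurement tables
#'
#' The package's measurement exchange format is a tab-separated table with
#' columns `sample_id`, `pool` (`CH4`, `DIC`, `MEOH`, `LIPID:<moiety>`,
#' `RNA`), `replicate`, `time_days`, `value`, `value_type`
#' (`delta_permil` or `atom_fraction`) and `sd` (may be NA). One row per
#' pool, replicate and sampling time. [write_measurements()] emits the same
#' dialect, so exports round-trip.
#'
#' @param path file path.
#' @param x measurement data.frame.
#' @return `read_measurements()` returns a validated data.frame;
#'   `write_measurements()` returns `path` invisibly.
#' @export
read_measurements <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_measurements(df)
}

#' @rdname read_measurements
#' @export
write_measurements <- function(x, path) {
  x <- validate_measurements(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_measurements <- function(df) {
  missing <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing)) {
    stop("measurement table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$value_type), c("delta_permil", "atom_fraction"))
  if (length(bad)) {
    stop("measurement table schema error: unknown value_type ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df[MEASUREMENT_COLUMNS]
}

# 13C atom fraction of every row, whatever the stored value_type
measurement_fractions <- function(df) {
  ifelse(df$value_type == "atom_fraction",
         df$value,
         delta_to_fraction(df$value))
}

# replicate mean / sd of the atom fraction of one pool at one time;
# time = NULL means the latest sampling time present for that pool
pool_summary <- function(df, pool, time = NULL) {
  rows <- df[df$pool == pool, , drop = FALSE]
  if (!nrow(rows)) {
    stop("measurement table schema error: pool '", pool, "' not present",
         call. = FALSE)
  }
  if (is.null(time)) time <- max(rows$time_days)
  rows <- rows[rows$time_days == time, , drop = FALSE]
  if (!nrow(rows)) {
    stop("measurement table schema error: pool '", pool,
         "' has no rows at time ", time, call. = FALSE)
  }
  f <- measurement_fractions(rows)
  d <- ifelse(rows$value_type == "delta_permil", rows$value,
              fraction_to_delta(rows$value))
  # stated per-row measurement sd (instrument precision), usable as a draw
  # scale only when the rows are stored in delta units
  stated <- if (all(rows$value_type == "delta_permil") && !all(is.na(rows$sd))) {
    mean(rows$sd, na.rm = TRUE)
  } else {
    NA_real_
  }
  list(fraction = mean(f), fractions = f,
       delta_mean = mean(d), delta_sd = stats::sd(d), stated_sd = stated,
       deltas = d, n = nrow(rows), time = time)
}
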