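# build a measurement table in code from known atom fractions; value_type
# delta_permil so the stated sd column is usable as a draw scale
make_mixing_table <- function(f_ch4, f_dic, f_meoh, n_rep = 3,
                              harvest_day = 43, noise_sd = 0, seed = 1,
                              stated_sd = noise_sd) {
  set.seed(seed)
  rows <- expand.grid(replicate = seq_len(n_rep),
                      pool = c("CH4", "DIC", "MEOH"),
                      stringsAsFactors = FALSE)
  f <- c(CH4 = f_ch4, DIC = f_dic, MEOH = f_meoh)[rows$pool]
  delta <- misosip::fraction_to_delta(unname(f)) +
    stats::rnorm(nrow(rows), 0, noise_sd)
  data.frame(
    sample_id = "fixture",
    pool = rows$pool,
    replicate = rows$replicate,
    time_days = ifelse(rows$pool == "MEOH", 0, harvest_day),
    value = delta,
    value_type = "delta_permil",
    sd = stated_sd,
    stringsAsFactors = FALSE
  )
}

# lipid-moiety table for the assimilation estimator: one labeled substrate
make_lipid_table <- function(f_lipid_end, f_label_pool, label_pool,
                             moieties = "LIPID:phytane", n_rep = 3,
                             harvest_day = 10) {
  rows <- expand.grid(replicate = seq_len(n_rep),
                      pool = c(moieties, label_pool),
                      stringsAsFactors = FALSE)
  f <- ifelse(rows$pool == label_pool, f_label_pool,
              f_lipid_end[match(rows$pool, moieties)])
  data.frame(
    sample_id = "fixture",
    pool = rows$pool,
    replicate = rows$replicate,
    time_days = ifelse(rows$pool == "MEOH", 0, harvest_day),
    value = unname(f),
    value_type = "atom_fraction",
    sd = NA_real_,
    stringsAsFactors = FALSE
  )
}

# write a pathway JSON from an R list and load it
load_pathway_from_list <- function(doc) {
  path <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null"), path)
  misosip::load_pathway(path)
}

# minimal valid two-compound pathway used as a base for invalid variants
tiny_pathway <- function() {
  list(
    sources = c("MEOH", "DIC"),
    compounds = list(
      list(name = "methyl_unit", n_carbons = 1),
      list(name = "two_carbon", n_carbons = 2)
    ),
    reactions = list(
      list(product = "methyl_unit", assignments = list("MEOH")),
      list(product = "two_carbon",
           assignments = list(list("methyl_unit", 1), "DIC"))
    )
  )
}
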