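# Build a long-format trait table from a named list:
# list(S1 = list(RTD = c(...), D = c(...)), ...)
make_table <- function(species_values) {
  rows <- list()
  for (sp in names(species_values)) {
    for (tr in names(species_values[[sp]])) {
      v <- species_values[[sp]][[tr]]
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp,
        individual = sprintf("%s_I%02d", sp, seq_along(v)),
        trait = tr, value = v, stringsAsFactors = FALSE)
    }
  }
  trait_table(do.call(rbind, rows))
}

# tiny heterogeneous RTD + D config used by several tests
small_config <- function(seed = 7, n_species = 40, total = 200,
                         within = 0.3) {
  simulation_config(
    n_species = n_species, total_individuals = total,
    traits = list(
      trait_spec("RTD", log_mean = log(0.25), log_sd = 0.45,
                 within_log_sd = within),
      trait_spec("D", log_mean = log(0.35), log_sd = 0.40,
                 within_log_sd = within)),
    n_per_species = c(1L, 10L), seed = seed)
}
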