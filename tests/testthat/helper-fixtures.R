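# in-code fixtures shared across the suite

fix_catalog <- function() {
  ddd_catalog(c("amoxicillin", "doxycycline", "trimethoprim", "sulfadimidine"),
              c(20, 10, 4, 20),
              c("penicillins", "tetracyclines", "trimethoprim", "sulfonamides"),
              long_acting_factor = c(1, 1, 1, 2))
}

fix_journal_df <- function() {
  data.frame(
    event_id = c("E1", "E2", "E2", "E3"),
    farm_id = c("F1", "F1", "F1", "F2"),
    age_category = c("weaned_piglet", "weaned_piglet", "weaned_piglet",
                     "fattening_pig"),
    substance = c("amoxicillin", "trimethoprim", "sulfadimidine",
                  "doxycycline"),
    amount_mg = c(5000, 960, 4800, 15000),
    n_animals = c(20, 10, 10, 30),
    n_days = c(3, 2, 2, 5),
    application_date = "2019-01-10",
    entry_date = "2019-01-12",
    stringsAsFactors = FALSE)
}

fix_census <- function() {
  farm_census(data.frame(
    farm_id = c("F1", "F2", "F2"),
    age_category = c("weaned_piglet", "fattening_pig", "weaned_piglet"),
    animals_per_year = c(2000, 1050, 500),
    continuous_recording = c(TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE))
}

# an indicator table built directly from per-farm TOTAL values, for
# benchmark/agreement tests that do not need the journal path
fix_table <- function(ati, nddd = ati, category = "weaned_piglet",
                      farm_id = sprintf("F%03d", seq_along(ati))) {
  df <- data.frame(farm_id = farm_id, age_category = category,
                   substance_class = "TOTAL",
                   nt = ati, ati = ati, nddd = nddd,
                   nddd_per_animal_year = nddd, stringsAsFactors = FALSE)
  class(df) <- c("amu_indicator_table", "data.frame")
  df
}

# small simulation config used by several tests
fix_sim_config <- function(..., seed = 42L) {
  sim_config(n_fattening = 15L, n_breeding = 2L, n_sow_pool = 8L,
             n_farrow_finish = 10L, seed = seed, ...)
}
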