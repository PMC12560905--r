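# Small simulation scenarios reused across tests. The "toy" herd is large
# enough to separate the variance components without making the suite slow.

toy_scenario <- function(traits = "DMY", seed = 7, records_per_cow = 3,
                         n_cows = 40) {
  sim_scenario(
    n_founder_males = 6, n_founder_females = 30, n_generations = 3,
    n_males_per_gen = 5, n_females_per_gen = 30, n_sires_used = 4,
    n_cows_with_records = n_cows, records_per_cow = records_per_cow,
    traits = traits, seed = seed
  )
}

# The validation herd used for parameter-recovery runs: ~2,000 recorded
# cows on a three-generation pedigree; 5 test-days per cow for univariate
# runs, the default herd's 8 for bivariate runs (cross-trait components
# gain from within-cow replication at no extra solver cost).
recovery_scenario <- function(traits, seed, records_per_cow = 5) {
  sim_scenario(
    n_founder_males = 60, n_founder_females = 1000, n_generations = 3,
    n_males_per_gen = 60, n_females_per_gen = 1000, n_sires_used = 40,
    n_cows_with_records = 2000, records_per_cow = records_per_cow,
    traits = traits, seed = seed
  )
}

toy_sim <- function(...) {
  sc <- toy_scenario(...)
  ped <- simulate_pedigree(sc)
  c(simulate_records(ped, sc), list(ped = ped, scenario = sc))
}
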