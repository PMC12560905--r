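test_that("the simulator is fully deterministic under a fixed seed", {
  sc <- toy_scenario(traits = c("DMY", "FP"), seed = 99)
  ped1 <- simulate_pedigree(sc); ped2 <- simulate_pedigree(sc)
  expect_identical(as.data.frame(ped1), as.data.frame(ped2))
  r1 <- simulate_records(ped1, sc); r2 <- simulate_records(ped2, sc)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$truth$breeding_values, r2$truth$breeding_values)
  # and a different seed changes the data
  r3 <- simulate_records(ped1, sc, seed = 100)
  expect_false(identical(r1$records$dmy_kg, r3$records$dmy_kg))
})

test_that("pedigree layout matches the scenario", {
  sc1 <- sim_scenario(n_founder_males = 4, n_founder_females = 16, n_generations = 1,
                      n_cows_with_records = 5, records_per_cow = 2)
  ped1 <- simulate_pedigree(sc1)
  expect_equal(nrow(ped1), 20)
  expect_true(all(ped1$sire_idx == 0L))   # one generation -> founders only

  sc4 <- sim_scenario(n_founder_males = 20, n_founder_females = 80, n_generations = 4,
                      n_males_per_gen = 20, n_females_per_gen = 80, n_sires_used = 10,
                      n_cows_with_records = 50, records_per_cow = 2, seed = 3)
  ped4 <- simulate_pedigree(sc4)
  depth <- pedigree_depth(ped4)
  gen <- attr(ped4, "generation")
  expect_equal(max(depth), 4)
  # youngest generation sits at the full design depth
  expect_lt(abs(mean(depth[gen == 3]) - 4), 0.5)
})

test_that("gene-dropped breeding values have the pedigree covariance structure", {
  # zero covariance -> all zero
  ped <- as_pedigree(random_pedigree_df(20, 3, 30, seed = 2))
  expect_true(all(simulate_breeding_values(ped, matrix(0), seed = 1) == 0))

  # founder variance reproduces sigma2_a = 0.449
  nf <- 5000
  founders <- as_pedigree(data.frame(animal = paste0("F", 1:nf)))
  bv <- simulate_breeding_values(founders, matrix(0.449), seed = 4)
  expect_lt(abs(var(as.vector(bv)) - 0.449), 3 * 0.449 * sqrt(2 / (nf - 1)))

  # parent-offspring covariance is half the additive variance
  n_pair <- 4000
  df <- data.frame(
    animal = c(paste0("P", 1:n_pair), paste0("Q", 1:n_pair), paste0("O", 1:n_pair)),
    sire = c(rep(NA, 2 * n_pair), paste0("P", 1:n_pair)),
    dam = c(rep(NA, 2 * n_pair), paste0("Q", 1:n_pair))
  )
  ped2 <- as_pedigree(df)
  bv2 <- simulate_breeding_values(ped2, matrix(1), seed = 5)
  sires <- bv2[paste0("P", 1:n_pair), 1]; off <- bv2[paste0("O", 1:n_pair), 1]
  expect_lt(abs(cov(sires, off) - 0.5), 3 * sqrt(1.25 / n_pair))

  # per-animal variance scales with 1 + F: within-family spread shrinks for
  # inbred offspring via the Mendelian-sampling term, checked through the
  # empirical variance of full-sib deviations
  expect_error(simulate_breeding_values(ped2, matrix(c(1, 2, 2, 1), 2)), "semidefinite")
})

test_that("records decompose exactly and track their generative parts", {
  sc <- toy_scenario(traits = c("DMY", "FP", "PP"), seed = 31, n_cows = 30)
  ped <- simulate_pedigree(sc)
  sim <- simulate_records(ped, sc)
  rec <- sim$records
  expect_equal(nrow(rec), 30 * sc$records_per_cow)
  # shift yields sum exactly to the daily yield
  expect_equal(rec$my_morn_kg + rec$my_noon_kg + rec$my_night_kg, rec$dmy_kg,
               tolerance = 1e-9)
  expect_true(all(rec$dim >= 15 & rec$dim <= 308))
  expect_true(all(rec$season %in% c("spring", "summer", "fall", "winter")))

  # all variance off and flat profiles -> records equal their fixed part
  vc0 <- default_variance_components()
  vc0$sigma2_a <- 1e-12; vc0$sigma2_m <- 0; vc0$sigma2_pe <- 0; vc0$sigma2_e <- 1e-12
  flat <- lapply(default_fixed_effect_profiles(), function(pr) lapply(pr, function(v) v * 0))
  sc0 <- sim_scenario(
    n_founder_males = 4, n_founder_females = 20, n_generations = 2,
    n_males_per_gen = 4, n_females_per_gen = 20, n_sires_used = 2,
    n_cows_with_records = 10, records_per_cow = 3, traits = "DMY",
    variance_components = vc0, rg = c(), rp = c(),
    fixed_effect_profiles = flat, seed = 8
  )
  sim0 <- simulate_records(simulate_pedigree(sc0), sc0)
  expect_equal(sim0$records$dmy_kg, rep(28.5, 30), tolerance = 0.01)
})

test_that("phenotypic variance matches the sum of generative components", {
  # single fixed-effect cell: flat profiles, so the phenotypic variance is
  # sigma2_a + sigma2_m + sigma2_pe + sigma2_e up to sampling error
  flat <- lapply(default_fixed_effect_profiles(), function(pr) lapply(pr, function(v) v * 0))
  sc <- sim_scenario(
    n_founder_males = 30, n_founder_females = 600, n_generations = 2,
    n_males_per_gen = 30, n_females_per_gen = 600, n_sires_used = 20,
    n_cows_with_records = 600, records_per_cow = 4, traits = "DMY",
    fixed_effect_profiles = flat, seed = 12
  )
  sim <- simulate_records(simulate_pedigree(sc), sc)
  vc <- sc$variance_components
  total <- vc$sigma2_a + vc$sigma2_m + vc$sigma2_pe + vc$sigma2_e
  v_emp <- var(sim$records$dmy_kg)
  # repeated records per cow are correlated; allow a generous sampling band
  expect_lt(abs(v_emp - total) / total, 0.15)
})

test_that("the default scenario reproduces the emulated herd means", {
  sc <- sim_scenario(seed = 2)
  ped <- simulate_pedigree(sc)
  expect_equal(sum(ped$sex == "F"), 3750)
  expect_equal(sum(ped$sex == "M"), 300)
  sim <- simulate_records(ped, sc)
  expect_equal(nrow(sim$records), 2992 * 8)
  # grand means: tolerance covers residual sampling error plus genetic drift
  # of the founder sample propagated through the pedigree
  expect_lt(abs(mean(sim$records$dmy_kg) - 28.5), 0.2)
  expect_lt(abs(mean(sim$records$fat_pct) - 3.94), 0.06)
  expect_lt(abs(mean(sim$records$protein_pct) - 3.35), 0.05)
})

test_that("injected defects are recorded and removed by the cleaning pipeline", {
  sc <- sim_scenario(
    n_founder_males = 10, n_founder_females = 100, n_generations = 3,
    n_males_per_gen = 10, n_females_per_gen = 100, n_sires_used = 5,
    n_cows_with_records = 150, records_per_cow = 4, traits = c("DMY", "FP", "PP"),
    outlier_rate = 0.02, duplicate_rate = 0.02,
    missingness_rates = c(fat_pct = 0.01), seed = 44
  )
  sim <- simulate_records(simulate_pedigree(sc), sc)
  inj <- sim$truth$injected
  expect_equal(length(inj$outliers), ceiling(0.02 * 600))
  expect_equal(length(inj$duplicates), ceiling(0.02 * 600))
  res <- clean_records(standardize_records(sim$records))
  kept <- res$records$record_id
  # every injected impossible yield is gone, every untouched record with
  # in-range DIM survives unless it was the duplicate copy
  expect_length(intersect(kept, inj$outliers), 0)
  expect_length(intersect(kept, inj$duplicates), 0)
  rep <- as.data.frame(res$report)
  expect_equal(rep$records_removed[rep$stage == "Remove Duplicate Records"],
               length(inj$duplicates))
  out_stage <- rep$records_removed[grepl("Outliers", rep$stage)]
  expect_equal(out_stage, length(inj$outliers))
})
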