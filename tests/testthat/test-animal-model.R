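# A fixed small herd shared by the oracle comparisons.
small_fit_data <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) sim <<- toy_sim(traits = "DMY", seed = 7, n_cows = 40,
                                      records_per_cow = 3)
    sim
  }
})

fixed_small <- ~ parity_class + season + dim_stage
vc_tab <- tibble::tibble(trait = "DMY", sigma2_a = 0.449, sigma2_m = 0.031,
                         sigma2_pe = 0.288, sigma2_e = 0.407)

test_that("the sparse restricted likelihood equals the dense formula", {
  sim <- small_fit_data()
  d <- dense_designs(sim$records, sim$ped, fixed_small)
  A <- build_A(sim$ped)
  for (th in list(c(0.449, 0.031, 0.288, 0.407), c(1, 0.2, 0.1, 0.5), c(0.05, 0.01, 0.9, 1.3))) {
    m2l_dense <- dense_reml_m2l(d$y, d$X, d$Za, d$Zm, d$Zp, A, th)
    ll_pkg <- reml_loglik(sim$records, sim$ped, "DMY",
                          tibble::tibble(trait = "DMY", sigma2_a = th[1], sigma2_m = th[2],
                                         sigma2_pe = th[3], sigma2_e = th[4]),
                          fixed = fixed_small)
    expect_equal(-2 * ll_pkg, m2l_dense, tolerance = 1e-9)
  }
})

test_that("REML matches a brute-force dense maximization on a small instance", {
  sim <- small_fit_data()
  fit <- reml_fit(sim$records, sim$ped, "DMY", fixed = fixed_small)
  d <- dense_designs(sim$records, sim$ped, fixed_small)
  A <- build_A(sim$ped)
  opt <- optim(log(c(0.4, 0.05, 0.3, 0.4)),
               function(lt) dense_reml_m2l(d$y, d$X, d$Za, d$Zm, d$Zp, A, exp(lt)),
               method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-13))
  expect_equal(-2 * fit$loglik, opt$value, tolerance = 1e-4)
})

test_that("with unrelated cows, single records and a+e only, MME reduce to OLS", {
  set.seed(15)
  n <- 60
  rec <- tibble::tibble(
    record_id = sprintf("r%03d", 1:n), ear_tag = sprintf("c%03d", 1:n),
    test_date = as.Date("2023-06-01"), parity = sample(1:4, n, TRUE),
    season = sample(c("spring", "summer"), n, TRUE),
    dim = sample(15:300, n), bw_kg = 575,
    dmy_kg = rnorm(n, 28, 2), flags = ""
  )
  ped <- as_pedigree(data.frame(animal = rec$ear_tag))
  vc <- tibble::tibble(trait = "DMY", sigma2_a = 1e-8, sigma2_m = 0,
                       sigma2_pe = 0, sigma2_e = 1)
  mme <- build_mme(rec, ped, "DMY", vc, fixed = ~ parity_class + season,
                   random = "a")
  recs <- add_model_factors(rec)
  ols <- coef(lm(dmy_kg ~ parity_class + season, data = droplevels(recs)))
  got <- mme$solution[seq_along(ols)]
  expect_equal(unname(got), unname(ols), tolerance = 1e-5)
  # shrinkage limit: with a negligible additive variance ratio the
  # predicted breeding values collapse to zero
  blups <- mme$solution[grepl("^DMY:a:", names(mme$solution))]
  expect_lt(max(abs(blups)), 1e-6)
})

test_that("MME solutions equal dense GLS on a related toy herd", {
  sim <- small_fit_data()
  mme <- build_mme(sim$records, sim$ped, "DMY", vc_tab, fixed = fixed_small)
  d <- dense_designs(sim$records, sim$ped, fixed_small)
  A <- build_A(sim$ped)
  V <- 0.449 * d$Za %*% A %*% t(d$Za) + 0.031 * d$Zm %*% A %*% t(d$Zm) +
    0.288 * d$Zp %*% t(d$Zp) + 0.407 * diag(length(d$y))
  Vi <- solve(V)
  beta <- solve(t(d$X) %*% Vi %*% d$X, t(d$X) %*% Vi %*% d$y)
  expect_equal(unname(mme$solution[seq_along(beta)]), as.vector(beta),
               tolerance = 1e-8)
  # BLUP of the additive effects from the GLS residual projection
  ahat <- 0.449 * A %*% t(d$Za) %*% Vi %*% (d$y - d$X %*% beta)
  got <- mme$solution[paste0("DMY:a:", sim$ped$animal)]
  expect_equal(unname(got), as.vector(ahat), tolerance = 1e-8)
})

test_that("the restricted likelihood is invariant to the fixed-effect coding", {
  # treatment coding vs cell-means coding span the same column space with a
  # unimodular change of basis, so the restricted likelihood is unchanged
  sim <- small_fit_data()
  ll1 <- reml_loglik(sim$records, sim$ped, "DMY", vc_tab, fixed = fixed_small)
  ll2 <- reml_loglik(sim$records, sim$ped, "DMY", vc_tab,
                     fixed = ~ 0 + parity_class + season + dim_stage)
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("pure-noise data drive the additive variance to the boundary", {
  sim <- toy_sim(traits = "DMY", seed = 23, n_cows = 60, records_per_cow = 3)
  rec <- sim$records
  set.seed(1)
  rec$dmy_kg <- rnorm(nrow(rec), 28.5, 1)
  fit <- reml_fit(rec, sim$ped, "DMY", fixed = fixed_small)
  expect_lt(fit$vc$sigma2_a / sum(fit$vc[, c("sigma2_a", "sigma2_m", "sigma2_pe", "sigma2_e")]),
            0.05)
})

test_that("heritability and repeatability follow their definitions", {
  vc <- vc_tab
  h <- heritability(vc)
  tot <- 0.449 + 0.031 + 0.288 + 0.407
  expect_equal(h$h2, 0.449 / tot, tolerance = 1e-12)
  expect_equal(round(h$h2, 3), 0.382)
  r <- repeatability(vc)
  expect_equal(r$repeatability, (0.449 + 0.288) / tot, tolerance = 1e-12)
  expect_equal(r$repeatability, 0.6272, tolerance = 1e-3)
  # degenerate corners
  expect_equal(heritability(tibble::tibble(trait = "x", sigma2_a = 0, sigma2_m = 0,
                                           sigma2_pe = 0, sigma2_e = 1))$h2, 0)
  expect_equal(heritability(tibble::tibble(trait = "x", sigma2_a = 1, sigma2_m = 0,
                                           sigma2_pe = 0, sigma2_e = 0))$h2, 1)
  expect_equal(repeatability(tibble::tibble(trait = "x", sigma2_a = 0, sigma2_m = 0,
                                            sigma2_pe = 0, sigma2_e = 1))$repeatability, 0)
  # sigma2_pe = 0 makes repeatability equal heritability
  vc2 <- tibble::tibble(trait = "x", sigma2_a = 0.4, sigma2_m = 0.1,
                        sigma2_pe = 0, sigma2_e = 0.5)
  expect_equal(repeatability(vc2)$repeatability, heritability(vc2)$h2)
  expect_error(heritability(tibble::tibble(trait = "x", sigma2_a = 0, sigma2_m = 0,
                                           sigma2_pe = 0, sigma2_e = 0)), "positive")
})

test_that("correlation accessors handle the degenerate covariance cases", {
  fake <- structure(list(
    traits = c("FP", "PP"), k = 2L, random = c("a", "pe"),
    Sigma = list(a = diag(c(0.2, 0.1)), pe = diag(c(0.1, 0.05)),
                 e = diag(c(0.3, 0.1))),
    ai_inv = NULL, vc = NULL
  ), class = "lactaqg_reml")
  gc <- genetic_correlations(fake)
  expect_equal(gc$rg, 0)                       # diagonal additive covariance
  fake$Sigma$a <- matrix(c(0.2, sqrt(0.2 * 0.1), sqrt(0.2 * 0.1), 0.1), 2)
  expect_equal(genetic_correlations(fake)$rg, 1)   # perfect correlation
  fake$Sigma$a <- diag(c(0, 0.1))
  expect_true(is.na(genetic_correlations(fake)$rg)) # zero variance -> missing
})

test_that("lactation-stage boundaries assign 100/101/201 correctly", {
  expect_equal(dim_stage(c(100, 101, 200, 201, 15)),
               c("early", "mid", "mid", "late", "early"))
})

test_that("a single-stage subset equals a direct fit", {
  sim <- toy_sim(traits = "DMY", seed = 29, n_cows = 50, records_per_cow = 4)
  rec <- add_model_factors(sim$records)
  early <- rec[rec$dim_stage == "early", ]
  ctl <- reml_control(factr = 1e9)
  # the stage subset leaves < 2 records per cow, so the weak-identifiability
  # warning is expected here
  suppressWarnings({
    direct <- reml_fit(early, sim$ped, "DMY", fixed = ~ parity_class + season,
                       random = c("a", "pe"), control = ctl)
    strat <- stage_stratified_fit(sim$records, sim$ped, "DMY",
                                  fixed = ~ parity_class + season,
                                  random = c("a", "pe"), stages = "early",
                                  control = ctl)
  })
  expect_equal(strat$fits$early$loglik, direct$loglik, tolerance = 1e-6)
  expect_equal(strat$parameters$h2, heritability(direct)$h2, tolerance = 1e-4)
})

test_that("record cows missing from the pedigree are a named error", {
  sim <- small_fit_data()
  rec <- sim$records
  rec$ear_tag[1] <- "GHOST_COW"
  expect_error(reml_fit(rec, sim$ped, "DMY", fixed = fixed_small), "GHOST_COW")
})

test_that("tidy/glance expose the fit in broom shape", {
  sim <- small_fit_data()
  fit <- reml_fit(sim$records, sim$ped, "DMY", fixed = fixed_small)
  td <- tidy(fit)
  expect_setequal(td$component, c("a", "m", "pe", "e"))
  expect_true(all(td$estimate >= 0))
  gl <- glance(fit)
  expect_equal(gl$n_records, nrow(add_model_factors(sim$records)))
  expect_equal(gl$convergence, 0)
  expect_s3_class(autoplot(fit), "ggplot")
})
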