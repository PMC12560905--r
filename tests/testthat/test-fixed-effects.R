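make_records <- function(df) {
  # minimal record tibble around explicit factor columns for LSM tests
  n <- nrow(df)
  out <- tibble::tibble(
    record_id = sprintf("r%03d", seq_len(n)), ear_tag = sprintf("c%03d", seq_len(n)),
    test_date = as.Date("2023-06-01"), parity = 1L, season = "summer",
    dim = 50L, bw_kg = 575, dmy_kg = df$y, flags = ""
  )
  cbind(out, df[setdiff(names(df), "y")])
}

test_that("LSM equal raw group means on balanced one-factor data", {
  set.seed(1)
  df <- data.frame(g = factor(rep(c("lo", "hi"), each = 25)),
                   y = rnorm(50, rep(c(20, 30), each = 25)))
  tab <- fit_lsm(make_records(df), trait = "DMY", factors = "g")
  means <- tapply(df$y, df$g, mean)
  expect_equal(unname(setNames(tab$lsm, tab$level)[names(means)]),
               unname(as.vector(means)), tolerance = 1e-12)
  expect_equal(tab$n, c(25L, 25L))
})

test_that("identical groups share one letter; separated groups get all-distinct letters", {
  set.seed(2)
  y <- rnorm(60, 25)
  df_same <- data.frame(g = factor(rep(c("a", "b"), 30)), y = y)
  tab <- fit_lsm(make_records(df_same), trait = "DMY", factors = "g")
  expect_equal(tab$letters[1], tab$letters[2])
  df_far <- data.frame(g = factor(rep(c("a", "b", "c"), each = 30)),
                       y = rnorm(90, rep(c(10, 20, 30), each = 30), 0.5))
  tab2 <- fit_lsm(make_records(df_far), trait = "DMY", factors = "g")
  expect_setequal(tab2$letters, c("A", "B", "C"))
  # descending LSM receives letter A
  expect_equal(tab2$letters[which.max(tab2$lsm)], "A")
  expect_s3_class(autoplot(tab2), "ggplot")
})

test_that("LSM on unbalanced two-factor data match a normal-equations oracle", {
  set.seed(3)
  df <- data.frame(
    g = factor(sample(c("a", "b", "c"), 120, replace = TRUE, prob = c(.5, .3, .2))),
    h = factor(sample(c("u", "v"), 120, replace = TRUE, prob = c(.7, .3)))
  )
  df$y <- 20 + 2 * (df$g == "b") + 5 * (df$g == "c") - 3 * (df$h == "v") + rnorm(120)
  tab <- fit_lsm(make_records(df), trait = "DMY", factors = c("g", "h"))
  # oracle: solve the normal equations directly, average predictions over
  # the factorial grid of the other factor with equal weights
  X <- model.matrix(~ g + h, df)
  beta <- solve(t(X) %*% X, t(X) %*% df$y)
  grid <- expand.grid(g = levels(df$g), h = levels(df$h))
  Xg <- model.matrix(~ g + h, grid)
  pred <- as.vector(Xg %*% beta)
  for (lv in levels(df$g)) {
    expect_equal(tab$lsm[tab$factor == "g" & tab$level == lv],
                 mean(pred[grid$g == lv]), tolerance = 1e-10)
  }
})

test_that("empty factor levels are a named error", {
  df <- data.frame(g = factor(rep("a", 20), levels = c("a", "ghost")),
                   y = rnorm(20))
  expect_error(fit_lsm(make_records(df), trait = "DMY", factors = "g"), "ghost")
})

test_that("the letter display handles the canonical structures", {
  mk <- function(sig_pairs, k, means) {
    p <- matrix(1, k, k, dimnames = list(names(means), names(means)))
    for (pr in sig_pairs) p[pr[1], pr[2]] <- p[pr[2], pr[1]] <- 0.001
    letter_display(p, alpha = 0.05, means = means)
  }
  # all pairs significant
  expect_equal(unname(mk(list(c(1, 2), c(1, 3), c(2, 3)), 3,
                         c(x = 30, y = 20, z = 10))), c("A", "B", "C"))
  # nothing significant
  expect_equal(unname(mk(list(), 3, c(x = 30, y = 20, z = 10))),
               rep("A", 3))
  # chain: 1~2, 2~3 but 1 != 3  ->  A, AB, B
  expect_equal(unname(mk(list(c(1, 3)), 3, c(x = 30, y = 20, z = 10))),
               c("A", "AB", "B"))
  # invariant to input order of the levels
  m <- c(x = 30, y = 20, z = 10)
  p <- matrix(1, 3, 3, dimnames = list(names(m), names(m)))
  p["x", "z"] <- p["z", "x"] <- 0.001
  perm <- c("z", "x", "y")
  out1 <- letter_display(p, means = m)
  out2 <- letter_display(p[perm, perm], means = m)
  expect_equal(out1[names(m)], out2[names(m)])
})

test_that("Bonferroni-adjusted pairwise p-values are never below raw ones", {
  set.seed(8)
  df <- data.frame(g = factor(rep(c("a", "b", "c", "d"), each = 15)),
                   y = rnorm(60, rep(c(20, 21, 22, 23), each = 15), 2))
  recs <- add_model_factors(make_records(df))
  fit <- stats::lm(dmy_kg ~ g, data = recs)
  emm <- emmeans::emmeans(fit, "g")
  raw <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))$p.value
  adj <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "bonferroni"))$p.value
  expect_true(all(adj >= raw - 1e-12))
  expect_true(all(adj <= 1))
  expect_equal(adj, pmin(raw * length(raw), 1), tolerance = 1e-10)
})

test_that("VIF follows its closed form", {
  set.seed(4)
  # columns orthogonal to each other and to the intercept -> VIF exactly 1
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(250), 50, 5))))[, 2:5]
  v <- compute_vif(Q)
  expect_equal(v$vif$vif, rep(1, 4), tolerance = 1e-8)
  # empirically exact (centred) correlation r = 0.9 -> VIF = 1 / (1 - 0.81)
  z <- qr.Q(qr(cbind(1, matrix(rnorm(400), 200, 2))))[, 2:3]
  x1 <- z[, 1]; x2 <- 0.9 * z[, 1] + sqrt(1 - 0.81) * z[, 2]
  v2 <- compute_vif(cbind(x1, x2))
  expect_equal(v2$vif$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-8)
  # duplicated column -> infinite VIF with a warning, not an error
  expect_warning(v3 <- compute_vif(cbind(x1, x1)), "collinearity")
  expect_true(all(is.infinite(v3$vif$vif)))
})

test_that("ADULT linear + categorical codings give finite, consistent VIFs", {
  set.seed(6)
  bw <- pmin(pmax(rnorm(600, 575, 45), 450), 780)
  adult_cat <- cut(bw, quantile(bw, c(0, 1/3, 2/3, 1)), include.lowest = TRUE,
                   labels = c("low", "medium", "high"))
  v <- compute_vif(data.frame(adult_m = as.numeric(scale(bw)), adult_cat = adult_cat))
  vif_m <- v$vif$vif[v$vif$covariate == "adult_m"]
  expect_true(is.finite(vif_m))
  # consistency with the defining regression R^2
  r2 <- summary(lm(scale(bw) ~ adult_cat))$r.squared
  expect_equal(vif_m, 1 / (1 - r2), tolerance = 1e-8)
})

test_that("mid-lactation prediction: exact copy gives R2 = 1, noise gives ~0", {
  set.seed(10)
  n_cows <- 300
  base <- rnorm(n_cows, 28, 3)
  mk_rec <- function(mid_vals) {
    tibble::tibble(
      record_id = sprintf("r%04d", 1:(2 * n_cows)),
      ear_tag = rep(sprintf("c%03d", 1:n_cows), 2),
      test_date = as.Date("2023-06-01"), parity = 2L, season = "summer",
      dim = rep(c(50L, 150L), each = n_cows),
      dmy_kg = c(base, mid_vals),
      my_morn_kg = rnorm(2 * n_cows, 9), my_noon_kg = rnorm(2 * n_cows, 9.5),
      my_night_kg = rnorm(2 * n_cows, 9.3),
      fat_pct = rnorm(2 * n_cows, 3.9, 0.2), protein_pct = rnorm(2 * n_cows, 3.35, 0.2),
      bw_kg = 575, flags = ""
    )
  }
  res_copy <- suppressWarnings(predict_mid_from_early(mk_rec(base)))
  expect_equal(res_copy$r_squared, 1, tolerance = 1e-10)
  res_noise <- predict_mid_from_early(mk_rec(rnorm(n_cows, 28, 3)))
  expect_lt(res_noise$r_squared, 0.05)
})

test_that("mid-lactation prediction recovers a known standardized slope", {
  set.seed(12)
  n_cows <- 800
  early <- rnorm(n_cows)
  mid <- 0.65 * early + sqrt(1 - 0.65^2) * rnorm(n_cows)
  rec <- tibble::tibble(
    record_id = sprintf("r%04d", 1:(2 * n_cows)),
    ear_tag = rep(sprintf("c%04d", 1:n_cows), 2),
    test_date = as.Date("2023-06-01"), parity = 2L, season = "summer",
    dim = rep(c(60L, 160L), each = n_cows),
    dmy_kg = c(28 + 3 * early, 29 + 3 * mid),
    my_morn_kg = rnorm(2 * n_cows, 9, 0.5), my_noon_kg = rnorm(2 * n_cows, 9.5, 0.5),
    my_night_kg = rnorm(2 * n_cows, 9.3, 0.5),
    fat_pct = rnorm(2 * n_cows, 3.9, 0.2), protein_pct = rnorm(2 * n_cows, 3.35, 0.2),
    bw_kg = 575, flags = ""
  )
  res <- predict_mid_from_early(rec)
  b <- res$coefficients[res$coefficients$term == "early_dmy_kg", ]
  expect_lt(abs(b$estimate - 0.65), 3 * b$se)
  expect_error(predict_mid_from_early(rec[c(1, n_cows + 1), ]), "few cows")
})
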