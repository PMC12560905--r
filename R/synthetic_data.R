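#' Simulation scenario for a synthetic dairy herd
#'
#' Bundles every knob of the herd generator: pedigree layout, herd size,
#' generative variance components, fixed-effect profiles, and the rates of
#' data defects injected for testing the cleaning protocol.
#'
#' The defaults emulate the study herd the package is designed around: a
#' pedigree of about 3,750 females and 300 males over five discrete
#' generations, roughly 3,000 recorded cows with 8 test-day records each
#' over lactation weeks 3--44, trait means of 28.5 kg (DMY), 3.94% (FP) and
#' 3.35% (PP), and variance components whose heritabilities are
#' 0.382 / 0.292 / 0.360. Residual variances default to
#' \eqn{\sigma^2_e = \sigma^2_a/h^2 - (\sigma^2_a+\sigma^2_m+\sigma^2_{pe})},
#' i.e. they are derived from the target heritability rather than set
#' directly, so the generative h2 equals the stated value by construction.
#'
#' Cross-trait structure: the additive covariance between two traits is
#' `rg * sqrt(sigma2_a1 * sigma2_a2)`; maternal and permanent-environment
#' effects are uncorrelated across traits; the residual covariance absorbs
#' the remainder needed to reach the target phenotypic correlation `rp`.
#'
#' @param n_founder_males,n_founder_females Founder counts (generation 0).
#' @param n_generations Number of discrete generations including founders.
#' @param n_males_per_gen,n_females_per_gen Offspring produced per
#'   non-founder generation.
#' @param n_sires_used Sires sampled from the previous generation's males.
#' @param n_cows_with_records Number of cows that receive test-day records
#'   (sampled from non-founder females).
#' @param records_per_cow Test-day records per recorded cow.
#' @param traits Subset of `c("DMY", "FP", "PP")`.
#' @param trait_means Named vector of trait means (kg for DMY, % otherwise).
#' @param variance_components Tibble with columns `trait`, `sigma2_a`,
#'   `sigma2_m`, `sigma2_pe`, `sigma2_e`.
#' @param rg,rp Named vectors of pairwise genetic / phenotypic correlations,
#'   names like `"DMY:FP"`.
#' @param fixed_effect_profiles Named list (per trait) of named lists with
#'   elements `parity`, `season`, `dim_stage`, `bw_class` (effect offsets per
#'   level, centred internally under the generator's level frequencies).
#' @param missingness_rates Named vector of per-column missingness rates to
#'   inject (names among the record columns).
#' @param outlier_rate Fraction of records whose DMY is replaced by a
#'   biologically impossible value (> 60 or < 2 kg).
#' @param duplicate_rate Fraction of records duplicated (same ear tag and
#'   test date).
#' @param seed Default seed used when the simulation functions are called
#'   without one.
#' @return A list of class `"sim_scenario"`.
#' @export
sim_scenario <- function(n_founder_males = 60,
                         n_founder_females = 750,
                         n_generations = 5,
                         n_males_per_gen = 60,
                         n_females_per_gen = 750,
                         n_sires_used = 40,
                         n_cows_with_records = 2992,
                         records_per_cow = 8,
                         traits = c("DMY", "FP", "PP"),
                         trait_means = c(DMY = 28.5, FP = 3.94, PP = 3.35),
                         variance_components = default_variance_components(),
                         rg = c("DMY:FP" = -0.435, "DMY:PP" = -0.809, "FP:PP" = 0.551),
                         rp = c("DMY:FP" = -0.144, "DMY:PP" = -0.153, "FP:PP" = 0.352),
                         fixed_effect_profiles = default_fixed_effect_profiles(),
                         missingness_rates = NULL,
                         outlier_rate = 0,
                         duplicate_rate = 0,
                         seed = 1L) {
  traits <- match.arg(traits, c("DMY", "FP", "PP"), several.ok = TRUE)
  stopifnot(
    n_founder_males > 0, n_founder_females > 0, n_generations >= 1,
    n_sires_used > 0, n_cows_with_records > 0, records_per_cow >= 1,
    records_per_cow <= 294, outlier_rate >= 0, outlier_rate <= 1,
    duplicate_rate >= 0, duplicate_rate <= 1
  )
  vc <- dplyr::filter(as_tibble(variance_components), .data$trait %in% traits)
  if (!all(traits %in% vc$trait)) abort("`variance_components` must cover all `traits`.")
  sc <- list(
    n_founder_males = n_founder_males, n_founder_females = n_founder_females,
    n_generations = n_generations, n_males_per_gen = n_males_per_gen,
    n_females_per_gen = n_females_per_gen, n_sires_used = n_sires_used,
    n_cows_with_records = n_cows_with_records, records_per_cow = records_per_cow,
    traits = traits, trait_means = trait_means[traits],
    variance_components = vc[match(traits, vc$trait), ],
    rg = rg, rp = rp,
    fixed_effect_profiles = fixed_effect_profiles[traits],
    missingness_rates = missingness_rates,
    outlier_rate = outlier_rate, duplicate_rate = duplicate_rate,
    seed = as.integer(seed)
  )
  structure(sc, class = "sim_scenario")
}

#' Generative variance components
#'
#' Per-trait additive, maternal and permanent-environment variances with the
#' residual derived from the target narrow-sense heritability
#' (`sigma2_e = sigma2_a / h2 - sigma2_a - sigma2_m - sigma2_pe`), so that
#' `h2 = sigma2_a / (sigma2_a + sigma2_m + sigma2_pe + sigma2_e)` holds
#' exactly for the generative values.
#'
#' @param h2 Named vector of target heritabilities per trait.
#' @return Tibble with columns `trait`, `sigma2_a`, `sigma2_m`, `sigma2_pe`,
#'   `sigma2_e`, `h2`.
#' @export
default_variance_components <- function(h2 = c(DMY = 0.382, FP = 0.292, PP = 0.360)) {
  base <- tibble(
    trait = c("DMY", "FP", "PP"),
    sigma2_a = c(0.449, 0.165, 0.068),
    sigma2_m = c(0.031, 0.008, 0.003),
    sigma2_pe = c(0.288, 0.092, 0.038)
  )
  base$h2 <- unname(h2[base$trait])
  base$sigma2_e <- with(base, sigma2_a / h2 - sigma2_a - sigma2_m - sigma2_pe)
  if (any(base$sigma2_e <= 0)) abort("Derived residual variance must be positive.")
  base[, c("trait", "sigma2_a", "sigma2_m", "sigma2_pe", "sigma2_e", "h2")]
}

#' Default fixed-effect profiles for the generator
#'
#' Level offsets (trait units) for parity 1--5+, the four seasons, the three
#' lactation stages, and the six mature-body-weight classes. The shapes
#' follow the qualitative patterns of the system being emulated: yield rises
#' to a parity-4 peak and then declines, winter is the best and summer the
#' worst season, the lactation curve is an inverted U peaking in
#' mid-lactation, and yield increases with body weight up to 650--700 kg.
#' Milk-composition effects are an order of magnitude smaller and move
#' opposite to yield in summer. Magnitudes are package choices (the emulated
#' tables are data-dependent); profiles are centred before use so they do
#' not shift the grand mean.
#'
#' @return Named list per trait of named lists of level offsets.
#' @export
default_fixed_effect_profiles <- function() {
  list(
    DMY = list(
      parity = c(`1` = 0, `2` = 2.5, `3` = 4.2, `4` = 5.0, `5+` = 3.2),
      season = c(spring = 1.0, summer = -1.5, fall = 0.6, winter = 1.8),
      dim_stage = c(early = 0, mid = 1.2, late = -0.8),
      bw_class = c(-2.5, -1.0, 0, 1.0, 1.6, 1.2)
    ),
    FP = list(
      parity = c(`1` = 0.06, `2` = 0.10, `3` = -0.08, `4` = -0.05, `5+` = 0.11),
      season = c(spring = 0.02, summer = -0.08, fall = -0.03, winter = 0.09),
      dim_stage = c(early = 0, mid = -0.05, late = 0.06),
      bw_class = c(0.10, 0.07, 0.04, 0, -0.04, -0.08)
    ),
    PP = list(
      parity = c(`1` = 0.03, `2` = 0.02, `3` = -0.02, `4` = -0.01, `5+` = 0.02),
      season = c(spring = 0.01, summer = -0.05, fall = 0.05, winter = 0.08),
      dim_stage = c(early = 0, mid = -0.03, late = 0.04),
      bw_class = c(0.05, 0.02, 0.01, 0, -0.01, -0.03)
    )
  )
}

# Pairwise correlation vector ("T1:T2" names) -> covariance matrix over traits
.pair_cov_matrix <- function(traits, variances, pair_corr) {
  k <- length(traits)
  M <- diag(variances, k)
  dimnames(M) <- list(traits, traits)
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      key <- paste(traits[i], traits[j], sep = ":")
      key2 <- paste(traits[j], traits[i], sep = ":")
      r <- pair_corr[[key]] %||% pair_corr[[key2]] %||% 0
      M[i, j] <- M[j, i] <- r * sqrt(variances[i] * variances[j])
    }
  }
  M
}

#' Generative covariance matrices of a scenario
#'
#' Expands the per-trait components and pairwise correlations of a
#' [sim_scenario()] into the four cross-trait covariance matrices used by
#' the generator (additive, maternal, permanent environment, residual).
#' The residual covariance is the phenotypic covariance implied by `rp`
#' minus the additive covariance (maternal and pe are cross-trait
#' uncorrelated); an error is raised if any resulting matrix is not
#' positive semidefinite.
#'
#' @param scenario A `sim_scenario`.
#' @return List with matrices `Sigma_a`, `Sigma_m`, `Sigma_pe`, `Sigma_e`.
#' @export
scenario_covariances <- function(scenario) {
  vc <- scenario$variance_components
  tr <- scenario$traits
  Sa <- .pair_cov_matrix(tr, vc$sigma2_a, scenario$rg)
  Sm <- diag(vc$sigma2_m, length(tr)); dimnames(Sm) <- list(tr, tr)
  Sp <- diag(vc$sigma2_pe, length(tr)); dimnames(Sp) <- list(tr, tr)
  ptot <- vc$sigma2_a + vc$sigma2_m + vc$sigma2_pe + vc$sigma2_e
  Ptot <- .pair_cov_matrix(tr, ptot, scenario$rp)
  Se <- Ptot - Sa - Sm - Sp
  diag(Se) <- vc$sigma2_e
  for (nm in c("Sa", "Sm", "Sp", "Se")) {
    ev <- min(eigen(get(nm), symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) abort(paste0("Generative covariance matrix ", nm, " is not PSD."))
  }
  list(Sigma_a = Sa, Sigma_m = Sm, Sigma_pe = Sp, Sigma_e = Se)
}

#' Simulate a discrete-generation pedigree
#'
#' Generation 0 is a set of unrelated founders; each later generation is
#' produced by sampling `n_sires_used` sires and (with replacement) dams
#' from the previous generation. The result is reproducible under `seed`.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed (defaults to `scenario$seed`).
#' @return A [as_pedigree()] object with a `"generation"` attribute (integer
#'   generation per animal, 0 = founder).
#' @export
simulate_pedigree <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed)
  nm0 <- scenario$n_founder_males; nf0 <- scenario$n_founder_females
  animal <- c(sprintf("M0_%04d", seq_len(nm0)), sprintf("F0_%04d", seq_len(nf0)))
  sex <- c(rep("M", nm0), rep("F", nf0))
  sire <- dam <- rep(NA_character_, nm0 + nf0)
  gen <- rep(0L, nm0 + nf0)
  prev_m <- animal[sex == "M"]; prev_f <- animal[sex == "F"]
  if (scenario$n_generations > 1) {
    for (g in seq_len(scenario$n_generations - 1)) {
      n_off <- scenario$n_males_per_gen + scenario$n_females_per_gen
      if (length(prev_m) < 1 || length(prev_f) < 1) {
        abort("Impossible mating constraints: a generation has no available sires or dams.")
      }
      sires <- sample(prev_m, min(scenario$n_sires_used, length(prev_m)))
      osex <- sample(rep(c("M", "F"), c(scenario$n_males_per_gen, scenario$n_females_per_gen)))
      off <- sprintf("%s%d_%04d", osex, g, seq_len(n_off))
      animal <- c(animal, off)
      sire <- c(sire, sample(sires, n_off, replace = TRUE))
      # each dam is used for at most a few matings per generation
      dam_pool <- rep(prev_f, length.out = max(n_off, length(prev_f)))
      dam <- c(dam, sample(dam_pool, n_off, replace = FALSE))
      sex <- c(sex, osex)
      gen <- c(gen, rep(g, n_off))
      prev_m <- off[osex == "M"]; prev_f <- off[osex == "F"]
    }
  }
  ped <- as_pedigree(tibble(
    animal = animal, sire = sire, dam = dam, sex = sex,
    birth_year = 2015L + gen
  ))
  attr(ped, "generation") <- setNames(gen, animal)[ped$animal]
  ped
}

#' Pedigree depth per animal
#'
#' Depth 1 for founders, otherwise 1 + the maximum parental depth (i.e. the
#' number of generations on the longest ancestral path).
#'
#' @param ped A `pedigree`.
#' @return Integer vector in pedigree order, named by animal.
#' @export
pedigree_depth <- function(ped) {
  assert_pedigree(ped)
  n <- nrow(ped)
  depth <- integer(n)
  for (i in seq_len(n)) {
    ps <- ped$sire_idx[i]; pd <- ped$dam_idx[i]
    depth[i] <- 1L + max(if (ps > 0L) depth[ps] else 0L, if (pd > 0L) depth[pd] else 0L)
  }
  setNames(depth, ped$animal)
}

#' Gene-drop correlated breeding values down a pedigree
#'
#' Founders draw from N(0, Sigma); each descendant receives the parental
#' average plus a Mendelian-sampling deviation with covariance
#' \eqn{(0.5 - 0.25 (F_s + F_d))\Sigma} (the unknown-parent cases use 0.75
#' or 1 in place of the bracket). Marginally every animal's vector is
#' N(0, Sigma) scaled by its own diagonal of the relationship matrix, and
#' jointly the values have covariance \eqn{A \otimes \Sigma}.
#'
#' @param ped A `pedigree`.
#' @param Sigma Trait covariance matrix (PSD), possibly 1x1.
#' @param seed Optional integer seed.
#' @return Numeric matrix, animals (pedigree order) x traits.
#' @export
simulate_breeding_values <- function(ped, Sigma, seed = NULL) {
  assert_pedigree(ped)
  if (!is.null(seed)) set.seed(seed)
  Sigma <- as.matrix(Sigma)
  k <- nrow(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < -1e-8) abort("`Sigma` must be positive semidefinite.")
  Lh <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) # Sigma^(1/2)
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  f <- .inbreeding_vec(s, d)
  bv <- matrix(0, n, k, dimnames = list(ped$animal, colnames(Sigma)))
  noise <- matrix(rnorm(n * k), n, k) %*% t(Lh)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (si > 0L && di > 0L) {
      msv <- 0.5 - 0.25 * (f[si] + f[di])
      bv[i, ] <- 0.5 * (bv[si, ] + bv[di, ]) + sqrt(msv) * noise[i, ]
    } else if (si > 0L || di > 0L) {
      p <- max(si, di)
      msv <- 0.75 - 0.25 * f[p]
      bv[i, ] <- 0.5 * bv[p, ] + sqrt(msv) * noise[i, ]
    } else {
      bv[i, ] <- noise[i, ]
    }
  }
  bv
}

# Level frequencies implied by the generator's sampling scheme, used to
# centre effect profiles so they do not displace the grand mean.
.parity_probs <- c(`1` = 230, `2` = 1188, `3` = 1256, `4` = 212, `5+` = 106) / 2992
.season_probs <- c(spring = 92, summer = 92, fall = 91, winter = 90) / 365
.stage_probs <- c(early = 86, mid = 100, late = 108) / 294
.bw_breaks <- c(-Inf, 500, 550, 600, 650, 700, Inf)
.bw_labels <- c("<=500", "500-550", "550-600", "600-650", "650-700", ">700")

.bw_class_probs <- function(mean = 575, sd = 45, lo = 450, hi = 780) {
  p <- stats::pnorm(c(.bw_breaks[-1][-6], hi), mean, sd) - stats::pnorm(c(lo, .bw_breaks[2:6]), mean, sd)
  p <- pmax(p, 0)
  setNames(p / sum(p), .bw_labels)
}

.centre_profile <- function(profile, probs) {
  profile <- unname(profile)
  profile - sum(profile * probs)
}

#' Simulate multi-trait test-day records under the repeatability animal model
#'
#' Generates phenotypes as
#' `mean + parity + season + stage + bw + a(cow) + m(dam) + pe(cow) + e(record)`
#' per trait, with additive and maternal values gene-dropped over the
#' pedigree, permanent-environment values per cow, and residuals per record.
#' DIM is sampled over lactation weeks 3--44 (days 15--308); the daily milk
#' yield is decomposed into three shift yields that sum to it exactly.
#' Optionally injects missing values, impossible outliers, and duplicate
#' rows so the cleaning protocol can be tested with known ground truth.
#'
#' @param ped Pedigree from [simulate_pedigree()] (any pedigree works; cows
#'   are sampled from non-founder females, falling back to all females).
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed (defaults to `scenario$seed`).
#' @return List with `records` (tibble of test-day records) and `truth`
#'   (generative values: breeding values, maternal values, pe values,
#'   covariance matrices, centred effect profiles, injected-defect ids).
#' @export
simulate_records <- function(ped, scenario, seed = scenario$seed) {
  assert_pedigree(ped)
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(seed)
  traits <- scenario$traits
  k <- length(traits)
  covs <- scenario_covariances(scenario)

  females <- which(ped$sex == "F")
  eligible <- females[ped$sire_idx[females] > 0L | ped$dam_idx[females] > 0L]
  if (length(eligible) < scenario$n_cows_with_records) eligible <- females
  if (length(eligible) < scenario$n_cows_with_records) {
    abort("Pedigree has fewer females than `n_cows_with_records`.")
  }
  cows <- sort(sample(eligible, scenario$n_cows_with_records))
  n_cows <- length(cows)
  rpc <- scenario$records_per_cow
  n_rec <- n_cows * rpc

  a <- simulate_breeding_values(ped, covs$Sigma_a)
  m <- simulate_breeding_values(ped, covs$Sigma_m)
  colnames(a) <- colnames(m) <- traits
  pe <- matrix(rnorm(n_cows * k), n_cows, k) %*% chol(covs$Sigma_pe + diag(1e-12, k))
  e <- matrix(rnorm(n_rec * k), n_rec, k) %*% chol(covs$Sigma_e + diag(1e-12, k))
  colnames(pe) <- colnames(e) <- traits

  # per-cow attributes
  parity <- sample(names(.parity_probs), n_cows, replace = TRUE, prob = .parity_probs)
  bw <- rnorm(n_cows, 575, 45)
  bw <- pmin(pmax(bw, 450), 780)
  bw_class <- cut(bw, .bw_breaks, labels = .bw_labels)
  calving <- as.Date("2022-01-01") + sample.int(730, n_cows, replace = TRUE) - 1L

  dim_days <- unlist(lapply(seq_len(n_cows), function(i) sort(sample(15:308, rpc))))
  rec_cow <- rep(seq_len(n_cows), each = rpc)
  test_date <- calving[rec_cow] + dim_days
  season <- season_from_month(as.integer(format(test_date, "%m")))
  stage <- dim_stage(dim_days)

  profiles <- lapply(scenario$fixed_effect_profiles, function(pr) list(
    parity = .centre_profile(pr$parity, .parity_probs),
    season = .centre_profile(pr$season, .season_probs),
    dim_stage = .centre_profile(pr$dim_stage, .stage_probs),
    bw_class = .centre_profile(pr$bw_class, .bw_class_probs())
  ))

  cow_idx_in_ped <- cows
  dam_idx <- ped$dam_idx[cow_idx_in_ped]
  has_dam <- dam_idx > 0L
  Y <- matrix(NA_real_, n_rec, k, dimnames = list(NULL, traits))
  for (t in seq_len(k)) {
    pr <- profiles[[traits[t]]]
    fx <- pr$parity[match(parity[rec_cow], names(.parity_probs))] +
      pr$season[match(season, names(.season_probs))] +
      pr$dim_stage[match(stage, names(.stage_probs))] +
      pr$bw_class[as.integer(bw_class[rec_cow])]
    mval <- ifelse(has_dam[rec_cow], m[pmax(dam_idx[rec_cow], 1L), t], 0)
    Y[, t] <- scenario$trait_means[[traits[t]]] + fx +
      a[cow_idx_in_ped[rec_cow], t] + mval + pe[rec_cow, t] + e[, t]
  }

  rec <- tibble(
    record_id = sprintf("r%06d", seq_len(n_rec)),
    ear_tag = ped$animal[cow_idx_in_ped][rec_cow],
    test_date = test_date,
    parity = as.integer(sub("\\+", "", parity[rec_cow])),
    season = season,
    dim = dim_days,
    bw_kg = round(bw[rec_cow], 1)
  )
  if ("DMY" %in% traits) {
    rec$dmy_kg <- round(Y[, "DMY"], 2)
    # shift decomposition: noisy proportions around the herd's shift pattern,
    # rescaled so the three shifts sum exactly to the (rounded) daily yield
    base <- c(9.4, 9.6, 9.5) / 28.5
    props <- matrix(stats::rgamma(n_rec * 3, shape = rep(base * 300, each = n_rec)), n_rec, 3)
    props <- props / rowSums(props)
    sh <- round(props[, 1:2] * rec$dmy_kg, 2)
    rec$my_morn_kg <- sh[, 1]
    rec$my_noon_kg <- sh[, 2]
    rec$my_night_kg <- round(rec$dmy_kg - sh[, 1] - sh[, 2], 2)
  }
  if ("FP" %in% traits) rec$fat_pct <- round(Y[, "FP"], 3)
  if ("PP" %in% traits) rec$protein_pct <- round(Y[, "PP"], 3)
  rec$flags <- ""

  truth <- list(
    scenario = scenario,
    cows = ped$animal[cow_idx_in_ped],
    breeding_values = a, maternal_values = m,
    pe_values = `rownames<-`(pe, ped$animal[cow_idx_in_ped]),
    covariances = covs,
    profiles = profiles,
    injected = list(outliers = character(0), duplicates = character(0),
                    missing = tibble(record_id = character(0), column = character(0)))
  )

  # --- defect injection (for QC testing) ---
  if (scenario$outlier_rate > 0 && "DMY" %in% traits) {
    n_out <- ceiling(scenario$outlier_rate * nrow(rec))
    idx <- sample.int(nrow(rec), n_out)
    hi <- runif(n_out) < 0.8
    rec$dmy_kg[idx] <- ifelse(hi, round(runif(n_out, 61, 80), 2), round(runif(n_out, 0.1, 1.9), 2))
    truth$injected$outliers <- rec$record_id[idx]
  }
  if (!is.null(scenario$missingness_rates)) {
    for (col in names(scenario$missingness_rates)) {
      if (!col %in% names(rec)) next
      r <- scenario$missingness_rates[[col]]
      if (r <= 0) next
      idx <- which(runif(nrow(rec)) < r)
      rec[[col]][idx] <- NA
      truth$injected$missing <- dplyr::bind_rows(
        truth$injected$missing, tibble(record_id = rec$record_id[idx], column = col)
      )
    }
  }
  if (scenario$duplicate_rate > 0) {
    n_dup <- ceiling(scenario$duplicate_rate * nrow(rec))
    idx <- sample.int(nrow(rec), n_dup)
    dup <- rec[idx, ]
    dup$record_id <- paste0(dup$record_id, "_dup")
    truth$injected$duplicates <- dup$record_id
    rec <- dplyr::bind_rows(rec, dup)
  }

  list(records = rec, truth = truth)
}
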