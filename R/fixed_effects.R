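#' Least-squares means of non-genetic factors
#'
#' Fits an additive ordinary-least-squares model of one trait on the
#' supplied factors (by default parity class, season, lactation stage and
#' mature-body-weight class), and reports per level of each factor the
#' classical (equal-weight) least-squares mean with its model SE, together
#' with a compact letter display from Bonferroni-adjusted pairwise
#' comparisons within the factor: levels sharing no capital letter differ
#' at the adjusted `alpha`.
#'
#' @param records Cleaned test-day records (factor columns are added with
#'   [add_model_factors()] if absent).
#' @param trait Trait code (`DMY`, `FP`, `PP`, or a shift yield).
#' @param factors Character vector of factor column names.
#' @param alpha Significance level for the letter display.
#' @param drop_empty Drop factor levels with no observations instead of
#'   raising an error (the pipeline uses this for sparsely populated
#'   body-weight classes).
#' @return A tibble of class `lsm_table`: `factor`, `level`, `n`, `trait`,
#'   `lsm`, `se`, `letters`.
#' @export
fit_lsm <- function(records, trait = "DMY",
                    factors = c("parity_class", "season", "dim_stage", "bw_class"),
                    alpha = 0.05, drop_empty = FALSE) {
  col <- trait_column(trait)
  if (!all(factors %in% names(records))) records <- add_model_factors(records)
  dat <- records[!is.na(records[[col]]), c(col, factors)]
  dat <- dat[stats::complete.cases(dat), ]
  for (f in factors) {
    dat[[f]] <- factor(dat[[f]])
    counts <- table(records[[f]])
    empty <- names(counts)[counts == 0]
    if (length(empty) && !drop_empty) {
      abort(sprintf("Factor `%s` has empty level(s): %s", f, paste(empty, collapse = ", ")))
    }
    dat[[f]] <- droplevels(dat[[f]])
  }
  form <- as.formula(paste0("`", col, "` ~ ", paste(factors, collapse = " + ")))
  fit <- lm(form, data = dat)
  if (anyNA(coef(fit))) {
    abort("Model is rank deficient beyond standard factor aliasing; check the design.")
  }
  out <- purrr::map_dfr(factors, function(f) {
    emm <- emmeans::emmeans(fit, specs = f, weights = "equal")
    es <- as.data.frame(emm)
    prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "bonferroni"))
    lev <- as.character(es[[1]])
    P <- matrix(1, length(lev), length(lev), dimnames = list(lev, lev))
    for (r in seq_len(nrow(prs))) {
      pair <- strsplit(prs$contrast[r], " - ", fixed = TRUE)[[1]]
      pair <- gsub("^\\(|\\)$", "", pair)
      P[pair[1], pair[2]] <- P[pair[2], pair[1]] <- prs$p.value[r]
    }
    letters <- letter_display(P, alpha = alpha, means = setNames(es$emmean, lev))
    tibble(
      factor = f, level = lev,
      n = as.integer(table(dat[[f]])[lev]), trait = trait,
      lsm = es$emmean, se = es$SE, letters = unname(letters[lev])
    )
  })
  class(out) <- c("lsm_table", class(out))
  out
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: starting from a single group holding all
#' levels, every significant pair splits the groups containing both
#' members, and groups that become subsets of others are absorbed. Capital
#' letters are assigned to the surviving groups in order of the highest
#' mean they contain, so the display is deterministic and invariant to the
#' input order of levels.
#'
#' @param p Symmetric matrix of (adjusted) pairwise p-values with level
#'   dimnames.
#' @param alpha Significance level.
#' @param means Optional named vector of level means used to order the
#'   letters (defaults to the row order of `p`).
#' @return Named character vector of letter groups per level.
#' @export
letter_display <- function(p, alpha = 0.05, means = NULL) {
  lev <- rownames(p) %||% as.character(seq_len(nrow(p)))
  rank_of <- if (is.null(means)) {
    setNames(seq_along(lev), lev)
  } else {
    setNames(rank(-means[lev], ties.method = "first"), lev)
  }
  groups <- list(lev)
  for (i in seq_len(nrow(p) - 1)) {
    for (j in seq((i + 1), nrow(p))) {
      if (is.na(p[i, j]) || p[i, j] >= alpha) next
      a <- lev[i]; b <- lev[j]
      new_groups <- list()
      for (g in groups) {
        if (a %in% g && b %in% g) {
          new_groups <- c(new_groups, list(setdiff(g, a)), list(setdiff(g, b)))
        } else {
          new_groups <- c(new_groups, list(g))
        }
      }
      # absorb groups contained in another
      keep <- rep(TRUE, length(new_groups))
      for (u in seq_along(new_groups)) {
        for (v in seq_along(new_groups)) {
          if (u != v && keep[u] &&
              all(new_groups[[u]] %in% new_groups[[v]]) &&
              (length(new_groups[[u]]) < length(new_groups[[v]]) || u > v)) {
            keep[u] <- FALSE
          }
        }
      }
      groups <- new_groups[keep]
    }
  }
  # order groups by the best-ranked (largest-mean) member
  best <- vapply(groups, function(g) min(rank_of[g]), numeric(1))
  groups <- groups[order(best)]
  out <- setNames(rep("", length(lev)), lev)
  for (k in seq_along(groups)) {
    out[groups[[k]]] <- paste0(out[groups[[k]]], LETTERS[k])
  }
  # present letters sorted within each level for readability
  vapply(out, function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""), character(1))
}

#' F-tests of the non-genetic factors
#'
#' Sequential ANOVA F-tests of each factor in the additive fixed-effect
#' model for one trait.
#'
#' @inheritParams fit_lsm
#' @return Tibble `term`, `df`, `statistic`, `p_value`.
#' @export
fixed_effect_anova <- function(records, trait = "DMY",
                               factors = c("parity_class", "season", "dim_stage", "bw_class")) {
  col <- trait_column(trait)
  if (!all(factors %in% names(records))) records <- add_model_factors(records)
  dat <- records[, c(col, factors)]
  dat <- droplevels(dat[stats::complete.cases(dat), ])
  form <- as.formula(paste0("`", col, "` ~ ", paste(factors, collapse = " + ")))
  an <- anova(lm(form, data = dat))
  tibble(
    term = rownames(an)[seq_along(factors)],
    df = an$Df[seq_along(factors)],
    statistic = an$`F value`[seq_along(factors)],
    p_value = an$`Pr(>F)`[seq_along(factors)]
  )
}

#' Variance inflation factors
#'
#' For each column of the covariate design (factors are expanded to
#' dummies), `VIF = 1/(1 - R^2)` from regressing that column on all the
#' others plus an intercept. Perfectly collinear columns yield `Inf` with
#' a warning rather than an error.
#'
#' @param design Data frame or numeric matrix of covariates (at least two
#'   columns after expansion); no intercept column.
#' @return List with `vif` (tibble `covariate`, `vif`) and `warnings`.
#' @export
compute_vif <- function(design) {
  if (is.data.frame(design)) {
    # factors expand to k-1 treatment dummies (the intercept is implicit in
    # every per-column regression)
    design <- model.matrix(~ ., data = as.data.frame(design))[, -1, drop = FALSE]
  }
  design <- as.matrix(design)
  if (ncol(design) < 2) abort("At least two covariate columns are required.")
  warnings <- character(0)
  vifs <- vapply(seq_len(ncol(design)), function(j) {
    yj <- design[, j]
    Xo <- cbind(1, design[, -j, drop = FALSE])
    fit <- stats::lm.fit(Xo, yj)
    rss <- sum(fit$residuals^2)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(NA_real_)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else max(1 / (1 - r2), 1)
  }, numeric(1))
  nm <- colnames(design) %||% paste0("x", seq_len(ncol(design)))
  if (any(is.infinite(vifs))) {
    warnings <- sprintf("Perfect collinearity: %s", paste(nm[is.infinite(vifs)], collapse = ", "))
    warn(warnings)
  }
  list(vif = tibble(covariate = nm, vif = vifs), warnings = warnings)
}

#' Predict mid-lactation yield from early-lactation records
#'
#' Per cow, averages daily milk yield, shift yields and milk composition
#' over early lactation (DIM <= 100 d) and regresses the cow's mean
#' mid-lactation DMY (101--200 d) on them by OLS. All variables are
#' standardized, so coefficients are comparable effect sizes.
#'
#' @param records Cleaned test-day records.
#' @return List with `coefficients` (tibble `term`, `estimate`, `se`,
#'   `p_value`; standardized scale), `r_squared`, and `n` (cows used).
#' @export
predict_mid_from_early <- function(records) {
  records <- as_tibble(records)
  pred_cols <- intersect(c("dmy_kg", "my_morn_kg", "my_noon_kg", "my_night_kg",
                           "fat_pct", "protein_pct"), names(records))
  early <- records[!is.na(records$dim) & records$dim <= 100, ]
  mid <- records[!is.na(records$dim) & records$dim >= 101 & records$dim <= 200, ]
  e_means <- dplyr::summarise(dplyr::group_by(early, .data$ear_tag),
                              dplyr::across(dplyr::all_of(pred_cols), ~ mean(.x, na.rm = TRUE)),
                              .groups = "drop")
  m_means <- dplyr::summarise(dplyr::group_by(mid, .data$ear_tag),
                              mid_dmy = mean(.data$dmy_kg, na.rm = TRUE), .groups = "drop")
  dat <- dplyr::inner_join(e_means, m_means, by = "ear_tag")
  dat <- dat[stats::complete.cases(dat), ]
  if (nrow(dat) < length(pred_cols) + 2) {
    abort("Too few cows with both early- and mid-lactation records.")
  }
  Z <- as.data.frame(scale(dat[, c(pred_cols, "mid_dmy")]))
  names(Z) <- c(paste0("early_", pred_cols), "mid_dmy")
  fit <- lm(mid_dmy ~ . - 1, data = Z)
  sm <- summary(fit)
  list(
    coefficients = tibble(
      term = rownames(sm$coefficients),
      estimate = sm$coefficients[, 1], se = sm$coefficients[, 2],
      p_value = sm$coefficients[, 4]
    ),
    r_squared = 1 - sum(resid(fit)^2) / sum(Z$mid_dmy^2),
    n = nrow(dat)
  )
}
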