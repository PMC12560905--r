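#' Narrow-sense heritability
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_m + sigma2_pe + sigma2_e)`: the
#' denominator is the full phenotypic variance of the model, including the
#' maternal component. For a fitted model the SE is obtained by the delta
#' method on the inverse average-information matrix.
#'
#' @param x A `lactaqg_reml` fit, or a tibble with columns `trait`,
#'   `sigma2_a`, `sigma2_m`, `sigma2_pe`, `sigma2_e`.
#' @return Tibble `trait`, `h2`, `h2_se` (SE is `NA` without a fit).
#' @export
heritability <- function(x) {
  if (inherits(x, "lactaqg_reml")) {
    vc <- x$vc
    out <- heritability(vc)
    if (!is.null(x$ai_inv)) {
      out$h2_se <- vapply(seq_len(nrow(vc)), function(t) {
        .delta_se_h2(x, vc$trait[t])
      }, numeric(1))
    }
    return(out)
  }
  vc <- as_tibble(x)
  total <- vc$sigma2_a + vc$sigma2_m + vc$sigma2_pe + vc$sigma2_e
  if (any(total <= 0)) abort("Total variance must be positive.")
  tibble(trait = vc$trait, h2 = vc$sigma2_a / total, h2_se = NA_real_)
}

.delta_se_h2 <- function(fit, trait) {
  nms <- vapply(c("a", "m", "pe", "e"), function(b) .theta_name(b, trait, trait), character(1))
  nms <- nms[nms %in% names(fit$theta)]
  th <- fit$theta[nms]
  a <- th[[.theta_name("a", trait, trait)]]
  T_ <- sum(th)
  g <- setNames(rep(-a / T_^2, length(th)), names(th))
  g[[.theta_name("a", trait, trait)]] <- (T_ - a) / T_^2
  V <- fit$ai_inv[names(th), names(th), drop = FALSE]
  sqrt(max(as.numeric(t(g) %*% V %*% g), 0))
}

#' Repeatability
#'
#' The expected correlation between repeated records of the same cow:
#' `r = (sigma2_a + sigma2_pe) / (sigma2_a + sigma2_m + sigma2_pe +
#' sigma2_e)` (the conventional definition; the maternal component enters
#' the denominator only). Always at least as large as the heritability.
#'
#' @inheritParams heritability
#' @return Tibble `trait`, `repeatability`.
#' @export
repeatability <- function(x) {
  vc <- if (inherits(x, "lactaqg_reml")) x$vc else as_tibble(x)
  total <- vc$sigma2_a + vc$sigma2_m + vc$sigma2_pe + vc$sigma2_e
  if (any(total <= 0)) abort("Total variance must be positive.")
  tibble(trait = vc$trait, repeatability = (vc$sigma2_a + vc$sigma2_pe) / total)
}

#' Genetic and phenotypic correlations from a multi-trait fit
#'
#' `rg(t1, t2) = cov_a(t1, t2) / sqrt(sigma2_a(t1) sigma2_a(t2))`, and the
#' phenotypic correlation analogously on the summed covariance blocks.
#' Pairs where either trait has (numerically) zero additive variance are
#' reported as missing. SEs for `rg` come from the delta method on the
#' average-information matrix.
#'
#' @param fit A multi-trait `lactaqg_reml`.
#' @return Tibble `trait1`, `trait2`, `rg`, `rg_se`, `rp`.
#' @export
genetic_correlations <- function(fit) {
  stopifnot(inherits(fit, "lactaqg_reml"))
  if (fit$k < 2) abort("Genetic correlations require a multi-trait fit.")
  Sa <- as.matrix(fit$Sigma$a)
  P <- Reduce(`+`, lapply(fit$Sigma, as.matrix))
  tr <- fit$traits
  out <- list()
  for (i in seq_len(fit$k - 1)) for (j in seq((i + 1), fit$k)) {
    va1 <- Sa[i, i]; va2 <- Sa[j, j]
    rg <- if (va1 <= 1e-12 || va2 <= 1e-12) NA_real_ else Sa[i, j] / sqrt(va1 * va2)
    rg_se <- NA_real_
    if (!is.na(rg) && !is.null(fit$ai_inv)) {
      nms <- c(.theta_name("a", tr[i], tr[j]), .theta_name("a", tr[i], tr[i]),
               .theta_name("a", tr[j], tr[j]))
      if (all(nms %in% rownames(fit$ai_inv))) {
        cv <- Sa[i, j]
        g <- c(1 / sqrt(va1 * va2),
               -cv / (2 * va1^1.5 * sqrt(va2)),
               -cv / (2 * sqrt(va1) * va2^1.5))
        V <- fit$ai_inv[nms, nms]
        rg_se <- sqrt(max(as.numeric(t(g) %*% V %*% g), 0))
      }
    }
    rp <- P[i, j] / sqrt(P[i, i] * P[j, j])
    out[[length(out) + 1L]] <- tibble(trait1 = tr[i], trait2 = tr[j],
                                      rg = rg, rg_se = rg_se, rp = rp)
  }
  dplyr::bind_rows(out)
}

#' Stage-stratified genetic-parameter estimation
#'
#' Fits the animal model independently within each lactation stage
#' (early <= 100 d, mid 101--200 d, late >= 201 d by default). The
#' lactation-stage factor is dropped from the within-stage fixed model
#' (it is constant inside a stage); empty stages are skipped with a
#' warning.
#'
#' @inheritParams reml_fit
#' @param stages Stage labels to fit (subset of `early`, `mid`, `late`).
#' @return List with `fits` (named list of `lactaqg_reml`) and `parameters`
#'   (tibble: stage, trait, components, h2, h2_se, repeatability).
#' @export
stage_stratified_fit <- function(records, ped, traits = "DMY",
                                 fixed = ~ parity_class + season + bw_class,
                                 random = c("a", "m", "pe"),
                                 stages = c("early", "mid", "late"),
                                 control = reml_control()) {
  records <- add_model_factors(records)
  fits <- list()
  rows <- list()
  for (st in stages) {
    sub <- records[!is.na(records$dim_stage) & records$dim_stage == st, ]
    if (nrow(sub) == 0) {
      warn(paste0("Stage `", st, "` has no records; skipped."))
      next
    }
    fit <- reml_fit(sub, ped, traits = traits, fixed = fixed,
                    random = random, control = control)
    fits[[st]] <- fit
    h <- heritability(fit)
    r <- repeatability(fit)
    rows[[st]] <- dplyr::mutate(
      dplyr::left_join(dplyr::left_join(fit$vc, h, by = "trait"), r, by = "trait"),
      stage = st, .before = 1
    )
  }
  list(fits = fits, parameters = dplyr::bind_rows(rows))
}

# ---------------------------------------------------------------------------
# broom-style methods
# ---------------------------------------------------------------------------

#' Tidy a fitted animal model
#'
#' @param x A `lactaqg_reml`.
#' @param ... Unused.
#' @return Tibble of every estimated (co)variance component with its SE:
#'   `component` (`a`, `m`, `pe`, `e`), `trait1`, `trait2`, `estimate`,
#'   `std_error`.
#' @export
tidy.lactaqg_reml <- function(x, ...) {
  nm <- names(x$theta)
  comp <- sub("^(sigma2|cov)_([ampe]+)\\..*$", "\\2", nm)
  pair <- sub("^(sigma2|cov)_[ampe]+\\.", "", nm)
  t1 <- sub(":.*$", "", pair)
  t2 <- ifelse(grepl(":", pair), sub("^.*:", "", pair), t1)
  tibble(component = comp, trait1 = t1, trait2 = t2,
         estimate = unname(x$theta), std_error = unname(x$theta_se))
}

#' One-row summary of a fitted animal model
#'
#' @inheritParams tidy.lactaqg_reml
#' @return Tibble: `logLik`, `n_records`, `n_animals`, `p_fixed`,
#'   `n_components`, `convergence`, `evaluations`.
#' @method glance lactaqg_reml
#' @export
glance.lactaqg_reml <- function(x, ...) {
  tibble(
    logLik = x$loglik, n_records = x$n_records, n_animals = x$n_animals,
    p_fixed = x$p_fixed, n_components = length(x$theta),
    convergence = x$convergence$code, evaluations = x$convergence$evaluations
  )
}

#' @method print lactaqg_reml
#' @export
print.lactaqg_reml <- function(x, ...) {
  cat(sprintf("<lactaqg_reml> %s animal model: %s\n",
              if (x$k == 1) "single-trait" else sprintf("%d-trait", x$k),
              paste(x$traits, collapse = ", ")))
  cat(sprintf("  records: %d   animals: %d   random: %s   logLik: %.3f\n",
              x$n_records, x$n_animals, paste(x$random, collapse = "+"), x$loglik))
  print(dplyr::left_join(x$vc[, c("trait", "sigma2_a", "sigma2_m", "sigma2_pe", "sigma2_e")],
                         heritability(x), by = "trait"))
  invisible(x)
}
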