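#' Descriptive statistics for a trait
#'
#' Sample summaries matching the conventions of standard dairy trait
#' reports: SD with the n-1 denominator, CV = SD/mean x 100, and moment
#' (biased) skewness \eqn{m_3/m_2^{3/2}} and Pearson (non-excess) kurtosis
#' \eqn{m_4/m_2^2}, for which a normal distribution gives 3.
#'
#' @param values Numeric vector (missing values dropped).
#' @param trait Trait label (`DMY`, `MY-Morn`, `MY-Noon`, `MY-Night`, `FP`,
#'   `PP`).
#' @return One-row tibble: `trait`, `n`, `mean`, `sd`, `cv_pct`, `min`,
#'   `max`, `skewness`, `kurtosis`.
#' @export
summarize_trait <- function(values, trait = "DMY") {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) abort("At least two non-missing values are required.")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) abort("Constant input: skewness and kurtosis are undefined.")
  tibble(
    trait = trait, n = n, mean = m, sd = sd(values),
    cv_pct = if (m > 0) sd(values) / m * 100 else NA_real_,
    min = min(values), max = max(values),
    skewness = mean((values - m)^3) / m2^1.5,
    kurtosis = mean((values - m)^4) / m2^2
  )
}

#' Descriptive summary of all recorded traits
#'
#' Applies [summarize_trait()] to every milk trait present in the records
#' (daily and shift yields in kg, fat and protein in %).
#'
#' @param records Test-day records.
#' @return Tibble with one row per trait.
#' @export
summarize_traits <- function(records) {
  present <- .trait_columns[unname(.trait_columns) %in% names(records)]
  purrr::map_dfr(names(present), function(tr) {
    v <- records[[present[[tr]]]]
    if (sum(!is.na(v)) < 2) return(NULL)
    summarize_trait(v, tr)
  })
}

#' Skewness screen for approximate normality
#'
#' Flags traits whose absolute moment skewness exceeds a threshold
#' (default 0.5) as candidates for a power transform before linear-model
#' analysis; mild skew below the threshold is tolerated, mixed models being
#' robust to small departures from normality.
#'
#' @param summary A row (or rows) from [summarize_trait()]/[summarize_traits()].
#' @param threshold Absolute-skewness cut-off.
#' @return Tibble `trait`, `skewness`, `transform_recommended`, `message`.
#' @export
normality_screen <- function(summary, threshold = 0.5) {
  summary <- as_tibble(summary)
  flag <- abs(summary$skewness) > threshold
  tibble(
    trait = summary$trait, skewness = summary$skewness,
    transform_recommended = flag,
    message = ifelse(
      flag,
      sprintf("|skewness| = %.2f exceeds %.2f: transform recommended", abs(summary$skewness), threshold),
      sprintf("|skewness| = %.2f within %.2f: no transform needed", abs(summary$skewness), threshold)
    )
  )
}

#' Box-Cox power transform by profile likelihood
#'
#' Selects the power lambda on a grid by maximizing the profile
#' log-likelihood of the transformed sample under a normal model,
#' \eqn{-n/2 \log \hat\sigma^2_\lambda + (\lambda - 1)\sum \log y}, and
#' returns the transformed values \eqn{(y^\lambda - 1)/\lambda}
#' (\eqn{\log y} at \eqn{\lambda = 0}).
#'
#' @param values Positive numeric vector.
#' @param lambda_grid Candidate powers.
#' @return List with `lambda` (best power), `transformed` (vector), and
#'   `profile` (tibble `lambda`, `loglik`).
#' @export
box_cox <- function(values, lambda_grid = seq(-2, 2, by = 0.05)) {
  values <- values[!is.na(values)]
  if (any(values <= 0)) abort("Box-Cox requires strictly positive values.")
  n <- length(values)
  slog <- sum(log(values))
  ll <- vapply(lambda_grid, function(lam) {
    z <- if (abs(lam) < 1e-12) log(values) else (values^lam - 1) / lam
    -n / 2 * log(mean((z - mean(z))^2)) + (lam - 1) * slog
  }, numeric(1))
  best <- lambda_grid[which.max(ll)]
  z <- if (abs(best) < 1e-12) log(values) else (values^best - 1) / best
  list(lambda = best, transformed = z, profile = tibble(lambda = lambda_grid, loglik = ll))
}
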