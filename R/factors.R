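#' Factor codings for the fixed-effect model
#'
#' Level definitions shared by the cleaning protocol, the least-squares
#' means analysis and the animal model:
#' * `season_from_month()`: spring (Mar--May), summer (Jun--Aug),
#'   fall (Sep--Nov), winter (Dec--Feb);
#' * `dim_stage()`: early (DIM <= 100 d), mid (101--200 d), late (>= 201 d);
#' * `parity_class()`: parities 1--4 kept, 5 and above pooled as `"5+"`;
#' * `bw_class()`: six mature-body-weight classes with breaks at
#'   500, 550, 600, 650 and 700 kg.
#'
#' @param month Integer month (1--12); `NA` allowed.
#' @param dim Days in milk.
#' @param parity Positive integer parity.
#' @param bw_kg Mature body weight in kg.
#' @return Character (season) or factor vectors with fixed level sets.
#' @name factor-codings
NULL

#' @rdname factor-codings
#' @export
season_from_month <- function(month) {
  out <- rep(NA_character_, length(month))
  out[month %in% 3:5] <- "spring"
  out[month %in% 6:8] <- "summer"
  out[month %in% 9:11] <- "fall"
  out[month %in% c(12L, 1L, 2L)] <- "winter"
  out
}

.season_levels <- c("spring", "summer", "fall", "winter")
.stage_levels <- c("early", "mid", "late")
.parity_levels <- c("1", "2", "3", "4", "5+")

#' @rdname factor-codings
#' @export
dim_stage <- function(dim) {
  out <- rep(NA_character_, length(dim))
  out[!is.na(dim) & dim <= 100] <- "early"
  out[!is.na(dim) & dim >= 101 & dim <= 200] <- "mid"
  out[!is.na(dim) & dim >= 201] <- "late"
  out
}

#' @rdname factor-codings
#' @export
parity_class <- function(parity) {
  out <- as.character(parity)
  out[!is.na(parity) & parity >= 5] <- "5+"
  factor(out, levels = .parity_levels)
}

#' @rdname factor-codings
#' @export
bw_class <- function(bw_kg) {
  cut(bw_kg, .bw_breaks, labels = .bw_labels)
}

#' Attach model factors to test-day records
#'
#' Adds the factor columns used by [fit_lsm()] and [reml_fit()]:
#' `parity_class`, `season` (as a factor), `dim_stage`, `bw_class`.
#'
#' @param records Test-day record tibble (see [standardize_records()]).
#' @return The records with the four factor columns appended/replaced.
#' @export
add_model_factors <- function(records) {
  records <- as_tibble(records)
  records$parity_class <- parity_class(records$parity)
  records$season <- factor(as.character(records$season), levels = .season_levels)
  records$dim_stage <- factor(dim_stage(records$dim), levels = .stage_levels)
  records$bw_class <- bw_class(records$bw_kg)
  records
}
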