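#' Standardize raw test-day rows
#'
#' Maps raw column names onto the canonical record schema, coerces types,
#' parses test dates (several common formats), derives the season from the
#' test month when it is absent, and fills a missing daily milk yield from
#' the three shift yields (DMY is defined as their sum). Rows whose date
#' string cannot be parsed are flagged `undecipherable_date` for removal at
#' the first cleaning stage; rows where the recorded DMY disagrees with the
#' shift sum by more than 0.1 kg are flagged `shift_sum_mismatch`.
#'
#' @param rows Data frame of raw rows.
#' @param schema Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(ear_tag = "ID", dmy_kg = "milk")`.
#'   Canonical columns: `record_id`, `ear_tag`, `test_date`, `parity`,
#'   `season`, `dmy_kg`, `my_morn_kg`, `my_noon_kg`, `my_night_kg`,
#'   `fat_pct`, `protein_pct`, `bw_kg`, `dim`.
#' @return Tibble of standardized records with a `flags` column
#'   (semicolon-separated audit tags).
#' @export
standardize_records <- function(rows, schema = NULL) {
  rows <- as_tibble(rows)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(rows)) {
        names(rows)[names(rows) == schema[[canon]]] <- canon
      }
    }
  }
  if (!"ear_tag" %in% names(rows)) abort("Mandatory column `ear_tag` is missing (check `schema`).")
  n <- nrow(rows)
  num_cols <- c("parity", "dmy_kg", "my_morn_kg", "my_noon_kg", "my_night_kg",
                "fat_pct", "protein_pct", "bw_kg", "dim")
  out <- tibble(
    record_id = if ("record_id" %in% names(rows)) as.character(rows$record_id) else sprintf("r%06d", seq_len(n)),
    ear_tag = trimws(as.character(rows$ear_tag))
  )
  out$ear_tag[!is.na(out$ear_tag) & out$ear_tag == ""] <- NA_character_
  raw_date <- if ("test_date" %in% names(rows)) rows$test_date else rep(NA, n)
  parsed <- .parse_test_date(raw_date)
  out$test_date <- parsed$date
  for (col in num_cols) {
    out[[col]] <- if (col %in% names(rows)) suppressWarnings(as.numeric(rows[[col]])) else rep(NA_real_, n)
  }
  out$parity <- as.integer(out$parity)
  out$dim <- as.integer(out$dim)
  season <- if ("season" %in% names(rows)) tolower(trimws(as.character(rows$season))) else rep(NA_character_, n)
  season[season %in% c("", "na")] <- NA_character_
  season[season == "autumn"] <- "fall"
  derive <- is.na(season) & !is.na(out$test_date)
  season[derive] <- season_from_month(as.integer(format(out$test_date[derive], "%m")))
  out$season <- season

  shifts_ok <- !is.na(out$my_morn_kg) & !is.na(out$my_noon_kg) & !is.na(out$my_night_kg)
  shift_sum <- out$my_morn_kg + out$my_noon_kg + out$my_night_kg
  fill <- is.na(out$dmy_kg) & shifts_ok
  out$dmy_kg[fill] <- shift_sum[fill]

  flags <- character(n)
  flags <- .add_flag(flags, parsed$undecipherable, "undecipherable_date")
  flags <- .add_flag(flags, shifts_ok & !is.na(out$dmy_kg) & abs(out$dmy_kg - shift_sum) > 0.1,
                     "shift_sum_mismatch")
  out$flags <- flags
  out
}

.parse_test_date <- function(x) {
  if (inherits(x, "Date")) return(list(date = x, undecipherable = rep(FALSE, length(x))))
  s <- trimws(as.character(x))
  s[!is.na(s) & s == ""] <- NA_character_
  d <- as.Date(rep(NA, length(s)))
  for (fmt in c("%Y-%m-%d", "%Y/%m/%d", "%d/%m/%Y", "%m/%d/%Y", "%d-%m-%Y")) {
    todo <- is.na(d) & !is.na(s)
    if (!any(todo)) break
    cand <- as.Date(s[todo], format = fmt)
    # reject silent roll-overs (e.g. "31/02/2023" parsing to March)
    ok <- !is.na(cand) & format(cand, fmt) == s[todo]
    d[todo][ok] <- cand[ok]
  }
  list(date = d, undecipherable = is.na(d) & !is.na(s))
}

.add_flag <- function(flags, which, tag) {
  which <- which & !is.na(which)
  flags[which] <- ifelse(flags[which] == "", tag, paste(flags[which], tag, sep = ";"))
  flags
}

#' Cleaning configuration
#'
#' Thresholds of the tiered cleaning protocol: the fraction of core traits
#' beyond which a record is dropped (default > 30%), the maximum per-column
#' missingness for mean imputation (< 5%), the Z-score and IQR multipliers
#' for outlier flagging, the biologically possible daily-milk-yield range
#' (2--60 kg), and the retained lactation window in weeks (3--44).
#'
#' @param core_missing_max,impute_max,z_threshold,iqr_mult,dmy_range,dim_weeks
#'   See description.
#' @return Named list of thresholds.
#' @export
qc_config <- function(core_missing_max = 0.3, impute_max = 0.05, z_threshold = 3,
                      iqr_mult = 1.5, dmy_range = c(2, 60), dim_weeks = c(3, 44)) {
  stopifnot(core_missing_max > 0, impute_max > 0, z_threshold > 0, iqr_mult > 0,
            length(dmy_range) == 2, dmy_range[1] < dmy_range[2],
            length(dim_weeks) == 2, dim_weeks[1] <= dim_weeks[2])
  list(core_missing_max = core_missing_max, impute_max = impute_max,
       z_threshold = z_threshold, iqr_mult = iqr_mult,
       dmy_range = dmy_range, dim_weeks = dim_weeks)
}

.core_fields <- c("dmy_kg", "my_morn_kg", "my_noon_kg", "my_night_kg",
                  "fat_pct", "protein_pct", "bw_kg")
.analysis_fields <- c("dmy_kg", "fat_pct", "protein_pct")

#' Tiered cleaning of test-day records
#'
#' Applies the seven cleaning stages in fixed order and returns the
#' surviving records together with a per-stage audit report:
#' 1. remove records lacking an ear tag or with an undecipherable date;
#' 2. remove records whose parity or season is missing and cannot be
#'    inferred (season from the test month, parity from a calving table);
#' 3. remove records with more than 30% of the seven core traits missing;
#' 4. deduplicate per ear tag and test date, keeping the most complete
#'    (fewest missing core fields) then earliest-entered record;
#' 5. mean-impute analysis traits (DMY, fat %, protein %) whose column
#'    missingness is below 5%, using parity x season cell means (global
#'    mean as fallback); records still missing an analysis trait are
#'    removed;
#' 6. flag statistical outliers (|Z| > 3 within parity x season cells, or
#'    outside 1.5 x IQR) and delete biologically impossible values
#'    (DMY outside 2--60 kg); extreme-but-possible values are kept with an
#'    `outlier_extreme` flag;
#' 7. restrict days in milk to lactation weeks 3--44 (days 15--308);
#'    records with missing DIM are removed here.
#'
#' Imputation never changes a non-missing value, and re-running the
#' pipeline on its own output removes nothing.
#'
#' @param records Standardized records (see [standardize_records()]).
#' @param ped Optional `pedigree` (used for stage-2 inference context).
#' @param calving_table Optional tibble `ear_tag`, `calving_date` listing
#'   prior calvings, enabling parity inference at stage 2.
#' @param config A [qc_config()].
#' @return List with `records` (cleaned tibble) and `report` (a
#'   `cleaning_report` tibble: stage, records in/removed/out, reason,
#'   cumulative removal %, surviving cows, imputed cell count).
#' @export
clean_records <- function(records, ped = NULL, calving_table = NULL, config = qc_config()) {
  records <- as_tibble(records)
  initial <- nrow(records)
  stages <- list()
  note <- paste(
    "Counts reflect exact arithmetic on the supplied records;",
    "records_out = records_in - records_removed at every stage."
  )
  add_stage <- function(stage, before, after, reason, n_imputed = 0L) {
    stages[[length(stages) + 1L]] <<- tibble(
      stage = stage, records_in = nrow(before),
      records_removed = nrow(before) - nrow(after), reason = reason,
      records_out = nrow(after),
      cumulative_removal_pct = if (initial > 0) (initial - nrow(after)) / initial * 100 else 0,
      cows_out = length(unique(after$ear_tag[!is.na(after$ear_tag)])),
      n_imputed = n_imputed
    )
  }

  if (initial == 0) {
    rep0 <- tibble(stage = character(0), records_in = integer(0),
                   records_removed = integer(0), reason = character(0),
                   records_out = integer(0), cumulative_removal_pct = numeric(0),
                   cows_out = integer(0), n_imputed = integer(0))
    return(list(records = records,
                report = .new_cleaning_report(rep0, initial, note)))
  }

  # Traits absent from the dataset altogether (all-missing columns) are not
  # part of the completeness rules: a single-trait file is a valid input.
  recorded <- function(fields) {
    fields[vapply(fields, function(f) any(!is.na(records[[f]])), logical(1))]
  }
  core_fields <- recorded(.core_fields)
  analysis_fields <- recorded(.analysis_fields)
  if (!length(core_fields)) core_fields <- .core_fields

  # Stage 1 -- key identifiers
  cur <- records
  keep <- !is.na(cur$ear_tag) & !is.na(cur$test_date) &
    !grepl("undecipherable_date", cur$flags)
  nxt <- cur[keep, ]
  add_stage("Remove Missing Records: Key IDs", cur, nxt,
            "Missing ear tag or undecipherable test date")

  # Stage 2 -- parity / season, after inference
  cur <- nxt
  cur <- infer_from_pedigree(cur, ped = ped, calving_table = calving_table)
  nxt <- cur[!is.na(cur$parity) & !is.na(cur$season), ]
  add_stage("Remove Missing Records: Core Vars", cur, nxt,
            "Missing parity/season not inferable")

  # Stage 3 -- high-missingness records
  cur <- nxt
  miss_frac <- rowMeans(is.na(as.matrix(cur[, core_fields])))
  nxt <- cur[miss_frac <= config$core_missing_max, ]
  add_stage("Remove High-Missing Records (>30%)", cur, nxt,
            "Excessive missing core fields")

  # Stage 4 -- duplicates per ear tag + test date
  cur <- nxt
  n_miss <- rowSums(is.na(as.matrix(cur[, core_fields])))
  key <- paste(cur$ear_tag, cur$test_date)
  ord <- order(key, n_miss, seq_len(nrow(cur)))
  keep_idx <- sort(ord[!duplicated(key[ord])])
  nxt <- cur[keep_idx, ]
  add_stage("Remove Duplicate Records", cur, nxt,
            "Duplicate ear tag x test date (most complete kept)")

  # Stage 5 -- mean imputation of analysis traits
  cur <- nxt
  n_imp <- 0L
  for (col in analysis_fields) {
    frac <- mean(is.na(cur[[col]]))
    if (frac > 0 && frac < config$impute_max) {
      cell <- paste(cur$parity, cur$season)
      cell_mean <- ave(cur[[col]], cell, FUN = function(v) mean(v, na.rm = TRUE))
      cell_mean[is.nan(cell_mean)] <- mean(cur[[col]], na.rm = TRUE)
      idx <- is.na(cur[[col]])
      cur[[col]][idx] <- cell_mean[idx]
      cur$flags <- .add_flag(cur$flags, idx, paste0("imputed_", col))
      n_imp <- n_imp + sum(idx)
    }
  }
  nxt <- cur[stats::complete.cases(cur[, analysis_fields, drop = FALSE]), ]
  add_stage("Mean Imputation (Numerical Vars)", cur, nxt,
            "Analysis traits imputed (<5% missing) or record removed", n_imputed = n_imp)

  # Stage 6 -- outliers: flag statistical, delete impossible
  cur <- nxt
  for (col in analysis_fields) {
    v <- cur[[col]]
    cell <- paste(cur$parity, cur$season)
    mu <- ave(v, cell, FUN = function(x) mean(x, na.rm = TRUE))
    sg <- ave(v, cell, FUN = function(x) if (sum(!is.na(x)) >= 10) sd(x, na.rm = TRUE) else NA_real_)
    mu[is.na(sg)] <- mean(v, na.rm = TRUE)
    sg[is.na(sg)] <- sd(v, na.rm = TRUE)
    z <- abs(v - mu) / ifelse(sg > 0, sg, Inf)
    qs <- quantile(v, c(0.25, 0.75), na.rm = TRUE)
    iqr_lo <- qs[1] - config$iqr_mult * diff(qs)
    iqr_hi <- qs[2] + config$iqr_mult * diff(qs)
    is_out <- !is.na(v) & (z > config$z_threshold | v < iqr_lo | v > iqr_hi)
    cur$flags <- .add_flag(cur$flags, is_out & !grepl("outlier_extreme", cur$flags), "outlier_extreme")
  }
  impossible <- !is.na(cur$dmy_kg) &
    (cur$dmy_kg < config$dmy_range[1] | cur$dmy_kg > config$dmy_range[2])
  nxt <- cur[!impossible, ]
  add_stage("Identify and Remove Invalid Outliers", cur, nxt,
            sprintf("DMY outside %g-%g kg (biologically impossible)",
                    config$dmy_range[1], config$dmy_range[2]))

  # Stage 7 -- lactation window
  cur <- nxt
  lo <- (config$dim_weeks[1] - 1) * 7 + 1
  hi <- config$dim_weeks[2] * 7
  nxt <- cur[!is.na(cur$dim) & cur$dim >= lo & cur$dim <= hi, ]
  add_stage(sprintf("Restrict DIM: Lactation Weeks %d-%d", config$dim_weeks[1], config$dim_weeks[2]),
            cur, nxt, sprintf("DIM outside days %d-%d or missing", lo, hi))

  report <- .new_cleaning_report(dplyr::bind_rows(stages), initial, note)
  list(records = nxt, report = report)
}

.new_cleaning_report <- function(df, initial, note) {
  structure(df, class = c("cleaning_report", class(df)),
            initial_records = initial, note = note)
}

#' @method print cleaning_report
#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d initial records\n", attr(x, "initial_records")))
  NextMethod()
  cat("Note:", attr(x, "note"), "\n")
  invisible(x)
}

#' Backfill parity and season of records
#'
#' Season is derived from the test-date month. Parity is inferable only
#' when a calving table is supplied: it is taken as the number of listed
#' prior calvings on or before the test date plus one (no prior calvings
#' on file leaves parity missing). Non-missing values are never changed.
#'
#' @inheritParams clean_records
#' @return The records with `parity`/`season` backfilled where possible.
#' @export
infer_from_pedigree <- function(records, ped = NULL, calving_table = NULL) {
  records <- as_tibble(records)
  idx <- is.na(records$season) & !is.na(records$test_date)
  records$season[idx] <- season_from_month(as.integer(format(records$test_date[idx], "%m")))
  if (!is.null(calving_table) && any(is.na(records$parity))) {
    ct <- as_tibble(calving_table)
    need <- which(is.na(records$parity) & !is.na(records$test_date))
    for (i in need) {
      prior <- sum(ct$ear_tag == records$ear_tag[i] &
                     as.Date(ct$calving_date) <= records$test_date[i], na.rm = TRUE)
      if (prior > 0) records$parity[i] <- prior + 1L
    }
  }
  records
}
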