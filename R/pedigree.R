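#' Pedigree construction and validation
#'
#' `as_pedigree()` turns a data frame of animal/sire/dam triples into a
#' validated, topologically sorted pedigree; `read_pedigree()` reads one from
#' a CSV file. Parents that are referenced but have no row of their own are
#' appended as founders. Unknown parents may be coded as `NA`, the empty
#' string, or `"0"`.
#'
#' The returned object is a tibble of class `"pedigree"` with columns
#' `animal`, `sire`, `dam`, `sex`, `birth_year` plus integer columns
#' `sire_idx` and `dam_idx` (row index of each parent, `0L` = unknown).
#' Rows are ordered so that every parent precedes all of its offspring
#' (Kahn layering with ties broken by input order, so the result is
#' reproducible).
#'
#' @param df Data frame with at least an `animal` column; `sire`, `dam`,
#'   `sex`, `birth_year` are optional.
#' @param path Path to a CSV file.
#' @param dialect Named character vector mapping the canonical column names
#'   (`animal`, `sire`, `dam`, `sex`, `birth_year`) to the names used in the
#'   file, e.g. `c(animal = "ID", sire = "FID", dam = "MID")`.
#' @return A `pedigree` tibble (see Details).
#' @examples
#' ped <- as_pedigree(data.frame(
#'   animal = c("C", "A", "B"), sire = c("A", NA, NA), dam = c("B", NA, NA)
#' ))
#' ped$animal # founders first
#' @export
as_pedigree <- function(df) {
  if (!is.data.frame(df)) abort("`df` must be a data frame.")
  if (!"animal" %in% names(df)) abort("`df` must have an `animal` column.")

  norm_id <- function(x) {
    x <- trimws(as.character(x))
    x[!is.na(x) & (x == "" | x == "0")] <- NA_character_
    x
  }
  animal <- norm_id(df$animal)
  if (anyNA(animal)) abort("`animal` identifiers must be non-empty.")
  if (anyDuplicated(animal)) {
    dup <- unique(animal[duplicated(animal)])
    abort(paste0("Duplicate animal rows: ", paste(utils::head(dup, 10), collapse = ", ")))
  }
  sire <- if ("sire" %in% names(df)) norm_id(df$sire) else rep(NA_character_, length(animal))
  dam  <- if ("dam"  %in% names(df)) norm_id(df$dam)  else rep(NA_character_, length(animal))
  if (any(!is.na(sire) & sire == animal) || any(!is.na(dam) & dam == animal)) {
    abort("An animal cannot be its own parent.")
  }
  sex <- if ("sex" %in% names(df)) as.character(df$sex) else rep(NA_character_, length(animal))
  birth_year <- if ("birth_year" %in% names(df)) {
    suppressWarnings(as.integer(df$birth_year))
  } else {
    rep(NA_integer_, length(animal))
  }

  # Referenced-but-absent parents become founders, appended after the input
  # rows (their relative order follows first mention).
  parents <- unique(c(sire, dam))
  missing_parents <- setdiff(parents[!is.na(parents)], animal)
  if (length(missing_parents)) {
    parent_sex <- ifelse(missing_parents %in% sire, "M", "F")
    animal <- c(animal, missing_parents)
    sire <- c(sire, rep(NA_character_, length(missing_parents)))
    dam <- c(dam, rep(NA_character_, length(missing_parents)))
    sex <- c(sex, parent_sex)
    birth_year <- c(birth_year, rep(NA_integer_, length(missing_parents)))
  }

  n <- length(animal)
  pos <- seq_len(n)
  sidx <- match(sire, animal, nomatch = 0L)
  didx <- match(dam, animal, nomatch = 0L)

  # Kahn layering: repeatedly emit (in input order) all animals whose parents
  # are already placed. No progress with rows remaining implies a cycle.
  placed <- logical(n)
  ord <- integer(0)
  while (length(ord) < n) {
    ready <- !placed & (sidx == 0L | placed[pmax(sidx, 1L)]) &
      (didx == 0L | placed[pmax(didx, 1L)])
    if (!any(ready)) {
      cyc <- .find_pedigree_cycle(which(!placed), sidx, didx, animal)
      abort(paste0("Pedigree contains a cycle: ", paste(cyc, collapse = " -> ")))
    }
    ord <- c(ord, pos[ready])
    placed[ready] <- TRUE
  }

  out <- tibble(
    animal = animal[ord], sire = sire[ord], dam = dam[ord],
    sex = sex[ord], birth_year = birth_year[ord]
  )
  new_pos <- match(seq_len(n), ord)
  out$sire_idx <- ifelse(sidx[ord] == 0L, 0L, new_pos[pmax(sidx[ord], 1L)])
  out$dam_idx <- ifelse(didx[ord] == 0L, 0L, new_pos[pmax(didx[ord], 1L)])
  class(out) <- c("pedigree", class(out))
  out
}

# Walk parent pointers from an unplaced node until a repeat names the cycle.
.find_pedigree_cycle <- function(remaining, sidx, didx, ids) {
  start <- remaining[1]
  seen <- integer(0)
  cur <- start
  while (!cur %in% seen) {
    seen <- c(seen, cur)
    nxt <- c(sidx[cur], didx[cur])
    nxt <- nxt[nxt %in% remaining]
    if (!length(nxt)) break
    cur <- nxt[1]
  }
  ids[c(seen[which(seen == cur):length(seen)], cur)]
}

#' @rdname as_pedigree
#' @export
read_pedigree <- function(path, dialect = NULL) {
  if (!file.exists(path)) abort(paste0("Pedigree file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (dialect[[canon]] %in% names(df)) {
        names(df)[names(df) == dialect[[canon]]] <- canon
      }
    }
  }
  if (!"animal" %in% names(df)) abort("No `animal` column after applying `dialect`.")
  as_pedigree(df)
}

#' @method print pedigree
#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(x$sire_idx == 0L & x$dam_idx == 0L)
  cat(sprintf("<pedigree> %d animals (%d founders)\n", nrow(x), founders))
  NextMethod()
}

is_pedigree <- function(x) inherits(x, "pedigree")

assert_pedigree <- function(ped) {
  if (!is_pedigree(ped)) abort("Expected a `pedigree` object (see `as_pedigree()`).")
  if (any(ped$sire_idx >= seq_len(nrow(ped))) || any(ped$dam_idx >= seq_len(nrow(ped)))) {
    abort("Pedigree is not topologically sorted; rebuild it with `as_pedigree()`.")
  }
  invisible(ped)
}

#' Inbreeding coefficients from a pedigree
#'
#' Computes the inbreeding coefficient F for every animal with the
#' Meuwissen–Luo algorithm: the diagonal of the numerator relationship
#' matrix is accumulated as \eqn{A_{ii} = \sum_j L_{ij}^2 D_j} over the
#' ancestors j of i, without forming A, and \eqn{F_i = A_{ii} - 1}.
#' Unknown parents are treated as unrelated non-inbred founders.
#'
#' @param ped A `pedigree`.
#' @return A tibble with columns `animal` and `f` (inbreeding coefficient,
#'   0 for founders), in pedigree order.
#' @export
inbreeding <- function(ped) {
  assert_pedigree(ped)
  tibble(animal = ped$animal, f = .inbreeding_vec(ped$sire_idx, ped$dam_idx))
}

.inbreeding_vec <- function(s, d) {
  n <- length(s)
  f <- numeric(n)
  dvec <- numeric(n) # Mendelian-sampling variance scale D_i
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    dvec[i] <- if (si > 0L && di > 0L) {
      0.5 - 0.25 * (f[si] + f[di])
    } else if (si > 0L) {
      0.75 - 0.25 * f[si]
    } else if (di > 0L) {
      0.75 - 0.25 * f[di]
    } else 1
    if (si == 0L || di == 0L) next # F = 0 when any parent unknown

    # ancestors of i (including i), then one descending sweep accumulating L
    anc <- i
    frontier <- i
    while (length(frontier)) {
      p <- c(s[frontier], d[frontier])
      p <- unique(p[p > 0L])
      frontier <- setdiff(p, anc)
      anc <- c(anc, frontier)
    }
    anc <- sort(anc, decreasing = TRUE)
    L <- numeric(n)
    L[i] <- 1
    aii <- 0
    for (j in anc) {
      lj <- L[j]
      if (lj == 0) next
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * lj
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * lj
      aii <- aii + lj * lj * dvec[j]
    }
    f[i] <- aii - 1
  }
  f
}

#' Numerator relationship matrix (A)
#'
#' Builds the additive (numerator) relationship matrix by the tabular
#' method: \eqn{A_{ii} = 1 + 0.5 A_{sd}} and
#' \eqn{A_{ij} = 0.5 (A_{j,s} + A_{j,d})} for j preceding i, with unknown
#' parents contributing 0. The matrix is dense; to keep memory bounded the
#' function refuses pedigrees larger than `max_n` animals — for large
#' pedigrees use [build_A_inverse()] (sparse) or [inbreeding()] (diagonal
#' only).
#'
#' @param ped A `pedigree`.
#' @param max_n Hard size guard for the dense matrix (default 2000).
#' @return A dense symmetric matrix with dimnames = animal ids. Diagonal
#'   entries are `1 + F`; founders have diagonal exactly 1.
#' @export
build_A <- function(ped, max_n = 2000L) {
  assert_pedigree(ped)
  n <- nrow(ped)
  if (n > max_n) {
    abort(sprintf(
      "Pedigree has %d animals; dense A is only built for n <= %d. Use build_A_inverse() or inbreeding().",
      n, max_n
    ))
  }
  s <- ped$sire_idx; d <- ped$dam_idx
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (si > 0L) A[j, si] else numeric(i - 1L)
      ad_ <- if (di > 0L) A[j, di] else numeric(i - 1L)
      aij <- 0.5 * (as_ + ad_)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Direct construction of \eqn{A^{-1}} by Henderson's rules with the
#' inbreeding correction of Quaas: for each animal the Mendelian-sampling
#' variance \eqn{D_i} is computed from parental inbreeding coefficients
#' (Meuwissen–Luo), and \eqn{\alpha_i = 1/D_i} contributions are scattered
#' over the animal and its known parents.
#'
#' @param ped A `pedigree`.
#' @return A sparse symmetric matrix (`dsCMatrix`) with dimnames = animal ids.
#' @export
build_A_inverse <- function(ped) {
  assert_pedigree(ped)
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  f <- .inbreeding_vec(s, d)
  fs <- ifelse(s > 0L, f[pmax(s, 1L)], 0)
  fd <- ifelse(d > 0L, f[pmax(d, 1L)], 0)
  dvec <- ifelse(
    s > 0L & d > 0L, 0.5 - 0.25 * (fs + fd),
    ifelse(s > 0L | d > 0L, 0.75 - 0.25 * (fs + fd), 1)
  )
  alpha <- 1 / dvec
  i <- seq_len(n)

  ii <- c(i); jj <- c(i); xx <- c(alpha)                         # (i,i): +a
  ks <- which(s > 0L)
  ii <- c(ii, ks, s[ks]); jj <- c(jj, s[ks], ks)
  xx <- c(xx, -alpha[ks] / 2, -alpha[ks] / 2)                    # (i,s)
  kd <- which(d > 0L)
  ii <- c(ii, kd, d[kd]); jj <- c(jj, d[kd], kd)
  xx <- c(xx, -alpha[kd] / 2, -alpha[kd] / 2)                    # (i,d)
  ii <- c(ii, s[ks]); jj <- c(jj, s[ks]); xx <- c(xx, alpha[ks] / 4)  # (s,s)
  ii <- c(ii, d[kd]); jj <- c(jj, d[kd]); xx <- c(xx, alpha[kd] / 4)  # (d,d)
  kb <- which(s > 0L & d > 0L)
  ii <- c(ii, s[kb], d[kb]); jj <- c(jj, d[kb], s[kb])
  xx <- c(xx, alpha[kb] / 4, alpha[kb] / 4)                      # (s,d)

  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Matrix::drop0(Ainv), uplo = "U")
}

#' Export a relationship matrix as tidy coordinates
#'
#' @param A A (possibly sparse) symmetric relationship matrix with dimnames.
#' @param lower_only Keep only the lower triangle (including the diagonal).
#' @return Tibble with columns `row_id`, `col_id`, `value` (zeros dropped).
#' @export
relationship_coordinates <- function(A, lower_only = TRUE) {
  T <- as(as(A, "generalMatrix"), "TsparseMatrix")
  ids_r <- rownames(T) %||% as.character(seq_len(nrow(T)))
  ids_c <- colnames(T) %||% as.character(seq_len(ncol(T)))
  out <- tibble(
    row_id = ids_r[T@i + 1L], col_id = ids_c[T@j + 1L], value = T@x,
    .i = T@i, .j = T@j
  )
  if (lower_only) out <- dplyr::filter(out, .data$.i >= .data$.j)
  out <- dplyr::filter(out, .data$value != 0)
  dplyr::select(dplyr::arrange(out, .data$.i, .data$.j), -".i", -".j")
}
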