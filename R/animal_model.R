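#' @section The repeatability animal model:
#' Phenotypes are modelled per trait as
#' `y = mu + PARITY + SEASON + DIM stage + BW class + a + m + pe + e`
#' with additive genetic effects `a ~ N(0, A sigma2_a)` (A the numerator
#' relationship matrix), maternal effects `m ~ N(0, A sigma2_m)` indexed by
#' the dam of the record's cow, permanent-environment effects
#' `pe ~ N(0, I sigma2_pe)` shared by all records of one cow, and residuals
#' `e ~ N(0, I sigma2_e)`. In multi-trait form each scalar variance becomes
#' a trait covariance matrix and the random-effect covariances are
#' Kronecker products with A (or I).
#' @name animal-model
#' @keywords internal
NULL

# ---------------------------------------------------------------------------
# Model structure: designs, pedigree links, sparse building blocks
# ---------------------------------------------------------------------------

.reml_structure <- function(records, ped, traits, fixed, random) {
  assert_pedigree(ped)
  random <- match.arg(random, c("a", "m", "pe"), several.ok = TRUE)
  if (!"a" %in% random) abort("The additive genetic effect `a` is always included.")
  traits <- match.arg(traits, names(.trait_columns), several.ok = TRUE)
  cols <- vapply(traits, trait_column, character(1))

  records <- add_model_factors(as_tibble(records))
  fvars <- all.vars(fixed)
  need <- c("ear_tag", cols, fvars)
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(paste0("Records lack columns: ", paste(miss, collapse = ", ")))
  keep <- stats::complete.cases(records[, need])
  records <- droplevels(records[keep, ])
  n <- nrow(records)
  if (n == 0) abort("No complete records to analyse.")

  unknown <- setdiff(unique(records$ear_tag), ped$animal)
  if (length(unknown)) {
    abort(paste0("Record cows absent from pedigree: ",
                 paste(utils::head(unknown, 10), collapse = ", "),
                 if (length(unknown) > 10) " ..."))
  }

  # phantom founder dams for recorded cows with unknown dam (maternal effect)
  if ("m" %in% random) {
    cow_rows <- match(unique(records$ear_tag), ped$animal)
    no_dam <- cow_rows[ped$dam_idx[cow_rows] == 0L]
    if (length(no_dam)) {
      warn(sprintf("%d recorded cow(s) have an unknown dam; phantom dams added for the maternal effect.",
                   length(no_dam)))
      ped_df <- as_tibble(ped)[, c("animal", "sire", "dam", "sex", "birth_year")]
      phantom <- paste0("phantom_dam_", ped$animal[no_dam])
      ped_df$dam[match(ped$animal[no_dam], ped_df$animal)] <- phantom
      ped <- as_pedigree(ped_df)
    }
  }

  X <- model.matrix(fixed, data = records)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)

  n_anim <- nrow(ped)
  cow_idx <- match(records$ear_tag, ped$animal)
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = cow_idx, x = 1, dims = c(n, n_anim))
  terms <- list(a = list(K = "A", q = n_anim, Z = Za))
  if ("m" %in% random) {
    dam_idx <- ped$dam_idx[cow_idx]
    terms$m <- list(K = "A", q = n_anim,
                    Z = Matrix::sparseMatrix(i = seq_len(n), j = dam_idx, x = 1, dims = c(n, n_anim)))
  }
  cow_levels <- sort(unique(cow_idx))
  if ("pe" %in% random) {
    terms$pe <- list(K = "I", q = length(cow_levels),
                     Z = Matrix::sparseMatrix(i = seq_len(n), j = match(cow_idx, cow_levels),
                                              x = 1, dims = c(n, length(cow_levels))))
    rec_per_cow <- n / length(cow_levels)
    if (rec_per_cow < 2) {
      warn(sprintf("Cows average %.2f records: permanent-environment variance is weakly identifiable.",
                   rec_per_cow))
    }
  }
  terms <- terms[intersect(c("a", "m", "pe"), names(terms))]

  Ainv <- build_A_inverse(ped)
  chA <- Matrix::Cholesky(Ainv, LDL = FALSE, perm = TRUE)
  logdetA <- -2 * determinant(chA, logarithm = TRUE, sqrt = TRUE)$modulus[1]

  W <- cbind(Matrix::Matrix(X, sparse = TRUE), do.call(cbind, lapply(terms, `[[`, "Z")))
  WtW <- Matrix::drop0(Matrix::crossprod(W))
  Y <- as.matrix(records[, cols, drop = FALSE])
  colnames(Y) <- traits
  WtY <- as.matrix(Matrix::crossprod(W, Y))
  YtY <- crossprod(Y)

  list(records = records, ped = ped, traits = traits, k = length(traits),
       fixed = fixed, random = names(terms), X = X, p = p, n = n,
       terms = terms, W = W, WtW = WtW, Y = Y, WtY = WtY, YtY = YtY,
       Ainv = Ainv, chA = chA, logdetA = as.numeric(logdetA),
       cow_idx = cow_idx, cow_levels = cow_levels)
}

# Pattern-mapped assembler: C(theta) = sum_c coef_c(theta) * B_c with the
# sparse B_c fixed, so each likelihood evaluation only rewrites the numeric
# slot of one symmetric template and updates the cached Cholesky
# factorization in place.
.make_assembler <- function(S) {
  k <- S$k
  qs <- vapply(S$terms, `[[`, numeric(1), "q")
  dim1 <- S$p + sum(qs)                      # equations per trait
  dimC <- k * dim1
  off_term <- S$p + c(0, cumsum(qs))[seq_along(qs)]
  names(off_term) <- names(S$terms)

  shift <- function(M, r_off, c_off, upper_only) {
    T <- as(as(M, "generalMatrix"), "TsparseMatrix")
    i <- T@i + 1L + r_off; j <- T@j + 1L + c_off; x <- T@x
    if (upper_only) { sel <- i <= j; i <- i[sel]; j <- j[sel]; x <- x[sel] }
    list(i = i, j = j, x = x)
  }

  comps <- list()
  for (t1 in seq_len(k)) for (t2 in t1:k) {
    O1 <- (t1 - 1L) * dim1; O2 <- (t2 - 1L) * dim1
    comps[[length(comps) + 1L]] <-
      c(shift(S$WtW, O1, O2, upper_only = t1 == t2), list(kind = "data", t1 = t1, t2 = t2))
    for (trm in names(S$terms)) {
      K <- if (S$terms[[trm]]$K == "A") S$Ainv else Matrix::Diagonal(S$terms[[trm]]$q)
      comps[[length(comps) + 1L]] <-
        c(shift(K, O1 + off_term[trm], O2 + off_term[trm], upper_only = t1 == t2),
          list(kind = trm, t1 = t1, t2 = t2))
    }
  }

  all_i <- unlist(lapply(comps, `[[`, "i"))
  all_j <- unlist(lapply(comps, `[[`, "j"))
  template <- Matrix::sparseMatrix(i = all_i, j = all_j,
                                   x = rep(1, length(all_i)), dims = c(dimC, dimC))
  template <- as(Matrix::forceSymmetric(template, uplo = "U"), "CsparseMatrix")
  Tt <- as(template, "TsparseMatrix")
  key <- (as.numeric(Tt@j)) * dimC + as.numeric(Tt@i)
  ord <- order(key)
  stopifnot(!is.unsorted(key[ord]))
  lookup <- key[ord]
  for (c_ in seq_along(comps)) {
    ck <- (as.numeric(comps[[c_]]$j) - 1) * dimC + (as.numeric(comps[[c_]]$i) - 1)
    comps[[c_]]$map <- ord[match(ck, lookup)]
    stopifnot(!anyNA(comps[[c_]]$map))
  }
  list(template = template, comps = comps, dim1 = dim1, dimC = dimC,
       off_term = off_term, nx = length(template@x))
}

# Inverses of the k x k covariance blocks; names a/m/pe/e -> matrix
.sigma_inverses <- function(Sig) {
  lapply(Sig, function(M) {
    M <- as.matrix(M)
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) abort("A covariance block is not positive definite.")
    list(inv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
  })
}

# Evaluate MME + restricted log-likelihood at covariance blocks `Sig`
# (named list a/[m]/[pe]/e of k x k matrices). Returns -2*loglik and pieces.
.reml_eval <- function(S, asm, Sig, chol_cache = NULL, want_sol = TRUE) {
  k <- S$k
  inv <- .sigma_inverses(Sig)
  Einv <- inv$e$inv
  xs <- numeric(asm$nx)
  for (cp in asm$comps) {
    coef <- if (cp$kind == "data") Einv[cp$t1, cp$t2] else inv[[cp$kind]]$inv[cp$t1, cp$t2]
    if (coef != 0) xs[cp$map] <- xs[cp$map] + coef * cp$x
  }
  C <- asm$template
  C@x <- xs
  ch <- if (is.null(chol_cache)) {
    Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
  } else {
    Matrix::update(chol_cache, C, mult = 0)
  }
  rhs <- as.vector(S$WtY %*% Einv)              # blocks stacked trait-major
  sol <- as.vector(Matrix::solve(ch, rhs))
  quad <- sum(S$YtY * Einv) - sum(sol * rhs)
  logdetC <- 2 * determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus[1]

  qa <- S$terms$a$q
  logdetG <- qa * inv$a$logdet + k * S$logdetA
  if ("m" %in% S$random) logdetG <- logdetG + S$terms$m$q * inv$m$logdet + k * S$logdetA
  if ("pe" %in% S$random) logdetG <- logdetG + S$terms$pe$q * inv$pe$logdet
  NP <- k * (S$n - S$p)
  m2l <- NP * log(2 * pi) + logdetC + S$n * inv$e$logdet + logdetG + quad
  list(m2l = as.numeric(m2l), quad = as.numeric(quad), sol = if (want_sol) sol else NULL,
       ch = ch, logdetC = as.numeric(logdetC))
}

# Expand a variance-component specification into k x k covariance blocks.
.vc_to_sigmas <- function(vc, traits, random) {
  k <- length(traits)
  if (is.list(vc) && !is.data.frame(vc) && all(c("Sigma_a", "Sigma_e") %in% names(vc))) {
    Sig <- list(a = as.matrix(vc$Sigma_a))
    if ("m" %in% random) Sig$m <- as.matrix(vc$Sigma_m)
    if ("pe" %in% random) Sig$pe <- as.matrix(vc$Sigma_pe)
    Sig$e <- as.matrix(vc$Sigma_e)
    return(Sig)
  }
  vc <- as_tibble(vc)
  vc <- vc[match(traits, vc$trait), ]
  if (anyNA(vc$trait)) abort("`vc` must contain one row per trait.")
  Sig <- list(a = diag(vc$sigma2_a, k))
  if ("m" %in% random) Sig$m <- diag(vc$sigma2_m, k)
  if ("pe" %in% random) Sig$pe <- diag(vc$sigma2_pe, k)
  Sig$e <- diag(vc$sigma2_e, k)
  Sig
}

# ---------------------------------------------------------------------------
# Public: mixed-model equations at fixed variance components
# ---------------------------------------------------------------------------

#' Henderson's mixed-model equations for the animal model
#'
#' Assembles (and solves) the sparse mixed-model equations of the
#' repeatability animal model at the supplied variance components. Mostly
#' useful for inspection and for validating the solver against a dense
#' generalized-least-squares computation on small examples; [reml_fit()]
#' uses the same internals.
#'
#' @param records Cleaned test-day records.
#' @param ped A `pedigree` containing every record cow.
#' @param traits Character vector of trait codes (length 1 for univariate).
#' @param vc Variance components: either a tibble with columns `trait`,
#'   `sigma2_a`, `sigma2_m`, `sigma2_pe`, `sigma2_e`, or a list of
#'   covariance matrices `Sigma_a`, `Sigma_m`, `Sigma_pe`, `Sigma_e`.
#' @param fixed One-sided formula of fixed effects.
#' @param random Random terms to include (`"a"` always on).
#' @return List of class `mme_system`: coefficient matrix `C`, right-hand
#'   side `rhs`, `solution` (named: fixed effects then random-effect levels,
#'   per trait), `loglik` (restricted log-likelihood at `vc`), and the
#'   dimension bookkeeping (`p`, `q`, trait/term offsets).
#' @export
build_mme <- function(records, ped, traits = "DMY", vc,
                      fixed = ~ parity_class + season + dim_stage + bw_class,
                      random = c("a", "m", "pe")) {
  S <- .reml_structure(records, ped, traits, fixed, random)
  asm <- .make_assembler(S)
  Sig <- .vc_to_sigmas(vc, S$traits, S$random)
  ev <- .reml_eval(S, asm, Sig)
  C <- asm$template
  # rebuild the numeric slot for the returned matrix
  inv <- .sigma_inverses(Sig)
  xs <- numeric(asm$nx)
  for (cp in asm$comps) {
    coef <- if (cp$kind == "data") inv$e$inv[cp$t1, cp$t2] else inv[[cp$kind]]$inv[cp$t1, cp$t2]
    xs[cp$map] <- xs[cp$map] + coef * cp$x
  }
  C@x <- xs
  sol_names <- .solution_names(S)
  structure(list(
    C = C, rhs = as.vector(S$WtY %*% inv$e$inv),
    solution = setNames(ev$sol, sol_names),
    loglik = -0.5 * ev$m2l, traits = S$traits, random = S$random,
    p = S$p, q = vapply(S$terms, `[[`, numeric(1), "q"),
    dim_per_trait = asm$dim1, term_offsets = asm$off_term
  ), class = "mme_system")
}

.solution_names <- function(S) {
  base <- c(colnames(S$X),
            unlist(lapply(names(S$terms), function(trm) {
              lv <- if (S$terms[[trm]]$K == "A") S$ped$animal else S$ped$animal[S$cow_levels]
              paste0(trm, ":", lv)
            })))
  as.vector(vapply(S$traits, function(tr) paste0(tr, ":", base), character(length(base))))
}

#' Restricted log-likelihood at given variance components
#'
#' @inheritParams build_mme
#' @return The REML log-likelihood (including its normal constant).
#' @export
reml_loglik <- function(records, ped, traits = "DMY", vc,
                        fixed = ~ parity_class + season + dim_stage + bw_class,
                        random = c("a", "m", "pe")) {
  S <- .reml_structure(records, ped, traits, fixed, random)
  asm <- .make_assembler(S)
  ev <- .reml_eval(S, asm, .vc_to_sigmas(vc, S$traits, S$random), want_sol = FALSE)
  -0.5 * ev$m2l
}

# ---------------------------------------------------------------------------
# REML estimation
# ---------------------------------------------------------------------------

#' Optimizer settings for [reml_fit()]
#'
#' @param maxit Maximum quasi-Newton iterations.
#' @param factr L-BFGS-B convergence factor (relative reduction tolerance
#'   `factr * .Machine$double.eps`).
#' @param ndeps Finite-difference step on the log/Cholesky parameter scale.
#' @param bound Log-scale box half-width: variance ratios are searched in
#'   `exp(c(-bound, bound))`.
#' @param verbose Print optimizer progress.
#' @return Named list of settings.
#' @export
reml_control <- function(maxit = 200L, factr = 1e8, ndeps = 1e-4,
                         bound = 14, verbose = FALSE) {
  list(maxit = maxit, factr = factr, ndeps = ndeps, bound = bound, verbose = verbose)
}

#' REML estimation of the repeatability animal model
#'
#' Estimates the variance components of the animal model by restricted
#' maximum likelihood. The restricted likelihood is evaluated exactly
#' through one sparse Cholesky factorization of the mixed-model equations
#' per evaluation and maximized by quasi-Newton (L-BFGS-B) on an
#' unconstrained parameterization: log variance ratios with the residual
#' variance profiled out in the single-trait case, and Cholesky factors of
#' the four trait covariance matrices in the multi-trait case (which keeps
#' every component matrix positive semidefinite by construction). At the
#' optimum the average-information matrix is assembled from working
#' vectors, and standard errors of the components (and of derived
#' parameters such as heritability) come from its inverse.
#'
#' Multi-trait fits are warm-started from single-trait fits of each trait
#' unless `init` is given.
#'
#' @inheritParams build_mme
#' @param init Optional starting components (same formats as `vc` in
#'   [build_mme()]).
#' @param control A [reml_control()].
#' @return An object of class `lactaqg_reml` with components `vc`
#'   (per-trait tibble of variance components and SEs), `Sigma` (covariance
#'   blocks), `loglik`, `ai` (average-information matrix), `theta` /
#'   `theta_se` (the free components and their SEs), `convergence`, and the
#'   model bookkeeping. Methods: [tidy()], [glance()], [autoplot()],
#'   [heritability()], [repeatability()], [genetic_correlations()].
#' @export
reml_fit <- function(records, ped, traits = "DMY",
                     fixed = ~ parity_class + season + dim_stage + bw_class,
                     random = c("a", "m", "pe"),
                     init = NULL, control = reml_control()) {
  S <- .reml_structure(records, ped, traits, fixed, random)
  if (S$n <= S$p) abort("More fixed-effect parameters than records.")
  asm <- .make_assembler(S)
  if (S$k == 1L) {
    .reml_fit_uni(S, asm, init, control)
  } else {
    .reml_fit_multi(S, asm, init, control, records, ped, fixed)
  }
}

# --- univariate: profile residual variance, optimize log ratios -------------
.reml_fit_uni <- function(S, asm, init, control) {
  terms <- S$random
  gamma0 <- if (!is.null(init)) {
    Sig0 <- .vc_to_sigmas(init, S$traits, S$random)
    vapply(terms, function(trm) Sig0[[trm]][1, 1] / Sig0$e[1, 1], numeric(1))
  } else {
    setNames(c(a = 0.5, m = 0.1, pe = 0.5)[terms], terms)
  }
  cache <- new.env()
  cache$ch <- NULL
  nev <- 0L
  profiled <- function(lg) {
    g <- exp(lg)
    Sig <- setNames(lapply(seq_along(terms), function(i) matrix(g[i])), terms)
    Sig$e <- matrix(1)
    ev <- .reml_eval(S, asm, Sig, chol_cache = cache$ch, want_sol = FALSE)
    if (is.null(cache$ch)) cache$ch <- ev$ch
    nev <<- nev + 1L
    NP <- S$n - S$p
    se2 <- ev$quad / NP
    qa <- S$terms$a$q
    logdetG <- qa * lg[1] + S$logdetA
    if ("m" %in% terms) logdetG <- logdetG + S$terms$m$q * lg[match("m", terms)] + S$logdetA
    if ("pe" %in% terms) logdetG <- logdetG + S$terms$pe$q * lg[match("pe", terms)]
    val <- NP * (log(2 * pi) + 1 + log(se2)) + ev$logdetC + logdetG
    if (control$verbose) cat(sprintf("  -2l=%.6f at gamma=%s\n", val, paste(signif(g, 4), collapse = ",")))
    attr(val, "se2") <- se2
    val
  }
  opt <- optim(log(pmax(gamma0, 1e-4)), function(lg) as.numeric(profiled(lg)),
               method = "L-BFGS-B",
               lower = rep(-control$bound, length(terms)),
               upper = rep(control$bound, length(terms)),
               control = list(maxit = control$maxit, factr = control$factr,
                              ndeps = rep(control$ndeps, length(terms))))
  final <- profiled(opt$par)
  se2 <- attr(final, "se2")
  comps <- c(exp(opt$par) * se2, e = se2)
  names(comps) <- c(terms, "e")
  Sig <- setNames(lapply(comps, function(v) matrix(v, dimnames = list(S$traits, S$traits))),
                  names(comps))
  .finish_fit(S, asm, Sig, opt, evals = nev)
}

# --- multi-trait: Cholesky-parameterized covariance blocks ------------------
.chol_to_par <- function(M) {
  L <- t(chol(as.matrix(M) + diag(1e-10, nrow(M))))
  k <- nrow(L)
  c(log(diag(L)), L[lower.tri(L)])
}

.par_to_sigma <- function(par, k) {
  L <- matrix(0, k, k)
  diag(L) <- exp(par[seq_len(k)])
  L[lower.tri(L)] <- par[-seq_len(k)]
  L %*% t(L)
}

.reml_fit_multi <- function(S, asm, init, control, records, ped, fixed) {
  k <- S$k
  terms <- S$random
  npb <- k * (k + 1) / 2
  if (is.null(init)) {
    # warm start: univariate fit per trait, zero cross covariances
    uni <- lapply(S$traits, function(tr) {
      f <- reml_fit(records, ped, traits = tr, fixed = fixed, random = S$random,
                    control = reml_control(maxit = control$maxit, factr = control$factr * 100))
      f$vc
    })
    Sig0 <- list()
    for (trm in c(terms, "e")) {
      col <- paste0("sigma2_", trm)
      Sig0[[trm]] <- diag(vapply(uni, function(u) u[[col]][1], numeric(1)), k)
    }
  } else {
    Sig0 <- .vc_to_sigmas(init, S$traits, S$random)
  }
  blocks <- c(terms, "e")
  par0 <- unlist(lapply(blocks, function(b) .chol_to_par(Sig0[[b]])))
  par_to_sig <- function(par) {
    Sig <- list()
    for (bi in seq_along(blocks)) {
      Sig[[blocks[bi]]] <- .par_to_sigma(par[(bi - 1) * npb + seq_len(npb)], k)
    }
    Sig
  }
  cache <- new.env(); cache$ch <- NULL
  nev <- 0L
  obj <- function(par) {
    Sig <- par_to_sig(par)
    ev <- tryCatch(.reml_eval(S, asm, Sig, chol_cache = cache$ch, want_sol = FALSE),
                   error = function(e) NULL)
    if (is.null(ev)) return(1e12)
    if (is.null(cache$ch)) cache$ch <- ev$ch
    nev <<- nev + 1L
    if (control$verbose) cat(sprintf("  -2l=%.6f\n", ev$m2l))
    ev$m2l
  }
  np <- length(par0)
  diag_idx <- as.vector(outer(seq_len(k), (seq_along(blocks) - 1) * npb, `+`))
  lower <- rep(-Inf, np); upper <- rep(Inf, np)
  lower[diag_idx] <- -control$bound; upper[diag_idx] <- control$bound
  par0[diag_idx] <- pmin(pmax(par0[diag_idx], -control$bound + 1e-6), control$bound - 1e-6)
  opt <- optim(par0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = control$maxit, factr = control$factr,
                              ndeps = rep(control$ndeps, np)))
  Sig <- par_to_sig(opt$par)
  .finish_fit(S, asm, Sig, opt, evals = nev)
}

# --- shared finishing: AI matrix, SEs, object assembly ----------------------
.finish_fit <- function(S, asm, Sig, opt, evals) {
  ev <- .reml_eval(S, asm, Sig)
  ai <- .average_information(S, asm, Sig, ev)
  theta <- ai$theta
  theta_se <- setNames(rep(NA_real_, length(theta)), names(theta))
  ai_inv <- tryCatch(solve(ai$AI), error = function(e) NULL)
  if (!is.null(ai_inv)) theta_se <- setNames(sqrt(pmax(diag(ai_inv), 0)), names(theta))

  k <- S$k
  vc <- tibble(trait = S$traits)
  for (trm in c("a", "m", "pe", "e")) {
    col <- paste0("sigma2_", trm)
    vc[[col]] <- if (trm %in% names(Sig)) diag(as.matrix(Sig[[trm]])) else rep(0, k)
    secol <- paste0(col, "_se")
    vc[[secol]] <- if (trm %in% names(Sig)) {
      vapply(seq_len(k), function(t) {
        nm <- .theta_name(trm, S$traits[t], S$traits[t])
        theta_se[[nm]] %||% NA_real_
      }, numeric(1))
    } else rep(NA_real_, k)
  }

  structure(list(
    traits = S$traits, k = k, random = S$random,
    n_records = S$n, n_animals = nrow(S$ped), p_fixed = S$p,
    vc = vc, Sigma = Sig,
    loglik = -0.5 * ev$m2l,
    theta = theta, theta_se = theta_se,
    ai = ai$AI, ai_inv = ai_inv,
    fixed_effects = .fixed_effect_table(S, ev$sol, asm),
    convergence = list(code = opt$convergence, message = opt$message %||% "",
                       evaluations = evals, counts = opt$counts),
    fixed = S$fixed
  ), class = "lactaqg_reml")
}

.theta_name <- function(block, t1, t2) {
  if (t1 == t2) sprintf("sigma2_%s.%s", block, t1) else sprintf("cov_%s.%s:%s", block, t1, t2)
}

.fixed_effect_table <- function(S, sol, asm) {
  purrr::map_dfr(seq_len(S$k), function(t) {
    off <- (t - 1) * asm$dim1
    tibble(trait = S$traits[t], term = colnames(S$X),
           estimate = sol[off + seq_len(S$p)])
  })
}

# Average-information matrix over the free components (variances and, in
# multi-trait fits, cross-trait covariances of every block):
# AI_ij = 0.5 * (dV/dtheta_i P y)' P (dV/dtheta_j P y), with P applied
# through the factored mixed-model equations.
.average_information <- function(S, asm, Sig, ev) {
  k <- S$k
  inv <- .sigma_inverses(Sig)
  Einv <- inv$e$inv
  n <- S$n
  # residuals and Py (n x k matrices)
  fitted <- matrix(0, n, k)
  for (t in seq_len(k)) {
    off <- (t - 1) * asm$dim1
    wt <- ev$sol[off + seq_len(asm$dim1)]
    fitted[, t] <- as.vector(S$W %*% wt)
  }
  E <- S$Y - fitted
  Py <- E %*% Einv

  # per-block, per-trait working vectors g = Z K Z' Py[, s]
  gvec <- list()
  for (trm in names(Sig)) {
    Zt <- if (trm == "e") NULL else S$terms[[trm]]$Z
    g <- matrix(0, n, k)
    for (s in seq_len(k)) {
      if (trm == "e") {
        g[, s] <- Py[, s]
      } else if (S$terms[[trm]]$K == "A") {
        u <- as.vector(Matrix::crossprod(Zt, Py[, s]))
        v <- as.vector(Matrix::solve(S$chA, u))
        g[, s] <- as.vector(Zt %*% v)
      } else {
        u <- as.vector(Matrix::crossprod(Zt, Py[, s]))
        g[, s] <- as.vector(Zt %*% u)
      }
    }
    gvec[[trm]] <- g
  }

  theta <- c(); fvecs <- list()
  for (trm in names(Sig)) {
    M <- as.matrix(Sig[[trm]])
    for (t1 in seq_len(k)) for (t2 in t1:k) {
      nm <- .theta_name(trm, S$traits[t1], S$traits[t2])
      theta[nm] <- M[t1, t2]
      f <- matrix(0, n, k)
      f[, t1] <- f[, t1] + gvec[[trm]][, t2]
      if (t2 != t1) f[, t2] <- f[, t2] + gvec[[trm]][, t1]
      else f[, t1] <- gvec[[trm]][, t1]
      fvecs[[nm]] <- f
    }
  }

  # P f for every working vector, via one MME solve each
  Pf <- lapply(fvecs, function(f) {
    u <- f %*% Einv
    rhs <- as.vector(as.matrix(Matrix::crossprod(S$W, u)))
    s2 <- as.vector(Matrix::solve(ev$ch, rhs))
    ws <- matrix(0, n, k)
    for (t in seq_len(k)) {
      off <- (t - 1) * asm$dim1
      ws[, t] <- as.vector(S$W %*% s2[off + seq_len(asm$dim1)])
    }
    (f - ws) %*% Einv
  })
  npar <- length(theta)
  AI <- matrix(0, npar, npar, dimnames = list(names(theta), names(theta)))
  for (i in seq_len(npar)) for (j in i:npar) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(fvecs[[i]] * Pf[[j]])
  }
  list(AI = AI, theta = theta)
}
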