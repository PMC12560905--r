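# Independent oracles used across the suite. They deliberately avoid the
# package's computational paths: dense matrix algebra, direct allele
# transmission, and textbook recursions.

# -2 * restricted log-likelihood from the dense phenotypic covariance
# V = sa2 Za A Za' + sm2 Zm A Zm' + sp2 Zp Zp' + se2 I.
dense_reml_m2l <- function(y, X, Za, Zm, Zp, A, theta) {
  n <- length(y)
  V <- theta[4] * diag(n) + theta[1] * Za %*% A %*% t(Za)
  if (!is.null(Zm)) V <- V + theta[2] * Zm %*% A %*% t(Zm)
  if (!is.null(Zp)) V <- V + theta[3] * Zp %*% t(Zp)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtVX, t(X) %*% Vi)
  as.numeric((n - ncol(X)) * log(2 * pi) +
               determinant(V, logarithm = TRUE)$modulus +
               determinant(XtVX, logarithm = TRUE)$modulus +
               t(y) %*% P %*% y)
}

# dense design pieces for a set of records + pedigree (small instances only)
dense_designs <- function(records, ped, fixed = ~ parity_class + season + dim_stage) {
  recs <- add_model_factors(records)
  fvars <- all.vars(fixed)
  recs <- droplevels(recs[stats::complete.cases(recs[, c("dmy_kg", fvars)]), ])
  X <- model.matrix(fixed, recs)
  X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  n <- nrow(recs)
  ci <- match(recs$ear_tag, ped$animal)
  nA <- nrow(ped)
  Za <- matrix(0, n, nA); Za[cbind(seq_len(n), ci)] <- 1
  Zm <- matrix(0, n, nA); Zm[cbind(seq_len(n), ped$dam_idx[ci])] <- 1
  cl <- sort(unique(ci))
  Zp <- matrix(0, n, length(cl)); Zp[cbind(seq_len(n), match(ci, cl))] <- 1
  list(y = recs$dmy_kg, X = X, Za = Za, Zm = Zm, Zp = Zp, records = recs)
}

# Monte-Carlo gene dropping: each founder gets two unique alleles, each
# descendant inherits one random allele per parent; the relationship
# estimate is twice the identity-by-descent kinship. Returns the estimate
# and its per-entry Monte-Carlo standard error.
gene_drop_A <- function(ped, n_rep = 1e5, seed = 1) {
  set.seed(seed)
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  a1 <- matrix(0L, n, n_rep); a2 <- matrix(0L, n, n_rep)
  next_allele <- 0L
  for (i in seq_len(n)) {
    if (s[i] > 0L) {
      pick <- stats::runif(n_rep) < 0.5
      a1[i, ] <- ifelse(pick, a1[s[i], ], a2[s[i], ])
    } else {
      next_allele <- next_allele + 1L; a1[i, ] <- next_allele
    }
    if (d[i] > 0L) {
      pick <- stats::runif(n_rep) < 0.5
      a2[i, ] <- ifelse(pick, a1[d[i], ], a2[d[i], ])
    } else {
      next_allele <- next_allele + 1L; a2[i, ] <- next_allele
    }
  }
  A_hat <- matrix(0, n, n); A_se <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) {
      srep <- 1 + (a1[i, ] == a2[i, ])
    } else {
      srep <- ((a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
                 (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])) / 2
    }
    A_hat[i, j] <- A_hat[j, i] <- mean(srep)
    A_se[i, j] <- A_se[j, i] <- stats::sd(srep) / sqrt(n_rep)
  }
  list(A = A_hat, se = A_se)
}

# random discrete-generation pedigree data frame (unsorted input welcome)
random_pedigree_df <- function(n_founders = 20, gens = 3, per_gen = 30,
                               p_male = 0.3, seed = 1) {
  set.seed(seed)
  an <- paste0("F", seq_len(n_founders))
  sex <- sample(c("M", "F"), n_founders, replace = TRUE, prob = c(p_male, 1 - p_male))
  si <- da <- rep(NA_character_, n_founders)
  prev_m <- an[sex == "M"]; prev_f <- an[sex == "F"]
  for (g in seq_len(gens - 1)) {
    off <- paste0("G", g, "_", seq_len(per_gen))
    osex <- sample(c("M", "F"), per_gen, replace = TRUE, prob = c(p_male, 1 - p_male))
    an <- c(an, off)
    si <- c(si, sample(prev_m, per_gen, replace = TRUE))
    da <- c(da, sample(prev_f, per_gen, replace = TRUE))
    sex <- c(sex, osex)
    prev_m <- off[osex == "M"]; prev_f <- off[osex == "F"]
    if (!length(prev_m)) prev_m <- an[sex == "M"]
    if (!length(prev_f)) prev_f <- an[sex == "F"]
  }
  data.frame(animal = an, sire = si, dam = da, sex = sex)
}
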