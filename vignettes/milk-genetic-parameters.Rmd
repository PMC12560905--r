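---
title: "Estimating genetic parameters of milk production traits from test-day records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genetic parameters of milk production traits from test-day records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lactaqg` implements the full analysis chain a dairy quantitative geneticist
runs on Dairy Herd Improvement (DHI) test-day records: pedigree preparation,
tiered quality control with an audit trail, descriptive screening,
least-squares means of the non-genetic factors, and pedigree-based REML
estimation of variance components, heritabilities, repeatabilities and
genetic correlations under a repeatability animal model. Because raw herd
data of this kind are almost always access-restricted, the package also
ships a stochastic herd simulator that generates records with *known*
genetic parameters, so every stage of the pipeline can be validated by
parameter recovery instead of by comparison to unavailable data.

# The model

Each test-day observation of a trait (daily milk yield DMY in kg, fat
percentage FP, protein percentage PP) is modelled as

$$
y_{ijklm} = \mu + \mathrm{PARITY}_i + \mathrm{SEASON}_j + \mathrm{DIM}_k +
\mathrm{BW}_l + a_m + m_{d(m)} + pe_m + e_{ijklm}
$$

with fixed classes for parity (1, 2, 3, 4, 5+), calendar season of the test
date (spring = March–May, summer = June–August, fall = September–November,
winter = December–February, following a sharply continental climate),
lactation stage by days in milk (early ≤ 100 d, mid 101–200 d, late
≥ 201 d) and mature body weight (six classes with breaks at 500, 550, 600,
650 and 700 kg), and random effects

* additive genetic: $a \sim N(0, A\,\sigma^2_a)$, $A$ the numerator
  relationship matrix of the pedigree;
* maternal: $m \sim N(0, A\,\sigma^2_m)$, indexed by the dam of the cow the
  record belongs to. No separate maternal relationship structure is
  defined, so the same $A$ (on the same pedigree) is used; dams unknown to
  the pedigree receive phantom founder dams with a warning;
* permanent environment: $pe \sim N(0, I\,\sigma^2_{pe})$, one level per
  recorded cow, shared by all of her records — this is what makes it a
  *repeatability* model and requires repeated records per cow to be
  identifiable (the package warns below an average of two);
* residual: $e \sim N(0, I\,\sigma^2_e)$.

The direct–maternal genetic covariance is fixed at zero; the model contains
no such term. Narrow-sense heritability uses the full model variance in the
denominator,

$$
h^2 = \frac{\sigma^2_a}{\sigma^2_a + \sigma^2_m + \sigma^2_{pe} + \sigma^2_e},
$$

and repeatability is the conventional
$r = (\sigma^2_a + \sigma^2_{pe}) / \sigma^2_P$ — the maternal variance
appears in the denominator only, so $r \ge h^2$ always. In multi-trait form
every scalar variance becomes a trait covariance matrix and the genetic
correlation is $r_g = \mathrm{cov}_a(t_1,t_2)/\sqrt{\sigma^2_a(t_1)\sigma^2_a(t_2)}$,
with the phenotypic correlation defined analogously on the summed blocks.

# Pedigree machinery

`as_pedigree()` topologically sorts animal/sire/dam triples (Kahn layering
with ties broken by input order, so results are reproducible), appends
referenced-but-absent parents as founders, and refuses cycles and
duplicates outright. Inbreeding coefficients use the Meuwissen–Luo
ancestor-tracing algorithm, which never forms $A$; `build_A_inverse()`
assembles the sparse $A^{-1}$ directly by Henderson's rules with the
inbreeding correction. The dense tabular $A$ is only available behind an
explicit size guard (2,000 animals by default) because it is quadratic in
memory; everything the estimator needs is sparse.

# Quality control

`clean_records()` applies seven stages in a fixed order: (1) records
without an ear tag or with an undecipherable date are dropped (date parsing
rejects silent roll-overs such as February 31); (2) records whose parity or
season is missing after inference — season from the test month, parity from
an optional calving table as prior calvings + 1 — are dropped; (3) records
missing more than 30% of the seven core traits (daily yield, three shift
yields, fat %, protein %, body weight) are dropped; (4) duplicates per ear
tag × test date keep the most complete record (fewest missing core fields,
then first entered); (5) the three analysis traits are mean-imputed within
parity × season cells when their column missingness is below 5%, and
records still incomplete afterwards are dropped; (6) records are flagged as
statistical outliers (|Z| > 3 within parity × season cells, or beyond
1.5 × IQR) and deleted only when biologically impossible (DMY outside
2–60 kg) — extreme but possible values stay, flagged; (7) days in milk are
restricted to lactation weeks 3–44 (days 15–308).

Design choices worth stating explicitly: the seven-field definition of
"core traits" and the parity × season stratum for Z-scores and imputation
are package conventions (the protocol being emulated does not enumerate
them); with single-breed data the "breed" stratum of breed–parity–season
imputation collapses to parity × season; and the audit report enforces
exact arithmetic — `records_out = records_in − records_removed` at every
stage, with both record-level and cow-level counts carried, because
screening tables in the field are often printed with small internal
inconsistencies and an audit trail is only useful if it balances. Cleaning
is idempotent: re-running the pipeline on its own output removes nothing.

# Descriptive conventions

`summarize_trait()` reports the sample SD (n − 1), CV = SD/mean × 100, and
*moment* estimators of shape: skewness $m_3/m_2^{3/2}$ and Pearson
(non-excess) kurtosis $m_4/m_2^2$, for which a normal distribution gives 3.
These biased moment forms are the convention of descriptive trait tables in
this literature; they differ from the unbiased variants by $O(1/n)$, which
is irrelevant at herd scale. The normality screen flags |skewness| > 0.5
(default) as transform-worthy; milder skew is tolerated because mixed
models are robust to small departures and the untransformed scale keeps
parameters interpretable. `box_cox()` provides the sensitivity check: a
grid-profile likelihood with $y \mapsto (y^\lambda - 1)/\lambda$.

# Non-genetic effects

`fit_lsm()` fits the additive fixed-effect model by OLS and reports
classical equal-weight least-squares means — each level's prediction
averaged over the factorial grid of the other factors with equal weights,
not observed margins — with Bonferroni-adjusted pairwise comparisons whose
multiplier is the number of contrasts within the factor. The compact letter
display uses the insert-and-absorb algorithm with letters assigned by
descending LSM, so the output is deterministic and invariant to level input
order. The lactation-stage factor is part of the default model because it
is part of the animal model's fixed structure; six body-weight classes are
the default coding (configurable). Model-based SEs are reported as such —
no attempt is made to reproduce any particular published SE, which depends
on the raw data. The `compute_vif()` diagnostic supports the usual check
that a linear mature-weight covariate and its categorical coding can
coexist; with tertile codings the VIF sits near the conventional warning
threshold of 5, which is a property of that coding, not of any dataset.

# REML: numerical strategy

The restricted log-likelihood is evaluated *exactly* through Henderson's
mixed-model equations: one sparse Cholesky factorization of the coefficient
matrix per evaluation gives $\log|C|$, the solutions, and the quadratic
form, and the standard identity
$\log|V| + \log|X'V^{-1}X| = \log|C| + \log|R| + \log|G|$ assembles the
likelihood. The coefficient matrix is built once as a symbolic pattern
(data cross-products plus $A^{-1}$ and identity blocks, Kronecker-expanded
over traits) and every subsequent evaluation only rewrites its numeric
values and updates the cached factorization, so an evaluation at ~10,000
equations costs tens of milliseconds.

Maximization is quasi-Newton (L-BFGS-B with finite-difference gradients) on
an unconstrained scale: log variance *ratios* with the residual variance
profiled out analytically in the single-trait case (three free parameters),
and Cholesky factors of the four trait covariance matrices in the
multi-trait case (which keeps every block positive semidefinite by
construction; multi-trait fits warm-start from single-trait fits with zero
cross-covariances). This replaces the more traditional EM-with-AI-
acceleration iteration: the EM updates and analytic AI gradients both need
trace terms of the inverse coefficient matrix, which require a selected
(Takahashi) inversion that the sparse backend does not expose, whereas
direct maximization of the same restricted likelihood reaches the same
optimum with only factorizations and solves. The average-information matrix
*is* computed at the optimum — its working vectors need only MME solves —
and standard errors of the components, of $h^2$ (delta method) and of $r_g$
come from its inverse. Likelihood values carry their full normal constant,
so they are directly comparable to dense textbook evaluations; the test
suite checks agreement with an independent dense implementation to 1e-9 at
fixed components and 1e-4 at the optimum.

Boundary behaviour: the log parameterization cannot produce negative
variances; a component that truly is zero converges to a numerically tiny
value (the box bound corresponds to variance ratios of about $e^{\pm 14}$).
Convergence is governed by the optimizer's relative-reduction criterion
(`factr = 1e8`, roughly 2e-8 relative); `reml_control()` exposes it.

# The herd simulator

`sim_scenario()` defaults describe the herd the package is designed
around: five discrete generations totalling 3,750 females and 300 males,
2,992 recorded cows with 8 test-day records each across lactation weeks
3–44, trait means 28.5 kg / 3.94% / 3.35%, and generative components
(additive 0.449 / 0.165 / 0.068, maternal 0.031 / 0.008 / 0.003, permanent
environment 0.288 / 0.092 / 0.038) whose residuals are *derived* as
$\sigma^2_e = \sigma^2_a/h^2 - (\sigma^2_a+\sigma^2_m+\sigma^2_{pe})$ so
the generative heritabilities equal 0.382 / 0.292 / 0.360 exactly by
construction. Cross-trait structure: additive covariances follow the
generative genetic correlations (−0.435 DMY–FP, −0.809 DMY–PP, 0.551
FP–PP), maternal and permanent-environment effects are cross-trait
uncorrelated, and the residual covariance absorbs whatever is needed to
reach the generative phenotypic correlations (−0.144, −0.153, 0.352) —
all four matrices are checked for positive semidefiniteness.

Breeding and maternal values are gene-dropped: founders draw from
$N(0, \Sigma)$ and descendants receive the parental average plus a
Mendelian-sampling deviation with covariance
$(0.5 - 0.25(F_s + F_d))\Sigma$, so the values jointly have covariance
$A \otimes \Sigma$ — the same structure the estimator assumes. Fixed-effect
profiles follow the qualitative field patterns (parity-4 peak, winter
high / summer low, inverted-U lactation curve, rising body-weight
gradient); their magnitudes are package choices, and every profile is
centred under the generator's own level frequencies so the grand mean stays
at the trait mean. Daily yield is decomposed into three shift yields that
sum to it exactly. For cleaning tests the generator can inject missing
cells, biologically impossible yields and duplicate rows, all recorded by
id in the returned truth object.

What the simulator does *not* emulate: continuous lactation-curve shapes
(stage offsets stand in for them, consistent with the three-level DIM
factor in the model), heat-stress or management covariates, genomic
structure, culling and unbalanced recording patterns, or selection (matings
are random, so estimates are unbiased in a way selected field data need not
be). Recovery tests passing therefore validate the estimator and the
pipeline plumbing under the model's own assumptions — they do not certify
any particular real herd's estimates.

# Validation problem sizes

Parameter-recovery runs use a herd of 2,000 recorded cows on a
three-generation pedigree (~3,200 animals, ~9,800 mixed-model equations):
large enough that a single replicate estimates $h^2$ with an SE near 0.04
(the same order as published SEs from herds of this size, which the suite
checks as an order-of-magnitude property), small enough that ten univariate
replicates and five bivariate replicates per trait pair run on a desktop in
minutes. Univariate runs use 5 test-day records per cow; bivariate runs use
the default herd's 8, because cross-trait covariance components gain
precision from within-cow replication while the solver cost — set by the
number of equations, not records — is unchanged. Replicate means over 10
(univariate) and 5 (bivariate) seeds are compared with the generative
values within ±0.05 ($h^2$) and ±0.07 ($r_g$).

# Known limitations

* The model treats days in milk as a three-level stage factor; random
  regression / covariance-function longitudinal models are out of scope.
* Unknown-parent groups, metafounders and genomic relationship matrices are
  not implemented; unknown parents are unrelated founders.
* Bonferroni adjustment applies to fixed-effect contrasts only; no
  multiplicity control is applied across variance-component inferences.
* The multi-trait optimizer is quasi-Newton on up to 12 free covariance
  parameters (two traits); trivariate fits work but are appreciably slower.
* Imputation is cell-mean based; no lactation-curve-aware imputation.
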