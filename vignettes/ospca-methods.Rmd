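---
title: "Orthogonal smoothed PCA: model, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal smoothed PCA: model, conventions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ospca)
```

This vignette records how the decompositions in **ospca** are defined, the
conventions and numerical choices behind the implementation, what the
synthetic-data generator does and does not emulate, and the design decisions
taken where more than one reasonable reading existed.

## The four decompositions

All four methods operate on a samples × metabolites matrix whose rows carry
group labels and an order (time, rank). Write $X$ for the scaled matrix,
$n$ for the number of measurements, $g$ for the number of groups.

**PCA** solves $\tfrac1n X'X w_x = \lambda w_x$. **Smoothed PCA** keeps the
PCA objective but mixes a roughness penalty into the constraint:
$\max \operatorname{var}(t)$ subject to
$(1-\kappa)\,w_x'w_x + \kappa\,(Dt)'(Dt) = w_x' P w_x = 1$ with
$P = (1-\kappa) I + \kappa X'D'DX$, a generalized eigenproblem whose
eigenvectors are *not* orthogonal and whose loadings have no sampling
distribution — `loading_test()` refuses it by design.

**OS-PCA** introduces the auxiliary score $s = X w_y$ and maximizes
$\operatorname{cov}(t, s)$ with $w_x'w_x = 1$ and $w_y' P w_y = 1$.
Eliminating $w_y$ through the stationarity conditions

$$\tfrac1n X'X w_y = 2\lambda_x w_x, \qquad
  \tfrac1n X'X w_x = 2\lambda_y P w_y$$

yields the ordinary symmetric eigenproblem
$\tfrac1{n^2} X'X P^{-1} X'X w_x = \lambda w_x$ with
$\lambda = 4\lambda_x\lambda_y$. Orthonormal $w_x$, a unique solution, and
exact reduction to PCA at $\kappa = 0$ follow. A consequence of the algebra
worth recording: normalizing $w_y \propto P^{-1}X'Xw_x$ to
$w_y'Pw_y = 1$ forces $\lambda_x = \lambda_y = \sqrt{\lambda}/2$ and
$\operatorname{cov}(t,s) = \sqrt{\lambda} \ge 0$, which is how the package
stores the Lagrange multipliers and why the per-component covariance is
nonnegative without any extra sign rule.

**Repeated measurements.** With technical replicates, a row-stochastic
averaging operator $M$ (one row per replicate set, entries $1/n_i$) replaces
$X'X$ by $X'M'MX$ and $P$ by $Q = (1-\kappa)I + \kappa X'M'D'DMX$, where $D$
now lives on the replicate-set-level (collapsed) design: smoothing applies
to the *averaged* score sequence, and replicate order within a set is
irrelevant. Scores $t = Xw_x$ stay per-measurement; auxiliary scores are
reported per replicate set as $Ms = MXw_y$.

## Scaling conventions

* **Divisor-n variance** everywhere. Score variances are written
  $\operatorname{var}(t) = \tfrac1n t't$, so autoscaling divides by the
  population standard deviation. Pearson correlations are divisor-invariant,
  so loadings and their tests are unaffected; score magnitudes are not.
* **Autoscaling** (`autoscale()`) for PCA, smoothed PCA and OS-PCA. The
  loading-as-correlation identity needs unit column variances.
* **Averaged-data autoscaling** (`autoscale_by_average()`) for the
  repeated-measurement fit. The loading identity there needs
  $\operatorname{var}(Mx_p) = 1$, so the columns of $X$ are shifted and
  scaled by the column statistics of $MX$ — $MX$ ends up exactly autoscaled
  while $X$ itself generally retains nonzero column means. An alternative
  reading (autoscale $X$ directly) coincides with this one for balanced
  replicate sets with symmetric within-set variation; we chose the reading
  that makes the repeated-measurement correlation identity exact.
* Constant columns (or columns whose replicate means are constant) carry no
  correlation information; they are dropped with a warning, never silently.
* Missing values are rejected by default; an explicit
  `na_action = "impute_median"` is the only built-in fallback.

## The difference operator

`difference_matrix()` slides the stencil $[1, -1]$ (order 1) or
$[1, -2, 1]$ (order 2) along consecutive order-sorted samples *within each
group*; no row straddles a group boundary, which is what makes the row
counts $n - g$ and $n - 2g$. Two deliberate choices:

* **Unweighted differences.** Consecutive samples are differenced with
  constant coefficients regardless of the numeric gaps in the order values
  (incubation times 0, 10, …, 7200 s are treated as ranks). Encoding the
  gaps as weights would change the penalty into a divided-difference
  smoother, a different method.
* **Second-difference stencil fixed at $[1,-2,1]$**, which annihilates
  per-group linear-in-position trends (verified as a test invariant). With
  `diff_order = 2`, linear score trends are unpenalized and only curvature
  costs; with `diff_order = 1` any non-constant trend costs.

Groups with fewer than `diff_order + 1` samples contribute no rows, with a
warning. Ties in order within a group are kept in input order (stable sort)
and reported via a message.

## Tunable parameters

* **κ (smoothing parameter), in [0, 1).** No default and no automatic
  selection: the appropriate amount of smoothing is a subject-matter choice,
  and results depend on it materially (a strongly smoothness-dominated
  series supports κ = 0.999; mild smoothing, κ = 0.1). κ = 1 would make the
  penalty matrix potentially singular and is rejected; κ = 0.999 is
  admissible and covered by tests. `penalty_matrix()` keeps the minimum
  eigenvalue at ≥ 1 − κ, so Cholesky factorization succeeds on the whole
  admissible range.
* **diff_order ∈ {1, 2}**, default 2 (leaves linear trends free).
* **ncomp**, default `min(n − 1, p, 5)`; truncated with a warning at the
  number of eigenvalues above `1e-12`.
* **q_threshold**, default 0.05, only flags rows; the full table is always
  returned.

## Inference

Loadings are computed *as correlations* (`stats::cor`), not through the
proportionality shortcut; the proportionality to $w_x$ is asserted in tests
instead, which keeps implementation and identity independent. The t-test
$t = r\sqrt{n_\mathrm{eff}-2}/\sqrt{1-r^2}$ uses
$n_\mathrm{eff} = n$ (plain) or the number of replicate sets $u$ (repeated),
two-sided. FDR control is Benjamini–Hochberg via `stats::p.adjust` — the
ubiquitous default in metabolomics; no other procedure is currently exposed.
One caveat is inherited from treating the correlation test as exact: $s$ is
estimated from the same data whose columns it is correlated against, so the
test is exactly calibrated only for a direction held fixed independently of
the data. The test suite therefore calibrates type-I error under a
fixed-direction null; for data-driven components the q-values should be
read as a principled ranking with approximate error control.

`order_association()` reports the Spearman correlation of each component's
score sequence with the within-group rank of the order covariate. It is the
package's mechanical version of choosing the phenotype-associated component
by inspecting score plots — the component to test is a per-question choice,
not always component 1 (a group-offset pattern is perfectly smooth within
groups and can outrank a time trend at high κ).

## Numerical choices

* $P^{-1}$ via Cholesky (`chol2inv`); the eigenproblem matrix
  $\tfrac1{n^2} X'X P^{-1} X'X$ is symmetrized before `eigen(symmetric =
  TRUE)`, guaranteeing a real spectrum and orthonormal $w_x$.
* $w_y$ is normalized by the literal quadratic form $\sqrt{v'Pv}$, making
  $w_y'Pw_y = 1$ exact to machine precision rather than relying on the
  algebraic identity $v'Pv = n^2\lambda$.
* Per component, $(w_x, w_y)$ are sign-flipped jointly so the
  largest-magnitude element of $w_x$ is positive; this fixes the arbitrary
  score direction without touching $\operatorname{cov}(t,s)$.
* Eigenvalues are clamped at 0 and components ranked descending; eigenvalues
  below `1e-12` are treated as null space (they would make the $w_y$
  recovery division-by-zero) and excluded from contribution totals.
* Smoothed PCA solves the generalized problem through the Cholesky factor of
  $P$ ($R^{-T} A R^{-1}$), which makes $w'Pw = 1$ automatic.
* Generator output and all pipeline CSVs are written at 10 significant
  digits, so a rerun with the same configuration is byte-identical.

## The synthetic-data generator

`simulate_metabolome()` emulates the structure of the two motivating study
designs: a multi-group time course (default: 3 groups × 11 time points,
0–7200 s, 60 metabolites) and, with `replicates > 1`, a rank-order design
with technical replicates. It plants

* a smooth latent trend over the *within-group rank* of the order covariate
  (saturating exponential $1 - e^{-3u}$ by default, mimicking isotopomer
  turnover curves; linear and sigmoid available), shared across groups,
* centered equally spaced group offsets on a disjoint metabolite subset,
* i.i.d. Gaussian noise (sd 0.3 by default against coefficient magnitude 1);
  replicates share latents and differ only in noise.

It does **not** emulate real mass-spectrometry artifacts: missingness
mechanisms, heteroscedastic intensity noise, bounded ratio scales,
correlated metabolite blocks, or batch effects. Passing recovery tests on
this generator shows the estimator and test chain work where the model's
assumptions hold — not that any particular real dataset satisfies them.

Latents are functions of rank rather than the raw order values because the
difference penalty itself is rank-based; a generator trending over raw
seconds (0…7200) would concentrate its entire dynamic range in the first two
intervals.

## Verification problem sizes

The property suite runs on 50 random autoscaled matrices with
$n \in [6, 20]$, $p \in [4, 50]$ (reduction to PCA at κ = 0, orthonormality
and penalty-norm constraints, stationarity residuals, loading identities);
20 instances of size 6 × 4 for the covariance-objective optimality check
against a 20-restart BFGS search over the constraint surface; 20 simulated
datasets for roughness monotonicity over κ ∈ {0, 0.1, 0.5, 0.9, 0.999}; 1000
random pairs for the t-test oracle; and 100 simulation seeds at
effect/noise = 3 for planted-trend recovery (sensitivity ≥ 0.9 at q < 0.05,
component chosen by `order_association`). These sizes were chosen so the
whole suite runs in well under a minute while keeping each property's
failure modes (rank deficiency with $p > n$, κ near 1, near-degenerate
eigenvalues) represented.

## Known limitations

* Dense $p \times p$ algebra throughout; intended for metabolome-scale
  $p$ (hundreds), not transcriptome-scale. No SVD dual trick.
* No automatic κ selection (cross-validation is out of scope by design).
* No selection-effect correction for testing loadings of data-driven
  components (see above).
* Unequal time spacing is deliberately not encoded in the penalty.
* Near-degenerate eigenvalue pairs make individual components unstable (as
  in any PCA); contributions and subspaces remain stable.
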