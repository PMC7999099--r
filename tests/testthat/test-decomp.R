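test_that("PCA solves the hand-worked rank-1 toy", {
  x <- rbind(c(1, 1), c(-1, -1)) # centered; (1/2) X'X = [[1,1],[1,1]]
  d <- chain_design(2)
  fit <- ospca(x, d, method = "pca", ncomp = 1, scale = FALSE)
  expect_equal(fit$eigenvalues, 2, tolerance = 1e-12)
  expect_equal(unname(fit$weights_x[, 1]), c(1, 1) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(unname(fit$scores_t[, 1]), c(sqrt(2), -sqrt(2)),
               tolerance = 1e-12)
  expect_equal(fit$contribution, 1)
  expect_identical(fit$contribution_basis, "variance")
})

test_that("PCA satisfies the eigen-equation and contributions normalize", {
  inst <- rand_instance(10, 6, 21)
  fit <- ospca(inst$x, inst$design, method = "pca", ncomp = 6,
               scale = FALSE)
  G <- crossprod(inst$x) / 10
  for (j in 1:6) {
    expect_lt(max_abs(G %*% fit$weights_x[, j] -
                        fit$eigenvalues[j] * fit$weights_x[, j]), 1e-10)
  }
  expect_equal(sum(fit$contribution), 1, tolerance = 1e-12)
  expect_warning(ospca(inst$x, inst$design, method = "pca", ncomp = 12,
                       scale = FALSE), "truncated")
})

test_that("smoothed PCA reduces to PCA at kappa = 0", {
  inst <- rand_instance(9, 5, 31)
  fp <- ospca(inst$x, inst$design, method = "pca", scale = FALSE)
  fs <- ospca(inst$x, inst$design, method = "spca", kappa = 0,
              diff_order = 1, scale = FALSE)
  expect_equal(fs$eigenvalues, fp$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(unname(fs$scores_t)), abs(unname(fp$scores_t)),
               tolerance = 1e-8)
})

test_that("smoothed PCA satisfies the generalized eigen-equation with w'Pw = 1", {
  for (seed in c(41, 42)) {
    inst <- rand_instance(12, 8, seed)
    fit <- ospca(inst$x, inst$design, method = "spca", kappa = 0.5,
                 diff_order = 2, ncomp = 4, scale = FALSE)
    G <- crossprod(inst$x) / 12
    P <- fit$penalty
    for (j in 1:4) {
      w <- fit$weights_x[, j]
      expect_lt(max_abs(G %*% w - fit$eigenvalues[j] * (P %*% w)), 1e-8)
      expect_equal(drop(crossprod(w, P %*% w)), 1, tolerance = 1e-10)
    }
  }
})

test_that("smoothing reduces the roughness of the leading score", {
  sim <- simulate_metabolome(seed = 17)
  D <- difference_matrix(sim$design, 2)
  rough1 <- function(fit) {
    s <- fit$scores_t[, 1]
    drop(crossprod(D %*% (s / sqrt(sum(s^2)))))
  }
  f0 <- ospca(sim$data, sim$design, method = "spca", kappa = 0, ncomp = 1)
  f1 <- ospca(sim$data, sim$design, method = "spca", kappa = 0.1, ncomp = 1)
  expect_lte(rough1(f1), rough1(f0) + 1e-9)
})

test_that("OS-PCA at kappa = 0 coincides with PCA", {
  inst <- rand_instance(8, 5, 51)
  fp <- ospca(inst$x, inst$design, method = "pca", scale = FALSE)
  fo <- ospca(inst$x, inst$design, method = "ospca", kappa = 0,
              diff_order = 1, scale = FALSE)
  # covariance cov(t, s) equals the PCA variance spectrum, w_x = w_y
  expect_equal(fo$cov_ts, fp$eigenvalues, tolerance = 1e-10)
  expect_equal(unname(fo$weights_x), unname(fo$weights_y),
               tolerance = 1e-8)
  expect_equal(abs(unname(fo$scores_t)), abs(unname(fp$scores_t)),
               tolerance = 1e-8)
  # covariance-based contributions equal the PCA variance contributions
  expect_equal(fo$contribution, fp$contribution, tolerance = 1e-10)
})

test_that("OS-PCA weights are orthonormal and satisfy both stationarity relations", {
  for (kap in c(0.1, 0.999)) {
    inst <- rand_instance(10, 7, 61)
    fit <- ospca(inst$x, inst$design, method = "ospca", kappa = kap,
                 diff_order = 2, ncomp = 4, scale = FALSE)
    expect_lt(max_abs(crossprod(fit$weights_x) - diag(4)), 1e-10)
    G <- crossprod(inst$x)
    P <- fit$penalty
    n <- fit$n
    for (j in 1:4) {
      wx <- fit$weights_x[, j]
      wy <- fit$weights_y[, j]
      expect_equal(drop(crossprod(wy, P %*% wy)), 1, tolerance = 1e-10)
      # (1/n) G w_y = 2 lambda_x w_x   and   (1/n) G w_x = 2 lambda_y P w_y
      expect_lt(max_abs(G %*% wy / n - 2 * fit$lambda_x[j] * wx), 1e-8)
      expect_lt(max_abs(G %*% wx / n - 2 * fit$lambda_y[j] * (P %*% wy)),
                1e-8)
      expect_equal(4 * fit$lambda_x[j] * fit$lambda_y[j],
                   fit$eigenvalues[j], tolerance = 1e-8)
      # sign pairing: cov(t, s) >= 0
      expect_gte(fit$cov_ts[j], 0)
    }
  }
})

test_that("eigen-solution attains the covariance-objective maximum", {
  set.seed(99)
  for (inst_i in 1:3) {
    x <- autoscale(matrix(rnorm(24), 6, 4))
    d <- chain_design(6)
    fit <- ospca(x, d, method = "ospca", kappa = 0.5, diff_order = 1,
                 ncomp = 1, scale = FALSE)
    eig_obj <- cov_objective(x, fit$weights_x[, 1], fit$weights_y[, 1])
    expect_equal(eig_obj, fit$cov_ts[1], tolerance = 1e-10)
    best <- search_objective_max(x, fit$penalty, restarts = 10,
                                 seed = inst_i)
    expect_gte(eig_obj, best - 1e-6)
  }
})

test_that("repeated-measurement OS-PCA reduces to plain OS-PCA for singletons", {
  inst <- rand_instance(9, 6, 71)
  fo <- ospca(inst$x, inst$design, method = "ospca", kappa = 0.7,
              diff_order = 1, scale = FALSE)
  des_rep <- sample_design(paste0("s", 1:9), rep("a", 9), 1:9,
                           replicate_set = paste0("r", 1:9))
  fr <- ospca(inst$x, des_rep, method = "ospca_rep", kappa = 0.7,
              diff_order = 1, scale = FALSE)
  expect_equal(unname(fr$weights_x), unname(fo$weights_x),
               tolerance = 1e-10)
  expect_equal(unname(fr$scores_avg), unname(fo$scores_s),
               tolerance = 1e-10)
  expect_equal(fr$eigenvalues, fo$eigenvalues, tolerance = 1e-10)
})

test_that("duplicating rows into replicates reproduces the unduplicated fit", {
  set.seed(81)
  x <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("m", 1:6)))
  d <- chain_design(10)
  fo <- ospca(x, d, method = "ospca", kappa = 0.9, diff_order = 2)
  xdup <- x[rep(1:10, each = 2), ]
  rownames(xdup) <- paste0("s", rep(1:10, each = 2), "_", 1:2)
  ddup <- sample_design(rownames(xdup), rep("a", 20), rep(1:10, each = 2),
                        replicate_set = rep(paste0("r", 1:10), each = 2))
  fdup <- ospca(xdup, ddup, method = "ospca_rep", kappa = 0.9,
                diff_order = 2)
  for (j in seq_len(fo$ncomp)) {
    sgn <- sign(sum(fdup$scores_avg[, j] * fo$scores_s[, j]))
    expect_lt(max_abs(sgn * fdup$scores_avg[, j] - fo$scores_s[, j]), 1e-8)
  }
  # the auxiliary-weight constraint uses the averaged penalty
  Q <- fdup$penalty
  expect_lt(max_abs(diag(crossprod(fdup$weights_y, Q %*% fdup$weights_y)) -
                      1), 1e-10)
})

test_that("contribution ratios are labeled by basis and normalized", {
  sim <- simulate_metabolome(seed = 23)
  fo <- ospca(sim$data, sim$design, method = "ospca", kappa = 0.999)
  tab <- contribution_ratios(fo)
  expect_identical(unique(tab$basis), "covariance")
  expect_true(all(tab$contribution >= 0))
  expect_lte(sum(tab$contribution), 1 + 1e-12)
  full <- suppressWarnings(
    ospca(sim$data, sim$design, method = "ospca", kappa = 0.999,
          ncomp = min(nrow(sim$data) - 1, ncol(sim$data))))
  expect_equal(sum(contribution_ratios(full)$contribution), 1,
               tolerance = 1e-8)
  fp <- ospca(sim$data, sim$design, method = "pca")
  expect_identical(contribution_ratios(fp)$basis[1], "variance")
})

test_that("model surface: print, summary, coef, predict behave", {
  sim <- simulate_metabolome(seed = 29)
  fit <- ospca(sim$data, sim$design, method = "ospca", kappa = 0.9,
               ncomp = 3)
  expect_output(print(fit), "OS-PCA")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.ospca")
  expect_output(print(sm), "contribution")
  expect_equal(dim(coef(fit)), c(ncol(sim$data), 3))
  expect_equal(dim(coef(fit, "y")), c(ncol(sim$data), 3))
  pr <- predict(fit, sim$data)
  expect_equal(unname(pr), unname(fit$scores_t), tolerance = 1e-12)
  prs <- predict(fit, sim$data, type = "s")
  expect_equal(unname(prs), unname(fit$scores_s), tolerance = 1e-12)
  fp <- ospca(sim$data, sim$design, method = "pca")
  expect_error(coef(fp, "y"), "auxiliary")
  expect_error(ospca(sim$data, sim$design, method = "ospca"), "kappa")
  expect_error(ospca(sim$data, method = "ospca", kappa = 0.5), "design")
})
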