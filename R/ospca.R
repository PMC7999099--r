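#' Fit PCA, smoothed PCA, or orthogonal smoothed PCA
#'
#' Fits one of four decompositions of a samples x metabolites matrix whose
#' rows carry a time course or rank order:
#'
#' * `"pca"` — ordinary PCA: the eigendecomposition of `(1/n) X'X`.
#' * `"spca"` — smoothed PCA: the generalized eigenproblem
#'   `(1/n) X'X w = lambda P w` with the roughness-penalized constraint
#'   `w'Pw = 1`, `P = (1-kappa) I + kappa X'D'DX`. Its eigenvectors are not
#'   mutually orthogonal and its loadings admit no correlation
#'   interpretation, so [loading_test()] refuses this method.
#' * `"ospca"` — orthogonal smoothed PCA: maximizes the covariance between a
#'   score `t = X w_x` (unit-norm `w_x`) and an auxiliary score `s = X w_y`
#'   (`w_y' P w_y = 1`), solved as the ordinary symmetric eigenproblem
#'   `(1/n^2) X'X P^{-1} X'X w_x = lambda w_x`. The `w_x` are orthonormal and
#'   the loadings are correlations between `s` and each metabolite, so they
#'   support hypothesis testing.
#' * `"ospca_rep"` — OS-PCA for repeated measurements: as `"ospca"` with
#'   `X'X` replaced by `X'M'MX` and the penalty built on the replicate-set
#'   averages (`Q = (1-kappa) I + kappa X'M'D'DMX`, `D` on the collapsed
#'   design); auxiliary scores are reported per replicate set as `M X w_y`.
#'
#' Scaling is applied internally: autoscaling (divisor-n unit variance) for
#' `"pca"`, `"spca"` and `"ospca"`, and averaged-data autoscaling
#' ([autoscale_by_average()]) for `"ospca_rep"`, as the loading-as-correlation
#' identity requires. Per component the pair `(w_x, w_y)` is sign-flipped
#' jointly so the largest-magnitude element of `w_x` is positive; the
#' covariance `cov(t, s)` is nonnegative by construction.
#'
#' @param x numeric samples x metabolites matrix. If it has row names they
#'   are matched against `design$sample_id`; otherwise rows are assumed to be
#'   in the order the ids were passed to [sample_design()].
#' @param design a [sample_design()] (or a data frame with columns
#'   `sample_id`, `group`, `order` and optionally `replicate_set`). Optional
#'   for `method = "pca"`, where a single-group design in row order is
#'   assumed.
#' @param method one of `"pca"`, `"spca"`, `"ospca"`, `"ospca_rep"`
#'   (`"ospca-rep"` is accepted as an alias).
#' @param kappa smoothing parameter in `[0, 1)`; required for every method
#'   except `"pca"`. There is no automatic selection: the appropriate amount
#'   of smoothing is a subject-matter choice (0.999 suits strongly
#'   smoothness-dominated series, 0.1 mild smoothing).
#' @param diff_order order of the difference penalty, 1 or 2. A second
#'   difference (default) penalizes curvature and leaves linear-in-order
#'   score trends unpenalized.
#' @param ncomp number of components to retain; default
#'   `min(n - 1, p, 5)`. Truncated with a warning if it exceeds the number
#'   of eigenvalues above `1e-12`.
#' @param scale logical; set `FALSE` only if `x` is already scaled as the
#'   chosen method requires.
#'
#' @return An object of class `"ospca"`; a list with components including
#'   `weights_x` (p x k), `weights_y` (p x k, `NULL` for pca/spca),
#'   `eigenvalues`, `lambda_x`, `lambda_y`, `cov_ts`, `scores_t` (n x k),
#'   `scores_s`, `scores_avg` (u x k, repeated case), `contribution`
#'   (fractions) with `contribution_basis` (`"variance"` or `"covariance"` —
#'   the two are not comparable), the scaled matrix `x_scaled`, the
#'   structure operators `D`, `M`, `penalty`, and the `design`.
#' @seealso [loading_test()], [summary.ospca()], [predict.ospca()]
#' @examples
#' sim <- simulate_metabolome(seed = 1)
#' fit <- ospca(sim$data, sim$design, method = "ospca", kappa = 0.999)
#' summary(fit)
#' @export
ospca <- function(x, design = NULL,
                  method = c("pca", "spca", "ospca", "ospca_rep"),
                  kappa = NULL, diff_order = 2L, ncomp = NULL,
                  scale = TRUE) {
  cl <- match.call()
  if (length(method) == 1L && method == "ospca-rep") method <- "ospca_rep"
  method <- match.arg(method)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be a numeric matrix")
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))

  if (is.null(design)) {
    if (method != "pca") {
      stop("a sample design is required for method '", method,
           "' (the difference penalty needs group and order information)")
    }
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("sample", seq_len(nrow(x)))
    design <- sample_design(ids, rep("all", nrow(x)), seq_len(nrow(x)))
  }
  design <- as_sample_design(design)
  x <- align_rows(x, design)

  if (method != "pca") {
    if (is.null(kappa)) {
      stop("'kappa' must be given explicitly for method '", method, "'")
    }
  } else {
    kappa <- NA_real_
  }

  M <- NULL
  D <- NULL
  if (method == "ospca_rep") {
    M <- averaging_matrix(design)
    D <- difference_matrix(collapse_replicates(design), diff_order)
  } else if (method != "pca") {
    D <- difference_matrix(design, diff_order)
  }

  if (scale) {
    xs <- if (method == "ospca_rep") autoscale_by_average(x, M) else
      autoscale(x)
  } else {
    xs <- x
    attr(xs, "scaled_center") <- rep(0, ncol(x))
    attr(xs, "scaled_scale") <- rep(1, ncol(x))
    attr(xs, "dropped_columns") <- character(0)
  }

  n <- nrow(xs)
  p <- ncol(xs)
  if (is.null(ncomp)) ncomp <- min(n - 1L, p, 5L)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop("'ncomp' must be at least 1")

  fit <- switch(method,
    pca = fit_pca_core(xs, ncomp),
    spca = fit_spca_core(xs, D, kappa, ncomp),
    ospca = fit_ospca_core(xs, D, kappa, ncomp, M = NULL),
    ospca_rep = fit_ospca_core(xs, D, kappa, ncomp, M = M)
  )

  k <- ncol(fit$weights_x)
  comp_names <- paste0("comp", seq_len(k))
  dimnames(fit$weights_x) <- list(colnames(xs), comp_names)
  scores_t <- xs %*% fit$weights_x
  dimnames(scores_t) <- list(design$sample_id, comp_names)
  scores_s <- scores_avg <- NULL
  if (!is.null(fit$weights_y)) {
    dimnames(fit$weights_y) <- list(colnames(xs), comp_names)
    scores_s <- xs %*% fit$weights_y
    dimnames(scores_s) <- list(design$sample_id, comp_names)
    if (!is.null(M)) {
      scores_avg <- M %*% scores_s
      dimnames(scores_avg) <- list(rownames(M), comp_names)
    }
  }

  structure(list(
    call = cl,
    method = method,
    kappa = kappa,
    diff_order = if (method == "pca") NA_integer_ else
      as.integer(attr(D, "diff_order")),
    ncomp = k,
    n = n,
    p = p,
    design = design,
    x_scaled = xs,
    scaling = if (scale) attr(xs, "scaling") else "pre-scaled",
    dropped_columns = attr(xs, "dropped_columns"),
    D = D,
    M = M,
    penalty = fit$penalty,
    weights_x = fit$weights_x,
    weights_y = fit$weights_y,
    eigenvalues = fit$eigenvalues,
    eigenvalues_all = fit$eigenvalues_all,
    lambda_x = fit$lambda_x,
    lambda_y = fit$lambda_y,
    cov_ts = fit$cov_ts,
    scores_t = scores_t,
    scores_s = scores_s,
    scores_avg = scores_avg,
    contribution = fit$contribution,
    contribution_basis = fit$contribution_basis
  ), class = "ospca")
}

align_rows <- function(x, design) {
  n <- nrow(design)
  if (nrow(x) != n) {
    stop("data has ", nrow(x), " rows but the design describes ", n,
         " measurements")
  }
  if (!is.null(rownames(x))) {
    missing_ids <- setdiff(design$sample_id, rownames(x))
    if (length(missing_ids)) {
      stop("sample id(s) in the design but not in the data: ",
           paste(missing_ids, collapse = ", "))
    }
    x <- x[design$sample_id, , drop = FALSE]
  } else {
    x <- x[attr(design, "input_order"), , drop = FALSE]
    rownames(x) <- design$sample_id
  }
  x
}

fix_sign <- function(w) {
  i <- which.max(abs(w))
  if (w[i] < 0) -1 else 1
}

truncate_ncomp <- function(ncomp, npos, method) {
  if (ncomp > npos) {
    warning("only ", npos, " component(s) with eigenvalue above tolerance; ",
            "'ncomp' truncated from ", ncomp, " for method '", method, "'")
    npos
  } else ncomp
}

fit_pca_core <- function(xs, ncomp) {
  n <- nrow(xs)
  G <- crossprod(xs) / n
  ee <- eigen(G, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  npos <- sum(vals > 1e-12)
  k <- truncate_ncomp(ncomp, npos, "pca")
  W <- ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) W[, j] <- W[, j] * fix_sign(W[, j])
  list(
    weights_x = W, weights_y = NULL, penalty = NULL,
    eigenvalues = vals[seq_len(k)], eigenvalues_all = vals,
    lambda_x = NULL, lambda_y = NULL, cov_ts = NULL,
    contribution = vals[seq_len(k)] / sum(vals[vals > 1e-12]),
    contribution_basis = "variance"
  )
}

fit_spca_core <- function(xs, D, kappa, ncomp) {
  n <- nrow(xs)
  p <- ncol(xs)
  G <- crossprod(xs) / n
  P <- penalty_matrix(xs, D, kappa)
  R <- tryCatch(chol(P), error = function(e) {
    stop("the penalty matrix is numerically singular; use a smaller kappa",
         call. = FALSE)
  })
  Rinv <- backsolve(R, diag(p))
  A <- crossprod(Rinv, G) %*% Rinv
  A <- (A + t(A)) / 2
  ee <- eigen(A, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  npos <- sum(vals > 1e-12)
  k <- truncate_ncomp(ncomp, npos, "spca")
  W <- Rinv %*% ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) W[, j] <- W[, j] * fix_sign(W[, j])
  list(
    weights_x = W, weights_y = NULL, penalty = P,
    eigenvalues = vals[seq_len(k)], eigenvalues_all = vals,
    lambda_x = NULL, lambda_y = NULL, cov_ts = NULL,
    contribution = vals[seq_len(k)] / sum(vals[vals > 1e-12]),
    contribution_basis = "variance"
  )
}

# Shared solver for OS-PCA (M = NULL) and its repeated-measurement variant
# (M = averaging operator, D on the collapsed design). Works with
# G = X'X or X'M'MX and penalty P or Q; the eigenproblem is
# (1/n^2) G P^{-1} G w_x = lambda w_x, whose matrix is symmetric, so the
# w_x are orthonormal. Per component, w_y is recovered from the stationarity
# relation w_y propto P^{-1} G w_x and normalized to w_y' P w_y = 1; the
# Lagrange multipliers then satisfy lambda_x = lambda_y = sqrt(lambda)/2 and
# cov(t, s) = sqrt(lambda) >= 0.
fit_ospca_core <- function(xs, D, kappa, ncomp, M = NULL) {
  n <- nrow(xs)
  p <- ncol(xs)
  if (is.null(M)) {
    G <- crossprod(xs)
    P <- penalty_matrix(xs, D, kappa)
  } else {
    G <- crossprod(M %*% xs)
    P <- penalty_matrix(xs, D, kappa, M = M)
  }
  R <- tryCatch(chol(P), error = function(e) {
    stop("the penalty matrix is numerically singular; use a smaller kappa",
         call. = FALSE)
  })
  Pinv <- chol2inv(R)
  K <- G %*% Pinv %*% G / n^2
  K <- (K + t(K)) / 2
  ee <- eigen(K, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  npos <- sum(vals > 1e-12)
  k <- truncate_ncomp(ncomp, npos, "ospca")
  Wx <- matrix(0, p, k)
  Wy <- matrix(0, p, k)
  cov_ts <- numeric(k)
  for (j in seq_len(k)) {
    wx <- ee$vectors[, j]
    Gwx <- G %*% wx
    v <- drop(Pinv %*% Gwx)
    wy <- v / sqrt(drop(crossprod(v, P %*% v)))  # exact w_y' P w_y = 1
    sgn <- fix_sign(wx)
    Wx[, j] <- sgn * wx
    Wy[, j] <- sgn * wy
    cov_ts[j] <- drop(crossprod(wx, G %*% wy)) / n
  }
  all_cov <- sqrt(vals[vals > 1e-12])
  list(
    weights_x = Wx, weights_y = Wy, penalty = P,
    eigenvalues = vals[seq_len(k)], eigenvalues_all = vals,
    lambda_x = cov_ts / 2, lambda_y = cov_ts / 2, cov_ts = cov_ts,
    contribution = cov_ts / sum(all_cov),
    contribution_basis = "covariance"
  )
}

#' Contribution ratios of a fitted decomposition
#'
#' For PCA and smoothed PCA the contribution of a component is its share of
#' the total score variance; for OS-PCA (plain or repeated-measurement) it is
#' its share of the total covariance between explanatory and auxiliary
#' scores. The two bases measure different statistics and must never be
#' compared across methods, so every output carries the basis label.
#'
#' @param object a fitted [ospca()] model.
#' @return A data frame with columns `component`, `eigenvalue`,
#'   `contribution` (fraction of the total over all components above
#'   tolerance) and `basis`.
#' @export
contribution_ratios <- function(object) {
  stopifnot(inherits(object, "ospca"))
  data.frame(
    component = seq_len(object$ncomp),
    eigenvalue = object$eigenvalues,
    contribution = object$contribution,
    basis = object$contribution_basis,
    stringsAsFactors = FALSE
  )
}

#' @export
print.ospca <- function(x, ...) {
  lab <- c(pca = "PCA", spca = "smoothed PCA", ospca = "OS-PCA",
           ospca_rep = "OS-PCA (repeated measurements)")[[x$method]]
  cat(lab, " fit: ", x$n, " samples x ", x$p, " metabolites, ",
      x$ncomp, " component(s)\n", sep = "")
  if (!is.na(x$kappa)) {
    cat("kappa = ", format(x$kappa), ", difference order ", x$diff_order,
        "\n", sep = "")
  }
  cat("contribution (", x$contribution_basis, "): ",
      paste(sprintf("%.2f%%", 100 * x$contribution), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Summarize a fitted decomposition
#'
#' @param object a fitted [ospca()] model.
#' @param ... unused.
#' @return An object of class `"summary.ospca"`: the contribution table of
#'   [contribution_ratios()] plus cumulative contributions and fit metadata.
#' @export
summary.ospca <- function(object, ...) {
  tab <- contribution_ratios(object)
  tab$cumulative <- cumsum(tab$contribution)
  structure(list(
    method = object$method, kappa = object$kappa,
    diff_order = object$diff_order, n = object$n, p = object$p,
    u = if (is.null(object$M)) object$n else nrow(object$M),
    scaling = object$scaling,
    dropped_columns = object$dropped_columns,
    table = tab
  ), class = "summary.ospca")
}

#' @export
print.summary.ospca <- function(x, digits = 4, ...) {
  cat("Method:", x$method, "\n")
  if (!is.na(x$kappa)) {
    cat("kappa:", x$kappa, " difference order:", x$diff_order, "\n")
  }
  cat("Data:", x$n, "measurements x", x$p, "metabolites")
  if (x$u != x$n) cat(" (", x$u, " replicate sets)", sep = "")
  cat("; scaling:", x$scaling, "\n")
  if (length(x$dropped_columns)) {
    cat("Dropped constant column(s):",
        paste(x$dropped_columns, collapse = ", "), "\n")
  }
  tab <- x$table
  tab$contribution <- sprintf("%.*f%%", digits - 2, 100 * tab$contribution)
  tab$cumulative <- sprintf("%.*f%%", digits - 2, 100 * tab$cumulative)
  tab$eigenvalue <- signif(tab$eigenvalue, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Extract weight vectors
#'
#' @param object a fitted [ospca()] model.
#' @param type `"x"` for the explanatory weights `w_x`, `"y"` for the
#'   auxiliary weights `w_y` (OS-PCA methods only).
#' @param ... unused.
#' @return p x k numeric matrix.
#' @export
coef.ospca <- function(object, type = c("x", "y"), ...) {
  type <- match.arg(type)
  if (type == "x") return(object$weights_x)
  if (is.null(object$weights_y)) {
    stop("method '", object$method, "' has no auxiliary weight vectors")
  }
  object$weights_y
}

#' Project new samples onto fitted components
#'
#' Applies the scaling learned at fit time (dropping any columns that were
#' dropped then) and projects onto the fitted weight vectors.
#'
#' @param object a fitted [ospca()] model.
#' @param newdata numeric matrix with the same metabolite columns as the
#'   training data (matched by name when column names are present).
#' @param type `"t"` for explanatory scores `X w_x`, `"s"` for auxiliary
#'   scores `X w_y`.
#' @param ... unused.
#' @return Scores matrix with one row per row of `newdata`.
#' @export
predict.ospca <- function(object, newdata, type = c("t", "s"), ...) {
  type <- match.arg(type)
  if (missing(newdata)) {
    return(if (type == "t") object$scores_t else object$scores_s)
  }
  newdata <- as.matrix(newdata)
  vars <- colnames(object$x_scaled)
  if (!is.null(colnames(newdata))) {
    miss <- setdiff(vars, colnames(newdata))
    if (length(miss)) {
      stop("newdata lacks metabolite(s): ", paste(miss, collapse = ", "))
    }
    newdata <- newdata[, vars, drop = FALSE]
  } else if (ncol(newdata) != length(vars)) {
    stop("newdata has ", ncol(newdata), " columns; expected ", length(vars))
  }
  xs <- apply_scaling(newdata, attr(object$x_scaled, "scaled_center"),
                      attr(object$x_scaled, "scaled_scale"))
  W <- if (type == "t") object$weights_x else coef(object, "y")
  xs %*% W
}

#' Score scatter plot
#'
#' Plots two components of the fitted scores against each other, colored by
#' group, or one component against the order covariate when `against_order`
#' is `TRUE`.
#'
#' @param x a fitted [ospca()] model.
#' @param components length-2 (or length-1 with `against_order = TRUE`)
#'   component indices.
#' @param scores `"t"` (explanatory), `"s"` (auxiliary) or `"avg"`
#'   (replicate-set averaged auxiliary, repeated-measurement fits only).
#' @param against_order plot the first requested component against the order
#'   covariate instead of a score-score scatter.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the plotted coordinates.
#' @export
plot.ospca <- function(x, components = c(1, 2),
                       scores = c("t", "s", "avg"),
                       against_order = FALSE, ...) {
  scores <- match.arg(scores)
  S <- switch(scores, t = x$scores_t, s = x$scores_s, avg = x$scores_avg)
  if (is.null(S)) {
    stop("fit has no '", scores, "' scores (method '", x$method, "')")
  }
  if (scores == "avg") {
    d <- collapse_replicates(x$design)
  } else {
    d <- x$design
  }
  grp <- factor(d$group, levels = unique(d$group))
  pch <- (15:25)[(as.integer(grp) - 1L) %% 11L + 1L]
  col <- as.integer(grp) + 1L
  lab <- paste0(toupper(substr(scores, 1, 1)), components)
  if (against_order) {
    xy <- cbind(d$order, S[, components[1]])
    colnames(xy) <- c("order", lab[1])
  } else {
    if (length(components) < 2L) stop("need two components for a scatter")
    xy <- S[, components[1:2]]
    colnames(xy) <- lab[1:2]
  }
  graphics::plot(xy, col = col, pch = pch,
                 xlab = colnames(xy)[1], ylab = colnames(xy)[2], ...)
  if (nlevels(grp) > 1L) {
    graphics::legend("topright", legend = levels(grp),
                     col = seq_len(nlevels(grp)) + 1L,
                     pch = (15:25)[(seq_len(nlevels(grp)) - 1L) %% 11L + 1L],
                     bty = "n")
  }
  invisible(xy)
}

#' @importFrom stats screeplot
#' @export
screeplot.ospca <- function(x, ...) {
  graphics::barplot(100 * x$contribution,
                    names.arg = paste0("comp", seq_len(x$ncomp)),
                    ylab = paste0("contribution (", x$contribution_basis,
                                  ", %)"),
                    ...)
  invisible(x$contribution)
}
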