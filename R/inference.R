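#' Loadings and hypothesis tests for one component
#'
#' On autoscaled data the loading of metabolite p on a component is the
#' Pearson correlation between a score vector and that metabolite's level:
#' `corr(t, x_p)` for PCA and `corr(s, x_p)` for OS-PCA, where `s = X w_y`
#' is the auxiliary score. For the repeated-measurement fit the correlation
#' is taken between the replicate-set averages `M s` and `M x_p`, with one
#' observation per replicate set. Because these loadings are genuine
#' correlation coefficients they admit the standard t-test
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees of freedom
#' (n replaced by the number of replicate sets in the repeated case);
#' two-sided p-values are adjusted to q-values by Benjamini-Hochberg.
#' The OS-PC loading is elementwise proportional to `w_x`, so ranking by
#' loading and ranking by weight agree — but only the correlation has a
#' reference distribution.
#'
#' Smoothed PCA (`method = "spca"`) is refused: its eigenvectors come from a
#' generalized eigenproblem, are not orthogonal, and carry no
#' loading-as-correlation interpretation, so no hypothesis test exists for
#' them.
#'
#' @param object a fitted [ospca()] model.
#' @param component which component to test (the choice is per-question:
#'   e.g. a time-trend component or a rank-associated component).
#' @param q_threshold significance threshold stored with the table and used
#'   by its `significant` flag column.
#' @return A data frame of class `"ospca_loadings"` with one row per
#'   metabolite: `metabolite`, `component`, `r`, `t`, `df`, `p`, `q`, and
#'   `significant` (`q < q_threshold`).
#' @seealso [select_metabolites()], [loading_t_test()], [adjust_fdr()]
#' @examples
#' sim <- simulate_metabolome(seed = 1)
#' fit <- ospca(sim$data, sim$design, method = "ospca", kappa = 0.999)
#' head(loading_test(fit, component = 1))
#' @export
loading_test <- function(object, component = 1L, q_threshold = 0.05) {
  stopifnot(inherits(object, "ospca"))
  if (object$method == "spca") {
    stop("loadings of smoothed PCA have no correlation interpretation and ",
         "cannot be tested; fit method 'ospca' to obtain testable loadings")
  }
  component <- as.integer(component)
  if (component < 1L || component > object$ncomp) {
    stop("'component' must be between 1 and ", object$ncomp)
  }
  r <- compute_loadings(object, component)
  n_eff <- if (object$method == "ospca_rep") nrow(object$M) else object$n
  tt <- loading_t_test(r, n_eff)
  q <- adjust_fdr(tt$p)
  out <- data.frame(
    metabolite = colnames(object$x_scaled),
    component = component,
    r = unname(r),
    t = tt$t,
    df = tt$df,
    p = tt$p,
    q = q,
    significant = q < q_threshold,
    stringsAsFactors = FALSE
  )
  attr(out, "q_threshold") <- q_threshold
  attr(out, "method") <- object$method
  class(out) <- c("ospca_loadings", "data.frame")
  out
}

#' Component loadings as correlations
#'
#' @param object a fitted [ospca()] model (not `"spca"`).
#' @param component component index.
#' @return Named numeric vector of correlations, one per metabolite.
#' @export
compute_loadings <- function(object, component = 1L) {
  stopifnot(inherits(object, "ospca"))
  if (object$method == "spca") {
    stop("loadings of smoothed PCA have no correlation interpretation")
  }
  j <- as.integer(component)
  if (object$method == "pca") {
    score <- object$scores_t[, j]
    mat <- object$x_scaled
  } else if (object$method == "ospca") {
    score <- object$scores_s[, j]
    mat <- object$x_scaled
  } else { # ospca_rep: correlate replicate-set averages
    score <- object$scores_avg[, j]
    mat <- object$M %*% object$x_scaled
  }
  r <- drop(stats::cor(score, mat))
  names(r) <- colnames(object$x_scaled)
  r
}

#' t-test of a correlation-type loading
#'
#' Tests `r = 0` with the statistic `t = r sqrt(n_eff - 2) / sqrt(1 - r^2)`,
#' referred to a t-distribution with `n_eff - 2` degrees of freedom, where
#' `n_eff` is the number of paired observations entering the correlation
#' (samples, or replicate sets for averaged loadings). Two-sided.
#'
#' @param r correlation(s) in `[-1, 1]`; vectorized.
#' @param n_eff number of paired observations; must be at least 3.
#' @return A data frame with columns `t`, `df`, `p` and logical `infinite_t`
#'   flagging `|r| = 1` (reported as `t = Inf`, `p = 0`).
#' @examples
#' loading_t_test(0.6, 11) # t = 2.25
#' @export
loading_t_test <- function(r, n_eff) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  n_eff <- as.integer(n_eff)
  if (length(n_eff) != 1L || n_eff < 3L) {
    stop("'n_eff' must be a single count >= 3 ",
         "(a correlation test needs at least 3 paired observations)")
  }
  r <- pmin(pmax(r, -1), 1)
  df <- n_eff - 2L
  exact <- abs(r) >= 1
  t <- ifelse(exact, sign(r) * Inf, r * sqrt(df) / sqrt(1 - r^2))
  p <- ifelse(exact, 0, 2 * stats::pt(-abs(t), df = df))
  data.frame(t = t, df = df, p = p, infinite_t = exact)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' order-preserving (ties stable). A thin, name-stable wrapper around
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p_values p-values in `[0, 1]`.
#' @return q-values in the input order; empty input gives an empty result.
#' @export
adjust_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Select significant metabolites from a loading-test table
#'
#' Keeps metabolites with `q < q_threshold`, sorted by `|r|` descending; the
#' sign of `r` is the direction of association with the (auxiliary) score.
#'
#' @param results a table from [loading_test()].
#' @param q_threshold q-value cutoff (default 0.05).
#' @return The filtered, reordered table.
#' @export
select_metabolites <- function(results, q_threshold = 0.05) {
  stopifnot(is.data.frame(results), all(c("r", "q") %in% names(results)))
  out <- results[results$q < q_threshold, , drop = FALSE]
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Association of component scores with the ordered covariate
#'
#' Correlates each retained component's score sequence with the within-group
#' rank of the order covariate. A loading test targets one component chosen
#' by the question at hand; for time-trend questions a natural, design-only
#' rule is to test the component whose (auxiliary) score tracks the order
#' most strongly — the component this function ranks first.
#'
#' @param object a fitted [ospca()] model.
#' @param scores which score matrix to correlate: `"s"` (auxiliary; default,
#'   and what the loading test correlates against), `"t"`, or `"avg"`
#'   (replicate-set level, repeated-measurement fits).
#' @param method correlation type passed to [stats::cor()] (default
#'   `"spearman"`: only the ordering matters).
#' @return Named numeric vector, one correlation per retained component.
#' @examples
#' sim <- simulate_metabolome(seed = 1)
#' fit <- ospca(sim$data, sim$design, method = "ospca", kappa = 0.9)
#' order_association(fit)
#' @export
order_association <- function(object, scores = c("s", "t", "avg"),
                              method = "spearman") {
  stopifnot(inherits(object, "ospca"))
  scores <- match.arg(scores)
  S <- switch(scores, t = object$scores_t, s = object$scores_s,
              avg = object$scores_avg)
  if (is.null(S)) {
    if (scores == "s" && !is.null(object$scores_t)) S <- object$scores_t
    else stop("fit has no '", scores, "' scores (method '", object$method,
              "')")
  }
  d <- if (scores == "avg") collapse_replicates(object$design) else
    object$design
  rk <- stats::ave(d$order, d$group, FUN = rank)
  drop(stats::cor(S, rk, method = method))[seq_len(ncol(S))]
}

#' @export
print.ospca_loadings <- function(x, n = 10L, ...) {
  cat("Loading tests (", attr(x, "method"), "), component ",
      x$component[1], ": ", nrow(x), " metabolites, ",
      sum(x$significant), " significant at q < ",
      attr(x, "q_threshold"), "\n", sep = "")
  ord <- order(-abs(x$r))
  print(as.data.frame(x)[utils::head(ord, n), ], ...)
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more rows)\n", sep = "")
  invisible(x)
}
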