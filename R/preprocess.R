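# Column statistics with the divisor-n variance convention used throughout:
# score variances are written var(t) = (1/n) t't, so autoscaling must match.
col_stats_n <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sd_n <- sqrt(colMeans(sweep(x, 2L, mu, "-")^2))
  list(center = mu, scale = sd_n)
}

apply_scaling <- function(x, center, scale) {
  sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
}

#' Autoscale a data matrix (zero mean, unit variance per metabolite)
#'
#' Standardizes every column to mean 0 and variance 1, using the divisor-n
#' variance (not n-1) so that column variances agree with the `(1/n) t't`
#' score-variance convention of the decompositions. Columns with zero
#' variance carry no correlation information and are removed with a warning.
#'
#' @param x numeric samples x metabolites matrix (no missing values; see
#'   Details).
#' @param na_action `"error"` (default) rejects missing values;
#'   `"impute_median"` replaces each missing cell by its column median first.
#' @details Missing values are not part of the underlying model; the default
#'   is to refuse them so that silent imputation never changes a result.
#' @return The scaled matrix with attributes `scaled_center`, `scaled_scale`,
#'   `scaling` (`"autoscaled"`) and `dropped_columns`.
#' @examples
#' autoscale(matrix(c(1, 2, 3, 4, 6, 8), 3, 2))
#' @export
autoscale <- function(x, na_action = c("error", "impute_median")) {
  x <- as.matrix(x)
  na_action <- match.arg(na_action)
  x <- handle_missing(x, na_action)
  if (nrow(x) < 2L) stop("autoscaling needs at least 2 samples")
  st <- col_stats_n(x)
  keep <- st$scale > 0
  if (!all(keep)) {
    warning("dropping constant column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  out <- apply_scaling(x, st$center[keep], st$scale[keep])
  attr(out, "scaled_center") <- st$center[keep]
  attr(out, "scaled_scale") <- st$scale[keep]
  attr(out, "scaling") <- "autoscaled"
  attr(out, "dropped_columns") <- names(st$scale)[!keep]
  out
}

#' Autoscale against replicate-set averages
#'
#' The repeated-measurement decomposition requires the *averaged* data matrix
#' `M X` to be autoscaled while the model itself still operates on the
#' per-measurement matrix `X`. This function therefore shifts and scales the
#' columns of `X` by the mean and (divisor-u) standard deviation of the
#' corresponding column of `M X`, so that `M X` is exactly autoscaled; the
#' residual column means of `X` itself are generally nonzero. With all
#' replicate sets singletons (`M` the identity) this reduces to
#' [autoscale()].
#'
#' @param x numeric samples x metabolites matrix.
#' @param M averaging operator from [averaging_matrix()].
#' @param na_action as in [autoscale()].
#' @return The transformed matrix with attributes `scaled_center`,
#'   `scaled_scale`, `scaling` (`"autoscaled_by_average"`) and
#'   `dropped_columns` (columns whose replicate-mean is constant).
#' @export
autoscale_by_average <- function(x, M, na_action = c("error", "impute_median")) {
  x <- as.matrix(x)
  na_action <- match.arg(na_action)
  x <- handle_missing(x, na_action)
  if (ncol(M) != nrow(x)) {
    stop("averaging operator has ", ncol(M), " columns but the data has ",
         nrow(x), " rows")
  }
  if (nrow(M) < 2L) stop("need at least 2 replicate sets")
  mx <- M %*% x
  st <- col_stats_n(mx)
  keep <- st$scale > 0
  if (!all(keep)) {
    warning("dropping column(s) whose replicate-set means are constant: ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  out <- apply_scaling(x, st$center[keep], st$scale[keep])
  attr(out, "scaled_center") <- st$center[keep]
  attr(out, "scaled_scale") <- st$scale[keep]
  attr(out, "scaling") <- "autoscaled_by_average"
  attr(out, "dropped_columns") <- names(st$scale)[!keep]
  out
}

handle_missing <- function(x, na_action) {
  if (!anyNA(x)) return(x)
  if (na_action == "error") {
    bad <- which(is.na(x), arr.ind = TRUE)
    stop("data contains ", nrow(bad), " missing value(s), e.g. at row ",
         bad[1, 1], ", column ", bad[1, 2],
         "; re-run with na_action = \"impute_median\" to impute column medians")
  }
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- stats::median(x[!nas, j])
  }
  x
}
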