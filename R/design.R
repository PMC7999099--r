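#' Sample design for ordered (time-course or rank-order) data
#'
#' Builds the sample-design object that every smoothed decomposition in this
#' package relies on: which group each measurement belongs to, where it sits
#' along the ordered covariate (incubation time, taste rank, ...), and which
#' measurements are technical replicates of the same underlying sample.
#'
#' Rows are stored sorted by group (in order of first appearance), then by
#' `order` ascending, then by replicate set (first appearance), then by input
#' position. Ties in `order` within a group are therefore broken by input
#' position; this is logged via a message because the difference operator
#' penalizes adjacent pairs and tie order matters for it.
#'
#' @param sample_id character vector of unique measurement identifiers.
#' @param group group label per measurement (strain, condition, ...). A single
#'   label is fine for one-group designs.
#' @param order numeric rank or time per measurement. Only the ordering is
#'   used downstream: differences between consecutive samples are unweighted,
#'   so unequal spacing (e.g. 0, 10, ..., 7200 s) does not change the penalty.
#' @param replicate_set optional identifier naming which distinct sample a
#'   measurement repeats; `NULL` means every measurement is its own singleton.
#'   Within a replicate set, `group` and `order` must be constant.
#'
#' @return A data frame of class `"sample_design"` with columns `sample_id`,
#'   `group`, `order`, `replicate_set`, sorted as described, carrying
#'   attributes `input_order` (original row positions of the sorted rows) and
#'   `n_groups`.
#' @examples
#' sample_design(paste0("s", 1:6), rep(c("a", "b"), each = 3), rep(1:3, 2))
#' @export
sample_design <- function(sample_id, group, order, replicate_set = NULL) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (n < 2L) stop("a sample design needs at least 2 measurements")
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  group <- as.character(group)
  order <- as.numeric(order)
  if (length(group) != n || length(order) != n) {
    stop("'group' and 'order' must have one entry per sample id")
  }
  if (anyNA(order)) stop("'order' contains missing or non-numeric values")
  if (is.null(replicate_set)) {
    replicate_set <- sample_id
  } else {
    replicate_set <- as.character(replicate_set)
    if (length(replicate_set) != n) {
      stop("'replicate_set' must have one entry per sample id")
    }
  }

  for (rs in unique(replicate_set)) {
    idx <- replicate_set == rs
    if (length(unique(group[idx])) > 1L) {
      stop("replicate set '", rs, "' spans more than one group")
    }
    if (length(unique(order[idx])) > 1L) {
      stop("replicate set '", rs, "' has non-constant order values")
    }
  }

  grp_rank <- match(group, unique(group))
  set_rank <- match(replicate_set, unique(replicate_set))
  perm <- order(grp_rank, order, set_rank, seq_len(n))

  # tie report: same group + order shared by different replicate sets
  key <- paste(group, order, sep = "\r")
  tied <- tapply(replicate_set, key, function(z) length(unique(z)) > 1L)
  if (any(tied)) {
    message("ties in 'order' within a group broken by input position")
  }

  out <- data.frame(
    sample_id = sample_id[perm],
    group = group[perm],
    order = order[perm],
    replicate_set = replicate_set[perm],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "input_order") <- perm
  attr(out, "n_groups") <- length(unique(group))
  class(out) <- c("sample_design", "data.frame")
  out
}

#' @export
print.sample_design <- function(x, ...) {
  cat("Sample design:", nrow(x), "measurements,",
      attr(x, "n_groups"), "group(s),",
      length(unique(x$replicate_set)), "replicate set(s)\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

is_sample_design <- function(x) inherits(x, "sample_design")

as_sample_design <- function(x) {
  if (is_sample_design(x)) return(x)
  if (is.data.frame(x)) {
    need <- c("sample_id", "group", "order")
    if (!all(need %in% names(x))) {
      stop("design must have columns sample_id, group, order",
           " (replicate_set optional)")
    }
    return(sample_design(x$sample_id, x$group, x$order,
                         if ("replicate_set" %in% names(x)) x$replicate_set))
  }
  stop("cannot interpret 'design'; supply sample_design() or a data frame")
}

# TRUE when rows already follow the canonical sort of sample_design()
design_is_sorted <- function(design) {
  grp_rank <- match(design$group, unique(design$group))
  set_rank <- match(design$replicate_set, unique(design$replicate_set))
  perm <- order(grp_rank, design$order, set_rank, seq_len(nrow(design)))
  identical(perm, seq_len(nrow(design)))
}

#' Collapse a design to one row per replicate set
#'
#' The repeated-measurement decomposition penalizes roughness of the averaged
#' score sequence, so its difference operator lives on the replicate-set level
#' design: one row per distinct sample, in the same sorted order the rows of
#' the averaging operator use.
#'
#' @param design a [sample_design()].
#' @return A `sample_design` with one row per replicate set; `sample_id` takes
#'   the replicate-set identifier.
#' @export
collapse_replicates <- function(design) {
  design <- as_sample_design(design)
  first <- !duplicated(design$replicate_set)
  sample_design(design$replicate_set[first], design$group[first],
                design$order[first])
}

#' First- or second-difference operator over ordered samples
#'
#' Builds the banded matrix `D` whose rows take first differences
#' (stencil `c(1, -1)`) or second differences (stencil `c(1, -2, 1)`) of
#' consecutive order-sorted samples, separately within each group: no row
#' straddles a group boundary, so with g groups of sufficient size `D` has
#' `n - g` rows (order 1) or `n - 2g` rows (order 2). Penalizing `||D s||^2`
#' enforces smoothness of a score sequence along the time course or rank
#' order. Differences are unweighted: the numeric gaps between order values
#' are ignored by design.
#'
#' @param design a [sample_design()] (already sorted by construction). A
#'   design whose rows were manually reordered is rejected.
#' @param diff_order 1 or 2.
#' @return A `(rows) x n` matrix with column names from `design$sample_id`
#'   and attributes `diff_order` and `row_group` (group label per row). Groups
#'   with fewer than `diff_order + 1` samples contribute zero rows, with a
#'   warning.
#' @examples
#' d <- sample_design(paste0("s", 1:4), rep("a", 4), 1:4)
#' difference_matrix(d, 1)
#' @export
difference_matrix <- function(design, diff_order = 1L) {
  design <- as_sample_design(design)
  if (!design_is_sorted(design)) {
    stop("design rows are not in the canonical sorted order; ",
         "rebuild it with sample_design()")
  }
  if (length(diff_order) != 1L || !diff_order %in% c(1L, 2L)) {
    stop("'diff_order' must be 1 or 2")
  }
  diff_order <- as.integer(diff_order)
  n <- nrow(design)
  stencil <- if (diff_order == 1L) c(1, -1) else c(1, -2, 1)

  blocks <- list()
  row_group <- character(0)
  for (grp in unique(design$group)) {
    idx <- which(design$group == grp)
    m <- length(idx)
    nrows <- m - diff_order
    if (nrows < 1L) {
      warning("group '", grp, "' has too few samples for difference order ",
              diff_order, "; it contributes no smoothness constraint")
      next
    }
    B <- matrix(0, nrows, n)
    for (r in seq_len(nrows)) {
      B[r, idx[r:(r + diff_order)]] <- stencil
    }
    blocks[[length(blocks) + 1L]] <- B
    row_group <- c(row_group, rep(grp, nrows))
  }
  D <- if (length(blocks)) do.call(rbind, blocks) else matrix(0, 0, n)
  colnames(D) <- design$sample_id
  attr(D, "diff_order") <- diff_order
  attr(D, "row_group") <- row_group
  D
}

#' Replicate-averaging operator
#'
#' Builds the row-stochastic matrix `M` (one row per replicate set, one
#' column per measurement) whose nonzero entries are the reciprocal of each
#' set's size, so that `M %*% X` is the matrix of per-sample replicate means.
#' When every measurement is its own singleton, `M` is the identity.
#'
#' @param design a [sample_design()].
#' @return A `u x n` matrix, `u` the number of replicate sets, with row names
#'   from the replicate-set identifiers, column names from the sample ids, and
#'   attribute `replicate_sizes`.
#' @examples
#' d <- sample_design(paste0("s", 1:6), rep("a", 6), rep(1:2, each = 3),
#'                    replicate_set = rep(c("r1", "r2"), each = 3))
#' averaging_matrix(d)
#' @export
averaging_matrix <- function(design) {
  design <- as_sample_design(design)
  if (!design_is_sorted(design)) {
    stop("design rows are not in the canonical sorted order; ",
         "rebuild it with sample_design()")
  }
  sets <- unique(design$replicate_set)
  n <- nrow(design)
  M <- matrix(0, length(sets), n,
              dimnames = list(sets, design$sample_id))
  sizes <- integer(length(sets))
  for (i in seq_along(sets)) {
    idx <- which(design$replicate_set == sets[i])
    sizes[i] <- length(idx)
    M[i, idx] <- 1 / length(idx)
  }
  names(sizes) <- sets
  attr(M, "replicate_sizes") <- sizes
  M
}

#' Roughness penalty matrix for the auxiliary-weight constraint
#'
#' Forms the p x p matrix that replaces the identity in the unit-norm
#' constraint of the smoothed decompositions:
#' `P = (1 - kappa) I + kappa X'D'DX` (plain flavor), or, when an averaging
#' operator is supplied, `Q = (1 - kappa) I + kappa X'M'D'DMX` (averaged
#' flavor, with `D` built on the replicate-set-level design). For
#' `kappa` in `[0, 1)` the matrix is symmetric positive definite with minimum
#' eigenvalue at least `1 - kappa`; `kappa = 0` gives the identity.
#'
#' @param x numeric samples x metabolites matrix (already centered/scaled as
#'   the decomposition requires).
#' @param D difference operator from [difference_matrix()]. With `M` present
#'   it must have `ncol(D) == nrow(M)` (replicate-set level).
#' @param kappa smoothing parameter in `[0, 1)`.
#' @param M optional averaging operator from [averaging_matrix()].
#' @return Symmetric p x p matrix with attributes `kappa` and `flavor`
#'   (`"plain"` or `"averaged"`).
#' @export
penalty_matrix <- function(x, D, kappa, M = NULL) {
  x <- as.matrix(x)
  if (length(kappa) != 1L || is.na(kappa) || kappa < 0 || kappa >= 1) {
    stop("'kappa' must lie in [0, 1); kappa = 1 can make the penalty ",
         "matrix singular (values such as 0.999 are admissible)")
  }
  p <- ncol(x)
  if (is.null(M)) {
    if (ncol(D) != nrow(x)) {
      stop("difference operator has ", ncol(D), " columns but the data has ",
           nrow(x), " rows")
    }
    DX <- D %*% x
    flavor <- "plain"
  } else {
    if (ncol(M) != nrow(x)) {
      stop("averaging operator has ", ncol(M), " columns but the data has ",
           nrow(x), " rows")
    }
    if (ncol(D) != nrow(M)) {
      stop("with an averaging operator, D must be built on the collapsed ",
           "(replicate-set level) design: expected ", nrow(M),
           " columns, got ", ncol(D))
    }
    DX <- D %*% (M %*% x)
    flavor <- "averaged"
  }
  P <- diag(1 - kappa, p) + kappa * crossprod(DX)
  P <- (P + t(P)) / 2
  dimnames(P) <- list(colnames(x), colnames(x))
  attr(P, "kappa") <- kappa
  attr(P, "flavor") <- flavor
  P
}
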