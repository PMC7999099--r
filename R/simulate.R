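#' Simulate an ordered metabolome dataset with planted structure
#'
#' Generates a samples x metabolites matrix that emulates the structure of
#' time-course / rank-order metabolomics studies: a smooth latent trend over
#' the ordered covariate shared by all groups, a group-offset latent that
#' separates groups on a disjoint metabolite subset, i.i.d. Gaussian
#' measurement noise, and optional technical replicates that share latents
#' and differ only in noise. The defaults mirror a three-group, eleven-time-
#' point turnover experiment.
#'
#' The trend latent is a function of the within-group rank of the ordered
#' covariate (matching the unweighted differencing of the model):
#' saturating `1 - exp(-3 u)`, `linear` `u`, or `sigmoid`
#' `1 / (1 + exp(-6(u - 1/2)))`, with `u` the rank scaled to `[0, 1]`;
#' latents are standardized to zero mean, unit (divisor-n) variance across
#' samples. Planted metabolites carry coefficient `effect_size` with
#' alternating sign so both association directions occur.
#'
#' @param n_groups number of groups.
#' @param timepoints ordered covariate values within each group (shared by
#'   all groups).
#' @param replicates technical replicates per (group, timepoint) sample.
#' @param n_metabolites total number of metabolite columns.
#' @param n_trend_metabolites how many columns load on the smooth trend.
#' @param n_groupdiff_metabolites how many columns load on the group
#'   contrast (disjoint from the trend set).
#' @param trend_shape `"saturating"`, `"linear"` or `"sigmoid"`.
#' @param effect_size latent-to-observation coefficient magnitude.
#' @param noise_sd standard deviation of the Gaussian measurement noise.
#' @param seed integer seed; the output is fully determined by it. `NULL`
#'   uses (and advances) the session RNG.
#'
#' @return A list of class `"ospca_sim"`: `data` (matrix with sample ids as
#'   row names), `design` (a [sample_design()]), and `truth` — a list with
#'   the planted metabolite names (`trend_metabolites`,
#'   `groupdiff_metabolites`), per-measurement latents (`trend_latent`,
#'   `group_latent`) and the coefficient vectors.
#' @examples
#' sim <- simulate_metabolome(seed = 42)
#' dim(sim$data)
#' @export
simulate_metabolome <- function(n_groups = 3,
                                timepoints = c(0, 10, 20, 40, 80, 160, 320,
                                               640, 1280, 2560, 7200),
                                replicates = 1,
                                n_metabolites = 60,
                                n_trend_metabolites = 10,
                                n_groupdiff_metabolites = 5,
                                trend_shape = c("saturating", "linear",
                                                "sigmoid"),
                                effect_size = 1,
                                noise_sd = 0.3,
                                seed = NULL) {
  trend_shape <- match.arg(trend_shape)
  stopifnot(n_groups >= 1, length(timepoints) >= 2, replicates >= 1,
            n_metabolites >= 1, n_trend_metabolites >= 0,
            n_groupdiff_metabolites >= 0, noise_sd >= 0)
  if (n_trend_metabolites + n_groupdiff_metabolites > n_metabolites) {
    stop("planted trend and group-difference metabolite sets must be ",
         "disjoint and fit within 'n_metabolites'")
  }
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(seed)
  }

  timepoints <- sort(as.numeric(timepoints))
  m <- length(timepoints)
  groups <- paste0("g", seq_len(n_groups))
  base <- expand.grid(tp_idx = seq_len(m), group = groups,
                      stringsAsFactors = FALSE)
  base <- base[order(match(base$group, groups), base$tp_idx), ]
  base$order <- timepoints[base$tp_idx]
  base$set_id <- paste0(base$group, "_t", base$tp_idx)

  rep_idx <- rep(seq_len(nrow(base)), each = replicates)
  meas <- base[rep_idx, ]
  meas$rep <- rep(seq_len(replicates), times = nrow(base))
  meas$sample_id <- if (replicates > 1) {
    paste0(meas$set_id, "_r", meas$rep)
  } else meas$set_id
  n <- nrow(meas)

  u <- (meas$tp_idx - 1) / (m - 1)
  raw_trend <- switch(trend_shape,
    saturating = 1 - exp(-3 * u),
    linear = u,
    sigmoid = 1 / (1 + exp(-6 * (u - 0.5)))
  )
  std_n <- function(z) {
    s <- sqrt(mean((z - mean(z))^2))
    if (s == 0) z - mean(z) else (z - mean(z)) / s
  }
  trend_latent <- std_n(raw_trend)
  # centered, equally spaced group offsets
  offsets <- seq_len(n_groups) - (n_groups + 1) / 2
  group_latent <- std_n(offsets[match(meas$group, groups)])

  met_names <- sprintf("met%03d", seq_len(n_metabolites))
  trend_set <- met_names[seq_len(n_trend_metabolites)]
  group_set <- met_names[n_trend_metabolites +
                           seq_len(n_groupdiff_metabolites)]
  beta_trend <- stats::setNames(numeric(n_metabolites), met_names)
  beta_group <- stats::setNames(numeric(n_metabolites), met_names)
  if (n_trend_metabolites > 0) {
    beta_trend[trend_set] <- effect_size *
      rep_len(c(1, -1), n_trend_metabolites)
  }
  if (n_groupdiff_metabolites > 0) {
    beta_group[group_set] <- effect_size *
      rep_len(c(1, -1), n_groupdiff_metabolites)
  }

  X <- outer(trend_latent, beta_trend) + outer(group_latent, beta_group) +
    matrix(stats::rnorm(n * n_metabolites, sd = noise_sd), n, n_metabolites)
  dimnames(X) <- list(meas$sample_id, met_names)

  design <- sample_design(meas$sample_id, meas$group, meas$order,
                          replicate_set = if (replicates > 1) meas$set_id)
  structure(list(
    data = X,
    design = design,
    truth = list(
      trend_metabolites = trend_set,
      groupdiff_metabolites = group_set,
      trend_latent = stats::setNames(trend_latent, meas$sample_id),
      group_latent = stats::setNames(group_latent, meas$sample_id),
      beta_trend = beta_trend,
      beta_group = beta_group,
      trend_shape = trend_shape,
      effect_size = effect_size,
      noise_sd = noise_sd
    )
  ), class = "ospca_sim")
}

#' @export
print.ospca_sim <- function(x, ...) {
  cat("Simulated metabolome:", nrow(x$data), "measurements x",
      ncol(x$data), "metabolites;",
      length(x$truth$trend_metabolites), "trend-loaded,",
      length(x$truth$groupdiff_metabolites), "group-offset\n")
  invisible(x)
}

#' Recovery of planted metabolites by loading-test selection
#'
#' Compares the metabolites selected at `q < q_threshold` on one component
#' against the planted metabolites of a simulation truth record and reports
#' the confusion counts, sensitivity and specificity.
#'
#' @param object a fitted [ospca()] model on the simulated data (methods
#'   with testable loadings only), or directly a table from
#'   [loading_test()].
#' @param truth the `truth` element of a [simulate_metabolome()] result.
#' @param component component whose loadings are tested (ignored when a
#'   loadings table is supplied).
#' @param q_threshold selection threshold.
#' @param planted which planted set counts as positive: `"trend"`,
#'   `"groupdiff"`, or `"either"`.
#' @return A list with `selected` (metabolite names), the confusion counts
#'   `tp`, `fp`, `fn`, `tn`, and `sensitivity` / `specificity` (`NA` when the
#'   corresponding denominator is empty).
#' @export
recovery_report <- function(object, truth, component = 1L,
                            q_threshold = 0.05,
                            planted = c("trend", "groupdiff", "either")) {
  planted <- match.arg(planted)
  lt <- if (inherits(object, "ospca")) {
    loading_test(object, component = component, q_threshold = q_threshold)
  } else object
  stopifnot(is.data.frame(lt), all(c("metabolite", "q") %in% names(lt)))
  pos <- switch(planted,
    trend = truth$trend_metabolites,
    groupdiff = truth$groupdiff_metabolites,
    either = union(truth$trend_metabolites, truth$groupdiff_metabolites)
  )
  sel <- select_metabolites(lt, q_threshold)$metabolite
  all_mets <- lt$metabolite
  tp <- length(intersect(sel, pos))
  fp <- length(setdiff(sel, pos))
  fn <- length(setdiff(intersect(pos, all_mets), sel))
  tn <- length(all_mets) - tp - fp - fn
  npos <- tp + fn
  nneg <- tn + fp
  list(selected = sel, tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = if (npos > 0) tp / npos else NA_real_,
       specificity = if (nneg > 0) tn / nneg else NA_real_)
}
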