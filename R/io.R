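#' Read a data matrix and sample-design table from CSV
#'
#' The data CSV has sample ids in its first column and one numeric column
#' per metabolite (header row of metabolite names). The design CSV has
#' columns `sample_id`, `group`, `order`, and optionally `replicate_set`.
#' Rows are returned sorted by the canonical design order; the original
#' input order is retained in the design's `input_order` attribute.
#'
#' @param data_path path to the data CSV.
#' @param design_path path to the design CSV.
#' @return A list with `data` (numeric matrix, rows aligned to the sorted
#'   design) and `design` (a [sample_design()]).
#' @export
read_dataset <- function(data_path, design_path) {
  raw <- utils::read.csv(data_path, check.names = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("data file '", data_path, "' is empty or has no metabolite columns")
  }
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s) in data: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      v <- suppressWarnings(as.numeric(trimws(as.character(vals[[j]]))))
      bad <- which(is.na(v) & !is.na(vals[[j]]) &
                     trimws(as.character(vals[[j]])) != "NA")
      if (length(bad)) {
        stop("non-numeric cell(s) in data column '", names(vals)[j],
             "' at row(s) ", paste(utils::head(ids[bad], 5), collapse = ", "))
      }
      vals[[j]] <- v
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- ids

  des <- utils::read.csv(design_path, stringsAsFactors = FALSE,
                         comment.char = "#")
  need <- c("sample_id", "group", "order")
  if (!all(need %in% names(des))) {
    stop("design file must have columns sample_id, group, order ",
         "(replicate_set optional); found: ",
         paste(names(des), collapse = ", "))
  }
  ord <- suppressWarnings(as.numeric(trimws(as.character(des$order))))
  if (anyNA(ord)) {
    stop("non-numeric 'order' value(s) in design at sample id(s): ",
         paste(des$sample_id[is.na(ord)], collapse = ", "))
  }
  des$order <- ord
  missing_in_design <- setdiff(ids, des$sample_id)
  missing_in_data <- setdiff(des$sample_id, ids)
  if (length(missing_in_design) || length(missing_in_data)) {
    stop("sample ids do not match between data and design.\n",
         if (length(missing_in_design))
           paste0("  in data only: ",
                  paste(missing_in_design, collapse = ", "), "\n") else "",
         if (length(missing_in_data))
           paste0("  in design only: ",
                  paste(missing_in_data, collapse = ", "), "\n") else "")
  }
  design <- sample_design(des$sample_id, des$group, des$order,
                          if ("replicate_set" %in% names(des))
                            des$replicate_set)
  list(data = x[design$sample_id, , drop = FALSE], design = design)
}

# single format for all numeric CSV output: 10 significant digits
fmt_num <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 10, format = "g") else x
}

write_stamped_csv <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", stamp), con)
  df[] <- lapply(df, fmt_num)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
}

#' Run the full decomposition + loading-test pipeline and write results
#'
#' Reads a dataset, fits the requested decomposition, tests loadings of the
#' requested component (unless the method does not support testing), and
#' writes CSV outputs plus a run manifest to `out_dir`. Every output file
#' starts with a comment line naming the method, kappa and difference order,
#' so result files are self-describing.
#'
#' Files written: `scores_t.csv`, `scores_s.csv` and `scores_avg.csv` (when
#' the method produces them), `weights_x.csv`, `weights_y.csv`,
#' `eigenvalues.csv` (with contribution and basis columns), `loadings.csv`
#' (r, t, df, p, q, significance flag), and `run_manifest.txt`.
#'
#' @param config a list (see [pipeline_config()]) with elements `data`,
#'   `design` (paths), `method`, `kappa`, `diff_order`, `ncomp`,
#'   `test_component`, `q_threshold`, `out`.
#' @return Invisibly, a list with the fitted model, the loading-test table
#'   (or `NULL`), and the paths written.
#' @export
run_pipeline <- function(config) {
  config <- do.call(pipeline_config, config)
  ds <- read_dataset(config$data, config$design)
  fit <- ospca(ds$data, ds$design, method = config$method,
               kappa = config$kappa, diff_order = config$diff_order,
               ncomp = config$ncomp)
  lt <- NULL
  if (fit$method != "spca") {
    lt <- loading_test(fit, component = config$test_component,
                       q_threshold = config$q_threshold)
  }

  out_dir <- config$out
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stamp <- paste0("method=", fit$method,
                  " kappa=", if (is.na(fit$kappa)) "NA" else fit$kappa,
                  " diff_order=", fit$diff_order)
  paths <- character(0)
  put <- function(df, name) {
    path <- file.path(out_dir, name)
    write_stamped_csv(df, path, stamp)
    paths <<- c(paths, path)
  }

  put(data.frame(sample_id = rownames(fit$scores_t), fit$scores_t,
                 check.names = FALSE), "scores_t.csv")
  if (!is.null(fit$scores_s)) {
    put(data.frame(sample_id = rownames(fit$scores_s), fit$scores_s,
                   check.names = FALSE), "scores_s.csv")
  }
  if (!is.null(fit$scores_avg)) {
    put(data.frame(replicate_set = rownames(fit$scores_avg), fit$scores_avg,
                   check.names = FALSE), "scores_avg.csv")
  }
  put(data.frame(metabolite = rownames(fit$weights_x), fit$weights_x,
                 check.names = FALSE), "weights_x.csv")
  if (!is.null(fit$weights_y)) {
    put(data.frame(metabolite = rownames(fit$weights_y), fit$weights_y,
                   check.names = FALSE), "weights_y.csv")
  }
  put(contribution_ratios(fit), "eigenvalues.csv")
  if (!is.null(lt)) {
    tab <- as.data.frame(lt)
    names(tab)[names(tab) == "significant"] <-
      paste0("significant_at_", config$q_threshold)
    put(tab, "loadings.csv")
  }

  manifest <- c(
    paste0("# ", stamp),
    paste0("package_version: ",
           as.character(utils::packageVersion("ospca"))),
    paste0("data: ", config$data),
    paste0("design: ", config$design),
    paste0("n_measurements: ", fit$n),
    paste0("n_metabolites: ", fit$p),
    paste0("n_replicate_sets: ",
           if (is.null(fit$M)) fit$n else nrow(fit$M)),
    paste0("ncomp: ", fit$ncomp),
    paste0("test_component: ", config$test_component),
    paste0("q_threshold: ", config$q_threshold),
    paste0("scaling: ", fit$scaling),
    paste0("dropped_columns: ",
           if (length(fit$dropped_columns))
             paste(fit$dropped_columns, collapse = ", ") else "none")
  )
  manifest_path <- file.path(out_dir, "run_manifest.txt")
  writeLines(manifest, manifest_path)
  paths <- c(paths, manifest_path)

  invisible(list(fit = fit, loadings = lt, paths = paths))
}

#' Validate and complete a pipeline configuration
#'
#' @param data,design input CSV paths.
#' @param method decomposition method (as in [ospca()]; `"ospca-rep"`
#'   accepted).
#' @param kappa smoothing parameter; mandatory for every method but `"pca"`.
#' @param diff_order 1 or 2.
#' @param ncomp number of components (`NULL` for the default).
#' @param test_component component whose loadings are tested.
#' @param q_threshold q-value cutoff for the significance flag.
#' @param out output directory.
#' @return The validated config list.
#' @export
pipeline_config <- function(data, design,
                            method = c("pca", "spca", "ospca", "ospca_rep"),
                            kappa = NULL, diff_order = 2L, ncomp = NULL,
                            test_component = 1L, q_threshold = 0.05,
                            out = "ospca_results") {
  if (length(method) == 1L && method == "ospca-rep") method <- "ospca_rep"
  method <- match.arg(method)
  if (method != "pca" && is.null(kappa)) {
    stop("'kappa' is mandatory for method '", method,
         "': the amount of smoothing is dataset-specific and never defaulted")
  }
  for (pth in c(data, design)) {
    if (!file.exists(pth)) stop("input file not found: ", pth)
  }
  list(data = data, design = design, method = method, kappa = kappa,
       diff_order = diff_order, ncomp = ncomp,
       test_component = as.integer(test_component),
       q_threshold = q_threshold, out = out)
}

#' Write a simulated dataset to CSV
#'
#' Writes `data.csv`, `design.csv` and `truth.csv` (planted metabolite
#' roles) for a [simulate_metabolome()] result, in the formats
#' [read_dataset()] reads back.
#'
#' @param sim an `"ospca_sim"` object.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, out_dir) {
  stopifnot(inherits(sim, "ospca_sim"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  data_path <- file.path(out_dir, "data.csv")
  df <- data.frame(sample_id = rownames(sim$data), sim$data,
                   check.names = FALSE)
  df[] <- lapply(df, fmt_num)
  utils::write.csv(df, data_path, row.names = FALSE, quote = FALSE)
  design_path <- file.path(out_dir, "design.csv")
  utils::write.csv(as.data.frame(sim$design), design_path,
                   row.names = FALSE, quote = FALSE)
  truth_path <- file.path(out_dir, "truth.csv")
  role <- ifelse(names(sim$truth$beta_trend) %in% sim$truth$trend_metabolites,
                 "trend",
                 ifelse(names(sim$truth$beta_group) %in%
                          sim$truth$groupdiff_metabolites,
                        "groupdiff", "null"))
  utils::write.csv(data.frame(
    metabolite = names(sim$truth$beta_trend),
    role = role,
    beta_trend = fmt_num(unname(sim$truth$beta_trend)),
    beta_group = fmt_num(unname(sim$truth$beta_group))
  ), truth_path, row.names = FALSE, quote = FALSE)
  invisible(c(data_path, design_path, truth_path))
}
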