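#' strokefc: connectivity, graph metrics and stability selection for
#' lower-limb outcomes after stroke
#'
#' @keywords internal
#' @importFrom rlang .data .env
#' @importFrom ggplot2 autoplot
"_PACKAGE"

#' @export
ggplot2::autoplot

#' Pipeline configuration with study defaults
#'
#' Every tunable of the pipeline in one list, defaulting to the values the
#' analysis was designed around: 0.9 mm framewise-displacement and 5-SD
#' global-signal outlier thresholds; 0.008-0.09 Hz band; graph threshold
#' grid 0.15-0.50 step 0.01; elastic-net tuning over alpha in [0.05, 1] and
#' lambda in [0.0002, 0.36] with 100 candidates, 5-fold cross-validation,
#' 20 repeats and a 90% selection-frequency rule; FDR level 0.05.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `fc_config`.
#' @export
fc_config <- function(...) {
  cfg <- list(
    roi_set = "SMN",
    fd_threshold_mm = 0.9,
    gs_sd_threshold = 5,
    low_hz = 0.008,
    high_hz = 0.09,
    tau_min = 0.15,
    tau_max = 0.50,
    tau_step = 0.01,
    n_alpha = 10,
    n_lambda = 10,
    alpha_range = c(0.05, 1),
    lambda_range = c(0.0002, 0.36),
    n_folds = 5,
    repeats = 20,
    freq_threshold = 0.9,
    fdr_alpha = 0.05,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "fc_config")
}

#' Write / read an ROI panel as per-subject CSVs plus a JSON manifest
#'
#' One CSV per subject (rows = ROIs, columns = frames, ROI labels in the
#' first column) and a `manifest.json` recording TR, ROI labels, subject
#' ids, and per-subject FD traces — diff-able, desk-scale artifacts.
#'
#' @param panel An [fc_panel()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "fc_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in panel_subjects(panel)) {
    m <- panel$series[[s]]
    df <- data.frame(roi = rownames(m), m, check.names = FALSE)
    utils::write.csv(df, file.path(dir, paste0(s, ".csv")), row.names = FALSE)
  }
  manifest <- list(
    tr_seconds = panel$tr_seconds,
    roi_labels = panel$roi_labels,
    subjects = panel_subjects(panel),
    fd = panel$fd,
    outlier_flags = panel$outlier_flags
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_panel
#' @return For `read_panel`, the reconstructed [fc_panel()].
#' @export
read_panel <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  series <- lapply(mf$subjects, function(s) {
    f <- file.path(dir, paste0(s, ".csv"))
    if (!file.exists(f)) stop("missing time-series file for subject ", s)
    df <- utils::read.csv(f, check.names = FALSE)
    if (names(df)[1] != "roi") stop(f, ": first column must be `roi`")
    m <- as.matrix(df[-1])
    dimnames(m) <- list(df$roi, NULL)
    m
  })
  names(series) <- mf$subjects
  fd <- if (!is.null(mf$fd)) lapply(mf$fd, as.numeric) else NULL
  flags <- if (!is.null(mf$outlier_flags)) lapply(mf$outlier_flags, as.logical) else NULL
  fc_panel(series, tr_seconds = mf$tr_seconds, fd = fd, outlier_flags = flags)
}

#' Write a result tibble as TSV
#'
#' @param x A tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical CSV
#'
#' @param path CSV with a `subject` column and one column per measure.
#' @param required Columns that must be present.
#' @return A tibble with the direction flags of [clinical_measures_meta()]
#'   attached.
#' @export
read_clinical <- function(path, required = "subject") {
  df <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("clinical file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  meta <- clinical_measures_meta()
  attr(df, "higher_is_better") <- stats::setNames(meta$higher_is_better,
                                                  meta$measure)
  df
}

#' Run the whole analysis on a cohort
#'
#' End-to-end convenience wrapper: denoise the panel, build the edge table,
#' run the edgewise FDR screen, compute threshold-AUC graph metrics, and
#' run stability selection for every measure x metric — returning all
#' intermediate tables.
#'
#' @param panel An [fc_panel()].
#' @param clinical Clinical tibble with `subject`.
#' @param roi_set [roi_set()] used for ordering/flipping (default taken
#'   from `config$roi_set`).
#' @param flip_subjects Subject ids needing hemisphere standardisation.
#' @param config An [fc_config()].
#' @param measures Outcomes to analyse (default all numeric columns).
#' @return List with `panel` (denoised), `edges`, `edgewise`, `auc`,
#'   `stability`, `clinical_correlations`, `config`.
#' @export
run_pipeline <- function(panel, clinical, roi_set = NULL,
                         flip_subjects = NULL, config = fc_config(),
                         measures = NULL) {
  if (is.null(roi_set)) roi_set <- strokefc::roi_set(config$roi_set)
  panel <- preprocess_panel(panel,
                            fd_threshold_mm = config$fd_threshold_mm,
                            gs_sd_threshold = config$gs_sd_threshold,
                            low_hz = config$low_hz, high_hz = config$high_hz)
  edges <- connectivity_matrices(panel, roi_set, flip_subjects = flip_subjects)
  edgewise <- edgewise_associations(edges, clinical, measures = measures,
                                    alpha = config$fdr_alpha)
  grid_tau <- default_threshold_grid(config$tau_min, config$tau_max,
                                     config$tau_step)
  auc_tab <- graph_metric_auc(edges, grid = grid_tau)
  enet_g <- enet_grid(config$n_alpha, config$n_lambda,
                      config$alpha_range, config$lambda_range)
  stability <- stability_selection_all(auc_tab, clinical, measures = measures,
                                       repeats = config$repeats,
                                       freq_threshold = config$freq_threshold,
                                       grid = enet_g, n_folds = config$n_folds,
                                       base_seed = config$seed)
  list(panel = panel, edges = edges, edgewise = edgewise, auc = auc_tab,
       stability = stability,
       clinical_correlations = clinical_correlations(clinical),
       config = config)
}
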