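#' ROI time-series panel
#'
#' Container for a cohort of per-subject ROI x time BOLD matrices, the
#' sampling interval, nuisance regressors, framewise displacement and
#' outlier flags. Analysis outputs downstream of the panel are tibbles;
#' the panel itself stays matrix-shaped because every operation on it
#' (confound regression, band-pass filtering, correlation) is linear algebra
#' over frames.
#'
#' @param series Named list of numeric matrices (n_rois x n_timepoints), one
#'   per subject, all with identical rownames (ROI labels).
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param confounds Optional named list of matrices (n_confounds x
#'   n_timepoints) parallel to `series`.
#' @param fd Optional named list of framewise-displacement vectors (mm).
#' @param outlier_flags Optional named list of logical vectors.
#' @return An object of class `fc_panel`.
#' @export
fc_panel <- function(series, tr_seconds, confounds = NULL, fd = NULL,
                     outlier_flags = NULL) {
  stopifnot(is.list(series), length(series) >= 1L, tr_seconds > 0)
  if (is.null(names(series)) || anyDuplicated(names(series))) {
    stop("`series` must be a named list with unique subject ids")
  }
  labs <- rownames(series[[1L]])
  if (is.null(labs)) stop("each series matrix needs ROI labels as rownames")
  for (s in names(series)) {
    m <- series[[s]]
    if (!is.matrix(m) || !identical(rownames(m), labs)) {
      stop("subject ", s, ": series must be a matrix sharing the ROI labels")
    }
    if (anyNA(m)) stop("subject ", s, ": missing values in time series")
  }
  structure(
    list(series = series, tr_seconds = tr_seconds, roi_labels = labs,
         confounds = confounds, fd = fd, outlier_flags = outlier_flags,
         log = tibble::tibble(subject = character(), event = character())),
    class = "fc_panel"
  )
}

#' @export
print.fc_panel <- function(x, ...) {
  nt <- vapply(x$series, ncol, integer(1))
  cat("<fc_panel> ", length(x$series), " subjects, ",
      length(x$roi_labels), " ROIs, ",
      paste(range(nt), collapse = "-"), " frames, TR = ",
      x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

#' Long-format view of a panel
#'
#' @param x An `fc_panel`.
#' @param ... Unused.
#' @return Tibble with columns `subject`, `roi`, `frame`, `signal`.
#' @importFrom tibble as_tibble
#' @method as_tibble fc_panel
#' @export
as_tibble.fc_panel <- function(x, ...) {
  purrr::imap_dfr(x$series, function(m, s) {
    tibble::tibble(
      subject = s,
      roi = rep(rownames(m), ncol(m)),
      frame = rep(seq_len(ncol(m)), each = nrow(m)),
      signal = as.vector(m)
    )
  })
}

#' Subject ids of a panel
#' @param panel An `fc_panel`.
#' @export
panel_subjects <- function(panel) names(panel$series)
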