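#' Pearson ROI-to-ROI correlation matrix for one subject
#'
#' Sample Pearson correlation over the subject's (unscrubbed) frames, unit
#' diagonal. Zero-variance ROIs yield `NA` rows/columns with a warning and
#' are excluded downstream.
#'
#' @param x ROI x time matrix, or an [fc_panel()] together with `subject`.
#' @param subject Subject id when `x` is a panel.
#' @return Symmetric correlation matrix with ROI dimnames.
#' @export
pearson_matrix <- function(x, subject = NULL) {
  if (inherits(x, "fc_panel")) {
    stopifnot(!is.null(subject))
    x <- x$series[[subject]]
    if (is.null(x)) stop("unknown subject: ", subject)
  }
  stopifnot(is.matrix(x))
  if (ncol(x) < 3L) stop("need at least 3 usable frames, have ", ncol(x))
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance ROI(s): ",
            paste(rownames(x)[sds == 0], collapse = ", "),
            "; correlations set to NA")
  }
  r <- suppressWarnings(stats::cor(t(x)))
  diag(r) <- 1
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r)[sds == 0] <- 1
  (r + t(r)) / 2
}

#' Fisher z-transform of correlations
#'
#' Variance-stabilising `atanh` transform; correlations at the boundary are
#' clipped to `1 - 1e-7` in absolute value so the transform stays finite.
#'
#' @param r Correlation value(s) or matrix in `[-1, 1]`.
#' @return `atanh(r)` with clipping; for matrices the diagonal is `NA`
#'   (self-correlation carries no information).
#' @examples
#' fisher_z(0.5) # 0.5493
#' @export
fisher_z <- function(r) {
  z <- atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7))
  if (is.matrix(z)) diag(z) <- NA_real_
  z
}

#' Per-subject connectivity edge table for a cohort
#'
#' Computes each subject's Pearson matrix over the frames that survived
#' scrubbing, Fisher-transforms it, optionally standardises hemispheres for
#' flagged subjects, and returns the unique ROI pairs in long form — the
#' table downstream edgewise statistics consume.
#'
#' @param panel A denoised [fc_panel()].
#' @param roi_set [roi_set()] restricting and ordering the ROIs.
#' @param flip_subjects Character vector of subject ids whose hemispheres
#'   must be swapped (left-lesion subjects), applied as the homologue
#'   permutation of [flip_hemispheres()].
#' @return Tibble of class `fc_edge_table` with columns `subject`, `roi_i`,
#'   `roi_j` (`roi_i` < `roi_j` in set order), `r`, `z`.
#' @export
connectivity_matrices <- function(panel, roi_set = NULL, flip_subjects = NULL) {
  stopifnot(inherits(panel, "fc_panel"))
  labs <- if (is.null(roi_set)) panel$roi_labels else roi_set$roi
  missing_rois <- setdiff(labs, panel$roi_labels)
  if (length(missing_rois)) {
    stop("panel lacks ROI(s): ", paste(missing_rois, collapse = ", "))
  }
  pairs <- which(upper.tri(diag(length(labs))), arr.ind = TRUE)
  out <- purrr::map_dfr(panel_subjects(panel), function(s) {
    r <- pearson_matrix(panel$series[[s]][labs, , drop = FALSE])
    if (s %in% flip_subjects) {
      if (is.null(roi_set)) stop("hemisphere flipping requires `roi_set`")
      r <- flip_hemispheres(r, roi_set)
    }
    tibble::tibble(
      subject = s,
      roi_i = labs[pairs[, 1]],
      roi_j = labs[pairs[, 2]],
      r = r[pairs]
    )
  })
  out$z <- fisher_z(out$r)
  class(out) <- c("fc_edge_table", class(out))
  out
}

#' Reassemble a subject's correlation matrix from an edge table
#'
#' @param edges An `fc_edge_table` (see [connectivity_matrices()]).
#' @param subject Subject id.
#' @param value `"r"` or `"z"`.
#' @return Symmetric matrix with unit (`r`) or `NA` (`z`) diagonal.
#' @export
edge_table_matrix <- function(edges, subject, value = c("r", "z")) {
  value <- match.arg(value)
  e <- dplyr::filter(edges, .data$subject == .env$subject)
  if (!nrow(e)) stop("unknown subject: ", subject)
  labs <- unique(c(e$roi_i, e$roi_j))
  m <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  m[cbind(e$roi_i, e$roi_j)] <- e[[value]]
  m[cbind(e$roi_j, e$roi_i)] <- e[[value]]
  diag(m) <- if (value == "r") 1 else NA_real_
  m
}
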