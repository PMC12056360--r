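#' Flag motion/global-signal outlier frames
#'
#' A frame is an outlier when framewise displacement exceeds
#' `fd_threshold_mm` (default 0.9 mm) or the global BOLD signal deviates
#' from its mean by more than `gs_sd_threshold` standard deviations
#' (default 5).
#'
#' @param fd_series Framewise displacement per frame (mm).
#' @param global_signal Mean BOLD signal per frame (same length).
#' @param fd_threshold_mm FD threshold in mm.
#' @param gs_sd_threshold Global-signal threshold in SD units.
#' @return Logical vector of outlier flags.
#' @examples
#' detect_outlier_frames(c(0.1, 1.0, 0.2), c(0, 0, 0))
#' @export
detect_outlier_frames <- function(fd_series, global_signal,
                                  fd_threshold_mm = 0.9, gs_sd_threshold = 5) {
  if (length(fd_series) == 0L) stop("empty FD series")
  if (length(fd_series) != length(global_signal)) {
    stop("FD and global-signal series must have the same length")
  }
  gs_dev <- abs(global_signal - mean(global_signal))
  gs_sd <- stats::sd(global_signal)
  gs_flag <- if (is.na(gs_sd) || gs_sd == 0) {
    rep(FALSE, length(global_signal))
  } else gs_dev > gs_sd_threshold * gs_sd
  (fd_series > fd_threshold_mm) | gs_flag
}

#' Regress nuisance confounds out of every ROI series
#'
#' Replaces each ROI time series by the residual of an ordinary
#' least-squares fit on an intercept plus the subject's confound regressors
#' (white-matter/CSF signals, motion parameters). Rank-deficient confound
#' sets are reduced to a full-rank basis with a warning.
#'
#' @param panel An [fc_panel()] with per-subject `confounds`.
#' @return The panel with residualised series.
#' @export
regress_confounds <- function(panel) {
  stopifnot(inherits(panel, "fc_panel"))
  for (s in panel_subjects(panel)) {
    X <- panel$series[[s]]
    C <- panel$confounds[[s]]
    D <- cbind(intercept = rep(1, ncol(X)),
               if (!is.null(C) && nrow(C)) t(C))
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) {
      warning("subject ", s, ": rank-deficient confounds, dropping ",
              ncol(D) - qrD$rank, " dependent column(s)")
      D <- D[, qrD$pivot[seq_len(qrD$rank)], drop = FALSE]
    }
    panel$series[[s]] <- X - t(stats::lm.fit(D, t(X))$fitted.values)
  }
  panel
}

#' Temporal band-pass filter ROI time series
#'
#' Zero-phase filtering in the frequency domain: the discrete Fourier
#' transform of each series is masked to retain only components with
#' `low_hz <= f <= high_hz` (DC is always removed) and inverted. The default
#' band 0.008-0.09 Hz is the standard resting-state band; at TR = 3 s the
#' Nyquist frequency is 1/6 Hz, so the upper edge must stay below that.
#'
#' @param panel An [fc_panel()].
#' @param low_hz Lower band edge (Hz).
#' @param high_hz Upper band edge (Hz).
#' @return The panel with filtered series.
#' @export
bandpass_filter <- function(panel, low_hz = 0.008, high_hz = 0.09) {
  stopifnot(inherits(panel, "fc_panel"), low_hz >= 0, high_hz > low_hz)
  nyquist <- 1 / (2 * panel$tr_seconds)
  if (high_hz > nyquist + 1e-12) {
    stop(sprintf(
      "high_hz = %g Hz exceeds the Nyquist frequency %g Hz implied by TR = %g s",
      high_hz, nyquist, panel$tr_seconds))
  }
  for (s in panel_subjects(panel)) {
    panel$series[[s]] <- .bandpass_matrix(panel$series[[s]],
                                          panel$tr_seconds, low_hz, high_hz)
  }
  panel
}

.bandpass_matrix <- function(X, tr, low_hz, high_hz) {
  nt <- ncol(X)
  freqs <- seq(0, nt - 1) / (nt * tr)
  freqs <- pmin(freqs, 1 / tr - freqs) # fold to [0, Nyquist]
  keep <- freqs >= low_hz & freqs <= high_hz & seq_len(nt) != 1L
  Fx <- stats::mvfft(t(X))
  Fx[!keep, ] <- 0
  out <- t(Re(stats::mvfft(Fx, inverse = TRUE)) / nt)
  dimnames(out) <- dimnames(X)
  out
}

#' Remove flagged outlier frames ("scrubbing")
#'
#' Deletes flagged frames from the series (and confounds/FD) so that all
#' downstream correlations are computed over clean frames only. Subjects
#' with more than half their frames flagged are unusable and raise an error
#' unless `drop_unusable = TRUE`, in which case they are removed and logged.
#'
#' @param panel An [fc_panel()] with `outlier_flags` set (see
#'   [detect_outlier_frames()]).
#' @param drop_unusable Drop (rather than error on) subjects with > 50%
#'   flagged frames.
#' @return The panel restricted to unflagged frames; the number of retained
#'   frames per subject is appended to `panel$log`.
#' @export
scrub <- function(panel, drop_unusable = FALSE) {
  stopifnot(inherits(panel, "fc_panel"))
  if (is.null(panel$outlier_flags)) stop("panel has no outlier flags; run detect_outlier_frames() first")
  bad_subjects <- character(0)
  for (s in panel_subjects(panel)) {
    flags <- panel$outlier_flags[[s]]
    if (mean(flags) > 0.5) {
      if (!drop_unusable) {
        stop("subject ", s, ": ", sum(flags), "/", length(flags),
             " frames flagged (> 50%), subject unusable")
      }
      bad_subjects <- c(bad_subjects, s)
      next
    }
    keep <- !flags
    panel$series[[s]] <- panel$series[[s]][, keep, drop = FALSE]
    if (!is.null(panel$confounds[[s]]) && nrow(panel$confounds[[s]])) {
      panel$confounds[[s]] <- panel$confounds[[s]][, keep, drop = FALSE]
    }
    if (!is.null(panel$fd[[s]])) panel$fd[[s]] <- panel$fd[[s]][keep]
    panel$outlier_flags[[s]] <- flags[keep]
    panel$log <- dplyr::bind_rows(
      panel$log,
      tibble::tibble(subject = s,
                     event = paste0("scrub: kept ", sum(keep), "/",
                                    length(keep), " frames")))
  }
  for (s in bad_subjects) {
    panel$series[[s]] <- NULL
    panel$confounds[[s]] <- NULL
    panel$fd[[s]] <- NULL
    panel$outlier_flags[[s]] <- NULL
    panel$log <- dplyr::bind_rows(
      panel$log, tibble::tibble(subject = s, event = "excluded: > 50% frames flagged"))
  }
  panel
}

#' Full denoising pipeline for an ROI panel
#'
#' Applies, in fixed order: outlier-frame detection (FD > 0.9 mm or global
#' signal > 5 SD by default), confound regression, temporal band-pass
#' filtering, and scrubbing by frame deletion.
#'
#' @inheritParams detect_outlier_frames
#' @inheritParams bandpass_filter
#' @inheritParams scrub
#' @param panel An [fc_panel()].
#' @return The denoised panel.
#' @export
preprocess_panel <- function(panel, fd_threshold_mm = 0.9, gs_sd_threshold = 5,
                             low_hz = 0.008, high_hz = 0.09,
                             drop_unusable = TRUE) {
  stopifnot(inherits(panel, "fc_panel"))
  flags <- lapply(panel_subjects(panel), function(s) {
    fd <- panel$fd[[s]]
    if (is.null(fd)) fd <- rep(0, ncol(panel$series[[s]]))
    detect_outlier_frames(fd, colMeans(panel$series[[s]]),
                          fd_threshold_mm, gs_sd_threshold)
  })
  panel$outlier_flags <- stats::setNames(flags, panel_subjects(panel))
  panel <- regress_confounds(panel)
  panel <- bandpass_filter(panel, low_hz, high_hz)
  scrub(panel, drop_unusable = drop_unusable)
}
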