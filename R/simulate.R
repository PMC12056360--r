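#' Configuration for a synthetic stroke cohort
#'
#' Defines a cohort whose ROI time series are drawn from a multivariate
#' normal with known, per-subject covariance. Ground-truth association with
#' a clinical measure is planted either at the edge level (a latent trait
#' shifts the Fisher-z of one ROI pair per subject, and the clinical score is
#' a linear function of those true z values) or at the node level (the latent
#' trait shifts a whole row of the correlation matrix, moving that node's
#' graph metrics predictably). Defaults mirror the study conditions: 37
#' subjects, the 24-ROI sensorimotor network, 200 frames at TR = 3 s.
#'
#' @param n_subjects Number of subjects (default 37).
#' @param roi_set An [roi_set()] (default the 24-ROI `"SMN"`).
#' @param n_timepoints Frames per subject (default 200).
#' @param tr_seconds Repetition time in seconds (default 3).
#' @param base_covariance Optional ROI x ROI correlation matrix (symmetric,
#'   unit diagonal after scaling). Default: exchangeable with off-diagonal
#'   0.2, a typical within-network resting-state level.
#' @param planted_edges Tibble/data.frame with columns `roi_i`, `roi_j`,
#'   `effect` (slope of the clinical score on the edge's Fisher z).
#' @param planted_nodes Tibble/data.frame with columns `roi`,
#'   `metric` (one of `"GE"`, `"CC"`, `"BC"`) and `effect`.
#' @param noise_sd SD of Gaussian noise added to the clinical score.
#' @param outlier_frame_rate Probability that a frame is a motion spike
#'   (must be in `[0, 0.5)`).
#' @param edge_modulation SD (on the Fisher-z scale) of the per-subject
#'   latent shift applied at each planted location (default 0.3).
#' @param target_measure Clinical column that carries the planted signal
#'   (default `"FM"`). Lower-is-better measures (GAIT, TUG) receive the
#'   negated latent score.
#' @param confound_strength Scale of nuisance-regressor leakage into the
#'   BOLD signal (0 disables confounds).
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#' @return A list of class `fc_sim_config`.
#' @export
sim_config <- function(n_subjects = 37, roi_set = strokefc::roi_set("SMN"),
                       n_timepoints = 200, tr_seconds = 3,
                       base_covariance = NULL,
                       planted_edges = NULL, planted_nodes = NULL,
                       noise_sd = 1, outlier_frame_rate = 0,
                       edge_modulation = 0.3, target_measure = "FM",
                       confound_strength = 0, seed = 1L) {
  p <- nrow(roi_set)
  stopifnot(p >= 3L, n_subjects >= 2L, n_timepoints >= 10L, tr_seconds > 0,
            noise_sd >= 0, edge_modulation >= 0)
  if (outlier_frame_rate < 0 || outlier_frame_rate >= 0.5) {
    stop("`outlier_frame_rate` must be in [0, 0.5)")
  }
  if (is.null(base_covariance)) {
    base_covariance <- matrix(0.2, p, p)
    diag(base_covariance) <- 1
  } else {
    stopifnot(is.matrix(base_covariance), nrow(base_covariance) == p)
    if (max(abs(base_covariance - t(base_covariance))) > 1e-10) {
      stop("`base_covariance` must be symmetric")
    }
    base_covariance <- stats::cov2cor(base_covariance)
  }
  dimnames(base_covariance) <- list(roi_set$roi, roi_set$roi)
  planted_edges <- .check_planted(planted_edges, c("roi_i", "roi_j", "effect"),
                                  roi_set$roi)
  planted_nodes <- .check_planted(planted_nodes, c("roi", "metric", "effect"),
                                  roi_set$roi)
  if (nrow(planted_nodes) && !all(planted_nodes$metric %in% c("GE", "CC", "BC"))) {
    stop("planted node metric must be one of GE, CC, BC")
  }
  structure(
    list(n_subjects = n_subjects, roi_set = roi_set,
         n_timepoints = n_timepoints, tr_seconds = tr_seconds,
         base_covariance = base_covariance,
         planted_edges = planted_edges, planted_nodes = planted_nodes,
         noise_sd = noise_sd, outlier_frame_rate = outlier_frame_rate,
         edge_modulation = edge_modulation, target_measure = target_measure,
         confound_strength = confound_strength, seed = as.integer(seed)),
    class = "fc_sim_config"
  )
}

.check_planted <- function(x, cols, labels) {
  if (is.null(x)) {
    x <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  x <- tibble::as_tibble(x)
  stopifnot(all(cols %in% names(x)))
  if (nrow(x)) {
    stopifnot(all(is.finite(x$effect)))
    lab_cols <- setdiff(cols, c("effect", "metric"))
    for (cc in lab_cols) {
      bad <- setdiff(x[[cc]], labels)
      if (length(bad)) stop("unknown ROI in planted spec: ", paste(bad, collapse = ", "))
    }
  }
  x
}

#' Metadata for the clinical measure battery
#'
#' Lists every clinical column the generator produces with its
#' direction-of-better flag: GAIT (coordination) and TUG (Timed Up and Go)
#' improve as they decrease; all others improve as they increase.
#'
#' @return Tibble with columns `measure` and `higher_is_better`.
#' @export
clinical_measures_meta <- function() {
  tibble::tibble(
    measure = c("FM", "fGS", "pGS", "GAIT", "TUG", "FGA",
                "proprioception", "monofilament", "vibration", "lesion_load"),
    higher_is_better = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE,
                         TRUE, TRUE, TRUE, FALSE)
  )
}

# cohort-level means/SDs used for the non-target (pure noise) measures
.measure_scales <- function() {
  tibble::tribble(
    ~measure,         ~mean, ~sd,
    "FM",              24.1, 4.0,
    "fGS",             0.69, 0.41,
    "pGS",             0.53, 0.30,
    "GAIT",            18.5, 6.9,
    "TUG",             30.5, 25.2,
    "FGA",             12.5, 4.3,
    "proprioception",  0.03, 0.46,
    "monofilament",   -0.05, 0.10,
    "vibration",      -0.11, 0.39,
    "lesion_load",     23.7, 25.3
  )
}

#' Simulate a cohort with planted ground truth
#'
#' Draws each subject's ROI time series from a multivariate normal whose
#' correlation matrix is the configured base matrix, shifted on the Fisher-z
#' scale at every planted location by an independent standard-normal latent
#' trait scaled by `edge_modulation`. The target clinical measure is the
#' effect-weighted sum of the subject's *true* planted quantities (edge z
#' values, or threshold-AUC graph metrics of the true correlation matrix for
#' node plants) plus Gaussian noise; remaining measures are independent
#' noise at cohort-realistic scales.
#'
#' @param config An [sim_config()].
#' @return List with elements `panel` (an [fc_panel()]), `clinical`
#'   (tibble, one row per subject), and `truth` (planted parameters,
#'   per-subject latents and pre-noise scores, seed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "fc_sim_config"))
  set.seed(config$seed)
  p <- nrow(config$roi_set)
  labs <- config$roi_set$roi
  n <- config$n_subjects
  nt <- config$n_timepoints
  ids <- sprintf("sub%03d", seq_len(n))

  pe <- config$planted_edges
  pn <- config$planted_nodes
  n_loc <- nrow(pe) + nrow(pn)
  latents <- matrix(stats::rnorm(n * max(n_loc, 1L)), nrow = n)

  series <- vector("list", n); names(series) <- ids
  confounds <- vector("list", n); names(confounds) <- ids
  fd_list <- vector("list", n); names(fd_list) <- ids
  truth_pred <- matrix(0, n, n_loc)
  grid <- default_threshold_grid()

  for (s in seq_len(n)) {
    Z <- atanh(pmin(pmax(config$base_covariance, -1 + 1e-7), 1 - 1e-7))
    diag(Z) <- Inf # placeholder; diagonal restored below
    if (nrow(pe)) {
      for (k in seq_len(nrow(pe))) {
        i <- match(pe$roi_i[k], labs); j <- match(pe$roi_j[k], labs)
        Z[i, j] <- Z[j, i] <- Z[i, j] + config$edge_modulation * latents[s, k]
      }
    }
    if (nrow(pn)) {
      for (k in seq_len(nrow(pn))) {
        i <- match(pn$roi[k], labs)
        u <- config$edge_modulation * latents[s, nrow(pe) + k]
        Z[i, -i] <- Z[i, -i] + u
        Z[-i, i] <- Z[-i, i] + u
      }
    }
    R <- tanh(Z)
    diag(R) <- 1
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 1e-10) {
      where <- if (nrow(pe)) {
        paste0("edge (", pe$roi_i[1], ", ", pe$roi_j[1], ")")
      } else if (nrow(pn)) paste0("node ", pn$roi[1]) else "base matrix"
      stop("planted covariance not positive definite for subject ", ids[s],
           "; offending plant: ", where)
    }
    if (nrow(pe)) {
      truth_pred[s, seq_len(nrow(pe))] <-
        vapply(seq_len(nrow(pe)), function(k) {
          atanh(R[match(pe$roi_i[k], labs), match(pe$roi_j[k], labs)])
        }, numeric(1))
    }
    if (nrow(pn)) {
      sweep_res <- metric_threshold_sweep(R, grid = grid)
      aucs <- auc_graph_metrics(sweep_res)
      for (k in seq_len(nrow(pn))) {
        truth_pred[s, nrow(pe) + k] <-
          aucs$auc[aucs$node == pn$roi[k] & aucs$metric == pn$metric[k]]
      }
    }

    X <- t(MASS::mvrnorm(nt, mu = rep(0, p), Sigma = R))
    rownames(X) <- labs

    if (config$confound_strength > 0) {
      C <- rbind(
        drift = seq_len(nt) / nt - 0.5,
        resp = sin(2 * pi * seq_len(nt) / 20),
        wm = as.numeric(stats::filter(stats::rnorm(nt), 0.8, method = "recursive"))
      )
      load <- matrix(stats::rnorm(p * nrow(C), sd = config$confound_strength),
                     p, nrow(C))
      X <- X + load %*% C
    } else {
      C <- matrix(numeric(0), nrow = 0, ncol = nt)
    }

    trace <- simulate_motion_trace(nt, config$outlier_frame_rate,
                                   seed = NULL)
    if (any(trace$spike)) {
      # motion spikes corrupt all ROIs at once, as real scanner frames do
      X[, trace$spike] <- X[, trace$spike] +
        matrix(stats::rnorm(p * sum(trace$spike), sd = 5), p)
    }
    series[[s]] <- X
    confounds[[s]] <- C
    fd_list[[s]] <- trace$fd
  }

  scores_pre_noise <- if (n_loc) {
    as.numeric(truth_pred %*% c(pe$effect, pn$effect))
  } else rep(0, n)
  meta <- clinical_measures_meta()
  target_flip <- if (config$target_measure %in% meta$measure &&
                     !meta$higher_is_better[meta$measure == config$target_measure]) -1 else 1
  scores <- target_flip * scores_pre_noise + stats::rnorm(n, sd = config$noise_sd)

  scales <- .measure_scales()
  clinical <- tibble::tibble(subject = ids)
  for (m in scales$measure) {
    mu <- scales$mean[scales$measure == m]
    sdv <- scales$sd[scales$measure == m]
    vals <- stats::rnorm(n, mu, sdv)
    if (m %in% c("proprioception", "monofilament", "vibration")) {
      vals <- pmin(pmax(vals, -1), 1)
    }
    if (m == "lesion_load") vals <- abs(vals)
    clinical[[m]] <- vals
  }
  if (!config$target_measure %in% names(clinical)) {
    stop("unknown target measure: ", config$target_measure)
  }
  clinical[[config$target_measure]] <- scores
  attr(clinical, "higher_is_better") <-
    stats::setNames(meta$higher_is_better, meta$measure)

  panel <- fc_panel(series, tr_seconds = config$tr_seconds,
                    confounds = confounds, fd = fd_list)
  truth <- list(
    planted_edges = pe, planted_nodes = pn,
    latents = latents[, seq_len(max(n_loc, 0L)), drop = FALSE],
    true_predictors = truth_pred,
    scores_pre_noise = scores_pre_noise,
    target_measure = config$target_measure,
    seed = config$seed
  )
  list(panel = panel, clinical = clinical, truth = truth)
}

#' Simulate a framewise-displacement trace with motion spikes
#'
#' Baseline FD is `|N(0.2, 0.05)|` mm (ordinary scanner motion, well under
#' the 0.9 mm scrubbing threshold); each frame independently becomes a spike
#' exceeding 0.9 mm with probability `outlier_frame_rate`.
#'
#' @param n_timepoints Number of frames.
#' @param outlier_frame_rate Spike probability per frame.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return Tibble with columns `frame`, `fd` (mm) and `spike` (logical).
#' @export
simulate_motion_trace <- function(n_timepoints, outlier_frame_rate = 0,
                                  seed = NULL) {
  stopifnot(n_timepoints >= 1, outlier_frame_rate >= 0, outlier_frame_rate < 0.5)
  if (!is.null(seed)) set.seed(seed)
  fd <- abs(stats::rnorm(n_timepoints, 0.2, 0.05))
  fd <- pmin(fd, 0.85) # baseline never crosses the scrubbing threshold
  spike <- stats::runif(n_timepoints) < outlier_frame_rate
  fd[spike] <- 0.9 + abs(stats::rnorm(sum(spike), 0.3, 0.1))
  tibble::tibble(frame = seq_len(n_timepoints), fd = fd, spike = spike)
}

#' Simulate a lesion/CST mask pair with known lesion load
#'
#' Builds binary 3-D masks realising exactly the requested per-slice
#' corticospinal-tract areas and lesion-tract overlaps, so the slice-weighted
#' lesion load is hand-checkable. Voxels are laid out deterministically
#' within each axial slice; extra lesion voxels outside the tract can be
#' added to exercise the invariance of the load to extratract lesion.
#'
#' @param shape Integer vector `c(nx, ny, n_slices)`.
#' @param cst_profile Integer vector of CST voxel counts per axial slice.
#' @param lesion_spec Integer vector of lesion-CST overlap counts per slice
#'   (`lesion_spec[k] <= cst_profile[k]`).
#' @param extra_lesion Voxels of lesion placed outside the CST per slice.
#' @param seed Unused randomness hook kept for interface symmetry.
#' @return List with binary arrays `lesion` and `cst`, and
#'   `true_lesion_load` computed arithmetically from the profiles using the
#'   max-area/area slice weighting of [weighted_lesion_load()].
#' @export
simulate_lesion_volumes <- function(shape, cst_profile, lesion_spec,
                                    extra_lesion = 0, seed = NULL) {
  stopifnot(length(shape) == 3L, length(cst_profile) == shape[3],
            length(lesion_spec) == length(cst_profile))
  if (any(lesion_spec > cst_profile)) {
    stop("lesion-CST overlap exceeds CST area in slice(s) ",
         paste(which(lesion_spec > cst_profile), collapse = ", "))
  }
  per_slice <- shape[1] * shape[2]
  if (any(cst_profile + extra_lesion > per_slice)) {
    stop("slice too small for requested CST area plus extratract lesion")
  }
  cst <- array(0L, shape)
  lesion <- array(0L, shape)
  for (k in seq_len(shape[3])) {
    sl_cst <- matrix(0L, shape[1], shape[2])
    sl_les <- matrix(0L, shape[1], shape[2])
    if (cst_profile[k] > 0) sl_cst[seq_len(cst_profile[k])] <- 1L
    if (lesion_spec[k] > 0) sl_les[seq_len(lesion_spec[k])] <- 1L
    if (extra_lesion > 0) {
      out_idx <- per_slice - seq_len(extra_lesion) + 1L
      out_idx <- out_idx[out_idx > cst_profile[k]]
      sl_les[out_idx] <- 1L
    }
    cst[, , k] <- sl_cst
    lesion[, , k] <- sl_les
  }
  nz <- cst_profile > 0
  true_ll <- if (any(nz)) {
    sum(lesion_spec[nz] * max(cst_profile[nz]) / cst_profile[nz])
  } else 0
  list(lesion = lesion, cst = cst, true_lesion_load = true_ll)
}
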