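#' Between-limb sensory asymmetry index
#'
#' `(unaffected - affected) / (unaffected + affected)`; negative values mean
#' greater impairment on the affected side. Undefined (returned as `NA` with
#' a warning) when the two scores sum to zero.
#'
#' @param unaffected,affected Scores in the same units.
#' @return Index in `[-1, 1]` for same-signed scores.
#' @examples
#' asymmetry_index(4, 6) # -0.2
#' @export
asymmetry_index <- function(unaffected, affected) {
  s <- unaffected + affected
  out <- (unaffected - affected) / s
  if (any(s == 0, na.rm = TRUE)) {
    warning("zero score sum: asymmetry index undefined, set to NA")
    out[s == 0] <- NA_real_
  }
  out
}

#' Edgewise association of connectivity with one clinical measure
#'
#' For every ROI pair, fits the simple linear regression of the subjects'
#' Fisher-z connectivity on the clinical measure (complete cases) and
#' reports the slope t statistic and its two-sided p value. Edges with fewer
#' than `min_n` complete observations are skipped.
#'
#' @param edges An `fc_edge_table` from [connectivity_matrices()].
#' @param clinical Tibble with a `subject` column and the measure column.
#' @param measure Name of the clinical column to test.
#' @param min_n Minimum complete observations per edge (default 4).
#' @return Tibble with columns `roi_i`, `roi_j`, `measure`, `n`, `slope`,
#'   `t`, `p`.
#' @export
fit_edgewise <- function(edges, clinical, measure, min_n = 4L) {
  stopifnot(measure %in% names(clinical), "subject" %in% names(clinical))
  y <- clinical[[measure]][match(edges$subject, clinical$subject)]
  if (all(is.na(y))) stop("no complete observations for measure ", measure)
  if (stats::var(y, na.rm = TRUE) == 0) {
    stop("measure ", measure, " has zero variance")
  }
  # slope t of z ~ y equals the correlation t: t = r sqrt((n-2)/(1-r^2))
  wide <- tidyr::pivot_wider(edges, id_cols = c("roi_i", "roi_j"),
                             names_from = "subject", values_from = "z")
  zmat <- as.matrix(wide[, -(1:2)])
  ysub <- clinical[[measure]][match(colnames(zmat), clinical$subject)]
  stats_per_edge <- t(apply(zmat, 1, function(zr) {
    ok <- !is.na(zr) & !is.na(ysub)
    n_e <- sum(ok)
    if (n_e < min_n || stats::var(ysub[ok]) == 0 || stats::var(zr[ok]) == 0) {
      return(c(n_e, NA_real_, NA_real_, NA_real_))
    }
    r_e <- stats::cor(zr[ok], ysub[ok])
    slope <- r_e * stats::sd(zr[ok]) / stats::sd(ysub[ok])
    t_e <- r_e * sqrt((n_e - 2) / max(1 - r_e^2, .Machine$double.eps))
    p_e <- 2 * stats::pt(-abs(t_e), n_e - 2)
    c(n_e, slope, t_e, p_e)
  }))
  tibble::tibble(
    roi_i = wide$roi_i, roi_j = wide$roi_j, measure = measure,
    n = as.integer(stats_per_edge[, 1]), slope = stats_per_edge[, 2],
    t = stats_per_edge[, 3], p = stats_per_edge[, 4]
  )
}

#' Benjamini-Hochberg step-up adjusted p values
#'
#' Standard linear step-up procedure: with `m` hypotheses and order
#' statistics `p_(1) <= ... <= p_(m)`, the adjusted value is
#' `min_k>=i (m p_(k) / k)` capped at 1. The family is all edges of one
#' network for one measure.
#'
#' @param p Raw p values in `[0, 1]` (`NA` allowed and preserved).
#' @return Adjusted p values, same order as the input.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Orient a t score so positive means "better function, higher connectivity"
#'
#' Measures where a lower score is better (GAIT, TUG) have their t scores
#' negated so that across measures a positive value always reads as better
#' performance with greater connectivity.
#'
#' @param t Slope t score(s).
#' @param higher_is_better Logical flag(s) for the measure.
#' @return Sign-adjusted t.
#' @export
sign_adjust <- function(t, higher_is_better) {
  ifelse(higher_is_better, 1, -1) * t
}

#' Edgewise screen across measures with FDR control
#'
#' Runs [fit_edgewise()] for each requested measure, adjusts p values by
#' Benjamini-Hochberg within each measure's edge family, flags significance
#' at `alpha`, and sign-adjusts t scores by the measure's direction flag.
#'
#' @inheritParams fit_edgewise
#' @param measures Character vector of clinical columns (default: all
#'   numeric columns except `subject`).
#' @param alpha FDR significance level (default 0.05).
#' @param higher_is_better Named logical vector; defaults to the attribute
#'   stored on `clinical`, else to [clinical_measures_meta()], else `TRUE`.
#' @return Tibble of class `fc_edgewise` with columns `roi_i`, `roi_j`,
#'   `measure`, `n`, `slope`, `t`, `p`, `p_fdr`, `significant`,
#'   `sign_adjusted_t`.
#' @export
edgewise_associations <- function(edges, clinical, measures = NULL,
                                  alpha = 0.05, higher_is_better = NULL,
                                  min_n = 4L) {
  if (is.null(measures)) {
    measures <- setdiff(names(clinical)[vapply(clinical, is.numeric, logical(1))],
                        "subject")
  }
  if (is.null(higher_is_better)) {
    higher_is_better <- attr(clinical, "higher_is_better")
    if (is.null(higher_is_better)) {
      meta <- clinical_measures_meta()
      higher_is_better <- stats::setNames(meta$higher_is_better, meta$measure)
    }
  }
  out <- purrr::map_dfr(measures, function(m) {
    tab <- fit_edgewise(edges, clinical, m, min_n = min_n)
    tab$p_fdr <- bh_fdr(tab$p)
    tab$significant <- !is.na(tab$p_fdr) & tab$p_fdr < alpha
    hib <- if (m %in% names(higher_is_better)) higher_is_better[[m]] else TRUE
    tab$sign_adjusted_t <- sign_adjust(tab$t, hib)
    tab
  })
  class(out) <- c("fc_edgewise", class(out))
  out
}
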