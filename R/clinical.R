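#' Pairwise correlations between clinical measures
#'
#' Pairwise complete-case Pearson correlations with two-sided p values and
#' display stars (0.05 / 0.01 / 0.001), the descriptive inter-measure
#' correlation table. Cells with fewer than `min_pairs` complete pairs are
#' left missing.
#'
#' @param clinical Tibble with `subject` and numeric measure columns.
#' @param measures Columns to correlate (default all numeric but `subject`).
#' @param min_pairs Minimum complete pairs per cell (default 4).
#' @return Tibble with columns `measure_1`, `measure_2`, `n`, `r`, `p`,
#'   `stars`, one row per unordered pair.
#' @export
clinical_correlations <- function(clinical, measures = NULL, min_pairs = 4L) {
  if (is.null(measures)) {
    measures <- setdiff(names(clinical)[vapply(clinical, is.numeric, logical(1))],
                        "subject")
  }
  stopifnot(length(measures) >= 2L, all(measures %in% names(clinical)))
  pairs <- utils::combn(measures, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- clinical[[pairs[1, k]]]
    b <- clinical[[pairs[2, k]]]
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < min_pairs) {
      return(tibble::tibble(measure_1 = pairs[1, k], measure_2 = pairs[2, k],
                            n = sum(ok), r = NA_real_, p = NA_real_,
                            stars = NA_character_))
    }
    ct <- stats::cor.test(a[ok], b[ok])
    tibble::tibble(
      measure_1 = pairs[1, k], measure_2 = pairs[2, k], n = sum(ok),
      r = unname(ct$estimate), p = ct$p.value,
      stars = dplyr::case_when(ct$p.value < 0.001 ~ "***",
                               ct$p.value < 0.01 ~ "**",
                               ct$p.value < 0.05 ~ "*",
                               TRUE ~ "")
    )
  })
}

#' Cohort descriptive summary
#'
#' Mean (SD) and observation count for numeric columns; category percentages
#' for character/factor/logical columns. Empty or all-missing columns are
#' reported with `NA` statistics.
#'
#' @param clinical Tibble with a `subject` column.
#' @return Tibble with columns `measure`, `level` (`NA` for numeric),
#'   `n`, `mean`, `sd`, `percent`.
#' @export
cohort_summary <- function(clinical) {
  stopifnot(nrow(clinical) > 0)
  cols <- setdiff(names(clinical), "subject")
  purrr::map_dfr(cols, function(cn) {
    v <- clinical[[cn]]
    if (is.numeric(v)) {
      vv <- v[!is.na(v)]
      tibble::tibble(measure = cn, level = NA_character_, n = length(vv),
                     mean = if (length(vv)) mean(vv) else NA_real_,
                     sd = if (length(vv) > 1) stats::sd(vv) else
                       if (length(vv) == 1) 0 else NA_real_,
                     percent = NA_real_)
    } else {
      v <- as.character(v)
      tab <- table(v[!is.na(v)])
      if (!length(tab)) {
        return(tibble::tibble(measure = cn, level = NA_character_, n = 0L,
                              mean = NA_real_, sd = NA_real_, percent = NA_real_))
      }
      tibble::tibble(measure = cn, level = names(tab), n = as.integer(tab),
                     mean = NA_real_, sd = NA_real_,
                     percent = 100 * as.integer(tab) / sum(tab))
    }
  })
}
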