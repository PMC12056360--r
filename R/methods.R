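#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an elastic-net fit
#'
#' One row per feature with the standardised coefficient of the
#' RMSE-minimising model.
#'
#' @param x An `fc_enet` from [fit_elastic_net_cv()].
#' @param ... Unused.
#' @return Tibble with columns `feature`, `beta`, `selected`.
#' @method tidy fc_enet
#' @export
tidy.fc_enet <- function(x, ...) {
  tibble::tibble(feature = names(x$beta), beta = unname(x$beta),
                 selected = x$beta != 0)
}

#' @rdname tidy.fc_enet
#' @method glance fc_enet
#' @export
glance.fc_enet <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, lambda = x$lambda, cv_rmse = x$cv_rmse,
                 n = x$n, n_folds = x$n_folds,
                 n_selected = sum(x$beta != 0))
}

#' Tidy a stability-selection result
#'
#' @param x An `fc_stability` from [stability_selection()].
#' @param ... Unused.
#' @return The per-feature selection tibble.
#' @method tidy fc_stability
#' @export
tidy.fc_stability <- function(x, ...) x$selection

#' @rdname tidy.fc_stability
#' @method glance fc_stability
#' @export
glance.fc_stability <- function(x, ...) {
  tibble::tibble(n = x$n, n_features = x$n_features,
                 n_repeats = x$n_repeats,
                 freq_threshold = x$freq_threshold,
                 n_strong = sum(x$selection$strong),
                 mean_cv_rmse = mean(x$repeats$cv_rmse))
}

#' @export
print.fc_enet <- function(x, ...) {
  cat("<fc_enet> alpha =", signif(x$alpha, 3), " lambda =", signif(x$lambda, 3),
      " CV RMSE =", signif(x$cv_rmse, 4), "\n",
      sum(x$beta != 0), "of", length(x$beta), "features selected\n")
  invisible(x)
}

#' @export
print.fc_stability <- function(x, ...) {
  cat("<fc_stability> ", x$n_repeats, " repeats on n = ", x$n, "; strong set (>= ",
      ceiling(x$freq_threshold * x$n_repeats), "/", x$n_repeats, "): ",
      sum(x$selection$strong), " feature(s)\n", sep = "")
  strong <- x$selection[x$selection$strong, ]
  if (nrow(strong)) print(strong)
  invisible(x)
}

#' Plot nodal metric curves over the threshold sweep
#'
#' @param object An `fc_sweep` from [metric_threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot: one panel per metric, one line per node.
#' @method autoplot fc_sweep
#' @export
autoplot.fc_sweep <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$tau, y = .data$value,
                               group = .data$node, colour = .data$node)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = expression(threshold ~ tau), y = "nodal metric",
                  colour = "node") +
    ggplot2::theme_minimal()
}

#' Plot selection frequencies and rank percents of a stability fit
#'
#' @param object An `fc_stability` from [stability_selection()].
#' @param ... Unused.
#' @return A ggplot bar chart of selection frequency per feature, strong
#'   set highlighted.
#' @method autoplot fc_stability
#' @export
autoplot.fc_stability <- function(object, ...) {
  d <- object$selection
  d$feature <- stats::reorder(d$feature, d$selection_freq)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature, y = .data$selection_freq,
                                  fill = .data$strong)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$freq_threshold, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "#2166AC")) +
    ggplot2::labs(x = NULL, y = "selection frequency", fill = "strong") +
    ggplot2::theme_minimal()
}

#' Heatmap of a subject's connectivity matrix
#'
#' @param edges An `fc_edge_table`.
#' @param subject Subject id.
#' @param value `"r"` or `"z"`.
#' @return A ggplot tile heatmap.
#' @export
plot_connectivity <- function(edges, subject, value = c("r", "z")) {
  value <- match.arg(value)
  m <- edge_table_matrix(edges, subject, value)
  d <- tibble::tibble(
    roi_i = rep(rownames(m), ncol(m)),
    roi_j = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$roi_j, y = .data$roi_i,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = value) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Sign-adjusted t scores of significant edges
#'
#' @param object An `fc_edgewise` from [edgewise_associations()].
#' @param ... Unused.
#' @return A ggplot of sign-adjusted t per significant edge, by measure.
#' @method autoplot fc_edgewise
#' @export
autoplot.fc_edgewise <- function(object, ...) {
  d <- dplyr::filter(object, .data$significant)
  if (!nrow(d)) stop("no FDR-significant edges to plot")
  d$edge <- paste(d$roi_i, d$roi_j, sep = " - ")
  d$edge <- stats::reorder(d$edge, d$sign_adjusted_t)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sign_adjusted_t, y = .data$edge,
                                  colour = .data$measure)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "sign-adjusted t", y = NULL, colour = "measure") +
    ggplot2::theme_minimal()
}
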