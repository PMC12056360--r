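#' Normality gate and Box-Cox transform for an outcome
#'
#' Applies the Shapiro-Wilk test; when p < `alpha` the outcome is Box-Cox
#' transformed at the profile-likelihood-maximising lambda (shifting
#' non-positive data first). Returns both the (possibly transformed) values
#' and a transform record.
#'
#' @param values Numeric outcome vector (3-5000 non-missing values).
#' @param alpha Normality-test level gating the transform (default 0.05).
#' @return List with `values` (transformed or original) and `record`, a
#'   one-row tibble (`shapiro_W`, `shapiro_p`, `transformed`, `lambda`,
#'   `shift`).
#' @export
prepare_outcome <- function(values, alpha = 0.05) {
  v <- values[!is.na(values)]
  if (length(v) < 3L) stop("need at least 3 non-missing values")
  if (stats::sd(v) == 0) stop("constant outcome: normality test undefined")
  sw <- stats::shapiro.test(v)
  if (sw$p.value >= alpha) {
    rec <- tibble::tibble(shapiro_W = unname(sw$statistic),
                          shapiro_p = sw$p.value, transformed = FALSE,
                          lambda = NA_real_, shift = 0)
    return(list(values = values, record = rec))
  }
  bc <- boxcox_transform(values)
  rec <- tibble::tibble(shapiro_W = unname(sw$statistic),
                        shapiro_p = sw$p.value, transformed = TRUE,
                        lambda = bc$lambda, shift = bc$shift)
  list(values = bc$values, record = rec)
}

#' Box-Cox power transform with maximum-likelihood lambda
#'
#' Finds the lambda maximising the Box-Cox profile log-likelihood
#' `-n/2 log sigma_hat^2(lambda) + (lambda - 1) sum log y` and applies
#' `y(lambda) = (y^lambda - 1)/lambda` (`log y` at lambda = 0). Non-positive
#' data are shifted by `-min(y)` plus a small offset first; the shift is
#' returned so the transform is reproducible.
#'
#' @param values Positive (after shift) numeric vector.
#' @param lambda_range Search interval for lambda (default `[-2, 3]`).
#' @return List with `values` (transformed), `lambda`, `shift`.
#' @export
boxcox_transform <- function(values, lambda_range = c(-2, 3)) {
  ok <- !is.na(values)
  y <- values[ok]
  if (length(y) < 3L || stats::sd(y) == 0) {
    stop("Box-Cox transform needs >= 3 non-constant values")
  }
  shift <- 0
  if (min(y) <= 0) {
    shift <- -min(y) + 0.001 * diff(range(y))
    if (shift <= -min(y)) shift <- -min(y) + 1e-8 # degenerate range guard
    y <- y + shift
  }
  log_y <- log(y)
  n <- length(y)
  profile_ll <- function(lam) {
    z <- if (abs(lam) < 1e-10) log_y else (y^lam - 1) / lam
    s2 <- mean((z - mean(z))^2)
    -n / 2 * log(s2) + (lam - 1) * sum(log_y)
  }
  opt <- stats::optimize(profile_ll, lambda_range, maximum = TRUE, tol = 1e-6)
  lambda <- opt$maximum
  transform <- function(v) {
    v <- v + shift
    if (abs(lambda) < 1e-10) log(v) else (v^lambda - 1) / lambda
  }
  out <- rep(NA_real_, length(values))
  out[ok] <- transform(values[ok])
  list(values = out, lambda = lambda, shift = shift)
}

#' Tuning grid for the elastic net
#'
#' 100 candidate models: 10 mixing values alpha linearly spaced on
#' `[0.05, 1]` crossed with 10 penalties lambda log-spaced on
#' `[0.0002, 0.36]` (the penalty range spans three decades, hence the log
#' spacing).
#'
#' @param n_alpha,n_lambda Grid resolution per axis.
#' @param alpha_range,lambda_range Axis ranges.
#' @return Tibble with columns `alpha`, `lambda` (one row per candidate).
#' @export
enet_grid <- function(n_alpha = 10, n_lambda = 10,
                      alpha_range = c(0.05, 1),
                      lambda_range = c(0.0002, 0.36)) {
  alphas <- seq(alpha_range[1], alpha_range[2], length.out = n_alpha)
  lambdas <- exp(seq(log(lambda_range[1]), log(lambda_range[2]),
                     length.out = n_lambda))
  tidyr::expand_grid(alpha = alphas, lambda = lambdas)
}

#' Cross-validated elastic net over the 100-model tuning grid
#'
#' Standardises features internally, evaluates every (alpha, lambda)
#' candidate by k-fold cross-validated RMSE, refits the minimising pair on
#' the full data, and returns the coefficients on the standardised scale
#' (so magnitudes are comparable across features).
#'
#' @param x Numeric feature matrix (subjects x features, complete cases).
#' @param y Outcome vector.
#' @param grid Tuning grid from [enet_grid()].
#' @param n_folds Cross-validation folds (default 5); reduced with a
#'   warning when `n < 2 * n_folds`.
#' @param seed Optional seed controlling the fold assignment.
#' @return List of class `fc_enet`: `alpha`, `lambda`, `cv_rmse`,
#'   `beta` (named, standardised scale), `intercept`, `cv_table` (RMSE per
#'   candidate), `n`, `n_folds`.
#' @export
fit_elastic_net_cv <- function(x, y, grid = enet_grid(), n_folds = 5,
                               seed = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), !anyNA(x), !anyNA(y))
  n <- nrow(x)
  if (n < 10L) stop("need at least 10 complete cases, have ", n)
  if (n < 2L * n_folds) {
    n_folds <- max(2L, floor(n / 2))
    warning("too few cases for requested folds; using ", n_folds, " folds")
  }
  if (!is.null(seed)) set.seed(seed)
  folds <- sample(rep(seq_len(n_folds), length.out = n))
  alphas <- sort(unique(grid$alpha))
  lambdas <- sort(unique(grid$lambda), decreasing = TRUE)

  sse <- matrix(0, length(alphas), length(lambdas),
                dimnames = list(NULL, NULL))
  for (f in seq_len(n_folds)) {
    test <- folds == f
    for (ai in seq_along(alphas)) {
      fit <- glmnet::glmnet(x[!test, , drop = FALSE], y[!test],
                            alpha = alphas[ai], lambda = lambdas,
                            standardize = TRUE)
      pred <- stats::predict(fit, newx = x[test, , drop = FALSE],
                             s = lambdas, exact = FALSE)
      sse[ai, ] <- sse[ai, ] + colSums((pred - y[test])^2)
    }
  }
  rmse <- sqrt(sse / n)
  best <- which(rmse == min(rmse), arr.ind = TRUE)[1, ]
  alpha_star <- alphas[best[1]]
  lambda_star <- lambdas[best[2]]

  full <- glmnet::glmnet(x, y, alpha = alpha_star, lambda = lambdas,
                         standardize = TRUE)
  co <- as.numeric(stats::coef(full, s = lambda_star, exact = FALSE))
  sds <- apply(x, 2, stats::sd)
  beta_std <- co[-1] * sds # coefficient per SD of the feature
  names(beta_std) <- colnames(x)

  cv_table <- tibble::tibble(
    alpha = rep(alphas, each = length(lambdas)),
    lambda = rep(lambdas, length(alphas)),
    rmse = as.vector(t(rmse))
  )
  structure(
    list(alpha = alpha_star, lambda = lambda_star,
         cv_rmse = min(rmse), beta = beta_std, intercept = co[1],
         cv_table = cv_table, n = n, n_folds = n_folds),
    class = "fc_enet"
  )
}

#' Repeated elastic-net stability selection with the 90% rule
#'
#' Repeats the cross-validated elastic net `repeats` times (default 20),
#' redrawing only the fold assignment each time (seed = `base_seed` +
#' repeat index). A feature "selected" in a repeat has a nonzero coefficient
#' in that repeat's RMSE-minimising model; features selected in at least
#' `freq_threshold` (default 90%) of repeats form the strong-association
#' set. Coefficients of strong features are averaged over the repeats where
#' they were selected and ranked proportionally, the largest magnitude set
#' to 100; direction is the sign of the simple Pearson correlation between
#' the raw feature and the raw outcome.
#'
#' @inheritParams fit_elastic_net_cv
#' @param y_raw Outcome on the original scale for the direction
#'   correlations (defaults to `y`; pass the pre-transform values when `y`
#'   was Box-Cox transformed).
#' @param repeats Number of repeats (default 20).
#' @param freq_threshold Selection-frequency cut for the strong set
#'   (default 0.9).
#' @param base_seed Base seed; repeat r uses `base_seed + r`.
#' @return List of class `fc_stability`: `selection` tibble (per feature:
#'   `feature`, `selection_count`, `selection_freq`, `strong`, `mean_beta`,
#'   `rank_percent`, `direction`), `repeats` tibble (per repeat: chosen
#'   `alpha`, `lambda`, `cv_rmse`), and the settings.
#' @export
stability_selection <- function(x, y, y_raw = y, repeats = 20,
                                freq_threshold = 0.9, grid = enet_grid(),
                                n_folds = 5, base_seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), repeats >= 1)
  p <- ncol(x)
  feats <- colnames(x)
  if (is.null(feats)) feats <- colnames(x) <- paste0("x", seq_len(p))

  sel <- matrix(FALSE, repeats, p, dimnames = list(NULL, feats))
  betas <- matrix(0, repeats, p, dimnames = list(NULL, feats))
  rep_info <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fit <- fit_elastic_net_cv(x, y, grid = grid, n_folds = n_folds,
                              seed = base_seed + r)
    sel[r, ] <- fit$beta != 0
    betas[r, ] <- fit$beta
    rep_info[[r]] <- tibble::tibble(repeat_id = r, alpha = fit$alpha,
                                    lambda = fit$lambda, cv_rmse = fit$cv_rmse,
                                    n_selected = sum(fit$beta != 0))
  }
  counts <- colSums(sel)
  strong <- counts >= ceiling(freq_threshold * repeats)
  mean_beta <- vapply(seq_len(p), function(j) {
    if (counts[j] == 0) return(0)
    mean(betas[sel[, j], j])
  }, numeric(1))
  rank_percent <- rep(NA_real_, p)
  if (any(strong)) {
    rank_percent[strong] <- rank_coefficients(mean_beta[strong])
  }
  direction <- vapply(seq_len(p), function(j) {
    r_xy <- suppressWarnings(stats::cor(x[, j], y_raw,
                                        use = "pairwise.complete.obs"))
    if (is.na(r_xy)) 0 else sign(r_xy)
  }, numeric(1))

  selection <- tibble::tibble(
    feature = feats,
    selection_count = as.integer(counts),
    selection_freq = counts / repeats,
    strong = strong,
    mean_beta = mean_beta,
    rank_percent = rank_percent,
    direction = direction
  )
  structure(
    list(selection = selection, repeats = dplyr::bind_rows(rep_info),
         n_repeats = repeats, freq_threshold = freq_threshold,
         base_seed = base_seed, n = nrow(x), n_features = p),
    class = "fc_stability"
  )
}

#' Proportional coefficient ranking
#'
#' The largest absolute mean coefficient is assigned 100; every other
#' coefficient receives `100 |beta| / max |beta|`.
#'
#' @param beta Mean coefficients of the strong-association set.
#' @return Numeric vector of rank percents (empty input gives empty output).
#' @examples
#' rank_coefficients(c(0.5, -0.25)) # 100, 50
#' @export
rank_coefficients <- function(beta) {
  if (!length(beta)) return(numeric(0))
  100 * abs(beta) / max(abs(beta))
}

#' Stability selection for every (outcome, metric) pair of a cohort
#'
#' The full graph-metric association procedure: for each clinical outcome
#' and each nodal metric (GE, CC, BC fitted as separate models), gate the
#' outcome through Shapiro-Wilk/Box-Cox, form the complete-case subjects x
#' ROI AUC feature matrix, and run [stability_selection()].
#'
#' @param auc_table Output of [graph_metric_auc()].
#' @param clinical Clinical tibble with `subject`.
#' @param measures Outcome columns (default all numeric except `subject`).
#' @param metrics Metrics to model (default GE, CC, BC).
#' @inheritParams stability_selection
#' @return Tibble of class `fc_stability_table`: one row per (measure,
#'   metric, ROI) in a strong set, with `selection_count`, `mean_beta`,
#'   `rank_percent`, `direction`, plus a `records` attribute holding the
#'   transform records and full `fc_stability` objects.
#' @export
stability_selection_all <- function(auc_table, clinical, measures = NULL,
                                    metrics = c("GE", "CC", "BC"),
                                    repeats = 20, freq_threshold = 0.9,
                                    grid = enet_grid(), n_folds = 5,
                                    base_seed = 1L) {
  if (is.null(measures)) {
    measures <- setdiff(names(clinical)[vapply(clinical, is.numeric, logical(1))],
                        "subject")
  }
  records <- list()
  rows <- list()
  for (m in measures) {
    for (g in metrics) {
      wide <- tidyr::pivot_wider(
        dplyr::filter(auc_table, .data$metric == g),
        id_cols = "subject", names_from = "node", values_from = "auc")
      y_all <- clinical[[m]][match(wide$subject, clinical$subject)]
      ok <- stats::complete.cases(as.data.frame(wide[-1])) & !is.na(y_all)
      x <- as.matrix(wide[ok, -1])
      y_raw <- y_all[ok]
      if (length(y_raw) < 10L) next
      prep <- prepare_outcome(y_raw)
      res <- stability_selection(x, prep$values, y_raw = y_raw,
                                 repeats = repeats,
                                 freq_threshold = freq_threshold,
                                 grid = grid, n_folds = n_folds,
                                 base_seed = base_seed)
      key <- paste(m, g, sep = ".")
      records[[key]] <- list(transform = prep$record, fit = res)
      strong <- dplyr::filter(res$selection, .data$strong)
      if (nrow(strong)) {
        rows[[key]] <- dplyr::mutate(
          dplyr::select(strong, node = "feature", "selection_count",
                        "mean_beta", "rank_percent", "direction"),
          measure = m, metric = g, n = res$n, .before = 1)
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(measure = character(), metric = character(), n = integer(),
                   node = character(), selection_count = integer(),
                   mean_beta = numeric(), rank_percent = numeric(),
                   direction = numeric())
  attr(out, "records") <- records
  class(out) <- c("fc_stability_table", class(out))
  out
}
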