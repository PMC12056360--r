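test_that("normality gate transforms only non-normal outcomes", {
  set.seed(61)
  normal_y <- stats::rnorm(200)
  prep_n <- prepare_outcome(normal_y)
  expect_false(prep_n$record$transformed)
  expect_identical(prep_n$values, normal_y)
  skewed_y <- exp(stats::rnorm(200))
  prep_s <- prepare_outcome(skewed_y)
  expect_true(prep_s$record$transformed)
  expect_lt(prep_s$record$shapiro_p, 0.05)
  expect_error(prepare_outcome(c(1, 2)), "3")
  expect_error(prepare_outcome(rep(1, 10)), "constant")
})

test_that("Box-Cox lambda recovery and agreement with the MASS oracle", {
  skip_if_not_installed("MASS")
  set.seed(62)
  # lognormal: lambda ~ 0 and transform ~ log
  y <- exp(stats::rnorm(500))
  bc <- boxcox_transform(y)
  expect_lt(abs(bc$lambda), 0.15)
  # already normal (positive): lambda ~ 1
  y1 <- stats::rnorm(500, 50, 5)
  expect_lt(abs(boxcox_transform(y1)$lambda - 1), 0.5)
  # oracle: MASS profile likelihood over a fine grid
  oracle <- MASS::boxcox(y ~ 1, lambda = seq(-1, 1, 0.001), plotit = FALSE)
  lambda_mass <- oracle$x[which.max(oracle$y)]
  expect_lt(abs(bc$lambda - lambda_mass), 0.01)
})

test_that("lambda = 0 branch equals the log transform", {
  y <- c(0.5, 1, 2, 4, 8, 16, 32, 64, 128, 256) # exact geometric: lambda -> 0
  bc <- boxcox_transform(y)
  expect_lt(abs(bc$lambda), 0.02)
  direct_log <- log(y + bc$shift)
  if (abs(bc$lambda) < 1e-10) {
    expect_equal(bc$values, direct_log, tolerance = 1e-12)
  }
  # non-positive data are shifted, transform still finite
  bc_shift <- boxcox_transform(c(-2, 0, 1, 3, 5, 8, 2, 4, 7, 9))
  expect_gt(bc_shift$shift, 2)
  expect_true(all(is.finite(bc_shift$values)))
})

test_that("the tuning grid has 100 candidates over the stated ranges", {
  g <- enet_grid()
  expect_equal(nrow(g), 100)
  expect_equal(range(g$alpha), c(0.05, 1))
  expect_equal(range(g$lambda), c(0.0002, 0.36), tolerance = 1e-12)
  # lambda log-spaced: ratios constant
  l <- sort(unique(g$lambda))
  expect_equal(diff(log(l)), rep(diff(log(l))[1], 9), tolerance = 1e-10)
})

test_that("cross-validated elastic net finds a planted predictor", {
  set.seed(63)
  n <- 100
  x <- matrix(stats::rnorm(n * 24), n, dimnames = list(NULL, paste0("f", 1:24)))
  y <- x[, 1]
  fit <- fit_elastic_net_cv(x, y, seed = 1)
  expect_s3_class(glance(fit), "tbl_df")
  expect_gt(abs(fit$beta["f1"]), 0)
  expect_true(all(abs(fit$beta[-1]) < abs(fit$beta["f1"])))
  expect_equal(nrow(fit$cv_table), 100)
  td <- tidy(fit)
  expect_equal(td$selected, fit$beta != 0, ignore_attr = TRUE)
})

test_that("a pure-noise outcome selects almost nothing on average", {
  set.seed(64)
  counts <- vapply(1:20, function(r) {
    x <- matrix(stats::rnorm(40 * 10), 40)
    y <- stats::rnorm(40)
    fit <- fit_elastic_net_cv(x, y, seed = r)
    sum(fit$beta != 0)
  }, numeric(1))
  expect_lte(stats::median(counts), 2)
})

test_that("duplicated features are not co-selected at the lasso end", {
  set.seed(65)
  n <- 60
  x1 <- stats::rnorm(n)
  x <- cbind(a = x1, b = x1, c = stats::rnorm(n))
  y <- 2 * x1 + stats::rnorm(n, sd = 0.1)
  fit <- glmnet::glmnet(x, y, alpha = 1, lambda = c(0.5, 0.2, 0.1, 0.05))
  beta <- as.numeric(stats::coef(fit, s = 0.05))[-1]
  # lasso concentrates the twins' shared signal on one of them
  expect_lt(min(abs(beta[1:2])), 1e-8)
  expect_gt(max(abs(beta[1:2])), 1)
})

test_that("stability selection is deterministic and ranks proportionally", {
  set.seed(66)
  n <- 40
  x <- matrix(stats::rnorm(n * 8), n, dimnames = list(NULL, paste0("f", 1:8)))
  y <- 1.0 * x[, 1] - 0.5 * x[, 2] + stats::rnorm(n, sd = 0.4)
  res1 <- stability_selection(x, y, repeats = 10, base_seed = 7)
  res2 <- stability_selection(x, y, repeats = 10, base_seed = 7)
  expect_identical(res1$selection, res2$selection)
  sel <- res1$selection
  expect_true(all(sel$selection_count >= 0 & sel$selection_count <= 10))
  strong <- sel[sel$strong, ]
  expect_true(all(c("f1", "f2") %in% strong$feature))
  expect_equal(max(strong$rank_percent), 100)
  expect_equal(sum(strong$rank_percent == 100), 1)
  expect_equal(strong$rank_percent,
               100 * abs(strong$mean_beta) / max(abs(strong$mean_beta)))
  expect_equal(strong$direction[strong$feature == "f1"], 1)
  expect_equal(strong$direction[strong$feature == "f2"], -1)
})

test_that("rank_coefficients assigns 100 to the largest magnitude", {
  expect_equal(rank_coefficients(c(0.5, 0.25)), c(100, 50))
  expect_equal(rank_coefficients(0.3), 100)
  expect_equal(rank_coefficients(c(-0.4, 0.2)), c(100, 50))
  expect_equal(rank_coefficients(numeric(0)), numeric(0))
})

test_that("rescaling a feature column leaves the selected set unchanged", {
  set.seed(67)
  n <- 50
  x <- matrix(stats::rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  y <- x[, 1] + 0.8 * x[, 3] + stats::rnorm(n, sd = 0.3)
  x_scaled <- x
  x_scaled[, 3] <- x_scaled[, 3] * 1000
  r1 <- stability_selection(x, y, repeats = 5, base_seed = 3)
  r2 <- stability_selection(x_scaled, y, repeats = 5, base_seed = 3)
  expect_equal(r1$selection$selection_count, r2$selection$selection_count)
  expect_equal(r1$selection$strong, r2$selection$strong)
})

test_that("full procedure recovers a planted nodal effect end-to-end", {
  pn <- data.frame(roi = c("Ip_M1", "C_S1"), metric = "GE", effect = c(3, 3))
  cfg <- sim_config(n_subjects = 37, roi_set = roi_set("cortical_SMN"),
                    n_timepoints = 300, planted_nodes = pn,
                    noise_sd = 0.02, edge_modulation = 0.12, seed = 68)
  co <- simulate_cohort(cfg)
  edges <- connectivity_matrices(co$panel)
  auc_tab <- graph_metric_auc(edges)
  res <- stability_selection_all(auc_tab, co$clinical, measures = "FM",
                                 metrics = "GE", repeats = 10, base_seed = 1)
  expect_true(all(c("Ip_M1", "C_S1") %in% res$node))
  recs <- attr(res, "records")
  expect_named(recs, "FM.GE")
  expect_s3_class(glance(recs$FM.GE$fit), "tbl_df")
})
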