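test_that("identical config and seed reproduce the cohort bit for bit", {
  co1 <- small_cohort(seed = 41, outlier_frame_rate = 0.1,
                      confound_strength = 0.5)
  co2 <- small_cohort(seed = 41, outlier_frame_rate = 0.1,
                      confound_strength = 0.5)
  expect_identical(co1$panel$series, co2$panel$series)
  expect_identical(co1$clinical, co2$clinical)
  expect_identical(co1$truth, co2$truth)
})

test_that("null construction: no planted effect, no score-edge correlation", {
  cfg <- sim_config(n_subjects = 200, roi_set = roi_set("cortical_SMN"),
                    n_timepoints = 60, noise_sd = 1, seed = 42)
  co <- simulate_cohort(cfg)
  edges <- connectivity_matrices(co$panel)
  wide <- tidyr::pivot_wider(edges, id_cols = c("roi_i", "roi_j"),
                             names_from = "subject", values_from = "z")
  zmat <- as.matrix(wide[, -(1:2)])
  y <- co$clinical$FM[match(colnames(zmat), co$clinical$subject)]
  cors <- apply(zmat, 1, stats::cor, y = y)
  expect_true(all(abs(cors) < 0.2))
})

test_that("a strongly planted edge is the smallest-p edge downstream", {
  cfg <- sim_config(n_subjects = 100, roi_set = roi_set("cortical_SMN"),
                    n_timepoints = 150,
                    planted_edges = data.frame(roi_i = "Ip_M1", roi_j = "C_M1",
                                               effect = 1),
                    noise_sd = 0.1, seed = 43)
  co <- simulate_cohort(cfg)
  edges <- connectivity_matrices(co$panel)
  tab <- fit_edgewise(edges, co$clinical, "FM")
  top <- tab[which.min(tab$p), ]
  expect_setequal(c(top$roi_i, top$roi_j), c("Ip_M1", "C_M1"))
  # oracle: correlation of the planted true z with the score is strong
  oracle_r <- stats::cor(co$truth$true_predictors[, 1], co$clinical$FM)
  expect_gt(abs(oracle_r), 0.9)
})

test_that("planted effects never shrink mean |t| at the edge as they grow", {
  mean_abs_t <- vapply(c(0, 0.5, 2), function(eff) {
    ts <- vapply(1:6, function(rep) {
      cfg <- sim_config(n_subjects = 37, roi_set = roi_set("cortical_SMN"),
                        n_timepoints = 100,
                        planted_edges = data.frame(roi_i = "Ip_M1",
                                                   roi_j = "C_M1",
                                                   effect = eff),
                        noise_sd = 0.3, seed = 4300 + rep)
      co <- simulate_cohort(cfg)
      tab <- fit_edgewise(connectivity_matrices(co$panel), co$clinical, "FM")
      abs(tab$t[tab$roi_i == "Ip_M1" & tab$roi_j == "C_M1"])
    }, numeric(1))
    mean(ts)
  }, numeric(1))
  expect_true(all(diff(mean_abs_t) > 0))
})

test_that("lower-is-better target measures carry the negated latent score", {
  pe <- data.frame(roi_i = "Ip_M1", roi_j = "C_M1", effect = 1)
  cfg <- sim_config(n_subjects = 80, roi_set = roi_set("cortical_SMN"),
                    n_timepoints = 60, planted_edges = pe, noise_sd = 0.05,
                    target_measure = "TUG", seed = 44)
  co <- simulate_cohort(cfg)
  expect_lt(stats::cor(co$truth$scores_pre_noise, co$clinical$TUG), -0.9)
  expect_false(attr(co$clinical, "higher_is_better")[["TUG"]])
})

test_that("motion traces respect the spike rate and the 0.9 mm baseline cap", {
  t0 <- simulate_motion_trace(300, 0, seed = 45)
  expect_true(all(t0$fd < 0.9))
  expect_false(any(t0$spike))
  t1 <- simulate_motion_trace(200, 0.1, seed = 45)
  n_spikes <- sum(t1$spike)
  expect_true(abs(n_spikes - 20) <= 3 * sqrt(200 * 0.1 * 0.9))
  expect_true(all(t1$fd[t1$spike] > 0.9))
  expect_identical(t1, simulate_motion_trace(200, 0.1, seed = 45))
})

test_that("lesion volume construction honours the requested profiles", {
  v <- simulate_lesion_volumes(c(4, 4, 3), c(10, 5, 10), c(2, 5, 0))
  expect_equal(cst_slice_areas(v$cst), c(10L, 5L, 10L))
  expect_equal(as.integer(apply(v$lesion * v$cst, 3, sum)), c(2L, 5L, 0L))
  expect_equal(v$true_lesion_load, 12)
  expect_equal(weighted_lesion_load(v$lesion, v$cst), v$true_lesion_load)
  v0 <- simulate_lesion_volumes(c(3, 3, 2), c(4, 4), c(0, 0))
  expect_equal(v0$true_lesion_load, 0)
  vfull <- simulate_lesion_volumes(c(3, 3, 2), c(4, 2), c(4, 2))
  expect_equal(as.integer(apply(vfull$lesion * vfull$cst, 3, sum)),
               cst_slice_areas(vfull$cst))
  expect_error(simulate_lesion_volumes(c(3, 3, 2), c(4, 2), c(5, 0)),
               "exceeds")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(outlier_frame_rate = 0.7), "outlier_frame_rate")
  expect_error(sim_config(planted_edges = data.frame(roi_i = "nope",
                                                     roi_j = "C_M1",
                                                     effect = 1)),
               "unknown ROI")
  base <- matrix(0.95, 12, 12); diag(base) <- 1
  cfg <- sim_config(roi_set = roi_set("cortical_SMN"), base_covariance = base,
                    planted_edges = data.frame(roi_i = "Ip_M1", roi_j = "C_M1",
                                               effect = 1),
                    edge_modulation = 3, seed = 46)
  expect_error(simulate_cohort(cfg), "positive definite")
})
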