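make_panel <- function(x, tr = 3, confounds = NULL, fd = NULL, flags = NULL) {
  fc_panel(list(s1 = x), tr_seconds = tr,
           confounds = if (!is.null(confounds)) list(s1 = confounds),
           fd = if (!is.null(fd)) list(s1 = fd),
           outlier_flags = if (!is.null(flags)) list(s1 = flags))
}

test_that("outlier frames follow the FD-or-global-signal rule", {
  expect_equal(detect_outlier_frames(c(0.1, 1.0, 0.2), c(0, 0, 0)),
               c(FALSE, TRUE, FALSE))
  gs <- c(rep(0, 60), 50, rep(0, 60)) # lone spike far beyond 5 SD
  flags <- detect_outlier_frames(rep(0, 121), gs)
  expect_equal(which(flags), 61L)
  expect_false(any(detect_outlier_frames(stats::runif(50, 0, 3),
                                         stats::rnorm(50),
                                         fd_threshold_mm = Inf,
                                         gs_sd_threshold = Inf)))
  expect_error(detect_outlier_frames(numeric(0), numeric(0)), "empty")
})

test_that("confound regression produces OLS residuals orthogonal to confounds", {
  set.seed(31)
  nt <- 100
  conf <- matrix(stats::rnorm(2 * nt), 2)
  e <- stats::rnorm(nt)
  x <- rbind(a = 2 * conf[1, ] + e,
             b = conf[1, ], # identical to a confound: residual ~ 0
             c = stats::rnorm(nt))
  out <- regress_confounds(make_panel(x, confounds = conf))$series$s1
  expect_lt(max(abs(out["b", ])), 1e-10)
  expect_gt(stats::cor(out["a", ], e), 0.98)
  # residuals orthogonal to design (relative scale)
  expect_lt(max(abs(out %*% t(conf))) / max(abs(x)), 1e-8)
  # oracle: plain lm residuals
  expect_equal(out["a", ], unname(stats::residuals(stats::lm(x["a", ] ~ t(conf)))),
               tolerance = 1e-10)
})

test_that("intercept-only confound regression demeans the series", {
  x <- rbind(a = 1:20 + 5, b = rep(3, 20) + stats::rnorm(20))
  out <- regress_confounds(make_panel(x))$series$s1
  expect_equal(rowMeans(out), c(a = 0, b = 0))
  expect_equal(out["a", ], x["a", ] - mean(x["a", ]))
})

test_that("rank-deficient confounds are reduced with a warning", {
  set.seed(32)
  conf <- matrix(stats::rnorm(40), 2, 20)
  conf <- rbind(conf, conf[1, ] * 2) # dependent row
  x <- matrix(stats::rnorm(3 * 20), 3, dimnames = list(c("a", "b", "c"), NULL))
  expect_warning(out <- regress_confounds(make_panel(x, confounds = conf)),
                 "rank-deficient")
  expect_false(anyNA(out$series$s1))
})

test_that("band-pass keeps in-band sinusoids and removes DC and high bands", {
  tr <- 3
  nt <- 400
  tt <- (seq_len(nt) - 1) * tr
  inband <- sin(2 * pi * 0.05 * tt)
  x <- rbind(a = inband + 7, # DC offset must vanish
             b = sin(2 * pi * 0.15 * tt), # above the 0.09 Hz cut
             c = stats::rnorm(nt))
  out <- bandpass_filter(make_panel(x, tr = tr))$series$s1
  amp_ratio <- stats::sd(out["a", ]) / stats::sd(inband)
  expect_gt(amp_ratio, 0.9)
  expect_lt(abs(mean(out["a", ])), 1e-8)
  expect_lt(stats::sd(out["b", ]) / stats::sd(x["b", ]), 0.1)
  expect_lt(stats::var(out["c", ]), stats::var(x["c", ]))
})

test_that("band edges above Nyquist are rejected citing TR", {
  x <- matrix(stats::rnorm(60), 3, dimnames = list(c("a", "b", "c"), NULL))
  expect_error(bandpass_filter(make_panel(x, tr = 3), high_hz = 0.9), "TR")
})

test_that("scrubbing deletes flagged frames and flags unusable subjects", {
  set.seed(33)
  x <- matrix(stats::rnorm(3 * 200), 3, dimnames = list(c("a", "b", "c"), NULL))
  flags <- rep(FALSE, 200); flags[c(5, 60, 150)] <- TRUE
  out <- scrub(make_panel(x, flags = flags))
  expect_equal(ncol(out$series$s1), 197)
  expect_equal(out$series$s1, x[, !flags])
  # no flags: unchanged
  out0 <- scrub(make_panel(x, flags = rep(FALSE, 200)))
  expect_equal(out0$series$s1, x)
  # all frames flagged: unusable
  expect_error(scrub(make_panel(x, flags = rep(TRUE, 200))), "unusable")
  dropped <- scrub(make_panel(x, flags = rep(TRUE, 200)), drop_unusable = TRUE)
  expect_length(dropped$series, 0)
  expect_match(dropped$log$event, "excluded")
})

test_that("confound regression is near-idempotent", {
  set.seed(34)
  conf <- matrix(stats::rnorm(3 * 120), 3)
  x <- matrix(stats::rnorm(4 * 120), 4,
              dimnames = list(paste0("r", 1:4), NULL))
  p <- make_panel(x, confounds = conf)
  once <- regress_confounds(p)
  twice <- regress_confounds(once)
  expect_lt(max(abs(once$series$s1 - twice$series$s1)), 1e-6)
})

test_that("denoising does not inflate group variance of edge correlations", {
  co <- small_cohort(seed = 35, n_subjects = 8, confound_strength = 1,
                     outlier_frame_rate = 0.05)
  rs <- roi_set("cortical_SMN")
  raw_edges <- connectivity_matrices(co$panel, rs)
  den_edges <- connectivity_matrices(preprocess_panel(co$panel), rs)
  var_raw <- stats::var(raw_edges$r)
  var_den <- stats::var(den_edges$r)
  expect_lte(var_den, var_raw)
})
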