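test_that("dwell extraction flags boundary and terminally-cut segments as censored", {
  p <- manual_path(c("UNBENT", "BENT", "UNBENT"), c(0, 0.1, 0.4, 1),
                   duration = 1, dt = 0.1)
  d <- extract_dwells(p, "BENT")
  expect_equal(nrow(d), 1)
  expect_equal(d$duration, 0.3)
  expect_false(d$censored)   # interior dwell

  # trace ending bent: that dwell is right-censored
  p2 <- manual_path(c("UNBENT", "BENT"), c(0, 0.5, 2), duration = 2, dt = 0.1)
  d2 <- extract_dwells(p2, "BENT")
  expect_true(d2$censored)
  expect_identical(d2$side, "right")

  # dwell cut by incision is censored even mid-trace
  p3 <- manual_path(c("UNBENT", "BENT", "CLEAVED"), c(0, 0.5, 1, 3),
                    duration = 3, dt = 0.1)
  d3 <- extract_dwells(p3, "BENT")
  expect_true(d3$censored)
  expect_identical(d3$side, "right")

  expect_equal(nrow(extract_dwells(list(), "BENT")), 0)
})

test_that("the MLE rate is the reciprocal mean", {
  d <- structure(data.frame(duration = c(1, 2, 3), censored = FALSE,
                            side = "interior"),
                 state = "BENT", dt = NA_real_,
                 class = c("dwell_set", "data.frame"))
  est <- fit_exponential(d, "mle")
  expect_equal(est$k, 0.5)
  expect_equal(est$se, 0.5 / sqrt(3))
})

test_that("histogram least squares and MLE agree on a large exponential sample", {
  set.seed(41)
  x <- stats::rexp(10000, rate = 2)
  d <- structure(data.frame(duration = x, censored = FALSE, side = "interior"),
                 state = "BENT", dt = NA_real_,
                 class = c("dwell_set", "data.frame"))
  k_h <- fit_exponential(d, "hist_lsq")$k
  k_m <- fit_exponential(d, "mle")$k
  expect_lt(abs(k_h - k_m) / k_m, 0.05)
})

test_that("simulated bent dwells recover the unbending rate within 2 SE", {
  m <- kinetic_model(k_on = 1.4e8, conc = 20, k_off = 0.45,
                     cleavable = FALSE, kb_d = 0, kb_a = 0)
  set.seed(42)
  paths <- lapply(1:300, function(i) {
    p <- simulate_state_path(m, 60)
    attr(p, "dt") <- 0.05
    p
  })
  est <- fit_exponential(extract_dwells(paths, "BENT"), "mle_censored",
                         dt = 0.05)
  expect_lt(abs(est$k - 0.45), 2 * est$se)
})

test_that("censored dwells alone cannot be fitted", {
  d <- structure(data.frame(duration = c(1, 2), censored = TRUE,
                            side = "right"),
                 state = "BENT", dt = NA_real_,
                 class = c("dwell_set", "data.frame"))
  expect_error(fit_exponential(d, "mle_censored"), "censored")
})

test_that("the concentration series yields k_on from the slope and the K_d identity", {
  s <- data.frame(conc_nM = c(10, 30, 50),
                  k_bending = c(1.4, 4.2, 7.0), se_bending = 0.05,
                  k_unbending = c(0.45, 0.45, 0.45), se_unbending = 0.02)
  fit <- fit_concentration_series(s)
  expect_equal(fit$k_on, 1.4e8, tolerance = 1e-6)
  expect_equal(fit$k_off, 0.45)
  expect_equal(fit$K_d_nM, 0.45 / 1.4e8 * 1e9, tolerance = 1e-6)
  expect_equal(fit$K_d_nM, 3.214286, tolerance = 1e-4)
  # identity holds by construction
  expect_identical(fit$K_d_nM, fit$k_off / fit$k_on * 1e9)
})

test_that("a negative concentration slope is rejected as unphysical", {
  s <- data.frame(conc_nM = c(10, 30, 50),
                  k_bending = c(7, 4, 1), se_bending = 0.05,
                  k_unbending = 0.45, se_unbending = 0.02)
  expect_error(fit_concentration_series(s), "unphysical")
})

test_that("missed-event correction restores merged-dwell rates", {
  # simulation oracle: alternate exponential dwells, erase every opposite-state
  # gap shorter than the dead time, and concatenate across the erased gaps
  set.seed(40)
  k1 <- 7; k2 <- 0.45; td <- 0.75 * 0.05
  n <- 40000
  bent <- stats::rexp(n, k2)
  gaps <- stats::rexp(n - 1, k1)
  merged <- gaps < td
  grp <- cumsum(c(TRUE, !merged))
  obs <- as.numeric(rowsum(bent, grp)) +
    as.numeric(rowsum(c(gaps * merged, 0), grp))
  k2_obs <- 1 / mean(obs)
  expect_lt(k2_obs, 0.9 * k2)  # merging bias is material before correction
  corr <- correct_missed_events(k1, k2_obs, dt = 0.05)
  expect_lt(abs(corr$k_unbending - k2) / k2, 0.03)
})

test_that("Michaelis-Menten fit is exact on noiseless hyperbola points", {
  conc <- c(0.5, 1, 2, 4, 8, 16)
  v0 <- 12 * conc / (3 + conc)
  fit <- fit_michaelis_menten(conc, v0)
  expect_equal(fit$Km, 3, tolerance = 1e-6)
  expect_equal(fit$Vmax, 12, tolerance = 1e-6)
  # definition check: v0 at c = Km is Vmax / 2
  expect_equal(12 * 3 / (3 + 3), fit$Vmax / 2)
})

test_that("Michaelis-Menten fit tolerates realistic noise", {
  set.seed(43)
  conc <- c(0.5, 1, 2, 4, 8, 16, 32, 64)
  v0 <- 12 * conc / (3 + conc) + stats::rnorm(8, 0, 0.6)
  fit <- fit_michaelis_menten(conc, v0)
  expect_lt(abs(fit$Km - 3) / 3, 0.2)
})

test_that("full simulated series: k_unbending shows no concentration trend", {
  m <- kinetic_preset("EQ_DF61_dsdna")
  set.seed(44)
  ex <- bending_series_experiment(m, concs = c(5, 10, 20, 50), n_traces = 60,
                                  duration = 60, dt = 0.05)
  s <- ex$series
  lmfit <- stats::lm(k_unbending ~ conc_nM, data = s,
                     weights = 1 / s$se_unbending^2)
  cf <- summary(lmfit)$coefficients
  ci <- cf["conc_nM", "Estimate"] + c(-2, 2) * cf["conc_nM", "Std. Error"]
  expect_true(ci[1] <= 0 && ci[2] >= 0)
})
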