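test_that("absorbing bent state: zero off-rate and no incision gives one transition", {
  m <- kinetic_model(k_on = 1e8, conc = 50, k_off = 0, cleavable = FALSE,
                     kb_d = 0, kb_a = 0)
  p <- simulate_state_path(m, duration = 30, seed = 1)
  expect_identical(p$state, c("UNBENT", "BENT"))
  expect_equal(p$t_end[2], 30)
})

test_that("simulated dwells are exponential at the scheme rates", {
  # records much longer than the dwells, so that interior-dwell selection
  # (which discards boundary-truncated dwells) cannot distort the sample
  m <- kinetic_model(k_on = 1.4e8, conc = 20, k_off = 0.45, cleavable = FALSE,
                     kb_d = 0, kb_a = 0)
  set.seed(2)
  paths <- lapply(1:15, function(i) simulate_state_path(m, 2000))
  for (case in list(list(state = "UNBENT", rate = m$k_bind),
                    list(state = "BENT", rate = m$k_off))) {
    d <- extract_dwells(paths, case$state)
    x <- d$duration[!d$censored]
    expect_gt(length(x), 1e4)
    se <- (1 / case$rate) / sqrt(length(x))
    expect_lt(abs(mean(x) - 1 / case$rate), 2 * se)
    # and the full distribution matches Exp(rate) by KS
    expect_gt(stats::ks.test(x, "pexp", case$rate)$p.value, 0.01)
  }
})

test_that("cognate kinetics: nearly every bent entry ends in incision", {
  m <- kinetic_preset("NonEQ_DF61_flap", conc = 20, kb_d = 0, kb_a = 0)
  set.seed(4)
  n_bent <- 0; n_cleaved <- 0
  for (i in 1:2000) {
    p <- simulate_state_path(m, 60)
    n_bent <- n_bent + sum(p$state == "BENT")
    n_cleaved <- n_cleaved + attr(p, "cleaved")
  }
  expect_gte(n_cleaved / n_bent, 0.99)
})

test_that("seeded path and trace generation is bit-reproducible", {
  m <- kinetic_preset("EQ_DF61_dsdna", conc = 20)
  p1 <- simulate_state_path(m, 30, seed = 11)
  p2 <- simulate_state_path(m, 30, seed = 11)
  expect_identical(p1, p2)
  t1 <- emit_trace(p1, m, 0.05, seed = 12)
  t2 <- emit_trace(p2, m, 0.05, seed = 12)
  expect_identical(t1$donor, t2$donor)
  expect_identical(t1$acceptor, t2$acceptor)
})

test_that("emission symmetry and photon conservation", {
  m <- kinetic_model(k_on = 0, conc = 0, k_off = 0, E_unbent = 0.5,
                     E_bent = 0.5, sigma_E = 0, I_total = 300,
                     bg_d = 0, bg_a = 0, kb_d = 0, kb_a = 0)
  p <- simulate_state_path(m, 200, seed = 5)  # stays unbent at E = 0.5
  tr <- emit_trace(p, m, 0.1, seed = 6)
  n <- length(tr$donor)
  se <- sqrt(150 / n)
  expect_lt(abs(mean(tr$donor) - mean(tr$acceptor)), 4 * se)
  # total counts per frame match I_total + backgrounds
  m2 <- kinetic_preset("EQ_DF61_dsdna", conc = 20, kb_d = 0, kb_a = 0)
  p2 <- simulate_state_path(m2, 100, seed = 7)
  tr2 <- emit_trace(p2, m2, 0.05, seed = 8)
  expected <- m2$I_total + m2$bg_d + m2$bg_a
  se2 <- sqrt(expected / length(tr2$donor))
  expect_lt(abs(mean(tr2$donor + tr2$acceptor) - expected), 4 * se2)
})

test_that("a frame straddling a transition reports intermediate FRET", {
  m <- kinetic_model(k_on = 1e9, conc = 100, k_off = 0, E_unbent = 0.2,
                     E_bent = 0.8, sigma_E = 0, I_total = 1e5,
                     bg_d = 0, bg_a = 0, kb_d = 0, kb_a = 0)
  # transition exactly mid-frame: frame 5 of dt = 0.1 covers [0.4, 0.5)
  p <- manual_path(c("UNBENT", "BENT"), c(0, 0.45, 1), duration = 1)
  tr <- emit_trace(p, m, dt = 0.1, seed = 9)
  expect_lt(abs(tr$e_app[5] - 0.5), 0.02)   # convex average of 0.2 and 0.8
  expect_lt(abs(tr$e_app[1] - 0.2), 0.02)
  expect_lt(abs(tr$e_app[10] - 0.8), 0.02)
})

test_that("after incision the donor channel holds only background", {
  m <- kinetic_preset("NonEQ_DF61_flap", conc = 100, kb_d = 0, kb_a = 0)
  p <- manual_path(c("UNBENT", "BENT", "CLEAVED"), c(0, 1, 2, 10),
                   duration = 10)
  tr <- emit_trace(p, m, dt = 0.05, seed = 10)
  post <- tr$donor[50:200]
  expect_lt(abs(mean(post) - m$bg_d), 3 * sqrt(m$bg_d / length(post)) + 0.5)
})

test_that("burst simulation: photons stay inside bursts when background is zero", {
  m <- kinetic_model(E_unbent = 0.5, E_bent = 0.5, k_off = 0, conc = 0)
  s <- simulate_burst_set(m, n_bursts = 1, seed = 13, p_bent = 1, bg_rate = 0)
  truth <- attr(s, "truth")
  expect_true(all(s$t >= truth$start[1] & s$t <= truth$end[1]))
  expect_identical(nrow(s), as.integer(truth$n_photons[1]))
})

test_that("decay simulation recovers a single lifetime by MLE", {
  dc <- simulate_decay(data.frame(amplitude = 1, tau_ns = 2.5),
                       irf_width = 1e-9, n_photons = 20000, seed = 14)
  # with a negligible IRF the delays are a plain exponential; MLE = mean
  delays <- rep(dc$time_ns, dc$counts) - dc$t0
  tau_hat <- mean(delays)
  se <- tau_hat / sqrt(sum(dc$counts))
  expect_lt(abs(tau_hat - 2.5), 3 * se + 0.05)  # allow histogram binning bias
})

test_that("reconvolution fit recovers a two-component decay and its weighted mean", {
  dc <- simulate_decay(data.frame(amplitude = c(0.5, 0.5), tau_ns = c(1, 4)),
                       irf_width = 0.2, n_photons = 2e5, seed = 15)
  fd <- fit_decay(dc, n_components = 2)
  expect_lt(abs(fd$tau_avg_ns - 2.5), 0.15)
  expect_lt(abs(fd$tau_ns[1] - 1), 0.2)
  expect_lt(abs(fd$tau_ns[2] - 4), 0.4)
})

test_that("a zero-amplitude component reduces the fit to a single exponential", {
  dc <- simulate_decay(data.frame(amplitude = c(1, 0), tau_ns = c(2, 8)),
                       irf_width = 0.1, n_photons = 5e4, seed = 16)
  f1 <- fit_decay(dc, n_components = 1)
  expect_lt(abs(f1$tau_avg_ns - 2), 0.1)
})

test_that("invalid kinetic models are rejected", {
  expect_error(kinetic_model(k_on = -1), "finite")
  expect_error(kinetic_model(E_bent = 1.4), "0, 1")
  expect_error(kinetic_model(n_step = 0), "n_step")
  expect_error(simulate_state_path(kinetic_model(), duration = -1), "> 0")
})
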