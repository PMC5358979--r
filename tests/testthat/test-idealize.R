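test_that("forward log-likelihood matches exhaustive path enumeration", {
  set.seed(21)
  mu <- c(0.3, 0.6); sigma <- c(0.05, 0.08)
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  init <- c(0.4, 0.6)
  for (T in c(5, 8)) {
    obs <- stats::runif(T, 0.2, 0.7)
    fb <- fenkin:::.fb_two_state(obs, mu, sigma, A, init)
    expect_equal(fb$loglik, brute_force_loglik(obs, mu, sigma, A, init),
                 tolerance = 1e-10)
    # posteriors are proper probabilities
    expect_true(all(abs(rowSums(fb$gamma) - 1) < 1e-9))
  }
})

test_that("Viterbi decoding matches exhaustive argmax", {
  set.seed(22)
  mu <- c(0.3, 0.6); sigma <- c(0.06, 0.06)
  A <- matrix(c(0.85, 0.15, 0.25, 0.75), 2, 2, byrow = TRUE)
  init <- c(0.5, 0.5)
  for (rep in 1:5) {
    T <- sample(4:8, 1)
    obs <- stats::runif(T, 0.2, 0.7)
    dec <- fenkin:::.viterbi_two_state(obs, mu, sigma, A, init) + 1L
    expect_identical(as.integer(dec),
                     as.integer(brute_force_viterbi(obs, mu, sigma, A, init)))
  }
})

test_that("EM recovers a noiseless alternating two-level signal", {
  e <- rep(c(0.3, 0.3, 0.3, 0.6, 0.6), 20)
  I <- 1e5
  tr <- new_trace(donor = round(I * (1 - e)), acceptor = round(I * e),
                  dt = 0.1, meta = list(bg_d = 0, bg_a = 0))
  fit <- fit_two_state_hmm(tr)
  expect_lt(abs(fit$mu[1] - 0.3), 0.005)
  expect_lt(abs(fit$mu[2] - 0.6), 0.005)
  expect_true(all(fit$sigma <= 0.02))  # driven to the variance floor
})

test_that("EM log-likelihood is non-decreasing on simulated traces", {
  m <- kinetic_preset("EQ_DF61_dsdna", conc = 20)
  set.seed(23)
  for (i in 1:5) {
    tr <- emit_trace(simulate_state_path(m, 60), m, 0.05)
    fit <- fit_two_state_hmm(tr)
    expect_true(all(diff(fit$loglik_trace) > -1e-7))
  }
})

test_that("state means of the equilibrated-substrate simulation are recovered within 0.02", {
  # moderate concentration so both conformers dwell for many frames:
  # frames straddling transitions carry averaged FRET and would otherwise
  # drag the mean of whichever state has the shorter dwells
  m <- kinetic_preset("EQ_DF61_dsdna", conc = 5, kb_d = 0, kb_a = 0)
  set.seed(24)
  mus <- t(vapply(1:15, function(i) {
    tr <- emit_trace(simulate_state_path(m, 60), m, 0.05)
    fit_two_state_hmm(tr)$mu
  }, numeric(2)))
  expect_lt(abs(stats::median(mus[, 1]) - 0.27), 0.02)
  expect_lt(abs(stats::median(mus[, 2]) - 0.54), 0.02)
})

test_that("decoded path equals the truth path at high SNR", {
  m <- kinetic_model(k_on = 1.4e8, conc = 20, k_off = 0.45,
                     E_unbent = 0.2, E_bent = 0.8, sigma_E = 0.02,
                     I_total = 2000, bg_d = 5, bg_a = 5, kb_d = 0, kb_a = 0)
  set.seed(25)
  p <- simulate_state_path(m, 60)
  tr <- emit_trace(p, m, 0.05)
  fit <- fit_two_state_hmm(tr)
  dec <- viterbi_path(tr, fit)
  # frame-level agreement with truth (boundary frames may differ)
  tmid <- (seq_along(tr$donor) - 0.5) * tr$dt
  seg <- findInterval(tmid, p$t_start)
  truth_states <- p$state[seg]
  dseg <- findInterval(tmid, dec$t_start)
  dec_states <- dec$state[dseg]
  expect_gt(mean(truth_states == dec_states), 0.98)
})

test_that("frame misassignment stays below 5% for SNR >= 4", {
  set.seed(26)
  for (snr in c(4, 6, 10)) {
    sigma <- 0.3 / snr
    m <- kinetic_model(k_on = 1.4e8, conc = 20, k_off = 0.45,
                       E_unbent = 0.3, E_bent = 0.6, sigma_E = sigma,
                       I_total = 1e5, bg_d = 0, bg_a = 0, kb_d = 0, kb_a = 0)
    err <- vapply(1:5, function(i) {
      p <- simulate_state_path(m, 60)
      tr <- emit_trace(p, m, 0.05)
      fit <- fit_two_state_hmm(tr)
      dec <- viterbi_path(tr, fit)
      tmid <- (seq_along(tr$donor) - 0.5) * tr$dt
      truth_states <- p$state[findInterval(tmid, p$t_start)]
      dec_states <- dec$state[findInterval(tmid, dec$t_start)]
      mean(truth_states != dec_states)
    }, numeric(1))
    expect_lt(mean(err), 0.05)
  }
})

test_that("an unidentifiable fit with coincident means refuses to decode", {
  set.seed(27)
  e <- stats::rnorm(200, 0.5, 0.05)
  I <- 500
  tr <- new_trace(round(I * (1 - e)), round(I * e), dt = 0.1,
                  meta = list(bg_d = 0, bg_a = 0))
  fit <- fit_two_state_hmm(tr)
  fit$mu <- c(0.5, 0.5)  # force the degenerate case
  expect_error(viterbi_path(tr, fit), "unidentifiable")
})

test_that("quality screen accepts clean traces and flags small FRET changes", {
  m <- kinetic_preset("EQ_DF61_dsdna", conc = 20, kb_d = 0, kb_a = 0)
  set.seed(28)
  tr <- emit_trace(simulate_state_path(m, 60), m, 0.05)
  q <- screen_trace(tr)
  expect_identical(q$verdict, "accept")
  expect_gt(q$delta_E, 0.2)
  expect_lt(q$anticorr, 0)

  m2 <- kinetic_preset("EQ_DF61_dsdna", conc = 20, kb_d = 0, kb_a = 0,
                       E_unbent = 0.40, E_bent = 0.55)
  tr2 <- emit_trace(simulate_state_path(m2, 60), m2, 0.05)
  expect_identical(screen_trace(tr2)$verdict, "small_delta")
})

test_that("correlated channel steps are flagged as non-FRET", {
  # both channels drop together: intensity loss, not a conformational change
  set.seed(29)
  d <- c(rpois(100, 400), rpois(100, 110))
  a <- c(rpois(100, 200), rpois(100, 140))
  tr <- new_trace(d, a, dt = 0.1, meta = list(bg_d = 10, bg_a = 10))
  q <- screen_trace(tr)
  expect_identical(q$verdict, "no_anticorrelation")
})

test_that("aberrant brightness is excluded", {
  set.seed(30)
  d <- rpois(300, 300); a <- rpois(300, 300)
  spikes <- sample(300, 40)
  d[spikes] <- d[spikes] + 2000
  tr <- new_trace(d, a, dt = 0.1, meta = list(bg_d = 10, bg_a = 10))
  expect_identical(screen_trace(tr)$verdict, "aberrant")
})

test_that("the usable region ends at donor or acceptor bleaching", {
  m <- kinetic_preset("EQ_DF61_dsdna", conc = 20, kb_d = 0, kb_a = 0)
  p <- manual_path(c("UNBENT", "BENT", "BLEACHED"), c(0, 5, 20, 60),
                   duration = 60)
  attr(p, "bleach_channel") <- "donor"
  tr <- emit_trace(p, m, 0.1, seed = 31)
  expect_lt(abs(find_bleach_point(tr) - 200), 3)
  attr(p, "bleach_channel") <- "acceptor"
  tr2 <- emit_trace(p, m, 0.1, seed = 32)
  expect_lt(abs(find_bleach_point(tr2) - 200), 3)
})
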