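make_cleavage_model <- function(conc = 10, ...)
  kinetic_preset("NonEQ_DF61_flap", conc = conc, ...)

test_that("simulated cognate cleavage traces are predominantly category c", {
  m <- make_cleavage_model()
  set.seed(61)
  ex <- cleavage_experiment(m, n_traces = 150, duration = 30, dt = 0.05,
                            n_boot = 100)
  tab <- ex$category_table
  expect_identical(names(which.max(tab)), "c_bend_then_donor_loss")
  expect_gt(tab[["c_bend_then_donor_loss"]] / sum(tab), 0.5)
  # the category assignment is a partition
  expect_identical(sum(tab), 150L)
  # every category-c trace bent before losing its donor
  cc <- Filter(function(cl) cl$category == "c_bend_then_donor_loss",
               ex$classes)
  expect_true(all(vapply(cc, function(cl) cl$bent_at_loss, logical(1))))
})

test_that("acceptor bleaching before donor loss is category b", {
  m <- make_cleavage_model(kb_d = 0, kb_a = 0)
  p <- manual_path(c("UNBENT", "BLEACHED"), c(0, 10, 30), duration = 30)
  attr(p, "bleach_channel") <- "acceptor"
  tr <- emit_trace(p, m, 0.05, seed = 62)
  cl <- classify_trace(tr)
  expect_identical(cl$category, "b_acceptor_bleach_first")
})

test_that("a flat unbent trace with no loss is category e", {
  m <- make_cleavage_model(kb_d = 0, kb_a = 0)
  p <- manual_path("UNBENT", c(0, 30), duration = 30)
  tr <- emit_trace(p, m, 0.05, seed = 63)
  cl <- classify_trace(tr)
  expect_identical(cl$category, "e_never_bent")
  expect_false(cl$ever_bent)
})

test_that("donor loss without a resolved bend is category d", {
  m <- make_cleavage_model(kb_d = 0, kb_a = 0)
  # incision faster than the frame time: bent sliver of 4 ms at dt = 50 ms
  p <- manual_path(c("UNBENT", "BENT", "CLEAVED"), c(0, 10, 10.004, 30),
                   duration = 30)
  tr <- emit_trace(p, m, 0.05, seed = 64)
  cl <- classify_trace(tr)
  expect_identical(cl$category, "d_donor_loss_no_bend")
})

test_that("lag counting discretizes a 0.16 s bend into 3-4 frames", {
  m <- make_cleavage_model(kb_d = 0, kb_a = 0)
  p <- manual_path(c("UNBENT", "BENT", "CLEAVED"), c(0, 10, 10.16, 30),
                   duration = 30)
  tr <- emit_trace(p, m, 0.05, seed = 65)
  cl <- classify_trace(tr)
  expect_identical(cl$category, "c_bend_then_donor_loss")
  expect_true(cl$final_bent_frames %in% c(3L, 4L))
})

test_that("only the final bend before donor loss counts toward the lag", {
  m <- make_cleavage_model(kb_d = 0, kb_a = 0)
  # three abortive bends, then the productive one of 0.2 s
  p <- manual_path(
    c("UNBENT", "BENT", "UNBENT", "BENT", "UNBENT", "BENT", "UNBENT",
      "BENT", "CLEAVED"),
    c(0, 2, 3, 5, 6.5, 8, 9, 12, 12.2, 30), duration = 30)
  tr <- emit_trace(p, m, 0.05, seed = 66)
  cl <- classify_trace(tr)
  expect_identical(cl$category, "c_bend_then_donor_loss")
  expect_lte(cl$final_bent_frames, 5L)  # ~4 frames, never the earlier bends
  lags <- extract_lags(list(cl), dt = 0.05)
  expect_lt(lags$lag[1], 0.3)
})

test_that("gamma lag sampling matches its mean and the fit degrades to shape 1", {
  set.seed(67)
  lags <- stats::rgamma(1000, shape = 2, rate = 2 / 0.16)
  se <- stats::sd(lags) / sqrt(1000)
  expect_lt(abs(mean(lags) - 0.16), 2 * se)
  g <- fit_gamma(lags, n_boot = 200, seed = 68)
  expect_lt(abs(g$tau_avg - 0.16), 3 * g$tau_avg_se)
  expect_lt(abs(g$shape - 2), 3 * g$shape_se)
  expect_false(g$shape_flag)
  # exponential data: nested single-step case
  g1 <- fit_gamma(stats::rexp(1000, 6), n_boot = 200, seed = 69)
  expect_lt(abs(g1$shape - 1), 3 * g1$shape_se + 0.1)
  # k_STO * tau_avg = 1 identity
  expect_equal(g$k_STO * g$tau_avg, 1)
})

test_that("donor-loss accounting separates cleavage from photobleaching", {
  set.seed(70)
  m_mg <- make_cleavage_model()                       # cleavable
  m_ca <- make_cleavage_model(cleavable = FALSE)      # binding only
  tr_mg <- simulate_trace_set(m_mg, 60, 30, 0.05)
  tr_ca <- simulate_trace_set(m_ca, 60, 30, 0.05)
  cl_mg <- lapply(tr_mg, classify_trace)
  cl_ca <- lapply(tr_ca, classify_trace)
  st <- donor_loss_stats(cl_mg, cl_ca, dt = 0.05)
  expect_gt(st$mg$loss_fraction, st$ca$loss_fraction)
  # bleaching-only expectation over 30 s at kb_d = 0.02 /s
  expect_lt(abs(st$ca$loss_fraction - (1 - exp(-0.02 * 30))), 0.2)
  expect_error(donor_loss_stats(list(), cl_ca), "nonempty")
})

test_that("without photobleaching, donor loss equals the category-c bookkeeping", {
  set.seed(71)
  m <- make_cleavage_model(kb_d = 0, kb_a = 0)
  traces <- simulate_trace_set(m, 80, 30, 0.05)
  classes <- lapply(traces, classify_trace)
  cats <- vapply(classes, function(cl) cl$category, character(1))
  lossf <- vapply(classes, function(cl) cl$donor_loss_frame, integer(1))
  # aberrant traces are excluded before any loss accounting
  ok <- cats != "a_aberrant"
  expect_identical(sum(!is.na(lossf[ok])),
                   sum(cats[ok] %in% c("c_bend_then_donor_loss",
                                       "d_donor_loss_no_bend")))
})

test_that("cognate substrate is cleaved from the first bend (never-miss)", {
  set.seed(72)
  m <- make_cleavage_model(kb_d = 0, kb_a = 0)
  n_first <- 0; n_cleaved <- 0
  for (i in 1:500) {
    p <- simulate_state_path(m, 60)
    if (attr(p, "cleaved")) {
      n_cleaved <- n_cleaved + 1
      if (sum(p$state == "BENT") == 1) n_first <- n_first + 1
    }
  }
  expect_gt(n_cleaved, 400)
  expect_gte(n_first / n_cleaved, 0.97)
})

test_that("equal incision chains give matching k_STO for cognate and noncognate", {
  # lockdown (k_off), not incision rate, differs between substrates
  set.seed(73)
  m_cog <- make_cleavage_model(kb_d = 0, kb_a = 0)
  m_non <- make_cleavage_model(kb_d = 0, kb_a = 0)
  m_non$k_off <- 2    # unstable bent conformer, abortive bends
  ex1 <- cleavage_experiment(m_cog, n_traces = 250, duration = 30, dt = 0.05,
                             n_boot = 200)
  ex2 <- cleavage_experiment(m_non, n_traces = 400, duration = 30, dt = 0.05,
                             n_boot = 200)
  joint_se <- sqrt(ex1$fit$k_STO_se^2 + ex2$fit$k_STO_se^2)
  expect_lt(abs(ex1$fit$k_STO - ex2$fit$k_STO), 3 * joint_se)
})

test_that("viscosity regression: Kramers limit gives slope 1, inert viscogen 0", {
  eta <- c(1, 1.5, 2, 2.5)
  # suppress the "essentially perfect fit" note from noiseless input
  f1 <- suppressWarnings(viscosity_slope(eta, 6.3 / eta))
  expect_equal(f1$slope, 1, tolerance = 1e-9)
  f0 <- suppressWarnings(viscosity_slope(eta, rep(6.3, 4)))  # PEG-like control
  expect_equal(f0$slope, 0, tolerance = 1e-9)
  expect_error(viscosity_slope(c(1, 1.5), c(1, 2)), ">= 3")
  expect_error(viscosity_slope(c(1.5, 2, 2.5), c(1, 2, 3)), "eta_rel = 1")
})

test_that("simulated glycerol titration recovers the slope within 2 SE", {
  ex <- viscosity_experiment(seed = 74)
  expect_lt(abs(ex$fit$slope - 1.5), 2 * ex$fit$slope_se)
})
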