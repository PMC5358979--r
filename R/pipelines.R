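#' Simulate a set of traces for one condition
#'
#' @param model A `kinetic_model`.
#' @param n Number of molecules.
#' @param duration Record length per molecule, s.
#' @param dt Frame interval, s.
#' @param seed Integer seed (one stream for the whole set).
#' @return List of `fret_trace` objects (each carrying its truth path).
#' @export
simulate_trace_set <- function(model, n, duration, dt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i) {
    p <- simulate_state_path(model, duration)
    emit_trace(p, model, dt)
  })
}

#' Idealize a set of traces: HMM fit, quality screen, Viterbi decode
#'
#' @param traces List of `fret_trace`.
#' @param keep Quality verdicts to keep (default only `"accept"`).
#' @return List with `paths` (decoded `state_path`s of kept traces), `fits`,
#'   `quality` (all verdicts), `kept` (indices).
#' @export
idealize_set <- function(traces, keep = "accept") {
  fits <- vector("list", length(traces))
  verdicts <- character(length(traces))
  paths <- list()
  kept <- integer(0)
  for (i in seq_along(traces)) {
    fit <- tryCatch(fit_two_state_hmm(traces[[i]]), error = function(e) NULL)
    fits[[i]] <- fit
    if (is.null(fit)) { verdicts[i] <- "aberrant"; next }
    q <- screen_trace(traces[[i]], fit)
    verdicts[i] <- q$verdict
    if (q$verdict %in% keep) {
      p <- tryCatch(viterbi_path(traces[[i]], fit), error = function(e) NULL)
      if (!is.null(p)) {
        attr(p, "dt") <- traces[[i]]$dt
        paths <- c(paths, list(p))
        kept <- c(kept, i)
      }
    }
  }
  list(paths = paths, fits = fits, quality = verdicts, kept = kept)
}

#' Full bending-kinetics experiment over an enzyme concentration series
#'
#' For each concentration: simulate `n_traces` molecules, idealize with the
#' two-state HMM, screen, extract bent and unbent dwells, and fit exponential
#' rates. The per-concentration bending rates are then regressed against
#' concentration to give `k_on`, the unbending rates averaged to `k_off`, and
#' `K_d = k_off / k_on`.
#'
#' @param model A `kinetic_model` (its `conc` field is overridden per point).
#' @param concs Enzyme concentrations, nM.
#' @param n_traces Molecules per concentration.
#' @param duration Record length, s.
#' @param dt Frame interval, s.
#' @param seed Integer seed.
#' @param method Dwell-rate estimator passed to [fit_exponential()]. The
#'   censoring-aware MLE is the default: 60 s records truncated by
#'   photobleaching censor an appreciable share of dwells, and the plain
#'   interior-dwell estimators are length-biased under such windows.
#' @param missed_events Apply [correct_missed_events()] per concentration
#'   (default `TRUE`); at the highest concentrations the unbent dwells
#'   approach the frame interval and merged bent dwells would otherwise bias
#'   the unbending rate downward.
#' @return A list: `series` (the per-concentration rate table), `fit` (the
#'   [fit_concentration_series()] result).
#' @export
bending_series_experiment <- function(model, concs = c(5, 10, 20, 50),
                                      n_traces = 200, duration = 60,
                                      dt = 0.05, seed = NULL,
                                      method = "mle_censored",
                                      missed_events = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(concs, function(cc) {
    m <- model
    m$conc <- cc
    m$k_bind <- m$k_on * cc * 1e-9
    traces <- simulate_trace_set(m, n_traces, duration, dt)
    ide <- idealize_set(traces)
    bent <- extract_dwells(ide$paths, "BENT")
    unbent <- extract_dwells(ide$paths, "UNBENT")
    kb <- fit_exponential(unbent, method, dt = dt)   # bending rate
    ku <- fit_exponential(bent, method, dt = dt)     # unbending rate
    k_bending <- kb$k; k_unbending <- ku$k
    if (missed_events) {
      corr <- correct_missed_events(kb$k, ku$k, dt)
      k_bending <- corr$k_bending
      k_unbending <- corr$k_unbending
    }
    data.frame(conc_nM = cc,
               k_bending = k_bending,
               se_bending = kb$se * k_bending / kb$k,
               k_unbending = k_unbending,
               se_unbending = ku$se * k_unbending / ku$k,
               n_bending = kb$n_dwells, n_unbending = ku$n_dwells)
  })
  series <- do.call(rbind, rows)
  list(series = series, fit = fit_concentration_series(series))
}

#' Binding-isotherm experiment from per-molecule FRET histograms
#'
#' Generates per-molecule FRET values at each enzyme concentration — each
#' molecule is bent with the 1:1 occupancy `F / (F + K_d)` and reports a
#' Gaussian FRET value around its state mean — fits a two-Gaussian mixture per
#' histogram to extract the bent fraction, and fits the Langmuir isotherm.
#'
#' @param model A `kinetic_model` providing the state means, `sigma_E` and the
#'   labeling scheme. The truth `K_d` is `k_off / k_on`.
#' @param concs Enzyme concentrations, nM.
#' @param n_molecules Molecules per concentration.
#' @param S Immobilized substrate concentration, nM.
#' @param seed Integer seed.
#' @return List with `truth_Kd_nM`, `points` (conc, fraction_bent),
#'   `mixtures`, and `fit` (the `isotherm_fit`).
#' @export
isotherm_experiment <- function(model,
                                concs = c(0.5, 1, 2, 4, 8, 16, 32, 50),
                                n_molecules = 300, S = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Kd <- model$k_off / model$k_on * 1e9
  bent_side <- if (model$scheme == "flap") "low" else "high"
  mixtures <- list()
  frac <- numeric(length(concs))
  for (i in seq_along(concs)) {
    p_bent <- concs[i] / (concs[i] + Kd)
    bent <- stats::runif(n_molecules) < p_bent
    e <- ifelse(bent, model$E_bent, model$E_unbent) +
      stats::rnorm(n_molecules, 0, model$sigma_E)
    mx <- fit_mixture(e, k = 2, bent = bent_side)
    # at the extremes one population may vanish; read the fraction off the
    # single component's position instead
    if (mx$k == 1) {
      near_bent <- abs(mx$means - model$E_bent) < abs(mx$means - model$E_unbent)
      mx$fraction_bent <- if (near_bent) 1 else 0
    }
    mixtures[[i]] <- mx
    frac[i] <- mx$fraction_bent
  }
  fit <- fit_langmuir(concs, frac, S = S)
  list(truth_Kd_nM = Kd, points = data.frame(conc_nM = concs,
                                             fraction_bent = frac),
       mixtures = mixtures, fit = fit)
}

#' Single-turnover cleavage experiment: simulate, classify, fit lags
#'
#' Simulates cleavage traces (cleavable model, Mg2+), classifies every trace
#' into the five categories, extracts the bent-state lags of category-c traces
#' and fits the gamma lag distribution.
#'
#' @param model A cleavable `kinetic_model` (flap scheme).
#' @param n_traces Number of molecules.
#' @param duration Record length, s.
#' @param dt Frame interval, s (50 ms is the standard cleavage resolution).
#' @param seed Integer seed.
#' @param n_boot Bootstrap resamples for the gamma fit.
#' @return List with `classes`, `category_table`, `lags` (`lag_set`), and
#'   `fit` (`gamma_fit`).
#' @export
cleavage_experiment <- function(model, n_traces = 500, duration = 30,
                                dt = 0.05, seed = NULL, n_boot = 1000) {
  if (!is.null(seed)) set.seed(seed)
  if (!model$cleavable)
    warning("model is not cleavable; expect no category-c traces")
  traces <- simulate_trace_set(model, n_traces, duration, dt)
  classes <- lapply(traces, classify_trace)
  cats <- vapply(classes, function(cl) cl$category, character(1))
  lags <- extract_lags(classes, dt)
  fit <- if (nrow(lags) >= 50) fit_gamma(lags, n_boot = n_boot) else NULL
  list(classes = classes,
       category_table = table(factor(cats, levels = c(
         "a_aberrant", "b_acceptor_bleach_first", "c_bend_then_donor_loss",
         "d_donor_loss_no_bend", "e_never_bent"))),
       lags = lags, fit = fit, traces = traces)
}

#' Glycerol-titration experiment for the viscosity dependence of k_STO
#'
#' Generates cleavage lag sets at each relative viscosity — the mean lag grows
#' linearly, `tau(eta) = tau1 * (1 + slope * (eta - 1))`, the law implied by a
#' linear relative-slowdown plot — fits a gamma distribution per set, and
#' regresses the relative slowdown on relative viscosity.
#'
#' @param tau1 Mean lag at eta = 1, s.
#' @param truth_slope Ground-truth slope of the relative slowdown.
#' @param etas Relative viscosities (must include 1).
#' @param n_lags Lags per set.
#' @param replicates Independent replicate sets per viscosity.
#' @param shape Gamma shape of the lag distribution.
#' @param seed Integer seed.
#' @return List with `points`, `fit` (`viscosity_fit`), `truth_slope`.
#' @export
viscosity_experiment <- function(tau1 = 0.16, truth_slope = 1.5,
                                 etas = c(1, 1.5, 2, 2.5), n_lags = 300,
                                 replicates = 3, shape = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (r in seq_len(replicates)) {
    for (eta in etas) {
      tau <- tau1 * (1 + truth_slope * (eta - 1))
      lags <- stats::rgamma(n_lags, shape = shape, rate = shape / tau)
      g <- fit_gamma(lags, n_boot = 200)
      rows[[length(rows) + 1]] <- data.frame(
        eta_rel = eta, replicate = r, k_sto = g$k_STO)
    }
  }
  pts <- do.call(rbind, rows)
  fit <- viscosity_slope(pts$eta_rel, pts$k_sto, replicate = pts$replicate)
  list(points = pts, fit = fit, truth_slope = truth_slope)
}

#' Burst-histogram experiment at a fixed state FRET
#'
#' Simulates a solution-phase burst measurement of a single conformer at FRET
#' mean `E`, runs the binning + burst-search pipeline, and fits the burst
#' histogram with a single Gaussian.
#'
#' @param E State FRET mean.
#' @param n_bursts Molecule transits to draw.
#' @param seed Integer seed.
#' @param bin Bin width, s.
#' @param threshold Burst-count floor.
#' @param sigma_E Between-burst FRET jitter.
#' @param ... Further arguments to [simulate_burst_set()].
#' @return List with `stream`, `bursts`, `fit` (`mixture_fit`), `mean_E`.
#' @export
burst_fret_experiment <- function(E, n_bursts = 2000, seed = NULL,
                                  bin = 5e-4, threshold = 35,
                                  sigma_E = 0.02, ...) {
  m <- kinetic_model(E_unbent = E, E_bent = E, sigma_E = sigma_E,
                     k_off = 0, conc = 0)
  stream <- simulate_burst_set(m, n_bursts, seed = seed, p_bent = 1, ...)
  bursts <- find_bursts(bin_stream(stream, bin), threshold = threshold)
  fit <- burst_histogram(bursts, k = 1)
  list(stream = stream, bursts = bursts, fit = fit, mean_E = fit$means[1])
}
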