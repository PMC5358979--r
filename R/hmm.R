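#' Last usable frame before photobleaching or dye loss
#'
#' FRET analysis is only meaningful while both dyes are alive. The usable
#' region ends at the earlier of (i) loss of total (donor + acceptor) signal —
#' donor bleaching, or incision with donor departure — and (ii) permanent
#' loss of the acceptor while the donor stays bright (acceptor bleaching,
#' after which the apparent FRET collapses to a spurious low value). A
#' channel is considered lost from the first frame at which its 5-frame
#' running median stays below background + 3 SD (Poisson) to the end of the
#' record.
#'
#' @param trace A `fret_trace`. Background levels come from `trace$meta`
#'   (`bg_d`, `bg_a`) when present, otherwise from the lowest decile of each
#'   channel.
#' @return Integer index of the last usable frame (0 when the trace is dark
#'   throughout).
#' @export
find_bleach_point <- function(trace) {
  n <- length(trace$donor)
  bgs <- trace_backgrounds(trace)
  smooth <- function(x) if (length(x) >= 5) stats::runmed(x, 5) else x
  perm_dark_from <- function(x, bg) {
    thr <- bg + 3 * sqrt(bg + 1)
    below <- smooth(x) < thr
    if (!below[n]) return(NA_integer_)
    run <- rev(cumprod(rev(below)))
    which(run == 1)[1]
  }
  tot_dark <- perm_dark_from(trace$donor + trace$acceptor, bgs$bg_d + bgs$bg_a)
  acc_dark <- perm_dark_from(trace$acceptor, bgs$bg_a)
  last <- n
  if (!is.na(tot_dark)) last <- min(last, tot_dark - 1L)
  if (!is.na(acc_dark)) last <- min(last, acc_dark - 1L)
  max(last, 0L)
}

# channel backgrounds: from metadata when the trace carries it, otherwise the
# lowest-decile mean of each channel
trace_backgrounds <- function(trace) {
  bg_d <- if (!is.null(trace$meta$bg_d)) trace$meta$bg_d
    else mean(trace$donor[trace$donor <= stats::quantile(trace$donor, 0.1)])
  bg_a <- if (!is.null(trace$meta$bg_a)) trace$meta$bg_a
    else mean(trace$acceptor[trace$acceptor <= stats::quantile(trace$acceptor, 0.1)])
  list(bg_d = bg_d, bg_a = bg_a)
}

#' Fit a two-state hidden Markov model to a FRET trajectory
#'
#' Maximum-likelihood Baum-Welch EM on the apparent FRET efficiency with
#' Gaussian emissions, the operating mode of the usual trajectory-idealization
#' tools. State means initialize at the 20th/80th percentiles of the data;
#' iteration stops when the log-likelihood gain falls below `tol` or after
#' `max_iter` iterations. States are ordered so that `mu[1] < mu[2]`. A
#' variance floor (`sigma >= sqrt(var_floor)`) guards against degenerate
#' collapse onto repeated values. Frames after the photobleach point and
#' frames with undefined FRET are excluded.
#'
#' @param trace A `fret_trace` with at least 20 usable frames.
#' @param max_iter,tol EM stopping rule.
#' @param var_floor Lower bound on the emission variances.
#' @return An `hmm_fit`: list with `mu`, `sigma`, `A` (2x2 row-stochastic
#'   per-frame transition matrix), `init`, `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `frames` (indices used), `posterior` (per-frame state-2
#'   probability), `dt`.
#' @examples
#' m <- kinetic_preset("EQ_DF61_dsdna", conc = 20, kb_d = 0, kb_a = 0)
#' tr <- emit_trace(simulate_state_path(m, 60, seed = 1), m, 0.05, seed = 2)
#' fit <- fit_two_state_hmm(tr)
#' round(fit$mu, 2)
#' @export
fit_two_state_hmm <- function(trace, max_iter = 500, tol = 1e-6,
                              var_floor = 1e-4) {
  stopifnot(inherits(trace, "fret_trace"))
  bp <- find_bleach_point(trace)
  frames <- seq_len(bp)
  frames <- frames[is.finite(trace$e_app[frames])]
  if (length(frames) < 20) stop("need >= 20 usable frames")
  obs <- trace$e_app[frames]

  mu <- as.numeric(stats::quantile(obs, c(0.2, 0.8)))
  if (diff(mu) < 1e-3) mu <- mu + c(-0.05, 0.05)
  sigma <- rep(max(stats::sd(obs) / 2, sqrt(var_floor)), 2)
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  init <- c(0.5, 0.5)

  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    fb <- .fb_two_state(obs, mu, sigma, A, init)
    ll <- fb$loglik
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) && ll - ll_prev < tol) { converged <- TRUE; break }
    ll_prev <- ll
    g <- fb$gamma
    xi <- fb$xi
    ns <- colSums(g)
    mu_new <- colSums(g * obs) / ns
    var_new <- pmax(colSums(g * (outer(obs, mu_new, "-")^2)) / ns, var_floor)
    mu <- mu_new
    sigma <- sqrt(var_new)
    A <- xi / pmax(rowSums(xi), .Machine$double.xmin)
    A <- A / rowSums(A)
    init <- g[1, ]
    init <- init / sum(init)
  }

  # order states by mean
  if (mu[1] > mu[2]) {
    o <- c(2, 1)
    mu <- mu[o]; sigma <- sigma[o]; A <- A[o, o]; init <- init[o]
  }
  fb <- .fb_two_state(obs, mu, sigma, A, init)

  structure(list(mu = mu, sigma = sigma, A = A, init = init,
                 loglik = fb$loglik, loglik_trace = ll_trace, n_iter = it,
                 converged = converged, frames = frames,
                 posterior = fb$gamma[, 2], dt = trace$dt),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf(
    "Two-state HMM fit: mu = %.3f / %.3f (sigma %.3f / %.3f), logL = %.2f, %d iter%s\n",
    x$mu[1], x$mu[2], x$sigma[1], x$sigma[2], x$loglik, x$n_iter,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Viterbi idealization of a fitted trace
#'
#' Decodes the most probable state sequence under an [fit_two_state_hmm()] fit
#' and merges runs into contiguous segments with times `frame * dt` (frames
#' 0-based, segments half-open). Which HMM state is the bent conformer is
#' scheme-aware: in the flap labeling scheme the bent state is the low-FRET
#' state, in the internal (dsDNA) scheme the high-FRET state.
#'
#' @param trace A `fret_trace`.
#' @param fit Its `hmm_fit`. The fit must have converged and be identifiable
#'   (distinct state means).
#' @param scheme Labeling scheme; defaults to `trace$meta$scheme`, else
#'   `"dsdna"`.
#' @return A `state_path` of `UNBENT`/`BENT` segments spanning the fitted
#'   frames, with attribute `state_index` (the raw decoded low/high index per
#'   frame).
#' @export
viterbi_path <- function(trace, fit, scheme = NULL) {
  stopifnot(inherits(trace, "fret_trace"), inherits(fit, "hmm_fit"))
  if (!fit$converged) stop("HMM fit did not converge; refusing to decode")
  if (abs(diff(fit$mu)) < 1e-6)
    stop("state means coincide; two-state model unidentifiable")
  if (is.null(scheme))
    scheme <- if (!is.null(trace$meta$scheme)) trace$meta$scheme else "dsdna"
  obs <- trace$e_app[fit$frames]
  dec <- .viterbi_two_state(obs, fit$mu, fit$sigma, fit$A, fit$init)
  # state index 1 = low-FRET, 2 = high-FRET
  low_is_bent <- identical(scheme, "flap")
  lab <- if (low_is_bent) c("BENT", "UNBENT") else c("UNBENT", "BENT")
  states <- lab[dec + 1L]

  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  f0 <- fit$frames[1] - 1L  # 0-based offset of first fitted frame
  seg <- data.frame(
    state = r$values,
    t_start = (f0 + starts - 1) * trace$dt,
    t_end = (f0 + ends) * trace$dt,
    stringsAsFactors = FALSE)
  structure(seg, duration = max(seg$t_end), bleach_channel = NA_character_,
            cleaved = FALSE, dt = trace$dt, state_index = dec + 1L,
            frames = fit$frames,
            class = c("state_path", "data.frame"))
}

#' Trace-quality screening
#'
#' Applies the trace-selection rules used before dwell-time analysis:
#' molecules with aberrant total brightness are excluded (total intensity
#' deviating > 3 MAD from the trace median for more than 10% of frames, or any
#' single-frame excursion beyond 5 MAD); accepted traces must show a FRET
#' change of at least 0.2 between the two fitted states and anti-correlated
#' donor/acceptor changes at decoded transitions.
#'
#' @param trace A `fret_trace`.
#' @param fit Optional `hmm_fit` (computed if missing).
#' @return A `trace_quality` list: `verdict` (`"accept"`, `"aberrant"`,
#'   `"small_delta"` or `"no_anticorrelation"`), `delta_E`, `anticorr`
#'   (correlation of donor and acceptor jumps at transitions; `NA` when the
#'   decode has no transitions).
#' @export
screen_trace <- function(trace, fit = NULL) {
  stopifnot(inherits(trace, "fret_trace"))
  bp <- find_bleach_point(trace)
  # the bleach-boundary frame is partially dark by construction; screening it
  # as a brightness spike would reject clean traces
  use <- seq_len(max(bp - 1, 1))
  tot <- (trace$donor + trace$acceptor)[use]
  med <- stats::median(tot)
  dev <- abs(tot - med)
  madv <- stats::mad(tot)
  if (madv <= 0) madv <- sqrt(med + 1)
  aberrant <- mean(dev > 3 * madv) > 0.10 || any(dev > 5 * madv)
  if (aberrant)
    return(structure(list(verdict = "aberrant", delta_E = NA_real_,
                          anticorr = NA_real_), class = "trace_quality"))

  if (is.null(fit)) fit <- fit_two_state_hmm(trace)
  delta_E <- abs(diff(fit$mu))

  dec <- .viterbi_two_state(trace$e_app[fit$frames], fit$mu, fit$sigma,
                            fit$A, fit$init)
  trans <- which(diff(dec) != 0) + 1L
  anticorr <- NA_real_
  if (length(trans) > 0) {
    f <- fit$frames[trans]
    dd <- trace$donor[f] - trace$donor[f - 1]
    da <- trace$acceptor[f] - trace$acceptor[f - 1]
    anticorr <- if (length(f) >= 3 && stats::sd(dd) > 0 && stats::sd(da) > 0)
      stats::cor(dd, da)
    else
      sign(mean(dd * da))
  }

  verdict <- if (delta_E < 0.2) "small_delta"
  else if (!is.na(anticorr) && anticorr >= 0) "no_anticorrelation"
  else "accept"
  structure(list(verdict = verdict, delta_E = delta_E, anticorr = anticorr),
            class = "trace_quality")
}
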