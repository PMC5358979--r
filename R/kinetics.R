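#' Extract dwell durations of a state from idealized paths
#'
#' Collects the residence times of `state` across a set of idealized (or
#' ground-truth) paths. A dwell is *censored* when its true extent was not
#' observed: the first and last segments of each trace, and segments terminated
#' by incision or photobleaching rather than by a conformational transition.
#' Interior dwells (bounded on both sides by the alternating conformer) are
#' uncensored. The `side` column distinguishes left censoring (a trace's
#' first segment, whose start was never seen) from right censoring (last or
#' terminally cut segments, whose exposure is still informative).
#'
#' @param paths A `state_path` or list of them.
#' @param state `"BENT"` or `"UNBENT"`.
#' @return A `dwell_set`: data.frame with `duration` (s), `censored`
#'   (logical) and `side` (`"interior"`, `"left"`, `"right"`), attributes
#'   `state` and `dt` (frame interval of the first path that carries one,
#'   else `NA`).
#' @examples
#' seg <- data.frame(state = c("UNBENT", "BENT", "UNBENT"),
#'                   t_start = c(0, 0.1, 0.4), t_end = c(0.1, 0.4, 1))
#' p <- structure(seg, duration = 1, class = c("state_path", "data.frame"))
#' extract_dwells(p, "BENT")
#' @export
extract_dwells <- function(paths, state = c("BENT", "UNBENT")) {
  state <- match.arg(state)
  if (inherits(paths, "state_path")) paths <- list(paths)
  dur <- numeric(0)
  side <- character(0)
  dt <- NA_real_
  for (p in paths) {
    if (is.na(dt) && !is.null(attr(p, "dt"))) dt <- attr(p, "dt")
    n <- nrow(p)
    if (n == 0) next
    term <- p$state %in% c("CLEAVED", "BLEACHED")
    for (i in which(p$state == state)) {
      d <- p$t_end[i] - p$t_start[i]
      s <- if (i == 1) "left"
        else if (i == n || term[min(i + 1, n)]) "right"
        else "interior"
      dur <- c(dur, d)
      side <- c(side, s)
    }
  }
  structure(data.frame(duration = dur, censored = side != "interior",
                       side = side, stringsAsFactors = FALSE),
            state = state, dt = dt,
            class = c("dwell_set", "data.frame"))
}

#' Fit a single-exponential rate to a dwell-time set
#'
#' Three estimators are provided. `"hist_lsq"` reproduces the conventional
#' workflow: least-squares fit of `A * exp(-k t)` to the dwell-time histogram
#' (Freedman-Diaconis bin width). `"mle"` is the analytic maximum-likelihood
#' estimate; because dwells shorter than `min_frames` frames are discarded as
#' a missed-event guard, the estimator is the conditional (left-truncated)
#' MLE `k = 1/(mean - t_min)`, which reduces to `1/mean` when no frame
#' interval is known. `"mle_censored"` additionally counts the exposure of
#' right-censored dwells through the censored-exponential likelihood
#' `k = events / total time`; left-censored dwells (first segments, unknown
#' start) carry no usable information and are dropped.
#'
#' @param dwells A `dwell_set`.
#' @param method One of `"hist_lsq"`, `"mle"`, `"mle_censored"`.
#' @param dt Frame interval, s; defaults to the `dwell_set` attribute. Dwells
#'   shorter than `min_frames * dt` are discarded (missed-event guard).
#' @param min_frames Missed-event guard, in frames.
#' @param include_boundary Deprecated alias of nothing; first/last dwells are
#'   always treated as censored by [extract_dwells()].
#' @return A `rate_estimate`: list with `k` (s^-1), `se`, `method`, `n_dwells`.
#' @examples
#' d <- structure(data.frame(duration = c(1, 2, 3), censored = FALSE,
#'                           side = "interior"),
#'                state = "BENT", dt = NA_real_,
#'                class = c("dwell_set", "data.frame"))
#' fit_exponential(d, "mle")$k  # 0.5
#' @export
fit_exponential <- function(dwells,
                            method = c("hist_lsq", "mle", "mle_censored"),
                            dt = attr(dwells, "dt"), min_frames = 2,
                            include_boundary = NULL) {
  method <- match.arg(method)
  t_min <- if (!is.null(dt) && is.finite(dt)) min_frames * dt else 0

  unc <- dwells$duration[!dwells$censored]
  unc <- unc[unc >= t_min]
  if (method == "hist_lsq") {
    if (length(unc) < 20) stop("need >= 20 uncensored dwells for hist_lsq")
  } else if (length(unc) < 3) {
    if (method == "mle_censored" && any(dwells$censored)) {
      if (all(dwells$censored) || length(unc) == 0)
        stop("all dwells censored; no events to fit")
    } else stop("need >= 3 uncensored dwells")
  }

  if (method == "mle") {
    m <- mean(unc)
    k <- 1 / (m - t_min)
    se <- k / sqrt(length(unc))
    n <- length(unc)
  } else if (method == "mle_censored") {
    cen <- dwells$duration[dwells$side == "right"]
    cen <- cen[cen >= t_min]
    events <- length(unc)
    if (events == 0) stop("all dwells censored; no events to fit")
    total_time <- sum(unc - t_min) + sum(cen - t_min)
    k <- events / total_time
    se <- k / sqrt(events)
    n <- events + length(cen)
  } else {
    bw <- 2 * stats::IQR(unc) / length(unc)^(1 / 3)
    if (bw <= 0) bw <- diff(range(unc)) / 10
    breaks <- seq(min(unc), max(unc) + bw, by = bw)
    h <- graphics::hist(unc, breaks = breaks, plot = FALSE)
    keep <- h$counts > 0
    mids <- h$mids[keep]
    counts <- h$counts[keep]
    k0 <- 1 / max(mean(unc) - t_min, 1e-9)
    fit <- minpack.lm::nlsLM(counts ~ A * exp(-k * mids),
                             start = list(A = max(counts), k = k0),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    k <- stats::coef(fit)[["k"]]
    se <- summary(fit)$coefficients["k", "Std. Error"]
    n <- length(unc)
  }
  if (k <= 0) stop("fitted rate is non-positive")
  structure(list(k = unname(k), se = unname(se), method = method,
                 n_dwells = n), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("k = %.4g +/- %.2g s^-1 (%s, n = %d)\n",
              x$k, x$se, x$method, x$n_dwells))
  invisible(x)
}

#' First-order missed-event (dead-time) correction for two-state dwell rates
#'
#' Frame-based idealization cannot resolve excursions shorter than the
#' detection dead time: a sojourn in the opposite state that goes undetected
#' merges the two flanking dwells, inflating their apparent mean. To first
#' order, an observed dwell in state A is a geometric concatenation of
#' `N + 1` true dwells and `N` missed gaps with
#' `P(miss) = 1 - exp(-k_B * t_d)`, so
#' `E[observed] = (m_A + p * g) / (1 - p)` with `g` the mean of a missed gap.
#' This function inverts that relation jointly for both states by fixed-point
#' iteration. For majority-vote frame classification, an excursion shorter
#' than `dt/2` can never claim a frame and detection grows linearly to
#' certainty at one frame, giving the default dead time `0.75 * dt`.
#'
#' @param k_bending Apparent unbent-to-bent rate (from unbent dwells), s^-1.
#' @param k_unbending Apparent bent-to-unbent rate (from bent dwells), s^-1.
#' @param dt Frame interval, s.
#' @param dead_time Detection dead time, s.
#' @param max_iter,tol Fixed-point iteration control.
#' @return List with corrected `k_bending` and `k_unbending`.
#' @examples
#' correct_missed_events(6.4, 0.34, dt = 0.05)
#' @export
correct_missed_events <- function(k_bending, k_unbending, dt,
                                  dead_time = 0.75 * dt,
                                  max_iter = 100, tol = 1e-12) {
  m_U_obs <- 1 / k_bending    # observed mean unbent dwell
  m_B_obs <- 1 / k_unbending  # observed mean bent dwell
  td <- dead_time
  gap_mean <- function(k) {
    # mean of an exponential dwell conditioned on being shorter than td
    p <- 1 - exp(-k * td)
    if (p < 1e-12) return(td / 2)
    (1 / k - (1 / k + td) * exp(-k * td)) / p
  }
  k1 <- k_bending; k2 <- k_unbending
  for (i in seq_len(max_iter)) {
    p_U <- 1 - exp(-k1 * td)  # a missed unbent gap merges bent dwells
    p_B <- 1 - exp(-k2 * td)
    m_B <- (1 - p_U) * m_B_obs - p_U * gap_mean(k1)
    m_U <- (1 - p_B) * m_U_obs - p_B * gap_mean(k2)
    if (m_B <= 0 || m_U <= 0)
      stop("missed-event correction diverged; rates too fast for this dt")
    k1_new <- 1 / m_U; k2_new <- 1 / m_B
    if (abs(k1_new - k1) < tol && abs(k2_new - k2) < tol) break
    k1 <- k1_new; k2 <- k2_new
  }
  list(k_bending = k1, k_unbending = k2)
}

#' Concentration dependence of the bending rate: k_on, k_off and K_d
#'
#' Weighted least-squares line through the per-concentration bending rates
#' (weights `1/SE^2`, intercept fitted and reported, not forced through the
#' origin). The slope (s^-1 per nM) converts to the second-order association
#' rate constant in M^-1 s^-1; the dissociation rate constant is the plain
#' mean of the per-concentration unbending rates, which should be
#' concentration-independent; and `K_d = k_off / k_on` by construction.
#'
#' @param series data.frame with columns `conc_nM`, `k_bending`, `se_bending`,
#'   `k_unbending`, `se_unbending` (>= 3 concentrations).
#' @return A `conc_series_fit`: list with `k_on` (M^-1 s^-1), `k_on_se`,
#'   `intercept`, `k_off` (s^-1), `k_off_se`, `K_d_nM`, `points`, and the
#'   underlying `lm`.
#' @examples
#' s <- data.frame(conc_nM = c(10, 30, 50), k_bending = c(1.4, 4.2, 7.0),
#'                 se_bending = 0.1, k_unbending = c(0.45, 0.44, 0.46),
#'                 se_unbending = 0.02)
#' fit_concentration_series(s)$k_on
#' @export
fit_concentration_series <- function(series) {
  need <- c("conc_nM", "k_bending", "se_bending", "k_unbending")
  if (!all(need %in% names(series)))
    stop("series must have columns ", paste(need, collapse = ", "))
  if (nrow(series) < 3) stop("need >= 3 concentrations")
  w <- 1 / pmax(series$se_bending, 1e-12)^2
  lmfit <- stats::lm(k_bending ~ conc_nM, data = series, weights = w)
  slope <- stats::coef(lmfit)[["conc_nM"]]
  if (slope <= 0) stop("fitted slope is not positive: unphysical association")
  slope_se <- summary(lmfit)$coefficients["conc_nM", "Std. Error"]
  k_on <- slope * 1e9          # (s^-1 / nM) -> M^-1 s^-1
  k_off <- mean(series$k_unbending)
  k_off_se <- stats::sd(series$k_unbending) / sqrt(nrow(series))
  structure(list(k_on = k_on, k_on_se = slope_se * 1e9,
                 intercept = stats::coef(lmfit)[["(Intercept)"]],
                 k_off = k_off, k_off_se = k_off_se,
                 K_d_nM = k_off / k_on * 1e9,
                 points = series, lm = lmfit),
            class = "conc_series_fit")
}

#' @export
print.conc_series_fit <- function(x, ...) {
  cat(sprintf("k_on  = %.3g +/- %.2g M^-1 s^-1\n", x$k_on, x$k_on_se))
  cat(sprintf("k_off = %.3g +/- %.2g s^-1\n", x$k_off, x$k_off_se))
  cat(sprintf("K_d   = %.3g nM (= k_off / k_on)\n", x$K_d_nM))
  invisible(x)
}

#' Michaelis-Menten fit of bulk initial rates
#'
#' Nonlinear least squares of `v0 = Vmax * c / (Km + c)`.
#'
#' @param conc Enzyme concentrations, nM (>= 4 points).
#' @param v0 Initial rates, nM min^-1.
#' @return An `mm_fit`: list with `Km` (nM), `Vmax` (nM min^-1), their SEs,
#'   and the underlying `nls` fit.
#' @examples
#' conc <- c(1, 2, 5, 10, 20)
#' fit_michaelis_menten(conc, 10 * conc / (4 + conc))$Km
#' @export
fit_michaelis_menten <- function(conc, v0) {
  if (length(conc) < 4) stop("need >= 4 points")
  start <- list(Vmax = max(v0) * 1.2,
                Km = conc[which.min(abs(v0 - max(v0) / 2))])
  fit <- tryCatch(
    minpack.lm::nlsLM(v0 ~ Vmax * conc / (Km + conc), start = start,
                      lower = c(Vmax = 0, Km = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit failed: ",
                             conditionMessage(e)))
  cf <- summary(fit)$coefficients
  structure(list(Km = cf["Km", "Estimate"], Vmax = cf["Vmax", "Estimate"],
                 Km_se = cf["Km", "Std. Error"],
                 Vmax_se = cf["Vmax", "Std. Error"], fit = fit),
            class = "mm_fit")
}
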