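#' Classify a single-molecule cleavage trace
#'
#' Deterministic rule cascade reproducing the five trace categories used in
#' single-turnover cleavage fields of view:
#' \describe{
#'   \item{a_aberrant}{aberrant brightness (noise, blinking, step artifacts);
#'     excluded from all analysis.}
#'   \item{b_acceptor_bleach_first}{acceptor photobleached before any donor
#'     loss; excluded (lag analysis depends on the donor only).}
#'   \item{c_bend_then_donor_loss}{the molecule reached the bent state and then
#'     lost its donor in a single step without acceptor recovery — the
#'     cleavage signature. Requires a FRET change of at least 0.2 and
#'     anti-correlated channels. Only this category enters lag analysis.}
#'   \item{d_donor_loss_no_bend}{donor lost without a preceding resolved bent
#'     state (donor bleaching, or cleavage faster than the frame time).}
#'   \item{e_never_bent}{no donor loss within the record; overwhelmingly
#'     molecules that stayed unbent. (Rare bent-but-uncleaved traces also land
#'     here and are flagged in the details.)}
#' }
#'
#' @param trace A `fret_trace`.
#' @param path Optional idealized `state_path` (decoded if missing).
#' @param fit Optional `hmm_fit` for the trace.
#' @return A `cleavage_class`: list with `category`, `donor_loss_frame`
#'   (first all-background donor frame, `NA` if none), `acceptor_bleach_frame`,
#'   `bent_at_loss`, `final_bent_frames` (length of the last decoded bent run
#'   before donor loss), `ever_bent`, `quality` (the `trace_quality`).
#' @export
classify_trace <- function(trace, path = NULL, fit = NULL) {
  stopifnot(inherits(trace, "fret_trace"))
  n <- length(trace$donor)
  bgs <- trace_backgrounds(trace)
  bg_d <- bgs$bg_d
  bg_a <- bgs$bg_a
  thr_d <- bg_d + 3 * sqrt(bg_d + 1)
  thr_a <- bg_a + 3 * sqrt(bg_a + 1)

  perm_below <- function(x, thr) {
    # first index from which x stays below thr to the end, NA if none;
    # 5-frame running median guards against isolated background upticks
    sm <- if (n >= 5) stats::runmed(x, 5) else x
    below <- sm < thr
    if (!below[n]) return(NA_integer_)
    run <- rev(cumprod(rev(below)))
    which(run == 1)[1]
  }
  dloss <- perm_below(trace$donor, thr_d)
  if (!is.na(dloss) && dloss == 1) dloss <- NA_integer_  # dark from the start
  aloss <- perm_below(trace$acceptor, thr_a)
  if (!is.na(aloss) && aloss == 1) aloss <- NA_integer_

  # acceptor bleach = acceptor permanently dark while the donor is still bright
  # acceptor bleach needs the donor demonstrably bright for a few frames
  # afterwards; near-simultaneous channel loss is donor loss, not bleaching
  acceptor_bleach <- !is.na(aloss) && (is.na(dloss) || aloss + 2 < dloss) &&
    mean(trace$donor[aloss:min(n, if (is.na(dloss)) n else dloss - 1)]) > thr_d

  last_obs <- n
  if (!is.na(dloss)) last_obs <- min(last_obs, dloss - 1L)
  if (acceptor_bleach) last_obs <- min(last_obs, aloss - 1L)

  details <- function(category, quality = NULL, bent_at_loss = FALSE,
                      final_bent = 0L, ever_bent = FALSE)
    structure(list(category = category, donor_loss_frame = dloss,
                   acceptor_bleach_frame = if (acceptor_bleach) aloss else NA_integer_,
                   bent_at_loss = bent_at_loss,
                   final_bent_frames = final_bent, ever_bent = ever_bent,
                   quality = quality),
              class = "cleavage_class")

  # brightness screen on the live region (needs enough frames for statistics)
  if (last_obs >= 20) {
    tot <- (trace$donor + trace$acceptor)[seq_len(last_obs - 1)]
    med <- stats::median(tot)
    madv <- stats::mad(tot)
    if (madv <= 0) madv <- sqrt(med + 1)
    if (mean(abs(tot - med) > 3 * madv) > 0.10 ||
        any(abs(tot - med) > 5 * madv))
      return(details("a_aberrant"))
  }
  if (acceptor_bleach) return(details("b_acceptor_bleach_first"))
  if (last_obs < 2) {
    if (!is.na(dloss)) return(details("d_donor_loss_no_bend"))
    return(details("e_never_bent"))
  }

  low_is_bent <- identical(trace$meta$scheme, "flap")
  quality <- NULL
  bent_frames <- integer(0)
  use <- seq_len(last_obs)

  if (!is.null(path)) {
    frames <- attr(path, "frames")
    idx <- attr(path, "state_index")
    if (!is.null(frames) && !is.null(idx)) {
      bent_frames <- frames[idx == (if (low_is_bent) 1L else 2L)]
    } else {
      # truth-style path: frames whose midpoint lies in a BENT segment
      tmid <- (use - 0.5) * trace$dt
      seg <- findInterval(tmid, path$t_start)
      seg[seg == 0] <- 1
      bent_frames <- use[path$state[seg] == "BENT"]
    }
  } else if (last_obs >= 25) {
    # long live region: idealize with the HMM and apply the full screen
    decoded <- tryCatch({
      if (is.null(fit)) fit <- fit_two_state_hmm(trace)
      quality <- screen_trace(trace, fit)
      p <- viterbi_path(trace, fit)
      frames <- attr(p, "frames")
      idx <- attr(p, "state_index")
      frames[idx == (if (low_is_bent) 1L else 2L)]
    }, error = function(e) NULL)
    if (!is.null(quality) && quality$verdict == "aberrant")
      return(details("a_aberrant", quality = quality))
    if (!is.null(decoded)) bent_frames <- decoded
  }
  if (length(bent_frames) == 0 && is.null(quality)) {
    # short live region (the cognate cleavage case): threshold rule with the
    # minimum FRET change of 0.2 built in; the unbent level is read off the
    # first frames, which precede enzyme binding
    e <- trace$e_app[use]
    # the unbent level: most live frames precede binding or follow abortive
    # release, so the unbent side of the distribution is the crowded one
    e_u <- stats::quantile(e, if (low_is_bent) 0.8 else 0.2, na.rm = TRUE)
    bent <- if (low_is_bent) e < e_u - 0.2 else e > e_u + 0.2
    bent[is.na(bent)] <- FALSE
    bent_frames <- use[bent]
    # anti-correlation of the channels at the first bent entry
    if (length(bent_frames) > 0 && bent_frames[1] > 1) {
      f <- bent_frames[1]
      dd <- trace$donor[f] - trace$donor[f - 1]
      da <- trace$acceptor[f] - trace$acceptor[f - 1]
      if (dd * da > 0) bent_frames <- integer(0)  # correlated: not FRET
    }
  }

  bent_before <- bent_frames[bent_frames <= last_obs]
  ever_bent <- length(bent_before) > 0

  if (is.na(dloss))
    return(details("e_never_bent", quality = quality, ever_bent = ever_bent))

  bent_at_loss <- ever_bent && max(bent_before) >= last_obs - 1L
  ok_quality <- is.null(quality) || quality$verdict == "accept"
  if (bent_at_loss && ok_quality) {
    r <- rle(use %in% bent_before)
    final_bent <- as.integer(utils::tail(r$lengths[r$values], 1))
    # majority rule for the frame straddling the donor-loss step: count it
    # only if the dyes were present for more than half of it (its total
    # intensity is above half a typical live frame); E alone cannot decide,
    # since a mostly-dark frame shows background-dominated mid-range E
    lastf <- max(bent_before)
    if (!is.na(dloss) && lastf == dloss - 1L) {
      tot <- trace$donor + trace$acceptor
      ref_tot <- stats::median(tot[seq_len(max(last_obs - 1L, 1L))])
      if (tot[lastf] < ref_tot / 2) final_bent <- final_bent - 1L
    }
    if (final_bent >= 1L)
      return(details("c_bend_then_donor_loss", quality = quality,
                     bent_at_loss = TRUE,
                     final_bent = final_bent, ever_bent = TRUE))
    return(details("d_donor_loss_no_bend", quality = quality,
                   ever_bent = ever_bent))
  }
  details("d_donor_loss_no_bend", quality = quality, ever_bent = ever_bent)
}

#' Lag times before cleavage from category-c traces
#'
#' For each trace classified `c_bend_then_donor_loss`, the lag is the number
#' of frames spent in the final bent segment before the donor was lost, times
#' the frame interval. For noncognate substrates earlier abortive bending
#' events are deliberately not counted here — they belong to the dwell-time
#' analysis, not the lag. Traces whose final bent run has zero length are
#' reassigned to category d and dropped.
#'
#' @param classes List of `cleavage_class` objects (any mix of categories;
#'   only category c contributes).
#' @param dt Frame interval, s.
#' @return A `lag_set`: data.frame with `lag` (s) and `frames`, attribute
#'   `dt`.
#' @export
extract_lags <- function(classes, dt) {
  if (inherits(classes, "cleavage_class")) classes <- list(classes)
  fr <- vapply(classes, function(cl) {
    if (cl$category == "c_bend_then_donor_loss") cl$final_bent_frames
    else NA_integer_
  }, integer(1))
  fr <- fr[!is.na(fr) & fr > 0]
  structure(data.frame(lag = fr * dt, frames = fr),
            dt = dt, class = c("lag_set", "data.frame"))
}

#' Gamma fit of cleavage lag times: shape, mean lag and single-turnover rate
#'
#' Maximum-likelihood gamma fit of the lag-time distribution. The mean lag
#' `tau_avg = shape * scale` is the average bent-state residence before
#' incision, and the apparent single-turnover rate is `k_STO = 1/tau_avg`.
#' A fitted shape near 1 indicates a single rate-limiting step (pure
#' exponential decay); shapes above 1 give the rise-and-decay histogram that
#' signals two or more sequential steps. A shape below 1 is flagged. Standard
#' errors come from a seeded nonparametric bootstrap.
#'
#' @param lags A `lag_set` or numeric vector of lags, s (>= 50).
#' @param n_boot Bootstrap resamples.
#' @param seed Optional integer seed for the bootstrap.
#' @return A `gamma_fit`: list with `shape`, `scale`, `tau_avg` (s), `k_STO`
#'   (s^-1), `tau_avg_se`, `k_STO_se`, `shape_se`, `n`, `shape_flag`.
#' @examples
#' set.seed(1)
#' g <- fit_gamma(rgamma(200, shape = 2, rate = 12.5), seed = 2)
#' round(g$tau_avg, 2)
#' @export
fit_gamma <- function(lags, n_boot = 1000, seed = NULL) {
  x <- if (inherits(lags, "lag_set")) lags$lag else as.numeric(lags)
  x <- x[is.finite(x)]
  if (length(x) < 50) stop("need >= 50 lags")
  if (any(x <= 0)) stop("lags must be > 0")

  fit <- suppressWarnings(MASS::fitdistr(x, "gamma"))
  shape <- unname(fit$estimate["shape"])
  rate <- unname(fit$estimate["rate"])
  tau_avg <- shape / rate

  # closed-form gamma MLE approximation, fast enough to bootstrap
  shape_approx <- function(v) {
    s <- log(mean(v)) - mean(log(v))
    (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  boot_tau <- numeric(n_boot)
  boot_shape <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    xb <- x[sample.int(n, n, replace = TRUE)]
    boot_tau[b] <- mean(xb)   # gamma MLE preserves the sample mean
    boot_shape[b] <- shape_approx(xb)
  }
  tau_se <- stats::sd(boot_tau)
  structure(list(shape = shape, scale = 1 / rate, tau_avg = tau_avg,
                 k_STO = 1 / tau_avg,
                 tau_avg_se = tau_se, k_STO_se = tau_se / tau_avg^2,
                 shape_se = stats::sd(boot_shape), n = n,
                 shape_flag = shape < 1),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf(
    "gamma lag fit: shape %.2f +/- %.2f, tau_avg %.1f +/- %.1f ms, k_STO %.2f s^-1 (n = %d)%s\n",
    x$shape, x$shape_se, 1000 * x$tau_avg, 1000 * x$tau_avg_se, x$k_STO, x$n,
    if (x$shape_flag) " [flag: shape < 1, single-step decay]" else ""))
  invisible(x)
}

#' Donor-loss accounting across binding (Ca2+) and cleavage (Mg2+) conditions
#'
#' Compares the fraction of molecules that lost their donor between a
#' non-cleaving control (Ca2+: photobleaching only) and the catalytic
#' condition (Mg2+: photobleaching plus incision), and tabulates the
#' category breakdown per condition.
#'
#' @param classes_mg,classes_ca Lists of `cleavage_class` objects for the two
#'   conditions.
#' @param dt Frame interval, s (for the loss-time summaries).
#' @return A list with per-condition `loss_fraction`, `category_table`, and
#'   `loss_times` (s).
#' @export
donor_loss_stats <- function(classes_mg, classes_ca, dt = NA_real_) {
  if (length(classes_mg) == 0 || length(classes_ca) == 0)
    stop("both condition sets must be nonempty")
  one <- function(classes) {
    lossf <- vapply(classes, function(cl) cl$donor_loss_frame, integer(1))
    cats <- vapply(classes, function(cl) cl$category, character(1))
    list(loss_fraction = mean(!is.na(lossf)),
         category_table = table(factor(cats, levels = c(
           "a_aberrant", "b_acceptor_bleach_first", "c_bend_then_donor_loss",
           "d_donor_loss_no_bend", "e_never_bent"))),
         loss_times = lossf[!is.na(lossf)] * dt)
  }
  list(mg = one(classes_mg), ca = one(classes_ca))
}

#' Viscosity dependence of the single-turnover rate
#'
#' Ordinary least squares of the relative-rate transform against relative
#' viscosity. The default response is `k_STO(1) / k_STO(eta)` (the relative
#' slowdown), normalized within each replicate so the point at `eta = 1` is
#' exactly 1; a purely viscosity-limited conformational step then gives a
#' slope of 1 (Kramers regime), while steeper slopes indicate several coupled
#' viscosity-sensitive steps. `response = "direct"` regresses
#' `k_STO(eta) / k_STO(1)` instead; the slope magnitude is reported either
#' way.
#'
#' @param eta_rel Relative viscosities (>= 1, must include 1).
#' @param k_sto Single-turnover rates at each viscosity, s^-1.
#' @param replicate Optional replicate labels; normalization is within
#'   replicate.
#' @param response `"reciprocal"` (default) or `"direct"`.
#' @return A `viscosity_fit`: list with `slope`, `slope_se`, `points`, `lm`.
#' @examples
#' eta <- c(1, 1.5, 2, 2.5)
#' viscosity_slope(eta, 6.3 / eta)$slope  # 1
#' @export
viscosity_slope <- function(eta_rel, k_sto, replicate = NULL,
                            response = c("reciprocal", "direct")) {
  response <- match.arg(response)
  if (length(unique(eta_rel)) < 3) stop("need >= 3 viscosity levels")
  if (any(eta_rel < 1)) stop("relative viscosities must be >= 1")
  if (is.null(replicate)) replicate <- rep(1, length(eta_rel))
  y <- numeric(length(k_sto))
  for (r in unique(replicate)) {
    i <- replicate == r
    i1 <- i & abs(eta_rel - 1) < 1e-9
    if (!any(i1)) stop("each replicate needs a point at eta_rel = 1")
    k1 <- mean(k_sto[i1])
    y[i] <- if (response == "reciprocal") k1 / k_sto[i] else k_sto[i] / k1
  }
  lmfit <- stats::lm(y ~ eta_rel)
  cf <- summary(lmfit)$coefficients
  structure(list(slope = abs(cf["eta_rel", "Estimate"]),
                 slope_se = cf["eta_rel", "Std. Error"],
                 response = response,
                 points = data.frame(eta_rel = eta_rel, k_sto = k_sto,
                                     response = y, replicate = replicate),
                 lm = lmfit),
            class = "viscosity_fit")
}
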