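#' Simulate a confocal photon stream of diffusing-molecule bursts
#'
#' Emulates solution-phase smFRET: single molecules transiting the confocal
#' volume produce photon bursts with log-normally distributed durations and
#' Poisson photon statistics at the molecule's FRET efficiency, on top of a
#' uniform background in both channels. Burst durations are drawn, not
#' diffused; there is no excitation-volume model.
#'
#' @param model A `kinetic_model`; each burst's state is bent with probability
#'   `p_bent` (default: the equilibrium occupancy `k_bind / (k_bind + k_off)`),
#'   and its FRET mean is the corresponding state mean jittered by `sigma_E`.
#' @param n_bursts Number of molecule transits to draw.
#' @param seed Optional integer seed.
#' @param p_bent Probability a transit is in the bent state; overrides the
#'   equilibrium value. Use 1 (or equal state means) for single-state samples.
#' @param peak_rate Photon detection rate inside a burst, counts/s.
#' @param dur_meanlog,dur_sdlog Log-normal parameters of burst duration, s.
#' @param gap_mean Mean exponential inter-burst gap, s.
#' @param bg_rate Background photon rate per channel, counts/s.
#' @return A `photon_stream`: data.frame with columns `t` (s, sorted) and
#'   `channel` (`"donor"`/`"acceptor"`), with attributes `duration` and
#'   `truth` (per-burst start/end/state/E/n_photons).
#' @examples
#' m <- kinetic_preset("EQ_DF61_dsdna")
#' ps <- simulate_burst_set(m, n_bursts = 50, seed = 4, p_bent = 1)
#' nrow(ps)
#' @export
simulate_burst_set <- function(model, n_bursts, seed = NULL, p_bent = NULL,
                               peak_rate = 5e4, dur_meanlog = log(1.5e-3),
                               dur_sdlog = 0.5, gap_mean = 0.1,
                               bg_rate = 500) {
  stopifnot(inherits(model, "kinetic_model"))
  if (n_bursts < 1) stop("n_bursts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(p_bent)) {
    denom <- model$k_bind + model$k_off
    p_bent <- if (denom > 0) model$k_bind / denom else 0
  }

  gaps <- stats::rexp(n_bursts, 1 / gap_mean)
  durs <- stats::rlnorm(n_bursts, dur_meanlog, dur_sdlog)
  starts <- cumsum(gaps) + c(0, cumsum(durs))[seq_len(n_bursts)]
  ends <- starts + durs
  duration <- ends[n_bursts] + gap_mean

  bent <- stats::runif(n_bursts) < p_bent
  e_state <- ifelse(bent, model$E_bent, model$E_unbent)
  e_state <- pmin(pmax(e_state + stats::rnorm(n_bursts, 0, model$sigma_E), 0), 1)

  n_ph <- stats::rpois(n_bursts, peak_rate * durs)
  t <- numeric(sum(n_ph))
  ch <- character(sum(n_ph))
  pos <- 0L
  for (i in seq_len(n_bursts)) {
    if (n_ph[i] == 0) next
    ti <- sort(stats::runif(n_ph[i], starts[i], ends[i]))
    ci <- ifelse(stats::runif(n_ph[i]) < e_state[i], "acceptor", "donor")
    t[pos + seq_len(n_ph[i])] <- ti
    ch[pos + seq_len(n_ph[i])] <- ci
    pos <- pos + n_ph[i]
  }

  if (bg_rate > 0) {
    for (chan in c("donor", "acceptor")) {
      nb <- stats::rpois(1, bg_rate * duration)
      if (nb > 0) {
        t <- c(t, stats::runif(nb, 0, duration))
        ch <- c(ch, rep(chan, nb))
      }
    }
  }

  o <- order(t)
  stream <- data.frame(t = t[o], channel = ch[o], stringsAsFactors = FALSE)
  truth <- data.frame(start = starts, end = ends,
                      state = ifelse(bent, "BENT", "UNBENT"),
                      E = e_state, n_photons = n_ph)
  structure(stream, duration = duration, truth = truth,
            class = c("photon_stream", "data.frame"))
}

#' Write / read a photon stream as two-column delimited text (t_s, channel)
#'
#' @param stream A `photon_stream`.
#' @param path File path.
#' @param duration Total record duration, s (taken as `max(t)` when absent on
#'   read).
#' @export
write_photon_stream <- function(stream, path) {
  utils::write.table(data.frame(t_s = stream$t, channel = stream$channel),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_photon_stream
#' @export
read_photon_stream <- function(path, duration = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (is.null(duration)) duration <- max(d$t_s)
  structure(data.frame(t = d$t_s, channel = d$channel,
                       stringsAsFactors = FALSE),
            duration = duration, truth = NULL,
            class = c("photon_stream", "data.frame"))
}
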