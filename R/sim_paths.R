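#' Simulate a ground-truth state path of bending, unbending and incision
#'
#' Draws exact event times (Gillespie-style) for the kinetic scheme held in a
#' [kinetic_model()]: exponential unbound/extended dwells at rate
#' `k_on * conc`, then from the bent state competing risks of dissociation
#' (`k_off`) versus progression through `n_step` sequential incision steps of
#' rate `k_step` each (only when `cleavable`). Incision and photobleaching are
#' terminal. Photobleaching clocks for the two dyes run from time zero with
#' hazards `kb_d` and `kb_a`; whichever fires first truncates the path.
#'
#' @param model A `kinetic_model`.
#' @param duration Total observation time, s.
#' @param seed Optional integer seed for reproducibility.
#' @return A `state_path`: a data.frame with columns `state`
#'   (`"UNBENT"`, `"BENT"`, `"CLEAVED"`, `"BLEACHED"`), `t_start`, `t_end`
#'   (seconds, contiguous half-open segments). Attributes: `duration`,
#'   `bleach_channel` (`"donor"`, `"acceptor"` or `NA`), and `cleaved`
#'   (logical).
#' @examples
#' m <- kinetic_preset("EQ_DF61_dsdna", conc = 20, kb_d = 0, kb_a = 0)
#' p <- simulate_state_path(m, duration = 60, seed = 1)
#' table(p$state)
#' @export
simulate_state_path <- function(model, duration, seed = NULL) {
  stopifnot(inherits(model, "kinetic_model"))
  if (!is.finite(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.null(seed)) set.seed(seed)

  t_bleach_d <- if (model$kb_d > 0) stats::rexp(1, model$kb_d) else Inf
  t_bleach_a <- if (model$kb_a > 0) stats::rexp(1, model$kb_a) else Inf
  t_bleach <- min(t_bleach_d, t_bleach_a)
  bleach_channel <- if (!is.finite(t_bleach)) NA_character_
    else if (t_bleach_d <= t_bleach_a) "donor" else "acceptor"

  state <- character(0); t0 <- numeric(0); t1 <- numeric(0)
  t <- 0
  cur <- "UNBENT"
  cleaved <- FALSE
  while (t < duration) {
    if (cur == "UNBENT") {
      dwell <- if (model$k_bind > 0) stats::rexp(1, model$k_bind) else Inf
      nxt <- "BENT"
    } else {
      if (model$cleavable) {
        # competing risks per incision step
        dwell <- 0
        nxt <- "CLEAVED"
        for (s in seq_len(model$n_step)) {
          tot <- model$k_off + model$k_step
          dwell <- dwell + stats::rexp(1, tot)
          if (stats::runif(1) < model$k_off / tot) { nxt <- "UNBENT"; break }
        }
      } else {
        dwell <- if (model$k_off > 0) stats::rexp(1, model$k_off) else Inf
        nxt <- "UNBENT"
      }
    }
    t_end <- min(t + dwell, duration)
    state <- c(state, cur); t0 <- c(t0, t); t1 <- c(t1, t_end)
    t <- t_end
    if (t >= duration) break
    if (nxt == "CLEAVED") {
      state <- c(state, "CLEAVED"); t0 <- c(t0, t); t1 <- c(t1, duration)
      cleaved <- TRUE
      break
    }
    cur <- nxt
  }

  seg <- data.frame(state = state, t_start = t0, t_end = t1,
                    stringsAsFactors = FALSE)
  # truncate at the first photobleaching event (pre-cleavage only)
  if (t_bleach < duration) {
    cleave_t <- if (cleaved) seg$t_start[seg$state == "CLEAVED"][1] else Inf
    if (t_bleach < cleave_t) {
      keep <- seg$t_start < t_bleach
      seg <- seg[keep, , drop = FALSE]
      seg$t_end[nrow(seg)] <- t_bleach
      seg <- rbind(seg, data.frame(state = "BLEACHED", t_start = t_bleach,
                                   t_end = duration))
      cleaved <- FALSE
    }
  }
  rownames(seg) <- NULL
  structure(seg, duration = duration, bleach_channel = bleach_channel,
            cleaved = cleaved, class = c("state_path", "data.frame"))
}

#' Dwell durations of a state directly from a state path
#'
#' Internal convenience used by tests and the dwell extractor.
#' @param path A `state_path`.
#' @param state State label.
#' @return Numeric vector of segment durations, s.
#' @keywords internal
path_durations <- function(path, state) {
  i <- path$state == state
  path$t_end[i] - path$t_start[i]
}
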