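#' Render a state path into a camera-frame donor/acceptor trace
#'
#' Emits per-frame photon counts with shot noise. Each frame is split into 10
#' sub-intervals; the state occupancies over those sub-intervals set the frame's
#' expected fluxes, so frames straddling a transition show the averaged
#' (intermediate) FRET seen in real camera data. Per frame, the state FRET
#' means receive Gaussian jitter of SD `sigma_E`, then
#' `donor ~ Poisson(I_total * (1 - E) + bg_d)` and
#' `acceptor ~ Poisson(I_total * E + bg_a)`. After incision the donor dye
#' departs with the 5'flap, so both channels fall to background; after donor
#' bleaching likewise; after acceptor bleaching the donor recovers its full
#' unquenched intensity while the acceptor falls to background.
#'
#' @param path A `state_path` from [simulate_state_path()].
#' @param model The `kinetic_model` used to generate it.
#' @param dt Frame interval, s.
#' @param seed Optional integer seed.
#' @param n_sub Sub-intervals per frame used for time-averaging.
#' @return A `fret_trace`: list with `dt`, integer vectors `donor` and
#'   `acceptor`, `e_app` (apparent FRET, `NA` where both channels are zero),
#'   `truth` (the path) and `meta` (scheme, conc, backgrounds, ...).
#' @examples
#' m <- kinetic_preset("EQ_DF61_dsdna", conc = 20)
#' p <- simulate_state_path(m, 30, seed = 2)
#' tr <- emit_trace(p, m, dt = 0.05, seed = 3)
#' head(tr$e_app)
#' @export
emit_trace <- function(path, model, dt, seed = NULL, n_sub = 10) {
  stopifnot(inherits(path, "state_path"), inherits(model, "kinetic_model"))
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.null(seed)) set.seed(seed)

  duration <- attr(path, "duration")
  n_frames <- floor(duration / dt)
  if (max(path$t_end) > n_frames * dt + 1e-9 &&
      max(path$t_end) - n_frames * dt > dt)
    warning("path extends beyond an integer number of frames; truncating")

  # sub-interval midpoints for every frame at once
  sub <- (seq_len(n_sub) - 0.5) / n_sub * dt
  tmid <- rep((seq_len(n_frames) - 1) * dt, each = n_sub) + sub
  idx <- findInterval(tmid, path$t_start)
  st <- path$state[idx]
  stm <- matrix(st, nrow = n_sub)

  frac <- function(lab) colMeans(stm == lab)
  f_unbent <- frac("UNBENT")
  f_bent <- frac("BENT")
  f_dark <- frac("CLEAVED")      # donor departed: both channels background
  f_donly <- 0
  bl <- attr(path, "bleach_channel")
  if (any(st == "BLEACHED")) {
    if (identical(bl, "acceptor")) f_donly <- frac("BLEACHED")
    else f_dark <- f_dark + frac("BLEACHED")
  }

  eu <- pmin(pmax(model$E_unbent + stats::rnorm(n_frames, 0, model$sigma_E), 0), 1)
  eb <- pmin(pmax(model$E_bent + stats::rnorm(n_frames, 0, model$sigma_E), 0), 1)

  mu_d <- model$I_total * (f_unbent * (1 - eu) + f_bent * (1 - eb) + f_donly) +
    model$bg_d
  mu_a <- model$I_total * (f_unbent * eu + f_bent * eb) + model$bg_a
  donor <- stats::rpois(n_frames, mu_d)
  acceptor <- stats::rpois(n_frames, mu_a)

  new_trace(donor, acceptor, dt, truth = path,
            meta = list(scheme = model$scheme, conc = model$conc,
                        bg_d = model$bg_d, bg_a = model$bg_a,
                        I_total = model$I_total, viscosity = 1))
}

#' Construct a FRET trace object from raw channel counts
#'
#' @param donor,acceptor Non-negative per-frame counts (equal length).
#' @param dt Frame interval, s.
#' @param truth Optional ground-truth `state_path`.
#' @param meta Optional metadata list (`scheme`, `conc`, `bg_d`, `bg_a`, ...).
#' @return A `fret_trace`.
#' @export
new_trace <- function(donor, acceptor, dt, truth = NULL, meta = list()) {
  if (length(donor) != length(acceptor))
    stop("donor and acceptor must have equal length")
  if (any(donor < 0) || any(acceptor < 0)) stop("counts must be >= 0")
  tot <- donor + acceptor
  e_app <- ifelse(tot > 0, acceptor / tot, NA_real_)
  structure(list(dt = dt, donor = as.numeric(donor),
                 acceptor = as.numeric(acceptor), e_app = e_app,
                 truth = truth, meta = meta),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("FRET trace: %d frames at dt = %g s (%s scheme)\n",
              length(x$donor), x$dt,
              if (is.null(x$meta$scheme)) "unknown" else x$meta$scheme))
  invisible(x)
}

#' Write / read a trace as delimited text (frame, donor, acceptor)
#'
#' @param trace A `fret_trace`.
#' @param path File path.
#' @param dt Frame interval used when reading, s.
#' @return `read_trace` returns a `fret_trace`; `write_trace` the path,
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(
    data.frame(frame = seq_along(trace$donor) - 1L,
               donor = trace$donor, acceptor = trace$acceptor),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, dt) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  new_trace(d$donor, d$acceptor, dt = dt)
}
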