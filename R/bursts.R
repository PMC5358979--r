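#' Bin a photon stream into fixed-width intervals per channel
#'
#' Half-open bins `[i*bin, (i+1)*bin)`; a photon exactly on a boundary belongs
#' to the later bin. Counts are conserved.
#'
#' @param stream A `photon_stream` (columns `t`, `channel`).
#' @param bin Bin width, s (default 0.5 ms).
#' @return A `binned_stream`: data.frame with `bin_start` (s), `donor`,
#'   `acceptor`; attribute `bin`.
#' @export
bin_stream <- function(stream, bin = 5e-4) {
  if (!is.finite(bin) || bin <= 0) stop("bin must be > 0")
  duration <- attr(stream, "duration")
  if (is.null(duration)) duration <- max(stream$t)
  n_bins <- max(1L, as.integer(ceiling(duration / bin + 1e-12)))
  idx <- pmin(floor(stream$t / bin) + 1L, n_bins)
  d <- tabulate(idx[stream$channel == "donor"], nbins = n_bins)
  a <- tabulate(idx[stream$channel == "acceptor"], nbins = n_bins)
  structure(data.frame(bin_start = (seq_len(n_bins) - 1) * bin,
                       donor = d, acceptor = a),
            bin = bin, class = c("binned_stream", "data.frame"))
}

#' Burst search on a binned photon stream
#'
#' Candidate bursts are maximal runs of consecutive bins whose total counts
#' exceed the background by two Poisson standard deviations; a candidate is
#' kept only when its integrated counts exceed `threshold` (default 35, the
#' conventional floor for 0.5 ms binning). Per-burst FRET comes from the
#' integrated channel counts, `E = A / (A + D)`.
#'
#' @param binned A `binned_stream` from [bin_stream()].
#' @param threshold Minimum total counts per burst (burst kept when strictly
#'   above).
#' @param background Mean background counts per bin (both channels summed);
#'   estimated from the sub-90th-percentile bins when `NULL`.
#' @return A `burst_set`: data.frame with `start`, `end` (s), `donor`,
#'   `acceptor`, `total`, `E`; attributes `threshold`, `background`, `bin`.
#' @examples
#' s <- structure(data.frame(t = c(0.0012, 0.00125, 0.0013),
#'                           channel = c("donor", "acceptor", "acceptor")),
#'                duration = 0.01, class = c("photon_stream", "data.frame"))
#' b <- bin_stream(s, 5e-4)
#' find_bursts(b, threshold = 2, background = 0)
#' @export
find_bursts <- function(binned, threshold = 35, background = NULL) {
  stopifnot(inherits(binned, "binned_stream"))
  bin <- attr(binned, "bin")
  tot <- binned$donor + binned$acceptor
  if (is.null(background)) {
    q <- stats::quantile(tot, 0.9)
    background <- mean(tot[tot <= q])
  }
  cut <- background + 2 * sqrt(max(background, 0.25))
  above <- tot > cut
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  keep <- which(r$values)
  out <- data.frame(start = numeric(0), end = numeric(0), donor = integer(0),
                    acceptor = integer(0), total = integer(0), E = numeric(0))
  for (i in keep) {
    s <- starts[i]; e <- ends[i]
    dsum <- sum(binned$donor[s:e])
    asum <- sum(binned$acceptor[s:e])
    if (dsum + asum > threshold)
      out <- rbind(out, data.frame(
        start = binned$bin_start[s], end = binned$bin_start[e] + bin,
        donor = dsum, acceptor = asum, total = dsum + asum,
        E = asum / (dsum + asum)))
  }
  rownames(out) <- NULL
  structure(out, threshold = threshold, background = background, bin = bin,
            class = c("burst_set", "data.frame"))
}

#' Gaussian fit of a burst-FRET histogram
#'
#' Delegates to [fit_mixture()] on the per-burst FRET efficiencies and also
#' reports the mean(s) as percentages, the convention used for burst
#' histograms.
#'
#' @param bursts A `burst_set` (>= 300 bursts recommended).
#' @param k Number of Gaussian components (1 or 2).
#' @param bent Bent-state orientation passed to [fit_mixture()].
#' @return A `mixture_fit` with an extra element `means_percent`.
#' @export
burst_histogram <- function(bursts, k = 1, bent = c("high", "low")) {
  stopifnot(inherits(bursts, "burst_set"))
  bent <- match.arg(bent)
  if (nrow(bursts) < 300)
    warning("fewer than 300 bursts; Gaussian fit may be unstable")
  f <- fit_mixture(bursts$E, k = k, bent = bent)
  f$means_percent <- 100 * f$means
  f
}
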