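#' Analytic reference free-energy profile for DNA junction bending
#'
#' Constructs a piecewise-smooth bending potential U(theta) over
#' theta in \[80, 180\] degrees emulating the free-energy landscape of a
#' nicked-flap junction: bending from the extended conformer (~165 deg, the
#' reference zero) down to ~140 deg costs little — comparable to plain duplex
#' DNA — after which breaking the junction base stacking imposes a steep rise
#' to a barrier of height `barrier` toward the protein-bound bent geometry
#' (~100 deg), beyond which a shallow bent well descends by `well_depth`.
#'
#' The profile is, by construction, exactly `barrier` kcal/mol between its
#' global maximum and the extended minimum at 165 deg.
#'
#' @param barrier Barrier height, kcal/mol (> 0). Default 14.
#' @param theta_min,theta_max Domain, degrees.
#' @param flat_to Low-cost region boundary, degrees (default 140).
#' @param barrier_pos Barrier position, degrees (default 100).
#' @param shallow_cost U at `flat_to` relative to the 165-degree reference,
#'   kcal/mol (default 1.5, i.e. at most ~2).
#' @param well_depth Depth of the bent well below the barrier top, kcal/mol.
#' @return A `bending_potential`: list with vectorized `U(theta)` (kcal/mol,
#'   0 at 165 deg), `dU(theta)` (kcal/mol/deg), and `params`.
#' @examples
#' bp <- make_reference_potential(barrier = 14)
#' bp$U(c(165, 140, 100))
#' @export
make_reference_potential <- function(barrier = 14, theta_min = 80,
                                     theta_max = 180, flat_to = 140,
                                     barrier_pos = 100, shallow_cost = 1.5,
                                     well_depth = 2) {
  if (barrier <= 0) stop("barrier height must be > 0")
  if (shallow_cost >= barrier) stop("shallow_cost must be below the barrier")
  th_ref <- 165
  a <- shallow_cost / (flat_to - th_ref)^2     # shallow quadratic about 165

  U <- function(theta) {
    u <- numeric(length(theta))
    hi <- theta >= flat_to
    u[hi] <- a * (theta[hi] - th_ref)^2
    mid <- theta < flat_to & theta >= barrier_pos
    u[mid] <- shallow_cost + (barrier - shallow_cost) *
      (1 - cos(pi * (flat_to - theta[mid]) / (flat_to - barrier_pos))) / 2
    lo <- theta < barrier_pos
    u[lo] <- barrier - well_depth *
      (1 - cos(pi * (barrier_pos - theta[lo]) / (barrier_pos - theta_min))) / 2
    u
  }
  dU <- function(theta) {
    g <- numeric(length(theta))
    hi <- theta >= flat_to
    g[hi] <- 2 * a * (theta[hi] - th_ref)
    mid <- theta < flat_to & theta >= barrier_pos
    g[mid] <- -(barrier - shallow_cost) / 2 *
      sin(pi * (flat_to - theta[mid]) / (flat_to - barrier_pos)) *
      pi / (flat_to - barrier_pos)
    lo <- theta < barrier_pos
    g[lo] <- well_depth / 2 *
      sin(pi * (barrier_pos - theta[lo]) / (barrier_pos - theta_min)) *
      pi / (barrier_pos - theta_min)
    g
  }
  structure(list(U = U, dU = dU,
                 params = list(barrier = barrier, theta_min = theta_min,
                               theta_max = theta_max, flat_to = flat_to,
                               barrier_pos = barrier_pos,
                               shallow_cost = shallow_cost,
                               well_depth = well_depth, theta_ref = th_ref)),
            class = "bending_potential")
}

#' Custom bending potential from user functions
#'
#' @param U Vectorized potential, kcal/mol.
#' @param dU Its derivative, kcal/mol/deg.
#' @param theta_min,theta_max Domain, degrees.
#' @return A `bending_potential`.
#' @export
bending_potential <- function(U, dU, theta_min = 80, theta_max = 180) {
  structure(list(U = U, dU = dU,
                 params = list(theta_min = theta_min, theta_max = theta_max)),
            class = "bending_potential")
}

#' Adaptive-biasing-force sampling of a bending potential
#'
#' Reconstructs the mean force along the bending coordinate by ABF: the
#' domain is segmented into `windows` discrete windows confined by harmonic
#' wall potentials, each window subdivided into `bin` -degree bins into which
#' instantaneous force samples are accumulated; the adaptive bias (the negated
#' running mean force per bin) is ramped in linearly until `ramp_samples`
#' samples have been collected in a bin, after which it fully cancels the mean
#' force and sampling becomes diffusive across the window. Dynamics are
#' overdamped Langevin at temperature `temp` (the molecular degrees of freedom
#' are not modeled; the integrator is a sampling engine for the 1-D
#' coordinate).
#'
#' @param potential A `bending_potential`.
#' @param windows Number of windows (default 9).
#' @param bin Bin width, degrees (default 0.2).
#' @param ramp_samples Samples per bin before the bias is fully applied
#'   (default 2000).
#' @param wall_k Wall force constant, kcal/mol/deg^2 (default 50).
#' @param steps Langevin steps per window.
#' @param dt Integrator time step (reduced units).
#' @param friction Friction coefficient (reduced units).
#' @param temp Temperature, K.
#' @param seed Optional integer seed (each window consumes the RNG stream in
#'   sequence, so runs are reproducible end to end).
#' @return A `pmf_profile`: data.frame with `theta` (bin centers, deg),
#'   `mean_force` (kcal/mol/deg), `n` (samples); attributes `bin`,
#'   `window_edges`, `kT`, `potential`.
#' @examples
#' bp <- make_reference_potential(barrier = 6)
#' prof <- run_abf(bp, steps = 1e5, seed = 1)
#' head(prof)
#' @export
run_abf <- function(potential, windows = 9, bin = 0.2, ramp_samples = 2000,
                    wall_k = 50, steps = 1e6, dt = 2e-3, friction = 1,
                    temp = 300, seed = NULL) {
  stopifnot(inherits(potential, "bending_potential"))
  if (!is.null(seed)) set.seed(seed)
  p <- potential$params
  lo_all <- p$theta_min
  hi_all <- p$theta_max
  kT <- 1.987204e-3 * temp  # kcal/mol

  n_bins_total <- round((hi_all - lo_all) / bin)
  if (abs(n_bins_total * bin - (hi_all - lo_all)) > 1e-9)
    stop("domain must be an integer number of bins")
  # window edges snapped to the bin grid
  edge_bins <- round(seq(0, n_bins_total, length.out = windows + 1))
  edges <- lo_all + edge_bins * bin

  # tabulated system force -dU/dtheta on a fine grid (extended past the walls)
  grid_dx <- bin / 10
  grid_x <- seq(lo_all - 5, hi_all + 5, by = grid_dx)
  grid_force <- -potential$dU(grid_x)

  theta_centers <- lo_all + (seq_len(n_bins_total) - 0.5) * bin
  fsum <- numeric(n_bins_total)
  count <- numeric(n_bins_total)

  for (w in seq_len(windows)) {
    wlo <- edges[w]; whi <- edges[w + 1]
    b0 <- edge_bins[w] + 1
    b1 <- edge_bins[w + 1]
    nb <- b1 - b0 + 1
    res <- .abf_window((wlo + whi) / 2, wlo, whi, bin,
                       grid_x[1], grid_dx, grid_force,
                       as.integer(steps), dt, friction, kT, wall_k,
                       as.integer(ramp_samples),
                       numeric(nb), numeric(nb))
    fsum[b0:b1] <- res$fsum
    count[b0:b1] <- res$count
  }

  mean_force <- ifelse(count > 0, fsum / count, NA_real_)
  structure(data.frame(theta = theta_centers, mean_force = mean_force,
                       n = count),
            bin = bin, window_edges = edges, kT = kT,
            class = c("pmf_profile", "data.frame"))
}

#' Integrate a mean-force profile into a free-energy curve
#'
#' The potential of mean force follows from `dA/dtheta = -<F>` by trapezoidal
#' integration over the contiguous bin centers; windows share bin-grid edges,
#' so concatenating their force estimates stitches the profile without
#' additional matching constants. The curve is shifted so its minimum is 0.
#'
#' @param profile A `pmf_profile` from [run_abf()].
#' @return A data.frame with `theta` (deg) and `G` (kcal/mol, min 0), class
#'   `pmf_curve`.
#' @export
integrate_pmf <- function(profile) {
  stopifnot(inherits(profile, "pmf_profile"))
  bad <- which(profile$n == 0 | !is.finite(profile$mean_force))
  if (length(bad) > 0)
    stop("bins never visited near theta = ",
         paste(round(profile$theta[bad[seq_len(min(5, length(bad)))]], 1),
               collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  th <- profile$theta
  f <- profile$mean_force
  # A(theta) = -int <F> dtheta, trapezoid on bin centers
  dA <- -(utils::head(f, -1) + utils::tail(f, -1)) / 2 * diff(th)
  G <- c(0, cumsum(dA))
  G <- G - min(G)
  structure(data.frame(theta = th, G = G),
            class = c("pmf_curve", "data.frame"))
}

#' Barrier height of a reconstructed bending free-energy profile
#'
#' The barrier is the profile maximum minus its value at the extended-DNA
#' minimum (the lowest point at angles above `extended_above` degrees).
#'
#' @param curve A `pmf_curve` (or a `pmf_profile`, integrated on the fly).
#' @param extended_above Angle above which the extended minimum is sought,
#'   degrees.
#' @return Barrier height, kcal/mol.
#' @export
barrier_height <- function(curve, extended_above = 140) {
  if (inherits(curve, "pmf_profile")) curve <- integrate_pmf(curve)
  ext <- curve$theta > extended_above
  if (!any(ext)) stop("no bins above the extended-region boundary")
  max(curve$G) - min(curve$G[ext])
}

#' Write a PMF curve as two-column CSV (theta_deg, G_kcal_mol)
#'
#' @param curve A `pmf_curve`.
#' @param path File path.
#' @export
write_pmf <- function(curve, path) {
  utils::write.csv(data.frame(theta_deg = curve$theta,
                              G_kcal_mol = curve$G),
                   path, row.names = FALSE)
  invisible(path)
}
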