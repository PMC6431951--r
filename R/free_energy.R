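#' Free-energy profile F(|D|) from sampled knot separations
#'
#' Histograms the pooled |D| samples, converts to
#' `F = -kBT log p(|D|)`, and fixes the additive constant by zeroing the
#' mean of F over the entropic plateau window (default
#' `|D| in [0.35 N, 0.55 N]`, away from both the intertwined state and
#' the walls). Empty bins carry NA, never -Inf.
#'
#' @param D numeric vector of |D| samples (beads), pooled over runs.
#' @param N chain length in beads (sets the plateau window).
#' @param kBT thermal energy.
#' @param bin_width histogram bin width in beads.
#' @param plateau_window numeric `c(lo, hi)` as fractions of N.
#' @return a `polyknot_profile`: list with `bin_centers`, `counts`, `F`,
#'   `F_corrected` (NULL until [subtract_entropy()]), and the settings.
#' @export
estimate_profile <- function(D, N, kBT = 1, bin_width = 2,
                             plateau_window = c(0.35, 0.55)) {
  if (length(D) == 0) stop("empty |D| sample")
  # bins start at -bin_width/4 so that the (half-)integer grid |D| takes
  # values on is symmetric about each bin center; this makes the
  # histogram's effective abscissa equal the center, which the exact
  # entropy subtraction relies on
  breaks <- seq(-bin_width / 4,
                max(D) + 1.25 * bin_width, by = bin_width)
  counts <- tabulate(findInterval(D, breaks, rightmost.closed = FALSE),
                     nbins = length(breaks) - 1)
  centers <- head(breaks, -1) + bin_width / 2
  p <- counts / sum(counts)
  FF <- ifelse(counts > 0, -kBT * log(p), NA_real_)
  prof <- structure(list(bin_centers = centers, counts = counts, F = FF,
                         F_corrected = NULL, kBT = kBT,
                         bin_width = bin_width, N = N,
                         plateau_window = plateau_window),
                    class = "polyknot_profile")
  prof$F <- FF - plateau_level(centers, FF, N, plateau_window)
  prof
}

plateau_level <- function(centers, FF, N, win) {
  sel <- centers >= win[1] * N & centers <= win[2] * N & !is.na(FF)
  if (!any(sel)) return(min(FF, na.rm = TRUE))
  mean(FF[sel])
}

#' @export
print.polyknot_profile <- function(x, ...) {
  cat("<polyknot_profile>", length(x$bin_centers), "bins of width",
      x$bin_width, "beads;", sum(x$counts), "samples",
      if (!is.null(x$F_corrected)) "(entropy-subtracted)" else "", "\n")
  invisible(x)
}

#' Microstate fraction of the sliding-segment model
#'
#' Two indistinguishable segments of length `lk` slide freely on a linear
#' string of `N` beads (they may overlap, mimicking intertwined knots).
#' The fraction of microstates at center separation `D` is
#' `omega = 2 (N - lk + 1 - D) / [(N - lk + 2)(N - lk + 1)]`,
#' which sums to 1 exactly over `D = 0 .. N - lk + 1`.
#'
#' @param D separation(s) between segment centers, in
#'   `[0, N - lk + 1]` (real values allowed: the formula extends
#'   linearly between integers).
#' @param N string length (beads).
#' @param lk segment length (beads), `lk < N`.
#' @return probability fraction(s).
#' @export
microstate_fraction <- function(D, N, lk) {
  stopifnot(lk < N, lk >= 1)
  M1 <- N - lk + 1
  if (any(D < 0 | D > M1)) stop("D out of range [0, N - lk + 1]")
  2 * (M1 - D) / ((M1 + 1) * M1)
}

#' Sliding-segment entropy
#'
#' `S(|D|) = kB ln omega(|D|; N, lk)`, in units of kB. Undefined
#' (masked as NA, with no error) where `omega = 0`.
#'
#' @inheritParams microstate_fraction
#' @return entropy value(s) in kB units.
#' @export
entropy_S <- function(D, N, lk) {
  w <- microstate_fraction(D, N, lk)
  ifelse(w > 0, log(w), NA_real_)
}

#' Subtract the exact sliding-segment entropy from a profile
#'
#' `F_corrected(|D|) = F(|D|) + T S(|D|)`: removes the purely entropic
#' part of the knot-separation free energy, so that data generated by
#' the pure sliding-segment model flattens out completely and only the
#' rigidity- and chirality-dependent features remain. `lk` should be the
#' measured mean size of a separated knot at the bending rigidity of the
#' data. The corrected profile is re-zeroed on the plateau window.
#'
#' @param profile a `polyknot_profile`.
#' @param N string length (beads).
#' @param lk mean separated-knot size (beads).
#' @return the profile with `F_corrected` filled in.
#' @export
subtract_entropy <- function(profile, N = profile$N, lk) {
  Dmax <- N - lk + 1
  S <- rep(NA_real_, length(profile$bin_centers))
  ok <- profile$bin_centers >= 0 & profile$bin_centers < Dmax
  S[ok] <- entropy_S(profile$bin_centers[ok], N, lk)
  fc <- profile$F + profile$kBT * S
  profile$F_corrected <- fc - plateau_level(profile$bin_centers, fc, N,
                                            profile$plateau_window)
  profile
}

#' Extract barrier, minimum depth and interaction distance
#'
#' From a free-energy profile with a resolved minimum/barrier region
#' (typically the entropy-subtracted one), measures the three
#' interaction features: `eps_b`, the barrier height above the entropic
#' plateau; `eps_d`, the depth of the intertwined minimum at |D| = 0
#' below the barrier top; and `D_int`, the onset of the knot-knot
#' interaction, defined as the largest |D| below N/2 at which F exceeds
#' the plateau by the detection threshold while scanning |D| downward.
#'
#' @param profile a `polyknot_profile`.
#' @param N chain length (beads).
#' @param threshold detection threshold above the plateau for `D_int`;
#'   default is twice the standard deviation of F over the plateau
#'   window (the profile's own noise scale).
#' @return a list with `eps_b`, `eps_d`, `D_int` (NA where undefined,
#'   e.g. no minimum at the origin in the low-rigidity regime).
#' @export
extract_features <- function(profile, N = profile$N, threshold = NULL) {
  FF <- if (!is.null(profile$F_corrected)) profile$F_corrected else profile$F
  ctr <- profile$bin_centers
  win <- profile$plateau_window
  sel <- ctr >= win[1] * N & ctr <= win[2] * N & !is.na(FF)
  if (!any(sel)) return(list(eps_b = NA_real_, eps_d = NA_real_,
                             D_int = NA_real_))
  plateau <- mean(FF[sel])
  if (is.null(threshold)) {
    s <- sd(FF[sel])
    threshold <- if (is.finite(s) && s > 0) 2 * s else 1e-8
  }
  scan <- which(ctr < N / 2 & !is.na(FF))
  scan <- scan[order(ctr[scan], decreasing = TRUE)]
  above <- FF[scan] > plateau + threshold
  if (!any(above)) return(list(eps_b = NA_real_, eps_d = NA_real_,
                               D_int = NA_real_))
  first <- which(above)[1]
  D_int <- ctr[scan[first]]
  barrier_sel <- !is.na(FF) & ctr <= D_int
  eps_b <- max(FF[barrier_sel]) - plateau
  F0 <- FF[which(!is.na(FF))[1]]           # first resolved bin (|D| ~ 0)
  min_bin <- ctr[which(!is.na(FF))[1]]
  eps_d <- if (min_bin <= profile$bin_width &&
               F0 < max(FF[barrier_sel])) max(FF[barrier_sel]) - F0
           else NA_real_
  list(eps_b = eps_b, eps_d = eps_d, D_int = D_int)
}

#' Elastic bending energy stored in a knot
#'
#' Modelling the knot as a loop of radius R plus a braided region of
#' extent ~2R with the same curvature gives a knot length
#' `(2 pi + 2) R = sigma n` and bending energy
#' `E_b(n) = 2 (pi + 1)^2 kappa_b / (sigma n)`.
#'
#' @param n knot size in beads (> 0).
#' @param kappa_b bending rigidity.
#' @param sigma bond length.
#' @return bending energy.
#' @export
knot_bending_energy <- function(n, kappa_b, sigma = 1) {
  if (any(n <= 0)) stop("n must be > 0")
  2 * (pi + 1)^2 * kappa_b / (sigma * n)
}

#' Elastic free energy of a knot of size n
#'
#' Bending cost plus the quadratic tension penalty `Q n^2 / 2` from the
#' chain length the knot takes up under stretching.
#'
#' @inheritParams knot_bending_energy
#' @param Q tension coefficient (energy per bead^2).
#' @return free energy at size `n` (vectorized).
#' @export
elastic_free_energy <- function(n, kappa_b, Q, sigma = 1) {
  knot_bending_energy(n, kappa_b, sigma) + 0.5 * Q * n^2
}

#' Equilibrium knot size of the elastic model
#'
#' Argmin of [elastic_free_energy()] per knot:
#' `n* = (2 (pi + 1)^2 sigma kappa_b / Q)^(1/3)`. Scales as
#' `kappa_b^(1/3)`, reproducing the sublinear growth of the separated
#' knot size with rigidity.
#'
#' @inheritParams elastic_free_energy
#' @return equilibrium size in beads (real; round for a bead count).
#' @examples
#' equilibrium_knot_size(20, Q = 0.015)  # ~35.8 -> 36 beads
#' @export
equilibrium_knot_size <- function(kappa_b, Q, sigma = 1) {
  stopifnot(Q > 0)
  (2 * (pi + 1)^2 * sigma * kappa_b / Q)^(1 / 3)
}

#' Calibrate the tension coefficient Q from measured knot sizes
#'
#' With one calibration point the minimum condition is inverted exactly:
#' `Q = 2 (pi + 1)^2 sigma kappa_b / n^3`. With several points Q is
#' fitted by least squares of the predicted equilibrium sizes against
#' the measured ones.
#'
#' @param sizes data.frame (or list) with columns/fields `kappa_b` and
#'   `n` (measured knot sizes in beads, > 0).
#' @param sigma bond length.
#' @return fitted Q.
#' @export
fit_Q <- function(sizes, sigma = 1) {
  kb <- sizes$kappa_b; n <- sizes$n
  stopifnot(length(kb) >= 1, length(kb) == length(n))
  if (any(n <= 0)) stop("knot sizes must be > 0")
  if (length(kb) == 1) return(2 * (pi + 1)^2 * sigma * kb / n^3)
  qs <- 2 * (pi + 1)^2 * sigma * kb / n^3
  obj <- function(Q) sum((equilibrium_knot_size(kb, Q, sigma) - n)^2)
  optimize(obj, c(min(qs) / 10, max(qs) * 10), tol = 1e-12)$minimum
}
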