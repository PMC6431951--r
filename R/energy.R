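#' Pairwise WCA energy
#'
#' Purely repulsive Weeks-Chandler-Andersen potential,
#' `4 eps [ (sigma/r)^12 - (sigma/r)^6 + 1/4 ]` for `r <= 2^(1/6) sigma`
#' and zero beyond; continuous at the cutoff.
#'
#' @param r pair distance(s), > 0.
#' @param params a `polyknot_params`.
#' @return energy (vectorized over `r`).
#' @examples
#' p <- model_params(N = 10)
#' wca_pair_energy(1, p)        # = epsilon
#' wca_pair_energy(2^(1/6), p)  # = 0 at the cutoff
#' @export
wca_pair_energy <- function(r, params) {
  if (any(r <= 0)) stop("r must be > 0")
  sr6 <- (params$sigma / r)^6
  u <- 4 * params$epsilon * (sr6^2 - sr6 + 0.25)
  u[r > 2^(1 / 6) * params$sigma] <- 0
  u
}

#' FENE bond energy
#'
#' Kremer-Grest finitely extensible bond,
#' `-(kappa R0^2 / 2) ln(1 - (b/R0)^2)`; diverges as the bond approaches
#' the extension limit R0, which (combined with WCA repulsion) makes bonds
#' impenetrable and freezes the chain topology.
#'
#' @param b bond length(s), `0 <= b < R0`.
#' @param params a `polyknot_params`.
#' @return energy (vectorized over `b`).
#' @export
fene_bond_energy <- function(b, params) {
  if (any(b < 0)) stop("bond length must be >= 0")
  if (any(b >= params$R0))
    stop("overstretched bond: b >= R0 (topology safety violation)")
  -0.5 * params$kappa_fene * params$R0^2 * log(1 - (b / params$R0)^2)
}

#' Bending energy of a conformation
#'
#' Sum over interior joints of `kappa_b (1 - cos phi_i)`, with `phi_i` the
#' angle between consecutive bond vectors. Zero iff the chain is straight.
#'
#' @param conf a `polyknot_conformation` (N >= 3).
#' @param params a `polyknot_params`.
#' @return total bending energy.
#' @export
bending_energy <- function(conf, params) {
  pos <- conf$positions
  if (nrow(pos) < 3) stop("bending energy needs N >= 3")
  u <- bond_vectors(pos)
  nu <- sqrt(rowSums(u * u))
  if (any(nu == 0)) stop("degenerate geometry: zero-length bond")
  n <- nrow(u)
  cosphi <- rowSums(u[-n, , drop = FALSE] * u[-1, , drop = FALSE]) /
    (nu[-n] * nu[-1])
  sum(params$kappa_b * (1 - cosphi))
}

#' Smooth repulsive wall energy
#'
#' Truncated-and-shifted Lennard-Jones 9-3 wall used for the planes x = 0
#' and x = L: purely repulsive, zero (with zero force) beyond its cutoff
#' `(2/5)^(1/6) wall_sigma`.
#'
#' @param d distance(s) from the wall plane, > 0.
#' @param params a `polyknot_params`.
#' @return energy (vectorized over `d`).
#' @export
wall_energy <- function(d, params) {
  if (any(d <= 0)) stop("wall distance must be > 0")
  sw <- params$wall_sigma
  t3 <- (sw / d)^3
  u <- params$wall_eps * ((2 / 15) * t3^3 - t3 + sqrt(10) / 3)
  u[d >= (2 / 5)^(1 / 6) * sw] <- 0
  u
}

#' Total potential energy, by component
#'
#' WCA is summed over all distinct bead pairs (bonded neighbours
#' included), FENE over the N-1 bonds, bending over the N-2 interior
#' joints, and the wall term over interior beads against both walls.
#'
#' @param conf a `polyknot_conformation`.
#' @param params a `polyknot_params`.
#' @return an `polyknot_energy` list with components `wca`, `fene`,
#'   `bending`, `walls` and `total`.
#' @export
total_energy <- function(conf, params) {
  res <- .energy_cpp(conf$positions, params)
  stop_on_status(res$status, res$bad_index)
  out <- list(wca = res$wca, fene = res$fene, bending = res$bending,
              walls = res$walls,
              total = res$wca + res$fene + res$bending + res$walls)
  class(out) <- "polyknot_energy"
  out
}

#' @export
print.polyknot_energy <- function(x, ...) {
  cat(sprintf("<polyknot_energy> total %.6g (wca %.4g fene %.4g bend %.4g walls %.4g)\n",
              x$total, x$wca, x$fene, x$bending, x$walls))
  invisible(x)
}

#' Forces on every bead
#'
#' Analytic gradient `-dU/dr` of the total potential. Forces on the
#' tethered termini are reported but never integrated.
#'
#' @param conf a `polyknot_conformation`.
#' @param params a `polyknot_params`.
#' @return N x 3 matrix of forces.
#' @export
forces <- function(conf, params) {
  res <- .forces_cpp(conf$positions, params)
  stop_on_status(res$status, res$bad_index)
  res$forces
}

stop_on_status <- function(status, bad_index = NA) {
  if (status == 0) return(invisible())
  msg <- switch(as.character(status),
    "1" = paste0("overstretched bond at bead ", bad_index,
                 ": topology safety violated"),
    "2" = paste0("bead ", bad_index, " penetrated a wall"),
    "3" = "non-finite energy: instability (try a smaller dt)",
    "4" = paste0("degenerate geometry (zero separation) at bead ", bad_index),
    paste("unknown error status", status))
  stop(msg, call. = FALSE)
}
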