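#' Chain conformation
#'
#' A single chain state: ordered bead positions (an N x 3 matrix, columns
#' x, y, z in sigma units) plus optional velocities. Bead 1 and bead N are
#' the tethered termini; x is the stretching axis.
#'
#' @param positions numeric N x 3 matrix of bead coordinates.
#' @param velocities optional N x 3 matrix of bead velocities.
#' @return object of class `polyknot_conformation`.
#' @examples
#' conf <- conformation(straight_chain_positions(10, bond = 1))
#' nrow(conf$positions)
#' @export
conformation <- function(positions, velocities = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  storage.mode(positions) <- "double"
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    stopifnot(dim(velocities)[1] == nrow(positions), ncol(velocities) == 3)
    storage.mode(velocities) <- "double"
  }
  structure(list(positions = positions, velocities = velocities),
            class = "polyknot_conformation")
}

#' Validate a conformation against model constraints
#'
#' Checks the two structural invariants: every bond is strictly shorter
#' than the FENE extension limit R0, and every interior bead lies strictly
#' between the wall planes x = 0 and x = L.
#'
#' @param conf a `polyknot_conformation`.
#' @param params a `polyknot_params`.
#' @param walls check the wall constraint (disable for free-space arcs).
#' @return the conformation, invisibly; errors on violation.
#' @export
validate_conformation <- function(conf, params, walls = TRUE) {
  stopifnot(inherits(conf, "polyknot_conformation"))
  pos <- conf$positions
  b <- bond_lengths(pos)
  if (any(b >= params$R0))
    stop("overstretched bond at index ", which(b >= params$R0)[1],
         " (length ", signif(max(b), 4), " >= R0)")
  if (any(b <= 0)) stop("zero-length bond")
  if (walls) {
    xin <- pos[-c(1, nrow(pos)), 1]
    if (length(xin) && (any(xin <= 0) || any(xin >= params$L_wall)))
      stop("interior bead outside the wall planes")
  }
  invisible(conf)
}

bond_lengths <- function(pos) {
  d <- diff(pos)
  sqrt(rowSums(d * d))
}

bond_vectors <- function(pos) diff(pos)

#' @export
print.polyknot_conformation <- function(x, ...) {
  cat("<polyknot_conformation>", nrow(x$positions), "beads",
      if (!is.null(x$velocities)) "(with velocities)" else "", "\n")
  invisible(x)
}

#' Straight chain positions along the stretching axis
#'
#' @param N bead count.
#' @param bond bond length.
#' @param origin 3-vector of the first bead.
#' @return N x 3 position matrix along +x.
#' @export
straight_chain_positions <- function(N, bond = 1, origin = c(0, 0, 0)) {
  cbind(origin[1] + bond * (seq_len(N) - 1),
        rep(origin[2], N), rep(origin[3], N))
}
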