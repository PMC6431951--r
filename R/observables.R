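#' Center of a knot arc along the chain
#'
#' @param arc `c(s, e)` 0-based inclusive bead indices.
#' @return `(s + e) / 2`, possibly half-integer.
#' @export
knot_center <- function(arc) unname((arc[1] + arc[2]) / 2)

#' Knot separation order parameter |D|
#'
#' The absolute linear distance (in beads) between the centers of the two
#' knots. For separated knots it is the distance between the two isolated
#' arc centers; for intertwined knots, the distance between the nested
#' knot's center and the center of the whole composite arc (the host
#' knot's start and end are taken to coincide with the composite's).
#'
#' @param record a `polyknot_knotrecord` from [find_prime_components()].
#' @return list with `D_abs` (nonnegative scalar, beads) and `state`.
#' @export
separation_D <- function(record) {
  if (record$n_isolated >= 2) {
    c1 <- knot_center(c(record$arcs[[1]]$s, record$arcs[[1]]$e))
    c2 <- knot_center(c(record$arcs[[2]]$s, record$arcs[[2]]$e))
    list(D_abs = abs(c1 - c2), state = "separated")
  } else if (record$n_isolated == 1) {
    if (is.null(record$composite_arc))
      stop("intertwined record without a composite arc")
    cn <- knot_center(c(record$arcs[[1]]$s, record$arcs[[1]]$e))
    cc <- knot_center(record$composite_arc)
    list(D_abs = abs(cn - cc), state = "intertwined")
  } else {
    stop("record has no isolated components")
  }
}

#' Knot orientation director
#'
#' The normalized sum of cross products of consecutive bond vectors over
#' a knot arc -- the idealized normal of the knot loop, oriented by
#' arc-length traversal (right-hand rule). For the host knot of an
#' intertwined pair, pass the nested arc as `exclude` so the director is
#' built only from the bonds of the composite region complementary to
#' the nested knot.
#'
#' @param conf a `polyknot_conformation` or n x 3 matrix.
#' @param arc `c(s, e)` 0-based inclusive bead indices (>= 3 bonds).
#' @param exclude optional `c(s, e)` subarc whose bonds are omitted.
#' @return a `polyknot_director`: list with unit 3-vector `U` and flag
#'   `defined` (`FALSE` when the cross-product sum vanishes; such frames
#'   are excluded from angle statistics, not imputed).
#' @export
orientation_director <- function(conf, arc, exclude = NULL) {
  pos <- if (inherits(conf, "polyknot_conformation")) conf$positions
         else as.matrix(conf)
  bonds <- seq(arc[1], arc[2] - 1)        # bond j = r_{j+1} - r_j, 0-based
  if (!is.null(exclude))
    bonds <- setdiff(bonds, seq(exclude[1], exclude[2] - 1))
  if (length(bonds) < 3) stop("arc must contain at least 3 bonds")
  u <- pos[bonds + 2, , drop = FALSE] - pos[bonds + 1, , drop = FALSE]
  # consecutive pairs present in the bond set
  j <- bonds[-length(bonds)]
  ok <- (j + 1) %in% bonds
  a <- u[-nrow(u), , drop = FALSE][ok, , drop = FALSE]
  b <- u[-1, , drop = FALSE][ok, , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  s <- colSums(cr)
  n <- sqrt(sum(s^2))
  if (n < 1e-10)
    return(structure(list(U = c(NA, NA, NA), defined = FALSE),
                     class = "polyknot_director"))
  structure(list(U = s / n, defined = TRUE), class = "polyknot_director")
}

dir_vec <- function(U) if (inherits(U, "polyknot_director")) U$U else U

#' Angle between two knot directors
#'
#' `theta = arccos(U1 . U2)` in radians, in `[0, pi]`; the dot product is
#' clamped to `[-1, 1]` for floating-point safety.
#'
#' @param U1,U2 `polyknot_director` objects or unit 3-vectors.
#' @return angle in radians.
#' @export
theta_angle <- function(U1, U2) {
  u1 <- dir_vec(U1); u2 <- dir_vec(U2)
  acos(max(-1, min(1, sum(u1 * u2))))
}

#' Signed angle between director projections on the YZ plane
#'
#' Measures the relative rotation of the two knot loops about the
#' stretching axis x: the magnitude is the angle between the normalized
#' YZ-plane projections V1, V2 (two-argument arctangent of
#' `(|V1 x V2|, V1 . V2)`), and the sign is the sign of the x component
#' of `U1 x U2`. Antisymmetric under argument swap. Returns `NA` when
#' either projection has vanishing norm.
#'
#' @param U1,U2 `polyknot_director` objects or unit 3-vectors.
#' @param tol norm below which a YZ projection counts as vanishing.
#' @return signed angle in `(-pi, pi]`, or `NA`.
#' @export
theta_perp <- function(U1, U2, tol = 1e-10) {
  u1 <- dir_vec(U1); u2 <- dir_vec(U2)
  v1 <- u1[2:3]; v2 <- u2[2:3]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < tol || n2 < tol) return(NA_real_)
  v1 <- v1 / n1; v2 <- v2 / n2
  cross2 <- v1[1] * v2[2] - v1[2] * v2[1]
  mag <- atan2(abs(cross2), sum(v1 * v2))
  sx <- u1[2] * u2[3] - u1[3] * u2[2]     # x component of U1 x U2
  sgn <- if (sx >= 0) 1 else -1
  sgn * mag
}

#' Per-frame order parameters from a knot table
#'
#' Combines a trajectory with its knot-localization table into the
#' order-parameter series: |D| with the separated/intertwined state, the
#' loop angles theta and theta-perp, and the handedness of the nested
#' knot when intertwined. For separated frames the directors are built
#' on the two isolated arcs; for intertwined frames U1 uses the nested
#' knot's bonds and U2 the composite-arc bonds complementary to the
#' nested arc. Frames with undefined directors keep NA angles.
#'
#' @param traj a `polyknot_trajectory`.
#' @param knot_table data.frame from [analyze_trajectory()].
#' @return data.frame with columns `frame`, `state`, `D_abs`, `theta`,
#'   `theta_perp`, `nested_handedness`.
#' @export
order_params <- function(traj, knot_table) {
  rows <- lapply(seq_len(nrow(knot_table)), function(r) {
    k <- knot_table[r, ]
    out <- data.frame(frame = k$frame, state = NA_character_,
                      D_abs = NA_real_, theta = NA_real_,
                      theta_perp = NA_real_,
                      nested_handedness = NA_integer_)
    if (is.na(k$n_isolated) || k$n_isolated < 1) return(out)
    pos <- traj$frames[k$frame, , ]
    if (k$n_isolated >= 2) {
      out$state <- "separated"
      c1 <- (k$s1 + k$e1) / 2; c2 <- (k$s2 + k$e2) / 2
      out$D_abs <- abs(c1 - c2)
      U1 <- orientation_director(pos, c(k$s1, k$e1))
      U2 <- orientation_director(pos, c(k$s2, k$e2))
    } else {
      out$state <- "intertwined"
      if (is.na(k$s_comp)) return(out)
      cn <- (k$s1 + k$e1) / 2; cc <- (k$s_comp + k$e_comp) / 2
      out$D_abs <- abs(cn - cc)
      out$nested_handedness <- k$h1
      U1 <- orientation_director(pos, c(k$s1, k$e1))
      U2 <- orientation_director(pos, c(k$s_comp, k$e_comp),
                                 exclude = c(k$s1, k$e1))
    }
    if (U1$defined && U2$defined) {
      out$theta <- theta_angle(U1, U2)
      out$theta_perp <- theta_perp(U1, U2)
    }
    out
  })
  do.call(rbind, rows)
}
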