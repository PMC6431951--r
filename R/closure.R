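#' Minimally interfering closure of an open arc
#'
#' Circularizes an open subchain so its topology can be assigned. Two
#' closure branches are compared: (a) the direct terminus-to-terminus
#' segment, chosen when the terminus separation is smaller than the sum of
#' the two termini's distances to the surface of the arc's bounding box
#' (a cheap proxy for how deeply each terminus is buried inside the arc's
#' hull); otherwise (b) outward closure, in which each terminus is
#' extended radially away from the arc's centroid to a sphere of about
#' twice the arc's bounding radius and the two outward points are joined
#' along that sphere, adding as little spurious entanglement as possible.
#'
#' @param arc numeric n x 3 matrix of ordered arc vertices (n >= 3), or a
#'   `polyknot_conformation`.
#' @param whole_chain_context optional m x 3 matrix of the full chain the
#'   arc was taken from; when supplied it only enlarges the closure
#'   sphere so the auxiliary arcs also clear the rest of the chain.
#' @return a `polyknot_polygon`: a closed vertex cycle (matrix with class
#'   attribute); the final edge from last to first row is implicit.
#' @export
close_arc_mic <- function(arc, whole_chain_context = NULL) {
  if (inherits(arc, "polyknot_conformation")) arc <- arc$positions
  arc <- as.matrix(arc)
  if (nrow(arc) < 3) stop("arc must have >= 3 points")
  e1 <- arc[1, ]; e2 <- arc[nrow(arc), ]
  d_direct <- sqrt(sum((e1 - e2)^2))

  lo <- apply(arc, 2, min); hi <- apply(arc, 2, max)
  box_dist <- function(p) min(p - lo, hi - p)
  if (d_direct < box_dist(e1) + box_dist(e2)) {
    return(structure(arc, class = "polyknot_polygon"))
  }

  ref <- if (is.null(whole_chain_context)) arc else
    rbind(arc, as.matrix(whole_chain_context))
  ctr <- colMeans(arc)
  rad <- 2.2 * max(sqrt(rowSums(sweep(ref, 2, ctr)^2)), 1e-8)

  outward <- function(e) {
    d <- e - ctr
    n <- sqrt(sum(d^2))
    if (n < 1e-10) d <- c(1, 0, 0) else d <- d / n
    d
  }
  d2 <- outward(e2); d1 <- outward(e1)
  # great-circle interpolation from the end-terminus direction back to the
  # start-terminus direction, on the closure sphere
  cosang <- max(-1, min(1, sum(d1 * d2)))
  ang <- acos(cosang)
  if (ang < 1e-8) {
    pts <- rbind(ctr + rad * d2, ctr + rad * d1)
  } else {
    if (pi - ang < 1e-6) {
      # nearly antipodal: route through an arbitrary orthogonal direction
      ortho <- if (abs(d2[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      ortho <- ortho - sum(ortho * d2) * d2
      ortho <- ortho / sqrt(sum(ortho^2))
      mids <- rbind(d2, ortho, d1)
    } else {
      mids <- rbind(d2, d1)
    }
    pts <- NULL
    for (seg in seq_len(nrow(mids) - 1)) {
      a <- mids[seg, ]; b <- mids[seg + 1, ]
      th <- acos(max(-1, min(1, sum(a * b))))
      nstep <- max(2L, ceiling(th / (pi / 8)))
      for (k in 0:(nstep - 1)) {
        f <- k / nstep
        v <- (sin((1 - f) * th) * a + sin(f * th) * b) / sin(th)
        pts <- rbind(pts, ctr + rad * v)
      }
    }
    pts <- rbind(pts, ctr + rad * d1)
  }
  structure(rbind(arc, pts), class = "polyknot_polygon")
}

#' @export
print.polyknot_polygon <- function(x, ...) {
  cat("<polyknot_polygon>", nrow(x), "vertices (closed)\n")
  invisible(x)
}
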