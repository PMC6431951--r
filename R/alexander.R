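#' Alexander determinants of a closed polygon
#'
#' Evaluates |Delta(-1)| and |Delta(-2)| of the Alexander polynomial from
#' a crossing diagram of the polygon. The polygon is first simplified by
#' KMT (triangle-elimination) reduction, then projected along a random
#' direction; projections with degenerate crossings (grazing or
#' collinear) are re-drawn with a fresh rotation, up to `max_retries`
#' times, with deterministic seeding so results are reproducible. The
#' determinant at t = -2 is only defined up to powers of 2 (the Alexander
#' polynomial is defined up to units +-t^m), so all factors of 2 are
#' divided out; every label the package classifies has odd determinants,
#' so no information is lost.
#'
#' @param poly a `polyknot_polygon` or an n x 3 matrix of closed-cycle
#'   vertices.
#' @param seed integer key for the deterministic projection sequence
#'   (e.g. the frame index).
#' @param max_retries bound on degenerate-projection retries.
#' @param reduce apply KMT reduction first (keep `TRUE`; exposed for
#'   testing projection invariance on raw polygons).
#' @return integer vector `c(det_m1, det_m2)`.
#' @examples
#' tri <- rbind(c(0, 0, 0), c(1, 0, 0.1), c(0.5, 1, -0.1))
#' alexander_determinants(tri)  # unknot: (1, 1)
#' @export
alexander_determinants <- function(poly, seed = 1L, max_retries = 50L,
                                   reduce = TRUE) {
  v <- as.matrix(poly)
  if (nrow(v) < 3) return(c(det_m1 = 1L, det_m2 = 1L))
  if (reduce) v <- .kmt_cpp(v, TRUE)
  if (nrow(v) <= 3) return(c(det_m1 = 1L, det_m2 = 1L))
  dg <- crossing_diagram(v, seed, max_retries)
  dets_from_diagram(dg)
}

# Extract a non-degenerate crossing diagram; rows (s_over, s_under, sign).
crossing_diagram <- function(verts, seed = 1L, max_retries = 50L) {
  for (a in seq_len(max_retries)) {
    cr <- .crossings_cpp(verts, rotation_from_key(seed * 1009L + a))
    if (!(nrow(cr) == 1 && ncol(cr) == 1 && is.na(cr[1, 1]))) return(cr)
  }
  stop("no non-degenerate projection found after ", max_retries,
       " retries (", nrow(verts), " vertices)")
}

# Alexander determinants at t = -1, -2 from a crossing diagram.
# Arcs are the strands between consecutive underpasses along the curve;
# arc j ends at underpass j, so underpass k joins arcs k and k+1, and the
# matrix row for underpass k involves generators k, k+1 and the overpass
# arc, with entries depending on the crossing sign.
dets_from_diagram <- function(cr) {
  n <- nrow(cr)
  if (n < 3) return(c(det_m1 = 1L, det_m2 = 1L))
  o <- order(cr[, 2])
  s_under <- cr[o, 2]; s_over <- cr[o, 1]; sgn <- cr[o, 3]
  arc_of <- function(s) {
    j <- findInterval(s, s_under) + 1L
    if (j > n) 1L else j
  }
  over_arc <- vapply(s_over, arc_of, integer(1))
  vals <- vapply(c(-1, -2), function(tt) {
    M <- matrix(0, n, n)
    for (k in seq_len(n)) {
      i <- over_arc[k]
      k1 <- if (k == n) 1L else k + 1L
      if (i == k || i == k1) {
        M[k, k] <- M[k, k] - 1
        M[k, k1] <- M[k, k1] + 1
      } else if (sgn[k] > 0) {
        M[k, k] <- 1; M[k, k1] <- -tt; M[k, i] <- tt - 1
      } else {
        M[k, k] <- -tt; M[k, k1] <- 1; M[k, i] <- tt - 1
      }
    }
    abs(det(M[-n, -n, drop = FALSE]))
  }, numeric(1))
  d1 <- round(vals[1])
  d2 <- round(vals[2])
  while (d2 > 0 && d2 %% 2 == 0) d2 <- d2 / 2
  c(det_m1 = as.integer(d1), det_m2 = as.integer(d2))
}

#' Classify a topology from its Alexander determinant pair
#'
#' Pure lookup: (1,1) unknot; (3,7) trefoil; (9,49) granny/square
#' composite of two trefoils; anything else `other`. Chirality is not
#' inferred here -- the Alexander polynomial cannot distinguish
#' enantiomers; see [handedness()].
#'
#' @param det_m1,det_m2 nonnegative integers, |Delta(-1)| and |Delta(-2)|.
#' @return a `polyknot_topology` list with fields `det_m1`, `det_m2`,
#'   `label` (one of `"unknot"`, `"trefoil"`, `"composite_3131"`,
#'   `"other"`).
#' @export
classify_topology <- function(det_m1, det_m2) {
  stopifnot(det_m1 >= 0, det_m2 >= 0)
  key <- paste(det_m1, det_m2)
  label <- switch(key,
                  "1 1" = "unknot",
                  "3 7" = "trefoil",
                  "9 49" = "composite_3131",
                  "other")
  structure(list(det_m1 = as.integer(det_m1), det_m2 = as.integer(det_m2),
                 label = label),
            class = "polyknot_topology")
}

#' @export
print.polyknot_topology <- function(x, ...) {
  cat(sprintf("<polyknot_topology> %s (|D(-1)| = %d, |D(-2)| = %d)\n",
              x$label, x$det_m1, x$det_m2))
  invisible(x)
}

# topology label of a subarc [s, e] (0-based inclusive) of a chain;
# the arc is KMT-reduced before MIC closure.
arc_label <- function(pos, s, e, seed = 1L) {
  arc <- pos[(s + 1):(e + 1), , drop = FALSE]
  if (nrow(arc) <= 3) return("unknot")
  red <- .kmt_cpp(arc, FALSE)
  if (nrow(red) <= 3) return("unknot")
  d <- alexander_determinants(close_arc_mic(red), seed = seed,
                              reduce = FALSE)
  classify_topology(d[1], d[2])$label
}
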