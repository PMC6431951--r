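# (2,3)-torus curve with major radius 2.4 and unit tube winding: this
# aspect ratio minimizes curve length per unit strand clearance (length
# ~35.9, minimum strand separation ~2.0 at scale 1), so spliced knots eat
# as little chain slack as a near-tight trefoil.
TORUS_LEN <- 35.9
torus_curve <- function(t, mirror = FALSE) {
  z <- sin(3 * t)
  if (mirror) z <- -z
  cbind((2.4 + cos(3 * t)) * cos(2 * t), (2.4 + cos(3 * t)) * sin(2 * t), z)
}

#' Closed trefoil template from the (2,3)-torus curve
#'
#' Equal-arc-length discretization of a (2,3)-torus parameterization
#' (major radius 2.4, unit winding amplitude, times `scale`).
#' Handedness +1 (right-handed, space writhe ~ +3.4) is the mirror image
#' (z -> -z) of -1; the two outputs superimpose exactly under reflection.
#'
#' @param n_beads number of vertices (>= 30 for a faithful curve).
#' @param handedness +1 (right) or -1 (left).
#' @param scale geometric scale factor; bond length is roughly
#'   `scale * 35.9 / n_beads` and the closest strand approach ~2 scale.
#' @param sigma bead diameter used for the self-avoidance check; the
#'   curve must keep non-adjacent beads at least `sigma` apart.
#' @return n_beads x 3 matrix of closed-cycle vertices.
#' @export
make_torus_trefoil <- function(n_beads = 60L, handedness = 1L, scale = 1,
                               sigma = 1) {
  stopifnot(n_beads >= 30, handedness %in% c(-1L, 1L))
  v <- torus_trefoil_vertices(n_beads, handedness, scale)
  dmin <- min_nonadjacent_distance(v, closed = TRUE)
  if (dmin < sigma)
    stop("scale too small for self-avoidance: minimum non-adjacent bead ",
         "distance ", signif(dmin, 3), " < sigma = ", sigma)
  v
}

# equal-arc-length discretization without the bead-count / clearance
# checks (open templates use fewer, tighter beads and are relaxed later)
torus_trefoil_vertices <- function(n_beads, handedness, scale) {
  tt <- seq(0, 2 * pi, length.out = 4000)
  dense <- torus_curve(tt, mirror = handedness > 0) * scale
  seg <- sqrt(rowSums(diff(dense)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  want <- seq(0, total, length.out = n_beads + 1)[1:n_beads]
  idx <- findInterval(want, s, rightmost.closed = TRUE)
  f <- (want - s[idx]) / pmax(s[idx + 1] - s[idx], 1e-12)
  dense[idx, ] + f * (dense[idx + 1, ] - dense[idx, ])
}

min_nonadjacent_distance <- function(v, closed = TRUE) {
  n <- nrow(v)
  d <- as.matrix(dist(v))
  adj <- abs(row(d) - col(d)) <= 1
  if (closed) adj <- adj | abs(row(d) - col(d)) == n - 1
  min(d[!adj & upper.tri(d)])
}

# Open trefoil template: cut the closed curve at its outermost vertex,
# shear the ends apart along the end-to-end direction by `opening`, and
# rotate so the end-to-end vector lies along +x with both ends on the
# x axis.
make_open_trefoil <- function(n_beads = 18L, handedness = 1L, scale = 0.49,
                              opening = 1.2) {
  closed <- torus_trefoil_vertices(n_beads, handedness, scale)
  ctr <- colMeans(closed)
  r2 <- rowSums(sweep(closed, 2, ctr)^2)
  cut <- which.max(r2)
  ord <- c(seq(cut, n_beads), seq_len(cut - 1))[seq_len(n_beads)]
  arc <- closed[ord, , drop = FALSE]
  m <- nrow(arc)
  ete <- arc[m, ] - arc[1, ]
  if (sqrt(sum(ete^2)) < 1e-8) ete <- c(1, 0, 0)
  shear_dir <- ete / sqrt(sum(ete^2))
  arc <- arc + outer((seq_len(m) - 1) / (m - 1) * opening, shear_dir)
  align_to_x(arc)
}

# rigid-transform an arc so its first vertex is the origin and its
# end-to-end vector points along +x
align_to_x <- function(arc) {
  arc <- sweep(arc, 2, arc[1, ])
  v <- arc[nrow(arc), ]
  nv <- sqrt(sum(v^2))
  if (nv < 1e-10) return(arc)
  a <- v / nv
  b <- c(1, 0, 0)
  cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(cr^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(arc)
    # antiparallel: rotate pi about y
    R <- diag(c(-1, 1, -1))
    return(arc %*% t(R))
  }
  k <- cr / s
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + s * K + (1 - cth) * (K %*% K)
  arc %*% t(R)
}

#' Knot placement specification
#'
#' @param handedness +1 (right) or -1 (left).
#' @param center_bead requested center of the knot template along the
#'   chain (0-based bead index).
#' @param template_beads beads in the trefoil template.
#' @param scale template scale factor; default gives ~0.97 sigma bonds.
#' @param knot_type only `"trefoil"` is supported.
#' @return a `polyknot_knotspec` list.
#' @export
knot_spec <- function(handedness = 1L, center_bead, template_beads = 18L,
                      scale = NULL, knot_type = "trefoil") {
  stopifnot(knot_type == "trefoil")
  if (is.null(scale)) scale <- 0.97 * template_beads / TORUS_LEN
  structure(list(knot_type = knot_type, handedness = as.integer(handedness),
                 center_bead = as.integer(center_bead),
                 template_beads = as.integer(template_beads),
                 scale = scale),
            class = "polyknot_knotspec")
}

#' Build a stretched chain carrying knots
#'
#' Constructs a chain of `params$N` beads tethered at (0,0,0) and
#' (L,0,0) with open-trefoil templates spliced at the requested centers,
#' followed by a short zero-temperature relaxation. In the intertwined
#' arrangement the second template is inserted into the middle of the
#' first one's bead sequence (one knot nested inside the other along the
#' chain). The construction is verified: every bond below R0 and the
#' full-chain closure classifying as the two-trefoil composite;
#' geometric clashes that relaxation cannot repair raise an error.
#'
#' @param params a `polyknot_params`.
#' @param spec1,spec2 `polyknot_knotspec` objects (spec1 leftmost; for
#'   the intertwined arrangement spec2 is the nested knot).
#' @param intertwined logical.
#' @param relax_steps zero-temperature relaxation iterations.
#' @return a `polyknot_conformation`.
#' @examples
#' \donttest{
#' p <- desk_params()
#' conf <- build_two_knot_chain(p, knot_spec(+1, 30), knot_spec(+1, 70))
#' }
#' @export
build_two_knot_chain <- function(params, spec1, spec2,
                                 intertwined = FALSE, relax_steps = 400L) {
  if (intertwined) {
    conf <- build_intertwined(params, spec1, spec2, relax_steps)
  } else {
    stopifnot(spec1$center_bead < spec2$center_bead)
    t1 <- make_open_trefoil(spec1$template_beads, spec1$handedness,
                            spec1$scale)
    t2 <- make_open_trefoil(spec2$template_beads, spec2$handedness,
                            spec2$scale)
    conf <- splice_templates(params, list(t1, t2),
                             centers = c(spec1$center_bead,
                                         spec2$center_bead),
                             relax_steps = relax_steps)
  }
  lbl <- arc_label(conf$positions, 0L, params$N - 1L)
  if (lbl != "composite_3131")
    stop("construction failed: full-chain closure is '", lbl,
         "' (geometric clash that relaxation could not repair)")
  conf
}

# Intertwined arrangement: the nested template (spec2) is inserted into
# the bead sequence of the host template at an interior vertex, so the
# nested knot's arc lies inside the host knot's arc along the chain.
# Insertion points are tried in order of distance from the host template's
# centroid (innermost first) until the construction verifies: composite
# full-chain closure and exactly one isolated prime component.
build_intertwined <- function(params, spec1, spec2, relax_steps) {
  outer_t <- make_open_trefoil(spec1$template_beads, spec1$handedness,
                               spec1$scale)
  inner_t <- make_open_trefoil(spec2$template_beads, spec2$handedness,
                               spec2$scale)
  m1 <- nrow(outer_t)
  ctr <- colMeans(outer_t)
  cand <- order(rowSums(sweep(outer_t, 2, ctr)^2))
  cand <- cand[cand >= 5 & cand <= m1 - 5]
  last_err <- NULL
  for (ins in cand) {
    dirv <- outer_t[ins + 1, ] - outer_t[ins, ]
    dirv <- dirv / sqrt(sum(dirv^2))
    inner_r <- align_to_dir(inner_t, dirv)
    inner_p <- sweep(inner_r, 2, outer_t[ins, ] + 0.9 * dirv, FUN = "+")
    shift <- inner_p[nrow(inner_p), ] + 0.9 * dirv - outer_t[ins + 1, ]
    combined <- rbind(outer_t[seq_len(ins), , drop = FALSE], inner_p,
                      sweep(outer_t[(ins + 1):m1, , drop = FALSE], 2,
                            shift, FUN = "+"))
    conf <- tryCatch({
      cf <- splice_templates(params, list(align_to_x(combined)),
                             centers = spec1$center_bead,
                             relax_steps = relax_steps)
      if (arc_label(cf$positions, 0L, params$N - 1L) != "composite_3131")
        stop("closure is not the two-trefoil composite")
      rec <- find_prime_components(cf)
      if (rec$n_isolated != 1L) stop("arrangement is not intertwined")
      cf
    }, error = function(e) e)
    if (!inherits(conf, "error")) return(conf)
    last_err <- conf
  }
  stop("intertwined construction failed at every insertion point ",
       "(geometric clash that relaxation could not repair): ",
       conditionMessage(last_err))
}

#' Build a stretched chain with a single knot
#'
#' Same splicing machinery as [build_two_knot_chain()] for one trefoil;
#' used for localization fixtures and director reference states.
#'
#' @inheritParams build_two_knot_chain
#' @param spec a `polyknot_knotspec`.
#' @return a `polyknot_conformation`.
#' @export
build_one_knot_chain <- function(params, spec, relax_steps = 400L) {
  t1 <- make_open_trefoil(spec$template_beads, spec$handedness, spec$scale)
  conf <- splice_templates(params, list(t1), centers = spec$center_bead,
                           relax_steps = relax_steps)
  lbl <- arc_label(conf$positions, 0L, params$N - 1L)
  if (lbl != "trefoil")
    stop("construction failed: full-chain closure is '", lbl, "'")
  conf
}

align_to_dir <- function(arc, dirv) {
  ax <- align_to_x(arc)
  # rotate +x onto dirv
  b <- dirv / sqrt(sum(dirv^2))
  a <- c(1, 0, 0)
  cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(cr^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(ax)
    return(ax %*% diag(c(-1, 1, -1)))
  }
  k <- cr / s
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + s * K + (1 - cth) * (K %*% K)
  ax %*% t(R)
}

# Assemble a chain of params$N beads between the walls from straight
# x-axis sections and pre-aligned templates (first/last vertex on the
# x axis, end-to-end along +x), then relax at zero temperature.
splice_templates <- function(params, templates, centers,
                             relax_steps = 400L) {
  N <- params$N; L <- params$L_wall
  m <- vapply(templates, nrow, integer(1))
  spans <- vapply(templates, function(tp) tp[nrow(tp), 1] - tp[1, 1],
                  numeric(1))
  starts <- floor(centers - m / 2)
  ends <- starts + m - 1
  if (any(starts < 5) || any(ends > N - 6))
    stop("templates do not fit with >= 5-bead margins")
  if (length(starts) > 1 && any(starts[-1] - ends[-length(ends)] < 5))
    stop("templates overlap or have < 5-bead separation")

  nb_straight <- (N - 1) - sum(m - 1)
  x_left <- L - sum(spans)
  bond <- x_left / nb_straight
  if (bond <= 0.55 || bond >= 1.25)
    stop("infeasible geometry: straight-section bond length ",
         signif(bond, 3), " outside (0.55, 1.25); adjust N, L or templates")

  # extra clearance: template may dip below its entry x; need margin
  pos <- matrix(0, N, 3)
  cur <- c(0, 0, 0)
  bead <- 1L
  pos[1, ] <- cur
  for (k in seq_along(templates)) {
    nstraight <- starts[k] - (bead - 1L)      # bonds before template start
    for (i in seq_len(nstraight)) {
      cur <- cur + c(bond, 0, 0)
      bead <- bead + 1L
      pos[bead, ] <- cur
    }
    tp <- sweep(templates[[k]], 2, c(cur[1], 0, 0), FUN = "+")
    if (min(tp[, 1]) <= 0.3 || max(tp[, 1]) >= L - 0.3)
      stop("template protrudes past a wall; move center_bead inward")
    for (i in 2:nrow(tp)) {
      bead <- bead + 1L
      pos[bead, ] <- tp[i, ]
    }
    cur <- tp[nrow(tp), ]
  }
  while (bead < N) {
    cur <- cur + c(bond, 0, 0)
    bead <- bead + 1L
    pos[bead, ] <- cur
  }
  pos[N, ] <- c(L, 0, 0)

  b <- bond_lengths(pos)
  if (any(b >= params$R0 * 0.999))
    stop("construction produced an overstretched bond (",
         signif(max(b), 3), " sigma)")
  conf <- conformation(pos)
  if (relax_steps > 0) conf <- relax_minimize(conf, params, relax_steps)
  conf
}

#' Zero-temperature relaxation
#'
#' Steepest descent with backtracking on the full potential; the energy
#' is non-increasing across accepted iterations, termini stay fixed and
#' the topology is unchanged (steps are capped well below the bond
#' impenetrability scale).
#'
#' @param conf a `polyknot_conformation`.
#' @param params a `polyknot_params`.
#' @param n_steps maximum descent iterations.
#' @param ftol force-component convergence threshold.
#' @return the relaxed `polyknot_conformation`.
#' @export
relax_minimize <- function(conf, params, n_steps = 500L, ftol = 1e-6) {
  res <- .minimize_cpp(conf$positions, params, as.integer(n_steps), ftol)
  stop_on_status(res$status, res$bad_index)
  conformation(res$pos, conf$velocities)
}

#' Monte Carlo sampler of the sliding-segment model
#'
#' Draws uniform samples over the microstates of two indistinguishable
#' length-`lk` segments sliding on a linear string of `N` beads
#' (overlap allowed), and returns the center separations D. The
#' empirical histogram converges to [microstate_fraction()].
#'
#' @param N string length (beads).
#' @param lk segment length (beads), `lk < N`.
#' @param n_samples number of draws.
#' @param seed RNG seed (the caller's RNG stream is left untouched).
#' @return integer vector of D values.
#' @export
sliding_segment_mc <- function(N, lk, n_samples, seed = 1L) {
  stopifnot(lk < N)
  M <- N - lk + 1                       # admissible start positions
  a <- rep(seq_len(M), times = M:1)     # unordered pairs a <= b
  b <- unlist(lapply(seq_len(M), function(i) i:M))
  idx <- with_seed(seed, sample.int(length(a), n_samples, replace = TRUE))
  b[idx] - a[idx]
}

#' Sample a surrogate order-parameter series from a target free energy
#'
#' Draws |D| frames from `p(D) ~ exp(-F_target/kBT)` so the analysis
#' stack can be validated without molecular dynamics: feeding the result
#' to [estimate_profile()] recovers `F_target` up to an additive
#' constant.
#'
#' @param F_target data.frame with columns `D` and `F` (kBT), or a
#'   `polyknot_profile` (its `bin_centers` and `F` are used).
#' @param n_frames number of frames to draw.
#' @param seed RNG seed.
#' @param kBT thermal energy.
#' @param jitter half-width of uniform within-bin jitter added to the
#'   sampled D values (0 keeps them exactly on the grid).
#' @return data.frame shaped like an order-parameter series: `frame`,
#'   `state`, `D_abs`, `theta`, `theta_perp`, `nested_handedness`.
#' @export
surrogate_knot_trajectory <- function(F_target, n_frames, seed = 1L,
                                      kBT = 1, jitter = 0) {
  if (inherits(F_target, "polyknot_profile"))
    F_target <- data.frame(D = F_target$bin_centers, F = F_target$F)
  ok <- is.finite(F_target$F)
  D <- F_target$D[ok]
  w <- exp(-F_target$F[ok] / kBT)
  d <- with_seed(seed, {
    out <- sample(D, n_frames, replace = TRUE, prob = w / sum(w))
    if (jitter > 0) out <- out + runif(n_frames, -jitter, jitter)
    out
  })
  data.frame(frame = seq_len(n_frames), state = "separated", D_abs = d,
             theta = NA_real_, theta_perp = NA_real_,
             nested_handedness = NA_integer_)
}
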