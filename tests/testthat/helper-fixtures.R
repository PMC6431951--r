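# Shared fixtures, built once per test run. Everything is generated in
# code; seeds are fixed so the suite is deterministic.

fx <- new.env()

fx$params10 <- model_params(N = 10, L_wall = 12, kappa_b = 5)

# jittered straight chains for gradient/parity property tests
fx$random_small_conf <- function(seed, N = 10, bond = 1.05, jitter = 0.08) {
  pos <- straight_chain_positions(N, bond = bond, origin = c(0.6, 0, 0))
  pos[2:(N - 1), ] <- pos[2:(N - 1), ] +
    with_seed_test(seed, matrix(rnorm(3 * (N - 2), sd = jitter), N - 2, 3))
  conformation(pos)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# closed parametric templates
fx$trefoil_R <- make_torus_trefoil(60, +1, scale = 1)
fx$trefoil_L <- make_torus_trefoil(60, -1, scale = 1)

fx$figure_eight <- local({
  t <- seq(0, 2 * pi, length.out = 161)[1:160]
  cbind((2 + cos(2 * t)) * cos(3 * t),
        (2 + cos(2 * t)) * sin(3 * t),
        sin(4 * t))
})

# single-knot chain (80 beads) and its known template window
fx$params80 <- desk_params(N = 80, L_wall = 54)
fx$one_knot <- build_one_knot_chain(fx$params80, knot_spec(+1, 40, 18))

# separated two-knot chains, both chirality pairs (desk scale)
fx$params100 <- desk_params(N = 100, L_wall = 70)
fx$two_pp <- build_two_knot_chain(fx$params100, knot_spec(+1, 30, 18),
                                  knot_spec(+1, 70, 18))
fx$two_pm <- build_two_knot_chain(fx$params100, knot_spec(+1, 30, 18),
                                  knot_spec(-1, 70, 18))

# separated fixture small enough for the exhaustive localization oracle
fx$params76 <- desk_params(N = 76, L_wall = 46)
fx$two_small <- build_two_knot_chain(fx$params76, knot_spec(+1, 22, 18),
                                     knot_spec(-1, 54, 18))

# intertwined fixture
fx$params120 <- desk_params(N = 120, L_wall = 78)
fx$intertwined <- build_two_knot_chain(fx$params120, knot_spec(+1, 60, 30),
                                       knot_spec(-1, 60, 18),
                                       intertwined = TRUE)

mirror_z <- function(conf) {
  pos <- conf$positions
  pos[, 3] <- -pos[, 3]
  conformation(pos, conf$velocities)
}

rotate_about_x <- function(conf, angle) {
  R <- matrix(c(1, 0, 0,
                0, cos(angle), -sin(angle),
                0, sin(angle), cos(angle)), 3, 3, byrow = TRUE)
  conformation(conf$positions %*% t(R), conf$velocities)
}

# independent exhaustive O(N^2) localization oracle: scan every (s, e),
# classify each closure, return the shortest (then leftmost) match
exhaustive_shortest_arc <- function(conf, target, min_len = 6L) {
  pos <- conf$positions
  N <- nrow(pos)
  best <- NULL
  for (s in 0:(N - min_len)) {
    for (e in (s + min_len - 1):(N - 1)) {
      if (!is.null(best) && (e - s) >= (best[2] - best[1])) next
      if (polyknot:::arc_label(pos, s, e) == target) {
        if (is.null(best) || (e - s) < (best[2] - best[1]) ||
            ((e - s) == (best[2] - best[1]) && s < best[1]))
          best <- c(s, e)
      }
    }
  }
  best
}

# brute-force enumeration of the sliding-segment model: all unordered
# placements (overlap allowed) of two length-lk segments on N sites
enumerate_omega <- function(N, lk) {
  M <- N - lk + 1
  counts <- integer(M + 1)          # D ranges 0 .. M (om(M) = 0 bins empty)
  for (a in seq_len(M)) for (b in a:M) {
    D <- b - a
    counts[D + 1] <- counts[D + 1] + 1L
  }
  counts / sum(counts)
}
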