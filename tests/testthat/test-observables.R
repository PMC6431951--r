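test_that("knot centers and |D| are plain arithmetic on arc indices", {
  expect_equal(knot_center(c(40, 70)), 55)
  expect_equal(knot_center(c(0, 0)), 0)
  expect_equal(knot_center(c(10, 15)), 12.5)

  mk_rec <- function(arcs, comp = NULL) {
    structure(list(arcs = lapply(arcs, function(a)
      list(s = a[1], e = a[2], handedness = 1L)),
      composite_arc = comp, n_isolated = length(arcs)),
      class = "polyknot_knotrecord")
  }
  r <- separation_D(mk_rec(list(c(40, 70), c(140, 170))))
  expect_equal(r$D_abs, 100)
  expect_equal(r$state, "separated")
  r2 <- separation_D(mk_rec(list(c(100, 130)), comp = c(90, 160)))
  expect_equal(r2$D_abs, 10)
  expect_equal(r2$state, "intertwined")
  r3 <- separation_D(mk_rec(list(c(100, 130)), comp = c(85, 145)))
  expect_equal(r3$D_abs, 0)
  expect_error(separation_D(mk_rec(list(c(1, 20)))), "composite")
})

regular_polygon_yz <- function(n = 12, reverse = FALSE) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  pos <- cbind(0, cos(th), sin(th))
  if (reverse) pos <- pos[rev(seq_len(n + 1)), ]
  pos
}

test_that("the orientation director is the oriented loop normal", {
  # CCW in the YZ plane (seen from +x) -> U = +x; reverse -> -x
  U <- orientation_director(regular_polygon_yz(), c(0, 12))
  expect_equal(U$U, c(1, 0, 0), tolerance = 1e-12)
  Ur <- orientation_director(regular_polygon_yz(reverse = TRUE), c(0, 12))
  expect_equal(Ur$U, c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(U$U^2)), 1)

  # straight run of bonds: vanishing sum -> undefined, not imputed
  line <- straight_chain_positions(8, 1)
  expect_false(orientation_director(line, c(0, 7))$defined)
  expect_error(orientation_director(line, c(0, 2)), "3 bonds")
})

test_that("theta and theta_perp implement the clamped angle formulas", {
  expect_equal(theta_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(theta_angle(c(0, 0, 1), c(0, 1, 0)), pi / 2)
  expect_equal(theta_angle(c(0, 0, 1), c(0, 0, -1)), pi)
  # clamping: numerically unnormalized dot just over 1
  expect_equal(theta_angle(c(0, 0, 1 + 1e-14), c(0, 0, 1)), 0)

  expect_equal(theta_perp(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_equal(theta_perp(c(0, 0, 1), c(0, 1, 0)), -pi / 2)
  u1 <- c(0.3, 0.5, 0.2); u2 <- c(-0.2, 0.1, 0.9)
  expect_equal(theta_perp(u2, u1), -theta_perp(u1, u2))
  expect_true(is.na(theta_perp(c(1, 0, 0), c(0, 1, 0))))
})

test_that("mirror and rotation covariance of the angle observables", {
  with_seed_test(19, {
    for (i in 1:20) {
      u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
      u2 <- rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
      # reflection through the XZ plane (y -> -y): theta unchanged,
      # theta_perp flips sign (chirality-swapped arrangements)
      m1 <- u1 * c(1, -1, 1); m2 <- u2 * c(1, -1, 1)
      expect_equal(theta_angle(m1, m2), theta_angle(u1, u2))
      expect_equal(theta_perp(m1, m2), -theta_perp(u1, u2))
      # rotation about x: both invariant
      a <- runif(1, 0, 2 * pi)
      R <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                  3, 3, byrow = TRUE)
      expect_equal(theta_angle(R %*% u1, R %*% u2), theta_angle(u1, u2))
      expect_equal(theta_perp(drop(R %*% u1), drop(R %*% u2)),
                   theta_perp(u1, u2))
      # rotation about an arbitrary axis: theta still invariant
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      Rg <- diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
      expect_equal(theta_angle(Rg %*% u1, Rg %*% u2), theta_angle(u1, u2))
    }
  })
})

test_that("relaxed trefoil directors track handedness along x", {
  # energy-minimized single-knot chains: the director's x projection
  # changes sign with the knot's handedness
  p <- fx$params80
  confR <- relax_minimize(fx$one_knot, p, 1500L)
  aR <- shortest_knotted_arc(confR, "trefoil")
  uR <- orientation_director(confR, aR)
  confL <- relax_minimize(mirror_z(fx$one_knot), p, 1500L)
  aL <- shortest_knotted_arc(confL, "trefoil")
  uL <- orientation_director(confL, aL)
  expect_true(uR$defined && uL$defined)
  expect_equal(sign(uR$U[1]) * sign(uL$U[1]), -1)
})

test_that("order-parameter series combine localization and directors", {
  p <- fx$params100
  pr <- run_protocol(3000L, sample_every = 1000L, seed = 41L)
  tr <- integrate_chain(fx$two_pm, p, pr)
  kt <- analyze_trajectory(tr)
  op <- order_params(tr, kt)
  expect_equal(names(op), c("frame", "state", "D_abs", "theta",
                            "theta_perp", "nested_handedness"))
  expect_true(all(op$state %in% c("separated", "intertwined")))
  expect_true(all(op$D_abs >= 0 & op$D_abs <= p$N, na.rm = TRUE))
  ok <- !is.na(op$theta)
  expect_true(all(op$theta[ok] >= 0 & op$theta[ok] <= pi))

  # intertwined record path: U2 on the composite-complement bonds
  kti <- knot_record_row <- polyknot:::knot_record_row(
    find_prime_components(fx$intertwined), frame = 1)
  tri <- structure(list(frames = array(fx$intertwined$positions,
                                       c(1, fx$params120$N, 3)),
                        params = fx$params120),
                   class = "polyknot_trajectory")
  opi <- order_params(tri, kti)
  expect_equal(opi$state, "intertwined")
  expect_equal(opi$nested_handedness, -1L)
})
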