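test_that("minimally interfering closure preserves or creates no topology", {
  # nearly closed ring: drop one vertex from a closed trefoil
  ring <- fx$trefoil_R[-15, ]
  poly <- close_arc_mic(ring)
  expect_equal(unname(alexander_determinants(poly)), c(3, 7))

  # straight segment: unknot
  seg <- straight_chain_positions(10, 1)
  expect_equal(classify_topology(
    alexander_determinants(close_arc_mic(seg))[1],
    alexander_determinants(close_arc_mic(seg))[2])$label, "unknot")

  # open trefoil with termini pulled far apart along x: direct closure
  # is chosen (no auxiliary vertices) and the trefoil survives
  ot <- polyknot:::make_open_trefoil(24, +1, scale = 0.97 * 24 / 35.9,
                                     opening = 1.2)
  stretched <- ot
  stretched[, 1] <- stretched[, 1] * 3          # pull along x
  poly2 <- close_arc_mic(stretched)
  expect_error(close_arc_mic(stretched[1:2, ]), ">= 3")
  d <- alexander_determinants(close_arc_mic(ot))
  expect_equal(classify_topology(d[1], d[2])$label, "trefoil")
})

test_that("Alexander determinants identify the reference knots", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0.1), c(0.5, 1, -0.1))
  expect_equal(unname(alexander_determinants(tri)), c(1, 1))
  expect_equal(unname(alexander_determinants(fx$trefoil_R)), c(3, 7))
  expect_equal(unname(alexander_determinants(fx$trefoil_L)), c(3, 7))
  expect_equal(unname(alexander_determinants(fx$figure_eight)), c(5, 11))
  # granny and square composites from the constructed two-knot chains
  pp <- close_arc_mic(.kmt_cpp(fx$two_pp$positions, FALSE))
  pm <- close_arc_mic(.kmt_cpp(fx$two_pm$positions, FALSE))
  expect_equal(unname(alexander_determinants(pp, reduce = FALSE)), c(9, 49))
  expect_equal(unname(alexander_determinants(pm, reduce = FALSE)), c(9, 49))
})

test_that("determinants are projection-invariant and mirror-invariant", {
  for (poly in list(fx$trefoil_R, fx$figure_eight)) {
    ref <- alexander_determinants(poly, seed = 1)
    for (s in 2:21)
      expect_equal(alexander_determinants(poly, seed = s), ref)
  }
  m <- fx$trefoil_R; m[, 3] <- -m[, 3]
  expect_equal(alexander_determinants(m), alexander_determinants(fx$trefoil_R))
})

test_that("the topology classifier implements the lookup table", {
  expect_equal(classify_topology(1, 1)$label, "unknot")
  expect_equal(classify_topology(3, 7)$label, "trefoil")
  expect_equal(classify_topology(9, 49)$label, "composite_3131")
  expect_equal(classify_topology(5, 11)$label, "other")
  expect_equal(classify_topology(7, 16)$label, "other")
  expect_error(classify_topology(-1, 1))
})

test_that("shortest-arc search matches the exhaustive oracle", {
  # unknotted stretched chain: nothing to find
  p <- fx$params80
  straight <- conformation(straight_chain_positions(
    p$N, p$L_wall / (p$N - 1)))
  expect_null(shortest_knotted_arc(straight, "trefoil"))

  # single spliced trefoil (template window [31, 49])
  a <- shortest_knotted_arc(fx$one_knot, "trefoil")
  oracle <- exhaustive_shortest_arc(fx$one_knot, "trefoil")
  expect_equal(unname(a), unname(oracle))
  expect_true(a[1] >= 26 && a[2] <= 54)  # within a few beads of the splice
  # complement closes to an unknot
  rem <- polyknot:::excise_arc(fx$one_knot$positions, a[1], a[2])
  expect_equal(polyknot:::arc_label(rem, 0L, nrow(rem) - 1L), "unknot")

  # two separated trefoils: composite arc spans both knotted regions
  comp <- shortest_knotted_arc(fx$two_small, "composite_3131")
  comp_oracle <- exhaustive_shortest_arc(fx$two_small, "composite_3131")
  expect_equal(unname(comp), unname(comp_oracle))
  t1 <- shortest_knotted_arc(fx$two_small, "trefoil")
  expect_true(comp[1] <= t1[1] && comp[2] > t1[2])
})

test_that("prime components: separated vs intertwined semantics", {
  rec <- find_prime_components(fx$two_small)
  expect_equal(rec$n_isolated, 2L)
  expect_equal(rec$state, "separated")
  expect_equal(rec$arcs[[1]]$handedness, 1L)
  expect_equal(rec$arcs[[2]]$handedness, -1L)
  # excision of an isolated arc leaves a clean trefoil
  rem <- polyknot:::excise_arc(fx$two_small$positions,
                               rec$arcs[[1]]$s, rec$arcs[[1]]$e)
  red <- .kmt_cpp(rem, FALSE)
  expect_equal(unname(alexander_determinants(close_arc_mic(red),
                                             reduce = FALSE)), c(3, 7))

  reci <- find_prime_components(fx$intertwined)
  expect_equal(reci$n_isolated, 1L)
  expect_equal(reci$state, "intertwined")
  expect_equal(reci$arcs[[1]]$handedness, -1L)   # nested knot is the (-)
  expect_false(is.null(reci$composite_arc))
  expect_true(reci$composite_arc[1] <= reci$arcs[[1]]$s &&
                reci$composite_arc[2] >= reci$arcs[[1]]$e)

  # wrong-topology error on a single-knot chain
  expect_error(find_prime_components(fx$one_knot), "wrong topology")
})

test_that("handedness flips under mirror reflection, stable across projections", {
  a <- shortest_knotted_arc(fx$one_knot, "trefoil")
  h <- handedness(fx$one_knot, a)
  expect_equal(h, 1L)
  expect_equal(handedness(mirror_z(fx$one_knot), a), -1L)

  # closed templates: requested sign, mirror antisymmetry
  expect_equal(handedness(fx$trefoil_R), 1L)
  expect_equal(handedness(fx$trefoil_L), -1L)

  # diagram signed-crossing sum: sign equals handedness for every
  # projection (directional writhe of a trefoil diagram)
  for (s in 1:20) {
    expect_gt(polyknot:::diagram_signed_sum(fx$trefoil_R, s), 0)
    expect_lt(polyknot:::diagram_signed_sum(fx$trefoil_L, s), 0)
  }
  expect_error(handedness(fx$figure_eight), "trefoil")
})

test_that("subarc monotonicity holds around the shortest trefoil arc", {
  a <- shortest_knotted_arc(fx$one_knot, "trefoil")
  pos <- fx$one_knot$positions
  for (pad in c(2L, 5L, 9L)) {
    s <- max(0L, a[1] - pad)
    e <- min(nrow(pos) - 1L, a[2] + pad)
    expect_equal(polyknot:::arc_label(pos, s, e), "trefoil")
  }
})

test_that("trajectory knot tables have the documented layout", {
  p <- fx$params100
  pr <- run_protocol(4000L, sample_every = 1000L, seed = 13L)
  tr <- integrate_chain(fx$two_pp, p, pr)
  kt <- analyze_trajectory(tr)
  expect_equal(names(kt), c("frame", "n_isolated", "s1", "e1", "h1", "s2",
                            "e2", "h2", "s_comp", "e_comp", "touches_end"))
  expect_equal(nrow(kt), n_frames(tr))
  expect_true(all(kt$n_isolated %in% c(1L, 2L)))
  expect_true(all(kt$h1 %in% c(-1L, 1L)))
})
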