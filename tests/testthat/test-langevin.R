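test_that("zero-temperature start from a minimum is a fixed point", {
  # uniform straight chain between the tethers: every interior force
  # cancels exactly by symmetry, so Verlet must not move anything
  p <- model_params(N = 20, L_wall = 19, kappa_b = 8)
  pos <- straight_chain_positions(20, bond = 1)
  conf0 <- conformation(pos, matrix(0, 20, 3))
  pr <- run_protocol(200L, sample_every = 200L, seed = 1L)
  tr <- integrate_chain(conf0, p, pr, thermostat = FALSE)
  expect_identical(tr$final$positions, pos)
})

test_that("velocity-Verlet core conserves energy with the thermostat off", {
  p <- fx$params100
  pr <- run_protocol(10000L, sample_every = 100L, seed = 3L)
  tr <- integrate_chain(fx$two_pp, p, pr, thermostat = FALSE)
  E <- tr$pe + tr$ke
  # secular drift: compare first and last tenth of the run
  n <- length(E)
  drift <- abs(mean(E[seq(0.9 * n, n)]) - mean(E[seq_len(n / 10)])) /
    abs(mean(E))
  expect_lt(drift, 1e-4)
})

test_that("terminal beads never move and runs are bit-reproducible", {
  p <- fx$params100
  pr <- run_protocol(2000L, sample_every = 200L, seed = 9L)
  tr1 <- integrate_chain(fx$two_pp, p, pr)
  tr2 <- integrate_chain(fx$two_pp, p, pr)
  expect_identical(tr1$frames, tr2$frames)
  for (i in seq_len(n_frames(tr1))) {
    expect_identical(tr1$frames[i, 1, ], c(0, 0, 0))
    expect_identical(tr1$frames[i, p$N, ], c(p$L_wall, 0, 0))
  }
  pr2 <- run_protocol(2000L, sample_every = 200L, seed = 10L)
  tr3 <- integrate_chain(fx$two_pp, p, pr2)
  expect_false(identical(tr1$frames, tr3$frames))
})

test_that("kinetic temperature estimator behaves", {
  p <- fx$params10
  conf <- fx$random_small_conf(2)
  mk_traj <- function(vscale) {
    vel <- with_seed_test(5, matrix(rnorm(30), 10, 3)) * vscale
    vel[c(1, 10), ] <- 0
    structure(list(frames = array(conf$positions, c(1, 10, 3)),
                   velocities = array(vel, c(1, 10, 3)),
                   ke = sum(0.5 * vel^2), pe = 0, params = p),
              class = "polyknot_trajectory")
  }
  expect_equal(kinetic_temperature(mk_traj(0)), 0)
  expect_equal(kinetic_temperature(mk_traj(2)),
               4 * kinetic_temperature(mk_traj(1)))
  # Maxwell-Boltzmann at kBT = 1, many dof for a tight estimate
  vel <- with_seed_test(6, matrix(rnorm(3e5), 1e5, 3))
  big <- structure(list(frames = array(0, c(1, 1e5, 3)),
                        velocities = array(vel, c(1, 1e5, 3)),
                        ke = sum(0.5 * vel^2), pe = 0, params = p),
                   class = "polyknot_trajectory")
  # N_mobile convention subtracts the two termini
  expect_equal(kinetic_temperature(big) * (1e5 - 2) / 1e5, 1,
               tolerance = 0.02)
  big$velocities <- NULL
  expect_error(kinetic_temperature(big), "velocities")
})

test_that("thermostat keeps equipartition at test-scale coupling", {
  # tau_frict = 10 for desk-scale equilibration (production value 1000
  # would need ~1e6 steps to couple; flagged test-only coupling)
  p <- desk_params(N = 40, L_wall = 28, tau_frict = 10)
  conf <- build_one_knot_chain(p, knot_spec(+1, 20, 18))
  pr <- run_protocol(30000L, sample_every = 50L,
                     equilibration_steps = 10000L, seed = 21L)
  tr <- integrate_chain(conf, p, pr)
  temps <- 2 * tr$ke / (3 * (p$N - 2))
  # s.e. from coarse blocks to absorb autocorrelation
  blocks <- tapply(temps, cut(seq_along(temps), 12), mean)
  se <- sd(blocks) / sqrt(length(blocks))
  expect_lt(abs(mean(temps) - 1), 3 * se + 0.02)
})

test_that("topology is conserved along a thermostatted run", {
  p <- fx$params100
  pr <- run_protocol(20000L, sample_every = 1000L, seed = 31L)
  tr <- integrate_chain(fx$two_pm, p, pr)
  labs <- vapply(seq_len(n_frames(tr)), function(i)
    polyknot:::arc_label(tr$frames[i, , ], 0L, p$N - 1L, seed = i),
    character(1))
  expect_true(all(labs == "composite_3131"))
})

test_that("single-bead wall statistics obey detailed balance", {
  # 3-bead chain, middle bead mobile inside long-range walls: the MD
  # position histogram must match an independent Metropolis sampler of
  # the same Boltzmann density (thinned so samples are ~independent)
  p <- model_params(N = 3, L_wall = 2.6, kappa_b = 0, tau_frict = 5,
                    wall_sigma = 2)
  pos0 <- rbind(c(0, 0, 0), c(1.3, 0, 0), c(2.6, 0, 0))
  pr <- run_protocol(200000L, sample_every = 400L,
                     equilibration_steps = 5000L, seed = 77L)
  tr <- integrate_chain(conformation(pos0), p, pr)
  md_x <- tr$frames[, 2, 1]

  u_of <- function(xyz) total_energy(conformation(rbind(
    c(0, 0, 0), xyz, c(2.6, 0, 0))), p)$total
  mc_x <- with_seed_test(88, {
    x <- c(1.3, 0, 0); u <- u_of(x)
    out <- numeric(1000)
    for (i in seq_len(1000)) {
      for (j in 1:25) {
        prop <- x + runif(3, -0.3, 0.3)
        ok_bonds <- sqrt(sum(prop^2)) < 1.45 &&
          sqrt(sum((prop - c(2.6, 0, 0))^2)) < 1.45  # FENE domain
        if (ok_bonds && prop[1] > 0.05 && prop[1] < 2.55) {
          up <- u_of(prop)
          if (log(runif(1)) < u - up) { x <- prop; u <- up }
        }
      }
      out[i] <- x[1]
    }
    out
  })
  ks <- suppressWarnings(stats::ks.test(md_x, mc_x))
  expect_gt(ks$p.value, 0.01)
})

test_that("instability and overstretch abort with diagnostic errors", {
  p <- model_params(N = 10, L_wall = 12, kappa_b = 5, dt = 0.5)
  conf <- fx$random_small_conf(4)
  pr <- run_protocol(5000L, sample_every = 100L, seed = 2L)
  expect_error(integrate_chain(conf, p, pr),
               "overstretched|instability|penetrated|smaller dt")
})
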