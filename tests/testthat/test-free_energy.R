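test_that("profiles reproduce constructed distributions", {
  # uniform samples: flat F within binomial noise
  D <- with_seed_test(1, runif(2e5, 0, 60))
  prof <- estimate_profile(D, N = 100, bin_width = 2)
  # first bin is only partially covered by the continuous support
  inner <- prof$F[prof$bin_centers > 1 & prof$bin_centers < 55]
  expect_lt(max(abs(inner), na.rm = TRUE), 0.08)

  # two bins with counts (2000, 1000): dF = kBT ln 2
  D2 <- c(rep(1, 2000), rep(3, 1000))
  prof2 <- estimate_profile(D2, N = 8, bin_width = 2)
  expect_equal(prof2$F[2] - prof2$F[1], log(2))

  # inverse-sampling recovery of a constructed double-well profile
  D_grid <- seq(1, 79, by = 2)
  F0 <- 1.2 * cos(D_grid / 8) + 0.02 * D_grid
  surro <- surrogate_knot_trajectory(data.frame(D = D_grid, F = F0),
                                     n_frames = 1e5, seed = 7)
  rec <- estimate_profile(surro$D_abs, N = 80, bin_width = 2)
  # grid point k sits in bin k by construction of the binning
  rF <- rec$F[seq_along(F0)]
  shift <- mean(rF - F0)
  expect_lt(sqrt(mean((rF - F0 - shift)^2)), 0.1)

  expect_error(estimate_profile(numeric(0), N = 10), "empty")
})

test_that("Eq-7 microstate fraction matches exhaustive enumeration", {
  # exact brute force for all 3 <= lk < N <= 30
  for (N in 4:30) for (lk in 3:(N - 1)) {
    M1 <- N - lk + 1
    expect_equal(microstate_fraction(0:M1, N, lk), enumerate_omega(N, lk),
                 tolerance = 1e-12)
  }
  # normalization exact up to N = 200
  for (N in c(50, 123, 200)) {
    lk <- 17
    expect_equal(sum(microstate_fraction(0:(N - lk + 1), N, lk)), 1)
  }
  expect_equal(microstate_fraction(0, 10, 3), 2 / 9)
  expect_equal(microstate_fraction(8, 10, 3), 0)
  expect_error(microstate_fraction(9, 10, 3), "out of range")
})

test_that("entropy is the log microstate fraction", {
  expect_equal(entropy_S(0, 10, 3) - entropy_S(4, 10, 3), log(2))
  # maximal at D = 0, monotone decreasing
  s <- entropy_S(0:7, 10, 3)
  expect_true(all(diff(s) < 0))
  expect_true(is.na(entropy_S(8, 10, 3)))
})

test_that("entropy subtraction flattens sliding-segment data", {
  N <- 100; lk <- 15
  D <- sliding_segment_mc(N, lk, 1e5, seed = 11)
  prof <- estimate_profile(D, N = N, bin_width = 2)
  prof <- subtract_entropy(prof, N, lk)
  sel <- !is.na(prof$F_corrected) & prof$bin_centers <= N - lk - 4
  fit <- lm(prof$F_corrected[sel] ~ prof$bin_centers[sel])
  ci <- confint(fit)[2, ]
  expect_true(ci[1] < 0 && ci[2] > 0)    # slope CI covers zero
  expect_lt(max(abs(prof$F_corrected[sel])), 0.15)

  # constant shift in S only shifts F_corrected
  p2 <- prof; p2$F <- prof$F + 3
  p2 <- subtract_entropy(p2, N, lk)
  expect_equal(p2$F_corrected, prof$F_corrected)
})

test_that("feature extraction reads off constructed profiles exactly", {
  # constructed ground truth: plateau 0 beyond D = 45, onset at 45
  # (F jumps to 0.1 there), barrier 1.5 at D = 31, minimum -2 at D ~ 0
  centers <- seq(1, 99, by = 2)
  N <- 100
  FF <- numeric(length(centers))
  ramp <- centers <= 45 & centers >= 31
  FF[ramp] <- 0.1 + (1.5 - 0.1) * (45 - centers[ramp]) / 14
  well <- centers < 31
  FF[well] <- seq(-2, 1.5, length.out = sum(well) + 1)[seq_len(sum(well))]
  prof <- structure(list(bin_centers = centers, counts = rep(100, 50),
                         F = FF, F_corrected = NULL, kBT = 1,
                         bin_width = 2, N = N,
                         plateau_window = c(0.5, 0.95)),
                    class = "polyknot_profile")
  f <- extract_features(prof, N, threshold = 0.05)
  expect_equal(f$D_int, 45)
  expect_equal(f$eps_b, 1.5)
  expect_equal(f$eps_d, 3.5)

  # threshold robustness: D_int moves < 2 beads for +-50% threshold
  f_lo <- extract_features(prof, N, threshold = 0.025)
  f_hi <- extract_features(prof, N, threshold = 0.075)
  expect_lt(abs(f_lo$D_int - f_hi$D_int), 2)

  # no minimum at the origin: eps_d undefined, eps_b still defined
  FF2 <- FF
  FF2[centers <= 29] <- seq(3, 1.5, length.out = sum(centers <= 29))
  prof2 <- prof; prof2$F <- FF2
  f2 <- extract_features(prof2, N, threshold = 0.05)
  expect_true(is.na(f2$eps_d))
  expect_false(is.na(f2$eps_b))
})

test_that("elastic model: closed forms, scaling and Q calibration", {
  expect_equal(knot_bending_energy(36, 20), 2 * (pi + 1)^2 * 20 / 36)
  expect_equal(knot_bending_energy(36, 20), 19.06, tolerance = 1e-3)
  expect_equal(knot_bending_energy(72, 20), knot_bending_energy(36, 20) / 2)
  expect_equal(knot_bending_energy(36, 0), 0)
  expect_error(knot_bending_energy(0, 20), "n must be")

  # closed-form argmin vs integer grid search of the two-knot free energy
  for (kb in c(2.5, 5, 10, 15, 20)) {
    nstar <- equilibrium_knot_size(kb, Q = 0.015)
    grid <- 1:200
    ngrid <- grid[which.min(elastic_free_energy(grid, kb, Q = 0.015))]
    expect_lte(abs(nstar - ngrid), 1)
  }
  # kb^(1/3) scaling: octupling kb doubles n*
  expect_equal(equilibrium_knot_size(8 * 7, 0.015),
               2 * equilibrium_knot_size(7, 0.015))

  # single-point inversion is an exact round trip
  for (n in c(20, 36, 50)) {
    Q <- fit_Q(data.frame(kappa_b = 20, n = n))
    expect_equal(equilibrium_knot_size(20, Q), n)
  }
  # recovery from synthetic sizes generated by the model
  kbs <- c(2.5, 5, 10, 15, 20)
  Q_true <- 0.0123
  sizes <- data.frame(kappa_b = kbs,
                      n = equilibrium_knot_size(kbs, Q_true))
  expect_equal(fit_Q(sizes), Q_true, tolerance = 1e-6)
  expect_error(fit_Q(data.frame(kappa_b = 20, n = -3)), "sizes must be")
})
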