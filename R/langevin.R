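#' Run protocol for a Langevin simulation
#'
#' The production protocol of the two-knot study stores one frame every
#' 100 tau_MD (10^4 steps at dt = 0.01) over runs of 2e7 tau_MD with 2e5
#' tau_MD equilibration; that is cluster-scale. Desk-scale tests use far
#' fewer steps and denser sampling.
#'
#' @param n_steps production steps (frames are sampled from these).
#' @param sample_every store one frame every this many steps.
#' @param equilibration_steps steps run and discarded before sampling.
#' @param seed integer seed for the thermostat noise stream.
#' @return object of class `polyknot_protocol`.
#' @export
run_protocol <- function(n_steps, sample_every = 10000L,
                         equilibration_steps = 0L, seed = 1L) {
  stopifnot(n_steps >= 0, sample_every >= 1, equilibration_steps >= 0)
  structure(list(n_steps = as.integer(n_steps),
                 sample_every = as.integer(sample_every),
                 equilibration_steps = as.integer(equilibration_steps),
                 seed = as.integer(seed)),
            class = "polyknot_protocol")
}

#' Integrate the chain with underdamped Langevin dynamics
#'
#' Velocity-Verlet core with a LAMMPS-style Langevin thermostat: at every
#' force evaluation each mobile bead receives a friction force
#' `-(m/tau_frict) v` and an independent Gaussian kick of variance
#' `2 m kBT / (tau_frict dt)` per component. The two terminal beads are
#' tethered and never move. The run aborts with an error if any bond
#' reaches R0 (topology safety) or positions become non-finite. With a
#' fixed seed the output is bit-reproducible.
#'
#' @param conf initial `polyknot_conformation`; if velocities are absent
#'   they are drawn from the Maxwell-Boltzmann distribution at `kBT`
#'   (seeded from the protocol seed).
#' @param params a `polyknot_params`.
#' @param protocol a `polyknot_protocol`.
#' @param thermostat logical; `FALSE` turns off friction and noise,
#'   giving plain energy-conserving velocity Verlet.
#' @param store_velocities keep per-frame velocities (needed for
#'   [kinetic_temperature()]).
#' @return a `polyknot_trajectory`: frame positions (and velocities) as
#'   `n_frames x N x 3` arrays plus per-frame potential/kinetic energy.
#' @export
integrate_chain <- function(conf, params, protocol, thermostat = TRUE,
                            store_velocities = TRUE) {
  validate_conformation(conf, params)
  pos <- conf$positions
  N <- nrow(pos)
  vel <- conf$velocities
  if (is.null(vel)) {
    vel <- with_seed(protocol$seed + 1000003L, matrix(
      rnorm(3 * N, sd = sqrt(params$kBT / params$mass)), N, 3))
    vel[c(1, N), ] <- 0
  }
  gamma <- params$mass / params$tau_frict
  res <- .langevin_cpp(pos, vel, params, protocol$equilibration_steps,
                       protocol$n_steps, protocol$sample_every, params$dt,
                       params$mass, gamma, params$kBT, protocol$seed,
                       store_velocities, thermostat)
  if (res$status != 0)
    stop_on_status(res$status, paste0(res$bad_index, " at step ", res$step))
  traj <- list(frames = res$frames,
               velocities = if (store_velocities) res$velocities else NULL,
               pe = res$pe, ke = res$ke,
               final = conformation(res$final_pos, res$final_vel),
               params = params, protocol = protocol)
  class(traj) <- "polyknot_trajectory"
  traj
}

#' @export
print.polyknot_trajectory <- function(x, ...) {
  cat("<polyknot_trajectory>", n_frames(x), "frames of",
      dim(x$frames)[2], "beads\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `polyknot_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[1]

#' Extract one frame as a conformation
#' @param traj a `polyknot_trajectory`.
#' @param i frame index (1-based).
#' @return a `polyknot_conformation`.
#' @export
traj_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  pos <- traj$frames[i, , ]
  vel <- if (!is.null(traj$velocities) && length(traj$velocities))
    traj$velocities[i, , ] else NULL
  conformation(pos, vel)
}

#' Kinetic temperature of a trajectory
#'
#' `2 <KE> / (3 N_mobile)` in units of kBT, where the average runs over
#' frames and only the N - 2 mobile beads carry kinetic energy (the
#' tethered termini are frozen).
#'
#' @param traj a `polyknot_trajectory` stored with velocities.
#' @return scalar temperature estimate in kBT.
#' @export
kinetic_temperature <- function(traj) {
  if (is.null(traj$velocities) || !length(traj$velocities))
    stop("trajectory was stored without velocities")
  n_mobile <- dim(traj$frames)[2] - 2L
  mean(traj$ke) * 2 / (3 * n_mobile) / traj$params$kBT
}
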