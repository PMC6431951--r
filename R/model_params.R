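#' Model parameters for the stretched bead-spring chain
#'
#' Collects all reduced-unit constants of the chain model: WCA excluded
#' volume, Kremer-Grest FENE bonds, cosine bending, the confining walls,
#' and the Langevin run constants. Defaults are the production values of
#' the two-knot study (N = 300 beads, walls at L = 205 sigma); desk-scale
#' fixtures typically use [desk_params()].
#'
#' @param N bead count (>= 3).
#' @param epsilon WCA energy scale; the package energy unit (= kBT).
#' @param sigma bead diameter; the package length unit.
#' @param mass bead mass; the package mass unit.
#' @param kappa_fene FENE strength, energy/length^2 (Kremer-Grest: 30).
#' @param R0 maximum FENE bond extension (Kremer-Grest: 1.5 sigma).
#' @param kappa_b bending rigidity in kBT; persistence length is
#'   approximately `sigma * kappa_b / kBT`.
#' @param L_wall separation of the two confining walls along x.
#' @param kBT thermal energy (fixed to epsilon in this model).
#' @param dt integration timestep in tau_MD.
#' @param tau_frict friction self-correlation time in tau_MD; the Langevin
#'   friction coefficient is `mass / tau_frict`.
#' @param seed integer seed for the simulation RNG stream.
#' @param wall_eps strength of the repulsive 9-3 wall potential.
#' @param wall_sigma range of the wall potential.
#' @return object of class `polyknot_params` (a validated named list).
#' @examples
#' p <- model_params(N = 100, kappa_b = 20, L_wall = 70)
#' p$kappa_b
#' @export
model_params <- function(N = 300L, epsilon = 1, sigma = 1, mass = 1,
                         kappa_fene = 30, R0 = 1.5, kappa_b = 20,
                         L_wall = 205, kBT = 1, dt = 0.01,
                         tau_frict = 1000, seed = 1L,
                         wall_eps = 1, wall_sigma = 1) {
  p <- list(N = as.integer(N), epsilon = epsilon, sigma = sigma, mass = mass,
            kappa_fene = kappa_fene, R0 = R0, kappa_b = kappa_b,
            L_wall = L_wall, kBT = kBT, dt = dt, tau_frict = tau_frict,
            seed = as.integer(seed), wall_eps = wall_eps,
            wall_sigma = wall_sigma)
  class(p) <- "polyknot_params"
  validate_params(p)
  p
}

#' Desk-scale default parameters
#'
#' The production system (N = 300, L = 205 sigma) at desk scale: N = 100
#' beads between walls 70 sigma apart, preserving the ~0.68 extension
#' ratio of the production setup.
#'
#' @inheritParams model_params
#' @param ... passed on to [model_params()].
#' @return a `polyknot_params` object.
#' @export
desk_params <- function(N = 100L, L_wall = 70, kappa_b = 20, ...) {
  model_params(N = N, L_wall = L_wall, kappa_b = kappa_b, ...)
}

validate_params <- function(p) {
  stopifnot(inherits(p, "polyknot_params"))
  if (p$N < 3L) stop("N must be >= 3")
  if (!(p$R0 > p$sigma) || !(p$sigma > 0)) stop("need R0 > sigma > 0")
  if (p$kappa_b < 0) stop("kappa_b must be >= 0")
  if (p$dt <= 0) stop("dt must be > 0")
  if (p$L_wall <= 0) stop("L_wall must be > 0")
  if (p$epsilon <= 0 || p$mass <= 0 || p$kBT <= 0)
    stop("epsilon, mass and kBT must be > 0")
  invisible(p)
}

#' @export
print.polyknot_params <- function(x, ...) {
  cat("<polyknot_params> N =", x$N, " kappa_b =", x$kappa_b,
      " L_wall =", x$L_wall, "\n")
  cat("  WCA eps =", x$epsilon, " sigma =", x$sigma,
      " FENE kappa =", x$kappa_fene, " R0 =", x$R0, "\n")
  cat("  kBT =", x$kBT, " dt =", x$dt, " tau_frict =", x$tau_frict,
      " seed =", x$seed, "\n")
  invisible(x)
}

#' Write / read model parameters as a flat key-value config file
#'
#' Parameters are serialized in Debian-control (DCF) format, one
#' `key: value` pair per line, all values in reduced units. The
#' round-trip `read_params(write_params(p, f))` is lossless.
#'
#' @param params a `polyknot_params` object.
#' @param path file path.
#' @return `write_params` returns `path` invisibly; `read_params` returns
#'   a `polyknot_params` object.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  vals <- vapply(unclass(params), function(v) format(v, digits = 17),
                 character(1))
  m <- matrix(vals, nrow = 1, dimnames = list(NULL, names(vals)))
  write.dcf(m, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  m <- read.dcf(path)
  v <- as.list(m[1, ])
  num <- setdiff(names(v), c("N", "seed"))
  v[num] <- lapply(v[num], as.numeric)
  v[c("N", "seed")] <- lapply(v[c("N", "seed")], function(x)
    as.integer(as.numeric(x)))
  do.call(model_params, v)
}
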