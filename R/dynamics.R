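#' Langevin integrator parameters
#'
#' Dimensionless CG units: friction 0.843 and timestep 0.2 (the standard
#' settings for this model class), temperature in Kelvin through k_B T in
#' kcal/mol. Masses are uniform (the model does not resolve per-residue
#' masses). The stability bound friction * dt < 2 is enforced.
#'
#' @param friction friction coefficient (1/CG time unit).
#' @param dt integration timestep (CG time units).
#' @param temperature Kelvin.
#' @param mass uniform bead mass (CG mass units).
#' @return a `langevin_params`.
#' @export
langevin_params <- function(friction = 0.843, dt = 0.2, temperature = 300,
                            mass = 10) {
  stopifnot(friction > 0, dt > 0, mass > 0, temperature >= 0)
  if (friction * dt >= 2) stop("unstable settings: friction * dt must be < 2")
  structure(list(friction = friction, dt = dt, temperature = temperature,
                 mass = mass), class = "langevin_params")
}

#' Simulation configuration
#'
#' @param n_steps number of integration steps (>= 1).
#' @param save_interval save a frame every this many steps.
#' @param seed integer seed; recorded in the trajectory.
#' @param boundary "periodic" (minimum-image wrapping for pair interactions,
#'   unwrapped coordinates stored), "reflective" (walls at the box faces),
#'   or "open".
#' @param electrostatics [electrostatic_params()] or `NULL` (off).
#' @param kappa AFM restraint strength (0 = off).
#' @param reference_image reference `afm_image` when kappa > 0.
#' @param tip [tip_model()] for the restraint rendering.
#' @param ev_eps excluded-volume strength (kcal/mol).
#' @param langevin a [langevin_params()].
#' @return a `simulation_config`.
#' @export
simulation_config <- function(n_steps, save_interval = max(1, n_steps %/% 200),
                              seed = 1,
                              boundary = c("periodic", "reflective", "open"),
                              electrostatics = NULL, kappa = 0,
                              reference_image = NULL,
                              tip = tip_model(smoothing = "soft"),
                              ev_eps = 0.6, langevin = langevin_params()) {
  boundary <- match.arg(boundary)
  stopifnot(n_steps >= 1, save_interval >= 1)
  if (kappa > 0 && is.null(reference_image))
    stop("kappa > 0 requires a reference image")
  structure(list(n_steps = as.integer(n_steps),
                 save_interval = as.integer(save_interval),
                 seed = as.integer(seed), boundary = boundary,
                 electrostatics = electrostatics, kappa = kappa,
                 reference_image = reference_image, tip = tip,
                 ev_eps = ev_eps, langevin = langevin),
            class = "simulation_config")
}

boundary_code <- function(boundary)
  c(open = 0L, periodic = 1L, reflective = 2L)[[boundary]]

#' Run a Langevin dynamics simulation
#'
#' Underdamped Langevin dynamics with an exact Ornstein-Uhlenbeck
#' friction-noise substep (BAOAB splitting; reduces to velocity Verlet as
#' friction goes to 0). Deterministic for a given seed. Frames are saved
#' every `save_interval` steps (plus the initial frame); per-term energies,
#' kinetic energy, and -- when the AFM restraint is active -- the cosine
#' similarity are logged at each saved frame.
#'
#' @param system a `cg_system`; its `xyz` is the initial structure.
#' @param config a [simulation_config()].
#' @param velocities optional initial velocities (default: Maxwell-Boltzmann
#'   draw at the configured temperature).
#' @return a `cg_trajectory`: `frames` (beads x 3 x n_frames, unwrapped
#'   Angstrom), `steps`, `energies` (per-term, kcal/mol), `cs`,
#'   `afm_zero_image`, `velocities` (final), `seed`, `config`, `system`.
#' @export
run_simulation <- function(system, config, velocities = NULL) {
  set.seed(config$seed)
  lv <- config$langevin
  restraint <- if (config$kappa > 0)
    afm_restraint(config$kappa, config$reference_image, config$tip) else NULL
  res <- run_langevin_cpp(
    system$xyz, velocities, topo_list(system),
    nb_list(system, electrostatics = config$electrostatics,
            ev_eps = config$ev_eps,
            periodic = config$boundary == "periodic"),
    afm_cpp_bundle(restraint, lv$temperature),
    rep_len(lv$mass, nrow(system$beads)), lv$friction, lv$dt,
    kbt(lv$temperature), config$n_steps, config$save_interval,
    boundary_code(config$boundary))
  structure(list(frames = res$frames, steps = res$steps,
                 energies = res$energies, cs = res$cs,
                 afm_zero_image = res$afm_zero_image,
                 velocities = res$velocities, seed = config$seed,
                 config = config, system = system),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", dim(x$frames)[3], "frames of", dim(x$frames)[1],
      "beads; steps 0 ..", max(x$steps), "\n")
  invisible(x)
}

#' Single Langevin step
#'
#' One BAOAB update; mainly useful for integrator-level testing and custom
#' protocols. Deterministic given the RNG state.
#'
#' @param xyz current positions.
#' @param velocities current velocities.
#' @param system the `cg_system` (topology/nonbonded context).
#' @param config a [simulation_config()] (its n_steps is ignored).
#' @return list with updated `xyz` and `velocities`.
#' @export
langevin_step <- function(xyz, velocities, system, config) {
  s <- system; s$xyz <- xyz
  lv <- config$langevin
  restraint <- if (config$kappa > 0)
    afm_restraint(config$kappa, config$reference_image, config$tip) else NULL
  res <- run_langevin_cpp(
    xyz, velocities, topo_list(s),
    nb_list(s, electrostatics = config$electrostatics, ev_eps = config$ev_eps,
            periodic = config$boundary == "periodic"),
    afm_cpp_bundle(restraint, lv$temperature),
    rep_len(lv$mass, nrow(xyz)), lv$friction, lv$dt, kbt(lv$temperature),
    1L, 1L, boundary_code(config$boundary))
  list(xyz = res$frames[, , 2], velocities = res$velocities)
}

#' Centre a system in its box
#'
#' @param system a `cg_system`.
#' @param box optional new box edges.
#' @return the translated system.
#' @export
center_in_box <- function(system, box = NULL) {
  if (!is.null(box)) system$box <- box
  shift <- system$box / 2 - colMeans(system$xyz)
  system$xyz <- sweep(system$xyz, 2, shift, "+")
  system
}

#' Randomly place DNA duplexes around a molecule
#'
#' Adds `n_copies` of a duplex at uniformly random positions and
#' orientations inside the box, rejecting placements that come closer than
#' `min_separation` to the existing system or to each other. Deterministic
#' per seed.
#'
#' @param system the `cg_system` to decorate (e.g. a centred protein).
#' @param dna a duplex `cg_system` (e.g. from [build_bdna_duplex()]).
#' @param n_copies number of copies (the binding protocols use 5).
#' @param min_separation minimum inter-molecule bead distance, A.
#' @param seed integer seed.
#' @param max_attempts rejection-sampling budget per copy.
#' @return merged `cg_system`; DNA chains are uniquely relabelled.
#' @export
place_random_dna <- function(system, dna, n_copies = 5, min_separation = 20,
                             seed = 1, max_attempts = 500) {
  set.seed(seed)
  box <- system$box
  margin <- max(dna$beads$radius)
  out <- system
  for (copy in seq_len(n_copies)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      q <- rnorm(4); q <- q / sqrt(sum(q^2))
      R <- quaternion_rotation(q)
      centre <- runif(3, margin, box - margin)
      xyz <- sweep(sweep(dna$xyz, 2, colMeans(dna$xyz)) %*% t(R), 2,
                   centre, "+")
      dmin <- min_pair_dist(out$xyz, xyz)
      if (dmin >= min_separation) {
        d2 <- dna; d2$xyz <- xyz
        d2$beads$mol <- sprintf("dna%02d", copy)
        out <- merge_systems(out, d2)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("DNA placement failed after ", max_attempts,
           " attempts (box too crowded for min_separation)")
  }
  out
}

quaternion_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

min_pair_dist <- function(a, b) {
  best <- Inf
  for (r in seq_len(nrow(b))) {
    d2 <- min(rowSums(sweep(a, 2, b[r, ])^2))
    if (d2 < best) best <- d2
  }
  sqrt(best)
}

#' Release the AFM restraint and relax
#'
#' Continues from the final frame of a restrained trajectory (or any
#' system) with kappa = 0, so the structure relaxes under the
#' native-structure-based potential alone. Logs the inter-chain Q-score and
#' the hinge angle per saved frame when selections are given.
#'
#' @param system the `cg_system` whose `xyz` is the restrained structure.
#' @param config [simulation_config()]; its kappa/reference are overridden
#'   to 0/NULL.
#' @param chains length-2 chain labels for the inter-subunit Q-score.
#' @param arm_a,arm_b,pivot bead selections for the hinge-angle log.
#' @return a `cg_trajectory` with extra elements `inter_q` and `angle`.
#' @export
release_restraint_protocol <- function(system, config, chains = NULL,
                                       arm_a = NULL, arm_b = NULL,
                                       pivot = NULL) {
  config$kappa <- 0
  config$reference_image <- NULL
  traj <- run_simulation(system, config)
  nf <- dim(traj$frames)[3]
  if (!is.null(chains))
    traj$inter_q <- vapply(seq_len(nf), function(f)
      qscore(system, traj$frames[, , f], which = "inter", chains = chains),
      numeric(1))
  if (!is.null(arm_a))
    traj$angle <- vapply(seq_len(nf), function(f)
      hinge_angle_from_coords(traj$frames[, , f], arm_a, arm_b, pivot),
      numeric(1))
  traj
}
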