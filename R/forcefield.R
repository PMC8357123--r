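#' Debye screening length
#'
#' lambda_D = sqrt(eps0 eps_k kB T / (2 NA e^2 I)), evaluated with CODATA
#' constants and returned in Angstrom.
#'
#' @param ionic_strength monovalent ionic strength, mol/L.
#' @param temperature Kelvin.
#' @param eps_k relative dielectric constant of the solvent.
#' @return Debye length in Angstrom.
#' @export
debye_length <- function(ionic_strength, temperature = 300, eps_k = 78) {
  if (any(ionic_strength <= 0) || temperature <= 0 || eps_k <= 0)
    stop("ionic strength, temperature and dielectric must be positive")
  with(.const, 1e10 * sqrt(eps0_SI * eps_k * kB_SI * temperature /
                             (2 * NA_SI * e_SI^2 * ionic_strength * 1000)))
}

#' Electrostatics parameter set
#'
#' Bundles ionic strength, temperature and dielectric with the derived Debye
#' length and interaction cutoff (default 5 lambda_D, energy-shifted at the
#' cutoff). Coulomb prefactor 332.0637 kcal A/(mol e^2); energies kcal/mol.
#'
#' @param ionic_strength mol/L.
#' @param temperature Kelvin.
#' @param eps_k dielectric constant (fixed 78 by default; the model has no
#'   temperature/salt-dependent dielectric unless you supply one).
#' @param cutoff_factor cutoff as a multiple of the Debye length.
#' @return an `electrostatic_params` list.
#' @export
electrostatic_params <- function(ionic_strength, temperature = 300,
                                 eps_k = 78, cutoff_factor = 5) {
  lambda <- debye_length(ionic_strength, temperature, eps_k)
  structure(list(ionic_strength = ionic_strength, temperature = temperature,
                 eps_k = eps_k, lambda = lambda,
                 cutoff = cutoff_factor * lambda),
            class = "electrostatic_params")
}

empty_topo_system <- function(n, radius = 2.5, box = c(200, 160, 200)) {
  beads <- data.frame(chain = "A", resid = seq_len(n), class = "CA",
                      charge = 0, radius = radius)
  cg_system(beads, matrix(0, n, 3), box = box)
}

# Nonbonded bundle for the C++ kernels.
nb_list <- function(system, charges = NULL, electrostatics = NULL,
                    ev_eps = 0.6, ev_on = TRUE, periodic = FALSE,
                    excl_elec = NULL, excl_ev = NULL) {
  if (is.null(charges)) charges <- system$beads$charge
  if (is.null(excl_elec)) excl_elec <- bonded_exclusions(system)
  if (is.null(excl_ev)) {
    excl_ev <- excl_elec
    if (nrow(system$contacts))
      excl_ev <- rbind(excl_ev, cbind(system$contacts$i, system$contacts$j))
  }
  dh_on <- !is.null(electrostatics)
  list(charge = as.numeric(charges), radius = as.numeric(system$beads$radius),
       excl_elec = as_int_matrix(excl_elec), excl_ev = as_int_matrix(excl_ev),
       dh_on = dh_on,
       eps_k = if (dh_on) electrostatics$eps_k else 78,
       lambda = if (dh_on) electrostatics$lambda else 1,
       dh_cutoff = if (dh_on) electrostatics$cutoff else 0,
       ev_on = ev_on, ev_eps = ev_eps,
       box = as.numeric(system$box), periodic = periodic)
}

energy_report <- function(res) {
  structure(list(energies = res$energies, total = res$total,
                 forces = res$forces, cs = res$cs,
                 afm_zero_image = res$afm_zero_image),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat("energy_report (kcal/mol):\n")
  print(round(x$energies, 6))
  cat("total:", format(x$total, digits = 10), "\n")
  invisible(x)
}

#' Bonded energies and forces (bonds, angles, dihedrals)
#'
#' Harmonic bonds/angles and periodic dihedrals about their native reference
#' values: U = kf (r - r0)^2 + kf (theta - theta0)^2 + kf (1 - cos(phi -
#' phi0)). Zero at the native structure by construction. Near-collinear
#' angle triples are regularized (sin theta floored).
#'
#' @param system a `cg_system` carrying the topology.
#' @param xyz coordinates (defaults to the native coordinates).
#' @return an `energy_report` (forces in kcal/mol/A).
#' @export
bonded_energy_forces <- function(system, xyz = system$xyz) {
  s <- system; s$contacts <- empty_contacts()
  res <- energy_forces_cpp(xyz, topo_list(s),
                           nb_list(s, ev_on = FALSE), NULL)
  energy_report(res)
}

#' Go native-contact energy and forces
#'
#' 12-10 well per native contact: U = eps (5 (r0/r)^12 - 6 (r0/r)^10),
#' minimum -eps at r = r0.
#'
#' @inheritParams bonded_energy_forces
#' @return an `energy_report`.
#' @export
go_contact_energy_forces <- function(system, xyz = system$xyz) {
  s <- system
  s$bonds <- empty_bonds(); s$angles <- empty_angles()
  s$dihedrals <- empty_dihedrals()
  res <- energy_forces_cpp(xyz, topo_list(s), nb_list(s, ev_on = FALSE), NULL)
  energy_report(res)
}

#' Excluded-volume energy and forces
#'
#' Purely repulsive U = eps ((sigma/r)^12 - 1) for r < sigma = r_i + r_j,
#' zero beyond; 1-2/1-3 bonded neighbours and native-contact pairs are
#' excluded (contacts carry their own repulsive core).
#'
#' @inheritParams bonded_energy_forces
#' @param ev_eps repulsion strength, kcal/mol.
#' @param periodic apply minimum-image wrapping in the system box.
#' @return an `energy_report`.
#' @export
excluded_volume_energy_forces <- function(system, xyz = system$xyz,
                                          ev_eps = 0.6, periodic = FALSE) {
  s <- system
  topo <- topo_list(s) # keep topology for exclusions; zero the term weights
  topo$bond_k[] <- 0; topo$angle_k[] <- 0; topo$dihedral_k[] <- 0
  topo$contact_eps[] <- 0
  res <- energy_forces_cpp(xyz, topo, nb_list(s, ev_eps = ev_eps,
                                              periodic = periodic), NULL)
  energy_report(res)
}

#' Debye-Hueckel energy and forces
#'
#' Screened Coulomb pair sum U = sum_ij 332.0637 q_i q_j exp(-r/lambda) /
#' (eps_k r), truncated at the parameter cutoff with an energy shift;
#' bonded 1-2/1-3 pairs (or an explicit exclusion list) are skipped.
#'
#' @param system a `cg_system` (geometry, radii, default exclusions).
#' @param xyz coordinates.
#' @param charges per-bead charges (defaults to `system$beads$charge`).
#' @param params an [electrostatic_params()] object.
#' @param exclusions optional 2-column matrix of excluded pairs.
#' @param periodic minimum-image wrapping in the system box.
#' @return an `energy_report`.
#' @export
dh_energy_forces <- function(system, xyz = system$xyz, charges = NULL,
                             params, exclusions = NULL, periodic = FALSE) {
  s <- system
  topo <- topo_list(s)
  topo$bond_k[] <- 0; topo$angle_k[] <- 0; topo$dihedral_k[] <- 0
  topo$contact_eps[] <- 0
  res <- energy_forces_cpp(xyz, topo,
                           nb_list(s, charges = charges,
                                   electrostatics = params, ev_on = FALSE,
                                   excl_elec = exclusions,
                                   periodic = periodic), NULL)
  energy_report(res)
}

#' Unshifted Debye-Hueckel pair energy
#'
#' @param q1,q2 charges (e).
#' @param r separation (A).
#' @param lambda Debye length (A).
#' @param eps_k dielectric constant.
#' @return energy in kcal/mol.
#' @export
dh_pair_energy <- function(q1, q2, r, lambda, eps_k = 78) {
  .const$coulomb * q1 * q2 * exp(-r / lambda) / (eps_k * r)
}

#' Total energy and forces for all enabled terms
#'
#' @param system a `cg_system`.
#' @param xyz coordinates.
#' @param charges per-bead charges (default from the system).
#' @param electrostatics [electrostatic_params()] or `NULL` to disable.
#' @param afm an [afm_restraint()] or `NULL`.
#' @param temperature Kelvin (sets k_B T for the AFM term).
#' @param ev_eps excluded-volume strength; `ev_on = FALSE` disables it.
#' @param ev_on logical.
#' @param periodic minimum-image wrapping.
#' @return an `energy_report`; `total` equals the sum of term energies.
#' @export
total_energy_forces <- function(system, xyz = system$xyz, charges = NULL,
                                electrostatics = NULL, afm = NULL,
                                temperature = 300, ev_eps = 0.6,
                                ev_on = TRUE, periodic = FALSE) {
  res <- energy_forces_cpp(xyz, topo_list(system),
                           nb_list(system, charges = charges,
                                   electrostatics = electrostatics,
                                   ev_eps = ev_eps, ev_on = ev_on,
                                   periodic = periodic),
                           afm_cpp_bundle(afm, temperature))
  energy_report(res)
}

#' Build the native-contact list from reference coordinates
#'
#' Unordered unique pairs with reference distance <= cutoff. Within a chain
#' the residue separation must be at least `min_seq_sep` (default 4);
#' across chains any pair qualifies. Pairs that are bonded or share a bonded
#' neighbour (1-2/1-3) are never contacts.
#'
#' @param system a `cg_system`.
#' @param cutoff contact distance cutoff, A (default 6.5, CA-CA).
#' @param min_seq_sep minimum intra-chain residue separation.
#' @param eps well depth assigned to each contact, kcal/mol.
#' @param reference coordinates to measure native distances from.
#' @return contacts data.frame (`i, j, r0, eps`).
#' @export
build_native_contacts <- function(system, cutoff = 6.5, min_seq_sep = 4,
                                  eps = 0.6, reference = system$xyz) {
  n <- nrow(reference)
  if (!n) stop("empty reference coordinates")
  d <- as.matrix(stats::dist(reference))
  excl <- bonded_exclusions(system)
  exset <- if (nrow(excl)) paste(pmin(excl[, 1], excl[, 2]),
                                 pmax(excl[, 1], excl[, 2])) else character()
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (!nrow(idx)) return(empty_contacts())
  i <- idx[, 1]; j <- idx[, 2]
  ch <- system$beads$chain; rs <- system$beads$resid
  keep <- (ch[i] != ch[j]) | (abs(rs[i] - rs[j]) >= min_seq_sep)
  keep <- keep & !(paste(i, j) %in% exset)
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(empty_contacts())
  data.frame(i = i, j = j, r0 = d[cbind(i, j)], eps = eps)
}

#' Randomly scramble the charge arrangement
#'
#' Control used to test whether a predicted binding surface is dictated by
#' the surface-charge arrangement: the multiset of charge values (zeros
#' included) is preserved while their placement among the beads is
#' uniformly permuted, relocating the charges to random positions.
#' Deterministic per seed.
#'
#' @param charges numeric charge vector.
#' @param seed integer seed.
#' @param beads bead indices to permute among (default: all beads).
#' @return shuffled charge vector with attribute `provenance = "SHUFFLED"`.
#' @export
shuffle_charges <- function(charges, seed, beads = seq_along(charges)) {
  if (!length(charges)) stop("empty charge set")
  out <- charges
  if (length(beads) > 1) {
    set.seed(seed)
    out[beads] <- charges[sample(beads)]
  }
  attr(out, "provenance") <- "SHUFFLED"
  out
}

#' RESPAC-style surface-charge fit
#'
#' Least-squares fit of partial charges on surface beads so that the
#' Debye-Hueckel potential they generate reproduces a reference
#' electrostatic potential sampled at points around the molecule, subject to
#' an equality constraint on the total charge. Non-surface beads get zero.
#' A small ridge term guarantees a unique solution; rank-deficient designs
#' are reported.
#'
#' @param samples data.frame/matrix with columns x, y, z, value: reference
#'   potential (kcal/mol per unit charge) at sample points.
#' @param xyz bead coordinates.
#' @param surface_beads indices of beads to carry charge; `NULL` applies the
#'   accessibility heuristic: any bead with at least one sample point within
#'   `surface_radius`.
#' @param total_charge equality constraint on the summed fitted charge.
#' @param params [electrostatic_params()] defining lambda and eps_k.
#' @param ridge ridge regularization weight.
#' @param surface_radius heuristic radius, A.
#' @return charge vector (length = beads) with attributes `provenance =
#'   "RESPAC_FIT"`, `surface_beads`, `residual` (root-mean-square misfit).
#' @export
respac_fit_charges <- function(samples, xyz, surface_beads = NULL,
                               total_charge = 0, params, ridge = 1e-6,
                               surface_radius = 12) {
  samples <- as.data.frame(samples)
  pts <- as.matrix(samples[, c("x", "y", "z")])
  v <- samples$value
  n <- nrow(xyz)
  # distance matrix sample x bead
  d <- sqrt(outer(rowSums(pts^2), rep(1, n)) +
              outer(rep(1, nrow(pts)), rowSums(xyz^2)) -
              2 * pts %*% t(xyz))
  if (is.null(surface_beads))
    surface_beads <- which(apply(d, 2, min) <= surface_radius)
  if (!length(surface_beads)) stop("no surface beads identified")
  A <- .const$coulomb * exp(-d[, surface_beads, drop = FALSE] / params$lambda) /
    (params$eps_k * d[, surface_beads, drop = FALSE])
  m <- length(surface_beads)
  if (nrow(A) < m)
    warning("fewer potential samples than fitted charges; fit is ridge-dominated")
  G <- crossprod(A) + ridge * diag(m)
  if (rcond(G) < 1e-12)
    warning("rank-deficient charge-fit design; ridge term controls the solution")
  K <- rbind(cbind(2 * G, rep(1, m)), c(rep(1, m), 0))
  rhs <- c(2 * crossprod(A, v), total_charge)
  sol <- solve(K, rhs)
  q <- numeric(n)
  q[surface_beads] <- sol[seq_len(m)]
  attr(q, "provenance") <- "RESPAC_FIT"
  attr(q, "surface_beads") <- surface_beads
  attr(q, "residual") <- sqrt(mean((A %*% sol[seq_len(m)] - v)^2))
  q
}
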