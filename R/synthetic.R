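#' Toy two-armed hinge protein
#'
#' A minimal stand-in for a two-subunit hinge: two chains ("A", "B"), each
#' a rod-like hairpin arm (out-strand, tip, back-strand) whose first few
#' out-strand beads interdigitate near the origin -- the globular junction.
#' Inter-chain native contacts exist only in that junction region, so an
#' "open" state (one chain rotated about the junction) breaks inter-arm
#' contacts while intra-arm (cross-strand) contacts persist, mirroring
#' inter- versus intra-subunit Q-scores. Positive charges decorate the
#' inner (out-strand) face near the junction, the toy analog of the
#' DNA-binding patch on the hinge inside.
#'
#' The two arms lie in the x-y plane (small +/- z offsets so the strands
#' can cross), symmetric about +y; the junction pivot is at the origin
#' (attribute `pivot`). Arm selections, the inner binding-site beads and
#' the junction beads are attached as attributes.
#'
#' @param beads_per_arm beads per strand (>= 5).
#' @param native_angle inter-arm angle of the closed state, degrees.
#' @param bead_spacing along-strand spacing, A.
#' @param charge charge per decorated bead (e).
#' @param n_charged_per_arm decorated out-strand beads per arm (from the
#'   junction outward).
#' @param contact_eps intra-arm Go well depth, kcal/mol.
#' @param interface_eps inter-chain (junction) well depth, kcal/mol;
#'   stronger, as dimer interfaces are.
#' @param bond_k,angle_k,dihedral_k,hinge_angle_k local force constants;
#'   `hinge_angle_k` applies to angle triples at the arm base (soft pivot).
#' @param radius bead radius, A.
#' @param box box edges.
#' @return a `cg_system` with attributes `arms` (list A/B of bead indices),
#'   `inner_site`, `junction`, `pivot`.
#' @export
make_toy_hinge <- function(beads_per_arm = 10, native_angle = 30,
                           bead_spacing = 3.8, charge = 1,
                           n_charged_per_arm = 3, contact_eps = 1.8,
                           interface_eps = 4, bond_k = 50, angle_k = 25,
                           dihedral_k = 1, hinge_angle_k = 1,
                           radius = 2.5, box = c(120, 120, 60)) {
  stopifnot(beads_per_arm >= 5, native_angle > 0, native_angle < 180)
  n <- beads_per_arm
  half <- native_angle / 2 * pi / 180
  build_arm <- function(sgn, zoff) {
    # sgn = -1 for chain A (leans -x), +1 for chain B
    u <- c(sgn * sin(half), cos(half), 0)          # along-arm direction
    v <- c(sgn * cos(half), -sin(half), 0)         # outer perpendicular
    p0 <- c(sgn * 1.6, 2.6, zoff)                  # base of the out-strand
    out <- t(vapply(0:(n - 1), function(k) p0 + u * bead_spacing * k,
                    numeric(3)))
    tip <- p0 + u * (bead_spacing * (n - 1) + 2.5) + v * 2.25
    back <- t(vapply((n - 1):0, function(k)
      p0 + u * bead_spacing * k + v * 4.5, numeric(3)))
    rbind(out, tip, back)
  }
  xa <- build_arm(-1, +1.1)
  xb <- build_arm(+1, -1.1)
  per <- 2 * n + 1
  beads <- data.frame(chain = rep(c("A", "B"), each = per),
                      resid = rep(seq_len(per), 2), class = "CA",
                      charge = 0, radius = radius,
                      stringsAsFactors = FALSE)
  xyz <- rbind(xa, xb)
  # decorate the inner face: first out-strand beads of each chain
  dec <- c(seq_len(n_charged_per_arm), per + seq_len(n_charged_per_arm))
  beads$charge[dec] <- charge

  # bonds: within-chain pairs closer than 4.2 A (consecutive strand beads,
  # tip closures); no bonds between the chains
  bonds <- empty_bonds()
  for (off in c(0, per)) {
    d <- as.matrix(stats::dist(xyz[off + seq_len(per), , drop = FALSE]))
    idx <- which(upper.tri(d) & d <= 4.2, arr.ind = TRUE)
    bonds <- rbind(bonds, data.frame(i = off + idx[, 1], j = off + idx[, 2],
                                     r0 = d[idx], kf = bond_k),
                   # close the hairpin at its base so the arm is a stiff loop
                   data.frame(i = off + 1L, j = off + per,
                              r0 = d[1, per], kf = bond_k))
  }
  topo <- bonded_angles_dihedrals(bonds, xyz, angle_k, dihedral_k)
  # soften angle triples touching the two base beads of each chain (pivot)
  base <- c(1, 2, per + 1, per + 2)
  soft <- topo$angles$i %in% base | topo$angles$j %in% base |
    topo$angles$k %in% base
  topo$angles$kf[soft] <- hinge_angle_k
  sys <- cg_system(beads, xyz, bonds = bonds, angles = topo$angles,
                   dihedrals = topo$dihedrals, box = box)
  con <- build_native_contacts(sys, cutoff = 6.5, min_seq_sep = 4,
                               eps = contact_eps)
  inter <- sys$beads$chain[con$i] != sys$beads$chain[con$j]
  con$eps[inter] <- interface_eps
  sys$contacts <- con
  attr(sys, "arms") <- list(A = seq_len(per), B = per + seq_len(per))
  attr(sys, "inner_site") <- dec
  attr(sys, "junction") <- c(1:2, per + 1:2)
  attr(sys, "pivot") <- c(0, 0, 0)
  sys
}

#' Open a toy hinge by rotating one chain about the junction
#'
#' Rotates chain B about the z axis through the construction pivot so the
#' inter-arm angle increases by `delta`; apply before translating the
#' system elsewhere.
#'
#' @param system a [make_toy_hinge()] system (in construction frame).
#' @param delta opening increment, degrees.
#' @return the opened system.
#' @export
open_toy_hinge <- function(system, delta) {
  pivot <- attr(system, "pivot")
  if (is.null(pivot)) pivot <- c(0, 0, 0)
  out <- rigid_transform(system, chains = "B",
                         rotation = rotation_matrix(c(0, 0, 1), -delta),
                         center = pivot)
  for (a in c("arms", "inner_site", "junction", "pivot"))
    attr(out, a) <- attr(system, a)
  out
}

#' Synthetic AFM image of a two-armed molecule
#'
#' Two rod ridges of Gaussian cross-section meeting at a brighter junction
#' at the grid centre, arms symmetric about +y; additive Gaussian noise,
#' heights clipped at zero. The ground-truth angle is stored in the
#' `truth_angle` attribute.
#'
#' @param angle inter-arm angle, degrees (0, 180].
#' @param arm_length_px ridge length, pixels.
#' @param pixel_size A/pixel (the experimental hinge pixel is 18.75 A).
#' @param height ridge height, A.
#' @param ridge_sigma_px Gaussian cross-section width, pixels.
#' @param noise_sd additive noise SD, A.
#' @param nx,ny grid size (default: square, 2 * (arm_length_px + 6)).
#' @param junction_boost junction blob amplitude relative to the ridges;
#'   > 1 guarantees the image apex sits on the junction (as real hinge
#'   blobs do), which the angle metrology relies on. Set 1 for a reference
#'   with no extra blob (e.g. flexible-fitting references, where an
#'   artificial central mass would bias the fitted arms inward).
#' @param seed noise seed.
#' @return an `afm_image` with attributes `truth_angle`, `center_px`.
#' @export
synth_afm_image <- function(angle, arm_length_px = 14, pixel_size = 18.75,
                            height = 30, ridge_sigma_px = 1, noise_sd = 0,
                            nx = NULL, ny = NULL, junction_boost = 1.25,
                            seed = 1) {
  stopifnot(angle > 0, angle <= 180)
  if (is.null(nx)) nx <- 2 * (arm_length_px + 6)
  if (is.null(ny)) ny <- nx
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  dirs <- (90 + c(-1, 1) * angle / 2) * pi / 180
  H <- matrix(0, nx, ny)
  px <- rep(seq_len(nx), times = ny) - cx
  py <- rep(seq_len(ny), each = nx) - cy
  for (a in dirs) {
    ux <- cos(a); uy <- sin(a)
    t <- pmin(pmax(px * ux + py * uy, 0), arm_length_px)
    d2 <- (px - t * ux)^2 + (py - t * uy)^2
    H <- pmax(H, height * exp(-d2 / (2 * ridge_sigma_px^2)))
  }
  if (junction_boost > 1)
    H <- pmax(H, junction_boost * height *
                exp(-(px^2 + py^2) / (2 * (2 * ridge_sigma_px)^2)))
  if (noise_sd > 0) {
    set.seed(seed)
    H <- H + rnorm(length(H), 0, noise_sd)
  }
  img <- afm_image(pmax(matrix(H, nx, ny), 0), pixel_size,
                   origin = c(0, 0))
  attr(img, "truth_angle") <- angle
  attr(img, "center_px") <- c(cx, cy)
  img
}

#' Synthetic exponential dwell times with censoring
#'
#' @param rate dissociation rate, 1/step.
#' @param n number of draws.
#' @param censor_at censoring horizon (steps; Inf = none).
#' @param seed integer seed.
#' @return data.frame `duration, censored` with attribute `rate`.
#' @export
synth_dwell_times <- function(rate, n, censor_at = Inf, seed = 1) {
  stopifnot(rate > 0, n >= 1)
  set.seed(seed)
  t <- rexp(n, rate)
  cens <- t > censor_at
  out <- data.frame(duration = pmin(t, censor_at), censored = cens)
  attr(out, "rate") <- rate
  out
}

#' Toy globular protein with a charged surface patch
#'
#' A compact chain folded on a cubic lattice (snake path), stabilized by
#' its own native contacts, with a positively charged patch on one face --
#' a minimal binder for DNA-binding-surface prediction tests.
#'
#' @param side lattice side (side^3 beads).
#' @param spacing lattice constant, A.
#' @param patch_charge charge per patch bead (e).
#' @param n_patch number of patch beads (taken from the +y face, from the
#'   centre outward).
#' @param contact_eps Go well depth.
#' @param bond_k,angle_k local force constants.
#' @param radius bead radius.
#' @param box box edges.
#' @return a `cg_system` with attribute `patch` (charged bead indices).
#' @export
make_toy_patch_protein <- function(side = 3, spacing = 3.8, patch_charge = 1,
                                   n_patch = 6, contact_eps = 0.6,
                                   bond_k = 50, angle_k = 10, radius = 2.5,
                                   box = c(90, 90, 90)) {
  # boustrophedon path through the side^3 lattice => consecutive beads
  # are lattice neighbours
  coords <- list()
  for (z in seq_len(side)) {
    ys <- if (z %% 2) seq_len(side) else rev(seq_len(side))
    for (yi in seq_along(ys)) {
      y <- ys[yi]
      flip <- (z %% 2 + yi) %% 2
      xs <- if (flip) seq_len(side) else rev(seq_len(side))
      for (x in xs) coords[[length(coords) + 1]] <- c(x, y, z)
    }
  }
  xyz <- (do.call(rbind, coords) - (side + 1) / 2) * spacing
  nb <- nrow(xyz)
  beads <- data.frame(chain = "P", resid = seq_len(nb), class = "CA",
                      charge = 0, radius = radius, stringsAsFactors = FALSE)
  d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nb, , drop = FALSE])^2))
  bonds <- data.frame(i = seq_len(nb - 1), j = 2:nb, r0 = d, kf = bond_k)
  topo <- bonded_angles_dihedrals(bonds, xyz, angle_k, dihedral_k = 0)
  sys <- cg_system(beads, xyz, bonds = bonds, angles = topo$angles, box = box)
  sys$contacts <- build_native_contacts(sys, cutoff = 6.5, min_seq_sep = 3,
                                        eps = contact_eps)
  face <- which(xyz[, 2] == max(xyz[, 2]))
  ctr <- colMeans(xyz[face, , drop = FALSE])
  face <- face[order(rowSums(sweep(xyz[face, , drop = FALSE], 2, ctr)^2))]
  patch <- head(face, n_patch)
  sys$beads$charge[patch] <- patch_charge
  attr(sys, "patch") <- patch
  sys
}
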