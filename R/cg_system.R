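#' Coarse-grained system container
#'
#' A `cg_system` bundles beads (one row per coarse-grained particle), their
#' reference (native) coordinates, the bonded topology with reference values,
#' the native-contact list, and the simulation box. Protein chains carry one
#' CA bead per residue; DNA chains carry PHOSPHATE/SUGAR/BASE beads.
#'
#' @param beads data.frame with columns `chain` (character), `resid`
#'   (integer), `class` (one of `"CA"`, `"PHOSPHATE"`, `"SUGAR"`, `"BASE"`),
#'   `charge` (elementary charges), `radius` (Angstrom), and optionally
#'   `resname`.
#' @param xyz numeric matrix, one row per bead, columns x/y/z in Angstrom.
#' @param bonds data.frame `i, j, r0, kf` (kf in kcal/mol/A^2; U = kf (r-r0)^2).
#' @param angles data.frame `i, j, k, theta0, kf` (theta0 radians).
#' @param dihedrals data.frame `i, j, k, l, phi0, kf`.
#' @param contacts data.frame `i, j, r0, eps` (unordered unique pairs).
#' @param box numeric length-3 box edge lengths in Angstrom.
#' @return object of class `cg_system`.
#' @export
cg_system <- function(beads, xyz,
                      bonds = empty_bonds(), angles = empty_angles(),
                      dihedrals = empty_dihedrals(), contacts = empty_contacts(),
                      box = c(200, 160, 200)) {
  beads <- as.data.frame(beads)
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, nrow(xyz) == nrow(beads))
  if (is.null(beads$resname)) beads$resname <- "GLY"
  if (is.null(beads$mol)) beads$mol <- beads$chain  # molecule id for analyses
  stopifnot(all(beads$class %in% c("CA", "PHOSPHATE", "SUGAR", "BASE")))
  stopifnot(all(beads$radius > 0))
  is_prot <- tapply(beads$class == "CA", beads$chain, any)
  is_dna <- tapply(beads$class != "CA", beads$chain, any)
  if (any(is_prot & is_dna))
    stop("a chain mixes CA beads with DNA beads")
  n <- nrow(beads)
  for (df in list(bonds, angles, dihedrals, contacts)) {
    idx <- unlist(df[intersect(names(df), c("i", "j", "k", "l"))])
    if (length(idx) && (any(idx < 1) || any(idx > n)))
      stop("topology refers to bead indices outside 1..", n)
  }
  if (nrow(bonds) && any(bonds$r0 <= 0)) stop("bond r0 must be positive")
  if (nrow(contacts)) {
    key <- paste(pmin(contacts$i, contacts$j), pmax(contacts$i, contacts$j))
    if (anyDuplicated(key)) stop("duplicate native contacts")
    if (any(contacts$r0 <= 0)) stop("contact r0 must be positive")
  }
  stopifnot(length(box) == 3, all(box > 0))
  structure(list(beads = beads, xyz = unname(xyz), bonds = bonds,
                 angles = angles, dihedrals = dihedrals, contacts = contacts,
                 box = box),
            class = "cg_system")
}

empty_bonds <- function() data.frame(i = integer(), j = integer(),
                                     r0 = numeric(), kf = numeric())
empty_angles <- function() data.frame(i = integer(), j = integer(),
                                      k = integer(), theta0 = numeric(),
                                      kf = numeric())
empty_dihedrals <- function() data.frame(i = integer(), j = integer(),
                                         k = integer(), l = integer(),
                                         phi0 = numeric(), kf = numeric())
empty_contacts <- function() data.frame(i = integer(), j = integer(),
                                        r0 = numeric(), eps = numeric())

#' @export
print.cg_system <- function(x, ...) {
  cat("cg_system:", nrow(x$beads), "beads,",
      length(unique(x$beads$chain)), "chain(s) [",
      paste(unique(x$beads$chain), collapse = " "), "]\n")
  cat("  bonds:", nrow(x$bonds), " angles:", nrow(x$angles),
      " dihedrals:", nrow(x$dihedrals), " contacts:", nrow(x$contacts), "\n")
  cat("  box:", paste(round(x$box, 1), collapse = " x "), "A\n")
  invisible(x)
}

#' Bead indices of one or more chains
#'
#' @param system a `cg_system`.
#' @param chains character vector of chain labels; `NULL` selects all beads.
#' @return integer vector of bead indices.
#' @export
chain_beads <- function(system, chains = NULL) {
  if (is.null(chains)) return(seq_len(nrow(system$beads)))
  which(system$beads$chain %in% chains)
}

#' Apply a rigid-body transform to selected chains
#'
#' Rotates and translates the coordinates of the selected chains; all other
#' beads are untouched. Intra-chain geometry is preserved exactly (up to
#' floating point), so topology reference values remain valid.
#'
#' @param system a `cg_system`.
#' @param chains chain labels to move (`NULL` = all).
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 shift in Angstrom.
#' @param center rotation center (default: centroid of the selection).
#' @return the transformed `cg_system`.
#' @export
rigid_transform <- function(system, chains = NULL, rotation = diag(3),
                            translation = c(0, 0, 0), center = NULL) {
  sel <- chain_beads(system, chains)
  if (!length(sel)) stop("empty chain selection")
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be a proper orthonormal matrix")
  if (is.null(center)) center <- colMeans(system$xyz[sel, , drop = FALSE])
  moved <- sweep(system$xyz[sel, , drop = FALSE], 2, center) %*% t(rotation)
  system$xyz[sel, ] <- sweep(moved, 2, center + translation, "+")
  system
}

#' Rotation matrix about an axis
#'
#' @param axis length-3 axis (normalized internally).
#' @param angle rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Merge two coarse-grained systems
#'
#' Concatenates beads and topology; bead indices of `b` are offset. Chain
#' labels of `b` may be relabelled to stay unique.
#'
#' @param a,b `cg_system` objects.
#' @param relabel if TRUE (default), chains of `b` colliding with chains of
#'   `a` get a numeric suffix.
#' @return merged `cg_system` (box taken from `a`).
#' @export
merge_systems <- function(a, b, relabel = TRUE) {
  off <- nrow(a$beads)
  bb <- b$beads
  if (relabel) {
    clash <- unique(bb$chain[bb$chain %in% a$beads$chain])
    for (ch in clash) {
      new <- ch
      k <- 1
      while (new %in% c(a$beads$chain, bb$chain)) { new <- paste0(ch, k); k <- k + 1 }
      bb$chain[bb$chain == ch] <- new
    }
    clash <- unique(bb$mol[bb$mol %in% a$beads$mol])
    for (mm in clash) {
      new <- mm
      k <- 1
      while (new %in% c(a$beads$mol, bb$mol)) { new <- paste0(mm, k); k <- k + 1 }
      bb$mol[bb$mol == mm] <- new
    }
  }
  shift_idx <- function(df) {
    for (col in intersect(names(df), c("i", "j", "k", "l")))
      df[[col]] <- df[[col]] + off
    df
  }
  cg_system(rbind(a$beads, bb), rbind(a$xyz, b$xyz),
            rbind(a$bonds, shift_idx(b$bonds)),
            rbind(a$angles, shift_idx(b$angles)),
            rbind(a$dihedrals, shift_idx(b$dihedrals)),
            rbind(a$contacts, shift_idx(b$contacts)),
            box = a$box)
}

# Bond-graph neighbour pairs at graph distance 1 (1-2) and 2 (1-3),
# as a 2-column matrix of bead indices.
bonded_exclusions <- function(system) {
  n <- nrow(system$beads)
  if (!nrow(system$bonds)) return(matrix(integer(), 0, 2))
  adj <- vector("list", n)
  for (r in seq_len(nrow(system$bonds))) {
    i <- system$bonds$i[r]; j <- system$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  pairs <- list()
  for (i in seq_len(n)) {
    one <- adj[[i]]
    two <- unique(unlist(adj[one]))
    nb <- setdiff(unique(c(one, two)), i)
    nb <- nb[nb > i]
    if (length(nb)) pairs[[length(pairs) + 1L]] <- cbind(i, nb)
  }
  if (!length(pairs)) return(matrix(integer(), 0, 2))
  do.call(rbind, pairs)
}

# Internal: topology bundle for the C++ kernels.
topo_list <- function(system) {
  list(
    bonds = as_int_matrix(cbind(system$bonds$i, system$bonds$j)),
    bond_r0 = as.numeric(system$bonds$r0),
    bond_k = as.numeric(system$bonds$kf),
    angles = as_int_matrix(cbind(system$angles$i, system$angles$j, system$angles$k)),
    angle_theta0 = as.numeric(system$angles$theta0),
    angle_k = as.numeric(system$angles$kf),
    dihedrals = as_int_matrix(cbind(system$dihedrals$i, system$dihedrals$j,
                                    system$dihedrals$k, system$dihedrals$l)),
    dihedral_phi0 = as.numeric(system$dihedrals$phi0),
    dihedral_k = as.numeric(system$dihedrals$kf),
    contacts = as_int_matrix(cbind(system$contacts$i, system$contacts$j)),
    contact_r0 = as.numeric(system$contacts$r0),
    contact_eps = as.numeric(system$contacts$eps)
  )
}

as_int_matrix <- function(m) {
  if (!length(m)) return(matrix(integer(), 0, 2))
  storage.mode(m) <- "integer"
  m
}
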