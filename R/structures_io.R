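#' Build a C-alpha bead model from a PDB file
#'
#' One bead per residue at the C-alpha position. Sequential residues in the
#' same chain are bonded unless there is a residue-numbering gap or the
#' CA-CA distance exceeds `break_dist` (chain break). Angles and dihedrals
#' are built from consecutive bonded triples/quadruples with reference
#' values taken from the input coordinates. Alternate locations are resolved
#' by keeping the highest-occupancy record (with a message).
#'
#' @param pdb_source path to a PDB file, or a `bio3d` pdb object.
#' @param chains chain IDs to keep (`NULL` = all chains with CA atoms).
#' @param radius bead radius in Angstrom.
#' @param bond_k,angle_k,dihedral_k force constants (kcal/mol / A^2 or rad^2).
#' @param break_dist CA-CA distance (A) beyond which a chain break is called.
#' @param box box edges passed to [cg_system()].
#' @return a `cg_system` with zero charges (see [respac_fit_charges()]).
#' @export
load_ca_model <- function(pdb_source, chains = NULL, radius = 2.5,
                          bond_k = 50, angle_k = 10, dihedral_k = 0.5,
                          break_dist = 4.5, box = c(200, 160, 200)) {
  pdb <- if (inherits(pdb_source, "pdb")) pdb_source else
    bio3d::read.pdb(pdb_source, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$elety == "CA" & at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (!nrow(at)) stop("no C-alpha atoms in the selection")
  alt <- !is.na(at$alt) & at$alt != "" & at$alt != " "
  if (any(alt)) {
    message("resolving ", sum(alt), " altloc CA records by highest occupancy")
    key <- paste(at$chain, at$resno)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ix) {
      ix[which.max(ifelse(is.na(at$o[ix]), 1, at$o[ix]))]
    }))
    at <- at[sort(keep), , drop = FALSE]
  }
  ord <- order(match(at$chain, unique(at$chain)), at$resno)
  at <- at[ord, , drop = FALSE]
  n <- nrow(at)
  beads <- data.frame(chain = at$chain, resid = at$resno, class = "CA",
                      charge = 0, radius = radius, resname = at$resid,
                      stringsAsFactors = FALSE)
  xyz <- cbind(at$x, at$y, at$z)
  # bonded runs: consecutive residues, same chain, no numbering gap, close
  same <- beads$chain[-n] == beads$chain[-1]
  seqok <- diff(beads$resid) == 1
  d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-n, , drop = FALSE])^2))
  link <- same & seqok & d <= break_dist
  topo <- serial_chain_topology(which(link), xyz, bond_k, angle_k, dihedral_k)
  cg_system(beads, xyz, bonds = topo$bonds, angles = topo$angles,
            dihedrals = topo$dihedrals, box = box)
}

# Bonds i -> i+1 for the given start indices; angles/dihedrals for
# consecutive bonded runs. Reference values measured from xyz.
serial_chain_topology <- function(starts, xyz, bond_k, angle_k, dihedral_k) {
  bonds <- empty_bonds(); angles <- empty_angles(); dihs <- empty_dihedrals()
  if (length(starts)) {
    i <- starts; j <- starts + 1L
    bonds <- data.frame(i = i, j = j,
                        r0 = sqrt(rowSums((xyz[j, , drop = FALSE] -
                                             xyz[i, , drop = FALSE])^2)),
                        kf = bond_k)
    run <- starts[(starts + 1L) %in% starts]  # bonds i-(i+1) and (i+1)-(i+2)
    if (length(run)) {
      a <- run; b <- run + 1L; c3 <- run + 2L
      angles <- data.frame(i = a, j = b, k = c3,
                           theta0 = vapply(seq_along(a), function(q)
                             angle_value(xyz[a[q], ], xyz[b[q], ], xyz[c3[q], ]),
                             numeric(1)),
                           kf = angle_k)
    }
    quad <- starts[(starts + 1L) %in% starts & (starts + 2L) %in% starts]
    if (length(quad)) {
      a <- quad; b <- quad + 1L; c3 <- quad + 2L; d4 <- quad + 3L
      dihs <- data.frame(i = a, j = b, k = c3, l = d4,
                         phi0 = vapply(seq_along(a), function(q)
                           dihedral_value(xyz[a[q], ], xyz[b[q], ],
                                          xyz[c3[q], ], xyz[d4[q], ]),
                           numeric(1)),
                         kf = dihedral_k)
    }
  }
  list(bonds = bonds, angles = angles, dihedrals = dihs)
}

angle_value <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p3 - p2
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, ct)))
}

dihedral_value <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- crossp(b1, b2); n2 <- crossp(b2, b3)
  m <- crossp(n1, n2)
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

crossp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

#' Write a coarse-grained system as a PDB file
#'
#' CA beads are written with atom name CA; DNA beads as P / C4' / N1.
#' Optionally stores a per-bead score in the B-factor column (e.g. contact
#' probabilities or conservation scores, for colouring in a viewer).
#'
#' @param system a `cg_system`.
#' @param path output file path.
#' @param b_factor optional numeric vector, one value per bead.
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, path, b_factor = NULL) {
  elety <- c(CA = "CA", PHOSPHATE = "P", SUGAR = "C4'", BASE = "N1")[
    system$beads$class]
  if (is.null(b_factor)) b_factor <- rep(0, nrow(system$beads))
  bio3d::write.pdb(file = path, xyz = as.vector(t(system$xyz)),
                   resno = system$beads$resid, chain = system$beads$chain,
                   resid = system$beads$resname, elety = elety,
                   b = round(b_factor, 2))
  invisible(path)
}

#' Read a PDB file back as beads and coordinates
#'
#' Inverse of [write_structure()] for bead records; topology is not stored
#' in PDB and is left empty (rebuild with [load_ca_model()] or the DNA
#' builder as appropriate).
#'
#' @param path PDB file path.
#' @param radius bead radius assigned to all beads.
#' @return a `cg_system` without topology.
#' @export
read_structure <- function(path, radius = 2.5) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  cls <- c("CA" = "CA", "P" = "PHOSPHATE", "C4'" = "SUGAR", "N1" = "BASE")[at$elety]
  if (anyNA(cls)) stop("unrecognized atom names for CG bead classes")
  beads <- data.frame(chain = at$chain, resid = at$resno, class = unname(cls),
                      charge = 0, radius = radius, resname = at$resid,
                      stringsAsFactors = FALSE)
  cg_system(beads, cbind(at$x, at$y, at$z))
}

#' Write a trajectory as step-stamped text XYZ
#'
#' Plain-text format: a header line with the bead count, then one block per
#' frame (`STEP <n>` followed by one `x y z` line per bead, Angstrom).
#'
#' @param trajectory a `cg_trajectory` (see [run_simulation()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- dim(trajectory$frames)[1]
  nf <- dim(trajectory$frames)[3]
  cat(sprintf("# hingesim trajectory beads=%d frames=%d\n", n, nf), file = con)
  for (f in seq_len(nf)) {
    cat(sprintf("STEP %d\n", trajectory$steps[f]), file = con)
    write.table(format(trajectory$frames[, , f], digits = 10), con,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path file path.
#' @return a `cg_trajectory` with `frames` (beads x 3 x frames) and `steps`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# hingesim trajectory ", "", lines[1]), " ")[[1]]
  n <- as.integer(sub("beads=", "", hdr[1]))
  nf <- as.integer(sub("frames=", "", hdr[2]))
  frames <- array(NA_real_, c(n, 3, nf))
  steps <- integer(nf)
  pos <- 2L
  for (f in seq_len(nf)) {
    steps[f] <- as.integer(sub("STEP ", "", lines[pos]))
    if (n > 0) {
      block <- lines[(pos + 1L):(pos + n)]
      frames[, , f] <- matrix(as.numeric(unlist(strsplit(trimws(block), " +"))),
                              ncol = 3, byrow = TRUE)
    }
    pos <- pos + n + 1L
  }
  structure(list(frames = frames, steps = steps), class = "cg_trajectory")
}
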