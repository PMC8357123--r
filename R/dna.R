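#' Build an idealized B-form DNA duplex
#'
#' Three beads per nucleotide (phosphate, sugar, base) threaded on an ideal
#' B-form helix (default rise 3.38 A, twist 34.3 deg/bp). The second strand
#' is the reverse complement, antiparallel, generated by the duplex dyad
#' symmetry. The 5'-terminal phosphate of each strand is omitted by default
#' (common CG convention), so an n-bp duplex has 6n - 2 beads. Bonds, angles
#' and dihedrals are taken from the constructed geometry; intra-duplex native
#' contacts (Go wells at the built distances) keep the duplex shape-stable --
#' there is no melting or sequence-dependent thermodynamics.
#'
#' @param sequence 5'->3' sequence of strand 1 (A/C/G/T only, length >= 2).
#' @param rise axial rise per base pair, Angstrom.
#' @param twist helical twist per base pair, degrees.
#' @param phosphate_charge charge on phosphate beads (elementary charges);
#'   default -0.6 e, the counterion-condensation convention.
#' @param omit_5prime_phosphate drop each strand's 5'-terminal phosphate.
#' @param radius bead radius, Angstrom (all DNA beads).
#' @param contact_cutoff,contact_eps native-contact generation: pairs closer
#'   than the cutoff (and not bonded/1-3) get a Go well of depth `contact_eps`.
#' @param bond_k,angle_k,dihedral_k local force constants.
#' @param chains labels for the two strands.
#' @param box box edges passed to [cg_system()].
#' @return a `cg_system` for the duplex, centred on the helix axis (z).
#' @export
build_bdna_duplex <- function(sequence, rise = 3.38, twist = 34.3,
                              phosphate_charge = -0.6,
                              omit_5prime_phosphate = TRUE, radius = 2.5,
                              contact_cutoff = 9, contact_eps = 2,
                              bond_k = 50, angle_k = 10, dihedral_k = 0.5,
                              chains = c("D", "E"), box = c(200, 160, 200)) {
  sequence <- toupper(sequence)
  bases <- strsplit(sequence, "")[[1]]
  if (length(bases) < 2) stop("sequence must have length >= 2")
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("sequence must contain only A, C, G, T")
  n <- length(bases)
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  strand2_seq <- rev(comp[bases])            # reverse complement, 5'->3'

  # cylindrical site geometry: radius (A), phase (deg), z offset (A)
  site <- list(S = c(6.9, 0, 0), B = c(2.4, 15, 0),
               P = c(8.9, -twist / 2, -rise / 2))
  gamma0 <- 143 # dyad phase offset between the strands (deg)
  place <- function(bp, phase, mirror) {
    # mirror = FALSE: strand 1 at bp index bp (0-based); TRUE: strand 2
    f <- function(s) {
      a <- if (!mirror) bp * twist + s[2] else bp * twist - s[2] + gamma0
      z <- if (!mirror) bp * rise + s[3] else bp * rise - s[3]
      c(s[1] * cos(a * pi / 180), s[1] * sin(a * pi / 180), z)
    }
    f(site[[phase]])
  }
  one_strand <- function(seqv, chain, mirror) {
    rows <- list(); xyz <- list()
    for (k in seq_along(seqv)) {
      bp <- if (!mirror) k - 1 else length(seqv) - k   # bp index on the helix
      resname <- paste0("D", seqv[k])
      add <- function(class) {
        rows[[length(rows) + 1]] <<- data.frame(
          chain = chain, resid = k, class = class,
          charge = if (class == "PHOSPHATE") phosphate_charge else 0,
          radius = radius, resname = resname, stringsAsFactors = FALSE)
        xyz[[length(xyz) + 1]] <<- place(bp, substr(class, 1, 1), mirror)
      }
      if (!(k == 1 && omit_5prime_phosphate)) add("PHOSPHATE")
      add("SUGAR"); add("BASE")
    }
    list(beads = do.call(rbind, rows), xyz = do.call(rbind, xyz))
  }
  s1 <- one_strand(bases, chains[1], mirror = FALSE)
  s2 <- one_strand(strand2_seq, chains[2], mirror = TRUE)
  beads <- rbind(s1$beads, s2$beads)
  xyz <- rbind(s1$xyz, s2$xyz)

  # backbone/base bonds within each strand: S(i)-B(i), S(i)-P(i+1), P(i)-S(i)
  bonds <- empty_bonds()
  for (ch in chains) {
    ix <- which(beads$chain == ch)
    for (k in unique(beads$resid[ix])) {
      S <- ix[beads$resid[ix] == k & beads$class[ix] == "SUGAR"]
      B <- ix[beads$resid[ix] == k & beads$class[ix] == "BASE"]
      P <- ix[beads$resid[ix] == k & beads$class[ix] == "PHOSPHATE"]
      Pn <- ix[beads$resid[ix] == k + 1 & beads$class[ix] == "PHOSPHATE"]
      pair <- function(i, j) if (length(i) && length(j))
        data.frame(i = i, j = j, r0 = sqrt(sum((xyz[i, ] - xyz[j, ])^2)),
                   kf = bond_k) else NULL
      bonds <- rbind(bonds, pair(S, B), pair(P, S), pair(S, Pn))
    }
  }
  topo <- bonded_angles_dihedrals(bonds, xyz, angle_k, dihedral_k)
  sys <- cg_system(beads, xyz, bonds = bonds, angles = topo$angles,
                   dihedrals = topo$dihedrals, box = box)
  # min_seq_sep 1: nearest-neighbour (stacking) pairs are genuine duplex
  # contacts here; without them excluded volume would unwind the helix
  sys$contacts <- build_native_contacts(sys, cutoff = contact_cutoff,
                                        min_seq_sep = 1, eps = contact_eps)
  sys
}

# Angles for every bonded triple and dihedrals for every simple bonded
# 4-path, with reference values measured from xyz.
bonded_angles_dihedrals <- function(bonds, xyz, angle_k, dihedral_k) {
  n <- nrow(xyz)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  ang <- list(); dih <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      for (q in seq_len(ncol(cmb))) {
        a <- cmb[1, q]; c3 <- cmb[2, q]
        ang[[length(ang) + 1]] <- data.frame(
          i = a, j = j, k = c3,
          theta0 = angle_value(xyz[a, ], xyz[j, ], xyz[c3, ]), kf = angle_k)
      }
    }
  }
  # a dihedral is ill-defined (and its force singular) when an interior
  # triple is near-collinear; skip those
  sin_angle <- function(a, b, c3) {
    u <- xyz[a, ] - xyz[b, ]; v <- xyz[c3, ] - xyz[b, ]
    cr <- crossp(u, v)
    sqrt(sum(cr^2)) / sqrt(sum(u^2) * sum(v^2))
  }
  for (r in seq_len(nrow(bonds))) {
    j <- bonds$i[r]; k <- bonds$j[r]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], c(j, i))) {
      if (sin_angle(i, j, k) < 0.25 || sin_angle(j, k, l) < 0.25) next
      dih[[length(dih) + 1]] <- data.frame(
        i = i, j = j, k = k, l = l,
        phi0 = dihedral_value(xyz[i, ], xyz[j, ], xyz[k, ], xyz[l, ]),
        kf = dihedral_k)
    }
  }
  list(angles = if (length(ang)) do.call(rbind, ang) else empty_angles(),
       dihedrals = if (length(dih)) do.call(rbind, dih) else empty_dihedrals())
}

#' Reverse complement of a DNA sequence
#'
#' @param sequence A/C/G/T string.
#' @return the partner strand read 5'->3'.
#' @export
reverse_complement <- function(sequence) {
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  paste(rev(comp[strsplit(toupper(sequence), "")[[1]]]), collapse = "")
}
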