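# Shared fixtures and numeric oracles, built in code at test time.

# central-difference gradient of a scalar function of an N x 3 matrix
num_grad <- function(f, x, h = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_len(nrow(x))) for (c in 1:3) {
    xp <- x; xp[i, c] <- xp[i, c] + h
    xm <- x; xm[i, c] <- xm[i, c] - h
    g[i, c] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# relative agreement between analytic forces and -num_grad
grad_error <- function(report, f, x, h = 1e-5) {
  g <- num_grad(f, x, h)
  max(abs(-g - report$forces)) / max(abs(report$forces), 1e-10)
}

# random self-avoiding-ish coil with full topology, native values perturbed
# away from the current coordinates so every term exerts force
random_coil_system <- function(n = 30, seed = 1, charged = TRUE) {
  set.seed(seed)
  steps <- matrix(rnorm(3 * (n - 1)), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * 3.8
  xyz <- rbind(0, apply(steps, 2, cumsum))
  beads <- data.frame(chain = "A", resid = seq_len(n), class = "CA",
                      charge = if (charged) sample(c(-1, 0, 1), n, TRUE) else 0,
                      radius = 2.5)
  d <- sqrt(rowSums((xyz[-1, ] - xyz[-n, ])^2))
  bonds <- data.frame(i = 1:(n - 1), j = 2:n, r0 = d * 0.97, kf = 50)
  topo <- hingesim:::bonded_angles_dihedrals(bonds, xyz, angle_k = 10,
                                             dihedral_k = 1)
  topo$angles$theta0 <- pmax(0.2, topo$angles$theta0 - 0.1)
  topo$dihedrals$phi0 <- topo$dihedrals$phi0 + 0.3
  dm <- as.matrix(dist(xyz))
  cand <- which(upper.tri(dm) & dm > 6 & dm < 12, arr.ind = TRUE)
  cand <- cand[abs(cand[, 1] - cand[, 2]) >= 4, , drop = FALSE]
  cand <- cand[seq_len(min(nrow(cand), 12)), , drop = FALSE]
  contacts <- data.frame(i = cand[, 1], j = cand[, 2],
                         r0 = dm[cand] * 0.9, eps = 0.8)
  cg_system(beads, xyz, bonds = bonds, angles = topo$angles,
            dihedrals = topo$dihedrals, contacts = contacts,
            box = c(60, 60, 60))
}

# two-bead harmonic dumbbell (bond U = kf (r - r0)^2)
dumbbell <- function(kf = 5, r0 = 3.8) {
  beads <- data.frame(chain = "A", resid = 1:2, class = "CA", charge = 0,
                      radius = 2.5)
  cg_system(beads, matrix(c(0, 0, 0, r0, 0, 0), 2, 3, byrow = TRUE),
            bonds = data.frame(i = 1, j = 2, r0 = r0, kf = kf),
            box = c(50, 50, 50))
}

# toy hinge pre-placed over a synthetic reference image for fitting runs
fitting_setup <- function(target_angle = 79, preopen_frac = 0.7) {
  h <- make_toy_hinge()
  start <- open_toy_hinge(h, preopen_frac * (target_angle - 30))
  start$box <- c(108, 108, 40)
  start$xyz <- sweep(start$xyz, 2, c(54, 54, 4.1), "+")
  ref <- synth_afm_image(target_angle, arm_length_px = 12, pixel_size = 3,
                         height = 6, ridge_sigma_px = 1.2, junction_boost = 1)
  list(native = h, start = start, ref = ref,
       arms = attr(h, "arms"), junction = attr(h, "junction"))
}

# open toy hinge with a duplex bound at the inner site (closure protocol)
closure_setup <- function(open_by = 49) {
  h <- make_toy_hinge()
  op <- open_toy_hinge(h, open_by)
  dna <- build_bdna_duplex("ACGTACGT")
  bis <- (open_by / 2) * pi / 180
  dna$xyz <- sweep(sweep(dna$xyz, 2, colMeans(dna$xyz)), 2,
                   c(sin(bis), cos(bis), 0) * 19, "+")
  sys <- merge_systems(op, dna)
  sys$box <- c(120, 120, 80)
  sys$xyz <- sweep(sys$xyz, 2, sys$box / 2 - colMeans(sys$xyz), "+")
  for (a in c("arms", "inner_site", "junction"))
    attr(sys, a) <- attr(h, a)
  sys
}

# trajectory object with hand-made frames (for analysis-level oracles)
fake_trajectory <- function(frames, steps, system = NULL) {
  structure(list(frames = frames, steps = steps, system = system),
            class = "cg_trajectory")
}
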