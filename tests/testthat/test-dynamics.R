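test_that("zero temperature, zero force leaves positions unchanged", {
  sys <- dumbbell()
  cfg <- simulation_config(50, save_interval = 10, seed = 1,
                           boundary = "open",
                           langevin = langevin_params(temperature = 0))
  tr <- run_simulation(sys, cfg)
  expect_lt(max(abs(tr$frames[, , dim(tr$frames)[3]] - sys$xyz)), 1e-12)
})

test_that("identical seeds give bit-identical trajectories", {
  sys <- random_coil_system(15, seed = 2)
  cfg <- simulation_config(500, save_interval = 100, seed = 99,
                           boundary = "open")
  expect_identical(run_simulation(sys, cfg)$frames,
                   run_simulation(sys, cfg)$frames)
  # single-step driver is deterministic too
  set.seed(5)
  st1 <- langevin_step(sys$xyz, matrix(0, 15, 3), sys, cfg)
  set.seed(5)
  st2 <- langevin_step(sys$xyz, matrix(0, 15, 3), sys, cfg)
  expect_identical(st1$xyz, st2$xyz)
})

test_that("stability bound on friction * dt is enforced", {
  expect_error(langevin_params(friction = 11, dt = 0.2), "unstable")
})

test_that("thermostat satisfies equipartition on a harmonic dumbbell", {
  # bond U = kf (r - r0)^2 i.e. spring constant 2 kf on the bond length;
  # Var(r) = kBT / (2 kf)
  sys <- dumbbell(kf = 5)
  cfg <- simulation_config(1e6, save_interval = 50, seed = 7,
                           boundary = "open")
  tr <- run_simulation(sys, cfg)
  dr <- sqrt(colSums((tr$frames[1, , ] - tr$frames[2, , ])^2))
  expect_lt(abs(var(dr) / (kbt(300) / 10) - 1), 0.03)
  # kinetic energy per degree of freedom = kBT / 2
  ke_dof <- mean(tr$energies[-1, "kinetic"]) / 6
  expect_lt(abs(ke_dof / (kbt(300) / 2) - 1), 0.03)
})

test_that("free diffusion follows MSD = 6 D t with D = kBT/(m gamma)", {
  beads <- data.frame(chain = "A", resid = 1, class = "CA", charge = 0,
                      radius = 2.5)
  sys <- cg_system(beads, matrix(0, 1, 3), box = c(50, 50, 50))
  cfg <- simulation_config(1e6, save_interval = 1000, seed = 3,
                           boundary = "open")
  tr <- run_simulation(sys, cfg)
  x <- t(tr$frames[1, , ])
  steps_dt <- 1000 * 0.2
  disp2 <- rowSums((x[-1, ] - x[-nrow(x), ])^2)
  D <- kbt(300) / (10 * 0.843)
  expect_lt(abs(mean(disp2) / (6 * D * steps_dt) - 1), 0.1)
})

test_that("integrator reduces to energy-conserving Verlet at small friction", {
  sys <- dumbbell(kf = 5)
  cfg <- simulation_config(1e5, save_interval = 1000, seed = 11,
                           boundary = "open",
                           langevin = langevin_params(friction = 1e-12))
  tr <- run_simulation(sys, cfg)
  etot <- rowSums(tr$energies[, c("bond", "kinetic")])
  expect_lt(max(abs(etot - etot[1])) / max(abs(etot[1]), kbt(300)), 1e-3)
})

test_that("periodic minimum-image pair energies match a brute-force oracle", {
  set.seed(8)
  n <- 12
  beads <- data.frame(chain = letters[1:n], resid = 1, class = "CA",
                      charge = sample(c(-1, 1), n, TRUE), radius = 2.5)
  box <- c(30, 24, 27)
  xyz <- cbind(runif(n, 0, 30), runif(n, 0, 24), runif(n, 0, 27))
  sys <- cg_system(beads, xyz, box = box)
  params <- electrostatic_params(0.1)
  got <- dh_energy_forces(sys, params = params,
                          periodic = TRUE)$energies[["electrostatic"]]
  shift <- function(d, L) d - L * round(d / L)
  acc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum(shift(xyz[i, ] - xyz[j, ], box)^2))
    if (d < params$cutoff)
      acc <- acc + dh_pair_energy(beads$charge[i], beads$charge[j], d,
                                  params$lambda) -
        dh_pair_energy(beads$charge[i], beads$charge[j], params$cutoff,
                       params$lambda)
  }
  expect_equal(got, acc, tolerance = 1e-10)
})

test_that("random DNA placement respects separation, seeds, and uniformity", {
  prot <- center_in_box(make_toy_patch_protein(), c(90, 90, 90))
  dna <- build_bdna_duplex("ACGT")
  sys1 <- place_random_dna(prot, dna, n_copies = 3, min_separation = 15,
                           seed = 4)
  sys2 <- place_random_dna(prot, dna, n_copies = 3, min_separation = 15,
                           seed = 4)
  expect_identical(sys1$xyz, sys2$xyz)
  mols <- dna_molecules(sys1)
  expect_length(mols, 3)
  sel <- c(list(protein_beads(sys1)), mols)
  for (a in seq_along(sel)) for (b in seq_along(sel)) {
    if (a < b) {
      dmin <- min(hingesim:::min_dist_series_cpp(
        array(sys1$xyz, c(nrow(sys1$xyz), 3, 1)), sel[[a]], sel[[b]]))
      expect_gte(dmin, 15)
    }
  }
  # centroid distribution uniform across box octants
  ctrs <- vapply(1:400, function(s) {
    sy <- place_random_dna(prot, dna, n_copies = 1, min_separation = 15,
                           seed = 1000 + s)
    colMeans(sy$xyz[dna_beads(sy), ])
  }, numeric(3))
  octant <- paste(ctrs[1, ] > 45, ctrs[2, ] > 45, ctrs[3, ] > 45)
  counts <- table(factor(octant, levels = unique(paste(
    rep(c(TRUE, FALSE), each = 4),
    rep(rep(c(TRUE, FALSE), each = 2), 2), rep(c(TRUE, FALSE), 4)))))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("an isolated duplex retains its native contacts over 1e5 steps", {
  dna <- build_bdna_duplex("ACGTACGTACGTACGTAT")
  cfg <- simulation_config(1e5, save_interval = 5000, seed = 21,
                           boundary = "open")
  tr <- run_simulation(dna, cfg)
  q <- vapply(seq_len(dim(tr$frames)[3]), function(f)
    qscore(dna, tr$frames[, , f]), numeric(1))
  expect_gte(min(q), 0.9)
})

test_that("the AFM restraint drives the similarity upward", {
  su <- fitting_setup()
  cs0 <- afm_restraint_energy_forces(su$start,
                                     restraint = afm_restraint(1, su$ref))$cs
  gains <- vapply(1:10, function(s) {
    cfg <- simulation_config(2e4, save_interval = 2e4, seed = 100 + s,
                             boundary = "reflective", kappa = 150,
                             reference_image = su$ref)
    tail(run_simulation(su$start, cfg)$cs, 1) - cs0
  }, numeric(1))
  expect_gt(median(gains), 0)
})

test_that("restraint release zeroes the AFM term and logs Q and angle", {
  sys <- closure_setup()
  cfg <- simulation_config(2e4, save_interval = 2000, seed = 5,
                           boundary = "reflective",
                           electrostatics = electrostatic_params(0.01),
                           kappa = 100,
                           reference_image = synth_afm_image(79))
  arms <- attr(sys, "arms")
  tr <- release_restraint_protocol(sys, cfg, chains = c("A", "B"),
                                   arm_a = arms$A, arm_b = arms$B,
                                   pivot = attr(sys, "junction"))
  expect_true(all(tr$energies[, "afm"] == 0))
  expect_length(tr$inter_q, dim(tr$frames)[3])
  expect_true(all(is.finite(tr$angle)))
})
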