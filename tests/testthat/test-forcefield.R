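test_that("Debye length matches the closed form and its scaling laws", {
  # frozen from hand evaluation of the formula with CODATA constants
  expect_equal(debye_length(0.100, 300, 78), 9.6188, tolerance = 1e-4)
  expect_equal(debye_length(0.4) / debye_length(0.1), 0.5, tolerance = 1e-12)
  lam <- debye_length(c(0.1, 0.15, 0.2, 0.25, 0.4))
  expect_true(all(diff(lam) < 0))
  expect_error(debye_length(-1), "positive")
})

test_that("Debye-Hueckel pair energy matches hand evaluation", {
  # (332.0637 / (78 * 10)) * exp(-1) = 0.15661...
  expect_equal(dh_pair_energy(1, 1, r = 10, lambda = 10, eps_k = 78),
               332.0637 / 780 * exp(-1), tolerance = 1e-12)
  expect_lt(dh_pair_energy(1, -1, 10, 10), 0)
})

test_that("screened interaction weakens monotonically with ionic strength", {
  sys <- dumbbell(r0 = 8)
  sys$bonds <- hingesim:::empty_bonds()
  sys$beads$charge <- c(1, -1)
  en <- sapply(c(0.1, 0.15, 0.2, 0.25, 0.4), function(I)
    dh_energy_forces(sys, params = electrostatic_params(I))$energies[["electrostatic"]])
  expect_true(all(diff(abs(en)) < 0))
})

test_that("every energy term passes gradient checks on random coils", {
  for (seed in 1:3) {
    sys <- random_coil_system(30, seed = seed)
    x <- sys$xyz
    params <- electrostatic_params(0.15)
    cases <- list(
      bonded = function(xx) bonded_energy_forces(sys, xx),
      contact = function(xx) go_contact_energy_forces(sys, xx),
      excl = function(xx) excluded_volume_energy_forces(sys, xx),
      dh = function(xx) dh_energy_forces(sys, xx, params = params),
      total = function(xx) total_energy_forces(sys, xx,
                                               electrostatics = params))
    for (nm in names(cases)) {
      rep <- cases[[nm]](x)
      expect_lt(grad_error(rep, function(xx) cases[[nm]](xx)$total, x), 1e-5)
    }
  }
})

test_that("bonded terms vanish at the native structure", {
  sys <- random_coil_system(20, seed = 4)
  sys$bonds$r0 <- sqrt(rowSums((sys$xyz[sys$bonds$j, ] -
                                  sys$xyz[sys$bonds$i, ])^2))
  sys$angles <- hingesim:::empty_angles()
  sys$dihedrals <- hingesim:::empty_dihedrals()
  expect_lt(abs(bonded_energy_forces(sys)$total), 1e-10)

  # single stretched bond: U = kf * delta^2
  db <- dumbbell(kf = 7, r0 = 3.8)
  x <- db$xyz; x[2, 1] <- 3.8 + 0.5
  expect_equal(bonded_energy_forces(db, x)$total, 7 * 0.25,
               tolerance = 1e-10)
})

test_that("Go wells have depth -eps at r0 and decay to zero", {
  sys <- random_coil_system(25, seed = 5)
  con <- sys$contacts
  xyz <- sys$xyz
  # move contact pairs exactly to r0 is impossible globally; use a 2-bead case
  beads <- data.frame(chain = c("A", "B"), resid = 1:2, class = "CA",
                      charge = 0, radius = 2.5)
  two <- cg_system(beads, matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE),
                   contacts = data.frame(i = 1, j = 2, r0 = 5, eps = 0.7),
                   box = c(50, 50, 50))
  expect_equal(go_contact_energy_forces(two)$total, -0.7, tolerance = 1e-12)
  far <- two$xyz; far[2, 1] <- 500
  expect_lt(abs(go_contact_energy_forces(two, far)$total), 1e-8)
})

test_that("excluded volume is zero beyond contact and repulsive inside", {
  beads <- data.frame(chain = c("A", "B"), resid = 1:2, class = "CA",
                      charge = 0, radius = 2.5)
  mk <- function(r) cg_system(beads, matrix(c(0, 0, 0, r, 0, 0), 2, 3,
                                            byrow = TRUE), box = c(50, 50, 50))
  expect_equal(excluded_volume_energy_forces(mk(5.2))$total, 0)
  e_half <- excluded_volume_energy_forces(mk(2.5))$total
  e_close <- excluded_volume_energy_forces(mk(4.5))$total
  expect_gt(e_half, e_close)
  expect_gt(e_close, 0)
})

test_that("energies are invariant under rigid motions and obey Newton's law", {
  sys <- random_coil_system(24, seed = 6)
  params <- electrostatic_params(0.2)
  r0 <- total_energy_forces(sys, electrostatics = params)
  set.seed(9)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- hingesim:::quaternion_rotation(q)
  x2 <- sweep(sys$xyz %*% t(R), 2, c(7, -4, 11), "+")
  r1 <- total_energy_forces(sys, x2, electrostatics = params)
  expect_equal(r1$total, r0$total, tolerance = 1e-8)
  expect_lt(max(abs(colSums(r0$forces))), 1e-8)
})

test_that("native contact builder obeys cutoff, separation and exclusions", {
  beads <- data.frame(chain = c("A", "B"), resid = 1:2, class = "CA",
                      charge = 0, radius = 2.5)
  two <- cg_system(beads, matrix(c(0, 0, 0, 5, 0, 0), 2, 3, byrow = TRUE),
                   box = c(50, 50, 50))
  expect_equal(nrow(build_native_contacts(two, cutoff = 6.5)), 1)

  # i, i+2 in one chain excluded by the separation rule
  beads3 <- data.frame(chain = "A", resid = 1:3, class = "CA", charge = 0,
                       radius = 2.5)
  three <- cg_system(beads3, matrix(c(0, 0, 0, 3.8, 0, 0, 5, 3, 0), 3, 3,
                                    byrow = TRUE), box = c(50, 50, 50))
  expect_equal(nrow(build_native_contacts(three, cutoff = 6.5,
                                          min_seq_sep = 4)), 0)

  # brute-force oracle on a coil
  sys <- random_coil_system(30, seed = 7)
  got <- build_native_contacts(sys, cutoff = 8, min_seq_sep = 4)
  cnt <- 0
  for (i in 1:29) for (j in (i + 1):30) {
    if (abs(i - j) >= 4 &&
        sqrt(sum((sys$xyz[i, ] - sys$xyz[j, ])^2)) <= 8) cnt <- cnt + 1
  }
  # the builder additionally drops 1-2/1-3 pairs, which |i-j| >= 4 already
  # guarantees here
  expect_equal(nrow(got), cnt)
})

test_that("RESPAC fit reproduces a monopole and beats unit charges", {
  set.seed(1)
  prot <- make_toy_patch_protein()
  params <- electrostatic_params(0.1)
  th <- acos(runif(300, -1, 1)); ph <- runif(300, 0, 2 * pi)
  ctr <- colMeans(prot$xyz)
  pts <- sweep(cbind(15 * sin(th) * cos(ph), 15 * sin(th) * sin(ph),
                     15 * cos(th)), 2, ctr, "+")
  dctr <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  samples <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                        value = 332.0637 * exp(-dctr / params$lambda) /
                          (params$eps_k * dctr))
  q <- respac_fit_charges(samples, prot$xyz, total_charge = 1, params = params)
  expect_equal(sum(q), 1, tolerance = 1e-8)        # constraint is exact
  expect_lt(attr(q, "residual") / mean(abs(samples$value)), 0.02)

  # zero reference potential -> zero charges
  s0 <- samples; s0$value <- 0
  q0 <- respac_fit_charges(s0, prot$xyz, total_charge = 0, params = params)
  expect_lt(max(abs(q0)), 1e-8)

  # residual no worse than a naive unit-charge assignment
  surf <- attr(q, "surface_beads")
  A <- 332.0637 * exp(-as.matrix(stats::dist(rbind(pts, prot$xyz)))[
    seq_len(300), 300 + surf] / params$lambda) /
    (params$eps_k * as.matrix(stats::dist(rbind(pts, prot$xyz)))[
      seq_len(300), 300 + surf])
  naive <- rep(1 / length(surf), length(surf))
  expect_lte(attr(q, "residual"),
             sqrt(mean((A %*% naive - samples$value)^2)))
})

test_that("charge shuffling preserves the multiset and is seed-deterministic", {
  ch <- c(1, 0, -1, 0.5, 0, 0, 2)
  s1 <- shuffle_charges(ch, seed = 42)
  s2 <- shuffle_charges(ch, seed = 42)
  s3 <- shuffle_charges(ch, seed = 43)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_equal(sum(s1), sum(ch))
  expect_equal(sort(s1[s1 != 0]), sort(ch[ch != 0]))
  expect_equal(attr(s1, "provenance"), "SHUFFLED")
  expect_false(identical(as.numeric(s1), as.numeric(s3)) &&
                 identical(as.numeric(s2), as.numeric(s3)))
})

test_that("total energy is the sum of its terms and terms can be disabled", {
  sys <- random_coil_system(20, seed = 8)
  params <- electrostatic_params(0.15)
  tot <- total_energy_forces(sys, electrostatics = params)
  expect_equal(tot$total, sum(tot$energies), tolerance = 1e-8)
  no_el <- total_energy_forces(sys)
  expect_equal(no_el$energies[["electrostatic"]], 0)
  expect_equal(no_el$total,
               tot$total - tot$energies[["electrostatic"]], tolerance = 1e-8)
})
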