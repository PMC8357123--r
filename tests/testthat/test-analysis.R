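# Analyses are checked against brute-force oracles on hand-made trajectories.

# trajectory with one protein bead at the origin and one "DNA" bead whose
# distance follows a prescribed series
distance_series_traj <- function(dists, save_interval = 100) {
  nf <- length(dists)
  frames <- array(0, c(2, 3, nf))
  for (f in seq_len(nf)) frames[2, 1, f] <- dists[f]
  fake_trajectory(frames, steps = save_interval * (seq_len(nf) - 1))
}

test_that("contact probability equals the per-frame fraction and oracle", {
  dists <- c(rep(5, 25), rep(30, 75))
  tr <- distance_series_traj(dists)
  prof <- contact_probability(tr, protein_sel = 1, dna_sel = 2, cutoff = 10)
  expect_equal(prof$probability, 0.25)

  # always within cutoff -> 1; no DNA -> 0
  tr1 <- distance_series_traj(rep(4, 10))
  expect_equal(contact_probability(tr1, 1, 2, 10)$probability, 1)
  sys <- make_toy_patch_protein()
  cfg <- simulation_config(200, save_interval = 100, seed = 1,
                           boundary = "open")
  trp <- run_simulation(sys, cfg)
  prof0 <- contact_probability(trp, protein_sel = 1:5, dna_sel = integer(0))
  expect_true(all(prof0$probability == 0))

  # brute-force double-loop oracle on a random small trajectory
  set.seed(13)
  nf <- 20
  frames <- array(rnorm(8 * 3 * nf, sd = 8), c(8, 3, nf))
  tr2 <- fake_trajectory(frames, steps = seq_len(nf))
  got <- contact_probability(tr2, protein_sel = 1:4, dna_sel = 5:8,
                             cutoff = 9)$probability
  want <- sapply(1:4, function(i) {
    mean(sapply(seq_len(nf), function(f) {
      any(sapply(5:8, function(j)
        sqrt(sum((frames[i, , f] - frames[j, , f])^2)) < 9))
    }))
  })
  expect_equal(got, want)
})

test_that("contact probability is invariant under frame reordering", {
  set.seed(14)
  nf <- 15
  frames <- array(rnorm(6 * 3 * nf, sd = 6), c(6, 3, nf))
  tr <- fake_trajectory(frames, steps = seq_len(nf))
  perm <- sample(nf)
  tr2 <- fake_trajectory(frames[, , perm], steps = seq_len(nf))
  expect_equal(contact_probability(tr, 1:3, 4:6, 8)$probability,
               contact_probability(tr2, 1:3, 4:6, 8)$probability)
})

test_that("binding events follow the hysteresis definition", {
  # dips below d_on once, stays 500 frames, then leaves past d_off
  dists <- c(rep(20, 10), rep(8, 500), rep(20, 10))
  tr <- distance_series_traj(dists, save_interval = 100)
  ev <- detect_binding_events(tr, sites = list(s = 1),
                              dna_copies = list(d = 2))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 500 * 100)
  expect_false(ev$censored)

  # oscillation between d_on and d_off: one continuous event
  osc <- c(rep(20, 5), rep(c(9, 13), 50), rep(20, 5))
  ev2 <- detect_binding_events(distance_series_traj(osc),
                               sites = list(s = 1), dna_copies = list(d = 2))
  expect_equal(nrow(ev2), 1)

  # still bound at the end: censored
  ev3 <- detect_binding_events(distance_series_traj(c(rep(20, 5), rep(8, 20))),
                               sites = list(s = 1), dna_copies = list(d = 2))
  expect_true(ev3$censored)

  expect_error(detect_binding_events(tr, sites = list(s = 1),
                                     dna_copies = list(d = 2),
                                     d_on = 10, d_off = 9), "hysteresis")
  expect_warning(detect_binding_events(tr, sites = list(a = 1, b = 1),
                                       dna_copies = list(d = 2)), "overlap")
})

test_that("event tables equal a brute-force state machine on random walks", {
  set.seed(15)
  for (rep_i in 1:3) {
    dists <- pmax(0.5, 15 + cumsum(rnorm(300, 0, 2)))
    tr <- distance_series_traj(dists, save_interval = 50)
    ev <- detect_binding_events(tr, sites = list(s = 1),
                                dna_copies = list(d = 2),
                                d_on = 10, d_off = 15)
    # independent replay
    bound <- FALSE; start <- NA; rows <- NULL
    for (f in seq_along(dists)) {
      if (!bound && dists[f] < 10) { bound <- TRUE; start <- tr$steps[f] }
      else if (bound && dists[f] > 15) {
        rows <- rbind(rows, c(start, tr$steps[f], 0)); bound <- FALSE
      }
    }
    if (bound) rows <- rbind(rows, c(start, tr$steps[length(dists)], 1))
    if (is.null(rows)) {
      expect_equal(nrow(ev), 0)
    } else {
      expect_equal(ev$start, rows[, 1])
      expect_equal(ev$end, rows[, 2])
      expect_equal(as.integer(ev$censored), rows[, 3])
    }
  }
})

test_that("survival curves are Kaplan-Meier with censoring handled", {
  # no censoring: P(15) = 2/3 for durations {10, 20, 30}
  ev <- data.frame(duration = c(10, 20, 30), censored = FALSE)
  cv <- survival_curve(ev)
  p15 <- cv$P[max(which(cv$duration <= 15))]
  expect_equal(p15, 2 / 3, tolerance = 1e-12)
  expect_equal(cv$P[cv$duration == 0], 1)

  # hand-computed KM with censoring: events 2, 4+, 6, 8+, 10
  cv2 <- survival_curve(data.frame(duration = c(2, 4, 6, 8, 10),
                                   censored = c(FALSE, TRUE, FALSE, TRUE,
                                                FALSE)))
  # S(2) = 4/5; S(6) = 4/5 * 2/3; S(10) = 0
  expect_equal(cv2$P[cv2$duration == 2], 0.8)
  expect_equal(cv2$P[cv2$duration == 6], 0.8 * 2 / 3, tolerance = 1e-12)
  expect_equal(cv2$P[cv2$duration == 10], 0)
  expect_warning(survival_curve(data.frame(duration = 1:3, censored = TRUE)),
                 "censored")
  expect_error(survival_curve(data.frame()), "empty")
})

test_that("dissociation-rate fits are exact on analytic curves and scale", {
  tt <- seq(0, 3000, by = 100)
  cv <- data.frame(duration = tt, P = exp(-1e-3 * tt))
  fit <- fit_dissociation_rate(cv)
  expect_equal(fit$rate, 1e-3, tolerance = 1e-6)

  # doubling all durations halves the rate
  cv2 <- data.frame(duration = 2 * tt, P = exp(-1e-3 * tt))
  expect_equal(fit_dissociation_rate(cv2)$rate, 5e-4, tolerance = 1e-6)

  # 1000 synthetic exponential dwells: recovery within 10%
  dw <- synth_dwell_times(1e-3, 1000, seed = 2)
  fit3 <- fit_dissociation_rate(survival_curve(dw), events = dw)
  expect_lt(abs(fit3$rate / 1e-3 - 1), 0.1)
  expect_true(is.finite(fit3$se) && fit3$se > 0)
})

test_that("Q-scores count native contacts with the 1.2 tolerance", {
  h <- make_toy_hinge()
  expect_equal(qscore(h, h$xyz), 1)
  # 7 of 10 synthetic pairs within tolerance
  con <- data.frame(i = 1:10, j = 11:20, r0 = 5)
  xyz <- matrix(0, 20, 3)
  xyz[11:20, 1] <- c(rep(5, 7), rep(10, 3))
  expect_equal(qscore(con, xyz), 0.7)

  # brute-force recount on random perturbations
  set.seed(16)
  for (k in 1:3) {
    x <- h$xyz + matrix(rnorm(length(h$xyz), 0, 1.2), ncol = 3)
    d <- sqrt(rowSums((x[h$contacts$i, ] - x[h$contacts$j, ])^2))
    expect_equal(qscore(h, x), mean(d < 1.2 * h$contacts$r0))
  }
})

test_that("Q-score is non-increasing under uniform expansion", {
  h <- make_toy_hinge()
  ctr <- colMeans(h$xyz)
  qs <- vapply(c(1, 1.1, 1.25, 1.5, 2), function(s) {
    x <- sweep(sweep(h$xyz, 2, ctr) * s, 2, ctr, "+")
    qscore(h, x)
  }, numeric(1))
  expect_true(all(diff(qs) <= 0))
})

test_that("protein-DNA Q neglects DNA identity and tolerates sliding", {
  dna <- build_bdna_duplex("ACGTACGTACGTACGTAT")
  nprot <- 6
  # protein beads parallel to the helix axis, middle of the duplex
  pz <- seq(15, 45, length.out = nprot)
  pxyz <- cbind(11, 0, pz)
  beads <- data.frame(chain = "P", resid = seq_len(nprot), class = "CA",
                      charge = 0, radius = 2.5)
  sys <- merge_systems(cg_system(beads, pxyz, box = c(200, 160, 200)), dna)
  refset <- crystal_dna_contacts(sys, cutoff = 15)
  expect_equal(sort(refset), seq_len(nprot))   # all within 15 A
  expect_equal(qscore_protein_dna(refset, sys$xyz, dna_beads(sys)), 1)
  # remove the DNA
  expect_equal(qscore_protein_dna(refset, sys$xyz, integer(0)), 0)
  # slide the DNA one helical repeat (10 bp) along its axis
  slid <- sys$xyz
  slid[dna_beads(sys), 3] <- slid[dna_beads(sys), 3] + 10 * 3.38
  q_slid <- qscore_protein_dna(refset, slid, dna_beads(sys))
  expect_lt(1 - q_slid, 0.2)
})

test_that("representative structure is the PCA-density mode", {
  # 90 frames tightly clustered + 10 outliers, constructed in distance space
  set.seed(17)
  nf <- 100; nsite <- 3
  frames <- array(0, c(nsite + 1, 3, nf))
  for (f in 1:nf) {
    base <- if (f <= 90) 8 else 60
    frames[nsite + 1, , f] <- c(base + rnorm(1, 0, 0.5), 0, 0)
    for (i in seq_len(nsite)) frames[i, , f] <- c((i - 1) * 2, 0, 0)
  }
  tr <- fake_trajectory(frames, steps = seq_len(nf))
  rep <- representative_structure(tr, site_residues = seq_len(nsite),
                                  dna_sel = nsite + 1)
  expect_lte(rep$frame, 90)

  # neighbour counts equal brute force in PC space
  dmin <- hingesim:::min_dist_series_cpp(frames, seq_len(nsite), nsite + 1)
  sc <- prcomp(dmin)$x[, 1:min(3, ncol(dmin)), drop = FALSE]
  D <- as.matrix(dist(sc))
  expect_equal(rep$counts, unname(rowSums(D <= 10)))

  # identical frames: degenerate, frame 1
  same <- fake_trajectory(array(frames[, , 1], c(nsite + 1, 3, 5)), 1:5)
  expect_warning(r2 <- representative_structure(same, seq_len(nsite),
                                                nsite + 1), "degenerate")
  expect_equal(r2$frame, 1L)
})

test_that("conservation profile counts query identity per column", {
  msa <- c(q = "ACD-F", a = "ACD-F", b = "ACDEF", c = "GCD-F", d = "ACH-F")
  prof <- conservation_profile(msa, "q")
  expect_equal(prof$score, c(0.8, 1, 0.8, 1))
  expect_equal(prof$column, c(1, 2, 3, 5))
  # all rows identical -> 1 everywhere
  same <- conservation_profile(c(a = "MKV", b = "MKV", c = "MKV"), 1)
  expect_true(all(same$score == 1))
  # hand count on a 5 x 10 toy MSA with gaps in the denominator rule
  set.seed(18)
  mat <- matrix(sample(c("A", "R", "N", "-"), 50, TRUE), 5, 10)
  mat[1, ] <- sample(c("A", "R", "N"), 10, TRUE)
  prof2 <- conservation_profile(mat, 1, ignore_gaps = TRUE)
  want <- sapply(1:10, function(cc) {
    col <- mat[, cc]; ng <- col != "-"
    sum(col == mat[1, cc] & ng) / sum(ng)
  })
  expect_equal(prof2$score, want)
  expect_error(conservation_profile(msa, "missing"), "not found")
})

test_that("site derivation picks contiguous high-probability runs", {
  prof <- data.frame(bead = 1:20, chain = "A", resid = 1:20,
                     probability = c(rep(0.1, 5), rep(0.9, 4), rep(0.1, 3),
                                     rep(0.6, 5), rep(0.1, 3)))
  sites <- derive_sites(prof, threshold = 0.5, min_run = 3)
  expect_equal(names(sites), c("I", "II"))
  expect_equal(sites$I, 6:9)
  expect_equal(sites$II, 13:17)
})
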