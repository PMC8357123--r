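test_that("hard-max rendering follows the max rule", {
  spec <- list(nx = 5, ny = 5, pixel_size = 10, origin = c(0, 0))
  tip <- tip_model(apex_radius = 0, smoothing = "hard")
  one <- render_pseudo_afm(matrix(c(25, 25, 10), 1, 3), radii = 2,
                           image_spec = spec, tip = tip)
  expect_equal(one$heights[3, 3], 12)
  expect_equal(sum(one$heights > 0), 1)

  # two beads stacked in a pixel: height from the upper bead
  two <- render_pseudo_afm(rbind(c(25, 25, 10), c(26, 24, 4)), radii = 2,
                           image_spec = spec, tip = tip)
  expect_equal(two$heights[3, 3], 12)

  # empty system: all-zero image
  empty <- render_pseudo_afm(matrix(0, 0, 3), radii = numeric(0),
                             image_spec = spec, tip = tip)
  expect_true(all(empty$heights == 0))
})

test_that("soft rendering approaches hard rendering at large beta", {
  spec <- list(nx = 6, ny = 6, pixel_size = 10, origin = c(0, 0))
  set.seed(2)
  # beads at pixel centres so the parabolic cap matters only laterally
  ctrs <- expand.grid(x = c(15, 35, 45), y = c(15, 25, 45))
  xyz <- cbind(ctrs$x, ctrs$y, runif(9, 5, 12))
  # sharp tip (cap radius 2 A) so lateral bleed into neighbouring pixels
  # is negligible and the log-sum-exp limit is the binning maximum
  hard <- render_pseudo_afm(xyz, radii = 2, image_spec = spec,
                            tip = tip_model(smoothing = "hard"))
  soft <- render_pseudo_afm(xyz, radii = 2, image_spec = spec,
                            tip = tip_model(smoothing = "soft", beta = 10,
                                            tip_s = 2))
  expect_lt(max(abs(hard$heights - soft$heights)), 0.1)
})

test_that("cosine similarity identities hold exactly", {
  set.seed(3)
  H <- matrix(runif(36), 6, 6)
  expect_equal(cosine_similarity(H, H), 1.0)
  expect_equal(cosine_similarity(H, 2 * H), 1.0)    # scale invariance
  A <- matrix(0, 4, 4); A[1:2, ] <- 1
  B <- matrix(0, 4, 4); B[3:4, ] <- 1
  expect_equal(cosine_similarity(A, B), 0.0)        # disjoint support
  expect_equal(cosine_similarity(A, B), cosine_similarity(B, A))
  expect_error(cosine_similarity(A, matrix(0, 4, 4)), "all-zero")
  expect_error(cosine_similarity(A, matrix(1, 5, 4)), "shape")
})

test_that("AFM restraint energy follows kappa kBT (1 - cs)", {
  # kappa = 3000, cs = 0.8 -> V = 600 kBT
  expect_equal(3000 * kbt(300) * (1 - 0.8) / kbt(300), 600)
  # and the implementation reproduces the linear form
  su <- fitting_setup()
  rs <- afm_restraint(3000, su$ref)
  rep <- afm_restraint_energy_forces(su$start, restraint = rs)
  expect_equal(rep$total, 3000 * kbt(300) * (1 - rep$cs), tolerance = 1e-10)
  # perfect match: render the reference geometry itself => cs = 1, V = 0
  self <- afm_restraint(10, su$ref)
  img_as_sys <- su$ref
  expect_equal(cosine_similarity(su$ref, img_as_sys), 1)
})

test_that("restraint forces match finite differences and vanish off-stage", {
  su <- fitting_setup()
  rs <- afm_restraint(150, su$ref)
  x <- su$start$xyz[1:10, ]
  rad <- su$start$beads$radius[1:10]
  rep <- afm_restraint_energy_forces(x, rad, rs)
  err <- grad_error(rep, function(xx)
    afm_restraint_energy_forces(xx, rad, rs)$total, x, h = 1e-5)
  expect_lt(err, 1e-4)

  # molecule far outside the imaged region: zero pseudo-image, no force
  off <- x; off[, 3] <- -50
  rep2 <- afm_restraint_energy_forces(off, rad, rs)
  expect_true(rep2$afm_zero_image)
  expect_true(all(rep2$forces == 0))
})

test_that("hinge-angle metrology recovers constructed angles", {
  for (a in c(50, 79, 90, 120, 160)) {
    m <- measure_hinge_angle(synth_afm_image(a))
    expect_lt(abs(as.numeric(m) - a), 6)
  }
  # collinear rods
  m180 <- measure_hinge_angle(synth_afm_image(180))
  expect_lt(abs(as.numeric(m180) - 180), 6)
  # unresolved arms: a single blob
  blob <- afm_image(outer(exp(-((1:20) - 10)^2 / 8),
                          exp(-((1:20) - 10)^2 / 8)) * 30, 18.75)
  expect_error(measure_hinge_angle(blob), "not resolved")
})

test_that("metrology is stable under image rotation (discretization only)", {
  img <- synth_afm_image(100)
  base <- as.numeric(measure_hinge_angle(img))
  # rotate the height field by 30 degrees about the grid centre by resampling
  H <- img$heights; n <- nrow(H)
  ctr <- (n + 1) / 2
  a <- 30 * pi / 180
  rot <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    x <- cos(a) * (i - ctr) + sin(a) * (j - ctr) + ctr
    y <- -sin(a) * (i - ctr) + cos(a) * (j - ctr) + ctr
    i0 <- floor(x); j0 <- floor(y)
    if (i0 >= 1 && i0 < n && j0 >= 1 && j0 < n) {
      fx <- x - i0; fy <- y - j0
      rot[i, j] <- (1 - fx) * (1 - fy) * H[i0, j0] + fx * (1 - fy) * H[i0 + 1, j0] +
        (1 - fx) * fy * H[i0, j0 + 1] + fx * fy * H[i0 + 1, j0 + 1]
    }
  }
  got <- as.numeric(measure_hinge_angle(afm_image(rot, img$pixel_size)))
  expect_lt(abs(got - base), 5)
})

test_that("two-Gaussian mixture fit recovers known parameters", {
  set.seed(3)
  ang <- c(rnorm(11200, 25, 6), rnorm(4800, 60, 12))  # 0.7/0.3 mixture
  fit <- fit_angle_mixture(ang)
  expect_lt(abs(fit$means[1] - 25), 2)
  expect_lt(abs(fit$means[2] - 60), 2)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-8)
  expect_false(fit$degenerate)
  # identical angles: degenerate single cluster flagged
  flat <- fit_angle_mixture(rep(30, 50))
  expect_true(flat$degenerate)
})

test_that("AFM images round-trip through TSV", {
  img <- synth_afm_image(90, noise_sd = 1, seed = 4)
  f <- tempfile(fileext = ".tsv")
  write_afm_image(img, f)
  back <- read_afm_image(f)
  expect_equal(back$pixel_size, img$pixel_size)
  expect_lt(max(abs(back$heights - img$heights)), 1e-6)
})

test_that("median filter smooths single-frame spikes", {
  x <- rep(20, 21); x[11] <- 80
  expect_equal(median_filter(x)[11], 20)
})
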