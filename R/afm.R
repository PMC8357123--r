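#' AFM height image
#'
#' Rectangular grid of heights (Angstrom) above the stage (z = 0), with a
#' pixel size and the world coordinates of the lower-left corner of pixel
#' (1,1). The first matrix index runs along x, the second along y.
#'
#' @param heights numeric matrix of non-negative heights, Angstrom.
#' @param pixel_size Angstrom per pixel (18.75 A = 1.875 nm for the
#'   experimental hinge images).
#' @param origin length-2 world coordinates of the grid's lower-left corner.
#' @return an `afm_image`.
#' @export
afm_image <- function(heights, pixel_size = 18.75, origin = c(0, 0)) {
  heights <- as.matrix(heights)
  if (!length(heights)) stop("empty height grid")
  if (any(heights < 0)) stop("heights must be >= 0 (relative to the stage)")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(heights = heights, pixel_size = pixel_size,
                 origin = as.numeric(origin)),
            class = "afm_image")
}

#' @export
print.afm_image <- function(x, ...) {
  cat("afm_image:", nrow(x$heights), "x", ncol(x$heights), "pixels,",
      x$pixel_size, "A/pixel, max height",
      round(max(x$heights), 2), "A\n")
  invisible(x)
}

#' Tip model for pseudo-AFM rendering
#'
#' `smoothing = "hard"`: each bead is binned to the pixel under its (x, y)
#' with height z + r; an apex radius > 0 additionally spreads a parabolic
#' cap to neighbouring pixels. `smoothing = "soft"`: smooth log-sum-exp over
#' parabolic-cap candidate heights (sharpness `beta`), differentiable in the
#' coordinates and converging to a hard maximum as beta grows; `tip_s` is
#' the parabolic cap radius (defaults to half the pixel size at render
#' time).
#'
#' @param apex_radius lateral capture radius of the tip apex, A (0 = point
#'   tip).
#' @param smoothing "hard" or "soft".
#' @param beta softmax sharpness, 1/A.
#' @param tip_s parabolic cap radius for soft rendering, A (`NULL`: half a
#'   pixel).
#' @return a `tip_model`.
#' @export
tip_model <- function(apex_radius = 0, smoothing = c("hard", "soft"),
                      beta = 2, tip_s = NULL) {
  smoothing <- match.arg(smoothing)
  if (apex_radius < 0) stop("apex_radius must be >= 0")
  if (beta <= 0) stop("beta must be positive")
  structure(list(apex_radius = apex_radius, smoothing = smoothing,
                 beta = beta, tip_s = tip_s), class = "tip_model")
}

tip_sharpness <- function(tip, pixel_size) {
  if (!is.null(tip$tip_s)) tip$tip_s
  else max(tip$apex_radius, pixel_size / 2)
}

#' Render a pseudo-AFM image from coordinates
#'
#' Pixel height is the (soft)maximum over nearby beads of the bead-top
#' height z + r seen through the tip model; pixels with no bead above the
#' stage are 0. An empty system gives an all-zero image.
#'
#' @param xyz coordinates (matrix) or a `cg_system`.
#' @param radii per-bead radii (taken from the system if omitted).
#' @param image_spec an `afm_image` to copy the grid from, or a list with
#'   `nx, ny, pixel_size, origin`.
#' @param tip a [tip_model()].
#' @return an `afm_image`.
#' @export
render_pseudo_afm <- function(xyz, radii = NULL, image_spec, tip = tip_model()) {
  if (inherits(xyz, "cg_system")) {
    if (is.null(radii)) radii <- xyz$beads$radius
    xyz <- xyz$xyz
  }
  if (is.null(radii)) stop("radii required when xyz is a matrix")
  if (inherits(image_spec, "afm_image")) {
    nx <- nrow(image_spec$heights); ny <- ncol(image_spec$heights)
    px <- image_spec$pixel_size; org <- image_spec$origin
  } else {
    nx <- image_spec$nx; ny <- image_spec$ny
    px <- image_spec$pixel_size
    org <- if (is.null(image_spec$origin)) c(0, 0) else image_spec$origin
  }
  if (!nrow(xyz))
    return(afm_image(matrix(0, nx, ny), px, org))
  H <- render_afm_cpp(xyz, rep_len(radii, nrow(xyz)), nx, ny, px,
                      org[1], org[2], tip$smoothing == "soft", tip$beta,
                      tip_sharpness(tip, px), tip$apex_radius)
  afm_image(pmax(H, 0), px, org)
}

#' Cosine similarity between two height images
#'
#' sum(Ha Hb) / (sqrt(sum(Ha^2)) sqrt(sum(Hb^2))); symmetric, invariant to
#' scaling either image, in [0, 1] for non-negative heights.
#'
#' @param image_a,image_b `afm_image`s or plain matrices of the same shape.
#' @return similarity score.
#' @export
cosine_similarity <- function(image_a, image_b) {
  a <- if (inherits(image_a, "afm_image")) image_a$heights else image_a
  b <- if (inherits(image_b, "afm_image")) image_b$heights else image_b
  if (!all(dim(a) == dim(b))) stop("images must have the same grid shape")
  sa <- sum(a^2); sb <- sum(b^2)
  if (sa == 0 || sb == 0) stop("cosine similarity undefined for all-zero image")
  sum(a * b) / sqrt(sa * sb)
}

#' AFM fitting restraint
#'
#' V = kappa k_B T (1 - c.s.(H_ref, H_sim(R))), with the pseudo-image
#' rendered in soft mode so the restraint is differentiable. kappa is the
#' dimensionless fitting strength (10 barely biases; 3000 fits while
#' preserving subunit structure; 10000 fits at the cost of distortion, in
#' the full-size system).
#'
#' @param kappa dimensionless restraint strength (>= 0).
#' @param reference reference `afm_image`.
#' @param tip a [tip_model()] (`smoothing` forced to "soft").
#' @return an `afm_restraint`.
#' @export
afm_restraint <- function(kappa, reference, tip = tip_model(smoothing = "soft")) {
  if (kappa < 0) stop("kappa must be >= 0")
  stopifnot(inherits(reference, "afm_image"))
  tip$smoothing <- "soft"
  structure(list(kappa = kappa, reference = reference, tip = tip),
            class = "afm_restraint")
}

# Bundle for the C++ kernels; NULL when no restraint.
afm_cpp_bundle <- function(afm, temperature) {
  if (is.null(afm) || afm$kappa == 0) return(NULL)
  ref <- afm$reference
  list(ref = ref$heights, pixel_size = ref$pixel_size,
       x0 = ref$origin[1], y0 = ref$origin[2], beta = afm$tip$beta,
       tip_s = tip_sharpness(afm$tip, ref$pixel_size),
       kappa_kbt = afm$kappa * kbt(temperature))
}

#' AFM restraint energy and forces
#'
#' Energy in kcal/mol (kappa k_B T (1 - c.s.)) with analytic forces through
#' the soft pixel heights. If the simulated image is all zero (molecule left
#' the imaged region) no force is applied and the frame is flagged.
#'
#' @param xyz coordinates or `cg_system`.
#' @param radii per-bead radii.
#' @param restraint an [afm_restraint()].
#' @param temperature Kelvin.
#' @return an `energy_report` with elements `cs` and `afm_zero_image`.
#' @export
afm_restraint_energy_forces <- function(xyz, radii = NULL, restraint,
                                        temperature = 300) {
  if (inherits(xyz, "cg_system")) {
    if (is.null(radii)) radii <- xyz$beads$radius
    xyz <- xyz$xyz
  }
  b <- afm_cpp_bundle(restraint, temperature)
  if (is.null(b)) {
    z <- list(energies = c(afm = 0), total = 0,
              forces = matrix(0, nrow(xyz), 3), cs = NA_real_,
              afm_zero_image = FALSE)
    return(energy_report(z))
  }
  res <- afm_score_forces_cpp(xyz, rep_len(radii, nrow(xyz)), b$ref,
                              b$pixel_size, b$x0, b$y0, b$beta, b$tip_s,
                              b$kappa_kbt)
  energy_report(list(energies = c(afm = res$energy), total = res$energy,
                     forces = res$forces, cs = res$cs,
                     afm_zero_image = res$zero_image))
}

#' Write an AFM image as a TSV height grid
#'
#' One-line header (`# pixel_size <A> origin <x> <y>`), then the height
#' matrix, tab-separated, rows along x.
#'
#' @param image an `afm_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_afm_image <- function(image, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# pixel_size %.6g origin %.6g %.6g\n", image$pixel_size,
              image$origin[1], image$origin[2]), file = con)
  write.table(image$heights, con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an AFM image written by [write_afm_image()]
#'
#' @param path file path.
#' @return an `afm_image`.
#' @export
read_afm_image <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), " +")[[1]]
  H <- as.matrix(read.table(path, sep = "\t", skip = 1))
  dimnames(H) <- NULL
  afm_image(H, pixel_size = as.numeric(hdr[3]),
            origin = as.numeric(hdr[5:6]))
}
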