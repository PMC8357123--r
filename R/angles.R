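#' Measure the hinge angle from an AFM image
#'
#' Reproduces the image metrology used for hinge-angle time series: (i) find
#' the highest pixel within the mask (the globular hinge domain); (ii) for
#' each direction on a 1-degree grid, sum the heights inside a parallelogram
#' extending radially from that point (default 10 pixels long, 5 wide);
#' (iii) take the two directions that are local maxima of this sum,
#' enforcing a minimum angular separation; (iv) return the angle between
#' the two centre lines, folded into [0, 180] degrees.
#'
#' @param image an `afm_image`.
#' @param mask logical matrix (same shape) marking the globular domain;
#'   `NULL` uses the whole image.
#' @param arm_length_px,arm_width_px parallelogram dimensions in pixels.
#' @param angular_step search grid, degrees.
#' @param min_separation minimum angular separation between the two selected
#'   arm directions, degrees.
#' @return the hinge angle in degrees, with attributes `directions` (the two
#'   arm directions) and `apex` (pixel indices of the highest masked pixel).
#' @export
measure_hinge_angle <- function(image, mask = NULL, arm_length_px = 10,
                                arm_width_px = 5, angular_step = 1,
                                min_separation = 20) {
  H <- image$heights
  if (is.null(mask)) mask <- matrix(TRUE, nrow(H), ncol(H))
  if (!any(mask)) stop("empty mask")
  masked <- H
  masked[!mask] <- -Inf
  apex <- which(masked == max(masked), arr.ind = TRUE)[1, ]
  # sub-pixel apex: height-weighted centroid of the summit (>= 90% of max)
  nbx <- pmax(1, apex[1] - 2):pmin(nrow(H), apex[1] + 2)
  nby <- pmax(1, apex[2] - 2):pmin(ncol(H), apex[2] + 2)
  w <- pmax(masked[nbx, nby, drop = FALSE] - 0.9 * max(masked), 0)
  cx <- sum(outer(nbx, rep(1, length(nby))) * w) / sum(w)
  cy <- sum(outer(rep(1, length(nbx)), nby) * w) / sum(w)
  # pixels within reach of the parallelogram; the disc of radius
  # `arm_width_px` around the apex belongs to the junction blob, not to
  # either arm, so the radial window starts beyond it
  t_min <- arm_width_px
  r <- t_min + arm_length_px + arm_width_px
  ix <- pmax(1, floor(cx - r)):pmin(nrow(H), ceiling(cx + r))
  iy <- pmax(1, floor(cy - r)):pmin(ncol(H), ceiling(cy + r))
  grid <- expand.grid(ix = ix, iy = iy)
  ox <- grid$ix - cx; oy <- grid$iy - cy
  hv <- H[cbind(grid$ix, grid$iy)]
  phis <- seq(0, 360 - angular_step, by = angular_step)
  sums <- vapply(phis, function(phi) {
    a <- phi * pi / 180
    t <- ox * cos(a) + oy * sin(a)      # radial coordinate
    w <- -ox * sin(a) + oy * cos(a)     # transverse coordinate
    sum(hv[t > t_min & t <= t_min + arm_length_px & abs(w) <= arm_width_px / 2])
  }, numeric(1))
  np <- length(phis)
  prev <- c(np, seq_len(np - 1)); nxt <- c(seq_len(np)[-1], 1)
  # an arm must carry meaningful mass: at least two apex-heights of summed
  # height in its parallelogram, or the blob has no resolvable arms
  floor_sum <- 2 * max(masked)
  is_max <- sums >= sums[prev] & sums >= sums[nxt] & sums > floor_sum
  cand <- which(is_max)[order(sums[is_max], decreasing = TRUE)]
  picked <- integer()
  for (c0 in cand) {
    if (all(vapply(picked, function(p) {
      d <- abs(phis[c0] - phis[p]) %% 360
      min(d, 360 - d) >= min_separation
    }, logical(1)))) picked <- c(picked, c0)
    if (length(picked) == 2) break
  }
  if (length(picked) < 2) stop("arms not resolved: fewer than two arm directions")
  # sub-degree refinement: circular centroid of the peak plateau
  dirs <- vapply(picked, function(p) {
    offs <- seq(-10, 10, by = angular_step) / angular_step
    vals <- sums[((p - 1 + offs) %% np) + 1]
    vals <- pmax(vals - 0.9 * sums[p], 0)
    phis[p] + angular_step * sum(offs * vals) / sum(vals)
  }, numeric(1))
  d <- abs(dirs[1] - dirs[2]) %% 360
  ang <- min(d, 360 - d)
  if (ang > 180) ang <- 360 - ang
  structure(ang, directions = dirs, apex = apex)
}

#' Median-filter an angle time series
#'
#' @param x numeric series (degrees).
#' @param window odd window width (default 5).
#' @return filtered series.
#' @export
median_filter <- function(x, window = 5) {
  as.numeric(stats::runmed(x, window, endrule = "median"))
}

#' Hinge angle from coordinates
#'
#' Angle (degrees) between the centroid directions of two arm selections
#' seen from a pivot selection; the coordinate-space analog of
#' [measure_hinge_angle()] used when bead positions are available.
#'
#' @param xyz coordinates or `cg_system`.
#' @param arm_a,arm_b bead index vectors for the two arms.
#' @param pivot bead indices of the junction (default: union centroid).
#' @return angle in degrees.
#' @export
hinge_angle_from_coords <- function(xyz, arm_a, arm_b, pivot = NULL) {
  if (inherits(xyz, "cg_system")) xyz <- xyz$xyz
  org <- if (is.null(pivot)) colMeans(xyz[c(arm_a, arm_b), , drop = FALSE])
         else colMeans(xyz[pivot, , drop = FALSE])
  axis_of <- function(sel) {
    sub <- xyz[sel, , drop = FALSE]
    u <- prcomp(sub)$rotation[, 1]          # principal axis of the arm
    if (sum(u * (colMeans(sub) - org)) < 0) u <- -u  # point away from pivot
    u
  }
  v1 <- axis_of(arm_a); v2 <- axis_of(arm_b)
  ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Two-Gaussian mixture fit of a hinge-angle distribution
#'
#' Maximum-likelihood Gaussian mixture (unequal variances) fitted by EM,
#' used to resolve the closed and open conformational states in an angle
#' frequency distribution. Deterministic: model-based initialization
#' (mclust).
#'
#' @param angles numeric sample, degrees.
#' @param n_components number of Gaussian components (default 2).
#' @return list with `weights`, `means`, `sds` (component order by
#'   increasing mean), `loglik`, and `degenerate` (TRUE when the sample
#'   collapses to fewer clusters than requested).
#' @export
fit_angle_mixture <- function(angles, n_components = 2) {
  if (length(angles) < 10 * n_components)
    stop("need at least ", 10 * n_components, " samples")
  if (stats::sd(angles) < 1e-12)
    return(list(weights = 1, means = mean(angles), sds = 0,
                loglik = NA_real_, degenerate = TRUE))
  # Mclust evaluates a constructed mclustBIC() call in this frame
  mclustBIC <- mclust::mclustBIC
  fit <- mclust::Mclust(angles, G = n_components, modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed")
  ord <- order(fit$parameters$mean)
  list(weights = as.numeric(fit$parameters$pro)[ord],
       means = as.numeric(fit$parameters$mean)[ord],
       sds = sqrt(as.numeric(fit$parameters$variance$sigmasq))[ord],
       loglik = fit$loglik, degenerate = FALSE)
}
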