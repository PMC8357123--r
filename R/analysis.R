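#' Protein and DNA bead selections
#'
#' @param system a `cg_system`.
#' @return integer bead indices.
#' @export
protein_beads <- function(system) which(system$beads$class == "CA")

#' @rdname protein_beads
#' @export
dna_beads <- function(system) which(system$beads$class != "CA")

#' DNA molecules as bead-index lists
#'
#' Groups DNA beads by molecule id (the `mol` bead column, set by
#' [place_random_dna()]; defaults to the chain label).
#'
#' @param system a `cg_system`.
#' @return named list of bead-index vectors, one per DNA molecule.
#' @export
dna_molecules <- function(system) {
  sel <- dna_beads(system)
  if (!length(sel)) return(list())
  split(sel, system$beads$mol[sel])
}

#' Per-residue DNA-contact probability
#'
#' For each selected protein bead, the fraction of frames in which any
#' selected DNA bead lies within the cutoff.
#'
#' @param trajectory a `cg_trajectory`.
#' @param protein_sel,dna_sel bead index vectors (defaults: all protein /
#'   all DNA beads of the trajectory's system).
#' @param cutoff contact distance, A (default 10).
#' @return data.frame `bead, chain, resid, probability` with attributes
#'   `cutoff` and `n_frames`.
#' @export
contact_probability <- function(trajectory, protein_sel = NULL,
                                dna_sel = NULL, cutoff = 10) {
  sys <- trajectory$system
  if (is.null(protein_sel)) protein_sel <- protein_beads(sys)
  if (is.null(dna_sel)) dna_sel <- dna_beads(sys)
  if (!length(protein_sel)) stop("empty protein selection")
  nf <- dim(trajectory$frames)[3]
  if (!nf) stop("empty trajectory")
  if (!length(dna_sel)) {
    p <- rep(0, length(protein_sel))
  } else {
    dmin <- min_dist_series_cpp(trajectory$frames, protein_sel, dna_sel)
    p <- colMeans(dmin < cutoff)
  }
  has_sys <- !is.null(sys)
  out <- data.frame(bead = protein_sel,
                    chain = if (has_sys) sys$beads$chain[protein_sel] else NA,
                    resid = if (has_sys) sys$beads$resid[protein_sel] else NA,
                    probability = p)
  attr(out, "cutoff") <- cutoff
  attr(out, "n_frames") <- nf
  out
}

#' Derive binding-site residue sets from a contact profile
#'
#' Connected runs (along the bead index) of residues whose contact
#' probability exceeds a threshold; runs shorter than `min_run` are
#' dropped. Sites are labelled "I", "II", ... by decreasing peak
#' probability.
#'
#' @param profile output of [contact_probability()].
#' @param threshold probability threshold (default 0.5).
#' @param min_run minimum run length in beads.
#' @return named list of bead-index vectors.
#' @export
derive_sites <- function(profile, threshold = 0.5, min_run = 3) {
  hot <- profile$probability >= threshold
  if (!any(hot)) return(list())
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= min_run)
  sites <- lapply(runs, function(q) profile$bead[starts[q]:ends[q]])
  peak <- vapply(runs, function(q)
    max(profile$probability[starts[q]:ends[q]]), numeric(1))
  sites <- sites[order(peak, decreasing = TRUE)]
  names(sites) <- as.character(utils::as.roman(seq_along(sites)))
  sites
}

#' Detect binding events with hysteresis
#'
#' A DNA molecule binds a site when its minimum distance to the site's
#' beads drops below `d_on` and unbinds when it exceeds `d_off` (> d_on, so
#' boundary chatter does not fragment events). Events still bound at the
#' final frame are right-censored there.
#'
#' @param trajectory a `cg_trajectory`.
#' @param sites named list of protein bead-index vectors.
#' @param dna_copies named list of DNA bead-index vectors (default:
#'   [dna_molecules()] of the trajectory's system).
#' @param d_on,d_off binding/unbinding thresholds, A.
#' @return data.frame `site, copy, start, end, duration, censored` (steps).
#' @export
detect_binding_events <- function(trajectory, sites, dna_copies = NULL,
                                  d_on = 10, d_off = 15) {
  if (d_off <= d_on) stop("hysteresis requires d_off > d_on")
  if (is.null(dna_copies)) dna_copies <- dna_molecules(trajectory$system)
  if (is.null(names(sites))) names(sites) <- seq_along(sites)
  if (is.null(names(dna_copies))) names(dna_copies) <- seq_along(dna_copies)
  for (a in seq_along(sites)) for (b in seq_along(sites)) {
    if (a < b && length(intersect(sites[[a]], sites[[b]])))
      warning("site definitions '", names(sites)[a], "' and '",
              names(sites)[b], "' overlap")
  }
  steps <- trajectory$steps
  rows <- list()
  for (sn in names(sites)) for (cn in names(dna_copies)) {
    dmin <- min_dist_series_cpp(trajectory$frames, sites[[sn]],
                                dna_copies[[cn]])
    s <- apply(dmin, 1, min)
    bound <- FALSE; start <- NA_integer_
    for (f in seq_along(s)) {
      if (!bound && s[f] < d_on) { bound <- TRUE; start <- steps[f] }
      else if (bound && s[f] > d_off) {
        rows[[length(rows) + 1]] <- data.frame(
          site = sn, copy = cn, start = start, end = steps[f],
          censored = FALSE)
        bound <- FALSE
      }
    }
    if (bound)
      rows[[length(rows) + 1]] <- data.frame(
        site = sn, copy = cn, start = start, end = steps[length(s)],
        censored = TRUE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = character(), copy = character(), start = integer(),
               end = integer(), censored = logical())
  out$duration <- out$end - out$start
  out[, c("site", "copy", "start", "end", "duration", "censored")]
}

#' Survival curve of binding events
#'
#' Kaplan-Meier estimate of P(duration >= t); right-censored events
#' contribute to the risk set while observed. P(0) = 1.
#'
#' @param events data.frame from [detect_binding_events()] (or with columns
#'   `duration`, `censored`), possibly pre-filtered to one site.
#' @return data.frame `duration, P, n_risk`; attribute `all_censored` is
#'   TRUE when no dissociation was observed.
#' @export
survival_curve <- function(events) {
  if (!nrow(events)) stop("empty event table")
  if (is.null(events$censored)) events$censored <- FALSE
  all_cens <- all(events$censored)
  if (all_cens)
    warning("all events censored: survival curve is uninformative")
  fit <- survival::survfit(
    survival::Surv(events$duration, !events$censored) ~ 1)
  out <- data.frame(duration = c(0, fit$time), P = c(1, fit$surv),
                    n_risk = c(nrow(events), fit$n.risk))
  attr(out, "all_censored") <- all_cens
  out
}

#' Dissociation rate from a survival curve
#'
#' Weighted least-squares slope of ln P versus t over the fit window
#' (default P in [0.1, 1]); rate = -slope, in 1/step. Points are weighted
#' by the number at risk when available. The standard error is a bootstrap
#' over events when the event table is supplied.
#'
#' @param curve data.frame `duration, P` (optionally `n_risk`).
#' @param events optional event table for the bootstrap.
#' @param window P-range used in the fit.
#' @param n_boot bootstrap replicates.
#' @return list `rate`, `se`, `n_points`.
#' @export
fit_dissociation_rate <- function(curve, events = NULL, window = c(0.1, 1),
                                  n_boot = 200) {
  if (any(diff(curve$P) > 1e-12)) stop("survival curve must be non-increasing")
  fit1 <- function(cv) {
    pts <- cv[cv$P > 0 & cv$P >= window[1] & cv$P <= window[2], , drop = FALSE]
    if (nrow(pts) < 2) return(NA_real_)
    w <- if (!is.null(pts$n_risk)) pts$n_risk else rep(1, nrow(pts))
    -unname(coef(lm(log(pts$P) ~ pts$duration, weights = w))[2])
  }
  rate <- fit1(curve)
  if (is.na(rate)) stop("fewer than 2 usable curve points in the fit window")
  se <- NA_real_
  if (!is.null(events) && sum(!events$censored) >= 2) {
    boots <- vapply(seq_len(n_boot), function(b) {
      ev <- events[sample(nrow(events), replace = TRUE), , drop = FALSE]
      if (all(ev$censored)) return(NA_real_)
      fit1(survival_curve(ev))
    }, numeric(1))
    se <- sd(boots, na.rm = TRUE)
  }
  list(rate = rate, se = se, n_points = nrow(curve))
}

#' Native-contact Q-score
#'
#' Fraction of native contacts formed in a frame: a contact counts as
#' formed when the pair distance is below `tolerance` times its native
#' distance (default 1.2). `which` selects intra-chain, inter-chain, or all
#' contacts; `chains` restricts to specific chains (intra) or a specific
#' chain pair (inter).
#'
#' @param system a `cg_system` (its contacts and chain labels), or a
#'   contacts data.frame (`i, j, r0`).
#' @param xyz frame coordinates.
#' @param tolerance distance tolerance factor.
#' @param which "all", "intra", or "inter".
#' @param chains optional chain filter.
#' @return Q in [0, 1].
#' @export
qscore <- function(system, xyz, tolerance = 1.2,
                   which = c("all", "intra", "inter"), chains = NULL) {
  which <- match.arg(which)
  if (inherits(system, "cg_system")) {
    con <- system$contacts
    ch <- system$beads$chain
  } else {
    con <- system
    ch <- NULL
    if (which != "all") stop("chain-based subsets need a cg_system")
  }
  if (!nrow(con)) stop("no native contacts defined")
  if (which == "intra") {
    keep <- ch[con$i] == ch[con$j]
    if (!is.null(chains)) keep <- keep & ch[con$i] %in% chains
    con <- con[keep, , drop = FALSE]
  } else if (which == "inter") {
    keep <- ch[con$i] != ch[con$j]
    if (!is.null(chains))
      keep <- keep & ch[con$i] %in% chains & ch[con$j] %in% chains
    con <- con[keep, , drop = FALSE]
  }
  if (!nrow(con)) stop("contact subset is empty")
  d <- sqrt(rowSums((xyz[con$i, , drop = FALSE] -
                       xyz[con$j, , drop = FALSE])^2))
  mean(d < tolerance * con$r0)
}

#' Reference protein-DNA contact residues
#'
#' Protein beads within `cutoff` of any DNA bead in a reference structure;
#' the reference set for [qscore_protein_dna()].
#'
#' @param system a `cg_system` holding the reference complex coordinates.
#' @param protein_sel,dna_sel bead selections (defaults: all).
#' @param cutoff contact distance, A (default 15).
#' @return integer vector of protein bead indices.
#' @export
crystal_dna_contacts <- function(system, protein_sel = NULL, dna_sel = NULL,
                                 cutoff = 15) {
  if (is.null(protein_sel)) protein_sel <- protein_beads(system)
  if (is.null(dna_sel)) dna_sel <- dna_beads(system)
  frames <- array(system$xyz, c(nrow(system$xyz), 3, 1))
  dmin <- min_dist_series_cpp(frames, protein_sel, dna_sel)
  protein_sel[dmin[1, ] <= cutoff]
}

#' Protein-DNA Q-score (DNA identity neglected)
#'
#' Fraction of reference-contacting protein beads that are within `cutoff`
#' (default 15 A) of ANY DNA bead in the frame. Ignoring which DNA particle
#' is contacted makes the score robust to DNA sliding.
#'
#' @param reference_contacts protein bead indices contacting DNA in the
#'   reference complex (see [crystal_dna_contacts()]).
#' @param xyz frame coordinates.
#' @param dna_sel DNA bead indices in the frame.
#' @param cutoff contact distance, A.
#' @return Q in [0, 1].
#' @export
qscore_protein_dna <- function(reference_contacts, xyz, dna_sel, cutoff = 15) {
  if (!length(reference_contacts)) stop("empty reference contact list")
  if (!length(dna_sel)) return(0)
  frames <- array(xyz, c(nrow(xyz), 3, 1))
  dmin <- min_dist_series_cpp(frames, reference_contacts, dna_sel)
  mean(dmin[1, ] <= cutoff)
}

#' Representative structure by PCA density
#'
#' Per frame, the vector of minimum distances from each binding-site bead
#' to any DNA bead is projected on the first three principal components;
#' the frame with the most neighbours within a radius of 10 (unitless PC
#' space) is the representative (ties: earliest frame).
#'
#' @param trajectory a `cg_trajectory`.
#' @param site_residues protein bead indices of the binding site.
#' @param dna_sel DNA bead indices (default: all DNA beads).
#' @param radius neighbour radius in PC space.
#' @param n_pc number of principal components (default 3).
#' @return list `frame` (index), `counts`, `scores`, `degenerate`.
#' @export
representative_structure <- function(trajectory, site_residues,
                                     dna_sel = NULL, radius = 10, n_pc = 3) {
  if (is.null(dna_sel)) dna_sel <- dna_beads(trajectory$system)
  nf <- dim(trajectory$frames)[3]
  if (nf < 2) stop("need at least 2 frames")
  dmin <- min_dist_series_cpp(trajectory$frames, site_residues, dna_sel)
  if (all(apply(dmin, 2, sd) < 1e-12)) {
    warning("degenerate (constant) distance vectors; returning frame 1")
    return(list(frame = 1L, counts = rep(nf, nf), scores = NULL,
                degenerate = TRUE))
  }
  pc <- prcomp(dmin)
  k <- min(n_pc, ncol(pc$x))
  sc <- pc$x[, seq_len(k), drop = FALSE]
  D <- as.matrix(stats::dist(sc))
  counts <- rowSums(D <= radius)   # includes self, uniformly
  list(frame = which.max(counts), counts = unname(counts), scores = sc,
       degenerate = FALSE)
}

#' Per-residue conservation from a multiple sequence alignment
#'
#' For each non-gap column of the query row, the fraction of sequences
#' whose aligned character equals the query's. With `ignore_gaps = TRUE`
#' (default) gap rows are excluded from the denominator of a column.
#'
#' @param msa alignment: path to an aligned FASTA, a character matrix, or a
#'   named character vector of equal-length aligned sequences.
#' @param query name or row index of the query sequence.
#' @param ignore_gaps exclude gap characters from the denominator.
#' @return data.frame `position` (query residue number), `column`
#'   (alignment column), `residue`, `score`.
#' @export
conservation_profile <- function(msa, query = 1, ignore_gaps = TRUE) {
  if (is.character(msa) && length(msa) == 1 && file.exists(msa)) {
    aln <- bio3d::read.fasta(msa)
    m <- aln$ali
  } else if (is.matrix(msa)) {
    m <- msa
  } else {
    m <- do.call(rbind, strsplit(toupper(msa), ""))
    rownames(m) <- names(msa)
  }
  if (is.character(query)) {
    query <- match(query, rownames(m))
    if (is.na(query)) stop("query row not found in the alignment")
  }
  if (query < 1 || query > nrow(m)) stop("query row out of range")
  m <- toupper(m)
  gap <- m %in% c("-", ".")
  dim(gap) <- dim(m)
  qrow <- m[query, ]
  cols <- which(!gap[query, ])
  score <- vapply(cols, function(cc) {
    col <- m[, cc]; g <- gap[, cc]
    denom <- if (ignore_gaps) sum(!g) else length(col)
    if (denom == 0) return(0)
    sum(col == qrow[cc] & !g) / denom
  }, numeric(1))
  data.frame(position = seq_along(cols), column = cols,
             residue = qrow[cols], score = score, row.names = NULL)
}
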