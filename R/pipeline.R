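#' Predict DNA-binding surfaces by free-binding simulations
#'
#' For each salt concentration: random placement of DNA duplexes around the
#' (centred) protein, a free Langevin run with Debye-Hueckel + excluded
#' volume between protein and DNA, then per-residue contact probabilities,
#' binding-event detection, survival/rate fits and the PCA-density
#' representative frame. Multiple runs per salt are pooled.
#'
#' @param protein a protein `cg_system` (charges assigned).
#' @param dna a duplex `cg_system` (e.g. [build_bdna_duplex()]).
#' @param salts ionic strengths, mol/L (the full protocol uses 0.1, 0.15,
#'   0.2, 0.25, 0.4).
#' @param n_runs runs per salt.
#' @param steps steps per run.
#' @param seed master seed; run r at salt s uses seed + 1000 s + r.
#' @param n_dna DNA copies per run.
#' @param sites named list of site bead-index vectors; `NULL` derives them
#'   from the pooled contact profile ([derive_sites()]).
#' @param charges optional per-bead protein charge override (e.g. a
#'   shuffled set).
#' @param box simulation box edges.
#' @param save_interval frame saving interval.
#' @param d_on,d_off binding-event hysteresis thresholds, A.
#' @param min_separation initial placement separation, A.
#' @return list per salt: `profile`, `events`, `rates` (per site),
#'   `representative`, `trajectories` (last run kept), plus `sites`.
#' @export
run_binding_surface_prediction <- function(protein, dna, salts = c(0.1, 0.4),
                                           n_runs = 4, steps = 2e5, seed = 1,
                                           n_dna = 2, sites = NULL,
                                           charges = NULL,
                                           box = c(90, 90, 90),
                                           save_interval = 500,
                                           d_on = 10, d_off = 15,
                                           min_separation = 15) {
  if (!is.null(charges)) protein$beads$charge <- as.numeric(charges)
  protein$box <- box
  protein <- center_in_box(protein)
  out <- list()
  for (si in seq_along(salts)) {
    salt <- salts[si]
    prof_acc <- NULL; events <- NULL; last <- NULL
    for (r in seq_len(n_runs)) {
      run_seed <- seed + 1000 * si + r
      sys <- place_random_dna(protein, dna, n_copies = n_dna,
                              min_separation = min_separation,
                              seed = run_seed)
      cfg <- simulation_config(steps, save_interval = save_interval,
                               seed = run_seed, boundary = "periodic",
                               electrostatics = electrostatic_params(salt))
      traj <- run_simulation(sys, cfg)
      prof <- contact_probability(traj)
      prof_acc <- if (is.null(prof_acc)) prof else {
        prof_acc$probability <- prof_acc$probability + prof$probability
        prof_acc
      }
      use_sites <- sites
      if (!is.null(use_sites)) {
        ev <- detect_binding_events(traj, use_sites, d_on = d_on,
                                    d_off = d_off)
        if (nrow(ev)) {
          ev$run <- r
          events <- rbind(events, ev)
        }
      }
      last <- traj
    }
    prof_acc$probability <- prof_acc$probability / n_runs
    if (is.null(sites)) {
      use_sites <- derive_sites(prof_acc)
      events <- NULL
      if (length(use_sites)) {
        # replay event detection on the stored final run only
        events <- detect_binding_events(last, use_sites, d_on = d_on,
                                        d_off = d_off)
        events$run <- n_runs
      }
    }
    rates <- list()
    if (!is.null(events) && nrow(events)) {
      for (sn in unique(events$site)) {
        ev <- events[events$site == sn, , drop = FALSE]
        if (any(!ev$censored)) {
          cv <- survival_curve(ev)
          rates[[sn]] <- fit_dissociation_rate(cv, events = ev)
        }
      }
    }
    rep_frame <- NULL
    if (!is.null(sites) && length(sites))
      rep_frame <- tryCatch(
        representative_structure(last, site_residues = sites[[1]]),
        error = function(e) NULL, warning = function(w) NULL)
    out[[as.character(salt)]] <- list(salt = salt, profile = prof_acc,
                                      events = events, rates = rates,
                                      representative = rep_frame,
                                      trajectory = last)
  }
  structure(list(results = out, sites = sites, seed = seed),
            class = "binding_prediction")
}

#' AFM flexible-fitting protocol
#'
#' Repeated restrained runs from a roughly pre-placed start structure (use
#' [rigid_transform()] / [open_toy_hinge()] to pre-place). Per run the
#' final cosine similarity, intra-chain Q-scores, inter-chain Q-score and
#' the coordinate hinge angle are reported; fitted structures are the final
#' frames.
#'
#' @param start_system pre-placed `cg_system` (with `arms` attribute or
#'   explicit selections below).
#' @param reference_image reference `afm_image`.
#' @param kappa fitting strength (dimensionless; 3000 is the
#'   structure-preserving choice at full scale).
#' @param n_runs number of independent runs.
#' @param steps steps per run.
#' @param seed master seed; run r uses seed + r.
#' @param arm_a,arm_b,pivot selections for the hinge angle (defaults from
#'   the `arms`/`pivot` attributes).
#' @param electrostatics optional [electrostatic_params()].
#' @param save_interval frame saving interval.
#' @param boundary boundary condition (reflective keeps the molecule over
#'   the imaged stage).
#' @return list: `runs` data.frame (`run, seed, cs, intra_q, inter_q,
#'   angle`), `structures` (final frames), `system`, `kappa`.
#' @export
run_afm_fitting <- function(start_system, reference_image, kappa,
                            n_runs = 20, steps = 1e5, seed = 1,
                            arm_a = NULL, arm_b = NULL, pivot = NULL,
                            electrostatics = NULL, save_interval = 1000,
                            boundary = "reflective") {
  arms <- attr(start_system, "arms")
  if (is.null(arm_a) && !is.null(arms)) { arm_a <- arms$A; arm_b <- arms$B }
  rows <- list(); structures <- list()
  for (r in seq_len(n_runs)) {
    cfg <- simulation_config(steps, save_interval = save_interval,
                             seed = seed + r, boundary = boundary,
                             electrostatics = electrostatics, kappa = kappa,
                             reference_image = reference_image)
    traj <- run_simulation(start_system, cfg)
    xyz <- traj$frames[, , dim(traj$frames)[3]]
    chains <- unique(start_system$beads$chain)
    intra <- min(vapply(chains, function(ch)
      qscore(start_system, xyz, which = "intra", chains = ch), numeric(1)))
    inter <- qscore(start_system, xyz, which = "inter")
    ang <- if (!is.null(arm_a))
      hinge_angle_from_coords(xyz, arm_a, arm_b, pivot) else NA_real_
    rows[[r]] <- data.frame(run = r, seed = seed + r,
                            cs = tail(traj$cs, 1), intra_q = intra,
                            inter_q = inter, angle = ang)
    structures[[r]] <- xyz
  }
  list(runs = do.call(rbind, rows), structures = structures,
       system = start_system, kappa = kappa)
}

#' Hinge-closure protocol (restraint release)
#'
#' Starting from an open structure with DNA bound at the inner site, the
#' AFM restraint is switched off and the system relaxes under the
#' native-structure-based potential at low salt. Per run: the closure step
#' (first frame with inter-chain Q >= `q_close`), whether the final
#' inter-chain Q reached `q_closed`, and whether the DNA stayed bound
#' (never beyond `d_off` from the inner site up to closure).
#'
#' @param system open `cg_system` including the bound DNA.
#' @param site inner-site protein bead indices.
#' @param n_runs,steps,seed run plan (run r uses seed + r).
#' @param ionic_strength mol/L (closure is run at low salt, default 0.01).
#' @param chains the two protein chains for the inter-chain Q.
#' @param arm_a,arm_b,pivot hinge-angle selections.
#' @param q_close Q threshold defining the closure step.
#' @param q_closed Q threshold defining successful reclosure.
#' @param d_off retention threshold, A.
#' @param save_interval frame saving interval.
#' @param boundary boundary condition.
#' @return list: `runs` data.frame (`run, seed, closure_step, reclosed,
#'   retained, q_final, q_max`), `summary` (mean closure step, retention
#'   fraction, reclosure fraction), `trajectory` (last run).
#' @export
run_closure_protocol <- function(system, site, n_runs = 20, steps = 4e5,
                                 seed = 1, ionic_strength = 0.01,
                                 chains = c("A", "B"), arm_a = NULL,
                                 arm_b = NULL, pivot = NULL, q_close = 0.7,
                                 q_closed = 0.8, d_off = 15,
                                 save_interval = 2000,
                                 boundary = "reflective") {
  arms <- attr(system, "arms")
  if (is.null(arm_a) && !is.null(arms)) { arm_a <- arms$A; arm_b <- arms$B }
  dna <- dna_beads(system)
  rows <- list(); last <- NULL
  for (r in seq_len(n_runs)) {
    cfg <- simulation_config(steps, save_interval = save_interval,
                             seed = seed + r, boundary = boundary,
                             electrostatics =
                               electrostatic_params(ionic_strength))
    traj <- release_restraint_protocol(system, cfg, chains = chains,
                                       arm_a = arm_a, arm_b = arm_b,
                                       pivot = pivot)
    q <- traj$inter_q
    dmin <- apply(min_dist_series_cpp(traj$frames, site, dna), 1, min)
    close_f <- which(q >= q_close)[1]
    closure_step <- if (is.na(close_f)) NA_integer_ else traj$steps[close_f]
    upto <- if (is.na(close_f)) length(dmin) else close_f
    rows[[r]] <- data.frame(run = r, seed = seed + r,
                            closure_step = closure_step,
                            reclosed = max(q) >= q_closed,
                            retained = all(dmin[seq_len(upto)] <= d_off),
                            q_final = q[length(q)], q_max = max(q))
    last <- traj
  }
  runs <- do.call(rbind, rows)
  list(runs = runs,
       summary = list(
         mean_closure_step = mean(runs$closure_step, na.rm = TRUE),
         reclosure_fraction = mean(runs$reclosed),
         retention_fraction = mean(runs$retained & runs$reclosed)),
       trajectory = last)
}

#' Slide-off assay for trapped DNA
#'
#' Free runs from a closed structure with DNA trapped inside, at high salt;
#' binding events at the inner site are tracked until the DNA exits, and
#' the dissociation rate is fitted from the pooled survival curve.
#'
#' @param system closed `cg_system` with trapped DNA.
#' @param site inner-site protein bead indices.
#' @param n_runs,steps,seed run plan.
#' @param ionic_strength mol/L (default 0.4, the weak-binding condition).
#' @param d_on,d_off hysteresis thresholds, A.
#' @param save_interval frame saving interval.
#' @param boundary boundary condition.
#' @return list: `events` (pooled), `curve`, `rate` (`NULL` when every
#'   event is censored), `all_censored`.
#' @export
run_slideoff_assay <- function(system, site, n_runs = 8, steps = 2e5,
                               seed = 1, ionic_strength = 0.4, d_on = 10,
                               d_off = 15, save_interval = 500,
                               boundary = "reflective") {
  events <- NULL
  for (r in seq_len(n_runs)) {
    cfg <- simulation_config(steps, save_interval = save_interval,
                             seed = seed + r, boundary = boundary,
                             electrostatics =
                               electrostatic_params(ionic_strength))
    traj <- run_simulation(system, cfg)
    ev <- detect_binding_events(traj, sites = list(inner = site),
                                d_on = d_on, d_off = d_off)
    if (nrow(ev)) { ev$run <- r; events <- rbind(events, ev) }
  }
  if (is.null(events) || !nrow(events))
    return(list(events = events, curve = NULL, rate = NULL,
                all_censored = NA))
  all_cens <- all(events$censored)
  curve <- suppressWarnings(survival_curve(events))
  rate <- if (all_cens) NULL else fit_dissociation_rate(curve, events = events)
  list(events = events, curve = curve, rate = rate, all_censored = all_cens)
}

#' Plot an AFM image
#'
#' @param x an `afm_image`.
#' @param ... passed to [graphics::image()].
#' @export
plot.afm_image <- function(x, ...) {
  nx <- nrow(x$heights); ny <- ncol(x$heights)
  graphics::image(x$origin[1] + (seq_len(nx) - 0.5) * x$pixel_size,
                  x$origin[2] + (seq_len(ny) - 0.5) * x$pixel_size,
                  x$heights, xlab = "x (A)", ylab = "y (A)", asp = 1, ...)
  invisible(x)
}

#' Plot a survival curve on a log scale
#'
#' @param curve output of [survival_curve()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_survival <- function(curve, ...) {
  keep <- curve$P > 0
  graphics::plot(curve$duration[keep], curve$P[keep], log = "y", type = "s",
                 xlab = "duration (steps)", ylab = "P(bound >= t)", ...)
  invisible(curve)
}
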