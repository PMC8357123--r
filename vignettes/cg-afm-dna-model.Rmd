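---
title: "A coarse-grained model for AFM-guided protein conformations and protein-DNA binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model for AFM-guided protein conformations and protein-DNA binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

hingesim implements a residue-level simulation-and-analysis pipeline for a
recurring problem in single-molecule structural biology: an atomic force
microscope (AFM) shows a conformation of a flexible multi-domain protein --
here, the open state of an SMC-protein hinge dimer -- that no crystal or
cryo-EM structure captures, and one wants (i) a structural model of that
conformation consistent with the image, and (ii) predictions of where
double-stranded DNA binds it, with relative binding strengths.

# The model

**Protein.** One bead per residue at the C-alpha position. Consecutive
residues are connected by stiff harmonic bonds; angles and dihedrals are
restrained harmonically (periodic for dihedrals) about their values in the
reference structure; a structure-based (Go) 12-10 potential

$$U_{\mathrm{Go}}(r) = \varepsilon\left[5\left(\tfrac{r_0}{r}\right)^{12} -
6\left(\tfrac{r_0}{r}\right)^{10}\right]$$

acts between residue pairs in contact in the reference structure (C-alpha
distance below 6.5 A, sequence separation at least 4), with minimum
$-\varepsilon$ at the native distance $r_0$. This biases sampling toward
the reference conformation without forbidding large-scale motion. The full
sequence-based statistical local potentials of AICG2+-class models are
deliberately replaced by these shape-preserving harmonic forms: the
inter-molecular physics of the binding problem rests on electrostatics and
excluded volume, not on the intra-molecular fluctuation spectrum.

**DNA.** Three beads per nucleotide (phosphate, sugar, base) threaded on an
ideal B-form helix (rise 3.38 A, twist 34.3 deg/bp, configurable); the
second strand is generated by the duplex dyad symmetry. The 5'-terminal
phosphate of each strand is omitted (a common CG convention; configurable).
Phosphates carry -0.6 e, the counterion-condensation value. The duplex is
held together by its own Go contacts (depth 2 kcal/mol, cutoff 9 A,
including nearest-neighbour stacking pairs); there is no melting model and
no sequence-dependent shape -- the duplex is a shape-stable charged rod, which
is exactly its role in the binding problem.

**Protein-DNA interactions** are screened electrostatics plus excluded
volume only. The Debye-Hueckel pair energy is

$$U_{ij} = \frac{332.0637\,q_i q_j}{\varepsilon_k\, r_{ij}}
  e^{-r_{ij}/\lambda_D}\ \mathrm{kcal/mol},\qquad
\lambda_D = \sqrt{\frac{\varepsilon_0 \varepsilon_k k_B T}{2 N_A e^2 I}}$$

with $\varepsilon_k = 78$ fixed, truncated at $5\lambda_D$ with an energy
shift; 1-2 and 1-3 bonded neighbours are excluded. At 100 mM and 300 K,
$\lambda_D = 9.62$ A. Excluded volume is a purely repulsive
$\varepsilon[(\sigma/r)^{12}-1]$ below $\sigma = r_i + r_j$, zero beyond;
native-contact pairs are exempt (the Go well carries its own core).

**Surface charges.** Rather than unit charges on charged residues,
`respac_fit_charges()` fits partial charges on surface beads by constrained
ridge least squares so the Debye-Hueckel potential they generate reproduces
a reference electrostatic potential sampled around the molecule, with the
total charge fixed exactly. Surface beads are identified by a sampling
heuristic (any bead within 12 A of a sample point; configurable). The
`shuffle_charges()` control scrambles the charge arrangement -- a uniform
permutation of the per-bead charge vector, relocating the charges to random
positions -- to test whether a predicted binding surface is dictated by
where the charges sit.

**AFM restraint.** The flexible-fitting potential is

$$V_{\mathrm{AFM}}(\mathbf R) = \kappa\, k_B T\, (1 - \mathrm{c.s.}(\mathbf R)),
\qquad
\mathrm{c.s.} = \frac{\sum_p H^{\mathrm{exp}}_p H^{\mathrm{sim}}_p}
{\sqrt{\sum_p (H^{\mathrm{exp}}_p)^2}\sqrt{\sum_p (H^{\mathrm{sim}}_p)^2}}$$

where the pseudo-image $H^{\mathrm{sim}}$ is rendered from the coordinates.
Rendering is a tip model: a bead at lateral distance $d$ from a pixel
centre contributes an effective height $z + r - d^2/(2s)$ (parabolic cap of
radius $s$, default half a pixel). The `"hard"` mode takes the maximum
(clipped at the stage, height 0); the `"soft"` mode used inside the
restraint takes a log-sum-exp with sharpness $\beta$ (default 2/A), which
is smooth in the coordinates, converges to the hard maximum as $\beta$
grows, and yields analytic forces by the chain rule through the pixel
heights and the cosine similarity. If the molecule leaves the imaged
region (all-zero pseudo-image) no force is applied and the frame is
flagged. $\kappa$ is dimensionless: at full scale, 10 barely biases, 3000
fits while preserving subunit structure, 10000 fits at the cost of
distortion.

**Dynamics.** Underdamped Langevin dynamics, friction 0.843 per CG time
unit and timestep 0.2 (the standard settings for this model class), via a
BAOAB splitting whose friction-noise substep is the exact
Ornstein-Uhlenbeck update; it reduces to velocity Verlet as friction goes
to zero, and the stability bound (friction x dt < 2) is enforced. Masses
are uniform (10 CG units) -- the model makes no claim about real time, so
all rates are reported per step, and the mass merely sets the diffusive
time scale; a smaller mass makes the toy systems relax in fewer steps at
identical equilibrium statistics. Boundaries are periodic (minimum-image
wrapping inside pair interactions, unwrapped coordinates stored),
reflective (for fitting runs over a stage), or open.

# Trajectory analyses

* `contact_probability()`: per-residue fraction of frames with any DNA bead
  within 10 A (cutoff configurable, recorded in the output attributes).
* `detect_binding_events()`: a DNA molecule binds a site when its minimum
  distance to the site beads drops below 10 A and unbinds above 15 A; the
  hysteresis prevents boundary chatter from fragmenting events; events
  still bound at the last frame are right-censored.
* `survival_curve()` / `fit_dissociation_rate()`: Kaplan-Meier estimate of
  P(bound >= t) and a weighted least-squares slope of ln P over
  P in [0.1, 1]; rate = -slope, per step; standard error by bootstrap over
  events.
* `qscore()`: fraction of native contacts with distance below 1.2x their
  native value; intra-chain (structural integrity) and inter-chain
  (dimer closure) variants. `qscore_protein_dna()`: fraction of
  reference-contacting protein residues within 15 A of ANY DNA bead --
  neglecting DNA-bead identity makes the score robust to DNA sliding.
* `representative_structure()`: per frame, the vector of minimum
  site-residue-to-DNA distances is projected on the first three principal
  components; the frame with the most neighbours within radius 10
  (unitless PC space) is representative; ties go to the earliest frame.
* `measure_hinge_angle()`: finds the highest pixel of the hinge blob, sums
  heights in a 10 x 5-pixel parallelogram extending radially over a
  1-degree direction grid, takes the two local maxima at least 20 degrees
  apart, and returns the angle between them. Three numerical refinements
  matter at pixel scale and are part of this implementation: the apex is
  refined to the sub-pixel height-weighted centroid of the summit (a
  half-pixel apex error otherwise skews apparent directions by several
  degrees); the disc of radius equal to the parallelogram width around the
  apex is excluded from the arm sums (it belongs to the junction blob and
  otherwise biases both arms inward); each selected direction is refined to
  the circular centroid of its peak plateau (the plain sums plateau under
  discretization). A direction only counts as an arm if its parallelogram
  carries at least two apex-heights of summed mass; a featureless blob
  therefore reports "arms not resolved". With these choices the
  synthesis-measurement loop closes to within 1 degree over 40-170 degrees.
* `fit_angle_mixture()`: two-component Gaussian mixture
  (maximum-likelihood EM via mclust, deterministic model-based
  initialization) for resolving closed and open states in an angle
  distribution; `median_filter()` (window 5) for angle time series.
* `conservation_profile()`: per query residue, the fraction of aligned
  sequences with the query's character; gap rows are excluded from the
  denominator by default. The score is query-identity fraction -- simple,
  monotone, and sufficient for mapping conserved patches onto structures.

# Synthetic study systems

The generators produce every input the pipeline needs, with ground truth
embedded as attributes, so the full build-simulate-analyze loop is testable
without any external data.

`make_toy_hinge()` is the stand-in for a two-subunit hinge: two chains,
each a stiff hairpin arm (10 beads per strand, 3.8 A spacing, closed at
both ends) whose first out-strand beads interdigitate near the origin --
the junction. Inter-chain contacts exist only there, so opening one chain
about the junction breaks inter-arm contacts while intra-arm contacts
persist, mirroring inter- versus intra-subunit Q-scores. The native
inter-arm angle is 30 degrees (closed state); positive unit charges sit on
the three inner-face beads of each arm base (the DNA-binding patch).
Defaults were set once, from stability requirements that define what the
toy is: intra-arm wells of 1.8 kcal/mol and angle stiffness 25
kcal/mol/rad^2 make an isolated arm hold intra-arm Q >= 0.95 in >  99% of
equilibrium frames (a "subunit" whose integrity score is meaningful), and
an inter-chain interface of 4 kcal/mol per contact keeps the closed dimer
stable at low salt against a bound DNA competitor -- real SMC hinge dimers
are stable nanomolar dimers. For this 42-bead toy the restraint scale that
fits without distortion is kappa ~ 150, and overdriving by two to three
orders of magnitude (kappa ~ 60000) is what visibly distorts the arms; the
full-size/toy kappa values differ because kappa multiplies a global,
size-intensive similarity deficit while the opposing elastic cost scales
with the moved substructure.

`synth_afm_image()` draws two Gaussian-cross-section rod ridges meeting at
the grid centre at a controlled angle, plus (by default) a brighter
junction blob that guarantees the image apex sits on the junction, as real
hinge blobs do; additive Gaussian noise, clipped at zero. For
flexible-fitting references the blob is turned off (`junction_boost = 1`):
an artificial central mass would pull both fitted arms inward by ~10
degrees. Arm length defaults to 14 pixels so that arms fill the
metrology parallelogram with margin, as real coiled-coil arms (~50 nm at
1.875 nm/pixel) do.

`synth_dwell_times()` draws exponential dwell times with optional
right-censoring; `make_toy_patch_protein()` is a 27-bead lattice globule
with a +6 e face patch used for binding-surface prediction and salt
screening.

What passing on these toys does and does not show: it validates the
energetics, the integrator, the restraint calculus, and every analysis
against exact constructions and brute-force oracles, and it shows the
protocol logic (fit, release, bind, screen) behaves as designed under
conditions where the answer is known. It does not show that the simplified
local potentials reproduce real protein fluctuation spectra, that real AFM
noise (scars, tip convolution artefacts, drift) is handled, or that rates
per step map to seconds.

# Numerical choices

* Harmonic forms: bond $U = k(r-r_0)^2$, angle $U = k(\theta-\theta_0)^2$,
  dihedral $U = k(1 - \cos(\phi - \phi_0))$; near-collinear angle triples
  are regularized ($\sin\theta$ floored), and dihedrals whose interior
  triple is within ~15 degrees of collinear are dropped at topology-build
  time -- their forces are genuinely singular there, and straight rod
  segments otherwise detonate.
* Chain breaks in PDB input: a residue-number gap or a C-alpha step above
  4.5 A ends the bonded run; no bonded terms cross a break. Altlocs are
  resolved by highest occupancy.
* The Debye-Hueckel cutoff ($5\lambda_D$) is energy-shifted, not
  force-shifted: energies are continuous, the residual force discontinuity
  at the cutoff is below 1e-3 of the contact-scale forces.
* Per-bead forces are capped at 500 kcal/mol/A inside the integrator --
  two orders of magnitude above normal force scales, so ordinary
  trajectories are untouched, while a rare thermal overshoot into an
  $r^{-12}$ core is damped out instead of detonating the run.
* Tie-breaks are deterministic everywhere (earliest frame, lowest index).
* One master seed per protocol; run r uses seed + r; every output records
  its seed, and identical seeds give bit-identical trajectories.
* Problem sizes used by the tests and the acceptance script: 30-bead coils
  for force checks, 1e6-step dumbbell runs for the thermostat, 20 x 6e4-step
  fitting runs, 20 x 1e5-step closure runs, and 2 x 4 x 2.5e5-step binding
  runs with an 8-bp duplex -- sizes at which every protocol-level claim is
  reproduced from scratch in minutes on one core.

# Known limitations

* Intra-molecular potentials are simplified (no sequence-based statistical
  local terms, no base-pairing/stacking thermodynamics); conclusions should
  rest on inter-molecular electrostatics + excluded volume, which is what
  the pipeline models faithfully.
* No explicit ions, no Poisson-Boltzmann solver: reference potentials for
  the charge fit are inputs (or synthetic).
* The tip model is a parabolic cap; real tip shapes and tapping mechanics
  are out of scope.
* Rates are per simulation step; the step-to-time mapping is undefined.
* The conservation score is query-identity fraction; alignments are inputs
  (no homology search).
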