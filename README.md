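# hingesim

Coarse-grained Langevin dynamics and analysis for AFM-guided protein
conformations and protein–DNA binding, in R.

## The problem

Flexible multi-domain proteins — the motivating case is the hinge dimer of
an SMC chromosome-organizing complex — adopt conformations in
high-speed AFM movies that no crystal or cryo-EM structure captures. Given
a height image of such a conformation, a reference ("native") structure of
the closed state, and a DNA sequence, this package

1. builds residue-level (one bead per C&alpha;) protein models and
   three-bead-per-nucleotide B-form DNA duplexes,
2. runs structure-based (Gō) Langevin dynamics in which protein and DNA
   interact only through Debye–Hückel screened electrostatics and excluded
   volume, with surface charges fitted to reproduce a reference
   electrostatic potential (RESPAC-style),
3. flexibly fits the model into the AFM image through a differentiable
   restraint `V = κ·k_B·T·(1 − c.s.)`, where `c.s.` is the cosine
   similarity between the experimental image and a pseudo-AFM image
   rendered from the coordinates, and
4. quantifies the results: per-residue DNA-contact probabilities,
   binding-event detection with hysteresis, Kaplan–Meier survival curves
   and dissociation rates (per step), intra-/inter-subunit and protein–DNA
   Q-scores, PCA-density representative structures, image-based hinge-angle
   metrology with a two-Gaussian mixture fit, and conservation mapping from
   an alignment.

Synthetic generators (a toy two-armed hinge, pseudo-AFM reference images,
exponential dwell times, a charged-patch globule) make the full pipeline
testable with no external data.

## Core model

Bonded terms are harmonic about the reference structure; native contacts
use a 12–10 well `ε[5(r₀/r)¹² − 6(r₀/r)¹⁰]`; electrostatics is

    U_ij = 332.0637 q_i q_j exp(−r/λ_D) / (ε_k r)   kcal/mol,
    λ_D  = sqrt(ε₀ ε_k k_B T / (2 N_A e² I))

with ε_k = 78 and a 5λ_D shifted cutoff; integration is BAOAB Langevin
(friction 0.843, timestep 0.2, CG units). Energies are kcal/mol, lengths
Å, charges in e. See the methods vignette
(`vignettes/cg-afm-dna-model.Rmd`) for every default and the reasoning
behind it.

## Worked example

```r
library(hingesim)

hinge <- make_toy_hinge()          # two-armed toy hinge, closed at 30 deg
open  <- open_toy_hinge(hinge, 49) # rotate one subunit about the junction
arms  <- attr(hinge, "arms")

hinge_angle_from_coords(hinge, arms$A, arms$B, attr(hinge, "junction"))
hinge_angle_from_coords(open,  arms$A, arms$B, attr(hinge, "junction"))
qscore(hinge, open$xyz, which = "inter")   # dimer interface lost
qscore(hinge, open$xyz, which = "intra")   # subunits intact

img <- synth_afm_image(79)                 # synthetic two-arm height map
measure_hinge_angle(img)                   # image-based metrology

dw  <- synth_dwell_times(rate = 1e-3, n = 1000, seed = 2)
fit_dissociation_rate(survival_curve(dw), events = dw)

debye_length(0.1)                          # A, at 300 K, eps_k = 78
```

prints

```
inter-arm angle (closed): 30 deg
inter-arm angle (open):   79 deg
inter-subunit Q after opening: 0
intra-subunit Q after opening: 1
measured hinge angle: 78.2 deg
fitted rate: 0.000966 +/- 3.5e-05 per step
Debye length at 100 mM: 9.62 A
```

Opening the toy hinge breaks exactly the inter-subunit contacts (Q drops
to 0) while each arm stays native (Q = 1); the image metrology recovers
the constructed 79° angle to about a degree; the survival fit recovers the
known 10⁻³/step dissociation rate within its bootstrap error.

The protocol drivers compose these pieces: `run_afm_fitting()` (restrained
runs scored by c.s. and Q), `run_closure_protocol()` (restraint release
and reclosure with DNA retention), `run_binding_surface_prediction()`
(free binding across salt concentrations) and `run_slideoff_assay()`
(trapped-DNA escape).

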