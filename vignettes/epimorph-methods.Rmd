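---
title: "epimorph: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epimorph: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what is being
modelled, which knobs matter, what the synthetic world does and does not
emulate, and where genuinely open design questions were settled.

# 1. The measurements

## Zigzag index

A junction *side* is the polyline between two tricellular vertices of the
cell mosaic.  For a set of sides the zigzag index is the **ratio of sums**

$$Z = \frac{\sum_i L_{TJ,i}}{\sum_i L_{St,i}},$$

with $L_{TJ}$ the traced path length and $L_{St}$ the vertex-to-vertex
chord.  The ratio-of-sums (rather than the mean of per-side ratios) weights
long sides more and is invariant to how a side is subdivided; it is always
$\ge 1$ and equals 1 exactly for straight mosaics.  Sampling follows the
assay's convention: square windows of 840 µm² (side ≈ 28.98 µm) placed
uniformly at random, five windows per sample; a side belongs to a window iff
**both** its vertices lie inside, and sides touching the field border are
never eligible.  Window indices are averaged into a per-sample value;
samples are summarized per clone as mean ± SE; clones are compared with a
two-sided pooled-variance Student's *t*-test at α = 0.05.

Open points settled here: the window is square (the assay states only an
area); windows may overlap; "contained in the window" is read literally as
both endpoints inside (a midpoint rule would admit sides lying mostly
outside); the straight reference line runs vertex-to-vertex.

## Barrier physiology

With solution A (140 mM NaCl, 5 KCl, 1 MgCl₂, 1 CaCl₂, plus non-ionic
ballast) apical and solution B (70 mM NaCl, 130 sucrose, otherwise
identical) basolateral, the dilution potential of a monolayer with relative
permeabilities β = P_Na/P_Cl and κ = P_K/P_Cl is taken as the
monovalent-ion Goldman–Hodgkin–Katz form

$$V = \frac{RT}{F}\,\ln\frac{\beta\,[Na]_{ap} + \kappa\,[K]_{ap} + [Cl]_{bl}}
                            {\beta\,[Na]_{bl} + \kappa\,[K]_{bl} + [Cl]_{ap}},$$

apical minus basolateral, after blank subtraction.  Divalent cations enter
only through their Cl⁻ counter-ions (so [Cl] totals are NaCl + KCl + 2MgCl₂ +
2CaCl₂); glucose, sucrose and HEPES are treated as electro-neutral ballast;
concentrations are used rather than activities (the simpler reproducible
default — an activity-coefficient table can be applied upstream by scaling
the concentrations).  K⁺ is tied to Na⁺ (κ = β) by default, in which case
the inversion for β is closed-form; a decoupled κ falls back to bracketed
root finding (`uniroot` on log β over [10⁻⁸, 10⁸], argument tolerance
1e-15).  The inversion demands the corrected potential lie strictly inside
the two Nernst limits and names those limits in its error otherwise.

Absolute permeabilities come from the Kimizuka–Koketsu conductance
relation

$$P_{Na} + P_{Cl} = \frac{RT}{F^2\,\mathrm{TER}\,C},\qquad
  P_{Na} = \frac{\beta}{1+\beta}(P_{Na}+P_{Cl}),$$

with $C$ the symmetric-side NaCl concentration (140 mM → 1.4·10⁻⁴ mol/cm³)
— the assumed reference, configurable.  Units contract: TER in Ω·cm², C in
mol·cm⁻³, permeabilities in cm·s⁻¹; F = 96485 C/mol, R = 8.314 J/(mol·K),
T defaults to 310.15 K.

Tracer flux uses the sink assumption (apical concentration ≪ C₀ = 0.2 mM),
making the transferred amount linear, Q(t) = P_app·A·C₀·t.  Raw
fluorescence is converted through an ordinary-least-squares standard curve,
and P_app = slope/(A·C₀) with the slope converted from nmol/h to mol/s.  A
negative fitted slope is returned signed, with a warning — clamping would
bias summaries of noisy low-permeability monolayers.

# 2. The synthetic world

`monolayer_spec()` states the world: a Poisson-disc seeded Voronoi mosaic
clipped to the field, each interior edge replaced by a sinusoidal
perpendicular displacement with an integer number of periods so the
endpoints stay pinned at the vertices.  The sinusoid was chosen over a
random-walk tortuosity because it gives analytic control: the truth index
is a monotone function of amplitude at fixed wavelength, and the truth
network *is* the polyline set, so ground truth is exact by construction.

Defaults and why:

| parameter | default | rationale |
|---|---|---|
| field, cells | 120 × 120 µm, 220 | ≈ 65 µm² cells, confluent MDCK II scale |
| `pixel_size_um` | 0.1 | high-zoom 63× confocal sampling; not stated by the assay, a package choice |
| `junction_width_um` | 0.25 | junction-marker belt width at TJ level |
| `psf_sigma_um` | 0.12 | confocal lateral PSF |
| `tortuosity_wavelength_um` | 3 | sawtooth period visible in wild-type MDCK junctions |
| `background_level`, `junction_level`, `noise_sd` | 10, 100, 2 | ~45:1 peak SNR, routine confocal |
| `myosin_mode = "two_row"`: offset 0.5 µm, spacing 0.5 µm, σ 0.15 µm | | puncta rows flanking the junction, resolvable at the default PSF |
| `min_edge_um` | 0.8 | interior Voronoi edges shorter than this are contracted to one vertex: random tessellations contain near-degenerate vertices whose separations are below imaging resolution, which no tracer (manual or automatic) could resolve |

Noise is additive Gaussian on the blurred render (Poisson shot noise is
available behind `shot_noise = TRUE` but off by default; recovery tests do
not need it).  All randomness flows from one seed per spec; identical spec
+ seed gives bit-identical images and truth.

The electro and flux generators run the *same* forward relations the
analysis inverts, so noiseless datasets invert exactly — that round trip is
an internal-consistency check, not evidence about real epithelia.
Measurement noise defaults are instrument-resolution scale (0.5 Ω, 0.1 mV:
a volt-ohm meter reading a stable insert repeatedly).  This matters for the
unbiasedness check: inversions involving 1/TER and exp(VF/RT) are convex,
so any noise creates an O(σ²) Jensen bias; at instrument-scale noise that
bias is far below one measurement SD, making "mean error < half a
replicate SE over 1000 replicates" a test of estimator correctness rather
than of noise folklore.  The flux default samples every 10 min for 5 h
(30 points, kinetic plate-reader style).  The single 1-h endpoint of the
classic protocol is supported (a lone point is fit through the origin), but
a criterion of the form "within 3 fitted SEs in ≥ 99% of replicates" is a
statement about *t*-tail mass: slope errors are t-distributed with n − 2
degrees of freedom, and P(|t| < 3) only exceeds 0.99 for roughly n ≥ 16, so
the stated world uses a kinetic series for which the criterion is a fair
test of the estimator.

What the generator does **not** emulate: uneven illumination and
vignetting, intensity variation along junctions, cytoplasmic background
structure, 3-D stacks (single plane only), cell-size heterogeneity beyond
Poisson-disc spacing, real (non-sinusoidal) junction waviness, and any
mechanical origin of tortuosity — amplitude is imposed geometrically, not
emergent from junctional tension.  A green test therefore establishes that
the measurement pipeline is correct on images whose degradation model is
known; it does not validate segmentation on arbitrary real micrographs.

# 3. Extraction numerics

`segment_junctions()` subtracts a constant (median) background by default
(rolling-mean available), thresholds with Otsu (fixed value available) and
removes connected components under 20 px.  An empty foreground is an error
that names the threshold used.

`extract_network()` thins the mask (Zhang–Suen), then must decide which
skeleton pixels are junction nodes.  The textbook crossing-number criterion
(≥ 3 dark–bright transitions around a pixel) fails on a systematic thinning
artifact: at shallow-angle Y-junctions the skeleton forms a *doubled
staircase* in which every pixel sees exactly two transitions, so whole
junctions vanish and two sides merge into one V-shaped path.  The package
instead uses a geometric criterion: cell interiors (background components,
noise holes under 30 px excluded) are dilated across the ridge until their
fronts meet at the centerline, and a skeleton pixel with ≥ 3 distinct cell
labels within 2 px is a node.  Every meeting point of three cells produces
a node by construction.  For masks with no resolvable cells (synthetic line
patterns), the crossing-number rule remains as a fallback.

Remaining steps: node pixels within 3 px fuse into one vertex (centroid);
node neighbourhoods are cut out so arms separate; each branch component is
ordered by the shortest pixel-graph path between its two most distant
endpoints (double-BFS when the doubled staircase leaves no degree-1 pixel),
which also discards redundant staircase pixels; terminal spurs under 1 µm
are pruned; node-to-node stubs with chords under 0.6 µm are contracted
(mirroring the generator's 0.8 µm edge collapse); traced polylines are
smoothed with a Gaussian of σ = 0.6 px, endpoints pinned; sides passing
within 3 px of the image edge are flagged `border`.  Closed rings touching
no node are dropped and counted.

The smoothing σ is the one genuinely tuned analysis constant, and it trades
two biases: the raw 8-connected staircase *inflates* traced length (≈ +5%
on straight mosaics), while smoothing *attenuates* genuine oscillation
(crest rounding).  σ = 0.6 px was calibrated once against noiseless
synthetic benchmarks as the best compromise across truth indices 1.0–1.65;
the acceptance suite pins the resulting accuracy (straight mosaics ≤ 1.02;
within 5% of truth up to ≈ 1.65, ordering preserved, rotation-stable to
< 1%).  The residual signed bias — slightly positive for straight, a few
percent negative at high tortuosity — is a known limitation; comparisons
between conditions measured with the same settings are unaffected in
ordering.

Line scans sample channels by bilinear interpolation at half-pixel steps,
averaging across a perpendicular breadth; transverse profiles are
classified by counting local maxima with prominence ≥ 20% of the profile
range (robust to the default noise; configurable), giving
`none` / `single_peak` / `double_peak` — the readout separating continuous
junctional myosin from the knockout-style two-row punctate phenotype.

# 4. Statistics and degenerate inputs

The pooled-variance Student test is the default (the assay names Student's
*t*-test); Welch is available behind `var_equal = FALSE`.  Testing is
two-sided; no multiple-testing correction is applied (matching the assay;
the pipeline report notes this).  Zero pooled variance with equal means
returns t = 0, p = 1 by convention; with unequal means it is an error.
Zigzag summaries use SE, barrier summaries use SD — each figure
convention's own presentation.

Degenerate-input conventions: sides whose vertices coincide (loops) are
excluded from morphometry with a logged message; empty side sets, empty
masks, blank images, potentials outside the Nernst interval, non-positive
calibration slopes and oversized windows are errors; windows containing no
eligible side are re-drawn up to 100 times before erroring.

# 5. Limitations

* Ground truth exists only for the synthetic world; accuracy on real
  micrographs depends on segmentation quality that this package cannot
  certify.
* The skeleton tracer under-reads very tortuous junctions (few percent at
  index ≈ 1.65) and is not intended beyond index ≈ 1.8 at 0.1 µm pixels.
* GHK/Kimizuka–Koketsu forms are the standard dilution-potential
  conventions (monovalent ions, concentrations, symmetric reference);
  monolayers dominated by divalent conductances would need a different
  model.
* No time-lapse tracking, no Ussing-chamber circuit modelling, no
  liquid-junction corrections beyond blank subtraction, single-plane images
  only.
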