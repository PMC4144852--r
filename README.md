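# epimorph

Epithelial junction morphometry and tight-junction barrier physiology, with a
fully synthetic validation world.

## The problem

In confluent epithelial monolayers (MDCK cells being the canonical model),
the shape of cell–cell junctions carries biology: scaffold proteins such as
ZO-1 control whether the apical junction belt is tortuous ("zigzag") or
straight, and tight-junction composition sets the paracellular barrier.  Two
families of measurements quantify this:

1. **Junction-shape morphometry.** From a fluorescence image of a junction
   marker, trace every junction *side* (the segment between two tricellular
   vertices) and compute the **zigzag index**

   `zigzag index = Σ L_TJ / Σ L_St`

   over all sides contained in a sampled analysis window (840 µm² is the
   field-standard area, five random windows per sample), where `L_TJ` is the
   traced path length of a side and `L_St` its straight vertex-to-vertex
   chord.  A straight mosaic gives exactly 1; more tortuous junctions give
   larger values.  Window indices are averaged per sample and samples are
   summarized as mean ± SE per clone, compared by Student's *t*-test.

2. **Barrier physiology.** Transepithelial resistance, blank-subtracted and
   area-scaled (`TER = (R_raw − R_blank)·A`, Ω·cm²); charge selectivity
   `β = P_Na/P_Cl` obtained by inverting the Goldman–Hodgkin–Katz dilution
   potential measured across an apical 140 mM / basolateral 70 mM NaCl
   gradient,

   `V = (RT/F)·ln[(β[Na]_ap + κ[K]_ap + [Cl]_bl) / (β[Na]_bl + κ[K]_bl + [Cl]_ap)]`;

   absolute permeabilities from the Kimizuka–Koketsu conductance relation,
   `P_Na + P_Cl = RT/(F² · TER · C_NaCl)` split as `β:(1)`; and tracer
   apparent permeability `P_app = (dQ/dt)/(A·C₀)` from a FITC-dextran flux
   series with a linear fluorescence standard curve.

Because real confocal data for this assay are rarely deposited, `epimorph`
ships a **synthetic-data module**: Voronoi cell mosaics whose junctions are
decorated with controllable sinusoidal tortuosity (plus an optional myosin
channel rendered continuously or as the knockout-style *two rows* of
puncta), rendered into confocal-like images with PSF blur and noise — with
the exact ground-truth network attached — and simulated electrophysiology /
flux datasets generated through the same forward relations the analysis
inverts.  Every stage of the pipeline is therefore testable against exact
truth.

## Worked example

```r
library(epimorph)

# simulate a small monolayer with tortuous junctions and known ground truth
spec <- monolayer_spec(field_width_um = 60, field_height_um = 60,
                       n_cells = 55, tortuosity_amplitude_um = 0.56,
                       noise_sd = 2, seed = 11)
img <- generate_monolayer(spec)
img
#> synthetic_image: channels [junction], 600 x 600 px, 0.1 um/px
#> junction_network: 104 vertices, 158 sides (56 border), field 60 x 60 um

# measure it exactly as a real image would be measured
mask <- segment_junctions(img)
net  <- extract_network(mask, img$pixel_size_um)
wz   <- window_zigzag(net, window_area_um2 = 840, n_windows = 5, seed = 11)
round(wz$indices, 3)
#> [1] 1.275 1.274 1.289 1.283 1.262
wz$n_sides_total
#> [1] 126
pooled_zigzag_index(img$truth)   # exact generator truth
#> [1] 1.301011

# barrier physiology from a simulated dilution-potential experiment
es  <- electro_spec(true_P_Na = 1.5e-5, true_P_Cl = 2e-6, seed = 11)
res <- analyze_electro(generate_electro_dataset(es))
round(colMeans(res[c("TER_ohm_cm2", "beta")]), 2)
#> TER_ohm_cm2        beta
#>      116.44        7.42
signif(colMeans(res[c("P_Na_cm_s", "P_Cl_cm_s")]), 3)
#> P_Na_cm_s P_Cl_cm_s
#>  1.50e-05  2.02e-06

# tracer flux
flux <- generate_flux_dataset(flux_spec(true_P_app = 1e-6, seed = 11))
signif(analyze_flux(flux)$P_app_cm_s, 3)
#> [1] 1e-06
```

The five window indices scatter around the pipeline's estimate of the truth
index 1.301 (the ~2–3 % shortfall is the documented smoothing/skeleton bias
of the tracer; see the methods vignette).  More than 80 sides pooled over
five windows matches the analysis scale of the original assay.  The
recovered β = 7.42 ± measurement noise brackets the true P_Na/P_Cl = 7.5,
and noiseless simulations invert exactly.

A report-style orchestration (`run_pipeline(config)`) simulates several
clones, measures them, runs the clone comparisons and writes JSON + CSV
outputs; a thin CLI (`exec/epimorph`) exposes `simulate`, `measure`,
`barrier` and `report` subcommands.

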