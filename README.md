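# periomap

Porosity-weighted diffusion mapping and viability analytics for
tooth-in-situ organ culture.

An intact tooth cultured in its bony socket is fed by diffusion alone, so
the central question for such an organ-culture system is *where the medium
cannot easily go*. `periomap` answers it from a single CT-like greyscale
slice:

1. **Porosity calibration.** Greyscale is proportional to mineral density,
   so intensity is mapped linearly between two endpoints — air (porosity
   100%) and dense cortical bone (porosity 0%):
   `φ(g) = clamp((g_cort − g) / (g_cort − g_air), 0, 1)`.
2. **Porosity-weighted geodesic map.** From each medium inlet (two points
   at the junctional epithelium, one at the inferior alveolar canal) every
   pixel gets the minimum over permeable paths of
   `Σ step_length (mm) / φ(destination pixel)` — an effective tissue depth
   in which a millimetre of dense bone counts for several contour bands.
   Computed as an exact Dijkstra shortest path on the 8-connected pixel
   graph; per-inlet maps are combined by per-pixel minimum and quantized
   into 1 mm contour bands; the slowest decile is flagged as the
   hard-to-reach region.
3. **In-silico ink test.** An explicit finite-difference solution of
   `∂c/∂t = ∇·(D(x)∇c)` with `D = D0·φ`, harmonic-mean interface
   diffusivities and Dirichlet sources at the inlets; first-arrival times
   over an 18 h window are compared to the map by Spearman rank
   correlation.

Around the map the package implements the culture system's analytics:
XTT viability per gram (`(A450 − A690)/g/mL`), glucose consumption per gram
per day, histomorphometry field summaries with ANOVA + Tukey HSD group
comparison, the bioreactor chewing-cycle force waveform (10 pre-cycles −5
to −45 N at 0.25 Hz, then 1,400 cycles −5 to −100 N at 1 Hz), and seeded
generators for a labelled molar-in-mandible phantom and synthetic assay
tables, so the whole pipeline runs with no external data.

## Worked example

```r
library(periomap)

pipe <- run_perfusion_pipeline()   # phantom -> porosity -> maps -> sim
pipe$map
#> <diffusion_map> (porosity-weighted) 256 x 256 pixels, 0.0492 mm/pixel, band width 1 mm
#>   3 inlet(s); 34.9% reachable; cost range [0.00, 107.30] effective mm; max band 108
pipe$comparison
#> <map_sim_comparison> Spearman rho = 0.974 on 22002 mutually reached pixels
#>   reached only in map: 902; only in simulation: 0
#>   slow-region Jaccard overlap (q = 0.90): 0.706
```

The combined map reaches 34.9% of the slice (the tissue; air, tooth and
cortical shell are excluded or blocked), with effective depths up to
107 mm inside the densified interradicular septum. The simulated tracer
ranks pixels almost identically to the static map (ρ = 0.974), and the two
slowest-decile masks overlap with Jaccard 0.71. The slow mask covers the
root-bifurcation zone (671 px) and the deep trabecular rim behind the
cortical shell (553 px) — the regions such a culture is most likely to
starve.

Assay arithmetic on hand-held numbers:

```r
xtt_score(0.75, 0.05, tissue_weight = 0.5, pooled_volume = 1.5)
#> [1] 0.9333333        # absorbance / g / mL
glucose_consumption(100, 80, medium_volume = 50,
                    tissue_weight = 2, days_in_culture = 4)
#> [1] 1.25             # mg glucose / g / day
w <- render_waveform(default_regime(), sample_rate = 100)
c(nrow(w) / 100, count_cycles(w, "pre_cycle"), count_cycles(w, "main"))
#> [1] 1440   10 1400   # seconds, pre-cycles, main cycles
```

## Analysis workflow

The `analysis/` scripts run the study end to end, writing tables and images
under `results/`:

| script | what it does |
|---|---|
| `01_phantom.R` | generate and export the labelled phantom slice + inlets |
| `02_porosity.R` | endpoint estimation and porosity calibration |
| `03_diffusion_map.R` | per-inlet and combined weighted maps, contour bands, slow regions |
| `04_perfusion_sim.R` | tracer simulation, map-vs-simulation concordance, threshold sensitivity |
| `05_assays.R` | XTT / glucose / histomorphometry analytics and group comparisons |
| `06_loading.R` | chewing waveform rendering and cycle verification |

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

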