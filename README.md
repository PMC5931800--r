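# dscircuit

Quantification of direction-selective (DS) retinal circuit structure and
function, for experimenters and modelers who need the standard battery of
measurements on this circuit as tested, scriptable R functions:

* **ooDSGC physiology** — direction selectivity index (DSI), von Mises
  tuning-curve fits, circular-SD tuning width, cosine-weighted tuning
  strength, ON/OFF response segmentation and ON-OFF preferred-direction
  difference (Δϕ); DSI-histogram mixture gating, ooDSGC isolation,
  cardinal-subtype clustering, spike-train quality control, and
  population comparison by two-sample KS tests.
* **SAC mosaic regularity** — Voronoi domain regularity index (VDRI) with
  edge exclusion, density-matched hard-core random nulls, per-animal
  summaries, and territory-size-binned outcome rates.
* **Anatomy** — dendrite orientation classification, IPL stratification
  profiles and peak calls, stratification-band distances, arbor territory
  areas, plexus coverage, homotypic contact rates with a flipped-channel
  chance control, and projection-phenotype frequency tables.
* **Synthetic data with known truth** — spike populations (von Mises ×
  Naka–Rushton × Poisson rate law), mosaics of controlled regularity, and
  anatomical fixtures, so every analysis is testable by parameter
  recovery.

## The statistics at the core

For a tuning curve of spike counts $n_i$ at directions $\theta_i$:

$$\mathrm{DSI} = \frac{\lVert \sum_i n_i\,\hat u(\theta_i) \rVert}{\sum_i n_i},
\qquad
\sigma_{circ} = \sqrt{-2 \ln \bar R},
\qquad
S = \frac{P - N}{P + N},$$

where $\bar R$ is the mean resultant length of the count-weighted
direction distribution, and $P$ (resp. $N$) is the cosine-weighted sum of
the two sampled responses nearest the preferred (resp. null) axis. For a
cell-body mosaic, $\mathrm{VDRI} = \mathrm{mean}/\mathrm{SD}$ of the
interior Voronoi domain areas; regularity is judged against simulated
random arrays matched in density. See `vignettes/dscircuit-methods.Rmd`
for the full model, parameter meanings, and design choices.

## Worked example

```r
library(dscircuit)

protocol <- stimulus_protocol(contrasts = c(150, 300))
truth <- synthetic_truth(
  cells = list(
    cell_params("ds1",  mu_on = 90,  mu_off = 110, kappa_on = 3,
                gain = 30, null_rate = 0.5),
    cell_params("ds2",  mu_on = 182, mu_off = 185, kappa_on = 1.5,
                gain = 30, null_rate = 2),
    cell_params("flat", is_ds = FALSE, gain = 10, null_rate = 1)),
  protocol = protocol, seed = 2026)
rs <- generate_population(truth)
rs
#> spike_response_set: 3 cells, 12 directions x 2 contrasts x 8 trials; 10569 spikes

cell_metrics(rs, contrast = 300)[, c("cell_id", "dsi", "pref_dir_deg",
                                     "width_deg", "strength",
                                     "delta_phi_deg")]
#>   cell_id    dsi pref_dir_deg width_deg strength delta_phi_deg
#> 1     ds1 0.7771         99.7      40.7   0.9627         21.06
#> 2     ds2 0.5956        184.6      58.3   0.8868          5.17
#> 3    flat 0.0284        227.6     152.9   0.0451          2.36
```

`ds1` is sharply tuned (high DSI, 41° width, strength 0.96) with its
preferred direction recovered near the generating 90°/110° pair and a
Δϕ near the generated 20° ON-OFF misalignment. `ds2`'s higher
null-direction spiking broadens its curve (58°) and weakens its DSI —
the same signature by which a degraded circuit is detected in recorded
populations. The untuned cell sits at DSI ≈ 0.03 and would be excluded by
the 0.25 gate.

```r
mosaic <- generate_mosaic("hardcore", density = 600, d_min = 8, seed = 2026)
vres <- voronoi_domains(mosaic)
vres
#> voronoi_result: 110 interior cells ( 40 edge-excluded ), VDRI 2.433

nul <- random_null(600, d_min = 8, n_sims = 99, seed = 1)
sprintf("null VDRI mean %.2f, 99th percentile %.2f",
        nul$mean, nul$quantiles[["99%"]])
#> "null VDRI mean 2.07, 99th percentile 2.53"
```

A hard-core field scores within its own density-matched null envelope
(2.43 < 2.53), i.e. it is not more regular than random placement with
soma exclusion — whereas a jittered-lattice mosaic scores far above it.

End-to-end two-genotype experiments, including stage-by-stage cell
counts and KS comparisons, run via `run_physiology_experiment()` and
`run_mosaic_experiment()`; a thin command-line driver over the same
functions is in `inst/cli/dscircuit.R`.

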