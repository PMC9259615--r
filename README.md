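# penkit

Quantitative analysis of PEN DNA reaction networks hosted in proteinosome
microcompartments, for synthetic-biology groups building compartmentalised
reaction cascades and for anyone extracting autocatalytic kinetics from
per-droplet time-lapse fluorescence data.

Proteinosomes immobilise template DNA at a high local concentration
(~0.12 µM inside each droplet) while primers and the PEN enzymes —
**P**olymerase, **E**xonuclease, **N**ickase — diffuse freely across the
semi-permeable membrane. The dispersion-wide template concentration is
then nanomolar, and the kinetics of the compartmentalised reaction differ
sharply from the same chemistry in buffer: rates scale with droplet
density, and small changes in exonuclease concentration can switch the
autocatalytic amplifier off entirely. penkit packages the full analysis
chain for such experiments, plus a mechanistic simulator so every stage is
testable without microscopy data.

## What is inside

* **Simulator** — a two-compartment reaction model per droplet,
  `ds_j/dt = v_prod(s_j) − v_deg(s_j) + k_ex (s_out − s_j)`, with saturating
  production `v_prod = k_pol·P·T·s/(K_m+s)·1/(1+s/K_i)` (product inhibition
  included) and Michaelis-type exonuclease degradation
  `v_deg = k_exo·E·s/(K_exo+s)`; autocatalytic and linear (trigger) nodes,
  two-population cascades, and synthetic image stacks and FRAP traces with
  ground truth (`simulate_compartment_network()`,
  `synthesize_image_stack()`, `synthesize_frap_trace()`).
* **Image analysis** — droplet detection by blur → Otsu threshold → hole
  filling → watershed, with circularity (4πA/P², contour perimeter) and
  equivalent-diameter filters (defaults 0.7–1.0 and 17–25 µm), per-droplet
  trace extraction, size statistics and proteinosome-count calibration
  (`segment_proteinosomes()`, `extract_traces()`, `fit_calibration()`).
* **Rate extraction** — the logistic model `A(x) = L/(1 + e^{k(x−x0)})`
  fitted over a window ending at the half-decay of a Gaussian fitted to
  the first differences, `t_f = b1 + c1·√(ln(a1/f))` at `f = a1/2`; the
  reported rate is `|k|` (min⁻¹). `estimate_rate()` returns a classed
  model object with `print`, `summary`, `coef`, `predict`, `plot` and
  `residuals` methods.
* **FRAP** — double normalisation, piecewise exponential recovery
  `I(t) = 1 − A·e^{−(t−t0)/τ}`, immobile fraction from the fitted plateau,
  and `D = 0.88 r²/(4 τ ln 2)` averaged over bleaching events
  (`fit_recovery()`, `diffusion_coefficient()`, `aggregate_frap()`).
* **Pipeline** — a seeded, checksummed end-to-end run
  (`run_pipeline()`, JSON/YAML configs via `load_config()`).

## Worked example

Simulate a dispersion of six template-loaded proteinosomes at 0.6 nM
total template, extract one droplet's autocatalytic rate, and fit a
synthetic FRAP experiment:

```r
library(penkit)

lay <- network_layout(
  list(list(node_kind = "autocatalytic", T_in = 0.12,
            n_compartments = 6, radius_um = 12.1)),
  volume_fraction = 0.005)          # 0.12 uM x 0.005 = 0.6 nM total
ts <- simulate_compartment_network(pen_params(), lay, primer0_outside = 1,
                                   duration = 450, dt = 3,
                                   seed = 1, noise_sd = 2)
ts
#> Trace set: 7 traces over 151 time points (0..450 min)
#>    bulk : 1 trace(s)
#>    population1 : 6 trace(s)

estimate_rate(ts$traces[[1]])
#> Autocatalytic rate fit (window fallback, t <= 270 min):
#>   rate |k| = 0.02343 min^-1 (max slope 0.5321 RFU min^-1), x0 = 118.7 min, L = 90.85

frap <- synthesize_frap_trace(A = 0.8, tau = 5, immobile_fraction = 0.3,
                              t0 = 10, t_grid = seq(0, 60, 0.25),
                              noise_sd = 0.02, seed = 2)
fit_recovery(frap$trace)
#> FRAP recovery fit (free_plateau): A = 0.8, tau = 5.04 s, plateau = 0.761, immobile fraction = 0.3
```

The rate fit reports the logistic rate constant `|k|` with the fit-window
end (`t_f`) and which window rule produced it; the sigmoid midpoint sits
near 119 min, consistent with the slow collective onset at this droplet
density. The FRAP fit recovers the generating bleach depth (0.8), time
constant (5 s) and immobile fraction (0.3); converting τ with a 2 µm
bleach spot gives `diffusion_coefficient(5.04, 2)` ≈ 0.25 µm² s⁻¹.

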