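---
title: "Models and methods behind penkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind penkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(penkit)
```

penkit quantifies PEN DNA reaction networks (polymerase, exonuclease,
nickase acting on short templates and primers) hosted inside proteinosome
microcompartments. This vignette explains the models the package
implements, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical decisions taken where the
design was genuinely open.

## The two-compartment reaction model

A proteinosome immobilises template DNA at a high local concentration
(`T_in`, default 0.12 uM) while primer strands and enzymes diffuse freely
across its membrane. The simulator reduces each droplet to a well-mixed
compartment coupled to a shared bulk phase by first-order exchange. For a
diffusible strand `s` (nM) in compartment `j`:

$$\frac{ds_j}{dt} = v_\mathrm{prod}(s_j) - v_\mathrm{deg}(s_j)
  + k_\mathrm{ex}\,(s_\mathrm{out} - s_j),$$

and in the bulk phase, with volume weights $V_j/V_\mathrm{out}$ from the
layout's compartment radii and volume fraction:

$$\frac{ds_\mathrm{out}}{dt} = -v_\mathrm{deg}(s_\mathrm{out})
  + \sum_j \frac{V_j}{V_\mathrm{out}}\,k_\mathrm{ex}\,(s_j - s_\mathrm{out}).$$

The mechanism (primer binding, polymerase extension, nicking, release,
exonuclease degradation, product inhibition) is lumped into two saturating
rate laws:

* production at an autocatalytic template,
  $v_\mathrm{prod} = k_\mathrm{pol} P\, T\, \dfrac{s}{K_m+s}\,
  \dfrac{1}{1+s/K_i}$ — linear amplification at low primer, occupancy
  saturation at $K_m$, and product inhibition at high primer from the
  primer occupying both template ends;
* degradation, $v_\mathrm{deg} = k_\mathrm{exo} E\, \dfrac{s}{K_\mathrm{exo}+s}$.

A linear (trigger) node produces the downstream substrate at
$k_\mathrm{pol} P\, T_1\, s_1/(K_m+s_1)$ without consuming its input
(templated catalysis), so the trigger population's signal rises while its
substrate survives and falls as the exonuclease consumes it — the pulse
shape of a two-node cascade.

The observable is a duplex-proportional fluorescence proxy,
$F = F_0 + \alpha\,[T\,s/(K_m+s) + 0.1\,s]$: an intercalating dye reports
template-bound strand plus a small free-strand contribution (the 0.1
weight is an arbitrary fixed constant exposed as `ext_coef`).

### Default parameters and why

| parameter | default | units | role |
|---|---|---|---|
| `k_pol` | 10 | min^-1 per nM template | lumped polymerase/nickase turnover |
| `K_m` | 200 | nM | primer half-saturation on the template |
| `K_i` | 200 | nM | product inhibition onset |
| `k_exo` | 1.0 | min^-1 nM^-1 | degradation per nM exonuclease |
| `K_exo` | 100 | nM | degradation half-saturation |
| `k_ex` | 10 | min^-1 | membrane exchange (time constant 6 s) |
| `P` | 1 | – | polymerase activity (1 = 12.8 U mL^-1) |
| `E` | 0.6 | nM | exonuclease concentration |
| `alpha`, `F0` | 1, 100 | RFU nM^-1, RFU | gain and baseline |

No rate constants for this enzyme system are published, so the defaults
are calibrated once to the qualitative behaviours the system is known
for, and are never presented as fitted values:

* **Fast exchange.** Small DNA refreshes across the membrane within
  seconds, so `k_ex` (6 s time constant) far exceeds every reaction rate.
* **Collective growth.** With `k_pol * T_in / K_m < k_ex`, a single
  compartment cannot sustain amplification on its own: exchange drains
  product faster than one droplet makes it. Growth is a property of the
  dispersion — the shared primer pool amplifies at a rate close to
  $\phi\, p\, k_\mathrm{ex}/(k_\mathrm{ex}-p)$ with $\phi$ the compartment
  volume fraction and $p = k_\mathrm{pol} T_\mathrm{in}/K_m$ — making the
  per-droplet rate proportional to **total** template, the headline
  effect of compartmentalising this chemistry. Doubling proteinosome
  density roughly doubles the observed rate even though every droplet is
  identical.
* **Exonuclease switch-off.** At 0.6 nM total template the collective
  growth rate crosses zero between 4.8 and 9.6 nM exonuclease, so
  dispersions are completely switched off at 9.6 nM while a bulk reaction
  at micromolar template (production far above degradation) keeps a
  positive rate at every exonuclease level in that range.

A consequence of keeping production linear in template: bulk simulations
at micromolar template are strongly time-compressed relative to real
buffer kinetics. Bulk comparisons made by the package are therefore
qualitative (sign and insensitivity, not time scales); quantitative
buffer-scale checks use synthetic logistic traces directly.

### What the generator emulates — and what it does not

Emulated: sigmoidal growth with onset delay and plateau, pulse-shaped
trigger-node profiles, exonuclease-dependent switch-off,
density-dependent rates, near-monodisperse (RSD 14%) and polydisperse
(RSD 48%, log-normal) droplet populations, uniform-interior droplet
images with additive Gaussian noise, and exponential FRAP recovery with
an immobile fraction.

Not emulated: membrane edge enrichment visible in real confocal images,
Poisson (shot) photon statistics, intra-compartment diffusion gradients,
stochastic chemical kinetics, dNTP depletion (plateaus arise from product
inhibition and degradation only), photobleaching during imaging, and
stage drift. Passing tests therefore demonstrate correctness of the
analysis pipeline on data with exactly the stated structure, not
robustness to every artefact of real microscopy.

Initial condition: the primer is taken as already equilibrated across the
membrane at $t=0$ (uniform concentration), because exchange is fast
compared with one 3-minute frame. Measurement noise in simulated studies
is additive Gaussian with a standard deviation of 2 RFU (2% of the
baseline), matching the visual noise level of per-droplet microscopy
traces; the underlying state stays deterministic.

## Rate extraction

Kinetic profiles are fitted with the logistic model in its conventional
form for these reactions,

$$A(x) = \frac{L}{1 + e^{k(x-x_0)}},$$

in which a growing sigmoid has $k<0$; the reported rate is $|k|$
(min^-1). For a normalised trace $L$ is fixed at 1; otherwise $L$ is
free and, because the model has no offset term, the early-trace baseline
(mean of the first five samples) is subtracted first — this makes the
fitted rate invariant under positive affine maps of the signal. A
plateau-scaled slope rate $|k| L/4$ (signal units per minute, the
maximum slope of the fitted sigmoid) is also reported, but it inherits
the variance of the free plateau on truncated windows, so analyses in
this package rank rates by $|k|$.

The fit window ends where exponential growth demonstrably ends: the raw
first differences of the signal (no smoothing by default; a 3-point
moving average is available) are fitted with a Gaussian
$a_1 e^{-((x-b_1)/c_1)^2}$ and the window closes at the half-decay of
that Gaussian, $t_f = b_1 + c_1\sqrt{\ln(a_1/f)}$ with $f = a_1/2$ (the
logarithm is natural, forced by inverting the exponential). The Gaussian
peak is bounded to the sampled time range; the fit counts as converged
only if the solver succeeds and $a_1$ exceeds twice a
median-absolute-deviation estimate of the residual noise. If the
Gaussian fails, if its midpoint falls beyond the sampled range (growth
still accelerating at the end of acquisition), or if the window would
contain no resolvable rise or fewer than 5 samples, a fallback window of
60% of the trace duration (configurable) is used and recorded in
`window_source`.

Flat traces — total excursion below 5 times a scale-free noise estimate
— are classified as no-growth with rate 0 rather than fitted.
`classify_profile` separates flat, sigmoidal and pulse shapes (a pulse
requires a sustained post-peak decline of at least 20% of the peak
excursion on a 5-point-smoothed trace).

Population summaries use pointwise means and standard deviations across
droplets and Tukey box statistics for rates: quartiles (type-7), adjacent
values at 1.5 IQR, outside points listed. The whisker rule is a
convention choice; quartile definitions differ across software by a few
percent at these group sizes.

## FRAP analysis

Normalisation is double: background-corrected bleach signal over
background-corrected reference, then division by the pre-bleach mean
(whole-droplet transport experiments divide additionally by the
background-corrected whole-droplet signal). Shared gain drift and shared
offsets cancel exactly.

Recovery is fitted as $I(t) = 1$ before the bleach and
$1 - A e^{-(t-t_0)/\tau}$ after it, with $t_0$ the time of the first
post-bleach sample (the bleach instant and $t_0$ are treated as the same
moment). When an F-ratio on nested fits rejects the two-parameter model
at the 5% level, a free-plateau extension $p - B e^{-(t-t_0)/\tau}$ is
used and the immobile fraction is
$1 - (p - I_{0^+})/(1 - I_{0^+})$ with $I_{0^+}$ the fitted
intensity just after the bleach; a last-5-samples variant is reported
alongside for QC, since either convention is defensible. The apparent
diffusion coefficient uses the half-time relation
$D = 0.88\, r^2 / (4 \tau \ln 2)$ with the bleach-spot radius $r$ always
supplied by the user, and per-event values are averaged arithmetically
over bleaching events. Apparent coefficients from spot bleaching in
crowded droplets are comparative numbers, not absolute ones; no
diffusion-equation (profile-based) model is attempted.

## Segmentation

The detection pipeline is the classic recipe for fluorescent droplets:
Gaussian blur (sigma 2 px, chosen to suppress empty pixels before
thresholding), Otsu's threshold on the blurred frame rescaled to [0, 1]
(making detection invariant to positive intensity scaling), hole
filling, watershed on the distance map to split touching droplets, then
particle filters. Circularity is $4\pi A/P^2$ with the perimeter taken
as the Euclidean length of the object's outer contour chain — pixel
counting overestimates perimeters badly enough to push disks above 1.3 —
and values marginally above 1 from discretisation are clipped to 1. The
size filter applies to the equivalent-area-circle **diameter** in
microns, default closed interval [17, 25], consistent with droplet radii
near 12 um. Segmentation runs once on a reference frame and masks are
reused across frames (sedimented droplets do not move; no tracking).
Per-frame trace values are integrated mask intensity divided by mask
area.

One known ambiguity is left visible rather than resolved: a printed
droplet summary of 12.1 ± 1.8 um is quoted with RSD 14% although
1.8/12.1 is 14.9%; `size_statistics` reports the unrounded value and the
package does not force agreement.

## Numerical choices

Integration is fixed-step classical RK4. Each recording interval (one
frame) is subdivided so the internal step stays below the stability
limit of the fastest linearised rate (membrane exchange dominates);
components in $(-10^{-12}, 0)$ after a step are clamped to zero, larger
negative or non-finite states abort with the offending time. The
fixed-step scheme is deterministic and directly checkable against a
forward-Euler oracle at 100-fold finer steps (agreement within 0.5% is a
tested invariant). Nonlinear least squares uses Levenberg–Marquardt
throughout, which converges cleanly on zero-residual (noiseless)
round-trip fixtures where Gauss–Newton implementations stall.

Problem sizes in the test-suite and acceptance studies: 4–6 compartments
per dispersion for single-population sweeps and 6–24 per population for
the two-node network (matching the tens of droplets analysed per field
of view), 450-minute runs sampled every 3 minutes, 100-replicate
recovery studies, 50 synthetic frames of 256 x 256 px at 0.65 um/px for
segmentation, and 20 bleaching events for diffusion estimates.

## Limitations

The rate constants are effective, not measured; only the qualitative
behaviour of the dispersion is calibrated. The well-mixed two-compartment
reduction hides the diffusion boundary layer around each droplet, and
with production linear in template the bulk micromolar regime is
time-compressed. The logistic rate constant compresses at the top of the
density sweep when the growth phase spans only a handful of frames.
These are exactly the regimes where per-droplet imaging data, not a
lumped model, should be the arbiter.
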