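---
title: "Quantifying specific oxygen uptake rates in perfused microculture: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying specific oxygen uptake rates in perfused microculture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sourflow)
```

## The measurement problem

Adherent cell cultures consume oxygen, and the specific oxygen uptake rate
(sOUR, oxygen consumed per cell per unit time) is a sensitive readout of
metabolic state. Classical sOUR methods require sampling or detaching
cells to count them, which perturbs exactly the phenotype one wants to
observe. In a perfused microfluidic chamber both quantities can instead be
measured non-invasively:

* **cell number** from phase-contrast microscopy (PCM) time-lapse images
  of the whole chamber, and
* **oxygen uptake** from the dissolved-oxygen (DO) differential between
  optical sensors at the chamber inlet and outlet.

At a volumetric flow rate $Q$ and cell number $X$, the quasi-steady mass
balance gives

$$\mathrm{sOUR} = \frac{Q\,(O_{2,in} - O_{2,out})}{X},$$

reported here in amol cell$^{-1}$ s$^{-1}$ ($Q$ in µL h$^{-1}$ at the
interface, L s$^{-1}$ internally; concentrations in µM, with
1 mg L$^{-1}$ O$_2$ = 31.25 µM).

`sourflow` implements the full chain — image tiles to cell density, sensor
phases to calibrated DO, their fusion into time-resolved sOUR, growth
kinetics, and respiratory-event detection — together with a ground-truthed
synthetic-data generator that makes every stage testable end to end
without any instrument.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the analysis chain is validated.

**Growth.** Density stays at the seeding value through an optional lag
phase, then grows exponentially at $\mu_{max}$, smoothly capped (a $C^1$
exponential approach, identity below 90% of the cap) so confluency never
exceeds a saturation value. Default conditions mirror the two cell lines
the device was characterised with: CHO-like cultures seeded at
$3\times10^4$ cells cm$^{-2}$ with no lag and $\mu_{max} = 0.041$ h$^{-1}$;
mouse embryonic stem cell (mESC)-like cultures seeded at $5\times10^4$
cells cm$^{-2}$ with a 72 h lag and $\mu_{max} = 0.035$ h$^{-1}$. The
chamber is $\sim$25 µL perfused at 300 µL h$^{-1}$. The chamber growth
area is not a printed device parameter; the package default is 0.8 cm²
(consistent with a 25 µL working volume at typical chamber depth) and it
is always explicit in the configuration.

**Confluency and packing.** Confluency $c$ relates to density through the
mean single-cell footprint $f$ (default 500 ± 100 µm²) and a packing
factor $p(c) \ge 1$ describing how much denser than isolated cells the
cells pack inside colonies: $c \, p(c) = \mathrm{density} \times f$. In
isolated-cell mode $p \equiv 1$; in colony mode the generator uses a
linear ramp $p(c) = 1 + s\,\max(0, c - c_0)$. The steep mESC preset
($s = 7.8$, $c_0 = 0.3$) reproduces the regime where dense, 3-D-like
colonies break the monolayer assumption — deliberately, so that the
quality-control flag for that failure mode can be exercised rather than
hidden.

**Images.** Cells are drawn as dark textured ellipses with a bright halo
rim on a noisy background — a stylised PCM appearance, not physics-based
optics. This is sufficient because segmentation is validated against the
generator's own per-pixel ground truth, not against real optics. The
renderer places exactly the true number of cells, then rescales cell areas
by bisection until the painted fraction matches the true confluency
(tolerance `max(0.002, 0.004 * confluency)`): the tight tolerance matters
because the realised painted-area-per-cell is what the density calibration
(below) learns. In colony mode new cells are placed in contact with
existing ones whenever the painted area runs ahead of schedule, which
produces contact clusters and a realised packing factor that tracks the
analytic curve closely. Confluency requests above 0.92 are refused (the
geometric packing limit of the renderer), naming the maximum.

**Sensor traces.** The three channels follow the mass balance: noise-free
outlet $= \mathrm{inlet} - \mathrm{sOUR}\cdot X/Q$ (clipped at 0 µM), with
a pure transport delay (default 15 min — tubing dead volume over flow
rate) and a first-order sensor response (default time constant 10 min)
applied; the in-situ channel reads the undelayed chamber concentration
minus an overgrowth bias, because cells proliferating on top of the
chamber-floor sensor deplete oxygen locally. No quantitative overgrowth
model exists to borrow, so the bias is a free design choice, documented
here: a linear ramp in confluency reaching full depletion of the inlet
setpoint at confluency 1.5 (i.e. only partial depletion within the
monolayer range). Gaussian read noise (default 1.5 µM, a realistic figure
for phase-fluorimetric optical DO sensors) is added per channel, and spike
artifacts are injected at identical timestamps with identical amplitude on
inlet AND outlet — by construction common mode, which is exactly how the
device behaves and why the differential measurement is robust to them.

**Respiratory assay.** The assay preset seeds densely
($5\times10^5$ cells cm$^{-2}$, no growth over the 13 h span) and switches
medium at 2.5 h (oligomycin, ATP-synthase inhibitor, sOUR $\times$0.2) and
6 h (FCCP, uncoupler, sOUR $\times$3). The baseline sOUR of the assay
preset is 6 amol cell$^{-1}$ s$^{-1}$ — inside the 5–15 range typical of
mESC steady state — chosen so that, at the assay seeding density, the
noise-free in-situ trace responds to both switches strictly monotonically
within the first hour without clipping at 0 µM; larger baselines drive the
uncoupled state into full depletion, which is realistic but makes the
simulated trace less useful as a test oracle.

**What the generator does not emulate.** Real PCM optics (defocus,
illumination gradients, debris), cell motility and mitotic rounding,
sensor drift between calibrations, and 3-D colony overgrowth beyond the
packing-factor abstraction. Tests passing on synthetic data therefore
demonstrate the correctness of the analysis arithmetic and its robustness
to the modelled noise sources — not performance on real microscopes, which
requires retraining the pixel classifier on labelled real images.

## Segmentation and density

Tiles are stitched by translating calibrated stage coordinates into image
space (row-major, origin top-left; µm to px via a single scalar, y-flip
configurable), with feathered averaging in overlaps and an optional
cross-correlation refinement within a small search radius. The stitched
image is partitioned into a rectangular analysis grid (the full-chamber
convention is 47 × 15 = 705 regions); regions containing the in-situ
sensor or ragged chamber edges carry no growth information and are
de-selected. The package ships a synthetic de-selection fixture
(`chamber_deselection_synthetic_47x15.csv`, border regions plus a central
13 × 6 sensor block, 198 regions) constructed to mirror the documented
retained/discarded bookkeeping; it is a stand-in, since the original
manual selection is not published data. De-selection here is data-driven
(indices or geometric exclusion zones in the configuration) — a GUI is out
of scope.

Pixel classification is a ridge-regularised logistic model on handcrafted
features: raw intensity, windowed mean and SD at two scales (integral
images), gradient magnitude, and a Laplacian-of-Gaussian response that
lights up the halo rim. This is the lightest model family that satisfies
"trainable"; the published trainable-segmentation methods this emulates
are more elaborate, but on synthetic imagery the linear model already
reaches held-out pixel accuracy above 0.99, and the contract tested —
confluency error below 5% absolute from 5% to 80% coverage — is the one
that matters for density. A score of exactly 0 resolves to background
(conservative confluency). Post-processing removes connected components
under 30 px and fills interior holes under 100 px (defaults,
config-exposed; no published values exist for either).

Confluency per region is the cell-pixel fraction; the culture-wide value
is the unweighted mean over retained regions. Edge regions can differ
slightly in pixel count, so a pixel-weighted mean is defensible too; the
unweighted mean is used because it matches the per-region bookkeeping
convention, and the difference is below the segmentation error.

**Packing-corrected confluency (PCC).** Density is obtained as
$\mathrm{PCC}/f$ with $\mathrm{PCC} = c \cdot \hat p(c)$. The packing
curve $\hat p$ is a monotone piecewise-linear function (at most 5 knots)
calibrated on ground-truthed fixtures by isotonic regression of the
required packing factor $\mathrm{density}\cdot\hat f/c$ against
confluency. The footprint anchor $\hat f$ is the largest realised
footprint (painted area per cell) among the sparsest third of the
fixtures: taking the maximum keeps every required packing factor at or
above 1, so the $\ge 1$ constraint of the model never truncates the fit
and any residual footprint misestimate cancels through the curve — the
calibration contract is that `density_from_pcc` reproduces the fixture
densities, and that contract, not the exact footprint value, is what
recovery depends on. Calibration refuses fixture sets spanning less than
20 percentage points of confluency (extrapolation unsafe). A raw
confluency above 0.85 raises the monolayer QC flag: beyond that point the
PCC conversion under-counts 3-D colonies, a demonstrated (not corrected)
limitation.

## Oxygen calibration and uptake

Optical DO sensors report a phase shift; the package uses the tan-phase
Stern–Volmer form standard for phase-fluorimetric sensors,
$\tan\varphi_0 / \tan\varphi = 1 + K_{SV}\,C$, anchored by a two-point
calibration: zero oxygen (sulfite solution, $\varphi_0$) and
air-saturated water ($\varphi_{air}$, $c_{air}$, default 200 µM at 37 °C —
the air-saturation concentration is configurable since it depends on
medium and temperature). Any strictly monotone two-point-anchored form
satisfies the same contract; this one is the sensor-class standard. A
calibration point is accepted only when the phase varies by no more than
±0.05° over the trailing 3 minutes. Anchors reproduce exactly:
`phase_to_do` maps $\varphi_0 \mapsto 0$ and
$\varphi_{air} \mapsto c_{air}$ to machine precision, and
`phase_from_concentration` is its exact inverse. Concentrations are
clipped to the sensor range 0–1406.25 µM (0–45 mg L$^{-1}$) with a clip
flag; non-finite phases yield flagged `NA`s, never a crash.

**Spike handling.** Common-mode artifacts are flagged where *both*
channels deviate from their rolling median by more than 5 robust SDs at
the same timestamp. Because the artifact hits both sensors identically it
cancels exactly in the differential, so flagged samples are excluded only
from uptake smoothing while the raw differential is retained — deleting
them would be both unnecessary and harmful to the time base.

**Uptake.** $\mathrm{OUR} = Q(O_{2,in} - O_{2,out})$, computed per sample
and smoothed with a centred rolling median (default window 5 samples =
75 min at the 15-min sensor cadence; whether the original analysis
smoothed before the division is not stated anywhere, so the window is
config-exposed and 1 disables it). The differential is then time-advanced
by the known outlet transport delay — differencing happens first, so
common-mode spikes cancel before any re-indexing. Without this
compensation the measured differential corresponds to an earlier, smaller
$X$ and sOUR is biased low by roughly $\mu \tau$ (about 1.3% at CHO growth
rates with the default delay); with it the noise-free recovery error drops
to ~0.3%. Negative sOUR values arise whenever sensor noise exceeds the
true differential — characteristic of early cultures with few cells — and
are retained with a `negative_flag` rather than deleted: they are excluded
from default plots and plateau estimation as pure measurement artifacts,
but remain auditable in the data. Density (imaged every 30 min) is
linearly interpolated onto the sensor timestamps; no extrapolation beyond
the imaging span.

The in-situ channel is calibrated and cleaned identically but is *never*
used in the mass balance: cell overgrowth makes its absolute level
unrepresentative of peri-cellular oxygen. It feeds event detection only,
as a qualitative channel.

## Growth kinetics, plateau, events

Growth rate and doubling time follow $\mu = \ln(X/X_0)/t$ and
$g = \ln 2/\mu$; replicate scatter uses the population form
$\sigma = \sqrt{\sum(x-\bar x)^2 / n}$ (divisor $n$). $\mu_{max}$ comes
from sliding log-linear window fits. Two numerical choices matter here,
both made after measuring the alternatives on generated data:

* **Window width 15 h** (not shorter): $\mu_{max}$ is a max over many
  correlated window slopes, and with 10 h windows at 5% multiplicative
  density noise the max-statistic inflates the estimate by 12–18%. At 15 h
  the measured bias is about +8% and noise-free fixtures remain exact.
* **Log-domain rolling-median pre-filter (5 samples).** The median of a
  monotone window is its centre point, so exact exponentials pass through
  unchanged, while the filter keeps the $R^2 \ge 0.95$ window gate from
  coupling window selection to upward noise (a window that fluctuates high
  also fits better, which is precisely the selection bias one must avoid).
  If no window passes the absolute gate, a relative gate (90% of the best
  $R^2$) keeps $\mu_{max}$ defined.

Lag duration is estimated by back-extrapolating the best exponential
window to the seeding density — exact on noise-free lag fixtures, and
within one imaging interval under noise.

The sOUR-versus-density curve uses log-spaced density bins with per-bin
medians; the **plateau** is the median sOUR over densities above
$5\times10^4$ cells cm$^{-2}$ (the density beyond which CHO-like uptake
stabilises). The median, not the mean, is used throughout because early
cultures can show a transient sOUR spike.

**Event detection** on the in-situ channel is a transparent
threshold-on-slope-plus-shift rule rather than a learned change-point
model: a candidate requires a backward slope above 10 µM h$^{-1}$ *and* a
consistent level shift above 10 µM between the four samples before and
after, with a 2 h refractory window. The backward slope matters: a centred
slope sees the change one sample early and would date events before their
cause. Rising in-situ oxygen means uptake fell (inhibitor), falling means
uptake rose (uncoupler). Slow growth-driven depletion can satisfy the
shift criterion late in a culture, so event lists from growth (rather than
assay) runs should be read against the growth curve. On the assay
conditions the detector finds both switches in 50/50 seeded runs at zero
false events on event-free runs, with zero-sample latency at the 15-min
cadence.

## Validation protocol and problem sizes

The end-to-end recovery check simulates three independent replicate
cultures per condition (mirroring the triplicate-culture design used for
the real device) at constant true sOUR of 5, 20 and 60
amol cell$^{-1}$ s$^{-1}$, runs the complete pipeline — rendered tiles
through segmentation, PCC density, phase-encoded sensor CSVs through
calibration, despiking and the mass balance — and compares the mean
plateau across replicates with truth (tolerance 15% under default noise;
the replicate mean matters because at 5 amol cell$^{-1}$ s$^{-1}$ the
differential is only 2–7 µM against 1.5 µM channel noise, giving a
single-culture plateau SD near 7%). In the idealised variant (noise off,
ground-truth masks, packing model calibrated on the run's own ground
truth, which isolates the oxygen path and unit arithmetic) recovery is
within 1%. Validation runs use a 243 × 243 px canvas (2 × 2 tiles of
128 px at 10% overlap, 1.8 µm px$^{-1}$) and 12 imaging time points over
40 h — small enough to keep the whole suite fast, large enough that a
canvas holds 50–1700 cells across the confluency range.

## Known limitations

* The pixel classifier is linear on handcrafted features; real PCM data
  will need retraining and possibly richer features.
* PCC assumes a monolayer; above ~85% raw confluency (3-D mESC colonies)
  density is under-estimated and only flagged, not corrected.
* The in-situ overgrowth bias is a free phenomenological choice; absolute
  in-situ levels carry no quantitative meaning here.
* Oxygen solubility corrections for temperature/salinity, multi-point
  sensor calibration and drift correction are out of scope; recalibrate
  per experiment instead.
* The event detector's fixed thresholds are tuned for step-like assay
  responses at the 15-min cadence; gradual metabolic shifts require
  lowering the slope threshold and accepting growth-induced detections.
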