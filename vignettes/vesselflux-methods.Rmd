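---
title: "Models and methods behind vesselflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vesselflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselflux)
```

vesselflux re-implements, as tested reusable code, the analysis chain of a
tumor–microvessel co-culture experiment: permeability of an endothelialized
channel, invasion morphometry, NADH lifetime imaging, extracellular
metabolomics, and a metabolomics-constrained flux balance analysis (FBA)
whose objective is hyaluronic-acid (HA) production. This vignette describes
each model, the tunable parameters and why their defaults were chosen, what
the synthetic generator does and does not emulate, and the numerical
decisions taken where the underlying procedures are conventionally left
unspecified.

## Vessel permeability

### Forward model

The generator treats the channel as a well-mixed cylindrical compartment of
radius $r$ (default 150 µm, i.e. a 300 µm needle-cast channel) exchanging
tracer across its wall with flux density $J = P\,(c_\mathrm{vessel} -
c_\mathrm{wall})$ into a 1-D radial diffusion grid (conservative
finite-difference form, reflecting outer boundary at 300 µm depth). Matrix
diffusivity defaults to $D = 200\ \mu m^2/s$, the order of magnitude of a
free small dye in dilute collagen. Because the channel is fed by media
reservoirs, the vessel compartment carries an effective volume
`reservoir_factor` (default 10) times the channel volume, which makes
$c_\mathrm{vessel}$ decay slowly rather than exhausting within seconds at
high $P$. The wall flux uses the series conductance $g = (1/P +
\Delta r/2D)^{-1}$, the second-order-accurate coupling of a membrane to the
first grid cell; with it, halving the grid changes the simulated trace by
well under 1 %. Frames are emitted every 2 s for 5 min.

The reported matrix intensity $I_\mathrm{ECM}$ is the integrated matrix
tracer normalized to the vessel ROI area. Under this (integrated-density)
convention the textbook estimator

$$P_D = \frac{r}{2}\,\frac{1}{I_\mathrm{vessel}(0)}\,
        \frac{dI_\mathrm{ECM}}{dt}$$

is exact at early times, and total intensity $I_\mathrm{vessel} +
I_\mathrm{ECM}/\mathrm{reservoir\ factor}$ is conserved (checked to 0.1 %).

### Two estimators and the automatic window

`fit_ecm_slope()` implements the classical linear-portion slope. The
automatic window expands from the first frame while the fit $r^2$ stays
above 0.95 (minimum 5 frames) *and* the matrix intensity stays below 10 %
of the baseline vessel intensity. The second condition matters: the
integrated-flux curve is concave but smooth, so an $r^2$ criterion alone
happily keeps most of a strongly saturating trace and the slope can
underestimate $P$ several-fold. The 10 % cap is the point where the
transmural driving force — the quantity the formula assumes constant — has
itself decayed by about 10 %.

The slope estimator has a structural limit: with 2 s frames, the driving
force at $P = 10\ \mu m/s$ decays with a time constant comparable to the
sampling interval ($r/2P = 7.5$ s, plus wall concentration build-up
$\propto P\sqrt{t/D}$), so *no* windowed straight-line fit can see the
initial slope. `estimate_permeability()` therefore also provides a
`"kinetic"` method — a one-parameter least-squares inversion of the same
radial forward model (coarser grid, $D$ and reservoir factor assumed known)
on the normalized traces, with the model normalized by its own three-frame
baseline exactly as the data are. The default `"auto"` mode uses the slope
method when the validity-capped window holds at least 10 frames and the
kinetic fit otherwise. On noiseless synthetic movies this recovers $P \in
\{0.1, 1, 10\}\ \mu m/s$ within 5 %, and with 5 % multiplicative frame
noise the median error over 20 seeds is about 4 %.

$I_\mathrm{vessel}(0)$ is the mean of the first three frames after
background subtraction (the acquisition starts immediately after tracer
loading, so a fixed short baseline is the natural reading of "initial
intensity").

## Invasion and shape morphometry

Segmentation is Gaussian blur (default $\sigma = 2$ px) → Otsu threshold →
connected components → minimum-area filter (default 20 µm²); all defaults
are arguments because the upstream conventions (ImageJ macros) do not pin
them. Shape descriptors follow the ImageJ conventions: circularity
$4\pi A/P^2$ capped at 1 (the raw value is retained), aspect ratio from the
second-central-moment equivalent ellipse. Perimeter uses chain-code length
with the Vossepoel–Smeulders corner correction ($0.980\,N_{even} +
1.406\,N_{odd} - 0.091\,N_{corner}$): plain boundary-pixel counting puts
disk circularity near 1.2, while this estimator is accurate to ~1 % for
disks of radius ≥ 10 px, which is what makes the "disks measure ≥ 0.9"
check meaningful. A $+1/12$ px² Sheppard term corrects the pixel-sampling
bias of the second moments.

Coordinates are pixel centers, 0-based, $x$ increasing toward the
endothelial channel; invasion distance is the signed nucleus displacement
from the channel edge (both the signed mean and the invaded-only mean are
reported, since the handling of cells behind the edge is a genuine
ambiguity). Normalization to a control mean is applied per replicate
before pooling.

Adhesion counting: white top-hat (disc radius 5 px) → per-cell Otsu on the
within-cell intensities → puncta ≥ 0.25 µm². The per-cell Otsu needs a
threshold over an arbitrary pixel subset, so a histogram-based Otsu on a
numeric vector is implemented internally (image-wide Otsu implementations
only accept whole images).

The collagen contraction ratio divides mean fiber signal in a 10 µm
peri-cellular ring by that of the remaining bulk matrix. Fibers are
enhanced with a Hessian tubeness filter (rectified negative minor
eigenvalue, scale-normalized, default scale 2 px ≈ fiber width at 10×).
For a featureless field the filter response vanishes identically, so the
raw reflectance is used instead and the homogeneous-field ratio is exactly
1; the ratio is exactly invariant to global intensity scaling in both
branches.

Motility: per-track mean speed (path length over duration) and
origin-centered paths. On simulated 2-D random walks the mean squared
displacement grows linearly with slope $2\sigma^2/\Delta t$ within 15 %
over 200 tracks, the closed-form check for an unbiased walk.

### What the generator emulates, and what it does not

The invasion generator places non-overlapping ellipses whose ground-truth
aspect ratio increases stochastically with distance invaded past the edge
(gain 0.5 per 100 µm, ±40 % cell-to-cell), with placement SD 120 µm; the
bias parameter shifts the placement mean toward the channel. It does not
render textured cytoplasm, overlapping/touching cells, uneven
illumination, or 3-D structure — maximum-intensity projections are taken
as given. Passing tests therefore demonstrate estimator correctness on
clean geometry at realistic SNR, not robustness to clumped or poorly
stained samples.

## NADH FLIM

Decays are two-component exponentials integrated per TCSPC bin (256 bins
over a 12.5 ns laser period) and Poisson-sampled at the configured photon
budget. The fit is weighted nonlinear least squares (Levenberg–Marquardt)
of $A(a_1 e^{-t/\tau_1} + (1-a_1)e^{-t/\tau_2}) + bg$ from the histogram
peak onward, Poisson weights $\sqrt{\max(\mathrm{counts},1)}$,
parameterized so $0 \le a_1 \le 1$ and $0 < \tau_1 < \tau_2$ by
construction (logit/log/positive-gap), with multi-start initialization at
$(\tau_1, \tau_2) \in \{(0.3, 2.0), (0.5, 3.0)\}$ ns and the best reduced
$\chi^2$ kept. If the converged lifetimes are within a factor 1.5 the
two components are not identifiable and the decay is refit and reported as
mono-exponential ($a_1 = 1$). The mean lifetime is amplitude-weighted,
$\tau_m = a_1\tau_1 + a_2\tau_2$, the "tm" convention of standard TCSPC
software; intensity is the raw photon sum (no background or laser-power
normalization — a documented caveat, since instrument normalization is not
reconstructible from histograms alone). No instrument response function is
applied by default (delta IRF); a Gaussian IRF of configurable width can be
convolved in by the generator. Median recovery error of $\tau_m$ at the
experimental design point ($a_1 = 0.8$, $\tau = 0.4/2.5$ ns) is under 5 %
from $10^4$ photons per pixel.

## Exchange fluxes from metabolomics

Concentrations at 0/24/48 h are blank-corrected as $C(t) - (B(t) - B(0))$ —
removing cell-free drift while anchoring $t = 0$ so fold changes are
unaffected — and converted to per-cell rates by

$$v = \frac{\Delta C \cdot V}{\int_0^T N(t)\,dt}, \qquad
  \int_0^T N = N_0\frac{e^{\mu T} - 1}{\mu}\ \xrightarrow{\mu \to 0}\ N_0 T,$$

in fmol/cell/h with positive = secretion. The exponential growth integral
(rather than an endpoint average) matters because tumor lines grow
appreciably over 48 h; the $\mu \to 0$ limit is taken analytically below
$|\mu T| < 10^{-8}$. SDs propagate to first order from the endpoint
concentration SDs. Rates are endpoint-based (0 → 48 h) by default;
metabolites below quantification at $t=0$ get `NA` fold changes rather
than fabricated ratios. Noiseless closure against the generator is within
1 % for $|\mu| \le 0.03$/h. Conversion to the FBA unit mmol/gDW/h uses a
configurable cell dry mass, default 400 pg/cell (typical for a mammalian
tumor line); the round trip is exact.

## Flux balance analysis

### The reduced network

The packaged network (~66 reactions, single compartment) is an original
reduced reconstruction covering the pathway roles needed for the
condition comparison: glycolysis split into upper (hexokinase–aldolase)
and lower stages, lactate dehydrogenase, a lumped TCA cycle with pyruvate
and glutamate (via glutamate dehydrogenase) entry points, pyruvate
carboxylase / PEPCK anaplerosis, oxidative phosphorylation (P/O = 2.5,
FADH₂ folded into NADH), an ATP demand, glutamine synthetase and
glutaminase, synthesis and catabolism routes for the non-essential amino
acids, lumped catabolism for the essential ones whose exchanges are
constrained, HA synthesis from UDP-glucuronate + UDP-N-acetylglucosamine
(one disaccharide unit ≈ 2 glucose + 1 glutamine amide + 1 acetyl-CoA +
ATP), a biomass drain (0.25 mmol/gDW of each amino acid, 30 mmol ATP/gDW),
and one exchange per tracked metabolite (positive flux = secretion).
Water, protons and phosphate are not tracked. Absolute fluxes from this
stand-in are not comparable to a genome-scale model; directional condition
contrasts are the meaningful output.

### Constraints, objective, ensemble

Measured rates become exchange bounds $[v - k\,\mathrm{SD},\,
v + k\,\mathrm{SD}]$ ($k = 1$) intersected with the default bounds; the
eight amino acids glycine, leucine, lysine, phenylalanine, threonine,
tryptophan, tyrosine and valine stay unconstrained (their measured bounds
routinely make the LP infeasible); measured growth rate bounds the biomass
reaction and an oxygen consumption rate bounds the O₂ exchange. The LP
maximizes HA synthesis. Because LP optima are non-unique, reported fluxes
come from a parsimonious second stage minimizing total absolute flux at
the fixed optimum (negative parts introduced only for reversible
reactions), so per-reaction comparisons are well defined.

The N-simulation ensemble (default 1000) redraws the *center* of every
measured bound from a normal truncated to the default network bounds with
the measurement SD, keeping the ±SD band around the drawn center, and
solves each draw; infeasible draws are counted and dropped (a >50 % rate
triggers a hard warning). Resampling measured constraints is the natural
reading of an uncertainty ensemble here: it is the only stochastic element
available once the network and objective are fixed, and the band (rather
than pinning exchanges to sampled points) avoids spurious infeasibility
from rate vectors that violate elemental balance.

The two default condition constraint sets encode the study's qualitative
contrast — under endothelial conditioned media: higher glucose uptake
(−400 vs −300 fmol/cell/h), higher lactate secretion (+600 vs +500),
glutamate flipped from secretion (+15) to consumption (−10), more proline
secretion, and ~45 % higher O₂ consumption (320 vs 220 fmol/cell/h) with
15 % measurement SDs. With these inputs the ensemble reproduces the
expected directions: higher HA synthesis, ATP demand, upper glycolysis,
pyruvate→lactate and glutamate→α-KG flux under conditioned media, in every
seed replicate tested.

### The LP engine

No linear-programming package is part of the package's dependency set, so
the solver is built in: a dense bounded-variable two-phase primal simplex
(Dantzig pricing, Bland fallback on stalls, row equilibration, periodic
refactorization, tolerances $10^{-9}$). At the network's scale (≈ 44
metabolites × 64–90 variables) a solve takes ~15 ms. Correctness is
established against an independent brute-force vertex-enumeration oracle —
all basic solutions of $Sv = 0$ with nonbasic variables at bounds — on 50
seeded random networks, with agreement to $10^{-9}$, plus mass-balance
($\max|Sv| \le 10^{-8}$) and bound ($10^{-9}$ slack) invariants on every
optimal solution.

## Reproducibility and problem sizes

Every stochastic generator takes its seed from the configuration and
restores the caller's RNG state; identical configurations give
bit-identical outputs, and the demo pipeline writes a manifest with output
hashes so a re-run can be verified byte-for-byte. The test suite exercises
recovery at the sizes a single device/field yields in practice — 151-frame
movies, 40–100-cell fields, $10^4$–$10^5$ photons per pixel, 20-seed
replication for median-error statements, and 200-draw ensembles for the
condition contrast — which keeps the default suite in the minutes range
while leaving every tolerance at the level justified by the estimator
analyses above.

## Known limitations

- The permeability forward model is radially symmetric; it does not model
  focal leaks, wall heterogeneity, or convection.
- The kinetic permeability estimator assumes the matrix diffusivity and
  reservoir factor of the forward model; misspecifying $D$ biases fast-$P$
  estimates (the slope method is unaffected but regime-limited as above).
- FLIM fitting assumes a delta IRF by default and reports raw photon sums
  as intensity.
- The FBA network is a reduced stand-in: suitable for directional
  comparisons under measured constraints, not for absolute flux maps.
- Morphometry operates on 2-D projections; no volumetric shape metrics,
  and the tracker consumes tracks rather than creating them.
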