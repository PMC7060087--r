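---
title: "Modeling oxygen control and cell behavior in a double-layer microfluidic hypoxia chip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling oxygen control and cell behavior in a double-layer microfluidic hypoxia chip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxychip)
```

## The device and the physical model

The device `oxychip` models is a PDMS slab bonded to a glass coverslip. A
central collagen-gel channel (1300 µm wide) flanked by two media channels
(500 µm each) sits on the floor; two gas channels (1000 µm wide, separated
by 1300 µm so they do not shadow the gel during imaging) run in a second
layer at height $H_g$, and a polycarbonate (PC) film with roughly
2000-fold lower oxygen diffusivity than PDMS spans the device at height
$H_f$ to shut out atmospheric oxygen. All channels are 150 µm high.
Supplying gas mixtures with defined O~2~ fractions to the gas channels
sets the oxygen tension experienced by cells in the gel: equal supplies
give a uniform tension, unequal supplies a near-linear gradient across the
gel.

Oxygen tension $\phi$ is expressed throughout in percent of 1 atm
(21 = ambient air). Dissolved oxygen follows Henry's law, $c = S\,\phi/100$
with a per-material solubility $S$ (mM/atm), so at a material interface the
*partial pressure* is continuous while the *concentration* jumps by the
solubility ratio:

$$ \frac{c_\mathrm{PDMS}}{S_\mathrm{PDMS}} = \frac{c_\mathrm{channel}}{S_\mathrm{channel}}. $$

Working in partial-pressure form makes this partition condition automatic:
steady transport reduces to

$$ \nabla \cdot ( k \nabla \phi ) = 0, \qquad k = D S, $$

and transient transport to $S\,\partial\phi/\partial t = \nabla\cdot(k\nabla\phi)$,
where the permeability $k$ and the capacitance $S$ change per material.
No advection term appears in the cross-section: the cellular experiments
the model serves use static medium, and the gas channels are treated as
fixed-composition boundaries rather than flowing domains (next section).

Material properties (`default_materials()`): water-phase (medium, gel)
$D = 2.0\times10^{-9}$ m²/s, $S = 0.218$ mM/atm; PDMS
$D = 4.0\times10^{-9}$ m²/s, $S = 1.25$ mM/atm; PC film
$D = 2.0\times10^{-12}$ m²/s with the PDMS solubility; gas
$D = 2.0\times10^{-5}$ m²/s. PDMS is thus ~11× more permeable than water,
and the film ~2000× less permeable than PDMS — the two facts that make the
design work. Density and viscosity are carried for completeness but never
used: flow is parameterized, not solved.

## Flows as Péclet numbers

Channel flows enter only through the Péclet number $Pe = U L / D$. The
characteristic length $L$ is the channel *width*: this is the only choice
that reproduces the published conversion table (gas $Pe = 100$ in a 1 mm
channel ⇒ $Q = 18$ ml/min; medium $Pe = 500$ in a 500 µm channel ⇒
$U = 2.0\times10^{-3}$ m/s), and `pe_to_flow()` implements it. Fast gas
flow ($Pe_g \ge 10$) keeps the gas-channel composition constant along the
channel, which justifies modeling the channel walls as Dirichlet surfaces;
`boundary_set()` warns when a supplied gas `flow_spec` is below that
threshold. Slow medium flow is required for the opposite reason — fluid
must *not* outrun equilibration — and `channel_axis_model()` provides the
quasi-1-D plug-flow/wall-exchange balance
$U\,d\phi/dy = (v_{ex}/h)(\phi_{wall}-\phi)$ whose relaxation length
$\lambda = U h / v_{ex}$ makes that trade-off quantitative. The default
exchange velocity $v_{ex} = D/h$ is the diffusive conductance across the
channel height; it is a deliberately coarse, qualitative stand-in for the
full conjugate problem.

## Discretization and numerical choices

`build_cross_section()` discretizes the x–z cross-section (origin at the
gel-channel center, z up from the floor) into a rectilinear grid whose
edges are forced to coincide with every material interface, so no cell
straddles two materials; each interface-to-interface span is subdivided at
or finer than the requested resolution (default 25 µm, which gives the
150 µm channels 6 cells and the 500 µm film 20 layers; the film is always
given at least 2). Cells are classified by their centers.

Design choices that were genuinely open:

* **2-D cross-section.** The device is a 35 mm disc, modeled here as a
  35 mm-wide slab in the x–z plane. The consequences are discussed under
  *Limitations*.
* **Aqueous layer contiguous.** The PDMS posts separating gel from media
  channels are discrete in y; the modeled slice passes between posts, so
  gel + media form one 2300 µm water-like layer. The gel/medium labels are
  kept separate for readouts but share properties.
* **Glass floor = zero flux.** Glass is effectively oxygen-impermeable;
  the coverslip is a no-flux boundary rather than a material.
* **Ambient surface = Dirichlet 21.** Henry's law with atmospheric
  partial pressure applied directly at the outer PDMS surface (sides and
  top). Port holes through the film are ignored: they sit far from the
  imaging region (but see *Limitations*).

The finite-volume face conductance is the harmonic mean of the two
half-cell resistances, $g = A / (\tfrac{d_1}{k_1} + \tfrac{d_2}{k_2})$.
This discretization reproduces piecewise-linear composite-slab solutions
*exactly* (the test suite checks the three-layer gel|PDMS|film column
against the series-resistance closed form $J = \Delta\phi / \sum t_i/k_i$
at machine precision) and yields an M-matrix, so the discrete maximum
principle holds: steady fields are bounded by the extreme boundary values,
asserted on every solve in the tests. The sparse symmetric
positive-definite system is solved by direct Cholesky factorization.
Transients use implicit (backward) Euler with the per-cell capacitance
$S$; the factorization of $(M/\Delta t + A)$ is computed once and reused
across steps (default $\Delta t$ = 1 s in the API; the device studies in
the tests and the acceptance script use 5 s, under which the reported
equilibration time is converged to well under 5%). The equilibration
readout is the first time the gel-center value comes within 0.5 %O~2~ of
its steady value for a hypoxic step, or within 1 %O~2~ of 21 for
reoxygenation, matching how the device's response times are quoted.

Problem sizes: the default cross-section at 25 µm is 1400 × 160 =
224 000 cells; a steady solve takes a few seconds and a 25-minute
transient at $\Delta t = 5$ s under a minute on one core. Unit tests use
100 µm grids; the full-resolution solves live in the acceptance-level
tests and `scripts/acceptance.R`.

## Stern–Volmer oximetry

Phosphorescent nanoparticles embedded in the gel are quenched by oxygen;
their blue fluorescence is oxygen-insensitive. `reduce_roi()` splits the
imaging window (1024 × 50 px at 1.3 µm/px) into 100 µm sections and
space-averages each channel; the trailing partial section (1331 µm =
13 × 100 + 31) is dropped rather than averaged short — the 31 µm remnant
would otherwise carry a noisier mean. Ratiometric normalization

$$ \bar I' = \bar I_P \times \bar I_{F0} / \bar I_F $$

cancels any multiplicative illumination drift shared by the two channels,
because the drift factor in $\bar I_P$ divides out against the one in
$\bar I_F$ while the drift-free first-frame $\bar I_{F0}$ restores the
scale. Per section, the calibration

$$ \bar I'(c) = \bar I'_{BG} + \frac{\bar I'_A - \bar I'_{BG}}{1 + K_q\,c/100} $$

pins $\bar I'_A$ to the measured anoxia point (it is directly observed,
so it is not re-estimated), and fits $\bar I'_{BG}$ and $K_q$ by
Levenberg–Marquardt least squares on the nonlinear form; the linearized
Stern–Volmer plot only supplies starting values, because fitting the
linearized form would distort the error variance at low intensities.
Background is fitted per section independently — no spatial smoothing is
applied across sections, since nothing constrains the device-material
background to vary smoothly. Inversion (`intensity_to_oxygen()`) flags
intensities at or below background as *undefined* (not clamped) and clamps
brighter-than-anoxia intensities to 0 %O~2~ with a *clamped* flag, so
downstream code can distinguish physics from noise. The fitted $I_{BG}$
and $K_q$ are strongly correlated, which makes single-fit $K_q$ values
scatter far more than the reconstruction error they imply; recovery is
therefore judged on Monte-Carlo location (mean/median over seeded
replicates), as the tests do.

## Migration and proliferation statistics

`compute_speeds()` takes 3-D Euclidean step distances over the actual
inter-frame gap (nominally 10 min; longer gaps are flagged, not silently
rescaled). Aggregations: a pooled cross-track mean per time point, 4-h
window means, and the window series normalized to its first window.
Tracks are assigned to slow/fast subpopulations by their *median*
interval speed against a 15 µm/h threshold — the median is robust to
single-frame tracking jumps, which per-track means are not. Regional
counts over the gel window use $[-450,-150)$, $[-150,150)$, $[150,450]$
µm with an explicit `outside` bucket so counts are conserved; tie
handling at the region edges is half-open with the right edge closed
(the convention must simply be fixed; nothing in the data dictates it).

`compare_conditions()` runs Kruskal–Wallis (base `kruskal.test`) across
conditions, Dunn's rank-based post-hoc z tests (implemented here, with
the tie-corrected pooled-rank variance) under a configurable multiplicity
adjustment defaulting to Holm — no particular correction is canonical for
this battery, and Holm controls FWER without independence assumptions —
plus Welch's t for proliferation-fold pairs and a two-way ANOVA
(condition × 4-h window) for normalized speed series. Groups with fewer
than 3 observations are dropped with a warning.

## The synthetic-data generators

The generators exist so every analysis stage can be exercised and
validated without laboratory data; their defaults encode the study
conditions the analyses assume.

**Camera model** (`camera_model()`, `render_calibration_stack()`):
noiseless intensities follow the forward Stern–Volmer model exactly;
both channels share a multiplicative drift $g(t)$ anchored at
$g(t_0) = 1$; noise is additive Gaussian (sd 5) plus a Poisson-like
signal-dependent term (sd $\sqrt{\mu}$). At these defaults the per-section
averaging (≈3850 px) leaves sub-0.1% intensity noise, which is what a
well-exposed calibration stack looks like; the drift-immunity and
round-trip tests also run at ±20% drift to stress the normalization.

**Walk model** (`walk_model()`, `simulate_tracks()`): persistent random
walks at 10-min frames in the gel box (positions reflected at the walls).
Speeds are a two-component lognormal mixture: the slow mode is fixed
across oxygen while the fast mode scales with a piecewise-linear response
over the oxygen tensions the device realizes
(0.3, 1.3, 3.4, 5.3, 10.1, 21 %O~2~), encoding the observed ordering — a
local maximum near 5 %O~2~, elevated speeds under strong hypoxia relative
to normoxia, and no difference between 10 and 21 %O~2~. Absolute speed
levels are free parameters (only the 15 µm/h threshold landmark is
reported for real cells); the defaults (slow median 7 µm/h, fast median
22 µm/h at normoxia, 40% fast) place the slow mode near half the
threshold and the fast mode above it, making the published threshold
meaningful for synthetic data. The speed response follows a first-order
lag (default 4 h) after oxygen switches, reflecting that cells take hours
to re-adapt their motility. Division is Bernoulli per seeded cell over
24 h — each founder divides at most once, terminating its track and
spawning two daughters — with oxygen-dependent probabilities
(0.7 under strong hypoxia, 0.8 near 5 %O~2~, 0.4 at normoxia), chosen so
the expected daily fold change $1 + p$ mirrors the reported 1.7/1.8/1.4
folds; recovery is asserted within binomial confidence intervals. The
default cell count derives from the 2×10⁵ cells/ml seeding density over
the imaged gel volume. Every generator is deterministic under its seed
and restores the caller's RNG state.

What the generators deliberately do *not* emulate: oxygen consumption by
the cells, nutrient co-gradients (flagged in the source study as a
confounder of the regional counts), chemotactic bias, cell–cell
interactions, death (viability stays at 100%, consistent with the >90%
observed but not informative about it), and photobleaching beyond what
ratiometric normalization removes. Passing round-trip tests therefore
demonstrates that the *analysis pipeline* is faithful and unbiased under
the stated statistical structure — not that real cells follow the walk
model.

## Limitations

The main known gap is dimensional. The 2-D cross-section retains lateral
leakage through the PDMS slab but omits every path with a y-component:
the finite length of the gel/media channels, the Y-shaped media runs
approaching the device rim, and the punched access ports that connect
channels to the incubator atmosphere. Those paths raise the hypoxic floor
of the real (and fully 3-D simulated) device and soften its gradients; the
2-D model correspondingly sits *below* the reported 0.4 %O~2~ floor (it
converges to ≈0.01 %O~2~ at the default design) and yields a slightly
*wider* gradient (≈2.2–18.8 vs 3–18 %O~2~). The device-level conclusions
— sub-1% uniform hypoxia for films below 2 mm, near-linear supply
response, minutes-scale equilibration — are insensitive to this gap, but
absolute floor values are not, and the gel-center response to the film
height is compressed near the floor (the 0.25 and 0.5 mm designs are
numerically indistinguishable in 2-D where the 3-D device orders them).
Coarse 3-D extrusion was considered and rejected: without the port and
channel-end geometry it would inherit the same gap at several times the
cost. Other limitations: gas channels are fixed-composition surfaces
(valid only for $Pe_g \gtrsim 10$); no oxygen consumption term (the
seeding density is low enough that this is a second-order effect, and it
is out of the model's scope); the axial channel model is qualitative.
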