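---
title: "Modelling SAP-induced calcium spike trains in sperm flagella"
author: "flagspike"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling SAP-induced calcium spike trains in sperm flagella}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagspike)
```

## The biological problem

Sea urchin eggs release short peptides (sperm-activating peptides, SAPs)
that guide sperm by triggering trains of calcium spikes in the flagellum.
The transduction chain is well mapped at its upstream end: SAP binds a
receptor/guanylate-cyclase complex, cGMP rises, a cGMP-gated K⁺ channel
(KCNG) hyperpolarises the membrane, and a hyperpolarisation-activated
cation channel (spHCN) partially repolarises it.  Which calcium channel
then converts this electrical prelude into the observed repetitive
[Ca²⁺]ᵢ spikes is contested.  Two candidate circuits can be assembled from
channels known to be present:

* **CaV+BK** — T-type voltage-gated calcium channels cycling irreversibly
  through inactive → closed → open states, coupled to the
  calcium-activated potassium channel BK, which converts each calcium
  spike into extra hyperpolarising drive;
* **CatSper+NHE** — the sperm-specific CatSper channel, whose
  half-activation voltage shifts with intracellular pH, coupled to a
  voltage-sensitive electroneutral Na⁺/H⁺ exchanger (NHE) that alkalinises
  the flagellum when the membrane is hyperpolarised.

`flagspike` implements both circuits (and their weighted mixtures) behind
a common upstream module, as a Hodgkin–Huxley-style ODE system, together
with the analysis machinery needed to compare their predictions: resting
state derivations, stimulation/clamp protocols, spike-train statistics,
attractor analysis of the cGMP-clamped submodels, an evolutionary
parameter-space exploration, and least-squares fitting of the upstream
module.

## The model

The membrane potential follows charge balance,

$$C_m \frac{dV}{dt} = -\Big(g_L (V - E_L) + \sum_i g_i f_i^o (V - E_i)\Big),$$

with ohmic current densities for every channel (positive = outward).  The
four chemical observables are the extracellular SAP concentration $S$,
intraflagellar cGMP $G$, calcium $C$ and protons $H$:

$$\frac{dG}{dt} = \sigma_G - \delta_G G + \theta_G (k_H R_H + k_L R_L),
\qquad
\frac{dC}{dt} = \sigma_C - \delta_C C - \frac{s_f}{2 v_f F} \sum_j I_j,
\qquad
\frac{dH}{dt} = \sigma_H - \delta_H H - J_H / v_f,$$

where $R_H, R_L$ are receptor forms of an irreversible activation chain
$R_F \to R_H \to R_L \to R_I$ driven by SAP binding, the calcium sum runs
over the calcium-carrying channels of the active module, and $J_H$ is the
exchanger flux (reversible rapid-equilibrium random-order bi-bi kinetics).
Gating variables follow first-order kinetics with the rate laws
implemented in `kcng_equilibrium()`, `sphcn_gate()`, `cav_rates()`,
`bk_opening_rate()`, `nhe_rates()` and `catsper_gates()`; CatSper's
voltage gate is pH-modulated through the Hill shift `catsper_vhalf()` and
inactivated by calcium through a second gate.

Units are fixed package-wide: mV, s, pS µm⁻², fA µm⁻², pF µm⁻², nM for
cGMP and calcium, M for protons, fL for the flagellar volume and µm² for
its membrane area.  With these, the calcium flux factor
$s_f / (2 v_f F)$ is $9.72\times10^{4}$ nM s⁻¹ per fA µm⁻², and the bi-bi
exchanger flux in fmol s⁻¹ divided by the volume in fL is an M s⁻¹ rate
directly.  All concentrations inside the exchanger expression are
converted to molar before evaluation; the flux ratio is invariant to that
choice, but the documented convention keeps the derived proton leak rate
at its tabulated value.

### Fixed versus derived parameters

Reference values for every constant ship as presets
(`reference_params()`).  Three parameters are *not* free: they are pinned
by requiring that, without SAP, the system rests at
$V = E_m = -40$ mV, $G_r = 1.25$ nM, $C_r = 100$ nM, pH$_i$ = 7.1:

* the leak reversal potential, from zero net current,
  $E_L = E_m + \tfrac{1}{g_L}\sum_i g_i \hat f_i (E_m - E_i)$
  (`derive_leak_reversal()`), giving 80.16 mV for CaV+BK and
  −20.41 mV for CatSper+NHE;
* the module-independent calcium source
  $\sigma_C = \delta_C C_r + \tfrac{s_f}{2 v_f F}\sum_j \hat I_j$
  (`derive_calcium_source()`);
* the proton leak rate
  $\delta_H = (\sigma_H - \hat J_H / v_f) / H_r$
  (`derive_proton_leak()`), giving 1.280 s⁻¹.

`derive_parameters()` recomputes all three, so that user-edited parameter
sets remain self-consistent; `simulate_model()` does this by default, and
the test suite asserts that the derived rest is a fixed point of the
vector field to below 10⁻⁶ in every configuration.  Reversal potentials
$E_K = -80$ mV and $E_{Ca} = 144$ mV are Nernst values at 17 °C, held
fixed during simulation (they are treated as constants of the reference
condition, not as functions of the instantaneous concentrations).

## Protocols and reference dynamics

`protocol()` composes three event types: an instantaneous SAP pulse
($S(0^+) = S_0$; the standard stimulus is 25 nM), a pH clamp (the proton
ODE is removed and pH held exactly — an idealisation of sustained
NH₄Cl-induced alkalinisation), and a voltage pulse (V clamped for a fixed
duration).  Clamped variables are integrated out of the active system, so
`d(pH)/dt = 0` holds identically in the output rather than approximately.

Integration uses `deSolve::lsoda` (the system mixes millisecond gating
with ten-second envelopes), relative tolerance 10⁻⁸ and per-variable
absolute tolerances at 10⁻⁶ of each variable's natural scale (10⁻¹⁶ for
$H$, which is of order 10⁻⁷ M).  Halving the tolerances moves spike times
by less than 1% and never changes the spike count (asserted in the test
suite).

Under the standard 25-nM pulse the CaV+BK module produces its
characteristic train: ~17 large spikes with decaying amplitude and
growing interspike intervals, inter-spike minima on a plateau of
~430 nM, an abrupt drop of the elevated activity at ~16 s, and
low-amplitude fast ripples (~150 nM, period ~0.23 s) afterwards — the
signature of falling from the upper to the lower limit cycle of the
underlying clamped-cGMP bifurcation structure.

### The CatSper+NHE stimulus window

The CatSper+NHE module is bistable over a wide range of conditions: its
limit cycle coexists with a stable elevated-calcium focus, and the basins
are tightly interlaced.  Under the reference parameter set the 25-nM
response terminates on that focus after two spikes, whereas a 10-nM pulse
elicits the module's full oscillatory phenotype: a long train (17 spikes)
with strongly growing intervals (last/first ratio ≈ 3), calcium and pH
oscillating with the same period, and envelope statistics that pass the
physiological selection criteria.  The outcome at exactly 25 nM sits on a
knife edge: within the quoted precision of the maximal exchanger flux
(one significant digit), both behaviours occur.  The package does not
adjust any reference value; demonstrations of the module's oscillation
(vignette, period-equality checks, titration baselines) therefore use the
10-nM stimulus, which is inside the oscillatory window for the reference
set as shipped, and the 25-nM behaviour is reported as-is.  This is a
documented reproducibility limit of the tabulated parameterisation, not a
tuning choice.

## Spike-train quantification

`detect_spikes()` follows the experimental procedure for fluorescence
traces: cubic smoothing spline (generalised cross-validation), local
maxima above *baseline mean + 3 × baseline SD* with the baseline taken
from the pre-stimulus window, amplitudes $A_k$ read off the smooth curve
relative to zero signal.  Two numerical refinements make the same
procedure well-behaved on noiseless model output:

* the spline's default knot heuristic is far too coarse for densely
  sampled traces; knots are placed every ~10 ms;
* the 3 SD statistic degenerates when the baseline is exactly constant,
  so the detector uses `max(3 SD, 5% of the post-stimulus dynamic range)`
  both as the threshold rise and as a minimal topographic prominence.
  For noisy recordings the classical 3 SD rule dominates; for clean model
  output the 5% floor keeps sub-plateau ripples and spline ringing on
  steep spike fronts from being counted.  The test suite checks the
  detector against a brute-force discrete argmax oracle and against
  constructed trains with exactly known statistics.

`spike_features()` summarises a train by the mean interspike interval
$\bar T$ and the OLS slopes $b_A$ (of $A_k/A_1$ on the spike index,
including the unit first point) and $b_T$ (of $T_k/T_1$).
`meets_selection_criteria()` encodes the physiological acceptance region:
$\bar T \in [0.37, 1.38]$ s, $(b_T, b_A)$ in the decaying-amplitude /
growing-interval quadrant (clipped to the observed plot range
$[0, 0.5] \times [-0.25, 0]$ by default — the experimental convex hull is
not published, so the polygon is a configurable input), and a resting
calcium within ±10 nM of 100 nM ("about 100 nM" is stated without a
tolerance; ±10% is adopted once and used throughout).

## Clamped-cGMP attractor analysis

With cGMP clamped, the upstream chain decouples and each oscillator
becomes a 7- or 8-dimensional autonomous system parameterised by $G$
(`clamped_model()`).  `find_attractors()` deliberately avoids numerical
continuation — parts of this attractor structure defeat continuation
software — and instead integrates randomised initial conditions
(fractions uniform in [0,1], $V \in [-90, 30]$ mV, $C \in [10, 3000]$ nM,
pH ∈ [6.5, 8]) past a long transient (default 100 s), classifies tails as
fixed points (Newton-polished, Jacobian eigenvalues) or limit cycles
(calcium peaks recurring with period stable to <1%), and merges
duplicates.  This recovers the known structure: for CaV+BK with BK
removed a single limit cycle of near-constant ~0.2 s period; with BK a
bistable pair of cycles whose upper-branch period grows as $G$ falls; for
CatSper+NHE two coexisting stable equilibria near basal cGMP (the basis
of the voltage-pulse switching experiment) and a cycle/focus pair at
higher $G$.  The full model's spikes track the clamped-model cycle at the
instantaneous cGMP level to within 15% in amplitude and period (asserted
in the tests for mid-train spikes).

## Mixed scenarios and the evolutionary exploration

`mixed_parameters(theta_cv, theta_cs)` builds the extended 16-state model
with CaV and BK conductances scaled by `theta_cv`, CatSper by `theta_cs`,
and leak conductance and calcium extrusion as the corresponding weighted
sums of the two pure-module values; `(1,0)` and `(0,1)` reproduce the
pure modules exactly (machine-precision identity on the shared
coordinates, asserted).  `titrate()` implements the three interpolation
schemes (CaV+BK together, CaV only, BK only); adding BK alone to the
CatSper+NHE oscillator cancels the train at ~10% of the reference BK
conductance while ~1% merely modulates it.

`evolve_population()` explores the downstream parameter space in two
phases: neutral growth from a 21 × 21 grid of module weights
(θ ∈ {10⁻⁴, 0.1, …, 2.0}), each daughter obtained by multiplying every
downstream parameter by an independent lognormal factor
($e^x$, $x \sim N(0, 0.04)$) and appended unconditionally; then selective
growth seeded only from vectors passing the selection criteria.  The
original stopping rules were visual (clouds coalescing, stable
clustering); they are replaced by explicit daughter budgets plus the
cluster summary, all configurable.  Upstream parameters stay fixed at
their fitted point estimates, and the equilibrium-constrained parameters
are re-derived after every mutation so each daughter rests at the imposed
operating point.  `cluster_population()` groups vectors by single-linkage
(connectivity) clustering on $\log_{10}$ conductance coordinates — a
density-style criterion suited to the irregular, elongated clouds the
random walk produces — and reports each cluster's fraction of selected
vectors, the coarse sensitivity measure used to compare regimes.
`module_necessity()` re-simulates a vector with either calcium pathway
cancelled and labels each pathway essential, modulatory or irrelevant.

## Fitting the upstream module

`fit_upstream_cgmp()` fits $\{R_T, r_2, r_3, \delta_G, k_L, k_H\}$ to
multi-dose bulk cGMP kinetics.  During this phase cGMP is carried in the
bulk assay unit (pmol per 10⁸ cells) and the intraflagellar scaling
factor $\theta_G$ is deliberately not applied; the basal synthesis rate
is eliminated through $\sigma = \delta_G G_{basal}$, so the resting
constraint can never be violated by the optimiser.  Parameters are fitted
on a log₁₀ scale inside boxes spanning a factor 30 around the reference
values, with a seeded differential-evolution global stage
(`de_optim()`, rand/1/bin) followed by Levenberg–Marquardt polishing; a
faster multistart-polish path exists for well-conditioned problems such
as the replicate recovery studies.  On synthetic data the fit recovers
the generating parameters exactly at zero noise and with <15% median
error per parameter under 5% multiplicative noise across 20 replicates
(asserted).  A single-dose design leaves $R_T$ and $k_H$ weakly
identified, which the function flags.  `fit_membrane_early()` analogously
fits the KCNG/spHCN conductance densities and the cGMP buffering power to
the first second of the membrane-potential response, re-deriving the leak
reversal at every evaluation.

Digitised experimental kinetics are not bundled (the original numbers
exist only as published graphs); the module ships the synthetic emulator
(`make_cgmp_dataset()`) and accepts user tables in the same long format.

## Synthetic data

`make_fluorescence()` emulates an uncalibrated single-cell fluorescence
recording — intensity proportional to calcium plus baseline and Gaussian
noise (a shot-noise-like option scales the SD with √signal) — and carries
the ground-truth spike list of the noiseless trace, making
detector-recovery experiments self-scoring.  `make_constructed_train()`
generates bump trains whose envelope slopes are exact by construction,
the closure oracle for the whole quantification chain.  What these
generators do *not* emulate: photobleaching, uncaging artefacts, probe
saturation, or flagellar motion; passing the recovery tests therefore
demonstrates correctness of the quantification pipeline, not robustness
to every artefact of real recordings.

## Problem sizes and runtime choices

The test-suite and acceptance-script runs use the study's native
conditions (25-nM and 10-nM pulses, 25–30 s horizons) for the reference
trajectories; broad sweeps are scaled to remain desk-sized: attractor
scans use 3–10 random initial conditions with 25–100 s transients,
evolutionary-search demonstrations use small weight grids with budgets of
a few daughters (the machinery is identical at production scale, where a
full 441-vector grid with hundreds of daughters is simply a larger
budget), and replicate fitting studies use 19 time points per dose over
four doses.  All stochastic steps consume explicit seeds; two runs with
the same configuration are bit-identical.

## Known limitations

* cAMP dynamics are omitted (spHCN is modelled as never inactivating),
  and receptor adaptation/sensitisation is not modelled.
* The model is a mean-field, single-compartment description: no spatial
  structure along the flagellum and no channel-count stochasticity.
* $E_K$ and $E_{Ca}$ do not track the instantaneous ion concentrations.
* The CatSper+NHE oscillatory window at the reference parameter set
  excludes the 25-nM stimulus (see above); conclusions about that module
  at 25 nM depend on parameter digits beyond the quoted precision.
* The experimental envelope-coefficient hull and the percentages of
  experimental recordings falling in each quadrant summarise recordings
  that are not redistributable; the selection polygon is therefore an
  input, defaulting to the clipped quadrant.
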