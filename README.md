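# flagspike

Conductance-based modelling of the calcium spike trains that
sperm-activating peptides (SAPs) evoke in the sea urchin sperm flagellum.

Egg-derived peptides such as Speract trigger, within a second, a cGMP
rise, a membrane hyperpolarisation and then a train of intraflagellar
Ca²⁺ spikes that steers the sperm. Two rival channel circuits can explain
the train downstream of the shared receptor → cGMP → KCNG → spHCN chain:

* **CaV+BK** — T-type Ca²⁺ channels cycling irreversibly through
  inactive → closed → open states, sculpted by the Ca²⁺-activated K⁺
  channel BK;
* **CatSper+NHE** — the pH-, voltage- and Ca²⁺-gated channel CatSper fed
  by a voltage-sensitive Na⁺/H⁺ exchanger that alkalinises the flagellum
  under hyperpolarisation.

`flagspike` implements both circuits, their weighted mixtures and the
analysis toolbox needed to tell them apart: equilibrium parameter
derivations, stimulus / pH-clamp / voltage-pulse protocols, spike-train
statistics with physiological selection criteria, brute-force attractor
analysis of the cGMP-clamped submodels, an evolutionary exploration of
the mixed parameter space, upstream-module fitting, and synthetic-data
generators that double as test oracles.

The core dynamics follow a Hodgkin–Huxley formalism,

$$C_m \dot V = -\big(g_L (V - E_L) + \textstyle\sum_i g_i f_i^o (V - E_i)\big), \qquad
\dot C = \sigma_C - \delta_C C - \tfrac{s_f}{2 v_f F} \textstyle\sum_j I_j,$$

with first-order gating kinetics per channel, a cGMP balance driven by an
irreversible receptor-activation cascade, and (with NHE present) a proton
balance closed by bi-bi exchanger kinetics. The leak reversal potential,
the channel-independent Ca²⁺ source and the proton leak rate are not free
parameters: they are derived from the resting condition (V = −40 mV,
cGMP = 1.25 nM, Ca²⁺ = 100 nM, pH 7.1). See the methods vignette
(`vignettes/flagspike-methods.Rmd`) for the full model account.

## Worked example

```r
library(flagspike)

## equilibrium-constrained parameters of the CaV+BK variant
p <- derive_parameters(reference_params("cav_bk"), module_config("cav_bk"))
round(c(E_L = p$E_L, sigma_C = p$sigma_C), 2)
#>          E_L      sigma_C
#>        80.16 114706541.00

## simulate the standard 25 nM SAP pulse and quantify the train
ts <- simulate_model(p, module_config("cav_bk"),
                     protocol(ev_sap_pulse(0, 25), t_start = -2,
                              end_time = 25))
tr <- detect_spikes(ts)
round(spike_features(tr), 4)
#>    T_bar      b_A      b_T n_spikes
#>   0.6228  -0.0304   0.0270  17.0000
meets_selection_criteria(spike_features(tr), resting_C = 100)
#> [1] TRUE
```

The 25-nM CaV+BK response is a train of 17 spikes whose amplitudes decay
(`b_A < 0`) while the interspike intervals grow (`b_T > 0`), with a mean
interval of 0.62 s — inside the physiological acceptance window — an
inter-spike Ca²⁺ floor around 430 nM, and the elevated activity
collapsing at about 16 s. The CatSper+NHE variant oscillates with equal
Ca²⁺ and pH periods (e.g. under a 10-nM pulse), is abolished and locked
at elevated Ca²⁺ by a sustained pH clamp (`ev_clamp_ph()`), and can be
switched to a coexisting high-Ca²⁺ state by a 0.25-s depolarising pulse
(`ev_voltage_pulse()`) — the package's discriminating experiments between
the two circuits.

Other entry points: `clamped_model()` / `find_attractors()` /
`attractor_sweep()` for the cGMP-clamped bifurcation structure,
`mixed_parameters()` / `titrate()` / `evolve_population()` /
`cluster_population()` for mixed scenarios, `fit_upstream_cgmp()` /
`fit_membrane_early()` for upstream fitting, `make_fluorescence()` /
`make_cgmp_dataset()` / `make_constructed_train()` for synthetic data,
and `run_pipeline()` to compose stages from a YAML/JSON config.

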