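---
title: "Modelling autogenic hot melt extrusion: feed load, melt rheology and the screw-speed correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling autogenic hot melt extrusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sios2)
```

## The problem

Hot melt extrusion (HME) is a standard route to amorphous solid dispersions:
a drug is dissolved in a molten polymer carrier inside a corotating
twin-screw extruder and forced through a die. Finding suitable process
parameters — screw speed, throughput, melt temperature — is costly because
the governing unit operations (conveying, melting, mixing) interact and many
settings only reveal their effect after the process has equilibrated.

This package implements a two-model shortcut, the scale-independent
optimization strategy in its predictive form (SIOS 2.0). It predicts

* the **maximum throughput** from a barrel-load model of the feeding
  section, and
* the **melt temperature as a function of screw speed** from an autogenic
  viscosity correlation coupled to the material's melt rheology,

using only material characterization data plus a handful of extrusion
experiments on the target machine.

## Feed load and slip

The specific feed load `SFL = (m / rho_true) / (n d^3)` is a dimensionless
barrel-load number (mass flow `m`, true density `rho_true`, screw speed `n`,
screw diameter `d`). Its normalized form refers the load to the geometric
transport capacity of the feeding screw,

    SFL* = (m / rho_bulk) / ((1 - s) * l_pitch * A_free * n),

with the bulk density (the powder is uncompacted in the feeding zone), the
pitch `l_pitch` and free cross-section `A_free` of the feeding screw, and a
powder slip fraction `s` — the share of the geometric capacity the powder
does not realize. `SFL* = 0` is an empty feeding section, `SFL* = 1` a
completely filled one; beyond that a backlog forms. Two consequences:

* the maximum transportable mass flow is linear in screw speed with no
  intercept, `m_max = (1 - s) l_pitch A_free rho_bulk n`, so `s` falls out
  of a through-origin regression of `m_max` on `n`
  (`fit_slip()`) or from a single backlog point
  (`slip_from_filled_point()`);
* the maximum specific feed load is a pure material/machine constant,
  `SFLmax = (1 - s) (rho_bulk / rho_true) (A_free l_pitch) / d^3`
  (`sfl_max()`).

For the three bundled polymers the measured slips are narrow
(0.850–0.865), so differences in `SFLmax` are carried almost entirely by
bulk density; the resulting ranking is SOL > bBMA > PVPVA.

## Melt rheology

Melt viscosity follows a Carreau model with Arrhenius
time–temperature superposition,

    eta(gd, T) = eta0 * aT * (1 + aT * gd / gd_c)^(-c),
    aT = exp[(Ea/R) (1/T - 1/T_ref)],

with zero-shear viscosity `eta0` (Pa s), critical shear rate `gd_c` (1/s),
flow index `c` in [0, 1), activation energy `Ea` (J/mol) and a fixed
reference temperature `T_ref` (473 K for all bundled materials). The
Arrhenius form is appropriate far above the glass transition; a WLF shift is
deliberately out of scope. The exponent is negative (shear thinning), the
only reading consistent with the Ostwald relation `n = 1 - c` used by the
shear-rate correction below. `fit_carreau_arrhenius()` refits flow-curve
data by Levenberg–Marquardt least squares on log10 viscosity — viscosity
spans decades, so log-space residuals weight the decades evenly, which is
standard rheometry practice. Data at a single temperature leave `Ea`
unidentifiable and are rejected.

Temperature enters the model only through `aT`, and viscosity is strictly
monotone in it, so the inverse problem "which temperature produces viscosity
`eta*` at shear rate `gd`" has a unique solution but no closed form.
`invert_temperature()` brackets it on `T_ref ± 150 K` — generously wider
than any melt-extrusion-relevant window — and solves by `uniroot` to an
absolute tolerance of 1e-6 K. The tolerance is deliberately far below the
0.01 K reporting precision: the inversion sits inside the simulator and the
prediction chain, and a looser tolerance would leak into the fitted
correlation parameters at the 1e-5 level.

## The die as a capillary rheometer

With a pressure gauge at the die, every steady-state operating point yields
a viscosity measurement: wall shear stress `tau = dp * r_die / (2 l_die)`
over apparent wall shear rate `gd = 4 V / (pi r_die^3)` (Hagen–Poiseuille,
cylindrical die). For shear-thinning melts the apparent rate is corrected
after Weissenberg–Rabinowitsch, `gd_corr = (3n+1)/(4n) gd` with
`n = 1 - c`. Design choices here:

* The volume flow through the die is mass flow over **true density**; the
  melt density is not separately characterized, and the true density is the
  closest measured quantity. Readers with melt PVT data can pass their own
  density by constructing the volume flow directly.
* The die viscosity used by the correlations below applies the WR
  correction to the shear rate only (the stress is unchanged), matching how
  the correction is defined; `wr_correct = FALSE` switches to the apparent
  value for sensitivity analysis.
* Entrance-pressure (Bagley/Cogswell) corrections are out of scope; the die
  viscosities are therefore comparative rather than absolute.

## The autogenic correlations

In autogenic operation the barrel heaters are off and the melt temperature
is set entirely by viscous dissipation. This makes the process self-
regulating: a more viscous melt dissipates more screw power, heats up, and
thins; a less viscous one cools and thickens. Empirically the die viscosity
then depends on screw speed alone, not on the material:

    eta_die = tau_extruder / n,

where `tau_extruder` (Pa) is a characteristic stress of the machine in its
given screw/die configuration — its particular value has no physical
interpretation because screw speed, not a true shear rate, sits in the
denominator. `fit_tau_extruder()` estimates it as the mean of
`eta_die * n` over operating points, reported with its standard deviation;
the mean (rather than a nonlinear fit of `eta_die` against `1/n`) weights
all speeds equally and reports dispersion in the same units.

The second correlation ties the die viscosity to the material model.
Ideally `eta_die` would equal the Carreau–Arrhenius viscosity
`eta_calc` evaluated at the corrected die shear rate and the measured melt
temperature; a production extruder is an imperfect rheometer, but the ratio
is systematic on log–log axes:

    lg(eta_die / eta_calc) = s_extruder * lg(n / n_max) + i_extruder,

with `n_max` the machine's nominal speed and lg = log10
(`fit_viscosity_ratio()`, ordinary least squares, Pearson R of the
regression reported). Both fits exclude observations below 100 rpm
(configurable): at very low throughput the thermal equilibration to the
autogenic steady state is incomplete and the hyperbola visibly breaks down,
so those points carry a different physics, not just more noise.

Chaining the two correlations **predicts an operating point from screw
speed alone** (`predict_operating_point()`): mass flow from `SFLmax`, die
viscosity from the hyperbola, extruder-independent viscosity from the
log–log correlation, and melt temperature by numerically inverting the
Carreau–Arrhenius model. For physically sensible parameters (`Ea > 0`,
`s_extruder < 1`) the predicted melt temperature increases monotonically
with screw speed.

Because `tau_extruder`, `s_extruder` and `i_extruder` characterize the
machine, they transfer across materials. `crossover_parameters()` combines
donor fits by arithmetic mean — the natural choice given that an average
characteristic stress is already used to describe all materials on one
machine, and with only two donors nothing more elaborate is identifiable.
`crossover_validation()` then compares predictions for a material against
its own measured table, reporting per-point temperature differences and
relative mass-flow deviations (the mass-flow comparison uses the target's
bulk density with the donors' slip).

## The virtual extruder

`simulate_autogenic_campaign()` inverts the prediction chain to generate
steady-state observation tables from ground truth: at each speed the mass
flow fills the feeding section exactly (`SFL* = 1`, emulating a campaign
that ramps throughput and speed together at maximum barrel load), the die
pressure follows from the target die viscosity, and the melt temperature
from the temperature inversion. Gaussian measurement noise is then added —
additive on temperature (IR-camera-like, default 1 K) and multiplicative on
pressure (gauge-like, default 1%); no error model is available from
measured campaigns, so these are conventional instrument-class magnitudes.
The default speed ramp is 8 points from 100 to 500 rpm, respecting the
fitting window's lower edge. Campaigns are deterministic for a fixed seed.

What the simulator does **not** emulate: thermal transients and incomplete
equilibration (the very effect that motivates the 100 rpm cut), torque and
feeder limits, entrance-pressure effects, moisture plasticization, and any
drift of the extruder parameters with temperature. Passing closed-loop
tests therefore demonstrates the internal consistency of the fitting and
prediction chain, not the physical adequacy of the correlations — that
evidence must come from hardware campaigns.

## Reference data and chosen constants

The package bundles three carrier polymers (PVPVA/Plasdone S-630,
SOL/Soluplus, bBMA/Eudragit EPO) with refitted Carreau–Arrhenius
parameters, measured bulk/true densities and filled-section slips, plus a
27 mm class twin-screw geometry (28.3 mm screw, 4.91e-4 m² free
cross-section, 3 mm × 11.7 mm die). Two geometry values are not part of the
measured record and are package choices, overridable in
`zse27_geometry()`:

* `l_pitch = 0.0283 m` — square-pitched (one-diameter) conveying elements,
  the common feeding-section choice for this machine class. Consistency
  check: with this pitch the printed slips put the backlog speeds of all
  three polymers inside the 20–200 rpm range actually scanned.
* `n_max = 1200 rpm` — the nominal speed rating of the machine class; with
  it, the maximum campaign throughput of ~42 kg/h for PVPVA corresponds to
  ~1180 rpm, i.e. the campaigns end right at nominal capacity.

Extruder-parameter ground truths used in tests and the acceptance script
(tau 399/361/361 Pa, slopes 0.409/0.318/0.126, intercepts
0.131/0.036/0.045) are the fitted values measured on that machine.

## Numerical and testing choices

* Internal units are strictly SI (1/s, K, Pa, kg/s); rpm, °C, bar and kg/h
  exist only in file readers/writers and printed tables.
* Slip estimates ≥ 1 are errors (inconsistent with a filled section);
  negative estimates are returned unclamped with a warning, so downstream
  code can decide — silent clamping would fabricate a physical value.
* Problem sizes in the test-suite: 8-speed campaigns, 100-instance
  inversion-oracle sweeps, 200-replicate noise-recovery studies. These are
  the sizes at which the Monte-Carlo error of the recovery checks
  (bias ≈ sd/14 at 200 replicates) is comfortably below the asserted
  bias < sd/10 band; noise-recovery tolerances in unit tests were frozen
  from a one-off repeated-seed calibration at ~4 empirical standard
  deviations before the tests were written.
* The crossover bound of 5 K is asserted for speeds ≥ 500 rpm on a
  150–1000 rpm sweep: the transfer error is largest at low speed (where the
  donors' and target's log–log lines diverge) and production processes
  target the high-speed, high-throughput regime.

## Known limitations

The correlations are machine-specific: `tau_extruder`, `s_extruder`,
`i_extruder` must be refitted after any screw or die change. The method
presumes autogenic steady state; barrel-heated operation breaks the
self-regulation argument. Mass-flow crossover accuracy is limited by how
similar the donors' slip is to the target's — with the bundled materials
the transferred slip mispredicts mass flow by up to ~8%, which is why slip
should be measured per material whenever the feeding experiments are
affordable. Finally, one bundled material (bBMA) is known to follow its
literature rheology less closely; its crossover temperature predictions are
systematically low, though within ~5 K at production-relevant speeds.
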