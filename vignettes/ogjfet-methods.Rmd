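---
title: "Modelling an open-gate JFET biosensor: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an open-gate JFET biosensor: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogjfet)
```

## The device and the sensing principle

The open-gate JFET (OG-JFET) is a p-channel junction field-effect
transistor whose top gate is removed: a thin p-type epitaxial channel
(1.6 µm, $N_A = 5\times10^{15}\,\mathrm{cm^{-3}}$) sits on a thick n-type
substrate (450 µm, $N_D = 1\times10^{18}\,\mathrm{cm^{-3}}$), and the
channel is exposed to the sample through a native-SiO$_2$ window of length
$L_{OG} = 100$ µm.  Two knobs modulate the hole current between source and
drain:

* the **back gate** — the substrate-side of the p–n junction.  Reverse
  bias (back gate positive) widens the junction depletion region and thins
  the conducting channel from below; beyond roughly 0.67 V of forward
  drain-to-gate voltage the junction conducts directly (classified by
  `bias_mode()`, estimated only at ideal-diode level by
  `forward_diode_current()` — reverse mode is the sensing mode);
* the **sensing window** — charge bound at the oxide surface images into
  the semiconductor.  Positive surface charge depletes the channel from
  above; negative surface charge accumulates holes and raises the current.

`ogjfet` implements this chain end to end: interface electrochemistry →
vertical device electrostatics and transport → lateral channel current →
the characterization analyses applied to measured or synthetic data.

## Site-binding model of the oxide/electrolyte interface

The native oxide carries amphoteric silanol sites S–OH that protonate to
S–OH$_2^+$ (acid constant $K_a$, $\mathrm{p}K_a = 6$) or deprotonate to
S–O$^-$ (base constant $K_b$, $\mathrm{p}K_b = -2$).  The model is the
standard two-reaction site-binding description:

* point of zero charge $\mathrm{pH_{pzc}} = (\mathrm{p}K_a +
  \mathrm{p}K_b)/2 = 2$ for the defaults;
* surface potential
  $\psi_0 = -\ln 10\,\delta_w\,(k_BT/q)\,(\mathrm{pH} -
  \mathrm{pH_{pzc}})$ with the Nernst-attenuation factor
  $\delta_w = \beta/(\beta+1)$,
  $\beta = q^2 N_s \eta / (C_{eq} k_B T)$ and
  $\eta = 2\cdot 10^{-\Delta pK/2}$;
* surface proton activity
  $[H_s^+] = 10^{-\mathrm{pH}} e^{-q\psi_0/k_BT}$;
* surface charge density
  $\sigma_0 = qN_s\,\frac{H_s/K_a - K_b/H_s}{H_s/K_a + K_b/H_s + 1}$,
  bounded by $\pm qN_s$ and strictly increasing in $H_s$.

Two conventions had to be fixed where the site-binding literature is not
uniform:

* **$\Delta pK$** is taken as $\mathrm{p}K_a - \mathrm{p}K_b$ (= 8 for
  SiO$_2$ here, giving $\eta = 2\times10^{-4}$), the usual ISFET
  convention; the opposite sign is available through
  `oxide_surface(dpK_convention = "pKb_minus_pKa")` for sensitivity
  studies.
* **Equilibrium constants** follow
  $K_a = [\mathrm{SOH}][H_s]/[\mathrm{SOH_2^+}]$ and
  $K_b = [\mathrm{SO^-}][H_s]/[\mathrm{SOH}]$ literally, so
  $\mathrm{p}K_b = -2$ means $K_b = 100$ mol/L.  No re-interpretation is
  applied even though this makes the surface essentially fully
  deprotonated (σ$_0$ saturated near $-qN_s$) for pH ≳ 4.

The equivalent double-layer capacitance $C_{eq}$ has no published value
for this device; the default 0.2 F/m² (20 µF/cm²) is a standard
Gouy–Chapman–Stern magnitude and is exposed in the `[oxide]` configuration
block.  With $N_s = 5\times10^{12}\,\mathrm{cm^{-2}}$ this yields
$\beta \approx 3\times10^{-4}$: the closed-form surface-potential response
of native SiO$_2$ in this parameterization is strongly sub-Nernstian.  The
$\delta_w \to 1$ Nernst limit (−59.16 mV/pH at 298.15 K) is recovered as
$C_{eq}\to 0$ and is exercised in the tests.

$\psi_0$ is computed by the closed form, not by self-consistent iteration
against a double-layer model — that is how the charge table feeding the
device simulation is generated, and it is the reference behaviour; a
self-consistent loop would add a capacitance model without changing the
monotone structure the device model consumes.

```{r ph-table}
ph_charge_table(c(2, 4, 7, 9), oxide_surface())
```

## Drift-diffusion device core

The vertical structure is discretized in 1-D from the gate window
($x = 0$) to the back contact ($x = t_p + t_n$) by a finite-volume mesh
(`build_mesh()`), geometrically graded with three refinement anchors —
the surface (0.2 nm cells, enough to resolve sub-nanometre hole
accumulation layers), the metallurgical junction
($\sigma_{gauss}/4$ cells), and the back contact — with adjacent cells
never differing by more than a chosen ratio (default 1.5, capped at 3).
Doping is analytic: each species is constant in its home region and
decays as a Gaussian of length `gauss_sigma` (50 nm default) past the
junction, giving exactly one sign change.

Three solvers share the discretization:

* **`solve_equilibrium()`** — damped Newton on the nonlinear Poisson
  equation with equilibrium statistics.  The update is damped as
  $\delta\psi/(1+|\delta\psi|/4V_t)$, which saturates large excursions at
  a few thermal voltages per iteration and converges globally for these
  structures; convergence is declared when the largest update falls below
  $10^{-6}V_t$.
* **`solve_channel()`** — the same Poisson problem with split, spatially
  constant quasi-Fermi levels: holes at the local channel potential and
  electrons at the back-gate potential $V_r$.  This is the per-station
  vertical problem of the gradual-channel approximation.  The gate window
  enters as a displacement jump $\varepsilon\,\partial_x\psi = -\sigma_0$
  at the top boundary (the native oxide, 0.2–1 nm thick, is far below any
  practical mesh's electrostatic relevance and is treated as an
  infinitely thin charge sheet).  Continuation steps of 0.5 V in bias and
  2 mC/m² in surface charge warm-start each solve.
* **`solve_bias()`** — full Gummel iteration for the vertical diode
  between the top p-contact and the back gate: Poisson alternated with
  the two continuity equations, Scharfetter–Gummel exponential-fitting on
  every edge, Shockley–Read–Hall recombination
  $U = (np - n_i^2) / (\tau_p(n + n_1) + \tau_n(p + p_1))$ with a midgap
  trap ($n_1 = p_1 = n_i$), ohmic contacts as charge-neutral Dirichlet
  conditions, and bias continuation in 0.1 V steps.  Forward junction
  voltages above 0.85 V are refused (current overflow guard).  After
  convergence a flux-consistency pass re-solves both continuity equations
  against the identical frozen recombination field, which makes the
  discrete total current telescoping-exact across edges up to linear
  algebra roundoff.

Boltzmann statistics are the default carrier model.  A Fermi–Dirac option
(`material(statistics = "fermi_dirac")`) replaces the exponential carrier
relations with the $F_{1/2}$ integral (Bednarczyk–Bednarczyk approximant,
Joyce–Dixon inverse) in the equilibrium and contact relations; at the
substrate doping used here ($n/N_c \approx 0.036$) the correction to the
contact potential is a few millivolts, and the tests pin that comparison.
Band edges follow $E_c = -(V+\chi_0)-\alpha\,\Delta E_g$ and
$E_v = -(V+\chi_0+E_{g,0})+(1-\alpha)\Delta E_g$; bandgap narrowing is
off by default ($\Delta E_g = 0$, $\alpha = 0.5$), preserving
$E_c - E_v = E_{g,0}$ identically.

Material parameters not documented for the physical device use standard
silicon room-temperature values, all configurable:
$n_i = 10^{10}\,\mathrm{cm^{-3}}$ (at 300 K),
$\mu_n = 1417$, $\mu_p = 470\,\mathrm{cm^2/Vs}$ (constant, no field
dependence), $\tau_n = \tau_p = 1\,\mu s$, $\varepsilon_r = 11.7$.  The
implied p-layer resistivity $1/(qN_A\mu_p) \approx 2.66\,\Omega$cm is
consistent with the epitaxial specification of 3.0 Ωcm ± 10%.

### Numerical precision of terminal currents

Terminal currents are reported as the median edge total current times the
gate-window area, together with two diagnostics: the in/out contact
mismatch and the full edge spread.  In forward conduction these sit at
machine precision.  In deep reverse bias the 1-D leakage is
generation-limited to sub-picoamperes while the majority-carrier edge
fluxes it is computed from are ~12 orders of magnitude larger, so the
extracted current differences sit near the resolution of double-precision
subtraction; the conservation diagnostic is then noise-dominated and not
meaningful.  Quantitative conservation checks are therefore made on the
conducting regime (forward bias ≥ 0.3 V), where the criterion
$|I_{in}-I_{out}|/|I| < 10^{-4}$ holds comfortably.  This is a
floating-point statement about 1-D diode leakage, not a limitation of the
sensing-mode channel model, which never differences those fluxes.

## Gradual-channel current and the monotone response chain

`channel_current()` composes the vertical solves laterally.  At channel
potential $V \in [0, V_{ds}]$ the local junction reverse bias is
$V_{gs} + V$; the vertical solution there provides the **integrated hole
sheet density** $P_s = \int p\,dx$, and

$$I_{ds} = \frac{\mathrm{depth}}{L_{OG}} \int_0^{V_{ds}}
  q\,\mu_p\,P_s(V_{gs}+V)\,dV.$$

Using $\int p\,dx$ rather than a geometric "undepleted thickness" was a
deliberate choice: one definition covers both regimes — junction/surface
depletion ($P_s \approx N_A\,b$ with $b$ the undepleted thickness) and
surface accumulation under negative gate charge ($P_s$ gains
$|\sigma_0|/q$ mobile holes; with an insulated window the semiconductor
must image the full sheet charge).  $P_s(V_r)$ is tabulated on a 0.5 V
grid and interpolated monotonically (Hyman-filtered spline); pinch-off
needs no special casing because the integrand itself vanishes when the
bulk channel depletes, holding the integral at its pinch-off value, and a
fully pinched channel returns a configurable leakage floor.

This produces the qualitative response structure expected of the sensor:
higher pH → more negative σ₀ → more accumulated holes → higher current
(strictly ordered across pH 4–9, although with the saturated SiO$_2$
charge model the spacings are small); current decreasing in reverse
back-gate bias; output curves separating more in saturation than in the
ohmic region.  σ₀ is applied uniformly over the window (uniform analyte
coverage; site-density non-uniformity of real native oxide is out of
scope).  An equivalent-gate-potential coupling instead of the direct
charge boundary condition would be the main modelling alternative; the
charge form was chosen because it requires no extra capacitance
parameter.

Pinch-off is handled by clamping (no channel-length modulation), and the
forward-conduction mode is classified but not quantitatively modelled —
its current traverses the 450 µm substrate in 2-D, outside a vertical-1-D
description.  Absolute currents of the physical device are likewise not a
target: contact resistance and 2-D spreading are unmodelled.

## Extraction analyses

* `reference_voltage()` — piecewise-linear inverse interpolation of the
  back-gate voltage at a reference current, the simplest monotone method;
  input order is irrelevant, extrapolation is refused.  The grid
  resolution bounds the interpolation error and is the user's knob.
* `voltage_sensitivity()` / `current_sensitivity()` — unweighted ordinary
  least squares of reference voltage (or current) against analyte level,
  reporting slope, intercept, $r^2$ (linearity is part of the scientific
  claim) and the slope standard error.
* `step_response()` — the changepoint is the split maximizing the
  normalized two-sample mean contrast (CUSUM-type statistic); baseline
  and plateau are medians of the two segments; the noise floor is
  estimated from the median absolute first difference, and a shift below
  `noise_mult` (default 6) times that floor reports "no event" rather
  than a fold change.  The 10–90% transition time is measured on a
  rolling-median-smoothed copy.  All window parameters live in the
  `[extraction]` configuration block.
* `debye_length()` — $\lambda_D = \sqrt{\varepsilon_r\varepsilon_0 k_B T
  / (2 N_A q^2 \cdot 10^3 I)}$ for a 1:1-equivalent ionic strength $I$ in
  mol/L; defaults $\varepsilon_r = 78.5$, 298.15 K give 0.785 nm at
  physiological 0.15 M, inside the 0.7–2.2 nm band expected for 1X PBS.

## Synthetic data: what it emulates and what it does not

The generator (`generator_spec()`, `parametric_iv_family()`,
`step_trace()`) is a square-law JFET surrogate —
$I_{ds} = I_{dss}(1 - V_{gs,eff}/V_p)^2$ in saturation, the textbook
linear region below — deliberately independent of the drift-diffusion
solver, so that extraction correctness is established by exact
planted-parameter recovery rather than by the solver's own output.  Both
sources can feed the extraction module.  Defaults $I_{dss} = 1$ mA and
$V_p = 2$ V put the curves in the measured device's current range with
the standard reference currents (0.45–0.65 mA) inside every sweep.

Planted effects: a constant gate shift per analyte unit (parallel
curves); a current-keyed shift table interpolated monotonically in
current (non-parallel curves, reproducing reference-current-dependent
sensitivities — the transformation is refused if the table is so steep at
the requested levels that the sweep would fold); a per-level current
offset; additive i.i.d. Gaussian current noise, seeded and bitwise
reproducible.  The study conditions planted by default are the measured
characterization series: pH 4–9 at 51.26 mV/pH (reference 0.5 mA),
ssDNA at 101–370 ng/µL with 29.38–41.40 mV per concentration unit at
0.45–0.65 mA, cells at 25–100% with 0.15 mA per percent, and a
0.5 → 2.5 mA exhalation step.

Not emulated: drift, hysteresis, 1/f noise, temperature dependence,
probe-station artifacts.  Passing recovery tests therefore demonstrates
the correctness of the extraction arithmetic on well-behaved curves, not
robustness to real measurement pathologies.

## Configuration and interchange

Configuration is JSON (`load_config()`), blocks `device`, `material`,
`oxide`, `solver`, `extraction`; unknown blocks or keys are rejected by
name, positivity constraints are enforced, defaulted values are logged.
Lengths are accepted in µm and dopings in cm⁻³ at the configuration
surface, converted to SI internally.  CSV is the sole tabular
interchange, written at 12 significant digits so a write/read round trip
is lossless at double precision.  The command-line wrapper
(`cli_run()`, `inst/scripts/ogjfet-cli.R`) exposes `ph-sweep`,
`simulate`, `extract`, `synth` and `debye`.

## Problem sizes used in the shipped checks

The test suite and acceptance script run the equilibrium and channel
solves on 200–400-node meshes, transfer families on a 6-pH × 3-point
back-gate grid at $V_{ds} = 10$ V, output families on 2–3 pH levels, the
noisy-recovery study on 200 replicate seeds of 6-curve families, and the
synthetic recoveries on 150–180-point sweeps.  These sizes resolve every
quantity being asserted (mesh-halving moves the oracle comparisons well
inside their tolerances) while keeping a full run in tens of seconds.
The noisy-recovery check asserts coverage of the t-based 95% confidence
band within two binomial standard errors of its nominal rate — a
Monte-Carlo allowance fixed in advance, since an exact ≥95% threshold on
200 replicates would fail almost half the time for a perfectly calibrated
estimator.

## Known limitations

* 1-D vertical electrostatics + gradual channel, not 2-D finite elements:
  no lateral fringing at the window edges, no distinct source/drain
  implant regions, no substrate spreading resistance.
* The saturated site-binding charge of SiO$_2$ in this parameterization
  makes simulated pH spacings orders of magnitude smaller than measured
  super-Nernstian responses; the monotone structure, not the magnitude,
  is the modelled content.
* Constant mobilities; no impact ionization; no transients; isothermal
  (thermal-diffusion transport terms dropped).
* Reverse-bias 1-D leakage currents are physically meaningful in order of
  magnitude only (see the precision note above).
* Biomolecule and cell charge is represented only through planted shifts
  in the generator — no microscopic charge model for DNA or cells.
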