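---
title: "Ring-polymer dynamics for dissociative photodetachment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ring-polymer dynamics for dissociative photodetachment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The physical problem

When a photon detaches the excess electron from a molecular anion, the
nuclei are suddenly handed over from the bound anionic potential-energy
surface $V_a$ to the neutral surface $V_n$ at fixed positions and momenta
(the vertical, or Franck–Condon, approximation). If the neutral surface is
repulsive at the anion geometry, the molecule dissociates, and the
experiment records two correlated observables: the kinetic energy of the
detached electron (equivalently the electron binding energy
$E_b = h\nu - eKE$) and the translational kinetic-energy release $E_k$
between the heavy fragments. Because the parent anion is sampled at finite
temperature and light nuclei spread quantum mechanically, both observables
are broadened by the *quantum* thermal density of the nuclei, not the
classical one.

`rpdyn` implements this workflow end to end with the nuclear quantum
effects treated by the imaginary-time path-integral isomorphism:

1. **PIMD sampling** of the anionic state's quantum Boltzmann density,
2. **vertical detachment** of sampled configurations,
3. **RPMD propagation** of the dissociation on the neutral surface,
4. **observables**: the semiclassical photoelectron spectrum $I(E_b)$, the
   coincidence histogram $N(E_k, E_b)$, and per-trajectory product records
   (kinetic-energy release, cis/trans torsional channel, dissociation time
   and mechanism).

Electronic structure enters only through a *potential-surface contract*
(`potential_surface()`): energy, gradient and optionally a Hessian at any
geometry. In production studies of real molecules that contract is served
by on-the-fly quantum chemistry; here it is served by analytic model
surfaces so that every stage of the method is exercisable and verifiable on
a desk machine. The physics of the workflow is unchanged by that swap —
only the realism of the surface is.

## The ring-polymer model

For $n$ atoms and $N$ beads the classical-isomorphism Hamiltonian used
throughout is

$$
H_N(P, Q) \;=\; \sum_{i=1}^{n}\sum_{s=1}^{N}
   \frac{(P_i^s)^2}{2 m_i / N}
 + \sum_{i=1}^{n}\sum_{s=1}^{N} \frac{m_i N}{2 \beta^2 \hbar^2}
   \left(Q_i^s - Q_i^{s-1}\right)^2
 + \frac{1}{N} \sum_{s=1}^{N} V(Q^s),
$$

with cyclic bead indexing ($Q^0 \equiv Q^N$) and $\beta = 1/k_B T$. The
kinetic term uses the fictitious bead mass $m_i/N$; this scaling, together
with the $1/N$ on the potential, makes $H_N$ the standard primitive
ring-polymer Hamiltonian with conjugately rescaled momenta, so the
position-space Boltzmann distribution $\propto e^{-\beta H_N}$ is exactly
the standard finite-$N$ path-integral density. Consequences worth stating
explicitly:

* bead velocities are $N P_i^s / m_i$, and the **centroid velocity** of an
  atom is $N \,\overline{P_i^s} / m_i$ — this is the velocity used for
  fragment kinetic-energy release;
* equipartition gives each bead degree of freedom $k_B T/2$ of kinetic
  energy;
* with $N = 1$ every formula collapses to classical mechanics exactly (the
  spring term vanishes identically), so classical MD is the 1-bead special
  case of the same code path, not a separate implementation.

Position statistics sampled from $e^{-\beta H_N}$ are independent of the
momentum-scaling convention (the Hamiltonian is separable); a property test
asserts this by rescaling momenta and recomputing.

Internally everything is computed in Hartree atomic units ($\hbar = 1$),
with angstrom / eV / fs / amu / kelvin at every interface and all
conversion factors centralized in `unit_system()`. This removes unit
arithmetic from the dynamics entirely; model-unit studies (e.g. the
harmonic-oscillator benchmarks with $m = \omega = \hbar = 1$) set the
state via `units = "au"` and `thermo_context(beta = ...)`.

## Thermostatted sampling (PIMD)

`pimd_sample()` integrates the ring-polymer equations of motion with
velocity Verlet and a **massive Nosé–Hoover chain** thermostat: an
independent chain of $M$ links on every Cartesian degree of freedom of
every bead. Massive chains are the standard choice for path integrals
because the stiff, weakly anharmonic spring modes equilibrate poorly under
a single global thermostat.

Thermostat parameters (all exposed in `sampler_config()`):

| parameter | default | meaning |
|---|---|---|
| `m_links` | 4 | chain length per DOF |
| `tau_steps` | 20 | chain time constant, in units of $\Delta t$ |
| thermostat masses | $k_B T \tau^2$ | all links |
| splitting | half/full/half | symmetric, time-reversible |

The defaults are conventional robust choices; the chain update is the
standard reversible sweep (update links top-down, scale momenta, advance
link positions, sweep back up). We verified during calibration that
$\tau = 20\,\Delta t$ also decorrelates the slow centroid mode of a
harmonic test system faster than substantially shorter or longer time
constants, which matters for the statistical quality of sampled variances.

Sampling schedule: `burn_in` defaults to 20% of `n_steps`, and every
`sample_stride`-th post-burn-in configuration is recorded (stride 10 by
default). Initial conditions come from `initialize_thermal()`: beads
jittered around the template geometry with a small Gaussian spread
(default 0.05 Å) and Maxwell momenta consistent with the bead-mass
convention. Diagnostics (instantaneous temperature, Hamiltonian
components) are recorded on a stride and returned as a tibble.

The production-style defaults — 300 K, 32 beads, $\Delta t = 0.3$ fs,
$10^5$ steps — are the conditions under which the centroid-Taylor force
approximation (below) is accurate for molecular systems; the test suite
and the acceptance script scale `n_steps` down to desk size (stated per
run below) while keeping those physical conditions.

### Correctness anchors

The sampling stack is verified against closed forms rather than against
itself:

* **exact finite-$N$ Gaussian**: on a harmonic surface the ring-polymer
  position distribution is Gaussian with covariance
  $(\beta A)^{-1}$, $A = (m\omega^2/N) I + (mN/\beta^2\hbar^2) L$ ($L$ the
  cyclic Laplacian). A 4-bead sampler run is compared against this matrix
  inverse — the small-instance oracle for the whole stack.
* **quantum vs classical variance**: at $\beta\hbar\omega = 3$, a 32-bead
  run must reproduce $\langle x^2\rangle = (\hbar/2m\omega)
  \coth(\beta\hbar\omega/2)$ and a 1-bead run $k_BT/m\omega^2$, each
  within 2%; the quantum value strictly exceeds the classical one. With
  the thermostat above, an $8\times10^5$-step run (quantum) and a
  $6\times10^5$-step run (classical) carry a measured seed-to-seed spread
  of about 1%, giving that 2% check a comfortable margin.
* a high-barrier double well sampled at 300 K must never cross wells, and
  bead marginals must be exchangeable (chi-squared test).

## Centroid Taylor forces

The expensive part of on-the-fly path-integral dynamics is $N$ gradient
evaluations per step. The package implements the standard centroid
second-order Taylor approximation,

$$
\left(\frac{\partial V}{\partial Q}\right)_{Q_s} \approx
\left(\frac{\partial V}{\partial Q}\right)_{Q_c} +
\left(\frac{\partial^2 V}{\partial Q^2}\right)_{Q_c} (Q_s - Q_c),
$$

which replaces them with one gradient and one Hessian at the bead centroid
$Q_c$. The approximation is exact for quadratic surfaces (asserted at
machine precision) and its error grows quadratically with the bead spread
(asserted as a log–log slope of 2 on a cubic surface); since the spread
shrinks with temperature, the approximation is reliable above roughly
200 K — requesting it below that emits a warning rather than an error,
because the cutoff is soft.

Design choices here:

* the Hessian is **recomputed every step** at the current centroid by
  default (`hessian_stride = 1`), matching the per-step on-the-fly spirit;
  larger strides are an offered optimization;
* surfaces without an analytic Hessian get a symmetrized central finite
  difference of the *gradient* (step $10^{-3}$ Å), which is cheaper and
  better conditioned than second differences of the energy;
* spectra always use exact model energies at bead positions; the Taylor
  expansion applies to forces during dynamics only.

One practical caveat discovered while validating: "identical trajectories
on quadratic surfaces" can only mean *machine-precision* identical.
Algebraically equal force expressions differ by an ulp in floating point,
and thermostatted dynamics is chaotic by design, so ulp differences
amplify exponentially under the chain. The tests therefore assert exact
agreement of forces and of thermostat-free (linear, hence non-chaotic)
trajectories.

## Detachment and real-time dynamics (RPMD)

`detach()` switches selected ensemble members to the neutral surface
without touching positions or momenta, and tags each event with its
binding energy. For a multi-bead configuration the event's $E_b$ is the
**bead-averaged** gap $\overline{V_n(Q^s) - V_a(Q^s)}$, consistent with
the per-bead spectral convention; the centroid-gap alternative differs
only at second order in the bead spread.

`propagate_nve()` integrates the same equations of motion without the
thermostat — real-time RPMD — conserving $H_N$. Momenta are the PIMD
momenta carried over (a thermal resampling option exists but is off by
default). Trajectories record centroid positions, centroid velocities and
the conserved Hamiltonian on a uniform time grid; integration failures
become an `"error"` terminal status so ensemble runs always complete.

Termination: the default production rule is fragment-separation
(`stop_rule_distance()`, default 8 Å sustained for 50 steps on molecular
fixtures). Dissociation *timing* is deliberately decoupled from
termination and measured in post-processing from the relative-velocity
plateau (below), because "the dissociation is complete" is a statement
about the velocity profile, not about any particular distance.

Conservation versus step size: velocity-Verlet energy error scales as
$(\omega_{\max}\Delta t)^2$. At 300 K with 32 beads the stiffest spring
mode has a ~2.5 fs period, so the production step of 0.3 fs conserves
$H_N$ at the $10^{-4}$ relative level — ample for classifying products —
while the $10^{-6}$-level conservation checks in the tests use a 1-bead
system at $\Delta t = 0.01$ fs, where that tolerance is attainable. The
trade-off is intrinsic to the integrator, not to this implementation; the
time-reversal test (forward, negate momenta, backward, recover the start
to $10^{-8}$) pins down symplecticity independent of step size.

## Spectra

`photoelectron_spectrum()` realizes the semiclassical mapping
$I(E_b) \propto \int \delta\!\left(E_b - V_n(Q) + V_a(Q)\right) \rho_a(Q)\,dQ$
by histogramming the vertical gap over the sampled ensemble. Conventions:

* **per-bead** evaluation is the default — bead positions are samples of
  the quantum density $\rho_a$, so each bead contributes one sample;
  per-centroid is retained for comparison and coincides exactly at
  $N = 1$;
* the delta function is a histogram with 0.02 eV bins by default, with an
  optional Gaussian kernel; the raw sample mean and standard deviation are
  stored on the object so moment comparisons do not inherit binning bias;
* $E_b$ is measured from the anion reference (the sampled state), so the
  spectrum sits at the vertical gap of the Franck–Condon region.

The exactly solvable anchor is the **reflection principle**: a linear gap
$a\,x$ over a Gaussian density of width $\sigma$ must give a Gaussian
spectrum of standard deviation $|a|\sigma$ (asserted within 5% at $10^5$
samples). The qualitative anchor is spectral broadening by nuclear quantum
effects: on the bound-to-repulsive toy system in the quantum regime the
32-bead spectrum variance strictly exceeds the 1-bead variance, because
classical sampling misses zero-point spread along the mapped coordinate.

`coincidence_spectrum()` is a counting 2D histogram over dissociated
product records; undissociated records are excluded and reported, and the
marginals equal independently computed 1D histograms by construction.

## Product analysis

* **Kinetic-energy release**: $E_k = \tfrac12 \mu |v_A - v_B|^2$ from
  mass-weighted fragment center-of-mass *centroid* velocities, with
  $\mu = M_A M_B/(M_A + M_B)$; Galilean invariant by construction.
* **Torsional channel**: the signed dihedral follows the standard
  right-hand-rule torsion convention (and is therefore *invariant* under
  reversing the atom order, a property the tests assert). For reporting,
  angles are mapped to $(-90^\circ, 270^\circ]$ so the trans band around
  $180^\circ$ stays contiguous in histograms; the classifier is cis on
  $(-90^\circ, 90^\circ]$ and trans on $(90^\circ, 270^\circ]$ — a
  symmetric boundary between the two observed product bands (trans
  products cluster near 150–210°, cis products near ±45°).
* **Dissociation time**: the first time the fragment relative speed varies
  by less than `plateau_tol` (default $10^{-4}$ Å/fs) across a sliding
  window (default 10 fs) while the separation increases. The mechanism is
  *direct* if that time is below the cutoff (default 75 fs, the upper end
  of the direct-dissociation window in this class of systems) and
  *indirect* otherwise. The plateau rule quantifies what is visually read
  off relative-velocity/time plots; the cutoff is the one genuinely free
  parameter and is exposed.
* `boltzmann_ratio()` is the one-line equilibrium helper: a 0.38 eV isomer
  gap at 300 K gives $\sim 4\times10^{-7}$, i.e. "roughly $1:10^{-6}$" —
  why only the most stable isomer is experimentally accessible.

## The model systems: what they emulate and what they do not

`toy_photodetachment_system()` is a pseudo-diatomic two-state pair:
$V_a = \tfrac12 k (R - R_0)^2$ bound,
$V_n = A e^{-\alpha (R - R_0)} + E_\infty$ repulsive at the anion
geometry. Defaults ($k = 1.4$ eV/Å$^2$, $R_0 = 1.3$ Å, $A = 0.9$ eV,
$\alpha = 2$ Å$^{-1}$, $E_\infty = 3.7$ eV, two 2 amu atoms) were chosen
once, on physical grounds: the vertical gap $A + E_\infty = 4.6$ eV and
the classical release energy $A = 0.9$ eV mirror the energy scales of a
carboxylate-loss photodetachment, and the light reduced mass puts the
bound stretch at $\beta\hbar\omega \approx 3$ at 300 K — squarely in the
regime where nuclear quantum effects are visible.

`toy_torsional_system()` is a four-atom H–O–C–O chain: harmonic bonds and
angles, a torsional double well $(V_2/2)(1 - \cos 2\phi)$ with wells at
$\phi = 0$ (cis) and $180^\circ$ (trans) separated by a 1 eV barrier
$\gg k_B T$, and a neutral surface repulsive along the central O–C bond.
It reproduces, in miniature, the mechanism of isomer-selective
photodetachment: thermal sampling cannot cross the torsional barrier, the
repulsive release does not channel enough energy into the torsion to
isomerize, so trans-well anions give exclusively trans fragments and
cis-well anions give cis fragments.

What the toys deliberately do **not** emulate: real multidimensional
anharmonic landscapes, proton transfer, transition-state recrossing,
conical intersections or any electronic-structure realism; the bonded
angle and torsion terms do not switch off at large fragment separation
(their torques decay geometrically as $1/r$, which freezes the dihedral —
convenient and physically reasonable, but not a fitted property). Passing
tests on these systems validates the *method implementation* — sampling
statistics, conservation, mapping conventions, classification logic — not
the chemistry of any particular anion.

## Problem sizes and numerical choices used by the checks

All sizes are the package's own accuracy/cost choices:

* harmonic-oscillator variance: $8\times10^5$ PIMD steps (32 beads,
  $\Delta t = 0.015$ in model units) and $6\times10^5$ classical steps —
  Monte-Carlo spread ~1% against a 2% tolerance;
* finite-$N$ covariance oracle: 4 beads, $1.2\times10^5$ steps;
* spectral broadening: two $4\times10^4$-step samplers at 300 K;
* torsional channel purity: 3000-step PIMD per well, 20 RPMD trajectories
  per well, 180 fs each at $\Delta t = 0.3$ fs;
* classical release: $\Delta t = 0.005$ fs until 12 Å separation, which
  leaves the residual potential below $10^{-7}$ of the release energy;
* reflection principle: $10^5$ gap samples in 0.01 eV bins.

## Package shape

The simulator state (bead configurations, surfaces, integrators) is
array-based S3 — a phase-space matrix is not a data frame — while every
analysis-facing result is tabular: product records are tibbles, spectra
and ensembles have `tidy()`/`glance()` methods, and `autoplot()` /
`plot_*()` provide ggplot2 views. The full workflow is scriptable through
`run_pipeline()` + a YAML configuration (schema id `rpdyn/1`, unknown keys
rejected with their location), and a thin CLI (`rp_cli()`) exposes
`sample`, `detach`, `spectrum`, `analyze`, `run` and `fixtures`
subcommands with distinct exit codes for configuration (2) and runtime (3)
errors. Artifacts embed units, conventions, seed and a configuration hash;
reruns with the same configuration are byte-identical.

## Known limitations

* Pure-R integrators: throughput is roughly $10^4$ steps/s for a
  32-bead diatomic; production molecular applications would push the
  inner loops to compiled code.
* No normal-mode or staging transformation of the ring polymer: the
  primitive-coordinate integrator needs $\Delta t$ small against the
  stiffest spring mode.
* No thermostatted RPMD, Matsubara dynamics, or nonadiabatic effects after
  detachment; one neutral surface only.
* The plateau rule needs trajectories long enough to contain a full
  window after dissociation; the direct/indirect cutoff is a convention,
  not a derived quantity.
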