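---
title: "Multiscale pulmonary hemodynamics and its uncertainty analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale pulmonary hemodynamics and its uncertainty analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pulmnet)
```

## The model

`pulmnet` simulates pulse-wave propagation through a two-sided model of the
pulmonary circulation and quantifies how uncertain its predictions are under
uncertainty in the vascular parameters. Two spatial scales are coupled:

**Proximal scale.** The fifteen proximal pulmonary arteries (main pulmonary
artery to the segmental level) and twelve proximal veins are one-dimensional
compliant vessels. On each, mass and momentum conservation read

$$\partial_t A + \partial_x q = 0, \qquad
\partial_t q + \tfrac{\gamma+2}{\gamma+1}\,\partial_x\!\left(\tfrac{q^2}{A}\right)
 + \tfrac{A}{\rho}\,\partial_x p = -2\pi\nu(\gamma+2)\tfrac{q}{A},$$

with a power-law (blunt) velocity profile, $\gamma = 9$, blood density
$\rho = 1.055$ g/cm$^3$ and kinematic viscosity $\nu = 3.03\times10^{-2}$
cm$^2$/s. The wall is linearly elastic,
$p = \tfrac{4}{3}K(\sqrt{A/A_0} - 1)$ with $K = Eh/r_0$ taking one value
$K_A$ in all arteries and one value $K_V$ in all veins. The system is solved
with the two-step (Richtmyer) Lax-Wendroff scheme under an explicit CFL
check at every step.

**Distal scale.** Each of the eight terminal arteries feeds a self-similar,
strictly bifurcating structured tree whose daughter radii scale by factors
$\alpha$ (major) and $\beta$ (minor), $r_{ij} = \alpha^i\beta^j r_{\rm root}$,
terminated at a minimum radius $r_{\rm min}$, and mirrored by a venous tree
of identical radii (lengths differ through the arterial and venous
length-to-radius ratios $\ell_{rr}^A$, $\ell_{rr}^V$). Distal flow is
viscous-dominated and linear, so each vessel has a frequency-domain 2x2
admittance built from Womersley theory with a radius-dependent apparent
viscosity (the Fåhræus-Lindqvist effect, anchored so large vessels recover
$\mu = 0.032$ g/(cm s)). The whole two-sided bed condenses, by two-port
elimination memoized on the $(i,j)$ index pair, into a single "grand"
admittance per frequency; its inverse Fourier transform gives real periodic
kernels that couple the terminal artery and vein in the time domain through
a convolution boundary condition.

**Boundary data.** A periodic flow waveform drives the MPA inlet and a
left-atrial pressure waveform loads the four proximal venous outlets. The
study that motivated this package used MRI-derived and lumped-model
waveforms that are not redistributable, so the package generates parametric
stand-ins: a half-sine ejection pulse (optionally with a small backflow
lobe) and a baseline-plus-a/v-wave atrial pressure. Defaults -- period
0.85 s, stroke volume 70 cm$^3$, systolic fraction 0.4, 2% backflow, atrial
baseline 8 mmHg with 3/2 mmHg a/v waves -- give an adult-at-rest cardiac
output of about 4.9 L/min and wedge-range atrial pressures. These are
explicitly *not* the original measured waveforms; quantities that scale with
absolute flow magnitude are therefore reproduced in a scaled-down sense
only, while scale-invariant quantities (coefficients of variation,
sensitivity orderings) transfer more directly.

## Quantities of interest

At every proximal vessel midpoint the package reports pressure, flow, wall
shear stress $\mathrm{WSS} = \mu\,\bar U(\gamma+2)/R(t)$, cyclic stretch
$\mathrm{CS} = (\max R - \min R)/\min R$, and a wave-intensity
decomposition: with $dP_\pm = (dP \pm \rho c\,dU)/2$ and the wall-law wave
speed $c = \sqrt{(2K/3\rho)\sqrt{A/A_0}}$, samples split into forward and
backward compression and expansion waves (FCW/FEW/BCW/BEW), integrated per
wave type. The wave speed comes from the wall law rather than a PU-loop
estimate because it is exact within the model and free of estimator bias.
Distally, mean (DC) pressure and flow, Poiseuille WSS
$4\mu\bar Q/(\pi\bar R^3)$ and linear-wall CS are reconstructed along the
$\alpha$ pathway (repeated major daughters, the longest path) and the
$\beta$ pathway (repeated minor daughters, the shortest), the two extremes
of the bed.

## Uncertainty machinery

Eight parameters are uncertain with uniform priors: $K_A$ [5.60e5, 1.04e6],
$K_{ST}$ [1.75e5, 3.25e5], $K_V$ [5.95e5, 1.11e6] dyn/cm$^2$; $\alpha$
[0.80, 0.92], $\beta$ [0.60, 0.70]; $\ell_{rr}^A$, $\ell_{rr}^V$ [10, 50];
$r_{\rm min}$ [1e-3, 1e-2] cm. Model outputs are emulated with Legendre
polynomial chaos expansions fitted by ordinary least squares on the
canonical cube $[-1,1]^8$ (orthonormal basis; total-degree truncation;
$J = \binom{n+K}{n}$ basis functions). Means, variances, first-, second-
and total-order Sobol' indices follow from the coefficients; time-dependent
outputs additionally get generalized (variance-weighted, time-integrated)
Sobol' indices evaluated at the end of the cycle. The reference study design
is order $K = 4$ with 2000 training and 100 validation samples; the test
suite and the shipped acceptance study run reduced designs (order 1-2,
N = 32-64) so that the whole analysis fits in minutes on one core.

```{r example}
sim <- pulmsim(config = solver_config(dx = 0.25, n_per = 4096))
summary(sim)
wave_intensity(sim, "MPA")
distal_pathways(sim, "RIA D1")$alpha

ens <- run_ensemble(N = 32, seed = 1,
                    config = solver_config(dx = 0.25, n_per = 4096))
fit <- pce(ens$z[ens$ok, ], ens$mpa_p, order = 1, prior = ens$prior)
generalized_sobol(fit, ens$times)$GS_T
```

## Numerical choices

* **Grids.** Each vessel uses $n = \max(3, \mathrm{round}(L/\Delta x)+1)$
  nodes so ends land on nodes. The reference discretization is
  $\Delta x = 0.125$ cm and $\Delta t \approx 1.04\times10^{-4}$ s
  (8192 steps per cycle); ensemble studies use the coarser
  $\Delta x = 0.25$ cm, 4096 steps per cycle, which keeps the CFL number
  near 0.7 over the whole prior box and changes the converged MPA trace by
  well under 0.5% RMS (the suite checks this by time-step halving).
* **Spectral grid.** Coupling kernels and stored fields use 1024 samples
  per period (modes 0..512 with Hermitian extension), an integer decimation
  of the solver step so the convolution never interpolates.
* **Boundary closures.** All physical and junction boundaries use outgoing
  Riemann-invariant extrapolation with a first-order friction correction;
  junction unknowns (flow conservation plus static-pressure continuity) and
  the terminal convolution coupling are solved by damped Newton iteration
  with a 30%-per-step trust region on areas. Static rather than total
  pressure is matched at junctions, following the coupling equations as
  printed; the kinetic-energy correction is second order in $u/c$ here.
* **Startup.** Fields initialize at rest at the mean left-atrial pressure
  (areas and convolution histories consistent with it), and the inflow is
  ramped over the first cycle; a cold start from zero pressure drives a
  violent arterial-collapse transient at the stiffest prior corners. Cycles
  repeat until the beat-to-beat maximum change of inlet pressure falls
  below 1 dyn/cm$^2$ (up to 150 cycles).
* **Womersley factor.** The Bessel ratio $F_J = 2J_1(w_0)/(w_0 J_0(w_0))$,
  $w_0 = i^{3/2} r\sqrt{\omega\rho/\mu}$, is evaluated by power series up to
  $|w_0| = 20$ and by the Hankel asymptotic expansion beyond; the wave speed
  $c = g_\omega/C$ makes the oscillatory admittance reduce exactly to the
  Poiseuille matrix as $\omega \to 0$ (checked to 0.1% at
  $\omega L/c = 10^{-3}$).
* **Resonances.** The oscillatory two-port is singular where
  $\sin(\omega L/c) = 0$; with the viscous (complex) wave speed this does
  not occur on the real frequency grid, but the vessel admittance guards
  the case and the caller may retry with a one-part-in-$10^9$ frequency
  perturbation.
* **Terminal crossover.** A terminal node contributes its arterial segment
  in series with its venous mirror and no extra lumped capillary element;
  "capillary bed" readouts refer to this terminal node.
* **Normalized profiles.** Because $r_{\rm min}$ varies across draws,
  ensemble pathway profiles are compared on a normalized
  distance-from-termination coordinate (0 = smallest vessel, 1 = bed root),
  linearly interpolated to a fixed grid.

## Design decisions made where the formulation was open

* The venous mirror tree reuses the arterial radii node-for-node; the
  attached proximal venous radius is recorded but does not reshape the
  tree. This follows the two-sided bed geometry as published; generating
  venous radii from the venous root instead would break the node-for-node
  mirror that the condensation relies on.
* The through-flow at a distal vessel outlet is computed as
  $Q(L) = -Y_{21}P(0) - Y_{22}P(L)$, the sign-consistent form of the
  two-port relation: it reduces to $Q(L) = Q(0) = (P(0)-P(L))/R$ at DC,
  which mass conservation requires.
* Stored grand admittances use the symmetric into-port convention
  ($Y_{11} = Y_{22} = -Y_{12} = -Y_{21} = 1/R$ at DC); the coupling
  convolution negates the venous row so both returned flows are physical
  through-flows.
* Distal cyclic stretch uses the full pressure spectrum at each node, not
  only the mean and first harmonic.
* The regression design for the PCE is plain pseudo-random uniform sampling
  by default, with Latin hypercube sampling available by flag; the test
  suite uses the default design and records every seed.
* Serialization is plain text (CSV for networks, waveforms, profiles and
  Sobol' tables; JSON for study manifests).

## What the synthetic data do and do not show

The generator reproduces the *structure* of the study: periodic
physiological forcing at a realistic cardiac output, atrial a/v-wave
loading, and the full parameter prior. It does not reproduce the measured
inflow's notch and diastolic detail, patient-specific geometry, or
measurement noise. Green tests therefore demonstrate correctness of the
numerics and of the uncertainty machinery, and agreement with reported
ensemble summaries only up to the boundary-data surrogate: magnitudes tied
to the inflow shape (for example proximal cyclic stretch, which tracks
pulse pressure) sit below the reported values under the half-sine
stand-in, while scale-invariant uncertainty measures and sensitivity
orderings are expected to, and do, transfer.

## Known limitations

Vessel walls are purely elastic (no viscoelasticity), vessels are untapered,
gravity and lung-zone effects are absent, the venous system is not
collapsible, and the trees terminate at $r_{\rm min}$ with no capillary
sheet model. Parameters are independent under the prior; posterior
calibration to data is out of scope.
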