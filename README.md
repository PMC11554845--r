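# pulmnet

Multiscale simulation of pulmonary arterial and venous hemodynamics with
built-in uncertainty quantification.

## The problem

Pulmonary hypertension — in particular group II disease secondary to
left-heart failure — involves remodeling at two spatial scales at once: the
proximal arteries that couple to the right ventricle, and the microvascular
beds where wall shear stress (WSS) and cyclic stretch (CS) drive
mechanotransduction. Neither WSS nor CS in the microcirculation can be
measured in patients, so mechanistic models carry the load — provided their
parameter uncertainty is quantified. `pulmnet` is for computational
physiologists who want a fully tested, one-command version of that
analysis: a nonlinear 1D pulse-wave model of the 15 proximal pulmonary
arteries and 12 proximal veins, closed at eight terminal artery–vein pairs
by two-sided structured-tree models of the distal vasculature, with
polynomial-chaos emulation and variance-based (Sobol') sensitivity analysis
over the vascular parameters.

## The model in brief

Proximal vessels satisfy the 1D mass/momentum system with a blunt
power-law velocity profile (γ = 9) and a linear elastic wall
p = (4/3)K(√(A/A₀) − 1), solved by the two-step Lax–Wendroff scheme.
Each terminal artery feeds a self-similar bifurcating tree
(r_ij = αⁱβʲ r_root, terminated at r_min) mirrored by a venous tree;
Womersley-theory admittances with Fåhræus–Lindqvist viscosity condense
into one 2×2 "grand admittance" per bed, whose real time-domain kernels
couple artery to vein by periodic convolution. Eight parameters
(K_A, K_ST, K_V, α, β, ℓrr_A, ℓrr_V, r_min) carry uniform priors; Legendre
polynomial-chaos surrogates fitted by ordinary least squares yield means,
variances, and first/second/total and generalized Sobol' indices for
pressure, flow, WSS, CS and the four wave-intensity components
(FCW/FEW/BCW/BEW).

Boundary waveforms (MPA inflow, left-atrial pressure) are parametric
synthetic stand-ins at a cardiac output of ≈4.9 L/min — the measured
waveforms behind the original study are not redistributable — so
magnitude-dependent results are scaled-down reproductions while
scale-invariant uncertainty measures transfer directly.

## Worked example

```r
library(pulmnet)

sim <- pulmsim(config = solver_config(dx = 0.25, n_per = 4096))
print(sim)
#> Multiscale pulmonary haemodynamics simulation (converged, 18 cycles, CFL max 0.68)
#> MPA pressure (mmHg): 28.2 / 8.3 (mean 18.4); cardiac output 4.84 L/min
```

The simulation converged to a periodic steady state in 18 cardiac cycles:
systolic/diastolic MPA pressures of 28.2/8.3 mmHg around a mean of
18.4 mmHg — mildly hypertensive, as expected for midpoint-of-prior
stiffness and tree parameters — at the prescribed 4.84 L/min output.

```r
head(summary(sim), 3)
#>   vessel     side sys_p_mmHg dia_p_mmHg mean_p_mmHg   mean_q        cs mean_wss peak_wss
#> 1    MPA arterial   28.17362   8.338413    18.41922 80.70576 0.0245362 3.350025 13.35788
#> 2    LPA arterial   27.80769   9.011783    18.39885 32.19370 0.0232312 4.496392 19.26955
#> 3    RPA arterial   27.67260   9.081364    18.39312 48.51202 0.0229763 3.731471 14.34338
```

Mean flow splits 32/49 cm³/s between left and right lungs (the right
pulmonary artery is wider), arterial cyclic stretch is ≈2.3% and mean WSS
3–7 dyn/cm². Distal profiles, wave intensity and the uncertainty study:

```r
paths <- distal_pathways(sim, "RIA D1")    # alpha/beta pathway profiles
wave_intensity(sim, "MPA")$integrated      # FCW/FEW/BCW/BEW energies

ens <- run_ensemble(N = 64, seed = 1,
                    config = solver_config(dx = 0.25, n_per = 4096))
print(ens)
#> Prior ensemble: 64/64 successful samples (seed 1, random design)
#> mean arterial CS 2.10%, mean venous CS 0.34%
fit <- pce(ens$z[ens$ok, ], ens$mpa_p, order = 1, prior = ens$prior)
round(sort(generalized_sobol(fit, ens$times)$GS_T, decreasing = TRUE), 4)
#>  alpha   beta  lrr_A  r_min  lrr_V   K_ST    K_V    K_A
#> 0.5599 0.1715 0.1084 0.1048 0.0396 0.0108 0.0047 0.0005
```

The ranking puts the structured-tree geometry (α first, then β, the
length-to-radius ratios and the terminal radius) ahead of all three
stiffness parameters for proximal pressure — the study's central
sensitivity finding. `run_study("out/")` writes the QoI, Sobol' and manifest artifacts
in one call.

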