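# crowdLBM

Crowding-corrected Lattice-Boltzmann simulation of molecular diffusion in
two-dimensional crowded media — intracellular environments such as cell
membranes, where macromolecules occupy 25–40% of the available area and
steric exclusion slows every molecule down.

The classical Lattice-Boltzmann method (LBM) evolves mesoscopic molecule
populations cheaply but treats molecules as point-like, so it over-predicts
mixing whenever crowding matters. `crowdLBM` implements the corrected
scheme in which the post-collision D2Q5 populations are scaled by the
Scaled Particle Theory (SPT) probability that the moving species finds free
space in its target voxel:

$$F_{d,sp}(i,j,t) = F^{LB}_{d,sp}(i,j,t)\; P_{sp}(i_{next},j_{next},t),
  \qquad d = 1..4,$$

with blocked molecules returning to rest,
$F_{0,sp} = \rho_{sp}/m_{sp} - \sum_{d=1}^{4} F_{d,sp}$, so mass is
conserved exactly. $P_{sp} = 1/\gamma_{sp}$ comes from the 2D SPT activity
coefficient of a hard-disk mixture,

$$\ln\gamma_{sp} = -\ln(1-S_2) + \frac{2S_1}{1-S_2} r_{sp}
  + \left[\frac{S_0}{1-S_2} + \frac{S_1^2}{(1-S_2)^2}\right] r_{sp}^2,
  \qquad S_x = \frac{\pi}{\Delta x^2}\sum_i \rho_i r_i^x,$$

which for same-size square molecules on a lattice reduces to
$\ln\gamma = -\ln(1 - S_2)$ with $S_2$ the occupied area fraction. The BGK
relaxation parameter follows from the dilute diffusion coefficient,
$\omega = 2/(1 + 4 D^0 \Delta t/\Delta x^2)$; at $\omega = 1$ a classical
step is exactly the finite-difference four-neighbour average.

The package also contains the microscopic reference the scheme is validated
against — an on-lattice kinetic Monte Carlo (kMC) simulator with exact
excluded volume (one molecule per 10 nm site, hops to free neighbours at
rate $D^0/a^2$, exponential waiting times; compiled inner loop) — plus the
two comparison metrics: the relative distribution error
$100\,\lVert\rho_{kMC}-\rho_{cLBM}\rVert_F / \sum\rho_{kMC}$ and tracer
mean squared displacement estimators for both engines. Five benchmark
scenarios (`example1()`–`example5()`) are generated in code, from packed
columns to polydisperse hard-disk mixtures at 30% occupancy.

Who it is for: anyone who needs diffusion of many interacting
macromolecules over cell-scale times without paying the per-molecule cost
of Monte Carlo — and wants the microscopic cross-check in the same package.

## Worked example

The first benchmark packs every voxel of the first column to capacity: 100
tracer molecules A in one voxel, 900 B in the nine others (both with
$D^0 = 500$ nm²/ms, $\omega = 1$). B obstructs A vertically, so the
corrected engine should spread A more slowly than classical LBM — and agree
with the particle-level kMC ensemble.

```r
library(crowdLBM)
sc <- example1()
sc
#> Scenario: example 1: two-species packed first column
#> LatticeGeometry: (1000 nm)^2, dx = 100 nm (10 x 10 voxels), dt = 5 ms, periodic
#>   mode: lattice (site 10 nm), seed: 1, horizon: 50 ms
#>   A            N = 100     r = NA   A = 100    D0 = 500
#>   B            N = 900     r = NA   A = 100    D0 = 500

run       <- runEngine(sc, "clbm", tEnd = 30)   # corrected engine
classical <- runEngine(sc, "lbm",  tEnd = 30)   # point-like molecules
set.seed(1)
kmc <- runKmcEnsemble(sc, reps = 200, recordTimes = seq(5, 30, 5))

errorSeries(kmc, run, "A")
#>   time species     error
#> 1    5       A 24.061511
#> ...
#> 6   30       A  0.988067

errorSeries(kmc, classical, "A")
#>   time species    error
#> 1    5       A 47.08191
#> ...
#> 6   30       A 16.45201
```

At 30 ms the corrected engine misplaces about 1 of the 100 A molecules
relative to the kMC ensemble mean (error 0.99%, at this ensemble size
partly residual Monte-Carlo noise), while classical LBM misplaces 16 of
100 (16.5%) — the over-mixing the correction exists to remove. The large
early-time errors decay as the mesoscopic fields relax toward their
quasi-stable profiles.

A command-line wrapper for shell pipelines ships under
`inst/cli/clbm.R` (subcommands `scenario`, `run`, `kmc`, `compare`,
`spt-table`); the methods vignette (`vignettes/crowded-diffusion.Rmd`)
documents the model, its assumptions and its limitations.

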