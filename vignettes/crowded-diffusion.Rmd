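---
title: "Simulating diffusion in crowded two-dimensional media with crowdLBM"
author: "crowdLBM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating diffusion in crowded two-dimensional media with crowdLBM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdLBM)
```

## The problem

Intracellular media are crowded: macromolecules occupy a large fraction of
the cytoplasm volume and of membrane area, and the resulting steric
exclusion slows diffusion and raises thermodynamic activities. Microscopic
simulators (Monte Carlo variants that track every molecule) respect excluded
volume exactly but scale poorly with molecule number; the classical
Lattice-Boltzmann method (LBM) evolves mesoscopic molecule *populations*
cheaply but treats molecules as point-like, so it over-predicts mixing
whenever more than one species is present under crowding.

`crowdLBM` implements a crowding-corrected Lattice-Boltzmann scheme (the
`"clbm"` engine) for two-dimensional systems such as lateral protein
diffusion in membranes, together with the on-lattice kinetic Monte Carlo
(kMC) simulator used as its in-package computational experiment, and the
metrics that quantify their agreement.

## The mesoscopic model

The domain is a periodic square of side $L$ divided into voxels of side
$\Delta x$, assumed internally well mixed, in a fluid at rest. Each species
$sp$ carries a D2Q5 population field $F_{d,sp}(i,j,t)$ — molecules per voxel
committed to rest ($d = 0$) or to one of four neighbour directions — with
density $\rho_{sp} = m_{sp} \sum_d F_{d,sp}$. One time step $\Delta t$
executes:

1. **BGK collision** toward the fluid-at-rest equilibrium
   $F^{eq}_d = w_d\, \rho/m$ with weights $w_0 = 0$, $w_{1..4} = 1/4$:
   $F^{LB}_d = F_d + \omega\,(F^{eq}_d - F_d)$. The relaxation parameter
   follows from the dilute diffusion coefficient $D^0$ through
   $\omega = 2 / (1 + 4 D^0 \Delta t / \Delta x^2)$.
2. **Crowding correction** — the contribution of this scheme. Each mover is
   scaled by the probability that its *target* voxel offers free space,
   evaluated from densities at time $t$ (an explicit scheme; no
   self-consistency iteration):
   $F_d(i,j,t) = F^{LB}_d(i,j,t)\, P_{sp}(i_{next},j_{next},t)$, $d = 1..4$.
   Molecules denied entry return to rest, which closes the per-voxel mass
   balance exactly: $F_0 = \rho/m - \sum_{d=1}^4 F_d$.
3. **Streaming** of each mover population to its neighbour voxel, with
   periodic wrap.

$P_{sp} = 1/\gamma_{sp}$ is the inverse activity coefficient. For mixtures
of hard disks of radii $r_i$, Scaled Particle Theory gives

$$\ln\gamma_{sp} = -\ln(1-S_2) + \frac{2S_1}{1-S_2}\,r_{sp}
  + \left[\frac{S_0}{1-S_2} + \frac{S_1^2}{(1-S_2)^2}\right] r_{sp}^2,
  \qquad S_x = \frac{\pi}{\Delta x^2}\sum_i \rho_i r_i^x,$$

summed over **all** species in the voxel (self-crowding included — the
moment sum makes no exception, and excluding the moving species' own kind
would understate the occupied area). For the square lattice model
(same-size square molecules in square uniform packing, the geometry the kMC
reference lives on) this reduces to $\ln\gamma = -\ln(1-S_2)$ with
$S_2 = \Delta x^{-2}\sum_i \rho_i A_i$, the occupied area fraction, the same
for every species. A point-like tracer sees exactly the free area fraction:
$P = 1 - S_2$. With no crowding ($S_x \to 0$) every $P \to 1$ and the
classical LBM is recovered — in this implementation *bitwise*, because both
engines share one code path and multiplication by $P = 1$ is exact.

```{r spt}
sptTable(c(0, 0.1, 0.2, 0.3), rTracer = 1.5, rCrowder = 2)
```

### Parameters that matter

* `dx` (nm): voxel side. Sets the resolution of the mesoscopic fields and
  the scale on which voxels are assumed well mixed. The bundled examples use
  50 nm (100 nm in the first one).
* `dt` (ms): time step. Accuracy is best at $\omega = 1$, i.e.
  $\Delta t = \Delta x^2 / 4 D^0$ (`dtForUnitOmega`), where one step is
  exactly the finite-difference four-neighbour average at its stability
  limit. The engines require $0 < \omega \le 1$: over-relaxation can drive
  populations negative, which would break the $P \in [0,1]$ contract of the
  correction. With several species, `dt` is pinned by the fastest one and
  the others relax with $\omega < 1$.
* `radius` / `area` (nm, nm$^2$): the size entering the insertion
  probability. Disk radii feed the three-term expression; lattice-mode areas
  feed the occupied-fraction form.
* `D0` (nm$^2$/ms): dilute diffusion coefficient, position-independent; all
  crowding effects enter through $P$, not through $D$.
* `mass` (g/molecule): defaults to 1 so densities read as molecule counts.

### Numerical choices and degenerate inputs

* Saturated voxels ($S_2 \ge 1$) are not evaluated through the logarithm;
  their insertion probability is 0, the physically forced limit.
* $P$ is clamped into $[0,1]$ after exponentiation to absorb floating-point
  drift; a violation beyond $10^{-9}$ raises an error, since
  $\gamma \ge 1$ analytically.
* Because the scheme is explicit, several donors can feed one nearly-full
  voxel in the same step and push it transiently over capacity. There is no
  rationing rule in the scheme; the engine counts such voxel-steps
  (`overfill` slot), and the voxel's $P = 0$ on the next step drains it.
  Small $\Delta t$ keeps the effect negligible; the bundled scenarios
  record zero overfills.
* A negative rest population beyond $-10^{-9}$ (relative) aborts the run —
  it indicates $\omega > 1$ or a corrupted probability grid; smaller
  negatives are clipped and counted.
* Initial populations are placed at rest; at $\omega = 1$ the first
  collision erases this convention entirely, and at $\omega < 1$ it decays
  geometrically.

## The kinetic Monte Carlo reference

The reference simulator is the standard on-lattice kMC: sites of side $a$
(10 nm in every bundled scenario) hold at most one molecule; a molecule hops
to a free von Neumann neighbour at per-direction rate $D^0/a^2$, so a free
walker's MSD is $4 D^0 t$ exactly — the same dilute coefficient that
parameterizes $\omega$. Events are chosen proportionally to their rates and
the clock advances by exponential waiting times ($\mathrm{E}[\Delta t] =
1/R$). `runKmc`, `enumerateEvents` and `selectAndAdvance` implement this
procedure literally and serve as the correctness baseline.

The production engine (`runKmcEnsemble`, compiled) uses uniformization: hop
attempts into occupied sites are kept in the catalogue as null events, so
the total rate $R = \sum_{sp} 4 N_{sp} D^0_{sp}/a^2$ is constant, the event
count per recording interval is Poisson$(R\,\Delta t)$, and each event costs
O(1). Adding self-loops to a continuous-time Markov chain leaves its law
unchanged, so this is not an approximation; a seeded A/B test against the
reference implementation checks the equivalence in distribution. Ensemble
occupancies are coarse-grained to $\Delta x$ voxels and averaged over
repetitions for comparison with the mesoscopic fields.

## Comparison metrics

**Distribution error.** For one species at one time,
$error = 100\,\lVert \rho_{ref} - \rho_{test} \rVert_F / \sum_{ij}
\rho_{ref}$: an error of $x$% reads as $x$ of every 100 molecules sitting in
a different voxel than the reference predicts.

**Tracer MSD.** A mesoscopic field has no molecule identities, so the
package labels tracer subpopulations by origin voxel (`labelOrigins`; the
crowding coupling acts only through total densities, so relabeling does not
alter the dynamics) and takes the density-weighted second moment about each
origin's voxel center with minimum-image distances on the periodic box.
Displacement is thus resolved voxel-to-voxel; the estimate is flagged once
the rms displacement approaches the half box. For a free tracer this
estimator returns $4 D^0 t$ exactly.

**Which kMC displacement to compare.** The kMC ensemble records two
statistics. The *net* MSD (unwrapped per-molecule displacement) is the
standard quantity — but under excluded volume it carries the microscopic
back-correlation of single trajectories: a molecule that has just hopped is
more likely than chance to hop back into the vacancy it left, which reduces
the net MSD by roughly 13% at 20% occupancy and 31% at 40% in these
scenarios. A mesoscopic method cannot represent that vacancy memory: the
corrected engine thins each attempted move by the *current* free-space
probability of the target voxel and nothing else. The comparable kMC
quantity is therefore the *effective* displacement — the accumulated squared
displacement of the hops actually executed, $a^2 \times$ hops
(`msdEffective`), which counts how much motion was performed rather than
where the molecule netted out. For a free walker the two coincide in
expectation; under crowding the effective displacement matches the
mesoscopic estimator to well under 1% across 0–40% occupancy, while the net
MSD measures the additional, genuinely microscopic, correlation effect. Both
are reported so the distinction stays visible.

## The scenario catalogue

`example1()` to `example5()` regenerate the five benchmark configurations,
all on a (1000 nm)$^2$ periodic lattice with 1 g/molecule masses:

| | mode | $\Delta x$ | $\Delta t$ | content |
|-|------|-----------|-----------|---------|
| 1 | lattice | 100 | 5 | first column packed: 100 A in one voxel, 900 B in nine; $D^0 = 500$ |
| 2 | lattice | 50 | 0.625 | two-column regions 3/4/5 packed at 25/voxel with A/B/C; $D^0 = 1000/1050/1100$ |
| 3 | lattice | 50 | 0.625 | 100 tracers (1% area) + 0–4000 crowders (0–40%), random, $D^0 = 1000$ |
| 4 | disk | 50 | 0.625 | 796 tracers of $r$ = 2/1.5/1/0 among four crowder species filling 30% |
| 5 | disk | 50 | 0.625 | 1414 tracers ($r$ = 1.5) among one crowder species at 30%: $r_c$ = 2/1.5/1 |

Lattice-mode scenarios place every molecule on the 10 nm site grid
(deterministically for the packed examples, uniformly at random over free
sites for the rest), so the mesoscopic engines and the kMC reference share
one initial condition exactly; disk-mode scenarios place molecules at voxel
resolution. Placements are reproducible from the recorded seed, audited
against voxel capacity (lattice) or voxel saturation and the declared area
fractions (disk), and round-trip through the YAML configuration files
unchanged. Two details of the packed examples are figure-level conventions
rather than printed parameters and are therefore arguments with documented
defaults: the row of the A voxel in the first example (default: middle row)
and the leftmost column of region 3 in the second (default: voxel column 4,
regions counted left-to-right from 1).

## What the scenarios do and do not emulate

The generator reproduces the benchmark conditions: hard excluded volume,
uniform random or packed initial placements, size-polydisperse disk
mixtures, and dilute-limit diffusion coefficients of macromolecular
magnitude. It does not emulate hydrodynamic interactions, electrostatics,
binding, polymer shapes, anomalous-diffusion kinetics, or spatially
heterogeneous "pockets" formed by immobile obstacles — SPT assumes each
voxel is well mixed, and the known consequence is an overestimate of
insertion probabilities at high occupancy or around immobile species.
Passing validation here shows the mesoscopic correction reproduces its
microscopic reference under these idealized conditions, not that it captures
every feature of real membranes.

## Validation workflow and problem sizes

The tests and the acceptance script rerun the validations at sizes chosen
to keep Monte-Carlo standard errors well below the quantities measured: the
distribution-error comparisons use the full 1000-repetition ensembles
(50 repetitions where the error floor of a small ensemble is itself the
quantity of interest), and the MSD sweep uses 300 repetitions per crowding
condition over a 12.5 ms horizon — hop-count statistics are tight, so the
relative standard error is under 0.1% there, with the MSD pooled over all
molecules of the (dynamically identical) tracer and crowder species as pure
variance reduction.

```{r example, eval = FALSE}
sc <- example1()
run <- runEngine(sc, "clbm", tEnd = 30)          # corrected engine
classical <- runEngine(sc, "lbm", tEnd = 30)     # point-like molecules
kmc <- runKmcEnsemble(sc, reps = 200, recordTimes = seq(5, 30, 5))
errorSeries(kmc, run, "A")        # ~1.3% at 30 ms
errorSeries(kmc, classical, "A")  # ~16% at 30 ms
```

## Known limitations

* Two dimensions, D2Q5, square voxels, periodic boundaries only.
* Pure diffusion: no advection, no reactions, no multi-relaxation-time
  collision operators.
* The explicit correction admits transient overfill (audited, see above),
  and SPT's well-mixed-voxel assumption overestimates available space at
  high area fractions or around immobile crowders.
* The kMC reference supports single-size square molecules (one per site);
  the disk-mode scenarios are validated structurally (area fractions,
  saturation audits) and through the mesoscopic engine only.
* Mesoscopic MSD is resolved at voxel granularity and carries no
  information about sub-voxel motion or microscopic trajectory
  correlations; the net-vs-effective distinction above is the honest
  boundary of what a mesoscopic method can report.
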