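# eyeCPM

A Glazier–Graner–Hogeweg (cellular Potts) simulator of interommatidial
cell patterning in the *Drosophila* pupal eye.

Between ~20 and 40 hours after puparium formation, the interommatidial
precursor cells (IPCs) of the pupal eye sort into an interweaving
hexagonal lattice: one secondary pigment cell (2°) on every hexagon edge,
one tertiary pigment cell (3°) at every vertex where three ommatidia meet.
`eyeCPM` is for developmental and computational biologists who want to ask
which local mechanisms suffice to build that lattice: type-dependent
adhesion, intrinsic cell motility, contact-gated programmed cell death,
and apical expansion of the ommatidial cores.

## The model

Cells are sets of sites on a 2D periodic lattice evolving by
Metropolis-accepted boundary copy attempts against the effective energy

    H = sum_links J(tau_i, tau_j)
      + sum_cells lambda_A (A - A_T)^2
      + sum_cells lambda_P (P - P_T)^2

with acceptance `min(1, exp(-dH/T))`; one Monte Carlo Step (MCS) is one
copy attempt per site and represents about 2 s of development. Two
tissue-specific mechanisms complete the model:

* **Contact-gated death** — after 10,000 MCS, an IPC whose contact length
  `cs` with the cores is below a threshold `L` dies with per-MCS
  probability `P_MAX * (1 - cs/L)^lambda_Death` (wild type: `L = 16`,
  `lambda_Death = 1.2`, `P_MAX = 0.01`); death sets the cell's targets to
  0 and it shrinks away. Margin IPCs are exempt.
* **Apical expansion** — core target areas double in a linear ramp,
  crowding the surrounding IPCs into their niches.

The wild-type operating point pins `T = 60`, `J_OC,IPC = 35`,
`J_IPC,IPC = 55`, 50,000 MCS. Perturbation presets (`presetNames()`)
reproduce the in-silico experiments: reduced death (`L = 12`, `L = 10`),
flat and anti-preferential adhesion, blocked expansion (all cores, one
core, half of one core), growing IPCs, and death removal.

## A worked example

```r
library(eyeCPM)
res <- runExperiment("wild_type", seed = 1)
show(res)
#> SimulationResult 'wild_type' (seed 1): 50000 MCS, 78 cells, 7 2deg, 16 3deg (central 0/2)
tail(timeSeries(res)[, c("mcs", "n_cells", "n_tertiary", "n_tertiary_central")], 2)
#>       mcs n_cells n_tertiary n_tertiary_central
#> 100 49500      78         14                  2
#> 101 50000      78         16                  2
```

The field starts as a synthetic 4 × 4 hexagonal array of ommatidial cores
(~120 cells): cores double their apical targets by 10,000 MCS, the death
rule then removes a third to a half of the non-exempt IPCs, and by
20,000–30,000 MCS most three-ommatidia vertices hold a single 3°. Here 78
cells remain, 16 IPCs sit at vertices as scored 3°s, and both vertices
interior to the central 2 × 2 block of ommatidia ("central", insulated
from the non-dying margin) are occupied — the full complement.

`exportField()` writes any state as an integer label image + CSV cell
table; `importTracing()` builds an initial condition from a segmented
tracing; `runSweep()` batches presets over seeds into one table. A thin
command-line front end ships at `inst/cli/eyecpm.R`
(`run`, `sweep`, `generate`, `score` subcommands).

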