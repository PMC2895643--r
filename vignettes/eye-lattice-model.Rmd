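---
title: "Modeling interommatidial cell patterning with a cellular Potts simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling interommatidial cell patterning with a cellular Potts simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyeCPM)
```

## The biological problem

The *Drosophila* pupal eye is a crystalline mosaic of ~750 ommatidia. Each
ommatidial core (OC) — the cone-cell quartet plus the two primary pigment
cells, modeled here as a single simulated cell — is surrounded by
interommatidial precursor cells (IPCs) that, between roughly 20 and 40 hours
after puparium formation, sort into an interweaving hexagonal lattice:
exactly one secondary pigment cell (2°) on each hexagon edge and one
tertiary pigment cell (3°) at each vertex shared by three ommatidia.
`eyeCPM` simulates this process at the apical plane with a two-dimensional
Glazier–Graner–Hogeweg (GGH, also called cellular Potts) model and asks
which combination of mechanisms — differential adhesion, intrinsic motility,
contact-dependent programmed cell death (PCD), and apical expansion of the
cores — suffices to build the lattice.

## The model

Each cell is a set of sites on a periodic square lattice; Medium is a
distinguished, unconstrained cell representing the space beyond the tissue
margin. The effective energy is

$$H = \sum_{\text{links } (i,j)} J\big(\tau(\sigma_i), \tau(\sigma_j)\big)
  + \sum_{c} \lambda_A (A_c - A_{T,c})^2
  + \sum_{c} \lambda_P (P_c - P_{T,c})^2,$$

where the first sum runs over neighboring site pairs owned by different
cells, $J$ is the boundary energy per link between the owners' types
(lower $J$ = stronger adhesion), and the quadratic terms constrain each
cell's area $A$ and perimeter $P$ toward targets $A_T$, $P_T$.
Dynamics are boundary copy attempts: a random site proposes to copy the
owner of a random lattice neighbor, and the proposal is accepted with
probability $\min(1, e^{-\Delta H/T})$. One Monte Carlo Step (MCS) is one
attempt per lattice site and stands for about 2 s of development, so
10,000 MCS ≈ 5.5 h (`mcsToHours()`).

Two tissue-specific mechanisms complete the model:

* **Contact-gated death.** After an onset of 10,000 MCS, every living
  non-exempt IPC is evaluated once per MCS. With $cs$ its contact length
  with cores, the per-MCS death probability is
  $P_{\max}\,(1 - cs/L)^{\lambda_{\text{Death}}}$ for $cs < L$ and exactly
  0 at or above the threshold $L$ (wild type $L = 16$,
  $\lambda_{\text{Death}} = 1.2$, $P_{\max} = 0.01$). A cell that dies has
  its targets set to 0 and shrinks away under the area constraint. IPCs
  that touch Medium at initialization — the eye margin — never die, and
  ommatidia whose surrounding IPCs sit on or next to that margin are
  excluded from the "central" counts reported alongside whole-field
  counts.
* **Apical expansion.** Core targets ramp linearly from their initial
  values until the target area reaches twice its initial value. The ramp
  completes at 10,000 MCS: apical doubling takes about 5.5 h in vivo, and
  death is deferred to the same point precisely so that cell sizes have
  equilibrated when the death rule switches on. The target perimeter
  scales by $\sqrt{2}$ — the scaling that keeps a growing disc round —
  rather than doubling; a literal perimeter doubling at fixed roundness
  would force lobed, finger-like cores, which contradicts the observed
  circular profiles. `ExpansionSchedule` exposes `perim_multiplier` for
  anyone wanting a different choice.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| $T$ | 60 | motility; acceptance scale for energy-raising copies |
| $J_{OC,IPC}, J_{IPC,IPC}$ | 35, 55 | preferential adhesion of IPCs for cores |
| $J_{IPC,Med}, J_{OC,Med}, J_{OC,OC}$ | 70, 90, 200 | margin tensions; cores never touch |
| $\lambda_A$ (OC, IPC) | 6, 1 | inverse compressibility: stiff cores, crowdable IPCs |
| $\lambda_P$ (OC, IPC) | 1, 0 | only cores carry a perimeter constraint |
| $L, \lambda_{\text{Death}}, P_{\max}$ | 16, 1.2, 0.01 | death rule |
| onset, total | 10,000, 50,000 MCS | death onset; run length |

$J_{OC,IPC}$, $J_{IPC,IPC}$, $T$, $L$, $\lambda_{\text{Death}}$,
$P_{\max}$, the onset and the run length are the published operating
point. The remaining values are this package's declared defaults, chosen
once: the $J$ hierarchy follows
$J_{OC,OC} \gg J_{OC,Med} \gg J_{IPC,Med} > J_{IPC,IPC} \ge J_{OC,IPC}$;
cores are strongly shape-constrained so they stay round while IPCs carry
minimal constraints so crowding can deform them.

Neighborhood orders are a deliberate split. Boundary energy and perimeter
use the order-2 (8-site) shell, the common choice to reduce lattice
anisotropy. Copy attempts propose from the order-1 (4-site) shell. The
death rule's contact length $cs$ is counted in lattice units — order-1
edge links only. This last choice matters: counting diagonal links would
inflate every IPC's contact roughly threefold relative to the printed
$L = 16$, and the rule would lose its discriminating power (almost nothing
dies); with edge counting, an IPC squeezed out of its niche drops below
$L$ and is removed, which is the behavior the threshold is meant to
capture.

## The synthetic eye field

The published experiments start from a hand-traced micrograph of a
23:00–24:30 h APF eye. That tracing is not available, so the canonical
initializer is a synthetic field built to the same description
(`generateSyntheticField()`): a hexagonally offset `rows × cols` grid of
disc-shaped cores (default 4 × 4), the interstitial space partitioned into
IPCs seeded two per inter-core corridor so that every interior IPC touches
at least two cores, a bounding ring of IPCs (the non-dying margin), and
Medium outside. `importTracing()` preserves the original pathway for real
segmented tracings (integer PNG/TIFF label images plus a label→type map).

Geometry is calibrated to the printed death threshold: with core radius 9
and spacing 25, a core's initial order-2 circumference is ≈ 170 links,
about 10.7 × L, and its order-1 circumference is ≈ 72 edges, so the ~12
IPCs abutting each core start near the survival threshold and the
threshold separates winners from losers exactly in the crowding phase.
The Medium margin (32 sites) leaves room for the tissue, whose area grows
by roughly a third during core doubling, to expand without meeting itself
across the periodic boundary.

What the generator does **not** emulate: photoreceptors and cone cells
inside each core (the core is one cell), bristle groups and their local
death bias, mitoses (the tissue is post-mitotic at this stage), and the
irregular outline and tracing noise of a real micrograph. Passing tests on
synthetic fields therefore demonstrate the mechanisms, not segmentation
robustness on real images.

## Scoring

Following the published definitions, a 3° is an IPC contacting exactly
three distinct cores and a 2° is an IPC contacting exactly two cores and
exactly two 3°s; the two halves of a compartment-split core (the
`blocked_half_oc` variant) count as one core. Contacts for classification
are counted, like the death rule's contact lengths, in lattice units
(order-1 edge links) and require at least two shared edges — an isolated
single-edge touch is a transient pinch between jiggling membranes, not a
contact. Time series are recorded every
500 MCS, whole-field and restricted to central ommatidia, the central set
being fixed at initialization. `hexagonIPCCount()` implements the
half-cell counting rule used for the in vivo comparisons: cells straddling
the hexagonal outline drawn through the six surrounding core centers count
as half a cell.

## A wild-type run

```{r wildtype, eval = FALSE}
res <- runExperiment("wild_type", seed = 1)
tail(timeSeries(res)[, c("mcs", "n_cells", "n_secondary", "n_tertiary",
                         "n_tertiary_central")], 3)
```

Typical behavior at the default desk scale (4 × 4 ommatidia, lattice
≈ 166 × 143, 50,000 MCS, ~20-40 s on one CPU): the field starts with ~120
cells; cores double by 10,000 MCS, crowding the IPCs; death then removes
a third to a half of the non-exempt IPCs within a few thousand MCS; by
20,000–30,000 MCS most vertices hold a single 3° and the central
tertiary count sits at its final value, with occasional brief
excursions as cells jostle (see Limitations).

## Perturbation presets

`presetNames()` lists the in-silico experiments: reduced death
(`reduced_death_L12`, `reduced_death_L10`), adhesion variants
(`adhesion_flat`: $J_{OC,IPC} = J_{IPC,IPC}$; `adhesion_anti`: values
swapped), expansion variants (`no_expansion`, `no_death`,
`no_expansion_no_death`, `growing_ipcs`, `blocked_single_oc`,
`blocked_half_oc`). Each changes only the parameters its name implies.
The half-core block splits the central core into two compartments with
zero mutual boundary energy (they adhere as one body), one of which does
not expand.

Cross-preset comparisons in the test-suite use the post-onset time
average of a count (mean over all 500-MCS records from the 10,000-MCS
death onset to run end, averaged over five seeds). This uses the entire
recorded curve — the published comparisons are likewise curve-level — and
avoids anchoring a stochastic comparison to a single arbitrary snapshot.

## Numerical choices

* Ties in the Metropolis rule ($\Delta H = 0$) are accepted, consistent
  with $\min(1, e^0)$; exactly one uniform variate is drawn when
  $\Delta H > 0$ and none otherwise.
* Areas, perimeters and core contacts are cached and updated
  incrementally per accepted copy; tests verify the caches against full
  recomputation to $10^{-9}$.
* The sweep loop uses a PCG32 stream seeded from R's RNG, so a run is a
  deterministic function of `set.seed()`; identical (preset, seed) pairs
  give bit-identical trajectories.
* No connectivity constraint is imposed; cells can fragment under extreme
  deformation. Fragments are tolerated (the generator's repair pass and
  registry bookkeeping handle them); identity loss other than by death is
  limited to such pinch-offs.
* A dying cell keeps paying its area penalty at $A = 0$ until it is
  dropped from the registry, so the energy bookkeeping of the removal
  step stays exact.
* Degenerate inputs fail loudly: inconsistent registries raise integrity
  errors naming the offending cell, unmapped labels list themselves, and
  a synthetic geometry whose interior IPCs cannot touch two cores is a
  generation error.

## Limitations

* At the calibrated desk scale (IPCs of ~60–110 sites), $T = 60$ keeps
  the lattice gently liquid even after patterning completes: a settled
  vertex cell occasionally loses or gains a scored contact for one or a
  few 500-MCS records. Central tertiary counts therefore show rare
  transient excursions after their plateau, and strict
  "equals-final-and-remains" change-point estimates can land well after
  the visible completion of patterning. Enlarging the lattice would damp
  the jitter but would also detune the printed $L = 16$ from the
  geometry, since contact lengths scale with resolution while the
  threshold does not.
* The model is apical-plane only: no basal footprints, no photoreceptor
  or bristle influence, no signaling — death is a purely geometric rule.
* The two-cell-type reduction means core internal structure (cone cells,
  1°s) is invisible; experiments that resolve it need a different model.
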