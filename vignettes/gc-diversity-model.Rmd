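---
title: "Modeling clonal diversity in the germinal center reaction"
author: "gcsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling clonal diversity in the germinal center reaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Germinal centers (GCs) are transient structures in lymphoid tissue where
B cells mutate their receptors (BCRs) and compete for survival signals,
producing antibodies of increasing affinity. A purely deterministic
competition would leave each GC dominated by the single fittest clone, yet
sequencing studies find many GCs that retain a broad set of clones while
still maturing affinity. `gcsim` implements a spatial, stochastic
agent-based model of a single GC to ask how four experimental "handles"
shape the temporal evolution of clonal diversity:

1. the amount of antigen displayed on follicular dendritic cells (FDCs),
2. the affinity of the founder B cells that seed the GC,
3. epitope masking by soluble antibody (endogenous feedback or passive
   injection), and
4. the quantity and quality of T follicular helper (Tfh) cells.

## Model structure

### Shape space and affinity

BCRs and the (single, non-mutating) antigen epitope are points on an
abstract integer lattice of dimension `D = 4` with side `L = 10` — the
classical shape-space abstraction for antibody recognition. The *mutation
distance* `d` between two points is their L1 (city-block) distance, and
binding probability (affinity) is

```
a(d) = exp(-(d / gamma)^eta),     gamma = 2.8, eta = 2
```

so `a(0) = 1` and affinity decays as a Gaussian in mutation distance. With
these defaults, founder cells drawn at distance 5–6 bind with probability
~0.01–0.04: low but viable, which is what makes the founder-affinity
experiment meaningful. `D`, `L`, `gamma` and `eta` are exposed in
`gc_config()`; the exact values used in the reference literature live in
supplementary material we treat as a convention of the model lineage
rather than fixed truth.

Somatic hypermutation (SHM) moves a BCR one unit in one random dimension
(out-of-bound shifts are redrawn). Each daughter cell mutates independently
with probability 0.5 per division; mutation is silent for the first 24 h of
the reaction, so the earliest expansion is clonally faithful.

### Space, agents and zones

The GC is a sphere of radius 160 µm discretized at 5 µm, split into two
hemispheres: the dark zone (DZ, proliferation and SHM) and the light zone
(LZ, antigen capture and selection). Mobile agents (B cells, Tfh cells)
occupy at most one lattice site each and perform a random walk (B cells
7.5 µm/min, Tfh 10 µm/min) biased toward their current target zone;
within the target zone, moves that would leave it are rejected. We do not
model chemokine fields explicitly: the measured outcomes (diversity,
affinity, size) depend on which zone a cell occupies and whom it can touch,
not on fine motility realism. Tfh cells are confined to the LZ.

200 FDCs are placed in the LZ, each contributing a dendritic star (center
plus six orthogonal arms of 8 sites); its antigen allotment (1000, 3000 or
5000 units) is divided equally over its sites. Dendrites are a site
property: they do not block movement, and a B cell standing on a dendrite
site is in contact with it.

### The selection cycle

* **Founder influx.** Clonally distinct founder B cells enter the DZ as a
  Poisson process at 2 cells/h until 96 h (~180–200 founders), each
  performing 6 initial divisions. Clone identity is inherited and never
  changes.
* **Antigen capture.** Unselected centrocytes in contact with a dendrite
  site capture antigen stochastically; each success moves one unit from the
  site to the cell's pMHC tally. The per-attempt success probability is the
  product of BCR affinity and the *accessible antigen density* of the site
  (below), making capture both affinity- and availability-limited.
* **Tfh help.** Each Tfh cell polarizes toward the adjacent unengaged
  centrocyte with the highest pMHC (ties broken uniformly); only the
  polarized cell accrues signal, at `rate x multiplier x dt`. Engaged pairs
  hold position, so contacts persist until outcompeted. A centrocyte
  reaching the signal threshold (inclusive) is positively selected; one
  that exceeds its 10 h lifetime unselected dies by neglect. Cells that
  never capture antigen can never be selected.
* **Recycling with dynamic division number.** A selected cell returns to
  the DZ and divides `clamp(div_min + round(slope * ln(pMHC)), 1, 6)`
  times: cells that captured more antigen burst harder. The slope is
  calibrated (see below) so the run-average is 2–2.5 divisions per
  selection, the experimentally observed range. pMHC and signal reset on
  recycling.
* **Output and antibody feedback.** After completing its division program,
  a recycled cell exits as output with probability `p_output` (removed via
  the DZ) or rejoins the centrocyte pool. Output cells secrete antibody
  after a 48 h delay; the soluble pool is tracked in 10 log-spaced K_D bins
  (1–1000 nM), with per-bin concentration growing in proportion to the
  cumulative output of that affinity bin.
* **Epitope masking.** The antibody pool occupies FDC antigen according to
  the competitive Langmuir isotherm `theta = S/(1+S)`, `S = sum(C_i/K_Di)`,
  re-equilibrated on an hourly cadence (concentrations change on a scale of
  days, so a finer cadence only costs time). Masked antigen is integer
  bookkeeping per site; the ledger `free + masked + pMHC held + consumed =
  initial` is exact and audited at every recording step. Exogenous
  injection (at day 0 or 6; K_D 500 or 6.3 nM; default dose 10 nM = 10x the
  lowest K_D bin midpoint, chosen so a high-affinity injection produces
  strong masking while a 500 nM injection is weak) adds one fixed species.
* **Accessible antigen density.** A site with `free` unmasked units out of
  `tot` total presents density `free / max(tot, sat)` where `sat` is the
  site saturation density. Masking therefore lowers capture probability
  immediately (the free fraction falls), and depletion lowers it once a
  site drops below saturation — a gradual stringency ramp rather than a
  cliff. This is the mechanism by which low antigen amounts produce
  smaller GCs that collapse earlier, and by which antibody feedback raises
  selection stringency.
* **Collapse.** A GC whose live B-cell count falls below 10 after the
  influx window is recorded as collapsed (the simulation continues; the
  flag and time are kept). The threshold is a bookkeeping convention: the
  reaction has no natural discrete end.

The per-step phase order is fixed: influx, motility, division/SHM,
antibody re-equilibration, antigen capture, Tfh interactions, selection
decisions, collapse check, recording. Division and capture commute (a
division changes neither antigen nor another cell's capture), so on steps
without an antibody update they run as one fused pass; this is an
implementation detail with no observable consequence beyond the RNG
stream.

## Diversity metrics

For a clone census with counts `x_i` and mole fractions `p_i`:

* founder-cell Shannon entropy `fcSE = -sum(p_i ln p_i)` (nats),
* clonal dominance = `max(p_i)`,
* cumulative GC response `CGR = mean affinity x fcSE`, which rewards GCs
  that are simultaneously mature and diverse.

A collapsed (empty) GC contributes `fcSE = 0`, dominance 1, mean affinity
0 and size 0 to replicate averages from its collapse time onward. This
inclusion rule matters: replicate-mean affinity *drops* as GCs collapse,
which is the behavior population averages show when failed GCs are not
silently discarded. `aggregate_replicates(rule = "drop")` provides the
alternative accounting. Whether collapsed GCs should be included in or
dropped from the entropy average is genuinely open; we chose inclusion for
consistency with the affinity rule and expose the switch.

The day-18 snapshot (`snapshot_metrics()`) uses the recorded timepoint
nearest 432 h. Mean GC affinity averages over *all* live B cells in both
zones.

## Calibration

The study conditions are fixed up front: influx 2/h to 96 h,
antigen 1000/3000/5000 units per FDC, Tfh 100/200/300, signal multiplier
0.6/0.8/1/1.2, founder distance bands 5–6/6–7/7–8, injection K_D 500 or
6.3 nM at day 0 or 6, 21-day horizon. The kinetic constants the
supplementary literature would fix (capture attempt rate, Tfh signal rate
and threshold, division-map slope, output probability, antibody production
rate, site saturation) were calibrated once against the reaction-level
anchors: ~10–30% of centrocytes positively selected under default
conditions, mean divisions per selection in [2, 2.5], replicate-averaged
fcSE peaking near day 5, CGR peaking between days 10 and 12, and frequent
collapse after day 16 only in the low-antigen condition. Calibration was
performed by simulating small replicate sets across these conditions and
fixing the defaults recorded in `gc_config()`; they are not re-tuned per
experiment.

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `affinity_gamma`, `affinity_eta` | 2.8, 2 | shape-space distance, — | width/shape of the affinity function |
| `founder_rate_per_h`, `founder_stop_h` | 2, 96 | cells/h, h | founder influx window |
| `founder_d_min`, `founder_d_max` | 5, 6 | mutation distance | founder affinity band |
| `antigen_per_fdc` | 3000 | units | antigen load per FDC (1000 low / 5000 high) |
| `tfh_count`, `tfh_signal_multiplier` | 200, 1 | cells, — | Tfh quantity and quality |
| `tfh_signal_rate_per_h`, `tfh_signal_threshold` | 1, 2.5 | signal/h, signal | 2.5 h of polarized contact selects at multiplier 1 |
| `cc_lifetime_h` | 10 | h | centrocyte death-by-neglect deadline |
| `capture_rate_per_h` | 8 | attempts/h | antigen capture attempt rate in contact |
| `fdc_site_saturation` | 20 | units | site antigen density below which capture scales down |
| `pmhc_cap` | 8 | units | maximum displayed pMHC |
| `div_slope`, `div_min`, `div_max` | 1.1, 1, 6 | — | dynamic division map (mean ≈ 2.15 under defaults) |
| `p_output` | 0.3 | — | post-division exit probability |
| `ab_production_rate_nm_per_cell_h` | 3e-6 | nM/(cell·h) | endogenous antibody secretion |
| `ab_secretion_delay_h` | 48 | h | delay between output and secretion |
| `inject_dose_nm` | 10 | nM | exogenous antibody dose |
| `cycle_h`, `cycle_jitter` | 7, 0.3 | h, — | division cycle and its uniform jitter |
| `p_mutation`, `mutation_silent_h` | 0.5, 24 | —, h | SHM probability per daughter; silent phase |
| `extinction_threshold` | 10 | cells | collapse bookkeeping threshold |

## Numerical choices

* `dt = 1/120 h` (30 s of simulated time per step), the largest step for
  which each cell type's per-step
  move probability `speed x dt / spacing` stays at most 1, so realized
  speeds match configured speeds. (The model lineage uses finer steps; the
  observables here are insensitive once move probabilities are valid.)
* Recording cadence 4 h; the day-18 snapshot therefore lands exactly on
  432 h.
* The engine's inner randomness uses a splitmix64 generator seeded from
  R's RNG, so `run_gc(cfg, seed)` is exactly reproducible and all
  randomness derives from `set.seed()`.
* Blocked moves and deferred divisions (no free neighbor site) are legal
  no-ops retried later; nothing is destroyed by crowding.
* Ties (Tfh polarization, move targets, daughter placement) break
  uniformly at random under the run's RNG.
* The selection threshold comparison is inclusive (`signal >= threshold`).

## What the simulation does and does not emulate

The synthetic data produced by `run_gc()` are clone censuses with the
statistical structure the mechanism generates: staggered clonal expansion,
affinity-dependent establishment, competition-driven contraction, and
collapse. Real GC sequencing data additionally carry measurement
artifacts (sampling depth, lineage-inference error), multi-epitope
antigens, T–B entanglement kinetics, regulatory T cells, and distinct
memory/plasma export programs — none of which are modeled. Passing tests
demonstrate internal consistency of the mechanism and agreement with the
reaction-level anchors above, not that any particular biological GC will
show the same numbers.

Known limitations: a single epitope (antibody feedback can only raise
stringency, never redirect it); one aggregate output fate; hemispheric
zones without chemokine gradients; integer antigen units; Tfh cells as
passive signal dispensers that neither expand nor migrate between GCs.

## Problem sizes

Desk-scale analyses in the tests and the acceptance script use 10–20
replicate GCs per condition at the full 21-day horizon and full geometry,
which resolves the qualitative orderings studied here; the figure-level
experiments in the literature use 100 replicates, available via
`preset_scenario(..., n_replicates = 100)`.
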