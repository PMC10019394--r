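---
title: "gcabm: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gcabm: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcabm)
```

# What the simulator is

`gcabm` simulates one germinal-center (GC) reaction end to end and emits
B-cell receptor (BcR) repertoires whose ground truth — lineage, mutation
history, affinity, and cell type of every sequence — is fully known. It is
a hybrid of four layers: an agent-based model (ABM) of cellular dynamics;
a nucleotide-level IgH sequence per cell mutated through a somatic
hypermutation (SHM) fate tree; a continuous shape space mapping sequences'
positions to affinities; and a per-cell BLIMP1/BCL6/IRF4 ordinary
differential equation (ODE) network deciding plasma-cell (PC) fate.

This vignette documents the model assumptions, the parameters that matter
(with units and defaults), the numerical choices, and the places where the
design was genuinely open and a decision had to be made.

# The agent-based reaction

Cells carry a position inside a sphere (default radius 160 µm). The
hemisphere `z <= 0` is the dark zone (DZ), `z > 0` the light zone (LZ).
Chemokine-driven zonal segregation is modelled phenomenologically: each
cell performs a persistent random walk (speed 150 µm/h, direction
resampling at 2/h) with a configurable drift (weight 0.5) towards its
target zone — DZ for centroblasts (CB) and selected centrocytes, LZ for
centrocytes (CC). We deliberately do not solve chemokine fields on a
lattice: none of the quantities this package reports (clone counts,
diversity indices, affinity distributions, export counts) depends on
gradient microstructure, only on zonal residence. For the same reason
positions are continuous rather than lattice points; the sphere and the
two zones are what carry meaning.

Founder influx is a Bernoulli event per step with probability
`p(t) = mu * dt / (1 + exp((t - alpha)/beta))`, `mu = 2` cells/h,
`alpha = 96` h (when influx shuts off), `beta = 6` h (shut-off
smoothness). At the production resolution `dt = 0.002` h this gives
`p(0) = 0.004` and a deterministic expected total of ~192 founders
("approximately 200" in round numbers) over 504 h; `expectedFounders()`
computes the exact step sum. Each founder opens a new clone, draws a
germline sequence without replacement from the pool, and starts at the
configured shape-space distance from the antigen (default 6, affinity
~0.01) in the BCL6-high naive GRN state.

The per-step phase order is fixed and documented in `?gcStep`: influx,
migration, CB cycling/division (with SHM), CB-to-CC differentiation,
FDC contact, Tfh contact, selection, recycling, CC apoptosis, removal,
GRN integration, time advance. A fixed order keeps runs bit-reproducible
under a seed; the stochastic draws themselves come from named RNG streams
(influx, migration, SHM, selection, germline) derived from one master
seed, so toggling one mechanism does not perturb the draws of another.

## Division, output and accounting

CBs divide when their cycle timer (default 7 h) expires, up to a division
budget (6 for founders and per selection round). At division the mother
continues as one daughter — same cell identifier — and exactly one new
lineage node is created. This convention makes the conservation law exact
at every step: live + exported + apoptosed = created. Both post-division
cells run SHM independently once SHM is switched on (24 h).

Output cells arise only through asymmetric division of recycled
(positively selected) CBs: with probability 0.72, if the mother retains
captured antigen (threshold 1 unit), the antigen-retaining daughter is
exported. It leaves as a PC if its BLIMP1 level is at or above
`thetaPC = 8e-8` M, and as a memory B cell (MBC) otherwise — MBCs have no
separate mechanism, they are the non-PC output. Exported cells are inert;
their state is frozen at export.

## Selection

In the LZ a CC contacts an FDC as a hazard (rate 3/h); a contact captures
antigen with probability proportional to affinity (capped at 1). Capture
increments retained antigen and gates BCR signalling into the GRN for the
contact duration (0.6 h). CCs holding antigen contact Tfh cells (rate
3/h), gating affinity-scaled CD40 signalling. A CC is selected when its
time-integrated CD40 signal reaches a threshold (default 1e-8 M); it then
returns to the DZ and re-enters the division programme. Unselected CCs
die when their lifespan (10 h) expires. The contact rates, durations and
the integrated-signal threshold are one annotated configuration ledger
(`gcConfig()`), chosen in the range used by GC ABMs of this lineage; the
qualitative behaviour (affinity-dependent competition, few clones
surviving) is robust to their exact values, and they are not treated as
claims.

# BcR sequences and the SHM fate tree

Each germline sequence is an annotated IgH V-CDR3-J nucleotide sequence:
seven contiguous regions (FWR1, CDR1, FWR2, CDR2, FWR3, CDR3, FWR4) in
0-based half-open coordinates tiling the full length, a reading frame,
and V/J labels. The synthetic generator draws codon-aligned region
lengths centred on IMGT-typical values (84/30/51/30/114/48/45 nt,
~402 nt total, CDR3 48 nt) with ±2 codons of uniform jitter, and fills
them with uniformly random sense codons, so founders are stop-free by
construction. The generator emulates the summary properties of
reconstructed single-GC heavy-chain pools (length scales, seven-region
annotation, small V/J catalogue for stratification); it does not emulate
germline gene usage biases, junctional diversity, or a D segment — the
synthetic sequence is its own germline, since the simulation never needs
germline inference. Per-region length distributions beyond the two
printed scales are a configuration choice, not a claim.

At each division the number of mutations is untruncated
`Poisson(lambda = 0.4)` — the product of a 1e-3 per-bp per-division rate
and the ~400 nt heavy chain. Truncating at 3 mutations would only
approximate the same arithmetic; there is no mechanistic cap, so we do
not impose one. Each mutation is routed independently through the fate
tree: region, then replacement vs silent, then (for replacements) effect.
The printed anchors fix the CDR branch: region probabilities 0.10 / 0.03
/ 0.19 for CDR1/2/3 and per-CDR affinity-change factors 0.79 / 0.76 /
0.75, giving a per-mutation affinity-change probability of 0.2443 and
~0.1 per division. The remaining mass and splits are defaults shipped as
data: FWR region probabilities 0.25/0.14/0.25/0.04 (roughly
length-proportional, summing with the CDRs to 1), replacement probability
0.75 in FWRs, and FWR replacement effects split evenly between lethal and
neutral. Affinity-changing effects are structurally confined to CDR
replacements (a validity invariant), and lethal mass sits on the FWRs,
where a nonsense mutation destroys the receptor scaffold.

Sequence edits are made consistent with the drawn fate at codon level: a
silent mutation must be synonymous, a replacement must change the amino
acid, a lethal mutation must create an in-frame stop, and a non-lethal
outcome must not. The retry protocol is: pick a uniform position in the
region, try the three alternative nucleotides in random order, and move
to a fresh position if none matches; failure is declared only after every
(position, nucleotide) pair in the region is exhausted. Positions and
nucleotides are uniform — no hotspot model. If a drawn fate is impossible
in a short region (e.g. no stop-creating edit exists), the engine
degrades the fate (lethal to plain replacement, replacement to silent)
rather than aborting the run; with realistic region sizes this is a
vanishingly rare edge case.

The sequence-affinity registry makes affinity a function of sequence for
the whole run: every distinct nucleotide sequence is pinned to one
(shape-space position, affinity) pair at first registration, and a cell
re-deriving a known sequence inherits the registered values. Collisions
are resolved first-registration-wins; registering a known sequence with a
different affinity is treated as an invariant breach and aborts.

# Shape space and affinity

The shape space is a continuous 4-D box of side 10 (arbitrary units) with
the antigen at a fixed position, defaulting to the centre (5,5,5,5) — the
extent is stated in the model lineage, the antigen's placement is not, and
the centre maximises the reachable distance range symmetrically. Affinity
is `exp(-(d/Gamma)^2)` of the L1 distance `d`, with `Gamma = 2.8`. The
width is not printed in the main text of the model lineage; 2.8 is pinned
by the anchor that distance 6 corresponds to affinity ~0.01, which the
test suite checks. An affinity-changing mutation moves one uniformly
chosen coordinate by a signed step: magnitude ~ Normal(1, 0.1) with
negative draws re-sampled (a magnitude is a length; at mean 1, sd 0.1 the
negative mass is ~1e-23), sign equiprobable and independent of position —
steps may increase or decrease the distance. Coordinates clamp to
[0, 10]: the lineage states an extent but no boundary rule, and clamping
preserves the extent without biasing the direction choice. Founder
placement draws a uniform point on the L1 sphere of the configured radius
(rejection-sampled into the box), so the founder distance is exact.

# The gene-regulatory network

Each cell integrates the three-equation bistable BLIMP1 (p) / BCL6 (b) /
IRF4 (r) core with squared-Hill interactions; BCR signalling adds to BCL6
decay, CD40 signalling adds to IRF4 production scaled linearly by
affinity. Concentrations are in M, time in hours. The kinetic defaults
(dissociation constants 1e-8 M, unit decay rates, basal rates 1e-14 /
2e-8 / 1e-9 M/h, induced rates 9e-8 / 1e-6 / 2.6e-8 M/h) follow the
published bistable parameterisation of this network and ship as data
(`grnParameters()`), not constants. The signal scales `bcr0 = 15`/h and
`cd0 = 5e-7` M/h are chosen inside the bistable regime such that (i) the
unsignalled system has a BCL6-high/BLIMP1-low state and a
BLIMP1-high/BCL6-low state, with the PC threshold 8e-8 M between the two
BLIMP1 levels, and (ii) a sustained CD40 pulse at affinity near 1 drives
the naive state across the threshold while zero affinity never does. Both
properties are verified numerically in the test suite with a multi-start
damped-Newton fixed-point search (`grnFixedPoints()`) and pulse
integration — they are checked, not assumed. Signals are event-gated:
nonzero only during FDC/Tfh contact windows, because the model ties them
to those interactions.

Integration is fixed-step classical Runge-Kutta (RK4), one GRN step per
ABM step at the production `dt = 0.002` h, with states floored at zero.
The tests verify fourth-order convergence by Richardson extrapolation,
agreement with a closed-form solution in the linear limit, and agreement
with an independent adaptive solver (`deSolve::lsoda`) to 1e-6 relative.
A configurable time-scale factor (default 1) is carried in case GRN hours
and ABM hours ever need decoupling.

# Repertoires and statistics

A subclone is the set of cells sharing one exact BcR nucleotide sequence;
a clone is all subclones of one founder. DNA-mode counting counts every
cell once; RNA mode multiplies each PC by `pcFactor` (default 100),
emulating the elevated immunoglobulin mRNA content of PCs. Clone
frequency is the sum of its subclone frequencies.

Conventions that the definitions leave open, fixed here and configurable:

* **Dominance.** "Upper 25%" is implemented as abundance at or above the
  75th percentile with linear interpolation (R quantile type 7), ties
  included; the alternative convention is abundance >= 0.5% of all
  sequences.
* **D50.** The smallest prefix of the descending clone-size vector whose
  sum reaches *at least* half the total (>= rather than >), divided by
  the clone count.
* **Pielou evenness** is `H'/ln S`; for a single clone it is undefined
  (0/0) and reported as missing rather than 0.
* **Chao1** is the classic estimator `S_obs + F1^2/(2 F2)` with the
  bias-corrected fallback `S_obs + F1(F1-1)/2` when no doubletons exist;
  the original analyses this mirrors name no variant.
* **Clonal grouping** of AIRR-style records stratifies by V gene, J gene
  and CDR3 length, then single-linkage clusters at >= 85% CDR3 nucleotide
  identity (Hamming on equal lengths) — single linkage matching the
  default behaviour of the standard upstream tool.

All indices are tested against independent brute-force oracles on
randomised tables.

# Problem sizes, the smoke configuration, and limitations

The production condition (504 h at dt = 0.002 h, 252,000 steps, ~192
founders) is what `gcConfig()` describes; it is a long-running simulation
by design. The package's tests and examples run a scaled-down 48 h
configuration (`smokeConfig()`: dt = 0.02 h, influx 0.4 cells/h, founder
distance 2, 4 h cycle, 4 divisions per round) chosen so that every
mechanism — SHM, selection, recycling, asymmetric export, lethal
mutations, apoptosis — demonstrably fires within the short horizon while
the conservation, registry and lineage invariants are checked throughout.
Enlarging `dt` scales all per-step hazards linearly (they are `rate*dt`
forms), so the scaled run exercises the same code paths at coarser
resolution; it is an exerciser, not a study condition, and its outputs
are not quantitative claims about the 21-day reaction.

Known limitations, intentional in scope: no antigen-specific repertoires
(the shape space generalises, it does not bind a real antigen); no
mutation hot/cold spots, key or blocking mutations, or framework effects
on affinity through rigidity or entropy; no light chain, D-gene or
junctional reconstruction; no explicit MBC differentiation mechanism
beyond the asymmetric-division rule; no antibody feedback or
multi-GC/blood compartment. Passing tests on synthetic pools show the
machinery is correct under the stated distributions; they do not show
that real repertoires follow those distributions.
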