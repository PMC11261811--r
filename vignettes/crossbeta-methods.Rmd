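---
title: "Designing parallel beta-sheet nanofibrils: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing parallel beta-sheet nanofibrils: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossbeta)
```

crossbeta implements a computational pipeline for discovering short
peptides that self-assemble into *parallel* beta-sheet nanofibrils —
two-layer cross-beta spines of the Class-1 symmetry type, in which the
N-to-C strand vectors within each sheet point the same way while the two
sheets stack antiparallel to each other. The pipeline has four stages:
a geometric scaffold builder, Monte Carlo sequence design on that fixed
scaffold, event-driven coarse-grained aggregation simulations that test
whether a designed sequence actually assembles with the intended strand
organization, and amide-I FTIR analytics that classify the product as
parallel or antiparallel by the beta-index criterion. This vignette
records the models behind each stage, the tunable parameters and their
defaults, and the design decisions taken where the methodology left the
choice open.

## Scaffold geometry

The design algorithm never moves the backbone: sequences are draped onto
a fixed two-layer scaffold. `build_cross_beta_scaffold()` constructs an
idealized extended-strand geometry rather than a relaxed atomistic one:
each strand runs along x with a rise of 3.4 Å per residue, strands stack
along y at the in-sheet spacing `d_strand` (default 5.5 Å), and the two
sheets stack along z at `d_sheet` (default 12 Å). These spacings are the
construction targets for the cross-beta spine used throughout; the
carbonyl oxygen is extended 1.23 Å toward the partner strand so that the
canonical H-bond ladders of parallel (O_i -> N_{i+1}) and antiparallel
(O_i -> N_{8-i}) sheets appear at realistic N···O distances (4.27-4.41 Å
at 5.5 Å spacing). Class 1 places parallel strands within each sheet and
reverses the second sheet; Class 8 (the comparison fixture) alternates
strand direction within each sheet. An idealized geometry is sufficient
here because scoring depends only on the residue-residue contact map and
H-bond count, both of which are stable features of the cross-beta
arrangement rather than of any particular relaxed snapshot.

Two measurement helpers, `measure_d_strand()` (mean nearest CA-CA
distance between adjacent in-sheet strands) and `measure_d_sheet()`
(distance between the sheets' mean planes along their common normal),
verify that a built or file-loaded scaffold realizes its nominal
spacings; construction enforces agreement to 0.1 Å in-sheet.

`replicate_unit()` extends a scaffold by applying a rigid transform
cumulatively, refusing configurations that bring any two atoms of
different copies within 1.0 Å — a hard floor that catches construction
errors without forbidding tight zipper interfaces. `cap_termini()` flags
N-acetylation/C-amidation; its only modelling consequence is that the
scoring stage drops the terminal-charge interactions. PDB files are
written and parsed through bio3d, with a line-oriented pre-scan so that
malformed ATOM records are reported with their line number.

## The design score

A candidate sequence s on a scaffold is scored by

```
gamma(s) = dG_binding(s) - lambda * P_aggregation(s)
```

where lower is better. `dG_binding` is the interaction energy of a
designated *test chain* (the chain with the most neighbours) with the
rest of the assembly: a sum of residue-pair contact energies over all
inter-chain residue pairs whose CA positions lie within 6.5 Å, plus a
constant term (-0.5 per bond) for each backbone H-bond the test chain
makes, plus — when the termini are uncapped — the interactions of the
free N(+) and C(-) termini with charged contact partners.
`P_aggregation` is an additive per-residue intrinsic aggregation
propensity. `lambda` (the full-scale searches use 2.0 and 3.0) balances
the two terms.

Both tables ship as plain-text TSV under `inst/extdata/` and are
interchangeable via `contact_potential(file=)` and
`aggregation_scale(file=)`. The shipped defaults are the package's own
residue-level model, in dimensionless score units with no kcal/mol
claim:

* the aggregation scale blends Kyte-Doolittle hydropathy with
  Chou-Fasman beta-sheet propensity, `0.1*KD + 0.5*(Pbeta - 1)`;
* the contact table is dominated by *like-residue stacking*: identical
  hydrophobic or polar residues receive a deep diagonal term (the
  in-register ladders — hydrophobic stacks, Asn/Gln-type polar zippers,
  aromatic stacking — that stabilize parallel in-register amyloid),
  while generic cross-residue hydrophobic mixing is kept weak
  (`-0.5*sqrt(s_a*s_b)`); opposite charges attract moderately (-0.6),
  like charges repel (+1).

This shape is a deliberate choice: because the scaffold's dominant
contacts are in-register (residue i against residue i of the adjacent
parallel strand), a stacking-dominated table makes the design search
reward sequences whose residues are strong self-stackers, which is also
exactly the property that drives parallel (rather than antiparallel)
assembly in the aggregation model below. Published absolute binding
energies are not reproducible from a residue-level table and are not a
target; only the score *combination* identity and the search behaviour
are.

## Monte Carlo sequence design

`run_design()` starts from a random sequence satisfying the hydration
case — the constraint fixing how many hydrophobic, polar, charged and
other residues the peptide contains (Case 1: 5/0/2/0, Case 2: 5/2/0/0
for the 7-mers) — and performs `n_steps` (default 10000) trial moves:
with equal probability either a *mutation* (one position redrawn
uniformly within its residue class, possibly to the same residue, which
keeps the within-class proposal unbiased) or an *exchange* (two
positions swapped regardless of class). Both moves preserve the case by
construction, so every visited sequence is feasible. Moves are accepted
by the Metropolis rule on the score difference with a dimensionless
sequence temperature (default 1.0, giving order-unity acceptance on the
shipped tables; the methodology source does not state an acceptance
scale, and no annealing is applied). The same sequence is draped on
every chain, so a mutation is implicitly applied to all chains at once.
Because the scaffold is fixed, the contact list is precomputed once and
each step costs a table-lookup sum. The trace is a tibble (one row per
step with the score breakdown, move type and acceptance flag); `tidy()`,
`glance()` and `autoplot()` give the broom-style views, and the top-k
report takes the lowest-scoring distinct sequences with ties broken by
first visit.

## Coarse-grained model and event-driven dynamics

Aggregation is simulated with a four-bead-per-residue model: three
backbone spheres (NH, CaH, CO; diameters 3.3/3.7/4.0 Å, united-atom
masses) and one side-chain sphere per residue with residue-specific
diameter, mass and CA-R bond length from `inst/extdata/cg_beads.tsv`
(side-chain diameters and bond lengths are physically reasonable
placeholder values, flagged as such in the file; masses are residue
minus backbone). Chains are held near the extended-strand template by
hard bond windows: covalent bonds plus angle/geometry pseudo-bonds
within and between consecutive residues, and a CA(i)-CA(i+2) pseudo-bond
that biases the backbone toward extension. All windows are ±2.375% of
the template length (common discontinuous-dynamics practice,
configurable). Keeping the chains semi-rigid replaces the full
coil-to-strand folding transition, which would dominate the
computational budget at desk scale; the simulations therefore probe
assembly and strand organization, not folding kinetics.

Interactions are discontinuous: hard cores at additive contact
diameters, square wells for backbone H-bonds (NH-CO of different
chains) and for side-chain pairs (outer distance 1.5 contact diameters;
depths taken from the attractive entries of the contact table at 1.0
kcal/mol per score unit). Internal units are Å, amu and kcal/mol, making
the time unit `Å*sqrt(amu/(kcal/mol))` ≈ 48.9 fs; at 296-310 K, kT is
0.59-0.62 kcal/mol, which sits in the window where in-register parallel
ladders (stacking rungs of 2-3.5 kcal/mol plus H-bonds) are stable while
weaker mismatched contacts exchange — the model's fibrillization window.

The H-bond well is deliberately *moderate and narrow*: depth 1.0
kcal/mol with outer distance 4.2 Å against a 3.65 Å NH-CO contact.
Dimer-scale experiments during model development showed that a wider
well (4.5 Å) lets each NH reach two carbonyls at once, so sheared and
reversed (antiparallel) backbone pairings accumulate enough H-bond
energy to lock in whatever orientation first touches; at 4.2 Å those
mis-registered pairings sit near the outer well edge and detach, while
in-register ladders — which for the designed sequences are the parallel
ones, because only they engage the deep like-residue stacking rungs —
hold and grow. In two-chain studies of GAIDWVK this geometry yielded
parallel ladders in every dimer that assembled.

The dynamics engine (C++, `src/dmd.cpp`) is a standard asynchronous
event-driven simulator: beads fly ballistically between discrete events
— elastic core collisions, energy-book-kept well captures/escapes (with
reflection when the radial kinetic energy cannot pay the well depth),
hard reflections at bond-window walls, Andersen-thermostat ghost
collisions that redraw one bead's velocity from the Maxwell-Boltzmann
distribution, and snapshot events. Event discovery uses cell lists (cell
size at least the largest interaction range, neighbour search over the
27-cell stencil, cell-boundary-crossing events) with minimum-image
periodic boundaries; predictions are scheduled within a short time
horizon and a periodic stencil-limited resweep recovers anything beyond
it, keeping the event queue small. Systems too small for three cells per
box edge fall back to all-pairs prediction with the same horizon scheme.
Stale events are invalidated by per-bead collision counters. All
randomness flows through R's RNG, so runs are exactly reproducible under
`set.seed()`. With the thermostat off, total energy is conserved to
floating-point accuracy, and for few-bead systems the event sequence is
validated against a brute-force time-stepping oracle in the test suite.

The Andersen rate defaults to 0.1 per bead per time unit in `run_dmd()`.
The aggregation screens in the workflow use 0.02: velocity redraws
destroy the ballistic centre-of-mass motion that transports chains at
these scales, and the lower rate keeps diffusion realistic while still
holding the set temperature within a few percent.

## Fibril metrics

Analysis operates on a *frame*: a tibble of bead/atom positions with
chain, residue and atom labels, carrying the periodic box edge as an
attribute when it comes from a simulation (chains are then made whole
and all distances are minimum-image, making the metrics invariant under
rewrapping).

A backbone H-bond is an amide donor (N/NH) within 4.5 Å of a carbonyl
acceptor (O if present, else the CO bead), excluding intra-chain
neighbours closer than three residues. The 4.5 Å default accommodates
the idealized scaffolds at 5.5 Å strand spacing (N···O 4.27-4.41 Å) and
contains the engine's 4.2 Å well, so one criterion serves both idealized
fixtures and trajectories. A *strand pair* is called when the H-bonded
residues on either chain include a consecutive run of at least 3 —
suppressing transient single contacts in kinetics traces. On these
pairs:

* `beta_content` is the percentage of all residues lying in qualifying
  ladders;
* `parallel_fraction` is the percentage of H-bonded strand *pairs*
  (not residues) whose N-to-C end-to-end vectors have positive dot
  product; a frame with no pairs reports `NA` ("no sheets") rather than
  0%, so coil frames cannot masquerade as antiparallel;
* `count_layers` counts the connected components (of at least two
  strands) of the strand-pair graph within the largest aggregate, where
  aggregates are chains linked by any CA-CA contact within 13 Å — a
  cutoff spanning the 12 Å inter-sheet stacking distance;
* `largest_aggregate` is that aggregate's chain count.

These definitions are declared conventions: the quantity "% parallel
beta-sheet content" has no single published operationalization, so the
pair-based definition used here is stated prominently rather than
inferred.

## FTIR beta-index analytics

`preprocess_spectrum()` flattens the baseline linearly between two
anchor windows (defaults 1590-1605 and 1710-1725 cm^-1) and smooths with
a Savitzky-Golay filter (window 9 points, order 3 — "smoothing" is
otherwise unspecified in the source methodology, and this choice
preserves peak heights to within a few percent at realistic noise).
`fit_amide_i()` fits a Gaussian mixture to 1600-1700 cm^-1 by
Levenberg-Marquardt with four default components (main beta ~1628,
oligomer/alpha band ~1650, random coil ~1665, high-frequency beta
~1695), data-driven initial heights, and center bounds of ±12 cm^-1
around the initial values.

The beta-index is the ratio of fitted peak *heights* — height, not area,
because the index is described in the literature as an intensity ratio —
of the peak between 1693 and 1697 cm^-1 to the main beta-sheet peak
between 1624 and 1632 cm^-1, with index 0 when no high-frequency peak is
present. Indices strictly below 0.1 are called parallel; 0.1 itself is
antiparallel (the "under 0.1" rule read strictly; the boundary case is a
documented convention). Group comparisons use a one-tailed two-sample
t-test, Welch by default with a pooled-variance option. The synthetic
generator builds spectra as Gaussians plus linear baseline plus seeded
noise; its antiparallel preset places the high-frequency component at
1695 cm^-1, inside the index's reading window, with height ratio 0.25.

## The design-round workflow and its scaled-down conditions

`run_round()` chains the stages: for each (case, lambda) it designs a
sequence, then `screen_sequence()` simulates it at each screening
temperature, picks the temperature with the highest final beta content,
re-runs there for the extended duration, and classifies the final
structure: below 20% beta content is "low fibril content" (a declared
threshold), at least 50% parallel pairs is "predominantly parallel",
otherwise "<50% parallel". `refine_scaffold()` takes the best
predominantly-parallel candidate and drapes it on a 16-chain capped
Class-1 scaffold as the second round's starting geometry — the
translation-based extension used here is an analogue of crystal-symmetry
replication, not a reproduction of any particular code path.

The default simulation conditions are the package's scaled-down study
conditions, chosen once: 12 chains in a 50 Å periodic box (~160 mM;
the full-scale condition of 48 chains in a 200 Å box at ~10 mM is
available by passing those values, but first-encounter times at 10 mM
are far beyond desk scale), screens of 3000 reduced time units at
296/303/310 K, and an extended run of 12000 units (~0.6 ns-equivalent
of ballistic CG time; published aggregation runs are microseconds, so
agreement is expected at classification level only, never
quantitatively). Under these conditions the reference design GAIDWVK
assembles into a beta-sheet aggregate with all-parallel strand pairs
within the extended run.

## What the synthetic generators do and do not emulate

The fixture generators (`make_fixtures()`, `coil_frame()`,
`preset_spectrum()`, the CG builder) emulate the *structural signatures*
the analytics read: ideal Class-1/Class-8 geometry, dispersed coils,
amide-I band shapes with and without the antiparallel component. They do
not emulate conformational heterogeneity, multi-layer stacking disorder,
instrument drift beyond linear baselines, or concentration effects.
Passing tests therefore certify the measurement and classification
machinery and the model's internal physics — energy conservation,
thermostat statistics, orientation selectivity — not quantitative
agreement with any experimental spectrum or aggregation rate.

## Known limitations

* The contact potential and aggregation scale are residue-level
  stand-ins in arbitrary score units; printed binding free energies of
  the reference designs are out of reach by construction.
* CG chains are semi-rigid extended strands: random-coil kinetics,
  folding bottlenecks and sequences that remain coil (rather than
  failing to nucleate) are outside the model.
* The H-bond wells are isotropic; directionality is approximated by the
  narrow well width rather than by auxiliary-bead criteria.
* Sheet-stacking (steric-zipper interface) registry across layers is
  neither designed for nor analyzed, and layer counting depends on a
  declared 13 Å contact cutoff.
* The mapping from reduced time to physical microseconds is nominal;
  kinetic comparisons between sequences are qualitative.
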