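---
title: "Methods: locating pH-activation switch residues of VDE"
author: "vdeswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locating pH-activation switch residues of VDE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdeswitch)
```

This vignette is the package's own account of its models and numerical
choices: what is computed, under which assumptions, which parameters matter
and why their defaults are what they are, and what the synthetic-data
generators do and do not emulate.

## The titration model

Violaxanthin de-epoxidase is switched on when the thylakoid lumen acidifies
from about pH 7 to about pH 5.2. Residues that implement that switch must
change protonation state over exactly that interval, so the pipeline's first
stage is titration of the ionizable residues.

Each site $i$ is binary: $x_i = 1$ when ionized (charged), $0$ when neutral.
A microstate $\mathbf{x}$ has energy

$$E(\mathbf{x}; \mathrm{pH}) = \sum_i x_i\,\varepsilon_i(\mathrm{pH})
  + \sum_{i<j} x_i x_j W_{ij},$$

where $W_{ij}$ (kcal mol$^{-1}$) is the electrostatic interaction between
the *ionized* forms of sites $i$ and $j$ — an input, produced upstream by a
continuum-electrostatics package, not computed here — and the per-site term
is $\varepsilon_i = \ln(10)\,k_BT\,(\mathrm{p}K_{a,i} - \mathrm{pH})$ for
acids (ASP, GLU, TYR, CYS, C-terminus) and the sign-reversed expression for
bases (HIS, LYS, ARG, N-terminus). Ionized means deprotonated for an acid
and protonated for a base, which is why one ionization convention serves
both kinds while the *protonated fraction* is derived per kind
($1 - \langle x\rangle$ for acids, $\langle x\rangle$ for bases).

Temperature is fixed at 298 K unless overridden ($k_BT = 0.593$,
$\ln(10)\,k_BT = 1.364$ kcal mol$^{-1}$). The electrostatic inputs carry no
temperature of their own and the MD protocol this kind of data accompanies
is typically thermostatted at 300 K; the 2 K difference is far below the
resolution of any quantity computed here.

Two solvers share this energy function. `enumerate_titration` sums all
$2^N$ microstates exactly and is the package-internal oracle; it refuses
$N > 20$. `mc_titration` runs single-site-flip Metropolis sampling per grid
pH — proposals uniform over sites, first 20% of steps discarded as burn-in
(standard practice; the results are insensitive to the exact fraction for
the chain lengths used). The inner loop is compiled (Rcpp) and draws from
R's RNG, so `set.seed`-style seeds make curves bit-reproducible. In the
non-interacting limit both reduce exactly to Henderson–Hasselbalch,
$f = 1/(1 + 10^{\mathrm{pH} - \mathrm{p}K_a})$, which the test suite asserts
at machine precision.

**Apparent pKa** is read off a curve as the pH where the protonated fraction
crosses $1/2$, linearly interpolated between bracketing grid points. A curve
that never crosses inside the grid yields `NA` with an `out-of-range` flag;
a non-monotone curve (possible for strongly coupled sites) yields the
lowest-pH crossing plus a `non-monotone` flag and a warning, rather than a
silent choice among crossings.

**Candidate selection** is the closed window rule: sites with intrinsic
$\mathrm{p}K_a \in [5.0, 7.0]$ (inclusive), ordered by residue number, each
annotated with $|f(\mathrm{pH}_{to}) - f(\mathrm{pH}_{from})|$ over the
7 → 5.2 transition. The window is the filter and the protonation change an
annotation because the two criteria are *not* equivalent: a boundary residue
at pKa 5.0 changes by only ≈ 38% under Henderson–Hasselbalch, yet belongs in
the window. Selecting on the window and reporting the change keeps both
facts visible instead of silently reconciling them. An optional `pad`
argument widens the window symmetrically (default 0) for sensitivity
analyses that allow for the ±0.5 uncertainty typical of computed pKas.

## Electrostatic node maps

Pairwise energies are averaged per unordered residue pair (duplicate
observations, in either orientation, are averaged on load) and become edges
of an undirected graph when $|\bar E| > $ cutoff. Two thresholds are kept
deliberately distinct:

* **analysis cutoff, 0.2 kcal mol⁻¹** — defines the graph used for density
  and k-cores;
* **display threshold, 0.4 kcal mol⁻¹** — only filters what the DOT export
  renders.

They serve different purposes (a sparser picture is easier to read than to
analyze), so the JSON report carries the density of both graphs rather than
guessing which one a reader wants.

Density is $2|E| / (|N|(|N|-1))$ and is undefined (flagged, not 0) below two
nodes. The k-core decomposition is the classic iterative pruning: a node's
core number is the largest $k$ such that it survives repeated deletion of
all nodes of degree $< k$; edge signs are ignored once an edge passed the
cutoff. "Interaction hubs" are the connected components of the subgraph
induced at a minimum core level — cohesive subgroups of mutually coupled
residues, the structures that reorganize when the enzyme's dimer interface
forms. The implementation is a direct ~20-line pruning loop; tests check it
against both an exhaustive definition-checking oracle (every vertex subset,
graphs up to 12 nodes) and `igraph::coreness`, two independent routes.

DOT output styles acids red, bases blue, stabilizing (negative) edges green,
destabilizing red, and widths by
$\mathrm{penwidth} = |E| \cdot (11 - 0.2)/4$ px with $|E|$ clipped at
4 kcal mol⁻¹ so widths never exceed the 11 px maximum (the formula alone
would; clipping is this package's choice). Node labels use the field's
one-letter convention (`D86`, `H168`), chain-prefixed (`B-H121`) whenever
more than one chain is present. The emitted text embeds each edge's signed
energy so the rendering is parseable back (`parse_dot_edges`), which the
tests use for a lossless round-trip check above the display threshold.

Contact maps are the minimal inter-atomic distance (Å, the convention for
crystal-structure work, hence *not* converted to nm) between every residue
pair of two chains.

## Trajectory integrity

Coordinates are normalized to nm on load; PDB input (Å) is divided by 10.
The monitored hydrogen bond is a plain donor–hydrogen distance (e.g. His
ND1 to Tyr HH). No angle criterion is applied: the quantity of interest is
the two-step excursion from a ~0.2 nm bound state to 0.5–0.7 nm broken
plateaus, for which distance alone is decisive and robust.

**Rupture events** use a hysteresis detector with three tunables: an event
opens when the distance exceeds `broken_thr` (default 0.45 nm) for at least
`dwell` (50) consecutive frames and closes when it drops below `formed_thr`
(0.25 nm) for as long. The defaults sit between the bound state and the
lowest broken plateau with comfortable margins on both sides; the dwell
suppresses single-frame spikes and brief recrossings. All three are
arguments (and CLI flags), since sensible values scale with the frame
spacing of the input.

**Solvent contacts** count water *oxygens* within 0.5 nm of the center atom
(one count per molecule); counting every solvent atom is an option, since
conventions differ and the choice roughly triples the numbers.

**Cavity volume** is a probe-accessible grid estimator: cells of an axis-
aligned grid are blocked when their center lies within (van der Waals
radius + 0.14 nm probe) of any protein atom, and the free cells 6-connected
to a seed cell are flood-filled; the volume is the filled count times the
cell volume. A seed point inside an atom's van der Waals sphere is an error;
a seed in an interstice where the probe fits nowhere gives a defined zero.
This is a deliberately coarse stand-in for pocket-detection tools, adequate
when the volume serves as a before/after indicator of barrel opening; the
tests require < 5% change per halving of the 0.05 nm default spacing on
analytic cavities rather than agreement with any particular pocket
algorithm.

**RMSF** is computed per alpha carbon about its time-mean position after
least-squares superposition of every frame onto the first (via
`bio3d::fit.xyz`), dividing the time variance by $n$ frames. It is compared
to crystallographic B-factors by Pearson correlation, with both series also
returned standardized (deviation from the mean in units of overall standard
deviation) for plotting on one axis.

All of these metrics are invariant under rigid-body motion of whole frames
— asserted property-style in the tests with random rotations/translations.

## Conservation contrast

Column conservation is the frequency of the modal residue among the
*non-gap* characters; an all-gap column is undefined (`NA`), never 0%, and
modal ties break alphabetically for determinism. The strict consensus
(threshold 1.0, the default) writes a residue only where every sequence
agrees. Reference numbering maps alignment columns to the ungapped 1-based
positions of a designated reference sequence (mature-protein convention).

The group contrast classifies a position as `conserved_all` when one
residue is modal at the threshold in *every* group and identical across
groups; otherwise `group_specific_substitution`, upgraded to
`non_ionizable_substitution` when some group's modal residue falls outside
the ionizable set {D, E, H, K, R, Y, C}. That last class is the
evolutionarily interesting one here: plant VDEs carry acidic switch
residues that diatom VDEs replace with non-ionizable ones, consistent with
the diatom enzyme activating at higher pH. Alignments are consumed, never
computed — producing them is an upstream alignment tool's job.

## What the generators emulate — and what they do not

`gen_titration_system` draws residue types with intrinsic pKas inside
per-type ranges (ASP 2.5–5.5, GLU 3.5–5.8, HIS 5.5–7.5, LYS 9.5–11.5,
ARG 11–13, TYR 9–11, CYS 8–10 — textbook solution values widened for
protein-environment shifts) and sparse couplings (density 0.3, magnitudes
0.2–1.5 kcal mol⁻¹) whose signs follow the ionized charges: like charges
repel ($W > 0$), unlike attract. This emulates the *structure* of
continuum-electrostatics output, not its physics: there is no dielectric
model and no conformational relaxation, so passing tests show the samplers
and selection logic are correct, not that any particular protein's pKas
would be reproduced.

`gen_trajectory` programs the integrity signatures directly: baseline
0.2 nm with Gaussian jitter clamped at 2σ (σ = 0.015 nm, so the bound state
never strays past the 0.25 nm hysteresis threshold and the programmed onset
frame is recoverable exactly rather than "±noise"), a plateau drawn from
{0.5, 0.7} nm, optional reformation, ~5 in-shell water oxygens before the
rupture and ~12 after. The water roster is fixed and oxygens are relocated
between the 0.25–0.45 nm shell and a parked zone per frame — influx without
diffusion, which exercises counters and event logic but says nothing about
hydration dynamics. Alpha carbons get per-residue jitter amplitudes with
matching pseudo B-factors ($B = 8\pi^2\langle u^2\rangle/3$), so the
RMSF–B-factor correlation has a known, non-trivial target. Frames are
written as standard multi-model PDB so the same files exercise the parser
used for real trajectories.

`gen_alignment` plants programmed columns (conserved histidine,
D→E ionizable substitution, D→L non-ionizable substitution) on a gapless
reference with background mutations at 2% per column per sequence,
background and programmed columns kept disjoint so the ground-truth classes
are exact at the strict threshold.

All generators are byte-deterministic under their seed.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use sizes chosen to make every
oracle comparison exact or tight while remaining quick to re-run: exhaustive
k-core verification on 500 graphs of up to 12 nodes; Monte-Carlo versus
enumeration on 10-site systems at $10^5$ steps per pH (3 systems × 3 chains,
max per-site error bounded at 0.02); rupture recovery over 20 seeds of
500-frame trajectories; cavity convergence between 0.05 and 0.025 nm grids.
Enumeration at 10 sites is exact, so the MC tolerance measures pure sampling
error; it passes with roughly half the bound to spare.

Degenerate inputs follow one rule: *flag, don't guess*. Empty site tables
titrate to empty curves; a half-point outside the grid is `NA` +
`out-of-range`; density below two nodes is `NA` + `undefined`; zero-variance
series give a flagged `NA` correlation; unmappable alignment positions are
returned in a `skipped` set rather than aborting the mappable ones.

## Known limitations

* Intrinsic pKas and couplings are inputs; without upstream continuum-
  electrostatics output the titration stage characterizes synthetic systems
  only.
* The published node maps and MD traces for VDE itself derive from specific
  crystal structures and 10 ns simulations; this package reproduces the
  *method* and validates it against oracles and generators, not those
  particular figures.
* The cavity estimator has no notion of pocket boundaries open to bulk
  solvent — the bounding box is the boundary; choose it to enclose the
  cavity of interest.
* Solvent-accessible surface area is not implemented; reported SAS changes
  in this system's literature are unit-ambiguous, and the volume and contact
  metrics carry the same information for the before/after question asked
  here.
* The Metropolis sampler flips one site at a time; for systems with very
  strong couplings (tens of $k_BT$) mixing can stall, and enumeration or
  tempering schemes would be preferable. The acceptance check's coupling
  range stays within the regime where single-flip sampling mixes well.
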