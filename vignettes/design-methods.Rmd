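---
title: "Multi-target RNA design: model, operators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-target RNA design: model, operators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mofold)
```

## The design problem

Given `n` target secondary structures θ₁…θₙ of common length `N`
(pseudoknots allowed; a structure is just a set of base pairs), an
optional IUPAC sequence constraint, and a list of objective functions to
minimize, `rna_design()` searches for RNA sequences that

1. are *compatible* with every target — every pair (i, j) of every target
   can form as AU, GC or GU — and satisfy the sequence constraint at all
   times, and
2. are Pareto optimal under the objective vector.

Multi-objective search replaces the weighted objective sums of classical
inverse folding: a single run returns the whole trade-off front, and no
weights need tuning. Weak Pareto optimality (strong dominance in the
sort) is available via `design_control(weak_pareto = TRUE)`.

## Sampling compatible sequences

The pair-union *dependency graph* couples positions that must remain
pairable. Because all three legal pair types join a purine with a
pyrimidine, a compatible assignment exists iff every connected component
is 2-colorable; `build_graph()` rejects odd cycles with an "incompatible
targets" error before any search starts.

Components are decomposed into paths whose endpoints ("start and end"
vertices) have degree ≠ 2; a pure cycle is cut at one arbitrarily chosen
vertex. Per path, the table χ(k, x, s) counts compatible assignments of
the first k path positions ending in nucleotide x given start nucleotide
s (constraint-violating entries are zeroed). The indicator
λ(t, u, i, j) = 1 iff every path between endpoints i and j admits an
assignment with t at i and u at j. Assignment then proceeds: root
nucleotide at a randomly chosen start/end vertex, depth-first traversal
of the remaining start/end vertices with λ-checked backtracking, interior
path positions filled from end to start among `{x : χ(k,x,s) > 0}`.

Two deliberate properties of this sampler:

* **GU avoidance.** Candidates are ordered so that the class of the root
  (G/C or A/U) takes priority and GU-forming choices come last; an
  unconstrained component therefore only ever receives AU/UA/GC/CG
  (verified by a χ² uniformity test at 10⁴ draws), and GU pairs appear
  only when the constraint forces them. GU-rich regions of sequence space
  are empirically poor design territory, which motivates the bias.
* **No uniformity guarantee under constraints.** The biased, backtracking
  sampler does not sample the constrained sequence space uniformly; it
  trades uniformity for constraint robustness. (The unconstrained
  per-component distribution *is* uniform over the four GU-free
  assignments.)

A note on complexity: the backtracking over start/end vertices uses
forward checking — a candidate nucleotide is rejected as soon as it
empties the feasible set of a neighbouring start/end vertex — which keeps
strongly constrained, densely coupled components (common with 3–4
targets) from triggering exponential retry cascades.

## Reproduction operators

All four operators return sequences that are still compatible and
constraint-satisfying; constraint-blocked repairs degrade to no-ops on
the affected component rather than producing invalid children.

* **Point mutation** (`p_M` per position, default 0.05): loop positions
  mutate freely; paired positions apply a transition (A↔G, C↔U, repaired
  to spanning-tree depth 1, which suffices because a transition preserves
  the purine/pyrimidine classes) or a transversion (class flip, which
  forces reassignment of the whole component) with probability ½ each.
* **Negative design**: the predicted structure of the method with the
  lowest structure similarity is scanned 5′→3′ for pairs absent from all
  targets; their nucleotides are changed so the two positions can no
  longer pair. Pairs whose endpoints share a component are skipped
  (disrupting them would break a required pair). When exactly one
  endpoint is an isolated vertex, the isolated one is mutated — the
  cheapest disruption; this tie-break is a package choice where either
  endpoint would be admissible.
* **Positive design**: target pairs missing from the prediction get a G
  or C at the upstream position (by purine/pyrimidine class), repaired by
  a GC-biased transition restricted to spanning-tree depth
  `max_depth` (default 3) — deep enough to convert AU runs to GC, shallow
  enough to stay a local move. It can be disabled (`op_positive = FALSE`,
  CLI `--opPos 0`) when low-GC designs are wanted.
* **Crossover**: one-point splice at uniform p ∈ [1, N−1]; components
  straddling the cut are copied entirely from the first parent. With a
  single hairpin target this reduces to classical one-point crossover.

After every operator application (and after initialization), undesired
mononucleotide tracts (`tract_len`, off by default) and user-supplied
IUPAC motifs (`motifs`) trigger one additional point mutation inside the
detected region. Operator invocation frequencies are equal by default
(`op_weights`); the relative frequencies are a free parameter of the
method and are exposed rather than hard-coded.

## NSGA-II loop

Initialization draws `pop_size` (default 100) compatible sequences.
Each generation: evaluate all properties and objectives, assign
non-dominated ranks and crowding distances, stop if the rank-1 count has
been stable for `n_term` generations (default 50 — the stop rule needs a
value and the stagnation window should exceed the operators' typical
improvement interval; `conv = FALSE` disables early stopping) or the
generation cap (default 200) is reached; otherwise select parents by
binary crowding tournament (lower rank wins, ties to larger crowding,
full ties by fair coin) from the best `pop_size` individuals, create
`pop_size` children, truncate the old population to `pop_size` by (rank,
crowding) and append the children. Duplicates are allowed and share the
evaluation cache. Evaluation is sequential; the design contract is that
any parallel evaluation must reproduce the sequential, seed-determined
result, and same-seed runs are byte-identical (tested).

## Objectives and engines

Objectives are minimized arithmetic expressions over property references
`r(METHOD:PROPERTY)`. `multistable_problem()` builds the standard set —
f1 = Σᵢ(E(θᵢ) − G), f2 = Σᵢ<ⱼ|E(θᵢ) − E(θⱼ)|, f3 = |GC% − ρ| with
ρ = 50% by default — and `device_problem()` the two-state device set
F1–F5 (ground-state stability, prescribed state gap, mean similarity,
GC content, optional barrier).

The **toy engine** is a Nussinov-style DP over nested structures with
pair scores GC = −3, AU = −2, GU = −1, minimum hairpin loop 3 and kT = 1
for the partition function; constrained folding forces the constraint's
pairs and unpaired positions ('*' positions stay free). It is a fixed,
non-physical artifact of the package: it makes designs, tests and demos
hermetic and exhaustively verifiable (the test suite checks MFE,
partition function and constrained MFE against complete enumeration up
to length 12), but its energies say nothing about real RNAs, so passing
toy-engine benchmarks demonstrates the correctness of the *search
machinery*, not laboratory viability of a design. Its direct-path
barrier heuristic mirrors findpath: single-pair moves between the two
structures, beam of `lookahead` partial paths ranked by running saddle;
the result upper-bounds the true saddle (verified against exhaustive
move-graph search on small instances).

**External engines**: ViennaRNA is driven through its python bindings via
a shipped batch helper (`rnafold`, `rnaeval`, `findpath` adapters;
dangles default −d2; Turner 2004 or Turner 1999 parameter sets). Engines
that are not installed are reported as configuration errors *at startup*,
never mid-run; an engine failure on a particular sequence marks that
individual with worst-case objectives (10⁹) and a warning, so selection
discards it without aborting the run — the treatment of such failures is
a package choice. Other tools are reachable through the generic
command-template adapter with a user-supplied parser.

## Benchmark generation and scoring

`gen_pk_target_set()` rejection-samples random sequences and takes the
two best distinct structures from the engine's suboptimal list, accepting
a pair when the bracket Hamming distance is ≥ 10% of the length and ≥ 20%
of nucleotides are paired. The third published criterion — at least one
pseudoknot — requires a pseudoknot-capable engine; with the built-in
nested-only toy engine it is waived and flagged on the result, so
toy-engine benchmark sets emulate the *selection pressure* of the
published protocol but not its pseudoknotted structure class.
`score_designs()` reports n1 (some target is the ground state), n2
(all targets are — "completely multistable"), and the δe1/δe2 gaps of the
representative design (lowest δe2, ties by lowest δe1). `apsd()` gives
the normalized average pairwise structure distance of a target set,
`boltzmann_classification()` the customary "summed target Boltzmann
probability ≥ 0.4" classification.

Structure distance itself is the partner-array mismatch count (positions
whose pairing partner differs), which is bracket-alphabet-independent and
pseudoknot-safe; the bracket-string Hamming distance is kept as a
separate function because the benchmark selection criteria are defined on
the notation. Wildcard ('*') positions of a reference structure carry no
dependency-graph edges and are excluded from distances against it.

## Problem sizes used in the shipped tests

The acceptance suite runs hermetically on one CPU: χ-table enumeration to
path length 6; 10⁴ applications per operator on random 2–4-target
instances up to 40 nt; 200 random fronts against brute-force dominance;
10⁴ sampling draws; 200 random sequences to length 12 against exhaustive
folding; a 20-nt two-target problem (verified solvable by exhaustive
scan) solved for ≥ 9/10 seeds at population 50; and ten 30-nt toy
benchmark sets at population 30/50 generations, matching the published
small-population pseudoknot-benchmark settings. These sizes are the
package's chosen desk-scale study conditions; the published full-scale
benchmarks (50–100 sets, hundreds of nucleotides, external engines) are
reproducible with the same functions given the corresponding engines and
time.

## The device worked example and its conventions

`device_example()` returns the 95-nt theophylline-aptamer hammerhead
ON-switch sequence with the aptamer domain at nt 43–72. The ligand-bound
state is modelled, as is standard for aptamer constraints, by enforcing
the aptamer's P2 stem pairs ((50,62)…(54,58)) and keeping the
binding-core nucleotides single-stranded, all other positions free.
`device_energy_gap()` computes E(inactive) − E(active) from the
constrained and unconstrained MFE (Turner 2004, −d2);
`device_barrier()` runs findpath (look-ahead 1000) between the two MFE
structures (Turner 1999, −d2, matching the engine generation of the
published value). Two caveats follow from the available engine: the
published gap (1.0 kcal/mol) was computed with a *different*
nearest-neighbour implementation whose MFE structure for this sequence
differs from ViennaRNA 2.x's — ViennaRNA's unconstrained MFE already
sequesters part of the aptamer core, so the recomputed gap
(8.3 kcal/mol) measures the same quantity under a different energy
model; and the recomputed barrier (13.9 kcal/mol vs the published 11.9)
inherits the MFE-structure differences between ViennaRNA generations.
Both numbers are computed, not calibrated; the conventions above are
fixed in code.

## Known limitations

* Pseudoknotted *design* needs a pseudoknot-capable prediction engine;
  the built-in engine is nested-only (compatibility handling and
  structure distances are fully pseudoknot-safe).
* The constrained sampler is intentionally biased (GU-avoiding,
  backtracking) and may not reach every compatible sequence under tight
  constraints.
* Evaluation is sequential in this implementation.
* The toy engine's energies are non-physical by construction.
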