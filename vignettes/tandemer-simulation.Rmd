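---
title: "Simulating tandem mass-isotopomer distributions with tandemr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating tandem mass-isotopomer distributions with tandemr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemr)
```

## The problem

In ¹³C metabolic flux analysis, cells are fed isotopically labeled nutrients
and the labeling of intracellular metabolites is measured by mass
spectrometry.  Tandem MS (MS/MS) yields richer, positional information: after
isolating a parent ion with mass shift $M{+}i$, collision produces a product
fragment whose own mass shift $m{+}j$ is measured.  The relative abundance of
each transition $[M{+}i] > [m{+}j]$ over a *metabolite fragment pair* — a
parent atom set $N$ and a product atom set $K \subseteq N$ of one metabolite —
is the tandem mass-isotopomer ("tandemer") distribution.  Fitting fluxes to
such data requires simulating these distributions, quickly and many times,
from a candidate flux vector.

The naive route — solving for the full isotopomer distribution of every
metabolite, then marginalizing — needs $2^n$ variables per $n$-atom
metabolite and becomes intractable for metabolites with many tracked atoms.
`tandemr` instead propagates only the fragment pairs actually needed for the
requested measurements, in the spirit of elementary-metabolite-unit (EMU)
decompositions of mass-isotopomer simulation, extended to the
two-dimensional parent/product structure of MS/MS data.

## The model

For a fragment pair $A^N_K$, the tandemer distribution matrix $[A]^N_K$ has
$|N|+1$ rows and $|K|+1$ columns; entry $(i, j)$ is the probability of
observing $i$ labels in the parent fragment and $j$ in the product fragment.
A transition is *feasible* iff $i - (|N| - |K|) \le j \le i$, so exactly
$(|N| - |K| + 1)(|K| + 1)$ entries can be non-zero; `is_feasible()` and
`n_feasible()` expose this, and every matrix produced by the package zeroes
infeasible entries exactly.

At isotopic steady state the balance of each fragment pair reads

$$[A]^N_K \sum_i v_i \;=\; \sum_{i\,\in\,\text{uni}} [S(A^N_K, i)]\, v_i
\;+\; \sum_{i\,\in\,\text{bi}} [S_1(A^N_K, i)] \otimes [S_2(A^N_K, i)]\, v_i$$

where the sums run over reactions producing $A$, $v_i$ are fluxes,
$S(\cdot, i)$ is the substrate fragment pair obtained by pulling the atoms of
$N$ (and $K$) back through reaction $i$'s atom map, and $\otimes$ is the
Cauchy product (2-D convolution, `cauchy_product()`) that combines the two
substrate fragment pairs of a condensation reaction.  A condensation in
which one substrate receives no parent atoms degrades to a uni-substrate
term.

## The algorithm

1. **Closure** (`identify_mfps()`): starting from the target fragment pairs,
   pull fragments back through every producing reaction until no new pairs
   appear.  Pairs on *media* metabolites (labeling supplied externally)
   become boundary nodes; their matrices come directly from the tracer
   isotopomer distributions via `tandemer_from_isotopomers()`.
2. **Clustering** (`cluster_and_sort()`): uni-substrate links preserve both
   fragment sizes while condensation links come from strictly smaller parent
   fragments, so cycles only form among same-shape pairs.  Strongly
   connected components of the dependency graph are ordered topologically,
   non-decreasing in parent size, ties broken by the smallest canonical pair
   id — the ordering is fully deterministic.
3. **Cascade solve** (`assemble_cluster()`, `solve_cluster()`): each cluster
   yields one small linear system $A_i X_i = B_i Y_i$ whose unknown rows are
   the vectorized (feasible-entry) tandemer distributions.  The diagonal of
   $A_i$ is minus the total production flux of each unknown's metabolite,
   off-diagonals carry within-cluster uni link fluxes, and $B_i$ (negated
   fluxes) pairs with rows of $Y_i$ holding boundary/earlier-cluster
   distributions and memoized Cauchy products.

Under this sign convention `rowSums(A) == rowSums(B)` whenever the flux
vector balances, which forces every solved row to sum to one *without*
renormalization — conservation is a consequence of flux balance, and the
package treats a violation as an error rather than papering over it.

```{r toy}
toy <- toy_network()
graph <- cluster_and_sort(identify_mfps(toy$network, toy$targets))
graph
lengths(graph$clusters)
sim <- simulate_tandemers(toy$network, toy$fluxes, toy$tracers, toy$targets)
sim$results[["E^{1,2,3,4}_{2,3}"]]
```

## Numerical choices

* **Dense solves.**  Cluster matrices observed on all shipped and generated
  models are tiny (a handful of unknowns), so each system is solved by a
  dense LU factorization (`solve()`), never an explicit inverse.  The
  reciprocal condition number is estimated first; `rcond < 1e-12` raises an
  error naming the cluster's fragment pairs rather than returning garbage.
* **Clamping.**  Floating-point negatives with magnitude below `1e-12` are
  clamped to zero; anything more negative signals an inconsistent model or a
  near-singular system and is a hard error.
* **Normalization tolerances.**  Matrices must sum to 1 within `1e-9`;
  tracer/flux input files are validated at `1e-6` (measurement-scale
  tolerance for user-supplied data).
* **Zero fluxes.**  A reaction with zero flux contributes nothing; a
  metabolite whose *total* production flux is zero but whose labeling is
  needed is an error — its steady-state labeling is undefined.
* **Degenerate fragments.**  An empty product fragment is legal (the matrix
  is a column vector equal to the parent-fragment MID); an empty parent
  fragment is degenerate and dropped during closure.

## Model input conventions

Models are plain text, one reaction per line
(`v6: B (abcd) + C (ef) -> E (cdef)`), with one lowercase letter per tracked
atom, `<->` for reversible reactions (always expanded to `_f`/`_b`
irreversible pairs, since the balance equations are written over
unidirectional fluxes), `#media` declaring media metabolites explicitly
(declaring beats inferring from missing producers), and `|` separating
equally weighted alternative atom maps for rotationally symmetric
metabolites.  Reactions with more than two tracked-atom substrates are
rejected by default because the condensation algebra is defined for binary
convolutions; `split_nary = TRUE` rewrites them as a cascade of binary
condensations through auto-generated intermediates that inherit the parent
reaction's flux.  Cofactors may appear without a label string and are
ignored by the labeling math (and by the steady-state check, whose scope is
the tracked carbon skeleton).

A media metabolite's labeling is always taken from the tracer specification,
even if the network also produces it internally: "media" here means "the
labeling of this pool is known and fixed", the standard boundary condition
of steady-state labeling models.  Modeling dilution of an internal pool by
unlabeled influx is done explicitly with an uptake reaction from a media
species.

## Oracles

Because the cascade is the package's own contribution, it ships with two
independent brute-force validators
(`simulate_isotopomers_bruteforce()`):

* a **damped fixed-point** iteration over all $2^n$ isotopomer abundances
  (damping 0.5, residual is the maximum absolute balance violation,
  tolerance `1e-12`, capped at 10,000 iterations — robust on cyclic
  networks), and
* a **cumomer cascade**: exact linear solves per cumulative-isotopomer
  weight followed by Möbius inversion back to isotopomer space.

The two agree to `1e-10` on every test network, and the cluster cascade is
required to match their marginalizations to `1e-8` on over a hundred seeded
random networks.

`cumomer_report()` sizes the equivalent cumomer model.  The total is
$\sum 2^n$ over all tracked metabolites, media included (their cumomers are
variables of the classic formulation even when their values are known).  For
cluster granularity two conventions exist and the package implements both
rather than choosing silently: `convention = "weight"` (default) counts one
cluster per cumomer weight level over non-media metabolites — the unit of
work of the classic weight-ordered cascade, one flux-matrix solve per weight,
weight-0 cumomers excluded — while `convention = "scc"` gives the finest
strongly-connected-component decomposition, which is much smaller (max 4 on
the methionine fixture versus 10,197 for the weight-7 level).  Comparisons
of method cost against the fragment-pair cascade use the `"weight"`
convention, because that is the linear-algebra block size the cumomer method
actually inverts.

## The methionine fixture

The shipped methionine model
(`inst/extdata/methionine_model_synthetic.txt`) is a *synthetic
reconstruction* of a published small model of mammalian methionine
metabolism whose original spreadsheet is not redistributed here.  The carbon
bookkeeping pins it down: Met 5 (four backbone carbons + S-methyl), SAM 15
(backbone + methyl + adenine 5 + ribose 5), SAH 14 (SAM minus methyl), MTA
11 (adenine + ribose + methyl, after loss of the SAM carboxyl carbon as
CO₂ and of the propylamine group), HCys 4, with media methionine (5), ATP
(10) and the 5-methyl-THF methyl carbon (1).  These counts give
$\sum 2^n = 52{,}306$ isotopomers exactly, and with intact-metabolite parent
fragments and adenine (SAM/SAH/MTA) or non-methyl-backbone (Met/HCys)
product fragments the closure contains 35 fragment pairs with a largest
cluster of 4 — the two four-membered remethylation loops
Met → SAM → SAH → HCys → Met on the backbone carbons.  The salvage-pathway
atom map (which ribose carbons of MTA become the methionine backbone) is
fixed by chemistry only up to ordering; the reconstruction uses ribose
C1–C4 in order, which does not affect any of the counts above.

## The random-network generator

`random_network()` emulates the *structure* of small labeling models:
1–6 tracked atoms per metabolite, random injective atom maps (so tracked
atoms are conserved by construction), condensations at a configurable rate,
an enforced reversible interconversion (guaranteeing at least one cycle),
and per-metabolite media uptake and efflux reactions.  The uptake/efflux
pairs play two roles: they emulate medium exchange and pool dilution, and
they guarantee that a strictly positive steady-state flux vector exists, so
`random_fluxes()` (random positive start, alternating projection onto the
flux-balance subspace and the positivity box) always terminates.
`random_tracers()` draws Dirichlet($\alpha = 0.5$) isotopomer distributions
per media metabolite — sparse, strongly positional labeling, the hardest
case for bookkeeping errors.

What the generator does *not* emulate: natural isotope abundance,
measurement noise, multiple tracer elements, genome-scale network size, or
thermodynamically meaningful flux magnitudes.  A green property suite
therefore certifies the algebra and the bookkeeping — that the cascade
equals brute force on every atom-mapped steady-state network of this class —
not agreement with any particular biological measurement.

The default verification runs the cascade-versus-brute-force comparison on
100 seeded networks with up to 7 internal metabolites, 6 atoms per
metabolite and 12 core reactions, three random fragment-pair targets each;
these sizes keep the full isotopomer oracle exact and fast while covering
cycles, condensations, self-condensations and self-loops.

## Known limitations

* Linearity in the tracers holds only when no condensation reaction lies in
  a target's closure: Cauchy-product rows are *bilinear* in the boundary
  labeling, so mixing two tracer experiments is generally not the same as
  mixing their simulated results.  The test suite asserts both the linear
  (condensation-free) case and a counterexample.
* Single label element only (e.g. ¹³C); no natural-abundance correction —
  simulated distributions correspond to idealized, corrected measurements.
* Isotopic steady state only; no time-course (non-stationary) simulation,
  no flux fitting and no gradients — this package is the forward simulator
  such tools would embed.
* The brute-force oracles are guarded to networks with at most $2^{16}$
  total isotopomers; they are validators, not production solvers.
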