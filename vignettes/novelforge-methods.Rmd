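---
title: "Methods: novelty-first protein fold discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: novelty-first protein fold discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(novelforge)
```

# The problem and the approach

Catalogued protein structure space — the CATH hierarchy of class,
architecture, topology and homologous superfamily — covers what nature
and large-scale structure prediction have revealed, but says nothing
about how much of *physically permissible* fold space remains
unoccupied. This package implements two fitness-agnostic search engines
for that unoccupied region, together with the evaluation machinery
needed to decide whether a candidate is genuinely new:

* a **fold-recombining genetic algorithm** that evolves a population of
  sequence fragments under selection for compactness alone, and
* a **structure-first foldtuning loop** that iteratively finetunes a
  generative sequence model on its own most-compact, least-assignable
  outputs.

Both engines treat every learned model as an *adapter*: a plain function
with a documented signature (sequence likelihood, contact density,
structure prediction, inverse folding, energy scoring, structure search,
generative sampling with a finetune hook). The package ships
deterministic surrogates for all seven, so the full pipelines run at
desk scale with no downloads; production systems bind real models to the
same signatures.

# Burial fraction

The single selective force in both engines is the burial fraction

$$ B(s) \;=\; \mathrm{clamp}\!\left(1 - \frac{\mathrm{SASA}_{\text{folded}}(s)}
{\mathrm{SASA}_{\text{linear chain}}(s)},\, 0,\, 1\right), $$

the fraction of the chain's maximal (linear-chain) accessible surface
that the fold buries. It is composition-aware but conformation-
independent in its denominator, rewards globularity, and carries no
information about secondary structure or function. A candidate is
**compact** when $B > 0.5$ (strict).

Two reference scales realise the denominator:

* **All-atom structures** — the sum of per-residue theoretical maximum
  accessible areas on the extended Gly-X-Gly (Tien-style) scale, the
  standard composition-dependent reference.
* **C$\alpha$-only surrogate structures** — the per-residue accessible
  area of an ideal extended C$\alpha$ chain, which has the closed form
  $2\pi (r + p) b$ with pseudo-radius $r = 3.0$ Å, probe $p = 1.4$ Å and
  virtual bond $b = 3.8$ Å, i.e. 105.06 Å² per residue. This puts the
  extended chain at $B \approx 0$ and compact hydrophobic lattice folds
  at $B \approx 0.6$–$0.7$, giving the 0.5 threshold the same meaning it
  has for all-atom models.

SASA itself is Shrake–Rupley with a **deterministic golden-spiral point
set** (default 960 points; the pipeline functions default to 240 points,
which on 40–80-residue surrogate chains differs from the 960-point value
by well under 1% while being four times faster). Atom radii are keyed by
element (C 1.70, N 1.55, O 1.52, S 1.80 Å); hydrogens are dropped at
parse time; the probe is water at 1.4 Å.

# Structure comparison

Rigid-body superposition is the Kabsch least-squares rotation with
reflection correction. The TM-score for two equal-length chains under
the fixed residue-$i \leftrightarrow$ residue-$i$ correspondence is

$$ \mathrm{TM} = \max_{\text{superpositions}} \frac{1}{L} \sum_{i=1}^{L}
\frac{1}{1 + (d_i/d_0)^2}, \qquad
d_0 = \max\!\big(1.24\,(L-15)^{1/3} - 1.8,\; 0.5\big), $$

maximised over fragment-seeded superpositions: seed windows of length
$L, L/2, L/4, \dots, 4$ at quarter-length offsets, each refined by
iterating "superpose on the current subset, re-select residues with
$d_i$ below the cutoff" to convergence. The implementation is exact
against an independently written reference implementation on a frozen
ten-pair fixture table (maximum deviation $4\times10^{-7}$). The 0.5-Å
$d_0$ floor covers chains shorter than 21 residues.

For unequal-length comparisons (the surrogate search engine and novel-
candidate clustering) the shorter chain is slid along the longer and the
maximum fixed-alignment TM is taken, with $d_0$ from the longer length —
a deliberately conservative stand-in for an alignment-free structure
search tool. The engine exposes a window stride and a seed-density
parameter; the package-default stride of 1 is exhaustive, and toy-scale
studies use coarser strides where only the 0.5 threshold decision
matters.

# The sequence sampler

The composite energy over sequence space is

$$ E(s) = -w_1 \bar{L}(s) - w_2 C(s), $$

with $\bar{L}$ the mean per-residue log-likelihood and $C$ the contact
density (contacts per residue), both adapter-supplied and standardised
to $O(1)$ per residue; default weights are 1. Replica-exchange Metropolis
MCMC runs single-site mutation proposals (uniform position, uniform over
the 19 alternative residues) with neighbour-pair swap attempts every
`swap_interval` steps, alternating even/odd pairings, accepted with
probability $\min(1, \exp((1/T_i - 1/T_j)(E_i - E_j)))$.

**Temperature ladder.** The default ladder is geometric over
$[0.2, 2.0]$ with four replicas, and offspring refinement in the GA runs
at the cold end ($T = 0.2$). The scale was set by measuring the
surrogate energy's per-mutation $|\Delta E|$ (median $\approx 0.16$):
a ladder over $[1, 4]$ would equilibrate every replica far above the
descent regime (refinement at $T = 1$ demonstrably *raises* energy on
this landscape), while $T = 0.2$ accepts roughly half of typical uphill
moves and descends reliably. Production likelihood models with different
energy scales should re-match the ladder to their own $|\Delta E|$.

# The genetic algorithm

Full-scale defaults: an 800-fragment founder library
of 40-mers sampled by seeded REMC runs (best state per run, duplicates
regenerated), an initial population of 100 drawn at random, 200 epochs,
20 offspring per epoch, selection back to 100.

Choices the protocol sketch above leaves open, fixed here:

* **Recombination** — interior splice ($a[1..x] + b[y..L_b]$, interior
  cut points) and end-to-end fusion, mixed 50/50; fusion is what lets
  40-residue fragments grow into domain-scale products. Children are
  capped at 250 residues and floored at 10 (scorers need a minimum
  context; single-digit peptides are not meaningful domains).
* **Selection** — weighted sampling *without replacement* with weight
  $B_i + 10^{-6}$; the floor keeps zero-burial individuals selectable,
  and the two-member oracle (weights 0.8/0.2 give survival odds 4:1)
  pins the proportionality exactly.
* **Parent choice** — two parents uniformly without replacement.
* **Mutation** — independent per-position substitution at rate 0.02.
* **Refinement** — 100 Metropolis steps at the cold ladder temperature,
  over the same energy landscape the fragment library was sampled from.

Every individual can be annotated against the reference library during
the run; novel candidates (compact and unassignable) are deduplicated
incrementally in epoch order (descending burial within an epoch, ties by
id), a candidate being absorbed by the first existing representative it
matches at TM $\ge$ 0.5. This makes the cumulative novel-fold counter
non-decreasing by construction. `run_ga(annotate = FALSE)` skips
annotation entirely for compactness-trend studies where the reference
library plays no role.

# Annotation, census and rates

Assignment is strict: a candidate receives the CATH label of its best
hit only when that hit's TM-score exceeds 0.5; exact ties break by
lexicographic target id; a best hit of 0.526 is an assignment, a best
hit of exactly 0.5 is not. Novelty = compact AND unassigned. Census
percentages (e.g. superfamily growth 5,841 → 6,573 = +12.5%, topology
growth 1,349 → 2,081 = +54.3%) are computed in exact integer arithmetic
with half-even rounding to one decimal, because the inputs are integer
counts and floating-point "ties" would otherwise be representation
artifacts. Discovery rates are reported as fraction, per-million and
one-decimal percent (1018 novel over 5 × 10,000 generated = 2.0%;
732 new topologies over 214,683,839 predictions ≈ 3.41 per million).

# Structure-first foldtuning

Each round: sample `n_samples` sequences at (top_k 950, temperature
1.5) → predict structures → burial → annotate → keep the novel
survivors → rank by descending burial (ties lexicographic) → finetune
the generator on the top 100 → next round. Five rounds by default. When
fewer than 100 survive, all survivors are used and a warning is raised.
Round reports carry the population mean burial, the novel count, the
number of *unique* CATH labels among assigned samples, and the
structural hit rate (assigned fraction). The hyperparameter scan harness
computes the same five statistics per (top_k, temperature) cell from the
base (un-finetuned) model.

Round percentages are always computed exactly from the raw counts and
their true denominator; no separately quoted percentage is ever carried
alongside a count, so the two cannot drift apart.

# Inverse-folding funnels

For a template, `n = 200` re-designed sequences are drawn from the
inverse-folding adapter, preclustered at 60% sequence identity (greedy
by input order over exact-match fractions; designs are equal-length so
no alignment is needed), and each representative contributes one point:
energy per residue of its predicted structure versus TM-score to the
template. The stability filter is strict on both axes:
$\bar{E} < -2.2$ REU/aa and TM $> 0.5$.

Funnel criteria are traditionally applied by eye; this package fixes a
quantitative rule table (all constants exposed in `funnel_params()`):
Spearman $\rho$ between energy and TM; the low-energy subset at the
25th energy percentile; `trapped_fraction` = share of that subset below
TM 0.5; TM modes counted in 0.1-wide bins, a mode being a bin strictly
above both neighbours with at least 3 points. Rules in order:
`off_target_minimum` if the low-energy median TM is below 0.5;
`multi_minimum` if the subset has $\ge 2$ modes; `flat` if
$|\rho| < 0.15$ (all-equal energies are flat by convention); `funnel`
if $\rho \le -0.3$ and trapped fraction $< 0.1$; otherwise `ambiguous`.
Landscapes with fewer than 10 points are reported `insufficient`. The
rank-based metrics make the verdict invariant to point order and to
affine rescaling of the energies.

# The surrogate backends

The surrogates exist to make every contract testable and every trend
mechanically real, not to be physically realistic:

* **Structure predictor** — greedy self-avoiding chain growth on a cubic
  lattice (3.8 Å spacing, C$\alpha$ pseudo-atoms of radius 3.0 Å): each
  residue takes the free neighbour creating the most new
  hydrophobic–hydrophobic contacts (Kyte–Doolittle > 0 defines
  hydrophobic), ties rotated by a hash of the sequence *prefix* and
  position, dead ends resolved by backtracking. Hashing the prefix
  rather than the whole sequence means a mutation perturbs the fold only
  from its own position onward — the locality that makes inverse-folding
  TM degrade smoothly with mutation load.
* **Likelihood** — an order-2 Markov model (Laplace smoothing) fit to a
  bundled 200-sequence corpus drawn from a planted second-order process,
  so corpus members reliably out-score their shuffles.
* **Contact density / energy** — contact counts on the predicted lattice
  fold (pairs under 8 Å at sequence separation $\ge 3$); pseudo-energy
  $-1.0 \cdot$ (hydrophobic–hydrophobic contacts) $- 0.2 \cdot$ (all
  contacts).
* **Inverse folder** — per-position re-noising of the template sequence.
* **Generator** — an interpolated 3-mer model with top-k truncation
  (token-vocabulary top_k mapped to the 20-letter alphabet as
  $\lceil$top_k/50$\rceil$) and temperature scaling; finetuning mixes the
  current tables 50/50 with tables re-estimated from the provided set.
  The smoothing mass per table cell is small (0.02) so that a
  ~100-sequence finetuning set actually dominates its own re-estimate —
  with heavier smoothing, finetuning would flatten the model instead of
  enriching it.

The hydrophobicity → compactness link gives both engines a real gradient
to climb, so the trend tests measure genuine selection response rather
than noise. What the surrogates do **not** emulate: secondary structure
and realistic backbone geometry; robust sequence→structure maps (the
lattice predictor is chaotic downstream of a mutation, so surrogate
inverse-folding landscapes skew toward the off-target archetype —
verdicts of `funnel` on surrogate templates are rare); realistic
structure-search hit rates (a handful of synthetic reference folds means
almost nothing is assignable, where production reference libraries make
assignment the common outcome); and any biophysical energy scale.
Passing tests therefore demonstrate the correctness of the decision
machinery and the direction of the selection/enrichment responses, not
biological performance.

# Determinism and problem sizes

Every stochastic step derives its stream from one user-facing seed via a
stage-name hash fan-out (`stage_seed()`); surrogate backends are pure
functions of (input, seed). Full runs are bit-reproducible.

The test suite and the acceptance script run the pipelines at desk
scale, chosen as the smallest sizes at which the studied effects are
mechanically unambiguous: GA trend runs use a 60-fragment founder
library from short (2-replica × 25-step) REMC — deliberately lightly
optimised, so the founding population is diverse in burial and far from
selection saturation, mirroring a rising compactness curve — with
population 30, 6 offspring, 20 epochs, and 100 refinement steps;
foldtuning trend runs use 500–1,000 samples per round for five rounds
against a 4-fold synthetic reference library. The full-scale defaults
(population 100, 800 fragments, 10,000 samples per round) remain the
package defaults.

# Known limitations

* Single-chain, canonical-residue models only; mmCIF, hydrogens and
  assemblies are out of scope.
* The burial reference scale is fixed (one documented scale per atom
  representation), not user-selectable.
* The funnel rule-table constants are package decisions; the qualitative
  criteria they operationalise were stated only "by eye" in the source
  protocol.
* The surrogate search engine is a windowed fixed-alignment TM, not an
  alignment-free search; it is conservative (it can only under-report
  similarity for folds related by non-trivial alignments).
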