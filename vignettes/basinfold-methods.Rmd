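---
title: "Fragment-assembly sampling with basin-hopping search: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-assembly sampling with basin-hopping search: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The sampling problem

Fragment assembly predicts a protein's tertiary structure by repeatedly
splicing short backbone torsion fragments (here 9-mers and 3-mers) into a
growing chain and accepting or rejecting each insertion with a Metropolis
Monte Carlo criterion against a coarse, knowledge-based score. The decision
variables are the per-residue backbone torsions $(\phi, \psi, \omega)$; bond
lengths and angles are held at ideal values, and each sidechain is a single
centroid pseudoatom. A move with score change $\Delta E$ is accepted with
probability

$$P = \begin{cases}1 & \Delta E \le 0\\ \exp(-\Delta E / kT) & \Delta E > 0,\end{cases}$$

where $kT$ is a single temperature parameter in score units.

`basinfold` implements three search protocols over this representation:

* **Baseline staged protocol** (`runBaseline()`): four stages with
  per-stage move budgets of 2000; 2000; 10 substages of 4000; and
  4000 + 8000 attempts (multiplied by `increaseCycles`). Stage 1
  randomises the extended starting conformation
  ($\phi=-150^\circ, \psi=150^\circ, \omega=180^\circ$) until every residue
  has been changed once or its budget is exhausted. Stage 3 alternates two
  score weight sets across its substages and terminates a substage early
  when the structure has varied by less than `convergenceRmsd` (default
  3 Å of C$\alpha$ RMSD) over 100 accepted insertions, against a rolling
  reference. Stage 4 switches to 3-mers, and its last phase uses a
  conservative insertion operator that samples several candidate moves and
  proposes the one with the smallest lever-arm penalty. The temperature is
  quenched: constant at 2 $kT$ units, raised by 1 unit after every 150
  consecutive rejections, and reset to 2 on any acceptance.
* **Bilevel basin-hopping** (`runBasinHopping(variant = "bilevel")`):
  replaces stages 2–3 by alternating *forced perturbation* (a fragment
  insertion accepted unconditionally, restricted to non-terminal loop
  residues) and *greedy local search* (insertions restricted to
  secondary-structure element residues, kept only if they strictly lower
  the score). Successive local minima are compared with the Metropolis rule
  under a geometric simulated-annealing schedule, and an archive retains
  the 10 lowest-scoring minima seen. The run stops when a fixed budget of
  scoring-function calls is consumed; each archived structure is then
  polished by a stage 4 shortened by a factor of 10, keeping the
  per-decoy evaluation budget comparable to the baseline.
* **Iterated local search (ILS)** (`variant = "ils"`): the same engine
  with both operators free to act on any window, i.e. the unconstrained
  generalisation of the bilevel scheme.

## Scoring

Production fragment-assembly codes use proprietary stage-dependent weight
sets over statistical potentials. Those terms are not reproduced here;
`basinfold` ships a documented, simplified five-term family sufficient to
give the search a funnel on synthetic targets (`scoreTerms()`):

| term | definition | intent |
|---|---|---|
| `clash` | $\sum \max(0, d_0 - d_{ij})^2$ over C$\alpha$/centroid pairs, $|i-j|\ge2$; onset $d_0$ = 3.6 Å for C$\alpha$–C$\alpha$, 3.0 Å with a centroid | excluded volume |
| `compactness` | $(R_g - 2.2N^{0.38})^2$ | globularity |
| `contact` | $-\tfrac12\sum_i \min(\mathrm{deg}_i, 8)$ over C$\alpha$ contacts ($<8$ Å, $|i-j|\ge3$) | packing reward |
| `ss_pair` | $-$ number of contacts between predicted-strand residues | sheet pairing |
| `hbond_proxy` | $-$ number of predicted-helix residues with helical $(\phi,\psi)$ | helix formation |

The contact degree is saturated at 8 neighbours per residue and the
C$\alpha$ clash onset sits at the non-bonded backbone spacing (3.6 Å);
without both, over-collapsed globules outscore native-like packing and
fragment quality stops mattering. Even so, the toy score remains degenerate
between alternative packings of the same elements — the native is
*near*-optimal, not the unique global minimum, which is the main reason
best-archive RMSDs on toy targets plateau around a few Ångström rather
than converging to zero.

Weight sets `score0`–`score5` combine these terms per stage (stage 1:
clash-only; stage 2: weak guidance; stage 3: two alternating sets; stage 4
and final reporting: the full set). All weights are non-negative, lower
scores are better, and sets can be overridden from a YAML file
(`readWeightSets()`). Every scoring call increments an evaluation ledger,
because all protocol budgets are counted in scoring calls.

## Geometry

Coordinates are built from torsions with the standard internal-coordinate
(NeRF) construction using fixed ideal geometry (N–C$\alpha$ 1.458 Å,
C$\alpha$–C 1.525 Å, C–N 1.329 Å; angles 111.2°, 116.2°, 121.7°), which
implies a trans C$\alpha$–C$\alpha$ virtual bond of
`idealCaCaDistance()` ≈ 3.804 Å. The centroid pseudoatom sits 2.5 Å from
C$\alpha$ along the local pseudo-C$\beta$ direction (at C$\alpha$ for
glycine); it only needs to be a coarse sidechain proxy for the clash term.
The torsion→Cartesian→torsion round trip is exact to numerical precision
(tested to 1e-6). Contact maps use C$\alpha$ distance < 8 Å at sequence
separation ≥ 3 by default; neither value is canonical and both are exposed
as parameters.

The lever-arm penalty used by the conservative stage-4 operator
(`gunnPenalty()`) is the unsuperposed C$\alpha$ RMSD of all residues
outside the insertion window after rebuilding both chains in the canonical
frame (which holds the pre-window segment fixed). The exact historical
cost function for this purpose is defined in terms of a six-number rigid
body representation that is not reproduced here; the package's penalty is
a transparent proxy with the same monotone intent (zero iff the insertion
leaves the rest of the chain unmoved), and the conservative operator
(`gunnBiasedMove()`) proposes the minimum-penalty candidate among 10
uniform draws.

## Basin-hopping design choices

Several components of the basin-hopping engine are open design points; the
package's choices are:

* **Move partition (bilevel).** Roles derive deterministically from the
  secondary-structure string: H/E residues are *elements*, maximal L-runs
  touching a terminus are *terminal loops* (never altered by either
  operator), remaining L residues are *loops*. A perturbation window is
  any 9-mer window containing at least one non-terminal loop residue, and
  only those loop residues are overwritten; a local-search insertion
  overwrites only element residues in its window. This realises the
  loop/element split with full 9-mer windows still usable.
* **Annealing schedule.** Geometric cooling from $T_{start}=2.5$ to
  $T_{end}=0.5$ over the expected number of local-minimum comparisons
  (budget divided by the local-search cost); all three values are
  config-exposed. Geometric cooling gives the stated behaviour of
  disruptive transitions early and conservative ones late with a single
  smooth law.
* **Local search.** Greedy strict-improvement with a per-iteration budget
  of 50 proposals or 20 consecutive failures (config-exposed); the inner
  loop also truncates exactly at the global scoring budget so that runs
  are budget-comparable to the baseline.
* **Archive.** Capacity 10; ties broken in favour of the earlier
  candidate, making runs reproducible. Stage-4 polishing replaces each
  archived structure one-to-one and the archive is re-sorted by polished
  score; polishing never evicts a member in favour of a structure that was
  not archived.
* **Scoring during basin-hopping.** A single full weight set (`score3`)
  scores perturbation/local-search states. Stage 3's alternation exists to
  decorrelate successive substages of one long Metropolis chain; the
  basin-hopping segment restarts its search state at every perturbation,
  so one consistent set keeps local-minimum scores comparable across the
  run (config-exposed via `basinHoppingConfig(scoreSet =)`).

## Exploration analytics

* **Local measures** (`localProfile()`): per-residue accepted-change
  counts per stage, and the per-residue fraction of the unique torsion
  triplets available in the 9-mer library that were sampled at least once.
  All accepted moves count, including perturbation and hill-climbing moves
  later discarded by the local-minimum comparison — transient acceptance
  is still useful exploration.
* **Global measures**: structures are sampled every 100th accepted move
  (baseline) or from local minima only (basin-hopping; perturbed
  non-minimum states would overstate exploration). Pairwise Hamming
  distances between binary contact maps feed classical MDS
  (`classicalMDS()`, double-centering + eigendecomposition, $k=2$) for
  visualisation, and PAM clustering (`pamCluster()`, BUILD + SWAP, ties to
  the lowest index, 20 clusters) for the entropy measure.
* **Entropy** (`entropyMeasure()`): each run's path through the clusters
  is a Markov chain; the package reports the occupancy-weighted transition
  entropy $-\sum_i \pi_i \sum_j p_{ij}\log p_{ij} / \log K \in [0,1]$.
  The original formulation is cited but not printed in full in the
  literature this package follows; a plain occupancy entropy is provided
  as an alternative (`mode = "occupancy"`) and neither is claimed to be
  the historical definition.
* **Mack–Skillings test** (`mackSkillings()`): the replicated two-way
  rank statistic (within-block ranks, summed cell mean ranks, quadratic
  form against the null covariance, $\chi^2_{k-1}$), reducing to Friedman
  for one replicate. The conservative post-hoc compares pairwise
  $|S_i - S_j|$ to a critical value calibrated by Monte-Carlo permutation
  within blocks of the *maximum* pairwise difference (50,000 iterations at
  $\alpha = 0.05$ by default). No installed R package provides this test,
  so it is implemented here and checked against Friedman reduction and
  exact permutation enumeration.
* **RMSD densities** (`rmsdKDE()`): Gaussian KDE at a fixed bandwidth of
  0.7 Å on a 512-point grid spanning the data ± 4 bandwidths.

## Model selection

`clusterDecoys()` is a Calibur-style greedy largest-first clustering under
pairwise C$\alpha$ RMSD: the decoy with the most unassigned neighbours
within the threshold becomes the next centre and claims them exclusively.
The prefilter uses two *exact* lower bounds (radius-of-gyration difference
and a triangle-inequality bound anchored at a reference decoy) to skip
superpositions that cannot fall under the threshold, so results are
bit-identical with the prefilter on or off. `autoThreshold()` stands in
for Calibur's automatic threshold rule, which is not described in the
source this package follows: it scans percentiles of sampled pairwise
RMSDs for the smallest threshold at which the most-neighboured decoy
covers a tenth of the set. `selectModels()` reports the top-1 and top-3
cluster centres, with RMSDs to a native structure when given.

## Synthetic data

`makeToyTarget()` builds toy folds (helix bundles, meander sheets, mixed
α/β) with a known native: element torsions at canonical helix/strand
values, 4-residue turns from numerically calibrated templates, and
per-seed jitter. When the templates alone do not reach the target's
invariants (no C$\alpha$ pair under 3 Å; $R_g \le 1.3 \cdot 2.2N^{0.38}$),
the generator polishes turn torsions loop-by-loop with Nelder–Mead under a
compactness + clash objective — still deterministic given the seed. Sheet
layouts cap strand length around seven residues because long two-strand
hairpins are geometrically incompatible with the compactness invariant.

`makeLibrary()` emulates a fragment-picker output: per-window ranked
lists (depth 25 for 9-mers, 200 for 3-mers in standard use) where each
window contains the exact native fragment with probability equal to the
enrichment parameter and decoy fragments drawn from three Ramachandran
basins (α, β, polyproline-II-like) with secondary-structure-conditional
weights. `makeSsPrediction()` degrades the true secondary structure to a
chosen Q3 accuracy. What this substrate does *not* emulate: real fragment
libraries' sequence-dependent ranking, correlated errors in secondary
structure prediction, non-ideal bond geometry, and real energy functions —
so passing tests demonstrate correct search mechanics and analytics, not
predictive accuracy on real proteins.

## Problem sizes and numerical conventions

The test-suite and the acceptance script run desk-scale configurations
chosen to exercise every control path in seconds: 12–30-residue targets,
`increaseCycles` 0.005–0.5 (budgets are floored with a minimum of one
attempt so fractional multipliers are usable), basin-hopping budgets of a
few thousand scoring calls, and 4–10 runs per condition. Angles are
degrees in $(-180, 180]$ (wrapped with `wrapAngle()`; 180 and −180 are
identified), residues and windows are 1-based, insertion windows are
closed intervals, and a single R RNG stream seeded once per run drives
all stochastic choices in documented order (window, fragment, then the
acceptance uniform), making every run bit-reproducible from its seed.
Score ties never occur in exact arithmetic but archive ties are resolved
first-seen-wins; PAM and clustering ties resolve to the lowest index.

## Known limitations

* The score family is a stand-in: absolute score values are not
  comparable to any production package, only the protocol mechanics are.
* The lever-arm penalty is a proxy, not the historical six-number cost.
* `omega` is effectively trans throughout (fragments may supply other
  values, but the fixtures never do, and there is no cis-proline
  handling).
* The bilevel protocol requires at least one non-terminal loop residue;
  all-helix or all-sheet targets without internal loops are a protocol
  error by design.
* Large toy targets (over ~100 residues) can take tens of seconds to
  generate when the turn polish engages.
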