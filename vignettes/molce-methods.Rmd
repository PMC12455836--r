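---
title: "Contrastive explanations for molecular classifiers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive explanations for molecular classifiers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the approach

Feature-attribution explanations of molecular classifiers assign weights
to fingerprint bits, which chemists cannot act on directly. `molce`
instead asks a contrastive question: given a compound predicted into
class `y*` (the *fact*), which chemically small modifications move the
model's probability mass towards an alternative class `y'` (the *foil*)?
It answers by enumerating virtual analogues of the test compound and
scoring each with the normalized probability shift

$$\delta = \frac{p_{y^*}}{p_{y^*}+p_{y'}} - \frac{q_{y^*}}{q_{y^*}+q_{y'}}$$

where $p$ and $q$ are the model's class-probability vectors for the
original compound and the analogue. $\delta$ lives in $[-1, 1]$: $+1$ is
a complete shift of the relative probability towards the foil class, $0$
no shift, negative values reinforce the fact class. Because only the two
designated classes enter, $\delta$ is invariant to a common rescaling of
the pair (the ratio normalizes), and swapping the roles of $p$ and $q$
flips its sign. Degenerate inputs with $p_{y^*}+p_{y'}=0$ (or the same
for $q$) raise an error rather than returning 0 — silent zeros would
bias every downstream average.

Analogues come from two generators:

* **Substituent foils.** The compound is decomposed into its
  Bemis–Murcko scaffold (ring systems plus linkers; exocyclic atoms
  multiply bonded to a scaffold atom, such as amide carbonyl oxygens, are
  retained) and its substituents. One substituent at a time is replaced
  by each fragment from the pool of all unique substituents observed in
  the reference data set; all other substituents and the scaffold stay
  fixed. A compound with a single substitution site has its lone
  substituent replaced — the "preserve one, replace the others" recipe is
  vacuous at one site, and single-site compounds would otherwise receive
  no substituent foils at all.
* **Scaffold foils.** The scaffold is replaced by an alternative scaffold
  that shares its *reduced carbon skeleton* — the scaffold with every
  heteroatom turned into carbon, every bond order set to one, and every
  acyclic atom with exactly two bonded neighbours contracted away,
  iterated to a fixed point. A reduced skeleton therefore stands for a
  family of scaffolds varying in heteroatoms and linker lengths. The
  skeleton-to-scaffolds dictionary is built once from a reference
  compound collection; at query time candidates are restricted to
  scaffolds whose heavy-atom count differs from the original's by at most
  a fraction `size_tolerance` (default 0.15, i.e. an 85 % size cut-off,
  real-valued, hydrogens excluded), and the query scaffold itself is
  excluded — a self-swap is a null perturbation.

Global explanations average $\delta$ per replacement fragment over many
compounds; substituent averages are restricted to foils of single-site
parents so a fragment's mean is not confounded by which other substituent
was retained. Scaffold averages use all scaffold foils; we see no reason
to restrict them, since the whole substituent set is carried over
unchanged. Counts per fragment are reported so that low-support means can
be filtered by the user.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `size_tolerance` | 0.15 | maximal relative atom-count deviation of alternative scaffolds |
| `selective_fold` | 100 | potency fold-difference at or above which a compound is selective |
| `nonselective_fold` | 10 | fold-difference at or below which it is non-selective |
| `activity_cutoff_nm` | 10000 | potency ceiling (nM); both targets must be at least this potent |
| `max_ratio` (replicates) | 10 | largest tolerated max/min replicate ratio (one log unit); averaged below, discarded above |
| `n_bits` | 2048 | folded fingerprint length (ECFP, bond diameter 4) |
| `grid` | leaf size 1/2/5/10 × trees 25/50/100/200/400 | balanced-forest hyperparameter grid, selected by macro F1 on an inner 70/30 stratified validation split |
| `test_fraction` | 0.3 | test share per stratified trial; `n_trials` defaults to 10 |

Thresholds are inclusive ("at least 100-fold", "at most tenfold"); folds
strictly between 10 and 100 are a gray zone and excluded. The 10 µM
requirement is read as a ceiling (potency value ≤ 10,000 nM), consistent
with data sets spanning the low-micromolar to low-nanomolar range. When a
compound–target pair carries several measurement types they are never
merged; Ki is preferred over IC50 over Kd.

## Chemistry backend and numerical choices

Molecules are handled as plain graphs (element vector + bond list,
implicit hydrogens, kekulized aromatic rings) parsed and canonicalized
through OpenBabel (ChemmineR/ChemmineOB). All identity comparisons —
deduplication of foils, dictionary keys, pool membership — are on
OpenBabel canonical SMILES; the canonicalization algorithm is recorded in
the dictionary file header because keys are only portable across tools
that agree on it.

Attachment sites are expressed as atom indices in the canonical scaffold
SMILES. The extracted scaffold subgraph is mapped onto the re-parse of
its canonical form by colored VF2 isomorphism (elements as vertex colors,
bond orders as edge colors). When OpenBabel re-kekulizes an aromatic ring
differently the exact match can fail; the match is then retried with
ring-bond orders coarsened — within an aromatic system alternative kekulé
assignments are resonance-equivalent — and among the resulting mappings
the one preserving the most bond orders is taken, so bonds with fixed
orders are never mismapped. Any residual ambiguity corresponds exactly to
a scaffold automorphism, under which attachment sites are chemically
equivalent; reattaching every extracted substituent at its recorded site
reproduces a graph isomorphic to the parent (this invariant is tested
across the whole synthetic library).

Assembled foils are vetted against a standard maximum-valence table
(C 4, N 3, O 2, S 6, P 5, halogens 1); assemblies that exceed an atom's
capacity, or that OpenBabel cannot sanitize, are dropped and counted.
Every emitted foil parses, is canonical, and differs from its parent.

Scaffold-foil attachment sites on the alternative scaffold are assigned
deterministically: substituents are placed, in order, on the
lowest-canonical-rank atoms with free valence, preferring unused atoms.
We considered guiding the assignment by a maximum common substructure
between the original and the alternative scaffold, which would preserve
more of the local substitution context, but chose the rank-based rule: it
is simple, needs no MCS machinery, is guaranteed deterministic, and for
the size-filtered, topologically equivalent scaffolds the dictionary
returns the difference matters little because the whole substituent
multiset is preserved either way. The known cost is a positional bias
(e.g. two substituents land on adjacent ring positions); it is uniform
across all alternatives of a compound, so within-compound rankings are
unaffected.

Linker contraction applies only to acyclic atoms — removing ring atoms of
degree 2 would destroy the rings the skeleton is meant to preserve — and
iterates to a fixed point, which makes the result independent of removal
order and the operation idempotent. Degree-1 (terminal branch) atoms
never match the rule. If the two neighbours of a removed atom are already
bonded, no duplicate bond is added.

Other deterministic tie-breaks: the fact class is the model's argmax with
ties broken by class-name order; foil rankings break $\delta$ ties by the
canonical fragment string; duplicated foil structures keep the first
occurrence of the fixed enumeration order (sites in order, pool sorted).

## The modeling harness

Compounds are represented by OpenBabel's extended-connectivity
fingerprint with bond diameter 4, natively 4096 bits, folded to `n_bits`
by OR-ing halves. Class imbalance — selectivity data sets have many more
non-selective than selective compounds — is handled by a balanced random
forest: each tree's bootstrap draws the minority-class size from *every*
class (stratified `sampsize` in randomForest). Probabilities are
tree-vote fractions; this contract is what the applicability-domain
confidence measure (maximal class probability) relies on. The forest
backend exposes the minimal samples per leaf (`nodesize`) and the tree
count; a separately tunable minimum-split parameter is not available, so
the selection grid has those two dimensions.

Performance is reported as balanced accuracy (macro mean of per-class
recall, reducing to ½(TPR+TNR) for two classes), macro-averaged
precision, recall and F1 (per-class one-vs-rest values, arithmetic mean;
a never-predicted class contributes precision 0 and is logged), and MCC
(textbook binary formula for 2×2 matrices, the standard multi-category
generalization otherwise; a zero denominator yields 0 with a warning).

## What the synthetic fixtures emulate — and what they do not

`fixture_spec()` defines a combinatorial library of 8 scaffolds × 12
substituent fragments, assembled exhaustively (every scaffold with every
single fragment and every ordered fragment pair at two sites),
deduplicated, and sampled to `n_compounds` (default 300, seed 0). Mono-
and di-substituted compounds are drawn in roughly equal numbers, as in an
analogue-series library; left to itself the two-substituent stratum would
dominate 12:1 and starve the single-site substituent aggregation. The
scaffold library is chosen so that scaffolds share reduced skeletons in
groups (benzene/pyridine/pyrimidine/piperidine; naphthalene/quinoline;
two linked-ring systems), making scaffold foils non-trivial. A planted
motif (trifluoromethyl, carried by one fragment) determines class: 80 %
of carriers fall into the motif class, non-carriers follow the class
balance (defaults: three classes, one third each — two "selective"
classes and one "non-selective", mirroring pairwise selectivity studies).

The closed-form toy classifier outputs
$P(\text{motif class}) = \text{logit}^{-1}(a \cdot \text{matches} + b)$
with $a = 2$, $b = -1$, the remainder split equally. Every scored foil
can therefore be checked against a hand-computed value, and the planted
fragment must rank first by mean contrastive behavior — which it does,
both under the toy oracle and under a forest trained on the true labels.
As a negative control, labels are shuffled and a small forest (50 trees,
leaf size 5, 1024 bits) retrained: the planted fragment then neither
ranks first nor exceeds a mean-shift magnitude of 0.2, the bound we fixed
before running the control. The applicability check compares the maximal
Tanimoto similarity to training compounds between test instances and
foils and requires the median shift to stay below 0.2, likewise fixed in
advance. End-to-end checks use the seed-0 library (300 compounds), 15
motif-free test compounds and their few hundred foils; property checks on
the reduction transform use a 50-scaffold suite of ring pairs with
variable linkers and heteroatom substitutions.

What passing these tests shows: the decomposition/assembly algebra is
exact, the score implements its formula, the pipeline recovers a class-
determining fragment that the model actually uses, and it stops
reporting one when there is nothing to learn. What they do not show:
behaviour on real pharmacology. The fixtures contain no activity cliffs,
no correlated substituent effects, no stereochemistry, no charged or
tautomeric species, and a chemical space that is tiny and fully
enumerable; real selectivity data will produce noisier probability
estimates, and contrastive shifts there inherit all caveats of the
underlying model's calibration.

## Known limitations

* Stereochemistry, formal charges and isotopes are dropped at
  decomposition time; the fingerprints are 2D and the fragment identity
  deliberately ignores them.
* Canonical SMILES identity is backend-defined; dictionaries must be
  built and queried with the same canonicalization (the file header
  records it).
* Scaffold-foil site assignment is rank-based, not context-preserving
  (see above); per-site explanations should not be read into scaffold
  foils.
* VF2-based canonical mapping enumerates isomorphisms and is exponential
  for pathologically symmetric scaffolds; typical drug-like scaffolds are
  far from that regime.
* Multi-class analyses compute $\delta$ for one designated foil class per
  run; looping over all non-fact classes is a convenience left to the
  caller.
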