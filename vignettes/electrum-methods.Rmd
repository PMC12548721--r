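---
title: "Methods: fingerprinting mononuclear metal complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprinting mononuclear metal complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electrum)
```

## The representation problem

Transition-metal complexes resist the molecular fingerprints that work so
well for organic molecules: their bonding violates covalent valence rules,
their coordination numbers and geometries vary widely, and most toolkit
sanitizers simply reject their SMILES. This package encodes a mononuclear
complex from nothing more than the SMILES of its ligands and the identity
of its central metal, producing a fixed-length integer vector suitable for
similarity search and standard machine-learning models.

The encoding has two blocks:

1. **Ligand block (default 512 entries).** Every ligand is processed with a
   circular-substructure (Morgan-type) scheme: each heavy atom receives an
   integer identifier at radius 0 hashed from its invariants (element,
   degree, formal charge, attached hydrogens, ring membership,
   aromaticity), and identifiers at radii 1 and 2 are produced by hashing
   the sorted multiset of (bond type, neighbor identifier) pairs, so the
   result never depends on atom input order. An identifier is emitted at a
   radius only while the environment still grows, i.e. while some atom sits
   at exactly that bond distance. Identifiers are folded modulo the block
   length into a *count* vector, and the ligand vectors of a complex are
   summed elementwise. Retaining counts rather than bits makes the sum
   exactly additive: a complex with k copies of a ligand holds k times that
   ligand's folded vector, and the sum is invariant to ligand order.
2. **Metal block (86 entries).** The neutral ground-state electron
   configuration of the metal, one bit per electron slot over the fifteen
   subshells 1s–6p in Madelung filling order (2+2+6+2+6+2+10+6+2+10+6+2+14+10+6
   = 86 slots, the electron count of radon). Each subshell's block is
   filled unarily with the tabulated occupancy, aufbau exceptions included
   (Cr, Cu, Nb, Mo, Ru, Rh, Pd, Ag, La, Ce, Gd, Pt, Au, ...), so for every
   element up to Z = 86 the popcount equals the atomic number and no two
   elements share an encoding.

At the defaults this gives 512 + 86 = 598 features. Two baselines used as
controls share the ligand block: *ligands-only* drops the metal entirely,
and *atomic* replaces the 86-bit block by the raw atomic number as a single
trailing feature.

```{r widths}
fp <- electrum_fingerprint("N.N.Cl.Cl.[Pt]")
fp
c(length(fp$ligand_part), length(fp$metal_part), length(fp$combined))
```

### Design choices in the encoding

Several aspects were genuinely open and were fixed as follows.

* **Bit layout of the metal block.** One slot per electron through the 6p
  subshell is the only unary layout whose width is exactly 86; occupancies
  fill each subshell block from its first slot.
* **Neutral atom, not ion.** Charge annotations on the metal token
  (`[Ru+2]`) are parsed and ignored for encoding. Encoding the ion would
  leak the oxidation state into the features of exactly the task where the
  oxidation state is the learning target.
* **Elements beyond the window.** Pa (Z = 91) appears in the supported
  metal list; its 7s/5f/6d electrons fall outside the window and are
  dropped with a warning, keeping the width fixed.
* **Counts, not bits.** "Cumulative presence of substructures" only holds
  exactly if multiplicity is retained; binarizing before summation would
  make duplicate ligands partially invisible.
* **Pinned hash.** The identifier hash (a 31-bit polynomial over the
  invariant tuples) is fixed and versioned (`electrum_hash_version()`);
  fingerprints are comparable only within one hash version. No
  bit-compatibility with any external toolkit is claimed.
* **Stereochemistry is ignored.** Stereo descriptors are parsed and
  discarded, so cis- and trans-diamminedichloroplatinum share one
  fingerprint. This is a known representational limit, asserted by a
  regression test rather than hidden.
* **Default metal set.** The 50 metals spanned by the two benchmark
  curations (48 coordination-number metals plus Pd and Ag from the
  oxidation-state subset).

## Sanitization-free parsing and decomposition

The package carries its own small SMILES parser and writer. The reason is
not novelty: standard toolkits re-perceive valence and aromaticity on
import, which either rejects or silently "repairs" organometallic species,
and the curation algorithm below requires graph surgery whose result must
re-serialize without any such repair. The parser derives implicit
hydrogens for organic-subset atoms from default valences only (choosing
the smallest allowed valence that covers the bond sum), keeps bracket
atoms' declared hydrogen counts and charges verbatim, and never corrects
anything.

Full complex SMILES are curated in four steps: disconnected fragments
without the metal are dropped as counterions (logged, never silently);
exactly one metal-set atom must remain or the record is rejected (zero →
missing metal, two or more → multinuclear, out of scope); the metal is
deleted from the graph and each remaining connected component becomes one
ligand SMILES; the coordination number is the metal's edge count in the
parsed graph, so an η⁴-bound or chelating ligand contributes one per bond,
and the bond-order labels of the deleted edges are recorded per ligand
(stored, but never consumed by the fingerprint). Ligand atoms keep the
charges the input declared. Atoms that entered as bare organic-subset
symbols are re-emitted bare, so a formerly metal-bound amine nitrogen
re-perceives its full hydrogen complement when the ligand is read
standalone — matching how ligand strings extracted from crystallographic
SMILES are conventionally written.

```{r decompose}
rec <- decompose_complex("[Co]%10%11(NCCN%10)(NCCN%11)(Cl)Cl.[Na+]")
rec
complex_to_component_string(rec)
```

Class-support filtering (`filter_by_class_support()`, default threshold
1000) reproduces the dataset rule of keeping only label classes populous
enough to stratify into folds.

## Neighbor search

Chemical-space maps are built from the k-nearest-neighbor graph of the
fingerprints under the Manhattan (L1) distance, which respects the count
semantics. The search is exact brute force with row blocking — at the
scales this package targets, exactness costs little and allows the entire
graph to be validated against an independent all-pairs computation. Ties
at equal distance resolve toward the lower index, making the graph
deterministic. The default k of 20 is a conventional choice (the upstream
layout tools do not fix one); the edge list exports as plain delimited
text for external layout software. Tree layout and interactive rendering
are deliberately out of scope.

## The evaluation harness

The benchmark model is a multilayer perceptron with hidden layers
512/256/128/64/32 (ReLU), softmax or identity head, Adam optimization,
minibatches of 200, L2 penalty 1e-4, learning rate 1e-3, at most 200
epochs with tolerance-based stopping (1e-4 over 10 stagnant epochs) —
the stock defaults of the common reference implementation of this model
family, pinned here so that "no hyperparameter tuning" stays reproducible.
No R package on hand provides a multi-hidden-layer perceptron, so the
network is implemented directly in base matrix operations.

Classification uses stratified 5-fold cross-validation (stratification is
a deliberate choice: the real datasets are severely imbalanced, and
unstratified folds risk empty classes); regression uses 3-fold. Metrics
are macro-averaged: one-vs-rest AUROC (rank statistic), one-vs-rest
average precision computed step-wise without interpolation, and unweighted
per-class precision/recall/F1, plus accuracy; regression reports R². The
scrambled-label control permutes labels once at dataset level (not per
fold) with the run's seed before folding — a model that beats its
scrambled companion by more than fold noise has learned something real.
All randomness in a run flows from the single configuration seed, so
identical configurations reproduce identical per-fold metrics.

Feature scaling is off by default (the benchmarks feed raw counts); an
optional standardization flag exists for the atomic baseline whose
trailing feature lives on a different scale.

## The synthetic generator

Real curated datasets derive from a licensed structural database and are
not redistributable here, so the package ships a generator that emulates
their schema: it samples a metal and a target coordination number (2–6 by
default), draws ligands from a pool of about twenty small real ligands
spanning denticities 1–3 (halides, aqua, ammine, carbonyl, cyanide,
pyridine, phosphines, plus ethylenediamine-, acetylacetonate- and
bipyridine-type chelates and a tridentate triamine) until the denticities
sum to the target, and emits both the component string and a bonded
complex SMILES in which secondary donor atoms attach through ring-closure
bonds. The coordination number of the emitted structure therefore equals
the denticity sum *by construction*, which is what makes the decomposition
pipeline testable end to end. Counterion fragments are appended with
probability 0.3 to exercise stripping.

Label injection provides controllable signal: `metal_dependent` labels are
atomic-number quantile bins — a deterministic function of the metal alone
that varies smoothly with the electron-configuration encoding, so
metal-aware features can learn it while metal-blind features face pure
chance; `ligand_dependent` bins the total heavy-atom count and ignores the
metal; `none` is random. At the evaluation scale used throughout (500
complexes, 5 folds) the expected pattern is full-encoding AUROC near 1,
ligands-only and all scrambled controls near 0.5, and the atomic baseline
in between (its scalar is informative but less separable than the binary
block).

What the generator does **not** emulate: the long-tailed metal and
coordination-number imbalance of crystallographic data, realistic
co-occurrence of metals with their preferred ligands and geometries, 3-D
geometry, and chemical plausibility of every sampled combination. Passing
tests on synthetic data therefore demonstrate the *mechanics* — encoding
widths, invariants, decomposition correctness, harness behavior — not
predictive performance on real complexes, which depends on the external
curated datasets.

## Numerical and degenerate-input conventions

* Identifier hashes live in [0, 2^31 − 1]; all arithmetic is exact in
  doubles.
* Folding an empty identifier list yields the zero vector, but an empty or
  unparseable ligand SMILES is an error — silent zero vectors would mask
  upstream parsing bugs.
* k-NN with k ≥ n − 1 returns the complete digraph; k < 1 errors.
* A class absent from true labels is excluded from macro averages with a
  message; a class too small to stratify aborts with a pointer to
  `filter_by_class_support()`.
* Constant regression targets error (R² undefined).
* Problem sizes in the shipped checks (500 generated complexes for the
  decomposition and harness runs, 200 points for the neighbor-search
  oracle, 200 permutation trials) were chosen as the smallest sizes at
  which the stochastic checks are stable.

## Known limitations

Stereoisomers collapse (by design, for now); multinuclear complexes and
metalloligands are rejected rather than approximated; hapticity is
represented only through edge counts, not bonding mode; the parser covers
the SMILES dialect of the supported workflows (organic subset, brackets,
rings including `%nn`, dots, stereo-tolerant) rather than the full
grammar; and elements beyond Z = 96 are unsupported.
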