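---
title: "Graph-based molecular signatures for herbicide discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based molecular signatures for herbicide discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbsig)
```

## The modelling problem

Herbicide discovery needs the same early triage that drug discovery has
had for decades: given a small molecule, estimate whether it is likely to
be herbicidally active, and whether it is likely to be toxic to humans or
to non-target species (honey bee, mallard, minnow), before anything is
synthesised.  `herbsig` implements a complete desk-scale pipeline for
this task: molecules come in as SMILES, are represented as graph-based
signatures, and feed random-forest classifiers (binary activity,
mutagenicity) or regressors (LC50/LD50-style continuous endpoints), plus
two knowledge-based tools — herbicide-likeness property windows and
enriched-substructure mining between active and inactive classes.

## The molecular representation

A molecule is modelled as an unweighted, undirected graph: nodes are
heavy atoms (hydrogens are collapsed onto their heavy atom as a count),
edges are covalent bonds.  Aromatic perception and canonicalization are
delegated to OpenBabel; the package's own SMILES reader then builds the
graph from the canonical aromatic rendering, which guarantees that any
two renderings of the same molecule produce the same graph and hence the
same features.  Formal charges are kept; stereochemistry is parsed but
ignored throughout.  Salts and mixtures are reduced to their largest
component before featurization so that all atom pairs have finite graph
distances; compounds above 2 kDa trigger a warning, reflecting the
intended applicability domain of small agrochemical-like molecules.

### Pharmacophore typing

Each atom receives one or more labels from a fixed, ordered 7-label
vocabulary: Hydrophobic, Aromatic, Donor, Acceptor, PosIonizable,
NegIonizable, Neutral.  The default rules are deliberately simple,
standard pharmacophore families:

* Aromatic — aromatic-perceived atoms;
* Donor — N/O carrying at least one hydrogen;
* Acceptor — N/O with formal charge at most 0;
* Hydrophobic — C, S or halogen not bonded to a charged atom;
* PosIonizable — positive formal charge, or an aliphatic amine nitrogen;
* NegIonizable — negative formal charge, or the acidic oxygen of a
  carboxylic/sulfonic/phosphonic acid group;
* Neutral — assigned only when nothing else matches.

The rule table is a plain-text configuration (builtin attribute
predicates prefixed `@`, or substructure patterns with optional atom
selectors), because the literature behind pharmacophore-based signature
methods rarely pins down the exact label definitions; the default table
is a documented, replaceable choice, not a claim of equivalence with any
specific published implementation.  Labels are the union over all
matching rules, so rule order never matters.

### The cutoff scanning matrix

All-pairs shortest-path distances (in bond steps) are computed by
breadth-first search.  For every unordered label pair $(a,b)$ — 28 pairs
over 7 labels — and every cutoff $c$ in a grid (default 1–10 bond steps,
step 1), the signature records the number of unordered atom pairs
$(i,j)$ with $d(i,j) \le c$ that realise the label pair.  Each atom pair
contributes once per distinct unordered label pair it realises;
unreachable pairs contribute nothing.  Rows are cumulative distributions,
hence non-decreasing in the cutoff — an invariant asserted by the test
suite on every featurized molecule.

Design notes:

* **Cutoff grid 1–10.**  Ten bond steps cover the diameter of most
  molecules under 500 Da; the grid is configurable.
* **Raw counts, not normalised.**  Cumulative counts grow with molecule
  size, and size itself is predictive of herbicidal activity (see the
  likeness windows below), so the default preserves it.  A
  `normalise` switch divides by heavy-atom count.
* **Multi-label atoms** contribute to every label pair they realise, once
  per unordered pair, avoiding double counting of $(a,b)$ versus $(b,a)$.

The pair block is concatenated with a 10-descriptor physicochemical
block: molecular weight, logP, H-bond acceptor and donor counts,
rotatable bonds, ring count, aromatic ring count, heavy atom count, TPSA
and the fraction of sp3 carbons.  Counts are computed on the heavy-atom
graph (HBA = N/O with charge ≤ 0; HBD = N/O with ≥ 1 H; rotatable = a
single, acyclic, non-aromatic bond between two non-terminal atoms — the
classic definition without the amide exclusion); logP and TPSA come from
OpenBabel; molecular weight from a standard atomic-mass table.  The
default feature vector is therefore 28 × 10 + 10 = 290 columns with a
stable layout.

## Herbicide-likeness windows

Two property windows summarise where known herbicidally active compounds
live: a 90% tier (MW < 517 Da, ≤ 9 acceptors, ≤ 4 donors, < 9 rotatable
bonds, logP in [−1.7, 6.1]) and a 95% tier (MW < 700 Da, ≤ 11 acceptors,
≤ 6 donors, < 11 rotatable bonds, logP in [−3.0, 6.1]).  Boundary
semantics are read literally: "< 517 Da" and "fewer than 9" are strict,
"up to 9" is inclusive, and the logP intervals are closed; the 95% tier
mirrors the 90% tier's semantics bound-for-bound.  `herbicide_likeness()`
reports pass/fail and the violated bounds per tier.

## The model laboratory

The default learner is a random forest with 300 trees, for both
classification (class probabilities) and regression; small linear
learners (binomial GLM, least squares) are available where speed or
exactness matters.  Evaluation follows a fixed protocol:

* **Stratified 10-fold cross-validation.**  Each class is shuffled and
  dealt so fold sizes differ by at most one sample and per-fold class
  prevalence is within one sample of the global prevalence.  Out-of-fold
  predictions are pooled and the headline metrics computed once on the
  pooled vector — matching the single reported value per dataset that
  this kind of study publishes — with per-fold metrics alongside.
* **Blind tests.**  A random 10% holdout (simple random sampling, with a
  stratified option) kept outside all training and selection.
* **Metrics.**  Accuracy, sensitivity, specificity and MCC from the
  confusion matrix; ROC-AUC as the rank-concordance (Mann–Whitney)
  statistic with ties counted one half; PR-AUC by step integration of
  the precision–recall curve; Pearson's r and RMSE for regression, plus
  a trimmed Pearson's r computed after removing the `round(0.1 n)`
  points with the largest absolute residuals — a reporting device for
  outlier sensitivity that never touches the model.
* **Fisher r-to-z.**  Correlations from different models are compared
  with $z = (\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2) /
  \sqrt{1/(n_1-3) + 1/(n_2-3)}$ and a two-sided normal p-value at the
  conventional 0.05 threshold.
* **Greedy forward selection.**  Optional dimensionality reduction:
  starting from the empty set, repeatedly add the feature that maximises
  the cross-validated metric, stopping when the improvement drops below
  a tolerance; ties break towards the lower column index.  When used
  inside cross-validation it is re-run within each training fold, so
  selection never sees the evaluation fold.

The classification threshold defaults to 0.5 and is configurable; a
hyperparameter grid search is deliberately not wired into the default
path.  Regression endpoints are modelled on the scale supplied by the
caller, with an optional log10 pre-transform left to the user because
LC50/LD50 data arrive in heterogeneous units.

## Enriched-substructure mining

To ask "what makes a herbicide", the package mines connected
substructures that are frequent among actives and rare among inactives.
Rather than wrapping an external miner, it enumerates *all* connected
edge-induced subgraphs up to a size cap (default 8 atoms; C++ under
`src/`), deduplicated by an exact canonical form (minimisation over
colour-preserving vertex orderings; atoms are coloured by element and
aromatic flag, bonds by order and aromaticity, charges ignored).
Support is molecule-level presence — a molecule counts once however many
embeddings it holds — which makes the enumeration route provably
equivalent to subgraph-isomorphism search, an equivalence the tests
assert on small molecules.  Fragments are reported as SMILES-like
patterns in which aromatic atoms may appear outside complete rings, as
in SMARTS.

A fragment qualifies when `support_pos >= min_support_pos`,
`support_neg <= max_support_neg` and
`fold_change = support_pos / max(support_neg, eps) >= min_fold`, with
`eps = 1/(2 n_neg)` regularising zero negative support.  Results rank by
fold change, then positive support, then size, largest first: among
equally supported discriminating patterns the maximal motif leads, so a
planted motif outranks its own sub-paths; a `maximal_only` filter can
additionally collapse fragments contained in an equally-supported
superfragment.  Preset bundles expose four support regimes (1%, 5%,
1–10%, 2–10%) crossed with 5- or 10-fold enrichment; the two-number
regimes are read as "at least 1% (resp. 2%) support among actives and at
most 10% among inactives", which is the most conservative reading of
that shorthand.

## Synthetic data with planted ground truth

Because the curated herbicidal and toxicity datasets behind this kind of
study are external, every pipeline stage is validated on synthetic
structure–activity data with known ground truth.  Molecules are
assembled from a scaffold/decorator grammar (benzene, pyridine,
cyclohexane, thiophene, furan, butane scaffolds; alkyl, halogen,
hydroxyl, methoxy, amino, carboxyl, nitrile, trifluoromethyl
decorations), so planted fragments are chemically well-formed.  Activity
follows one of three rules: a planted substructure (default: a
chloroacetic-acid arm, pattern `ClCC(=O)O`, whose parts — chlorine and
carboxyl — appear separately throughout the inactive class but never in
that combination), a descriptor window, or their conjunction; the
default prevalence is 0.22, matching the class balance typical of
curated herbicidal-activity collections, with optional label-flip noise.
The default descriptor window (MW ≤ 120 Da) splits the grammar's mass
distribution near its median so both classes are well-populated.
Regression endpoints are a stated linear function of the true
descriptors (default `2 − 0.01·MW + 0.5·logP`) plus Gaussian noise.

What the generator does *not* emulate: the chemical diversity of real
screening libraries, activity cliffs, assay noise structure, or any
specific target's SAR.  Passing the recovery experiments therefore shows
that the pipeline is *correct* (it finds structure that is genuinely
there, at the stated prevalence and noise), not that it would attain any
particular accuracy on real herbicide data.

## Numerical choices and degenerate inputs

* Fold assignment, blind splits, forests and the generator are all
  deterministic under recorded seeds; model files persist alongside a
  plain-text JSON spec (algorithm, hyperparameters, seed, features,
  training checksum).
* Trim counts use half-up rounding (`floor(x + 0.5)`), so 10% of 25 is
  3, not base R's banker's 2.
* MCC is defined as 0 when any confusion-matrix margin is empty;
  correlation on zero-variance vectors raises a contract error rather
  than returning NaN.
* Single-atom molecules yield empty distance censuses and all-zero pair
  blocks; disconnected pairs are an explicit unreachable sentinel and
  contribute to no signature bin (they cannot occur after
  largest-component reduction).
* An implicit bond between two aromatic atoms is only treated as
  aromatic when it lies in a ring, so biaryl single bonds (biphenyl) are
  read correctly from canonical SMILES.
* The fragment enumerator caps the number of visited subgraphs and
  raises an error suggesting a smaller `max_atoms` rather than running
  away on pathological inputs.

## Problem sizes used in validation

The recovery experiments run at desk scale, chosen so the full suite
re-runs quickly on a laptop: classification recovery uses n = 500
molecules at prevalence 0.22 with the default 300-tree forest under
10-fold cross-validation (pooled AUC ≥ 0.95 expected, and ≈ 0.5 on
label-shuffled nulls averaged over three seeds); mining recovery uses the
same 500 molecules with fragments up to 5 atoms under the 5%/10%/10-fold
regime; oracle-agreement checks use 200 random molecules (distances),
100 molecules × 5 renderings (signature invariance) and 50 random
confusion matrices / score vectors (metrics).

## Known limitations

* The SMILES reader covers the organic subset plus bracket atoms —
  sufficient for agrochemical-like molecules — and defers exotic
  valence models to the canonicalizer's judgement.
* logP and TPSA are OpenBabel's models; other toolkits will differ
  slightly, which shifts descriptor columns but not the signature block.
* Exhaustive fragment enumeration is exponential in the size cap; it is
  intended for `max_atoms` ≤ 8 on datasets of hundreds to thousands of
  molecules, not for library-scale mining.
* No applicability-domain estimation beyond the 2 kDa warning, no 3-D
  descriptors or conformers, and no statistical significance testing of
  fragment enrichment.
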