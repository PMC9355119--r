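---
title: "Methods: curation, descriptors, balancing, models and validation in oculotox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, descriptors, balancing, models and validation in oculotox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

oculotox builds classification models of ocular toxicity — GHS eye
irritation and corrosion hazard — from chemical structures. This vignette
explains the scientific procedure each module implements, the assumptions
behind it, the tunable parameters and their defaults, and the places where
the design was genuinely open and a choice had to be made.

## The modeling problem

Regulatory eye-hazard data label a compound as corrosive (GHS Cat 1, causes
irreversible damage), irritant (Cat 2A/2B, reversible effects) or not
classified (NC). Two binary endpoints are modeled — irritant vs
non-irritant and corrosive vs non-corrosive — plus a three-class problem
(corrosive / irritant / NC) obtained by collapsing Cat 2A and 2B into one
irritant class (`ghs_collapse()`). Such datasets are heavily imbalanced
toward NC compounds and contain many activity cliffs: structurally similar
molecules with different hazard calls. Both properties shape the pipeline —
the balancer deliberately keeps the *hardest* negatives, and the
instance-based MuDRA learner is included precisely because local
neighborhood evidence handles cliffs differently from a global forest.

## Curation

Raw structure tables carry salts, solvates, mixtures, inorganics and
duplicate records. `curate()` applies, in order:

1. **Standardization** (`standardize_structure()`): canonical SMILES via
   OpenBabel; recognized counter-ion/solvent fragments stripped (the
   principal organic fragment is kept); charges neutralized where valence
   rules permit — quaternary ammonium keeps its charge; pentavalent-written
   nitro groups rewritten to the charge-separated canonical form so both
   common spellings converge. The operation is idempotent, which the test
   suite checks by property.
2. **Inorganic/mixture removal**: records with no carbon atom are dropped
   as inorganic; records still holding more than one fragment after salt
   stripping are true mixtures and dropped.
3. **Duplicate resolution**: records are grouped by the canonical
   structure key. Concordant groups collapse to one record; groups whose
   labels disagree are removed entirely — a structure with inconsistent
   hazard calls cannot be trusted on either side of the boundary.

The counter-ion dictionary (`default_counterions()`) is an explicit,
user-replaceable list: alkali/alkaline-earth cations, halides, mineral and
common organic acid counter-ions, water and a few aprotic solvents. Simple
alcohols are deliberately *not* listed: ethanol or methanol co-fragments
are far more often genuine mixture components than solvates, so
`CCO.CCC` is treated as a mixture, not as ethanol-solvated propane. The
`curation_log` reconciles exactly: input count = output count + all
removal counts.

## Descriptor spaces

Three spaces are computed per compound, from a single structure parse
(`featurize()`):

* **MORGAN** — circular (radius-2) hashed fingerprints. The backend
  produces a 4096-bit ECFP4 vector, which is folded to the conventional
  2048 bits by OR-ing the halves; folding a hashed fingerprint is the
  standard way to fix its length and only increases collision density
  slightly.
* **KEYS166** — the public 166 structural keys (SMARTS-defined substructure
  indicators).
* **PHYSCHEM** — a whole-molecule continuous set (19 features: molecular
  weight and exact mass, logP, molar refractivity, TPSA, H-bond donor and
  acceptor counts, and atom/ring/rotatable-bond counts). The composition
  is toolkit-dependent by nature; `physchem_features()` records it rather
  than promising a particular census.

Before modeling, continuous blocks pass `filter_features()`: zero-variance
columns first, then, scanning pairs in fixed column order, the
later-indexed feature of any pair with |Pearson r| > 0.9 is removed. The
scan order makes the outcome deterministic; the survivors provably contain
no pair above the threshold, and re-filtering removes nothing (a
projection). Bit fingerprints are left unfiltered in the default pipeline:
the correlation filter is meant for continuous descriptor collections, and
truncating a hashed bit space would break its fixed-length contract.

## Balancing by similarity plus random under-sampling

With `n_pos` positives and a larger negative pool, `balance_dataset()`
selects `ceiling(n_pos/2)` negatives with the largest Tanimoto similarity
to their nearest positive, then `floor(n_pos/2)` uniformly at random
(seeded) from the remainder. The similarity half concentrates the
decision boundary — the negatives most confusable with positives — while
the random half preserves chemical-space coverage. Ties in the similarity
ranking break on (score descending, record id ascending), so the selection
is fully deterministic given the seed. At the published scales this yields
937 + 469 + 468 = 1,874 compounds for irritation and 209 + 105 + 104 = 418
for corrosion. Tanimoto similarity is |A∩B|/|A∪B| on fingerprint bits,
defined as 0 for two empty vectors.

## Models

**Random Forest** (`train_rf()`) operates on exactly one descriptor space:
500 trees by default, unlimited depth, square-root feature subsampling,
seeded and single-threaded for reproducibility. Labels come from class
probabilities with a conservative tie rule: binary predictions call the
more hazardous class at probability ≥ 0.5, and multiclass ties break
toward the more hazardous class (`hazard_order()`). In toxicology a false
negative costs more than a false positive, so ties never favor the safe
label.

**MuDRA** (`mudra_reference()`, `mudra_predict()`) is instance-based: no
model is fitted. For a query, each descriptor space retrieves the k most
similar training compounds (Tanimoto for bit spaces; `1/(1 + d)` with
Euclidean d on z-scaled features for continuous spaces, which maps
distance onto the same (0, 1] scale so spaces are comparable) and forms a
similarity-weighted class vote. The consensus label comes from the space
whose top neighbor is most similar to the query — the space that "knows"
the query best — and the confidence is that space's winning vote fraction.
The published description of the method leaves the weighting and consensus
rules open; the rules above are this package's fixed, documented choices
(k = 5 default, an optional similarity floor below which neighbors do not
vote, default 0). Every prediction exposes its per-space evidence
(nearest neighbor, similarity, local vote) so a read-across call can be
audited compound by compound.

## Applicability domain

`fit_ad()` implements the kNN Euclidean domain with one pooled threshold:
for each training compound, the mean Euclidean distance to its k nearest
other training compounds; ȳ and σ are the mean and SD of these values
over the training set, and

> D_T = ȳ + Z·σ,  Z = 0.5 by default.

A query is in-domain when its own mean k-nearest-training distance is
≤ D_T (boundary inclusive — a deterministic convention). k is not fixed by
the formula; the default k = 5 follows common kNN-domain practice and is
recorded in the fitted object. Continuous features are z-scaled with
training statistics before distances; bit vectors are used raw.
Coverage — the fraction of predictions inside the domain — is
non-decreasing in Z by construction, which the suite checks. The domain is
assessed for Random-Forest models in their own descriptor space; MuDRA
predictions are reported `NOT_ASSESSED`, since an instance-based method
carries its neighborhood evidence in the prediction itself.

## Validation

`five_fold_external_cv()` partitions the data into five stratified,
near-equal parts (each fold is an 80/20 modeling/test split). Stratified
rather than purely random assignment prevents degenerate folds; on the
balanced sets the pipeline produces, the two choices coincide in
distribution. Everything fitted — feature filters, forests, read-across
references, applicability domains — sees only the four training parts;
the held-out part is predicted externally, and pooled out-of-fold
predictions give the headline metrics (per-fold reports are retained; the
identity "pooled metrics = metrics of summed per-fold confusion counts"
is tested).

Eight statistics are reported from the confusion counts: Se, Sp,
CCR = (Se+Sp)/2, PPV, NPV, F1, MCC and Coverage. A metric with a zero
denominator is `NA`, never silently 0 — propagating an undefined value as
zero would bias averages. Multiclass problems are scored one-vs-all per
class and averaged unweighted, skipping undefined entries with a warning.
`acceptability_check()` applies the 0.6 threshold (inclusive) to Se, Sp,
CCR, PPV and NPV.

`y_randomization()` permutes the labels (seeded), reruns the full external
CV, and repeats — 10 rounds by default. Shuffled models should sit at
chance (CCR ≈ 0.5, MCC ≈ 0); a real model whose CCR exceeds every shuffled
round demonstrates the signal is not a fitting artifact. Per-round fold
seeds are derived from the master seed, so the whole procedure is
reproducible from one integer.

## The synthetic generator

`generate_fixture()` emits valid SMILES from a small scaffold grammar
(eight chain units, sixteen terminal groups — deliberately tiny so
substructure logic stays auditable) and plants a toxophore in positives: a
sulfonic acid group by default, a chemically sensible choice since
sulfonic acids are strong surface-active irritants. Labels follow
"contains toxophore XOR noise" with exactly `round(noise_rate × n)` flips.
Duplicates (half concordant, half discordant), salt forms, inorganics and
mixtures can be injected at configured rates, and the manifest records
every injection so curation tests can verify removal counts exactly.

Defaults describe the package's planted-signal validation setting: 400
compounds, balanced classes, 10% label noise. The larger balancing
demonstrations use 937 positives against 2,401 negatives and 209 positives
against a pool in the same proportion; the GHS fixture assembles
209/166/84/789 compounds per category. These are also the problem sizes
the acceptance script runs.

What the generator does *not* emulate: the chemical diversity of real
regulatory inventories (its grammar spans a few thousand scaffolds, not
millions), realistic descriptor correlation structure, or mechanisms of
ocular toxicity beyond a single planted substructure. Passing the
planted-signal tests therefore shows the pipeline machinery is correct —
external honesty of CV, chance-level collapse under Y-randomization,
recovery of a recoverable signal — not that any particular real endpoint
is predictable to the same accuracy.

## Numerical choices and degenerate inputs

* Correlation-filter tie-break: drop the later feature in column order.
* Similarity ranking ties: stable order by training index.
* MuDRA with zero similarity everywhere: the most hazardous class is
  returned with confidence 0 and a `low_evidence` flag, keeping the
  conservative direction of the tie rules.
* σ = 0 in the domain formula gives D_T = ȳ exactly; identical training
  points give D_T = 0 and only exact matches are in-domain.
* Constant features scale with σ set to 1 in z-scaling (they contribute 0
  to every distance).
* Two all-zero fingerprints have Tanimoto similarity 0 by convention.
* Balancing requires |negatives| ≥ |positives|; under-sampling cannot
  manufacture negatives, so the reverse imbalance is an error by design.

## Known limitations

* OpenBabel's circular fingerprints and structural keys are not
  bit-compatible with other toolkits' implementations of the same ideas;
  models and references must be built and queried within this package.
* The physicochemical set is small (19 features); correlation filtering
  at 0.9 typically removes only a few of them.
* Standardization normalizes the nitro chemotype explicitly; other
  resonance chemotypes rely on the canonicalizer's own perception.
* MuDRA stores its full training blocks; references over very large sets
  cost memory proportionally.
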