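# oculotox

QSAR modeling of eye irritation and corrosion hazard from chemical
structure.

Regulatory classification of ocular toxicity — GHS Cat 1 (corrosive,
irreversible damage), Cat 2A/2B (reversible irritation), NC (not
classified) — still leans on the in vivo rabbit Draize test.
Computational models trained on curated regulatory data offer a fast
alternative for flagging hazardous compounds before any animal is used.
oculotox is an R toolkit for building and rigorously validating such
models: it is aimed at computational toxicologists and cheminformaticians
who need a reproducible pipeline from raw structure tables to externally
validated classifiers and batch virtual screening.

## What the package implements

* **Curation** — `curate()`: canonical standardization (salt stripping
  against an explicit counter-ion dictionary, valence-safe neutralization,
  nitro-chemotype normalization), removal of inorganics and mixtures, and
  duplicate resolution (concordant groups collapse; discordant-label
  groups are removed). The log reconciles exactly with input/output
  counts.
* **Descriptors** — `featurize()`: 2048-bit Morgan (radius-2 circular)
  fingerprints, the public 166 structural keys, and a whole-molecule
  physicochemical set; `filter_features()` removes invariant features and
  one of each pair with |Pearson r| > 0.9.
* **Balancing** — `balance_dataset()`: the minority (toxic) class is kept
  whole and matched by `ceiling(n/2)` negatives with the largest Tanimoto
  similarity to their nearest positive plus `floor(n/2)` random
  negatives, i.e. hard boundary cases plus chemical-space coverage.
* **Models** — `train_rf()` (seeded probability Random Forest on one
  descriptor space) and MuDRA, multi-descriptor read-across
  (`mudra_reference()` / `mudra_predict()`): instance-based prediction
  where each descriptor space casts a similarity-weighted k-nearest-
  neighbor vote and the space with the most similar top neighbor decides.
* **Applicability domain** — `fit_ad()`: kNN Euclidean domain with the
  pooled threshold `D_T = ȳ + Z·σ` (Z = 0.5 default), where ȳ and σ
  summarize each training compound's mean distance to its k nearest
  neighbors; coverage is the fraction of predictions inside the domain.
* **Validation** — `five_fold_external_cv()` (stratified 5-fold external
  CV; all fitting strictly inside the training folds),
  `y_randomization()` (label shuffling, 10 rounds), and the full metric
  set Se, Sp, CCR = (Se+Sp)/2, PPV, NPV, F1, MCC, Coverage, with
  one-vs-all averaging for the 3-class GHS problem and an acceptability
  check at 0.6.
* **Screening** — `screen_compounds()` and `run_pipeline()`: config-driven
  end-to-end runs with provenance manifests, plus a thin CLI wrapper in
  `inst/cli/oculotox-cli.R`.
* **Synthetic data** — `generate_fixture()`: a scaffold-grammar SMILES
  generator with a planted toxophore signal, label noise, duplicates,
  salt forms, inorganics and mixtures, so the entire pipeline is testable
  without any proprietary data.

Structure handling (canonicalization, fingerprints, structural keys,
molecular properties) is backed by OpenBabel via the ChemmineOB package
and the `obabel` executable; forests are fitted with ranger.

## Worked example

A complete run on synthetic data with curation artifacts injected:

```r
library(oculotox)

raw <- generate_fixture(fixture_config(
  n_compounds = 300, noise_rate = 0.1, imbalance_ratio = 2,
  duplicate_rate = 0.05, salt_rate = 0.05,
  n_inorganics = 5, n_mixtures = 5, rng_seed = 7))

cur <- curate(raw)
print(cur$log)
#> Curation log: 325 records in, 293 records out
#>   removed (inorganic): 5
#>   removed (mixture): 5
#>   removed (discordant duplicate): 14
#>   removed (redundant duplicate): 8

pos <- cur$records[cur$records$label == "POS", ]
neg <- cur$records[cur$records$label == "NEG", ]
bal <- balance_dataset(pos, neg, balance_config(rng_seed = 7))
print(bal)
#> <balanced_set> 107 positives + 107 negatives (54 similarity-selected, 53 random)

df <- as.data.frame(bal)
blocks <- featurize(df$smiles, df$record_id,
                    spaces = c("MORGAN", "KEYS166"))

cv_rf <- five_fold_external_cv(
  blocks, df$label, classifier_spec("RF", "MORGAN", rng_seed = 7),
  seed = 7, ad = TRUE)
print(cv_rf)
#> <cv_result> RF on MORGAN, 5 folds, 214 pooled predictions
#>      CCR       Se      PPV       Sp      NPV       F1      MCC Coverage
#>     0.86     0.81     0.91     0.92     0.83     0.86     0.73     0.64

cv_mu <- five_fold_external_cv(
  blocks, df$label,
  classifier_spec("MUDRA", c("MORGAN", "KEYS166")), seed = 7)
print(cv_mu)
#> <cv_result> MUDRA on MORGAN+KEYS166, 5 folds, 214 pooled predictions
#>      CCR       Se      PPV       Sp      NPV       F1      MCC Coverage
#>     0.86     0.82     0.88     0.89     0.83     0.85     0.71       NA
```

Reading the output: the 325 raw records lose exactly the injected junk
(10 inorganics/mixtures, 8 redundant copies, 7 discordant duplicate pairs)
plus nothing else; balancing pairs the 107 surviving positives with 107
negatives split 54/53 between similarity and random selection; both
learners reach a pooled external-CV balanced accuracy (CCR) of 0.86 on the
planted signal, with every metric above the 0.6 acceptability threshold.
The Random-Forest coverage of 0.64 is the fraction of test compounds
inside its kNN applicability domain; MuDRA, being instance-based, reports
no domain (its per-compound neighborhood evidence plays that role).

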