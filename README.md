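# htscurate

Hierarchical curation, early-recognition evaluation and standard splits for
high-throughput screening (HTS) data, in R.

## Who this is for

HTS depositions (PubChem-style bioassay tables) are the raw material for
training virtual-screening models, but they arrive noisy on two axes: the
assay cascade (loose primary thresholds make most primary "actives" false
positives; confirmatory and counter screens must be combined to fix this)
and the chemistry (duplicate records, salt mixtures, charged forms, PAINS
interference chemotypes, non-drug-like matter). `htscurate` is for
cheminformaticians and ML practitioners who need to turn such a deposition
into a clean active/inactive dataset with an audit trail, and then
benchmark ranking models on it the way the field expects.

## What it implements

**Curation pipeline** (`run_curation_pipeline`) — ten ordered stages with a
per-record exclusion ledger and count conservation at every stage:
deduplication (triple-keyed on id, canonical SMILES, InChI), hierarchical
label assignment over a primary → confirmatory → counter screen DAG,
parser/valence filter, inorganic filter, mixture resolution, charge
neutralization (neutralize-by-atom), aromatization, PAINS substructure
filter (three switchable layers), Lipinski Rule-of-Five filter, and a final
flag review. Final labels are binary:

    active  ⇔  primary-active ∧ confirmatory-active ∧ ¬counter-active

**Early-recognition metrics** (`evaluate_all`) — for a label vector *y* and
score vector *s*:

* logAUC[0.001, 0.1] = (∫ TPR d log₁₀FPR over [10⁻³, 10⁻¹]) / 2 — exact
  step-ROC integration; perfect ranking → 1, identity ROC →
  0.099/(2 ln 10) ≈ 0.0215
* BEDROC(α = 20) — exponentially weighted early recognition in [0, 1]
* EF₁₀₀ = (actives in top 100 / 100) ÷ (n_actives / n)
* DCG₁₀₀ = Σᵢ relᵢ / log₂(i + 1)

**Splits** — adapted 5-fold cross-validation (every compound tested exactly
once, validation fold = cyclic predecessor of the test fold, only 5 models
trained) and Bemis-Murcko scaffold splits (scaffold-disjoint 3:1:1 with
bins > 10% of the library forced into training).

**Graph featurization** — 2D bond graphs and 3D distance-cutoff graphs
(6 Å, inclusive) over a documented 28-slot atom feature schema.

**Synthetic campaigns** (`generate_library`, `simulate_screens`) — seeded,
deterministic screening campaigns with planted artifacts and an analytic
per-stage exclusion oracle (`expected_curation_counts`), so the whole stack
is testable offline.

Chemistry (parsing, canonicalization, InChI, properties, SMARTS) runs on
the Bioconductor ChemmineR/ChemmineOB (OpenBabel) stack.

## Worked example

Simulate a 500-compound campaign (2% true hit rate, noisy primary screen,
60 planted artifacts), curate it, and evaluate a score vector:

```r
library(htscurate)

spec <- campaign_spec(n_compounds = 500, true_hit_rate = 0.02, seed = 42)
campaign <- simulate_screens(generate_library(spec))
curated <- run_curation_pipeline(campaign$records, campaign$hierarchy)
print(curated$report)
#> Curation report
#>         stage n_in n_out n_excluded
#>   deduplicate  500   490         10
#>     hierarchy  490   343        147
#>         parse  343   343          0
#>     inorganic  343   343          0
#>       mixture  343   337          6
#>    neutralize  337   337          0
#>     aromatize  337   337          0
#>         pains  337   330          7
#>  druglikeness  330   321          9
#>  flag_review  321   321          0
#> Total excluded: 179
```

The 10 planted duplicate rows die at deduplication. The hierarchy stage
removes 147 records: primary-screen false positives (the default
`primary_fp_rate` is 0.3) that the confirmatory screen refuted — under the
default policy they are dropped as ambiguous, not kept as inactives. The
planted mixtures, PAINS chemotypes and Rule-of-Five violators are excluded
at exactly their stages (a few were also primary false positives and left
earlier, at the hierarchy stage); salts and charged species survive in
standardized form, which is why `mixture`/`pains` show 6 and 7 rather than
10.

```r
set.seed(1)
scores <- ifelse(curated$records$label == "active",
                 runif(nrow(curated$records), 0.7, 1),
                 runif(nrow(curated$records)))
evaluate_all(as.integer(curated$records$label == "active"), scores)
#> Early-recognition metrics (alpha = 20, k = 100, FPR window [0.001, 0.1])
#>   logAUC : 0.0276
#>   BEDROC : 0.1120
#>   EF_100 : 3.210
#>   DCG_100: 1.948
```

A score vector that only mildly separates the 11 actives from 310
inactives earns an EF₁₀₀ of 3.2 (the top-100 selection is 3.2× richer in
actives than random picking) and a logAUC barely above the 0.0215 random
baseline — early-recognition metrics are deliberately hard to please.

```r
plan <- adapted_cv_folds(curated$records$compound_id, split_config(seed = 7))
print(plan)
#> Split plan (adapted_cv, seed 7): 5 fold(s)
#>   fold 1: train 192 / val 64 / test 65
#>   ...
```

A command-line front end covering `curate`, `split`, `evaluate`,
`featurize`, `stats` and `simulate` is installed at
`system.file("cli", "htscurate", package = "htscurate")`.

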