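---
title: "Curating and benchmarking high-throughput screening data with htscurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and benchmarking high-throughput screening data with htscurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A high-throughput screening (HTS) campaign tests hundreds of thousands of
compounds against a biological target. The raw deposition is noisy in two
distinct ways. First, the *assay cascade* is noisy: the primary screen uses a
deliberately loose activity threshold (to avoid missing true hits), so most
primary "actives" are false positives; follow-up confirmatory screens and
off-target counter screens exist precisely to clean this up, but their
verdicts must be combined correctly. Second, the *chemistry* is noisy:
depositions contain duplicated compounds under different identifiers,
salt/solvent mixtures, charged forms of neutral drugs, assay-interfering
chemotypes (PAINS), and molecules far outside drug-like property space.
Models trained on uncurated depositions learn these artifacts.

`htscurate` implements the full curation and benchmarking stack as a
reusable toolkit: a hierarchical, auditable curation pipeline; the four
early-recognition metrics used to evaluate virtual-screening models; the two
standard data-split schemes; molecular-graph featurization; and a synthetic
campaign simulator that makes the whole stack testable without downloading
anything.

## The curation pipeline

`run_curation_pipeline()` applies ten stages in a fixed order, each
attributing exclusions to the *first* failing stage and conserving counts
(`n_in = n_out + n_excluded` at every stage):

1. **Deduplication** — records are triple-checked on compound id, canonical
   SMILES and InChI; any shared key merges records into one duplicate group
   (transitively). Groups with identical outcomes keep the lexicographically
   smallest id; groups with conflicting outcomes are excluded entirely —
   picking a winner arbitrarily would inject label noise.
2. **Hierarchical label assignment** — a compound is finally *active* iff it
   is active in a primary screen, active in a downstream confirmatory
   screen, and not active in any linked counter screen. Primary inactives
   are final inactives. Primary actives never confirmed (untested or refuted
   in the confirmatory tier) are governed by `unconfirmed_policy`: the
   default `drop` treats them as ambiguous rather than as negatives, because
   the loose primary threshold makes "primary-active, unconfirmed" compatible
   with either truth; `inactive` is available for users who prefer a larger
   negative set. Counter-screen actives are removed rather than relabelled:
   they are genuinely active on the wrong target.
3. **Parser filter** — SMILES must parse and satisfy a standard valence
   model (the backend parser accepts hypervalent SMILES silently, so the
   package enforces valences itself). When a deposited InChI disagrees with
   the SMILES-derived InChI on the formula/connectivity skeleton, the record
   is flagged `representation-mismatch` instead of being dropped — a human
   decides, unless `strict = TRUE`.
4. **Inorganic filter** — fail if no carbon atom or any element outside
   {H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I}. CO2-like carbon species
   pass; the carbon rule is documented as an approximation. In the pipeline
   this whole-record rule applies only to single-component molecules;
   multi-component records are judged per component at the mixture stage
   (otherwise every salt would be discarded for its counter-ion before the
   mixture logic could strip it).
5. **Mixture resolution** — identical components collapse to one; if two
   distinct components sit within `mixture_mw_tolerance` (default 5 Da) of
   each other the record is discarded as ambiguous (no defensible way to
   pick); otherwise components are sieved by the inorganic and druglikeness
   rules, keeping a unique survivor, dropping the record when none survives,
   and keeping the heaviest (flagged) when several do.
6. **Neutralization** — neutralize-by-atom: each charged atom with no
   oppositely charged bonded neighbour is zeroed and hydrogens re-derived;
   internally compensated groups (nitro, N-oxide) stay; edits that would
   break valence (quaternary ammonium) are abandoned and flagged.
7. **Aromatization** — kekulized depositions are rewritten in aromatic
   canonical form so equivalent bonds carry equal representations.
8. **PAINS filter** — substructure screening against the package's curated
   catalog (below).
9. **Druglikeness** — Lipinski Rule-of-Five violations counted over
   MW > 500 Da, logP > 5, donors > 5, acceptors (N+O) > 10; the default
   tolerates one violation (Lipinski's original formulation), configurable
   to zero.
10. **Flag review** — ordinarily an audit log for human inspection; with
    `strict = TRUE` flagged records are excluded here.

Because structures rewritten by stages 5–7 get their InChI refreshed, the
pipeline is idempotent: run on its own output it excludes nothing.

### The PAINS catalog

The canonical pan-assay-interference pattern lists live in supplementary
materials and vendor files; this package ships its own hand-curated catalog
(`pains_catalog()`) of 18 SMARTS covering the classic families — quinones,
rhodanines and ene-rhodanines, catechols and hydroquinones, hydroxyphenyl
hydrazones, Mannich phenols, isothiazolinones, azo dyes, acyl hydrazones,
polyenes, alkylidene barbiturates, open thioureas, cyanoacrylates and
β-aminoketones — organized into the three conventional layers
(*promiscuity*, *optical interference*, *other interference*), each layer
individually switchable. It is a representative reimplementation, not a
copy of any published list; users with the full catalogs can substitute
them. Matching first runs a single union pattern (recursive SMARTS) and
only attributes per-pattern names on hits, which keeps campaign-scale
screening fast.

## Early-recognition metrics

In prospective virtual screening only the top of the ranked list is ever
purchased, so overall ROC-AUC is a poor headline number. The suite in
`evaluate_all()` therefore focuses on the early part of the ranking:

* **logAUC[0.001, 0.1]** — the empirical ROC is a right-continuous step
  function; we integrate TPR against log10(FPR) between FPR = 0.001 and
  0.1 and normalize by the two-decade window width. Each TPR plateau is
  summed exactly (plateau height times its clipped log-width), so the value
  is exact for the step ROC, not a quadrature approximation. A perfect
  ranking gives 1; a classifier on the identity ROC gives
  0.099/(2 ln 10) ≈ 0.0215.
* **BEDROC** — exponentially weighted early recognition with shape
  `alpha = 20` by default (the community convention, reported in every
  metric printout); bounded in [0, 1].
* **EF_k** — active fraction among the top k over the library active
  fraction, k = 100 by default.
* **DCG_k** — binary-relevance discounted cumulative gain,
  rel_i / log2(i+1), so rank 1 is undiscounted.

Ties: the default policy keeps input order (stable sort) and warns, because
silently reordering ties can flatter a model; `average_pessimistic` ranks
actives last inside every tie block, giving a worst-case audit value.
Degenerate label vectors (all active or all inactive) are a hard error for
the rank-curve metrics rather than a silent 0/1.

## Split schemes

`adapted_cv_folds()` implements the adapted cross-validation in which the
ids are shuffled once into k (default 5) near-equal folds; tuple *t* tests
fold *t*, validates on its cyclic predecessor and trains on the remaining
k−2 folds. Every compound is tested exactly once while only k models are
trained.

`scaffold_split()` bins compounds by Bemis-Murcko scaffold (the ring systems
plus linkers after iteratively pruning terminal atoms; acyclic molecules
share the empty-scaffold bin). Any bin holding more than
`big_bin_fraction` (default 10%) of the library is forced into training;
the remaining bins are shuffled by the seed, ordered by decreasing size
(the shuffle decides ties), and greedily assigned to whichever of
train/validation/test is furthest below its 3:1:1 target. No scaffold ever
spans two partitions, so test performance measures scaffold hopping. The
3:1:1 ratio is interpreted as train:validation:test. The scaffold itself is
the generic atom- and bond-typed framework; exocyclic terminal atoms
(including double-bonded oxygens) count as side chains — a deliberate,
documented simplification relative to variants that retain exocyclic double
bonds, and consistent as a binning key.

## Graph featurization

`atom_feature_matrix()` produces one row per heavy atom with a documented
28-slot schema (`atom_feature_schema()`): a 13-way element one-hot (12
organic elements + *other*), 5-way heavy-degree one-hot (0–3, ≥4), 4-way
attached-hydrogen one-hot (0–2, ≥3), 3-way hybridization one-hot (sp, sp2,
sp3; anything else all-zero), signed formal charge, an aromaticity flag and
a ring-membership flag. The schema is this package's own design (schema
version 1): the exact feature sets used by published graph benchmarks live
in their supplements, so the repo ships a fully documented equivalent
rather than guessing at one. Hydrogens are implicit (counts, not nodes),
matching common molecular-graph practice. `build_graph_2d()` uses covalent
bonds as edges with bond order/aromaticity/ring-bond features;
`build_graph_3d()` connects every atom pair within `distance_cutoff`
(default 6 Å, *inclusive* at the boundary) and stores coordinates verbatim.
Conformer generation is out of scope: 3D coordinates come from an SDF
(`read_sdf_conformers()`), whatever generator produced it.

## The synthetic campaign simulator

`generate_library()` + `simulate_screens()` emulate the data setting the
curation pipeline is built for, with ground truth attached:

* A deterministic fragment vocabulary (~16 substituent prefixes × 16
  substituents × 10 ring templates) is canonicalized and sieved once
  through the package's own filters, leaving ≈2,200 distinct, provably
  clean drug-like molecules. Clean campaign compounds are drawn from this
  pool, so any structural exclusion of a clean compound is by construction
  a pipeline bug.
* Planted artifacts are inserted at exact counts, one tag per record:
  duplicate rows (same structure and outcomes, fresh id), ambiguous
  mixtures (two pool molecules within 5 Da), salt adducts (pool molecule +
  counter-ion pair chosen so the MW-ambiguity rule cannot fire), charged
  species (ammonium/carboxylate forms whose neutralized parents are clean
  and outside the pool), PAINS chemotypes (quinone, catechol, rhodanine and
  azo families with varied substituents) and Rule-of-Five violators (long
  alkanes: MW > 500 and logP > 5, hence two violations). Artifacts are
  never true actives, so noiseless curation must recover truth exactly.
* Screens: the primary reports truth corrupted by `primary_fp_rate`
  (default 0.3 — the loose-threshold regime) and `primary_fn_rate`
  (default 0.01); the confirmatory tier tests only primary actives and
  reports truth flipped with `confirmatory_error_rate` (default 0, making
  the confirmatory screen the gold standard — the error model is an
  independent Bernoulli, a modelling choice, since real assays publish no
  error model); the counter screen fires on confirmed actives with
  `counter_cross_react_rate` (default 0.02). The default true hit rate is
  0.005, in the sub-1% range typical of real campaigns.
* `expected_curation_counts()` is an *independent oracle*: it predicts each
  stage's exclusion count from the planted tags and simulated outcomes
  alone, never touching the structural filters. The test suite requires the
  pipeline to match it exactly, stage by stage, on noiseless and noisy
  campaigns.

What the simulator does **not** emulate: real structural diversity (the
vocabulary is deliberately simple so filter outcomes are provable),
correlated assay noise, dose-response values, activity cliffs, or
borderline property values that straddle filter thresholds. Passing tests
demonstrate that the pipeline implements its stated rules exactly — not
that those rules are sufficient for any particular real deposition.

## Numerical and design notes

* Molecular weights, logP, donor/acceptor counts and InChI come from the
  OpenBabel-backed ChemmineR/ChemmineOB stack; molecular weights use
  standard atomic masses. Lipinski acceptors are the N+O count.
* Lone atoms/ions ("[Na+]") cannot be represented by the SDF container the
  backend uses; a small internal atomic-mass table handles their
  properties, which is all the mixture rules need.
* The mixture MW-ambiguity comparison is inclusive (≤ 5 Da). The 3D
  distance cutoff is inclusive (≤ 6 Å). Display rounding of percent-active
  is three decimals; the exact value is kept alongside.
* All randomness (fold shuffling, bin ordering, campaign generation) is
  driven by explicit integer seeds through a localized RNG that does not
  disturb the caller's random stream; identical seeds give byte-identical
  outputs.
* Problem sizes used by the shipped checks: metric oracles on 1,000 random
  instances (n ≤ 500); exhaustive monotonicity for n ≤ 8; curation truth
  recovery on a 2,000-compound campaign with 60 planted artifacts; 3D graph
  equivalence on 1,000 random point clouds (n ≤ 50). These sizes were
  chosen to exercise every code path at full coverage while keeping the
  suite quick to run.

## Known limitations

* The PAINS catalog is representative, not exhaustive (18 families vs ~480
  published patterns); per-record verdicts on real depositions will differ
  from runs using the full lists.
* Scaffold extraction prunes exocyclic double-bonded atoms; tools that keep
  them will bin some molecules differently.
* The inorganic rule is a carbon-presence + element-set heuristic; it
  passes carbon-containing inorganics like carbonates.
* No live database client is included: the expected record payload
  (id, isomeric SMILES, standard InChI, per-screen outcome codes) is
  documented on `read_compound_table()`, and any table in that shape works.
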