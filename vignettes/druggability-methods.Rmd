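---
title: "Assessing PPI druggability with a random-negative SVM ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing PPI druggability with a random-negative SVM ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppidrug)
```

## The problem

Of the tens of thousands of protein-protein interactions (PPIs) catalogued
for human, mouse, rat and HIV proteins, only a few dozen are validated
targets of small-molecule inhibitors. `ppidrug` rates every stored
interaction by how similar its structural, drug/chemical and functional
attributes are to those of the known drug-target PPIs, so that candidate
interactions can be prioritized for inhibitor discovery.

The statistical difficulty is that there is no trustworthy negative class:
an interaction without a known inhibitor may simply not have been assayed
yet. The scorer therefore treats the problem as positive/unlabeled
learning and manufactures negatives by resampling.

## The ensemble scoring model

Let $P$ be the fixed positive set (by default the ~30 known drug-target
PPIs that have a validated small-molecule inhibitor whose binding pocket
overlaps the interface) and $U$ the unlabeled pool of all other scored
units. For each of $N$ rounds ($N = 10{,}000$ by default):

1. draw $\lceil r\,|P|\rceil$ negatives uniformly without replacement from
   $U$, with ratio $r = 1$ so training sets are class-balanced;
2. standardize each feature by the training-set mean and standard
   deviation, and apply the same affine map to the pool;
3. fit a soft-margin SVM with a radial-basis-function kernel
   ($C = 1$, $\gamma = 1/d$ for $d$ features by default) on positives vs
   negatives;
4. predict every unit in $U$ and record which are judged positive.

The *druggability score* of a unit is its number of positive votes divided
by $N$; it lies in $[0, 1]$ in exact multiples of $1/N$ (9,999 votes of
10,000 give 0.9999). Because the negatives differ from round to round, a
unit scores highly only when it resembles the positives *no matter which
part of the unlabeled pool plays the negative role* — the resampling
averages out the arbitrariness of any single negative choice.

Scores are banded for display: red $\ge 0.99$, magenta $[0.9, 0.99)$,
hotpink $[0.8, 0.9)$, pink $[0.7, 0.8)$. The 0.9 cut separating "highly
druggable" matches the average score of the positive instances; the lower
cuts are display conventions.

### Assessment modes and pocket aggregation

Four assessments are run per interaction: one per attribute category
(`structural`, `drug_chemical`, `functional`) and one with `all`
attributes. The drug/chemical and functional modes score whole PPIs. The
structural and all-attribute modes score *interface pockets*: each
structure-bearing PPI contributes one scoring unit per candidate
ligand-binding pocket, and the PPI-level score is the maximum over its
pockets (the best pocket is what a chemist would target). A PPI whose
complex structure has not been solved is *unscored* in those modes — an
absent structure is missing information, not evidence of a score of 0.

### Choices the published procedure leaves open

* **Kernel hyperparameters.** Only the kernel family (RBF) and the class
  ratio (1:1) are fixed by the procedure we implement; we use the standard
  libsvm-lineage defaults $C = 1$, $\gamma = 1/d$, both configurable in
  `scoring_config()`.
* **Feature scaling.** RBF kernels need comparable feature scales; volumes
  in cubic Angstroms would otherwise dwarf binary flags. We z-scale per
  iteration from the training set only, so no information leaks from the
  pool's class composition into the scaling.
* **Decision rule.** "Judged positive" means the SVM decision value's
  sign (the default class prediction), not a probability threshold.
* **In-sample negatives.** Each round's models predict *every* pool unit,
  including the units serving as that round's negatives. Their votes are
  slightly depressed (a unit labelled negative tends to be predicted
  negative), which under the null pulls the pool mean a little below 0.5;
  the calibration tests bound this effect.
* **Seed policy.** Iteration $i$ derives its seed from the master seed by
  a fixed integer hash, so runs are bitwise reproducible and a single
  iteration can be replayed in isolation.
* **Degenerate rounds.** If every training row is identical the round
  warns, casts no positive votes, and still counts in the denominator, so
  scores remain exact multiples of $1/N$.

## Attribute derivation

`build_attribute_rows()` turns annotation tables into the feature rows
the classifier consumes. The rules, per interaction $(a, b)$:

* **OMIM co-annotation** — 1 iff both proteins are implicated in
  OMIM-registered diseases, not necessarily the same disease; 0 otherwise.
* **Network degree** — the number of distinct interaction partners of each
  protein in the stored network; a self-interaction makes a protein its
  own partner once.
* **Counts** — pathways (union over sources), FDA-approved drugs, assayed
  chemicals, paralogs, per partner; an unannotated protein counts 0, never
  errors.
* **GO identity and expression similarity** — symmetric set-similarity
  scores in $[0,1]$. The originally used formulas were published only in
  supplementary material we do not reproduce; the package defaults to the
  Jaccard index over GO-term sets and over expressed-body-site sets
  (expression is treated as binary site sets, matching the "expressed in
  34/44 body sites" presentation), and both accept a replacement function
  so another formula can be plugged in.
* **Structure mapping** — an interaction is structure-bearing when both
  proteins hit *distinct* chains of the same PDB entry at $\ge 80\%$
  sequence identity (inclusive) and those chains are in physical contact
  per the interface table. When several entries qualify we keep the one
  maximizing the smaller of the two identities, breaking ties by smallest
  entry id then chain pair — a deterministic rule the source procedure
  does not specify.
* **Motif eligibility** — a sequence motif qualifies for profile
  construction only with $\ge 2$ curated instances (one instance cannot be
  aligned).

Interactions are unordered: tables are canonicalized (lexicographic pair
order, with `_a`/`_b` paired columns swapped alongside), reversed
duplicates merged. When duplicates disagree on an attribute the first
non-missing value wins; conflicting non-missing values keep the value of
the lexicographically first source and warn. Cross-species interactions
carry a sorted composite label such as `HIV+human`.

## The synthetic generator

`generate_attribute_table()` emulates exactly the statistical structure
the scorer assumes, with auditable ground truth:

* background features are standard normal (continuous), Poisson with
  $\lambda = 3$ (counts) or Bernoulli with $p = 0.2$ (binary);
* positives and "planted" pool units are shifted by $\delta$ background
  standard deviations on the *first* $k$ features of each category (so
  which features are informative is always known); counts shift by
  $\delta\sqrt\lambda$ and binary rates by $\delta\sqrt{p(1-p)}$ capped at
  0.95;
* positives always carry a structure and pockets — a known drug-target
  PPI has, by definition, a solved complex with a validated ligand
  pocket — while a fraction `missingness` (default 0.9, mirroring how few
  catalogued interactions have solved complex structures) of pool units
  lack structural data;
* structure-bearing units get 1–4 pockets; in shifted units exactly one
  "good" pocket carries the shifted descriptors, so max-aggregation is
  genuinely exercised.

What it does **not** emulate: correlated features, heavy-tailed count
distributions, annotation biases (well-studied proteins have more of
everything), and any sequence- or structure-level realism. Passing the
calibration and recovery tests therefore shows the *procedure* is sound —
calibrated under the null, monotone in signal strength, able to recover
planted positives — not that any particular biological interaction is
druggable.

## Test-suite problem sizes and checks

The package's statistical checks run at deliberately modest sizes:

* **Null calibration** — pool of 200 units drawn i.i.d. from the positive
  distribution ($\delta = 0$), $N = 1{,}000$ iterations, 5 master seeds;
  the pool-mean score must stay in $[0.4, 0.6]$.
* **Recovery** — 50 planted units among 150 background at $\delta = 3$,
  $N = 1{,}000$: planted units must rank above background with AUC
  $\ge 0.9$.
* **Monotonicity** — mean score of the planted units, averaged over 5
  seeds at $N = 300$, must be non-decreasing over
  $\delta \in \{0, 0.5, 1, 2, 4\}$. The planted mean is the right
  monotone quantity for a mixed pool: background units' scores *fall* as
  $\delta$ grows (they become ever more clearly negative-like), so the
  overall pool mean is non-monotone by construction.
* **Oracle equivalence** — vote tallies against a literal per-iteration
  re-tally; deduplication, degree and graph export against $O(n^2)$
  enumeration on instances of up to 200 records.
* **Determinism** — a full simulate → annotate → score → report → export
  run is byte-identical across two invocations with the same master seed.

Note that the planted units participate in the negative resampling like
any pool unit, so at high $\delta$ the training negatives are contaminated
with positive-like units — exactly the situation the resampling scheme is
designed to tolerate, and the recovery test confirms it does.

## A worked example

```{r example}
syn <- generate_attribute_table(synth_config(
  n_positives = 30, n_background = 150, n_planted = 50,
  effect_size = 2, missingness = 0.8, seed = 42))
cfg <- scoring_config(n_iterations = 500, mode = "functional",
                      master_seed = 42)
fit <- druggability(syn$records, syn$positives, syn$schema, cfg)
fit
summary(fit)
```

The known worked examples ship as fixtures: the species census of the
71,500 stored non-redundant interactions and the 17 lung-cancer-related
PPIs assessed as highly druggable.

```{r fixtures}
species_summary(load_fixture("table2_species_counts"))
t4 <- load_fixture("table4_lung_cancer_scores")
count_by_threshold(t4, "all", 0.9)
top_result(t4, "all")
```

## Known limitations

* The original 30-positive attribute data, the proprietary pocket
  detector and the 2010 snapshots of the source databases are not
  available, so the package cannot reproduce the published headline
  accuracy (80.5%) or database census; it reproduces the *procedure* and
  the published worked-example tables.
* The GO-identity and expression-similarity formulas default to Jaccard
  because the original equations were not republished; scores produced
  with a different similarity will differ in the functional mode.
* At $N$ iterations the score granularity is $1/N$; ranks of units closer
  than a few Monte-Carlo standard errors ($\sqrt{s(1-s)/N}$) are not
  meaningful.
* Scoring cost grows linearly in $N$ and in the pool size times the
  training-set size; the default $N = 10{,}000$ on a large pool is an
  overnight-scale run on one core, which is why the tests run at
  $N \le 1{,}000$.
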