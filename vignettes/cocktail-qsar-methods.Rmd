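---
title: "Cocktail QSAR modelling of imbalanced bioassay data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cocktail QSAR modelling of imbalanced bioassay data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative high-throughput screens (qHTS) test hundreds of thousands of
substances and typically confirm well under 1% of them as actives. Two
things make such data awkward for QSAR classification: most learners drown
the minority class in the majority, and any validation statistic computed
on the raw class balance is dominated by the inactives. This package
implements a complete workflow for that setting, exercised here on
receptor-activation-style endpoints: curation of raw structure/score
tables, an ensemble learner built for imbalance, a two-component
applicability domain (AD), an iterative "rational" strategy for choosing
which inactives deserve a place in the training set, validation statistics
appropriate to rare-event screening, and substructure alert mining.

## Activity labelling

Each substance carries up to three assay scores on the 0-100 PubChem
scale: a primary single-concentration screen, a confirmatory
concentration-response retest, and a luciferase counterscreen that flags
compounds which stabilize the reporter enzyme rather than activate the
receptor. The label function is:

* **ACTIVE** — confirmatory score in 10-100 *and* counterscreen score 0;
* **INACTIVE** — primary score 0;
* **INCONCLUSIVE** — everything else (including counterscreen-positive
  retests and untested score patterns).

The active rule takes precedence. Inconclusive records survive curation
but never enter modelling. Absent scores satisfy neither positive clause,
so a record with no primary score cannot become inactive — a deliberate
reading of an under-specified corner.

## Structure curation

`curate()` applies, in order: a parse/error filter; an element whitelist
(H, B, C, N, O, F, Na, Mg, Si, P, S, Cl, K, Ca, Br, I) checked on the raw
structure before desalting; dissociation into connected components with
charge neutralization (carboxylates and other anions are protonated,
protonated amines deprotonated — OpenBabel's neutralization op — while
permanent charges such as quaternary nitrogen are non-neutralizable and
remove the record); a mixture filter (two or more carbon-containing
components) and a low-carbon filter (fewer than two carbons in the single
organic parent); canonicalization; and duplicate resolution on canonical
SMILES, where concordant groups keep one representative and groups with
both ACTIVE and INACTIVE members are removed entirely. A group mixing
INCONCLUSIVE with exactly one conclusive label keeps the conclusive label.
Stereochemistry is ignored throughout: modelling is 2D. Every removal is
logged, so `|input| = |kept| + removals + merges` is verifiable, and
`curate()` is idempotent on its own output.

All chemistry primitives run through the OpenBabel command line in
batches. Record identifiers travel as SMILES titles, so a malformed
structure is detected by its id missing from the converter's output,
not by positional bookkeeping.

## Features

Nine continuous descriptors are computed per structure: AlogP,
hydrogen-bond acceptors and donors, a Lipinski score (defined here as the
number of rule-of-five violations, 0-4), molecular weight, parent atom
number (heavy atoms of the desalted parent), parent molecular weight,
topological polar surface area, and rotatable bonds. For single-component
input, weight and parent weight coincide.

The substructure vocabulary is deliberately open: the 166 public MACCS
keys plus a built-in catalog of ~60 SMARTS patterns covering common ring
systems (indole, pyrrole, benzofuran, pyrimidine, quinoline, ...) and
functional groups (sulfonamide, sulfonyl, carboxylic acid, amide, ...).
"Mining" a vocabulary from a training set means keeping the catalog
patterns whose frequency reaches a floor (default 1% of training
structures); the result is deterministic and independent of input order.
Commercial fragment libraries are larger by two orders of magnitude; the
open stand-in trades resolution for reproducibility, which is the right
trade for a method-study package.

Descriptor preselection ranks every column by the Yates-corrected
chi-squared statistic of its presence-by-label 2x2 table and keeps the top
30%. Continuous descriptors are binarized at their training-set median for
the ranking only; the continuous values still enter the learner. Constant
columns carry no information and fill the quota last; remaining ties break
by column order for determinism.

## The learner

The classifier emulates partial logistic regression (PLR): PLS factors are
extracted against the binary response treated as continuous
(`mixOmics::pls`, unit-variance scaling), the number of factors (1-10) is
chosen by minimizing PRESS in a seeded internal 5-fold split, features
with zero loadings are dropped and the model refitted (at most twice), and
a logistic regression on the factor scores turns projections into a
positive prediction probability *p*. Degenerate inputs degrade gracefully:
a single informative column becomes a direct logistic fit, none at all an
intercept-only model returning the base rate. PLS components whose
projection turns numerically singular (possible under label noise) are
backed off before the logistic stage.

Three model shapes share this core:

* **single** — one model on the full training set;
* **composite** — the inactives are randomly partitioned into
  `round(n_inactive / (ratio * n_active))` chunks (never fewer than one)
  and each sub-model trains on *all* actives plus one chunk, giving
  balanced sub-models at the default ratio 1;
* **cocktail** — the single model plus the composite's sub-models, all
  with equal weight.

The chunk count uses the nearest integer rather than the ceiling: at
near-equal class sizes (exactly the situation Y-randomization creates) a
ceiling would split the inactives into half-size chunks and silently give
every sub-model a 2:1 active excess, biasing all probabilities upward. At
study-scale counts (e.g. 3,328 inactives to 832 actives) the two rules
agree.

A query's ensemble probability is the unweighted mean over the members
whose *structural domain* contains it; if no member qualifies the query
is out of the structural domain and receives no probability.

## Applicability domain

The AD has two components. A query is inside a member's structural domain
iff (1) its Jaccard (Tanimoto) similarity to at least one of that member's
training structures is at least 0.30 (inclusive), (2) all model
descriptors are computable, and (3) it carries at least one substructure
feature used in the model. The class-probability refinement then bands the
ensemble probability:

| band | probability | in AD? |
|------|-------------|--------|
| NEG_IN  | p <= 0.3        | yes |
| NEG_OUT | 0.3 < p < 0.4   | no  |
| INC_OUT | 0.4 <= p < 0.5  | no  |
| POS_OUT | 0.5 <= p < 0.7  | no  |
| POS_IN  | p >= 0.7        | yes |

INC_OUT and POS_OUT are sometimes tabulated with overlapping edges on
[0.5, 0.6); since the call rule makes p >= 0.5 a positive call, that
interval belongs to POS_OUT here and INC_OUT ends at 0.5. Coverage of a
prediction set is the fraction in POS_IN or NEG_IN.

## Rational selection of training inactives

The study design: actives split 90/10 into training and external test; a
fixed-size random pool of inactives becomes the selection set, the rest
the external test inactives. The first model trains on a 2:1 random
inactive draw. Each rational iteration predicts the unused pool in the
current model and adds an equal number of inactives from each of four
strata — out of structural domain, POS_OUT, NEG_OUT, and POS_IN (i.e.
false positives) — growing 2:1 to 3:1 to 4:1. Out-of-domain additions
widen the AD; false-positive additions erode spurious activity features
and buy specificity. A size-matched random 4:1 reference isolates the
effect. Final models then absorb the test actives plus four times as many
pool inactives (the external validation of a final model is
specificity-only, since its training set now contains the former test
actives).

Two desk-scale edge rules the original design never needed: a stratum
holding fewer than its quarter contributes everything and the deficit is
drawn from the largest remaining stratum; if the union of all four strata
is smaller than the requested addition, the whole union is taken and the
deficit recorded on the lineage.

## Validation

Cooper statistics (sensitivity, specificity, balanced accuracy) are
computed over in-AD predictions. `cooper()` returns unrounded
percentages, and balanced accuracy is identically their mean; for
table-style presentation values are rounded half-up to one decimal and
the balanced accuracy is recomputed from the rounded components, which is
how such tables are conventionally assembled. Prevalence-adjusted
predictive values use the closed form
`PPV = s*pi / (s*pi + (1-c)(1-pi))`, `NPV = c(1-pi) / (c(1-pi) + (1-s)pi)`
at assumed prevalences of 1/5/10% — under a 0.4%-active universe, PPV is
the statistic that keeps a screening model honest. Model agreement uses
the Matthews correlation coefficient, which equals the Pearson
correlation of the two binary call vectors.

Cross-validation is two-times-five-fold, stratified, and *independent*:
every fold-model rebuilds the vocabulary, the preselection and the whole
cocktail from its own 80% alone. Dispersion is the standard deviation
across the ten fold-models. Y-randomization replaces the labels by a
random half/half assignment and re-runs the cross-validation.

Reports carry two sets of Cooper statistics: over in-AD predictions (the
primary, reliability-filtered view) and over all structural-domain calls.
The second exists for chance-level diagnostics: a PRESS-regularized
learner under randomized labels is well calibrated, so its probabilities
pile up near 0.5 and the in-AD subset becomes too small to carry a rate
at desk scale. Chance level then shows as all-call balanced accuracy
~50% together with sensitivity + specificity ~100% (the no-discrimination
identity); the per-direction rates individually depend on where the 0.5
threshold cuts the skewed probability distribution and are not separately
informative.

## Alert mining

Activity alerts are ranked by `|baseline - xbar| * chi2`, where `xbar` is
the mean activity of the training structures containing the feature,
`chi2` the Yates-corrected independence statistic, and the baseline the
active fraction of the training set — 0.2 for the 1:4 final sets. The
absolute-difference factor
measures over-representation in either class; a feature occurring in more
inactives than actives can still alert for activity if its `xbar`
clears the baseline. (A strict "active/inactive ratio" of a 1:4 set would
be 0.25; the conventional 0.2 — the active fraction of the whole set — is
what the formula uses.) Inactivity alerts are the "pure" features —
present in zero actives — ranked by chi-squared alone. Scoring defaults
to the model's selected feature columns.

## The synthetic generator

`generate_fixture()` builds seeded universes with the statistical
structure the pipeline assumes. Molecules are assembled by concatenating
"appendable" SMILES fragments (each fragment is written so that any
concatenation stays valid), 5-40 heavy atoms, whitelist elements only.
Actives carry a planted heteroaromatic alert (indole, pyrrole,
benzofuran, or pyrimidine) with configurable penetrance (default 0.9);
inactives preferentially carry sulfonamide or carboxylic-acid motifs, and
a configurable "decoy" fraction of inactives (default 5-12% depending on
the config) carries an activity alert — the structurally clustered,
false-positive-prone inactives the rational strategy exists to exploit.
Contaminant injection (salts, mixtures, low-carbon species, forbidden
elements, duplicate pairs written as different SMILES strings of the same
molecule, with concordant or conflicting labels) tags every record with
its expected curation outcome, so curation tests are assertions against
ground truth, not against the code under test. Assay-score triples are
generated to be consistent with the labelling rules, with optional
luciferase interferers and label noise.

What the generator does *not* emulate: real medicinal-chemistry
diversity, correlated assay noise, and the sheer scale of public screens.
Passing tests show that the machinery is correct and that the rational
mechanism behaves directionally as described on data with planted
structure; they cannot certify effect sizes on real screening data.

## Problem sizes and defaults

Worked-example statistics are exact arithmetic on published counts and run
in milliseconds. The synthetic studies use 56-200 actives against
700-800 inactives; cross-validation fixtures use 200/800. These sizes
were chosen so the planted signal is comfortably learnable while a full
multi-seed study stays in the minutes range on a single CPU. The chunk
ratio defaults to 1 (balanced sub-models), `max_factors` to 10, the
similarity threshold to 0.30, the probability bands to 0.3/0.7, the CV
plan to 2x5, and all randomness flows from one master seed through named
substreams (`seed_substream`), making every artifact byte-reproducible.

## Known limitations

* The open vocabulary is far smaller than commercial key libraries;
  absolute performance numbers on real data will differ.
* Neutralization follows OpenBabel's rule set; exotic charge patterns
  beyond it remove the record rather than guessing chemistry.
* Tautomers, stereochemistry and 3D structure are out of scope.
* The probability-band AD is a hard filter; no conformal or
  distance-to-model refinement is attempted.
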