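---
title: "Methods: genetics-informed drug activity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetics-informed drug activity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genodrug)
```

## The problem

Most diseases are driven by many genes at once, and an agent that hits
several genetically implicated genes of a disease is a better
repositioning candidate than one that hits a single gene of uncertain
provenance.  `genodrug` turns that idea into a scoring-and-learning
pipeline with four stages: (i) score every recorded (gene, disease)
association for *druggability* from the quality of the databases that
record it; (ii) summarize, per drug and disease, the genetic evidence
behind the drug's targets into four features; (iii) learn drug--disease
activity with an ensemble of multi-label k-nearest-neighbour (MLKNN)
classifiers, one per feature, combined by simplex weights tuned on an
internal cross-validated precision--recall criterion; and (iv) audit
the input corpus with permutation and stratification statistics.

The universe of the classifier is the set of *eligible pairs*: a
(drug, disease) pair is eligible when the drug targets at least one
gene genetically associated with the disease.  Eligible pairs carrying
a clinical or approved indication are the positives; the remaining
eligible pairs are negatives.  Indications whose pair is not eligible
are retained in the corpus but excluded from training and evaluation
(their count is reported by `pair_labels()`), because nothing in the
feature space can distinguish them from the void.

## Druggability scores

Eight source databases are recognized and ranked by the empirical
quality of the disease genes they contribute, from Clinvar (8 points)
down through OMIM (7), HGMD (6), Orphanet (5), GWASdb (4), INTREPID
(3) and GAD (2) to DisGeNET (1 point).  The druggability score of a
(gene, disease) pair is the sum of the points of the *distinct*
databases recording it, so the score lies in 1..36 and the ceiling of
36 = 8 + 7 + ... + 1 is attained by a gene recorded everywhere.  Each
database counts once per pair no matter how many duplicate rows a dump
contains, a gene can carry different scores for different diseases,
and an unrecorded pair is a lookup error rather than a zero -- zeros
appear only downstream, in features of non-eligible cells.  The point
table is configurable (`points.tsv` with columns `source_db`,
`points`) so corpora with fewer sources, or a re-derived ranking, can
be used; the default follows the clinically-active-ratio ordering
above.  Ties in a user-derived ranking are not given shared points by
default; supply an explicit table if that is wanted.

## The four features

For drug $i$ and disease $l$, let $G(i,l)$ be the set of targeted
genes associated with $l$.  The features are

* `f1`: the summed druggability score over $G(i,l)$ — the reference
  two-gene example (one Clinvar gene, one DisGeNET gene) gives
  $8 + 1 = 9$;
* `f2`: `f1` normalized by $|G(i,l)| \times 36$, i.e. the average
  score rescaled by the single-gene ceiling — $9 / (2 \times 36) =
  0.125$ for the same example (the ceiling is read as $36 = 8 + 7 +
  \dots + 1$);
* `f3`: the number of genes in $G(i,l)$ that belong to ohnolog pairs
  (paralogs retained from whole-genome duplication, a proxy for
  reliable "top" disease genes);
* `f4`: `f3` divided by $|G(i,l)|$.

Two conventions were genuinely open.  First, `f4`'s denominator: we
divide by the targeted *disease* genes rather than all targets,
paralleling `f2`'s denominator in the worked example (both readings
are trivial to compute from the exported matrices if the other is
wanted).  Second, all 0/0 cases return 0 rather than an error,
because the negative class legitimately contains low-evidence pairs.
Feature vectors are disease-indexed: drug $i$'s instance is the
$q$-vector of its feature values over all diseases, which makes the
features disease-specific in the same way the druggability score is.

## MLKNN

For each label (disease) $l$ the model keeps the Laplace-smoothed
prior $P(H_1^l) = (s + \sum_i y_i(l)) / (2s + n)$ and two posterior
tables over the neighbour count $j = 0..k$:

$$P(E_j \mid H_b^l) = \frac{s + c_b^l[j]}{s(k+1) + \sum_{j'} c_b^l[j']}$$

where $c_1^l[j]$ counts training instances *carrying* $l$ that have
exactly $j$ positive neighbours for $l$ among their $k$ nearest
(excluding themselves), and $c_0^l[j]$ counts likewise among instances
not carrying $l$.  The tables therefore sum to the positive and
negative instance counts per label, and each smoothed posterior row
sums to one exactly.  A test instance with $C$ positive neighbours is
scored by the normalized two-hypothesis posterior
$P(H_1)P(E_C|H_1) / \sum_b P(H_b)P(E_C|H_b)$, which lies in $[0,1]$
so that a fixed 0.5 threshold defines the MAP hard label.

Numerical choices: distances are Euclidean on the feature vectors;
neighbour ties at the $k$-th distance are broken by ascending
training-row index, making every fit deterministic; an instance is
excluded from its own neighbourhood during fitting to prevent label
leakage; defaults are $k = 10$, $s = 1$, the canonical MLKNN
settings.  A $k$ larger than the available neighbour pool is a
configuration error, never silently capped -- tiny corpora must pass a
smaller $k$ explicitly.

## The ensemble

Each of the four features gets its own MLKNN model family: the
training drugs are split into five internal folds (stratified by
per-drug positive-label bands 0, 1--2, $\ge$3, so positive mass stays
balanced; a fold left without positives is redrawn once and then
raises an error), one model is fitted per fold, and the out-of-fold
scores form an honest score matrix per feature.  Candidate weight
vectors are enumerated on a simplex grid (step 0.1 over four weights:
286 compositions, plus the exact uniform vector so that complete ties
can resolve to uniform weighting), and each candidate is scored by the
AUPR of its combined out-of-fold matrix over eligible cells pooled
across all labels.  Ties are broken toward the uniform vector, then by
enumeration order.  Because the grid contains the corner vectors, the
tuned fitness can never fall below any single-feature predictor on the
same folds.  At deployment the five fold models of each feature are
averaged (their spread is reported as a per-cell standard deviation
but does not affect calls), the four feature matrices are combined
with the tuned weights, and eligible pairs at or above the threshold
(default 0.5) are called active.  AUPR is the model-selection metric
because positives are rare among eligible pairs and ROC AUC is
overoptimistic under that imbalance.

## Evaluation metrics

Binary metrics (precision, accuracy, recall, specificity, MCC) are
exact transcriptions of the standard confusion-count formulas; any
zero denominator yields `NA` rather than an error.  AUPR is the step
integral of precision over recall across distinct thresholds (flat
scores give the prevalence); AUC uses the Mann--Whitney rank identity.
The five multi-label metrics follow the MLKNN literature, with
coverage reported 0-based (steps beyond the top rank).  Within-instance
score ties are handled by the greater-or-equal rank convention
($\mathrm{rank}(l) = |\{l': s_{l'} \ge s_l\}|$) for average precision,
coverage and one-error, and by half credit for relevant/irrelevant
ties in ranking loss.  This keeps all rank metrics independent of
column order and of any strictly monotone transform of the scores,
and preserves the identities a perfect score matrix must satisfy
(average precision 1, ranking loss 0) -- an average-rank convention
would break the former whenever two relevant labels tie at the top.
Instances with no relevant label are skipped for the rank-based
metrics, with a logged count.

## Validation statistics

* **Tanimoto coefficient** $N_{AB} / (N_A + N_B - N_{AB})$ compares
  disease gene or drug sets by size and overlap.
* **Lin similarity** $IC(\mathrm{lcs}) / (IC(c_1) + IC(c_2))$ with
  $IC = -\log p$ and the least common subsumer chosen as the shared
  ancestor of maximal information content.  The formula is applied as
  stated, under which self-similarity is 0.5; the classical factor-2
  numerator (self-similarity 1) is available via `canonical = TRUE`.
* **Czekanowski--Dice distance**
  $|A \triangle B| / (|A \cup B| + |A \cap B|)$ for GO term sets.
* **Permutation test**: the gene column of the drug--target table is
  shuffled, preserving each drug's number of target slots and the
  global target multiset (the conservative, degree-preserving reading
  of "randomly assigned with targets"); the clinically-active ratio
  over the permuted eligible pairs forms the null.  The empirical
  p-value uses the +1 correction, $(1 + \#\{null \ge obs\}) / (1 +
  n_{perm})$, so it is never zero and bottoms out at $1/10001$ for the
  default 10,000 permutations.
* **Stratified ratio curves** bin eligible pairs by targeted-gene
  count, summed druggability score or ohnolog coverage and report
  per-bin clinically-active and approved ratios with a Spearman trend
  statistic.  Default bins are quartile-based: sparse tail bins are
  pooled because near-empty bins are zero-inflated (their ratio is
  0 with high probability at a ~5% base rate), which would bias the
  rank trend downward under the null.
* **Disease profile correlation**: Spearman rank correlation of two
  diseases' druggability-score vectors over the union of their scored
  genes, absent genes scoring 0; undefined below three genes.

## The synthetic corpus generator

`generate_corpus()` emulates the tripartite structure every stage
consumes: per-database Bernoulli gene--disease associations, uniform
drug target sets, ohnolog pairs over a random gene subset, and
indications drawn from the planted logistic model

$$P(\text{indicated}) = \mathrm{logis}(\beta_0 + \beta_1 f_1/36 +
\beta_3 f_3)$$

applied to eligible pairs.  The link uses `f1` and `f3` only -- the
two headline evidence drivers -- because `f2`/`f4` are deterministic
transforms of them and would confound recovery checks; `f1` is scaled
by 36 to keep slopes interpretable.  Defaults (300 genes, 25 diseases,
200 drugs, inclusion probabilities 0.006--0.012 giving roughly 19
associated genes per disease, 30% of genes in ohnolog pairs, 2--12
targets per drug, $\beta_0 = -3$ for a ~4.7% baseline rate on the
scale of real genetics-implicated clinically-active ratios,
$\beta_1 = 2$, $\beta_3 = 0.5$, and a 25% approval rate among
indicated pairs) were fixed once as the package's study conditions.
`indication_universe = "all"` instead draws indications over every
(drug, disease) pair, making them independent of the target structure;
this null mode is what calibration checks of the permutation test
require, since eligible-only indications are themselves the enrichment
signal the test detects.

What the generator does *not* emulate: correlated database coverage,
disease-ontology structure, chemical similarity between drugs, and
curation biases of real dumps.  Passing tests on generated corpora
therefore demonstrate the machinery's correctness and calibration, not
performance on any real corpus.

## Problem sizes and reproducibility

The test suite exercises corpora between 5 and 500 drugs; ensemble
checks use ten 200-drug corpora, trend-recovery checks one hundred
200-drug corpora, and permutation calibration five hundred 50-drug
null corpora at 99 permutations each, with one 9,999-permutation run
on a 100-drug enriched corpus -- sizes chosen so the whole suite
completes in about a minute while keeping every binomial band tight
enough to be meaningful.  All randomness flows through explicit seeds
(`withr::with_seed`), so datasets, folds, tuned weights and
predictions are bit-reproducible, and `write_dataset()` emits
canonical sorted TSVs so that write--load--write round trips are
byte-identical.

## Known limitations

* The eight-database point ranking is taken as given; re-deriving it
  needs the real clinical corpora.
* MLKNN sees disease-indexed feature vectors, so a disease absent from
  the association table at training time cannot be scored.
* The ensemble keeps its fold models at deployment (their average is
  the final predictor) rather than refitting on all data; this matches
  the averaging design and keeps the internal fitness honest, at the
  cost of models trained on 80% of the drugs each.
* Scores are ranking scores, not calibrated probabilities; on sparse
  corpora few eligible pairs may clear the default 0.5 threshold even
  when the ranking is strong.
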