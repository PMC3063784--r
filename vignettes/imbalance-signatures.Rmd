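---
title: "Selecting protein-imbalance signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting protein-imbalance signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasig)
```

## The problem

Plasma signalling-protein panels are commonly normalized per sample: every
abundance is re-expressed as a z-score relative to the mean and standard
deviation of the whole panel *in that sample*. This makes each value a
statement about relative excess or deficit, not absolute concentration, and
it has a consequence that motivates this package: a sample-level
displacement common to two proteins carries no class information, while the
*difference* between two proteins' z-scores cancels exactly that shared
displacement. Two proteins can therefore be individually useless for
separating cases from controls and still encode a perfectly clean class
signal in their difference — a signalling *imbalance*. `metasig` makes
those imbalances first-class variables ("metafeatures") and selects small
signatures over the expanded feature space with an exact combinatorial
optimizer, evaluated by a diverse classifier panel, with an iterative guard
against mislabelled training samples.

## Pipeline

### 1. Per-sample z-scores

For sample $i$ with panel mean $\mu_i$ and standard deviation $\sigma_i$
over the $n$ base proteins,
$z_{ij} = (x_{ij} - \mu_i)/\sigma_i$. The standard-deviation convention
(sample, $n-1$, the default, or population, $n$) is exposed as an option
because upstream assay pipelines rarely document which they used; the two
differ by a constant row factor and never change which features are
selected, only the numerical scale. A constant row (all proteins equal)
has no z-score and is rejected with the offending sample named.

### 2. Metafeature expansion

Every unordered pair $(a, b)$ of base proteins, $a$ before $b$ in panel
order, contributes a column $z_a - z_b$: $n(n-1)/2$ metafeatures, 7,140
for a 120-protein panel. The mirrored orientation $z_b - z_a$ is the same
variable up to sign — the selection machinery treats them identically, so
only the canonical orientation is generated; orientation is a display
concern. Metafeatures are always computed on z-scores, never raw values,
so that they inherit the per-sample normalization.

### 3. MDL entropy filter

Each column is discretized independently by recursive binary splitting:
the cut minimizing the class-weighted child entropy is accepted when its
information gain exceeds the minimum-description-length cost
$\frac{\log_2(N-1)}{N} + \frac{\Delta}{N}$, with
$\Delta = \log_2(3^c - 2) - [c\,\mathrm{Ent}(S) - c_1\mathrm{Ent}(S_1)
- c_2\mathrm{Ent}(S_2)]$, and recursion continues inside each accepted
interval. Features that earn no cut at all are discarded. Candidate cuts
are midpoints between adjacent distinct values, restricted to class
boundaries (a cut between two pure same-class runs can never be optimal);
equal-gain ties go to the smallest cut value, making the procedure fully
deterministic. Equal values in different classes share an interval. The
filter is a *training-set* construct: classifiers later consume continuous
values, and evaluation cohorts are never discretized. Unlimited recursion
depth is used — the MDL cost is the only stopping rule.

The filter is deliberately re-fit from scratch at every pruning iteration:
removing samples changes the class-entropy landscape, and a feature (even
a forced one) can legitimately stop passing after problematic samples are
removed.

### 4. Exact (α,β)-k feature selection

On the discretized training matrix, every between-class sample pair $p$
has an explaining set $D(p)$ (features whose intervals differ on the two
samples) and every within-class pair $q$ an agreeing set $S(q)$. The
selection problem asks for exactly $k$ features, containing a forced set,
such that every between-class pair is explained by at least $\alpha$
selected features and every within-class pair agreed on by at least
$\beta$, maximizing total pair coverage
$\sum_p |x \cap D(p)| + \sum_q |x \cap S(q)|$ — which is linear in the
selection indicators, each feature weighted by the number of pairs it
explains.

Parameter determination follows a maximal-stringency rule: $\alpha$ starts
at $\min(k, \min_p |D(p)|)$ — a signature of size $k$ can never beat
either bound — and decrements until a feasibility check passes ($\beta$
ignored); $\beta$ then starts at $\min(k, \min_q |S(q)|)$ and decrements
until the joint problem with the chosen $\alpha$ is feasible. The forced
features participate in these checks. $\alpha = 0$ is always feasible, so
the search terminates; an instance with an unseparable between-class pair
(two identical discretized rows in opposite classes) is reported as
infeasible with the pair named, before any solving.

The optimizer is a deterministic branch-and-bound written for this
problem (`src/fs_solver.cpp`). Branching follows the most-constrained
unmet pair (fewest undecided member features) and enumerates which of its
members enters the solution first; once all pair constraints are met the
optimal completion is closed-form (the largest-weight undecided features,
since adding features can only help coverage constraints). Pruning uses
(i) the weight bound — current objective plus the $k-\text{chosen}$
largest undecided weights, activated from the root by seeding with the
feasibility pass's solution, whose objective is recomputed, never trusted;
(ii) per-pair availability (covered + undecided members < required); and
(iii) miss budgets — a pair requiring $r$ of $k$ features tolerates at
most $k - r$ selected features outside its set, checked per pair and in
aggregate. Before the search, two reductions run: pairs requiring
coverage $k$ restrict the support to the intersection of their sets, and
duplicate pair constraints collapse to their strongest requirement.
Tie-breaks everywhere are by weight then original column order, so
repeated runs return the identical optimum; the objective value is
reported so alternative optima remain detectable. A node budget guards
against pathological instances; exceeding it raises an error carrying the
best incumbent rather than silently returning a non-optimum.

Two readings of the objective were possible — a single weighted sum of
difference- and similarity-coverage, or a lexicographic order between
them. The single equal-weight sum is implemented: nothing in the method's
logic distinguishes the two coverage kinds once α and β are fixed, and
equal weights keep the objective interpretable as "pairs explained".

### 5. Classifier panel

Signatures are evaluated by 25 classifiers spanning six families —
naive Bayes and Gaussian discriminants; logistic/regularized-linear
models, SVMs and a small neural network; nearest-neighbour rules with
$k \in \{1, 2, 3, 5\}$ (the $k=2$ member exists to differ from the 1-NN
member; even-$k$ vote ties go to the control class); classification
trees; bootstrap/boosting/forest ensembles; and a nearest-centroid rule
with zero shrinkage so that it performs no feature selection of its own.
Every member must succeed on any two-class training set the pipeline can
produce; quadratic discriminant analysis was considered for the Bayes
family and rejected because it fails outright on within-class
rank-deficient signatures, which legitimately occur when selected
metafeatures share a parent protein.
All members run at their implementation defaults — no tuning and no
cross-validation, since independent evaluation cohorts and a 25-member
average already guard against overfitting any single model. Every member
is seeded and single-threaded, so a report is reproducible bit for bit.
Probability ties predict control. Accuracy, sensitivity (case positive)
and specificity are computed per member and averaged unweighted;
samples labelled `other` are carried through prediction but excluded
from training and from every metric.

### 6. Disagreement pruning

A training sample contradicted by more than a fraction $\tau$ (default
0.30) of the panel under resubstitution is suspect: the flag threshold is
the smallest integer $c > \tau N$, i.e. 8 of 25. All flagged samples are
removed together, and the loop (filter → select → classify → flag)
repeats on the reduced set until: no sample is flagged; the signature
(as a set) reproduces the previous iteration's; the training set would
shrink below `min_train_fraction` (default half the original); or a hard
iteration cap. "Signature unchanged" is checked before the others so a
stabilized model stops the loop even when borderline samples remain
flagged — the behaviour matches the procedure's published description,
where a borderline sample at exactly the rounded-up threshold triggered
one more iteration that reproduced the signature and so ended the run.
Samples are removed, never relabelled.

## The synthetic generator

`generator_config()` describes the study conditions the pipeline is
validated under. Raw abundances are `baseline + effects + noise`:

* a per-sample baseline $\sim N(10, 1)$ shared by all proteins — exactly
  the quantity per-sample z-scoring exists to remove;
* background noise $N(0, \texttt{background\_sd})$ on every protein;
* **single markers**: `single_effect` added in cases (default 1.5 raw
  units against a background SD of 1 — a strong but not trivial marker);
* **imbalance pairs**: both members receive a shared per-sample offset
  $N(0, \texttt{shared\_noise\_sd})$, plus $\pm\texttt{imbalance\_effect}/2$
  with the sign set by the class and opposite on the two members: each
  member's class separation (`imbalance_effect`) is buried under the
  shared offset, while the difference separates by twice the effect with
  only background noise — the pattern metafeatures exist to expose;
* **mislabelling**: `round(fraction * n)` samples drawn uniformly without
  replacement get the opposite observed label. Class sizes are exact and
  the default matches a typical archived-cohort design (43 cases, 40
  controls).

The generator never emits pre-normalized data; the pipeline's own z-score
stage always runs, so its interaction with the planted structure is part
of every test. That interaction is worth understanding: the row
$\sigma_i$ includes the pair columns' shared offsets, so samples with
large offsets have inflated $\sigma_i$ and all their z-scores shrink.
This couples nominally independent columns and can leak weak class
information into pair members themselves. The validation configurations
therefore use enough background proteins (60–80) to stabilize
$\sigma_i$; with fewer than ~20 proteins and large shared offsets the
members themselves become partially informative, which is a property of
per-sample normalization, not a bug.

What the generator does *not* emulate: correlated background biology
(real cytokine co-regulation networks), heavy-tailed assay noise,
batch structure, or an "other dementias" class. Passing tests show the
machinery recovers planted structure under clean Gaussian conditions;
they do not certify performance on real plasma panels.

### Validation conditions

Two headline recovery checks run over 20 seeded replicates each:

* *Imbalance recovery*: 80 proteins, 40 + 40 samples, two planted pairs
  (`imbalance_effect` 1.5, `shared_noise_sd` 6, `background_sd` 0.6), no
  single markers, $k = 4$. In this regime a pair member's class
  separation is ~0.25 background-adjusted SDs (individually below the
  filter's acceptance in the large majority of draws) while the pair
  difference separates by ~3.5 SDs and always passes; the selected
  signature must contain both planted metafeatures in at least 80% of
  replicates.
* *Mislabel recovery*: 40 proteins, 40 + 40 samples, three strong
  imbalance pairs (`imbalance_effect` 2.5 against `background_sd` 0.5 —
  about seven background SDs of separation per pair difference), 5 of 80
  samples mislabelled, $k = 5$, the full 25-member panel, $\tau = 0.30$.
  The pruning loop's removed set must equal the planted mislabelled set
  in at least 80% of replicates. Pair-difference metafeatures are the
  right carrier for this check: per-sample z-scoring divides each row by
  its own panel SD, which caps the achievable class separation of any
  *single* protein (the marker's own variance inflates the denominator),
  whereas a pair difference divides signal and noise by the same factor
  and keeps its full separation. Under a capped separation a handful of
  clean-but-extreme samples per cohort sit close enough to the decision
  boundary to be flagged alongside the genuinely mislabelled ones.

Problem sizes here (and the smaller fixtures in the unit tests) were
chosen as the smallest panels in which the planted structure is
identifiable yet every replicate runs in seconds; the paper-scale
configuration (120 proteins, 7,260 columns, 83 training samples, k = 10
with 5 forced markers) is exercised by the analysis scripts under
`analysis/` and solves to proven optimality in about two minutes.

## Numerical and degenerate-input choices

* Entropies are in bits; probabilities of zero contribute zero.
* Z-scored rows are validated to mean 0 / SD 1 at tolerance $10^{-9}$.
* `read_panel()` refuses missing or non-numeric cells, naming the file
  line and column; silent imputation would corrupt every downstream
  stage.
* `best_cut()` on fewer than two distinct values returns nothing;
  `discretize_feature()` then discards the feature.
* Forcing a feature that failed the filter is a warning plus a drop, not
  an error: the published procedure's own trajectory includes a forced
  feature lost to the filter after pruning.
* The branch-and-bound's variable order is by coverage weight with
  column order as tie-break. Ordering by weight rather than by name
  changes nothing about which optimum is reported on ties *given the
  order is fixed*, and it is what makes the weight bound a prefix sum;
  determinism is the requirement, and it holds.

## Known limitations

* The exact solver's worst case is exponential; dense instances where
  α sits just below its cap are the hard region. The reductions and miss
  budgets handle the instances this pipeline produces (up to ~1,200
  passed features, ~3,400 pair constraints in the full-scale runs), but
  adversarial instances can exhaust the node budget, which is reported
  as an error with the incumbent attached.
* With very few proteins and dominant shared offsets, per-sample
  normalization itself makes pair members weakly informative (see the
  generator section); interpret member-level filter passes in that
  regime accordingly.
* The classifier panel matches the published procedure's *contract*
  (25 members, ≥5 families, defaults, deterministic) but not any
  specific historical implementation of each classifier; per-member
  agreement with other software is neither expected nor claimed.
* Tables comparing signatures on the original study's cohorts require
  that external dataset; given such files, `metric_table()` reproduces
  the layout (avg/stdev of accuracy, sensitivity, specificity over the
  panel) for any supplied signatures.
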