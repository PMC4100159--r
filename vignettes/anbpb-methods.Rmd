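---
title: "Methods: ANBPB encoding and class-weighted classification of S-nitrosylation sites"
author: "snoANBPB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ANBPB encoding and class-weighted classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snoANBPB)
```

# The prediction problem

S-nitrosylation modifies cysteine thiols with a nitric-oxide moiety. Given
a protein sequence and a candidate cysteine, the task is a binary
classification: is this site modified? The only input is local sequence
context, represented as a fixed-length peptide window centered on the
cysteine. This vignette documents the package's model, its assumptions,
the choices made where the design was genuinely open, and what the
synthetic test data do and do not establish.

# Windows

A window of odd length $L$ (default 21) covers $(L-1)/2$ residues on each
side of the site. Sites closer than that to a protein terminus are padded
with the letter `X`, which the package treats as "no amino acid": it is
tallied in no count matrix, looks up a neutral posterior during encoding,
and is excluded from composition denominators. Padding is therefore
informationless by construction — a deliberate choice, since the
alternative (treating `X` as a 21st symbol) would let the classifier learn
terminus proximity as a surrogate feature, which is not sequence
specificity. `PeptideWindowSet` validity enforces a single window length,
contiguous terminal padding only, and a non-`X` center; the extraction
functions additionally require the center to be cysteine (an
`allowAnyCenter` escape hatch exists for exploratory use).

Redundancy control is exact-duplicate removal only (`dedupExact`, first
occurrence of each (residues, label) pair wins; contradictory labels are
kept and flagged). Similarity-based clustering of near-duplicates is the
job of external tools and out of scope here.

# Position profiles

For each class, `countPositions` tallies $X_{ij}$, the count of amino acid
$i \in \{1..20\}$ at position $j \in \{1..L\}$. Two posterior models are
provided:

* **bpb** — raw positional frequencies $X_{ij}/n_j$, where $n_j$ is the
  per-position count of non-`X` residues.
* **anbpb** (default) — each count is referred to the binomial null
  $b(n, p)$ with $p = 1/20$ and standardized by the *observed spread of
  the twenty counts at that position*:
  $$p_{ij} = \Phi\!\left(\frac{X_{ij} - n\,p}{V_j}\right), \qquad
    V_j = \sqrt{\tfrac{1}{20}\sum_{i=1}^{20}(X_{ij}-\bar X_{\cdot j})^2}.$$

Dividing by $V_j$ rather than the binomial standard deviation
$\sqrt{np(1-p)}$ is the "adapted" part: positions where the residue
distribution is flat get a small $V_j$, amplifying whatever contrast
exists, while positions dominated by one residue get a large $V_j$,
damping it. Two readings of the spread were possible — variance or
standard deviation. The package uses the **population standard deviation
(divisor 20)**: the standardized score must be dimensionless in counts for
$\Phi$ to make sense, and a variance denominator would change the score's
scale with $n$. Degenerate positions with $V_j = 0$ (all twenty counts
equal) map to the neutral $\Phi(0) = 0.5$, which also covers the edge case
of an all-`X` column.

The standardization mean is $n\,p$ with the *nominal* number of windows
$n$, even at padded positions where fewer than $n$ real residues were
observed. The class sizes are global constants of a training set and the
padded fraction is small in realistic data; using per-position effective
counts would make posteriors at padded positions incommensurable between
the positive and negative profiles, whose padding patterns differ.

The propensity statistic $r_{xj}$ is the ratio of positional frequencies
(positive over negative), with an optional symmetric pseudocount (default
0, since the statistic is descriptive; the CLI exposes it). Cells whose
denominator frequency is zero at pseudocount 0 are reported as `NA` and
excluded from per-residue averages, as is the center column — it is
constitutively cysteine in both classes and its ratio is uninformative.

# Feature space

A window of length 21 becomes 42 features: the positive-profile posterior
of the window's own residue at each of the 20 *flanking* positions (left
to right), the same 20 from the negative profile, then the two
physicochemical composition fractions (classes
$\{A,C,D,E,H,L,P,Q,S,V,W\}$ and $\{C,D,G,N,P,S,T,W,Y\}$; their
complements are linearly dependent and therefore omitted). The center
position is excluded from the profile features — this is the only way
$2 \times 20 + 2 = 42$ features arise from a 21-mer, and the center
carries no between-class signal anyway. The layout (method, $L$, feature
count, center exclusion) is recorded on every encoded matrix and inside
every trained model, and predictions refuse mismatched layouts.

# Classifier

The decision function is a soft-margin SVM with RBF kernel
$k(x,y) = \exp(-\gamma\|x-y\|^2)$ and class-weighted penalties: errors on
the positive class cost $C\,W_{+1}$, on the negative class $C\,W_{-1}$.
Defaults are $C = 2^{4.5} = 22.6274$, $\gamma = 2^{-5} = 0.03125$,
$W_{+1} = 2$, $W_{-1} = 1$ — the operating point appropriate for the 1:2
imbalance of standard S-nitrosylation training sets. The quadratic program
is solved by libsvm (via `e1071`) at a fixed termination tolerance of
1e-6, recorded in the model. Decision values are *not* produced by
libsvm's predict path: the support vectors, dual coefficients and offset
are extracted at training time and the kernel expansion is evaluated by
the package, so a model serialized to JSON and reloaded reproduces the
original decision values to full serialized precision. A decision value of exactly 0 is called negative — the
conservative choice for site calling, where false positives waste
experimental follow-up.

Two searches mirror common practice: `gridSearchWeight` evaluates
$W_{+1} \in \{1, 1.5, 2, 2.5\}$ under a caller-chosen protocol and keeps
the MCC maximizer (ties toward the smaller weight, i.e. the weaker
intervention), and `gridSearchCostGamma` scans a $\log_2$ grid
($\log_2 C \in \{-5, -4.5, \dots, 15\}$,
$\log_2\gamma \in \{-15, \dots, 3\}$, 15-fold stratified CV) with ties
toward smaller $C$ then smaller $\gamma$ — smaller $C$ means a simpler
model at equal accuracy. The default grid contains the default operating
point.

Reproducibility bounds worth knowing: because the optimizer stops at
tolerance 1e-6, retraining after a row permutation reproduces decision
values only to about 1e-6–1e-5, and the exact-duplication identity
(doubling every row leaves the decision function unchanged) holds exactly
only when no dual variable sits at its box constraint; with active
constraints, duplication is equivalent to doubling $C$.

# Evaluation

`metricsFromCounts` computes Sn, Sp, Acc (percentages) and
$$\mathrm{MCC} = \frac{TP\cdot TN - FP\cdot FN}
  {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}$$
exactly, defining MCC = 0 when any denominator factor vanishes. Display
rounds half away from zero at 2 decimals (percentages) and 4 (MCC),
matching the precision of published tables; base R's round-half-to-even
would disagree with printed values on exact halves.

`countsFromRates` inverts that rounding: given printed Sn (or Acc) and Sp
plus class sizes, it reconstructs the unique integer confusion matrix via
half-up rounding and flags any cell falling outside its class size. This
enables *metric-consistency audits* of published results: recomputing
Acc/MCC from the reconstructed counts and comparing at printed precision.
One audited comparison row prints a sensitivity inconsistent with its own
specificity/accuracy/MCC (the implied value is 32/43 = 74.42%); the audit
reports the discrepancy rather than silently resolving it.

Two protocols are provided. The **jackknife** (leave-one-out) rebuilds,
for every held-out window, both the bi-profile and the classifier on the
remaining windows (`profileScope = "fold"`, the default). The
`"global"` scope builds the profile once on *all* windows and is provided
deliberately as a leakage diagnostic: on label-free data it manufactures
apparent skill, because each held-out window's own residues inflate its
class profile, and the package's tests demonstrate the gap. The
**repeated stratified k-fold** protocol (defaults k = 10, 50 repeats)
reshuffles stratified folds each repeat from a seeded generator and
reports per-repeat metrics pooled from fold counts, with mean and standard
deviation across repeats. `k = n` is accepted as the leave-one-out special
case (stratification is then moot) and reproduces the jackknife counts
with one repeat; any other `k` must not exceed the smaller class size.

# Synthetic data: what it shows and what it does not

`syntheticSpec`/`generateDataset` draw windows with a fixed `C` center and
iid residues per position: negatives from a background distribution
(uniform 1/20 by default, matching the ANBPB binomial null; a
SwissProt-like vector ships as `swissprotBackground`), positives from the
background with planted enrichments. An enrichment $(j, x, \rho)$ sets the
positive-class probability of residue $x$ at position $j$ to exactly
$\rho$ times its background value, renormalizing the other residues —
so the planted positional frequency ratio *is* $\rho$ and the propensity
estimator can be checked for bias against a known truth. $\rho = \infty$
plants the residue deterministically and `exclusive = TRUE` removes it
from negatives at that position, producing a dataset separable on a single
column. A `padFraction` share of windows is terminally truncated to
exercise the padding path.

Four canonical fixtures (fixed seeds, fixed sizes chosen to keep the whole
test-suite within a few minutes on one core) drive the test-suite: a
200+200 **null** (no signal — evaluation protocols should find none), the
2000+2000 **weak-motif** (K enriched threefold at position 3 — recovery of
a known ratio; at this size the ratio estimate carries binomial sampling
noise of sd ≈ 0.37, dominated by the negative-class frequency), the
100+100 **separable** (deterministic exclusive plant — the pipeline should
approach perfect accuracy), and a 100+100 **padded** variant (50%
truncated windows). What passing these fixtures shows: the estimators are
unbiased, the protocols are leakage-free, the pipeline wires together
correctly. What it does not show: performance on real S-nitrosylation
data. Real windows have autocorrelated composition, homologous
near-duplicates, position-coupled residues and non-uniform backgrounds;
none of these are simulated, and similarity-based redundancy reduction is
explicitly out of scope.

# Known limitations

* The bi-profile treats positions independently; coupled residue pairs
  (the basis of competing pair-composition predictors) are invisible to it.
* The ANBPB normal approximation is coarse at small class sizes (the
  binomial with $n < \sim 50$, $p = 1/20$ is visibly skewed), and at
  heavily padded positions the nominal-$n$ standardization overstates the
  expected count.
* The physicochemical class partitions are fixed constants taken from the
  predictor's definition, kept verbatim for comparability even where the
  "positively charged" labelling is chemically unconventional.
* Propensity ratios at cells with zero negative-set frequency are
  undefined at pseudocount 0 and excluded from averages rather than
  smoothed; choose a pseudocount explicitly if full coverage is needed.
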