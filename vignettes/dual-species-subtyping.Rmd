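---
title: "Pathway-level subtype classification across species: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-level subtype classification across species: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualsub)
```

# The problem

The consensus molecular subtypes (CMS1–4) of colorectal cancer were defined
in human cohorts, and the gene-level classifiers built for them transfer
poorly to mouse tumours: ortholog maps are incomplete and one-to-many,
absolute expression scales differ, and individual marker genes often carry
species-specific signal. `dualsub` takes the pathway route: expression is
summarised into per-sample gene-set enrichment scores, and classification
happens in that set space, where only within-sample ranks matter.

# The scoring model

For one sample, genes receive ranks $r_i$ (ties averaged; an all-constant
sample cannot be ranked and is rejected). Walking genes in decreasing rank
order, a set $S$ scores

$$ES(S) = \sum_{i=1}^{N}\left[P_{\mathrm{in}}(i) - P_{\mathrm{out}}(i)\right],$$

where $P_{\mathrm{in}}$ accumulates $|r_i|^\alpha$ over in-set genes
(normalised to total 1) and $P_{\mathrm{out}}$ accumulates $1/(N-|S|)$ over
the rest. Two properties anchor the tests: a singleton set on the top-ranked
gene scores exactly $N/2$ (and $-N/2$ on the bottom gene), and at
$\alpha = 0$ a set and its complement have opposite scores.

**Parameters.** $\alpha$ (unitless, default 0.25) controls how strongly high
ranks are weighted; the default follows the convention of the widely used
implementations of this statistic, since nothing in the method pins it down.
With `normalise = TRUE` (default) the whole score matrix is divided by its
global max − min, giving scores a comparable scale across runs. Sets lose
members under ortholog translation, so genes absent from the matrix are
dropped: below 80% surviving coverage a warning is raised, below 30% an
error — silently scoring a gutted set would be worse than failing.

Because only ranks enter, any strictly increasing per-sample transform of the
data (log bases, affine rescaling, monotone normalisations) leaves scores —
and therefore every downstream call — bit-identical. This is the level at
which cross-normalisation robustness is provable, and the suite asserts it.

# Nearest-template prediction

A template assigns each class a disjoint feature list (genes for the
gene-level option A, set names for the pathway options B/C; a feature in two
classes is uninformative and the container enforces disjointness). Features
are encoded as binary indicator columns, the data are restricted to the
template universe and centered per feature across the cohort (mean by
default, median optional), and each sample is assigned the class minimising
the cosine correlation distance $d = 1 - x\cdot t/(\lVert x\rVert\lVert
t\rVert) \in [0,2]$. Centering matters: on uncentered, all-positive data the
cosine distance degenerates toward the largest class indicator.

**Permutation significance.** The null shuffles the sample's own centered
values across the template universe $B$ times (default $B = 1000$) and
recomputes the distance to the assigned class;
$p = (1 + \#\{d^* \le d_{\mathrm{obs}}\})/(B+1) \in [1/(B+1), 1]$. This
preserves the sample's value distribution exactly. On instances small enough
to enumerate every permutation, the sampled $p$ is checked against the exact
enumeration value. Each sample's permutation stream is seeded from the run
seed plus a hash of the sample's *name*, so p-values are invariant to sample
order and to subsetting.

**Calibration vs selection.** Against a fixed, pre-specified class template,
the permutation p-value is uniform under the null, and the suite checks this
(Kolmogorov–Smirnov against uniform on a no-signal cohort). The p-value the
classifier reports, however, belongs to the *argmin* class — a minimum over
(roughly exchangeable) distances — and is therefore stochastically smaller
than uniform under the null by construction. It should be read as a
goodness-of-assignment score that the FDR gate thresholds, not as a
calibrated tail probability. The gate works: on no-signal cohorts the
end-to-end classified fraction at $q < 0.05$ stays near zero, which the
suite also asserts.

**Degenerate cases.** A sample whose centered vector is all zeros cannot be
scored (distance undefined) and is returned `"unclassified"` with NA
distances; a sample tied between classes (distance gap below $10^{-12}$) is
flagged ambiguous and likewise unclassified rather than broken arbitrarily.
Benjamini–Hochberg adjustment runs across samples within one classification
(not across classes), and calls with $q \ge$ `fdr_threshold` (default 0.05)
become `"unclassified"`. Unit-variance scaling of features is available but
off by default — centering suffices for cosine distance to measure shape,
and scaling amplifies near-constant features.

# Template derivation

**Option A (gene space).** An existing gene-level template is pushed through
the ortholog map. One-to-many expansions keep *all* targets (translated
templates may grow), unmapped markers are dropped and reported per class,
and a target symbol reached from two different classes is removed from both
and logged — such a symbol cannot discriminate. A class left empty is an
error, not a silent shrinkage.

**Option B (z-score rule).** ssGSEA scores are averaged per class, each
set's class-mean row is standardised using the sample SD over the class
means, and a set is class-specific when its z is strictly positive in
exactly one class and strictly negative in all others. Rows with zero SD are
excluded as degenerate. Note what this rule is: a *direction* pattern, not a
significance filter. A set with no real signal still shows the
one-positive/three-negative pattern with substantial probability (about 0.18
for four exchangeable class means), so option B inherits its specificity
from the quality of the input collection, not from the rule itself.

**Option C (four collections).** Curated signatures, hallmark sets and
microenvironment cell-population (MCP) marker sets are each ssGSEA-scored
and kept when one class is significantly higher than *each* other class in
turn — implemented as two-sided Welch t-tests (p < 0.01 by default) plus an
explicit mean-direction check, since unequal variances across subtypes are
the rule and only "higher" is meaningful here. The immune gene panel is
grouped by an L1-penalised *multinomial* logistic model (features
standardised, λ chosen at λ.1se by 10-fold cross-validation with
class-stratified folds under a recorded seed); a gene is assigned to the
class where its coefficient is positive, ties across classes resolved to the
largest coefficient and logged. Multinomial (rather than one-vs-rest) was
chosen because it fits all four classes jointly with one shared penalty,
making the per-class coefficient comparison at a single λ coherent. Each
class's gene group is then wrapped as one set, scored, and retained only if
the same t-test filter assigns it to its own class. The union of survivors
forms the template, with per-step counts and per-set provenance in the
report. MCP signatures are scored with ssGSEA like every other collection —
they are marker gene sets, and scoring them uniformly keeps the filter
comparable across steps.

**Diagnostics.** The reverse check builds per-class meta-signatures — up to
20 genes with linear fold change > 4 (computed as $2^{\Delta}$ of log2
class-mean differences; data are assumed log2) and Welch p < 0.05, ranked by
fold change — scores every sample by the median expression of each list, and
tabulates class-by-class medians; planted markers produce a
diagonal-dominant matrix. Cross-cohort concordance is the per-class Pearson
correlation of mean score profiles over a shared set universe (≥ 3 sets
required).

# The synthetic cohort generator

`simulate_cohort()` emulates a labelled reference cohort: gene baselines
$\mu_g \sim U(4, 10)$ (log2 scale), noise $\mathcal N(0, \sigma^2)$ with
$\sigma = 1$ by default, and each class's planted sets (disjoint by
construction, matching the template invariant) shifted by $+\delta$ in that
class's samples; defaults are 4 classes × 25 samples, 2000 genes, 5 sets of
20 genes per class, $\delta = 1.5$ — a separation comparable to a clear but
not trivial subtype signal. Optional signal-free samples (truth
`"unclassified"`) test the FDR gate. The paired species namespace drops a
gene's ortholog with probability 0.05 and doubles it with probability 0.05,
producing the dropout/expansion bookkeeping real maps show at roughly the
rate seen for well-annotated human–mouse symbol maps.

What it does *not* emulate: negative-binomial count noise (scores are
rank-based, so the marginal family is immaterial to what is being tested),
batch effects beyond monotone per-sample transforms, correlated gene blocks
outside the planted sets, partial or graded class membership, and any real
biology in the set definitions. Passing tests therefore demonstrate the
machinery — scoring, distances, permutation calibration, FDR gating,
derivation filters, ortholog bookkeeping — under clean planted structure,
not classifier accuracy on real tumours.

# Numerical choices

- Distance ties: gap below $10^{-12}$ → ambiguous, unclassified.
- Written results carry 12 significant digits; files round-trip to $10^{-9}$.
- Expression ranks use average ties everywhere (deterministic).
- The ssGSEA implementation is checked against a naive per-position
  running-sum oracle to $10^{-9}$ on random instances, and against closed
  forms exactly.
- Problem sizes in the suite (up to 2000 genes × 120 samples, B = 1000–2000
  permutations, 20 derivation replicates) were chosen as the smallest at
  which the asserted recovery and calibration properties are stable.

# Known limitations

- The reported per-sample p-value is selection-biased under the null (see
  above); interpret it through the FDR gate.
- The z-score rule does not control false selection on noise collections.
- Ortholog handling is purely map-driven: no synonym or alias resolution,
  no case folding (human `TGFB1` and mouse `Tgfb1` are distinct strings by
  design — silent case-folding manufactures false ortholog hits).
- Missing expression values are rejected, never imputed.
- Shipped templates and collections in examples are synthetic illustrations;
  deriving production templates requires the user's own reference cohort and
  curated collections.
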