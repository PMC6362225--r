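---
title: "Methods: staged analysis of structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged analysis of structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connstage)
```

# Scope and data model

`connstage` starts where tractography ends: its inputs are per-subject
square, symmetric, zero-diagonal matrices of streamline counts between
atlas regions, optional per-edge tract-average gFA (unitless, in [0, 1])
and ADC (mm²/s) maps defined exactly on the support of the weights, and a
subject table with an ordered clinical label (HC < II < IIIa < IIIb <
IIIc) and covariates. Upstream MRI processing — segmentation, parcellation,
diffusion reconstruction, tractography — is out of scope by design. The
central container (`CohortConnectomes`) stacks the matrices into a
regions × regions × subjects array aligned with the subject table; validity
methods enforce symmetry, nonnegativity and the scalar-map support
convention at construction, so downstream code can assume them.

# The analysis pipeline

## Consistency masking

Spurious streamline connections are a known bias of tractography-derived
networks, so edges are kept only when present (count > 0) in at least a
threshold fraction of subjects. "Presence" is strict positivity — the only
information available in a count matrix. The default threshold is 0.5 with
the tie retained (an edge present in exactly half the cohort survives),
matching a strict "discard if present in *less than* 50%" rule. The mask
is computed once on the full analysis cohort, patients and controls
together, and reused by the sensitivity subsets (scanner-only,
right-handers-only); a per-subset mask is available via the configuration
but changes the edge set between re-analyses, which complicates
comparison.

## Network measures

Nodal strength is the weighted degree s<sub>i</sub> = Σ<sub>j</sub>
w<sub>ij</sub>; total strength S = Σ<sub>i&lt;j</sub> w<sub>ij</sub>
(so Σs<sub>i</sub> = 2S identically). Tract-average gFA/ADC per subject
are plain (unweighted) means over that subject's present, retained edges;
a streamline-count-weighted mean is available
(`edgeAverage = "count_weighted"`) since either reading of "whole-brain
tract average" is defensible. When no edge survives, these averages are
`NA`, never 0 — a zero would silently masquerade as a valid measurement.

Two supplementary measures have genuinely open definitions for weighted
streamline networks, and the package commits to standard forms: global
efficiency uses inverse-weight edge lengths ℓ<sub>ij</sub> =
1/w<sub>ij</sub> and averages 1/d<sub>ij</sub> over ordered pairs
(unreachable pairs contribute 0); clustering uses the Onnela
geometric-mean triangle intensity on weights normalized by the network
maximum, with nodes of binary degree &lt; 2 scored 0. Both agree with
brute-force path/triangle enumeration in the test suite. Hubs are flagged
when cohort-mean nodal strength exceeds the across-region mean by more
than one SD (`sdFactor` configurable; rich-club analysis is out of scope).

## Covariate adjustment and effect sizes

Age, gender, handedness and a scanner-upgrade flag enter every analysis.
Categorical covariates are 0/1 indicators with fixed reference levels
(female, left-handed, pre-upgrade) — arbitrary but deterministic, so signs
are reproducible. Group tests are sequential-F ANCOVAs with covariates
entered before the group factor; effect sizes are Cohen's *d* between
*covariate-only* residual distributions (the two-step reading of
"d between GLM residuals, after correcting for covariates"), signed as
first-listed group minus second, so reduced connectivity in patients gives
positive d for HC-vs-patient contrasts. Covariate columns that are
constant within an analyzed subset (handedness among right-handers only)
are dropped rather than treated as errors; genuinely collinear designs
abort with the offending columns named.

## Ordered trend testing

The Jonckheere-Terpstra statistic sums pairwise exceedance counts over
ordered group pairs, with ties counted one half. A decreasing alternative
is evaluated by reversing the group order. The p-value is one-sided — the
alternative is directional by construction. Exact inference enumerates all
distinct assignments of the pooled values to the group sizes whenever
their number is at most `enumerationCap` (default 10⁶), so small fixtures
are always exact regardless of shape; otherwise a tie-corrected normal
approximation without continuity correction is used (the standard
tie-corrected variance with the three Hollander-Wolfe terms). Fully
constant data make the permutation null degenerate (SD 0); the package
returns p = 0.5 as a documented convention rather than the vacuous
enumeration value of 1, so mass-univariate scans are not biased by dead
nodes. Since the test has no native covariate adjustment, the nodal scan
applies it to covariate-residualized strengths by default
(`onResiduals = FALSE` reverts to raw values; the choice is exposed
because the source analyses are ambiguous on this point).

The scan collapses IIIa/IIIb/IIIc into stage III (the four-way split is
reserved for the discriminant analysis), tests every region for a
decreasing trend, and defines the *vulnerable set* at uncorrected
p &lt; α (default 0.05), with Benjamini-Hochberg flags at q = 0.05
reported alongside but not used for membership — mirroring how the
analysis is used to select a subnetwork for subsequent coupling tests
rather than to make per-region claims. Vulnerable-subnetwork strength is
the sum over edges with *both* endpoints in the set; the remainder is
total minus that sum, so cross edges count toward the remainder (the more
conservative split: cross edges share one vulnerable endpoint, and
assigning them to the subnetwork would blur its selectivity).

## Sparse discriminant analysis

Stage classes (II/IIIa/IIIb/IIIc, patients only) are characterized by
sparse linear discriminant directions over column-standardized nodal
strengths, via penalized optimal scoring: for each direction q = 1..Q
(Q = K−1 = 3), alternate (a) an elastic-net regression of the scored class
indicators Yθ<sub>q</sub> on X — ridge penalty λ plus an ℓ₁ path on
ridge-augmented rows, taking the least-penalized path point with at most
*m* nonzero loadings — and (b) a score update θ<sub>q</sub> ←
D<sub>π</sub>⁻¹YᵀXβ<sub>q</sub>/n, orthogonalized against the constant
vector and previous scores in the class-proportion inner product and
normalized. Convergence is declared at relative score change &lt; 10⁻⁶
(cap 200 iterations; non-convergence is flagged on the model, not an
error — near-degenerate discriminant eigenvalues make the score vector
rotate slowly inside a subspace that is itself stable). Initialization is
deterministic (leading singular vectors of the proportion-weighted
class-mean matrix), and each β column's dominant loading is made positive,
so fits are bit-reproducible without a seed. With the full feature budget
and vanishing ridge, optimal scoring is the classical LDA subspace, which
the tests verify against a generalized-eigenvalue oracle.

Defaults λ = 10⁻³ and m = 15 nonzero loadings per direction are package
choices: the ridge stabilizes the p ≈ n regression (82 regions, 71
patients) and a budget of ~15 regions per direction keeps loadings
interpretable as circumscribed subnetworks; both are exposed in the
configuration. Evaluation is leave-one-out: standardization and the whole
fit (including the sparsity pattern) are recomputed per fold — no
leakage — and the held-out subject is classified by the Euclidean nearest
class centroid in LDD space (ties break toward the first class in stage
order). The error is compared with chance (1 − 1/K) and with the
leave-one-out error of the majority-class predictor computed by the same
machinery; the confusion matrix is row-normalized to percentages of true
class size.

# The synthetic cohort generator

No patient data are distributed, so the generator supplies cohorts with
the statistical structure the analysis assumes, plus the planted truth
needed to score recovery. It emulates: the reference cohort composition
(76 HC, 25/17/17/12 patients), an 82-region network at ~30% edge density
with distance-decaying connection probability and log-normal
proximity-scaled integer weights, a 22-region vulnerable set whose
internal edges attenuate with stage rank (HC 0, II 0.5, stage III 1.0 of
δ<sub>max</sub> = 0.15 log units), class-specific profiles *inside* the
vulnerable set (one half affected in IIIa, the other half shared by IIIb
and IIIc — shared deliberately, so an overlapping IIIb/IIIc signature is a
recoverable property), diffuse per-rank gFA decrease and ADC increase,
age and scanner-upgrade effects multiplying all edges, demographic and
clinical marginals drawn to match the reference cohort table, and a
processing-speed T-score coupled to vulnerable-subnetwork strength.

Free parameters not fixed by the emulated design were chosen once on
realism grounds: edge-level log-normal noise SD 0.2 (≈20% CV, the order of
streamline-count test-retest variability); age slope −0.3%/year around the
cohort mean age; scanner factor 1.03 (≈3%, enough that covariate
adjustment has real work to do); cognition coupling of 4 T-points per SD
of vulnerable strength with residual SD 8.25, i.e. a planted within-group
correlation of 0.44 and a total within-group SD near the reference table's
9; per-stage speed decrements 9/18/16/11 T-points. The coupling targets
vulnerable-*specific* variation: the shared covariate factor is divided
out and the z-score taken within stage group, so the remainder network is
genuinely null for cognition and group means are set by the stage shifts
alone. Counts are rounded log-normal rather than negative-binomial —
only the ordering and effect-size structure matter downstream, and the
noise family is documented as replaceable.

What the generator does **not** emulate: anatomical geometry beyond
distance decay, distance-dependent false-positive structure, correlated
(subject-global) weight noise, diagnostic heterogeneity, or any
longitudinal process. Passing recovery tests therefore shows the pipeline
detects the planted effect structure at realistic sizes and noise — not
that real acquisitions satisfy these assumptions.

# Numerical conventions and test scales

Degenerate inputs have explicit conventions: empty networks give zero
strengths and `NA` tract averages; JT on constant data gives p = 0.5;
zero pooled SD flags Cohen's d as `NA`; constant feature columns are
dropped (with a warning) before discriminant fitting; complete separation
in logistic fits triggers a flagged small-ridge (10⁻⁴) IRLS refit;
nearest-centroid and majority-vote ties break toward the first class in
stage order. Exact JT enumeration switches to the normal approximation at
the enumeration-cap boundary, not a sample-size rule. Missing DUP/CPZ
values are excluded pairwise from correlations; nothing is imputed.

The test suite checks oracle equivalences exhaustively at small sizes
(all-relabeling JT enumeration at n ≤ 8; step-up FDR at length ≤ 6;
brute-force paths/triangles at ≤ 7 nodes), calibrates the nodal scan's
false-positive rate on ~2,000 null node-tests (25 null cohorts of 82
regions), and scores recovery on 20-50 default-configuration cohorts
(vulnerable-set sensitivity/specificity, cognition-coupling selectivity,
discriminant error against the naive baseline and the IIIc→IIIb confusion
pattern). These sizes are the package's chosen compromise between
Monte-Carlo resolution and a test suite that runs in minutes on one CPU.

# Known limitations

- The nodal scan is node-level; an edge-level mass-univariate scan and
  permutation-based family-wise error control are documented extensions.
- The discriminant analysis is exploratory: with 71 patients and 82
  features, leave-one-out error quantifies class separability, not
  generalizable prediction; no nested hyperparameter search is performed
  by default.
- Normalized rich-club curves, mixed-effects and Bayesian variants, and
  figure rendering are out of scope.
- The exact definitions some upstream analyses used for efficiency,
  clustering, tract averaging and the discriminant penalty are not
  recoverable from their descriptions; the package's choices above are
  standard forms, stated as assumptions and exposed as options where
  reasonable.
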