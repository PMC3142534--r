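---
title: "Patient networks from tumor-marker staining: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient networks from tumor-marker staining: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmanet)
```

## The problem

Tissue-microarray (TMA) studies score the percent of tumor cells staining
for each of a modest panel of protein markers ("pos", averaged over
replicate cores into "pos.mean"), across tens to hundreds of patients.
`tmanet` treats the *patients* as the nodes of a weighted correlation
network: patients whose staining profiles are positively correlated across
the panel are strongly connected, the network is clustered into patient
modules, and the modules — once ranked by crude mortality — become candidate
prognostic groups. A classification tree then compresses the full-panel
grouping into a rule over two or three markers with *percentile* thresholds,
which transfers to other cohorts and even other platforms (expression
arrays), because each threshold is re-derived from the target dataset's own
marker distribution.

## The model, step by step

**1. Network.** For patients $i,j$ with staining profiles $x_i, x_j$, the
signed adjacency is

$$a(i,j) = \left(\tfrac{1}{2} + \tfrac{1}{2}\,\mathrm{cor}(x_i, x_j)\right)^{\beta},$$

with Pearson correlation over the markers observed in *both* patients
(pairwise-complete; no imputation at this stage). The default
$\beta = 10$ with the signed option emphasises strong positive
correlations — anti-correlated patients are molecularly dissimilar and get
adjacency near 0. The unsigned variant $|\mathrm{cor}|^\beta$ is available
but not the default. Clustering uses the dissimilarity
$\mathrm{dissA} = 1 - a$, which satisfies $a + \mathrm{dissA} = 1$ exactly.
Patient pairs sharing fewer than `min_overlap` (default 5) observed
markers, or involving a zero-variance profile, have no estimable
correlation; `build_patient_network()` fills them with the median
off-diagonal adjacency and warns, since average-linkage clustering needs a
complete dissimilarity. The source data do not dictate a policy here; the
fill is deliberately neutral and logged.

**2. Modules.** Average-linkage (UPGMA) hierarchical clustering of
`dissA`, then an adaptive branch cut: the tree is cut at the $q$-quantile
of its merge heights, $q \in \{0.50, 0.75, 0.90, 0.95\}$ indexed by
`deepSplit` 0–3, and every branch smaller than `minClusterSize` (default 2)
is absorbed into the module with the smallest average dissimilarity to it.
This is a simplified quantile-height variant of dynamic tree cutting: it
keeps the adaptive-height and minimum-size semantics but does not reproduce
the published algorithm branch for branch. The package's recovery tests are
therefore phrased against *planted* structure (adjusted Rand index on
synthetic cohorts), not against another implementation's branch labels —
the original study's sixteen pre-merge modules are not reproducible without
its undeposited data in any case.

**3. Eigensamples and merging.** Each module is summarised by its
*eigensample*: the first right-singular vector of the row-standardised
members × markers submatrix — a marker-length profile interpretable as a
weighted average of the member profiles. Rows (patients) are standardised,
not columns, because column-centring within a module would subtract
exactly the shared profile the eigensample is meant to capture. Missing
entries are median-imputed per marker within the module first, and the
sign is oriented so the mean correlation with member profiles is
non-negative. Modules whose eigensamples satisfy
$1 - \mathrm{cor}(\mathrm{ME}_a, \mathrm{ME}_b) < \texttt{cutHeight}$
(default 0.15) are merged iteratively, closest pair first, recomputing
eigensamples after every merge. `optimize_merge()` instead selects
`cutHeight` from a grid by minimising the log-rank p-value of the merged
modules against survival; because the grouping is then chosen with respect
to the outcome, the result always carries `overfit = TRUE` and its p-value
is descriptive, not inferential — honest evaluation requires independent
data, which is what the validation module is for.

**4. Mortality groups and rule extraction.** Modules are ranked by crude
mortality (deaths/size, ties to the larger module) and labelled
`low`/`moderate`/`high` when there are three. A CART classification tree
(Gini impurity) approximates this grouping from the marker matrix; raw
cutpoints are converted to empirical percentiles (fraction of observed
training values strictly below the cutpoint), which reproduces the tree's
training assignments exactly under the type-7 quantile convention used at
application time. The packaged `wgcna_star_rule()` encodes the published
three-marker approximation: **high** if p53 > 75th percentile and
Na-K ATPase-β1 ≤ 33rd; **moderate** if p53 ≤ 75th and TGF-β receptor II
(cytoplasmic) > 66th; **low** otherwise, including the high-p53 /
high-Na-K-ATPase branch. The cytoplasmic TGF-β receptor II compartment is
the default (the nuclear measurement exists too); the marker column names
are arguments, so either can be supplied.

**5. The stepwise comparator.** `build_cox_rule()` implements the
conventional multimarker pipeline used as a benchmark: every marker is
dichotomized at the threshold minimising its univariate Cox Wald p-value
(scanning midpoints of consecutive distinct values, at least 5 patients a
side, ties toward the balanced split); markers reaching p < 0.05 enter a
backward stepwise Cox model pruned at 0.05; a classification tree
(complexity 0.1) over the *retained* markers against the death indicator
defines the final groups, with leaves re-labelled by training mortality
rank. The spec of this step is stated circularly in places; fitting the
tree to the death indicator and ranking leaves by observed mortality is the
design adopted here, and it reproduces planted two-marker rules (topology
and percentiles within ±5) in simulation. No multiplicity correction is
applied across the per-marker scans — that mirrors the benchmark being
modelled and is a documented property, not an oversight.

**6. Validation.** A rule is applied to an independent expression dataset
for every combination of probes representing its markers (three markers ×
two probes = eight rule versions). Percentiles are recomputed on the
validation dataset. A Cox model with the low group as reference yields
hazard ratios and Wald p-values for the moderate and high groups; a
combination *validates* when the high-group p-value is below α = 0.1. The
moderate-group p-value is reported but does not gate the flag, matching
how the published validation was read. An empty high group is
not-estimable and never validates; an empty reference group is an error.

## Survival statistics

Kaplan–Meier, k-group log-rank (hypergeometric variance), Kruskal–Wallis
with tie correction, and Fisher's exact test (enumeration when the
margin-consistent table count is tractable, seeded Monte Carlo otherwise)
are delegated to the standard `survival` and `stats` machinery behind thin,
typed wrappers; the test suite cross-checks each against independent
brute-force oracles (permutation/hypergeometric sums, full-table
enumeration, grid-maximised partial likelihood). Cox models use Efron tie
handling — monthly follow-up times produce heavy ties, and Efron is the
modern default — and report the generalized
$R^2 = 1 - \exp(-2(\ell_1 - \ell_0)/n)$ alongside complete-case $n$.
Degenerate covariates raise errors rather than silently dropping, and a
monotone partial likelihood (perfect risk-set separation) is reported as a
non-finite-MLE error; the dichotomization scan treats such thresholds as
non-qualifying.

## The synthetic cohort generator

No TMA data of this kind are publicly deposited, so the generator *is* the
test bed, and its defaults are the study conditions: 82 patients, 26
markers, three groups of 56/14/12, within-group profile correlation 0.7,
~6% missingness, administrative censoring at 121 months plus uniform loss
to follow-up, and per-group hazards calibrated (closed form + root
finding; see `calibrate_hazards()`) so expected observed mortality is
5.4%/22%/50%.

Staining values are built as group latent profile + noise in a Gaussian
space, then pushed through a Beta quantile transform
($100\,\mathrm{qbeta}(\Phi(z),\, s,\, 2s)$, default $s = 0.7$) and rounded
to whole percents. This reproduces the right skew and the boundary
pile-up at 0/100 seen in real percent-staining panels while keeping the
transform monotone, so rank-based constructs (percentile rules) are
unaffected and Pearson profile correlations are attenuated only mildly
(~0.04 at the 0.7 level, inside the generator's documented −0.1
tolerance). Missingness is MCAR by default; an optional survival-linked
mode inflates the rate for early deaths to power-test the
missingness-vs-survival check. Expression cohorts for validation emit each
rule marker as correlated continuous probe columns (probe–probe
correlation ≈ 0.85) with survival tied to the rule-assigned group.

What the generator does *not* emulate: spot-level imaging artifacts,
array-normalisation or batch effects, informative censoring, and any
particular inter-marker correlation structure (the published panel's is
uncharacterised, so it is left as a parameter rather than fixed).
Consequently, passing recovery tests demonstrate that the pipeline
recovers *planted correlation structure under realistic marginals and
censoring* — not that it would recover subtypes in any given real cohort.

## Numerical choices and degenerate inputs

- Percentiles use the type-7 (linear interpolation) empirical quantile;
  comparisons are strict `>` on the high side and `≤` otherwise. The
  convention matters less than applying it consistently on both the
  training and application sides, which the round-trip tests enforce.
- Tree pruning is on the impurity scale: a split is kept only when its
  count-scale Gini improvement is at least `complexity` × root impurity.
  (A cost-complexity parameter on the misclassification-risk scale keeps
  noise splits far more often at the same nominal value.)
- UPGMA merge order for tied heights follows `stats::hclust`; ties have
  measure zero for real-valued staining data and all oracle tests use
  continuous dissimilarities.
- Simulation sizes in the test suite (500 null replicates for test
  calibration, 50 seeds for recovery, 200 seeds for validation
  false-positive rates) were chosen to give binomial standard errors
  comfortably inside the asserted tolerances while keeping the default
  suite around a minute.
- Known arithmetic quirks of the motivating tables (a printed 22% beside
  4/14 counts; "2, 4 and 8" missing values beside a 66-patient complete
  case count) are inherited inconsistencies of the source material; the
  package asserts only the reproducible arithmetic.

## Limitations

Group mortality ordering at the default cohort size is noisy: with a
14-patient moderate group, the strict low < moderate < high ordering of
*observed* rates holds in about 82% of seeds (it exceeds 99% at three
times the cohort size); analyses of cohorts this small should lean on the
log-rank test rather than point mortality ranks. The adaptive cut is a
deliberate simplification of dynamic tree cutting, and the mortality-
optimised merge is, by construction, overfit — both are flagged in output
metadata. Validation power for the high-mortality group is limited by that
group's size (~8% of a cohort under the default rule), about 74% at
n = 150 under strong planted effects.
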