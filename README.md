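# tmanet

Patient-network analysis of tumor-marker tissue-microarray (TMA) data.

Most TMA analyses ask whether a single marker predicts outcome. `tmanet`
is for the complementary question: given a panel of markers scored as
percent of tumor cells staining ("pos.mean", 0–100) on a modest cohort,
do the *patients* fall into molecularly coherent groups with distinct
survival — and can those groups be compressed into a portable rule over a
handful of markers? It is aimed at biostatisticians and translational
researchers working with multimarker immunohistochemistry panels, and it
ships a synthetic-cohort generator so every stage is testable without
patient data.

## The method

Patients are the nodes of a signed weighted correlation network. For
staining profiles $x_i, x_j$ the adjacency is

$$a(i,j) = \left(0.5 + 0.5\,\mathrm{cor}(x_i, x_j)\right)^{\beta}, \qquad \beta = 10,$$

so strongly positively correlated patients are connected and
anti-correlated ones are not (soft thresholding). The dissimilarity
$\mathrm{dissA} = 1 - a$ feeds average-linkage clustering; an adaptive
branch cut (quantile-height with a minimum module size) defines patient
modules; modules with correlated eigensamples (first principal component
of the module's staining submatrix) are merged; and the surviving modules,
ranked by crude mortality, become `low` / `moderate` / `high` groups.
A classification tree then approximates the groups with a short decision
list over **percentile** thresholds — e.g. the packaged three-marker rule:
high mortality if p53 > 75th percentile and Na-K ATPase-β1 ≤ 33rd;
moderate if p53 ≤ 75th and TGF-β receptor II > 66th; low otherwise.
Because thresholds are percentiles, the rule transfers to independent
cohorts and platforms: on an expression dataset every probe-set
combination for the rule's markers is enumerated and checked with a Cox
model (low group as reference; a combination validates when the
high-group p-value is below 0.1). A conventional comparator — optimal
dichotomization, backward stepwise Cox, classification tree — is built by
`build_cox_rule()` for side-by-side evaluation.

## Worked example

```r
library(tmanet)

d   <- generate_tma_dataset(synth_config(seed = 2))   # 82 x 26 synthetic TMA
res <- run_pipeline(pipeline_config(seed = 2), data = d)
print(res)
#> Patient-network pipeline result
#>   modules: 3 pre-merge -> 3 after merging at cutHeight 0.15
#>     group     summary
#>       low 2/56 (3.6%)
#>  moderate  2/14 (14%)
#>      high  6/12 (50%)
#> Log-rank p = 6.01e-05
#> Threshold rule
#> ER_alpha @ 68th percentile
#>   <=: -> low
#>    >: BetaCatenin @ 43.8th percentile
#>     <=: -> moderate
#>      >: -> high
```

The network found three patient groups whose observed mortality climbs
from 3.6% to 50% (log-rank p = 6×10⁻⁵ — descriptive, since the merge is
tuned on the training cohort), and the tree compressed the 26-marker
grouping into a two-marker percentile rule. The rule's groups agree with
the network groups for 76 of 82 patients:

```r
print(res$crosstab_rule_vs_network)
#>           b
#> a          low moderate high
#>   low       53        3    0
#>   moderate   3       11    0
#>   high       0        0   12
#> N = 82, agree = 76 (93%), disagree = 6 (7.3%)
```

and on a synthetic expression cohort (two probes per marker, so every
probe combination is checked) the high-mortality group carries the risk:

```r
head(res$validation[, c("combination", "n_high", "hr_high", "p_high", "validates")], 3)
#>   combination n_high  hr_high       p_high validates
#> 1           1     24 8.154590 2.235123e-05      TRUE
#> 2           2     25 6.527073 3.054343e-04      TRUE
#> 3           3     27 8.628550 1.035398e-05      TRUE
```

Against the generator's planted truth this run recovers the groups with
adjusted Rand index 1.0. Individual stages are available as plain
functions (`build_patient_network()`, `dynamic_cut()`, `merge_modules()`,
`label_mortality_groups()`, `apply_threshold_rule()`, `validate_rule()`,
…) and all tabular inputs/outputs are delimited text; see the vignette in
`vignettes/patient-network-analysis.Rmd` for the full model description
and design notes.

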