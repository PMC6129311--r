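---
title: "Tissue-specific gene set weights: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-specific gene set weights: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissueweights)
```

## The model

`tissueweights` scores how specific each gene set in a collection is to
each human tissue, using two independent evidence channels of the kind
the Human Protein Atlas distributes: bulk RNA-seq expression (FPKM-like
units) and immunohistochemistry (IHC) protein detection calls on the
ordinal scale `Not detected < Low < Medium < High`.

**Gene level.** The weight for gene $i$ in tissue $t$ is
$w^g_{i,t} = e_{i,t} \, a_{i,t}$, where $e_{i,t}$ is the expression
fold-change of the gene in tissue $t$ relative to its mean across *all*
tissues in the table, and $a_{i,t} \in \{0,1\}$ indicates protein
detection at `Low` or above. The product demands corroborating evidence:
high RNA with an explicit `Not detected` protein call is zeroed, and a
detected protein with no transcript signal contributes nothing either.

Missing data are handled asymmetrically, and deliberately so:

* a missing RNA measurement sets $e_{i,t}=0$ — the gene is assumed not
  expressed there, and the missing cell also contributes 0 to the
  across-tissue mean in the denominator;
* a missing IHC record sets $a_{i,t}=1$ — absence of protein evidence
  leaves the decision to the RNA channel rather than vetoing it.

A gene whose mean expression is zero (all zero or all missing) gets
$e = 0$ in every tissue; the fold-change is simply undefined there and
zero is the only value consistent with "no evidence of expression".

**Set level.** For set $j$ with members $\mathbf m$ inside a universe of
$p$ genes, the tissue weight is the $-\log$ p-value of a competitive
one-sided two-sample t-test of mean member weight exceeding mean
complement weight. The competitive form matters: it asks whether the
set's genes are *more* tissue-active than the rest of the collection's
universe, not merely active. The test assumes (approximately) exchangeable
dependence among gene weights; no inter-gene correlation adjustment is
made, so sets whose members are unusually correlated will also score
high. For ranking tissue-specific biology this behaviour is acceptable
and even useful, but it is worth remembering when weights are compared
across collections.

**Multi-tissue level.** For a tissue group $\mathbf t$, the aggregate
weight is $w^m_j = \min_{t \in \mathbf t} w^s_{j,t}$ by default: a set
ranks highly only if it shows at least a basic level of activity in
*every* tissue of the group, which is the behaviour wanted when
profiling, say, the tissues jointly affected by a systemic disease. Mean
and median aggregators are available through the `aggregate` argument
for analyses that tolerate absence in a minority of tissues.

**Weighted FDR.** Given p-values from any external gene set testing
method, weights are standardized to mean one,
$w^{s*}_j = w^s_j / \bar w^s$, weighted p-values formed as
$p^*_j = p_j / w^{s*}_j$, and ordinary Benjamini–Hochberg applied to
$p^*$. Mean-one standardization plus independence of the weights from
the p-values under the null are exactly the conditions under which this
weighted BH retains valid FDR control; because the tissue weights are
computed from reference atlas data, not from the experiment under
analysis, the independence condition holds by construction.

## Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| `log_base` | natural log | Sets the scale of every $w^s$; base 10 divides all weights by $\ln 10$. Natural log is the default because weight magnitudes in the hundreds arise naturally from t-tails over thousands of genes. |
| `var_equal` | `FALSE` (Welch) | Member and complement sizes are wildly unbalanced (tens vs. thousands), so unequal-variance with Welch–Satterthwaite df is the safer default; pooled variance is available. |
| `min_set_size` | 2 | The minimum for a t-test. Sets smaller than this (after universe intersection) get an *undefined* weight plus a flag — not zero, which would conflate "untestable" with "no tissue specificity". |
| `restrict_to_measured` | `FALSE` | The test universe is the collection's own universe; genes absent from the expression/IHC tables enter with weight 0 via the missing-data rules. Setting `TRUE` intersects the universe with measured genes instead. |
| `drop_uncertain` | `FALSE` | Optionally discards IHC records labelled `Uncertain` before deriving activity. |
| `aggregate` | `"min"` | Multi-tissue aggregator; `"mean"`, `"median"` alternatives. |
| `q_threshold` | 0.2 | Reporting threshold for discovery counts in `glance()`. |

Ranking ties are always broken lexicographically by set name, so reports
are byte-reproducible.

## Numerical choices

* Tail probabilities are computed as the log survival function of the t
  distribution (`pt(log.p = TRUE)`), never by exponentiating and
  re-logging, so any finite t statistic yields a finite weight. The test
  suite checks agreement with an independent closed-form route through
  the regularized incomplete beta function at relative tolerance
  $10^{-9}$ on the log scale.
* Weighted p-values are capped at 1 before BH (the step-up procedure is
  defined on $[0,1]$), and a zero standardized weight maps to
  $p^* = 1$: a set with zero prior weight simply cannot be discovered,
  which keeps the vector finite and the discovery semantics clean.
* Degenerate competitive tests — fewer than two genes on either side, or
  both groups with zero variance — return an undefined weight plus a
  `degenerate` flag.
* Weight matrices are written with 17 significant digits and re-read
  through base R's `strtod`, making write/read round trips bit-exact.
* Sets present in a p-value table but missing from the weights are an
  error by default; dropping them is opt-in (`unmatched = "drop"`),
  because silently imputing a weight would disturb the mean-one
  condition unpredictably.

## Identifier spaces

Gene matching is exact string equality after whitespace trimming, with
an optional upper-casing flag. MSigDB collections use gene symbols while
HPA tables use Ensembl identifiers; because no universally correct
built-in conversion exists, `map_gene_ids()` takes an explicit
two-column mapping supplied by the user, expands one-to-many matches,
and reports members it had to drop.

## What the synthetic generator does and does not emulate

`simulate_hpa()` produces the same three inputs the readers accept:
log-normal baseline expression per (gene, tissue) — mimicking the
right-skew of FPKM data — with planted gene blocks multiplied by a
configurable fold in a target tissue; IHC calls whose detection
probability is, by default, tilted towards higher-expressed genes within
each tissue (a caricature of real RNA–protein concordance, toggleable to
independence); planted genes always detected in their target tissue; and
decoy sets drawn uniformly from the gene universe, size-matched to the
planted sets. `simulate_pvalue_study()` generates null p-values from
Uniform(0,1), alternatives from Beta(0.1, 1), and raw weights whose
association with the truth labels is favorable, independent or adverse.

What these generators deliberately do **not** model: HPA cell-type
granularity and reliability scores (beyond one optional column),
realistic inter-gene correlation, batch structure, or any particular
tissue's biology. Passing tests on synthetic data therefore demonstrate
the statistical machinery — missing-data rules, test calibration, FDR
control, recovery of planted signal — not the biological validity of
weights computed from any specific atlas release.

## Problem sizes used by the test and acceptance runs

The package validates itself at sizes chosen to exercise the statistics
while keeping a full run comfortable on a laptop: 1000 random
member/complement splits for the oracle comparison; 200 replicates of
2000 all-null sets for FDR control at $q = 0.1$ (bounded by three
Monte-Carlo standard errors above the target); 200 replicates of 1000
sets at 10% non-null for the power-direction checks; and 100 simulation
seeds of 2000 genes × 10 tissues with a 20-gene set planted at fold 5
among 100 decoys, requiring the planted set to rank first in at least
95% of seeds.

## Limitations

* Atlas measurements are finite-sample estimates of mRNA and protein
  abundance, which are themselves imperfect proxies for functional
  activity; weights inherit that uncertainty.
* The IHC channel is discretized to a binary indicator; graded activity
  (`Low` vs. `High`) is not exploited.
* The assumption that a missing IHC record means "possibly active"
  (a = 1) and a missing RNA record means "inactive" (e = 0) is a
  modelling choice, not a fact about the data.
* Weighted FDR helps only when weights correlate with true
  discoveries. Known adverse settings include phenotypes acting through
  processes not normally active in the tissue, through ubiquitously
  expressed housekeeping sets, or through the wrong tissue's biology —
  and collections containing a few sets with extremely large weights,
  which can promote nominally insignificant p-values. In such cases the
  sensible mitigations are filtering or discretizing the weights, or
  comparing results across candidate tissues; these are analysis
  strategies left to the user rather than package options.
* Weights derived from normal tissue may transfer poorly to neoplastic
  or morphologically abnormal samples.
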