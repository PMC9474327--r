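---
title: "A two-subset mixture model linking single-cell and bulk expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-subset mixture model linking single-cell and bulk expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scbulkmix)
```

## The model

A bulk RNA-seq measurement of one gene in one sample is, to good
approximation, proportional to the *mean* of that sample's single-cell
expression distribution. When the cell population contains two subsets — a
"subset +" with higher expression and a "subset −" with lower expression —
the single-cell distribution is a mixture

$$ y \sim r\,f_+(y) + (1 - r)\,f_-(y), $$

where $r$ is the subset-+ proportion and $f_\pm$ have means $\mu_\pm$. The
bulk value of a sample is then

$$ Y = k\,E[y] + e = k\,\big(r\mu_+ + (1-r)\mu_-\big) + e, $$

with proportionality constant $k$ (set to 1 throughout the closed forms) and
measurement error $e$ with variance $V_{err}$. Across donors, $(\mu_+,
\mu_-, r)$ are independent random variables with means $(E_+, E_-, E_r)$ and
variances $(V_+, V_-, V_r)$. Two closed forms follow:

$$ E[Y] = E_r E_+ + (1 - E_r) E_-, $$
$$ V[Y] = (E_+ - E_-)^2 V_r + E_r^2 V_+ + (1 - E_r)^2 V_- + (V_+ + V_-) V_r + V_{err}. $$

`expected_bulk()` and `variance_bulk()` implement these; `variance_terms()`
itemizes the five additive variance components. Two consequences drive the
package:

* **Differential expression (DE) can cancel.** A disease group may shift
  both subset means up ($d_\pm > 0$, where $d_\pm = \Delta\mu_\pm /
  (E_+ - E_-)$ are gap-normalized shifts) while the subset-+ proportion
  shrinks ($E_r \to \alpha_r E_r$). The bulk mean difference

  $$ E[Y_D] - E[Y_C] = (E_+ - E_-)\big(E_r(\alpha_r - 1) + \alpha_r E_r d_+
     + (1 - \alpha_r E_r) d_-\big) $$

  is zero exactly at $\alpha_r = (E_r - d_-)\,/\,(E_r (1 + d_+ - d_-))$
  (`cancellation_alpha_bound()`), and negative below it: genuine single-cell
  activation that a bulk t-test cannot see.

* **Differential variability (DV) has multiple routes.** $V[Y]$ depends on
  $E_r$ (through $E_r^2 V_+ + (1-E_r)^2 V_-$) and on the mean gap (through
  $(E_+-E_-)^2 V_r$), so proportion changes or subset-specific shifts alter
  the bulk *variance* even when means are engineered to stay equal.
  Cell-to-cell variability $V[y]$ does not appear at all: it averages out
  of the bulk value when samples contain many cells.

A note on the printed rendering of the cancellation bound in the source
literature: the typeset formula lost its division signs, so the implemented
form is the one recoverable by solving the mean-difference closed form for
$\alpha_r$; the property suite verifies, over 1000 random parameter sets,
that the bound zeroes the mean difference to $10^{-10}$.

## Parameters and conventions

| Parameter | Meaning | Units / range | Default |
|---|---|---|---|
| $E_+, E_-$ | expected subset means | expression units | — |
| $E_r$ | expected subset-+ proportion | $[0,1]$ | — |
| $V_+, V_-, V_r$ | across-donor variances | squared units | 0 |
| $d_+, d_-$ | gap-normalized mean shifts | unitless | 0 |
| $\alpha_r$ | proportion multiplier | $\ge 0$, $\alpha_r E_r \in [0,1]$ | 1 |
| $V_{err}$ | measurement-error variance | squared units | 0 |
| $V_{y+}, V_{y-}$ | within-subset cell variances | squared units | 1 |
| $N$, $n$ | samples per group, cells per sample | counts | preset |
| $k$ | bulk proportionality constant | $> 0$ | 1 |

Design choices where the convention was genuinely open:

* **Normalized vs absolute shifts.** The closed forms use $d_\pm$ normalized
  by the gap $E_+ - E_-$, while generative descriptions often add shifts
  directly to $E_\pm$. `shift_params()` stores the normalized convention and
  `apply_shift()` converts via $\Delta\mu_\pm = d_\pm (E_+ - E_-)$; absolute
  shifts can be supplied with `normalized = FALSE`. The worked presets have
  $E_+ - E_- = 1$, where the two conventions coincide.
* **Second moments are variances.** Every Normal$(\cdot,\cdot)$ in the
  simulator takes a *variance* as its second parameter, and $r$ is drawn
  from the unique uniform with mean $E_r$ and variance $V_r$
  (`uniform_from_mean_var()`): support $E_r \pm \sqrt{3 V_r}$.
  Standard-deviation parametrization would not reproduce the closed-form
  variance.
* **Strict validation, no clamping.** $E_r \notin [0,1]$, $\alpha_r E_r
  \notin [0,1]$, or an $r$-uniform support leaving $[0,1]$ are errors, never
  silently clamped; clamping would break the equivalence between the closed
  forms and the simulator that the test suite relies on.
* **$k \ne 1$** is accepted by the simulator; closed-form comparisons then
  rescale analytically (mean by $k$, cell-mean variance terms by $k^2$).

## The simulator

`simulate_bulk()` draws, per group, $N$ donor parameter triples, then $n$
cells per donor from the two-component normal mixture, and returns
$Y = k \bar y + e$ per sample with the ground-truth donor parameters
attached. Numerical and RNG choices:

* Each cell's subset membership is an independent Bernoulli($r$) draw — not
  a fixed $rn$ split — matching the i.i.d. mixture definition and
  contributing the binomial part of finite-$n$ noise.
* The measurement error is drawn once per sample (one bulk measurement per
  donor), not per technical replicate.
* Donor-level parameters and measurement errors are drawn first under the
  master seed; each donor's cells then use a deterministically derived
  sub-seed. Changing $n$ therefore never reshuffles donor parameters, which
  keeps convergence experiments internally consistent.
* Finite-cell correction: the empirical bulk variance converges to
  $V[Y] + k^2\,E[V[y\mid\mu_+,\mu_-,r]]/n$; `within_donor_variance()`
  supplies the correction term so moment-matching tests are exact at small
  $n$ rather than only in the $n \to \infty$ limit.

`preset_example(1)` and `preset_example(2)` package the two worked DV
scenarios (proportion route, variance $0.9131 \to 0.2981$; gap route,
variance $0.1092 \to 0.2275$), with $\alpha_r$ *computed* from
`cancellation_alpha_bound()` at construction so the equal-means property
holds to machine precision rather than to the precision of a transcribed
constant.

## The parameter-space sweep

`sweep_grid()` tabulates the bulk mean and variance differences over the
default $11 \times 11 \times 3$ grid ($d_\pm \in \{0, 0.1, \ldots, 1\}$,
$\alpha_r \in \{0.2, 0.5, 0.8\}$) around the baseline $E_+ = 2$, $E_- = 1$,
$E_r = 0.5$, $V_+ = 0.3$, $V_- = 0.1$, $V_r = 0.05$. Values with magnitude
below $10^{-12}$ are labelled `"boundary"` rather than forced into a sign;
grid points whose shifted proportion leaves $[0,1]$ are recorded as invalid
and skipped rather than aborting the sweep. Measurement error defaults to
zero here because it is additive and group-invariant, so it cancels from
the variance difference. The sweep deliberately calls the same
`mean_difference()` / `variance_bulk()` functions as everything else — there
is no second implementation to drift.

## The estimation pipeline

`run_pipeline()` chains the bulk-level analysis:

1. **Normalization** (`normalize_cells()`): $\log(1 + \text{count})$, then
   each cell rescaled to a row sum of $10^6$. All-zero cells stay zero and
   are flagged. This step targets raw counts; for data already on a
   continuous normalized scale — including this package's own simulated
   fixtures, which are mixture draws, not counts — pass `normalize = FALSE`.
2. **Pseudobulk** (`pseudobulk()`): per-sample mean of cell values, the
   empirical counterpart of $E[y]$.
3. **Filtering** (`filter_genes()`): keep genes with grand-mean bulk
   expression strictly greater than 20 (the proportionality assumption is
   technically unstable for weakly expressed genes). The grand mean over
   all samples is used, the plainer reading of a threshold "in the
   samples"; a per-sample-minimum variant was considered and rejected as a
   stricter test than the procedure describes.
4. **Testing** (`de_dv_test()`): two-sided Welch t-test for DE and
   two-sided variance-ratio F-test for DV, per gene; BH correction applied
   separately to the t and F p-value vectors *after* filtering (filter
   first, then correct over the tested genes); flags at adjusted
   $p < 0.05$. The F-test is two-sided ($p = 2\min(P(F \le f), P(F \ge
   f))$, as `var.test` computes) because DV in either direction is of
   interest — the canonical top DV gene in the motivating analysis
   *decreases* in variance. Zero-variance degeneracies are resolved by
   convention and flagged: both groups constant and equal, $p = 1$;
   constant but unequal, t $p = 0$; one group constant, F $p = 0$.
5. **Decomposition** (`decompose_sample()`, `decompose_gene()`): each
   sample's cell values for a gene are split into two clusters; the larger
   cluster mean is $\hat\mu_+$, the smaller $\hat\mu_-$, and $\hat r$ is
   the fraction of cells in the high cluster. The top DE and top DV genes
   (smallest raw p) are decomposed by default, plus any requested genes.

### Why exact 1-D 2-means instead of Lloyd's algorithm

For $k = 2$ in one dimension the optimal clusters are intervals, so the
global within-cluster-sum-of-squares optimum is found exactly by sorting and
scanning all $n - 1$ threshold partitions with prefix sums
($O(n \log n)$). The package implements that scan rather than Lloyd
iterations: it is deterministic (no seed, no restarts), never returns a
local optimum, and is validated in the test suite against an exhaustive
search over *all* 2-partitions for short vectors and against
`stats::kmeans` with extreme-point initialization (which the scan matches
or beats — the suite contains cases where Lloyd stalls in a local optimum).
Ties in the objective resolve to the split with the larger subset-+
cluster. Samples with fewer than two distinct values get the degenerate
convention $\hat\mu_+ = \hat\mu_- =$ the common value, $\hat r = 0$ (read
as an all-"subset −" population of low or constant expression), with a
flag.

## Synthetic fixtures and what they do (not) show

`archetype_panel()` + `generate_dataset()` produce multi-gene, multi-sample
datasets from the generative model itself, one independent two-component
gene per archetype, with per-donor ground truth retained:

* `null` — no group difference (16 of these in the standard panel);
* `de` — equal shifts in both subsets, proportion unchanged: mean moves,
  variance does not;
* `dv_proportion` — unequal subset variances and a proportion drop at the
  exact cancellation point: variance falls, means equal;
* `dv_shift` — tiny equal subset variances, strongly unequal shifts at the
  cancellation point: the widened gap raises variance, means equal;
* `cancel` — well-separated subsets ($|\mu_+ - \mu_-| = 10$ cell SDs) where
  a $+5$-unit subset-+ shift is exactly offset by $E_r: 0.5 \to 1/3$:
  invisible to the bulk t-test, recovered by decomposition.

Archetype expression levels default to grand means above 21 so fixtures
survive the $>20$ filter; labels are checked against the closed forms at
construction, so a mislabelled archetype fails before any sampling. Values
are continuous normal mixtures on an already-normalized scale. An optional
`nonnegative`/`counts` mode truncates at zero (and rounds) for I/O
realism — with $\mu_-$ near zero this produces the zero-inflated shape
typical of real single-cell data — but truncation perturbs the moments, so
oracle tests use the continuous mode.

Passing tests on these fixtures therefore show that the pipeline recovers
the model's own structure at realistic sizes. They do *not* show robustness
to features of real single-cell data the model abstracts away: library-size
variation, dropout beyond what truncation mimics, count discreteness,
correlated genes, more than two subsets, or doublets and other QC issues.

## Problem sizes and numerical tolerances

The validation suite uses: 1000 random parameter sets for each closed-form
identity (tolerance $10^{-10}$ relative); the full preset sizes $N = 1000$
samples and $n = 10^4$ cells for simulator-vs-closed-form moment checks
(acceptance bands of 4 Monte-Carlo standard errors); $N = 400$, $n = 50$
for the finite-cell correction check; exhaustive decomposition oracles on
vectors up to length 12; parameter recovery at $n = 10^4$ cells with
5-cell-SD component separation (all estimates within 0.05 of truth); and
the 20-gene panel at 100 samples/group and 500 cells/sample for the
end-to-end pipeline, where the raw false-positive count on the 16 null
genes is accepted inside the central 95% of Binomial(16, 0.05). These sizes
were chosen to keep every Monte-Carlo band at least four standard errors
wide at the tested scale.

## Known limitations

* Exactly two mixture components; no $k > 2$ decomposition or model.
* $(\mu_+, \mu_-, r)$ are assumed independent across donors; no covariance
  structure is modelled.
* Simulator components are normal; the closed forms hold for any component
  distributions with the stated means/variances, but presets and fixtures
  are normal-only.
* Estimated subset parameters inherit clustering bias when components
  overlap: $\hat r$ bias shrinks monotonically with separation
  $|\mu_+ - \mu_-| / \sqrt{V_y}$ (quantified in the test suite) and is
  material below ~3 cell SDs.
* The pipeline tests each gene independently; no shrinkage across genes or
  sample-level covariates.
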