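---
title: "Methods: selecting and benchmarking marker genes with markerbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selecting and benchmarking marker genes with markerbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerbench)
```

## The problem

After clustering single-cell RNA-seq data, analysts select a handful of
*marker genes* per cluster — genes whose expression distinguishes that
cluster from the rest — to annotate cell types. Although marker selection is
a form of differential expression (DE) testing, it is a distinct task: the
comparison is either *one-vs-rest* (the target cluster against all other
cells pooled) or *pairwise* (against each other cluster separately, with the
$K-1$ results aggregated), sample sizes are extremely unbalanced, every cell
is treated as a replicate, and only a fixed-size top-$n$ of the ranking is
ever used. markerbench implements the statistical selectors that popular
frameworks expose for this task, a count simulator with known marker-gene
ground truth, and the evaluation machinery to compare selectors — all in one
self-contained package, so that the selectors' behaviour (including their
documented pathologies) can be reproduced and studied without the original
frameworks.

## Preprocessing

Counts $X_{ig}$ (gene $g$, cell $i$) are log-normalized as
$Y_{ig} = \ln\!\big(1 + s\,X_{ig}/L_i\big)$, where $L_i$ is cell $i$'s
library size and the scale factor $s$ defaults to the median library size.
The median-library-size convention is a deliberate, recorded choice: any
fixed $s$ leaves rankings of scale-invariant tests unchanged and only shifts
reported fold-change magnitudes slightly. Natural log is used for
expression; base-2 logs appear only in reported fold-changes. Highly
variable genes are the top-$n$ by raw variance of $Y$ (ties broken by higher
mean, then gene order); mean–variance-trend modelling is intentionally out
of scope. `force_include()` re-adds required genes (e.g. expert-annotated
markers) after HVG selection.

## Two-group statistics

All selectors are built from per-gene two-group statistics
(`wilcoxon_test()`, `welch_t_test()`, `student_t_test()`,
`detection_test()`, `logistic_lrt()`, `poisson_two_group()`,
`auc_statistic()`, `cohens_d()`, `detection_lfc()`, `cosine_score()`):

* **Wilcoxon rank-sum.** $U = R_1 - n_1(n_1+1)/2$ with midranks;
  $z = (U - n_1 n_2/2)/\sqrt{\mathrm{Var}}$, where the variance optionally
  includes the tie term $\sum_t (t^3-t)/(n(n-1))$ — both conventions are in
  circulation, and with heavily tied sparse counts they differ. No
  continuity correction is applied, which keeps the $|z|$-order/p-order
  equivalence exact. $\mathrm{AUC} = U/(n_1 n_2)$ ties the rank-sum and ROC
  statistics together on every input.
* **t-tests.** Welch's $t$ with Welch–Satterthwaite degrees of freedom; the
  *overestimated-variance* variant substitutes $n_1$ for $n_2$ in the second
  variance term (deliberately inflating the standard error when the rest
  group is large); Student's $t$ pools variances with $n_1+n_2-2$ df.
* **Detection test.** Counts are binarized at a detection threshold and the
  two-sided exact conditional (hypergeometric) p-value of the $2\times2$
  detected/undetected table is computed by enumeration in log space. The
  named "exact binomial test" does not pin down its conditioning; the
  conditional test is the standard exact choice for a $2\times2$ table.
* **Logistic regression.** Gene-wise likelihood-ratio test of cluster
  membership on expression against the intercept-only model
  ($\chi^2_1$), capped at 100 IRLS iterations with deviance tolerance
  $10^{-8}$; perfect separation returns the capped fit with a convergence
  flag rather than an error.
* **Poisson GLM.** Group rates $\hat\lambda_k = \sum X / \sum L$ with
  library-size offsets (closed-form MLEs), likelihood-ratio against a
  shared rate.
* **Effect sizes.** Cohen's $d$ with the $(n-2)$-weighted pooled SD;
  detection-proportion log fold-change with pseudo-count $c = 0.5$ (the
  constant is not dictated by any source; 0.5 is the conventional Haldane
  correction); cosine similarity between a gene's expression vector and the
  0/1 cluster indicator.

**Degenerate inputs** follow a documented contract instead of propagating
`NaN`: zero spread with equal means gives statistic 0 and $p = 1$; zero
spread with unequal means caps the statistic at $\pm 10^3$.

**Log-space p-values.** p-values are computed and carried in natural-log
form (`log_p`) alongside the double-precision `p_value`. Ranking uses
`log_p` by default, so order is preserved far below the smallest positive
double; an explicit `emulate_underflow` mode ranks on the double instead, so
p-values below $\approx 5\times10^{-324}$ collapse to exactly 0 and tie —
reproducing, on purpose, the behaviour of implementations that store
p-values as doubles.

## Fold-change dialects

Two formulas for the log2 fold-change of log-normalized expression coexist:

$$f_g^{\text{(de-log, then average)}} =
  \log_2\!\Big(\tfrac{1}{n_1}\sum_{G_1}(e^{Y}-1)+1\Big) -
  \log_2\!\Big(\tfrac{1}{n_2}\sum_{G_2}(e^{Y}-1)+1\Big)$$

$$f_g^{\text{(average, then de-log)}} =
  \log_2\!\Big(e^{\bar Y_{G_1}}-1+\varepsilon\Big) -
  \log_2\!\Big(e^{\bar Y_{G_2}}-1+\varepsilon\Big),\quad
  \varepsilon = 10^{-9}$$

On a group with zero expression the second formula is dominated by
$\log_2 \varepsilon \approx -29.9$, producing spuriously large values
(`lfc_divergence_report()` flags $|f| > 10$ with zero detection in one
group; the threshold is exposed). A third dialect, `"counts"`, reports
$\log_2(\bar X + 1)$ differences for count-model selectors.

## Selection methods

A `method_spec()` combines a statistic, a comparison strategy, an
aggregation rule, a ranking strategy, a correction and an up-only filter;
`method_registry()` names 42 presets mirroring the documented framework
families. Pairwise p-values are aggregated as: **all** — maximum
(intersection–union); **some** — Holm-adjusted values, the
$\lfloor (K-1)/2\rfloor + 1$-th smallest (even counts resolve upward);
**any** — Simes combination $\min_j (K-1)\,p_{(j)}/j$, with the gene's best
within-comparison rank as the primary ordering key (the cited package's
ordering is described only as selecting "unions" of top genes; min-rank plus
Simes is our operationalization and is flagged as an interpretation).
Pairwise effect statistics are summarized by mean, median, min, max, or
min-rank. Rankings are `p_then_lfc` (ascending p, ties by descending
fold-change, then gene order), `score_raw`, or `score_abs`; Bonferroni or
Benjamini–Hochberg adjustments are attached per preset. All tie-breaks end
in gene order, so reruns are bit-identical.

For a $z$-based test, ranking by $|z|$ equals ranking by $p$ because the
normal CDF is monotone and shared by all genes. For Welch's $t$ the degrees
of freedom differ per gene, so each p-value comes from a different $t$
distribution and the equivalence fails: $t = 2.1$ at $\nu = 2$ has
$p \approx 0.171$ while $t = 2.0$ at $\nu = 200$ has $p \approx 0.047$.
`rank_equivalence_report()` verifies the theorem case and lists discordant
pairs for the Welch case.

## The simulator and its ground truth

`simulate_dataset()` draws, for $G$ genes, $N$ cells and $K$ clusters:

* gene base means $\gamma_g \sim \mathrm{Gamma}(a, b)$ (defaults
  $a = 0.6$, $b = 0.3$);
* DE factors $\beta_{gk} = \exp\!\big(\mathcal N(\mu_{DE}, \sigma_{DE})\big)$
  with probability $\pi_{DE}$ per gene–cluster pair, else $\beta_{gk} = 1$;
  defaults $\mu_{DE} = 3$, $\sigma_{DE} = 0.2$, $\pi_{DE} = 0.1$. Only
  up-regulation is simulated ($e^{\mu_{DE}} \approx 20$-fold);
* library sizes $L_i \sim \mathrm{LogNormal}(\mu_L, \sigma_L)$ (defaults
  $\ln 5000$, $0.35$);
* cluster labels with sizes fixed at their expectations (no cluster can be
  empty), default equal proportions;
* counts from a gamma–Poisson with cell mean
  $\mu_{ig} = L_i\,\gamma_g\,\beta_{g,k(i)} \big/ \sum_{g'}
  \gamma_{g'}\beta_{g',k(i)}$ and variance $\mu + \phi^2\mu^2$, with a
  single common biological coefficient of variation $\phi$ (default 0.4).

The DE location/scale defaults are the study conditions this generator
emulates; the remaining defaults are realistic droplet-scale values chosen
once (a median library of ~5,000 counts, a long-tailed gene-mean
distribution, moderate overdispersion) and recorded here. Deliberate
simplifications relative to full splat-style simulators: a common $\phi$
instead of a mean-dispersion trend, and no dropout or expression-outlier
machinery (their probabilities are zero in the emulated design). Passing
benchmarks on these simulations therefore demonstrates recovery under
clean gamma-Poisson DE structure — not robustness to ambient RNA, doublets,
batch effects, or continuous (non-cluster) structure, which real data
contain and this generator does not model.

**Ground truth.** For target cluster $k'$ the marker score of gene $g$ is
the mean log-ratio of DE factors,
$m_g = \frac{1}{K-1}\sum_{i \ne k'} \ln(\beta_{gk'}/\beta_{gi})$ (natural
log; the ranking is base-invariant). True marker sets are the top-$n$ genes
by $m_g$ among genes with mean log-normalized expression above 0.1 and
$m_g > 0$ — low-expression genes can carry large scores without looking
like markers, hence the eligibility filter, applied to the *observed*
simulated data because that is where selection happens.

**Parameter estimation.** `estimate_params()` assumes a single homogeneous
population: lognormal library-size parameters by moments of $\log L$; the
gene-mean gamma by maximum likelihood (`fitdistrplus`) on per-gene means of
library-size-normalized expression — maximum likelihood rather than moments
because at shape $\approx 0.6$ the moment estimator's sampling error
(driven by the gamma's kurtosis) is of the same order as the 10% accuracy
we target at $G = 2000$; and $\phi$ by a moment estimator
$\hat\phi^2 = \overline{(v - m\,s\,\overline{1/L})/m^2}$ over expressed
genes on counts normalized to the median library size (the
$s\,\overline{1/L}$ term corrects the Poisson part for library-size
spread). Because expression is normalized per cell, gene means are
identifiable only up to scale — the simulator itself renormalizes means by
$\sum_g \gamma_g \beta_{gk}$ — so the gamma is fitted on means rescaled to
unit average and the fitted rate equals the fitted shape by construction.
Round-trip checks therefore simulate from unit-mean parameters and run on
homogeneous data; with DE present the single-population assumption is
(knowingly, as in the reference workflow) violated. The DE location and
scale cannot be estimated from data at all and stay at their defaults.

Perturbation utilities for stability experiments: `downsample_cells()`
(simple random subsets at removal fractions such as 25/50/75%, labels
carried along, error if a cluster empties) and `remove_clusters()` (ordered
removal down to two clusters).

## Evaluation

* **Recovery** (`recovery_metrics()`, `benchmark_recovery()`): with
  selected set $S$ and truth set $T$, $\mathrm{recall} = |S \cap T|/|T|$,
  $\mathrm{precision} = |S \cap T|/|S|$, F1 their harmonic mean (0 when
  both are 0; empty truth gives all zeros). The benchmark filters method
  output to up-regulated genes — the simulated truth is up-regulated only —
  except for the `random` negative control, which would otherwise be
  enriched with true markers and stop bounding chance.
* **Predictive performance** (`predictive_eval()`): per-cluster top-5 genes
  pooled; stratified 5-fold cross-validation (fold proportions within one
  cell per cluster); classifiers KNN ($k=3$, Euclidean), linear SVM
  (cost 1 — the kernel is specified upstream, the cost is our fixed
  choice), and a parameter-free max-sum rule that standardizes each gene on
  the full dataset (fold-wise standardization would contradict its
  parameter-free character; this is a known sensitivity knob) and predicts
  the cluster with the largest summed marker expression. Per-cluster
  one-vs-rest F1 from the multiclass confusion matrix, median across
  clusters per fold. `f1_zscores()` standardizes fold-averaged medians
  across methods within a dataset; higher mean $z$ is better, and both sort
  directions are exposed rather than guessing a plotting convention.
* **Concordance** (`concordance_matrix()`): per-cluster top-10 overlap
  $|A \cap B| / \min(n, |A|, |B|)$ — the $\min$ denominator avoids
  mechanically penalizing set-valued methods — averaged over clusters with
  equal weights (cluster-size weighting would be equally defensible;
  unweighted is recorded), then complete-linkage clustering of Euclidean
  row distances.
* **Stability** (`stability_score()`): median per-cluster top-10 overlap
  between full-data and perturbed-data selections; clusters lost to the
  perturbation are excluded.
* **Characteristics and effect sizes** (`characteristics_table()`,
  `effect_size_table()`): cluster/overall mean and variance of selected
  genes, proportion up-regulated (fold-change recomputed so score-only
  methods are covered); one-vs-rest AUC, $|d|$ and $|f_g|$ medians,
  quantile-normalized across the three metric columns before ranking.
* **p-value census** (`pvalue_census()`): exactly-zero p-values per
  method/cluster without a top-$n$ cap, and adjusted p-values among the top
  40 excluding zeros; score-only methods are excluded and listed.

## Orchestration

`run_command()` drives `simulate`, `select`, `evaluate`, `benchmark` and
`diagnose` from a YAML configuration (defaults mirror the headline
conditions: 2000 genes, 2000 cells, 5 clusters, DE location 3 and scale
0.2, 3 replicates, top-20 recovery, top-5 prediction, top-10
concordance/stability). Unknown keys and unknown presets are rejected
before any work happens. Each run writes `run_info.json` with the seed and
an MD5 hash of the resolved configuration next to its artifacts — one
hash-carrying manifest per run rather than a hash embedded in every TSV,
keeping the tables clean for downstream parsing. Identical configuration
and seed reproduce every artifact byte for byte. A thin wrapper script at
`inst/cli/markerbench` exposes the same subcommands from a shell.

## Numerical choices and problem sizes

Replicate $r$ of a simulation uses `seed + r - 1`. The test suite and the
acceptance script run everything at desk scale, chosen once: oracle checks
on hundreds of small random instances; ranking-theorem checks on 1000
genes; simulator fidelity at $G = 2000$, $N = 2000$; the recovery
benchmark at 1000 genes × 1000 cells × 5 clusters; and the underflow case
study at 20,000 cells × 300 genes, where rank-sum $|z|$ comfortably
exceeds the $\approx 38.6$ threshold at which two-sided normal p-values
leave the double-precision range. At moderate cell counts the top of a
saturated (all-zero-p) ranking is exactly the largest fold-changes *among
the zero-p genes*; only once the zero-p set dominates the fold-change
ranking does the overlap with pure fold-change ranking reach 1, which is
the plateau the 20,000-cell setting exhibits.

## Known limitations

Negative-binomial GLMs with empirical-Bayes shrinkage, hurdle models,
bimodal likelihood-ratio tests, stability statistics and
machine-learning selectors are out of scope, as is faithful numerical
replication of external frameworks beyond their documented behaviour. The
simulator does not model dropout, outliers, batch effects, trajectories, or
a mean–dispersion trend. Whether a continuity correction belongs in the
rank-sum normal approximation is left off (both conventions exist; omitting
it preserves the exact $z$/p equivalence); the Poisson selector's offset
choice (library size) is likewise our reading of an underdocumented
detail.
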