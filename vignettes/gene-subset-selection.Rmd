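---
title: "Wrapper gene-subset selection with a GA, a redundancy-aware fitness, and the C-MANTEC constructive network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper gene-subset selection with a GA, a redundancy-aware fitness, and the C-MANTEC constructive network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoselect)
```

## The problem

Two-class microarray studies measure thousands of genes on tens-to-hundreds
of patients, so any classifier of disease outcome must first decide which
genes to use. `evoselect` implements a wrapper approach: candidate gene
subsets are scored by actually training and testing a classifier on them,
and a search procedure — either a genetic algorithm (GA) or stepwise
forward selection (SFS) — explores the subset space. Because wrapper search
on the raw gene list is intractable, a filter first ranks every gene by its
absolute Welch (unequal-variance) *t* statistic between the two classes and
retains the top 5% as the search pool. The Welch form is used because
within-class variances of expression measurements cannot be assumed equal;
the statistic is a ranking key only, so no multiplicity correction is
involved.

## The fitness the GA minimises

A chromosome is a binary mask over the pool: bit *i* set means gene *i* is
included. Its fitness, to be minimised, is

$$f(\mathbf{x}) \;=\; \bigl(1 - \mathrm{ACC}(\mathbf{x})\bigr)
 \;+\; \lambda \frac{k}{N}
 \;+\; \beta\,\mathrm{corr}(\mathbf{x}),$$

where ACC is the test-set accuracy of the wrapped classifier on the subset,
$k$ the number of active genes, $N$ the pool size, and

$$\mathrm{corr}(\mathbf{x}) \;=\; \frac{1}{t}\sum_{i<j} I(x_i, x_j)
 \;-\; \frac{1}{k}\sum_{j} I(x_j, C),
 \qquad t = \binom{k}{2},$$

the mean pairwise mutual information among selected genes minus their mean
mutual information with the class label $C$: low redundancy and high
relevance push $\mathrm{corr}$ down. For $k = 1$ no pairs exist and the
pairwise term is defined as 0. Both weights live in $[0,1]$; the defaults
$\lambda = 0.4$, $\beta = 0.25$ are the operating point at which the
calibration sweep of the original study found the best accuracy, and
`ga_fitness()` exposes the raw formula for inspection.

The GA itself uses a population of 100 chromosomes, 10 elites, scattered
(uniform) crossover for 80% of the non-elite offspring, and a bounded
multi-bit mutation for the rest: a mutation child flips $m \sim
\mathrm{Uniform}\{1..k\}$ loci, so late-generation chromosomes cannot
inflate. Parents are drawn fitness-proportionally (weight
$(\text{worst} - f) + 10^{-9}$, since $f$ is minimised) by stochastic
universal sampling. Initial chromosomes draw their size from
$\mathrm{Uniform}\{1..\min(50, N)\}$ — small-biased, because good expression
signatures are small. With the default 200 generations the search performs
at most $100 \times 200 = 20{,}000$ subset evaluations; `run_ga()` counts
them and memoises repeated masks, so the counter is an upper-bounded audit
figure. Within one run the wrapper uses a single fixed 60/40 holdout split
(resampling per generation is available behind
`ga_config(resample_split=)`), and the redundancy score is computed on
training rows only, so no test information leaks into selection.

### Numerical choices in the MI estimator

$I(\cdot,\cdot)$ is the plug-in estimate over a joint histogram, in nats.
Two choices matter and were made deliberately:

* **Bin placement.** Equal-frequency (quantile) bins are the default. On
  the standard bivariate-Gaussian benchmark ($\rho = 0.9$, $n = 10^4$, 10
  bins, where the true value is $-\tfrac12\log(1-\rho^2) = 0.830$ nats)
  equal-width bins waste resolution on sparse tails and under-estimate by
  up to 0.19 nats, while quantile bins stay within 0.12; `bin_method =
  "equal_width"` switches back.
* **Bin count inside the GA.** The plug-in MI of two *independent*
  variables is biased upward by roughly $(B-1)^2/(2n)$ nats for $B$ bins
  and $n$ samples. At microarray scale ($n \approx 60$–150 training rows) a
  fixed $B = 10$ yields a spurious ~0.5-nat pairwise "redundancy" between
  unrelated genes, which overwhelms the relevance term and makes every
  multi-gene subset look worse than the best single gene — a deceptive
  landscape in which the search cannot assemble the informative set.
  `run_ga()` therefore scales the bin count with the cube root of the
  training-sample count (≈4 bins at $n = 72$), the usual bias–variance
  compromise for histogram estimators; any fixed count can be pinned via
  `ga_config(n_bins=)`. The standalone estimators `mi_histogram()` and
  `redundancy_score()` keep the conventional default of 10 bins.

Ties and degenerate inputs: a constant vector occupies one bin and carries
zero information; MI estimates are clamped at 0; discrete inputs (such as
the 0/1 class label) use their categories as bins directly.

## The stepwise baseline

`run_sfs()` starts from the empty set, whose accuracy is that of always
predicting the training-majority class, and at each step adds the unused
pool gene whose inclusion maximises test accuracy, stopping when no
candidate strictly improves (an optional `min_delta` raises the bar).
Candidate ties fall to the lower pool column index so a trace is exactly
reproducible. The comparison count grows as roughly (pool size) × (final
subset size) — about 3,000 for a 600-gene pool and 5 selected genes — an
order of magnitude cheaper than the GA budget, but the greedy path cannot
discover genes that are informative only jointly: the test suite constructs
an XOR-structured pair on which SFS provably stops at one gene or none
while the GA assembles the pair.

## The C-MANTEC constructive network

C-MANTEC (Competitive MAjority Network Trained by Error Correction) grows a
single hidden layer of *thermal perceptrons* feeding a majority gate. A
thermal perceptron updates with plasticity
$T_{fac} = (T/T_0)\,e^{-|h|/T}$, where $h = \mathbf{w}\cdot\mathbf{x}$ and
the temperature $T$ anneals from $T_0$; updates therefore shrink both as
the neuron cools and as the pattern moves away from its hyperplane. Three
parameters govern training: `Imax` (the temperature budget $T_0$, i.e. how
many patterns a neuron may learn per cycle), `gfac` (the growing factor),
and `phi` (the noise threshold).

The published description of the algorithm leaves the inner mechanics to
its antecedent literature, so this implementation fixes them explicitly:

* presentation draws a misclassified pattern uniformly at random (seeded);
* among hidden neurons voting against the desired output, the one with the
  largest thermal factor learns ($\Delta\mathbf{w} = T_{fac}\, t\,
  \mathbf{x}$ with internal target $t \in \{-1,+1\}$), and its temperature
  drops by one;
* when no wrong-voting neuron reaches `gfac`, the learning cycle ends: the
  noise filter deletes every pattern whose learn count satisfies
  $\mathrm{NTL} \ge \mu + \varphi\,\sigma$ (population SD; all-equal counts
  delete nothing, since otherwise every pattern would trivially qualify —
  the description of the filter oscillates between "variance" and
  "standard deviations", and the SD reading is the default with
  `use_variance = TRUE` as the alternative), a fresh neuron initialised to
  classify the triggering pattern is added, and temperatures and learn
  counts reset;
* training stops when the majority gate classifies every retained pattern,
  which is guaranteed to terminate because each cycle performs at most
  (neurons × `Imax`) updates and the neuron count is guarded by
  `max_neurons`.

Inputs are standardised with training statistics; the bias input is fixed
at 1. An even hidden-layer vote falls to class 1 by default
(`tie_class`). With that tie rule a noiseless XOR problem is solved with
two neurons — an odd count is *not* forced — and linearly separable blobs
are learnt by a single neuron, both verified in the tests along with an
audit log guaranteeing every deletion satisfied the threshold at deletion
time.

## Classifier adapters and their grids

Six classifiers share one fit/predict contract (`make_classifier()`): LDA
(`MASS::lda`), SVM (`e1071::svm`; kernel, cost, degree, gamma, coef0),
naive Bayes (in-package, with Gaussian, kernel-density and discretised
variants; the discretised variant uses equal-frequency quartile bins with
Laplace smoothing, and the kernel-density/discretised flags are mutually
exclusive), C-MANTEC, kNN (in-package over explicit distance matrices so
Euclidean, chi-squared — on features min-shifted to non-negative with
training minima — and cosine distances share a code path; even votes fall
to class 1), and an MLP (in-package online backprop: one sigmoid hidden
layer, learning rate `alpha`, `n_cycles` epochs, seeded initialisation,
because those are exactly the knobs its declared grid sweeps). The declared
grid domains ship in `inst/extdata/param_grids.yaml`; `classifier_spec()`
validates against them unless `strict = FALSE`.

Scoring is deliberately asymmetric-free: with class 1 ("cancer") positive,
false-positive and false-negative rates are normalised by the *total*
number of test patterns, so `acc + fp_rate + fn_rate = 1` holds exactly and
every configuration lies on or below the FP + FN = 1 contradiagonal.

## Evaluation harness

`repeated_holdout()` redraws the 60/40 split (plain random by default;
stratification is opt-in since the reference protocol only says "randomly
varying") 50 times by default with seeds derived from one base seed, and
either evaluates a fixed subset or re-runs a selector per repetition.
`sweep_parameters()` maps a parameter grid to the (mean FP, mean FN) plane
and summarises a method's robustness by *compactness* — the SD of accuracy
over all configurations × repetitions — and the distance of the cloud's
mean point from the origin, $\sqrt{\overline{FP}^2 + \overline{FN}^2}$.
`selection_frequency()` reports how often each gene is selected across
runs (percent, 2 decimals), optionally broken down by classifier, and
`friedman_compare()` runs the rank-based Friedman test (chi-squared
approximation, blocks = repetitions) followed — only when significant at
0.05 — by Holm-corrected paired Wilcoxon signed-rank tests against the
worst-performing method as control. The post-hoc procedure is isolated in
one function so another correction can be swapped in.

## What the synthetic generator does and does not emulate

`generate_dataset()` plants `n_informative` genes as class-conditional
Gaussians whose means differ by `effect_size` within-class SDs, optional
redundant copies built as $\rho\,\tilde{x}_{\mathrm{parent}} +
\sqrt{1-\rho^2}\,\varepsilon$ against the *standardised* parent (the raw
parent's variance is inflated by the class-mean shift, which would
otherwise shrink the realised correlation below $\rho$), and pure-noise
genes for the rest; labels are independent Bernoulli draws matching a
target class-0 proportion, guarded to keep at least two samples per class.
Default shapes follow the published two-class cancer panels (thousands of
genes, tens-to-hundreds of samples, class-0 proportions 0.35–0.83). The
generator does *not* emulate platform-specific intensity distributions,
batch effects, probe-level noise, or missing values — so green tests here
demonstrate algorithmic correctness and recovery of planted structure, not
performance on any real microarray.

## Problem sizes used by the test-suite and acceptance script

Simulated problems are scaled to what the checks actually need: shape and
arithmetic checks run at 20–100 samples and up to 7,129 genes (the
ranking is vectorised, so wide matrices are cheap); GA property checks use
a 30-gene pool with 6 generations over 20 seeds; the planted-recovery
check uses the 200-gene pool with 5 informative genes at effect size 2,
120 samples, and a 60-generation GA (6,000-evaluation budget) over 10
seeds, where at least 80% of runs recover ≥4 of the 5 planted genes; the
robustness comparison runs reduced C-MANTEC and kNN grids (9 and 12
configurations) at 4 repetitions. `scripts/acceptance.R` re-derives all
headline numbers from scratch at these sizes from a single `--seed`.

## Known limitations

* Binary outcomes only; no multiclass extension of the majority gate or
  the evaluators.
* The plug-in MI estimator is biased at small $n$; the package compensates
  by bin-count scaling inside the GA, not by bias-corrected estimators.
* `MASS::lda` can fail on collinear subsets; the GA assigns such
  chromosomes a worst-case fitness and logs the event rather than
  repairing the subset.
* Holdout splits ignore patient-level structure (no grouping/blocking);
  repeated holdout under-estimates variance relative to nested CV when
  selection is re-run per repetition.
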