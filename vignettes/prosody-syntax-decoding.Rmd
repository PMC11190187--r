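---
title: "Decoding syntactic phrase boundaries under prosodic modulation: methods"
author: "prosyn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding syntactic phrase boundaries under prosodic modulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prosyn)
```

# The scientific question

When we listen to continuous speech, the brain must recover syntactic
structure -- where phrases close -- from an acoustic signal that also
carries prosody: pauses, pitch movements and lengthening that tend to
co-occur with phrase boundaries. `prosyn` implements a complete analysis
chain for asking whether prosodic boundary strength *modulates* the neural
encoding of syntactic phrase closure: if a decoder is trained to recognize
closing phrase boundaries from neural activity in a prosodically neutral
context, does it generalize better to words whose prosody and syntax agree
(the statistically typical combination) than to words where they conflict?

The package operates on three kinds of input: word tables with per-word
timing and a nonnegative *prosodic boundary strength* (computed upstream by
spectro-temporal wavelet analysis of the speech audio), bracketed
constituency trees, and continuous multichannel recordings with word-offset
event times. Because the neuroimaging data this design targets are
typically restricted, the package ships a synthetic-data module that
generates cohorts with the same statistical structure, so every stage of
the pipeline is exercised end to end by the test suite.

# Stimulus model: the two-gamma strength mixture

Prosodic boundary strength is positive and strongly right-skewed, with a
large mass of weak boundaries and a separate population of strong ones. We
model the strength distribution as a two-component gamma mixture

$$ f(x) = w_1\,\Gamma(x;\,k_1, \lambda_1) + w_2\,\Gamma(x;\,k_2, \lambda_2), $$

fitted by expectation-maximization (`fitGammaMixture()`). Design choices:

* **M-step.** The weighted gamma MLE is solved exactly per iteration:
  Newton iteration on $\log k - \psi(k) = \log \bar x_w - \overline{\log x}_w$
  with a method-of-moments style start. Because the M-step is an exact
  maximizer, the log-likelihood is non-decreasing across iterations; the
  fitted object stores the whole trace and its validity method checks
  monotonicity.
* **Initialization and restarts.** EM on mixtures is multimodal, so the
  fitter runs 5 restarts initialized by splitting the sample at jittered
  quantiles around the median (method-of-moments fits per side) and keeps
  the best final log-likelihood.
* **Convergence.** Relative log-likelihood change below $10^{-8}$, capped
  at 500 iterations; non-convergence returns the best iterate with a
  warning and a `converged = FALSE` flag.
* **Component order.** Components are sorted so component 2 has the larger
  mean; "weak" and "strong" always refer to components 1 and 2.

The weak/strong **binarization boundary** is the strength between the two
component means where the weighted densities cross,
$w_1 f_1(x) = w_2 f_2(x)$ -- equivalently the point of 0.5/0.5 posterior
membership -- found by bisection to $10^{-8}$ (`mixtureBoundary()`). If the
fitted components are too similar for a crossing to exist between their
means the fit is degenerate and the boundary is `NA`. A strength exactly at
the boundary is classified *weak*: the conservative tie-break, since weak
tokens feed the neutral pools. Note that the boundary depends on the
mixture *weights* as well as the shapes and rates, so component parameters
alone do not determine it.

Zero-strength tokens carry no usable spectral content; they are excluded
upstream (see the filters below), and `classifyStrength()` treats them as
an error rather than silently labeling them.

The stimulus-level association between binarized prosody and syntactic
closure is tested twice (`testAssociation()`): a binomial-family GLM of the
closing label on the prosody class (coefficient z), and a Gamma-family GLM
with inverse link of the continuous strength on the closing label
(coefficient t). Both are ordinary GLMs fitted by iteratively reweighted
least squares with asymptotic p-values. Because the inverse link is
decreasing, the package also reports the sign of the raw strength
difference so the direction is unambiguous.

# Syntactic labels: closing-node counts

Constituency trees are read from PTB-style bracketed text
(`parseBracketed()`), one sentence per line. For each word we count, under
a bottom-up traversal, the number of tree nodes whose rightmost terminal is
that word -- equivalently the run of closing brackets after the word in the
normalized bracket string (`closingNodeCounts()`). The count includes the
word's own preterminal, so every word closes at least one node. A word
carries a **closing phrase boundary** iff it closes *more than one* node;
a word that closes only its preterminal closes no phrase. This convention
makes the two classes partition all words with no third class. The
alternative reading -- dropping words that close exactly one node -- is
possible; the rule is centralized in `labelAndFilter()` if a user wants to
depart from the default.

Three filters are applied before analysis, in this order:
out-of-dictionary tokens (`<unk>`), sentence-final words (to avoid
end-of-sentence positional confounds), and zero-strength words. Counts are
computed on the full trees *before* any removal, so exclusions never
change another word's label. Each excluded token records the first
applicable reason.

# Generalization sets

Tokens are crossed into four prosody-by-syntax cells. Three balanced test
sets are assembled from them (`buildSplit()`):

| set        | cells                         | interpretation            |
|------------|-------------------------------|---------------------------|
| neutral    | weak+no, weak+yes             | prosodically uninformative|
| coherent   | weak+no, strong+yes           | prosody and syntax agree  |
| incoherent | weak+yes, strong+no           | prosody and syntax clash  |

`testSizePerClass` tokens are reserved from each cell -- with replacement
only when a cell is smaller than required, so undersized cells are
resampled ("used twice") while large cells never are. Each weak-cell
reservation is shared by the two test sets that draw on it; ids never leak
into the training pool, which takes all remaining weak tokens and
downsamples the majority class to exact balance. Downsampling (rather than
upsampling) avoids duplicated training rows that would leak across CV
folds. The default `testSizePerClass` is the smallest cell size, capped so
the training pool keeps at least 70% of the weak tokens; the reservation is
global rather than per-talk.

# Epoching and dimensionality reduction

Epochs are cut over the half-open window $[t_{\min}, t_\max)$ relative to
each word offset, with `round((tmax - tmin) * fs)` samples; an offset is
discarded when its gap to the *preceding* offset is under 100 ms (the later
of the two is dropped), and epochs extending past the recording are
discarded with a logged count. No baseline correction is applied.

Spatial dimensionality is reduced by SVD of the channels-by-(epochs x
samples) training matrix, keeping the smallest leading component set whose
cumulative energy reaches the cutoff (default 99%). "Energy" defaults to
squared singular values (variance), the conventional reading of a
percentage cutoff on an SVD spectrum; a `linear` switch uses the raw
singular values instead. The basis is fitted on *training epochs only* and
applied unchanged everywhere -- a leakage test asserts the basis is
bit-identical whether or not test data exist. In the design this package
emulates the reduction acts on source-space resolution matrices after
inverse modeling; here the identical contract is applied at sensor level,
a documented divergence that leaves every downstream interface unchanged.

# Decoding

`fitLogistic()` minimizes the L2-penalized logistic loss
$\sum_i \log(1 + e^{-\tilde y_i(x_i^\top w + b)}) + \|w\|^2/(2C)$ with an
unpenalized intercept -- the standard `C` parameterization (larger `C`,
weaker regularization). Newton-IRLS with step halving is used up to 700
features; wider problems (whole-window MVPA concatenates components x
samples) switch to L-BFGS on the identical objective. Both paths are
deterministic given the data; a unit test cross-checks the weights against
an independent ridge-logistic implementation.

**Whole-window MVPA** (`mvpaDecode()`): features are all component-sample
amplitudes in a 400 ms window (pre-offset $[-0.4, 0)$ or post-offset
$[0, 0.4)$), z-scored by the fold-training statistics. The training pool is
split into 10 shuffled folds; per fold a classifier (C = 1) is fitted on
nine tenths and scored by AUC on each *fixed* test set; per-condition AUCs
are the fold means. Scoring fixed, disjoint test sets per fold (rather than
the held-out tenth) reconciles randomized tenfold cross-validation with
test sets that must not overlap the training pool. Fold AUCs are averaged
(not pooled) -- the choice matters little at these sizes and is stated here
for reproducibility.

**Temporal decoding** (`temporalDecode()`): one classifier per timepoint,
features the component amplitudes at that sample. `C` is selected per
timepoint by nested fivefold cross-validation over a log-spaced grid of 11
values, one per decade from $10^{-5}$ to $10^5$, maximizing mean inner AUC
with ties broken toward the smallest `C` (strongest regularization); the
winner is refitted on the full pool and scored on the test sets.
Standardization inside the inner folds uses inner-training statistics;
the final refit standardizes by full-training-pool statistics. Test data
never contribute to standardization, training or `C` selection.

AUC is the Mann-Whitney probability that a random positive outscores a
random negative, ties counted 1/2; it is validated against a
pairwise-enumeration oracle.

# Group statistics

* **Paired sign-flip permutation tests** (`pairedPermutationTest()`) on
  per-subject AUCs against chance (0.5) or between conditions. With $n$
  subjects the null is enumerated exhaustively whenever $2^n$ fits the
  permutation budget (2048 = $2^{11}$ at the default cohort size), giving
  exact count-ratio p-values; random draws otherwise use the add-one
  convention so p is valid and never zero. Directional hypotheses (AUC
  above chance; coherent above the other conditions) use one-sided tests
  by default, with a two-sided switch.
* **Holm correction** (`holmAdjust()`) across the per-window condition
  tests and across contrasts, via `stats::p.adjust`.
* **Cluster-based permutation** (`clusterPermutationTest()`) over the
  temporal AUC series: pointwise one-sample t against 0, cluster-forming
  threshold the parametric two-sided t quantile at 0.05 (df $n-1$; the
  common default of this test family, configurable), cluster mass the sum
  of t inside maximal supra-threshold runs, null the maximum cluster mass
  over sign-flip permutations. Zero-variance timepoints get t = 0 with a
  warning. With one timepoint the procedure reduces to the pointwise
  permutation test (the t statistic is monotone in the flipped mean when
  the per-subject magnitudes are fixed).
* **Bayesian population prevalence** (`prevalenceEstimate()`): each subject
  is individually significant with probability
  $\theta = \alpha + \gamma(1-\alpha)$, where $\gamma$ is the prevalence of
  true effects. With a uniform (Beta(1,1)) prior on $\theta$ -- the cited
  approach's default -- the posterior after $k$ of $n$ significant subjects
  is Beta($k+1$, $n-k+1$); the MAP is
  $\max\{0, (k/n - \alpha)/(1-\alpha)\}$ and the 95% HPDI is found
  numerically on the $\theta$ posterior (narrowest interval of the required
  mass; one-sided closed forms at $k = 0$ or $k = n$), mapped through
  $\gamma = (\theta-\alpha)/(1-\alpha)$ and truncated to $[0,1]$. For
  $k = n = 11$ this gives MAP 1.00 and HPDI lower bound
  $(0.05^{1/12} - 0.05)/0.95 \approx 0.77$.

In the orchestrated pipeline, each subject's within-subject significance
(the $k$ of the prevalence model) is a one-sided t-test of the fold AUCs
against 0.5 at the configured $\alpha$ -- a pragmatic desk-scale choice; on
real data one would use a subject-level permutation test.

# The synthetic cohort

`genWordTable()` samples the latent prosody class first (strong with
probability `wStrong`), then the closing label from the class-conditional
probability, then the strength from the class's gamma component. This
direction of generation plants exactly the conditional frequencies the
stimulus analysis measures. Defaults are the study conditions: components
Gamma(1.1, 2.8) and Gamma(14, 10.7); P(closing | strong) = 0.72 and
P(closing | weak) = 0.44; 11 subjects. Word offsets are spaced by a shifted
exponential with 5% of gaps forced under 100 ms so the epoch discard rule
is always exercised.

Values the study conditions do not fix are free simulation parameters,
chosen once as follows and not revisited:

* `wStrong = 0.25`: the marginal rate of strong tokens is not a published
  quantity; a quarter of content words carrying a strong boundary is a
  plausible rate for continuous expository speech and leaves all four cells
  well-populated at desk scale.
* `nWords = 800` per subject: large enough for a stable mixture fit,
  an informative split (test sets of roughly 100-150 tokens) and reliable
  decoding, small enough that the full 11-subject pipeline runs in minutes
  on one CPU. `fs = 100` Hz and `nChannels = 60` for the same reason --
  after spatial reduction nothing downstream depends on the acquisition
  rate.
* Gains `coherent/neutral/incoherent = 0.5/0.3/0.15` against unit sensor
  noise: mid-range AUCs, away from both chance and ceiling, so ordering
  comparisons are informative.

`genRecording()` adds, to white Gaussian sensor noise, one response per
token: a fixed per-subject random spatial pattern (unit norm) times a
raised-cosine temporal profile of width 300 ms peaking 100 ms *after* the
word offset, plus an anticipatory component of width 200 ms peaking 100 ms
*before* offset at `preGain` (0.4) of the amplitude -- the simplest smooth
profile that reproduces post-offset-dominant decodability with weaker
above-chance pre-offset decoding. The response is signed by the syntactic
class (positive for closing, negative for non-closing) and scaled by a
per-cell gain: strong+closing gets `gainCoherent`, weak+non-closing
`gainNeutral`, and the two mismatched cells `gainIncoherent`. The signed
construction makes the *separability* of the two classes in a test set the
average of its two cell gains, which yields the planted ordering coherent
> neutral > incoherent for any `gainCoherent > gainNeutral >
gainIncoherent`.

What the generator does *not* emulate: spatially correlated or 1/f sensor
noise, per-token response variability, oscillatory activity, eye/muscle
artifacts, co-articulation between adjacent words, and any source-space
geometry. Passing tests therefore show that the *pipeline* recovers planted
structure under its own assumptions -- they are evidence about the code,
not about brains. In particular, with white noise the 99% SVD cutoff
retains nearly all channels; on real recordings with correlated noise the
reduction is far more aggressive.

# Numerical choices and degenerate inputs

* EM: relative tolerance $10^{-8}$, 500 iterations, 5 restarts; weighted
  gamma MLE Newton to $10^{-12}$; mixture boundary by bisection to
  $10^{-8}$; degenerate fits yield `NA` boundaries (warning) or errors at
  the boundary operation.
* Logistic: Newton with step halving, relative tolerance $10^{-8}$
  (temporal inner loops use $10^{-6}$), L-BFGS `factr 1e4` for wide
  problems; ties in the `C` grid go to the smallest value.
* Permutations: exhaustive enumeration whenever $2^n \le$ budget;
  count-ratio p with a $10^{-10}$-scale tie tolerance; add-one correction
  for random draws.
* Epoching: empty offset lists give an empty `EpochSet`, not an error;
  `tmin >= tmax` is an error; windows are half-open throughout.
* Splits: any empty prosody-by-syntax cell is an error naming the cell;
  a reservation the weak pool cannot support is an error.

# Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to make every statistical check informative on a single CPU:
20,000 draws for mixture recovery, 50,000 for distributional agreement,
the full default 11-subject cohort (800 words, 60 channels, 100 Hz) for
the planted-effect ordering and the chance-level contract, and 500
simulated null datasets for the cluster test's type-I error.

# Known limitations

* The pipeline consumes precomputed prosodic strengths and parsed trees;
  no audio analysis or parsing is performed.
* Sensor-level SVD stands in for source-space reduction (above).
* The cluster test is temporal only -- no channel-adjacency clustering and
  no TFCE.
* Temporal generalization (train-time x test-time) matrices are out of
  scope.
* The Gamma-GLM t statistic is reported on the inverse-link scale; use
  `strengthDirection` for the sign of the raw effect.

# A worked example

```{r example, eval = FALSE}
library(prosyn)
cfg <- synthConfig(nSubjects = 4, nWords = 500, seed = 9)
res <- runPipeline(pipelineConfig(
  synth = cfg, seed = 11,
  doTemporal = FALSE, verbose = FALSE
))
res$mixtureFit
res$group$windows$post$meanAuc
res$group$windows$post$prevalence$coherent
```

The README shows the same example with the numbers it prints.
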