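# prosyn

Prosody–syntax interaction analysis and cross-condition neural decoding.

## What this package is for

In continuous speech, prosodic boundary cues (pauses, pitch movement,
lengthening) tend to co-occur with syntactic phrase closure. `prosyn` is a
toolkit for researchers in the cognitive neuroscience of language who want
to quantify that association in a stimulus set and then test whether it
modulates the *neural* encoding of syntax: train a decoder to recognize
closing phrase boundaries from neural activity in a prosodically neutral
context, and measure how its performance generalizes to words where
prosody and syntax agree (coherent), are uninformative (neutral), or
conflict (incoherent).

The analysis chain:

1. **Stimulus model.** Per-word prosodic boundary strength
   $x > 0$ is modeled as a two-component gamma mixture
   $f(x) = w_1\Gamma(x; k_1, \lambda_1) + w_2\Gamma(x; k_2, \lambda_2)$
   fitted by EM; words are binarized weak/strong at the equal-posterior
   density crossing $w_1 f_1(x) = w_2 f_2(x)$. The prosody–syntax
   association is tested with a binomial GLM (closing ~ prosody class) and
   a Gamma GLM with inverse link (strength ~ closing).
2. **Syntax.** Bracketed constituency trees are parsed; each word's
   closing-node count is the number of constituents whose rightmost
   terminal is that word (equivalently its run of closing brackets). A
   word carries a closing phrase boundary iff it closes more than one
   node. Out-of-dictionary, sentence-final and zero-strength tokens are
   excluded.
3. **Generalization sets.** A class-balanced training pool of weak-prosody
   words plus three balanced test sets (neutral, coherent, incoherent)
   crossing prosody with phrase closure; undersized cells are resampled,
   and no token is shared between training and test.
4. **Decoding.** Word-offset epochs (100 ms inter-offset discard rule),
   SVD reduction at the 99% energy cutoff fitted on training epochs only,
   then L2-regularized logistic decoders: whole-window MVPA (C = 1,
   tenfold randomized CV, AUC on each test set) and per-timepoint temporal
   decoding with nested fivefold selection of C over a log-spaced
   $10^{-5}..10^5$ grid.
5. **Group statistics.** Exhaustive sign-flip paired permutation tests
   (2048 = 2^11 at the default cohort size), Holm correction,
   cluster-based permutation over the temporal AUC series, and Bayesian
   population prevalence: with $k$ of $n$ subjects individually
   significant at level $\alpha$, MAP prevalence
   $\max\{0, (k/n-\alpha)/(1-\alpha)\}$ with a 95% HPDI from the
   Beta($k{+}1$, $n{-}k{+}1$) posterior.

A synthetic-data module (`synthConfig()`, `genCohort()`) generates word
tables and multi-subject recordings with a planted, condition-modulated
signal, so the full pipeline runs and is tested without any restricted
neuroimaging data. See the methods vignette
(`vignettes/prosody-syntax-decoding.Rmd`) for the model details and every
numerical choice.

## A worked example

```r
library(prosyn)
cfg <- synthConfig(nSubjects = 4, nWords = 500, seed = 9)
res <- runPipeline(pipelineConfig(
  synth = cfg, seed = 11,
  doTemporal = FALSE, verbose = FALSE
))

res$mixtureFit
#> Two-component gamma mixture fit
#>   comp 1 (weak):   w = 0.774, shape = 1.115, rate = 2.813 (mean 0.397)
#>   comp 2 (strong): w = 0.226, shape = 18.554, rate = 14.295 (mean 1.298)
#>   boundary = 0.9484, loglik = -873.331, 133 iteration(s), converged: TRUE

round(unlist(res$group$windows$post$meanAuc), 3)
#>    neutral   coherent incoherent
#>      0.580      0.654      0.573

res$group$windows$post$prevalence$coherent
#> Population prevalence (k = 4 / n = 4, alpha = 0.05): MAP = 1.00, 95% HPDI: [0.53 1.00]
```

The mixture fit recovers the two latent strength populations the generator
planted (weak component near Gamma(1.1, 2.8); the strong component's
shape/rate are less identifiable at this sample size but its mean, 1.30,
is on target) and places the weak/strong boundary between the component
means. The post-offset group mean AUCs show the planted coherence
ordering: decoding syntactic boundaries generalizes best to the coherent
test set (0.654), worst to the incoherent one (0.573). All four subjects
are individually above chance in the coherent condition, giving a
prevalence MAP of 1.00 with 95% HPDI [0.53, 1.00] (the interval is wide at
n = 4). Outputs are also written as JSON/CSV to `res$outDir`, together
with a manifest that reproduces every number in the bundle.

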