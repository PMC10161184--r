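---
title: "Detecting semantic change with multi-model diachronic embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting semantic change with multi-model diachronic embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Word meanings drift. In biomedical text the drift can be abrupt: a term tied
to one experimental system is repurposed ("cas9" moving from bacterial
immunity to genome editing), or an acronym acquires a new referent when an
outbreak begins ("sars" in 2003 and again in 2020). `semdrift` detects such
events from year-binned corpora by asking, for every token, whether its
distributional context changed more between two adjacent years than embedding
models of the same year disagree among themselves.

The hard part is not embedding text; it is that word2vec-style models are
unstable. Two models trained on the same corpus with different seeds put the
same token in different places, and models trained on differently sized
corpora differ even more. A naive year-to-year distance therefore confounds
semantic change with model noise, and the noise floor itself changes over
time as corpora grow. The package's central statistic is built to cancel that
noise floor.

## The pipeline

**Preprocessing.** Documents arrive as JSON-lines records carrying a year, a
text, and optionally entity-annotation spans (0-based, end-exclusive
offsets). Annotated mentions are replaced right-to-left by a single synthetic
token `type_id` (e.g. `mesh_d045169`), so all surface forms of a concept
share one vector. Versioned documents (preprints) are filtered to their
latest version before binning. Tokenization splits sentences at final
punctuation and tokens at non-word boundaries, leaving `type_id` tokens
intact. Lemmatization is deliberately a pluggable contract — any idempotent
token-to-token function — with plain Unicode lowercasing as the default, so
the pipeline does not depend on a particular NLP runtime; sentences, not
documents, are the training unit.

**Replicate CBOW ensembles.** For each year we train `replicates` CBOW models
(default 10) with negative sampling. The training defaults — vector size
300, 10 epochs, minimum token frequency 5, context window 16, 5 negative
samples, 1e-3 frequency subsampling, linearly decaying learning rate — are
the classic word2vec-era settings for this task. The trainer is
single-threaded and seeded (`baseSeed + replicate`), so every vector is
bit-for-bit reproducible; replicate-to-replicate variation is therefore pure,
controlled training stochasticity, which is exactly the quantity the
intra-year distance is meant to measure.

**Alignment.** Each model lives in an arbitrary rotation of "semantic
space". We rotate every model onto an anchor model — by default replicate 0
of the latest year — with closed-form orthogonal Procrustes:
\(Q = UV^\top\) from the SVD \(X^\top Y = U\Sigma V^\top\), where the rows
of \(X\) and \(Y\) are the vectors of the vocabulary shared with the anchor.
No scaling, translation, centering or length-normalization is applied, and
the fitted rotation is applied to *all* rows of the model, so tokens absent
from the anchor year retain (rotated) coordinates. Orthogonality guarantees
every within-model cosine distance is untouched; only cross-model
comparisons change, and only for the better.

**The change metric.** For a token \(t\) and adjacent years \(y, y{+}1\):

- intra-year distance: mean cosine distance between \(t\)'s vectors over all
  \(R(R-1)/2\) unordered replicate pairs of one year — the noise floor;
- inter-year distance: mean over the full \(R^2\) Cartesian product of
  cross-year model pairs — the raw change signal;
- distance ratio: inter-year mean divided by the average of the two flanking
  years' intra-year means;
- frequency ratio: corpus-size-normalized frequency in \(y{+}1\) over
  \(y\);
- metric: distance ratio × frequency term.

A perfectly stable token (inter = intra, frequency ratio 1) scores 1, and
the metric strictly decreases as intra-year instability grows at fixed
inter-year distance — unstable tokens are penalized, stable ones rewarded.

Two conventions here are genuinely open and are therefore explicit
parameters rather than silent choices. First, the intra-year denominator:
we average the two flanking years' intra-year means (`intraMode = "mean"`),
because both years' instability contaminates the cross-year comparison; a
previous-year-only variant is available. Second, how frequency enters: the
default `"symmetric"` combiner multiplies by \(\max(f, 1/f)\), so collapses
in usage raise the signal just as surges do; the literal `"directional"`
product by \(f\) is a switch. The combiner used is recorded in the output's
attributes.

Relative (corpus-size-normalized) frequencies are used throughout because
real corpora grow enormously across two decades; raw counts would make every
token look like it surged.

**Changepoint calling.** Token series feed a two-sided CUSUM recursion on
successive differences with zero drift:
\(g^+_t = \max(0, g^+_{t-1} + (x_t - x_{t-1}) - k)\), symmetrically
\(g^-_t\); an alarm fires when an accumulator exceeds the threshold, both
accumulators reset after an alarm, and accumulators also reset at gaps
(years where the token fell below the frequency cutoff) — differences are
never taken across unobserved years. The threshold is the 99th percentile
(linear-interpolation quantile) of *all* metric values pooled across every
token and transition, so by construction about 1% of generated timepoints
are extreme enough to drive an alarm whatever the corpus. The reported
changepoint is the transition at which the alarm fires, with no backtracking
to the alarm's onset.

## The synthetic benchmark

Real corpora offer no ground truth, so validation uses a generator that
emulates the statistical structure the method responds to, not fluent
language. The background is a topical mixture: the 500-type vocabulary is
partitioned into 25-token topics by interleaving Zipf (\(s = 1\)) frequency
ranks — so every topic has exactly the same frequency profile — and each
sentence draws its tokens from a single topic by the members' relative
Zipf weights. Topicality matters beyond realism: it gives every token a
sharply determined co-occurrence signature, and only then do embedding
models stabilize as a corpus grows, the way they do on real text. (Under a
flat unigram/bigram background we measured the opposite — replicate
disagreement *grows* with corpus size, because the optimum is nearly flat
and the training trajectory diffuses — which silently inverts any
corpus-size diagnostic built on top.) The process is identical in every
year, so a null corpus is exchangeable across years.

A planted shift designates a target token, a change year, and two disjoint
context sets. Wherever the target is planted (per-sentence occurrence
probability 0.02 before the change, 0.06 after — a 3× usage rise), its four
flanking positions are filled from context set A before the change year and
from the mixture \((1{-}m)A + mB\) at and after it. By default the context
sets are two whole background topics: topic members are anchored by their
own plentiful background co-occurrences (they do not drift toward the
target), the identical frequency profiles keep the before/after regimes
statistically symmetric, and the shift is a genuine relocation between
coherent clusters — the way a term migrates between topical literatures.
Because CBOW encodes context distributions, the mixture weight \(m\) is
directly the effect size. During development we also examined dedicated
out-of-vocabulary context tokens and contiguous frequency-rank blocks; both
produce misleading benchmarks (rare dedicated tokens relocate to the target
instead of anchoring it, and rank-contiguous blocks give the two regimes
different noise levels). One realistic side effect of topic-pair contexts:
members of the incoming context topic experience a genuine context change
of their own when a frequent target invades their topic, and may draw
secondary changepoint calls at the same transition.

The reference benchmark trains 3 replicates of dimension 50 per year on 8
years × 20,000 twelve-token sentences, with one planted full context switch
(\(m = 1\)) plus the 3× frequency rise. These sizes keep a ten-seed
benchmark on a single CPU in minutes while leaving the vocabulary (~540
types) two orders of magnitude smaller than a real corpus's; dimension and
replicate count are scaled down alongside. The package's defaults (dim 300,
10 replicates) are the full-scale settings.

What passing this benchmark shows — and what it does not: recovery of a
planted context-distribution switch demonstrates the alignment, metric and
CUSUM machinery end to end, under exactly the kind of signal the method is
designed for. It does not demonstrate robustness to phenomena the generator
omits: polysemy, topic nonstationarity, vocabulary turnover, document-length
variation, OCR noise, or gradual (multi-year) drift. The null-calibration
and uneven-corpus diagnostics probe the second-order properties (false-alarm
rate, size-dependent noise floors) separately.

The uneven-corpus diagnostic ([stabilityDiagnostic()]) contrasts, on a
corpus whose early years have 10× fewer sentences, the naive single-model
distance to a mid-series reference year with the intra-normalized
multi-model statistic. We operationalize the contrast on the per-year level
of each statistic over a 100-token sample: the single-model distance sits
several-fold higher in the under-sampled years, while the multi-model ratio
stays near its large-corpus level, so the latter's across-year relative
spread is an order of magnitude smaller. Per-token standard deviations
within a year are not a reliable readout at these scales (both statistics'
token-level noise inflates roughly equally in small corpora); it is the
systematic year-level shift that the intra-year normalization removes.

## Numerical choices and degenerate inputs

- Cosine distances are clipped to \([0, 2]\) against floating-point
  rounding; zero-norm vectors are an error, and trained models never contain
  them.
- The intra-year denominator is floored at \(\varepsilon = 10^{-8}\) (with a
  warning) for the degenerate case of exactly agreeing replicates.
- Quantiles are linear-interpolation (type 7); the threshold's percentile
  rank is recovered by inverting the same interpolation.
- Procrustes handles rank-deficient cross-covariances by returning
  \(UV^\top\) anyway, with a degeneracy warning; fewer shared tokens than
  dimensions triggers an under-determination warning, fewer than 2 an error.
- Neighbour tables break distance ties lexicographically so output is
  deterministic.
- Overlapping or out-of-range annotation spans reject the document with a
  diagnostic rather than silently truncating: upstream taggers disagree
  about how to resolve overlaps, and guessing would corrupt offsets.
- Training vectors are single precision internally (the word2vec
  convention); all downstream statistics are double precision. The seeded
  single-worker trainer trades speed for exact reproducibility; multi-worker
  training would introduce nondeterministic update interleaving.

## Known limitations

- Only consecutive-year transitions are scored; a token absent in a middle
  year contributes two shorter runs, and changes spanning the gap are
  invisible.
- The CUSUM localization is the alarm transition, which for slow multi-year
  drifts lags the onset.
- One anchor model defines the common space; iterative multi-set alignment
  schemes might align better but are out of scope.
- The threshold pools all tokens, so a corpus in which most tokens genuinely
  change would raise the bar for every token.

## Reproducing the reference numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` recomputes,
from a fresh null corpus, the cosine anchor points and the percentile rank
of the derived global threshold; `tests/testthat/test-acceptance.R` runs the
ten-seed recovery benchmark and the calibration and stability diagnostics.
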