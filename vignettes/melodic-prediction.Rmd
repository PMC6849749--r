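---
title: "Modelling melodic expectation with melopredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling melodic expectation with melopredict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melopredict)
```

## The model

`melopredict` treats a melody as a sequence of discrete events — MIDI
pitch plus onset time on a 24-ticks-per-crotchet grid — and models a
listener who predicts each event from what came before.  The predictive
engine is a variable-order Markov model: it stores continuation counts
for every context up to an order bound and, at prediction time, blends
the maximum-likelihood estimates of all orders from the longest context
that has been seen down to a uniform floor over the alphabet.  The blend
is interpolated smoothing with escape method C: at an order where the
context has total count $N$ and $T$ distinct continuations,

$$p(s) = \frac{n(s)}{N+T} + \frac{T}{N+T}\,p_{\mathrm{lower}}(s).$$

This is the canonical PPM-C mixture; we chose it because it realizes a
weighted mixture of all lower-order predictions with weights that grow
with the diversity of what has followed the context, and because its
escape chain guarantees full support — every declared symbol keeps
nonzero probability, so information content is always finite.  Two
properties follow by construction and are property-tested: every emitted
distribution sums to one, and observing a (context, symbol) pair
strictly increases that symbol's predicted probability.

Two subsystems share this engine.  The **long-term model** (LTM) is
trained once on a corpus, simulating a lifetime of exposure to a style;
its order bound defaults to 3, a common compromise between specificity
and statistical reliability at folk-song corpus sizes.  The
**short-term model** (STM) starts empty at the beginning of every piece
and learns online — each event is predicted first, then added to the
counts — capturing sensitivity to within-piece repetition; its order
bound defaults to unbounded, since a single melody cannot overwhelm
memory.

## Viewpoints

Events are projected onto derived *viewpoints*: pitch interval `pi`,
chromatic scale degree `sd` (semitones above the tonic, taken mod 12 —
an explicit assumption, since octave-sensitive degrees would inflate the
alphabet on multi-octave corpora), inter-onset interval `ioi`, the
tempo-invariant `ioi-ratio` (stored as exact reduced fractions so the
alphabet stays finite on quantized corpora), and linked pairs such as
`pi x sd` that are defined only where both components are.  Undefined
positions (the first note for `pi`/`ioi`, the first two for `ioi-ratio`)
carry the marker `NA` and contribute neither as context nor as
predictands.

A viewpoint model predicts derived symbols; the predictor inverts the
viewpoint onto the basic alphabet of the attribute being predicted (the
candidate pitches, or candidate next iois).  When several basic symbols
share a derived symbol — every octave of a scale degree, for instance —
the derived mass is split equally among them and the result
renormalized.  Viewpoints that cannot be inverted at a position (no
previous pitch for `pi` at the first note) simply drop out there; if no
viewpoint applies, the prediction falls back to the uniform floor.  The
cross-domain link `sd x ioi-ratio` can be derived and studied, but is
not offered as a predictive viewpoint: inverting it requires the joint
pitch-by-ioi candidate space, and the standard configurations predict
pitch from `pi x sd` and onset from `ioi-ratio`.

## Combining predictions

Within a subsystem, the per-viewpoint distributions over the basic
alphabet are combined with entropy weights
$w_m = (H_m / H_{\max})^{-b}$, $H_{\max} = \log_2 |A|$, normalized to
sum to one; the two subsystems are then combined the same way.  The
scheme defaults to the arithmetic (weighted-mean) rule with $b = 2$;
both are configurable, and a geometric (renormalized weighted-product)
rule is provided.  $b$ controls how sharply certainty is rewarded —
values between 1 and 6 behave sensibly, and results in this package's
tests are not delicate in $b$.  Entropies entering the weights are
floored at $10^{-6}$ bits so that a degenerate, single-point
distribution cannot produce an infinite weight.

Pitch and onset are predicted in parallel and a note's probability is
the joint likelihood of the two.  Onset predictions begin at the second
event (the first has no ioi), so melody-level mean ICs are taken over
the events where both attributes are defined; this makes the joint mean
exactly the sum of the pitch and onset means.

## Similarity, segmentation, meter

**Compression distance** trains a model on $x$ alone and averages the
joint IC over the notes of $y$ (in bits per note).  The measure is
asymmetric; both directions and their mean are exposed, the symmetrized
mean being the default ranking key.  We deliberately do not normalize
by self-complexity or sequence length — distances stay interpretable as
bits per note, at the cost of longer, more complex queries having
larger distances overall.  Basic alphabets are resolved over both
melodies so that foreign material is scored on a shared support.

**Boundary detection** marks event $n$ as phrase-initial when its IC
exceeds the mean of the previous $w$ events by more than $k$ sample
standard deviations and exceeds the previous event's IC.  The window
defaults to $w = 10$ events (roughly one phrase of folk-song material)
and $k = 2$ (an ordinary outlier criterion); the standard deviation is
floored at $10^{-6}$ so flat windows cannot fire.  The boundary is
placed on the high-IC event itself — the first note of the new group.
Raising $k$ can only remove boundaries, which is tested.

**Metrical inference** treats the meter of a rhythm as a hidden pair
(category, phase).  The category prior is the empirical time-signature
frequency in an annotated corpus; the phase prior is uniform within a
category, over phases on the grid of the smallest ioi observed in
training (a tractable lattice that contains the true phase for corpora
notated from the bar line).  The likelihood of an onset given an
interpretation comes from a per-category PPM model over
(ioi, position-within-bar) symbols — making likelihood and prior both
conditional on the preceding rhythmic context — normalized over the
candidate iois realizable at that point, so likelihoods are comparable
across hypotheses.  Accumulation is in the log domain with per-event
renormalization, and per-event likelihoods are floored at $10^{-12}$
against degenerate rows.  The per-event predictive IC uses the
posterior from *before* the event, so metrical knowledge is never used
ahead of time; classification takes the category with maximal final
posterior mass summed over phases, breaking ties by prior and then by
label order.

## The two-culture analysis

Within-culture ICs use $k$-fold cross-validation (default 10): melodies
are shuffled by a seeded permutation, dealt round-robin into folds, and
each melody is scored under an LTM trained on the other folds.  The STM
is disabled throughout the analysis, isolating what the corpus alone
explains.  Between-culture ICs score every melody under the other
culture's full-corpus model.  Per-piece cultural distance is
$(\mathrm{IC}_{other} - \mathrm{IC}_{own})/\sqrt2$ — positive when a
piece is more predictable under its own culture's model — and
culture-neutral complexity is the orthogonal coordinate; the rotation
is an isometry, which is tested.  The summary's overall distance is the
mean of the per-piece *signed* distances (an interpretive choice: signed
and absolute means coincide only when every piece is own-model
predictable, which well-separated corpora approach), and accuracy is
the fraction of pieces with positive distance.  Corpora should be
deduplicated first with the interval-opening rule (openings of 10 pitch
intervals by default, rhythm ignored; the first occurrence in corpus
order survives).

One asymmetry deserves emphasis: own-culture models are cross-validated
but other-culture models are not, so if the two corpora share literal
duplicate pieces, the "foreign" model has memorized them and their
distances are driven negative.  Deduplication *within* a corpus does
not protect against duplicates *across* corpora; the analysis assumes
the cultures do not share compositions.

## Synthetic corpora

The generators exist so that every stage is testable against known
ground truth without external data.  A synthetic culture is a pair of
first-order Markov chains — one over scale degrees, one over ioi ratios
— plus a tonic and a melody-length range (15–25 events by default,
folk-song-like).  The default two-culture fixture contrasts a
diatonic-flavoured culture (seven degrees, strongly stepwise motion,
rhythm dominated by ratio 1) with a pentatonic-flavoured culture (five
degrees, wider gaps, rhythm favouring halving and doubling).  The
contrast loosely echoes a Western/Chinese folk-song comparison in which
pitch statistics separate the styles more than onset statistics and the
joint configuration separates them most; no ethnographic fidelity is
claimed.  Metrical rhythm corpora place onsets on a grid with
per-position accent probabilities, anchoring phase zero with a
guaranteed initial downbeat.  Perturbation operators (rhythm, interval,
contour, phrase-order, modulation) produce the manipulated variants
used in similarity experiments.

All generators are pure functions of (specification, seed) and restore
the caller's RNG state.  Because the melodies are first-order with
modest alphabets, passing tests show that the machinery recovers known
structure; they do not show that the defaults match the statistics of
any real repertoire — real melodies have longer-range structure,
phrase-level organization and non-stationarity that these chains lack.

Test and example problem sizes were chosen to make sampling noise small
relative to the effects tested while keeping runs desk-scale: 200
melodies per culture for the two-culture recovery, 40 rhythms per
category (8 bars each) for meter, 50 seeded trials for segmentation.

## Known limitations

- Monophonic input only; no harmony, voices, or audio.
- No key or tonic estimation: `sd` viewpoints require an annotated
  tonic.
- The PPM variant implements interpolated escape-C without update
  exclusion or hybrid LTM-plus-online updating; published results from
  other implementations are configuration-sensitive at the second
  decimal, and exact-number reproduction depends on smoothing details
  that vary between implementations.
- Boundary detection is single-level; no hierarchical grouping.
- The meter module's phase lattice assumes the smallest trained ioi
  divides the true phase offsets.
- The EsAC reader covers the common core of the notation (degrees,
  octave shifts, accidentals, underscores, dots, rests); exotic fields
  are ignored.
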