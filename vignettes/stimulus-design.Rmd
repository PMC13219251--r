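---
title: "Designing TP-controlled artificial-language streams with sylstream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing TP-controlled artificial-language streams with sylstream}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sylstream)
```

## The problem

Statistical-learning (SL) experiments expose listeners to streams of
syllables in which transitional probabilities (TPs) are high within
nonsense "pseudowords" and low at their boundaries.  In frequency-tagging
designs, syllables are presented isochronously (here 300 ms, i.e.
3.33 Hz) so that pseudowords of three syllables recur at 1.11 Hz, and
neural tracking at the pseudoword rate is read as evidence of TP
learning.  That inference is threatened by three classes of confounds:

1. **Statistical**: naive shuffling produces streams whose empirical TPs
   fluctuate around their targets, so some boundaries are more salient
   than others.
2. **Acoustic**: syllables that keep a fixed within-word position impose
   an envelope modulation at the word rate even in TP-uniform streams.
3. **Phonological**: if two neighbouring pseudowords share a distinctive
   feature at the same within-word position, that feature itself recurs
   at the word rate and can drive "word-rate" tracking without any TP
   computation.

`sylstream` generates stimuli that control all three: pseudoword lexicons
with minimal pairwise feature overlap, token streams with *exactly*
uniform transition counts in three modes, and diagnostics (information
traces, a Phonological Rhythmicity Index, amplitude-modulation spectra)
that make residual structure measurable.

## From phonemes to lexicons

Phonemes are rows of a binary distinctive-feature matrix (21 canonical
features: syl, son, cons, cont, delrel, lat, nas, strid, voi, sg, cg,
ant, cor, distr, lab, hi, lo, back, rnd, tense, long).  Ternary entries
collapse to presence/absence: only `+`/`1` counts as present.  By
default only single-character IPA symbols are retained; we count the
length mark `ː` as part of its base character, so long vowels survive
while affricates (`ts`) and diphthongs (`aɪ`) are excluded.

Syllables instantiate one fixed pattern over slots `c` (consonant,
`-syl`), `v` (short vowel) and `V` (long vowel, `+syl +long`); the
default `cV` with long vowels keeps vowel duration uniform for
isochronous presentation.  Each syllable carries the feature columns of
its phonemes; at the word level a syllable is summarised by 9 consonant
features (son, cont, lat, nas, voi, cor, lab, hi, back) evaluated on its
consonant and 6 vowel features (lab, hi, lo, back, tense, long) on its
vowel — a 15 × S binary matrix per word.

**Corpus controls.** Real frequency-of-use distributions are
Zipf-shaped; tokens that are much more or much less frequent than
typical carry lexical familiarity cues.  The uniformity filter
log-transforms counts, z-scores them, and removes tokens whose
two-sided standard-normal tail probability is ≤ α (default α = 0.05 for
syllables).  The same machinery filters pseudowords by phoneme
bigram/trigram and positional statistics, by presence (default) and
optionally by the same α rule.  Since the corpora used in practice
cannot be redistributed, the package ships a synthetic Zipf corpus
generator (`generate_synthetic_corpus()`): multinomial syllable draws
with rank-r probability ∝ r^(−s), chunked into trisyllabic "words" from
which n-gram and positional tables are derived.  This reproduces the
*shape* that the filters act on (heavy head, sparse tail), not any real
language's content — a green corpus test establishes that the filters
implement their definitions, not that the output resembles German.

**Phonotactic (OCP) controls.**  Consonants map to place classes
(labial, apical, other; labial wins when both `lab` and `cor` are
present so the classes partition) and manner classes (sonorant,
plosive, fricative, resolved in that order from `son`/`cont`); vowels
contribute their identity.  During word generation a candidate syllable
is rejected when its place, manner, or vowel equals that of any of the
previous `n_look_back = 2` syllables.  With trisyllabic words this
forces all three manners, places, and vowels within a word to be
distinct.

**Feature-overlap control.**  For one feature, each word contributes a
binary sequence over its S syllables.  A pair of words is *flagged* on
that feature iff the two sequences are identical **and** non-constant:
any such sequence recurs with the word period in a stream built from
the pair, while constant sequences carry no energy at the word rate.
This is deliberately broader than flagging only the single-position
case (e.g. `[1 0 0]` vs `[1 0 0]`); the broader rule is strictly more
conservative.  The pairwise overlap is the count of flagged features,
and lexicons are assembled to minimise the total over all pairs.

An exact consequence worth knowing (it constrains every possible
inventory): with OCP-manner active and S = 3, each word has exactly one
sonorant consonant, so its consonant-`son` sequence is one of only
three one-hot patterns.  Among any four words two must collide
(pigeonhole), so a four-word lexicon always has at least one pair with
overlap ≥ 1.  Demanding "no overlap at all" (`max_overlap = 1`)
together with the default OCP controls is therefore unsatisfiable, and
`assemble_lexicons()` reports the minimal achievable overlap in its
error.  The worked examples in this package use `max_overlap = 2`,
i.e. they allow exactly the provably unavoidable single shared feature
per pair.  Zero-overlap lexicons remain reachable (and are tested) for
registers not subject to the manner pigeonhole.

**Lazy best-first assembly.**  The search draws a seeded subsample
(`max_word_matrix`) of the register, computes the overlap matrix once,
and explores index-increasing prefixes with a monotone bucket priority
queue keyed on the accumulated overlap (an admissible bound: adding a
word never decreases it).  Complete combinations therefore emerge in
non-decreasing total-overlap order, lazily — only as many as requested
are materialised.  Equal-priority insertions are shuffled under the
seed, which randomises tie-breaking.  Pairs at or above `max_overlap`
are pruned, and (by default) so are pairs sharing a syllable, because
the stream graphs below require all W × S syllables to be distinct.
The comparison lag between two words' feature sequences defaults to the
word length S; other lags cyclically shift the second sequence and are
marked experimental, since their intended semantics is underdetermined.

## Exactly uniform transition counts: Eulerian circuits

A stream of T tokens from an alphabet of size N should satisfy: every
token occurs equally often, no token immediately repeats, and every
ordered pair of distinct tokens occurs equally often, i.e. each pair is
realized as close to μ = (T − 1)/(N(N − 1)) times as integrality
allows.  Any such sequence is the vertex-reading of an Eulerian circuit
on a balanced directed multigraph.  The package builds that graph with
exactly T edges, per-pair multiplicities ⌊·⌋/⌈·⌉, and drops the closing
edge on emission, reconciling integral edge counts with the T − 1
realized transitions.

Three modes:

* `word_structured` — vertices are the W words (complete digraph, no
  self-loops); the walked word sequence is expanded into syllables, so
  within-word TPs are exactly 1 and boundary TPs uniform at 1/(W−1).
* `position_random` — vertices are all N = W × S syllables, complete
  digraph; every off-diagonal TP ≈ 1/(N−1); no positional structure.
* `position_fixed` — syllables are partitioned into S position groups
  and edges only run from group p to group p+1 (mod S); each of the
  S·W² cross-group pairs receives ⌊R⌋/⌈R⌉ edges with R = T/(S·W²), so
  every admissible transition has TP ≈ 1/W and every syllable keeps its
  within-word position.

Surplus edges (when μ or R is fractional) are laid out as a circulant
over a seeded random relabeling of the vertices: offsets 1…extra add
one edge each, keeping in-degree = out-degree everywhere while
decorrelating the layout across streams.  Strong connectivity is
checked before every walk (it can only fail for degenerate
position-fixed settings with very few repetitions, where relabelings
are retried).

The walk itself is Hierholzer's algorithm with a greedy minimum-count
rule: at each step, among the unused out-edges of the current vertex,
take the one whose traversal count is smallest, breaking ties uniformly
at random under the seed; when stuck, splice a detour at the first
visited vertex with unused edges.  The greedy rule is what makes
empirical TPs converge to their targets within a few tokens rather than
only globally.  `naive_shuffle_stream()` implements the comparison
baseline (seeded permutation repaired by local swaps); its boundary-TP
variance is reliably larger, which the acceptance suite checks over 50
seeds.

## Information metrics

With P̂ᵢⱼ(t) the empirical next-token distribution from counts observed
strictly before t: surprisal S(t) = −log₂ P̂ of the realized transition;
per-source conditional entropy Hᵢ(t) with 0·log 0 = 0; H(t) their mean
over observed sources; and D(t) = log₂(N−1) − H(t) ≥ 0, the KL
divergence from uniform transitions, exactly 0 for perfectly uniform
counts.  One numerical choice: raw P̂ is zero before a pair's first
observation, which would make early surprisal infinite, so the
*surprisal trace only* uses add-one smoothing over the N−1 admissible
successors; entropy and divergence use raw counts.

A caveat the tests make explicit: at the default 15 repetitions the
position-random graph splits each vertex's 15 out-edges over 11 targets
as 7×1 + 4×2, so the final divergence is 0.0859 bits — the best any
stream can do, since 15 is not a multiple of 11 (D → 0 requires
divisibility, e.g. 22 repetitions).  A stated acceptance bound of
0.05 bits for this mode is therefore left red, with this analysis.

Structure-aware surprisal — the ideal observer that already knows the
words — is 0 within words (true TP = 1) and log₂(W−1) at boundaries;
the gap between it and the stream-level trace measures what inferring
word structure buys a learner.

## The Phonological Rhythmicity Index

Recode the TP pattern of a word-period stream as one "TP decay" per
period; a feature sequence counts as rhythmic only if it repeats for at
least two consecutive periods.  Kernels are therefore two concatenated
periods of the one-hot decay template at every cyclic lag (for S = 3:
`[1 0 0 1 0 0]`, `[0 1 0 0 1 0]`, `[0 0 1 0 0 1]`); arbitrary binary
templates, including non-uniformly periodic ones, are accepted.  For a
binary feature vector of length L, a window of the kernel length k
slides with stride 1 (L − k + 1 windows); a window scores one match iff
it equals any kernel exactly, with no double counting.  PRI =
matches / windows ∈ [0, 1]; the maximum across the 15 feature rows is
the worst-case confound of a stream.

The canonical worked example — kernels over
`[1 0 0 1 0 1 0 0 1 0 0 1 1 0 0]` — yields 3 matches in 10 windows.
Note that 3/10 = 0.30, although the accompanying prose reports the
ratio as "0.33"; this package treats the *match count* as authoritative
and returns 0.30.  Both numbers are surfaced here rather than silently
corrected.

Overlap-controlled lexicons exist precisely to keep this index low:
across seeded replicates, streams from minimal-overlap lexicons have
expected max-PRI no larger than streams from random lexicons of the
same register, and lexicon total overlap correlates positively with
mean stream max-PRI.  Both are asserted as directions, not magnitudes —
the published effect sizes depend on external corpora and benchmark
lexicons that are out of scope here.

## Audio rendering and modulation spectra

`render_stream_audio()` concatenates one fixed-duration slot (default
300 ms) per syllable, each normalized to a common RMS ("65 dB" is a
nominal digital-full-scale reference — 85 dB ≙ RMS 1.0 — not an SPL
calibration).  Internal synthesis is deterministic harmonic-plus-noise:
the vowel is four harmonics with hash-dependent weights; the consonant
portion's duration and texture are a *manner signature* (plosive:
closure + burst at 22% of the slot; fricative: 38% noise; sonorant: 30%
voiced hum, each ± small per-syllable jitter).  Because OCP gives every
word one consonant of each manner, word-mean envelopes come out nearly
equal — mimicking duration/amplitude-equalized natural syllables — while
position ensembles stay acoustically distinct.  That is exactly the
regime in which position-regular streams show envelope peaks at the
word rate and position-random streams do not.  The synthesis makes no
naturalness claims; it exists so spectra and pitch manipulations are
testable without recordings.  User-provided mono WAV syllables are
accepted instead: files within ±20% of the slot are uniformly
time-scaled, others padded/truncated with 10-ms cosine ramps.

Pitch contours of arbitrary duration are linearly resampled onto
syllable- or word-sized windows (endpoints preserved) and drive the
synthesis fundamental; for recordings, only the contour tracks are
exported — resynthesis of natural audio is a non-goal.

The amplitude-modulation spectrum takes the magnitude of the analytic
signal (FFT Hilbert transform), low-passes it at 30 Hz (FFT brick
wall), downsamples to 1 kHz, removes the mean, and computes the power
spectrum over the full duration, so the resolution is 1/duration —
0.0185 Hz for a 54-s stream, comfortably resolving 1.11 Hz.  Peak
*locations* are robust to these choices; absolute power is not, so
tests assert peak frequencies and power ratios only.  One practical
choice: spectra in the acceptance suite use long streams (45–90
repetitions, 162–324 s; 16 kHz sampling suffices for an envelope
analysis low-passed at 30 Hz).  The position-cycle component is an
exact spectral line whose power grows linearly with duration, whereas
the quasi-periodic recurrence of individual tokens (each token returns
roughly every N tokens under the Euler constraint) only contributes a
broad band; at 54 s the band can still rival the 1.11 Hz line for some
lexicons' manner arrangements, at 324 s it cannot.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `phoneme_pattern` | `cV` | syllable slots (c/v/V) |
| `syllable_alpha` | 0.05 | uniformity-filter threshold for syllables |
| `n_syllables_per_word` | 3 | word length S; sets the 1.11 Hz word rate |
| `n_look_back` | 2 | OCP window (syllables) |
| `bigram/trigram/position_alpha` | none | presence-only n-gram filters |
| `n_words_per_lexicon` | 4 | lexicon size W |
| `max_overlap` | 1 | pairwise flag bound (rejection at ≥); see pigeonhole note |
| `max_word_matrix` | 200 | overlap-matrix subsample; tests use 60–80 for speed |
| `n_repetitions` | 15 | token repetitions; stream length = reps × S × W |
| `max_rhythmicity` | none | max-PRI bound with reseeded retries |
| `syllable_duration_ms` | 300 | sets the 3.33 Hz syllable rate |

A single pipeline `seed` drives everything; each stochastic stage
derives a deterministic child seed, so whole bundles reproduce
bit-for-bit.

## What the synthetic world does not establish

The bundled inventory is a ~30-phoneme German-like miniature labelled
synthetic; the corpus generator reproduces Zipf shape only.  Green
tests establish that the algorithms meet their contracts (exact TP
uniformity, overlap minimality, PRI arithmetic, spectral peaks under
the stated synthesis), not that stimuli are intelligible, natural, or
matched to any real language's phonotactics.  Published corpus range
reductions, benchmark-lexicon comparisons, and effect sizes require
external data and are explicitly out of scope; the corresponding
properties are asserted as directions on synthetic data.  Mixed word
lengths, non-adjacent dependencies, entropy-varying streams, TTS, and
pitch-tier resynthesis of recordings are non-goals.
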