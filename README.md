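# sylstream

Artificial-language stimulus generation for statistical-learning (SL)
research: pseudoword lexicons with phonotactic and phonological
controls, syllable streams with *exactly* uniform transitional
probabilities (TPs), and diagnostics for frequency-tagging designs.

## Who this is for

Researchers building frequency-tagged SL experiments (behavioural or
EEG/MEG) in which syllables are presented isochronously (e.g. 300 ms →
3.33 Hz) and trisyllabic pseudowords emerge at the word rate
(1.11 Hz).  Neural or acoustic energy at the word rate is only
interpretable as TP learning if the stimuli control:

* **statistics** — empirical TPs should be flat, not merely flat in
  expectation;
* **acoustics** — position-regular baselines must reproduce the
  word-rate envelope peak that position-random streams lack;
* **phonology** — no distinctive feature should recur periodically at
  the word rate just because neighbouring pseudowords happen to share
  it at the same position.

## The core machinery

**TP uniformity via Eulerian circuits.** A stream of `T` tokens over an
alphabet of size `N` with no immediate repetitions and every ordered
pair realized `μ = (T−1)/(N(N−1))` times (up to integrality) is the
vertex-reading of an Eulerian circuit on a balanced directed
multigraph.  `sylstream` builds that graph for three modes —
word-structured (vertices = words; within-word TP = 1, boundary TP =
1/(W−1)), position-random (all N syllables, TP = 1/(N−1)), and
position-fixed (syllables restricted to their word position, TP = 1/W)
— and walks it with Hierholzer's algorithm under a greedy
minimum-count rule with seeded random tie-breaks.

**Phonological Rhythmicity Index (PRI).** Each stream becomes a binary
feature × position matrix; for every feature, two-period "TP decay"
kernels (for S = 3: `[1 0 0 1 0 0]`, `[0 1 0 0 1 0]`, `[0 0 1 0 0 1]`)
slide across the feature vector, and PRI = exact-match windows / total
windows.  The max across features is the worst-case phonological
confound.  Lexicons are assembled by a lazy best-first search that
yields word combinations in non-decreasing total feature overlap.

**Information metrics.** Online surprisal `S(t) = −log₂ P̂(t)`,
conditional entropy `H(t)`, and divergence from uniform
`D(t) = log₂(N−1) − H(t) ≥ 0`, plus the structure-aware surprisal that
is 0 within words and `log₂(W−1)` at boundaries.

## Worked example

```r
library(sylstream)

ft    <- load_feature_table()                    # bundled inventory
reg   <- build_syllable_register(ft, "cV")       # 152 cV syllables
words <- generate_word_register(reg, S = 3, n_words = 250,
                                max_word_tries = 25000, seed = 1)
lex   <- assemble_lexicons(words, n_lexicons = 1, max_overlap = 2,
                           max_word_matrix = 60, seed = 1)[[1]]
lex
#> <lexicon> 4 pseudowords, total overlap 3
#>   b_iː|z_ɛː|j_uː
#>   r_ɛː|p_uː|h_oː
#>   d_uː|x_yː|m_aː
#>   x_øː|m_iː|d_yː

s  <- generate_stream(lex, "word_structured", n_repetitions = 15, seed = 2)
s
#> <stream> word_structured: 180 syllables (12 distinct), seed 2
#>   b_iː z_ɛː j_uː d_uː x_yː m_aː b_iː z_ɛː j_uː x_øː m_iː d_yː ...

tp <- empirical_tp(s)
tp["b_iː", "z_ɛː"]          # within-word transition
#> [1] 1
# mean over the 12 word-boundary transitions: 0.333  (= 1/(W-1))

stream_pri_report(s)
#> <pri_report> max PRI = 0.143
#>   C_lab: 0.143
#>   C_cor: 0.126
#>   C_son: 0.114
#>   ...

w  <- render_stream_audio(generate_stream(lex, "position_fixed", 45, seed = 3))
ms <- amplitude_modulation_spectrum(w)
am_peak(ms, c(2, 5))$freq    # 3.33  (syllable rate)
am_peak(ms, c(0.5, 2))$freq  # 1.11  (word rate; absent in position_random)
```

The numbers mean: every within-word transition is deterministic
(TP = 1), boundaries are uniform at 1/3, at most 14% of PRI windows of
any feature match a word-periodic kernel, and the rendered audio
carries envelope peaks exactly at the syllable and word presentation
rates.

The whole pipeline (registers → corpus filters → OCP words → lexicons
→ streams → reports) runs from one seeded call or from the CLI:

```r
run_pipeline(list(n_words = 200, max_word_tries = 20000,
                  max_word_matrix = 60, max_overlap = 2,
                  n_lexicons = 1, seed = 5, output_dir = "out"))
```

```sh
Rscript inst/cli/sylstream.R evaluate --n_words 200 --max_word_tries 20000 \
    --max_word_matrix 60 --max_overlap 2 --n_lexicons 1 --seed 4 --out out
```

Note: the canonical defaults combine OCP-manner control with a strict
no-overlap bound (`max_overlap = 1`); for four trisyllabic words that
combination is provably unsatisfiable (a pigeonhole argument on the
one-hot sonorant sequences — see the vignette), so worked examples use
`max_overlap = 2`.

## Layout

* `R/` — phonology, corpus, lexicon, streams, metrics, audio, config
  modules
* `inst/extdata/phoneme_features_synthetic.csv` — miniature synthetic
  phoneme inventory (21 features)
* `inst/cli/sylstream.R` — command-line pipeline
* `vignettes/stimulus-design.Rmd` — models, assumptions, numerical
  choices, limitations
* `tests/testthat/` — unit, property, and acceptance suites
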