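Package: sylstream
Title: Artificial Language Syllable Streams with Transitional-Probability
    and Phonological Rhythmicity Controls
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates pseudoword lexicons and frequency-tagged syllable
    streams for statistical-learning experiments.  Pseudowords are built
    from a distinctive-feature phoneme inventory under obligatory contour
    principle (OCP) phonotactic constraints and corpus-frequency filters;
    lexicons are assembled to minimise pairwise phonological feature
    overlap.  Streams with exactly uniform empirical transitional
    probabilities are produced by walking Eulerian circuits on directed
    multigraphs with a greedy minimum-count rule, in three modes
    (word-structured, position-random, position-fixed).  Diagnostics
    include online surprisal/entropy/KL traces, a Phonological
    Rhythmicity Index based on binary kernel matching, and amplitude
    modulation spectra of rendered audio.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
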