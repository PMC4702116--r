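Package: bfbspace
Title: Evolution Space of Breakage-Fusion-Bridge Cycles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete and stochastic models of breakage-fusion-bridge (BFB)
    cycles in cancer genomes. Provides the fold-word/fold-sequence algebra of
    folded BFB structures and its reversal algorithm, 2-d poset trees and
    linear-extension counting of qualitatively distinct BFB evolutions, exact
    census recursions for sequences, evolutions and copy-number profiles, a
    stochastic model of unfolded structure lengths (order statistics of the
    multiplicative uniform process, fold-position likelihoods), simulation of
    BFB cascades and binned read-depth tracks, and maximum-likelihood ranking
    of candidate BFB evolutions against segmented amplicon read-depth
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
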