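Package: vicarscan
Title: Vicariance Signal in Historical Biogeography from Dated Phylogenies
Version: 1.0.0
Authors@R:
    person("Vicarscan", "Developers", email = "vicarscan@example.org",
           role = c("aut", "cre"))
Description: Ancestral geographic-range reconstruction on rooted, dated
    phylogenies under the dispersal-extinction-cladogenesis (DEC) likelihood
    model and dispersal-vicariance (DIVA-style) event parsimony, together
    with a whole-phylogeny vicariance summary statistic (per-node vicariance
    probabilities and indicators aggregated over a focal node set), clade-age
    and relative-age summaries from posterior samples of dated trees, and a
    forward simulator of Yule trees and DEC range histories with a logged,
    replayable event history for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
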