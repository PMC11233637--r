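Package: nudgesim
Title: Simulation and Analysis of Nudge Agents in Intergroup Token-Exchange Games
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates round-based token-exchange games between two groups of
    four players in which artificial "nudge" agents exhibit outgroup altruism,
    either nonadaptively (random outgroup allocation every round) or adaptively
    via a cluster hidden Markov model (CHMM) that predicts which outgroup
    participants are likely to reciprocate. Provides synthetic human allocation
    policies with ingroup bias, reciprocity and norm enforcement; the study
    dependent variables (per-wave ingroup favoritism, normalized allocations by
    target category, withdrawal-of-cooperation contrasts, fairness and
    humanness rating summaries); replicated experiment designs; and
    bootstrap/permutation inference over replicated games. Game logs round-trip
    through a documented CSV schema for audit and replay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
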