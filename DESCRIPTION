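Package: m6atlas
Title: Meta-Epitranscriptomic m6A Landscapes Along Developmental Hierarchies
Version: 0.1.0
Authors@R:
    person("m6atlas", "Maintainers", email = "maintainers@m6atlas.dev",
           role = c("aut", "cre"))
Description: Gene-level quantification of N6-methyladenosine (m6A) from
    paired immunoprecipitation (IP) and input count matrices using a
    negative-binomial Wald test, assembly of relative m6A Z-score landscapes
    across cell populations, classification of m6A inheritance along a rooted
    developmental hierarchy, integration of m6A with expression profiles by
    K-means co-clustering and hypergeometric gene-set enrichment, overlay of
    knockout differential expression with m6A target status, and mRNA decay
    half-life estimation from transcription-arrest time courses.  Includes a
    seeded synthetic-data generator that plants ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
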