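Package: formsem
Title: Form-Meaning Systematicity Analysis for Sign-Language Lexicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the correspondence between phonological form and
    semantic similarity across a sign-language lexicon. Builds a phonological
    vector space from categorical feature annotations (handshape, location,
    movement) by one-hot encoding and truncated singular value decomposition,
    pairs it with a pre-trained word-embedding space, and measures
    semantic-phonological similarity correlation both lexicon-wide over all
    unordered sign pairs and within semantically coherent regions obtained by
    Ward hierarchical clustering with a pruning-height sweep scored by
    silhouettes. Includes a seeded synthetic-lexicon generator with planted
    cluster structure and tunable form-meaning coupling for validation and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
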