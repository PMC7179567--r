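Package: motifTuples
Title: Closed Frequent Subsequence Tuples with Mutation Profiles for
    Sequence Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers closed frequent gap-less subsequences in a set of
    DNA, RNA or protein sequences, mines their closed co-occurrence
    combinations (duplicate members allowed), orders the combinations into
    frequent-sequence tuples by re-scanning the sequences, and attaches a
    mutation profile to each tuple via approximate matching under the edit
    distance. Tuples with profiles serve as feature descriptors for
    sequence classification: exact tuple matches score 1, recognised
    approximate matches score the ratio of the mutation-record frequency
    to the exact-match frequency. Includes labelled sparse-matrix (libsvm)
    export, conversion of mutation profiles to position-specific scoring
    matrices, and a seeded synthetic-sequence generator with planted
    motif tuples for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    Matrix,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
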