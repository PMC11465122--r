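Package: rpfp
Title: Recursive Prefix-Free Parsing and Run-Length BWT Index Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the run-length encoded Burrows-Wheeler transform, sampled
    suffix array and sampled LCP array of a text collection (for example a
    pangenome of many similar haplotypes) by recursive prefix-free parsing:
    the text is parsed into overlapping phrases delimited by Karp-Rabin
    trigger strings, the resulting parse is parsed again, and the index is
    constructed from the two dictionaries and the second-level parse alone,
    never holding the first-level parse. Includes a brute-force oracle for
    verification, a synthetic pangenome generator, FASTA input, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
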