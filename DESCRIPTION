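Package: splintstore
Title: Droplet DNA Data Storage with Splint-Ligation Assembly and Address-Primer Decoding
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end in-silico toolkit for droplet-based DNA digital
    data storage. Encodes 7-bit ASCII text into address-flanked DNA word
    fragments protected by a shortened Reed-Solomon code over GF(2^7), and
    16x16 four-colour pixel frames into 90-nt indexed oligo pools via a
    homopolymer-free two-pixel-per-codon code. Simulates programmable
    splint-ligation assembly of fragments into serial and parallel data
    pools with copy-number and yield bookkeeping, simulates error-bearing
    paired-end sequencing reads of the pools, and decodes reads by
    address-primer scanning, payload segmentation, consensus calling and
    error correction, including in-silico PCR random access. Ships
    calculators for ligation efficiency, serial-assembly yield, per-oligo
    byte accounting and droplet storage capacity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
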