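---
title: "Methods: droplet DNA data storage in silico"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet DNA data storage in silico}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(splintstore)
```

`splintstore` models a complete droplet-based DNA data-storage workflow:
encoding digital data into synthetic oligonucleotides, assembling those
oligos into longer data species by splint ligation, sequencing the
resulting pools with realistic errors, and decoding the reads back to the
original data. This vignette documents the model, every default parameter,
and the limitations of each stage.

## Address sequences

Every data-bearing fragment is flanked by 20-nt *address sequences*. An
address doubles as a PCR primer site (random access) and as a
synchronization marker for decoding: payload sizes and positions are never
stored explicitly, they are inferred by locating addresses in the reads.

`make_address_book()` samples addresses by rejection so that every pair of
addresses differs at **at least 8 of 20 positions**. This guarantees that
the scanner's mismatch tolerance (up to 5 mismatches in a 20-nt window,
see below) can never confuse two addresses: two hits on the same window
would require the addresses to agree on at least 10 positions.

```{r}
book <- make_address_book(n_forward = 3, n_internal = 0, n_reverse = 3, seed = 42)
book
```

Roles are `forward` (5' end of a word, PCR forward-primer site),
`internal`, and `reverse` (3' end). All sequences in the book are recorded
on the sense strand; a physical reverse PCR primer is the reverse
complement of the recorded reverse address.

## Text codec: 7-bit ASCII with a shortened Reed–Solomon code

A word is encoded as:

1. Characters map to their 7-bit ASCII codes (printable codes 1–127), one
   symbol per character.
2. Two parity symbols are appended by a **shortened Reed–Solomon code over
   GF(2^7)** (primitive polynomial $x^7 + x^3 + 1$, generator roots
   $\alpha^0, \alpha^1$). Two parity symbols correct **one symbol error**
   anywhere in the codeword — one corrupted character per word.
3. The symbol stream is serialized to bits (MSB first) and the bits map to
   bases two at a time: `00→A`, `01→C`, `10→G`, `11→T`. A word of $n$
   characters has $7(n+2)$ bits; when that is odd, **one zero bit is
   padded** (exactly one, by construction), giving a payload of
   $\lceil 7(n+2)/2 \rceil$ bases.
4. The payload is flanked by its forward and reverse addresses.

```{r}
wf <- encode_word("Apple", book[book$id == "F1", ], book[book$id == "R1", ])
wf
decode_word(wf$payload)
```

**Limitation (base straddling).** A base carries two bits that may belong
to two adjacent 7-bit symbols. A single-base substitution at such a
boundary corrupts *two* symbols, which exceeds the one-symbol correction
capacity. The guarantee is therefore: any single-base substitution whose
two bits fall **within one symbol** is always corrected; boundary
substitutions are corrected only when one of the two affected symbols
happens to decode cleanly. Deletions and insertions shift the frame and
are handled upstream, by consensus over read cohorts, not by the RS code.

## Pixel codec: homopolymer-free two-pixel codons

A 16×16 frame of 2-bit pixels (4 colours) is encoded two pixels (4 bits)
at a time into one of 16 three-base **codons**. The default table
(`build_codon_table()`, id `"lex16"`) takes the 16 lexicographically
smallest 3-mers that contain no two adjacent equal bases. Any
concatenation of such codons has a homopolymer run of at most 2: a run of
3 across a junction would force an adjacent repeat inside one codon.

Each frame fragments into **eight 90-nt oligos**: a 20-nt forward address,
a 2-nt base-4 index (oligo order within the frame), 48 nt of payload
(16 codons = 32 pixels), and a 20-nt reverse address. The logical density
of the codon code is $4/3 \approx 1.33$ bits per base.

```{r}
frame <- random_frame(seed = 7)
oligos <- encode_frame(frame, build_codon_table(),
                       book[book$id == "F1", ], book[book$id == "R1", ])
length(oligos); nchar(oligos[[1]]$full_seq)
```

## Splint-ligation assembly

Two single-stranded fragments are joined by a 30-nt **splint**: the
reverse complement of the last 15 nt of the upstream fragment followed by
the reverse complement of the first 15 nt of the downstream fragment
(`design_splint()`). `ligate()` forms a product only when both 15-mer
arms match exactly and the downstream fragment is 5'-phosphorylated.

Yield follows `yield_model()`:

* `efficiency = 0.185` by default — the per-junction ligation efficiency
  measured for the experimental system this package models (1.67×10^12 of
  9.04×10^12 input copies ligated, i.e. 18.5%).
* `mode = "expectation"` (deterministic: `copies × efficiency`) or
  `"bernoulli"` (binomial draw, seedable).

Serial assembly of $n+1$ fragments crosses $n$ junctions, so the full
product yield compounds as $e^n$: at the default efficiency, four
junctions retain `serial_efficiency(0.185, 4)` = 0.1% of input copies.
`assembly_program()` / `run_program()` chain `serial_step()` and
`parallel_step()` operations over named droplet pools, conserving copy
numbers between products and leftovers. `size_ladder()` summarizes a pool
by species length, the in-silico analogue of a gel lane.

```{r}
frags <- lapply(1:3, function(i)
  as_fragment(encode_word(c("DNAdata", "Stores", "Apple")[i],
                          book[book$id == paste0("F", i), ],
                          book[book$id == paste0("R", i), ]), copies = 1000))
prog <- assembly_program(
  serial_step("d1", "d2", "s2", design_splint(frags[[1]], frags[[2]])),
  serial_step("s2", "d3", "s3", design_splint(frags[[2]], frags[[3]])))
pools <- run_program(prog, list(d1 = pool(frags[[1]]), d2 = pool(frags[[2]]),
                                d3 = pool(frags[[3]])))
size_ladder(pools$s3)
```

## Read simulation

`simulate_reads()` draws `depth × n_species` reads, sampling species in
proportion to copy number. Each read passes through a per-base error
channel (`error_profile()`): independent substitution, deletion, and
insertion probabilities per position (defaults 0.003 / 0.001 / 0.001).
Half the reads, in expectation, are flipped to the antisense strand;
`paired = TRUE` adds a mate that is the read's reverse complement. Every
read carries a **truth ledger** row (species, orientation, error counts),
so simulated error classes can be compared against decoder-inferred ones
(`class_fractions()`).

The simulator reads full molecules end to end. It deliberately does *not*
model read-length truncation, quality-score decay along the read,
position- or motif-dependent error rates, chimeras, or PCR amplification
bias — pool composition enters only through copy numbers. Quality strings
are a constant placeholder (Q30).

## Decoding

`decode_pool()` runs the full pipeline:

1. **Orient**: each read is scanned in both orientations; the orientation
   with the larger total matched-address score wins.
2. **Scan** (`scan_addresses()`): a hit is a full 20-nt window with at
   most 5 mismatches, or an exact match of **at least 15 nt** where an
   address is truncated at a read end. Forward addresses may start in the
   first 6 positions or from position 21 onward (interior junctions of
   ligated products); other roles only from position 21. Overlaps resolve
   by longer match, then fewer mismatches, then leftmost.
3. **Segment**: payload $k$ is the span strictly between hits $k$ and
   $k+1$; junction spans between a reverse and the next forward address
   are empty by construction.
4. **Consensus**: reads grouped by (address path, payload ordinal); the
   cohort is the modal payload length, and the consensus is the
   per-position plurality base (lexicographic tie-break). Minority-length
   reads are excluded from the consensus but still counted — this is the
   length filter.
5. **Decode**: text payloads through `decode_word()` (with and without
   using the RS correction, reported separately as `words_no_ecc` and
   `words_ecc`); pixel payloads split into index + codons and rebuilt per
   frame with `decode_frame()`.
6. **Classify**: each aligned read is compared with its species reference
   (addresses + consensus spans) by the length rule — `perfect`,
   `substitution` (equal length), `deletion_1_2` (1–2 nt shorter),
   `insertion` (longer), `other`.

The report's filters are monotone by construction:
`aligned ≥ length_match ≥ perfect`.

```{r}
rs <- simulate_reads(pools$s3, depth = 30,
                     profile = error_profile(0.005, 0.001, 0.001, seed = 1),
                     paired = TRUE)
decode_pool(rs, book, codec = "text")
```

`random_access()` models PCR selection: keep the species (or reads) whose
sense strand contains the forward address followed by the reverse address.

## Quantification defaults

| quantity | function | value |
|---|---|---|
| ligation efficiency, printed copy numbers | `ligation_efficiency(1.67e12, 9.04e12)` | 18.5 % |
| 4-junction serial yield | `serial_efficiency(0.185, 4)` | 0.1 % |
| codon-code density | `codon_bit_density()` | 4/3 bits/bp |
| oligos per 16×16 frame | `oligos_per_frame()` | 8 |
| bytes per oligo, 0.28 kB file | `bytes_per_oligo(0.28, 8)` | 35 B |
| droplet capacity | `droplet_capacity(9.04e12, 1000, 33.7)` | ≈ 304.6 GB |

Percentages are rounded half-away-from-zero to one decimal
(`round_half_away()`), matching how such figures are conventionally
printed. GB means $10^9$ bytes.

## Design decisions and known discrepancies

* **Problem sizes are package choices.** Sequencing depths, copy numbers,
  and error rates used in examples and tests are desk-scale defaults, not
  measurements; real runs involve millions of reads.
* **Word length arithmetic.** "DNAdata Stores Apple" encodes to fragments
  of 72 + 68 + 65 nt whose two-junction serial product is 205 nt. The
  encoding rules stated above make this length exact; figures of a few
  base pairs less that circulate for this example are not reproducible
  from the stated layout and are treated as a typographical artefact.
* **Error correction scope.** One RS symbol per word; whole-word recovery
  under heavy corruption relies on depth and consensus, not on the code.
* **Ligation model.** Junction matching is exact 15+15 hybridization;
  partial hybridization, off-target splinting, and ligase kinetics are
  out of scope.
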