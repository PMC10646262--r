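make_sentence <- function(words = c("DNAdata", "Stores", "Apple"),
                          book = test_book(), copies = 1000) {
  frags <- word_fragments(words, book, copies)
  list(book = book, frags = frags, pool = serial_pool(frags))
}

test_that("reads are oriented using address information", {
  sc <- make_sentence()
  frag <- sc$frags[[1]]$seq
  o1 <- orient_read(frag, sc$book)
  expect_false(o1$flipped)
  expect_identical(o1$seq, frag)
  o2 <- orient_read(revcomp(frag), sc$book)
  expect_true(o2$flipped)
  expect_identical(o2$seq, frag)
  o3 <- orient_read(strrep("AC", 30), sc$book)
  expect_identical(o3$flag, "unknown")
  expect_false(o3$flipped)
})

test_that("address scanning finds error-free hits at exact offsets", {
  book <- test_book()
  p1 <- "ACGTACGTAC"  # 10-nt payload
  read <- paste0(book$seq[1], p1, book$seq[2], p1, book$seq[4])
  hits <- scan_addresses(read, book)
  expect_identical(nrow(hits), 3L)
  expect_identical(hits$address_id, c("F1", "F2", "R1"))
  expect_identical(hits$start, c(0L, 30L, 60L))
  expect_identical(hits$end, c(20L, 50L, 80L))
  expect_identical(hits$mismatches, c(0L, 0L, 0L))
})

test_that("partial 15-of-20 matching tolerates substitutions inside any address", {
  book <- test_book()
  payload <- "TTGACTGACT"
  read0 <- paste0(book$seq[1], payload, book$seq[2], payload, book$seq[4])
  for (pos in c(1, 10, 20, 31, 40, 50, 61, 70, 80)) {
    read <- read0
    cur <- substr(read, pos, pos)
    substr(read, pos, pos) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    hits <- scan_addresses(read, book)
    expect_identical(hits$address_id, c("F1", "F2", "R1"),
                     info = paste("substitution at", pos))
  }
})

test_that("scanning matches the exhaustive sliding-window oracle on 500 seeded reads", {
  book <- test_book(seed = 77)
  set.seed(38)
  for (case in 1:500) {
    L <- sample(20:60, 1)
    # half the cases embed real address material, half are pure noise
    read <- if (case %% 2 == 0) {
      a <- book$seq[sample(nrow(book), 1)]
      cut <- sample(0:10, 1)
      body <- substr(a, cut + 1, 20)
      pre <- if (cut > 0) random_seq(cut + 20) else ""
      out <- paste0(pre, body, random_seq(max(0, L - nchar(body) - nchar(pre))))
      substr(out, 1, max(nchar(out), 1))
    } else random_seq(L)
    got <- scan_addresses(read, book)
    want <- brute_scan(read, book)
    expect_identical(got, want, info = paste("case", case, read))
  }
})

test_that("payload segmentation recovers the encoder's layout exactly", {
  sc <- make_sentence()
  product <- Filter(function(f) nchar(f$seq) == 205L, sc$pool$members)[[1]]
  o <- orient_read(product$seq, sc$book)
  seg <- segment_payloads(o$seq, o$hits)
  expect_true(seg$aligned)
  expect_true(seg$terminal)
  expect_identical(seg$path, "F1-R1-F2-R2-F3-R3")
  pl <- seg$payloads
  expect_identical(nrow(pl), 5L)
  data_spans <- pl[pl$left_role == "forward", ]
  expect_identical(data_spans$length, c(32L, 28L, 25L))
  expect_identical(data_spans$seq,
                   vapply(c("DNAdata", "Stores", "Apple"), function(w)
                     encode_word(w, sc$book[1, ], sc$book[4, ])$payload,
                     character(1), USE.NAMES = FALSE))
  # junction spans are empty and flagged
  expect_true(all(pl$empty[pl$left_role == "reverse"]))
  # fewer than two hits marks the read unalignable
  expect_false(segment_payloads("ACGT", scan_addresses("ACGT", sc$book))$aligned)
})

test_that("consensus is the per-position plurality with lexicographic ties", {
  segs <- lapply(c("ACGT", "ACGT", "ACTT"), function(s) {
    structure(list(aligned = TRUE, path = "F1-R1", terminal = TRUE,
                   payloads = data.frame(ordinal = 0L, left_id = "F1",
                                         left_role = "forward", right_id = "R1",
                                         start = 20L, end = 24L, length = 4L,
                                         seq = s, empty = FALSE,
                                         stringsAsFactors = FALSE)),
              class = "segmented_read")
  })
  g <- group_and_consensus(segs)
  expect_identical(g$consensus, "ACGT")
  expect_identical(g$n_reads, 3L)
  expect_identical(g$n_modal, 3L)
  # 1-1 tie at a position: lexicographically smallest base wins
  segs2 <- segs[1:2]
  segs2[[2]]$payloads$seq <- "TCGT"
  expect_identical(group_and_consensus(segs2)$consensus, "ACGT")
  # minority-length reads are excluded from the cohort but counted
  segs3 <- c(segs, list(segs[[1]]))
  segs3[[4]]$payloads$seq <- "ACG"
  segs3[[4]]$payloads$length <- 3L
  g3 <- group_and_consensus(segs3)
  expect_identical(g3$n_reads, 4L)
  expect_identical(g3$n_modal, 3L)
  expect_identical(g3$modal_length, 4L)
})

test_that("the length rule classifies reads as in the error taxonomy", {
  ref <- "ACGTACGTAC"
  expect_identical(classify_read(ref, ref), "perfect")
  expect_identical(classify_read("ACGTACGTAG", ref), "substitution")
  expect_identical(classify_read("ACGTACGTA", ref), "deletion_1_2")
  expect_identical(classify_read("ACGTACGT", ref), "deletion_1_2")
  expect_identical(classify_read("ACGTACG", ref), "other")
  expect_identical(classify_read("ACGTACGTACA", ref), "insertion")
})

test_that("error-free end-to-end decoding recovers the programmed sentence", {
  sc <- make_sentence()
  rs <- simulate_reads(sc$pool, depth = 20,
                       profile = error_profile(0, 0, 0, seed = 10), paired = TRUE)
  rep <- decode_pool(rs, sc$book, codec = "text")
  full <- rep$species[rep$species$path == "F1-R1-F2-R2-F3-R3", ]
  expect_identical(full$text, "DNAdata Stores Apple")
  expect_identical(rep$aligned, rep$n_reads)
  expect_identical(rep$perfect, rep$n_reads)
  expect_true(all(rep$classes[["perfect"]] == 1))
})

test_that("decoded word order follows the programmed splint order", {
  book <- test_book(4)
  words <- c("DNAdata", "Stores", "Apple", "Orange")
  frags <- word_fragments(words, book)
  fwd <- serial_pool(frags)
  rs <- simulate_reads(fwd, depth = 15, profile = error_profile(0, 0, 0, seed = 11))
  rep <- decode_pool(rs, book, codec = "text")
  expect_true("DNAdata Stores Apple Orange" %in% rep$species$text)
  # permute the assembly order: the decoded sentence permutes with it
  perm <- serial_pool(frags[c(1, 3, 2, 4)])
  rs2 <- simulate_reads(perm, depth = 15, profile = error_profile(0, 0, 0, seed = 12))
  rep2 <- decode_pool(rs2, book, codec = "text")
  expect_true("DNAdata Apple Stores Orange" %in% rep2$species$text)
})

test_that("parallel pools demultiplex into one species per address path", {
  book <- test_book(4)
  head_words <- c("DNAdata", "Stores")
  tail_words <- c("Apple", "Orange", "Grape")
  heads <- word_fragments(head_words, book)
  head_pool <- serial_pool(heads)  # unit efficiency: the chain species only
  tails <- lapply(seq_along(tail_words), function(i) {
    wf <- encode_word(tail_words[i],
                      book[book$id == sprintf("F%d", i + 1), ],
                      book[book$id == sprintf("R%d", i + 1), ])
    as_fragment(wf, copies = 500)
  })
  # one shared upstream (the serial head) with three distinct splints
  chain <- Filter(function(f) nchar(f$seq) > 100, head_pool$members)[[1]]
  splints <- lapply(tails, function(t) design_splint(chain, t))
  res <- run_program(
    assembly_program(parallel_step("head", "tails", "out", splints)),
    list(head = head_pool, tails = pool(tails)))
  products <- Filter(function(f) nchar(f$seq) > 150, res$out$members)
  expect_length(products, 3L)
  rs <- simulate_reads(pool(products), depth = 15,
                       profile = error_profile(0, 0, 0, seed = 13))
  rep <- decode_pool(rs, book, codec = "text")
  texts <- rep$species$text
  expect_true(all(c("DNAdata Stores Apple", "DNAdata Stores Orange",
                    "DNAdata Stores Grape") %in% texts))
})

test_that("pixel pools decode back to their frames, including serial movie products", {
  book <- make_address_book(3, 0, 3, seed = 55)
  tab <- build_codon_table()
  frames <- lapply(1:3, random_frame)
  oligo_sets <- lapply(1:3, function(i)
    encode_frame(frames[[i]], tab, book[book$id == sprintf("F%d", i), ],
                 book[book$id == sprintf("R%d", i), ],
                 frame_id = sprintf("F%d", i)))
  # ligate index-matched oligos of the three frames into 270-nt products
  products <- lapply(0:7, function(k) {
    f1 <- as_fragment(oligo_sets[[1]][[k + 1]], copies = 100)
    f2 <- as_fragment(oligo_sets[[2]][[k + 1]], copies = 100)
    f3 <- as_fragment(oligo_sets[[3]][[k + 1]], copies = 100)
    res <- run_program(assembly_program(
      serial_step("a", "b", "ab", design_splint(f1, f2)),
      serial_step("ab", "c", "abc", design_splint(f2, f3))),
      list(a = pool(f1), b = pool(f2), c = pool(f3)))
    Filter(function(f) nchar(f$seq) == 270L, res$abc$members)[[1]]
  })
  expect_true(all(vapply(products, function(p) nchar(p$seq), integer(1)) == 270L))
  rs <- simulate_reads(pool(products), depth = 8,
                       profile = error_profile(0, 0, 0, seed = 14))
  rep <- decode_pool(rs, book, codec = "pixel", codon_table = tab)
  expect_setequal(names(rep$frames), c("F1", "F2", "F3"))
  for (i in 1:3) {
    expect_identical(rep$frames[[sprintf("F%d", i)]]$frame,
                     matrix(as.integer(frames[[i]]), 16, 16))
  }
})

test_that("consensus at depth rescues substitution-laden pools", {
  sc <- make_sentence()
  rs <- simulate_reads(sc$pool, depth = 100,
                       profile = error_profile(p_sub = 0.01, seed = 15))
  rep <- decode_pool(rs, sc$book, codec = "text")
  expect_true("DNAdata Stores Apple" %in% rep$species$text)
  # filter monotonicity on a corrupted read set
  expect_gte(rep$aligned, rep$length_match)
  expect_gte(rep$length_match, rep$perfect)
  # ECC monotonicity
  expect_gte(rep$words_ecc, rep$words_no_ecc)
})

test_that("random access selects species by ordered primer containment", {
  book <- test_book(4)
  words <- c("Apple", "Orange", "Grape")
  frags <- word_fragments(words, book)
  pl <- pool(frags)
  sel <- random_access(pl, "F2", "R2", book)
  expect_length(sel$members, 1L)
  expect_identical(sel$members[[1]]$id, "Orange")
  # wrong order: reverse primer site upstream of forward
  swapped <- pool(fragment("x", paste0(revcomp(book$seq[book$id == "R1"]),
                                       "ACGTACGTAC",
                                       book$seq[book$id == "F1"])))
  expect_warning(sel2 <- random_access(swapped, "F1", "R1", book),
                 "no species")
  expect_length(sel2$members, 0L)
  # read sets filter in either orientation, then decode alone
  rs <- simulate_reads(pl, depth = 20, profile = error_profile(0, 0, 0, seed = 16))
  sub <- random_access(rs, "F3", "R3", book)
  expect_true(all(sub$truth$species_id == "Grape"))
  rep <- decode_pool(sub, book, codec = "text")
  expect_identical(rep$species$text, "Grape")
})

test_that("an empty read set yields an empty report", {
  rep <- decode_pool(character(0), test_book(), codec = "text")
  expect_identical(rep$n_reads, 0L)
  expect_identical(rep$aligned, 0L)
})
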