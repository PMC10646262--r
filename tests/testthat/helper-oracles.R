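# Independent oracles used across tests. These deliberately avoid the
# package's own implementation paths.

# carry-less (Russian peasant) multiplication in GF(2^7) with modulus
# x^7 + x^3 + 1; no log/antilog tables
peasant_gf_mul <- function(a, b) {
  r <- 0L
  while (b > 0L) {
    if (bitwAnd(b, 1L)) r <- bitwXor(r, a)
    b <- bitwShiftR(b, 1L)
    a <- bitwShiftL(a, 1L)
    if (a >= 128L) a <- bitwXor(a, 137L)
  }
  r
}

# polynomial evaluation via the peasant multiplier (syndrome oracle)
peasant_poly_eval <- function(p, x) {
  acc <- 0L
  for (c in p) acc <- bitwXor(peasant_gf_mul(acc, x), as.integer(c))
  acc
}

# exhaustive sliding-window address scan: every address, every offset, every
# admissible window, then the same (longer, fewer mismatches, leftmost)
# greedy selection, all written as plain loops
brute_scan <- function(read, book, min_match = 15L, max_match = 20L) {
  L <- nchar(read)
  rows <- list()
  add <- function(id, role, start, w, mm) {
    rows[[length(rows) + 1L]] <<- data.frame(
      address_id = id, role = role, start = start, end = start + w,
      matched_length = w, mismatches = mm, stringsAsFactors = FALSE)
  }
  mism <- function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  for (i in seq_len(nrow(book))) {
    addr <- book$seq[i]
    for (start in 0:max(0L, L - max_match)) {
      if (L - start >= max_match) {
        mm <- mism(substr(read, start + 1L, start + max_match), addr)
        if (mm <= max_match - min_match) add(book$id[i], book$role[i], start, max_match, mm)
      }
    }
    for (w in min_match:(max_match - 1L)) {
      if (L >= w) {
        if (substr(read, 1L, w) ==
            substr(addr, max_match - w + 1L, max_match)) {
          add(book$id[i], book$role[i], 0L, w, 0L)
        }
        if (substr(read, L - w + 1L, L) == substr(addr, 1L, w)) {
          add(book$id[i], book$role[i], L - w, w, 0L)
        }
      }
    }
  }
  empty <- data.frame(address_id = character(0), role = character(0),
                      start = integer(0), end = integer(0),
                      matched_length = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(rows)) return(empty)
  cand <- do.call(rbind, rows)
  ok <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    ok[r] <- if (cand$role[r] == "forward") {
      cand$start[r] <= 5L || cand$start[r] >= 20L
    } else cand$start[r] >= 20L
  }
  cand <- cand[ok, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(-cand$matched_length, cand$mismatches, cand$start), , drop = FALSE]
  used <- rep(FALSE, nchar(read))
  sel <- integer(0)
  for (r in seq_len(nrow(cand))) {
    span <- (cand$start[r] + 1L):cand$end[r]
    if (!any(used[span])) {
      used[span] <- TRUE
      sel <- c(sel, r)
    }
  }
  out <- cand[sel, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shared fixtures -------------------------------------------------------------

test_book <- function(n = 3L, seed = 42L) {
  make_address_book(n_forward = n, n_internal = 0L, n_reverse = n, seed = seed)
}

# encode each word with its own forward/reverse address pair, as fragments
word_fragments <- function(words, book, copies = 1000) {
  lapply(seq_along(words), function(i) {
    wf <- encode_word(words[i],
                      book[book$id == sprintf("F%d", i), ],
                      book[book$id == sprintf("R%d", i), ])
    as_fragment(wf, copies = copies)
  })
}

# chain fragments serially; returns the pool of the final droplet. The
# default unit-efficiency model gives a clean product-only pool for decoding
# tests; pass yield_model(0.185) for yield arithmetic.
serial_pool <- function(frags, model = yield_model(1)) {
  pools <- stats::setNames(lapply(frags, pool),
                           sprintf("d%d", seq_along(frags)))
  steps <- list()
  cur <- "d1"
  for (i in seq_along(frags)[-1L]) {
    out <- sprintf("s%d", i)
    steps[[length(steps) + 1L]] <- serial_step(
      cur, sprintf("d%d", i), out, design_splint(frags[[i - 1L]], frags[[i]]))
    cur <- out
  }
  res <- run_program(assembly_program(steps), pools, model)
  res[[attr(res, "final")]]
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
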