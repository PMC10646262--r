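# Address-primer decoding: orient reads with reverse-primer information,
# scan the 20-nt address sequences to locate payloads of unknown size and
# position, segment payloads between consecutive hits, group cohorts and
# call per-position plurality consensus, classify per-read errors by the
# length rule, and decode text (RS error correction) or pixel (codon +
# index) payloads. Includes in-silico PCR random access.

#' Scan a read for address sequences
#'
#' A hit is either a full 20-base window with at most
#' `max_match - min_match` mismatches, or an exact contiguous match of
#' length >= `min_match` where the address is truncated at a read end.
#' Forward-role addresses are sought in the first 20 bases (window starts
#' 0-5, so a 15-mer suffix ending by base 20 qualifies) and, for ligated
#' multi-word products, at interior junctions (starts >= 20); all other
#' roles are sought from the 21st base onward. Overlapping candidates are
#' resolved by (longer match, fewer mismatches, leftmost) priority.
#'
#' @param read Read sequence (oriented 5'->3').
#' @param book An `address_book`.
#' @param min_match Minimum matched length (default 15).
#' @param max_match Full address length (20).
#' @return data.frame of hits ordered by position: `address_id`, `role`,
#'   `start`, `end` (0-based, half-open), `matched_length`, `mismatches`.
#' @export
scan_addresses <- function(read, book, min_match = 15L, max_match = 20L) {
  stopifnot(min_match <= max_match, max_match == 20L)
  read <- dna(read, allow_empty = TRUE)
  L <- nchar(read)
  max_mm <- max_match - min_match
  rint <- if (L) utf8ToInt(read) else integer(0)
  cand <- list()
  for (i in seq_len(nrow(book))) {
    addr <- book$seq[i]
    aint <- utf8ToInt(addr)
    # full 20-base windows
    if (L >= max_match) {
      starts <- 0:(L - max_match)                       # 0-based
      idx <- outer(starts, seq_len(max_match), `+`)     # 1-based columns
      mm <- rowSums(matrix(rint[idx], nrow = length(starts)) !=
                    matrix(aint, nrow = length(starts), ncol = max_match,
                           byrow = TRUE))
      keep <- which(mm <= max_mm)
      if (length(keep)) {
        cand[[length(cand) + 1L]] <- data.frame(
          address_id = book$id[i], role = book$role[i],
          start = starts[keep], end = starts[keep] + max_match,
          matched_length = max_match, mismatches = as.integer(mm[keep]),
          stringsAsFactors = FALSE)
      }
    }
    # exact truncated matches at the read ends
    for (w in min_match:(max_match - 1L)) {
      if (L >= w) {
        if (substr(read, 1L, w) == last_n(addr, w)) {     # read start
          cand[[length(cand) + 1L]] <- data.frame(
            address_id = book$id[i], role = book$role[i],
            start = 0L, end = w, matched_length = w, mismatches = 0L,
            stringsAsFactors = FALSE)
        }
        if (substr(read, L - w + 1L, L) == first_n(addr, w)) {  # read end
          cand[[length(cand) + 1L]] <- data.frame(
            address_id = book$id[i], role = book$role[i],
            start = L - w, end = L, matched_length = w, mismatches = 0L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  empty <- data.frame(address_id = character(0), role = character(0),
                      start = integer(0), end = integer(0),
                      matched_length = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  # role-specific search windows
  keep <- ifelse(cand$role == "forward",
                 cand$start <= 5L | cand$start >= 20L,
                 cand$start >= 20L)
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  # greedy selection: longer match, then fewer mismatches, then leftmost
  cand <- cand[order(-cand$matched_length, cand$mismatches, cand$start), ,
               drop = FALSE]
  taken <- logical(0)
  sel <- integer(0)
  for (r in seq_len(nrow(cand))) {
    span <- (cand$start[r] + 1L):cand$end[r]
    if (length(taken) < max(span)) taken[max(span)] <- FALSE
    if (!any(taken[span], na.rm = TRUE)) {
      taken[span] <- TRUE
      sel <- c(sel, r)
    }
  }
  out <- cand[sel, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Orient a read using reverse-primer information
#'
#' Both the read and its reverse complement are scanned; the orientation
#' with the larger total matched address score (matched bases minus
#' mismatches) wins. Reads with no detectable address in either orientation
#' pass through unflipped with flag `"unknown"`.
#'
#' @param read Read sequence.
#' @param book An `address_book`.
#' @param min_match Passed to [scan_addresses()].
#' @return List with `seq` (oriented read), `flipped`, `flag` (`"oriented"`
#'   or `"unknown"`), and `hits` (scan of the oriented read).
#' @export
orient_read <- function(read, book, min_match = 15L) {
  fwd_hits <- scan_addresses(read, book, min_match)
  rc <- revcomp(read)
  rev_hits <- scan_addresses(rc, book, min_match)
  score <- function(h) if (nrow(h)) sum(h$matched_length - h$mismatches) else 0
  sf <- score(fwd_hits); sr <- score(rev_hits)
  if (sf == 0 && sr == 0) {
    return(list(seq = read, flipped = FALSE, flag = "unknown", hits = fwd_hits))
  }
  if (sr > sf) list(seq = rc, flipped = TRUE, flag = "oriented", hits = rev_hits)
  else list(seq = read, flipped = FALSE, flag = "oriented", hits = fwd_hits)
}

#' Segment payloads between consecutive address hits
#'
#' Payload k is the bases strictly between hit k and hit k+1; its span
#' length is the data size. Zero-length payloads (adjacent hits, e.g. at a
#' ligation junction) are allowed and flagged.
#'
#' @param read Oriented read sequence.
#' @param hits Hit table from [scan_addresses()] (>= 2 rows, else the read
#'   is unalignable).
#' @return A `segmented_read`: list with `aligned`, `path` (dash-joined
#'   address ids), `terminal` (last hit has reverse role), and `payloads`
#'   data.frame (`ordinal`, `left_id`, `left_role`, `right_id`, `start`,
#'   `end`, `length`, `seq`, `empty`).
#' @export
segment_payloads <- function(read, hits) {
  if (is.null(hits) || nrow(hits) < 2L) {
    return(structure(list(aligned = FALSE, path = NA_character_,
                          terminal = FALSE, payloads = NULL),
                     class = "segmented_read"))
  }
  k <- seq_len(nrow(hits) - 1L)
  start <- hits$end[k]
  end <- hits$start[k + 1L]
  seqs <- substr(rep(read, length(k)), start + 1L, end)
  pl <- data.frame(ordinal = k - 1L,
                   left_id = hits$address_id[k], left_role = hits$role[k],
                   right_id = hits$address_id[k + 1L],
                   start = start, end = end, length = end - start,
                   seq = seqs, empty = end == start,
                   stringsAsFactors = FALSE)
  structure(list(aligned = TRUE,
                 path = paste(hits$address_id, collapse = "-"),
                 terminal = hits$role[nrow(hits)] == "reverse",
                 payloads = pl),
            class = "segmented_read")
}

# per-position plurality base over equal-length sequences; ties broken by
# the lexicographically smallest base
consensus_seq <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  L <- nchar(seqs[1L])
  if (L == 0L) return("")
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = L, byrow = TRUE)
  paste(apply(m, 2L, function(col) {
    tb <- table(factor(col, levels = c("A", "C", "G", "T")))
    names(tb)[which.max(tb)]   # which.max takes the first (lexicographic) max
  }), collapse = "")
}

#' Group segmented reads and call consensus payloads
#'
#' Reads are grouped by address path and payload ordinal. Within a group the
#' consensus cohort is the modal payload length (smallest modal length on
#' ties); minority-length reads are excluded from the consensus but still
#' counted - this is how the payload-length filter acts.
#'
#' @param segments List of `segmented_read`s (aligned ones are used).
#' @return data.frame with one row per (path, ordinal): `path`, `ordinal`,
#'   `left_id`, `left_role`, `n_reads`, `modal_length`, `n_modal`,
#'   `consensus`.
#' @export
group_and_consensus <- function(segments) {
  segments <- Filter(function(s) isTRUE(s$aligned), segments)
  if (!length(segments)) {
    return(data.frame(path = character(0), ordinal = integer(0),
                      left_id = character(0), left_role = character(0),
                      n_reads = integer(0), modal_length = integer(0),
                      n_modal = integer(0), consensus = character(0),
                      stringsAsFactors = FALSE))
  }
  pl <- do.call(rbind, lapply(segments, function(s) {
    cbind(s$payloads, path = s$path, stringsAsFactors = FALSE)
  }))
  keys <- split(pl, list(pl$path, pl$ordinal), drop = TRUE)
  out <- lapply(keys, function(g) {
    tb <- table(g$length)
    modal <- as.integer(names(tb)[which.max(tb)])  # smallest modal on ties
    cohort <- g$seq[g$length == modal]
    data.frame(path = g$path[1L], ordinal = g$ordinal[1L],
               left_id = g$left_id[1L], left_role = g$left_role[1L],
               n_reads = nrow(g), modal_length = modal,
               n_modal = length(cohort),
               consensus = if (modal == 0L) "" else consensus_seq(cohort),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$path, out$ordinal), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a read against a reference by the length rule
#'
#' `perfect`: equal; `substitution`: same length, unequal; `deletion_1_2`:
#' one or two bases shorter; `insertion`: longer; `other`: anything else.
#'
#' @param read,ref Sequences.
#' @return Class label.
#' @export
classify_read <- function(read, ref) {
  lr <- nchar(read); lf <- nchar(ref)
  if (lr == lf) {
    if (read == ref) "perfect" else "substitution"
  } else if ((lf - lr) %in% 1:2) {
    "deletion_1_2"
  } else if (lr > lf) {
    "insertion"
  } else {
    "other"
  }
}

#' Decode a read set: the full address-scanning pipeline
#'
#' orient -> scan -> segment -> group -> consensus -> codec decode. Serial
#' and parallel species are demultiplexed purely by their address paths. For
#' the text codec every non-empty payload span is RS-decoded; for the pixel
#' codec each data span is split into its 2-nt index and 48-nt codon payload
#' and frames are rebuilt per forward address and index.
#'
#' @param readset A `read_set` (simulated or loaded) or character vector of
#'   read sequences.
#' @param book An `address_book`.
#' @param codec `"text"` or `"pixel"`.
#' @param ecc_cfg An [ecc_config()] (text codec).
#' @param codon_table A [build_codon_table()] (pixel codec).
#' @param min_match Minimum address match length (default 15).
#' @return A `decode_report`: counts (`n_reads`, `n_flipped`, `n_unknown`,
#'   `aligned`, `length_match`, `perfect`, `words_no_ecc`, `words_ecc`),
#'   `groups` (consensus table), `species` (per-path summary with recovered
#'   text), `frames` (pixel codec), `classes` (per-read fractions),
#'   `length_hist`.
#' @export
decode_pool <- function(readset, book, codec = c("text", "pixel"),
                        ecc_cfg = ecc_config(), codon_table = NULL,
                        min_match = 15L) {
  codec <- match.arg(codec)
  if (codec == "pixel" && is.null(codon_table)) codon_table <- build_codon_table()
  reads <- if (is.character(readset)) readset
           else c(readset$reads$seq, if (isTRUE(readset$paired)) readset$mates$seq)
  empty_report <- structure(list(
    n_reads = 0L, n_flipped = 0L, n_unknown = 0L, aligned = 0L,
    length_match = 0L, perfect = 0L, words_no_ecc = 0L, words_ecc = 0L,
    groups = NULL, species = NULL, frames = NULL, classes = NULL,
    length_hist = NULL, codec = codec), class = "decode_report")
  if (!length(reads)) return(empty_report)

  oriented <- lapply(reads, orient_read, book = book, min_match = min_match)
  segs <- lapply(oriented, function(o) segment_payloads(o$seq, o$hits))
  groups <- group_and_consensus(segs)

  aligned_i <- which(vapply(segs, `[[`, logical(1L), "aligned"))
  gkey <- function(path, ordinal) paste(path, ordinal, sep = "#")
  modal_of <- stats::setNames(groups$modal_length, gkey(groups$path, groups$ordinal))
  cons_of <- stats::setNames(groups$consensus, gkey(groups$path, groups$ordinal))

  # data spans: payloads that follow a forward-role address hit
  is_data <- function(pl) pl$left_role == "forward"

  length_match <- 0L; perfect <- 0L
  words_no_ecc <- 0L; words_ecc <- 0L
  for (i in aligned_i) {
    s <- segs[[i]]
    pl <- s$payloads[is_data(s$payloads), , drop = FALSE]
    if (!nrow(pl)) next
    key <- gkey(s$path, pl$ordinal)
    lm <- all(pl$length == modal_of[key])
    pf <- lm && all(pl$seq == cons_of[key])
    length_match <- length_match + lm
    perfect <- perfect + pf
    if (codec == "text") {
      for (sq in pl$seq) {
        d <- decode_word(sq, ecc_cfg)
        words_ecc <- words_ecc + d$ok
        words_no_ecc <- words_no_ecc + (d$ok && d$corrections == 0L)
      }
    }
  }

  species <- NULL; frames <- NULL
  if (nrow(groups)) {
    data_groups <- groups[groups$left_role == "forward", , drop = FALSE]
    if (codec == "text") {
      sp <- split(data_groups, data_groups$path)
      species <- do.call(rbind, lapply(sp, function(g) {
        g <- g[order(g$ordinal), , drop = FALSE]
        words <- vapply(g$consensus, function(x) {
          d <- decode_word(x, ecc_cfg)
          if (d$ok) d$text else "?"
        }, character(1L))
        data.frame(path = g$path[1L], n_words = nrow(g),
                   text = paste(words, collapse = " "),
                   stringsAsFactors = FALSE)
      }))
      rownames(species) <- NULL
    } else {
      # split each data span into index + codon payload, re-consense per
      # (frame = forward address id, index ordinal)
      acc <- list()
      for (i in aligned_i) {
        s <- segs[[i]]
        pl <- s$payloads[is_data(s$payloads) & s$payloads$length >= 3L, , drop = FALSE]
        if (!nrow(pl)) next
        for (r in seq_len(nrow(pl))) {
          idx <- seq_to_index(substr(pl$seq[r], 1L, 2L))
          if (is.na(idx)) next
          acc[[length(acc) + 1L]] <- data.frame(
            frame = pl$left_id[r], index = idx,
            payload = substr(pl$seq[r], 3L, pl$length[r]),
            stringsAsFactors = FALSE)
        }
      }
      frames <- list()
      if (length(acc)) {
        acc <- do.call(rbind, acc)
        for (fid in sort(unique(acc$frame))) {
          g <- acc[acc$frame == fid, , drop = FALSE]
          payloads <- vapply(split(g, g$index), function(gg) {
            tb <- table(nchar(gg$payload))
            modal <- as.integer(names(tb)[which.max(tb)])
            consensus_seq(gg$payload[nchar(gg$payload) == modal])
          }, character(1L))
          frames[[fid]] <- decode_frame(payloads, codon_table)
        }
      }
      species <- data.frame(path = names(frames),
                            n_words = NA_integer_,
                            text = sprintf("<frame %s>", names(frames)),
                            stringsAsFactors = FALSE)
    }
  }

  # per-read classes against the species reference rebuilt from canonical
  # addresses and consensus spans (the raw-read error taxonomy)
  refs <- new.env(parent = emptyenv())
  path_ref <- function(path) {
    if (!is.null(refs[[path]])) return(refs[[path]])
    ids <- strsplit(path, "-", fixed = TRUE)[[1L]]
    g <- groups[groups$path == path, , drop = FALSE]
    g <- g[order(g$ordinal), , drop = FALSE]
    parts <- character(0)
    for (k in seq_along(ids)) {
      parts <- c(parts, book$seq[match(ids[k], book$id)])
      if (k <= nrow(g)) parts <- c(parts, g$consensus[g$ordinal == k - 1L])
    }
    refs[[path]] <- paste(parts, collapse = "")
    refs[[path]]
  }
  cls <- character(length(reads))
  for (i in seq_along(reads)) {
    if (!segs[[i]]$aligned) { cls[i] <- "other"; next }
    cls[i] <- classify_read(oriented[[i]]$seq, path_ref(segs[[i]]$path))
  }
  classes <- prop.table(table(factor(cls, levels = c(
    "perfect", "substitution", "deletion_1_2", "insertion", "other"))))

  structure(list(
    n_reads = length(reads),
    n_flipped = sum(vapply(oriented, `[[`, logical(1L), "flipped")),
    n_unknown = sum(vapply(oriented, `[[`, character(1L), "flag") == "unknown"),
    aligned = length(aligned_i),
    length_match = as.integer(length_match), perfect = as.integer(perfect),
    words_no_ecc = as.integer(words_no_ecc), words_ecc = as.integer(words_ecc),
    groups = groups, species = species, frames = frames,
    classes = classes, length_hist = table(nchar(reads)), codec = codec),
    class = "decode_report")
}

#' @export
print.decode_report <- function(x, ...) {
  cat(sprintf("<decode_report> %s codec: %d reads (%d flipped, %d unoriented)\n",
              x$codec, x$n_reads, x$n_flipped, x$n_unknown))
  cat(sprintf("  aligned %d >= length-match %d >= perfect %d\n",
              x$aligned, x$length_match, x$perfect))
  if (x$codec == "text") {
    cat(sprintf("  word payloads decoded: %d without ECC, %d with ECC\n",
                x$words_no_ecc, x$words_ecc))
    if (!is.null(x$species)) {
      for (r in seq_len(nrow(x$species))) {
        cat(sprintf("  species %s: \"%s\"\n", x$species$path[r], x$species$text[r]))
      }
    }
  } else if (length(x$frames)) {
    cat(sprintf("  frames recovered: %s\n", paste(names(x$frames), collapse = ", ")))
  }
  invisible(x)
}

#' In-silico PCR random access
#'
#' Retains species (or reads) whose sense strand carries the forward address
#' followed by the reverse address, in that order - the selection semantics
#' of amplifying one file out of a pool with its unique address pair.
#' Addresses are given as sense-strand sequences (the book convention); the
#' physical reverse PCR primer is the reverse complement of the reverse
#' address.
#'
#' @param x A `dna_pool` or `read_set`.
#' @param fwd,rev Primer sequences, or address ids when `book` is given.
#' @param book Optional `address_book` for id lookup.
#' @return Object of the same type containing only the selected species or
#'   reads; warns when nothing is selected.
#' @export
random_access <- function(x, fwd, rev, book = NULL) {
  if (!is.null(book)) {
    fwd <- book_lookup(book, fwd)$seq
    rev <- book_lookup(book, rev)$seq
  }
  fwd <- dna(fwd); rev <- dna(rev)
  hit <- function(s) {
    i <- regexpr(fwd, s, fixed = TRUE)
    j <- regexpr(rev, s, fixed = TRUE)
    i > 0L && j > 0L && i < j
  }
  if (inherits(x, "dna_pool")) {
    keep <- vapply(x$members, function(f) hit(f$seq), logical(1L))
    if (!any(keep)) warning("random access selected no species")
    out <- x; out$members <- x$members[keep]
    out
  } else if (inherits(x, "read_set")) {
    keep <- vapply(x$reads$seq, function(s) hit(s) || hit(revcomp(s)), logical(1L))
    if (!any(keep)) warning("random access selected no reads")
    out <- x
    out$reads <- x$reads[keep, , drop = FALSE]
    if (x$paired) out$mates <- x$mates[keep, , drop = FALSE]
    if (!is.null(x$truth)) {
      ids <- sub("/[12]$", "", x$reads$id[keep])
      out$truth <- x$truth[sub("/[12]$", "", x$truth$read_id) %in% ids, , drop = FALSE]
    }
    out
  } else {
    stop("random_access expects a dna_pool or read_set", call. = FALSE)
  }
}
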