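# Synthetic sequencing-read generator. Reads cover the full fragment
# (amplicon sequencing of <= 500-nt species); errors are drawn i.i.d. per
# base; strand orientation is flipped with probability 0.5 (both strands are
# sequenced); a truth ledger records every read's origin and edit counts so
# decoder-independent error-class fractions are exact.

#' Per-base error profile
#'
#' @param p_sub,p_del,p_ins Per-base substitution / deletion / insertion
#'   probabilities, each in \[0, 0.5). Defaults mimic low per-base MiSeq
#'   error magnitudes; note that published per-read error-class fractions
#'   entangle synthesis, ligation, PCR and sequencing and are not per-base
#'   rates.
#' @param seed RNG seed (reads are reproducible byte-for-byte).
#' @return An `error_profile`.
#' @export
error_profile <- function(p_sub = 0.001, p_del = 0, p_ins = 0, seed = 1L) {
  p <- c(p_sub, p_del, p_ins)
  if (any(p < 0) || any(p >= 0.5)) stop("error rates must be in [0, 0.5)", call. = FALSE)
  structure(list(p_sub = p_sub, p_del = p_del, p_ins = p_ins,
                 seed = as.integer(seed)),
            class = "error_profile")
}

# apply i.i.d. per-base errors to one sequence; insertions add a uniform
# random base before a position, substitutions draw uniformly from the 3
# alternatives. Returns the mutated sequence and edit counts.
mutate_seq <- function(seq, p_sub, p_del, p_ins) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  del <- stats::runif(L) < p_del
  ins <- stats::runif(L) < p_ins
  sub <- stats::runif(L) < p_sub & !del
  if (any(sub)) {
    for (i in which(sub)) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
  }
  out <- character(0)
  if (any(ins) || any(del)) {
    ins_base <- if (any(ins)) sample(c("A", "C", "G", "T"), sum(ins), replace = TRUE)
    pieces <- chars
    pieces[del] <- ""
    if (any(ins)) pieces[ins] <- paste0(ins_base, pieces[ins])
    out <- paste(pieces, collapse = "")
  } else {
    out <- paste(chars, collapse = "")
  }
  list(seq = out, n_sub = sum(sub), n_del = sum(del), n_ins = sum(ins))
}

#' Simulate sequencing reads from a pool
#'
#' Species are sampled proportional to copy number; the total read count is
#' `depth` times the number of positive-copy species. Each fragment's
#' orientation is flipped (reverse complemented) with probability 0.5 before
#' errors are applied. Quality strings are constant Q30 placeholders: the
#' decoder is count-based and ignores qualities.
#'
#' @param x A `dna_pool`.
#' @param depth Mean reads per species (>= 1).
#' @param profile An [error_profile()].
#' @param paired Emit R2 mates (full-length reverse complements with their
#'   own independent errors).
#' @return A `read_set`: list with `reads` (data.frame id/seq/qual), `mates`
#'   (same shape or NULL), `truth` (data.frame read_id, species_id, mate,
#'   flipped, n_sub, n_del, n_ins), `paired`.
#' @export
simulate_reads <- function(x, depth, profile = error_profile(), paired = FALSE) {
  stopifnot(inherits(x, "dna_pool"), depth >= 1)
  members <- Filter(function(f) f$copies > 0, x$members)
  if (!length(members)) stop("pool has no positive-copy species", call. = FALSE)
  seqs <- vapply(members, `[[`, character(1L), "seq")
  ids <- vapply(members, `[[`, character(1L), "id")
  cps <- vapply(members, `[[`, numeric(1L), "copies")
  rc <- revcomp(seqs)
  n <- as.integer(round(depth * length(members)))
  with_seed(profile$seed, {
    pick <- sample.int(length(members), n, replace = TRUE, prob = cps)
    flip <- stats::runif(n) < 0.5
    r1 <- vector("list", n)
    r2 <- if (paired) vector("list", n)
    for (i in seq_len(n)) {
      template <- if (flip[i]) rc[pick[i]] else seqs[pick[i]]
      r1[[i]] <- mutate_seq(template, profile$p_sub, profile$p_del, profile$p_ins)
      if (paired) {
        r2[[i]] <- mutate_seq(revcomp(template),
                              profile$p_sub, profile$p_del, profile$p_ins)
      }
    }
  })
  read_id <- sprintf("read%06d", seq_len(n))
  mk_df <- function(lst, suffix) {
    s <- vapply(lst, `[[`, character(1L), "seq")
    data.frame(id = paste0(read_id, suffix), seq = s,
               qual = strrep("?", nchar(s)),   # Phred+33 Q30
               stringsAsFactors = FALSE)
  }
  mk_truth <- function(lst, mate) {
    data.frame(read_id = paste0(read_id, if (mate == 2L) "/2" else "/1"),
               species_id = ids[pick], mate = mate, flipped = flip,
               n_sub = vapply(lst, `[[`, integer(1L), "n_sub"),
               n_del = vapply(lst, `[[`, integer(1L), "n_del"),
               n_ins = vapply(lst, `[[`, integer(1L), "n_ins"),
               stringsAsFactors = FALSE)
  }
  truth <- mk_truth(r1, 1L)
  mates <- NULL
  if (paired) {
    mates <- mk_df(r2, "/2")
    truth <- rbind(truth, mk_truth(r2, 2L))
  }
  structure(list(reads = mk_df(r1, if (paired) "/1" else ""),
                 mates = mates, truth = truth, paired = paired),
            class = "read_set")
}

# ledger-based class of one read: mirrors the decoder's length rule exactly
# for reads carrying at most one edit
truth_class <- function(n_sub, n_del, n_ins) {
  ifelse(n_sub + n_del + n_ins == 0L, "perfect",
  ifelse(n_del == 0L & n_ins == 0L, "substitution",
  ifelse(n_ins == 0L & n_del %in% 1:2, "deletion_1_2",
  ifelse(n_del == 0L & n_ins >= 1L, "insertion", "other"))))
}

#' Error-class fractions of a read set
#'
#' Decoder-independent classification from the simulation truth ledger:
#' `perfect` (no edits), `substitution` (substitutions only),
#' `deletion_1_2` (one or two deletions, no insertions), `insertion`
#' (insertions, no deletions), `other`. Fractions sum to 1. Also returns the
#' read-length histogram.
#'
#' @param readset A [simulate_reads()] result.
#' @return List with `fractions` (named numeric) and `length_hist` (table).
#' @export
class_fractions <- function(readset) {
  stopifnot(inherits(readset, "read_set"))
  tr <- readset$truth
  cls <- factor(truth_class(tr$n_sub, tr$n_del, tr$n_ins),
                levels = c("perfect", "substitution", "deletion_1_2",
                           "insertion", "other"))
  lens <- nchar(c(readset$reads$seq,
                  if (readset$paired) readset$mates$seq))
  list(fractions = prop.table(table(cls)), length_hist = table(lens))
}

#' Write a read set to FASTQ (and its truth ledger to TSV)
#'
#' @param readset A `read_set`.
#' @param prefix Output path prefix; emits `<prefix>.fastq` (or `_R1/_R2`
#'   when paired) and `<prefix>_truth.tsv`.
#' @return Character vector of written paths, invisibly.
#' @export
write_readset <- function(readset, prefix) {
  paths <- character(0)
  if (readset$paired) {
    p1 <- paste0(prefix, "_R1.fastq"); p2 <- paste0(prefix, "_R2.fastq")
    write_fastq(readset$reads, p1); write_fastq(readset$mates, p2)
    paths <- c(p1, p2)
  } else {
    p1 <- paste0(prefix, ".fastq")
    write_fastq(readset$reads, p1)
    paths <- p1
  }
  pt <- paste0(prefix, "_truth.tsv")
  utils::write.table(readset$truth, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, pt))
}

#' Load reads from FASTQ into a read set
#'
#' @param r1 FASTQ path. @param r2 Optional mate FASTQ path.
#' @return A `read_set` with an empty truth ledger.
#' @export
read_readset <- function(r1, r2 = NULL) {
  structure(list(reads = read_fastq(r1),
                 mates = if (!is.null(r2)) read_fastq(r2),
                 truth = NULL, paired = !is.null(r2)),
            class = "read_set")
}
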