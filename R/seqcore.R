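#' Validate a DNA sequence
#'
#' Checks that a sequence is a 5'->3' string over the strict four-letter
#' alphabet \{A, C, G, T\}. Lowercase input is accepted and upcased;
#' `N` and IUPAC ambiguity codes are rejected because the codec alphabet is
#' strictly four-letter.
#'
#' @param x Character vector of sequences.
#' @param allow_empty Logical; permit zero-length sequences (default `FALSE`).
#' @return The validated, upper-cased character vector.
#' @export
#' @examples
#' dna("acgt")
dna <- function(x, allow_empty = FALSE) {
  if (!is.character(x)) stop("sequence must be character", call. = FALSE)
  if (anyNA(x)) stop("sequence must not contain NA", call. = FALSE)
  x <- toupper(x)
  if (!allow_empty && any(nchar(x) == 0L)) {
    stop("empty sequence not allowed here", call. = FALSE)
  }
  bad <- regexpr("[^ACGT]", x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' at position %d of sequence %d",
                 substr(x[i], bad[i], bad[i]), bad[i], i), call. = FALSE)
  }
  x
}

#' Reverse complement
#'
#' @param x Character vector of DNA sequences (5'->3').
#' @return Character vector of reverse complements (5'->3').
#' @export
#' @examples
#' revcomp("AAAC") # "GTTT"
revcomp <- function(x) {
  x <- dna(x, allow_empty = TRUE)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Hamming distance between two equal-length sequences
#'
#' @param a,b DNA sequences of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  a <- dna(a, allow_empty = TRUE); b <- dna(b, allow_empty = TRUE)
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    stop(sprintf("length mismatch: %d vs %d", nchar(a), nchar(b)), call. = FALSE)
  }
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Longest homopolymer run
#'
#' @param s A DNA sequence.
#' @return Length of the longest run of identical bases (0 for empty input).
#' @export
#' @examples
#' max_homopolymer_run("AAAT") # 3
max_homopolymer_run <- function(s) {
  s <- dna(s, allow_empty = TRUE)
  if (nchar(s) == 0L) return(0L)
  max(rle(strsplit(s, "", fixed = TRUE)[[1L]])$lengths)
}

# ---- FASTA / FASTQ ---------------------------------------------------------

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` (first header token), `desc`
#'   (remainder of the header, possibly ""), and `seq`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fasta")
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  data.frame(id = id, desc = desc, seq = as.character(set),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a FASTA file
#'
#' @param records data.frame with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  seqs <- dna(records$seq, allow_empty = TRUE)
  set <- Biostrings::DNAStringSet(seqs)
  desc <- if ("desc" %in% names(records)) records$desc else rep("", nrow(records))
  names(set) <- ifelse(is.na(desc) | desc == "", records$id,
                       paste(records$id, desc))
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a FASTQ file (Sanger / Phred+33 qualities)
#'
#' @param path Path to a FASTQ file.
#' @return A data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(set)$qualities)
  if (length(set) && any(nchar(qual) != nchar(as.character(set)))) {
    i <- which(nchar(qual) != nchar(as.character(set)))[1L]
    stop(sprintf("FASTQ record %d: quality length differs from sequence length", i),
         call. = FALSE)
  }
  data.frame(id = sub("\\s.*$", "", names(set)), seq = as.character(set),
             qual = qual, row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param records data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq", "qual") %in% names(records)))
  if (any(nchar(records$qual) != nchar(records$seq))) {
    stop("quality length must equal sequence length", call. = FALSE)
  }
  set <- Biostrings::DNAStringSet(dna(records$seq, allow_empty = TRUE))
  names(set) <- records$id
  Biostrings::writeXStringSet(set, filepath = path, format = "fastq",
                              qualities = Biostrings::BStringSet(records$qual))
  invisible(path)
}

# ---- address books ---------------------------------------------------------

#' Construct an address sequence
#'
#' A 20-nt primer-compatible sequence used both as a PCR random-access handle
#' and as a decoding synchronisation marker.
#'
#' @param id Unique label.
#' @param seq 20-nt DNA sequence.
#' @param role One of `"forward"`, `"internal"`, `"reverse"`.
#' @return A one-row data.frame with columns `id`, `seq`, `role`.
#' @export
address_sequence <- function(id, seq, role = c("forward", "internal", "reverse")) {
  role <- match.arg(role)
  seq <- dna(seq)
  if (nchar(seq) != 20L) stop("address sequences are exactly 20 nt", call. = FALSE)
  data.frame(id = as.character(id), seq = seq, role = role,
             stringsAsFactors = FALSE)
}

#' Assemble an address book
#'
#' @param entries data.frame with columns `id`, `seq`, `role` (e.g. rbind of
#'   [address_sequence()] rows).
#' @return An `address_book` object (validated data.frame).
#' @export
address_book <- function(entries) {
  stopifnot(is.data.frame(entries), all(c("id", "seq", "role") %in% names(entries)))
  entries$seq <- dna(entries$seq)
  if (any(nchar(entries$seq) != 20L)) stop("all addresses must be 20 nt", call. = FALSE)
  if (anyDuplicated(entries$id)) stop("duplicate address ids", call. = FALSE)
  if (anyDuplicated(entries$seq)) stop("duplicate address sequences", call. = FALSE)
  if (!all(entries$role %in% c("forward", "internal", "reverse"))) {
    stop("roles must be forward/internal/reverse", call. = FALSE)
  }
  rownames(entries) <- NULL
  class(entries) <- c("address_book", "data.frame")
  entries
}

#' Generate a synthetic address book
#'
#' Addresses are drawn by seeded rejection sampling until every pair of
#' 20-mers is at pairwise Hamming distance >= `min_dist`, which guarantees
#' unambiguous partial (15-of-20) matching during decoding.
#'
#' @param n_forward,n_internal,n_reverse Number of addresses per role.
#' @param min_dist Minimum pairwise Hamming distance (default 8).
#' @param seed RNG seed.
#' @return An `address_book`.
#' @export
make_address_book <- function(n_forward = 2L, n_internal = 0L, n_reverse = 2L,
                              min_dist = 8L, seed = 1L) {
  n <- n_forward + n_internal + n_reverse
  seqs <- character(0)
  with_seed(seed, {
    tries <- 0L
    while (length(seqs) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE), collapse = "")
      ok <- all(vapply(seqs, function(s) hamming(s, cand) >= min_dist, logical(1L)))
      if (ok) seqs <- c(seqs, cand)
      tries <- tries + 1L
      if (tries > 10000L * n) stop("address sampling failed to converge", call. = FALSE)
    }
  })
  roles <- c(rep("forward", n_forward), rep("internal", n_internal),
             rep("reverse", n_reverse))
  ids <- c(sprintf("F%d", seq_len(n_forward)),
           if (n_internal) sprintf("I%d", seq_len(n_internal)),
           sprintf("R%d", seq_len(n_reverse)))
  address_book(data.frame(id = ids, seq = seqs, role = roles,
                          stringsAsFactors = FALSE))
}

#' Write an address book as FASTA
#'
#' The role is encoded in the description field (`role=forward` etc.).
#' @param book An `address_book`.
#' @param path Output path.
#' @export
write_address_book <- function(book, path) {
  write_fasta(data.frame(id = book$id, desc = paste0("role=", book$role),
                         seq = book$seq, stringsAsFactors = FALSE), path)
}

#' Read an address book from FASTA
#'
#' @param path FASTA path written by [write_address_book()].
#' @return An `address_book`.
#' @export
read_address_book <- function(path) {
  rec <- read_fasta(path)
  role <- sub("^.*role=(\\w+).*$", "\\1", rec$desc)
  address_book(data.frame(id = rec$id, seq = rec$seq, role = role,
                          stringsAsFactors = FALSE))
}

#' Look up addresses in a book
#'
#' @param book An `address_book`.
#' @param id Address id(s).
#' @return The matching rows.
#' @export
book_lookup <- function(book, id) {
  i <- match(id, book$id)
  if (anyNA(i)) stop(sprintf("address id '%s' not in book", id[is.na(i)][1L]), call. = FALSE)
  book[i, , drop = FALSE]
}

# run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}
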