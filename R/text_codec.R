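# Text words -> DNA payloads. Each 7-bit ASCII character is one GF(2^7)
# symbol; two RS parity symbols are appended per word; the bitstream is
# written 2 bits/base under the fixed map 00->A, 01->C, 10->G, 11->T, with a
# single 0 pad bit when the total bit count is odd.

BASE4 <- c("A", "C", "G", "T")

#' ASCII characters to 7-bit symbols
#'
#' @param text A single ASCII string (codes 1..127).
#' @return Integer vector of character codes, one per character.
#' @export
#' @examples
#' ascii_to_symbols("Apple") # 65 112 112 108 101
ascii_to_symbols <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (nchar(text) == 0L) return(integer(0))
  codes <- utf8ToInt(text)
  if (anyNA(codes) || any(codes > 127L) || any(codes < 1L)) {
    bad <- substr(text, which(is.na(codes) | codes > 127L | codes < 1L)[1L],
                  which(is.na(codes) | codes > 127L | codes < 1L)[1L])
    stop(sprintf("non-ASCII character '%s' cannot be encoded", bad), call. = FALSE)
  }
  as.integer(codes)
}

#' 7-bit symbols back to ASCII text
#'
#' @param symbols Integer vector in 1..127.
#' @return ASCII string.
#' @export
symbols_to_ascii <- function(symbols) {
  symbols <- as.integer(symbols)
  if (length(symbols) == 0L) return("")
  if (anyNA(symbols) || any(symbols < 1L) || any(symbols > 127L)) {
    stop("symbols out of printable ASCII range 1..127", call. = FALSE)
  }
  intToUtf8(symbols)
}

# symbols -> 0/1 integer vector, 7 bits per symbol, most significant first
symbols_to_bits <- function(symbols) {
  if (length(symbols) == 0L) return(integer(0))
  as.integer(vapply(as.integer(symbols),
                    function(s) bitwAnd(bitwShiftR(s, 6:0), 1L),
                    integer(7L)))
}

bits_to_symbols <- function(bits) {
  stopifnot(length(bits) %% 7L == 0L)
  if (length(bits) == 0L) return(integer(0))
  m <- matrix(as.integer(bits), nrow = 7L)
  as.integer(colSums(m * 2L^(6:0)))
}

#' Bits to DNA bases
#'
#' Two bits per base under the fixed map 00->A, 01->C, 10->G, 11->T.
#'
#' @param bits Either a character string of 0/1 or an integer 0/1 vector;
#'   the bit count must be even (callers apply the pad rule first).
#' @return A DNA sequence.
#' @export
#' @examples
#' bits_to_bases("00011011") # "ACGT"
bits_to_bases <- function(bits) {
  if (is.character(bits)) {
    stopifnot(length(bits) == 1L)
    bits <- if (nchar(bits) == 0L) integer(0) else
      as.integer(strsplit(bits, "", fixed = TRUE)[[1L]])
  }
  bits <- as.integer(bits)
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) stop("bits must be 0/1", call. = FALSE)
  if (length(bits) %% 2L != 0L) {
    stop("odd bit count: pad to an even number of bits first", call. = FALSE)
  }
  if (length(bits) == 0L) return("")
  idx <- 2L * bits[c(TRUE, FALSE)] + bits[c(FALSE, TRUE)] + 1L
  paste(BASE4[idx], collapse = "")
}

#' DNA bases to bits (inverse of [bits_to_bases()])
#'
#' @param s A DNA sequence.
#' @return Integer 0/1 vector, two bits per base.
#' @export
bases_to_bits <- function(s) {
  s <- dna(s, allow_empty = TRUE)
  if (nchar(s) == 0L) return(integer(0))
  v <- match(strsplit(s, "", fixed = TRUE)[[1L]], BASE4) - 1L
  as.integer(rbind(v %/% 2L, v %% 2L))
}

#' Expected payload length of an encoded word
#'
#' `ceil(7 (n + parity) / 2)` bases for an n-character word.
#' @param n_chars Word length in characters.
#' @param cfg An [ecc_config()].
#' @return Payload length in bases.
#' @export
word_payload_length <- function(n_chars, cfg = ecc_config()) {
  as.integer(ceiling(7L * (n_chars + cfg$parity_symbols) / 2))
}

#' Encode one ASCII word as an address-flanked DNA fragment
#'
#' The word's character codes plus RS parity are written to DNA and flanked
#' by a forward and a reverse 20-nt address, giving
#' `full_seq = fwd || payload || rev`.
#'
#' @param text ASCII word.
#' @param fwd,rev Address rows (from an `address_book`), distinct.
#' @param cfg An [ecc_config()].
#' @return A `word_fragment`: list with `text`, `forward_address`,
#'   `reverse_address` (one-row data.frames), `payload`, `full_seq`, `padded`.
#' @export
encode_word <- function(text, fwd, rev, cfg = ecc_config()) {
  stopifnot(is.data.frame(fwd), is.data.frame(rev))
  if (identical(fwd$seq, rev$seq)) stop("addresses must be distinct", call. = FALSE)
  code <- rs_encode(ascii_to_symbols(text), cfg)
  bits <- symbols_to_bits(code)
  padded <- length(bits) %% 2L == 1L
  if (padded) bits <- c(bits, 0L)
  payload <- bits_to_bases(bits)
  structure(list(text = text,
                 forward_address = fwd, reverse_address = rev,
                 payload = payload,
                 full_seq = paste0(fwd$seq, payload, rev$seq),
                 padded = padded),
            class = "word_fragment")
}

#' Decode a word payload
#'
#' Inverts [encode_word()]: bases -> bits (dropping the pad bit when the
#' count is odd) -> 7-bit symbols -> RS correction -> ASCII. Structural
#' failures (payload length inconsistent with an integer symbol count,
#' uncorrectable errors, non-ASCII decoded symbols) are reported via
#' `ok = FALSE`, not raised.
#'
#' @param payload DNA payload between the two addresses.
#' @param cfg An [ecc_config()].
#' @param expected_length Optional expected word length (characters); a
#'   mismatch sets `ok = FALSE`.
#' @return List with `text`, `corrections`, `ok`.
#' @export
decode_word <- function(payload, cfg = ecc_config(), expected_length = NULL) {
  fail <- list(text = NA_character_, corrections = 0L, ok = FALSE)
  payload <- tryCatch(dna(payload, allow_empty = TRUE), error = function(e) NULL)
  if (is.null(payload)) return(fail)
  bits <- bases_to_bits(payload)
  nsym <- length(bits) %/% 7L
  pad <- length(bits) %% 7L
  if (pad > 1L || nsym < cfg$parity_symbols + 1L) return(fail)
  if (pad == 1L) bits <- bits[-length(bits)]
  dec <- rs_decode(bits_to_symbols(bits), cfg)
  if (!dec$ok) return(fail)
  if (!is.null(expected_length) && length(dec$message) != expected_length) return(fail)
  text <- tryCatch(symbols_to_ascii(dec$message), error = function(e) NA_character_)
  if (is.na(text)) return(fail)
  list(text = text, corrections = dec$corrections, ok = TRUE)
}

#' @export
print.word_fragment <- function(x, ...) {
  cat(sprintf("<word_fragment> \"%s\"  %d nt (%s | %d nt payload%s | %s)\n",
              x$text, nchar(x$full_seq), x$forward_address$id,
              nchar(x$payload), if (x$padded) ", padded" else "",
              x$reverse_address$id))
  invisible(x)
}

#' Convert a word fragment (or pixel oligo) to an assembly fragment
#'
#' @param x A `word_fragment` or `pixel_oligo`.
#' @param id Fragment id (defaults to the word text or frame/index tag).
#' @param copies Copy number.
#' @param phosphorylated 5'-phosphorylation state (required downstream of a
#'   ligation junction).
#' @return A `dna_fragment` usable with [pool()] and [ligate()].
#' @export
as_fragment <- function(x, id = NULL, copies = 1, phosphorylated = TRUE) {
  if (inherits(x, "word_fragment")) {
    if (is.null(id)) id <- x$text
    fragment(id, x$full_seq, copies = copies, phosphorylated = phosphorylated)
  } else if (inherits(x, "pixel_oligo")) {
    if (is.null(id)) id <- sprintf("%s.i%d", x$frame_id, x$index_ordinal)
    fragment(id, x$full_seq, copies = copies, phosphorylated = phosphorylated)
  } else {
    stop("cannot convert to fragment", call. = FALSE)
  }
}
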