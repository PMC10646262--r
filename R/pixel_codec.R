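# Two-pixel-per-codon encoding of four-colour pixel frames. Two 2-bit pixels
# (4 bits) map to one of 16 three-base codons drawn from the 36 codons with
# no adjacent repeated base; any concatenation of such codons has a maximum
# homopolymer run of 2, so constant-colour regions never create long runs.
# Logical density: 4 bits / 3 bases = 1.33 bits per bp.

#' Construct / validate a pixel frame
#'
#' @param pixels Integer matrix of colour codes in 0..3; default frame
#'   geometry is 16 x 16 (256 pixels). Other geometries are accepted when the
#'   pixel count is a multiple of 32 (one oligo payload).
#' @return A `pixel_frame` matrix.
#' @export
pixel_frame <- function(pixels) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || any(pixels < 0L) || any(pixels > 3L)) {
    stop("pixel colours must be integers in 0..3", call. = FALSE)
  }
  if (length(pixels) %% 32L != 0L) {
    stop("pixel count must be a multiple of 32 (one oligo payload)", call. = FALSE)
  }
  structure(pixels, class = c("pixel_frame", class(pixels)))
}

#' Random pixel frame
#' @param seed RNG seed.
#' @param width,height Frame geometry (default 16 x 16).
#' @return A `pixel_frame`.
#' @export
random_frame <- function(seed = 1L, width = 16L, height = 16L) {
  with_seed(seed,
    pixel_frame(matrix(sample(0:3, width * height, replace = TRUE),
                       nrow = height, ncol = width)))
}

#' Build the two-pixel codon table
#'
#' Selects 16 three-base codons from the 36 codons containing no adjacent
#' repeated base. Because no codon has an internal adjacent repeat, every
#' ordered concatenation of table codons has a maximum homopolymer run of 2.
#' Unseeded, the 16 lexicographically smallest valid codons are used so the
#' table is reproducible; with a seed, 16 are sampled from the 36.
#'
#' @param seed Optional RNG seed for a sampled table.
#' @return A `codon_table`: list with `codons` (character 16, index = 4-bit
#'   value + 1) and `values` (named inverse lookup).
#' @export
build_codon_table <- function(seed = NULL) {
  b <- c("A", "C", "G", "T")
  all3 <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  cod <- paste0(all3$b1, all3$b2, all3$b3)
  ok <- substr(cod, 1, 1) != substr(cod, 2, 2) & substr(cod, 2, 2) != substr(cod, 3, 3)
  valid <- sort(cod[ok])
  stopifnot(length(valid) == 36L)
  codons <- if (is.null(seed)) valid[1:16] else with_seed(seed, sample(valid, 16L))
  values <- stats::setNames(0:15, codons)
  structure(list(codons = codons, values = values,
                 id = if (is.null(seed)) "lex16" else sprintf("seed%d", seed)),
            class = "codon_table")
}

# 2-nt big-endian base-4 index over the same 2-bit base map as the text codec
index_to_seq <- function(ordinal) {
  stopifnot(ordinal >= 0L, ordinal < 16L)
  paste0(BASE4[ordinal %/% 4L + 1L], BASE4[ordinal %% 4L + 1L])
}

seq_to_index <- function(s) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1L]], BASE4) - 1L
  if (length(v) != 2L || anyNA(v)) return(NA_integer_)
  4L * v[1L] + v[2L]
}

#' Encode a pixel frame into 90-nt indexed oligos
#'
#' Pixels are linearised row-major (top-left origin), paired, and each pair
#' written as one codon. 32 pixels (16 codons, 48 nt) fill one oligo:
#' `fwd address (20) || index (2) || payload (48) || rev address (20)` = 90 nt.
#' A 16 x 16 frame therefore yields exactly 8 oligos with index ordinals 0..7.
#'
#' @param frame A [pixel_frame()].
#' @param table A [build_codon_table()].
#' @param fwd,rev Address rows (distinct); `fwd$id` doubles as the frame id.
#' @param frame_id Optional frame label (default `fwd$id`).
#' @return List of `pixel_oligo` objects (`frame_id`, `index_ordinal`,
#'   `index_seq`, `payload`, `full_seq`, address rows).
#' @export
encode_frame <- function(frame, table, fwd, rev, frame_id = fwd$id) {
  if (!inherits(frame, "pixel_frame")) frame <- pixel_frame(frame)
  if (identical(fwd$seq, rev$seq)) stop("addresses must be distinct", call. = FALSE)
  px <- as.integer(t(unclass(frame)))          # row-major
  vals <- 4L * px[c(TRUE, FALSE)] + px[c(FALSE, TRUE)]  # two pixels -> 4 bits
  codons <- table$codons[vals + 1L]
  n_oligo <- length(codons) %/% 16L
  lapply(seq_len(n_oligo) - 1L, function(k) {
    payload <- paste(codons[(16L * k + 1L):(16L * k + 16L)], collapse = "")
    structure(list(frame_id = frame_id, index_ordinal = k,
                   index_seq = index_to_seq(k), payload = payload,
                   forward_address = fwd, reverse_address = rev,
                   full_seq = paste0(fwd$seq, index_to_seq(k), payload, rev$seq)),
              class = "pixel_oligo")
  })
}

#' Reconstruct a pixel frame from indexed payloads
#'
#' @param payloads Either a list of `pixel_oligo` objects or a named list /
#'   character vector of 48-nt payloads whose names are index ordinals
#'   ("0".."7"). Input order is irrelevant: the index drives placement.
#' @param table The [build_codon_table()] used at encoding time.
#' @param width,height Frame geometry (default 16 x 16).
#' @return List with `frame` (matrix, `NA` where data is missing), `mask`
#'   (logical matrix, TRUE = recovered), and `warnings` (character).
#' @export
decode_frame <- function(payloads, table, width = 16L, height = 16L) {
  n_px <- width * height
  n_oligo <- n_px %/% 32L
  if (length(payloads) && inherits(payloads[[1L]], "pixel_oligo")) {
    idx <- vapply(payloads, function(o) o$index_ordinal, integer(1L))
    payloads <- stats::setNames(vapply(payloads, function(o) o$payload,
                                       character(1L)), idx)
  }
  if (is.list(payloads)) payloads <- unlist(payloads)
  warnings <- character(0)
  px <- rep(NA_integer_, n_px)
  for (k in seq_len(n_oligo) - 1L) {
    key <- as.character(k)
    if (!key %in% names(payloads)) {
      warnings <- c(warnings, sprintf(
        "missing oligo index %d: pixels %d-%d masked", k, 32L * k, 32L * k + 31L))
      next
    }
    p <- payloads[[key]]
    if (nchar(p) != 48L) {
      warnings <- c(warnings, sprintf(
        "oligo index %d: payload length %d != 48, masked", k, nchar(p)))
      next
    }
    cods <- substring(p, seq(1L, 46L, 3L), seq(3L, 48L, 3L))
    vals <- unname(table$values[cods])
    if (anyNA(vals)) {
      warnings <- c(warnings, sprintf(
        "oligo index %d: %d unknown codon(s), pixel pair(s) masked",
        k, sum(is.na(vals))))
    }
    pair <- rbind(vals %/% 4L, vals %% 4L)
    px[(32L * k + 1L):(32L * k + 32L)] <- as.integer(pair)
  }
  frame <- matrix(px, nrow = height, ncol = width, byrow = TRUE)
  list(frame = frame, mask = !is.na(frame), warnings = warnings)
}

# ---- frame I/O -------------------------------------------------------------

#' Write / read a frame as a plain-text digit matrix
#'
#' One row of the frame per line, pixels as digits 0-3 with no separator.
#' @param frame A `pixel_frame`.
#' @param path File path.
#' @return `path` invisibly / a `pixel_frame`.
#' @export
write_frame_txt <- function(frame, path) {
  lines <- apply(unclass(frame), 1L, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_frame_txt
#' @export
read_frame_txt <- function(path) {
  lines <- readLines(path)
  m <- do.call(rbind, lapply(lines, function(l)
    as.integer(strsplit(l, "", fixed = TRUE)[[1L]])))
  pixel_frame(m)
}

# fixed 4-colour palette for PNG round trips
FRAME_PALETTE <- matrix(c(1, 1, 1,    # 0 white
                          0.90, 0.22, 0.21,  # 1 red
                          0.12, 0.53, 0.90,  # 2 blue
                          0.26, 0.63, 0.28), # 3 green
                        nrow = 4L, byrow = TRUE)

#' Write / read a frame as PNG (fixed 4-colour palette)
#'
#' @param frame A `pixel_frame`.
#' @param path File path.
#' @return `path` invisibly / a `pixel_frame`.
#' @export
write_frame_png <- function(frame, path) {
  m <- unclass(frame)
  img <- array(0, dim = c(nrow(m), ncol(m), 3L))
  for (ch in 1:3) img[, , ch] <- matrix(FRAME_PALETTE[m + 1L, ch], nrow(m), ncol(m))
  png::writePNG(img, target = path)
  invisible(path)
}

#' @rdname write_frame_png
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  flat <- cbind(as.vector(img[, , 1L]), as.vector(img[, , 2L]), as.vector(img[, , 3L]))
  d2 <- apply(FRAME_PALETTE, 1L, function(p)
    colSums((t(flat) - p)^2))
  pixel_frame(matrix(max.col(-d2) - 1L, nrow = dim(img)[1L], ncol = dim(img)[2L]))
}
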