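# Arithmetic over GF(2^7) with the primitive polynomial x^7 + x^3 + 1
# (0x89 = 137). The field order 128 matches the 7-bit ASCII symbol set, so
# one Reed-Solomon symbol carries exactly one character.

.gf <- new.env(parent = emptyenv())

gf_tables <- function() {
  if (is.null(.gf$exp)) {
    ex <- integer(254L)
    v <- 1L
    for (i in 0:253) {
      ex[i + 1L] <- v
      v <- bitwShiftL(v, 1L)
      if (v >= 128L) v <- bitwXor(v, 137L)
    }
    lg <- rep(NA_integer_, 128L)
    lg[ex[1:127] + 1L] <- 0:126
    .gf$exp <- ex
    .gf$log <- lg
  }
  .gf
}

gf_check <- function(a) {
  a <- as.integer(a)
  if (anyNA(a) || any(a < 0L) || any(a > 127L)) {
    stop("symbols must be integers in 0..127 (GF(2^7))", call. = FALSE)
  }
  a
}

#' Multiply in GF(2^7)
#' @param a,b Integers in 0..127.
#' @return Integer product in the field.
#' @export
gf_mul <- function(a, b) {
  a <- gf_check(a); b <- gf_check(b)
  if (a == 0L || b == 0L) return(0L)
  t <- gf_tables()
  t$exp[((t$log[a + 1L] + t$log[b + 1L]) %% 127L) + 1L]
}

#' Invert in GF(2^7)
#' @param a Nonzero integer in 1..127.
#' @return Multiplicative inverse.
#' @export
gf_inv <- function(a) {
  a <- gf_check(a)
  if (a == 0L) stop("zero has no inverse", call. = FALSE)
  t <- gf_tables()
  t$exp[((127L - t$log[a + 1L]) %% 127L) + 1L]
}

#' Power of the field generator
#' @param n Exponent (any integer).
#' @return alpha^n with alpha = x (= 2).
#' @export
gf_alpha_pow <- function(n) {
  t <- gf_tables()
  t$exp[(as.integer(n) %% 127L) + 1L]
}

# evaluate a polynomial with coefficients `p` (p[1] = highest degree) at x
gf_poly_eval <- function(p, x) {
  acc <- 0L
  for (c in p) acc <- bitwXor(gf_mul(acc, x), as.integer(c))
  acc
}

# generator polynomial with roots alpha^0 .. alpha^(nroots-1); monic,
# coefficients highest-degree first
rs_generator <- function(nroots) {
  g <- 1L
  for (j in 0:(nroots - 1L)) {
    r <- gf_alpha_pow(j)
    # multiply g(x) by (x + alpha^j); subtraction == addition in char 2
    g <- bitwXor(c(g, 0L), c(0L, vapply(g, gf_mul, integer(1L), b = r)))
  }
  g
}

#' Reed-Solomon configuration
#'
#' A shortened systematic RS code over GF(2^7). The default two parity
#' symbols correct t = 1 symbol error, i.e. one 7-bit ASCII character.
#'
#' @param parity_symbols Number of parity symbols (2t), default 2.
#' @return An `ecc_config` list with `field_order`, `symbol_bits`,
#'   `parity_symbols`, `prim_poly`, `shortened`.
#' @export
ecc_config <- function(parity_symbols = 2L) {
  parity_symbols <- as.integer(parity_symbols)
  stopifnot(parity_symbols >= 2L, parity_symbols %% 2L == 0L,
            parity_symbols < 127L)
  structure(list(field_order = 128L, symbol_bits = 7L,
                 parity_symbols = parity_symbols, prim_poly = 137L,
                 shortened = TRUE),
            class = "ecc_config")
}

#' Reed-Solomon encode (systematic)
#'
#' Appends `cfg$parity_symbols` parity symbols to the message so that the
#' codeword polynomial vanishes at alpha^0..alpha^(2t-1).
#'
#' @param symbols Integer message symbols in 0..127.
#' @param cfg An [ecc_config()].
#' @return Integer codeword `c(symbols, parity)`.
#' @export
rs_encode <- function(symbols, cfg = ecc_config()) {
  symbols <- gf_check(symbols)
  nroots <- cfg$parity_symbols
  if (length(symbols) + nroots > 127L) {
    stop("codeword too long for GF(2^7): message must have <= ",
         127L - nroots, " symbols", call. = FALSE)
  }
  gen <- rs_generator(nroots)   # length nroots + 1, gen[1] == 1
  par <- integer(nroots)
  for (s in symbols) {
    fb <- bitwXor(s, par[1L])
    par <- c(par[-1L], 0L)
    if (fb != 0L) {
      par <- bitwXor(par, vapply(gen[-1L], gf_mul, integer(1L), a = fb))
    }
  }
  c(symbols, par)
}

#' Reed-Solomon decode
#'
#' Syndrome decoding specialised to t = 1 (two parity symbols): at most one
#' symbol error is located and corrected. With more than one corrupted
#' symbol the decoder either fails (`ok = FALSE`) or miscorrects to a
#' different valid codeword; callers needing to detect the latter must
#' re-check message-level structure.
#'
#' @param codeword Integer codeword (message followed by parity).
#' @param cfg An [ecc_config()] (only `parity_symbols = 2` supported).
#' @return List with `message`, `corrections` (0 or 1), `ok`.
#' @export
rs_decode <- function(codeword, cfg = ecc_config()) {
  codeword <- gf_check(codeword)
  nroots <- cfg$parity_symbols
  if (nroots != 2L) stop("decoder implements t = 1 (two parity symbols)", call. = FALSE)
  n <- length(codeword)
  if (n < nroots + 1L || n > 127L) {
    return(list(message = integer(0), corrections = 0L, ok = FALSE))
  }
  s0 <- gf_poly_eval(codeword, gf_alpha_pow(0L))
  s1 <- gf_poly_eval(codeword, gf_alpha_pow(1L))
  msg_len <- n - nroots
  if (s0 == 0L && s1 == 0L) {
    return(list(message = codeword[seq_len(msg_len)], corrections = 0L, ok = TRUE))
  }
  if (s0 == 0L || s1 == 0L) {
    return(list(message = codeword[seq_len(msg_len)], corrections = 0L, ok = FALSE))
  }
  t <- gf_tables()
  pos_deg <- (t$log[s1 + 1L] - t$log[s0 + 1L]) %% 127L
  k <- n - 1L - pos_deg  # 0-based index from codeword start
  if (k < 0L || k >= n) {
    # error located in the virtual zero padding of the shortened code
    return(list(message = codeword[seq_len(msg_len)], corrections = 0L, ok = FALSE))
  }
  corrected <- codeword
  corrected[k + 1L] <- bitwXor(corrected[k + 1L], s0)
  list(message = corrected[seq_len(msg_len)], corrections = 1L, ok = TRUE)
}
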