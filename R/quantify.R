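# Copy-number and capacity arithmetic for the droplet storage system.
# Percentages are rounded half-away-from-zero to one decimal, matching how
# printed efficiencies are reported.

round_half_away <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Ligation efficiency from copy numbers
#'
#' @param ligated Copy number of the ligated product (qPCR-style count).
#' @param input Input copy number.
#' @return Percentage (one decimal): `100 * ligated / input`.
#' @export
#' @examples
#' ligation_efficiency(1.67e12, 9.04e12) # 18.5
ligation_efficiency <- function(ligated, input) {
  stopifnot(input > 0, ligated >= 0)
  if (ligated > input) stop("ligated copies cannot exceed input copies", call. = FALSE)
  round_half_away(100 * ligated / input, 1L)
}

#' Compounded serial-assembly efficiency
#'
#' After n junctions at per-junction efficiency e, the product fraction is
#' e^n.
#'
#' @param e Per-junction efficiency in (0, 1].
#' @param n Number of junctions (>= 1).
#' @return Percentage (one decimal): `100 * e^n`.
#' @export
#' @examples
#' serial_efficiency(0.185, 4) # 0.1
serial_efficiency <- function(e, n) {
  stopifnot(e > 0, e <= 1, n >= 1)
  round_half_away(100 * e^n, 1L)
}

#' Logical density of the two-pixel codon code
#'
#' @param bits Bits per codon (4: two 2-bit pixels).
#' @param bases Bases per codon (3).
#' @return Exact density in bits per base (4/3 = 1.33 bits/bp).
#' @export
codon_bit_density <- function(bits = 4, bases = 3) bits / bases

#' Oligos needed per pixel frame
#'
#' @param pixels Pixels per frame (256 for 16 x 16).
#' @param oligo_len Oligo length (90 nt).
#' @param index_len Index length (2 nt).
#' @param addr_len Address length (20 nt, two per oligo).
#' @param pixels_per_codon Pixels per codon (2).
#' @param codon_len Codon length (3 nt).
#' @return Oligo count: `ceil(pixels / (pixels_per_codon * payload / codon_len))`.
#' @export
#' @examples
#' oligos_per_frame() # 8
oligos_per_frame <- function(pixels = 256L, oligo_len = 90L, index_len = 2L,
                             addr_len = 20L, pixels_per_codon = 2L,
                             codon_len = 3L) {
  payload <- oligo_len - index_len - 2L * addr_len
  if (payload <= 0L || payload %% codon_len != 0L) {
    stop("payload length must be a positive multiple of the codon length",
         call. = FALSE)
  }
  as.integer(ceiling(pixels / (pixels_per_codon * payload / codon_len)))
}

#' Per-oligo byte accounting
#'
#' @param file_kb File size in kB (decimal: 1 kB = 1000 B).
#' @param n_oligos Number of oligos storing the file.
#' @return Bytes per oligo.
#' @export
#' @examples
#' bytes_per_oligo(0.28, 8) # 35
bytes_per_oligo <- function(file_kb, n_oligos) {
  stopifnot(file_kb > 0, n_oligos >= 1)
  file_kb * 1000 / n_oligos
}

#' Droplet storage capacity
#'
#' @param droplet_copies Oligo copies per droplet (~1e12 scale).
#' @param redundancy Copies kept per unique oligo (default 1000, the
#'   redundancy reserved for ligation yield).
#' @param bytes_per_oligo Payload bytes per unique oligo.
#' @return Capacity in GB (decimal: 1 GB = 1e9 B).
#' @export
#' @examples
#' droplet_capacity(9.04e12, 1000, 33.7) # 304.648
droplet_capacity <- function(droplet_copies = 9.04e12, redundancy = 1000,
                             bytes_per_oligo = 33.7) {
  stopifnot(droplet_copies > 0, redundancy >= 1, bytes_per_oligo > 0)
  (droplet_copies / redundancy) * bytes_per_oligo / 1e9
}
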