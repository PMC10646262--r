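# In-silico droplet splint-ligation assembly. Data strands are single
# stranded 5'->3'; a 30-nt splint is the reverse complement of the junction
# (last 15 nt of the upstream strand followed by the first 15 nt of the
# downstream strand). Splints act only as junction validators: their bases
# never enter the ligation product.

#' Construct a fragment
#'
#' @param id Species id.
#' @param seq Fragment sequence (5'->3').
#' @param copies Copy number (molecule count; expectations may be fractional).
#' @param phosphorylated 5'-phosphorylation state; ligation of a junction
#'   requires the downstream fragment to be phosphorylated (the no-ligation
#'   control sets this FALSE).
#' @return A `dna_fragment`.
#' @export
fragment <- function(id, seq, copies = 1, phosphorylated = TRUE) {
  structure(list(id = as.character(id), seq = dna(seq),
                 copies = as.numeric(copies),
                 phosphorylated = isTRUE(phosphorylated)),
            class = "dna_fragment")
}

#' Build a pool (one droplet's contents)
#'
#' @param ... `dna_fragment` objects, or a single list of them.
#' @return A `dna_pool`: list of fragments with distinct sequences
#'   (duplicate sequences are merged by summing copies).
#' @export
pool <- function(...) {
  frags <- list(...)
  if (length(frags) == 1L && !inherits(frags[[1L]], "dna_fragment")) {
    frags <- frags[[1L]]
  }
  stopifnot(all(vapply(frags, inherits, logical(1L), "dna_fragment")))
  if (any(vapply(frags, function(f) f$copies < 0, logical(1L)))) {
    stop("copy numbers must be >= 0", call. = FALSE)
  }
  seqs <- vapply(frags, `[[`, character(1L), "seq")
  if (anyDuplicated(seqs)) {
    keep <- !duplicated(seqs)
    for (i in which(duplicated(seqs))) {
      j <- which(seqs == seqs[i])[1L]
      frags[[j]]$copies <- frags[[j]]$copies + frags[[i]]$copies
    }
    frags <- frags[keep]
  }
  structure(list(members = frags, provenance = character(0)), class = "dna_pool")
}

#' @export
print.dna_pool <- function(x, ...) {
  cat(sprintf("<dna_pool> %d species\n", length(x$members)))
  for (f in x$members) {
    cat(sprintf("  %-24s %5d nt  %.6g copies\n", f$id, nchar(f$seq), f$copies))
  }
  invisible(x)
}

#' Yield model for ligation
#'
#' @param efficiency Per-junction ligation efficiency in (0, 1]; the default
#'   0.185 is the measured splint-ligation efficiency with excess T4 ligase.
#' @param mode `"expectation"` (deterministic expected copies, the default)
#'   or `"bernoulli"` (per-copy thinning; requires a seed).
#' @param seed RNG seed, mandatory for Bernoulli mode.
#' @return A `yield_model`.
#' @export
yield_model <- function(efficiency = 0.185,
                        mode = c("expectation", "bernoulli"), seed = NULL) {
  mode <- match.arg(mode)
  if (!(efficiency > 0 && efficiency <= 1)) {
    stop("efficiency must be in (0, 1]", call. = FALSE)
  }
  if (mode == "bernoulli" && is.null(seed)) {
    stop("bernoulli mode requires an explicit seed", call. = FALSE)
  }
  structure(list(efficiency = efficiency, mode = mode, seed = seed),
            class = "yield_model")
}

last_n <- function(s, n) substr(s, nchar(s) - n + 1L, nchar(s))
first_n <- function(s, n) substr(s, 1L, n)

#' Design the 30-nt splint bridging two fragments
#'
#' `splint = revcomp(last 15 nt of upstream || first 15 nt of downstream)`.
#'
#' @param upstream,downstream `dna_fragment`s (or objects accepted by
#'   [as_fragment()]); both must be at least 15 nt.
#' @return A `splint_oligo` with `seq`, `upstream_target`, `downstream_target`.
#' @export
design_splint <- function(upstream, downstream) {
  if (!inherits(upstream, "dna_fragment")) upstream <- as_fragment(upstream)
  if (!inherits(downstream, "dna_fragment")) downstream <- as_fragment(downstream)
  if (nchar(upstream$seq) < 15L || nchar(downstream$seq) < 15L) {
    stop("fragments must be at least 15 nt to design a splint", call. = FALSE)
  }
  junction <- paste0(last_n(upstream$seq, 15L), first_n(downstream$seq, 15L))
  structure(list(seq = revcomp(junction),
                 upstream_target = upstream$id,
                 downstream_target = downstream$id),
            class = "splint_oligo")
}

# does this splint hybridize the 3' end of `a` and the 5' end of `b`?
splint_matches <- function(splint, a, b) {
  nchar(a$seq) >= 15L && nchar(b$seq) >= 15L &&
    identical(splint$seq,
              revcomp(paste0(last_n(a$seq, 15L), first_n(b$seq, 15L))))
}

#' Ligate two fragments across a splint
#'
#' Hybridization requires exact 15-mer matches on both sides of the splint;
#' a mismatch is a recorded no-product outcome, not an error. In expectation
#' mode the product copy number is `min(copies) * efficiency`; in Bernoulli
#' mode it is binomially thinned. Unligated copies are retained as leftovers
#' so copy number is conserved at every junction.
#'
#' @param a Upstream fragment. @param b Downstream fragment.
#' @param splint A [design_splint()] result.
#' @param model A [yield_model()].
#' @return List with `product` (`dna_fragment` or `NULL`), `leftovers`
#'   (list of fragments with residual copies), and `ligated` (copies formed).
#' @export
ligate <- function(a, b, splint, model = yield_model()) {
  no_product <- list(product = NULL, leftovers = list(a, b), ligated = 0)
  if (!b$phosphorylated) return(no_product)       # nick cannot be sealed
  if (!splint_matches(splint, a, b)) return(no_product)
  avail <- min(a$copies, b$copies)
  formed <- if (model$mode == "expectation") {
    avail * model$efficiency
  } else {
    with_seed(model$seed, stats::rbinom(1L, floor(avail), model$efficiency))
  }
  prod <- fragment(paste(a$id, b$id, sep = "+"),
                   paste0(a$seq, b$seq), copies = formed,
                   phosphorylated = a$phosphorylated)
  la <- a; la$copies <- a$copies - formed
  lb <- b; lb$copies <- b$copies - formed
  list(product = prod, leftovers = list(la, lb), ligated = formed)
}

#' Assembly program steps
#'
#' A step associates two droplets at a y-junction. A serial step carries one
#' (or more) splints chaining products; a parallel step carries k >= 2
#' distinct splints sharing one upstream address so the droplet splits into
#' k product species.
#'
#' @param left,right Names of input droplets (pools).
#' @param out Name for the merged output droplet.
#' @param splints List of `splint_oligo`s.
#' @return An `assembly_step`.
#' @export
serial_step <- function(left, right, out, splints) {
  if (inherits(splints, "splint_oligo")) splints <- list(splints)
  structure(list(type = "serial", left = left, right = right, out = out,
                 splints = splints), class = "assembly_step")
}

#' @rdname serial_step
#' @export
parallel_step <- function(left, right, out, splints) {
  stopifnot(length(splints) >= 2L)
  up15 <- vapply(splints, function(s) last_n(s$seq, 15L), character(1L))
  if (length(unique(up15)) != 1L) {
    stop("parallel splints must share one upstream address (identical 3' 15-mer target)",
         call. = FALSE)
  }
  s <- serial_step(left, right, out, splints)
  s$type <- "parallel"
  s
}

#' Build an assembly program
#' @param ... `assembly_step`s, or one list of them.
#' @return An `assembly_program`.
#' @export
assembly_program <- function(...) {
  steps <- list(...)
  if (length(steps) == 1L && !inherits(steps[[1L]], "assembly_step")) {
    steps <- steps[[1L]]
  }
  stopifnot(all(vapply(steps, inherits, logical(1L), "assembly_step")))
  structure(list(steps = steps), class = "assembly_program")
}

#' Run an assembly program over named pools
#'
#' Steps execute in order; each step merges its two input droplets, attempts
#' every splint against all fragment pairs (upstream from `left`, downstream
#' from `right`), and writes products plus unligated leftovers to the `out`
#' droplet. Provenance records every junction. An empty program returns the
#' inputs unchanged.
#'
#' @param program An [assembly_program()].
#' @param pools Named list of [pool()]s.
#' @param model A [yield_model()].
#' @return The updated named list of pools, with attribute `"final"` naming
#'   the last output droplet (if any steps ran).
#' @export
run_program <- function(program, pools, model = yield_model()) {
  stopifnot(inherits(program, "assembly_program"), is.list(pools))
  known <- names(pools)
  for (s in program$steps) {     # validate references before executing
    if (!s$left %in% known || !s$right %in% known) {
      stop(sprintf("step '%s': unknown droplet '%s'", s$out,
                   setdiff(c(s$left, s$right), known)[1L]), call. = FALSE)
    }
    known <- union(known, s$out)
  }
  final <- NULL
  for (s in program$steps) {
    left <- pools[[s$left]]$members
    right <- pools[[s$right]]$members
    consumed_l <- numeric(length(left))
    consumed_r <- numeric(length(right))
    products <- list()
    prov <- character(0)
    for (sp in s$splints) {
      for (i in seq_along(left)) for (j in seq_along(right)) {
        a <- left[[i]]; b <- right[[j]]
        a$copies <- a$copies - consumed_l[i]
        b$copies <- b$copies - consumed_r[j]
        if (a$copies <= 0 || b$copies <= 0) next
        res <- ligate(a, b, sp, model)
        if (res$ligated > 0) {
          products <- c(products, list(res$product))
          consumed_l[i] <- consumed_l[i] + res$ligated
          consumed_r[j] <- consumed_r[j] + res$ligated
          prov <- c(prov, sprintf("%s: %s + %s -> %s (%.6g copies)",
                                  s$type, a$id, b$id, res$product$id, res$ligated))
        }
      }
    }
    leftovers <- c(
      lapply(seq_along(left), function(i) {
        f <- left[[i]]; f$copies <- f$copies - consumed_l[i]; f
      }),
      lapply(seq_along(right), function(j) {
        f <- right[[j]]; f$copies <- f$copies - consumed_r[j]; f
      }))
    leftovers <- Filter(function(f) f$copies > 0, leftovers)
    out <- pool(c(products, leftovers))
    out$provenance <- c(pools[[s$left]]$provenance, pools[[s$right]]$provenance, prov)
    pools[[s$out]] <- out
    final <- s$out
  }
  attr(pools, "final") <- final
  pools
}

#' Virtual gel: size ladder of a pool
#'
#' @param x A `dna_pool`.
#' @return data.frame with one row per distinct length, ascending: `length`,
#'   `species` (number of distinct species at that length), `copies`
#'   (aggregate copy number). Supports size-based multi-bit readout (a
#'   100-bp band as LSB up to a 500-bp band as MSB).
#' @export
size_ladder <- function(x) {
  stopifnot(inherits(x, "dna_pool"))
  if (!length(x$members)) {
    return(data.frame(length = integer(0), species = integer(0), copies = numeric(0)))
  }
  len <- vapply(x$members, function(f) nchar(f$seq), integer(1L))
  cp <- vapply(x$members, function(f) f$copies, numeric(1L))
  agg <- stats::aggregate(cbind(species = 1L, copies = cp),
                          by = list(length = len), FUN = sum)
  agg <- agg[order(agg$length), , drop = FALSE]
  agg$species <- as.integer(agg$species)
  rownames(agg) <- NULL
  agg
}

#' Write a pool as FASTA plus a copy-number sidecar
#'
#' @param x A `dna_pool`.
#' @param fasta_path,tsv_path Output paths (TSV columns: species_id, length,
#'   copies).
#' @export
write_pool <- function(x, fasta_path, tsv_path) {
  ids <- vapply(x$members, `[[`, character(1L), "id")
  seqs <- vapply(x$members, `[[`, character(1L), "seq")
  cps <- vapply(x$members, `[[`, numeric(1L), "copies")
  write_fasta(data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE), fasta_path)
  utils::write.table(
    data.frame(species_id = ids, length = nchar(seqs), copies = cps),
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Read a pool from FASTA plus a copy-number sidecar
#' @param fasta_path,tsv_path Paths written by [write_pool()]; `tsv_path`
#'   may be `NULL` (all copies 1).
#' @return A `dna_pool`.
#' @export
read_pool <- function(fasta_path, tsv_path = NULL) {
  rec <- read_fasta(fasta_path)
  cps <- rep(1, nrow(rec))
  if (!is.null(tsv_path)) {
    tab <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    cps <- tab$copies[match(rec$id, tab$species_id)]
    cps[is.na(cps)] <- 1
  }
  pool(lapply(seq_len(nrow(rec)), function(i)
    fragment(rec$id[i], rec$seq[i], copies = cps[i])))
}
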