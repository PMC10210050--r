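# IUPAC nucleotide alphabet: bitmask encoding A=1, C=2, G=4, T=8.
# A primer code is compatible with a template code iff the bitsets intersect.

IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# inverse lookup: bitset (1..15) -> minimal IUPAC letter
BITS_IUPAC <- character(15L)
BITS_IUPAC[IUPAC_BITS] <- names(IUPAC_BITS)

IUPAC_COMPLEMENT_FROM <- "ACGTMRWSYKVHDBN"
IUPAC_COMPLEMENT_TO   <- "TGCAKYWSRMBDHVN"

#' Reverse complement of IUPAC DNA strings
#'
#' Complements every IUPAC ambiguity code (e.g. `R` <-> `Y`) and reverses the
#' sequence. Gaps (`-`) are preserved in place.
#'
#' @param x Character vector of DNA sequences (IUPAC codes, optionally `-`).
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' reverse_complement("AGCAY")
#' @export
reverse_complement <- function(x) {
  comp <- chartr(IUPAC_COMPLEMENT_FROM, IUPAC_COMPLEMENT_TO, toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Degeneracy of an IUPAC sequence
#'
#' The number of distinct unambiguous sequences an IUPAC string expands to:
#' the product over positions of the size of each position's base set.
#'
#' @param x Character vector of IUPAC DNA sequences (no gaps).
#' @return Numeric vector of degeneracies (>= 1).
#' @examples
#' degeneracy("GAAAGCATCYCCTTATGTG")  # one Y -> 2
#' @export
degeneracy <- function(x) {
  vapply(x, function(s) {
    bits <- seq_to_bits(s, context = "degeneracy()")
    prod(popcount4(bits))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Expand a degenerate IUPAC sequence
#'
#' @param x A single IUPAC DNA sequence.
#' @param max_expansions Refuse to expand beyond this many sequences.
#' @return Character vector of all unambiguous A/C/G/T expansions.
#' @examples
#' expand_degenerate("ACY")
#' @export
expand_degenerate <- function(x, max_expansions = 64) {
  stopifnot(length(x) == 1L)
  d <- degeneracy(x)
  if (d > max_expansions) {
    abort(sprintf(
      "sequence expands to %d unambiguous sequences (limit %d)",
      d, max_expansions), class = "cladeprimer_degeneracy_error")
  }
  bits <- seq_to_bits(x, context = "expand_degenerate()")
  sets <- lapply(bits, bits_to_bases)
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

# per-code number of bases in the set (codes 1..15)
popcount4 <- function(bits) {
  (bitwAnd(bits, 1L) > 0L) + (bitwAnd(bits, 2L) > 0L) +
    (bitwAnd(bits, 4L) > 0L) + (bitwAnd(bits, 8L) > 0L)
}

bits_to_bases <- function(b) {
  c("A", "C", "G", "T")[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L]
}

# Encode one sequence as an integer vector of bitsets. Gaps become 0 when
# allow_gap, otherwise any non-IUPAC character is an error naming the position.
seq_to_bits <- function(s, allow_gap = FALSE, context = "sequence") {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  bits <- unname(IUPAC_BITS[ch])
  bad <- which(is.na(bits) & !(allow_gap & ch == "-"))
  if (length(bad) > 0L) {
    abort(sprintf("%s: illegal character '%s' at position %d",
                  context, ch[bad[1]], bad[1]),
          class = "cladeprimer_alphabet_error")
  }
  bits[is.na(bits)] <- 0L
  bits
}

# Validate a vector of sequences; errors name the offending id and position.
validate_dna <- function(seqs, ids, allow_gap = FALSE) {
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) {
      abort(sprintf("record '%s': empty sequence", ids[[i]]),
            class = "cladeprimer_alphabet_error")
    }
    seq_to_bits(seqs[[i]], allow_gap = allow_gap,
                context = sprintf("record '%s'", ids[[i]]))
  }
  invisible(TRUE)
}

# Normalise case and map RNA 'U' to 'T' (with a warning naming the records).
normalize_dna <- function(seqs, ids) {
  seqs <- toupper(seqs)
  has_u <- grepl("U", seqs, fixed = TRUE)
  if (any(has_u)) {
    warn(sprintf("mapped 'U' to 'T' in %d record(s): %s",
                 sum(has_u),
                 paste(head(ids[has_u], 5), collapse = ", ")))
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
  }
  seqs
}
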