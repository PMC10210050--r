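#' Thermodynamic parameter set
#'
#' Parameters for melting-temperature estimation. Two published
#' nearest-neighbor tables are provided: `"breslauer1986"` (default) with the
#' classic 11.7·log10\[Na+\] melting-point salt adjustment, and
#' `"santalucia1998"` (the unified duplex set) with its canonical entropy
#' correction 0.368·(N−1)·ln\[Na+\]. The Breslauer parameterization is the
#' default because it reproduces, within a small tolerance, the Tm values that
#' the widely used vendor primer-analysis tools print for typical 18-22 nt
#' primers at the default 50 mM monovalent salt and 250 nM primer.
#'
#' @param method `"nearest_neighbor"` or `"wallace"`.
#' @param nn_set `"breslauer1986"` or `"santalucia1998"`.
#' @param na_mM Monovalent cation concentration in mM (> 0).
#' @param primer_nM Total primer concentration in nM (> 0).
#' @return A list of class `thermo_params`.
#' @export
thermo_params <- function(method = c("nearest_neighbor", "wallace"),
                          nn_set = c("breslauer1986", "santalucia1998"),
                          na_mM = 50, primer_nM = 250) {
  method <- match.arg(method)
  nn_set <- match.arg(nn_set)
  if (na_mM <= 0 || primer_nM <= 0) {
    abort("concentrations must be positive", class = "cladeprimer_thermo_error")
  }
  structure(list(method = method, nn_set = nn_set,
                 na_mM = na_mM, primer_nM = primer_nM),
            class = "thermo_params")
}

# Nearest-neighbor stacks keyed by the 10 canonical dimers; the other six are
# looked up through the reverse complement. dH kcal/mol, dS cal/(mol K).
NN_TABLES <- list(
  breslauer1986 = list(
    dH = c(AA = -9.1, AT = -8.6, TA = -6.0, CA = -5.8, GT = -6.5,
           CT = -7.8, GA = -5.6, CG = -11.9, GC = -11.1, GG = -11.0),
    dS = c(AA = -24.0, AT = -23.9, TA = -16.9, CA = -12.9, GT = -17.3,
           CT = -20.8, GA = -13.5, CG = -27.8, GC = -26.7, GG = -26.6)
  ),
  santalucia1998 = list(
    dH = c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0),
    dS = c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  )
)

#' Wallace-rule melting temperature
#'
#' The 2-4 rule: 2 °C per A/T plus 4 °C per G/C. A quick screening baseline
#' for short oligos; requires an unambiguous sequence.
#'
#' @param seq A single A/C/G/T sequence.
#' @return Temperature in °C.
#' @examples
#' tm_wallace("AGCAGTGAGGAATATTGGTC")  # 58
#' @export
tm_wallace <- function(seq) {
  bits <- seq_to_bits(seq, context = "tm_wallace()")
  if (any(popcount4(bits) > 1L)) {
    abort("tm_wallace() requires an unambiguous sequence; expand degeneracies first (expand_degenerate())",
          class = "cladeprimer_thermo_error")
  }
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  at <- sum(ch %in% c("A", "T"))
  gc <- sum(ch %in% c("G", "C"))
  2 * at + 4 * gc
}

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm from a nearest-neighbor dH/dS sum with a monovalent-salt
#' correction, Tm = 1000·dH / (dS + R·ln(C/4)) − 273.15 (C/1 for
#' self-complementary oligos). Degenerate sequences are scored as the
#' arithmetic mean over all expansions (at most 16).
#'
#' @param seq A single IUPAC DNA sequence, length >= 8.
#' @param params A [thermo_params()] object.
#' @return Temperature in °C (deterministic to well below 0.1 °C).
#' @export
tm_nn <- function(seq, params = thermo_params()) {
  if (nchar(seq) < 8L) {
    abort("tm_nn() requires length >= 8", class = "cladeprimer_thermo_error")
  }
  if (degeneracy(seq) > 16) {
    abort("degeneracy > 16; refusing to average over that many expansions",
          class = "cladeprimer_thermo_error")
  }
  mean(vapply(expand_degenerate(seq, 16), tm_nn_one, numeric(1),
              params = params))
}

tm_nn_one <- function(s, params) {
  tab <- NN_TABLES[[params$nn_set]]
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  n <- length(ch)
  dimers <- paste0(ch[-n], ch[-1])
  keys <- ifelse(dimers %in% names(tab$dH), dimers,
                 reverse_complement(dimers))
  dH <- sum(tab$dH[keys])
  dS <- sum(tab$dS[keys])
  selfcomp <- identical(paste(ch, collapse = ""),
                        reverse_complement(paste(ch, collapse = "")))
  na_M <- params$na_mM / 1000
  if (params$nn_set == "breslauer1986") {
    # duplex initiation entropy depends on G/C content class
    dS <- dS + if (any(ch %in% c("G", "C"))) -16.8 else -20.1
    if (selfcomp) dS <- dS - 1.3
  } else {
    # unified set: terminal initiation per duplex end
    for (term in ch[c(1L, n)]) {
      if (term %in% c("A", "T")) {
        dH <- dH + 2.3; dS <- dS + 4.1
      } else {
        dH <- dH + 0.1; dS <- dS - 2.8
      }
    }
    if (selfcomp) dS <- dS - 1.4
    dS <- dS + 0.368 * (n - 1) * log(na_M)
  }
  conc <- params$primer_nM * 1e-9 / (if (selfcomp) 1 else 4)
  tm <- 1000 * dH / (dS + 1.987 * log(conc)) - 273.15
  if (params$nn_set == "breslauer1986") {
    tm <- tm + 11.7 * log10(na_M)
  }
  tm
}

#' Length of the 3'-terminal G/C run
#'
#' Length of the maximal suffix consisting only of G, C or S (the G/C
#' ambiguity code). Long 3' G/C runs over-stabilise the primer terminus and
#' raise the risk of non-specific priming; candidate filters typically cap
#' this at 3.
#'
#' @param seq A non-empty IUPAC DNA sequence.
#' @return Integer run length (0 when the last base is A/T-like).
#' @examples
#' three_prime_gc_run("ATGTGGCACGTCTATAGCCC")  # 4
#' @export
three_prime_gc_run <- function(seq) {
  ch <- rev(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  if (length(ch) == 0L) {
    abort("empty sequence", class = "cladeprimer_thermo_error")
  }
  run <- 0L
  for (c in ch) {
    if (c %in% c("G", "C", "S")) run <- run + 1L else break
  }
  run
}

#' Screen a primer pair (or a primer against itself) for dimers
#'
#' Slides the two oligos against each other in antiparallel orientation at
#' every ungapped offset and reports the longest contiguous complementary run,
#' the longest run anchored at `a`'s 3' terminus, and the offset of the best
#' duplex. Complementarity is IUPAC-aware (sets must intersect after
#' complementing). No loops or bulges are modelled: this is a screening-level
#' dimer check, not a free-energy minimisation.
#'
#' @param a,b Non-empty IUPAC DNA sequences, 5'→3'. Use `b = a` for a
#'   self-dimer scan.
#' @return A one-row tibble: `max_run`, `three_prime_run` (runs ending exactly
#'   at `a`'s 3' end), `best_offset` (shift of reversed `b` relative to `a`;
#'   0 means `b`'s 3' end aligns with `a`'s 5' end), `self_dimer`.
#' @export
dimer_scan <- function(a, b = a) {
  abits <- seq_to_bits(a, context = "dimer_scan(a)")
  # b antiparallel under a: position j of reversed b pairs with a[i];
  # complement of reversed b == reverse_complement(b) read left to right
  bcomp <- seq_to_bits(reverse_complement(b), context = "dimer_scan(b)")
  na_ <- length(abits); nb <- length(bcomp)
  max_run <- 0L; best_offset <- 0L; tp_run <- 0L
  for (off in (-(nb - 1L)):(na_ - 1L)) {
    i <- max(1L, 1L + off):min(na_, nb + off)
    j <- i - off
    comp <- bitwAnd(abits[i], bcomp[j]) > 0L
    r <- run_lengths(comp)
    if (r$max > max_run) {
      max_run <- r$max
      best_offset <- off
    }
    # run ending at a's 3' terminus (last position of a inside this overlap)
    if (i[length(i)] == na_ && r$tail > tp_run) tp_run <- r$tail
  }
  tibble(max_run = max_run, three_prime_run = tp_run,
         best_offset = best_offset, self_dimer = identical(a, b))
}

run_lengths <- function(x) {
  if (!any(x)) return(list(max = 0L, tail = 0L))
  r <- rle(x)
  list(max = max(r$lengths[r$values]),
       tail = if (r$values[length(r$values)]) r$lengths[length(r$lengths)] else 0L)
}
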