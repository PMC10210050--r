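# Shared helpers and independent oracles for property tests. These are kept
# deliberately naive and separate from the package's implementation paths.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive per-column variable/total site counter over a character matrix
oracle_variable_sites <- function(rows, cols) {
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  total <- 0L; variable <- 0L
  for (j in cols) {
    col <- mat[, j]
    if (any(col != "-")) {
      total <- total + 1L
      bases <- unique(col[col %in% c("A", "C", "G", "T")])
      if (length(bases) >= 2L) variable <- variable + 1L
    }
  }
  c(variable = variable, total = total)
}

# letter-set complement view, independent of the package's bit encoding
oracle_sets <- list(A = "A", C = "C", G = "G", T = "T",
                    M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                    S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
                    V = c("A", "C", "G"), H = c("A", "C", "T"),
                    D = c("A", "G", "T"), B = c("C", "G", "T"),
                    N = c("A", "C", "G", "T"))
oracle_comp <- c(A = "T", C = "G", G = "C", T = "A")

# exhaustive all-offset antiparallel dimer oracle (double loop on diagonals)
oracle_dimer <- function(a, b) {
  ach <- strsplit(a, "", fixed = TRUE)[[1]]
  bch <- rev(strsplit(b, "", fixed = TRUE)[[1]])  # b read 3'->5'
  na_ <- length(ach); nb <- length(bch)
  is_pair <- function(x, y) {
    # complementary iff the set of x intersects the complement-set of y
    any(oracle_sets[[x]] %in% oracle_comp[oracle_sets[[y]]])
  }
  max_run <- 0L; tp_run <- 0L
  for (off in (-(nb - 1L)):(na_ - 1L)) {
    run <- 0L
    for (i in max(1L, 1L + off):min(na_, nb + off)) {
      j <- i - off
      if (is_pair(ach[i], bch[j])) {
        run <- run + 1L
        if (run > max_run) max_run <- run
        if (i == na_ && run > tp_run) tp_run <- run
      } else {
        run <- 0L
      }
    }
  }
  c(max_run = max_run, three_prime_run = tp_run)
}

# hand-summed nearest-neighbor Tm oracle (Breslauer stacks typed out in
# duplex orientation, summed dimer by dimer)
oracle_tm_breslauer <- function(s, na_mM = 50, primer_nM = 250) {
  dH <- c("AA" = -9.1, "TT" = -9.1, "AT" = -8.6, "TA" = -6.0,
          "CA" = -5.8, "TG" = -5.8, "GT" = -6.5, "AC" = -6.5,
          "CT" = -7.8, "AG" = -7.8, "GA" = -5.6, "TC" = -5.6,
          "CG" = -11.9, "GC" = -11.1, "GG" = -11.0, "CC" = -11.0)
  dS <- c("AA" = -24.0, "TT" = -24.0, "AT" = -23.9, "TA" = -16.9,
          "CA" = -12.9, "TG" = -12.9, "GT" = -17.3, "AC" = -17.3,
          "CT" = -20.8, "AG" = -20.8, "GA" = -13.5, "TC" = -13.5,
          "CG" = -27.8, "GC" = -26.7, "GG" = -26.6, "CC" = -26.6)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  h <- 0; sct <- 0
  for (i in seq_len(length(ch) - 1L)) {
    d <- paste0(ch[i], ch[i + 1L])
    h <- h + dH[[d]]; sct <- sct + dS[[d]]
  }
  sct <- sct + if (any(ch %in% c("G", "C"))) -16.8 else -20.1
  selfcomp <- identical(s, cladeprimer::reverse_complement(s))
  if (selfcomp) sct <- sct - 1.3
  conc <- primer_nM * 1e-9 / (if (selfcomp) 1 else 4)
  1000 * h / (sct + 1.987 * log(conc)) - 273.15 + 11.7 * log10(na_mM / 1000)
}

# canonical view of a hits table for set comparison between engines
hit_key <- function(h) {
  d <- tibble::as_tibble(h)
  if (nrow(d) == 0L) return(character(0))
  sort(paste(d$template_id, d$strand, d$fwd_5p, d$fwd_mm,
             d$rev_5p, d$rev_mm, d$length_bp, d$seq, sep = "|"))
}

write_tmp_fasta <- function(ids, seqs, wrap = FALSE) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  lines <- unlist(purrr::map2(ids, seqs, function(i, s) {
    body <- if (wrap) {
      starts <- seq(1, nchar(s), by = 60)
      substring(s, starts, pmin(starts + 59, nchar(s)))
    } else s
    c(paste0(">", i), body)
  }))
  writeLines(lines, path)
  path
}
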