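#' In silico PCR parameters
#'
#' Mismatch and amplicon-length rules for binding-site search and simulated
#' amplification. Defaults follow common ecoPCR-style practice for fungal
#' barcoding: up to 3 mismatches per primer, a hard zero-mismatch window over
#' the last two 3' positions, and amplicons accepted between 200 and 2500 bp.
#'
#' @param max_mismatch Maximum mismatches allowed per primer (>= 0).
#' @param protected_3prime Number of 3'-terminal primer positions where any
#'   mismatch abolishes binding (counted from the primer's 3' end regardless
#'   of strand).
#' @param min_len,max_len Accepted amplicon length bounds in bp, measured with
#'   the 5'-anchored coordinate-difference convention (see
#'   [predict_amplicon_length()]).
#' @param ambig_template `"intersect"` (a template ambiguity code matches a
#'   primer position when the base sets intersect) or `"strict"` (any template
#'   ambiguity counts as a mismatch).
#' @return A list of class `pcr_params`.
#' @export
pcr_params <- function(max_mismatch = 3, protected_3prime = 2,
                       min_len = 200, max_len = 2500,
                       ambig_template = c("intersect", "strict")) {
  ambig_template <- match.arg(ambig_template)
  if (min_len > max_len) {
    abort("min_len > max_len", class = "cladeprimer_pcr_error")
  }
  if (max_mismatch < 0 || protected_3prime < 0) {
    abort("max_mismatch and protected_3prime must be >= 0",
          class = "cladeprimer_pcr_error")
  }
  structure(list(max_mismatch = as.integer(max_mismatch),
                 protected_3prime = as.integer(protected_3prime),
                 min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 ambig_template = ambig_template),
            class = "pcr_params")
}

as_primer_seq <- function(x) {
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  if (is.data.frame(x) && nrow(x) == 1L && "seq" %in% names(x)) {
    return(toupper(x$seq))
  }
  abort("primer must be a single sequence string or a one-row tibble with a 'seq' column",
        class = "cladeprimer_pcr_error")
}

# Vectorized scan of one strand string for a primer (both written 5'->3',
# template left to right; primer 3' end is its rightmost position).
# Returns start positions, mismatch counts and mismatch-position lists
# (positions indexed from the primer 5' end).
scan_strand <- function(pbits, tbits, params) {
  m <- length(pbits); L <- length(tbits)
  if (m > L) return(list(start = integer(0), mm = integer(0), pos = list()))
  starts <- seq_len(L - m + 1L)
  idx <- outer(starts - 1L, seq_len(m), `+`)
  tcodes <- matrix(tbits[idx], nrow = length(starts))
  if (params$ambig_template == "strict") {
    # template base must be a single base contained in the primer set
    tmpl_ok <- matrix(popcount4(tcodes) == 1L, nrow = length(starts))
    match_mat <- tmpl_ok &
      (matrix(bitwAnd(rep(pbits, each = length(starts)), tcodes),
              nrow = length(starts)) == tcodes) & tcodes > 0L
  } else {
    match_mat <- matrix(bitwAnd(rep(pbits, each = length(starts)), tcodes),
                        nrow = length(starts)) > 0L
  }
  mm <- m - rowSums(match_mat)
  prot_cols <- if (params$protected_3prime > 0L)
    (m - params$protected_3prime + 1L):m else integer(0)
  prot_ok <- if (length(prot_cols) > 0L)
    rowSums(!match_mat[, prot_cols, drop = FALSE]) == 0L else TRUE
  keep <- which(mm <= params$max_mismatch & prot_ok)
  list(start = starts[keep],
       mm = as.integer(mm[keep]),
       pos = lapply(keep, function(k) which(!match_mat[k, ])))
}

#' Find primer binding sites on a template
#'
#' Scans both strands of an ungapped template for positions where the primer
#' anneals with at most `max_mismatch` mismatches and no mismatch within the
#' protected 3' window. Matching is IUPAC-aware: a primer code matches a
#' template base when their base sets intersect (see `ambig_template` in
#' [pcr_params()] for the strict alternative).
#'
#' @param primer A primer sequence (string) or one-row primer tibble.
#' @param template A template: a string, or a one-row tibble with `id` and
#'   `seq`.
#' @param params A [pcr_params()] object.
#' @return A tibble with one row per site: `template_id`, `strand` (`+`/`-`),
#'   `start`/`end` (1-based plus-strand coordinates of the covered interval),
#'   `five_prime`/`three_prime` (plus-strand coordinates of the primer's 5'
#'   and 3' ends), `mismatches`, and `mismatch_positions` (list column,
#'   positions from the primer's 5' end).
#' @export
find_binding_sites <- function(primer, template, params = pcr_params()) {
  pseq <- as_primer_seq(primer)
  if (is.character(template)) {
    template <- tibble(id = "template", seq = toupper(template))
  }
  tid <- template$id[1]; tseq <- toupper(template$seq[1])
  pbits <- seq_to_bits(pseq, context = "primer")
  tbits <- seq_to_bits(tseq, context = sprintf("template '%s'", tid))
  L <- length(tbits); m <- length(pbits)
  out <- list()
  plus <- scan_strand(pbits, tbits, params)
  if (length(plus$start) > 0L) {
    out[[1]] <- tibble(
      template_id = tid, strand = "+",
      start = plus$start, end = plus$start + m - 1L,
      five_prime = plus$start, three_prime = plus$start + m - 1L,
      mismatches = plus$mm, mismatch_positions = plus$pos)
  }
  rc_bits <- seq_to_bits(reverse_complement(tseq), context = "template (rc)")
  minus <- scan_strand(pbits, rc_bits, params)
  if (length(minus$start) > 0L) {
    s <- minus$start; e <- s + m - 1L
    out[[length(out) + 1L]] <- tibble(
      template_id = tid, strand = "-",
      start = L - e + 1L, end = L - s + 1L,
      five_prime = L - s + 1L, three_prime = L - e + 1L,
      mismatches = minus$mm, mismatch_positions = minus$pos)
  }
  if (length(out) == 0L) return(empty_sites())
  arrange(bind_rows(out), .data$start, .data$strand)
}

empty_sites <- function() {
  tibble(template_id = character(0), strand = character(0),
         start = integer(0), end = integer(0),
         five_prime = integer(0), three_prime = integer(0),
         mismatches = integer(0), mismatch_positions = list())
}

#' Simulate PCR of a primer pair against a sequence database
#'
#' Finds all convergent forward/reverse binding-site pairs on every template
#' and reports the amplicons whose 5'-anchored length (downstream 5'
#' coordinate minus upstream 5' coordinate) lies within the configured
#' bounds. Both product orientations are reported: `strand = "+"` when the
#' forward primer sits on the plus strand, `"-"` for the mirrored
#' configuration. All valid site pairs are kept (nested or overlapping
#' amplicons are not deduplicated) and templates yielding more than one
#' amplicon are flagged: multi-banding is itself a specificity signal.
#'
#' @param fwd,rev Primer sequences (strings or one-row primer tibbles),
#'   both written 5'→3'.
#' @param db A sequence database tibble (`id`, `seq`, optional `lineage`)
#'   from [read_sequences()] or [make_database()].
#' @param params A [pcr_params()] object.
#' @return A tibble of class `pcr_hits`, one row per amplicon: `template_id`,
#'   `strand`, `fwd_5p`, `fwd_mm`, `rev_5p`, `rev_mm`, `length_bp`
#'   (5'-anchored), `total_mm`, `seq` (inclusive primer-to-primer product,
#'   plus-strand), `multi_amplicon`, and `lineage` when present in `db`.
#'   Ordered by `template_id`, then forward position.
#' @export
simulate_pcr <- function(fwd, rev, db, params = pcr_params()) {
  fseq <- as_primer_seq(fwd); rseq <- as_primer_seq(rev)
  if (nrow(db) == 0L) return(empty_hits(params))
  hits <- purrr::map_dfr(seq_len(nrow(db)), function(i) {
    tmpl <- db[i, ]
    fs <- find_binding_sites(fseq, tmpl, params)
    rs <- find_binding_sites(rseq, tmpl, params)
    pair_sites(fs, rs, tmpl, params)
  })
  if (nrow(hits) == 0L) return(empty_hits(params))
  hits <- hits |>
    group_by(.data$template_id) |>
    mutate(multi_amplicon = n() > 1L) |>
    ungroup() |>
    arrange(.data$template_id, .data$fwd_5p, .data$rev_5p, .data$strand)
  if ("lineage" %in% names(db)) {
    hits$lineage <- db$lineage[match(hits$template_id, db$id)]
  }
  attr(hits, "pcr_params") <- params
  class(hits) <- c("pcr_hits", class(hits))
  hits
}

pair_sites <- function(fs, rs, tmpl, params) {
  out <- list()
  # forward on plus, reverse on minus, reverse 5' downstream of forward 5'
  fp <- fs[fs$strand == "+", ]; rm_ <- rs[rs$strand == "-", ]
  if (nrow(fp) > 0L && nrow(rm_) > 0L) {
    g <- tidyr::crossing(fi = seq_len(nrow(fp)), ri = seq_len(nrow(rm_)))
    len <- rm_$five_prime[g$ri] - fp$five_prime[g$fi]
    keep <- len >= params$min_len & len <= params$max_len
    if (any(keep)) {
      g <- g[keep, ]; len <- len[keep]
      out[[1]] <- tibble(
        template_id = tmpl$id, strand = "+",
        fwd_5p = fp$five_prime[g$fi], fwd_mm = fp$mismatches[g$fi],
        rev_5p = rm_$five_prime[g$ri], rev_mm = rm_$mismatches[g$ri],
        length_bp = len,
        seq = substring(tmpl$seq, fp$five_prime[g$fi], rm_$five_prime[g$ri]))
    }
  }
  # mirrored orientation: reverse primer on plus, forward on minus
  rp <- rs[rs$strand == "+", ]; fm <- fs[fs$strand == "-", ]
  if (nrow(rp) > 0L && nrow(fm) > 0L) {
    g <- tidyr::crossing(fi = seq_len(nrow(fm)), ri = seq_len(nrow(rp)))
    len <- fm$five_prime[g$fi] - rp$five_prime[g$ri]
    keep <- len >= params$min_len & len <= params$max_len
    if (any(keep)) {
      g <- g[keep, ]; len <- len[keep]
      out[[length(out) + 1L]] <- tibble(
        template_id = tmpl$id, strand = "-",
        fwd_5p = fm$five_prime[g$fi], fwd_mm = fm$mismatches[g$fi],
        rev_5p = rp$five_prime[g$ri], rev_mm = rp$mismatches[g$ri],
        length_bp = len,
        seq = reverse_complement(
          substring(tmpl$seq, rp$five_prime[g$ri], fm$five_prime[g$fi])))
    }
  }
  if (length(out) == 0L) return(NULL)
  h <- bind_rows(out)
  h$total_mm <- h$fwd_mm + h$rev_mm
  h
}

empty_hits <- function(params) {
  h <- tibble(template_id = character(0), strand = character(0),
              fwd_5p = integer(0), fwd_mm = integer(0),
              rev_5p = integer(0), rev_mm = integer(0),
              length_bp = integer(0), seq = character(0),
              total_mm = integer(0), multi_amplicon = logical(0))
  attr(h, "pcr_params") <- params
  class(h) <- c("pcr_hits", class(h))
  h
}

#' Brute-force in silico PCR oracle
#'
#' A deliberately naive reference implementation: explicit per-offset,
#' per-position character comparisons over both strands, with no vectorised
#' shortcuts shared with [simulate_pcr()]. Intended as ground truth for
#' property tests on small databases (up to ~1e6 total bases).
#'
#' @inheritParams simulate_pcr
#' @return A tibble with the same columns and ordering as [simulate_pcr()].
#' @export
brute_force_pcr <- function(fwd, rev, db, params = pcr_params()) {
  fseq <- as_primer_seq(fwd); rseq <- as_primer_seq(rev)
  sets <- iupac_letter_sets()
  all_hits <- list()
  for (i in seq_len(nrow(db))) {
    tmpl_id <- db$id[i]; tseq <- toupper(db$seq[i])
    tch <- strsplit(tseq, "", fixed = TRUE)[[1]]
    fsites <- bf_scan(fseq, tch, params, sets)
    rsites <- bf_scan(rseq, tch, params, sets)
    hh <- list()
    for (fi in seq_len(nrow(fsites))) {
      for (ri in seq_len(nrow(rsites))) {
        if (fsites$strand[fi] == "+" && rsites$strand[ri] == "-") {
          len <- rsites$five_prime[ri] - fsites$five_prime[fi]
          if (len >= params$min_len && len <= params$max_len) {
            hh[[length(hh) + 1L]] <- tibble(
              template_id = tmpl_id, strand = "+",
              fwd_5p = fsites$five_prime[fi], fwd_mm = fsites$mm[fi],
              rev_5p = rsites$five_prime[ri], rev_mm = rsites$mm[ri],
              length_bp = len,
              seq = substr(tseq, fsites$five_prime[fi], rsites$five_prime[ri]))
          }
        } else if (fsites$strand[fi] == "-" && rsites$strand[ri] == "+") {
          len <- fsites$five_prime[fi] - rsites$five_prime[ri]
          if (len >= params$min_len && len <= params$max_len) {
            hh[[length(hh) + 1L]] <- tibble(
              template_id = tmpl_id, strand = "-",
              fwd_5p = fsites$five_prime[fi], fwd_mm = fsites$mm[fi],
              rev_5p = rsites$five_prime[ri], rev_mm = rsites$mm[ri],
              length_bp = len,
              seq = reverse_complement(
                substr(tseq, rsites$five_prime[ri], fsites$five_prime[fi])))
          }
        }
      }
    }
    if (length(hh) > 0L) all_hits[[length(all_hits) + 1L]] <- bind_rows(hh)
  }
  if (length(all_hits) == 0L) return(empty_hits(params))
  h <- bind_rows(all_hits)
  h$total_mm <- h$fwd_mm + h$rev_mm
  h <- h |>
    group_by(.data$template_id) |>
    mutate(multi_amplicon = n() > 1L) |>
    ungroup() |>
    arrange(.data$template_id, .data$fwd_5p, .data$rev_5p, .data$strand)
  if ("lineage" %in% names(db)) {
    h$lineage <- db$lineage[match(h$template_id, db$id)]
  }
  attr(h, "pcr_params") <- params
  class(h) <- c("pcr_hits", class(h))
  h
}

# letter-set view of the alphabet, independent of the bitmask encoding
iupac_letter_sets <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
       S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
       V = c("A", "C", "G"), H = c("A", "C", "T"),
       D = c("A", "G", "T"), B = c("C", "G", "T"),
       N = c("A", "C", "G", "T"))
}

# pairwise letter compatibility table derived from the letter sets
bf_compat_table <- function(sets, strict) {
  letters_ <- names(sets)
  out <- matrix(FALSE, length(letters_), length(letters_),
                dimnames = list(primer = letters_, template = letters_))
  for (p in letters_) {
    for (t in letters_) {
      out[p, t] <- if (strict) {
        length(sets[[t]]) == 1L && sets[[t]] %in% sets[[p]]
      } else {
        length(intersect(sets[[p]], sets[[t]])) > 0L
      }
    }
  }
  out
}

bf_scan <- function(primer, tch, params, sets) {
  pch <- strsplit(primer, "", fixed = TRUE)[[1]]
  m <- length(pch); L <- length(tch)
  compat <- bf_compat_table(sets, params$ambig_template == "strict")
  pidx <- match(pch, rownames(compat))
  scan_one <- function(chars, minus) {
    tidx <- match(chars, colnames(compat))
    found <- list()
    for (s in seq_len(L - m + 1L)) {
      ok <- compat[cbind(pidx, tidx[s:(s + m - 1L)])]
      bad <- which(!ok)
      if (length(bad) > params$max_mismatch) next
      if (any(bad > m - params$protected_3prime)) next
      found[[length(found) + 1L]] <- c(s, length(bad))
    }
    if (length(found) == 0L) {
      return(tibble(strand = character(0), five_prime = integer(0),
                    mm = integer(0)))
    }
    fm <- do.call(rbind, found)
    tibble(strand = if (minus) "-" else "+",
           five_prime = if (minus) L - fm[, 1] + 1L else fm[, 1],
           mm = fm[, 2])
  }
  if (m > L) {
    return(tibble(strand = character(0), five_prime = integer(0),
                  mm = integer(0)))
  }
  # minus strand: primer read along the reverse complement
  rch <- rev(vapply(tch, function(c)
    chartr(IUPAC_COMPLEMENT_FROM, IUPAC_COMPLEMENT_TO, c), character(1)))
  bind_rows(scan_one(tch, minus = FALSE), scan_one(rch, minus = TRUE))
}

#' Summarise taxonomic specificity of simulated amplification
#'
#' Rolls amplicon hits up into per-mismatch-allowance counts of amplified
#' templates, partitioned into the target clade versus everything else, with
#' a per-family breakdown. A template counts as amplified at allowance `k`
#' when it has at least one amplicon whose forward and reverse primers each
#' carry at most `k` mismatches; the amplified sets are therefore nested in
#' `k`. Templates without a lineage (or without the relevant rank) are
#' counted in an `unclassified` bucket with a warning.
#'
#' @param hits A `pcr_hits` tibble from [simulate_pcr()].
#' @param db The database the hits were computed from (`id`, `lineage`).
#' @param target_clade Length-2 character vector `c(rank, name)`, e.g.
#'   `c("family", "Parmeliaceae")`.
#' @param family_rank Rank used for the per-family breakdown.
#' @param k_max Largest mismatch allowance to tabulate; defaults to the
#'   `max_mismatch` the hits were computed under.
#' @return An object of class `specificity_summary`: a list with `by_group`
#'   (tibble `k`, `n_target`, `n_other`, `n_unclassified`, `n_total`),
#'   `by_family` (tibble `k`, `family`, `n`), `target_clade`, `n_templates`.
#' @export
summarize_specificity <- function(hits, db, target_clade,
                                  family_rank = "family", k_max = NULL) {
  stopifnot(length(target_clade) == 2L)
  params <- attr(hits, "pcr_params")
  k_max <- k_max %||% (if (!is.null(params)) params$max_mismatch else 3L)
  lineages <- db$lineage %||% rep(list(character(0)), nrow(db))
  tax <- tibble(
    template_id = db$id,
    clade = vapply(lineages, function(l)
      l[target_clade[1]] %||% NA_character_, character(1)),
    family = vapply(lineages, function(l)
      l[family_rank] %||% NA_character_, character(1))
  )
  n_unclass_db <- sum(is.na(tax$clade))
  if (n_unclass_db > 0L) {
    warn(sprintf("%d template(s) lack rank '%s'; counted as unclassified",
                 n_unclass_db, target_clade[1]))
  }
  h <- as_tibble(hits)[, c("template_id", "fwd_mm", "rev_mm")]
  h$k_eff <- pmax(h$fwd_mm, h$rev_mm)
  by_group <- purrr::map_dfr(0:k_max, function(k) {
    amp <- unique(h$template_id[h$k_eff <= k])
    cl <- tax$clade[match(amp, tax$template_id)]
    tibble(k = k,
           n_target = sum(!is.na(cl) & cl == target_clade[2]),
           n_other = sum(!is.na(cl) & cl != target_clade[2]),
           n_unclassified = sum(is.na(cl)),
           n_total = length(amp))
  })
  by_family <- purrr::map_dfr(0:k_max, function(k) {
    amp <- unique(h$template_id[h$k_eff <= k])
    if (length(amp) == 0L) {
      return(tibble(k = integer(0), family = character(0), n = integer(0)))
    }
    fam <- tax$family[match(amp, tax$template_id)]
    fam[is.na(fam)] <- "unclassified"
    out <- as_tibble(table(family = fam), n = "n")
    out$n <- as.integer(out$n)
    tibble(k = k, family = out$family, n = out$n)
  })
  structure(list(by_group = by_group, by_family = by_family,
                 target_clade = target_clade, n_templates = nrow(db)),
            class = "specificity_summary")
}

#' @export
print.specificity_summary <- function(x, ...) {
  cat(sprintf("<specificity summary: target %s '%s', %d templates>\n",
              x$target_clade[1], x$target_clade[2], x$n_templates))
  print(x$by_group)
  invisible(x)
}

#' @describeIn summarize_specificity Tidy the per-allowance counts into long
#'   form (`k`, `group`, `n`).
#' @param x A `specificity_summary`.
#' @param ... Unused.
#' @method tidy specificity_summary
#' @export
tidy.specificity_summary <- function(x, ...) {
  tidyr::pivot_longer(x$by_group, c("n_target", "n_other", "n_unclassified"),
                      names_to = "group", names_prefix = "n_",
                      values_to = "n")
}

#' @describeIn summarize_specificity One-row overview: templates in the
#'   database, amplified counts at the extreme allowances, off-target count
#'   at zero mismatches.
#' @method glance specificity_summary
#' @export
glance.specificity_summary <- function(x, ...) {
  bg <- x$by_group
  tibble(n_templates = x$n_templates,
         k_max = max(bg$k),
         amplified_k0 = bg$n_total[bg$k == 0],
         amplified_kmax = bg$n_total[bg$k == max(bg$k)],
         offtarget_k0 = bg$n_other[bg$k == 0] + bg$n_unclassified[bg$k == 0])
}

#' @describeIn summarize_specificity Stacked bar chart of amplified templates
#'   per mismatch allowance, target clade versus others.
#' @param object A `specificity_summary`.
#' @method autoplot specificity_summary
#' @export
autoplot.specificity_summary <- function(object, ...) {
  d <- tidy(object)
  d$group <- factor(d$group, levels = c("other", "unclassified", "target"))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$k), y = .data$n,
                                  fill = .data$group)) +
    ggplot2::geom_col(colour = "black", width = 0.7) +
    ggplot2::scale_fill_manual(
      values = c(target = "white", other = "grey55",
                 unclassified = "grey85")) +
    ggplot2::labs(
      x = "allowed mismatches per primer",
      y = "amplified templates",
      fill = NULL,
      title = sprintf("In silico specificity (target: %s %s)",
                      object$target_clade[1], object$target_clade[2])) +
    ggplot2::theme_classic()
}
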