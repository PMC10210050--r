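#' Candidate-primer design constraints
#'
#' @param tm_range Accepted melting-temperature range in °C (nearest-neighbor
#'   estimate under `thermo`).
#' @param max_degeneracy Maximum product of per-position IUPAC expansions.
#' @param max_gc3_run Maximum 3'-terminal G/C run length; candidates ending in
#'   a longer run are excluded (long 3' G/C runs risk non-specific binding).
#' @param min_discrimination Minimum sum of per-column discrimination scores
#'   over the candidate window.
#' @param w3p,omega 3'-end weighting of off-target mismatches: the last `w3p`
#'   primer positions count `omega`-fold. Mismatches at the 3' terminus
#'   abolish extension, so discrimination concentrated there is worth more.
#' @param min_gapfree_frac Minimum fraction of target rows that must be
#'   entirely gap-free across the window.
#' @param locus_tag Locus label used by [name_primer()].
#' @param thermo A [thermo_params()] object.
#' @return A list of class `design_constraints`.
#' @export
design_constraints <- function(tm_range = c(48, 62), max_degeneracy = 16,
                               max_gc3_run = 3, min_discrimination = 1,
                               w3p = 5, omega = 4, min_gapfree_frac = 1,
                               locus_tag = "mt-SSU",
                               thermo = thermo_params()) {
  stopifnot(length(tm_range) == 2L, tm_range[1] <= tm_range[2],
            max_degeneracy >= 1, omega >= 1, w3p >= 0,
            min_gapfree_frac >= 0, min_gapfree_frac <= 1)
  structure(list(tm_range = tm_range, max_degeneracy = max_degeneracy,
                 max_gc3_run = max_gc3_run,
                 min_discrimination = min_discrimination,
                 w3p = w3p, omega = omega,
                 min_gapfree_frac = min_gapfree_frac,
                 locus_tag = locus_tag, thermo = thermo),
            class = "design_constraints")
}

#' Minimal degenerate consensus over an alignment window
#'
#' Builds the per-column minimal IUPAC code covering all unambiguous bases
#' observed among the target rows, rejecting windows whose consensus would be
#' gapped or whose total degeneracy exceeds the cap.
#'
#' @param aln An alignment.
#' @param target_ids Row ids forming the target group.
#' @param window Integer vector of alignment columns (contiguous).
#' @param max_degeneracy Maximum allowed product of per-position expansions.
#' @param min_gapfree_frac Minimum fraction of target rows gap-free across
#'   the whole window.
#' @return A list with `seq` (IUPAC string, or `NULL` on rejection),
#'   `degeneracy`, and `reject_reason` (`NA` when accepted).
#' @export
consensus_with_degeneracy <- function(aln, target_ids, window,
                                      max_degeneracy = 16,
                                      min_gapfree_frac = 1) {
  m <- aln_bits_matrix(aln)[match(target_ids, aln$id), window, drop = FALSE]
  gapfree_rows <- rowSums(m == 0L) == 0L
  if (mean(gapfree_rows) < min_gapfree_frac) {
    return(list(seq = NULL, degeneracy = NA_real_,
                reject_reason = "too many gapped target rows in window"))
  }
  cons <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    Reduce(bitwOr, col, accumulate = FALSE)
  }, integer(1))
  # a column where gaps dominate the target rows has no usable consensus
  gap_frac <- colSums(m == 0L) / nrow(m)
  if (any(cons == 0L) || any(gap_frac > 0.5)) {
    return(list(seq = NULL, degeneracy = NA_real_,
                reject_reason = "gap in target consensus"))
  }
  d <- prod(popcount4(cons))
  if (d > max_degeneracy) {
    return(list(seq = NULL, degeneracy = d,
                reject_reason = sprintf("degeneracy %d exceeds cap %d",
                                        d, max_degeneracy)))
  }
  list(seq = paste(BITS_IUPAC[cons], collapse = ""), degeneracy = d,
       reject_reason = NA_character_)
}

#' Systematic primer nomenclature
#'
#' Builds names of the form `<locus>-<pos>-5'` (forward) or `<locus>-<pos>-3'`
#' (reverse), where `<pos>` is the reference coordinate of the primer's 5'
#' end: forward primers anneal to the non-coding strand and are annotated
#' 5'→3' along the coding strand, reverse primers the other way around.
#'
#' @param locus_tag Locus label, e.g. `"mt-SSU"`.
#' @param ref5 Reference coordinate of the primer's 5' end (>= 1).
#' @param orientation `"F"`/`"forward"` or `"R"`/`"reverse"`.
#' @return The primer name (ASCII apostrophe).
#' @examples
#' name_primer("mt-SSU", 581, "F")   # "mt-SSU-581-5'"
#' name_primer("mt-SSU", 1345, "R")  # "mt-SSU-1345-3'"
#' @export
name_primer <- function(locus_tag, ref5, orientation) {
  orientation <- normalize_orientation(orientation)
  if (any(ref5 < 1)) {
    abort("ref5 must be >= 1", class = "cladeprimer_design_error")
  }
  paste0(locus_tag, "-", ref5, ifelse(orientation == "F", "-5'", "-3'"))
}

normalize_orientation <- function(x) {
  out <- toupper(substr(x, 1, 1))
  if (!all(out %in% c("F", "R"))) {
    abort("orientation must be forward (F) or reverse (R)",
          class = "cladeprimer_design_error")
  }
  out
}

#' Parse a systematic primer name
#'
#' Inverse of [name_primer()]: recovers locus tag, 5'-end reference
#' coordinate and orientation.
#'
#' @param name Primer name such as `"mt-SSU-581-5'"`.
#' @return A tibble with columns `locus_tag`, `ref5`, `orientation`.
#' @export
parse_primer_name <- function(name) {
  m <- regmatches(name, regexec("^(.*)-([0-9]+)-([53])'$", name))
  bad <- lengths(m) != 4L
  if (any(bad)) {
    abort(sprintf("cannot parse primer name '%s'", name[which(bad)[1]]),
          class = "cladeprimer_design_error")
  }
  tibble(
    locus_tag = vapply(m, `[`, character(1), 2L),
    ref5 = as.integer(vapply(m, `[`, character(1), 3L)),
    orientation = ifelse(vapply(m, `[`, character(1), 4L) == "5", "F", "R")
  )
}

#' Predicted amplicon length from primer coordinates
#'
#' Difference of the two 5'-anchored reference coordinates,
#' `rev_ref5 - fwd_ref5`. This is the convention under which systematic
#' primer names directly give the expected product size (e.g. coordinates
#' 581 and 1345 give 764 bp); the inclusive-span alternative would add 1.
#'
#' @param fwd_ref5 Reference coordinate of the forward primer's 5' end.
#' @param rev_ref5 Reference coordinate of the reverse primer's 5' end; must
#'   be strictly downstream of `fwd_ref5`.
#' @return Amplicon length in bp.
#' @examples
#' predict_amplicon_length(581, 1345)  # 764
#' @export
predict_amplicon_length <- function(fwd_ref5, rev_ref5) {
  if (any(rev_ref5 <= fwd_ref5)) {
    abort("rev_ref5 must be strictly greater than fwd_ref5 (invalid pair geometry)",
          class = "cladeprimer_design_error")
  }
  rev_ref5 - fwd_ref5
}

#' Enumerate clade-specific primer candidates
#'
#' Slides windows of the requested lengths over the alignment, keeps windows
#' whose summed discrimination score meets the threshold, derives the minimal
#' degenerate target consensus, and emits forward and reverse candidates
#' (reverse candidates are the reverse-complemented consensus with the 3' end
#' at the window's upstream edge). Every returned candidate satisfies all
#' constraints.
#'
#' Scores per candidate: `target_coverage` is the fraction of target rows the
#' candidate matches with zero mismatches (gaps count as mismatches);
#' `off_min_mm`/`off_mean_mm` summarise mismatches against off-target rows;
#' `weighted3p` is the minimum over off-target rows of the mismatch count
#' with the last `w3p` primer positions weighted `omega`-fold.
#'
#' @param aln An alignment.
#' @param target_ids,offtarget_ids Disjoint non-empty sets of row ids.
#' @param length_range Primer length range `c(min, max)` in alignment columns.
#' @param constraints A [design_constraints()] object.
#' @param cmap Optional `coord_map`.
#' @param profile Optional precomputed [discrimination_profile()].
#' @return A tibble of candidates: `name`, `seq`, `orientation`, `ref5`,
#'   `tm`, `degeneracy`, `col_start`, `col_end`, `disc_sum`,
#'   `target_coverage`, `off_min_mm`, `off_mean_mm`, `weighted3p`. Empty
#'   (with a warning of class `cladeprimer_no_candidates`) when no window
#'   passes.
#' @export
enumerate_candidates <- function(aln, target_ids, offtarget_ids,
                                 length_range = c(18, 22),
                                 constraints = design_constraints(),
                                 cmap = NULL, profile = NULL) {
  check_labels(aln, target_ids, offtarget_ids)
  cmap <- cmap %||% build_coord_map(aln)
  profile <- profile %||%
    discrimination_profile(aln, target_ids, offtarget_ids, cmap)
  bits <- aln_bits_matrix(aln)
  tmat <- bits[match(target_ids, aln$id), , drop = FALSE]
  omat <- bits[match(offtarget_ids, aln$id), , drop = FALSE]
  score <- profile$score
  n_col <- ncol(bits)
  out <- list()
  for (len in seq.int(length_range[1], length_range[2])) {
    if (len > n_col) next
    wsum <- roll_sum(score, len)
    starts <- which(wsum >= constraints$min_discrimination)
    for (s in starts) {
      cols <- s:(s + len - 1L)
      # the window must sit on mapped reference coordinates at both ends
      if (is.na(cmap$col_to_ref[cols[1]]) ||
          is.na(cmap$col_to_ref[cols[len]])) next
      cons <- consensus_with_degeneracy(
        aln, target_ids, cols,
        max_degeneracy = constraints$max_degeneracy,
        min_gapfree_frac = constraints$min_gapfree_frac)
      if (is.null(cons$seq)) next
      cbits <- seq_to_bits(cons$seq)
      tmw <- tmat[, cols, drop = FALSE]
      omw <- omat[, cols, drop = FALSE]
      cov <- candidate_coverage(cbits, tmw)
      offs <- candidate_off_stats(cbits, omw, constraints$w3p,
                                  constraints$omega)
      tm_f <- tryCatch(tm_nn(cons$seq, constraints$thermo),
                       error = function(e) NA_real_)
      if (is.na(tm_f) || tm_f < constraints$tm_range[1] ||
          tm_f > constraints$tm_range[2]) next
      # forward candidate: 3' end at the window's downstream edge
      if (three_prime_gc_run(cons$seq) <= constraints$max_gc3_run) {
        out[[length(out) + 1L]] <- tibble(
          name = name_primer(constraints$locus_tag,
                             cmap$col_to_ref[cols[1]], "F"),
          seq = cons$seq, orientation = "F",
          ref5 = cmap$col_to_ref[cols[1]],
          tm = tm_f, degeneracy = cons$degeneracy,
          col_start = cols[1], col_end = cols[len],
          disc_sum = wsum[s], target_coverage = cov,
          off_min_mm = offs$min_mm, off_mean_mm = offs$mean_mm,
          weighted3p = offs$w3p_fwd)
      }
      rseq <- reverse_complement(cons$seq)
      if (three_prime_gc_run(rseq) <= constraints$max_gc3_run) {
        out[[length(out) + 1L]] <- tibble(
          name = name_primer(constraints$locus_tag,
                             cmap$col_to_ref[cols[len]], "R"),
          seq = rseq, orientation = "R",
          ref5 = cmap$col_to_ref[cols[len]],
          tm = tm_f, degeneracy = cons$degeneracy,
          col_start = cols[1], col_end = cols[len],
          disc_sum = wsum[s], target_coverage = cov,
          off_min_mm = offs$min_mm, off_mean_mm = offs$mean_mm,
          weighted3p = offs$w3p_rev)
      }
    }
  }
  if (length(out) == 0L) {
    warn("no alignment window satisfies the design constraints",
         class = "cladeprimer_no_candidates")
    return(empty_candidates())
  }
  distinct(bind_rows(out), .data$name, .data$seq, .keep_all = TRUE)
}

empty_candidates <- function() {
  tibble(name = character(0), seq = character(0), orientation = character(0),
         ref5 = integer(0), tm = numeric(0), degeneracy = numeric(0),
         col_start = integer(0), col_end = integer(0), disc_sum = integer(0),
         target_coverage = numeric(0), off_min_mm = numeric(0),
         off_mean_mm = numeric(0), weighted3p = numeric(0))
}

roll_sum <- function(x, k) {
  cs <- cumsum(c(0L, x))
  cs[(k + 1L):length(cs)] - cs[1:(length(cs) - k)]
}

# fraction of target rows matched with zero mismatches (gap = mismatch)
candidate_coverage <- function(cbits, tmw) {
  ok <- vapply(seq_len(nrow(tmw)), function(i) {
    all(bitwAnd(tmw[i, ], cbits) > 0L)
  }, logical(1))
  mean(ok)
}

# off-target mismatch statistics; weighted variants for both 3' orientations
candidate_off_stats <- function(cbits, omw, w3p, omega) {
  len <- length(cbits)
  wf <- rep(1, len); wr <- rep(1, len)
  if (w3p > 0) {
    wf[max(1L, len - w3p + 1L):len] <- omega   # forward: 3' at right edge
    wr[1:min(w3p, len)] <- omega               # reverse: 3' at left edge
  }
  mm <- t(vapply(seq_len(nrow(omw)), function(i) {
    miss <- bitwAnd(omw[i, ], cbits) == 0L
    c(sum(miss), sum(wf[miss]), sum(wr[miss]))
  }, numeric(3)))
  list(min_mm = min(mm[, 1]), mean_mm = mean(mm[, 1]),
       w3p_fwd = min(mm[, 2]), w3p_rev = min(mm[, 3]))
}

#' Pair and rank primer candidates
#'
#' Crosses forward and reverse candidates, keeps pairs with valid convergent
#' geometry whose predicted amplicon length and Tm difference satisfy the
#' constraints, and ranks them by (off-target weighted specificity
#' descending, target coverage descending, Tm difference ascending, amplicon
#' length ascending), with a deterministic tie-break on the two 5'
#' coordinates. Pair specificity is the sum of the two primers' 3'-weighted
#' minimum off-target mismatch scores.
#'
#' @param candidates A candidate tibble from [enumerate_candidates()] (must
#'   contain at least one forward and one reverse candidate).
#' @param amplicon_range Accepted predicted amplicon length range in bp.
#' @param max_delta_tm Maximum |Tm(fwd) − Tm(rev)| in °C.
#' @return A ranked tibble of pairs with columns `fwd_name`, `rev_name`,
#'   `fwd_seq`, `rev_seq`, `fwd_ref5`, `rev_ref5`, `amplicon_bp`,
#'   `delta_tm`, `pair_specificity`, `target_coverage`. Empty (with a
#'   warning of class `cladeprimer_no_pairs`) when nothing passes.
#' @export
design_pairs <- function(candidates, amplicon_range = c(200, 2500),
                         max_delta_tm = 5) {
  fwd <- candidates[candidates$orientation == "F", ]
  rev_ <- candidates[candidates$orientation == "R", ]
  if (nrow(fwd) == 0L || nrow(rev_) == 0L) {
    abort("need at least one forward and one reverse candidate",
          class = "cladeprimer_design_error")
  }
  g <- tidyr::crossing(fi = seq_len(nrow(fwd)), ri = seq_len(nrow(rev_)))
  pairs <- tibble(
    fwd_name = fwd$name[g$fi], rev_name = rev_$name[g$ri],
    fwd_seq = fwd$seq[g$fi], rev_seq = rev_$seq[g$ri],
    fwd_ref5 = fwd$ref5[g$fi], rev_ref5 = rev_$ref5[g$ri],
    fwd_tm = fwd$tm[g$fi], rev_tm = rev_$tm[g$ri],
    pair_specificity = fwd$weighted3p[g$fi] + rev_$weighted3p[g$ri],
    target_coverage = pmin(fwd$target_coverage[g$fi],
                           rev_$target_coverage[g$ri])
  ) |>
    filter(.data$rev_ref5 > .data$fwd_ref5) |>
    mutate(amplicon_bp = .data$rev_ref5 - .data$fwd_ref5,
           delta_tm = abs(.data$fwd_tm - .data$rev_tm)) |>
    filter(.data$amplicon_bp >= amplicon_range[1],
           .data$amplicon_bp <= amplicon_range[2],
           .data$delta_tm <= max_delta_tm)
  if (nrow(pairs) == 0L) {
    warn("no primer pair satisfies the pairing constraints",
         class = "cladeprimer_no_pairs")
    return(pairs)
  }
  arrange(pairs, desc(.data$pair_specificity), desc(.data$target_coverage),
          .data$delta_tm, .data$amplicon_bp, .data$fwd_ref5, .data$rev_ref5)
}
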