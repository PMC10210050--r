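#' Specification for a synthetic labelled alignment / database
#'
#' Describes a synthetic locus laid out as alternating conserved blocks and
#' length-variable segments (mirroring the conserved/variable architecture of
#' ribosomal loci), with discriminating windows planted inside chosen
#' conserved blocks: at the planted columns every off-target row carries the
#' same alternative base, so the expected per-column discrimination score and
#' window sums are known exactly. Within-group substitutions and deletions
#' are confined to the variable segments so the planted truth coordinates
#' stay exact. All randomness is driven by the single integer seed.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_target,n_offtarget Row counts per group (reference row excluded).
#' @param conserved_lengths Lengths of the conserved blocks (bp).
#' @param variable_lengths Lengths of the variable segments between blocks;
#'   must be one shorter than `conserved_lengths`.
#' @param planted_windows Tibble with columns `block` (index of the conserved
#'   block), `offset` (1-based start within the block) and `length`; each
#'   window must fit inside its block.
#' @param planted_divergence Fraction of window positions planted with an
#'   off-target difference; the planted count is `round(rate * length)` per
#'   window (0.45 on a 20-mer plants 9 differences).
#' @param within_divergence Per-position substitution rate among target rows
#'   inside variable segments.
#' @param offtarget_divergence Additional per-position substitution rate for
#'   off-target rows inside variable segments.
#' @param indel_prob Probability that a row carries one deletion in a given
#'   variable segment.
#' @param max_indel_frac Maximum deletion length as a fraction of its
#'   segment.
#' @param intron Optional `list(after = <reference position>, length = <bp>,
#'   ids = <character or NULL for all targets>)`: [make_database()] inserts a
#'   random insert of that length after the given reference position,
#'   emulating the long group-I introns that push amplicons past the size
#'   cutoff in intron-rich lineages.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_target = 10L, n_offtarget = 6L,
                         conserved_lengths = c(120L, 120L, 120L, 120L, 120L),
                         variable_lengths = c(80L, 200L, 220L, 80L),
                         planted_windows = tibble(block = c(2L, 4L),
                                                  offset = c(11L, 96L),
                                                  length = c(20L, 20L)),
                         planted_divergence = 0.45,
                         within_divergence = 0.02,
                         offtarget_divergence = 0.05,
                         indel_prob = 0.5,
                         max_indel_frac = 0.3,
                         intron = NULL) {
  if (length(variable_lengths) != length(conserved_lengths) - 1L) {
    abort("variable_lengths must be one shorter than conserved_lengths",
          class = "cladeprimer_fixture_error")
  }
  if (any(c(conserved_lengths, variable_lengths) <= 0L)) {
    abort("layout lengths must be positive",
          class = "cladeprimer_fixture_error")
  }
  rates <- c(planted_divergence, within_divergence, offtarget_divergence)
  if (any(rates < 0) || any(rates > 1)) {
    abort("divergence rates must be in [0, 1]",
          class = "cladeprimer_fixture_error")
  }
  pw <- as_tibble(planted_windows)
  if (nrow(pw) > 0L) {
    if (any(pw$block < 1L | pw$block > length(conserved_lengths))) {
      abort("planted window refers to a nonexistent conserved block",
            class = "cladeprimer_fixture_error")
    }
    if (any(pw$offset < 1L |
            pw$offset + pw$length - 1L > conserved_lengths[pw$block])) {
      abort("planted window does not fit inside its conserved block",
            class = "cladeprimer_fixture_error")
    }
  }
  structure(list(seed = as.integer(seed),
                 n_target = as.integer(n_target),
                 n_offtarget = as.integer(n_offtarget),
                 conserved_lengths = as.integer(conserved_lengths),
                 variable_lengths = as.integer(variable_lengths),
                 planted_windows = pw,
                 planted_divergence = planted_divergence,
                 within_divergence = within_divergence,
                 offtarget_divergence = offtarget_divergence,
                 indel_prob = indel_prob,
                 max_indel_frac = max_indel_frac,
                 intron = intron),
            class = "fixture_spec")
}

# Reference coordinates of each layout element. Blocks and segments
# interleave: B1 V1 B2 V2 ... Bn.
fixture_layout <- function(spec) {
  n <- length(spec$conserved_lengths)
  lens <- integer(2L * n - 1L)
  lens[seq(1L, 2L * n - 1L, by = 2L)] <- spec$conserved_lengths
  if (n > 1L) lens[seq(2L, 2L * n - 2L, by = 2L)] <- spec$variable_lengths
  end <- cumsum(lens)
  start <- end - lens + 1L
  kind <- rep(c("conserved", "variable"), length.out = 2L * n - 1L)
  tibble(element = seq_along(lens), kind = kind,
         index = c(rbind(seq_len(n), c(seq_len(n - 1L), NA)))[seq_along(lens)],
         start = start, end = end)
}

#' Generate a labelled synthetic alignment with planted truth
#'
#' Builds the ancestral sequence from the layout, derives target rows (the
#' gapless reference row `REF` plus mutated/indel-bearing target rows) and
#' off-target rows carrying the planted window differences, and records the
#' planted ground truth. The same seed gives byte-identical output.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `alignment` (reference row `REF`), `target_ids`
#'   (including `REF`), `offtarget_ids`, and `truth`: a list with `windows`
#'   (tibble: `block`, `ref_start`, `ref_end`, `n_diff`, `planted_positions`
#'   list column, `fwd_primer`, `rev_primer`, `expected_score_sum`),
#'   `layout`, `regions` (the conserved blocks as a `region`/`start`/`end`
#'   tibble) and `ancestor`.
#' @export
make_alignment <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    layout <- fixture_layout(spec)
    total_len <- max(layout$end)
    bases <- c("A", "C", "G", "T")
    ancestor <- sample(bases, total_len, replace = TRUE)

    # planted truth: per window, positions and the shared alternative base
    pw <- spec$planted_windows
    windows <- purrr::map_dfr(seq_len(nrow(pw)), function(w) {
      blk <- layout[layout$kind == "conserved" & layout$index == pw$block[w], ]
      ref_start <- blk$start + pw$offset[w] - 1L
      ref_end <- ref_start + pw$length[w] - 1L
      n_diff <- round(spec$planted_divergence * pw$length[w])
      pos <- sort(sample(ref_start:ref_end, n_diff))
      alt <- vapply(pos, function(p)
        sample(setdiff(bases, ancestor[p]), 1L), character(1))
      tibble(block = pw$block[w], ref_start = ref_start, ref_end = ref_end,
             n_diff = as.integer(n_diff),
             planted_positions = list(pos), alt_bases = list(alt),
             fwd_primer = paste(ancestor[ref_start:ref_end], collapse = ""),
             rev_primer = reverse_complement(
               paste(ancestor[ref_start:ref_end], collapse = "")),
             expected_score_sum = as.integer(n_diff * spec$n_offtarget))
    })
    planted_pos <- unlist(windows$planted_positions)
    var_segments <- layout[layout$kind == "variable", , drop = FALSE]
    var_pos <- unlist(purrr::map2(var_segments$start, var_segments$end, seq))

    mutate_row <- function(row, rate) {
      if (rate > 0 && length(var_pos) > 0L) {
        hit <- var_pos[rbinom(length(var_pos), 1L, rate) == 1L]
        row[hit] <- vapply(hit, function(p)
          sample(setdiff(bases, row[p]), 1L), character(1))
      }
      row
    }
    delete_runs <- function(row) {
      for (i in seq_len(nrow(var_segments))) {
        if (stats::runif(1) < spec$indel_prob) {
          seg_len <- var_segments$end[i] - var_segments$start[i] + 1L
          max_del <- max(1L, floor(spec$max_indel_frac * seg_len))
          del_len <- sample.int(max_del, 1L)
          del_start <- var_segments$start[i] +
            sample.int(seg_len - del_len + 1L, 1L) - 1L
          row[del_start:(del_start + del_len - 1L)] <- "-"
        }
      }
      row
    }

    rows <- list(REF = paste(ancestor, collapse = ""))
    target_ids <- c("REF", sprintf("T%02d", seq_len(spec$n_target)))
    for (id in target_ids[-1]) {
      r <- mutate_row(ancestor, spec$within_divergence)
      r <- delete_runs(r)
      rows[[id]] <- paste(r, collapse = "")
    }
    offtarget_ids <- sprintf("O%02d", seq_len(spec$n_offtarget))
    for (id in offtarget_ids) {
      r <- ancestor
      if (length(planted_pos) > 0L) {
        r[planted_pos] <- unlist(windows$alt_bases)
      }
      r <- mutate_row(r, spec$offtarget_divergence)
      r <- delete_runs(r)
      rows[[id]] <- paste(r, collapse = "")
    }

    aln <- as_alignment(
      tibble(id = names(rows), seq = unlist(unname(rows))), "REF")
    regions <- layout |>
      filter(.data$kind == "conserved") |>
      mutate(region = paste0("U", .data$index)) |>
      select("region", "start", "end")
    list(alignment = aln,
         target_ids = target_ids,
         offtarget_ids = offtarget_ids,
         truth = list(windows = windows, layout = layout,
                      regions = regions,
                      ancestor = paste(ancestor, collapse = "")))
  })
}

#' Generate a labelled synthetic sequence database
#'
#' De-gaps the rows of [make_alignment()] into ungapped templates, attaches
#' ranked lineages (targets in one family, off-targets spread over several
#' other families), and optionally inserts a long intron between the planted
#' windows of selected target templates so their predicted amplicon exceeds
#' a length cutoff by construction.
#'
#' @param spec A [fixture_spec()].
#' @param include_introns Insert the intron described by `spec$intron`
#'   (required non-`NULL` when `TRUE`).
#' @return A list with `db` (tibble `id`, `seq`, `lineage`), `target_ids`,
#'   `offtarget_ids` and `truth` (as in [make_alignment()], plus
#'   `amplicon_ref_len`, the 5'-anchored distance between the first window's
#'   start and the last window's end on the reference, and `intron_ids`).
#' @export
make_database <- function(spec, include_introns = FALSE) {
  fx <- make_alignment(spec)
  seqs <- gsub("-", "", fx$alignment$seq, fixed = TRUE)
  ids <- fx$alignment$id
  target_families <- "Parmeliaceae"
  off_families <- c("Herpotrichiellaceae", "Lichenotheliaceae",
                    "Nectriaceae", "Aspergillaceae", "Trichocomaceae")
  lineage <- lapply(seq_along(ids), function(i) {
    if (ids[i] %in% fx$target_ids) {
      c(kingdom = "Fungi", family = target_families, genus = "Melanelia")
    } else {
      k <- match(ids[i], fx$offtarget_ids)
      c(kingdom = "Fungi",
        family = off_families[((k - 1L) %% length(off_families)) + 1L],
        genus = paste0("Offgenus", k))
    }
  })
  db <- tibble(id = ids, seq = seqs, lineage = lineage)

  intron_ids <- character(0)
  if (include_introns) {
    if (is.null(spec$intron)) {
      abort("include_introns = TRUE but spec$intron is NULL",
            class = "cladeprimer_fixture_error")
    }
    intron_ids <- spec$intron$ids %||% setdiff(fx$target_ids, "REF")
    withr::with_seed(spec$seed + 1L, {
      insert <- paste(sample(c("A", "C", "G", "T"), spec$intron$length,
                             replace = TRUE), collapse = "")
      # per-row insertion point: count non-gap characters up to the
      # reference position, so the intron lands between the planted sites
      # in every template regardless of its deletions
      aln_rows <- match(intron_ids, fx$alignment$id)
      for (r in aln_rows) {
        row <- fx$alignment$seq[r]
        prefix_aln <- substr(row, 1L, spec$intron$after)
        cut <- nchar(gsub("-", "", prefix_aln, fixed = TRUE))
        s <- db$seq[db$id == fx$alignment$id[r]]
        db$seq[db$id == fx$alignment$id[r]] <-
          paste0(substr(s, 1L, cut), insert, substr(s, cut + 1L, nchar(s)))
      }
    })
  }

  truth <- fx$truth
  if (nrow(truth$windows) >= 2L) {
    truth$amplicon_ref_len <-
      truth$windows$ref_end[nrow(truth$windows)] - truth$windows$ref_start[1]
  }
  truth$intron_ids <- intron_ids
  list(db = db, target_ids = fx$target_ids,
       offtarget_ids = fx$offtarget_ids, truth = truth)
}
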