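#' Build an alignment-column / reference-coordinate map
#'
#' Maps every alignment column to its 1-based position in the ungapped
#' reference row (and back). Columns where the reference row carries a gap map
#' to no position; reference positions run 1..L without repeats.
#'
#' @param aln An alignment from [as_alignment()] or [read_alignment()].
#' @return An object of class `coord_map`: a list with `col_to_ref` (integer,
#'   `NA` at reference-gap columns), `ref_to_col` (integer, one column per
#'   reference position), `ref_len`, `n_col`, `reference_id`.
#' @export
build_coord_map <- function(aln) {
  ref <- aln$seq[aln$id == reference_id(aln)]
  ch <- strsplit(ref, "", fixed = TRUE)[[1]]
  nongap <- which(ch != "-")
  if (length(nongap) == 0L) {
    abort("reference row is all gaps", class = "cladeprimer_coord_error")
  }
  col_to_ref <- rep(NA_integer_, length(ch))
  col_to_ref[nongap] <- seq_along(nongap)
  structure(
    list(col_to_ref = col_to_ref,
         ref_to_col = nongap,
         ref_len = length(nongap),
         n_col = length(ch),
         reference_id = reference_id(aln)),
    class = "coord_map")
}

#' @export
print.coord_map <- function(x, ...) {
  cat(sprintf("<coord_map: %d columns -> reference '%s' (%d bp)>\n",
              x$n_col, x$reference_id, x$ref_len))
  invisible(x)
}

# Column span covered by a reference-coordinate interval, inclusive of
# insertion columns (reference gaps) that fall between the end points.
interval_cols <- function(cmap, start, end) {
  if (start < 1L || end > cmap$ref_len || start > end) {
    abort(sprintf("interval [%d, %d] outside reference range 1..%d",
                  start, end, cmap$ref_len),
          class = "cladeprimer_coord_error")
  }
  seq.int(cmap$ref_to_col[start], cmap$ref_to_col[end])
}

#' Default universal-region map for the fungal mtSSU
#'
#' The fungal mtSSU carries eight conserved "universal" blocks (U1..U8)
#' separated by length-variable segments; classical universal primers sit
#' inside the blocks. Exact block boundaries vary with the alignment, so
#' these defaults are deliberately editable (see [load_config()]); they are
#' chosen to bracket the classical primer sites in U2 (533-552) and
#' U6 (1505-1524) on the 1980 bp reference numbering.
#'
#' @return A tibble with columns `region`, `start`, `end` (1-based, inclusive,
#'   reference coordinates).
#' @export
default_regions <- function() {
  tibble(
    region = paste0("U", 1:8),
    start = c(80L, 480L, 668L, 942L, 1040L, 1505L, 1700L, 1880L),
    end   = c(140L, 560L, 775L, 980L, 1270L, 1560L, 1760L, 1940L)
  )
}

validate_region_map <- function(regions) {
  stopifnot(all(c("region", "start", "end") %in% names(regions)))
  if (any(regions$start > regions$end)) {
    abort("region with start > end", class = "cladeprimer_coord_error")
  }
  if (is.unsorted(regions$start, strictly = TRUE) ||
      any(utils::head(regions$end, -1) >= utils::tail(regions$start, -1))) {
    abort("regions must be non-overlapping and ascending",
          class = "cladeprimer_coord_error")
  }
  regions
}

#' Count variable sites in a reference interval
#'
#' For a group of alignment rows and a reference-coordinate interval, counts
#' the columns showing informative variation. `total` is the number of columns
#' in the interval's column span in which at least one group row has a non-gap
#' base (so groups with insertions can have different totals over the same
#' interval); `variable` is the subset of those columns with two or more
#' distinct unambiguous bases (A/C/G/T) among the group rows. Ambiguity codes
#' and gaps never create variability.
#'
#' @param aln An alignment.
#' @param group Character vector of row ids (non-empty, all present).
#' @param interval Length-2 integer vector `c(start, end)` in reference
#'   coordinates (1-based, inclusive).
#' @param cmap A `coord_map` from [build_coord_map()]; built on the fly if
#'   omitted.
#' @param total_mode `"nongap"` (default; columns with >= 1 non-gap group
#'   base) or `"all"` (every column in the span).
#' @return A one-row tibble with columns `variable` and `total`.
#' @export
count_variable_sites <- function(aln, group, interval, cmap = NULL,
                                 total_mode = c("nongap", "all")) {
  total_mode <- match.arg(total_mode)
  if (length(group) == 0L) {
    abort("empty group", class = "cladeprimer_coord_error")
  }
  if (!all(group %in% aln$id)) {
    abort("group contains ids not in the alignment",
          class = "cladeprimer_coord_error")
  }
  cmap <- cmap %||% build_coord_map(aln)
  cols <- interval_cols(cmap, interval[1], interval[2])
  m <- aln_matrix(aln)[match(group, aln$id), cols, drop = FALSE]
  nongap <- colSums(m != "-") > 0L
  is_base <- function(col) col %in% c("A", "C", "G", "T")
  variable <- vapply(seq_len(ncol(m)), function(j) {
    b <- m[, j]
    b <- unique(b[is_base(b)])
    length(b) >= 2L
  }, logical(1))
  total <- if (total_mode == "nongap") sum(nongap) else ncol(m)
  tibble(variable = sum(variable & nongap), total = total)
}

#' Per-column clade-discrimination profile
#'
#' Scores each alignment column by how many off-target rows differ from the
#' target-group consensus there. The consensus at a column is the set of
#' unambiguous bases observed among non-gap target rows; an off-target row
#' counts as differing when its base set does not intersect that consensus,
#' and an off-target gap counts as differing (a gap precludes primer binding).
#' Columns where every target row is a gap score 0 and are flagged.
#'
#' @param aln An alignment.
#' @param target_ids,offtarget_ids Disjoint, non-empty sets of row ids.
#' @param cmap Optional `coord_map`; built on the fly if omitted.
#' @return A tibble with one row per column: `col`, `ref_pos`, `consensus`
#'   (minimal IUPAC code of the target base set, `-` where all-gap), `score`
#'   (0..number of off-target rows) and `all_gap_target`.
#' @export
discrimination_profile <- function(aln, target_ids, offtarget_ids,
                                   cmap = NULL) {
  check_labels(aln, target_ids, offtarget_ids)
  cmap <- cmap %||% build_coord_map(aln)
  m <- aln_bits_matrix(aln)
  tm <- m[match(target_ids, aln$id), , drop = FALSE]
  om <- m[match(offtarget_ids, aln$id), , drop = FALSE]
  # per-column union of target base sets (gaps contribute 0)
  cons <- Reduce(bitwOr, lapply(seq_len(nrow(tm)), function(i) tm[i, ]))
  all_gap <- cons == 0L
  score <- integer(ncol(m))
  nz <- which(!all_gap)
  if (length(nz) > 0L) {
    for (i in seq_len(nrow(om))) {
      score[nz] <- score[nz] +
        as.integer(bitwAnd(om[i, nz], cons[nz]) == 0L)
    }
  }
  tibble(
    col = seq_len(ncol(m)),
    ref_pos = cmap$col_to_ref,
    consensus = ifelse(all_gap, "-", BITS_IUPAC[pmax(cons, 1L)]),
    score = score,
    all_gap_target = all_gap
  )
}

#' Variable-site report over inter-region segments
#'
#' For each group of rows and each segment between consecutive universal
#' regions (e.g. U2-U3, U3-U4, ...), reports variable/total site counts as in
#' a per-genus variability table.
#'
#' @param aln An alignment.
#' @param groups Named list of row-id character vectors (one entry per genus
#'   or clade).
#' @param regions Region map tibble (`region`, `start`, `end`); defaults to
#'   [default_regions()].
#' @param cmap Optional `coord_map`.
#' @param total_mode Passed to [count_variable_sites()].
#' @return A tibble with columns `group`, `segment`, `variable`, `total`.
#' @export
region_report <- function(aln, groups, regions = default_regions(),
                          cmap = NULL, total_mode = c("nongap", "all")) {
  total_mode <- match.arg(total_mode)
  regions <- validate_region_map(regions)
  if (nrow(regions) < 2L) {
    abort("need at least two regions to form inter-region segments",
          class = "cladeprimer_coord_error")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("groups must be a named list", class = "cladeprimer_coord_error")
  }
  cmap <- cmap %||% build_coord_map(aln)
  segs <- tibble(
    segment = paste0(head(regions$region, -1), "-", regions$region[-1]),
    start = head(regions$end, -1) + 1L,
    end = regions$start[-1] - 1L
  )
  segs <- segs[segs$start <= segs$end & segs$end <= cmap$ref_len, ]
  purrr::map_dfr(names(groups), function(g) {
    purrr::map_dfr(seq_len(nrow(segs)), function(i) {
      cv <- count_variable_sites(aln, groups[[g]],
                                 c(segs$start[i], segs$end[i]),
                                 cmap, total_mode = total_mode)
      tibble(group = g, segment = segs$segment[i],
             variable = cv$variable, total = cv$total)
    })
  })
}

check_labels <- function(aln, target_ids, offtarget_ids) {
  if (length(target_ids) == 0L || length(offtarget_ids) == 0L) {
    abort("target and off-target groups must both be non-empty",
          class = "cladeprimer_coord_error")
  }
  if (length(intersect(target_ids, offtarget_ids)) > 0L) {
    abort("target and off-target groups must be disjoint",
          class = "cladeprimer_coord_error")
  }
  missing <- setdiff(c(target_ids, offtarget_ids), aln$id)
  if (length(missing) > 0L) {
    abort(sprintf("ids not in alignment: %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "cladeprimer_coord_error")
  }
  invisible(TRUE)
}

# character matrix view of an alignment (rows x columns)
aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
}

# bitset matrix view; gaps are 0
aln_bits_matrix <- function(aln) {
  do.call(rbind, lapply(aln$seq, seq_to_bits, allow_gap = TRUE))
}
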