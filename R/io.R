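#' Read a sequence database from FASTA
#'
#' Reads a (multi-)FASTA file into a tibble with one row per record, optionally
#' attaching a ranked lineage from a taxonomy table. Sequences are upper-cased,
#' `U` is mapped to `T` with a warning, and gaps are rejected: a database holds
#' ungapped template sequences (use [read_alignment()] for aligned input).
#'
#' @param path Path to a FASTA file (`>`-headers, wrapped or unwrapped).
#' @param taxonomy Optional taxonomy: a path to a TSV with columns `id` and
#'   `lineage` (semicolon-delimited `rank:name` pairs), or a tibble as returned
#'   by [read_taxonomy()].
#' @return A tibble with columns `id`, `seq`, and `lineage` (a list column of
#'   named character vectors; `character(0)` where no taxonomy matched).
#' @seealso [read_taxonomy()], [write_sequences()]
#' @export
read_sequences <- function(path, taxonomy = NULL) {
  recs <- read_fasta_raw(path)
  if (anyDuplicated(recs$id)) {
    dup <- unique(recs$id[duplicated(recs$id)])
    abort(sprintf("duplicate sequence id(s) in '%s': %s",
                  path, paste(head(dup, 5), collapse = ", ")),
          class = "cladeprimer_io_error")
  }
  seqs <- normalize_dna(recs$seq, recs$id)
  if (any(grepl("-", seqs, fixed = TRUE))) {
    bad <- recs$id[grepl("-", seqs, fixed = TRUE)]
    abort(sprintf(
      "gapped sequences are not allowed in a database (found in: %s); use read_alignment()",
      paste(head(bad, 5), collapse = ", ")),
      class = "cladeprimer_io_error")
  }
  validate_dna(seqs, recs$id, allow_gap = FALSE)
  db <- tibble(id = recs$id, seq = seqs,
               lineage = rep(list(character(0)), length(seqs)))
  if (!is.null(taxonomy)) {
    tax <- if (is.character(taxonomy)) read_taxonomy(taxonomy) else taxonomy
    idx <- match(db$id, tax$id)
    missing_ids <- db$id[is.na(idx)]
    if (length(missing_ids) > 0L) {
      warn(sprintf("%d sequence id(s) absent from taxonomy (e.g. %s); lineage left empty",
                   length(missing_ids),
                   paste(head(missing_ids, 3), collapse = ", ")))
    }
    db$lineage[!is.na(idx)] <- tax$lineage[idx[!is.na(idx)]]
  }
  db
}

#' Read a taxonomy table
#'
#' Flat TSV with header columns `id` and `lineage`, the lineage encoded as
#' semicolon-delimited `rank:name` pairs (e.g.
#' `kingdom:Fungi;family:Parmeliaceae;genus:Melanelia`).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id` and `lineage` (list of named character
#'   vectors, names are ranks).
#' @export
read_taxonomy <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("id", "lineage") %in% names(tab))) {
    abort(sprintf("taxonomy '%s' must have columns 'id' and 'lineage'", path),
          class = "cladeprimer_io_error")
  }
  tibble(id = tab$id, lineage = lapply(tab$lineage, parse_lineage))
}

parse_lineage <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    abort(sprintf("malformed lineage field '%s' (expected rank:name;...)", x),
          class = "cladeprimer_io_error")
  }
  setNames(trimws(vapply(kv, `[`, character(1), 2L)),
           trimws(vapply(kv, `[`, character(1), 1L)))
}

format_lineage <- function(lin) {
  if (length(lin) == 0L) return("")
  paste(paste0(names(lin), ":", lin), collapse = ";")
}

#' Write sequences to FASTA
#'
#' @param db A tibble with columns `id` and `seq` (alignment rows allowed).
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(db, path, width = 70) {
  x <- Biostrings::BStringSet(setNames(db$seq, db$id))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write a taxonomy table
#'
#' @param db A tibble with columns `id` and `lineage` (list column).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(db, path) {
  out <- tibble(id = db$id,
                lineage = vapply(db$lineage, format_lineage, character(1)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a multiple sequence alignment from FASTA
#'
#' All rows must have equal length; one row is designated the coordinate
#' reference for [build_coord_map()].
#'
#' @param path Path to an aligned FASTA file (gaps as `-`).
#' @param reference_id Id of the reference row; must be present in the file.
#' @return An alignment: a tibble with columns `id` and `seq`, carrying the
#'   reference id as an attribute (see [as_alignment()]).
#' @export
read_alignment <- function(path, reference_id) {
  recs <- read_fasta_raw(path)
  seqs <- normalize_dna(recs$seq, recs$id)
  as_alignment(tibble(id = recs$id, seq = seqs), reference_id)
}

#' Construct an alignment from a tibble
#'
#' @param df A tibble (or data frame) with character columns `id` and `seq`;
#'   `seq` may contain `-` gaps, all rows equal length.
#' @param reference_id Id of the reference row.
#' @return The validated alignment tibble with attribute `reference_id` and
#'   class `cladeprimer_aln`.
#' @export
as_alignment <- function(df, reference_id) {
  df <- as_tibble(df)
  if (!all(c("id", "seq") %in% names(df))) {
    abort("alignment needs columns 'id' and 'seq'",
          class = "cladeprimer_io_error")
  }
  if (anyDuplicated(df$id)) {
    abort("duplicate row id(s) in alignment", class = "cladeprimer_io_error")
  }
  lens <- nchar(df$seq)
  if (length(unique(lens)) != 1L) {
    ref_len <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    bad <- df$id[lens != ref_len]
    abort(sprintf("ragged alignment: rows with deviating length: %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "cladeprimer_io_error")
  }
  if (lens[1] < 1L) {
    abort("alignment of length 0", class = "cladeprimer_io_error")
  }
  if (!reference_id %in% df$id) {
    abort(sprintf("reference_id '%s' not among alignment rows", reference_id),
          class = "cladeprimer_io_error")
  }
  validate_dna(df$seq, df$id, allow_gap = TRUE)
  structure(df,
            reference_id = reference_id,
            class = c("cladeprimer_aln", class(df)))
}

#' @export
print.cladeprimer_aln <- function(x, ...) {
  cat(sprintf("<alignment: %d rows x %d columns, reference '%s'>\n",
              nrow(x), nchar(x$seq[1]), attr(x, "reference_id")))
  NextMethod()
}

#' Reference row id of an alignment
#' @param aln An alignment from [as_alignment()] or [read_alignment()].
#' @return The reference row id (string).
#' @export
reference_id <- function(aln) {
  attr(aln, "reference_id")
}

#' Read a primer table
#'
#' TSV with header columns `name`, `sequence` and `orientation` (`F` or `R`),
#' plus optional `ref_coord` (reference coordinate of the 5' end) and `tm`.
#' Degenerate IUPAC codes are allowed in sequences.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `name`, `seq`, `orientation`, `ref5`, `tm`,
#'   `degeneracy`.
#' @export
read_primers <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("name", "sequence", "orientation")
  if (!all(need %in% names(tab))) {
    abort(sprintf("primer table '%s' must have columns %s",
                  path, paste(need, collapse = ", ")),
          class = "cladeprimer_io_error")
  }
  seqs <- normalize_dna(tab$sequence, tab$name)
  validate_dna(seqs, tab$name, allow_gap = FALSE)
  bad <- !tab$orientation %in% c("F", "R")
  if (any(bad)) {
    abort(sprintf("orientation must be 'F' or 'R' (offending primer: %s)",
                  tab$name[which(bad)[1]]),
          class = "cladeprimer_io_error")
  }
  tibble(
    name = tab$name,
    seq = seqs,
    orientation = tab$orientation,
    ref5 = if ("ref_coord" %in% names(tab)) as.integer(tab$ref_coord) else NA_integer_,
    tm = if ("tm" %in% names(tab)) as.numeric(tab$tm) else NA_real_,
    degeneracy = degeneracy(seqs)
  )
}

# FASTA reading via Biostrings, with errors re-signalled naming the file.
read_fasta_raw <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "cladeprimer_io_error")
  }
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e)),
            class = "cladeprimer_io_error")
    })
  if (length(x) == 0L) {
    abort(sprintf("no FASTA records in '%s'", path),
          class = "cladeprimer_io_error")
  }
  # drop description after first whitespace, as sequence tools conventionally do
  ids <- sub("\\s.*$", "", names(x))
  list(id = ids, seq = as.character(unname(x)))
}
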