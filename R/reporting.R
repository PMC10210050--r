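#' PCR success rate
#'
#' `100 * successes / total`, rounded half-up to one decimal (so 22/24 gives
#' 91.7 and 3/24 gives 12.5).
#'
#' @param successes,total Non-negative counts, `successes <= total`,
#'   `total > 0`. Vectorised.
#' @return Percentage(s) with one decimal.
#' @examples
#' success_rate(22, 24)  # 91.7
#' success_rate(3, 24)   # 12.5
#' @export
success_rate <- function(successes, total) {
  if (any(total <= 0)) {
    abort("total must be > 0", class = "cladeprimer_report_error")
  }
  if (any(successes < 0) || any(successes > total)) {
    abort("need 0 <= successes <= total", class = "cladeprimer_report_error")
  }
  round_half_up(100 * successes / total, 1L)
}

# round() in R rounds half to even; reported percentages round half up
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Tally amplification trials per group
#'
#' Adds per-group success rates to a table of amplified/sampled specimen
#' counts and computes grand totals.
#'
#' @param trials A tibble with columns `group`, `amplified`, `sampled`
#'   (counts per taxon or clade).
#' @return An object of class `pcr_tally`: the per-group tibble with a `rate`
#'   column; [glance()] returns the totals.
#' @examples
#' tally_table(tibble::tibble(group = "Usnea", amplified = 6, sampled = 7))
#' @export
tally_table <- function(trials) {
  trials <- as_tibble(trials)
  need <- c("group", "amplified", "sampled")
  if (!all(need %in% names(trials))) {
    abort("trials needs columns group, amplified, sampled",
          class = "cladeprimer_report_error")
  }
  bad <- which(trials$amplified > trials$sampled | trials$amplified < 0)
  if (length(bad) > 0L) {
    abort(sprintf("amplified > sampled in row %d (group '%s')",
                  bad[1], trials$group[bad[1]]),
          class = "cladeprimer_report_error")
  }
  out <- mutate(trials, rate = success_rate(.data$amplified, .data$sampled))
  structure(out, class = c("pcr_tally", class(out)))
}

#' @describeIn tally_table Per-group table as a plain tibble.
#' @param x A `pcr_tally`.
#' @param ... Unused.
#' @method tidy pcr_tally
#' @export
tidy.pcr_tally <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @describeIn tally_table Grand totals: groups, amplified and sampled sums,
#'   overall rate.
#' @method glance pcr_tally
#' @export
glance.pcr_tally <- function(x, ...) {
  tibble(n_groups = nrow(x),
         amplified = sum(x$amplified),
         sampled = sum(x$sampled),
         rate = success_rate(sum(x$amplified), sum(x$sampled)))
}

#' Published mtSSU primer panel
#'
#' The mtSSU primer table shipped with the package: the classical universal
#' pair (mrSSU1/mrSSU3R) and the mycobiont-specific panel, with their
#' annotated reference locations (on the 1980 bp *Triangularia anserina*
#' mtSSU numbering), sequences and published melting temperatures. The
#' `ref5` column is the 5'-anchored coordinate parsed from the location
#' annotation (descending annotation for reverse primers).
#'
#' @return A tibble with columns `name`, `role`, `location`, `orientation`,
#'   `seq`, `tm_published`, `ref5`, `ref3`.
#' @export
mtssu_primers <- function() {
  path <- system.file("extdata", "mtssu_primers.tsv",
                      package = "cladeprimer", mustWork = TRUE)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  loc <- strsplit(tab$location, "-", fixed = TRUE)
  tibble(
    name = tab$name,
    role = tab$role,
    location = tab$location,
    orientation = tab$orientation,
    seq = tab$sequence,
    tm_published = as.numeric(tab$tm),
    ref5 = as.integer(vapply(loc, `[`, character(1), 1L)),
    ref3 = as.integer(vapply(loc, `[`, character(1), 2L))
  )
}

#' Published per-genus amplification trial counts
#'
#' Amplified/sampled specimen counts for the mycobiont-specific primer pair
#' across lichen genera and clades, as shipped with the package.
#'
#' @return A tibble with columns `clade_group`, `group`, `amplified`,
#'   `sampled`.
#' @export
parmeliaceae_trials <- function() {
  path <- system.file("extdata", "parmeliaceae_trials.tsv",
                      package = "cladeprimer", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    clade_group = "c", group = "c", amplified = "i", sampled = "i"),
    progress = FALSE)
}

#' Load (and validate) a run configuration
#'
#' Reads a YAML configuration holding the parameter blocks of every module
#' (regions, thermo, design, pcr, fixtures). Unknown keys are rejected so a
#' typo cannot silently fall back to a default. The shipped reference
#' configuration documents every default.
#'
#' @param path Path to a YAML file, or `NULL` for the shipped defaults.
#' @return A nested list of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  ref_path <- system.file("extdata", "default_config.yaml",
                          package = "cladeprimer", mustWork = TRUE)
  defaults <- yaml::read_yaml(ref_path)
  if (is.null(path)) {
    return(structure(defaults, class = "run_config"))
  }
  user <- yaml::read_yaml(path)
  check_keys <- function(u, d, prefix = "") {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown) > 0L) {
      abort(sprintf("unknown config key(s): %s",
                    paste0(prefix, unknown, collapse = ", ")),
            class = "cladeprimer_config_error")
    }
    for (k in names(u)) {
      if (is.list(d[[k]]) && !is.null(names(d[[k]]))) {
        check_keys(u[[k]] %||% list(), d[[k]], paste0(prefix, k, "."))
      }
    }
  }
  check_keys(user, defaults)
  merged <- modifyList(defaults, user)
  structure(merged, class = "run_config")
}
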