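test_that("degenerate consensus uses minimal IUPAC codes and caps degeneracy", {
  aln <- as_alignment(
    tibble::tibble(id = c("t1", "t2", "t3"),
                   seq = c("ACGTACGTAC", "ATGTACGTAC", "ACGTACGAAC")),
    "t1")
  cons <- consensus_with_degeneracy(aln, c("t1", "t2", "t3"), 1:10)
  expect_equal(cons$seq, "AYGTACGWAC")  # {C,T} -> Y, {T,A} -> W
  expect_equal(cons$degeneracy, 4)

  # degeneracy cap: three columns of {A,C,G,T} give 64 > 16
  aln2 <- as_alignment(
    tibble::tibble(id = paste0("t", 1:4),
                   seq = c("AAACGCGTAC", "CCCCGCGTAC",
                           "GGGCGCGTAC", "TTTCGCGTAC")),
    "t1")
  cons2 <- consensus_with_degeneracy(aln2, paste0("t", 1:4), 1:10,
                                     max_degeneracy = 16)
  expect_null(cons2$seq)
  expect_match(cons2$reject_reason, "degeneracy 64")

  # gapped consensus column is rejected with a reason
  aln3 <- as_alignment(
    tibble::tibble(id = c("REF", "t1", "t2"),
                   seq = c("ACGTACGTAC", "ACG--CGTAC", "ACG--CGTAC")),
    "REF")
  cons3 <- consensus_with_degeneracy(aln3, c("t1", "t2"), 1:10)
  expect_null(cons3$seq)
  expect_match(cons3$reject_reason, "gap")
})

test_that("primer nomenclature encodes the 5' coordinate and round-trips", {
  expect_equal(name_primer("mt-SSU", 581, "F"), "mt-SSU-581-5'")
  expect_equal(name_primer("mt-SSU", 1345, "R"), "mt-SSU-1345-3'")
  expect_error(name_primer("mt-SSU", 0, "F"),
               class = "cladeprimer_design_error")

  parsed <- parse_primer_name(c("mt-SSU-581-5'", "mt-SSU-1345-3'"))
  expect_equal(parsed$ref5, c(581L, 1345L))
  expect_equal(parsed$orientation, c("F", "R"))
  expect_equal(parsed$locus_tag, c("mt-SSU", "mt-SSU"))
  # generated names always parse back to their coordinates
  for (r5 in c(1L, 57L, 1980L)) {
    for (o in c("F", "R")) {
      expect_equal(parse_primer_name(name_primer("locus", r5, o))$ref5, r5)
    }
  }
})

test_that("amplicon length is the 5'-anchored coordinate difference", {
  expect_equal(predict_amplicon_length(581, 1345), 764)
  expect_equal(predict_amplicon_length(533, 1524), 991)
  expect_error(predict_amplicon_length(100, 100),
               class = "cladeprimer_design_error")
  expect_error(predict_amplicon_length(1345, 581),
               class = "cladeprimer_design_error")
})

test_that("candidate enumeration recovers a planted discriminating window", {
  fx <- make_alignment(fixture_spec(seed = 3))
  cm <- build_coord_map(fx$alignment)
  cands <- enumerate_candidates(
    fx$alignment, fx$target_ids, fx$offtarget_ids,
    length_range = c(20, 20),
    constraints = design_constraints(tm_range = c(0, 100),
                                     min_discrimination = 30),
    cmap = cm)
  expect_gt(nrow(cands), 0)
  w <- fx$truth$windows
  # high-discrimination candidates either overlap a planted window or sit in
  # a length-variable segment where off-target deletions preclude binding
  overlaps <- purrr::map_lgl(seq_len(nrow(cands)), function(i) {
    any(cands$col_start[i] <= w$ref_end & cands$col_end[i] >= w$ref_start)
  })
  var_segs <- fx$truth$layout[fx$truth$layout$kind == "variable", ]
  in_variable <- purrr::map_lgl(seq_len(nrow(cands)), function(i) {
    any(cands$col_start[i] <= var_segs$end & cands$col_end[i] >= var_segs$start)
  })
  expect_true(all(overlaps | in_variable))
  expect_setequal(unique(cands$orientation), c("F", "R"))
  # the exact planted windows appear among the candidates
  expect_true(any(cands$col_start == w$ref_start[1] &
                    cands$col_end == w$ref_end[1]))
  # all constraints hold on every returned candidate
  expect_true(all(cands$disc_sum >= 30))
  expect_true(all(cands$degeneracy <= 16))
  expect_true(all(vapply(cands$seq, three_prime_gc_run, integer(1)) <= 3))
  # target consensus covers every target row exactly
  expect_true(all(cands$target_coverage == 1))
})

test_that("vacuous constraints admit candidates from conserved windows and
           the 3'-GC-run filter excludes G/C-run termini", {
  withr::local_seed(77)
  base <- strsplit(random_dna(60), "")[[1]]
  base[41:44] <- c("G", "C", "C", "C")
  base[45:60] <- sample(c("A", "T"), 16, replace = TRUE)
  aln <- as_alignment(
    tibble::tibble(id = c("t1", "t2", "o1"),
                   seq = rep(paste(base, collapse = ""), 3)),
    "t1")
  suppressWarnings({
    loose <- enumerate_candidates(
      aln, c("t1", "t2"), "o1", length_range = c(20, 20),
      constraints = design_constraints(tm_range = c(0, 200),
                                       max_gc3_run = 20,
                                       min_discrimination = 0))
  })
  # every gap-free window yields candidates when nothing filters
  expect_equal(sum(loose$orientation == "F"), 41)

  strict <- enumerate_candidates(
    aln, c("t1", "t2"), "o1", length_range = c(20, 20),
    constraints = design_constraints(tm_range = c(0, 200),
                                     max_gc3_run = 3,
                                     min_discrimination = 0))
  # the forward window ending in ...GCCC (3' run 4) must be gone
  ends_gccc <- strict$orientation == "F" & strict$col_end == 44
  expect_false(any(ends_gccc))
  expect_true(any(loose$orientation == "F" & loose$col_end == 44))
})

test_that("no-window and empty-pair cases warn with structured classes", {
  aln <- as_alignment(
    tibble::tibble(id = c("t1", "o1"),
                   seq = c("ACGTACGTACGTACGTACGTACGT",
                           "ACGTACGTACGTACGTACGTACGT")),
    "t1")
  expect_warning(
    out <- enumerate_candidates(aln, "t1", "o1",
                                length_range = c(20, 20),
                                constraints = design_constraints(
                                  min_discrimination = 5)),
    class = "cladeprimer_no_candidates")
  expect_equal(nrow(out), 0)
})

test_that("pairing enforces geometry, length and delta-Tm and ranks
           deterministically", {
  cands <- tibble::tibble(
    name = c("L-10-5'", "L-400-3'", "L-600-3'"),
    seq = c("ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA",
            "ACGTACGTACGTACGTTTTT"),
    orientation = c("F", "R", "R"),
    ref5 = c(10L, 400L, 600L),
    tm = c(55, 54, 53),
    degeneracy = c(1, 1, 1),
    col_start = c(10L, 381L, 581L), col_end = c(29L, 400L, 600L),
    disc_sum = c(9L, 9L, 9L),
    target_coverage = c(1, 1, 0.9),
    off_min_mm = c(9, 9, 9), off_mean_mm = c(9, 9, 9),
    weighted3p = c(20, 20, 24))
  pairs <- design_pairs(cands, amplicon_range = c(200, 2500),
                        max_delta_tm = 5)
  expect_equal(nrow(pairs), 2L)
  # higher weighted specificity wins despite lower coverage
  expect_equal(pairs$rev_name[1], "L-600-3'")
  expect_equal(pairs$amplicon_bp, c(590L, 390L))

  # delta-Tm of zero excludes unequal-Tm combinations
  expect_warning(
    none <- design_pairs(cands, amplicon_range = c(200, 2500),
                         max_delta_tm = 0),
    class = "cladeprimer_no_pairs")
  expect_equal(nrow(none), 0L)

  # single compatible F/R combination yields exactly one pair
  one <- design_pairs(cands[1:2, ], amplicon_range = c(200, 2500),
                      max_delta_tm = 5)
  expect_equal(nrow(one), 1L)
  expect_error(design_pairs(cands[cands$orientation == "F", ]),
               class = "cladeprimer_design_error")
})
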