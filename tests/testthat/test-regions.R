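mini_aln <- function(ids, seqs, ref = ids[1]) {
  as_alignment(tibble::tibble(id = ids, seq = seqs), ref)
}

test_that("coordinate map handles reference gaps", {
  aln <- mini_aln(c("REF", "r2"), c("AC-GT", "ACAGT"))
  cm <- build_coord_map(aln)
  expect_equal(cm$col_to_ref, c(1L, 2L, NA, 3L, 4L))
  expect_equal(cm$ref_to_col, c(1L, 2L, 4L, 5L))
  expect_equal(cm$ref_len, 4L)

  gapless <- mini_aln("REF", "ACGTACGTAC")
  expect_equal(build_coord_map(gapless)$col_to_ref, 1:10)

  allgap <- mini_aln(c("REF", "r2"), c("----", "ACGT"))
  expect_error(build_coord_map(allgap), "all gaps",
               class = "cladeprimer_coord_error")
})

test_that("variable-site counts match the hand-enumerated example", {
  aln <- mini_aln(c("g1", "g2", "g3"), c("ACGTA", "ACGTT", "ACCTA"))
  cv <- count_variable_sites(aln, c("g1", "g2", "g3"), c(1, 5))
  expect_equal(cv$variable, 2L)   # columns 3 (G/C) and 5 (A/T)
  expect_equal(cv$total, 5L)

  # identical rows: no variation
  same <- mini_aln(c("a", "b"), c("ACGTACGT", "ACGTACGT"))
  cv2 <- count_variable_sites(same, c("a", "b"), c(1, 8))
  expect_equal(cv2$variable, 0L)
  expect_equal(cv2$total, 8L)

  # all-gap group column excluded from the total; ambiguity codes are
  # never counted as variation
  aln3 <- mini_aln(c("REF", "a", "b"),
                   c("ACGTA", "A-GRA", "A-GTA"), ref = "REF")
  cv3 <- count_variable_sites(aln3, c("a", "b"), c(1, 5))
  expect_equal(cv3$total, 4L)
  expect_equal(cv3$variable, 0L)

  expect_error(count_variable_sites(aln, character(0), c(1, 5)),
               "empty group", class = "cladeprimer_coord_error")
})

test_that("variable-site counts agree with a brute-force oracle and are
           additive over disjoint intervals", {
  withr::local_seed(42)
  for (rep in 1:10) {
    n_rows <- sample(3:12, 1)
    n_cols <- sample(40:120, 1)
    rows <- vapply(seq_len(n_rows), function(i) {
      ch <- sample(c("A", "C", "G", "T", "-", "Y"), n_cols,
                   replace = TRUE, prob = c(rep(0.22, 4), 0.08, 0.04))
      paste(ch, collapse = "")
    }, character(1))
    rows[1] <- random_dna(n_cols)  # gapless reference
    ids <- c("REF", paste0("r", seq_len(n_rows - 1L)))
    aln <- mini_aln(ids, rows, ref = "REF")
    group <- sample(ids, sample(2:n_rows, 1))
    mid <- n_cols %/% 2
    a <- count_variable_sites(aln, group, c(1, mid))
    b <- count_variable_sites(aln, group, c(mid + 1, n_cols))
    whole <- count_variable_sites(aln, group, c(1, n_cols))
    rows_g <- aln$seq[match(group, aln$id)]
    ora <- oracle_variable_sites(rows_g, 1:n_cols)
    expect_equal(whole$variable, unname(ora["variable"]))
    expect_equal(whole$total, unname(ora["total"]))
    expect_equal(whole$variable, a$variable + b$variable)
    expect_equal(whole$total, a$total + b$total)
  }
})

test_that("discrimination profile counts off-target disagreements", {
  aln <- mini_aln(c("t1", "t2", "o1"), c("ACGT", "ACGT", "ATGT"))
  prof <- discrimination_profile(aln, c("t1", "t2"), "o1")
  expect_equal(prof$score, c(0L, 1L, 0L, 0L))
  expect_equal(prof$consensus[2], "C")

  # off-target equal to the consensus: all-zero profile
  aln2 <- mini_aln(c("t1", "t2", "o1"), c("ACGT", "ACTT", "ACTT"))
  prof2 <- discrimination_profile(aln2, c("t1", "t2"), "o1")
  expect_true(all(prof2$score == 0L))
  expect_equal(prof2$consensus[3], "K")  # target set {G,T}

  # all-gap target column scores 0 and is flagged; off-target gap differs
  aln3 <- mini_aln(c("REF", "t1", "o1"), c("ACGT", "A-GT", "A-G-"),
                   ref = "REF")
  prof3 <- discrimination_profile(aln3, "t1", "o1")
  expect_true(prof3$all_gap_target[2])
  expect_equal(prof3$score[2], 0L)
  expect_equal(prof3$score[4], 1L)  # target T vs off-target gap
})

test_that("profile is zero everywhere iff off-targets match the consensus", {
  withr::local_seed(7)
  base <- random_dna(60)
  aln <- mini_aln(c("t1", "t2", "o1", "o2"), rep(base, 4))
  prof <- discrimination_profile(aln, c("t1", "t2"), c("o1", "o2"))
  expect_true(all(prof$score == 0L))

  # plant one difference -> exactly one nonzero column
  ch <- strsplit(base, "")[[1]]
  ch[30] <- setdiff(c("A", "C", "G", "T"), ch[30])[1]
  aln2 <- mini_aln(c("t1", "t2", "o1", "o2"),
                   c(base, base, paste(ch, collapse = ""), base))
  prof2 <- discrimination_profile(aln2, c("t1", "t2"), c("o1", "o2"))
  expect_equal(which(prof2$score > 0L), 30L)
  expect_equal(prof2$score[30], 1L)
})

test_that("region report reproduces brute-force counts per group and segment", {
  fx <- make_alignment(fixture_spec(seed = 11))
  cm <- build_coord_map(fx$alignment)
  regions <- fx$truth$regions
  rep_tab <- region_report(fx$alignment,
                           list(target = fx$target_ids,
                                offtarget = fx$offtarget_ids),
                           regions = regions, cmap = cm)
  segs <- paste0(head(regions$region, -1), "-", regions$region[-1])
  expect_equal(sort(unique(rep_tab$segment)), sort(segs))
  expect_equal(nrow(rep_tab), 2L * length(segs))
  for (i in seq_len(nrow(rep_tab))) {
    seg_idx <- match(rep_tab$segment[i], segs)
    interval <- c(regions$end[seg_idx] + 1L, regions$start[seg_idx + 1L] - 1L)
    ids <- if (rep_tab$group[i] == "target") fx$target_ids else fx$offtarget_ids
    cols <- cm$ref_to_col[interval[1]]:cm$ref_to_col[interval[2]]
    ora <- oracle_variable_sites(fx$alignment$seq[match(ids, fx$alignment$id)],
                                 cols)
    expect_equal(rep_tab$variable[i], unname(ora["variable"]))
    expect_equal(rep_tab$total[i], unname(ora["total"]))
  }

  # a single fully conserved group reports zero variability everywhere
  cons <- region_report(fx$alignment, list(ref_only = "REF"),
                        regions = regions, cmap = cm)
  expect_true(all(cons$variable == 0L))
})
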