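loose_params <- function(...) {
  pcr_params(min_len = 1, max_len = 10000, ...)
}

test_that("binding-site search finds exact, mismatched and degenerate sites", {
  p0 <- pcr_params(max_mismatch = 0, protected_3prime = 2,
                   min_len = 1, max_len = 100)
  sites <- find_binding_sites("ACGT", "TTACGTTT", p0)
  plus <- sites[sites$strand == "+", ]
  expect_equal(plus$start, 3L)
  expect_equal(plus$mismatches, 0L)

  # a mismatch at the primer's final position kills the site at any k
  p3 <- pcr_params(max_mismatch = 3, protected_3prime = 2,
                   min_len = 1, max_len = 100)
  sites2 <- find_binding_sites("ACGT", "TTACGATT", p3)
  expect_false(any(sites2$strand == "+" & sites2$start == 3L))

  # IUPAC: primer Y matches template C and T
  for (tmpl in c("AAAACAAAA", "AAAATAAAA")) {
    s <- find_binding_sites("AAAYAA", tmpl, loose_params(max_mismatch = 0))
    expect_true(any(s$strand == "+" & s$mismatches == 0L))
  }

  # primer longer than template: no sites
  expect_equal(nrow(find_binding_sites(strrep("A", 30), "ACGT", p3)), 0L)
})

test_that("strict template-ambiguity mode turns template N into a mismatch", {
  tmpl <- "AAAANAAAAA"
  inter <- find_binding_sites("AAANAA", tmpl,
                              loose_params(max_mismatch = 0,
                                           protected_3prime = 0))
  expect_gt(nrow(inter), 0L)
  strict <- find_binding_sites("AAANAA", tmpl,
                               loose_params(max_mismatch = 0,
                                            protected_3prime = 0,
                                            ambig_template = "strict"))
  expect_equal(nrow(strict), 0L)
})

test_that("simulated PCR reproduces planted single-amplicon geometry", {
  withr::local_seed(21)
  fwd <- random_dna(20)
  rev_ <- random_dna(20)
  filler <- function(n) random_dna(n)
  # plant the sites so the two 5' ends are 764 bp apart: with both primers
  # 20 nt, the inter-primer filler is 764 - 20 - 20 + 1
  tmpl <- paste0(filler(100), fwd, filler(764 - 20 - 20 + 1),
                 reverse_complement(rev_), filler(150))
  db <- tibble::tibble(id = "tmpl1", seq = tmpl)
  hits <- simulate_pcr(fwd, rev_, db, pcr_params())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$length_bp, 764L)
  expect_equal(hits$fwd_5p, 101L)
  expect_equal(hits$rev_5p, 865L)
  expect_equal(nchar(hits$seq), 765L)  # inclusive primer-to-primer product
  expect_false(hits$multi_amplicon)

  # same sites 3000 bp apart exceed the default length cap
  tmpl_long <- paste0(filler(100), fwd, filler(3000 - 40),
                      reverse_complement(rev_), filler(150))
  far <- simulate_pcr(fwd, rev_, tibble::tibble(id = "t", seq = tmpl_long),
                      pcr_params())
  expect_equal(nrow(far), 0L)
})

test_that("simulate_pcr equals the brute-force oracle on random instances", {
  withr::local_seed(99)
  for (i in 1:25) {
    fwd <- random_dna(sample(15:25, 1))
    rev_ <- random_dna(sample(15:25, 1))
    L <- sample(300:1500, 1)
    tmpl <- random_dna(L)
    # plant near-matching sites in half the instances so hits occur
    if (i %% 2 == 0) {
      f2 <- strsplit(fwd, "")[[1]]
      f2[sample(seq_len(nchar(fwd) - 2), 1)] <- "N"
      pos_f <- sample(1:(L %/% 3), 1)
      pos_r <- pos_f + nchar(fwd) + sample(100:500, 1)
      substr(tmpl, pos_f, pos_f + nchar(fwd) - 1) <- paste(f2, collapse = "")
      rc <- reverse_complement(rev_)
      if (pos_r + nchar(rc) - 1 <= L) {
        substr(tmpl, pos_r, pos_r + nchar(rc) - 1) <- rc
      }
    }
    par <- pcr_params(max_mismatch = sample(0:3, 1), protected_3prime = 2,
                      min_len = 50, max_len = 2500,
                      ambig_template = sample(c("intersect", "strict"), 1))
    db <- tibble::tibble(id = paste0("t", i), seq = tmpl)
    fast <- simulate_pcr(fwd, rev_, db, par)
    slow <- brute_force_pcr(fwd, rev_, db, par)
    expect_identical(hit_key(fast), hit_key(slow))
  }
})

test_that("amplified template sets are nested in the mismatch allowance", {
  fxdb <- make_database(fixture_spec(seed = 13, offtarget_divergence = 0.2))
  w <- fxdb$truth$windows
  prev <- character(0)
  for (k in 0:3) {
    hits <- simulate_pcr(w$fwd_primer[1], w$rev_primer[2], fxdb$db,
                         pcr_params(max_mismatch = k))
    amplified <- unique(hits$template_id)
    expect_true(all(prev %in% amplified))
    prev <- amplified
  }
})

test_that("reverse-complementing the database mirrors every hit", {
  withr::local_seed(55)
  fxdb <- make_database(fixture_spec(seed = 55))
  w <- fxdb$truth$windows
  par <- pcr_params(max_mismatch = 1)
  fwd <- w$fwd_primer[1]; rev_ <- w$rev_primer[2]
  hits <- simulate_pcr(fwd, rev_, fxdb$db, par)
  db_rc <- dplyr::mutate(fxdb$db, seq = reverse_complement(seq))
  hits_rc <- simulate_pcr(fwd, rev_, db_rc, par)
  expect_equal(nrow(hits), nrow(hits_rc))
  # each plus-strand hit maps to a minus-strand hit with mirrored coordinates
  L <- setNames(nchar(fxdb$db$seq), fxdb$db$id)
  key_fwdrc <- sort(paste(hits$template_id,
                          chartr("+-", "-+", hits$strand),
                          L[hits$template_id] - hits$fwd_5p + 1L,
                          hits$fwd_mm, hits$length_bp))
  key_rc <- sort(paste(hits_rc$template_id, hits_rc$strand,
                       hits_rc$fwd_5p, hits_rc$fwd_mm, hits_rc$length_bp))
  expect_identical(key_rc, key_fwdrc)
})

test_that("specificity summary partitions templates and nests over k", {
  fxdb <- make_database(fixture_spec(seed = 2))
  w <- fxdb$truth$windows
  hits <- simulate_pcr(w$fwd_primer[1], w$rev_primer[2], fxdb$db,
                       pcr_params())
  s <- summarize_specificity(hits, fxdb$db, c("family", "Parmeliaceae"))
  expect_equal(s$by_group$n_target[s$by_group$k == 0],
               length(fxdb$target_ids))
  expect_true(all(s$by_group$n_other == 0L))
  expect_true(all(diff(s$by_group$n_total) >= 0L))
  expect_equal(s$by_group$n_target + s$by_group$n_other +
                 s$by_group$n_unclassified, s$by_group$n_total)
  fam <- s$by_family[s$by_family$k == 0, ]
  expect_equal(fam$family, "Parmeliaceae")

  # tidy/glance/autoplot surfaces
  td <- tidy(s)
  expect_setequal(unique(td$group), c("target", "other", "unclassified"))
  gl <- glance(s)
  expect_equal(gl$offtarget_k0, 0L)
  expect_s3_class(autoplot(s), "ggplot")

  # templates without lineage fall into the unclassified bucket
  db2 <- fxdb$db
  db2$lineage[db2$id == "T01"] <- list(character(0))
  expect_warning(s2 <- summarize_specificity(hits, db2,
                                             c("family", "Parmeliaceae")),
                 "unclassified")
  expect_equal(s2$by_group$n_unclassified[1], 1L)
})

test_that("an off-target mismatch planted in the forward site appears only
           at k >= 1", {
  withr::local_seed(60)
  fwd <- random_dna(20); rev_ <- random_dna(20)
  core <- random_dna(400)
  on_tmpl <- paste0(fwd, core, reverse_complement(rev_))
  f_mut <- strsplit(fwd, "")[[1]]
  pos <- 5L  # outside the protected 3' window
  f_mut[pos] <- setdiff(c("A", "C", "G", "T"), f_mut[pos])[1]
  off_tmpl <- paste0(paste(f_mut, collapse = ""), core,
                     reverse_complement(rev_))
  db <- tibble::tibble(id = c("on", "off"), seq = c(on_tmpl, off_tmpl),
                       lineage = list(c(family = "Parmeliaceae"),
                                      c(family = "Nectriaceae")))
  s <- summarize_specificity(
    simulate_pcr(fwd, rev_, db, pcr_params()), db,
    c("family", "Parmeliaceae"))
  expect_equal(s$by_group$n_other, c(0L, 1L, 1L, 1L))
  expect_equal(s$by_group$n_target, rep(1L, 4))
})
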