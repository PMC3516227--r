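test_that("a subject containing the query verbatim gives one full hit", {
  q <- random_nt(200, seed = 1)
  subj <- tbl_of(c(s1 = paste0(random_nt(80, seed = 2), q,
                               random_nt(60, seed = 3))))
  hits <- similarity_search(tbl_of(c(q1 = q)), subj, min_identity = 90,
                            min_length = 100)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 100)
  expect_equal(hits$aligned_length, 200L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$s_start, 80L)
  expect_equal(hits$s_end, 280L)
})

test_that("reverse-complement subjects are hit on the minus strand", {
  q <- random_nt(200, seed = 4)
  subj <- tbl_of(c(s1 = revcomp(q)))
  hits <- similarity_search(tbl_of(c(q1 = q)), subj)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_equal(hits$identity, 100)
  expect_equal(c(hits$s_start, hits$s_end), c(0L, 200L))
})

test_that("unrelated random sequences produce no hits (oracle-confirmed)", {
  q <- random_nt(1610, seed = 5)
  s <- random_nt(1000, seed = 6)
  hits <- similarity_search(tbl_of(c(q1 = q)), tbl_of(c(s1 = s)),
                            min_identity = 90, min_length = 100)
  expect_equal(nrow(hits), 0L)
  # independent full Smith-Waterman: the best local alignment of this pair
  # is itself nowhere near 100 columns at 90% identity
  o <- oracle_local_align(q, s)
  expect_true(nchar(o$q_aln) < 100 || o$identity < 90)
})

test_that("similarity_search agrees with the Smith-Waterman oracle", {
  withr::local_seed(42)
  n_checked <- 0
  n_exact <- 0
  for (k in 1:60) {
    core <- random_nt(sample(80:200, 1))
    # plant a mutated copy of the core so a genuine local hit exists
    mut <- strsplit(core, "")[[1]]
    pos <- sample(length(mut), ceiling(length(mut) * 0.05))
    mut[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
    subj <- paste0(random_nt(sample(20:150, 1)),
                   paste(mut, collapse = ""),
                   random_nt(sample(20:150, 1)))
    q <- core
    hits <- similarity_search(tbl_of(c(q1 = q)), tbl_of(c(s1 = subj)),
                              min_identity = 50, min_length = 30)
    o <- oracle_local_align(q, subj)
    fw <- hits[hits$strand == "+", , drop = FALSE]
    if (nrow(fw) == 0) next
    n_checked <- n_checked + 1
    # the reported hit must itself be a Smith-Waterman optimum: its
    # rescored alignment equals the oracle's exhaustive-DP maximum
    expect_equal(oracle_score_alignment(fw$q_aln[1], fw$s_aln[1]),
                 o$score)
    same_coords <- fw$s_start[1] == o$s_start - 1L &&
      fw$s_end[1] == o$s_end &&
      fw$q_start[1] == o$q_start - 1L && fw$q_end[1] == o$q_end
    if (same_coords) {
      expect_equal(fw$identity[1], o$identity, tolerance = 1e-9)
      n_exact <- n_exact + 1
    }
  }
  expect_gte(n_checked, 50)
  # co-optimal alignments may legitimately differ in traceback; exact
  # agreement must still be the rule, not the exception
  expect_gte(n_exact / n_checked, 0.8)
})

test_that("fragments with an exact 50-nt overlap merge into one contig", {
  a <- random_nt(100, seed = 7)
  b <- paste0(substr(a, 51, 100), random_nt(50, seed = 8))
  merged <- merge_overlapping_fragments(tbl_of(c(f1 = a, f2 = b)))
  expect_equal(nrow(merged), 1L)
  expect_equal(nchar(merged$residues), 150L)
  expect_equal(substr(merged$residues, 1, 100), a)
})

test_that("a 30-bp overlap is below the 40-bp merge floor", {
  a <- random_nt(100, seed = 9)
  b <- paste0(substr(a, 71, 100), random_nt(100, seed = 10))
  merged <- merge_overlapping_fragments(tbl_of(c(f1 = a, f2 = b)),
                                        min_identity = 99,
                                        min_overlap = 40)
  expect_equal(nrow(merged), 2L)
})

test_that("a tiling of fragments reconstructs the master", {
  master <- random_nt(1610, seed = 11)
  frags <- tbl_of(c(f1 = substr(master, 1, 700),
                    f2 = substr(master, 601, 1200),
                    f3 = substr(master, 1101, 1610)))
  merged <- merge_overlapping_fragments(frags)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$residues, master)
})

test_that("consensus of identical hits is that sequence", {
  q <- random_nt(300, seed = 12)
  subj <- tbl_of(setNames(rep(q, 5), paste0("s", 1:5)))
  hits <- similarity_search(tbl_of(c(q1 = q)), subj)
  prof <- build_consensus(hits, top_n = 5)
  expect_equal(prof$consensus, q)
  expect_equal(prof$n_hits, 5L)
  expect_equal(unname(colSums(prof$counts)), rep(5, 300))
})

test_that("majority wins a column; ties go A<C<G<T with gap losing", {
  # hand-built hit stack on a 4-nt query frame
  mk_hit <- function(id, s) tibble::tibble(
    query_id = "q", subject_id = id, strand = "+", identity = 100,
    aligned_length = 4L, s_start = 0L, s_end = 4L, q_start = 0L,
    q_end = 4L, q_aln = "ACGT", s_aln = s)
  hits <- dplyr::bind_rows(mk_hit("a", "AAGT"), mk_hit("b", "AAGT"),
                           mk_hit("c", "ACGT"), mk_hit("d", "AGTT"),
                           mk_hit("e", "ATCT"))
  attr(hits, "query_length") <- 4L
  prof <- build_consensus(hits, top_n = 5)
  # col1 A:5; col2 A:2,C:1,G:1,T:1 -> A; col3 G:3 -> G; col4 T:5
  expect_equal(prof$consensus, "AAGT")
  # tie between C and G resolved to C; gap loses a tie against a base
  hits2 <- dplyr::bind_rows(mk_hit("a", "ACGT"), mk_hit("b", "AGG-"))
  attr(hits2, "query_length") <- 4L
  prof2 <- build_consensus(hits2, top_n = 2)
  expect_equal(substr(prof2$consensus, 2, 2), "C")
  expect_equal(substr(prof2$consensus, 4, 4), "T")
})

test_that("consensus is invariant to hit order and warns when short", {
  q <- random_nt(250, seed = 13)
  subj <- tbl_of(setNames(vapply(1:6, function(i) {
    s <- strsplit(q, "")[[1]]
    pos <- sample(250, 8)
    s[pos] <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
    paste(s, collapse = "")
  }, ""), paste0("s", 1:6)))
  hits <- similarity_search(tbl_of(c(q1 = q)), subj, min_identity = 80)
  perm <- hits[sample(nrow(hits)), , drop = FALSE]
  attr(perm, "query_length") <- attr(hits, "query_length")
  expect_equal(build_consensus(hits, 6)$consensus,
               build_consensus(perm, 6)$consensus)
  expect_warning(build_consensus(hits, top_n = 300), "available")
})

test_that("ORF-overlap filter keeps >=75% coverage inclusively", {
  mk <- function(id, qs, qe) tibble::tibble(
    query_id = "q", subject_id = id, strand = "+", identity = 100,
    aligned_length = qe - qs, s_start = qs, s_end = qe, q_start = qs,
    q_end = qe, q_aln = "", s_aln = "")
  # ORF on query coordinates [100, 500) -> length 400
  hits <- dplyr::bind_rows(mk("full", 100L, 500L),    # 100% of the ORF
                           mk("half", 100L, 300L),    # 50%
                           mk("exact", 100L, 400L))   # exactly 75%
  kept <- filter_by_orf_overlap(hits, 100L, 500L, 0.75)
  expect_setequal(kept$subject_id, c("full", "exact"))
})

test_that("dedup collapses >=95% pairs within species only", {
  a <- random_nt(200, seed = 14)
  b <- strsplit(a, "")[[1]]
  b[sample(200, 8)] <- sample(c("A", "C", "G", "T"), 8, replace = TRUE)
  b <- paste(b, collapse = "")   # ~96% identical to a
  recs <- seq_tbl(id = c("r1", "r2"), residues = c(a, b),
                  species = c("sp1", "sp1"))
  expect_equal(nrow(dedupe_representatives(recs)), 1L)
  recs2 <- seq_tbl(id = c("r1", "r2"), residues = c(a, b),
                   species = c("sp1", "sp2"))
  expect_equal(nrow(dedupe_representatives(recs2)), 2L)
  # all pairwise well below 95%: no-op
  recs3 <- tbl_of(c(x = random_nt(200, seed = 15),
                    y = random_nt(200, seed = 16),
                    z = random_nt(200, seed = 17)), species = "sp1")
  expect_equal(nrow(dedupe_representatives(recs3)), 3L)
})

test_that("copy counting uses interval union and unrounded fractions", {
  mk <- function(id, sid, s, e, ident = 95) tibble::tibble(
    query_id = "q", subject_id = sid, strand = "+", identity = ident,
    aligned_length = e - s, s_start = s, s_end = e, q_start = 0L,
    q_end = e - s, q_aln = "", s_aln = "")
  hits <- dplyr::bind_rows(mk("h1", "chr1", 0L, 100L),
                           mk("h2", "chr1", 50L, 150L))
  res <- count_copies_and_fraction(hits, 90, assembly_size = 1000)
  expect_equal(res$copies, 2L)
  expect_equal(res$occupied_bp, 150L)
  expect_equal(res$fraction, 0.15)
  # the printed genome numbers give an unrounded 0.0077
  expect_equal(round(6.4e6 / 831.7e6, 4), 0.0077)
  empty <- count_copies_and_fraction(hits[0, ], 90, assembly_size = 1000)
  expect_equal(empty$copies, 0L)
  expect_equal(empty$fraction, 0)
})

test_that("in-silico PCR finds the printed primer pair when embedded", {
  fwd <- "CCAAGGATGTCAGGGACAAG"
  rev <- "CCCAGTTGTCTTCTGAATCATTC"
  insert <- random_nt(400, seed = 18)
  template <- tbl_of(c(t1 = paste0(random_nt(50, seed = 19), fwd, insert,
                                   revcomp(rev), random_nt(50, seed = 20))))
  amp <- in_silico_pcr(template, fwd, rev)
  amp <- amp[amp$strand == "+", , drop = FALSE]
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$product_length,
               nchar(fwd) + 400L + nchar(rev))
  expect_equal(amp$mismatches, 0L)
  # no reverse site -> no amplicon
  t2 <- tbl_of(c(t2 = paste0(random_nt(50, seed = 21), fwd, insert)))
  expect_equal(nrow(in_silico_pcr(t2, fwd, rev)), 0L)
})

test_that("3 mismatches in the forward site kill the amplicon at max 2", {
  fwd <- "CCAAGGATGTCAGGGACAAG"
  rev <- "CCCAGTTGTCTTCTGAATCATTC"
  bad_fwd <- fwd
  substr(bad_fwd, 2, 4) <- "TTT"   # 3 internal mismatches, 3' end intact
  template <- tbl_of(c(t1 = paste0("ACGT", bad_fwd, random_nt(200, seed = 22),
                                   revcomp(rev), "ACGT")))
  expect_equal(nrow(in_silico_pcr(template, fwd, rev, max_mismatch = 2)),
               0L)
  expect_gt(nrow(in_silico_pcr(template, fwd, rev, max_mismatch = 3)), 0L)
})
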