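test_that("the consensus scores 100% identity to itself", {
  tree <- parse_newick("(A:0.02,B:0.02);")
  cfg <- sim_config(tree, master_length = 400, seed = 3)
  recs <- tbl_of(c(self = cfg$master), species = "A")
  out <- identity_to_consensus(recs, cfg$master)
  expect_equal(out$identity, 100)
  expect_equal(out$compared, 400L)
})

test_that("records under the 150-site floor are dropped with a message", {
  tree <- parse_newick("(A:0.02,B:0.02);")
  cfg <- sim_config(tree, master_length = 400, seed = 3)
  recs <- tbl_of(c(long = cfg$master,
                   short = substr(cfg$master, 1, 140)), species = "A")
  expect_message(out <- identity_to_consensus(recs, cfg$master), "short")
  expect_equal(out$id, "long")
  expect_equal(attr(out, "dropped"), "short")
})

test_that("copies at 2% divergence score about 98% identity", {
  tree <- parse_newick("(A:0.02,B:0.02);")
  cfg <- sim_config(tree, master_length = 800, burst = 25, seed = 12)
  fam <- evolve_family(cfg)
  out <- identity_to_consensus(fam$records, cfg$master)
  expect_true(all(abs(out$identity - 98) < 1.5))
})

test_that("histogram respects right-closed bins and conserves counts", {
  ids <- tibble::tibble(id = c("a", "b"), species = c("s1", "s1"),
                        identity = c(97.6, 97.9), compared = c(200L, 200L))
  h <- histogram_identities(ids, bin_width = 0.5)
  h <- h[h$count > 0, ]
  expect_equal(nrow(h), 1L)
  expect_equal(h$bin_low, 97.5)
  expect_equal(h$bin_high, 98.0)
  expect_equal(h$count, 2L)
  # boundary value goes into the bin it closes
  ids2 <- tibble::tibble(id = "c", species = "s1", identity = 98.0,
                         compared = 200L)
  h2 <- histogram_identities(ids2, 0.5)
  expect_equal(h2$bin_high[h2$count > 0], 98.0)
  # conservation on a random batch
  withr::local_seed(5)
  ids3 <- tibble::tibble(id = as.character(1:40),
                         species = sample(c("x", "y"), 40, TRUE),
                         identity = stats::runif(40, 80, 100),
                         compared = 200L)
  expect_equal(sum(histogram_identities(ids3, 0.5)$count), 40L)
  expect_equal(nrow(histogram_identities(ids3[0, ], 0.5)), 0L)
})

test_that("group classification matches the published division", {
  ids <- tibble::tibble(id = c("a", "b", "c"), species = "s",
                        identity = c(97.5, 85, 91), compared = 200L)
  g <- classify_groups(ids)
  expect_equal(g$group, c("group1", "group2", "unassigned"))
  expect_error(classify_groups(ids, group1_floor = 80,
                               divergent_ceiling = 90), "floor")
})

test_that("identical coding sequences give zero counts and missing omega", {
  s <- "ATGAAACCCGGGTTT"
  r <- nei_gojobori(s, s)
  expect_equal(r$Sd, 0)
  expect_equal(r$Nd, 0)
  expect_equal(r$dS, 0)
  expect_equal(r$dN, 0)
  expect_true(is.na(r$omega))
})

test_that("TTT vs TTC is one synonymous difference with S(TTT) = 1/3", {
  # hand enumeration: TTT (Phe) third position T->C synonymous, T->A/G
  # nonsynonymous (Leu); positions 1-2 all nonsynonymous
  r <- nei_gojobori("TTTGGAATT", "TTCGGAATT")
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  # per-codon site counts for TTT alone
  expect_equal(mosaicTE:::ng_codon_sites("TTT"), 1 / 3, tolerance = 1e-12)
  # GGA (Gly): position 3 fully synonymous, positions 1-2 not
  # (first-position changes give Arg, Arg, or a stop)
  expect_equal(mosaicTE:::ng_codon_sites("GGA"), 1, tolerance = 1e-12)
})

test_that("S + N equals three times the compared codons (conservation)", {
  withr::local_seed(60)
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste,
                         collapse = ""), c("TAA", "TAG", "TGA"))
  for (k in 1:10) {
    a <- paste(sample(sense, 30, replace = TRUE), collapse = "")
    b <- paste(sample(sense, 30, replace = TRUE), collapse = "")
    # unrelated pairs are saturated; the distance warning is expected
    r <- suppressWarnings(nei_gojobori(a, b))
    expect_equal(r$S + r$N, 3 * r$codons_compared, tolerance = 1e-9)
  }
})

test_that("nei_gojobori matches an independent implementation (frozen)", {
  # 40-codon pair; dN/dS computed once with an independent
  # pathway-counting implementation and frozen here
  a <- paste0("GGAACTAACGTTCACATTATGAGAGTTACGGGTGTTTTAGAGACCGCCCGTAAGAACACC",
              "ATCATGGAAGCGAACGATATAGTCGGCGTAGAGCGGATGCTAGCCCACTCCTGGAAATAC")
  b <- paste0("GGAACTCACGTCGACATTATGAGAGTTCCGGGTGTTTTAGAAACCGCCCGGAAAAACACC",
              "ATCATGGAAGCGAAAGATATAGTCGGCGTAGAGCGGATGCTAGCCTACTCCTGGAATTAC")
  r <- nei_gojobori(a, b)
  expect_equal(r$dN, 0.06758791753257089, tolerance = 1e-12)
  expect_equal(r$dS, 0.16391465820420809, tolerance = 1e-12)
  expect_equal(r$codons_compared, 40L)
})

test_that("ambiguous and stop codons are skipped and counted", {
  r <- nei_gojobori("ATGNNNAAA", "ATGCCCAAA")
  expect_equal(r$codons_skipped, 1L)
  expect_equal(r$codons_compared, 2L)
  r2 <- nei_gojobori("ATGTAAAAA", "ATGTGGAAA")   # TAA stop skipped
  expect_equal(r2$codons_skipped, 1L)
})

test_that("all-present patterns need zero losses", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  pat <- data.frame(species = c("A", "B", "C", "D"), state = "present")
  expect_equal(dollo_loss_count(tr, pat)$losses, 0L)
})

test_that("single present taxon on a 3-taxon tree needs 2 losses", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  pat <- data.frame(species = c("A", "B", "C"),
                    state = c("present", "absent", "absent"))
  res <- dollo_loss_count(tr, pat)
  expect_equal(res$losses, 2L)
  expect_setequal(res$loss_branches, c("B", "C"))
  # brute-force enumeration of loss placements agrees
  expect_equal(oracle_dollo_min_losses(tr, pat), 2L)
})

test_that("dollo counts equal brute force on random trees and patterns", {
  for (k in 1:8) {
    withr::local_seed(700 + k)
    n <- sample(5:12, 1)
    tr <- ape::rtree(n)
    pat <- data.frame(
      species = tr$tip.label,
      state = sample(c("present", "absent"), n, replace = TRUE,
                     prob = c(0.4, 0.6)))
    if (!any(pat$state == "present")) pat$state[1] <- "present"
    res <- dollo_loss_count(tr, pat)
    expect_equal(res$losses, oracle_dollo_min_losses(tr, pat))
  }
})

test_that("unknown states are pruned before loss counting", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  pat <- data.frame(species = c("A", "B", "C"),
                    state = c("present", "unknown", "absent"))
  expect_equal(dollo_loss_count(tr, pat)$losses, 1L)
})

test_that("a present taxon outside the origin subtree is an error", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  pat <- data.frame(species = c("A", "B", "C"),
                    state = c("present", "absent", "present"))
  mrca_ab <- ape::getMRCA(tr, c("A", "B"))
  expect_error(dollo_loss_count(tr, pat, origin = mrca_ab),
               "single-gain")
})

test_that("concordant gene trees yield no transfer calls", {
  tree <- parse_newick(
    "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);")
  cfg <- sim_config(tree, master_length = 400, burst = 5, seed = 17)
  fam <- evolve_family(cfg)
  gene <- build_nj(p_distance(as_alignment(fam$records)))
  sp <- setNames(fam$records$species, fam$records$id)
  calls <- call_transfers(gene, sp)
  # copies seeded at the root duplicate before speciation, so species
  # need not be monophyletic in the gene tree -- but no transfers are called
  expect_equal(nrow(calls), 0L)
})

test_that("species-monophyletic gene trees are not mosaic", {
  gene <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  calls <- call_transfers(gene, sp)
  expect_equal(nrow(calls), 0L)
  expect_false(attr(calls, "mosaic"))
})

test_that("a simulated transfer is called with the right direction", {
  tree <- host4()
  cfg <- sim_config(tree, master_length = 500, burst = 20, seed = 5,
                    origin = "L",
                    transfers = data.frame(donor = "L", recipient = "T1",
                                           time = 0.9))
  fam <- evolve_family(cfg)
  gene <- build_nj(p_distance(as_alignment(fam$records)))
  sp <- setNames(fam$records$species, fam$records$id)
  calls <- call_transfers(gene, sp)
  expect_true(attr(calls, "mosaic"))
  expect_true(any(calls$recipient == "T1" &
                    grepl("L", calls$donor)))
})

test_that("interleaved two-species quartet is mosaic under Fitch", {
  gene <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  sp <- c(a1 = "A", b1 = "B", a2 = "A", b2 = "B")
  calls <- call_transfers(gene, sp)
  expect_true(attr(calls, "mosaic"))
  expect_gte(attr(calls, "fitch_changes"), 2L)
  # exhaustive internal-state enumeration agrees with the Fitch count
  expect_equal(oracle_fitch_min_changes(gene, as.list(sp)),
               attr(calls, "fitch_changes"))
})

test_that("untagged leaves are an error", {
  gene <- ape::read.tree(text = "((a1:1,b1:1):1,c1:1);")
  expect_error(call_transfers(gene, c(a1 = "A", b1 = "B")), "c1")
})

test_that("group separation is perfect at a 10-point divergence gap", {
  tree <- parse_newick("(A:0.01,B:0.01);")
  cfg <- sim_config(tree, master_length = 800, burst = 20, seed = 19)
  fam <- evolve_family(cfg)
  bg <- emit_background_family(cfg, age = 0.30, n_copies = 20,
                               species = "A")
  all_recs <- dplyr::bind_rows(fam$records, bg)
  ids <- identity_to_consensus(all_recs, cfg$master)
  g <- classify_groups(ids)
  recent <- g$group[g$id %in% fam$records$id]
  old <- g$group[g$id %in% bg$id]
  expect_true(all(recent == "group1"))
  expect_true(all(old == "group2"))
})
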