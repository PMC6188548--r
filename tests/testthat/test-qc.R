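# Alignment QC gates: the stated sequence filters in their stated order,
# codon-aware column trimming, the strict length gate, the taxon gate,
# and pruning with path-length preservation.

test_that("sequence QC applies the filters in order", {
  recs <- c(
    highN = paste0(strrep("ATG", 47), strrep("N", 160)),  # 301nt -> pad, 53% N
    ok = strrep("ATGAAACCC", 20),                          # 180 nt clean
    odd = paste0(strrep("ATGAAACCC", 16), "ATGAAACCCA"),   # 154 nt -> pad 2 N
    stopin = paste0("ATGTAA", strrep("ATGAAA", 30)),       # internal TAA
    short = strrep("ATG", 49))                             # 147 nt < 150
  q <- qc_sequences(recs)
  expect_setequal(names(q$records), c("ok", "odd"))
  expect_equal(nchar(q$records[["odd"]]) %% 3, 0)
  expect_identical(substr(q$records[["odd"]], 155, 156), "NN")
  rules <- q$report$rule[match(c("highN", "stopin", "short"), q$report$id)]
  expect_identical(rules, c("missing_data_gt_50pct", "internal_stop_codon",
                            "shorter_than_150nt"))
  # a terminal stop codon is not an internal stop
  recs2 <- c(endstop = paste0(strrep("ATGAAA", 30), "TAA"))
  expect_identical(names(qc_sequences(recs2)$records), "endstop")
})

test_that("alignment QC trims gap-majority codon columns and gates length", {
  base <- random_codon_alignment(10, 120, seed = 4, miss = 0)
  aln <- base
  aln[1:6, 5] <- "---"          # 6 of 10 gapped: remove
  aln[1:5, 7] <- "---"          # exactly half: keep
  q <- qc_alignment(aln)
  expect_true(q$keep)
  expect_identical(ncol(q$aln), 119L)
  expect_false(5 %in% q$kept_columns)
  expect_true(7 %in% q$kept_columns)
  # idempotence
  q2 <- qc_alignment(q$aln)
  expect_identical(q2$aln, q$aln)
  # alignments of exactly 100 codons are discarded (strict inequality)
  q3 <- qc_alignment(base[, 1:100])
  expect_false(q3$keep)
  q4 <- qc_alignment(base[, 1:101])
  expect_true(q4$keep)
  # sequences left with < 50 non-gap codons are removed
  aln5 <- base
  aln5[1, 1:75] <- "---"
  q5 <- qc_alignment(aln5)
  expect_false(rownames(base)[1] %in% rownames(q5$aln))
  expect_true("shorter_than_50_codons_post_trim" %in% q5$report$rule)
})

test_that("the taxon gate applies the three exclusion rules in order", {
  focal <- c("f1", "f2"); outg <- c("o1", "o2")
  expect_identical(taxon_gate(c("f1", "x", "y"), focal, outg)$reason,
                   "no_outgroup")
  expect_identical(taxon_gate(c("o1", "a", "b", "c", "d"), focal, outg)$reason,
                   "no_focal")
  expect_identical(taxon_gate(c("f1", "o1", "x"), focal, outg)$reason,
                   "fewer_than_4_taxa")
  expect_true(taxon_gate(c("f1", "o1", "x", "y"), focal, outg)$include)
})

test_that("pruning preserves path lengths and recovers the focal stem", {
  tree <- study_tree(seed = 5)
  clades <- study_clades()
  aln <- random_codon_alignment(41, 110, seed = 5, miss = 0)
  rownames(aln) <- tree$tip.label
  pr <- prune_dataset(aln, tree, clades$B)
  expect_true(pr$gate$include)
  expect_setequal(rownames(pr$aln), clades$B$prune_to)
  d_full <- ape::cophenetic.phylo(tree)
  d_sub <- ape::cophenetic.phylo(pr$tree)
  tx <- rownames(d_sub)
  expect_equal(d_sub, d_full[tx, tx], tolerance = 1e-12)
  # the tag marks the mole-rat stem
  e <- tagged_edge(pr$tree, "1")
  expect_setequal(clade_members_of(pr$tree, pr$tree$edge[e, 2]),
                  clades$B$members)
  # pruning to all taxa keeps every path length
  prall <- prune_tree(tree, tree$tip.label)
  expect_equal(ape::cophenetic.phylo(prall), d_full, tolerance = 1e-12)
  # a gene with no focal taxa is excluded
  aln2 <- aln[setdiff(rownames(aln), clades$B$members), ]
  pr2 <- prune_dataset(aln2, tree, clades$B)
  expect_false(pr2$gate$include)
})
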