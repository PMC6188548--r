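# Convergence-scan operations: ancestral-branch selection, the sitewise
# parallel/convergent decomposition, gene-level thresholds, and the
# branch-length trend.

test_that("the most ancestral comparable branch is the clade stem", {
  tr <- study_tree(seed = 2)
  clades <- study_clades()
  # all 8 mole-rats present: stem of the full clade
  e <- select_ancestral_branch(tr, clades$B$members)
  expect_setequal(clade_members_of(tr, tr$edge[e, 2]), clades$B$members)
  # only one golden mole present in the pruned tree: its terminal branch
  tr2 <- prune_tree(tr, c("goldenmole1", "tenrec", "elephant", "human"))
  e2 <- select_ancestral_branch(tr2, clades$A$members)
  expect_identical(tr2$edge[e2, 2], match("goldenmole1", tr2$tip.label))
  # 2 of 4 spalacids present: stem of their 2-taxon MRCA
  tr3 <- prune_tree(tr, c("spalacid1", "spalacid3", "mouse", "rat", "human"))
  e3 <- select_ancestral_branch(tr3, clades$C$members)
  expect_setequal(clade_members_of(tr3, tr3$edge[e3, 2]),
                  c("spalacid1", "spalacid3"))
  expect_error(select_ancestral_branch(tr3, c("zebra")), "no clade member")
})

test_that("sitewise PPs decompose point-mass joints correctly", {
  ns <- 20
  iL <- match("L", AA_ORDER); iV <- match("V", AA_ORDER)
  iI <- match("I", AA_ORDER)
  point <- function(a, x) {
    J <- array(0, c(ns, ns, 1)); J[a, x, 1] <- 1; J
  }
  # both branches L -> V: pure parallel
  pp <- site_convergence_pp(point(iL, iV), point(iL, iV))
  expect_equal(pp$pp_parallel, 1)
  expect_equal(pp$pp_convergent, 0)
  expect_equal(pp$pp_total, 1)
  # L -> V versus I -> V: pure convergent
  pp <- site_convergence_pp(point(iL, iV), point(iI, iV))
  expect_equal(pp$pp_parallel, 0)
  expect_equal(pp$pp_convergent, 1)
  # different derived states: nothing
  pp <- site_convergence_pp(point(iL, iV), point(iL, iI))
  expect_equal(pp$pp_total, 0)
  # unnormalised input is an error
  expect_error(site_convergence_pp(point(iL, iV) * 0.5, point(iL, iV)),
               "not normalised")
})

test_that("pp_total vanishes with no substitutions (short branches)", {
  tr <- parse_newick("(((A:1e-8,B:1e-8)#b1:1e-8,C:1e-8):1e-8,(D:1e-8,E:1e-8)#b2:1e-8);")
  mod <- dayhoff_model()
  aln <- matrix(rep(c("K", "K", "K", "K", "K"), 4), 5, 4,
                dimnames = list(LETTERS[1:5], NULL))
  enc <- encode_alignment(aln, "protein")
  J1 <- branch_joint_posterior(enc, tr, mod, tagged_edge(tr, "b1"))
  J2 <- branch_joint_posterior(enc, tr, mod, tagged_edge(tr, "b2"))
  pp <- site_convergence_pp(J1, J2)
  expect_lt(max(pp$pp_total), 1e-6)
})

test_that("parallel + convergent equals total at every site", {
  tr <- eight_taxon_tree(fg = FALSE)
  tr <- tag_clade_stem(tr, c("C", "D"), "b1")
  tr <- tag_clade_stem(tr, c("E", "F"), "b2")
  mod <- dayhoff_model()
  sim <- simulate_gene(tr, mod, 150, seed = 12)
  enc <- encode_alignment(sim$aln, "protein")
  J1 <- branch_joint_posterior(enc, tr, mod, tagged_edge(tr, "b1"))
  J2 <- branch_joint_posterior(enc, tr, mod, tagged_edge(tr, "b2"))
  pp <- site_convergence_pp(J1, J2)
  expect_equal(pp$pp_parallel + pp$pp_convergent, pp$pp_total,
               tolerance = 1e-12)
  expect_true(all(pp$pp_total >= 0 & pp$pp_total <= 1))
  # summed PP is additive over disjoint site blocks
  s1 <- gene_convergence_summary(pp[1:70, ])$summed_pp_total
  s2 <- gene_convergence_summary(pp[71:150, ])$summed_pp_total
  expect_equal(s1 + s2, gene_convergence_summary(pp)$summed_pp_total,
               tolerance = 1e-12)
})

test_that("gene summaries implement the two-tier threshold rule", {
  mk <- function(pps) data.frame(site = seq_along(pps), pp_parallel = pps / 2,
                                 pp_convergent = pps / 2, pp_total = pps)
  g <- gene_convergence_summary(mk(c(0.6, 0.6)))
  expect_true(g$flag_1.0); expect_false(g$flag_2.0)
  expect_identical(g$n_sites_pp_gt_half, 2L)
  g <- gene_convergence_summary(mk(rep(0.3, 4)))
  expect_true(g$flag_1.0)
  expect_identical(g$n_sites_pp_gt_half, 0L)  # excluded from the retained tier
  g <- gene_convergence_summary(mk(numeric(0)))
  expect_false(g$flag_1.0); expect_false(g$flag_2.0)
  expect_equal(g$summed_pp_total, 0)
})

test_that("the product form matches the exact endpoint joint (>= 2 edges apart)", {
  tr <- parse_newick(paste0("(((A:0.08,B:0.1)#b1:0.09,C:0.12):0.07,",
                            "((D:0.07,E:0.1)#b2:0.11,F:0.09):0.06);"))
  mod <- dayhoff_model()
  sim <- simulate_gene(tr, mod, 8, seed = 11)
  enc <- encode_alignment(sim$aln, "protein")
  e1 <- tagged_edge(tr, "b1"); e2 <- tagged_edge(tr, "b2")
  J1 <- branch_joint_posterior(enc, tr, mod, e1)
  J2 <- branch_joint_posterior(enc, tr, mod, e2)
  pp <- site_convergence_pp(J1, J2)
  ex <- site_convergence_pp_exact(enc, tr, mod, e1, e2)
  expect_equal(pp$pp_total, ex$pp_total, tolerance = 1e-3)
  expect_equal(pp$pp_parallel, ex$pp_parallel, tolerance = 1e-3)
})

test_that("branch pairs in ancestor-descendant relation are rejected", {
  tr <- eight_taxon_tree(fg = FALSE)
  tr <- tag_clade_stem(tr, c("A", "B", "C", "D"), "anc")
  tr <- tag_clade_stem(tr, c("C", "D"), "desc")
  expect_error(
    subterra:::check_branch_pair(tr, tagged_edge(tr, "anc"),
                                 tagged_edge(tr, "desc")),
    "overlaps")
})

test_that("the branch-length trend statistic behaves on edge cases", {
  tr <- convergence_vs_branchlength(c(2, 5, 11), c(0.05, 0.2, 0.8))
  expect_equal(tr$spearman, 1)
  expect_gt(tr$slope, 0)
  flat <- convergence_vs_branchlength(c(4, 4, 4), c(0.1, 0.2, 0.3))
  expect_equal(flat$spearman, 0)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_error(convergence_vs_branchlength(c(1, 2), c(0.1, 0.2)),
               "at least 3")
  degen <- convergence_vs_branchlength(c(1, 2, 3), c(0.1, 0.1, 0.1))
  expect_true(degen$degenerate)
})
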