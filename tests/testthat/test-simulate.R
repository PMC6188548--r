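# Synthetic-data generators: determinism, degenerate limits, injection
# bookkeeping, missingness, and the GO universe contract.

test_that("simulation is a pure function of (specification, seed)", {
  tr <- eight_taxon_tree()
  mix <- site_mixture()
  s1 <- simulate_gene(tr, mix, 60, seed = 123)
  s2 <- simulate_gene(tr, mix, 60, seed = 123)
  expect_identical(s1$aln, s2$aln)
  expect_identical(s1$classes, s2$classes)
  s3 <- simulate_gene(tr, mix, 60, seed = 124)
  expect_false(identical(s1$aln, s3$aln))
})

test_that("zero branch lengths copy the root state to every tip", {
  tr <- eight_taxon_tree()
  tr$edge.length[] <- 0
  sim <- simulate_gene(tr, site_mixture(), 30, seed = 5)
  for (i in 2:nrow(sim$aln))
    expect_identical(sim$aln[i, ], sim$aln[1, ])
})

test_that("class frequencies follow the mixture proportions", {
  tr <- eight_taxon_tree()
  mix <- site_mixture(p0 = 0.5, p1 = 0.3, omega0 = 0.2, omega2 = 2)
  sim <- simulate_gene(tr, mix, 4000, seed = 8)
  freq <- tabulate(sim$classes, 4) / 4000
  expect_equal(freq, mix$weights, tolerance = 0.05)
})

test_that("injection forces the target amino acid and keeps its books", {
  tr <- eight_taxon_tree(fg = FALSE)
  tr <- tag_clade_stem(tr, c("C", "D"), "b1")
  tr <- tag_clade_stem(tr, c("G", "H"), "b2")
  sim <- simulate_gene(tr, site_mixture(), 200, seed = 21, foreground = NULL)
  sim$tree <- tr
  inj <- inject_convergent_sites(sim, c("b1", "b2"), 6, "parallel", seed = 3)
  expect_identical(nrow(inj$injected), 6L)
  tab <- codon_table()
  for (i in seq_len(6)) {
    st <- inj$injected$site[i]
    v1 <- tr$edge[tagged_edge(tr, "b1"), 2]
    v2 <- tr$edge[tagged_edge(tr, "b2"), 2]
    expect_identical(tab$aa[inj$node_states[v1, st]], inj$injected$target_aa[i])
    expect_identical(tab$aa[inj$node_states[v2, st]], inj$injected$target_aa[i])
    # parallel mode: equal ancestral amino acids, different from the target
    u1 <- tr$edge[tagged_edge(tr, "b1"), 1]
    u2 <- tr$edge[tagged_edge(tr, "b2"), 1]
    expect_identical(tab$aa[sim$node_states[u1, st]],
                     tab$aa[sim$node_states[u2, st]])
    expect_false(tab$aa[sim$node_states[u1, st]] == inj$injected$target_aa[i])
  }
  # untouched lineages keep their states
  other <- setdiff(seq_len(nrow(sim$aln)), match(c("C","D","G","H"), rownames(sim$aln)))
  expect_identical(inj$aln[other, ], sim$aln[other, ])
  # n_sites = 0 leaves the alignment unchanged
  inj0 <- inject_convergent_sites(sim, c("b1", "b2"), 0, "parallel", seed = 3)
  expect_identical(inj0$aln, sim$aln)
  # convergent mode uses different ancestors
  injc <- inject_convergent_sites(sim, c("b1", "b2"), 4, "convergent", seed = 5)
  for (i in 1:4) {
    st <- injc$injected$site[i]
    u1 <- tr$edge[tagged_edge(tr, "b1"), 1]
    u2 <- tr$edge[tagged_edge(tr, "b2"), 1]
    expect_false(tab$aa[sim$node_states[u1, st]] ==
                   tab$aa[sim$node_states[u2, st]])
  }
})

test_that("missingness is seeded, bounded, and honours the keep list", {
  tr <- eight_taxon_tree()
  alns <- lapply(1:12, function(i)
    simulate_gene(tr, site_mixture(), 10, seed = i)$aln)
  a0 <- apply_missingness(alns, 0, seed = 1)
  expect_identical(a0, alns)
  a1 <- apply_missingness(alns, 0.45, seed = 2, keep = "A")
  a1b <- apply_missingness(alns, 0.45, seed = 2, keep = "A")
  expect_identical(a1, a1b)
  expect_true(all(vapply(a1, function(x) "A" %in% rownames(x), logical(1))))
  # heavy dropout usually violates the 4-taxon gate
  a2 <- apply_missingness(alns, 0.9, seed = 3)
  expect_gt(mean(vapply(a2, nrow, integer(1)) < 4), 0.5)
})

test_that("the GO universe generator satisfies the propagation closure", {
  u <- simulate_go_universe(n_genes = 120, n_terms = 25, depth = 3,
                            enriched = c(T005 = 6), study_size = 30, seed = 9)
  g <- u$graph
  for (t0 in g$terms) {
    for (ch in g$children[[t0]])
      expect_true(all(g$term_genes[[ch]] %in% g$term_genes[[t0]]))
  }
  expect_true(all(u$study %in% g$genes))
  expect_identical(u$truth, "T005")
})

test_that("with no enrichment the classic Fisher test is calibrated", {
  u <- simulate_go_universe(n_genes = 400, n_terms = 30, depth = 3,
                            enriched = NULL, study_size = 60, seed = 30)
  # study drawn uniformly: per-term type-I error at 0.05 stays near nominal
  set.seed(31)
  rates <- replicate(40, {
    study <- sample(u$graph$genes, 60)
    res <- go_enrichment(study, u$graph, "classic")
    mean(res$p < 0.05)
  })
  expect_lte(mean(rates), 0.05 + 3 * sqrt(0.05 * 0.95 / (40 * 30)))
})

test_that("study fixtures are reproducible and complete", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- make_study_fixture(d1, n_genes = 4, n_codons = 110,
                            sel_fraction = 0.25, inj_fraction = 0.25,
                            seed = 17)
  fx2 <- make_study_fixture(d2, n_genes = 4, n_codons = 110,
                            sel_fraction = 0.25, inj_fraction = 0.25,
                            seed = 17)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_identical(nrow(fx1$truth_genes), 4L)
  expect_true(file.exists(file.path(d1, "tree.nwk")))
  expect_identical(sum(fx1$truth_genes$selected), 1L)
  expect_identical(sum(!is.na(fx1$truth_genes$injected_pair)), 1L)
})
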