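# Pruning likelihood against closed forms, exhaustive enumeration, an
# independent phangorn fit, and the reversibility (re-rooting) invariance.

test_that("two-taxon likelihood matches the closed form", {
  m <- dayhoff_model()
  tr <- parse_newick("(A:0.1,B:0.3);")
  aln <- matrix(c("L", "V"), 2, 1, dimnames = list(c("A", "B"), NULL))
  ll <- log_likelihood(aln, tr, m)
  P1 <- transition_matrix(m, 0.1); P2 <- transition_matrix(m, 0.3)
  iL <- match("L", AA_ORDER); iV <- match("V", AA_ORDER)
  expect_equal(ll$total, log(sum(m$freqs * P1[, iL] * P2[, iV])),
               tolerance = 1e-12)
})

test_that("all-gap and all-missing columns contribute zero log-likelihood", {
  m <- dayhoff_model()
  tr <- parse_newick("((A:0.1,B:0.2):0.1,C:0.15);")
  aln <- matrix(c("L", "V", "I", "-", "-", "-", "X", "-", "X"), 3, 3,
                dimnames = list(c("A", "B", "C"), NULL))
  ll <- log_likelihood(aln, tr, m)
  expect_equal(ll$site_ll[2], 0, tolerance = 1e-12)
  expect_equal(ll$site_ll[3], 0, tolerance = 1e-12)
})

test_that("pruning equals exhaustive enumeration on random aa instances", {
  m <- dayhoff_model()
  for (seed in 1:8) {
    ntaxa <- 4 + seed %% 2
    tr <- random_tree(ntaxa, seed)
    aln <- random_aa_alignment(ntaxa, 12, seed + 100, miss = 0.08)
    ll <- log_likelihood(aln, tr, m)$total
    expect_equal(ll, oracle_loglik(aln, tr, m), tolerance = 1e-10)
  }
})

test_that("pruning equals exhaustive enumeration on random codon instances", {
  f <- default_codon_freqs()
  cm <- codon_model(2, 0.4, f)
  for (seed in 1:3) {
    tr <- random_tree(4, seed)
    aln <- random_codon_alignment(4, 6, seed + 50, miss = 0.1)
    ll <- log_likelihood(aln, tr, cm)$total
    # enumeration over internal states with the package's P(t) isolates the
    # pruning sum itself at full precision ...
    expect_equal(ll, oracle_loglik(aln, tr, cm, use_pkg_pmat = TRUE),
                 tolerance = 1e-10)
    # ... and the independent expm-based oracle agrees to its own accuracy
    expect_equal(ll, oracle_loglik(aln, tr, cm), tolerance = 1e-7)
  }
})

test_that("likelihood is invariant to re-rooting (reversible model)", {
  m <- dayhoff_model()
  tr <- random_tree(6, 3)
  aln <- random_aa_alignment(6, 25, 9, miss = 0)
  ll0 <- log_likelihood(aln, tr, m)$total
  for (out in c("t1", "t4")) {
    tr2 <- ape::root(ape::unroot(tr), outgroup = out, resolve.root = TRUE)
    tr2$edge.tag <- NULL
    ll2 <- log_likelihood(aln, tr2, m)$total
    expect_equal(ll2, ll0, tolerance = 1e-8)
  }
})

test_that("mixture likelihood is the weighted average of class likelihoods", {
  f <- default_codon_freqs()
  m1 <- codon_model(2, 0.1, f)
  m2 <- codon_model(2, 1.5, f)
  tr <- random_tree(5, 4)
  aln <- random_codon_alignment(5, 10, 77, miss = 0)
  l1 <- log_likelihood(aln, tr, m1)$site_ll
  l2 <- log_likelihood(aln, tr, m2)$site_ll
  lm <- log_likelihood(aln, tr, list(m1, m2), weights = c(0.3, 0.7))$site_ll
  expect_equal(lm, log(0.3 * exp(l1) + 0.7 * exp(l2)), tolerance = 1e-10)
})

test_that("alignment taxa must be a subset of the tree", {
  m <- dayhoff_model()
  tr <- parse_newick("(A:0.1,B:0.3);")
  aln <- matrix(c("L", "V"), 2, 1, dimnames = list(c("A", "Z"), NULL))
  expect_error(log_likelihood(aln, tr, m), "Z")
})

test_that("Dayhoff likelihood agrees with phangorn on a fixture", {
  skip_if_not_installed("phangorn")
  tr <- random_tree(6, 21)
  aln <- random_aa_alignment(6, 40, 22, miss = 0)
  pd <- phangorn::phyDat(aln, type = "AA")
  fitp <- phangorn::pml(tr, pd, model = "Dayhoff",
                        bf = dayhoff_model()$freqs)
  ours <- log_likelihood(aln, tr, dayhoff_model())$total
  expect_equal(ours, as.numeric(fitp$logLik), tolerance = 1e-6)
})
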