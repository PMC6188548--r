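# Branch-site Model A machinery: nesting, the LRT, empirical-Bayes site
# posteriors, PSS calling gates, the aggregated-PSS filter and BH FDR.

# one moderately sized fit shared across blocks
sel_fixture <- local({
  tr <- eight_taxon_tree()
  mix <- site_mixture(p0 = 0.425, p1 = 0.425, omega0 = 0.1, omega2 = 4)
  sim <- simulate_gene(tr, mix, 300, seed = 7)
  freqs <- codon_frequencies(sim$aln)
  m0 <- fit_m0(encode_alignment(sim$aln, "codon"), tr, freqs)
  f0 <- fit_model_a_null(sim$aln, tr, "1", freqs, m0)
  f1 <- fit_model_a(sim$aln, tr, "1", freqs, m0)
  list(tr = tr, sim = sim, f0 = f0, f1 = f1)
})

test_that("null fixes omega2 at 1 and is nested in the alternative", {
  expect_identical(sel_fixture$f0$omega2, 1)
  expect_gte(sel_fixture$f1$loglik, sel_fixture$f0$loglik)
  # class proportions are a distribution with the Model A structure
  for (f in list(sel_fixture$f0, sel_fixture$f1)) {
    w <- c(f$p0, f$p1, f$p2a, f$p2b)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_equal(f$p2a / f$p2b, f$p0 / f$p1, tolerance = 1e-6)
    expect_lt(f$omega0, 1)
  }
  expect_gte(sel_fixture$f1$omega2, 1)
})

test_that("the LRT follows the chi-square(1) reference", {
  expect_equal(branch_site_lrt(-100, -100)$p_value, 1)
  expect_equal(branch_site_lrt(-100, -100)$statistic, 0)
  lrt <- branch_site_lrt(-100, -100 + 3.841459 / 2)
  expect_equal(lrt$p_value, 0.05, tolerance = 1e-6)
  expect_equal(branch_site_lrt(-100, -97)$p_value,
               stats::pchisq(6, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(branch_site_lrt(-100, -97)$p_value, 0.01430588,
               tolerance = 1e-6)
  expect_warning(r <- branch_site_lrt(-100, -100.5), "clamp")
  expect_equal(r$statistic, 0)
})

# per-site class log-likelihood with fg omega on the tagged branch,
# computed via a two-model edge list (independent of bs_context)
ll_two_part <- function(aln, tr, bg_model, fg_model, s) {
  fg_edge <- tagged_edge(tr, "1")
  enc <- encode_alignment(aln, "codon")
  P <- lapply(seq_len(nrow(tr$edge)), function(e)
    transition_matrix(if (e == fg_edge) fg_model else bg_model,
                      tr$edge.length[e] * s))
  up <- subterra:::peel_up(enc, tr, P)
  ll <- subterra:::root_loglik_patterns(enc, tr, up, bg_model$freqs)
  ll[enc$pattern_of_site]
}

test_that("NEB posteriors follow the plug-in mixture formula", {
  f1 <- sel_fixture$f1
  neb <- eb_site_posteriors(f1, "NEB")
  expect_true(all(neb >= 0 & neb <= 1))
  # per-site class posteriors sum to one
  expect_equal(colSums(f1$site_post_neb), rep(1, f1$n_sites),
               tolerance = 1e-9)
  # hand-computed on a 4-taxon toy: p_k L_k / sum p_j L_j
  tr <- parse_newick("((A:0.1,B:0.1)#1:0.05,(C:0.1,D:0.1):0.05);")
  mix <- site_mixture(p0 = 0.4, p1 = 0.4, omega0 = 0.2, omega2 = 3)
  sim <- simulate_gene(tr, mix, 40, seed = 3)
  freqs <- codon_frequencies(sim$aln)
  m0 <- fit_m0(encode_alignment(sim$aln, "codon"), tr, freqs)
  fit <- fit_model_a(sim$aln, tr, "1", freqs, m0)
  w <- c(fit$p0, fit$p1, fit$p2a, fit$p2b)
  # recompute class likelihoods directly with independent mixture calls
  s <- fit$tree_scale /
    codon_model(fit$kappa, m0$omega, freqs, scale = FALSE)$rate
  mods <- list(
    bg = codon_model(fit$kappa, fit$omega0, freqs, scale = FALSE),
    neu = codon_model(fit$kappa, 1, freqs, scale = FALSE),
    fg = codon_model(fit$kappa, fit$omega2, freqs, scale = FALSE))
  Lk <- sapply(1:4, function(k) {
    bg <- if (k %in% c(1, 3)) mods$bg else mods$neu
    fg <- if (k <= 2) bg else mods$fg
    ll_two_part(sim$aln, tr, bg, fg, s)
  })
  neb2 <- sapply(seq_len(nrow(Lk)), function(i) {
    li <- exp(Lk[i, ] - max(Lk[i, ]))
    sum(w[3:4] * li[3:4]) / sum(w * li)
  })
  expect_equal(unname(eb_site_posteriors(fit, "NEB")), neb2,
               tolerance = 1e-8)
})

test_that("BEB is bounded, correlates with NEB, and flags injected sites", {
  f1 <- sel_fixture$f1
  beb <- eb_site_posteriors(f1, "BEB")
  neb <- eb_site_posteriors(f1, "NEB")
  expect_true(all(beb >= 0 & beb <= 1))
  expect_gt(stats::cor(beb, neb), 0.8)
  true2 <- which(sel_fixture$sim$classes >= 3)
  expect_gt(mean(beb[true2]), mean(beb[-true2]))
})

test_that("PSS calling applies all three gates and ignores input order", {
  f1 <- sel_fixture$f1
  lrt_sig <- branch_site_lrt(-1000, -990)     # p ~ 7.7e-6
  lrt_ns <- branch_site_lrt(-1000, -999.5)
  pps <- rep(0, f1$n_sites)
  pps[c(7, 9)] <- c(0.93, 0.40)
  expect_identical(call_pss(lrt_sig, f1, pps), 7L)
  expect_identical(call_pss(lrt_ns, f1, pps), integer(0))
  f1_null_omega <- f1; f1_null_omega$omega2 <- 1
  expect_identical(call_pss(lrt_sig, f1_null_omega, pps), integer(0))
  # permutation invariance: order of sites in the PP vector is positional,
  # shuffling which sites carry high PPs permutes the calls accordingly
  pps2 <- rep(0, f1$n_sites)
  pps2[c(9, 7)] <- c(0.93, 0.40)
  expect_identical(call_pss(lrt_sig, f1, pps2), 9L)
})

test_that("the aggregated-PSS filter follows the median-interval rule", {
  r <- pss_aggregation_filter(c(10, 15, 22))
  expect_false(r$retain)
  expect_equal(r$median_interval, 6)
  r <- pss_aggregation_filter(c(5, 40, 100))
  expect_true(r$retain)
  expect_equal(r$median_interval, 47.5)
  expect_true(pss_aggregation_filter(12)$retain)
  expect_true(pss_aggregation_filter(integer(0))$retain)
  # boundary: median exactly 10 is excluded
  expect_false(pss_aggregation_filter(c(10, 20, 30))$retain)
  # unsorted input is tolerated
  expect_false(pss_aggregation_filter(c(22, 10, 15))$retain)
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(rep(0.05, 4)), rep(0.05, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.02, 0.03, 0.8)
  expect_true(all(bh_fdr(p) >= p))
  expect_false(is.unsorted(bh_fdr(sort(p))))
})
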