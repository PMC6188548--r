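# Calibration and validation experiments: null LRT calibration, selection
# power and site recovery, convergence-injection detection, and the
# neutral branch-length/convergence trend. These drive the package's
# simulation-based validation and are reused by the acceptance script.

#' Default 8-taxon experiment trees
#'
#' `default_selection_tree()`: balanced 8-taxon tree with the foreground
#' tag on an internal clade stem (tag `"1"`). `default_pair_tree(t)`:
#' 6-taxon tree with two non-overlapping tagged branches (`"b1"`, `"b2"`)
#' of length `t` and short (0.05) peripheral branches, so the branch
#' endpoints are well resolved.
#'
#' @param t compared-branch length.
#' @return `phylo` with `edge.tag`.
#' @export
default_selection_tree <- function() {
  parse_newick(paste0("(((A:0.1,B:0.1):0.05,(C:0.1,D:0.1)#1:0.08):0.05,",
                      "((E:0.1,F:0.1):0.05,(G:0.1,H:0.1):0.05):0.05);"))
}

#' @rdname default_selection_tree
#' @export
default_pair_tree <- function(t = 0.1) {
  parse_newick(sprintf(
    "(((A:0.05,B:0.05)#b1:%g,C:0.05):0.05,((D:0.05,E:0.05)#b2:%g,F:0.05):0.05);",
    t, t))
}

#' Null calibration of the branch-site LRT
#'
#' Simulates genes under the null Model A (omega2 = 1), fits the
#' alternative and null models, and reports the rejection rate at
#' p < 0.05 — expected to be at or below the nominal level (the test is
#' conservative because omega2 sits on the boundary under the null).
#'
#' @param n_genes,n_codons simulation size (defaults: 200 genes of 500
#'   codons on 8 taxa, the package's reference calibration conditions).
#' @param seed master seed.
#' @param tree tagged tree (default [default_selection_tree()]).
#' @param mix null site-class mixture.
#' @return list: per-gene `results` data frame, `rejection_rate`, `n`.
#' @export
calibrate_null_lrt <- function(n_genes = 200, n_codons = 500, seed = 1,
                               tree = default_selection_tree(),
                               mix = site_mixture()) {
  stopifnot(mix$omega2 == 1)
  set.seed(seed)
  seeds <- sample.int(2^30, n_genes)
  rows <- lapply(seq_len(n_genes), function(g) {
    sim <- simulate_gene(tree, mix, n_codons, seed = seeds[g])
    freqs <- codon_frequencies(sim$aln)
    enc <- encode_alignment(sim$aln, "codon")
    m0 <- fit_m0(enc, tree, freqs)
    f0 <- fit_model_a_null(sim$aln, tree, "1", freqs, m0)
    f1 <- fit_model_a(sim$aln, tree, "1", freqs, m0)
    lrt <- branch_site_lrt(f0, f1)
    data.frame(gene = g, stat = lrt$statistic, p = lrt$p_value,
               omega2 = f1$omega2)
  })
  res <- do.call(rbind, rows)
  list(results = res, rejection_rate = mean(res$p < 0.05), n = n_genes)
}

#' Power and site recovery under foreground selection
#'
#' Simulates genes with omega2 on the foreground branch at a fraction of
#' sites (classes 2a/2b), runs the full test, and pools empirical-Bayes
#' site calls against the simulated truth.
#'
#' @param n_genes,n_codons simulation size (defaults: 50 genes of 1000
#'   codons).
#' @param omega2 foreground omega (default 4).
#' @param prop2 total proportion of 2a/2b sites (default 0.15).
#' @param seed master seed.
#' @param tree tagged tree.
#' @param eb_method site-call method for rejected genes.
#' @return list: per-gene `results`, `rejection_rate`, pooled site-call
#'   2x2 `site_table` (called x truth) over rejected genes, and the
#'   one-sided Fisher `site_p` for enrichment of true class-2 sites among
#'   calls.
#' @export
power_experiment <- function(n_genes = 50, n_codons = 1000, omega2 = 4,
                             prop2 = 0.15, seed = 1,
                             tree = default_selection_tree(),
                             eb_method = "BEB") {
  p01 <- (1 - prop2) / 2
  mix <- site_mixture(p0 = p01, p1 = p01, omega0 = 0.1, omega2 = omega2)
  set.seed(seed)
  seeds <- sample.int(2^30, n_genes)
  tab <- matrix(0, 2, 2, dimnames = list(called = c("yes", "no"),
                                         true2 = c("yes", "no")))
  rows <- lapply(seq_len(n_genes), function(g) {
    sim <- simulate_gene(tree, mix, n_codons, seed = seeds[g])
    freqs <- codon_frequencies(sim$aln)
    enc <- encode_alignment(sim$aln, "codon")
    m0 <- fit_m0(enc, tree, freqs)
    f0 <- fit_model_a_null(sim$aln, tree, "1", freqs, m0)
    f1 <- fit_model_a(sim$aln, tree, "1", freqs, m0)
    lrt <- branch_site_lrt(f0, f1)
    called <- rep(FALSE, n_codons)
    if (lrt$p_value < 0.05 && f1$omega2 > 1) {
      pps <- eb_site_posteriors(f1, eb_method)
      called[call_pss(lrt, f1, pps)] <- TRUE
    }
    true2 <- sim$classes >= 3
    data.frame(gene = g, p = lrt$p_value, omega2 = f1$omega2,
               n_called = sum(called),
               called_true = sum(called & true2),
               called_false = sum(called & !true2),
               n_true2 = sum(true2))
  })
  res <- do.call(rbind, rows)
  rej <- res$p < 0.05
  tab["yes", "yes"] <- sum(res$called_true[rej])
  tab["yes", "no"] <- sum(res$called_false[rej])
  tab["no", "yes"] <- sum(res$n_true2[rej]) - tab["yes", "yes"]
  tab["no", "no"] <- sum(rej) * n_codons - sum(tab)
  site_p <- if (sum(tab["yes", ]) > 0)
    stats::fisher.test(tab, alternative = "greater")$p.value else NA_real_
  list(results = res, rejection_rate = mean(rej), site_table = tab,
       site_p = site_p, n = n_genes)
}

#' Detection of injected parallel substitutions
#'
#' Simulates neutral codon genes, injects parallel substitutions on the
#' tagged branch pair, runs the Dayhoff convergence scan, and compares
#' sitewise total PPs at injected versus background sites.
#'
#' @param n_genes,n_codons,n_inject experiment size (defaults 20 x 300
#'   with 5 injected sites per gene).
#' @param t compared-branch length (default 0.1).
#' @param seed master seed.
#' @return list: pooled `mean_injected`, `mean_background`, their
#'   `ratio`, `frac_injected_above_half`, and the per-site records.
#' @export
convergence_detection_experiment <- function(n_genes = 20, n_codons = 300,
                                             n_inject = 5, t = 0.1,
                                             seed = 1) {
  tree <- default_pair_tree(t)
  mod <- dayhoff_model()
  set.seed(seed)
  seeds <- sample.int(2^30, n_genes)
  inj_pp <- c(); bg_pp <- c()
  for (g in seq_len(n_genes)) {
    sim <- simulate_gene(tree, site_mixture(), n_codons, seed = seeds[g],
                         foreground = NULL)
    sim$tree <- tree
    sim <- inject_convergent_sites(sim, c("b1", "b2"), n_inject,
                                   mode = "parallel", seed = seeds[g] + 1L)
    enc <- encode_alignment(translate_codons(sim$aln), "protein")
    fit <- fit_branch_lengths(enc, tree, mod)
    J1 <- branch_joint_posterior(enc, fit$tree, mod, tagged_edge(tree, "b1"))
    J2 <- branch_joint_posterior(enc, fit$tree, mod, tagged_edge(tree, "b2"))
    pp <- site_convergence_pp(J1, J2)
    inj <- sim$injected$site
    inj_pp <- c(inj_pp, pp$pp_total[inj])
    bg_pp <- c(bg_pp, pp$pp_total[-inj])
  }
  list(mean_injected = mean(inj_pp), mean_background = mean(bg_pp),
       ratio = mean(inj_pp) / max(mean(bg_pp), 1e-12),
       frac_injected_above_half = mean(inj_pp > 0.5),
       n_injected_sites = length(inj_pp))
}

#' Neutral convergence versus branch length trend
#'
#' Simulates neutral protein genes under Dayhoff over a grid of
#' compared-branch lengths and counts sites with total convergence
#' PP > 0.5 per gene; reports the rank correlation of the count with the
#' branch length.
#'
#' @param grid compared-branch lengths (5 points by default).
#' @param genes_per_point genes per grid point (default 50).
#' @param n_sites protein sites per gene (default 250).
#' @param seed master seed.
#' @return list: `results` (t, gene, count, summed), `spearman`,
#'   `p_value` (one-sided, positive association), and the per-point mean
#'   counts.
#' @export
branchlength_trend_experiment <- function(grid = c(0.05, 0.1, 0.2, 0.4, 0.8),
                                          genes_per_point = 50,
                                          n_sites = 250, seed = 1) {
  mod <- dayhoff_model()
  set.seed(seed)
  seeds <- matrix(sample.int(2^30, length(grid) * genes_per_point),
                  nrow = length(grid))
  rows <- list()
  for (gi in seq_along(grid)) {
    tree <- default_pair_tree(grid[gi])
    for (g in seq_len(genes_per_point)) {
      sim <- simulate_gene(tree, mod, n_sites, seed = seeds[gi, g])
      enc <- encode_alignment(sim$aln, "protein")
      fit <- fit_branch_lengths(enc, tree, mod)
      J1 <- branch_joint_posterior(enc, fit$tree, mod,
                                   tagged_edge(tree, "b1"))
      J2 <- branch_joint_posterior(enc, fit$tree, mod,
                                   tagged_edge(tree, "b2"))
      pp <- site_convergence_pp(J1, J2)
      rows[[length(rows) + 1]] <- data.frame(
        t = grid[gi], gene = g, count = sum(pp$pp_total > 0.5),
        summed = sum(pp$pp_total))
    }
  }
  res <- do.call(rbind, rows)
  ct <- suppressWarnings(stats::cor.test(res$t, res$count,
                                         method = "spearman",
                                         alternative = "greater"))
  list(results = res, spearman = unname(ct$estimate), p_value = ct$p.value,
       point_means = stats::aggregate(count ~ t, res, mean))
}
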