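# Posterior probabilities of parallel/convergent amino-acid substitutions
# between branch pairs, built from Dayhoff-model ancestral reconstructions:
# per-branch parent/child joint posteriors are combined across the two
# branches under a product (independence) approximation; the exact
# four-endpoint joint is available for validation on small trees.

#' Most ancestral comparable branch for a clade in a pruned gene tree
#'
#' The branch subtending the MRCA of the clade members present (the
#' clade's stem branch in this gene's tree); a single present member
#' yields its terminal branch.
#'
#' @param tree gene tree (already pruned to the gene's taxa).
#' @param clade_taxa taxa defining the clade.
#' @return edge index into `tree$edge`.
#' @export
select_ancestral_branch <- function(tree, clade_taxa) {
  present <- intersect(clade_taxa, tree$tip.label)
  if (!length(present)) stop("no clade member present in tree")
  node <- if (length(present) == 1) match(present, tree$tip.label) else
    ape::getMRCA(tree, present)
  e <- edge_of_node(tree, node)
  if (is.na(e)) stop("clade MRCA is the root: no stem branch in this gene")
  e
}

#' Sitewise parallel/convergent substitution posterior probabilities
#'
#' Combines the parent/child joint posteriors of two branches:
#' parallel = same ancestral and same derived amino acid on both branches
#' (ancestral != derived); convergent = different ancestral, same derived;
#' total = their sum.
#'
#' @param J1,J2 arrays (nstate x nstate x nsites) from
#'   [branch_joint_posterior()] for the two branches.
#' @return data frame with per-site `pp_parallel`, `pp_convergent`,
#'   `pp_total`.
#' @export
site_convergence_pp <- function(J1, J2) {
  stopifnot(identical(dim(J1), dim(J2)))
  ns <- dim(J1)[3]
  tots <- vapply(seq_len(ns), function(s) {
    m1 <- J1[, , s]; m2 <- J2[, , s]
    if (abs(sum(m1) - 1) > 1e-6 || abs(sum(m2) - 1) > 1e-6)
      stop("joint posteriors are not normalised at site ", s)
    diag(m1) <- 0; diag(m2) <- 0     # substitutions only (a != x)
    par <- sum(m1 * m2)              # same ancestral, same derived
    tot <- sum(colSums(m1) * colSums(m2))  # any ancestral pair, same derived
    c(par, tot - par, tot)
  }, numeric(3))
  data.frame(site = seq_len(ns), pp_parallel = tots[1, ],
             pp_convergent = tots[2, ], pp_total = tots[3, ])
}

#' Gene-level convergence summary
#'
#' Sums the sitewise total PPs and applies the two-tier reporting rule:
#' summed-PP thresholds (>= 1.0, >= 2.0) and the counts of individual
#' sites above the sitewise threshold (> 0.5).
#'
#' @param site_pp data frame from [site_convergence_pp()].
#' @param gene gene id (optional label).
#' @param branches length-2 labels for the branch pair (optional).
#' @return object of class `convergence_profile`.
#' @export
gene_convergence_summary <- function(site_pp, gene = NA_character_,
                                     branches = c(NA, NA)) {
  out <- list(
    gene = gene, branch_1 = branches[1], branch_2 = branches[2],
    site_pp = site_pp,
    summed_pp_parallel = sum(site_pp$pp_parallel),
    summed_pp_convergent = sum(site_pp$pp_convergent),
    summed_pp_total = sum(site_pp$pp_total),
    n_sites_pp_gt_half = sum(site_pp$pp_total > 0.5),
    flag_1.0 = sum(site_pp$pp_total) >= 1.0,
    flag_2.0 = sum(site_pp$pp_total) >= 2.0)
  class(out) <- "convergence_profile"
  out
}

#' @export
print.convergence_profile <- function(x, ...) {
  cat(sprintf("Convergence profile%s: %s vs %s\n",
              if (is.na(x$gene)) "" else paste0(" for ", x$gene),
              x$branch_1, x$branch_2))
  cat(sprintf("  summed PP total = %.3f (parallel %.3f + convergent %.3f)\n",
              x$summed_pp_total, x$summed_pp_parallel,
              x$summed_pp_convergent))
  cat(sprintf("  sites with PP > 0.5: %d; flags: >=1.0 %s, >=2.0 %s\n",
              x$n_sites_pp_gt_half, x$flag_1.0, x$flag_2.0))
  invisible(x)
}

#' Convergence scan of one gene for one branch pair
#'
#' Full per-gene convergence computation: translate the codon alignment,
#' fit branch lengths under the Dayhoff model, locate the most ancestral
#' comparable branch of each clade, compute each branch's joint posterior
#' and combine them sitewise.
#'
#' @param aln codon alignment (codon-string matrix) or protein alignment
#'   (`protein = TRUE`).
#' @param tree species tree (pruned internally to the gene's taxa).
#' @param clade1_taxa,clade2_taxa taxon sets of the two lineages.
#' @param gene gene id for labelling.
#' @param protein is `aln` already a protein alignment?
#' @param model amino-acid model (default [dayhoff_model()]).
#' @return `convergence_profile`, or `NULL` (with a message) when a clade
#'   has no member in the gene.
#' @export
scan_convergence <- function(aln, tree, clade1_taxa, clade2_taxa,
                             gene = NA_character_, protein = FALSE,
                             model = dayhoff_model()) {
  paln <- if (protein) as.matrix(aln) else translate_codons(as.matrix(aln))
  tree <- if (all(rownames(paln) %in% tree$tip.label) &&
              length(tree$tip.label) > nrow(paln))
    prune_tree(tree, rownames(paln)) else tree
  ok1 <- length(intersect(clade1_taxa, tree$tip.label)) > 0
  ok2 <- length(intersect(clade2_taxa, tree$tip.label)) > 0
  if (!ok1 || !ok2) {
    message("gene ", gene, ": clade with no member present, skipped")
    return(NULL)
  }
  enc <- encode_alignment(paln, "protein")
  fit <- fit_branch_lengths(enc, tree, model)
  e1 <- select_ancestral_branch(fit$tree, clade1_taxa)
  e2 <- select_ancestral_branch(fit$tree, clade2_taxa)
  if (e1 == e2 || overlapping_pair(fit$tree, e1, e2)) {
    message("gene ", gene, ": branch pair overlaps, skipped")
    return(NULL)
  }
  J1 <- branch_joint_posterior(enc, fit$tree, model, e1)
  J2 <- branch_joint_posterior(enc, fit$tree, model, e2)
  pp <- site_convergence_pp(J1, J2)
  prof <- gene_convergence_summary(pp, gene = gene,
                                   branches = c(paste(utils::head(
                                     intersect(clade1_taxa, tree$tip.label), 1),
                                     "stem"),
                                     paste(utils::head(
                                       intersect(clade2_taxa, tree$tip.label), 1),
                                       "stem")))
  prof$branch_lengths <- fit$tree$edge.length[c(e1, e2)]
  prof
}

overlapping_pair <- function(tree, e1, e2) {
  r <- try(check_branch_pair(tree, e1, e2), silent = TRUE)
  inherits(r, "try-error")
}

#' Convergence versus branch length trend
#'
#' Pearson and Spearman association between per-pair summed branch lengths
#' and per-pair totals of estimated convergent substitutions.
#'
#' @param totals per-pair counts/totals of convergent substitutions.
#' @param lengths per-pair summed branch lengths.
#' @return list with `pearson`, `spearman`, `slope`, `p_spearman` and `n`.
#' @export
convergence_vs_branchlength <- function(totals, lengths) {
  stopifnot(length(totals) == length(lengths))
  if (length(totals) < 3) stop("need at least 3 branch pairs for a trend")
  if (stats::sd(lengths) == 0)
    return(list(pearson = NA_real_, spearman = NA_real_, slope = NA_real_,
                p_spearman = NA_real_, n = length(totals),
                degenerate = TRUE))
  if (stats::sd(totals) == 0)   # no variation in outcome: no association
    return(list(pearson = 0, spearman = 0, slope = 0, p_spearman = 1,
                n = length(totals), degenerate = FALSE))
  ct <- suppressWarnings(stats::cor.test(lengths, totals, method = "spearman"))
  list(pearson = stats::cor(lengths, totals),
       spearman = unname(ct$estimate),
       slope = unname(stats::coef(stats::lm(totals ~ lengths))[2]),
       p_spearman = ct$p.value, n = length(totals), degenerate = FALSE)
}

#' Exact two-branch convergence PP by endpoint-state enumeration
#'
#' Validation oracle (and small-tree option): sums the site likelihood
#' over every assignment of states to internal nodes (and ambiguous
#' tips), then reads the parallel/convergent posterior masses off the
#' exact joint of the four branch endpoints. Cost grows as
#' states^(free nodes); intended for trees with few internal nodes.
#'
#' @param aln alignment matrix or encoded alignment.
#' @param tree `phylo` with fitted branch lengths.
#' @param model `subst_model`.
#' @param e1,e2 edge indices of the two branches.
#' @param sites site indices to evaluate (default all).
#' @return data frame as in [site_convergence_pp()].
#' @export
site_convergence_pp_exact <- function(aln, tree, model, e1, e2, sites = NULL) {
  enc <- if (is.list(aln) && !is.null(aln$tipp)) aln else
    encode_alignment(aln, if (model$type == "codon") "codon" else "protein")
  if (is.null(sites)) sites <- seq_len(enc$nsites)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  ns <- length(model$states)
  P <- edge_transition_matrices(tree, model)
  u1 <- tree$edge[e1, 1]; v1 <- tree$edge[e1, 2]
  u2 <- tree$edge[e2, 1]; v2 <- tree$edge[e2, 2]
  res <- matrix(0, length(sites), 3)
  for (si in seq_along(sites)) {
    pat <- enc$pattern_of_site[sites[si]]
    # per-node candidate state sets at this site
    cand <- lapply(seq_len(nn), function(n) {
      if (n > ntip) return(seq_len(ns))
      which(enc$tipp[[tree$tip.label[n]]][, pat] > 0)
    })
    free <- which(lengths(cand) > 1)
    if (prod(lengths(cand)[free]) > 4.2e6)
      stop("tree too large for exact endpoint enumeration (",
           length(free), " free nodes of ", ns, " states)")
    grid <- as.matrix(expand.grid(cand[free]))
    state_of <- function(n) {
      if (n %in% free) grid[, match(n, free)] else rep(cand[[n]], nrow(grid))
    }
    vals <- model$freqs[state_of(root_node(tree))]
    for (e in seq_len(nrow(tree$edge))) {
      vals <- vals * P[[e]][cbind(state_of(tree$edge[e, 1]),
                                  state_of(tree$edge[e, 2]))]
    }
    z <- sum(vals)
    a1 <- state_of(u1); x1 <- state_of(v1)
    a2 <- state_of(u2); x2 <- state_of(v2)
    sub <- a1 != x1 & a2 != x2 & x1 == x2
    par <- sum(vals[sub & a1 == a2])
    tot <- sum(vals[sub])
    res[si, ] <- c(par / z, (tot - par) / z, tot / z)
  }
  data.frame(site = sites, pp_parallel = res[, 1], pp_convergent = res[, 2],
             pp_total = res[, 3])
}
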