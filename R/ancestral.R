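# Marginal ancestral-state posteriors and parent/child branch joint
# posteriors via the inside-outside algorithm. Per-pattern scale factors
# cancel in the per-site normalisation.

#' Marginal ancestral state posteriors at every internal node
#'
#' @param aln alignment matrix or [encode_alignment()] object.
#' @param tree `phylo` with fitted branch lengths.
#' @param model a `subst_model` (single class).
#' @return list with `posteriors`: a list over internal node ids of
#'   nstate x nsites matrices of per-site state posteriors (columns sum
#'   to 1), plus the alphabet `states`.
#' @export
marginal_ancestral_posteriors <- function(aln, tree, model) {
  enc <- if (is.list(aln) && !is.null(aln$tipp)) aln else
    encode_alignment(aln, if (model$type == "codon") "codon" else "protein")
  if (all(tree$edge.length == 0) && enc$npat > 1)
    warning("all branch lengths are 0; fit the tree before reconstructing")
  P <- edge_transition_matrices(tree, model)
  up <- peel_up(enc, tree, P)
  down <- peel_down(enc, tree, P, up, model$freqs)
  ntip <- length(tree$tip.label)
  nodes <- ntip + seq_len(tree$Nnode)
  post <- lapply(nodes, function(n) {
    m <- up$ups[[n]] * down$downs[[n]]
    m <- m / rep(colSums(m), each = enc$nstate)
    m[, enc$pattern_of_site, drop = FALSE]
  })
  names(post) <- nodes
  list(posteriors = post, states = enc$states, nodes = nodes)
}

#' Joint posterior of (parent state, child state) on one branch
#'
#' For each site, the nstate x nstate matrix
#' J\[a, x\] = P(parent = a, child = x | data); entries sum to 1 per site.
#' For a tip branch with an observed unambiguous state only that column is
#' non-zero.
#'
#' @param aln alignment matrix or encoded alignment.
#' @param tree `phylo` with fitted branch lengths.
#' @param model `subst_model`.
#' @param branch edge index into `tree$edge`, or a tag name present in
#'   `tree$edge.tag`.
#' @return array nstate x nstate x nsites.
#' @export
branch_joint_posterior <- function(aln, tree, model, branch) {
  enc <- if (is.list(aln) && !is.null(aln$tipp)) aln else
    encode_alignment(aln, if (model$type == "codon") "codon" else "protein")
  e <- resolve_branch(tree, branch)
  P <- edge_transition_matrices(tree, model)
  up <- peel_up(enc, tree, P)
  down <- peel_down(enc, tree, P, up, model$freqs)
  v <- tree$edge[e, 2]
  J <- array(0, c(enc$nstate, enc$nstate, enc$nsites))
  Pe <- P[[e]]
  A <- down$Aout[[e]]
  U <- up$ups[[v]]
  for (pat in seq_len(enc$npat)) {
    m <- Pe * outer(A[, pat], U[, pat])   # A[a] P[a,x] U[x]
    m <- m / sum(m)
    for (s in which(enc$pattern_of_site == pat)) J[, , s] <- m
  }
  dimnames(J) <- list(enc$states, enc$states, NULL)
  J
}

resolve_branch <- function(tree, branch) {
  if (is.character(branch)) {
    e <- tagged_edge(tree, branch)
    if (is.na(e)) stop("no branch tagged '", branch, "' in tree")
    return(e)
  }
  if (!is.numeric(branch) || branch < 1 || branch > nrow(tree$edge))
    stop("unknown branch id: ", branch)
  as.integer(branch)
}
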