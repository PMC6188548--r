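# Felsenstein pruning over 20-state (amino acid) and 61-state (codon)
# alphabets, with per-site scaling, site-pattern compression, and the
# inside-outside (up/down) passes that ancestral posteriors are built from.
# Gaps and N/X are fully missing; other IUPAC codes expand to their
# compatible state sets.

NT_AMBIG <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                 B = c("C", "G", "T"), D = c("A", "G", "T"),
                 H = c("A", "C", "T"), V = c("A", "C", "G"))
AA_AMBIG <- list(B = c("N", "D"), Z = c("Q", "E"), J = c("I", "L"))

# compatible sense codons for a codon string; NULL => fully missing
codon_state_set <- function(cd) {
  tab <- codon_table()
  i <- match(cd, tab$codons)
  if (!is.na(i)) return(i)
  ch <- strsplit(cd, "")[[1]]
  if (any(ch %in% c("-", "N", "?"))) return(NULL)
  sets <- lapply(ch, function(x) NT_AMBIG[[x]])
  if (any(vapply(sets, is.null, logical(1)))) return(NULL)
  combs <- expand.grid(sets, stringsAsFactors = FALSE)
  idx <- match(apply(combs, 1, paste0, collapse = ""), tab$codons)
  idx <- idx[!is.na(idx)]  # stop codons drop out of the compatible set
  if (!length(idx)) NULL else idx
}

aa_state_set <- function(x) {
  i <- match(x, AA_ORDER)
  if (!is.na(i)) return(i)
  if (x %in% names(AA_AMBIG)) return(match(AA_AMBIG[[x]], AA_ORDER))
  NULL  # X, '-', '*', U, O -> missing
}

#' Encode an alignment for likelihood computation
#'
#' Compresses columns to unique site patterns and builds per-taxon partial
#' likelihood indicators over the model states.
#'
#' @param aln character matrix, taxa x sites: codon strings for
#'   `type = "codon"`, one-letter residues for `type = "protein"`.
#' @param type `"codon"` or `"protein"`.
#' @return list with tip partial matrices (`tipp`), pattern weights,
#'   per-site pattern index, and alphabet metadata.
#' @export
encode_alignment <- function(aln, type = c("codon", "protein")) {
  type <- match.arg(type)
  aln <- as.matrix(aln)
  if (is.null(rownames(aln))) stop("alignment must have taxon rownames")
  nstate <- if (type == "codon") 61L else 20L
  states <- if (type == "codon") codon_table()$codons else AA_ORDER
  key <- apply(aln, 2, paste0, collapse = "\r")
  upat <- !duplicated(key)
  pattern_of_site <- match(key, key[upat])
  weights <- as.numeric(tabulate(pattern_of_site, nbins = sum(upat)))
  sub <- aln[, upat, drop = FALSE]
  setfun <- if (type == "codon") codon_state_set else aa_state_set
  # cache state sets per distinct symbol
  syms <- unique(as.vector(sub))
  setmap <- lapply(syms, setfun)
  names(setmap) <- syms
  tipp <- lapply(rownames(aln), function(tx) {
    m <- matrix(0, nstate, ncol(sub))
    row <- sub[tx, ]
    for (j in seq_along(row)) {
      s <- setmap[[row[j]]]
      if (is.null(s)) m[, j] <- 1 else m[s, j] <- 1
    }
    m
  })
  names(tipp) <- rownames(aln)
  list(tipp = tipp, weights = weights, pattern_of_site = pattern_of_site,
       npat = length(weights), nsites = ncol(aln), nstate = nstate,
       states = states, type = type)
}

# transition matrices for every edge; `scale` multiplies branch lengths
edge_transition_matrices <- function(tree, model, scale = 1) {
  lapply(seq_len(nrow(tree$edge)), function(e)
    transition_matrix(model, tree$edge.length[e] * scale))
}

# children edge indices per internal node
node_child_edges <- function(tree) {
  split(seq_len(nrow(tree$edge)), tree$edge[, 1])
}

root_node <- function(tree) length(tree$tip.label) + 1L

# Upward (pruning) pass. Returns per-node scaled partials `ups` with
# per-pattern log scale factors `upscale`, and the per-edge messages
# M_e = P_e %*% ups[child] (`M`, with `Mscale`).
peel_up <- function(enc, tree, P) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  miss <- setdiff(tree$tip.label, names(enc$tipp))
  if (length(miss)) stop("taxon in tree absent from alignment: ",
                         paste(miss, collapse = ", "))
  ups <- vector("list", nn)
  upscale <- vector("list", nn)
  zero <- numeric(enc$npat)
  for (i in seq_len(ntip)) {
    ups[[i]] <- enc$tipp[[tree$tip.label[i]]]
    upscale[[i]] <- zero
  }
  M <- vector("list", nrow(tree$edge))
  Mscale <- vector("list", nrow(tree$edge))
  po <- postorder_edges(tree)
  for (e in po) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    M[[e]] <- P[[e]] %*% ups[[v]]
    Mscale[[e]] <- upscale[[v]]
    if (is.null(ups[[u]])) {
      ups[[u]] <- M[[e]]
      upscale[[u]] <- Mscale[[e]]
    } else {
      ups[[u]] <- ups[[u]] * M[[e]]
      upscale[[u]] <- upscale[[u]] + Mscale[[e]]
    }
    # rescale the parent's partial per pattern
    mx <- ups[[u]][cbind(max.col(t(ups[[u]]), ties.method = "first"),
                         seq_len(enc$npat))]
    bad <- mx <= 0
    if (any(bad)) mx[bad] <- 1  # impossible pattern; lnL will be -Inf
    ups[[u]] <- ups[[u]] / rep(mx, each = enc$nstate)
    upscale[[u]] <- upscale[[u]] + log(mx)
  }
  list(ups = ups, upscale = upscale, M = M, Mscale = Mscale)
}

# per-pattern log-likelihood from a completed up pass
root_loglik_patterns <- function(enc, tree, up, freqs) {
  r <- root_node(tree)
  lik <- colSums(freqs * up$ups[[r]])
  log(lik) + up$upscale[[r]]
}

# Downward (outside) pass. downs[[v]] are scaled outside partials such that
# posterior(v) propto ups[[v]] * downs[[v]]; Aout[[e]] is the outside
# partial at the parent of edge e excluding edge e's subtree (used for
# branch joints), with log scales `Ascale`.
peel_down <- function(enc, tree, P, up, freqs) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  r <- root_node(tree)
  downs <- vector("list", nn)
  downscale <- vector("list", nn)
  Aout <- vector("list", nrow(tree$edge))
  Ascale <- vector("list", nrow(tree$edge))
  downs[[r]] <- matrix(freqs, enc$nstate, enc$npat)
  downscale[[r]] <- numeric(enc$npat)
  kids <- node_child_edges(tree)
  pre <- rev(postorder_edges(tree))
  for (e in pre) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    A <- downs[[u]]
    As <- downscale[[u]]
    for (s in kids[[as.character(u)]]) {
      if (s == e) next
      A <- A * up$M[[s]]
      As <- As + up$Mscale[[s]]
    }
    Aout[[e]] <- A
    Ascale[[e]] <- As
    D <- crossprod(P[[e]], A)   # t(P) %*% A
    mx <- D[cbind(max.col(t(D), ties.method = "first"), seq_len(enc$npat))]
    mx[mx <= 0] <- 1
    downs[[v]] <- D / rep(mx, each = enc$nstate)
    downscale[[v]] <- As + log(mx)
  }
  list(downs = downs, downscale = downscale, Aout = Aout, Ascale = Ascale)
}

#' Phylogenetic log-likelihood under a substitution model or site-class mixture
#'
#' Felsenstein pruning with per-site scaling. For a mixture, per-site
#' likelihoods are the proportion-weighted average of the class
#' likelihoods. Gap/ambiguous states contribute partial likelihood 1 over
#' their compatible states.
#'
#' @param aln character matrix (taxa x sites; codon strings or residues),
#'   or an object from [encode_alignment()].
#' @param tree `phylo` with branch lengths in the model's units. Tips not
#'   in the alignment are pruned first.
#' @param model a `subst_model`, or a list of them for a mixture.
#' @param weights mixture proportions (required iff `model` is a list).
#' @param scale multiplier applied to all branch lengths.
#' @return list with `total` log-likelihood and per-site vector `site_ll`.
#' @export
log_likelihood <- function(aln, tree, model, weights = NULL, scale = 1) {
  if (inherits(model, "subst_model")) {
    model <- list(model); weights <- 1
  }
  if (is.null(weights) || length(weights) != length(model))
    stop("mixture needs one weight per model component")
  if (abs(sum(weights) - 1) > 1e-12) stop("mixture proportions must sum to 1")
  type <- model[[1]]$type
  enc <- if (is.list(aln) && !is.null(aln$tipp)) aln else
    encode_alignment(aln, if (type == "codon") "codon" else "protein")
  extra <- setdiff(names(enc$tipp), tree$tip.label)
  if (length(extra)) stop("taxon in alignment absent from tree: ",
                          paste(extra, collapse = ", "))
  if (length(tree$tip.label) > length(enc$tipp))
    tree <- prune_tree(tree, names(enc$tipp))
  class_ll <- vapply(model, function(m) {
    P <- edge_transition_matrices(tree, m, scale)
    up <- peel_up(enc, tree, P)
    root_loglik_patterns(enc, tree, up, m$freqs)
  }, numeric(enc$npat))
  class_ll <- matrix(class_ll, nrow = enc$npat)
  mx <- apply(class_ll, 1, max)
  pat_ll <- mx + log(as.vector(exp(class_ll - mx) %*% weights))
  list(total = sum(enc$weights * pat_ll),
       site_ll = pat_ll[enc$pattern_of_site])
}
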