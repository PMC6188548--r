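# Independent oracles used across the suite: exhaustive enumeration over
# internal-node state assignments (likelihoods, marginal and joint
# posteriors) with transition probabilities from Matrix::expm, plus small
# random-instance generators. Deliberately plain, loop-based code with no
# reuse of the package's pruning or eigensystem machinery.

oracle_pmat <- function(model, t) {
  as.matrix(Matrix::expm(model$Q * t))
}

# candidate states per node at one site (tips: observed/compatible states,
# internal: all states)
oracle_candidates <- function(aln, tree, model, site) {
  ns <- length(model$states)
  ntip <- length(tree$tip.label)
  lapply(seq_len(ntip + tree$Nnode), function(n) {
    if (n > ntip) return(seq_len(ns))
    sym <- aln[tree$tip.label[n], site]
    if (model$type == "codon") {
      i <- match(sym, model$states)
      if (!is.na(i)) i else seq_len(ns)   # missing/ambiguous: all states
    } else {
      i <- match(sym, model$states)
      if (!is.na(i)) i else seq_len(ns)
    }
  })
}

# Exhaustive enumeration over internal-node state assignments at one
# site (plus any explicitly queried nodes); unqueried tips are summed
# over their compatible states edge-locally. Returns the assignment grid
# and unnormalised probabilities.
oracle_site_joint <- function(aln, tree, model, site, P = NULL,
                              keep_nodes = integer(0)) {
  if (is.null(P))
    P <- lapply(seq_len(nrow(tree$edge)), function(e)
      oracle_pmat(model, tree$edge.length[e]))
  ntip <- length(tree$tip.label)
  cand <- oracle_candidates(aln, tree, model, site)
  enum <- sort(unique(c((ntip + 1):(ntip + tree$Nnode), keep_nodes)))
  grid <- as.matrix(expand.grid(cand[enum]))
  colnames(grid) <- enum
  state_of <- function(n) grid[, match(n, enum)]
  root <- ntip + 1L
  vals <- model$freqs[state_of(root)]
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    if (v %in% enum) {
      vals <- vals * P[[e]][cbind(state_of(u), state_of(v))]
    } else {
      # tip not queried: sum its compatible states into the edge factor
      w <- rowSums(P[[e]][, cand[[v]], drop = FALSE])
      vals <- vals * w[state_of(u)]
    }
  }
  list(grid = grid, vals = vals, enum = enum)
}

oracle_loglik <- function(aln, tree, model, use_pkg_pmat = FALSE) {
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    if (use_pkg_pmat) transition_matrix(model, tree$edge.length[e]) else
      oracle_pmat(model, tree$edge.length[e]))
  sum(vapply(seq_len(ncol(aln)), function(s)
    log(sum(oracle_site_joint(aln, tree, model, s, P)$vals)), numeric(1)))
}

oracle_marginal <- function(aln, tree, model, node, site) {
  j <- oracle_site_joint(aln, tree, model, site, keep_nodes = node)
  ns <- length(model$states)
  st <- j$grid[, match(node, j$enum)]
  p <- vapply(seq_len(ns), function(a) sum(j$vals[st == a]), numeric(1))
  p / sum(p)
}

oracle_branch_joint <- function(aln, tree, model, edge, site) {
  u <- tree$edge[edge, 1]; v <- tree$edge[edge, 2]
  j <- oracle_site_joint(aln, tree, model, site, keep_nodes = c(u, v))
  ns <- length(model$states)
  su <- j$grid[, match(u, j$enum)]
  sv <- j$grid[, match(v, j$enum)]
  m <- matrix(0, ns, ns)
  for (i in seq_along(j$vals)) m[su[i], sv[i]] <- m[su[i], sv[i]] + j$vals[i]
  m / sum(m)
}

# random rooted tree with exponential branch lengths
random_tree <- function(ntaxa, seed, mean_len = 0.15) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, rooted = TRUE, br = NULL)
  tr$tip.label <- paste0("t", seq_len(ntaxa))
  tr$edge.length <- 0.02 + stats::rexp(nrow(tr$edge), 1 / mean_len)
  tr$edge.tag <- rep(NA_character_, nrow(tr$edge))
  tr
}

# random alignment sampled independently per cell (not via the package
# simulator), with optional missing cells
random_aa_alignment <- function(ntaxa, nsites, seed, miss = 0.05) {
  set.seed(seed)
  m <- matrix(sample(subterra::AA_ORDER, ntaxa * nsites, TRUE),
              ntaxa, nsites, dimnames = list(paste0("t", 1:ntaxa), NULL))
  m[matrix(stats::runif(ntaxa * nsites) < miss, ntaxa)] <- "-"
  m
}

random_codon_alignment <- function(ntaxa, nsites, seed, miss = 0.05) {
  set.seed(seed)
  cods <- subterra::codon_table()$codons
  m <- matrix(sample(cods, ntaxa * nsites, TRUE),
              ntaxa, nsites, dimnames = list(paste0("t", 1:ntaxa), NULL))
  m[matrix(stats::runif(ntaxa * nsites) < miss, ntaxa)] <- "---"
  m
}

# a small fixed 8-taxon tree used by the simulation-based tests; the
# foreground tag sits on an internal (clade stem) branch
eight_taxon_tree <- function(fg = TRUE) {
  txt <- if (fg)
    "(((A:0.1,B:0.1):0.05,(C:0.1,D:0.1)#1:0.08):0.05,((E:0.1,F:0.1):0.05,(G:0.1,H:0.1):0.05):0.05);"
  else
    "(((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.08):0.05,((E:0.1,F:0.1):0.05,(G:0.1,H:0.1):0.05):0.05);"
  parse_newick(txt)
}

clade_members_of <- function(tree, node) {
  if (node <= length(tree$tip.label)) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}
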