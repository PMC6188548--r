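# Synthetic-data generators: codon alignments simulated on the study-shaped
# species tree under branch-site mixtures, injected parallel/convergent
# sites, per-gene taxon missingness, and synthetic GO universes. All
# generators are pure functions of (specification, seed).

#' Default codon frequencies for simulation
#'
#' Mildly AT-rich F1x4-style frequencies (product of nucleotide
#' frequencies renormalised over the 61 sense codons).
#' @return numeric vector of 61 frequencies.
#' @export
default_codon_freqs <- function() {
  nt <- c(T = 0.26, C = 0.22, A = 0.30, G = 0.22)
  ntm <- codon_nt_matrix()
  f <- nt[ntm[, 1]] * nt[ntm[, 2]] * nt[ntm[, 3]]
  unname(f / sum(f))
}

#' Branch-site site-class mixture specification
#'
#' @param p0,p1 proportions of the purifying (omega0) and neutral classes;
#'   classes 2a/2b take the remainder split as p0:p1.
#' @param omega0 background purifying omega in (0,1).
#' @param omega2 foreground omega for classes 2a/2b (1 = null model).
#' @param kappa transition/transversion ratio.
#' @return list of class `site_mixture`.
#' @export
site_mixture <- function(p0 = 0.45, p1 = 0.45, omega0 = 0.1, omega2 = 1,
                         kappa = 2.5) {
  stopifnot(p0 >= 0, p1 >= 0, p0 + p1 <= 1, p0 + p1 > 0,
            omega0 > 0, omega0 < 1, omega2 >= 0, kappa > 0)
  w <- c(p0, p1, (1 - p0 - p1) * p0 / (p0 + p1),
         (1 - p0 - p1) * p1 / (p0 + p1))
  stopifnot(abs(sum(w) - 1) < 1e-12)
  structure(list(p0 = p0, p1 = p1, weights = w, omega0 = omega0,
                 omega2 = omega2, kappa = kappa), class = "site_mixture")
}

# per-class (background omega, foreground omega) pairs for Model A
mixture_class_omegas <- function(mix) {
  rbind(bg = c(mix$omega0, 1, mix$omega0, 1),
        fg = c(mix$omega0, 1, mix$omega2, mix$omega2))
}

# size-safe sample (never interprets a length-1 x as 1:x)
sample_safe <- function(x, size, replace = FALSE, prob = NULL)
  x[sample.int(length(x), size, replace = replace, prob = prob)]

# vectorised categorical draw of child states along one edge
sample_children <- function(parent_states, P) {
  out <- integer(length(parent_states))
  for (a in unique(parent_states)) {
    idx <- which(parent_states == a)
    out[idx] <- sample.int(ncol(P), length(idx), replace = TRUE,
                           prob = P[a, ])
  }
  out
}

#' Simulate a codon alignment under a branch-site mixture
#'
#' Root codons are drawn from the equilibrium frequencies; each site is
#' assigned a site class; evolution proceeds along branches by the exact
#' CTMC transition probabilities, with the foreground branch using the
#' foreground omega of the site's class. Branch lengths are interpreted as
#' expected substitutions per codon averaged over the site classes
#' (background omegas).
#'
#' @param tree `phylo`; for a selection signal one branch must carry the
#'   foreground tag (default tag `"1"`); without a tag all classes use the
#'   background omegas.
#' @param mix [site_mixture()], or a single `subst_model` for one-class
#'   simulation (amino-acid models supported for protein genes).
#' @param n_codons number of sites.
#' @param seed RNG seed (mandatory; generators are pure in (specification, seed)).
#' @param codon_freqs equilibrium frequencies ([default_codon_freqs()]).
#' @param foreground foreground branch tag or edge index (`NULL` = none).
#' @return list of class `sim_gene`: `aln` (tip codon matrix or residue
#'   matrix), `node_states` (all-node integer state matrix), `classes`
#'   (per-site class), plus the ingredients needed to re-simulate subtrees.
#' @export
simulate_gene <- function(tree, mix, n_codons, seed,
                          codon_freqs = default_codon_freqs(),
                          foreground = "1") {
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  if (inherits(mix, "subst_model")) {
    # single-model simulation (codon or amino acid)
    mod <- mix
    nstate <- length(mod$states)
    states <- matrix(0L, nn, n_codons)
    states[root_node(tree), ] <- sample.int(nstate, n_codons, TRUE,
                                            prob = mod$freqs)
    P <- edge_transition_matrices(tree, mod)
    for (e in rev(postorder_edges(tree))) {
      u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      states[v, ] <- sample_children(states[u, ], P[[e]])
    }
    aln <- matrix(mod$states[states[1:ntip, ]], ntip, n_codons,
                  dimnames = list(tree$tip.label, NULL))
    return(structure(list(aln = aln, node_states = states,
                          classes = rep(1L, n_codons), tree = tree,
                          model = mod, type = mod$type, seed = seed),
                     class = "sim_gene"))
  }
  stopifnot(inherits(mix, "site_mixture"))
  fg_edge <- if (is.null(foreground)) NA_integer_ else {
    e <- try(resolve_branch(tree, foreground), silent = TRUE)
    if (inherits(e, "try-error")) NA_integer_ else e
  }
  om <- mixture_class_omegas(mix)
  # mixture-average rate (background omegas) defines the time units
  rates <- vapply(unique(as.vector(om)), function(w)
    codon_model(mix$kappa, w, codon_freqs, scale = FALSE)$rate, numeric(1))
  names(rates) <- sprintf("%.12g", unique(as.vector(om)))
  r_mix <- sum(mix$weights * rates[sprintf("%.12g", om["bg", ])])
  s <- 1 / r_mix
  models <- lapply(unique(as.vector(om)), function(w)
    codon_model(mix$kappa, w, codon_freqs, scale = FALSE))
  names(models) <- sprintf("%.12g", unique(as.vector(om)))
  classes <- sample.int(4, n_codons, TRUE, prob = mix$weights)
  states <- matrix(0L, nn, n_codons)
  states[root_node(tree), ] <- sample.int(61, n_codons, TRUE,
                                          prob = codon_freqs)
  for (e in rev(postorder_edges(tree))) {
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    kind <- if (!is.na(fg_edge) && e == fg_edge) "fg" else "bg"
    t_e <- tree$edge.length[e] * s
    for (k in 1:4) {
      idx <- which(classes == k)
      if (!length(idx)) next
      P <- transition_matrix(models[[sprintf("%.12g", om[kind, k])]], t_e)
      states[v, idx] <- sample_children(states[u, idx], P)
    }
  }
  codons <- codon_table()$codons
  aln <- matrix(codons[states[1:ntip, ]], ntip, n_codons,
                dimnames = list(tree$tip.label, NULL))
  structure(list(aln = aln, node_states = states, classes = classes,
                 tree = tree, mix = mix, codon_freqs = codon_freqs,
                 models = models, class_omegas = om, time_scale = s,
                 fg_edge = fg_edge, type = "codon", seed = seed),
            class = "sim_gene")
}

# re-simulate the subtree below node `v` at the given sites, starting from
# the (already set) states of v
resim_subtree <- function(sim, v, sites) {
  tree <- sim$tree
  desc_edges <- edges_below(tree, v)
  for (e in desc_edges) {   # already in root-to-tip order
    u <- tree$edge[e, 1]; w <- tree$edge[e, 2]
    t_e <- tree$edge.length[e] * sim$time_scale
    for (k in unique(sim$classes[sites])) {
      idx <- sites[sim$classes[sites] == k]
      P <- transition_matrix(sim$models[[sprintf("%.12g",
                                                 sim$class_omegas["bg", k])]],
                             t_e)
      sim$node_states[w, idx] <- sample_children(sim$node_states[u, idx], P)
    }
  }
  sim
}

# edge indices strictly below node v, parents before children
edges_below <- function(tree, v) {
  pre <- rev(postorder_edges(tree))
  keep <- logical(length(pre))
  inside <- c(v)
  out <- integer(0)
  for (e in pre) {
    if (tree$edge[e, 1] %in% inside) {
      out <- c(out, e)
      inside <- c(inside, tree$edge[e, 2])
    }
  }
  out
}

#' Inject parallel/convergent substitutions at chosen sites
#'
#' At `n_sites` randomly chosen eligible sites, forces the same derived
#' amino acid on the child nodes of both branches of a pair and
#' re-simulates the two subtrees below them conditional on the forced
#' states; the rest of the tree is untouched. Parallel mode requires the
#' two ancestral (parent-node) amino acids to coincide, convergent mode
#' requires them to differ; eligibility is by rejection over sites.
#'
#' @param sim a codon `sim_gene`.
#' @param branch_pair length-2 vector of edge indices or tags.
#' @param n_sites number of sites to inject.
#' @param mode `"parallel"` or `"convergent"`.
#' @param seed RNG seed.
#' @return `sim_gene` with updated alignment plus `injected` (data frame:
#'   site, mode, target amino acid).
#' @export
inject_convergent_sites <- function(sim, branch_pair, n_sites,
                                    mode = c("parallel", "convergent"),
                                    seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "sim_gene"), sim$type == "codon")
  set.seed(seed)
  if (n_sites == 0) {
    sim$injected <- data.frame(site = integer(0), mode = character(0),
                               target_aa = character(0))
    return(sim)
  }
  tree <- sim$tree
  e1 <- resolve_branch(tree, branch_pair[[1]])
  e2 <- resolve_branch(tree, branch_pair[[2]])
  check_branch_pair(tree, e1, e2)
  tab <- codon_table()
  u1 <- tree$edge[e1, 1]; v1 <- tree$edge[e1, 2]
  u2 <- tree$edge[e2, 1]; v2 <- tree$edge[e2, 2]
  anc1 <- tab$aa_index[sim$node_states[u1, ]]
  anc2 <- tab$aa_index[sim$node_states[u2, ]]
  eligible <- if (mode == "parallel") which(anc1 == anc2) else
    which(anc1 != anc2)
  if (length(eligible) < n_sites)
    stop("only ", length(eligible), " eligible sites for mode ", mode)
  sites <- sort(sample_safe(eligible, n_sites))
  aa_freq <- tapply(sim$codon_freqs, tab$aa_index, sum)
  target <- character(n_sites)
  for (i in seq_along(sites)) {
    st <- sites[i]
    banned <- unique(c(anc1[st], anc2[st]))
    choices <- setdiff(seq_len(20), banned)
    x <- sample_safe(choices, 1, prob = aa_freq[choices])
    target[i] <- AA_ORDER[x]
    for (v in c(v1, v2)) {
      cod <- which(tab$aa_index == x)
      sim$node_states[v, st] <- sample_safe(cod, 1, prob = sim$codon_freqs[cod])
    }
  }
  sim <- resim_subtree(sim, v1, sites)
  sim <- resim_subtree(sim, v2, sites)
  ntip <- length(tree$tip.label)
  sim$aln <- matrix(tab$codons[sim$node_states[1:ntip, ]], ntip,
                    ncol(sim$aln), dimnames = list(tree$tip.label, NULL))
  sim$injected <- data.frame(site = sites, mode = mode, target_aa = target)
  sim
}

check_branch_pair <- function(tree, e1, e2) {
  if (e1 == e2) stop("branch pair must be two distinct branches")
  below1 <- c(tree$edge[e1, 2], tree$edge[edges_below(tree, tree$edge[e1, 2]), 2])
  below2 <- c(tree$edge[e2, 2], tree$edge[edges_below(tree, tree$edge[e2, 2]), 2])
  if (tree$edge[e2, 2] %in% below1 || tree$edge[e1, 2] %in% below2)
    stop("branch pair overlaps: one branch is ancestral to the other")
  invisible(TRUE)
}

#' Apply per-gene taxon missingness
#'
#' Each taxon is dropped independently per gene with probability
#' `dropout`.
#'
#' @param alns list of alignment matrices (taxa x sites).
#' @param dropout per-taxon dropout probability in \[0, 1).
#' @param seed RNG seed.
#' @param keep taxa never dropped (e.g. a reference outgroup), optional.
#' @return list of alignments with rows removed.
#' @export
apply_missingness <- function(alns, dropout, seed, keep = character(0)) {
  stopifnot(dropout >= 0, dropout < 1)
  set.seed(seed)
  lapply(alns, function(a) {
    drop <- stats::runif(nrow(a)) < dropout & !(rownames(a) %in% keep)
    a[!drop, , drop = FALSE]
  })
}

#' Simulate a GO universe: DAG, annotations, and study sets
#'
#' Builds a random single-root DAG of `n_terms`, annotates genes to leaf
#' terms, propagates by the true-path rule, then draws study sets in which
#' chosen terms are over-represented at given odds ratios.
#'
#' @param n_genes,n_terms universe sizes.
#' @param depth DAG depth (levels below the root).
#' @param enriched named numeric vector: term id -> odds ratio (>1) of
#'   study membership for genes annotated to it. `NULL` = none.
#' @param study_size genes per study set.
#' @param seed RNG seed.
#' @return list: `graph` (an [annotation_graph()]), `study` (gene ids),
#'   `truth` (enriched term ids).
#' @export
simulate_go_universe <- function(n_genes = 500, n_terms = 40, depth = 4,
                                 enriched = NULL, study_size = 50, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  terms <- sprintf("T%03d", seq_len(n_terms))
  level <- c(0, sort(sample.int(depth, n_terms - 1, TRUE)))
  edges <- do.call(rbind, lapply(which(level > 0), function(i) {
    cand <- which(level == level[i] - 1)
    if (!length(cand)) cand <- 1
    par <- unique(sample_safe(cand, min(length(cand), sample.int(2, 1))))
    data.frame(child = terms[i], parent = terms[par])
  }))
  leaves <- setdiff(terms, edges$parent)
  ann <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene = g, term = sample_safe(leaves, min(length(leaves), sample.int(3, 1))))
  }))
  graph <- annotation_graph(edges, ann, domain = "BP")
  graph <- propagate_annotations(graph)
  w <- rep(1, n_genes); names(w) <- genes
  if (!is.null(enriched)) {
    for (tm in names(enriched)) {
      gset <- graph$term_genes[[tm]]
      w[gset] <- w[gset] * enriched[tm]
    }
  }
  study <- sample_safe(genes, study_size, prob = w)
  list(graph = graph, study = study,
       truth = if (is.null(enriched)) character(0) else names(enriched))
}
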