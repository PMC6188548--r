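# Gene-set statistics: Fisher's exact overrepresentation test, GO
# enrichment over an annotation DAG under the classic / elim / weight
# algorithms (true-path propagation first), and the exact multi-set
# intersection test.

#' One-sided Fisher overrepresentation p-value
#'
#' Upper-tail hypergeometric probability of observing at least
#' `k_in_study` annotated genes in the study set.
#'
#' @param k_in_study annotated genes in the study set.
#' @param study_size study set size.
#' @param k_in_background annotated genes in the background universe.
#' @param background_size universe size.
#' @return p-value in (0, 1].
#' @export
fisher_exact_enrichment <- function(k_in_study, study_size, k_in_background,
                                    background_size) {
  if (k_in_study > study_size || k_in_background > background_size ||
      study_size > background_size || k_in_study > k_in_background)
    stop("inconsistent counts: study must be contained in the background")
  stats::phyper(k_in_study - 1, k_in_background,
                background_size - k_in_background, study_size,
                lower.tail = FALSE)
}

#' Annotation graph (GO-style DAG with gene annotations)
#'
#' @param edges data frame with columns `child`, `parent` (term ids).
#' @param annotations data frame with columns `gene`, `term` (direct
#'   annotations).
#' @param domain optional domain tag (MF/CC/BP) recycled over terms.
#' @return object of class `annotation_graph` with per-term gene sets
#'   (`term_genes`), parent/children maps, and the gene universe.
#' @export
annotation_graph <- function(edges, annotations, domain = "BP") {
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent))
  terms <- sort(unique(c(edges$child, edges$parent,
                         as.character(annotations$term))))
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))
  g <- list(terms = terms,
            parents = lapply(parents, unique),
            children = lapply(children, unique),
            domain = rep(domain, length.out = length(terms)),
            term_genes = lapply(split(as.character(annotations$gene),
                                      factor(as.character(annotations$term),
                                             levels = terms)), unique),
            genes = sort(unique(as.character(annotations$gene))),
            propagated = FALSE)
  class(g) <- "annotation_graph"
  g$depth <- term_depths(g)   # also detects cycles
  g
}

# longest path from a root (term with no parents); stops on cycles
term_depths <- function(g) {
  depth <- stats::setNames(rep(NA_integer_, length(g$terms)), g$terms)
  indeg <- vapply(g$parents, length, integer(1))
  queue <- g$terms[indeg == 0]
  depth[queue] <- 0L
  remaining <- indeg
  processed <- 0L
  while (length(queue)) {
    t0 <- queue[1]; queue <- queue[-1]
    processed <- processed + 1L
    for (ch in g$children[[t0]]) {
      depth[ch] <- max(depth[ch], depth[t0] + 1L, na.rm = TRUE)
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (processed < length(g$terms)) stop("cycle detected in annotation graph")
  depth
}

#' Propagate annotations to ancestors (true-path rule)
#'
#' After propagation every gene annotated to a term is annotated to all of
#' the term's ancestors. Idempotent.
#'
#' @param graph an [annotation_graph()].
#' @return the graph with propagated `term_genes`.
#' @export
propagate_annotations <- function(graph) {
  stopifnot(inherits(graph, "annotation_graph"))
  ord <- graph$terms[order(graph$depth, decreasing = TRUE)]  # deepest first
  tg <- graph$term_genes
  for (t0 in ord) {
    for (p in graph$parents[[t0]])
      tg[[p]] <- unique(c(tg[[p]], tg[[t0]]))
  }
  graph$term_genes <- tg
  graph$propagated <- TRUE
  graph
}

ancestors_of <- function(graph, term) {
  out <- character(0)
  frontier <- graph$parents[[term]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(graph$parents[frontier])), out)
  }
  out
}

#' GO term enrichment: classic, elim, and weight algorithms
#'
#' `classic` tests every term independently by Fisher's exact test on the
#' propagated annotations. `elim` processes terms from the deepest DAG
#' level upward and removes the genes of significant (p < `cutoff`) terms
#' from all their ancestors before those are tested, decorrelating the
#' DAG. `weight` is a ratio-weighting variant in the same family: when a
#' child is more significant than its parent, the child's genes are
#' down-weighted in the parent (and its ancestors) by the ratio of
#' log-significances before the parent is tested.
#'
#' @param study character vector of study genes (subset of the graph's
#'   gene universe).
#' @param graph an [annotation_graph()] (propagated automatically).
#' @param algorithm `"classic"`, `"elim"` or `"weight"`.
#' @param cutoff internal significance cutoff for elim/weight (default
#'   0.05).
#' @return data frame: term, annotated, in_study, expected, p, algorithm,
#'   ordered by p.
#' @export
go_enrichment <- function(study, graph, algorithm = c("classic", "elim",
                                                      "weight"),
                          cutoff = 0.05) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(graph, "annotation_graph"))
  if (!graph$propagated) graph <- propagate_annotations(graph)
  study <- unique(as.character(study))
  bad <- setdiff(study, graph$genes)
  if (length(bad)) stop("study genes outside the annotation universe: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  N <- length(graph$genes)
  n_study <- length(study)
  terms <- graph$terms
  fisher_p <- function(gset, wmap = NULL) {
    if (is.null(wmap)) {
      K <- length(gset)
      k <- sum(gset %in% study)
    } else {
      w <- wmap[gset]
      K <- round(sum(w))
      k <- round(sum(w[gset %in% study]))
      k <- min(k, K)
    }
    if (K == 0) return(list(p = 1, K = 0, k = 0))
    list(p = fisher_exact_enrichment(k, n_study, K, N), K = K, k = k)
  }
  res <- data.frame(term = terms, annotated = NA_integer_,
                    in_study = NA_integer_, expected = NA_real_,
                    p = NA_real_, algorithm = algorithm,
                    stringsAsFactors = FALSE)
  ord <- terms[order(graph$depth[terms], decreasing = TRUE)]
  if (algorithm == "classic") {
    for (t0 in terms) {
      f <- fisher_p(graph$term_genes[[t0]])
      res[res$term == t0, c("annotated", "in_study", "p")] <-
        list(f$K, f$k, f$p)
    }
  } else if (algorithm == "elim") {
    removed <- lapply(terms, function(x) character(0))
    names(removed) <- terms
    for (t0 in ord) {
      gset <- setdiff(graph$term_genes[[t0]], removed[[t0]])
      f <- fisher_p(gset)
      res[res$term == t0, c("annotated", "in_study", "p")] <-
        list(f$K, f$k, f$p)
      if (f$p < cutoff) {
        for (a in ancestors_of(graph, t0))
          removed[[a]] <- union(removed[[a]], graph$term_genes[[t0]])
      }
    }
  } else { # weight (ratio-weighting variant)
    wmaps <- lapply(terms, function(t0) {
      w <- rep(1, N); names(w) <- graph$genes; w
    })
    names(wmaps) <- terms
    praw <- stats::setNames(rep(NA_real_, length(terms)), terms)
    for (t0 in ord) {
      f <- fisher_p(graph$term_genes[[t0]], wmaps[[t0]])
      praw[t0] <- f$p
      # down-weight genes of more-significant children in the ancestors
      for (ch in graph$children[[t0]]) {
        if (!is.na(praw[ch]) && praw[ch] < praw[t0] && praw[ch] < cutoff) {
          sig_ratio <- log(pmax(praw[ch], 1e-300)) /
            log(pmax(praw[t0], 1e-300))
          fac <- min(1, 1 / sig_ratio)
          gch <- graph$term_genes[[ch]]
          for (a in c(t0, ancestors_of(graph, t0)))
            wmaps[[a]][gch] <- wmaps[[a]][gch] * fac
        }
      }
      f <- fisher_p(graph$term_genes[[t0]], wmaps[[t0]])
      res[res$term == t0, c("annotated", "in_study", "p")] <-
        list(f$K, f$k, f$p)
    }
  }
  res$expected <- res$annotated * n_study / N
  res[order(res$p, res$term), ]
}

#' Exact multi-set intersection test
#'
#' Distribution of the m-way intersection size of independently and
#' uniformly drawn fixed-size subsets of a background of size N, computed
#' by iterated hypergeometric conditioning; reports the expected size
#' N * prod(n_i / N), the fold enrichment, and the upper-tail p-value of
#' the observed intersection.
#'
#' @param sets list (>= 2) of character vectors, all subsets of the
#'   background.
#' @param background character vector (the gene universe) or its size.
#' @return object of class `intersection_test`.
#' @export
multiset_intersection_test <- function(sets, background) {
  stopifnot(length(sets) >= 2)
  if (is.numeric(background) && length(background) == 1) {
    N <- as.integer(background)
    sizes <- vapply(sets, length, integer(1))
    observed <- length(Reduce(intersect, sets))
  } else {
    background <- unique(as.character(background))
    N <- length(background)
    for (s in sets) if (length(setdiff(s, background)))
      stop("set contains genes outside the background")
    sizes <- vapply(sets, function(s) length(unique(s)), integer(1))
    observed <- length(Reduce(intersect, lapply(sets, unique)))
  }
  if (any(sizes > N)) stop("a set is larger than the background")
  dist <- multiset_intersection_distribution(sizes, N)
  expected <- N * prod(sizes / N)
  p <- sum(dist[(observed + 1):length(dist)])  # P(K >= observed)
  res <- list(sizes = sizes, background = N, observed = observed,
              expected = expected,
              fold_enrichment = if (expected > 0) observed / expected else NA,
              p_value = min(1, max(p, .Machine$double.xmin)),
              distribution = dist)
  class(res) <- "intersection_test"
  res
}

#' @rdname multiset_intersection_test
#' @param sizes integer set sizes n_1..n_m.
#' @param N background size.
#' @return for the distribution function: numeric vector of
#'   P(K = 0..min(sizes)).
#' @export
multiset_intersection_distribution <- function(sizes, N) {
  stopifnot(length(sizes) >= 2, all(sizes >= 0), all(sizes <= N))
  kmax <- min(sizes)
  # P(|S1 cap S2| = k)
  p <- stats::dhyper(0:kmax, sizes[1], N - sizes[1], sizes[2])
  if (length(sizes) > 2) for (j in 3:length(sizes)) {
    pn <- numeric(kmax + 1)
    for (s in 0:kmax) {
      if (p[s + 1] == 0) next
      ks <- 0:s
      pn[ks + 1] <- pn[ks + 1] + p[s + 1] *
        stats::dhyper(ks, s, N - s, sizes[j])
    }
    p <- pn
  }
  p / sum(p)
}

#' @export
print.intersection_test <- function(x, ...) {
  cat(sprintf("Multi-set intersection test: m = %d sets, background N = %d\n",
              length(x$sizes), x$background))
  cat(sprintf("  observed %d, expected %.3f, fold enrichment %.3f, p = %.4g\n",
              x$observed, x$expected, x$fold_enrichment, x$p_value))
  invisible(x)
}
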