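# Maximum-likelihood fitting: branch lengths under an amino-acid model
# (coordinate-wise Brent sweeps with cached outside partials) and the M0
# codon fit (kappa, omega, tree scale) that seeds the branch-site models.

#' Fit branch lengths by maximum likelihood under a fixed model
#'
#' Coordinate-wise (Gauss-Seidel) optimisation: every branch length in
#' turn is optimised by Brent search with the inside/outside partials
#' refreshed under the lengths fitted so far; sweeps repeat until the
#' log-likelihood gain drops below `tol`.
#'
#' @param aln alignment matrix or encoded alignment.
#' @param tree starting `phylo`; its branch lengths are the initial values
#'   (zeros are nudged to 0.05).
#' @param model `subst_model` (typically [dayhoff_model()]).
#' @param max_sweeps maximum sweeps over all branches.
#' @param tol log-likelihood convergence tolerance between sweeps.
#' @param max_len upper bound per branch.
#' @return list with the fitted `tree`, `loglik`, number of `sweeps` used,
#'   and `converged` flag.
#' @export
fit_branch_lengths <- function(aln, tree, model, max_sweeps = 8, tol = 1e-4,
                               max_len = 20) {
  enc <- if (is.list(aln) && !is.null(aln$tipp)) aln else
    encode_alignment(aln, if (model$type == "codon") "codon" else "protein")
  tree$edge.length[tree$edge.length <= 0] <- 0.05
  ll_of <- function(tr) {
    P <- edge_transition_matrices(tr, model)
    up <- peel_up(enc, tr, P)
    sum(enc$weights * root_loglik_patterns(enc, tr, up, model$freqs))
  }
  ll <- ll_of(tree)
  converged <- FALSE
  sweeps <- 0
  for (sw in seq_len(max_sweeps)) {
    sweeps <- sw
    prev_tree <- tree
    P <- edge_transition_matrices(tree, model)
    for (e in seq_len(nrow(tree$edge))) {
      # refresh the partials with the lengths fitted so far (Gauss-Seidel)
      P[[e]] <- transition_matrix(model, tree$edge.length[e])
      up <- peel_up(enc, tree, P)
      down <- peel_down(enc, tree, P, up, model$freqs)
      v <- tree$edge[e, 2]
      A <- down$Aout[[e]]
      U <- up$ups[[v]]
      f <- function(t) {
        Pe <- transition_matrix(model, t)
        lik <- colSums(A * (Pe %*% U))
        lik[lik <= 0] <- .Machine$double.xmin
        -sum(enc$weights * log(lik))
      }
      opt <- stats::optimize(f, c(1e-9, max_len), tol = 1e-7)
      tree$edge.length[e] <- opt$minimum
      P[[e]] <- transition_matrix(model, opt$minimum)
    }
    new_ll <- ll_of(tree)
    if (new_ll < ll - 1e-8) { tree <- prev_tree; break }  # stale-partial overshoot
    if (new_ll - ll < tol) { ll <- new_ll; converged <- TRUE; break }
    ll <- new_ll
  }
  list(tree = tree, loglik = ll, sweeps = sweeps, converged = converged)
}

#' Fit the one-ratio M0 codon model
#'
#' Maximum-likelihood estimates of kappa, omega and a tree-scale factor
#' (all input branch lengths multiplied by one free constant), with codon
#' frequencies fixed (default F3x4 from the alignment). Three deterministic
#' starts; the best optimum is kept.
#'
#' @param aln codon alignment (taxa x codon-site matrix of codon strings)
#'   or encoded alignment.
#' @param tree `phylo`; relative branch lengths are taken as fixed.
#' @param codon_freqs 61 frequencies; computed by [codon_frequencies()]
#'   when `NULL` (requires `aln` to be a matrix).
#' @param starts matrix of starting values, columns kappa/omega/scale.
#' @return list with estimates (`kappa`, `omega`, `scale`), `loglik`,
#'   `freqs`, and `convergence` code from [stats::optim()].
#' @export
fit_m0 <- function(aln, tree, codon_freqs = NULL,
                   starts = rbind(c(2, 0.3, 1), c(4, 1, 0.5), c(1.5, 0.1, 2))) {
  if (is.null(codon_freqs)) {
    if (is.list(aln) && !is.null(aln$tipp))
      stop("codon_freqs required when aln is pre-encoded")
    codon_freqs <- codon_frequencies(aln)
  }
  enc <- if (is.list(aln) && !is.null(aln$tipp)) aln else
    encode_alignment(aln, "codon")
  nll <- function(par) {
    kappa <- exp(par[1]); omega <- exp(par[2]); nu <- exp(par[3])
    m <- codon_model(kappa, omega, codon_freqs, scale = TRUE)
    -log_likelihood(enc, tree, m, scale = nu)$total
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(
      stats::optim(log(starts[i, ]), nll, method = "L-BFGS-B",
                   lower = log(c(0.05, 1e-4, 1e-4)),
                   upper = log(c(100, 20, 100)),
                   control = list(factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("M0 optimisation failed from all starts")
  list(kappa = exp(best$par[1]), omega = exp(best$par[2]),
       scale = exp(best$par[3]), loglik = -best$value, freqs = codon_freqs,
       convergence = best$convergence)
}

#' General ML parameter fitting dispatcher
#'
#' Thin front-end over the specialised fitters: frees any of
#' `branch_lengths` (amino-acid models) and `kappa`/`omega`/`scale`
#' (codon models).
#'
#' @param aln alignment matrix.
#' @param tree `phylo`.
#' @param model `subst_model` template (its type selects the fitter).
#' @param free character vector of parameters to estimate.
#' @param ... passed to the underlying fitter.
#' @return the underlying fitter's result.
#' @export
fit_parameters <- function(aln, tree, model,
                           free = c("branch_lengths"), ...) {
  if ("branch_lengths" %in% free) {
    if (model$type != "aa")
      stop("branch-length fitting is provided for amino-acid models")
    return(fit_branch_lengths(aln, tree, model, ...))
  }
  if (any(c("kappa", "omega", "scale") %in% free)) {
    if (model$type != "codon") stop("kappa/omega fitting needs a codon model")
    return(fit_m0(aln, tree, ...))
  }
  stop("nothing to fit: ", paste(free, collapse = ", "))
}
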