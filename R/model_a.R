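# Branch-site Model A, its null, the 1-df LRT, and empirical-Bayes site
# identification (NEB and BEB).
#
# Model A: four site classes with proportions
#   p0 (omega0 on all branches), p1 (omega1 = 1 everywhere),
#   p2a = (1-p0-p1) p0/(p0+p1)  (background omega0, foreground omega2),
#   p2b = (1-p0-p1) p1/(p0+p1)  (background 1,      foreground omega2),
# i.e. with c = p0+p1 and r = p0/(p0+p1) the weights factor as
# (cr, c(1-r), (1-c)r, (1-c)(1-r)).
#
# Fitting strategy: kappa and the tree-scale factor are estimated once per
# gene under M0 and held fixed; the outer optimisation runs over
# (omega0, omega2) while (c, r) is profiled out by a closed-form EM.
# Class site-likelihoods do not depend on the proportions, so each outer
# evaluation needs one pruning pass at omega0 (the omega_bg = 1 pass is
# cached) plus a single extra transition matrix on the foreground branch.

# inside/outside context for one background omega: everything needed to
# get class site log-likelihoods for any foreground omega
bs_context <- function(enc, tree, fg_edge, kappa, omega_bg, freqs, s) {
  m <- codon_model(kappa, omega_bg, freqs, scale = FALSE)
  P <- edge_transition_matrices(tree, m, s)
  up <- peel_up(enc, tree, P)
  down <- peel_down(enc, tree, P, up, m$freqs)
  v <- tree$edge[fg_edge, 2]
  list(ll_pat = root_loglik_patterns(enc, tree, up, m$freqs),
       A = down$Aout[[fg_edge]], Ascale = down$Ascale[[fg_edge]],
       U = up$ups[[v]], Uscale = up$upscale[[v]],
       t_fg = tree$edge.length[fg_edge] * s,
       kappa = kappa, freqs = freqs)
}

# class site log-likelihood with foreground omega_fg on top of a context
bs_class_ll <- function(ctx, omega_fg) {
  m <- codon_model(ctx$kappa, omega_fg, ctx$freqs, scale = FALSE)
  Pe <- transition_matrix(m, ctx$t_fg)
  lik <- colSums(ctx$A * (Pe %*% ctx$U))
  lik[lik <= 0] <- .Machine$double.xmin
  log(lik) + ctx$Ascale + ctx$Uscale
}

modelA_weights <- function(c_, r_) c(c_ * r_, c_ * (1 - r_),
                                     (1 - c_) * r_, (1 - c_) * (1 - r_))

# profile out (c, r) by EM given the 4 x npat class log-likelihood matrix;
# returns maximised lnL, weights, and per-pattern class posteriors
bs_profile_proportions <- function(Lmat, wpat, c0 = 0.85, r0 = 0.6,
                                   iter = 200, tol = 1e-8) {
  mx <- apply(Lmat, 2, max)
  E <- exp(sweep(Lmat, 2, mx, "-"))      # 4 x npat
  c_ <- c0; r_ <- r0
  last <- -Inf
  for (it in seq_len(iter)) {
    w <- modelA_weights(c_, r_)
    mix <- colSums(E * w)
    ll <- sum(wpat * (log(mix) + mx))
    g <- E * w / rep(mix, each = 4)       # responsibilities
    Nk <- as.vector(g %*% wpat)
    N <- sum(Nk)
    c_ <- min(max((Nk[1] + Nk[2]) / N, 1e-6), 1 - 1e-6)
    r_ <- min(max((Nk[1] + Nk[3]) / N, 1e-6), 1 - 1e-6)
    if (ll - last < tol && it > 3) break
    last <- ll
  }
  w <- modelA_weights(c_, r_)
  mix <- colSums(E * w)
  list(loglik = sum(wpat * (log(mix) + mx)), c_ = c_, r_ = r_, weights = w,
       post = E * w / rep(mix, each = 4))
}

#' Fit branch-site Model A (alternative or null)
#'
#' Maximum-likelihood fit of the branch-site model on the branch tagged as
#' foreground. `fit_model_a_null()` fixes omega2 = 1 (the null the 1-df
#' LRT compares against).
#'
#' @param aln codon alignment: taxa x codon-site matrix of codon strings
#'   (see [codon_view()]), or nucleotide taxa x (3n) matrix.
#' @param tree `phylo` whose relative branch lengths are trusted; one
#'   branch must carry the foreground tag.
#' @param foreground branch tag (default `"1"`) or edge index.
#' @param codon_freqs optional 61 frequencies (default F3x4 from `aln`).
#' @param m0 optional precomputed [fit_m0()] result to share between the
#'   alternative and null fits.
#' @param null fit the null model (omega2 fixed at 1)?
#' @return object of class `modelA_fit`: estimates `p0, p1, p2a, p2b,
#'   omega0, omega2, kappa`, `loglik`, per-site NEB class posteriors, and
#'   the frozen context needed by [eb_site_posteriors()].
#' @export
fit_model_a <- function(aln, tree, foreground = "1", codon_freqs = NULL,
                        m0 = NULL, null = FALSE) {
  aln <- as.matrix(aln)
  if (nchar(aln[1, 1]) == 1) aln <- codon_view(aln)  # nucleotide columns
  tree <- match_tree_alignment(tree, aln)
  fg_edge <- resolve_branch(tree, foreground)
  if (is.null(codon_freqs)) codon_freqs <- codon_frequencies(aln)
  enc <- encode_alignment(aln, "codon")
  if (is.null(m0)) m0 <- fit_m0(enc, tree, codon_freqs)
  # time multiplier making unscaled-Q branch lengths match the M0 fit
  r_u <- codon_model(m0$kappa, m0$omega, codon_freqs, scale = FALSE)$rate
  s <- m0$scale / r_u
  ctx1 <- bs_context(enc, tree, fg_edge, m0$kappa, 1, codon_freqs, s)
  cache <- new.env(parent = emptyenv())
  ctx0_for <- function(w0) {
    key <- sprintf("%.12g", w0)
    if (is.null(cache[[key]]))
      cache[[key]] <- bs_context(enc, tree, fg_edge, m0$kappa, w0,
                                 codon_freqs, s)
    cache[[key]]
  }
  class_L <- function(w0, w2) {
    ctx0 <- ctx0_for(w0)
    rbind(ctx0$ll_pat, ctx1$ll_pat,
          if (w2 == w0) ctx0$ll_pat else bs_class_ll(ctx0, w2),
          if (w2 == 1) ctx1$ll_pat else bs_class_ll(ctx1, w2))
  }
  obj <- function(w0, w2) bs_profile_proportions(class_L(w0, w2), enc$weights)
  if (null) {
    op <- stats::optimize(function(w0) -obj(w0, 1)$loglik,
                          interval = c(1e-4, 0.999), tol = 1e-5)
    w0_hat <- op$minimum; w2_hat <- 1
    flagged <- FALSE
  } else {
    nullfit <- fit_model_a(aln, tree, foreground, codon_freqs, m0, null = TRUE)
    w0n <- nullfit$omega0
    starts <- rbind(c(w0n, 1), c(w0n, 2.5),
                    c(min(max(m0$omega, 0.05), 0.9), 5))
    f2 <- function(p) -obj(p[1], p[2])$loglik
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      o <- tryCatch(
        stats::optim(starts[i, ], f2, method = "L-BFGS-B",
                     lower = c(1e-4, 1), upper = c(0.999, 50),
                     control = list(factr = 1e10)),
        error = function(e) NULL)
      if (is.null(o)) next
      if (is.null(best) || o$value < best$value) best <- o
    }
    flagged <- is.null(best)
    if (flagged) {  # fall back to the null start evaluation
      best <- list(par = c(w0n, 1), value = f2(c(w0n, 1)), convergence = 1L)
    }
    # optimisers can only improve on the null start, but guard exactly
    if (-best$value < nullfit$loglik) {
      best <- list(par = c(w0n, 1), value = -nullfit$loglik,
                   convergence = best$convergence)
    }
    w0_hat <- best$par[1]; w2_hat <- best$par[2]
  }
  sol <- obj(w0_hat, w2_hat)
  post_site <- sol$post[, enc$pattern_of_site, drop = FALSE]
  fit <- list(p0 = sol$weights[1], p1 = sol$weights[2],
              p2a = sol$weights[3], p2b = sol$weights[4],
              omega0 = w0_hat, omega2 = w2_hat,
              kappa = m0$kappa, tree_scale = m0$scale,
              loglik = sol$loglik, null = null, flagged = flagged,
              site_post_neb = post_site,
              n_taxa = length(tree$tip.label), n_sites = enc$nsites,
              .ctx = list(enc = enc, tree = tree, fg_edge = fg_edge,
                          kappa = m0$kappa, freqs = codon_freqs, s = s,
                          ctx1 = ctx1))
  class(fit) <- "modelA_fit"
  fit
}

#' @rdname fit_model_a
#' @export
fit_model_a_null <- function(aln, tree, foreground = "1", codon_freqs = NULL,
                             m0 = NULL) {
  fit_model_a(aln, tree, foreground, codon_freqs, m0, null = TRUE)
}

# prune tree to the alignment's taxa (and check coverage)
match_tree_alignment <- function(tree, aln) {
  taxa <- rownames(aln)
  extra <- setdiff(taxa, tree$tip.label)
  if (length(extra)) stop("taxon in alignment absent from tree: ",
                          paste(extra, collapse = ", "))
  if (length(tree$tip.label) > length(taxa)) {
    tags <- tree$edge.tag
    tree2 <- ape::keep.tip(tree, taxa)
    tree2$edge.tag <- rep(NA_character_, nrow(tree2$edge))
    # re-attach tags by tagged clade membership
    if (!is.null(tags)) for (e in which(!is.na(tags))) {
      members <- clade_tips(tree, tree$edge[e, 2])
      kept <- intersect(members, taxa)
      if (length(kept))
        tree2 <- tag_clade_stem_or_tip(tree2, kept, tags[e])
    }
    tree <- tree2
  }
  tree
}

clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[intersect(unlist(ape::prop.part(tree)[node - ntip]), 1:ntip)]
}

tag_clade_stem_or_tip <- function(tree, taxa, tag) {
  res <- try(tag_clade_stem(tree, taxa, tag), silent = TRUE)
  if (inherits(res, "try-error")) tree else res
}

#' Branch-site likelihood ratio test
#'
#' Twice the log-likelihood difference, clamped at zero, referred to a
#' chi-square with 1 degree of freedom.
#'
#' @param lnL_null,lnL_alt log-likelihoods of the null and alternative
#'   Model A fits (or the fit objects themselves).
#' @return object of class `bs_lrt` with `statistic`, `df = 1`, `p_value`.
#' @export
branch_site_lrt <- function(lnL_null, lnL_alt) {
  if (inherits(lnL_null, "modelA_fit")) lnL_null <- lnL_null$loglik
  if (inherits(lnL_alt, "modelA_fit")) lnL_alt <- lnL_alt$loglik
  stopifnot(is.finite(lnL_null), is.finite(lnL_alt))
  if (lnL_alt < lnL_null - 1e-6)
    warning("alternative log-likelihood below null; optimiser issue, clamping")
  stat <- max(0, 2 * (lnL_alt - lnL_null))
  res <- list(lnL_null = lnL_null, lnL_alt = lnL_alt, statistic = stat,
              df = 1L, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  class(res) <- "bs_lrt"
  res
}

#' Empirical-Bayes posterior probability of the selected site classes
#'
#' Per-site posterior that the site belongs to class 2a or 2b (the classes
#' with omega2 on the foreground branch). NEB plugs in the MLEs; BEB
#' averages over a discrete uniform prior grid on (p0, p1, omega0, omega2),
#' weighting each gridpoint by its posterior given the data.
#'
#' @param fit alternative-model `modelA_fit`.
#' @param method `"BEB"` or `"NEB"`.
#' @param grid_n gridpoints per parameter dimension for BEB.
#' @return numeric vector, one PP per alignment site.
#' @export
eb_site_posteriors <- function(fit, method = c("BEB", "NEB"), grid_n = 10) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "modelA_fit"))
  if (method == "NEB")
    return(colSums(fit$site_post_neb[3:4, , drop = FALSE]))
  ctx <- fit$.ctx
  enc <- ctx$enc
  wpat <- enc$weights
  mid <- (2 * seq_len(grid_n) - 1) / (2 * grid_n)
  w0_grid <- mid                       # omega0 in (0,1)
  w2_grid <- 1 + 10 * mid              # omega2 in (1,11)
  pp <- expand.grid(p0 = mid, p1 = mid)
  pp <- pp[pp$p0 + pp$p1 < 1, ]        # uniform prior over the simplex grid
  n2 <- numeric(enc$npat)              # accumulated PP(2a+2b) numerator
  tot <- 0                             # accumulated gridpoint marginals
  ll_store <- vector("list", length(w0_grid) * length(w2_grid))
  # first pass: gridpoint log-marginals to find the max for stable exp
  k <- 0
  gp_ll <- matrix(NA_real_, nrow(pp), length(w0_grid) * length(w2_grid))
  for (i0 in seq_along(w0_grid)) {
    ctx0 <- bs_context(enc, ctx$tree, ctx$fg_edge, ctx$kappa, w0_grid[i0],
                       ctx$freqs, ctx$s)
    for (i2 in seq_along(w2_grid)) {
      k <- k + 1
      L <- rbind(ctx0$ll_pat, ctx$ctx1$ll_pat,
                 bs_class_ll(ctx0, w2_grid[i2]),
                 bs_class_ll(ctx$ctx1, w2_grid[i2]))
      mx <- apply(L, 2, max)
      E <- exp(sweep(L, 2, mx, "-"))
      ll_store[[k]] <- list(E = E, mx = mx)
      for (j in seq_len(nrow(pp))) {
        w <- modelA_weights(pp$p0[j] + pp$p1[j],
                            pp$p0[j] / (pp$p0[j] + pp$p1[j]))
        gp_ll[j, k] <- sum(wpat * (log(colSums(E * w)) + mx))
      }
    }
  }
  M <- max(gp_ll)
  post_gp <- exp(gp_ll - M)
  post_gp <- post_gp / sum(post_gp)
  for (k in seq_len(ncol(gp_ll))) {
    E <- ll_store[[k]]$E
    for (j in seq_len(nrow(pp))) {
      if (post_gp[j, k] < 1e-12) next
      w <- modelA_weights(pp$p0[j] + pp$p1[j],
                          pp$p0[j] / (pp$p0[j] + pp$p1[j]))
      mix <- colSums(E * w)
      n2 <- n2 + post_gp[j, k] * colSums(E[3:4, , drop = FALSE] *
                                           w[3:4]) / mix
    }
  }
  n2[n2 > 1] <- 1
  n2[enc$pattern_of_site]
}

#' Call positively selected sites
#'
#' Applies the gates: gene LRT p < `p_threshold`, omega2 > 1, and site
#' empirical-Bayes PP > `pp_threshold`.
#'
#' @param lrt `bs_lrt` for the gene.
#' @param fit alternative `modelA_fit`.
#' @param site_pps per-site PPs from [eb_site_posteriors()].
#' @param p_threshold,pp_threshold gates (defaults 0.05 and 0.5).
#' @return integer vector of 1-based site positions, sorted ascending.
#' @export
call_pss <- function(lrt, fit, site_pps, p_threshold = 0.05,
                     pp_threshold = 0.5) {
  stopifnot(inherits(lrt, "bs_lrt"), inherits(fit, "modelA_fit"))
  if (lrt$p_value >= p_threshold || fit$omega2 <= 1) return(integer(0))
  sort(which(site_pps > pp_threshold))
}

#' Aggregated-PSS alignment filter
#'
#' Alignment-error guard: compute the successive intervals between sorted
#' PSS positions; the gene is excluded when the median interval is <=
#' `max_median` amino acids. Genes with fewer than two PSSs have no
#' interval and are retained.
#'
#' @param pss_sites 1-based PSS positions.
#' @param max_median exclusion threshold on the median interval.
#' @return list with `retain` (logical) and `median_interval` (NA when
#'   fewer than 2 sites).
#' @export
pss_aggregation_filter <- function(pss_sites, max_median = 10) {
  pss_sites <- sort(pss_sites)
  if (length(pss_sites) < 2)
    return(list(retain = TRUE, median_interval = NA_real_))
  med <- stats::median(diff(pss_sites))
  list(retain = med > max_median, median_interval = med)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvalues numeric p-values in \[0, 1\].
#' @return adjusted p-values (monotone step-up, capped at 1).
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' @export
print.modelA_fit <- function(x, ...) {
  cat(sprintf("Branch-site Model A (%s), %d taxa, %d codon sites\n",
              if (x$null) "null: omega2 = 1" else "alternative",
              x$n_taxa, x$n_sites))
  cat(sprintf("  lnL = %.4f\n", x$loglik))
  print(round(coef(x), 4))
  if (x$flagged) cat("  [optimiser flagged: result from fallback start]\n")
  invisible(x)
}

#' @export
coef.modelA_fit <- function(object, ...) {
  c(p0 = object$p0, p1 = object$p1, p2a = object$p2a, p2b = object$p2b,
    omega0 = object$omega0, omega2 = object$omega2, kappa = object$kappa)
}

#' @export
logLik.modelA_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- if (object$null) 3 else 4  # p0, p1, omega0 (+ omega2)
  class(val) <- "logLik"
  val
}

#' @export
summary.modelA_fit <- function(object, ...) {
  out <- list(coef = coef(object), loglik = object$loglik,
              null = object$null,
              n_taxa = object$n_taxa, n_sites = object$n_sites,
              top_sites = utils::head(
                order(colSums(object$site_post_neb[3:4, , drop = FALSE]),
                      decreasing = TRUE), 5))
  class(out) <- "summary.modelA_fit"
  out
}

#' @export
print.summary.modelA_fit <- function(x, ...) {
  cat(sprintf("Branch-site Model A %s fit\n",
              if (x$null) "null" else "alternative"))
  cat(sprintf("  %d taxa, %d sites, lnL = %.4f\n", x$n_taxa, x$n_sites,
              x$loglik))
  print(round(x$coef, 4))
  cat("  highest NEB selected-class sites:", x$top_sites, "\n")
  invisible(x)
}

#' @export
print.bs_lrt <- function(x, ...) {
  cat(sprintf("Branch-site LRT: 2*dlnL = %.4f (df = 1), p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}
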