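# Substitution models: empirical Dayhoff amino-acid model and the
# Goldman-Yang-style codon model parameterised by kappa and omega.
# Reversible rate matrices are diagonalised through the symmetrised form
# B = diag(sqrt(pi)) Q diag(1/sqrt(pi)) so exp(Qt) reuses one eigensystem
# across branches.

# Published Dayhoff exchangeabilities, lower triangle in ARNDCQEGHILKMFPSTWYV
# order (row 2 = R vs A; row 3 = N vs A,R; ...).
DAYHOFF_EXCH_LOWER <- c(
  27, 98, 120, 36, 89, 198, 240, 23, 65, 41, 26, 72, 18, 250, 409, 371, 0, 24,
  208, 32, 0, 23, 246, 1, 9, 240, 64, 15, 464, 90, 14, 103, 154, 26, 201, 8,
  24, 905, 0, 103, 148, 139, 535, 77, 34, 318, 1, 14, 42, 495, 229, 23, 95,
  15, 0, 134, 1153, 125, 86, 24, 0, 71, 0, 0, 13, 95, 66, 0, 0, 18, 0, 0, 11,
  28, 44, 0, 0, 0, 0, 19, 161, 16, 0, 96, 49, 716, 28, 606, 18, 73, 153, 114,
  0, 153, 56, 53, 0, 0, 35, 81, 43, 61, 11, 83, 30, 0, 51, 79, 34, 0, 22, 37,
  10, 0, 7, 27, 17, 15, 34, 234, 30, 0, 0, 54, 7, 44, 26, 0, 48, 94, 35, 22,
  27, 127, 44, 257, 46, 336, 196, 12, 24, 192, 0, 37, 889, 18, 527, 157, 32,
  17, 33, 46, 28, 175, 243, 0, 33, 96, 136, 0, 13, 10, 92, 17, 62, 104, 0, 0,
  258, 11, 46, 13, 76, 698, 12, 245, 78, 0, 0, 48, 550, 75, 34, 30, 0, 42,
  157, 61, 0, 28)

DAYHOFF_FREQS <- c(
  0.0871269, 0.0409040, 0.0404320, 0.0468720, 0.0334740, 0.0382550,
  0.0495300, 0.0886119, 0.0336180, 0.0368860, 0.0853569, 0.0804819,
  0.0147530, 0.0397720, 0.0506799, 0.0695769, 0.0585419, 0.0104940,
  0.0299160, 0.0647179)

dayhoff_exchangeability <- function() {
  S <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  S[lower.tri(S)] <- DAYHOFF_EXCH_LOWER
  S <- S + t(S)
  S
}

# Build a reversible rate matrix from exchangeabilities and frequencies,
# optionally scaled to one expected substitution per unit time, and attach
# the symmetrised eigensystem used by transition_matrix().
make_rev_model <- function(S, freqs, states, scale = TRUE, type = "aa") {
  stopifnot(isTRUE(all.equal(S, t(S), tolerance = 1e-12)), all(S >= 0),
            all(freqs > 0))
  freqs <- freqs / sum(freqs)
  Q <- S * rep(freqs, each = nrow(S))  # q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freqs * diag(Q))
  if (scale) Q <- Q / rate
  sp <- sqrt(freqs)
  B <- Q * (sp / rep(sp, each = nrow(Q)))  # diag(sp) Q diag(1/sp), symmetric
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  mod <- list(Q = Q, freqs = freqs, states = states, type = type,
              rate = if (scale) 1 else rate,
              eig_values = eig$values,
              # P(t) = Pleft %*% diag(exp(lambda t)) %*% Pright
              Pleft = eig$vectors / sp,
              Pright = t(eig$vectors) * rep(sp, each = nrow(Q)))
  class(mod) <- "subst_model"
  mod
}

#' Dayhoff amino-acid substitution model
#'
#' Constructs the empirical Dayhoff rate matrix, either with the published
#' stationary frequencies or with frequencies estimated from a supplied
#' protein alignment (the "+F" style), scaled to one expected substitution
#' per unit time.
#'
#' @param freq_mode `"model_builtin"` for the published frequencies or
#'   `"empirical_from_alignment"` to count them from `alignment`.
#' @param alignment protein alignment matrix (taxa x sites, one-letter
#'   residues) used when `freq_mode = "empirical_from_alignment"`.
#' @return An object of class `subst_model` with rate matrix `Q`,
#'   `freqs`, state labels, and a cached eigensystem.
#' @export
dayhoff_model <- function(freq_mode = c("model_builtin", "empirical_from_alignment"),
                          alignment = NULL) {
  freq_mode <- match.arg(freq_mode)
  if (freq_mode == "model_builtin") {
    freqs <- DAYHOFF_FREQS
  } else {
    if (is.null(alignment)) stop("empirical frequencies need an alignment")
    res <- toupper(as.vector(as.matrix(alignment)))
    res <- res[res %in% AA_ORDER]
    if (!length(res)) stop("alignment has no unambiguous residues")
    counts <- table(factor(res, levels = AA_ORDER))
    if (any(counts == 0)) {
      warning("add-one smoothing applied: some amino acids unobserved")
      counts <- counts + 1
    }
    freqs <- as.numeric(counts) / sum(counts)
  }
  make_rev_model(dayhoff_exchangeability(), freqs, AA_ORDER, scale = TRUE,
                 type = "aa")
}

#' Codon substitution model (61 sense codons)
#'
#' Builds the standard reversible codon model: substitutions changing more
#' than one codon position have rate 0; single-position changes get rate
#' proportional to the target codon frequency, multiplied by `kappa` for
#' transitions and by `omega` for nonsynonymous changes.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param codon_freqs 61 equilibrium codon frequencies summing to 1.
#' @param scale if `TRUE`, scale Q to one expected substitution per codon
#'   per unit time; branch-site fits keep `scale = FALSE` and absorb units
#'   in a tree-scale parameter.
#' @return An object of class `subst_model` over the 61 sense codons.
#' @export
codon_model <- function(kappa, omega, codon_freqs, scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(codon_freqs) == 61)
  if (abs(sum(codon_freqs) - 1) > 1e-8)
    stop("codon frequencies must sum to 1 (within 1e-8)")
  tab <- codon_table()
  S <- codon_exch_matrix(kappa, omega)
  mod <- make_rev_model(S, codon_freqs, tab$codons, scale = scale,
                        type = "codon")
  mod$kappa <- kappa
  mod$omega <- omega
  mod
}

# exchangeability s_ij for the codon model: 0 unless one nt difference;
# kappa for transitions; omega for nonsynonymous changes
.codon_exch_env <- new.env(parent = emptyenv())
codon_exch_matrix <- function(kappa, omega) {
  if (is.null(.codon_exch_env$mask)) {
    ntm <- codon_nt_matrix()
    tab <- codon_table()
    n <- 61
    ndiff <- matrix(0L, n, n)
    ts <- matrix(FALSE, n, n)
    for (p in 1:3) {
      d <- outer(ntm[, p], ntm[, p], "!=")
      ndiff <- ndiff + d
      ts <- ts | (d & outer(ntm[, p], ntm[, p], is_transition))
    }
    one <- ndiff == 1L
    nonsyn <- outer(tab$aa_index, tab$aa_index, "!=")
    .codon_exch_env$mask <- list(one = one, ts = ts & one,
                                 nonsyn = nonsyn & one)
  }
  m <- .codon_exch_env$mask
  S <- matrix(0, 61, 61)
  S[m$one] <- 1
  S[m$ts] <- S[m$ts] * kappa
  S[m$nonsyn] <- S[m$nonsyn] * omega
  S
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a `subst_model`.
#' @param t branch length (>= 0), in the model's time units.
#' @return Row-stochastic matrix of transition probabilities.
#' @export
transition_matrix <- function(model, t) {
  if (!inherits(model, "subst_model")) stop("model must be a subst_model")
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  P <- (model$Pleft * rep(exp(model$eig_values * t), each = nrow(model$Pleft))) %*%
    model$Pright
  # clamp tiny negative round-off
  P[P < 0] <- 0
  P / rowSums(P)
}

#' F3x4 codon equilibrium frequencies
#'
#' Position-specific nucleotide frequencies estimated from a codon alignment,
#' multiplied across the three codon positions and renormalised over the 61
#' sense codons. `f1x4` pools positions; `f61` counts codons directly.
#'
#' @param aln codon alignment (taxa x codon-site character matrix of codon
#'   strings, or nucleotide taxa x (3*sites) matrix).
#' @param method one of `"f3x4"`, `"f1x4"`, `"f61"`.
#' @return numeric vector of 61 frequencies summing to 1.
#' @export
codon_frequencies <- function(aln, method = c("f3x4", "f1x4", "f61")) {
  method <- match.arg(method)
  codons <- toupper(as.vector(as.matrix(aln)))
  codons <- codons[grepl("^[ACGT]{3}$", codons)]
  if (!length(codons)) stop("no unambiguous codons in alignment")
  tab <- codon_table()
  if (method == "f61") {
    counts <- table(factor(codons, levels = tab$codons)) + 1 # add-one
    f <- as.numeric(counts) / sum(counts)
    return(f)
  }
  ntlev <- c("T", "C", "A", "G")
  pos <- vapply(1:3, function(p)
    as.numeric(table(factor(substr(codons, p, p), levels = ntlev)) + 1),
    numeric(4))
  pos <- sweep(pos, 2, colSums(pos), "/")
  if (method == "f1x4") pos[] <- rep(rowMeans(pos), 3)
  ntm <- codon_nt_matrix()
  f <- pos[ntm[, 1], 1] * pos[ntm[, 2], 2] * pos[ntm[, 3], 3]
  f / sum(f)
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s substitution model (%d states), mean rate %.4g\n",
              if (x$type == "aa") "Amino-acid" else "Codon",
              length(x$states), x$rate))
  if (!is.null(x$kappa))
    cat(sprintf("  kappa = %.4g, omega = %.4g\n", x$kappa, x$omega))
  invisible(x)
}
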