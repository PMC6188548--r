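# Screen orchestration: per-gene selection runs over a gene directory,
# convergence runs per branch pair, PSG set intersections, and the
# selection x convergence co-occurrence map. Per-gene failures are
# quarantined; completed output is reused on rerun.

#' Run the branch-site selection screen over a directory of genes
#'
#' For every FASTA in `gene_dir`: sequence and alignment QC, pruning to
#' the clade configuration, the taxon gate, the Model A alternative/null
#' fits, the LRT, empirical-Bayes PSS calls and the aggregated-PSS filter.
#'
#' @param gene_dir directory of per-gene FASTA files (aligned CDS).
#' @param tree master species tree (`phylo`).
#' @param clade clade definition (see [study_clades()]).
#' @param out_tsv optional path: results are appended there and genes
#'   already present are skipped on rerun.
#' @param eb_method `"BEB"` (default) or `"NEB"`.
#' @param max_genes optional cap (mainly for examples).
#' @param verbose print progress?
#' @return data frame: gene, n_taxa, n_codons, lnL0, lnL1, stat, p, p_fdr,
#'   omega2, n_pss, pss_sites, filter_flag, status.
#' @export
run_selection_screen <- function(gene_dir, tree, clade, out_tsv = NULL,
                                 eb_method = "BEB", max_genes = Inf,
                                 verbose = FALSE) {
  files <- sort(list.files(gene_dir, pattern = "\\.fa(sta)?$",
                           full.names = TRUE))
  if (!length(files)) stop("no FASTA files in ", gene_dir)
  done <- character(0)
  prev <- NULL
  if (!is.null(out_tsv) && file.exists(out_tsv)) {
    prev <- read_tsv(out_tsv)
    done <- prev$gene
  }
  rows <- list()
  n_run <- 0
  for (f in files) {
    gene <- sub("\\.fa(sta)?$", "", basename(f))
    if (gene %in% done) next
    if (n_run >= max_genes) break
    n_run <- n_run + 1
    row <- tryCatch(
      screen_one_gene(f, gene, tree, clade, eb_method),
      error = function(e) data.frame(
        gene = gene, n_taxa = NA, n_codons = NA, lnL0 = NA, lnL1 = NA,
        stat = NA, p = NA_real_, p_fdr = NA, omega2 = NA, n_pss = NA,
        pss_sites = "", filter_flag = "error",
        status = paste0("quarantined: ", conditionMessage(e))))
    rows[[gene]] <- row
    if (verbose) message(gene, ": ", row$status)
  }
  res <- do.call(rbind, c(list(prev), rows))
  rownames(res) <- NULL
  tested <- res$status == "tested" & !is.na(res$p)
  res$p_fdr <- NA_real_
  res$p_fdr[tested] <- bh_fdr(res$p[tested])
  if (!is.null(out_tsv)) write_tsv(res, out_tsv)
  res
}

screen_one_gene <- function(fasta, gene, tree, clade, eb_method) {
  base <- data.frame(gene = gene, n_taxa = NA_integer_,
                     n_codons = NA_integer_, lnL0 = NA_real_,
                     lnL1 = NA_real_, stat = NA_real_, p = NA_real_,
                     p_fdr = NA_real_, omega2 = NA_real_,
                     n_pss = NA_integer_, pss_sites = "",
                     filter_flag = "", status = "")
  seqs <- read_fasta(fasta, "dna")
  qa <- qc_alignment(seqs_to_matrix(seqs))
  if (!qa$keep) {
    base$status <- "excluded_qc_alignment"
    return(base)
  }
  pr <- prune_dataset(qa$aln, tree, clade)
  if (!pr$gate$include) {
    base$status <- paste0("excluded_", pr$gate$reason)
    return(base)
  }
  base$n_taxa <- nrow(pr$aln)
  base$n_codons <- ncol(pr$aln)
  freqs <- codon_frequencies(pr$aln)
  enc_tree <- pr$tree
  m0 <- fit_m0(encode_alignment(pr$aln, "codon"), enc_tree, freqs)
  fit0 <- fit_model_a_null(pr$aln, enc_tree, "1", freqs, m0)
  fit1 <- fit_model_a(pr$aln, enc_tree, "1", freqs, m0)
  lrt <- branch_site_lrt(fit0, fit1)
  base$lnL0 <- fit0$loglik
  base$lnL1 <- fit1$loglik
  base$stat <- lrt$statistic
  base$p <- lrt$p_value
  base$omega2 <- fit1$omega2
  pss <- integer(0)
  if (lrt$p_value < 0.05 && fit1$omega2 > 1) {
    pps <- eb_site_posteriors(fit1, eb_method)
    pss <- call_pss(lrt, fit1, pps)
  }
  base$n_pss <- length(pss)
  base$pss_sites <- paste(pss, collapse = ",")
  filt <- pss_aggregation_filter(pss)
  base$filter_flag <- if (filt$retain) "retain" else "exclude_median_interval"
  base$status <- "tested"
  base
}

#' Significant-gene sets from a selection table
#'
#' @param res result table from [run_selection_screen()].
#' @param p_threshold raw-p gate (0.05; FDR-adjusted values are reported
#'   alongside but not used as gates).
#' @return character vector of PSG gene ids (aggregation-filtered).
#' @export
psg_set <- function(res, p_threshold = 0.05) {
  ok <- res$status == "tested" & !is.na(res$p) & res$p < p_threshold &
    res$omega2 > 1 & res$filter_flag != "exclude_median_interval"
  res$gene[ok]
}

#' Intersections of per-lineage PSG sets
#'
#' For every combination of two or more lineages computes the observed
#' overlap, the expected overlap given the background, fold enrichment
#' and the exact upper-tail p-value.
#'
#' @param psg_sets named list of PSG gene id vectors.
#' @param background tested-gene universe (character vector).
#' @return list: `table` (one row per combination) and `membership`
#'   (gene x lineage logical matrix for UpSet-style output).
#' @export
intersect_psgs <- function(psg_sets, background) {
  stopifnot(length(psg_sets) >= 2, !is.null(names(psg_sets)))
  if (!length(background)) stop("empty background universe")
  combs <- unlist(lapply(2:length(psg_sets), function(m)
    utils::combn(names(psg_sets), m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(combs, function(cc) {
    tst <- multiset_intersection_test(psg_sets[cc], background)
    data.frame(lineages = paste(cc, collapse = "+"), m = length(cc),
               observed = tst$observed, expected = tst$expected,
               fold_enrichment = tst$fold_enrichment, p = tst$p_value)
  })
  genes <- sort(unique(unlist(psg_sets)))
  membership <- vapply(psg_sets, function(s) genes %in% s,
                       logical(length(genes)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = length(genes))
  rownames(membership) <- genes
  list(table = do.call(rbind, rows), membership = membership)
}

#' Selection x convergence co-occurrence map
#'
#' Gene level: genes that are PSGs in both lineages of a pair AND have
#' summed convergence PP >= 1.0. Site level: sites that are PSS in at
#' least one lineage AND convergent (sitewise PP > 0.5), reported with
#' per-lineage presence flags.
#'
#' @param sel1,sel2 selection tables of the two lineages (same gene
#'   universe and trimmed-alignment coordinates).
#' @param conv data frame with one row per gene: `gene`,
#'   `summed_pp_total`, and a list-column or comma-string `sites_gt_half`
#'   of sitewise-convergent site positions.
#' @return list: `gene_level` (data frame with flags and the combined
#'   call), `site_level` (gene, site, is_pss_lineage1, is_pss_lineage2,
#'   pp_gt_half), `proportion` (genes flagged at gene level / tested
#'   genes).
#' @export
cooccurrence_map <- function(sel1, sel2, conv) {
  common <- intersect(intersect(sel1$gene, sel2$gene), conv$gene)
  s1 <- sel1[match(common, sel1$gene), ]
  s2 <- sel2[match(common, sel2$gene), ]
  cv <- conv[match(common, conv$gene), ]
  len_mismatch <- !is.na(s1$n_codons) & !is.na(s2$n_codons) &
    s1$n_codons != s2$n_codons
  psg1 <- common %in% psg_set(s1)
  psg2 <- common %in% psg_set(s2)
  gene_level <- data.frame(
    gene = common,
    psg_in_both = psg1 & psg2,
    summed_pp_ge_1 = cv$summed_pp_total >= 1.0,
    cooccurs = psg1 & psg2 & cv$summed_pp_total >= 1.0)
  parse_sites <- function(x) {
    if (is.list(x)) return(lapply(x, as.integer))
    lapply(strsplit(ifelse(is.na(x), "", x), ","),
           function(v) as.integer(v[nzchar(v)]))
  }
  conv_sites <- parse_sites(cv$sites_gt_half)
  pss1 <- parse_sites(s1$pss_sites)
  pss2 <- parse_sites(s2$pss_sites)
  site_rows <- list()
  for (i in seq_along(common)) {
    hits <- intersect(conv_sites[[i]], union(pss1[[i]], pss2[[i]]))
    for (st in hits)
      site_rows[[length(site_rows) + 1]] <- data.frame(
        gene = common[i], site = st,
        is_pss_lineage1 = st %in% pss1[[i]],
        is_pss_lineage2 = st %in% pss2[[i]],
        pp_gt_half = TRUE)
  }
  site_level <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(gene = character(0), site = integer(0),
               is_pss_lineage1 = logical(0), is_pss_lineage2 = logical(0),
               pp_gt_half = logical(0))
  tested <- sum(s1$status == "tested" & s2$status == "tested", na.rm = TRUE)
  list(gene_level = gene_level, site_level = site_level,
       proportion = if (tested) sum(gene_level$cooccurs) / tested else NA,
       n_tested = tested,
       coordinate_warnings = common[len_mismatch])
}

#' Run the identical screen on a control branch set
#'
#' Same pipeline as [run_selection_screen()], with the output tagged by
#' the branch set's type for side-by-side summaries.
#'
#' @param gene_dir,tree as in [run_selection_screen()].
#' @param clades named list of clade definitions (focal and control).
#' @param which_clades names to run (default: all).
#' @param ... passed to [run_selection_screen()].
#' @return named list of selection tables, each with a `branch_set`
#'   attribute; plus a `summary` data frame (one row per branch set).
#' @export
run_control_comparison <- function(gene_dir, tree, clades,
                                   which_clades = names(clades), ...) {
  out <- list()
  for (nm in which_clades) {
    res <- run_selection_screen(gene_dir, tree, clades[[nm]], ...)
    attr(res, "branch_set") <- nm
    attr(res, "type") <- clades[[nm]]$type
    out[[nm]] <- res
  }
  summ <- do.call(rbind, lapply(names(out), function(nm) {
    r <- out[[nm]]
    tested <- sum(r$status == "tested", na.rm = TRUE)
    data.frame(branch = nm, type = clades[[nm]]$type,
               excluded = sum(r$status != "tested"),
               tested = tested,
               psgs = length(psg_set(r)),
               psgs_fdr = sum(r$status == "tested" & !is.na(r$p_fdr) &
                                r$p_fdr < 0.05 & r$omega2 > 1 &
                                r$filter_flag != "exclude_median_interval"))
  }))
  list(tables = out, summary = summ)
}

#' Convergence screen over a directory of genes for one clade pair
#'
#' @param gene_dir directory of per-gene FASTA (aligned CDS).
#' @param tree master species tree.
#' @param clade1,clade2 clade definitions.
#' @param max_genes optional cap.
#' @param verbose print progress?
#' @return data frame: gene, summed PPs, site counts, flags, and the
#'   comma-separated convergent site list (`sites_gt_half`).
#' @export
run_convergence_screen <- function(gene_dir, tree, clade1, clade2,
                                   max_genes = Inf, verbose = FALSE) {
  files <- sort(list.files(gene_dir, pattern = "\\.fa(sta)?$",
                           full.names = TRUE))
  rows <- list()
  n <- 0
  for (f in files) {
    if (n >= max_genes) break
    n <- n + 1
    gene <- sub("\\.fa(sta)?$", "", basename(f))
    row <- tryCatch({
      seqs <- read_fasta(f, "dna")
      qa <- qc_alignment(seqs_to_matrix(seqs))
      if (!qa$keep) NULL else {
        prof <- scan_convergence(qa$aln, tree,
                                 clade1$members, clade2$members, gene = gene)
        if (is.null(prof)) NULL else data.frame(
          gene = gene,
          summed_pp_parallel = prof$summed_pp_parallel,
          summed_pp_convergent = prof$summed_pp_convergent,
          summed_pp_total = prof$summed_pp_total,
          n_sites_gt_half = prof$n_sites_pp_gt_half,
          flag_1.0 = prof$flag_1.0, flag_2.0 = prof$flag_2.0,
          sites_gt_half = paste(
            prof$site_pp$site[prof$site_pp$pp_total > 0.5], collapse = ","))
      }
    }, error = function(e) NULL)
    if (!is.null(row)) rows[[gene]] <- row
    if (verbose && !is.null(row)) message(gene)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
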