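# Deterministic alignment quality control: per-sequence filters
# (missing-data, codon padding, internal stops, length), codon-aware
# gap-column trimming, alignment length gate, and the taxon-composition
# gate. Every exclusion cites exactly one rule; all steps are idempotent.

#' Per-sequence QC on coding sequences
#'
#' Order of operations: (1) remove sequences with more than 50% missing
#' data (N); (2) pad incomplete final codons with N; (3) remove sequences
#' with an internal stop codon in frame; (4) remove sequences shorter than
#' `min_nt` nucleotides.
#'
#' @param records named character vector of nucleotide sequences (no
#'   alignment gaps expected at this stage; gaps are ignored for the
#'   missing-data fraction).
#' @param max_missing maximum tolerated fraction of N (default 0.5,
#'   exclusive).
#' @param min_nt minimum sequence length in nucleotides (default 150;
#'   shorter sequences are removed).
#' @return list: `records` (kept, possibly padded) and `report` (data
#'   frame: id, action, rule).
#' @export
qc_sequences <- function(records, max_missing = 0.5, min_nt = 150) {
  stopifnot(length(records) > 0, !is.null(names(records)))
  rep_rows <- list()
  note <- function(id, action, rule)
    rep_rows[[length(rep_rows) + 1]] <<- data.frame(id = id, action = action,
                                                    rule = rule)
  out <- character(0)
  for (id in names(records)) {
    s <- toupper(records[[id]])
    bases <- gsub("-", "", s)
    n_frac <- mean(strsplit(bases, "")[[1]] == "N")
    if (n_frac > max_missing) {
      note(id, "removed", "missing_data_gt_50pct")
      next
    }
    if (nchar(bases) %% 3 != 0) {
      pad <- 3 - nchar(bases) %% 3
      bases <- paste0(bases, strrep("N", pad))
      note(id, "padded", "incomplete_final_codon")
    }
    cods <- substring(bases, seq(1, nchar(bases) - 2, 3),
                      seq(3, nchar(bases), 3))
    internal <- cods[-length(cods)]
    if (any(internal %in% c("TAA", "TAG", "TGA"))) {
      note(id, "removed", "internal_stop_codon")
      next
    }
    if (nchar(bases) < min_nt) {
      note(id, "removed", "shorter_than_150nt")
      next
    }
    out[id] <- bases
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(id = character(0), action = character(0), rule = character(0))
  list(records = out, report = report)
}

#' Alignment-level QC: gap-column trimming and length gates
#'
#' Removes codon columns in which more than half the taxa are gapped
#' (columns are removed in whole codon triplets to preserve frame), then
#' removes sequences left with fewer than 50 non-gap codons, and finally
#' keeps the alignment only if it is longer than `min_codons` codons
#' (strict inequality).
#'
#' @param aln codon alignment: taxa x codon-site character matrix of codon
#'   strings, or taxa x nucleotide matrix (converted).
#' @param max_gap_frac maximum gapped fraction per codon column (0.5).
#' @param min_seq_codons minimum non-gap codons per retained sequence.
#' @param min_codons post-trim alignment length gate (strict >).
#' @return list: `aln` (trimmed codon matrix or NULL when discarded),
#'   `keep` (logical), `report` (data frame of actions), and
#'   `kept_columns` (indices into the input codon columns, for mapping
#'   site coordinates back).
#' @export
qc_alignment <- function(aln, max_gap_frac = 0.5, min_seq_codons = 50,
                         min_codons = 100) {
  aln <- as.matrix(aln)
  if (nchar(aln[1, 1]) == 1) aln <- codon_view(aln)
  rep_rows <- list()
  note <- function(id, action, rule)
    rep_rows[[length(rep_rows) + 1]] <<- data.frame(id = id, action = action,
                                                    rule = rule)
  gapped <- apply(aln, 2, function(col) mean(col == "---" | col == "NNN"))
  kept_columns <- which(gapped <= max_gap_frac)
  if (length(kept_columns) < ncol(aln))
    note("(alignment)", sprintf("removed_%d_columns",
                                ncol(aln) - length(kept_columns)),
         "gap_columns_gt_50pct")
  aln2 <- aln[, kept_columns, drop = FALSE]
  ngap <- apply(aln2, 1, function(r) sum(r != "---"))
  short <- ngap < min_seq_codons
  for (id in rownames(aln2)[short])
    note(id, "removed", "shorter_than_50_codons_post_trim")
  aln2 <- aln2[!short, , drop = FALSE]
  keep <- ncol(aln2) > min_codons && nrow(aln2) > 0
  if (!keep) note("(alignment)", "discarded", "not_longer_than_100_codons")
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(id = character(0), action = character(0), rule = character(0))
  list(aln = if (keep) aln2 else NULL, keep = keep, report = report,
       kept_columns = kept_columns)
}

#' Taxon-composition gate
#'
#' Excludes a gene when it has no outgroup taxon, no focal taxon, or
#' fewer than `min_taxa` taxa in total.
#'
#' @param taxa taxa present in the gene alignment.
#' @param focal_taxa,outgroup_taxa configured taxon sets.
#' @param min_taxa minimum total taxa (default 4).
#' @return list: `include` (logical) and `reason` (`NA` when included;
#'   otherwise the single rule violated, rules checked in the stated
#'   order).
#' @export
taxon_gate <- function(taxa, focal_taxa, outgroup_taxa, min_taxa = 4) {
  if (!length(intersect(taxa, outgroup_taxa)))
    return(list(include = FALSE, reason = "no_outgroup"))
  if (!length(intersect(taxa, focal_taxa)))
    return(list(include = FALSE, reason = "no_focal"))
  if (length(taxa) < min_taxa)
    return(list(include = FALSE, reason = "fewer_than_4_taxa"))
  list(include = TRUE, reason = NA_character_)
}

#' Prune a gene dataset to a clade configuration
#'
#' Restricts the alignment to the configured taxa (focal clade plus its
#' allowed sister/outgroup taxa) and prunes the species tree to the
#' intersection, collapsing removed paths additively so path lengths
#' between retained tips are preserved.
#'
#' @param aln codon alignment matrix.
#' @param tree master species tree.
#' @param clade clade definition (list with `members`, `prune_to`,
#'   `outgroups`), e.g. one element of [study_clades()].
#' @return list: `aln`, `tree` (with the clade stem tagged `"1"`), and
#'   `gate` (the [taxon_gate()] result computed on the pruned taxa).
#' @export
prune_dataset <- function(aln, tree, clade) {
  aln <- as.matrix(aln)
  keep <- intersect(rownames(aln), unique(c(clade$prune_to, clade$members)))
  aln2 <- aln[keep, , drop = FALSE]
  gate <- taxon_gate(keep, clade$members, clade$outgroups)
  if (!gate$include || length(keep) < 2)
    return(list(aln = aln2, tree = NULL,
                gate = if (length(keep) < 2)
                  list(include = FALSE, reason = "fewer_than_4_taxa") else gate))
  tr <- prune_tree(tree, keep)
  tr <- tag_clade_stem_or_tip(tr, intersect(clade$members, keep), "1")
  if (is.na(tagged_edge(tr, "1")))
    return(list(aln = aln2, tree = NULL,
                gate = list(include = FALSE, reason = "no_focal_stem")))
  list(aln = aln2, tree = tr, gate = gate)
}
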