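# The study-shaped species tree and clade configuration used by the
# synthetic fixtures: four focal subterranean clades (A golden moles,
# B African mole-rats, C spalacids, D star-nosed mole) and four
# nonsubterranean control branch sets (E elephant+hyrax, F guinea pig,
# G murids, H common shrew), embedded in a 41-taxon mammal topology.

STUDY_TOPOLOGY <- paste0(
  "(platypus,(opossum,((((tenrec,(goldenmole1,goldenmole2)),(aardvark,(el",
  "ephant,hyrax))),(armadillo,sloth)),(((((human,chimp),macaque),lemur),(",
  "(rabbit,pika),((guineapig,(molerat1,(molerat2,((molerat3,molerat4),(mo",
  "lerat5,(molerat6,(molerat7,molerat8))))))),(squirrel,((mouse,rat),(spa",
  "lacid1,(spalacid2,(spalacid3,spalacid4)))))))),((hedgehog,(shrew,(mole",
  "_eur,starnosedmole))),((cow,pig),(horse,(dog,cat))))))));")

#' Clade configuration of the synthetic study design
#'
#' Focal clades A-D, control branch sets E-H, the taxa each per-clade run
#' is pruned to (the clade plus closely related nonfocal sister taxa and
#' outgroups), and the outgroup set used by the taxon gate.
#'
#' @return named list of clade definitions (`members`, `prune_to`,
#'   `outgroups`, `type`).
#' @export
study_clades <- function() {
  glires_bg <- c("rabbit", "pika", "squirrel", "mouse", "rat")
  afro_bg <- c("tenrec", "aardvark", "elephant", "hyrax")
  lauras_bg <- c("hedgehog", "cow", "pig", "horse", "dog", "cat")
  primates <- c("human", "chimp", "macaque", "lemur")
  list(
    A = list(members = c("goldenmole1", "goldenmole2"), type = "focal",
             prune_to = c("goldenmole1", "goldenmole2", afro_bg, primates),
             outgroups = primates),
    B = list(members = paste0("molerat", 1:8), type = "focal",
             prune_to = c(paste0("molerat", 1:8), "guineapig", glires_bg,
                          primates),
             outgroups = primates),
    C = list(members = paste0("spalacid", 1:4), type = "focal",
             prune_to = c(paste0("spalacid", 1:4), "mouse", "rat", "squirrel",
                          "rabbit", "pika", primates),
             outgroups = primates),
    D = list(members = "starnosedmole", type = "focal",
             prune_to = c("starnosedmole", "mole_eur", "shrew", lauras_bg,
                          primates),
             outgroups = primates),
    E = list(members = c("elephant", "hyrax"), type = "control",
             prune_to = c("elephant", "hyrax", afro_bg[c(1, 2)],
                          "goldenmole1", "goldenmole2", primates),
             outgroups = primates),
    F = list(members = "guineapig", type = "control",
             prune_to = c("guineapig", paste0("molerat", 1:8), glires_bg,
                          primates),
             outgroups = primates),
    G = list(members = c("mouse", "rat"), type = "control",
             prune_to = c("mouse", "rat", paste0("spalacid", 1:4), "squirrel",
                          "rabbit", "pika", primates),
             outgroups = primates),
    H = list(members = "shrew", type = "control",
             prune_to = c("shrew", "starnosedmole", "mole_eur", lauras_bg,
                          primates),
             outgroups = primates))
}

#' The 41-taxon study-shaped species tree
#'
#' Fixed topology mirroring the study design (focal clades of sizes 2, 8,
#' 4 and 1 with their sisters, controls, primate outgroups and two
#' non-placental outgroups); branch lengths drawn once from a seeded
#' exponential distribution (mean 0.06 substitutions per site) since
#' published per-branch lengths are not available.
#'
#' @param seed RNG seed for the branch lengths.
#' @param mean_length mean branch length.
#' @return `phylo` with 41 tips and an `edge.tag` vector (all `NA`;
#'   tag clade stems with [tag_clade_stem()] per run).
#' @export
study_tree <- function(seed = 20180901, mean_length = 0.06) {
  tr <- parse_newick(STUDY_TOPOLOGY)
  set.seed(seed)
  tr$edge.length <- 0.01 + stats::rexp(nrow(tr$edge), 1 / mean_length)
  tr
}

#' Write a complete synthetic study fixture to disk
#'
#' Simulates `n_genes` codon alignments on the study tree: a fraction get
#' branch-site positive selection on a focal clade stem, a fraction get
#' parallel substitutions injected on a focal branch pair, and per-gene
#' taxon missingness is applied. Writes per-gene FASTA, the tree (Newick),
#' a run configuration TSV and ground-truth TSVs.
#'
#' @param out_dir output directory (created).
#' @param n_genes,n_codons fixture scale (defaults 200 x 300).
#' @param sel_fraction fraction of genes with foreground selection
#'   (omega2 = `sel_omega2` at the 2a/2b site classes).
#' @param inj_fraction fraction of genes with injected parallel sites.
#' @param n_inject injected sites per injected gene.
#' @param sel_omega2 foreground omega for selected genes.
#' @param dropout per-taxon missingness probability.
#' @param seed master seed; per-gene seeds derive from it.
#' @param tree species tree (default [study_tree()] with the same seed).
#' @return invisibly, a list with the truth tables and file paths.
#' @export
make_study_fixture <- function(out_dir, n_genes = 200, n_codons = 300,
                               sel_fraction = 0.10, inj_fraction = 0.05,
                               n_inject = 5, sel_omega2 = 4,
                               dropout = 0.10, seed = 1, tree = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "genes"), showWarnings = FALSE)
  if (is.null(tree)) tree <- study_tree(seed = seed)
  clades <- study_clades()
  focal <- names(Filter(function(x) x$type == "focal", clades))
  set.seed(seed)
  n_sel <- round(sel_fraction * n_genes)
  n_inj <- round(inj_fraction * n_genes)
  sel_genes <- sample.int(n_genes, n_sel)
  inj_genes <- sample_safe(setdiff(seq_len(n_genes), sel_genes), n_inj)
  sel_clade <- sample_safe(focal, n_sel, replace = TRUE)
  pair_pool <- utils::combn(focal, 2)
  inj_pair <- pair_pool[, sample.int(ncol(pair_pool), n_inj, replace = TRUE),
                        drop = FALSE]
  gene_seeds <- sample.int(.Machine$integer.max %/% 4, n_genes)
  truth_genes <- vector("list", n_genes)
  truth_sites <- list()
  alns <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    gid <- sprintf("gene%04d", g)
    isel <- match(g, sel_genes)
    fg_clade <- if (!is.na(isel)) sel_clade[isel] else NA_character_
    mix <- if (!is.na(isel))
      site_mixture(p0 = 0.425, p1 = 0.425, omega0 = 0.1,
                   omega2 = sel_omega2) else
      site_mixture(p0 = 0.45, p1 = 0.45, omega0 = 0.1, omega2 = 1)
    tr <- tree
    if (!is.na(isel))
      tr <- tag_clade_stem(tr, clades[[fg_clade]]$members, "1")
    sim <- simulate_gene(tr, mix, n_codons, seed = gene_seeds[g],
                         foreground = if (is.na(isel)) NULL else "1")
    iinj <- match(g, inj_genes)
    pair <- NA_character_
    if (!is.na(iinj)) {
      cl1 <- inj_pair[1, iinj]; cl2 <- inj_pair[2, iinj]
      tr2 <- tag_clade_stem(sim$tree, clades[[cl1]]$members, "b1")
      tr2 <- tag_clade_stem(tr2, clades[[cl2]]$members, "b2")
      sim$tree <- tr2
      sim <- inject_convergent_sites(sim, c("b1", "b2"), n_inject,
                                     mode = "parallel",
                                     seed = gene_seeds[g] + 1L)
      pair <- paste0(cl1, "-", cl2)
      truth_sites[[gid]] <- cbind(gene = gid, pair = pair, sim$injected)
    }
    truth_genes[[g]] <- data.frame(
      gene = gid, selected = !is.na(isel),
      foreground_clade = fg_clade, omega2 = mix$omega2,
      injected_pair = pair, seed = gene_seeds[g])
    alns[[g]] <- sim$aln
    names(alns)[g] <- gid
  }
  alns <- apply_missingness(alns, dropout, seed = seed + 1L,
                            keep = c("human", "chimp"))
  for (g in seq_len(n_genes)) {
    gid <- sprintf("gene%04d", g)
    m <- alns[[g]]
    seqs <- stats::setNames(apply(m, 1, paste0, collapse = ""), rownames(m))
    write_fasta(seqs, file.path(out_dir, "genes", paste0(gid, ".fasta")))
  }
  write_tree_file(tree, file.path(out_dir, "tree.nwk"))
  tg <- do.call(rbind, truth_genes)
  write_tsv(tg, file.path(out_dir, "truth_genes.tsv"))
  ts <- if (length(truth_sites)) do.call(rbind, truth_sites) else
    data.frame(gene = character(0), pair = character(0), site = integer(0),
               mode = character(0), target_aa = character(0))
  write_tsv(ts, file.path(out_dir, "truth_sites.tsv"))
  cfg <- data.frame(
    key = c("n_genes", "n_codons", "sel_fraction", "inj_fraction",
            "n_inject", "sel_omega2", "dropout", "seed"),
    value = c(n_genes, n_codons, sel_fraction, inj_fraction, n_inject,
              sel_omega2, dropout, seed))
  write_tsv(cfg, file.path(out_dir, "config.tsv"))
  invisible(list(truth_genes = tg, truth_sites = ts, dir = out_dir))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
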