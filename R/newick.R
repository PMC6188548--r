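# Newick I/O with a "#tag" branch-label convention layered on top of ape.
# A label suffix "#1" (or "#A" ... any short tag) on a tip or internal node
# marks the branch subtending that node, mirroring common codon-model usage
# so one tree file can drive both the selection and convergence stages.

#' Parse a Newick string into a rooted tree with branch tags
#'
#' Wraps [ape::read.tree()] and extracts `#tag` suffixes on tip/node labels
#' into a per-edge tag vector stored as `tree$edge.tag` (aligned with
#' `tree$edge`; `NA` where untagged). Absent branch lengths default to 0.
#'
#' @param text Newick string (must end in `;`).
#' @return An `ape::phylo` object with an extra `edge.tag` component.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop(sprintf("malformed Newick: unbalanced parentheses (%d '(' vs %d ')')",
                 n_open, n_close))
  if (!grepl(";\\s*$", text))
    stop(sprintf("malformed Newick: missing terminating ';' near offset %d",
                 nchar(text)))
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick: ape could not parse the string")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  tags <- rep(NA_character_, nrow(tr$edge))
  strip <- function(labels) {
    has <- grepl("#", labels, fixed = TRUE)
    tag <- ifelse(has, sub("^[^#]*#", "", labels), NA_character_)
    list(clean = sub("#.*$", "", labels), tag = tag)
  }
  tl <- strip(tr$tip.label)
  tr$tip.label <- tl$clean
  for (i in which(!is.na(tl$tag)))
    tags[match(i, tr$edge[, 2])] <- tl$tag[i]
  if (!is.null(tr$node.label)) {
    nl <- strip(tr$node.label)
    tr$node.label <- nl$clean
    ntip <- length(tr$tip.label)
    for (i in which(!is.na(nl$tag))) {
      e <- match(ntip + i, tr$edge[, 2])
      if (!is.na(e)) tags[e] <- nl$tag[i]  # root itself has no edge
    }
  }
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip name: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr$edge.tag <- tags
  tr
}

#' Serialise a rooted tree (with branch tags) to Newick
#'
#' Inverse of [parse_newick()]: `edge.tag` entries are re-attached as
#' `#tag` label suffixes. Branch lengths are written to 12 significant
#' digits.
#'
#' @param tree `phylo` object, optionally with `edge.tag`.
#' @return Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tr <- tree
  ntip <- length(tr$tip.label)
  if (!is.null(tr$edge.tag)) {
    for (e in which(!is.na(tr$edge.tag))) {
      node <- tr$edge[e, 2]
      if (node <= ntip) {
        tr$tip.label[node] <- paste0(tr$tip.label[node], "#", tr$edge.tag[e])
      } else {
        if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
        tr$node.label[node - ntip] <-
          paste0(tr$node.label[node - ntip], "#", tr$edge.tag[e])
      }
    }
  }
  tr$edge.tag <- NULL
  ape::write.tree(tr, digits = 12)
}

#' Read / write a tagged tree file
#' @param path file path.
#' @return [read_tree_file()]: a `phylo` with `edge.tag`.
#' @export
read_tree_file <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' @rdname read_tree_file
#' @param tree `phylo` object.
#' @export
write_tree_file <- function(tree, path) {
  writeLines(write_newick(tree), path)
  invisible(path)
}

# --- small tree utilities used across modules ---------------------------

# edge index whose child is `node`
edge_of_node <- function(tree, node) match(node, tree$edge[, 2])

#' Edge index carrying a tag
#' @param tree `phylo` with `edge.tag`.
#' @param tag tag string.
#' @return edge index (NA if absent).
#' @export
tagged_edge <- function(tree, tag) {
  if (is.null(tree$edge.tag)) return(NA_integer_)
  which(tree$edge.tag == tag)[1]
}

# set a tag on the branch subtending the MRCA of `taxa` (stem branch);
#' Tag the stem branch of a clade
#'
#' Tags the branch subtending the MRCA of `taxa` (a single taxon tags its
#' terminal branch).
#' @param tree `phylo`.
#' @param taxa clade members (present members are used).
#' @param tag tag string (the foreground convention uses `"1"`).
#' @return tree with updated `edge.tag`.
#' @export
tag_clade_stem <- function(tree, taxa, tag) {
  taxa <- intersect(taxa, tree$tip.label)
  if (!length(taxa)) stop("no listed taxa present in tree")
  if (is.null(tree$edge.tag)) tree$edge.tag <- rep(NA_character_, nrow(tree$edge))
  node <- if (length(taxa) == 1) match(taxa, tree$tip.label) else
    ape::getMRCA(tree, taxa)
  e <- edge_of_node(tree, node)
  if (is.na(e)) stop("clade MRCA is the root; its stem branch does not exist")
  tree$edge.tag[e] <- tag
  tree
}

# prune a tagged tree to `taxa`, preserving path lengths; tags are dropped
#' Prune a tree to a taxon set, preserving path lengths
#' @param tree `phylo`.
#' @param taxa tips to keep.
#' @return pruned tree (tags reset).
#' @export
prune_tree <- function(tree, taxa) {
  taxa <- intersect(tree$tip.label, taxa)
  if (length(taxa) < 2) stop("cannot prune to fewer than 2 tips")
  tr <- ape::keep.tip(tree, taxa)
  tr$edge.tag <- rep(NA_character_, nrow(tr$edge))
  tr
}

# postorder permutation of edge indices (children visited before parents)
postorder_edges <- function(tree)
  ape::reorder.phylo(tree, "postorder", index.only = TRUE)
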