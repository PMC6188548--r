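# Strict FASTA I/O for coding DNA and protein sequences.

#' Read a FASTA file with validation
#'
#' Sequences are uppercased and checked against the chosen alphabet;
#' duplicate ids and illegal characters are errors (naming the record and
#' position), never silently coerced.
#'
#' @param path FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return named character vector of sequences (names = record ids, input
#'   order preserved).
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- seqinr::read.fasta(path, seqtype = if (alphabet == "dna") "DNA" else "AA",
                             as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = FALSE)
  ids <- names(recs)
  if (any(!nzchar(ids))) stop("empty record id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate record id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(vapply(recs, function(r) as.character(r)[1], character(1)))
  if (any(!nzchar(seqs))) stop("empty sequence for record ",
                               ids[!nzchar(seqs)][1])
  allowed <- if (alphabet == "dna") DNA_ALPHABET else PROTEIN_ALPHABET
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!ch %in% allowed)
    if (length(bad))
      stop(sprintf("illegal character '%s' at position %d of record '%s'",
                   ch[bad[1]], bad[1], ids[i]))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA (60-column wrapping)
#'
#' @param records named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  if (!length(records)) stop("no records to write")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("all records must be named")
  seqinr::write.fasta(lapply(unname(records), function(x) strsplit(x, "")[[1]]),
                      names = names(records), file.out = path, nbchar = 60)
  invisible(path)
}

#' Convert equal-length sequences to a taxa x column character matrix
#' @param seqs named character vector of aligned sequences.
#' @return character matrix with taxon rownames.
#' @export
seqs_to_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("sequences have unequal lengths; not an alignment")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

#' Collapse an alignment matrix back to named sequences
#' @param m character matrix with taxon rownames.
#' @return named character vector.
#' @export
matrix_to_seqs <- function(m) {
  stats::setNames(apply(m, 1, paste0, collapse = ""), rownames(m))
}

#' View a nucleotide alignment as codon columns
#' @param ntmat taxa x (3n) nucleotide character matrix.
#' @return taxa x n matrix of codon strings.
#' @export
codon_view <- function(ntmat) {
  nc <- ncol(ntmat)
  if (nc %% 3 != 0) stop("alignment length not a multiple of 3")
  idx <- seq(1, nc, by = 3)
  cm <- vapply(idx, function(j)
    paste0(ntmat[, j], ntmat[, j + 1], ntmat[, j + 2]),
    character(nrow(ntmat)))
  if (is.null(dim(cm))) cm <- matrix(cm, nrow = nrow(ntmat))
  rownames(cm) <- rownames(ntmat)
  cm
}

#' Translate a codon-string alignment to protein
#'
#' Stop codons become `*`, full gaps `-`, anything unresolvable `X`.
#' @param codmat taxa x codon-site matrix of codon strings.
#' @return protein character matrix.
#' @export
translate_codons <- function(codmat) {
  tab <- codon_table()
  tr <- function(cd) {
    out <- rep("X", length(cd))
    out[cd == "---"] <- "-"
    i <- match(cd, tab$codons)
    out[!is.na(i)] <- tab$aa[i[!is.na(i)]]
    out[cd %in% tab$stop_codons] <- "*"
    out
  }
  aa <- apply(codmat, 2, tr)
  if (is.null(dim(aa))) aa <- matrix(aa, nrow = nrow(codmat))
  rownames(aa) <- rownames(codmat)
  aa
}
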