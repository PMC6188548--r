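# Universal genetic code tables shared by the codon machinery.
# 61 sense codons (stops TAA/TAG/TGA excluded), amino acids in the
# conventional ARNDCQEGHILKMFPSTWYV order used by empirical aa models.

.codon_env <- new.env(parent = emptyenv())

#' Sense-codon table for the universal genetic code
#'
#' Returns the 61 sense codons together with their encoded amino acids and
#' the codon -> amino-acid index map used throughout the package.
#'
#' @return A list with components `codons` (character, length 61),
#'   `aa` (one-letter amino acid per codon), `aa_index` (integer index into
#'   [AA_ORDER]) and `stop_codons`.
#' @export
codon_table <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  nt <- c("T", "C", "A", "G")
  codons <- apply(expand.grid(nt, nt, nt, stringsAsFactors = FALSE)[, 3:1], 1, paste0,
                  collapse = "")
  aa <- vapply(codons, function(cd) {
    toupper(seqinr::translate(strsplit(cd, "")[[1]]))
  }, character(1))
  stops <- codons[aa == "*"]
  keep <- aa != "*"
  tab <- list(codons = codons[keep],
              aa = unname(aa[keep]),
              aa_index = match(unname(aa[keep]), AA_ORDER),
              stop_codons = stops)
  .codon_env$tab <- tab
  tab
}

# positions (1,2,3) x codon nucleotide index into c("T","C","A","G")
codon_nt_matrix <- function() {
  tab <- codon_table()
  m <- t(vapply(strsplit(tab$codons, ""), function(x)
    match(x, c("T", "C", "A", "G")), integer(3)))
  rownames(m) <- tab$codons
  m
}

is_transition <- function(n1, n2) {
  # indices into T,C,A,G: T<->C and A<->G are transitions
  (n1 <= 2 & n2 <= 2 & n1 != n2) | (n1 >= 3 & n2 >= 3 & n1 != n2)
}
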