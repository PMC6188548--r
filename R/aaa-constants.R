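# Alphabet constants (defined first in collation order).

#' Amino-acid ordering used by the substitution models
#'
#' The conventional ARNDCQEGHILKMFPSTWYV ordering shared by empirical
#' amino-acid models; all 20-state vectors and matrices in the package
#' follow it.
#' @export
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V")
PROTEIN_ALPHABET <- c(AA_ORDER, "X", "-", "B", "Z", "J", "U", "O", "*")
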