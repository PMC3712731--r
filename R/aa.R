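# Static amino-acid table. mod_term holds an opaque PSI-MOD-style identifier
# for the residue; identifiers are bundled, never fetched.
.aa_tab <- local({
  one <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")
  three <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
             "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
             "Tyr", "Val", "Xaa")
  data.frame(one = one, three = three,
             mod_term = ifelse(one == "X", "", paste0("MOD:", three)),
             stringsAsFactors = FALSE)
})

#' Amino-acid code table
#'
#' The 20 standard amino acids plus `X` (unknown residue, three-letter code
#' `Xaa`), with one-letter and three-letter codes and an opaque PSI-MOD-style
#' identifier per residue. The one-letter/three-letter mapping is bijective
#' over the standard residues.
#'
#' @return A data frame with columns `one`, `three` and `mod_term`.
#' @export
#' @examples
#' amino_acids()[amino_acids()$one == "L", ]
amino_acids <- function() .aa_tab

#' @rdname amino_acids
#' @param x character vector of residue codes (one- or three-letter,
#'   depending on the function).
#' @return `aa_three()` / `aa_one()` return the converted codes;
#'   `is_aa()` returns a logical vector.
#' @export
aa_three <- function(x) {
  i <- match(x, .aa_tab$one)
  if (anyNA(i)) stop("unknown one-letter amino-acid code: ",
                     paste(x[is.na(i)], collapse = ", "))
  .aa_tab$three[i]
}

#' @rdname amino_acids
#' @export
aa_one <- function(x) {
  i <- match(x, .aa_tab$three)
  if (anyNA(i)) stop("unknown three-letter amino-acid code: ",
                     paste(x[is.na(i)], collapse = ", "))
  .aa_tab$one[i]
}

#' @rdname amino_acids
#' @export
is_aa <- function(x) x %in% .aa_tab$one

# Alphabet used by the synthetic-sequence generator (standard residues only).
.aa_alphabet <- function() setdiff(.aa_tab$one, "X")
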