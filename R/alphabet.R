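#' Residue alphabets
#'
#' Resolve an alphabet specification to an ordered vector of single-letter
#' residue codes. `"AA"` gives the 20 standard amino acids, `"DNA"` gives
#' `A, C, G, T`; a character vector of distinct single letters is used as-is.
#'
#' @param alphabet `"AA"`, `"DNA"`, or a character vector of K >= 2 distinct
#'   single-character residue codes.
#' @return Character vector of residue letters, in a fixed order.
#' @examples
#' motif_alphabet("DNA")
#' @export
motif_alphabet <- function(alphabet = "AA") {
  if (length(alphabet) == 1 && alphabet %in% c("AA", "aa", "protein")) {
    return(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  }
  if (length(alphabet) == 1 && alphabet %in% c("DNA", "dna")) {
    return(c("A", "C", "G", "T"))
  }
  letters_out <- as.character(alphabet)
  if (length(letters_out) < 2) stop("alphabet must contain at least 2 letters")
  if (anyDuplicated(letters_out)) stop("alphabet letters must be distinct")
  if (any(nchar(letters_out) != 1)) stop("alphabet letters must be single characters")
  letters_out
}

# Encode a character sequence as 1-based integer codes into `letters`.
# `what` names the offending record in error messages.
encode_seq <- function(seq, letters, what = "sequence") {
  chars <- strsplit(seq, "")[[1]]
  codes <- match(chars, letters)
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop(sprintf("%s contains residue(s) not in the alphabet: %s",
                 what, paste(bad, collapse = ", ")))
  }
  codes
}

decode_seq <- function(codes, letters) paste(letters[codes], collapse = "")
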