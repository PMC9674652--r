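#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids, one-letter codes, alphabetical order.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Wild-type Abeta42 peptide sequence
#'
#' The 42-residue amyloid beta peptide, the default wild type for the
#' deep indel mutagenesis library.
#'
#' @return A single amino-acid string of length 42.
#' @export
abeta42 <- function() {
  "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"
}

#' Aliphatic residue set
#'
#' Residues counted as aliphatic for aggregation-prone-region and
#' alternative-core analyses. Glycine is included because the Abeta
#' aggregation-prone stretches are composed of aliphatic residues and
#' glycines.
#'
#' @return Character vector of one-letter codes.
#' @export
aliphatic_residues <- function() {
  c("G", "A", "V", "L", "I", "M")
}

# Split an AA string into residues after validating the alphabet.
aa_chars <- function(wt) {
  stopifnot(is.character(wt), length(wt) == 1L, nzchar(wt))
  ch <- strsplit(wt, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), aa_alphabet())
  if (length(bad)) {
    stop("invalid amino-acid letters in sequence: ", paste(bad, collapse = ", "))
  }
  ch
}

#' Read a wild-type protein sequence from FASTA
#'
#' @param path Path to a single-record amino-acid FASTA file.
#' @return The sequence as a single string.
#' @export
read_wt_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) != 1L) stop("expected exactly one FASTA record, got ", length(seqs))
  wt <- as.character(seqs[[1]])
  aa_chars(wt)  # validate
  wt
}
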