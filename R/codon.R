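#' Default codon usage table
#'
#' One representative codon per amino acid, biased towards common
#' Escherichia coli usage. Used to derive a consistent nucleotide coding
#' sequence for every designed variant; the choice only matters for the
#' definition of "one single nucleotide change" in read filtering, so any
#' fixed table is valid as long as it is used consistently.
#'
#' @return Named character vector mapping one-letter amino-acid codes to codons.
#' @export
default_codon_table <- function() {
  c(A = "GCG", C = "TGC", D = "GAT", E = "GAA", F = "TTT",
    G = "GGC", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
    M = "ATG", N = "AAC", P = "CCG", Q = "CAG", R = "CGT",
    S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAT")
}

#' Reverse-translate an amino-acid sequence
#'
#' @param aa_seq Amino-acid string.
#' @param codon_table Named codon vector as from [default_codon_table()].
#' @return Nucleotide coding sequence (no stop codon).
#' @export
reverse_translate <- function(aa_seq, codon_table = default_codon_table()) {
  ch <- aa_chars(aa_seq)
  missing <- setdiff(unique(ch), names(codon_table))
  if (length(missing)) {
    stop("codon table has no entry for: ", paste(missing, collapse = ", "))
  }
  paste(codon_table[ch], collapse = "")
}

# All sense codons encoding a given amino acid, from the standard genetic code.
sense_codons <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == aa]
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Minimum nucleotide changes for a substitution
#'
#' Minimum number of nucleotide substitutions converting the wild-type codon
#' at a position into any sense codon for the target amino acid. This defines
#' the "single nucleotide change" annotation used by the input-read filter.
#'
#' @param wt_codon Wild-type codon (3-nt string).
#' @param target_aa Target amino acid (one letter).
#' @return Integer minimum over all sense codons of the target amino acid.
#' @export
min_nt_changes <- function(wt_codon, target_aa) {
  cods <- sense_codons(target_aa)
  if (!length(cods)) stop("no sense codon for amino acid: ", target_aa)
  min(vapply(cods, function(cc) hamming(wt_codon, cc), integer(1)))
}
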