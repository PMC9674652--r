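# Shared fixtures and independent oracles.

# A short wild type for cheap end-to-end runs (first 12 residues of Abeta42).
short_wt <- function() "DAEFRHDSGYEV"

random_wt <- function(len) {
  paste(sample(aa_alphabet(), len, replace = TRUE), collapse = "")
}

# Brute-force "apply every mutation, collect strings" oracle, written with
# residue vectors and index arithmetic only (independent of canonicalize()).
brute_force_products <- function(wt, max_del_len = nchar(wt) - 3L) {
  ch <- strsplit(wt, "")[[1]]
  L <- length(ch)
  AA <- aa_alphabet()
  products <- list(substitution = character(0), insertion = character(0),
                   single_deletion = character(0), multi_deletion = character(0),
                   truncation = character(0))
  for (p in 1:L) for (a in AA) if (a != ch[p]) {
    m <- ch; m[p] <- a
    products$substitution <- c(products$substitution, paste(m, collapse = ""))
  }
  for (g in 1:(L + 1)) for (a in AA) {
    products$insertion <- c(products$insertion,
                            paste(append(ch, a, after = g - 1L), collapse = ""))
  }
  for (p in 1:L) {
    products$single_deletion <- c(products$single_deletion,
                                  paste(ch[-p], collapse = ""))
  }
  if (L >= 4L) {
    for (s in 2:(L - 1)) for (e in s:(L - 1)) {
      k <- e - s + 1L
      if (k >= 2L && k <= max_del_len) {
        products$multi_deletion <- c(products$multi_deletion,
                                     paste(ch[-(s:e)], collapse = ""))
      }
    }
  }
  if (L >= 5L) {
    for (k in 2:min(39L, L - 3L)) for (a in 0:k) {
      b <- k - a
      products$truncation <- c(products$truncation,
                               paste(ch[seq.int(a + 1L, L - b)], collapse = ""))
    }
  }
  products
}

# Assign classes to the union of brute-force products under the library's
# precedence rule, independently of build_library().
brute_force_classes <- function(products) {
  all_seqs <- unique(unlist(products))
  cls <- character(length(all_seqs))
  names(cls) <- all_seqs
  cls[all_seqs %in% products$substitution] <- "substitution"
  cls[all_seqs %in% products$insertion] <- "insertion"
  cls[all_seqs %in% products$multi_deletion] <- "multi_deletion"
  cls[all_seqs %in% products$truncation] <- "truncation"
  cls[all_seqs %in% products$single_deletion] <- "single_deletion"
  cls
}

# Minimal score table over a library, with every variant testable.
flat_scores <- function(library, ns = 0, se = 1) {
  data.frame(variant_id = library$variants$variant_id, ns = ns, se = se,
             z = ns / se, p = 1, q = 1, effect_class = "WT-like",
             stringsAsFactors = FALSE)
}
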