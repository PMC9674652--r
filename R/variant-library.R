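# Variant specs are rows of a data.frame with columns:
#   mclass : substitution | insertion | single_deletion | multi_deletion | truncation
#   pos    : residue position (substitution, single_deletion) or the mutant
#            position of the inserted residue (insertion; gap g inserts between
#            residues g-1 and g, so the inserted residue sits at position g)
#   aa     : new/inserted amino acid
#   start,end : removed interval, 1-based inclusive (multi_deletion)
#   n_del,c_del : residues removed from the N/C terminus (truncation)

empty_specs <- function(n = 0L) {
  data.frame(mclass = character(n), pos = integer(n), aa = character(n),
             start = integer(n), end = integer(n),
             n_del = integer(n), c_del = integer(n),
             stringsAsFactors = FALSE)
}

spec_frame <- function(mclass, pos = NA_integer_, aa = NA_character_,
                       start = NA_integer_, end = NA_integer_,
                       n_del = NA_integer_, c_del = NA_integer_) {
  data.frame(mclass = mclass, pos = as.integer(pos), aa = aa,
             start = as.integer(start), end = as.integer(end),
             n_del = as.integer(n_del), c_del = as.integer(c_del),
             stringsAsFactors = FALSE)
}

#' Enumerate all single amino-acid substitutions
#'
#' One spec per (position, amino acid) pair with the amino acid differing from
#' the wild-type residue: 19 per position, 19L in total. Order is
#' position-major, then alphabetical by substituted amino acid.
#'
#' @param wt Wild-type amino-acid string.
#' @return Spec data.frame (see [build_library()]).
#' @export
enumerate_substitutions <- function(wt) {
  ch <- aa_chars(wt)
  L <- length(ch)
  pos <- rep(seq_len(L), each = 20L)
  aa <- rep(aa_alphabet(), times = L)
  keep <- aa != ch[pos]
  spec_frame("substitution", pos = pos[keep], aa = aa[keep])
}

#' Enumerate all single amino-acid insertions
#'
#' One spec per (gap, amino acid) pair. Gap `g` inserts between residues
#' `g - 1` and `g`; `g = L + 1` appends after the last residue. The inserted
#' residue occupies position `g` of the mutant, which is the position the
#' spec reports.
#'
#' @param wt Wild-type amino-acid string.
#' @param gap_range Integer vector `c(first, last)` of gaps to cover;
#'   default all `L + 1` gaps.
#' @return Spec data.frame.
#' @export
enumerate_insertions <- function(wt, gap_range = NULL) {
  ch <- aa_chars(wt)
  L <- length(ch)
  if (is.null(gap_range)) gap_range <- c(1L, L + 1L)
  stopifnot(length(gap_range) == 2L)
  gaps <- seq.int(gap_range[1], gap_range[2])
  if (!length(gaps) || gap_range[1] < 1L || gap_range[2] > L + 1L ||
      gap_range[1] > gap_range[2]) {
    stop("gap_range must be a non-empty subinterval of [1, L + 1]")
  }
  spec_frame("insertion",
             pos = rep(gaps, each = 20L),
             aa = rep(aa_alphabet(), times = length(gaps)))
}

#' Enumerate all deletions
#'
#' Single-residue deletions at every position, plus internal multi-residue
#' deletions `[s, e]` with `2 <= s <= e <= L - 1` and length between
#' `max(2, min_len)` and `max_len`. Multi-residue removals touching either
#' terminus are truncations and are produced by [enumerate_truncations()].
#'
#' @param wt Wild-type amino-acid string.
#' @param min_len,max_len Deletion length bounds; defaults 1 and 39.
#' @return Spec data.frame.
#' @export
enumerate_deletions <- function(wt, min_len = 1L, max_len = 39L) {
  ch <- aa_chars(wt)
  L <- length(ch)
  if (!(min_len >= 1L && min_len <= max_len && max_len <= L - 3L)) {
    stop("deletion length bounds must satisfy 1 <= min_len <= max_len <= L - 3")
  }
  singles <- if (min_len == 1L) {
    spec_frame("single_deletion", pos = seq_len(L))
  } else empty_specs()
  lens <- seq.int(max(2L, min_len), max_len)
  multi <- do.call(rbind, lapply(lens, function(k) {
    s <- seq.int(2L, L - k)        # e = s + k - 1 <= L - 1
    if (!length(s)) return(empty_specs())
    spec_frame("multi_deletion", start = s, end = s + k - 1L)
  }))
  rbind(singles, multi)
}

#' Enumerate all truncations
#'
#' All ways of removing `a >= 0` residues from the N terminus and `b >= 0`
#' from the C terminus with `a + b` between 2 and `min(39, L - 3)`, i.e.
#' leaving a peptide of 3 to `L - 2` residues.
#'
#' @param wt Wild-type amino-acid string.
#' @return Spec data.frame.
#' @export
enumerate_truncations <- function(wt) {
  ch <- aa_chars(wt)
  L <- length(ch)
  if (L < 5L) stop("wild type must have at least 5 residues for truncations")
  ks <- seq.int(2L, min(39L, L - 3L))
  do.call(rbind, lapply(ks, function(k) {
    a <- 0:k
    spec_frame("truncation", n_del = a, c_del = k - a)
  }))
}

#' Apply variant specs to the wild type
#'
#' Vectorized canonicalization: returns the mutant protein string produced by
#' each spec row.
#'
#' @param specs Spec data.frame.
#' @param wt Wild-type amino-acid string.
#' @return Character vector of mutant sequences, one per spec.
#' @export
canonicalize <- function(specs, wt) {
  ch <- aa_chars(wt)
  L <- length(ch)
  out <- character(nrow(specs))
  cls <- specs$mclass
  i <- cls == "substitution"
  if (any(i)) {
    p <- specs$pos[i]
    if (any(p < 1L | p > L)) stop("substitution position out of range")
    out[i] <- paste0(substring(wt, 1L, p - 1L), specs$aa[i], substring(wt, p + 1L, L))
  }
  i <- cls == "insertion"
  if (any(i)) {
    g <- specs$pos[i]
    if (any(g < 1L | g > L + 1L)) stop("insertion gap out of range")
    out[i] <- paste0(substring(wt, 1L, g - 1L), specs$aa[i], substring(wt, g, L))
  }
  i <- cls == "single_deletion"
  if (any(i)) {
    p <- specs$pos[i]
    if (any(p < 1L | p > L)) stop("deletion position out of range")
    out[i] <- paste0(substring(wt, 1L, p - 1L), substring(wt, p + 1L, L))
  }
  i <- cls == "multi_deletion"
  if (any(i)) {
    s <- specs$start[i]; e <- specs$end[i]
    if (any(s > e | s < 1L | e > L)) stop("deletion interval out of range")
    out[i] <- paste0(substring(wt, 1L, s - 1L), substring(wt, e + 1L, L))
  }
  i <- cls == "truncation"
  if (any(i)) {
    a <- specs$n_del[i]; b <- specs$c_del[i]
    if (any(a < 0L | b < 0L | a + b > L - 3L)) stop("truncation out of range")
    out[i] <- substring(wt, a + 1L, L - b)
  }
  out
}

# Human-readable label for each spec, e.g. A2V, ins29K, E22del, del19-24, trunc5N0C
spec_labels <- function(specs, wt) {
  ch <- aa_chars(wt)
  lab <- character(nrow(specs))
  cls <- specs$mclass
  i <- cls == "substitution"
  lab[i] <- paste0(ch[specs$pos[i]], specs$pos[i], specs$aa[i])
  i <- cls == "insertion"
  lab[i] <- paste0("ins", specs$pos[i], specs$aa[i])
  i <- cls == "single_deletion"
  lab[i] <- paste0(ch[specs$pos[i]], specs$pos[i], "del")
  i <- cls == "multi_deletion"
  lab[i] <- paste0("del", specs$start[i], "-", specs$end[i])
  i <- cls == "truncation"
  lab[i] <- paste0("trunc", specs$n_del[i], "N", specs$c_del[i], "C")
  lab
}

# Display position annotation per spec: the position(s) the spec is drawn at.
spec_display_pos <- function(specs) {
  cls <- specs$mclass
  dp <- character(nrow(specs))
  i <- cls %in% c("substitution", "insertion", "single_deletion")
  dp[i] <- as.character(specs$pos[i])
  i <- cls == "multi_deletion"
  dp[i] <- paste0(specs$start[i], "-", specs$end[i])
  i <- cls == "truncation"
  dp[i] <- paste0("N", specs$n_del[i], "|C", specs$c_del[i])
  dp
}

CLASS_ORDER <- c("substitution", "insertion", "single_deletion",
                 "multi_deletion", "truncation", "wt")

#' Build the complete designed variant library
#'
#' Enumerates all five mutation classes, collapses degenerate specs that
#' produce the same coding sequence onto one designed variant, assigns exactly
#' one mutation class per unique product, and annotates a nucleotide coding
#' sequence plus the minimum number of nucleotide changes for substitutions.
#'
#' Class assignment on collisions follows fixed precedence: any product
#' reachable by removing a single residue (including positions 1 and L) is a
#' `single_deletion`; any remaining product identical to a truncation product
#' is a `truncation`; remaining contiguous internal removals are
#' `multi_deletion`. Substitutions and insertions cannot collide with other
#' classes because their products have different lengths or edit structure.
#'
#' @param wt Wild-type amino-acid string (default Abeta42).
#' @param gap_range Insertion gap range, default all `L + 1` gaps.
#' @param max_del_len Maximum deletion/truncation length (default 39).
#' @param codon_table Codon usage table for reverse translation.
#' @param wt_nt Optional wild-type nucleotide sequence; derived from
#'   `codon_table` when `NULL`.
#' @return An object of class `designed_library`: list with `wt`, `wt_nt`,
#'   `variants` (one row per unique coding sequence: `variant_id`,
#'   `canonical_seq`, `assigned_class`, `specs`, `display_pos`, `nt_seq`,
#'   `nt_min_changes`), `spec_table` (one row per spec with its
#'   `variant_id`), and `params`.
#' @export
build_library <- function(wt = abeta42(), gap_range = NULL, max_del_len = 39L,
                          codon_table = default_codon_table(), wt_nt = NULL) {
  ch <- aa_chars(wt)
  L <- length(ch)
  max_del_len <- min(max_del_len, L - 3L)
  specs <- rbind(
    enumerate_substitutions(wt),
    enumerate_insertions(wt, gap_range),
    enumerate_deletions(wt, 1L, max_del_len),
    enumerate_truncations(wt)
  )
  specs$product <- canonicalize(specs, wt)
  specs$label <- spec_labels(specs, wt)
  specs$display_pos <- spec_display_pos(specs)
  if (any(specs$product == wt)) stop("internal error: a spec reproduced the wild type")

  # deterministic order: class, then position, then amino acid
  cls_rank <- match(specs$mclass, CLASS_ORDER)
  pos_key <- ifelse(is.na(specs$pos),
                    ifelse(is.na(specs$start), specs$n_del * 1000L + specs$c_del,
                           specs$start * 1000L + specs$end),
                    specs$pos)
  specs <- specs[order(cls_rank, pos_key, specs$aa, method = "radix"), ]

  # collapse by product; class precedence within removal classes
  grp <- split(seq_len(nrow(specs)), specs$product)
  assign_one <- function(idx) {
    cl <- unique(specs$mclass[idx])
    if ("single_deletion" %in% cl) "single_deletion"
    else if ("truncation" %in% cl) "truncation"
    else if ("multi_deletion" %in% cl) "multi_deletion"
    else cl[1]
  }
  prod_seq <- names(grp)
  a_class <- vapply(grp, assign_one, character(1))
  # representative spec: first (in deterministic order) among specs of the
  # assigned class, so the variant id names what the variant is
  rep_idx <- mapply(function(idx, cl) idx[specs$mclass[idx] == cl][1], grp, a_class)
  variants <- data.frame(
    variant_id = specs$label[rep_idx],
    canonical_seq = prod_seq,
    assigned_class = a_class,
    specs = vapply(grp, function(idx) paste(specs$label[idx], collapse = ";"), character(1)),
    display_pos = vapply(grp, function(idx) paste(specs$display_pos[idx], collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(match(variants$assigned_class, CLASS_ORDER),
               match(variants$variant_id, specs$label), method = "radix")
  variants <- variants[ord, ]
  variants <- rbind(
    data.frame(variant_id = "WT", canonical_seq = wt, assigned_class = "wt",
               specs = "WT", display_pos = "", stringsAsFactors = FALSE),
    variants
  )
  rownames(variants) <- NULL

  if (is.null(wt_nt)) wt_nt <- reverse_translate(wt, codon_table)
  if (nchar(wt_nt) != 3L * L) stop("wt_nt length must be 3 * protein length")
  variants$nt_seq <- vapply(variants$canonical_seq, reverse_translate,
                            character(1), codon_table = codon_table)
  variants$nt_seq[1] <- wt_nt
  variants$nt_min_changes <- Inf
  variants$nt_min_changes[1] <- 0
  is_sub <- variants$assigned_class == "substitution"
  if (any(is_sub)) {
    first_spec <- sub(";.*$", "", variants$specs[is_sub])
    p <- as.integer(gsub("^[A-Z]|[A-Z]$", "", first_spec))
    target <- substr(first_spec, nchar(first_spec), nchar(first_spec))
    wt_codons <- substring(wt_nt, 3L * p - 2L, 3L * p)
    variants$nt_min_changes[is_sub] <-
      mapply(min_nt_changes, wt_codons, target)
    # substitutions keep the wild-type nucleotide background outside the codon,
    # with the representative codon at the mutated position
    rep_codon <- codon_table[target]
    variants$nt_seq[is_sub] <- paste0(substring(wt_nt, 1L, 3L * p - 3L), rep_codon,
                                      substring(wt_nt, 3L * p + 1L, 3L * L))
  }

  spec_table <- specs[, c("mclass", "pos", "aa", "start", "end",
                          "n_del", "c_del", "label", "display_pos", "product")]
  spec_table$variant_id <- variants$variant_id[match(spec_table$product, variants$canonical_seq)]
  rownames(spec_table) <- NULL

  structure(list(
    wt = wt, wt_nt = wt_nt, variants = variants, spec_table = spec_table,
    params = list(gap_range = if (is.null(gap_range)) c(1L, L + 1L) else gap_range,
                  max_del_len = max_del_len, codon_table = codon_table)
  ), class = "designed_library")
}

#' @export
print.designed_library <- function(x, ...) {
  cat("Designed DIM library:", nchar(x$wt), "aa wild type,",
      nrow(x$variants), "unique coding variants\n")
  print(table(x$variants$assigned_class)[CLASS_ORDER])
  invisible(x)
}

#' Per-class variant counts of a designed library
#'
#' @param library A `designed_library`.
#' @return Named integer vector over mutation classes (excluding the WT entry).
#' @export
class_counts <- function(library) {
  tab <- table(factor(library$variants$assigned_class,
                      levels = setdiff(CLASS_ORDER, "wt")))
  stats::setNames(as.integer(tab), names(tab))
}

#' Write a designed library to CSV
#'
#' @param library A `designed_library`.
#' @param path Output CSV path.
#' @export
write_library <- function(library, path) {
  utils::write.csv(library$variants, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the canonical sequences of a library as FASTA
#'
#' Headers carry `variant_id|assigned_class|specs|display_pos`.
#'
#' @param library A `designed_library`.
#' @param path Output FASTA path.
#' @export
write_library_fasta <- function(library, path) {
  v <- library$variants
  seqs <- Biostrings::AAStringSet(v$canonical_seq)
  names(seqs) <- paste(v$variant_id, v$assigned_class, v$specs, v$display_pos, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
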