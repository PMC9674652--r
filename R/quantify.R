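# Read-level quantification: merge read pairs, trim constant regions, apply
# the base-quality filter, and match the variant region exactly against the
# designed library.

#' Read-rejection sentinel
#'
#' Merge and trim return a reject sentinel instead of a result when a read
#' fails; `is_reject()` tests for it and `reject_reason()` names the cause.
#'
#' @param x Object returned by [merge_read_pair()] or [trim_flanks()].
#' @return `is_reject()`: logical; `reject_reason()`: the reason string or
#'   `NA` for accepted reads.
#' @export
is_reject <- function(x) inherits(x, "dim_reject")

#' @rdname is_reject
#' @export
reject_reason <- function(x) if (is_reject(x)) x$reason else NA_character_

reject <- function(reason) structure(list(reason = reason), class = "dim_reject")

phred_values <- function(qual) utf8ToInt(qual) - 33L

count_mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Merge a read pair by overlap consensus
#'
#' Reconstructs the sequenced construct from a read pair: read 2 is
#' reverse-complemented and the construct length is chosen (by ungapped
#' overlap search) to minimise mismatches in the overlap. At overlap
#' conflicts the higher-quality base wins; overlap qualities are the
#' per-base maximum.
#'
#' @param r1,r2 Read sequences (read 2 in sequencing orientation).
#' @param q1,q2 Phred+33 quality strings.
#' @param min_overlap Minimum overlap length considered (default 10).
#' @param max_overlap_mismatch Maximum tolerated mismatch fraction in the
#'   best overlap (default 0.25).
#' @return List with `seq` and `qual` of the merged construct, or a reject
#'   sentinel (see [is_reject()]) naming the reason when the pair cannot be
#'   merged.
#' @export
merge_read_pair <- function(r1, q1, r2, q2, min_overlap = 10L,
                            max_overlap_mismatch = 0.25) {
  r2c <- revcomp(r2)
  q2c <- paste(rev(strsplit(q2, "")[[1]]), collapse = "")
  l1 <- nchar(r1); l2 <- nchar(r2c)
  s1 <- strsplit(r1, "")[[1]]; s2 <- strsplit(r2c, "")[[1]]
  p1 <- phred_values(q1); p2 <- phred_values(q2c)

  lengths <- seq.int(max(l1, l2), l1 + l2 - min_overlap)
  if (!length(lengths)) return(reject("reads_too_short"))
  best <- NULL; best_mm <- Inf; best_frac <- Inf
  for (tl in lengths) {
    off <- tl - l2            # r2c starts at construct position off + 1
    lo <- off + 1L; hi <- min(l1, tl)
    ov <- hi - lo + 1L
    if (ov < min_overlap && tl != max(l1, l2)) next
    if (ov <= 0) next
    mm <- sum(s1[lo:hi] != s2[(lo:hi) - off])
    frac <- mm / ov
    if (frac < best_frac || (frac == best_frac && tl < best)) {
      best <- tl; best_mm <- mm; best_frac <- frac
    }
  }
  if (is.null(best) || best_frac > max_overlap_mismatch) {
    return(reject("unmergeable"))
  }
  off <- best - l2
  seq <- character(best); qual <- integer(best)
  idx1 <- seq_len(l1)
  seq[idx1] <- s1; qual[idx1] <- p1
  idx2 <- off + seq_len(l2)
  from2 <- idx2 > l1 | (p2 > qual[idx2])
  seq[idx2[from2]] <- s2[from2]
  qual[idx2] <- pmax(qual[idx2], p2)
  list(seq = paste(seq, collapse = ""),
       qual = intToUtf8(qual + 33L))
}

#' Trim constant flanking regions from a merged construct
#'
#' Locates the 5' and 3' constant regions at their expected positions
#' (ungapped) and accepts each flank iff its mismatch count is at most
#' `floor(max_mismatch_frac * flank_length)`.
#'
#' @param seq,qual Merged construct sequence and Phred+33 quality string.
#' @param flank5,flank3 Constant region sequences.
#' @param max_mismatch_frac Maximum mismatch fraction per flank (default 0.20).
#' @return List with `seq` and `qual` of the variant region, or a reject
#'   sentinel naming the reason.
#' @export
trim_flanks <- function(seq, qual, flank5, flank3, max_mismatch_frac = 0.20) {
  n5 <- nchar(flank5); n3 <- nchar(flank3); n <- nchar(seq)
  if (n < n5 + n3 + 1L) return(reject("too_short"))
  mm5 <- count_mismatches(substr(seq, 1L, n5), flank5)
  if (mm5 > floor(max_mismatch_frac * n5)) return(reject("flank5_mismatch"))
  mm3 <- count_mismatches(substr(seq, n - n3 + 1L, n), flank3)
  if (mm3 > floor(max_mismatch_frac * n3)) return(reject("flank3_mismatch"))
  list(seq = substr(seq, n5 + 1L, n - n3),
       qual = substr(qual, n5 + 1L, n - n3))
}

#' Base-quality filter over the variant region
#'
#' Keep iff every base of the region has Phred quality at or above
#' `min_phred` ("below 30" is strict).
#'
#' @param qual Phred+33 quality string of the variant region.
#' @param min_phred Minimum per-base quality (default 30).
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
quality_filter <- function(qual, min_phred = 30L) {
  if (!nzchar(qual)) return(TRUE)
  min(phred_values(qual)) >= min_phred
}

#' Count designed variants in one FASTQ sample
#'
#' Merges pairs, trims flanks, applies the quality filter, and matches the
#' variant region exactly against the designed library (at nucleotide level
#' by default, or by translated amino-acid product). Non-designed regions are
#' tallied and discarded. Identical read pairs are processed once and
#' weighted by their multiplicity, which leaves all counts unchanged.
#'
#' @param file1,file2 FASTQ paths (gzipped or plain) for the read pair.
#' @param library A `designed_library`.
#' @param flanks Constant regions ([default_flanks()]).
#' @param min_phred Quality threshold (default 30).
#' @param max_mismatch_frac Flank mismatch budget (default 0.20).
#' @param match_level `"nt"` (exact coding sequence) or `"aa"` (translated
#'   product).
#' @return List with `counts` (named integer vector over `variant_id`) and
#'   `qc` (reads in, merged, trimmed, quality-passed, designed, and discard
#'   tallies per reason).
#' @export
count_reads <- function(file1, file2, library, flanks = default_flanks(),
                        min_phred = 30L, max_mismatch_frac = 0.20,
                        match_level = c("nt", "aa")) {
  match_level <- match.arg(match_level)
  if (nrow(library$variants) == 0L) stop("empty designed library")
  fq1 <- read_fastq(file1)
  fq2 <- read_fastq(file2)
  if (length(fq1$seq) != length(fq2$seq)) stop("unpaired FASTQ files")
  n_reads <- length(fq1$seq)

  lut <- stats::setNames(library$variants$variant_id,
                         if (match_level == "nt") library$variants$nt_seq
                         else library$variants$canonical_seq)

  key <- paste(fq1$seq, fq1$qual, fq2$seq, fq2$qual, sep = "\r")
  tab <- table(key)
  uniq <- names(tab)
  mult <- as.integer(tab)
  parts <- strsplit(uniq, "\r", fixed = TRUE)

  qc <- c(reads = n_reads, merged = 0L, trimmed = 0L, quality_pass = 0L,
          designed = 0L, unmergeable = 0L, flank_reject = 0L,
          quality_fail = 0L, non_designed = 0L)
  counts <- integer(0)
  for (i in seq_along(parts)) {
    p <- parts[[i]]; w <- mult[i]
    m <- merge_read_pair(p[1], p[2], p[3], p[4])
    if (is_reject(m)) { qc["unmergeable"] <- qc["unmergeable"] + w; next }
    qc["merged"] <- qc["merged"] + w
    tr <- trim_flanks(m$seq, m$qual, flanks$flank5, flanks$flank3,
                      max_mismatch_frac)
    if (is_reject(tr)) { qc["flank_reject"] <- qc["flank_reject"] + w; next }
    qc["trimmed"] <- qc["trimmed"] + w
    if (!quality_filter(tr$qual, min_phred)) {
      qc["quality_fail"] <- qc["quality_fail"] + w; next
    }
    qc["quality_pass"] <- qc["quality_pass"] + w
    region <- tr$seq
    if (match_level == "aa") {
      if (nchar(region) %% 3L != 0L) {
        qc["non_designed"] <- qc["non_designed"] + w; next
      }
      region <- as.character(Biostrings::translate(
        Biostrings::DNAString(region), no.init.codon = TRUE))
    }
    vid <- lut[region]
    if (is.na(vid)) { qc["non_designed"] <- qc["non_designed"] + w; next }
    qc["designed"] <- qc["designed"] + w
    counts[vid] <- (if (vid %in% names(counts)) counts[vid] else 0L) + w
  }
  list(counts = counts, qc = qc)
}

#' Quantify all samples of a selection experiment
#'
#' Runs [count_reads()] over a sample sheet and assembles the per-variant
#' input/output count table per (biological, technical) replicate.
#'
#' @param sample_sheet Data frame `sample`, `bio_rep`, `tech_rep`, `role`
#'   (`"input"`/`"output"`), `file1`, `file2` (as returned by [emit_fastq()]).
#' @param library A `designed_library`.
#' @param ... Passed to [count_reads()].
#' @return List with `counts` (count table `variant_id`, `bio_rep`,
#'   `tech_rep`, `count_in`, `count_out`) and `qc` (per-sample QC list,
#'   serialisable to JSON).
#' @export
quantify_samples <- function(sample_sheet, library, ...) {
  needed <- c("sample", "bio_rep", "tech_rep", "role", "file1", "file2")
  stopifnot(all(needed %in% names(sample_sheet)))
  per_sample <- lapply(seq_len(nrow(sample_sheet)), function(i) {
    count_reads(sample_sheet$file1[i], sample_sheet$file2[i], library, ...)
  })
  names(per_sample) <- sample_sheet$sample

  keys <- unique(sample_sheet[, c("bio_rep", "tech_rep")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    r <- keys$bio_rep[i]; t <- keys$tech_rep[i]
    pick <- function(role) {
      j <- which(sample_sheet$bio_rep == r & sample_sheet$tech_rep == t &
                   sample_sheet$role == role)
      if (length(j) != 1L) stop("expected one ", role, " sample for bio ", r,
                                " tech ", t)
      per_sample[[j]]$counts
    }
    cin <- pick("input"); cout <- pick("output")
    ids <- union(names(cin), names(cout))
    data.frame(variant_id = ids, bio_rep = r, tech_rep = t,
               count_in = as.integer(ifelse(ids %in% names(cin), cin[ids], 0L)),
               count_out = as.integer(ifelse(ids %in% names(cout), cout[ids], 0L)),
               stringsAsFactors = FALSE)
  })
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  list(counts = counts, qc = lapply(per_sample, function(x) as.list(x$qc)))
}

#' Apply the input-read filters to a count table
#'
#' Drops variants with fewer than `min_input` input reads in any biological
#' replicate (technical replicates pooled), and variants reachable by a
#' single nucleotide change with fewer than `single_nt_min_input` input reads
#' pooled across all replicates. The wild type is never dropped. The filter
#' is idempotent.
#'
#' @param counts Count table.
#' @param library A `designed_library` (supplies `nt_min_changes`).
#' @param min_input Per-replicate minimum input reads (default 10).
#' @param single_nt_min_input Pooled input-read minimum for single-nt
#'   variants (default 1000).
#' @param wt_id Wild-type identifier.
#' @return Filtered count table (same columns), with attribute `dropped`
#'   listing removed variant ids.
#' @export
apply_read_filters <- function(counts, library, min_input = 10L,
                               single_nt_min_input = 1000L, wt_id = "WT") {
  pooled <- pool_technical(counts)
  by_var <- split(pooled, pooled$variant_id)
  min_in <- vapply(by_var, function(d) min(d$count_in), numeric(1))
  tot_in <- vapply(by_var, function(d) sum(d$count_in), numeric(1))
  nmc <- library$variants$nt_min_changes[match(names(by_var),
                                               library$variants$variant_id)]
  drop <- min_in < min_input |
    (!is.na(nmc) & nmc == 1 & tot_in < single_nt_min_input)
  drop[names(by_var) == wt_id] <- FALSE
  dropped <- names(by_var)[drop]
  out <- counts[!counts$variant_id %in% dropped, ]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
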