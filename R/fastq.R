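# FASTQ emission for the synthetic assay.
#
# Each counted molecule becomes one 125 bp paired-end read over the amplicon
# construct flank5 + variant-nt + flank3 (reads are shorter when the construct
# is). Correct bases carry Q37; erroneous bases carry Q20, so the Phred-30
# filter removes exactly the reads the error model corrupted and an
# err_rate = 0 dataset round-trips through quantification unchanged.

#' Default amplicon constant regions
#'
#' Fixed synthetic 25-nt upstream and 21-nt downstream constant regions
#' flanking the variant coding sequence in emitted reads.
#'
#' @return Named list with `flank5` and `flank3`.
#' @export
default_flanks <- function() {
  list(flank5 = "GCTAGCGGAGTGACCGTATCAACGT",   # 25 nt
       flank3 = "TGATCAGGCATGCAAGCTTGG")       # 21 nt
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

Q_HI <- rawToChar(as.raw(33L + 37L))  # 'F', Phred 37
Q_LO <- rawToChar(as.raw(33L + 20L))  # '5', Phred 20

# Inject independent per-base errors into a vector of reads; erroneous bases
# are replaced by a random different base and their quality set to Q20.
inject_errors <- function(reads, err_rate) {
  quals <- strrep(Q_HI, nchar(reads))
  if (err_rate <= 0) return(list(seq = reads, qual = quals))
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(reads)) {
    n <- nchar(reads[i])
    hit <- which(stats::runif(n) < err_rate)
    if (!length(hit)) next
    s <- strsplit(reads[i], "")[[1]]
    q <- strsplit(quals[i], "")[[1]]
    for (j in hit) {
      s[j] <- sample(setdiff(bases, s[j]), 1L)
      q[j] <- Q_LO
    }
    reads[i] <- paste(s, collapse = "")
    quals[i] <- paste(q, collapse = "")
  }
  list(seq = reads, qual = quals)
}

write_fastq <- function(ids, seqs, quals, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  q <- Biostrings::BStringSet(quals)
  qs <- Biostrings::QualityScaledDNAStringSet(dna, Biostrings::PhredQuality(q))
  Biostrings::writeQualityScaledXStringSet(qs, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

read_fastq <- function(path) {
  # suppress the benign metadata-column note emitted on FASTQ import
  qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  list(id = names(qs), seq = as.character(qs),
       qual = as.character(Biostrings::quality(qs)))
}

#' Emit paired FASTQ files for a simulated count table
#'
#' Each count becomes one read pair over the amplicon construct. Read 1 covers
#' the construct 5' end, read 2 the reverse complement of its 3' end, both up
#' to 125 bp; the pair overlaps over the whole construct when it is shorter
#' than 250 bp. Per-base errors occur independently at `cfg$err_rate`. Read
#' order is shuffled deterministically under the configuration seed.
#'
#' @param counts Count table from [simulate_counts()].
#' @param library A `designed_library` (supplies variant nt sequences).
#' @param dir Output directory for `<sample>_R1.fastq.gz` / `_R2.fastq.gz`.
#' @param cfg A `sim_config` (error rate and seed).
#' @param flanks Constant regions, as [default_flanks()].
#' @param read_len Read length (default 125).
#' @return Sample sheet data frame: `sample`, `bio_rep`, `tech_rep`, `role`,
#'   `file1`, `file2`.
#' @export
emit_fastq <- function(counts, library, dir, cfg = sim_config(),
                       flanks = default_flanks(), read_len = 125L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- library$variants
  nt <- stats::setNames(v$nt_seq, v$variant_id)
  construct <- stats::setNames(paste0(flanks$flank5, nt, flanks$flank3),
                               v$variant_id)
  if (any(nchar(construct) > 2L * read_len)) {
    stop("construct longer than paired-read coverage (2 x read_len)")
  }
  set.seed(cfg$seed + 2L)
  sheet <- list()
  for (r in sort(unique(counts$bio_rep))) for (t in sort(unique(counts$tech_rep))) {
    sub <- counts[counts$bio_rep == r & counts$tech_rep == t, ]
    if (!nrow(sub)) next
    for (role in c("input", "output")) {
      cnt <- if (role == "input") sub$count_in else sub$count_out
      ids <- rep(sub$variant_id, cnt)
      ids <- sample(ids)  # shuffle read order
      cons <- construct[ids]
      len <- nchar(cons)
      r1 <- substring(cons, 1L, pmin(read_len, len))
      r2 <- revcomp(substring(cons, pmax(1L, len - read_len + 1L), len))
      e1 <- inject_errors(r1, cfg$err_rate)
      e2 <- inject_errors(r2, cfg$err_rate)
      rid <- sprintf("read%07d", seq_along(ids))
      sample_name <- sprintf("bio%d_tech%d_%s", r, t, role)
      f1 <- file.path(dir, paste0(sample_name, "_R1.fastq.gz"))
      f2 <- file.path(dir, paste0(sample_name, "_R2.fastq.gz"))
      write_fastq(rid, e1$seq, e1$qual, f1)
      write_fastq(rid, e2$seq, e2$qual, f2)
      sheet[[length(sheet) + 1L]] <- data.frame(
        sample = sample_name, bio_rep = r, tech_rep = t, role = role,
        file1 = f1, file2 = f2, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, sheet)
}
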