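# Downstream atlas analyses: region assignment, class frequency tables,
# the deletion-effect matrix with hotspot detection, alternative aliphatic
# cores, truncation series, ROC/AUC, weighted correlation, growth rates.

#' Region scheme over the Abeta42 peptide
#'
#' Named intervals partitioning positions 1-42: the polar/charged stretches
#' (1-11, 12-16, 22-28) and the two aggregation-prone regions APR1 (17-21)
#' and APR2 (29-42), plus the derived N-terminal (1-28) / C-terminal (29-42)
#' super-regions and the aliphatic residue set.
#'
#' @param length Peptide length (default 42).
#' @return A `region_scheme` list: `regions` (data frame `name`, `start`,
#'   `end`), `nterm_end`, `aliphatic`.
#' @export
region_scheme <- function(length = 42L) {
  structure(list(
    regions = data.frame(
      name = c("1-11", "12-16", "APR1", "22-28", "APR2"),
      start = c(1L, 12L, 17L, 22L, 29L),
      end = c(11L, 16L, 21L, 28L, length),
      stringsAsFactors = FALSE),
    nterm_end = 28L,
    length = length,
    aliphatic = aliphatic_residues()
  ), class = "region_scheme")
}

region_of_position <- function(pos, scheme) {
  r <- scheme$regions
  idx <- vapply(pos, function(p) which(r$start <= p & r$end >= p)[1], integer(1))
  r$name[idx]
}

# Removed WT positions for every spec row (list of integer vectors).
removed_positions <- function(spec_table, L) {
  lapply(seq_len(nrow(spec_table)), function(i) {
    s <- spec_table[i, ]
    switch(s$mclass,
           single_deletion = s$pos,
           multi_deletion = seq.int(s$start, s$end),
           truncation = c(if (s$n_del > 0) seq_len(s$n_del),
                          if (s$c_del > 0) seq.int(L - s$c_del + 1L, L)),
           integer(0))
  })
}

#' Assign regions to every designed variant
#'
#' Substitutions, insertions and single deletions get the region containing
#' their position (the insertion at the gap between the N-terminal region and
#' the core is counted N-terminal). Multi-deletions and truncations get the
#' set of regions intersected by their removed residues plus an APR category
#' (`APR1 only`, `APR2 only`, `APR1+APR2`, `no APR`).
#'
#' Degenerate variants are assigned from their representative (first) spec;
#' position-expanded analyses use the spec table directly.
#'
#' @param library A `designed_library`.
#' @param scheme A [region_scheme()].
#' @return Data frame `variant_id`, `region` (first/point region or
#'   semicolon-joined set), `apr_category`, `nterm` (logical: mutation within
#'   positions 1 to `scheme$nterm_end`).
#' @export
assign_region <- function(library, scheme = region_scheme(nchar(library$wt))) {
  v <- library$variants
  L <- nchar(library$wt)
  st <- library$spec_table
  # representative spec of the assigned class (its label is the variant id)
  first <- st[match(v$variant_id, st$label), ]
  region <- character(nrow(v))
  apr <- rep(NA_character_, nrow(v))
  nterm <- rep(NA, nrow(v))
  apr1 <- scheme$regions[scheme$regions$name == "APR1", ]
  apr2 <- scheme$regions[scheme$regions$name == "APR2", ]
  for (i in seq_len(nrow(v))) {
    cls <- v$assigned_class[i]
    if (cls == "wt") { region[i] <- "WT"; next }
    s <- first[i, ]
    if (cls %in% c("substitution", "insertion", "single_deletion")) {
      p <- s$pos
      if (p < 1L || p > L + (cls == "insertion")) stop("position outside 1-", L)
      # the insertion appended after the last residue sits at position L + 1;
      # count it with the final region, as does the gap before the core
      pr <- min(p, L)
      if (cls == "insertion" && p == scheme$nterm_end + 1L) pr <- scheme$nterm_end
      region[i] <- region_of_position(pr, scheme)
      nterm[i] <- pr <= scheme$nterm_end
    } else {
      rem <- removed_positions(s, L)[[1]]
      region[i] <- paste(unique(region_of_position(rem, scheme)), collapse = ";")
      in1 <- any(rem >= apr1$start & rem <= apr1$end)
      in2 <- any(rem >= apr2$start & rem <= apr2$end)
      apr[i] <- if (in1 && in2) "APR1+APR2" else if (in1) "APR1 only"
                else if (in2) "APR2 only" else "no APR"
      nterm[i] <- all(rem <= scheme$nterm_end)
    }
  }
  data.frame(variant_id = v$variant_id, region = region, apr_category = apr,
             nterm = nterm, stringsAsFactors = FALSE)
}

#' Class frequency table
#'
#' Counts and fractions of NS+ / NS- / WT-like variants per mutation class
#' and region at one or more FDR thresholds.
#'
#' @param scores Score table from [score_counts()].
#' @param library A `designed_library`.
#' @param scheme A [region_scheme()].
#' @param fdr_levels FDR thresholds (default 0.1).
#' @param by Grouping: `"region"` (five regions / APR category) or
#'   `"terminus"` (N-terminal 1-28 vs core).
#' @return Tidy data frame `fdr`, `mclass`, `group`, `n`, `n_pos`, `n_neg`,
#'   `n_wtlike`, `f_pos`, `f_neg`, `f_wtlike`.
#' @export
class_frequency_table <- function(scores, library,
                                  scheme = region_scheme(nchar(library$wt)),
                                  fdr_levels = 0.1,
                                  by = c("terminus", "region")) {
  by <- match.arg(by)
  reg <- assign_region(library, scheme)
  v <- library$variants
  df <- merge(scores, reg, by = "variant_id")
  df$mclass <- v$assigned_class[match(df$variant_id, v$variant_id)]
  df <- df[df$mclass != "wt" & !is.na(df$z), ]
  df$group <- if (by == "terminus") ifelse(df$nterm, "1-28", "29-42") else {
    ifelse(is.na(df$apr_category), df$region, df$apr_category)
  }
  out <- list()
  for (fdr in fdr_levels) {
    cls <- rep("WT-like", nrow(df))
    cls[df$q < fdr & df$ns > 0] <- "NS+"
    cls[df$q < fdr & df$ns < 0] <- "NS-"
    agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                            by = list(mclass = df$mclass, group = df$group),
                            FUN = sum)
    for (lab in c("NS+", "NS-", "WT-like")) {
      a <- stats::aggregate(list(x = as.integer(cls == lab)),
                            by = list(mclass = df$mclass, group = df$group),
                            FUN = sum)
      agg[[c("NS+" = "n_pos", "NS-" = "n_neg", "WT-like" = "n_wtlike")[lab]]] <- a$x
    }
    agg$f_pos <- agg$n_pos / agg$n
    agg$f_neg <- agg$n_neg / agg$n
    agg$f_wtlike <- agg$n_wtlike / agg$n
    agg <- cbind(fdr = fdr, agg)
    out[[length(out) + 1L]] <- agg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deletion-effect matrix and positional marginals
#'
#' Builds the (first deleted position) x (last deleted position) matrix of
#' nucleation scores over deletion specs. Degenerate variants populate every
#' contributing cell with their shared score; single deletions occupy the
#' diagonal. Marginals give NS+ / NS- / WT-like frequencies per first
#' position, last position, and missing residue.
#'
#' @param scores Score table.
#' @param library A `designed_library`.
#' @param fdr FDR for the marginal classification (default 0.1).
#' @param include Spec classes entering the matrix; default single and
#'   internal multi-deletions.
#' @return List: `matrix` (L x L, NA where absent), `by_first`, `by_last`,
#'   `by_missing` (data frames `position`, `n`, `f_pos`, `f_neg`,
#'   `f_wtlike`).
#' @export
deletion_effect_matrix <- function(scores, library, fdr = 0.1,
                                   include = c("single_deletion", "multi_deletion")) {
  L <- nchar(library$wt)
  st <- library$spec_table[library$spec_table$mclass %in% include, ]
  s <- scores[match(st$variant_id, scores$variant_id), ]
  first <- ifelse(st$mclass == "single_deletion", st$pos, st$start)
  last <- ifelse(st$mclass == "single_deletion", st$pos, st$end)
  keep <- !is.na(s$ns)
  mat <- matrix(NA_real_, L, L, dimnames = list(first = 1:L, last = 1:L))
  mat[cbind(first[keep], last[keep])] <- s$ns[keep]

  cls <- rep(NA_character_, nrow(st))
  cls[keep] <- "WT-like"
  cls[keep & s$q < fdr & s$ns > 0] <- "NS+"
  cls[keep & s$q < fdr & s$ns < 0] <- "NS-"

  marg <- function(pos_of_spec) {
    expand <- data.frame(pos = unlist(pos_of_spec),
                         cls = rep(cls, lengths(pos_of_spec)),
                         stringsAsFactors = FALSE)
    expand <- expand[!is.na(expand$cls), ]
    res <- data.frame(position = seq_len(L))
    res$n <- tabulate(expand$pos, L)
    for (lab in c("NS+", "NS-", "WT-like")) {
      cnt <- tabulate(expand$pos[expand$cls == lab], L)
      res[[c("NS+" = "f_pos", "NS-" = "f_neg", "WT-like" = "f_wtlike")[lab]]] <-
        ifelse(res$n > 0, cnt / res$n, NA_real_)
    }
    res
  }
  list(matrix = mat,
       by_first = marg(as.list(first)),
       by_last = marg(as.list(last)),
       by_missing = marg(mapply(seq.int, first, last, SIMPLIFY = FALSE)))
}

#' Detect the deletion hotspot from a positional frequency vector
#'
#' Finds all maximal runs of consecutive positions whose NS+ frequency is
#' strictly greater than half the maximum frequency; the hotspot is the
#' longest run (ties: all longest runs are reported).
#'
#' @param freq Numeric vector of NS+ frequencies indexed by position
#'   (NA = position absent, treated as below threshold).
#' @return List: `threshold`, `runs` (data frame `start`, `end`), `hotspot`
#'   (data frame of the longest run(s); zero rows when all frequencies are
#'   zero or missing).
#' @export
detect_hotspot <- function(freq) {
  f <- ifelse(is.na(freq), -Inf, freq)
  m <- max(f)
  if (!is.finite(m) || m <= 0) {
    empty <- data.frame(start = integer(0), end = integer(0))
    return(list(threshold = NA_real_, runs = empty, hotspot = empty))
  }
  thr <- m / 2
  above <- f > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  len <- runs$end - runs$start + 1L
  list(threshold = thr, runs = runs, hotspot = runs[len == max(len), , drop = FALSE])
}

#' Scan for alternative aliphatic cores among bridging deletions
#'
#' Selects internal multi-residue deletions whose removed residues intersect
#' both the N-terminal (1 to `nterm_end`) and core (`nterm_end + 1` to L)
#' regions, computes the replacement segment (the `end - nterm_end` residues
#' immediately preceding the deletion start, which now occupy former core
#' positions), and keeps the variant iff that segment is exclusively
#' aliphatic. The core length of a variant is the maximal contiguous
#' aliphatic run ending at its C terminus.
#'
#' @param scores Score table (used to attach NS; variants without scores are
#'   kept with NA).
#' @param library A `designed_library`.
#' @param scheme A [region_scheme()].
#' @return List: `table` (one row per bridging deletion spec: `variant_id`,
#'   `start`, `end`, `replacement`, `aliphatic_replacement`, `core_length`,
#'   `ns`), `n_alternative_core` (unique variants passing the rule),
#'   `wt_core_length`.
#' @export
alternative_core_scan <- function(scores, library,
                                  scheme = region_scheme(nchar(library$wt))) {
  L <- nchar(library$wt)
  ne <- scheme$nterm_end
  ali <- scheme$aliphatic
  ch <- aa_chars(library$wt)
  core_len <- function(seq) {
    s <- rev(strsplit(seq, "")[[1]])
    n <- 0L
    for (x in s) { if (x %in% ali) n <- n + 1L else break }
    n
  }
  st <- library$spec_table
  md <- st[st$mclass == "multi_deletion" & st$start <= ne & st$end > ne, ]
  if (!nrow(md)) {
    return(list(table = data.frame(), n_alternative_core = 0L,
                wt_core_length = core_len(library$wt)))
  }
  n_repl <- md$end - ne   # number of core residues removed
  repl <- vapply(seq_len(nrow(md)), function(i) {
    from <- md$start[i] - n_repl[i]
    if (from < 1L) from <- 1L
    paste(ch[seq.int(from, md$start[i] - 1L)], collapse = "")
  }, character(1))
  ali_ok <- vapply(strsplit(repl, ""), function(x) all(x %in% ali), logical(1))
  tab <- data.frame(
    variant_id = md$variant_id, start = md$start, end = md$end,
    replacement = repl, aliphatic_replacement = ali_ok,
    core_length = vapply(md$product, core_len, integer(1)),
    ns = scores$ns[match(md$variant_id, scores$variant_id)],
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab,
       n_alternative_core = length(unique(tab$variant_id[tab$aliphatic_replacement])),
       wt_core_length = core_len(library$wt))
}

#' Truncation series profiles
#'
#' Orders pure N-terminal truncations (no C-terminal removal) by the number
#' of residues removed and pure C-terminal truncations likewise, attaching
#' merged NS and a 95 percent confidence interval, and counts NS+ calls
#' among the pure N-terminal series.
#'
#' @param scores Score table.
#' @param library A `designed_library`.
#' @param fdr FDR for the NS+ count (default 0.1).
#' @return List: `n_series`, `c_series` (data frames `removed`, `variant_id`,
#'   `ns`, `se`, `ci_lo`, `ci_hi`, `effect_class`), `n_pos_nterm`.
#' @export
truncation_series <- function(scores, library, fdr = 0.1) {
  st <- library$spec_table
  tr <- st[st$mclass == "truncation", ]
  build <- function(pure_n) {
    sel <- if (pure_n) tr$c_del == 0L else tr$n_del == 0L
    d <- tr[sel, ]
    removed <- if (pure_n) d$n_del else d$c_del
    s <- scores[match(d$variant_id, scores$variant_id), ]
    out <- data.frame(removed = removed, variant_id = d$variant_id,
                      ns = s$ns, se = s$se,
                      ci_lo = s$ns - 1.96 * s$se, ci_hi = s$ns + 1.96 * s$se,
                      q = s$q, stringsAsFactors = FALSE)
    out$effect_class <- "WT-like"
    out$effect_class[!is.na(out$q) & out$q < fdr & out$ns > 0] <- "NS+"
    out$effect_class[!is.na(out$q) & out$q < fdr & out$ns < 0] <- "NS-"
    out$effect_class[is.na(out$ns)] <- NA_character_
    out[order(out$removed), ]
  }
  n_series <- build(TRUE)
  c_series <- build(FALSE)
  list(n_series = n_series, c_series = c_series,
       n_pos_nterm = sum(n_series$effect_class == "NS+", na.rm = TRUE))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' AUC as the probability that a randomly chosen positive outranks a randomly
#' chosen negative, ties counted one half: computed from midranks.
#'
#' @param x Numeric scores.
#' @param labels Logical or 0/1 vector: `TRUE`/1 = positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(x, labels) {
  labels <- as.logical(labels)
  ok <- is.finite(x) & !is.na(labels)
  x <- x[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("need at least one positive and one negative label")
  r <- rank(x)  # midranks
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Weighted Pearson correlation
#'
#' Pearson correlation computed from weighted means and covariances.
#'
#' @param x,y Numeric vectors.
#' @param w Non-negative weights (default uniform; a natural choice is
#'   `1 / se^2`).
#' @return Weighted correlation coefficient.
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(w) == length(x), all(w >= 0))
  ok <- is.finite(x) & is.finite(y) & is.finite(w)
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  if (sum(w) <= 0) stop("weights must not all be zero")
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  cxy <- sum(w * (x - mx) * (y - my))
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) stop("zero weighted variance")
  cxy / sqrt(vx * vy)
}

#' Growth rate from an optical-density time series
#'
#' Maximum over sliding windows of the least-squares slope of `ln(OD)`
#' against time, i.e. the maximum exponential growth rate.
#'
#' @param time Time points (any unit; the rate is per that unit).
#' @param od Optical densities, strictly positive.
#' @param window Number of consecutive points per window (default 10).
#' @return Maximum window slope of `ln(OD)` vs time.
#' @export
growth_rate <- function(time, od, window = 10L) {
  stopifnot(length(time) == length(od), window >= 2L)
  if (any(od <= 0)) stop("optical densities must be positive")
  if (length(od) < window) stop("need at least ", window, " points")
  y <- log(od)
  n <- length(y)
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    tt <- time[idx]; yy <- y[idx]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))
  max(slopes)
}
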