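# Nucleation-score estimation from selection counts.
#
# ES_i = log(F_i output) - log(F_i input), natural log; NS_i = ES_i - ES_WT.
# Per-replicate errors use the Poisson delta method; replicates are merged by
# inverse-variance weighting and the table is re-centered so NS(WT) = 0.

#' Enrichment score from input/output counts
#'
#' `ES = ln(count_out / total_out) - ln(count_in / total_in)`. Natural log.
#' Vectorized over counts.
#'
#' @param count_in,count_out Variant read counts in the input and output pools.
#' @param total_in,total_out Total sample read counts.
#' @return Enrichment score(s); `NA` where a count is zero (no finite score).
#' @export
enrichment_score <- function(count_in, count_out, total_in, total_out) {
  stopifnot(all(total_in > 0), all(total_out > 0))
  es <- log(count_out / total_out) - log(count_in / total_in)
  es[count_in <= 0 | count_out <= 0] <- NA_real_
  es
}

#' Nucleation score: enrichment relative to wild type
#'
#' @param es Variant enrichment score(s).
#' @param es_wt Wild-type enrichment score in the same replicate.
#' @return `es - es_wt`.
#' @export
nucleation_score <- function(es, es_wt) {
  es - es_wt
}

#' Poisson delta-method error for a nucleation score
#'
#' `sigma^2 = 1/count_in + 1/count_out + 1/wt_in + 1/wt_out`, the leading-order
#' variance of `NS` when all four counts are independent Poisson.
#'
#' @param count_in,count_out Variant counts.
#' @param wt_in,wt_out Wild-type counts in the same replicate.
#' @return Standard deviation estimate(s); `NA` where any count is zero.
#' @export
error_estimate <- function(count_in, count_out, wt_in, wt_out) {
  s2 <- 1 / count_in + 1 / count_out + 1 / wt_in + 1 / wt_out
  s2[count_in <= 0 | count_out <= 0 | wt_in <= 0 | wt_out <= 0] <- NA_real_
  sqrt(s2)
}

#' Merge replicate nucleation scores by inverse-variance weighting
#'
#' Weights `w_r = 1 / sigma_r^2`; merged `NS = sum(w NS) / sum(w)`,
#' `SE = 1 / sqrt(sum(w))`. Replicates with missing NS or sigma are dropped.
#'
#' @param ns Per-replicate nucleation scores.
#' @param sigma Per-replicate error estimates.
#' @return List with `ns`, `se`, and `n_rep` (replicates used); `ns` is `NA`
#'   when no replicate is usable.
#' @export
merge_replicates <- function(ns, sigma) {
  ok <- is.finite(ns) & is.finite(sigma) & sigma > 0
  if (!any(ok)) return(list(ns = NA_real_, se = NA_real_, n_rep = 0L))
  w <- 1 / sigma[ok]^2
  list(ns = sum(w * ns[ok]) / sum(w), se = 1 / sqrt(sum(w)), n_rep = sum(ok))
}

#' Classify variants at a false discovery rate
#'
#' Two-sided z-test on `NS / SE` with Benjamini-Hochberg (default) adjustment
#' across all scored variants: `q < fdr` and `NS > 0` is `NS+`, `q < fdr` and
#' `NS < 0` is `NS-`, otherwise `WT-like`. Rows flagged non-nucleating keep
#' that class and take no part in the test.
#'
#' @param scores Data frame with columns `ns`, `se`, and optionally
#'   `effect_class` (rows already set to `"non_nucleating"` are preserved).
#' @param fdr FDR threshold (default 0.1).
#' @param method Multiple-testing adjustment, `"BH"` or `"BY"`.
#' @return `scores` with columns `z`, `p`, `q`, `effect_class`.
#' @export
classify_variants <- function(scores, fdr = 0.1, method = c("BH", "BY")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(scores), all(c("ns", "se") %in% names(scores)))
  if (is.null(scores$effect_class)) scores$effect_class <- NA_character_
  testable <- is.finite(scores$ns) & is.finite(scores$se) & scores$se > 0 &
    !(scores$effect_class %in% "non_nucleating")
  degenerate <- is.finite(scores$ns) & scores$ns != 0 &
    (!is.finite(scores$se) | scores$se == 0)
  if (any(degenerate)) {
    warning(sum(degenerate), " variant(s) with SE = 0 and NS != 0 left unclassified")
  }
  scores$z <- scores$p <- scores$q <- NA_real_
  scores$z[testable] <- scores$ns[testable] / scores$se[testable]
  scores$p[testable] <- 2 * stats::pnorm(-abs(scores$z[testable]))
  scores$q[testable] <- stats::p.adjust(scores$p[testable], method = method)
  cls <- scores$effect_class
  cls[testable] <- "WT-like"
  sig <- testable & scores$q < fdr
  cls[sig & scores$ns > 0] <- "NS+"
  cls[sig & scores$ns < 0] <- "NS-"
  scores$effect_class <- cls
  scores
}

# Pool technical replicates within each biological replicate.
pool_technical <- function(counts) {
  stopifnot(all(c("variant_id", "bio_rep", "count_in", "count_out") %in% names(counts)))
  agg <- stats::aggregate(counts[, c("count_in", "count_out")],
                          by = list(variant_id = counts$variant_id,
                                    bio_rep = counts$bio_rep),
                          FUN = sum)
  agg[order(agg$bio_rep, agg$variant_id), ]
}

#' Score a count table
#'
#' Full scoring pipeline: pools technical replicates within each biological
#' replicate, computes per-replicate enrichment and nucleation scores relative
#' to wild type with Poisson delta-method errors, optionally inflates errors
#' by a global overdispersion factor fitted from between-replicate scatter,
#' merges replicates by inverse-variance weighting, re-centers to wild type,
#' flags non-nucleating variants (input reads in every replicate, zero output
#' reads everywhere), and classifies at the given FDR.
#'
#' @param counts Count table: `variant_id`, `bio_rep`, optionally `tech_rep`,
#'   `count_in`, `count_out`.
#' @param library Optional `designed_library`; used only to identify the
#'   wild-type entry (default id `"WT"`).
#' @param fdr FDR threshold for classification.
#' @param wt_id Identifier of the wild-type variant.
#' @param overdispersion If `TRUE` (default), fit a single multiplicative
#'   variance-inflation factor from the between-replicate scatter of NS and
#'   apply it to all per-replicate errors.
#' @param method Multiple-testing adjustment passed to [classify_variants()].
#' @return A score table: one row per variant with per-replicate `es_r`,
#'   `ns_r`, `sigma_r` (list-columns flattened as wide columns), merged `ns`,
#'   `se`, `z`, `p`, `q`, `effect_class`, plus `phi` (the overdispersion
#'   factor) as an attribute.
#' @export
score_counts <- function(counts, library = NULL, fdr = 0.1, wt_id = "WT",
                         overdispersion = TRUE, method = "BH") {
  pooled <- pool_technical(counts)
  reps <- sort(unique(pooled$bio_rep))
  ids <- unique(pooled$variant_id)
  if (!wt_id %in% ids) stop("wild-type variant '", wt_id, "' absent from counts")

  wide_in <- matrix(0, nrow = length(ids), ncol = length(reps),
                    dimnames = list(ids, reps))
  wide_out <- wide_in
  idx <- cbind(match(pooled$variant_id, ids), match(pooled$bio_rep, reps))
  wide_in[idx] <- pooled$count_in
  wide_out[idx] <- pooled$count_out

  tot_in <- colSums(wide_in)
  tot_out <- colSums(wide_out)
  es <- log(sweep(wide_out, 2, tot_out, "/")) -
    log(sweep(wide_in, 2, tot_in, "/"))
  es[wide_in <= 0 | wide_out <= 0] <- NA_real_
  ns <- sweep(es, 2, es[wt_id, ], "-")
  sigma <- sqrt(sweep(1 / wide_in + 1 / wide_out, 2,
                      1 / wide_in[wt_id, ] + 1 / wide_out[wt_id, ], "+"))
  sigma[wide_in <= 0 | wide_out <= 0] <- NA_real_

  phi <- 1
  if (overdispersion && length(reps) >= 2L) {
    phi <- fit_overdispersion(ns, sigma, wt_id)
    sigma <- sigma * sqrt(phi)
  }

  merged <- lapply(seq_along(ids), function(i) merge_replicates(ns[i, ], sigma[i, ]))
  out <- data.frame(
    variant_id = ids,
    ns = vapply(merged, `[[`, numeric(1), "ns"),
    se = vapply(merged, `[[`, numeric(1), "se"),
    n_rep = vapply(merged, `[[`, integer(1), "n_rep"),
    stringsAsFactors = FALSE
  )
  # center so NS(WT) = 0 exactly (it already is up to rounding)
  out$ns <- out$ns - out$ns[out$variant_id == wt_id]

  # non-nucleating: input reads in every replicate, zero output reads everywhere
  nn <- rowSums(wide_in > 0) == length(reps) & rowSums(wide_out) == 0
  out$effect_class <- NA_character_
  out$effect_class[nn] <- "non_nucleating"
  out$ns[nn] <- NA_real_
  out$se[nn] <- NA_real_

  colnames(ns) <- paste0("ns_rep", reps)
  colnames(es) <- paste0("es_rep", reps)
  colnames(sigma) <- paste0("sigma_rep", reps)
  out <- cbind(out, es, ns, sigma)
  out <- classify_variants(out, fdr = fdr, method = method)
  rownames(out) <- NULL
  attr(out, "phi") <- phi
  attr(out, "log_base") <- "natural"
  out
}

# Global variance-inflation factor from between-replicate scatter:
# for each variant with >= 2 finite replicates, chi2 = sum((ns_r - ns_bar_w)^2
# / sigma_r^2) ~ phi * chisq(n - 1); phi is estimated as the ratio of the
# total chi2 to its degrees of freedom, floored at 1.
fit_overdispersion <- function(ns, sigma, wt_id) {
  chi2 <- 0
  df <- 0
  for (i in seq_len(nrow(ns))) {
    ok <- is.finite(ns[i, ]) & is.finite(sigma[i, ]) & sigma[i, ] > 0
    if (sum(ok) < 2L) next
    w <- 1 / sigma[i, ok]^2
    nbar <- sum(w * ns[i, ok]) / sum(w)
    chi2 <- chi2 + sum(w * (ns[i, ok] - nbar)^2)
    df <- df + sum(ok) - 1L
  }
  if (df == 0) return(1)
  max(1, chi2 / df)
}

#' Write a score table to CSV
#'
#' @param scores Score table from [score_counts()].
#' @param path Output CSV path.
#' @export
write_scores <- function(scores, path) {
  meta <- sprintf("# dimatlas score table v1; log=%s; phi=%.6g",
                  attr(scores, "log_base") %||% "natural",
                  attr(scores, "phi") %||% 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(scores, con, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#'
#' @param path CSV path.
#' @return Score table data frame.
#' @export
read_scores <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
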