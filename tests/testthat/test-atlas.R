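test_that("region assignment follows the atlas conventions", {
  lib <- build_library()
  reg <- assign_region(lib)
  v <- lib$variants
  # total function over the library
  expect_false(any(is.na(reg$region)))
  # substitution at position 5 sits in region 1-11
  expect_equal(reg$region[reg$variant_id == "R5A"], "1-11")
  expect_true(reg$nterm[reg$variant_id == "R5A"])
  # the insertion between positions 28 and 29 is reported at position 29 but
  # counted as an N-terminal mutation
  ins29 <- reg[reg$variant_id == "ins29A", ]
  expect_true(ins29$nterm)
  # a deletion spanning 20-30 intersects APR1, the 22-28 stretch and APR2
  d <- reg[reg$variant_id == "del20-30", ]
  expect_setequal(strsplit(d$region, ";")[[1]], c("APR1", "22-28", "APR2"))
  expect_equal(d$apr_category, "APR1+APR2")
  expect_false(d$nterm)
  # scheme intervals partition the peptide
  sch <- region_scheme()
  covered <- unlist(mapply(seq.int, sch$regions$start, sch$regions$end))
  expect_equal(sort(covered), 1:42)
})

test_that("class frequency tables are complete and consistent", {
  lib <- build_library(short_wt())
  set.seed(2)
  sc <- flat_scores(lib)
  # plant a uniformly NS+ cell: all substitutions significant positive
  subs <- lib$variants$assigned_class == "substitution"
  sc$ns[subs] <- 2; sc$q[subs] <- 0.001
  tab <- class_frequency_table(sc, lib, scheme = region_scheme(nchar(lib$wt)),
                               fdr_levels = c(0.1, 0.25))
  expect_true(all(abs(tab$f_pos + tab$f_neg + tab$f_wtlike - 1) < 1e-12))
  expect_true(all(tab$n_pos + tab$n_neg + tab$n_wtlike == tab$n))
  sub_rows <- tab[tab$mclass == "substitution", ]
  expect_true(all(sub_rows$f_pos == 1))
})

test_that("deletion matrix expands degenerate variants and matches marginals", {
  lib <- build_library()
  set.seed(3)
  sc <- flat_scores(lib)
  sc$ns <- stats::rnorm(nrow(sc))
  sc$q <- stats::runif(nrow(sc))
  dm <- deletion_effect_matrix(sc, lib)
  # the triple-degenerate deletion populates all three member cells
  ns_deg <- sc$ns[sc$variant_id == "del2-20"]
  expect_equal(dm$matrix[2, 20], ns_deg)
  expect_equal(dm$matrix[3, 21], ns_deg)
  expect_equal(dm$matrix[4, 22], ns_deg)
  # single deletions occupy the diagonal
  h13 <- sc$ns[sc$variant_id == "H13del"]
  expect_equal(dm$matrix[13, 13], h13)
  expect_equal(dm$matrix[14, 14], h13)  # degenerate pair shares the score
  # brute-force marginal oracle over the expanded spec list
  st <- lib$spec_table[lib$spec_table$mclass %in%
                         c("single_deletion", "multi_deletion"), ]
  s <- sc[match(st$variant_id, sc$variant_id), ]
  first <- ifelse(st$mclass == "single_deletion", st$pos, st$start)
  cls <- ifelse(s$q < 0.1, ifelse(s$ns > 0, "NS+", "NS-"), "WT-like")
  for (p in c(2, 13, 22, 30)) {
    sel <- first == p
    expect_equal(dm$by_first$n[p], sum(sel))
    expect_equal(dm$by_first$f_pos[p], mean(cls[sel] == "NS+"))
  }
})

test_that("hotspot detection applies the half-maximum run rule", {
  hs <- detect_hotspot(c(0, .1, .6, .7, .8, .2))
  expect_equal(hs$hotspot$start, 3)
  expect_equal(hs$hotspot$end, 5)
  # every value exceeds half of a constant maximum
  hs2 <- detect_hotspot(rep(0.4, 7))
  expect_equal(hs2$hotspot$start, 1)
  expect_equal(hs2$hotspot$end, 7)
  # scale invariance
  v <- c(0.05, 0.3, 0.31, 0.02, 0.28, 0.29, 0.3, 0.01)
  expect_equal(detect_hotspot(v)$runs, detect_hotspot(17.3 * v)$runs)
  # ties: all longest runs reported
  hs3 <- detect_hotspot(c(1, 1, 0, 1, 1))
  expect_equal(nrow(hs3$hotspot), 2)
  # degenerate input
  hs4 <- detect_hotspot(c(0, 0, NA))
  expect_equal(nrow(hs4$hotspot), 0)
})

test_that("alternative-core scan reproduces the worked bridging examples", {
  lib <- build_library()
  sc <- flat_scores(lib)
  acs <- alternative_core_scan(sc, lib)
  # the wild-type aliphatic core 29-42 is 14 residues long
  expect_equal(acs$wt_core_length, 14)
  # deletion 25-35 relocates VFFAEDV (18-24) onto core positions: E and D
  # break the aliphatic rule
  row <- acs$table[acs$table$start == 25 & acs$table$end == 35, ]
  expect_equal(row$replacement, "VFFAEDV")
  expect_false(row$aliphatic_replacement)
  # bridging set = internal deletions touching both 1-28 and 29-42
  expect_true(all(acs$table$start <= 28 & acs$table$end >= 29))
  # retained variants have exclusively aliphatic replacement segments
  ali <- aliphatic_residues()
  keep <- acs$table[acs$table$aliphatic_replacement, ]
  expect_true(all(vapply(strsplit(keep$replacement, ""),
                         function(x) all(x %in% ali), logical(1))))
  expect_equal(acs$n_alternative_core, length(unique(keep$variant_id)))
})

test_that("truncation series cover both termini with the core boundary at 28", {
  lib <- build_library()
  sc <- flat_scores(lib)
  sc$ns[] <- 0.5
  ts <- truncation_series(sc, lib)
  # removing 2..39 N-terminal residues
  expect_equal(ts$n_series$removed, 2:39)
  expect_equal(ts$c_series$removed, 2:39)
  # 27 pure N-terminal truncations leave the 29-42 core fully intact
  expect_equal(sum(ts$n_series$removed <= 28), 27)
  expect_true(all(ts$n_series$ci_lo < ts$n_series$ns))
  # a planted significant positive N-truncation set is counted
  sc2 <- flat_scores(lib)
  ids <- ts$n_series$variant_id[1:5]
  sc2$ns[sc2$variant_id %in% ids] <- 1
  sc2$q[sc2$variant_id %in% ids] <- 0.01
  expect_equal(truncation_series(sc2, lib)$n_pos_nterm, 5)
})

test_that("AUC agrees with brute-force pair counting and is rank invariant", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_error(roc_auc(1:5, rep(1, 5)), "at least one")
  set.seed(7)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    x <- round(stats::rnorm(n), 1)  # rounding forces ties
    lab <- stats::runif(n) < 0.4
    if (!any(lab) || all(lab)) next
    # O(n^2) oracle: P(pos > neg) + 0.5 P(tie)
    pos <- x[lab]; neg <- x[!lab]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_auc(x, lab), mean(cmp))
    # strictly monotone transform leaves AUC unchanged
    expect_equal(roc_auc(exp(2 * x), lab), roc_auc(x, lab))
  }
  # labels independent of scores concentrate near 1/2
  n <- 1e4
  x <- stats::rnorm(n); lab <- stats::runif(n) < 0.5
  n1 <- sum(lab); n0 <- n - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(roc_auc(x, lab) - 0.5), 3 * se)
})

test_that("AUC matches the field-standard ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  x <- stats::rnorm(300)
  lab <- stats::runif(300) < 0.3
  ref <- as.numeric(pROC::auc(pROC::roc(lab, x, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(x, lab), ref, tolerance = 1e-12)
})

test_that("weighted Pearson reduces to the classical estimate and to moments", {
  set.seed(9)
  x <- stats::rnorm(50); y <- 2 * x + stats::rnorm(50)
  expect_equal(weighted_pearson(x, y), stats::cor(x, y), tolerance = 1e-12)
  # exact linear relation scores 1 under any weights
  w <- stats::runif(50)
  expect_equal(weighted_pearson(x, 3 * x - 1, w), 1, tolerance = 1e-12)
  # direct weighted-moment oracle
  wp <- weighted_pearson(x, y, w)
  wn <- w / sum(w)
  mx <- sum(wn * x); my <- sum(wn * y)
  oracle <- sum(wn * (x - mx) * (y - my)) /
    sqrt(sum(wn * (x - mx)^2) * sum(wn * (y - my)^2))
  expect_equal(wp, oracle, tolerance = 1e-12)
  expect_error(weighted_pearson(x, y, rep(0, 50)), "zero")
})

test_that("growth rate equals the exponential slope and handles curvature", {
  t <- seq(0, 10, by = 1 / 6)  # 10-minute sampling in hours
  expect_equal(growth_rate(t, 0.05 * exp(0.3 * t)), 0.3, tolerance = 1e-10)
  expect_equal(growth_rate(t, rep(0.7, length(t))), 0)
  expect_error(growth_rate(t, c(-1, rep(1, length(t) - 1))), "positive")
  # logistic growth: max d ln(OD)/dt = r (1 - x0/K) at t = 0 for x0 << K
  r <- 0.5; K <- 1; x0 <- 0.01
  od <- K * x0 * exp(r * t) / (K + x0 * (exp(r * t) - 1))
  analytic <- r * (1 - x0 / K)
  expect_equal(growth_rate(t, od, window = 5), analytic, tolerance = 0.02)
})
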