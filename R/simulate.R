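# Synthetic selection-assay generator.
#
# The generative model mirrors the structure the scoring pipeline assumes:
# input frequencies are Dirichlet-distributed across the library; selection
# acts once as bulk exponential enrichment proportional to exp(NS_true);
# biological replicates add Gaussian noise to NS_true; technical replicates
# within a biological replicate share its frequencies and differ only by
# multinomial resampling at the sequencing depth.

#' Simulation configuration
#'
#' Defaults are the study conditions of the assay being emulated: 3 biological
#' x 5 technical replicates, sequencing depth 1e6 reads per sample, mild input
#' unevenness (Dirichlet concentration 50 per variant), replicate noise
#' SD 0.2 on the log scale, and a small probability of dead variants (zero
#' output frequency). The per-(class, region) effect mixture gives the
#' probability that a variant decreases (`w_neg`), matches (`w_null`) or
#' increases (`w_pos`) nucleation, with shared Gaussian component parameters.
#'
#' @param n_bio Biological replicates.
#' @param n_tech Technical replicates per biological replicate.
#' @param depth Reads per sample (input and output each).
#' @param alpha Dirichlet concentration per variant for input frequencies.
#' @param sigma_rep SD of the per-variant, per-biological-replicate noise
#'   added to the true score (log scale).
#' @param dead_prob Probability a variant is dead (zero output everywhere).
#' @param mixture Data frame with columns `mclass`, `region` (`"nterm"` /
#'   `"cterm"`), `w_neg`, `w_null`, `w_pos`; defaults from the observed
#'   per-class NS+/NS- fractions of the Abeta42 atlas.
#' @param mu_neg,sd_neg,mu_null,sd_null,mu_pos,sd_pos Gaussian component
#'   parameters of the effect mixture (log scale).
#' @param err_rate Per-base read error rate for FASTQ emission.
#' @param seed Integer seed; fixed seed reproduces every output exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_bio = 3L, n_tech = 5L, depth = 1e6, alpha = 50,
                       sigma_rep = 0.2, dead_prob = 9 / 3164,
                       mixture = default_effect_mixture(),
                       mu_neg = -3, sd_neg = 1, mu_null = 0, sd_null = 0.1,
                       mu_pos = 1.5, sd_pos = 0.5,
                       err_rate = 0, seed = 1L) {
  stopifnot(depth >= 1, sigma_rep >= 0, alpha > 0,
            n_bio >= 1, n_tech >= 1, dead_prob >= 0, dead_prob < 1)
  w <- mixture[, c("w_neg", "w_null", "w_pos")]
  if (any(abs(rowSums(w) - 1) > 1e-8)) {
    stop("mixture weights must sum to 1 in every (class, region) cell")
  }
  structure(list(n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
                 depth = depth, alpha = alpha, sigma_rep = sigma_rep,
                 dead_prob = dead_prob, mixture = mixture,
                 comp = list(neg = c(mu_neg, sd_neg), null = c(mu_null, sd_null),
                             pos = c(mu_pos, sd_pos)),
                 err_rate = err_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default effect mixture per mutation class and region
#'
#' Mixture weights (decrease / wild-type-like / increase) per mutation class
#' in the N-terminal (1-28) and C-terminal core (29-42) regions, taken from
#' the observed NS-/NS+ fractions of the Abeta42 nucleation atlas: positive
#' effects concentrate in the N terminus and core mutations are largely
#' deleterious.
#'
#' @return Data frame with columns `mclass`, `region`, `w_neg`, `w_null`, `w_pos`.
#' @export
default_effect_mixture <- function() {
  m <- data.frame(
    mclass = rep(c("substitution", "insertion", "single_deletion",
                   "multi_deletion", "truncation"), each = 2),
    region = rep(c("nterm", "cterm"), times = 5),
    w_neg = c(0.26, 0.76, 0.30, 0.76, 0.11, 1.00, 0.19, 0.94, 0.00, 1.00),
    w_pos = c(0.18, 0.06, 0.12, 0.05, 0.19, 0.00, 0.28, 0.01, 0.50, 0.00),
    stringsAsFactors = FALSE
  )
  m$w_null <- 1 - m$w_neg - m$w_pos
  m[, c("mclass", "region", "w_neg", "w_null", "w_pos")]
}

# Region of a variant for the effect mixture: "cterm" if the mutation touches
# the 29-42 core (any removed residue >= core_start; point mutations by their
# display position, with the insertion at the 28/29 gap counted N-terminal),
# else "nterm".
sim_region <- function(library, core_start = 29L) {
  v <- library$variants
  # representative spec of the assigned class (its label is the variant id)
  st <- library$spec_table
  first_spec <- st$display_pos[match(v$variant_id, st$label)]
  first_spec[v$assigned_class == "wt"] <- ""
  region <- rep("nterm", nrow(v))
  cls <- v$assigned_class
  pt <- cls %in% c("substitution", "insertion", "single_deletion")
  pos <- suppressWarnings(as.integer(first_spec))
  region[pt & !is.na(pos) & pos >= core_start] <- "cterm"
  # insertion at the gap between core_start-1 and core_start is N-terminal
  region[cls == "insertion" & !is.na(pos) & pos == core_start] <- "nterm"
  md <- cls == "multi_deletion"
  if (any(md)) {
    e <- as.integer(sub("^\\d+-", "", first_spec[md]))
    region[md][e >= core_start] <- "cterm"
  }
  tr <- cls == "truncation"
  if (any(tr)) {
    a <- as.integer(sub("^N(\\d+)\\|C(\\d+)$", "\\1", first_spec[tr]))
    b <- as.integer(sub("^N(\\d+)\\|C(\\d+)$", "\\2", first_spec[tr]))
    # any C-terminal removal reaches into the core; N-terminal removals only
    # when they extend to residue core_start or beyond
    region[tr] <- ifelse(b >= 1L | a >= core_start, "cterm", "nterm")
  }
  region[cls == "wt"] <- "nterm"
  region
}

#' Draw true nucleation scores for a library
#'
#' Each variant draws its latent effect from the configured
#' (class, region) mixture; the wild type is exactly 0. A variant is dead
#' with probability `cfg$dead_prob` (zero output frequency downstream).
#'
#' @param library A `designed_library`.
#' @param cfg A `sim_config`.
#' @return Data frame `variant_id`, `mclass`, `region`, `ns_true`, `dead`.
#' @export
sample_true_scores <- function(library, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  v <- library$variants
  region <- sim_region(library)
  key <- paste(v$assigned_class, region)
  mkey <- paste(cfg$mixture$mclass, cfg$mixture$region)
  row <- match(key, mkey)
  if (any(is.na(row) & v$assigned_class != "wt")) {
    stop("mixture has no cell for: ",
         paste(unique(key[is.na(row) & v$assigned_class != "wt"]), collapse = ", "))
  }
  n <- nrow(v)
  comp_draw <- function(i) {
    if (v$assigned_class[i] == "wt") return(0)
    wts <- as.numeric(cfg$mixture[row[i], c("w_neg", "w_null", "w_pos")])
    k <- sample.int(3L, 1L, prob = wts)
    par <- cfg$comp[[c("neg", "null", "pos")[k]]]
    stats::rnorm(1, par[1], par[2])
  }
  ns_true <- vapply(seq_len(n), comp_draw, numeric(1))
  dead <- stats::runif(n) < cfg$dead_prob
  dead[v$assigned_class == "wt"] <- FALSE
  data.frame(variant_id = v$variant_id, mclass = v$assigned_class,
             region = region, ns_true = ns_true, dead = dead,
             stringsAsFactors = FALSE)
}

#' Simulate a replicate count table
#'
#' Per biological replicate: input frequencies are Dirichlet(alpha); output
#' frequencies are proportional to `f_in * exp(ns_true + eps)` with
#' `eps ~ N(0, sigma_rep^2)` per variant, dead variants forced to zero before
#' renormalization. Per technical replicate, counts are multinomial draws at
#' the configured depth from the shared frequencies.
#'
#' @param library A `designed_library`.
#' @param effects Truth table from [sample_true_scores()].
#' @param cfg A `sim_config`.
#' @return Count table `variant_id`, `bio_rep`, `tech_rep`, `count_in`,
#'   `count_out`.
#' @export
simulate_counts <- function(library, effects, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  v <- library$variants
  if (!setequal(effects$variant_id, v$variant_id)) {
    stop("effects must cover exactly the library's variants")
  }
  effects <- effects[match(v$variant_id, effects$variant_id), ]
  if (all(effects$dead)) stop("all variants dead: degenerate simulation")
  set.seed(cfg$seed + 1L)
  n <- nrow(v)
  res <- vector("list", cfg$n_bio * cfg$n_tech)
  k <- 0L
  for (r in seq_len(cfg$n_bio)) {
    f_in <- stats::rgamma(n, shape = cfg$alpha)
    f_in <- f_in / sum(f_in)
    eps <- stats::rnorm(n, 0, cfg$sigma_rep)
    f_out <- f_in * exp(effects$ns_true + eps)
    f_out[effects$dead] <- 0
    f_out <- f_out / sum(f_out)
    for (t in seq_len(cfg$n_tech)) {
      cin <- stats::rmultinom(1, cfg$depth, f_in)[, 1]
      cout <- stats::rmultinom(1, cfg$depth, f_out)[, 1]
      k <- k + 1L
      res[[k]] <- data.frame(variant_id = v$variant_id, bio_rep = r,
                             tech_rep = t, count_in = cin, count_out = cout,
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write / read count tables
#'
#' @param counts Count table data frame.
#' @param path CSV path.
#' @export
write_counts <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
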