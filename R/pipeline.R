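# Pipeline orchestration: design -> simulate -> quantify -> score -> analyze
# with one structured config, deterministic seeds, and a run manifest.

#' Default run configuration
#'
#' All stage parameters with their assay defaults (flank mismatch budget 20
#' percent, Phred 30, 10 input reads per replicate, 1000 pooled input reads
#' for single-nt variants, FDR 0.1), a global seed, and the replicate
#' structure of the emulated experiment.
#'
#' @param seed Global integer seed.
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    wt = abeta42(),
    design = list(gap_range = NULL, max_del_len = 39L),
    sim = list(n_bio = 3L, n_tech = 5L, depth = 1e6, alpha = 50,
               sigma_rep = 0.2, dead_prob = 9 / 3164, err_rate = 0),
    quantify = list(use_fastq = FALSE, min_phred = 30L,
                    max_mismatch_frac = 0.20, match_level = "nt"),
    filters = list(min_input = 10L, single_nt_min_input = 1000L),
    score = list(fdr = 0.1, method = "BH", overdispersion = TRUE)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values in the file override the defaults; unknown keys are an error.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding both default and file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  cfg <- default_run_config()
  user <- yaml::read_yaml(path)
  merge_into <- function(base, upd, prefix = "") {
    for (k in names(upd)) {
      if (!k %in% names(base)) stop("unknown config key: ", prefix, k)
      if (is.list(base[[k]]) && is.list(upd[[k]])) {
        base[[k]] <- merge_into(base[[k]], upd[[k]], paste0(prefix, k, "."))
      } else base[[k]] <- upd[[k]]
    }
    base
  }
  cfg <- merge_into(unclass(cfg), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  class(cfg) <- "run_config"
  cfg
}

manifest_add <- function(manifest, stage, files, params) {
  rbind(manifest, data.frame(
    stage = stage, file = files, md5 = unname(tools::md5sum(files)),
    params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE, null = "null")),
    stringsAsFactors = FALSE))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, writing every table as CSV under
#' `out_dir` together with a manifest of output hashes and stage parameters.
#' Stages are individually resumable: a stage whose inputs are not in memory
#' reads the upstream artifact from `out_dir` and fails with the name of the
#' stage to run first when it is absent.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Output directory.
#' @param stages Subset of `c("design", "simulate", "quantify", "score",
#'   "analyze")` in pipeline order.
#' @return Invisibly, a list of the in-memory artifacts (`library`, `truth`,
#'   `counts`, `scores`, `analysis`).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = "dimatlas-run",
                         stages = c("design", "simulate", "quantify",
                                    "score", "analyze")) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("design", "simulate", "quantify", "score", "analyze")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame()
  art <- list()
  path <- function(f) file.path(out_dir, f)
  need <- function(obj, file, reader, stage_hint) {
    if (!is.null(obj)) return(obj)
    if (!file.exists(path(file))) {
      stop("missing artifact '", file, "': run stage '", stage_hint, "' first")
    }
    reader(path(file))
  }

  if ("design" %in% stages) {
    message("stage design: enumerating library")
    art$library <- build_library(config$wt,
                                 gap_range = config$design$gap_range,
                                 max_del_len = config$design$max_del_len)
    write_library(art$library, path("library.csv"))
    manifest <- manifest_add(manifest, "design", path("library.csv"), config$design)
  }

  if ("simulate" %in% stages) {
    message("stage simulate: drawing true scores and counts")
    art$library <- need(art$library, "library.csv", function(p) {
      build_library(config$wt, gap_range = config$design$gap_range,
                    max_del_len = config$design$max_del_len)
    }, "design")
    scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
    art$truth <- sample_true_scores(art$library, scfg)
    art$counts_raw <- simulate_counts(art$library, art$truth, scfg)
    utils::write.csv(art$truth, path("truth.csv"), row.names = FALSE)
    write_counts(art$counts_raw, path("counts_raw.csv"))
    files <- c(path("truth.csv"), path("counts_raw.csv"))
    if (isTRUE(config$quantify$use_fastq)) {
      sheet <- emit_fastq(art$counts_raw, art$library, path("fastq"), scfg)
      utils::write.csv(sheet, path("samples.csv"), row.names = FALSE)
      files <- c(files, path("samples.csv"))
    }
    manifest <- manifest_add(manifest, "simulate", files, config$sim)
  }

  if ("quantify" %in% stages) {
    message("stage quantify: building filtered count table")
    art$library <- need(art$library, "library.csv", function(p) {
      build_library(config$wt, gap_range = config$design$gap_range,
                    max_del_len = config$design$max_del_len)
    }, "design")
    if (isTRUE(config$quantify$use_fastq)) {
      sheet <- need(art$sheet, "samples.csv", utils::read.csv, "simulate")
      q <- quantify_samples(sheet, art$library,
                            min_phred = config$quantify$min_phred,
                            max_mismatch_frac = config$quantify$max_mismatch_frac,
                            match_level = config$quantify$match_level)
      counts <- q$counts
      jsonlite::write_json(q$qc, path("qc.json"), auto_unbox = TRUE, pretty = TRUE)
    } else {
      counts <- need(art$counts_raw, "counts_raw.csv", read_counts, "simulate")
    }
    art$counts <- apply_read_filters(counts, art$library,
                                     min_input = config$filters$min_input,
                                     single_nt_min_input = config$filters$single_nt_min_input)
    write_counts(art$counts, path("counts.csv"))
    manifest <- manifest_add(manifest, "quantify", path("counts.csv"),
                             c(config$quantify, config$filters))
  }

  if ("score" %in% stages) {
    message("stage score: nucleation scores and FDR classes")
    counts <- need(art$counts, "counts.csv", read_counts, "quantify")
    required <- c("variant_id", "bio_rep", "count_in", "count_out")
    missing_cols <- setdiff(required, names(counts))
    if (length(missing_cols)) {
      stop("count table schema error: missing column(s) ",
           paste(missing_cols, collapse = ", "))
    }
    art$scores <- score_counts(counts, art$library,
                               fdr = config$score$fdr,
                               overdispersion = config$score$overdispersion,
                               method = config$score$method)
    write_scores(art$scores, path("scores.csv"))
    manifest <- manifest_add(manifest, "score", path("scores.csv"), config$score)
  }

  if ("analyze" %in% stages) {
    message("stage analyze: atlas tables")
    art$library <- need(art$library, "library.csv", function(p) {
      build_library(config$wt, gap_range = config$design$gap_range,
                    max_del_len = config$design$max_del_len)
    }, "design")
    scores <- need(art$scores, "scores.csv", read_scores, "score")
    dir.create(path("analysis"), showWarnings = FALSE)
    freq <- class_frequency_table(scores, art$library, fdr_levels = config$score$fdr)
    utils::write.csv(freq, path("analysis/class_frequency.csv"), row.names = FALSE)
    dm <- deletion_effect_matrix(scores, art$library, fdr = config$score$fdr)
    utils::write.csv(dm$matrix, path("analysis/deletion_matrix.csv"))
    utils::write.csv(dm$by_first, path("analysis/deletion_by_first.csv"), row.names = FALSE)
    utils::write.csv(dm$by_last, path("analysis/deletion_by_last.csv"), row.names = FALSE)
    hs_first <- detect_hotspot(dm$by_first$f_pos)
    hs_last <- detect_hotspot(dm$by_last$f_pos)
    jsonlite::write_json(list(first = hs_first$hotspot, last = hs_last$hotspot,
                              threshold_first = hs_first$threshold,
                              threshold_last = hs_last$threshold),
                         path("analysis/hotspot.json"), auto_unbox = TRUE,
                         pretty = TRUE, dataframe = "columns")
    cores <- alternative_core_scan(scores, art$library)
    utils::write.csv(cores$table, path("analysis/alternative_cores.csv"), row.names = FALSE)
    ts <- truncation_series(scores, art$library, fdr = config$score$fdr)
    utils::write.csv(ts$n_series, path("analysis/truncations_nterm.csv"), row.names = FALSE)
    utils::write.csv(ts$c_series, path("analysis/truncations_cterm.csv"), row.names = FALSE)
    art$analysis <- list(freq = freq, deletion = dm,
                         hotspot = list(first = hs_first, last = hs_last),
                         cores = cores, truncations = ts)
    manifest <- manifest_add(manifest, "analyze",
                             list.files(path("analysis"), full.names = TRUE),
                             list(fdr = config$score$fdr))
  }

  utils::write.csv(manifest, path("manifest.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(config), path("config.yaml"))
  invisible(art)
}
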