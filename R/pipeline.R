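# End-to-end orchestration: simulate -> filter -> discover -> cluster ->
# validate -> motif-enrich, with a flat key=value config, per-stage seeds and
# a manifest that makes re-runs byte-comparable.

#' Build a pipeline configuration
#'
#' Defaults carry the analysis constants: FDR bound 0.10, weight-loss cut 5
#' percent, CRP cut 5 mg/l, threshold fraction 0.8 of the matrix scoring
#' range, 1500 bp promoter window.
#'
#' @param out_dir run directory (created if needed).
#' @param fdr_bound FDR bound for the intersected signature (default 0.10).
#' @param wl_cut weight-loss percentage for the WL/WS split (default 5).
#' @param si_cut CRP threshold in mg/l for systemic inflammation (default 5).
#' @param threshold_fraction motif hit threshold as a fraction of the scoring
#'   range (default 0.8).
#' @param promoter_window promoter length convention in bp (default 1500).
#' @param n_permutations SAM permutations (default 200).
#' @param seed master seed; per-stage seeds are derived as seed + stage index.
#' @param sim a [sim_config()] describing the synthetic study to generate.
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir, fdr_bound = 0.10, wl_cut = 5,
                            si_cut = 5, threshold_fraction = 0.8,
                            promoter_window = 1500, n_permutations = 200,
                            seed = 1L, sim = sim_config(seed = seed)) {
  stopifnot(fdr_bound >= 0, fdr_bound <= 1)
  structure(list(out_dir = out_dir, fdr_bound = fdr_bound, wl_cut = wl_cut,
                 si_cut = si_cut, threshold_fraction = threshold_fraction,
                 promoter_window = promoter_window,
                 n_permutations = n_permutations,
                 seed = as.integer(seed), sim = sim),
            class = "PipelineConfig")
}

#' Read a flat key=value pipeline config file
#'
#' Recognised keys are the [pipeline_config()] arguments plus `sim.`-prefixed
#' [sim_config()] fields (e.g. `sim.n_genes=2000`).
#'
#' @param path key=value text file.
#' @param out_dir run directory (overrides any `out_dir` key).
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  num <- suppressWarnings(as.numeric(vals))
  parsed <- ifelse(is.na(num), vals, num)
  args <- list()
  simargs <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    v <- if (is.na(num[i])) vals[i] else num[i]
    if (startsWith(k, "sim.")) simargs[[sub("^sim\\.", "", k)]] <- v
    else args[[k]] <- v
  }
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (is.null(args$out_dir)) stop("config must set out_dir")
  if (length(simargs)) {
    if (is.null(simargs$seed) && !is.null(args$seed))
      simargs$seed <- args$seed
    args$sim <- do.call(sim_config, simargs)
  }
  do.call(pipeline_config, args)
}

stage_log <- function(run_log, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  if (!is.null(run_log)) cat(line, "\n", file = run_log, append = TRUE)
  invisible(line)
}

# content checksum used in the manifest (no external digest dependency):
# a Mersenne-prime polynomial rolling hash over the serialized object,
# kept below 2^31 so double arithmetic stays exact
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% (2^31 - 1)
  sprintf("%08x", h)
}

#' Run the full synthetic-study analysis pipeline
#'
#' Stages, in order: simulate, filter, discover, cluster, validate, motifs.
#' Every intermediate table is written under `config$out_dir`; the manifest
#' records the config hash, the per-stage seeds and the row counts. Re-running
#' with the same config reproduces identical numeric outputs. Any stage
#' failure aborts with the stage name; partial outputs are retained.
#'
#' @param config a [pipeline_config()].
#' @param motifs named list of [weight_matrix()] objects for the motif stage
#'   (default: the bundled synthetic PFM panel).
#' @param stop_after last stage to execute (default "motifs", i.e. all).
#' @return invisibly, the manifest data.frame.
#' @export
run_pipeline <- function(config, motifs = NULL, stop_after = "motifs") {
  stopifnot(inherits(config, "PipelineConfig"))
  stages <- c("simulate", "filter", "discover", "cluster", "validate",
              "motifs")
  stop_after <- match.arg(stop_after, stages)
  last <- match(stop_after, stages)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  run_log <- file.path(config$out_dir, "run.log")
  cat("", file = run_log)
  manifest <- list()
  note <- function(stage, rows, seed = NA_integer_)
    manifest[[stage]] <<- data.frame(stage = stage, rows = rows, seed = seed)
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  finish <- function() {
    man <- do.call(rbind, manifest)
    man$config_hash <- config_hash(config[setdiff(names(config), "out_dir")])
    write_tsv_strict(man, file.path(config$out_dir, "manifest.tsv"))
    stage_log(run_log, "done", sprintf("%d stage(s) completed", nrow(man)))
    invisible(man)
  }
  if (is.null(motifs))
    motifs <- load_pfm_dir(system.file("extdata", "pfm",
                                       package = "cachexsig"),
                           threshold_fraction = config$threshold_fraction)

  # -- simulate
  stage <- "simulate"
  study <- tryCatch({
    study <- generate_expression_study(config$sim)
    write_expression_study(study,
                           file.path(config$out_dir, "expression.tsv"),
                           file.path(config$out_dir, "detection.tsv"),
                           file.path(config$out_dir, "clinical.tsv"))
    write_sim_config(config$sim, file.path(config$out_dir, "sim_config.txt"))
    stage_log(run_log, stage, sprintf("%d genes x %d samples",
                                      nrow(study$values), ncol(study$values)))
    note(stage, nrow(study$values), config$sim$seed)
    study
  }, error = function(e) fail(stage, e))
  if (last == 1) return(finish())

  # -- filter
  stage <- "filter"
  filtered <- tryCatch({
    f <- filter_all_absent(study)
    stage_log(run_log, stage,
              sprintf("%d of %d genes survive the all-absent filter",
                      nrow(f$values), nrow(study$values)))
    note(stage, nrow(f$values))
    f
  }, error = function(e) fail(stage, e))
  if (last == 2) return(finish())

  # -- discover
  stage <- "discover"
  disc <- tryCatch({
    sam <- sam_quantitative(filtered, n_permutations = config$n_permutations,
                            seed = config$seed + 1L)
    mod <- moderated_covariate_test(filtered)
    pr <- pearson_per_gene(filtered)
    sig <- intersect_signature(sam, mod, config$fdr_bound)
    stats_tab <- merge(merge(sam, mod[c("gene_id", "mod_t", "mod_p",
                                        "mod_fdr")], by = "gene_id"),
                       pr, by = "gene_id")
    write_tsv_strict(stats_tab, file.path(config$out_dir, "gene_stats.tsv"))
    write_tsv_strict(as.data.frame(sig),
                     file.path(config$out_dir, "signature.tsv"))
    stage_log(run_log, stage, sprintf("signature: %d genes (%d pos, %d neg)",
                                      nrow(sig),
                                      sum(sig$direction == "positive"),
                                      sum(sig$direction == "negative")))
    note(stage, nrow(sig), config$seed + 1L)
    list(sig = sig, stats = stats_tab)
  }, error = function(e) fail(stage, e))
  if (last == 3) return(finish())

  # -- cluster
  stage <- "cluster"
  tryCatch({
    cl <- cluster_subjects(filtered, disc$sig, method = "hierarchical",
                           k = 2, seed = config$seed + 2L)
    write_tsv_strict(data.frame(sample_id = names(cl$assignment),
                                cluster = cl$assignment),
                     file.path(config$out_dir, "clusters.tsv"))
    stage_log(run_log, stage,
              sprintf("WL/WS best-mapping accuracy %.3f", cl$accuracy))
    note(stage, length(cl$assignment), config$seed + 2L)
  }, error = function(e) fail(stage, e))
  if (last == 4) return(finish())

  # -- validate
  stage <- "validate"
  tryCatch({
    targets <- utils::head(disc$sig$gene_id, 9)
    ct <- generate_ct_table(config$sim, filtered, targets)
    write_tsv_strict(as.data.frame(ct), file.path(config$out_dir, "ct.tsv"))
    dct <- delta_ct(ct)
    wl <- filtered$clinical$weight_loss_pct
    qpcr <- do.call(rbind, lapply(targets, function(g) {
      d <- dct[dct$gene_id == g, ]
      d <- d[match(filtered$clinical$sample_id, d$sample_id), ]
      ft <- stats::cor.test(-d$delta_ct, wl)
      data.frame(gene_id = g, qpcr_r = unname(ft$estimate),
                 qpcr_p = ft$p.value)
    }))
    arr <- disc$stats[match(targets, disc$stats$gene_id),
                      c("gene_id", "pearson_r")]
    names(arr)[2] <- "array_r"
    conc <- concordance(merge(arr, qpcr, by = "gene_id"))
    write_tsv_strict(as.data.frame(conc),
                     file.path(config$out_dir, "concordance.tsv"))
    stage_log(run_log, stage, sprintf("%d of %d genes validated",
                                      attr(conc, "n_validated"),
                                      attr(conc, "n_tested")))
    note(stage, nrow(conc), config$sim$seed + 2L)
  }, error = function(e) fail(stage, e))
  if (last == 5) return(finish())

  # -- motifs
  stage <- "motifs"
  tryCatch({
    sets <- generate_promoter_sets(config$sim, motifs)
    enr <- motif_enrichment(sets$fg, sets$bg, motifs)
    write_tsv_strict(as.data.frame(enr),
                     file.path(config$out_dir, "motif_enrichment.tsv"))
    enrichment_heatmap(list(signature = enr),
                       file.path(config$out_dir, "motif_heatmap.tsv"))
    stage_log(run_log, stage, sprintf("%d motifs scanned", nrow(enr)))
    note(stage, nrow(enr), config$sim$seed + 1L)
  }, error = function(e) fail(stage, e))

  finish()
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `filter`, `discover`, `cluster`, `validate`,
#' `motifs` (each runs the pipeline up to and including that stage) and
#' `run-all`. Usage:
#' `cachexsig <subcommand> --out <dir> [--config <file>] [--seed <int>]
#' [--fdr-bound <frac>] [--permutations <int>] [--threshold-fraction <frac>]
#' [--log-level quiet|info]`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return exit status, invisibly.
#' @export
cachexsig_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("simulate", "filter", "discover", "cluster", "validate",
                   "motifs", "run-all")
  if (!length(args) || !(args[1] %in% subcommands)) {
    message("usage: cachexsig <", paste(subcommands, collapse = "|"),
            "> --out <dir> [options]")
    return(invisible(1L))
  }
  sub <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i[1] < length(args)) args[i[1] + 1] else default
  }
  out_dir <- opt("--out")
  if (is.null(out_dir)) {
    message("--out <dir> is required")
    return(invisible(1L))
  }
  quiet <- identical(opt("--log-level", "info"), "quiet")
  cfg_path <- opt("--config")
  seed <- as.integer(opt("--seed", "1"))
  config <- if (!is.null(cfg_path)) {
    read_pipeline_config(cfg_path, out_dir = out_dir)
  } else {
    pipeline_config(out_dir,
                    fdr_bound = as.numeric(opt("--fdr-bound", "0.10")),
                    threshold_fraction =
                      as.numeric(opt("--threshold-fraction", "0.8")),
                    n_permutations = as.integer(opt("--permutations", "200")),
                    seed = seed, sim = sim_config(seed = seed))
  }
  stop_after <- if (sub == "run-all") "motifs" else sub
  if (quiet) suppressMessages(run_pipeline(config, stop_after = stop_after))
  else run_pipeline(config, stop_after = stop_after)
  invisible(0L)
}
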