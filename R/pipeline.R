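#' Read and validate a pipeline configuration
#'
#' The whole pipeline is driven by one YAML file with three blocks:
#' `paths` (library, samples, fastq, outdir, optionally counts/results for
#' partial runs), `thresholds` (`fdr_max`, `fold_min`, `cpm_min`), `test`
#' (`prior`, `fdr_scope`) and `simulation` (the [sim_config()] fields plus
#' `seed` and the read-structure overrides). Omitted thresholds default to
#' the screen's constants: FDR 0.01, fold 1.5, CPM 0.5.
#'
#' @param path Path to a YAML config file.
#' @return A validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- path
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  cfg$paths <- cfg$paths %||% list()
  thr <- cfg$thresholds %||% list()
  thr$fdr_max <- thr$fdr_max %||% 0.01
  thr$fold_min <- thr$fold_min %||% 1.5
  thr$cpm_min <- thr$cpm_min %||% 0.5
  if (thr$fdr_max <= 0 || thr$fdr_max > 1) stop("fdr_max must be in (0, 1]")
  if (thr$fold_min <= 1) stop("fold_min must be > 1")
  if (thr$cpm_min < 0) stop("cpm_min must be non-negative")
  cfg$thresholds <- thr
  tst <- cfg$test %||% list()
  tst$prior <- tst$prior %||% 0.5
  tst$fdr_scope <- tst$fdr_scope %||% "per_pool"
  if (!tst$fdr_scope %in% c("per_pool", "global"))
    stop("test$fdr_scope must be 'per_pool' or 'global'")
  cfg$test <- tst
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(..., seed = NULL) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "),
          if (!is.null(seed)) paste0("(seed ", seed, ") "), ...)
}

manifest_add <- function(outdir, file, cfg_hash, seed) {
  line <- sprintf("%s\t%s\tpoolscreen %s\t%s\t%s",
                  basename(file), tools::md5sum(file)[[1]],
                  as.character(utils::packageVersion("poolscreen")),
                  cfg_hash, as.character(seed %||% "NA"))
  cat(line, "\n", sep = "",
      file = file.path(outdir, "MANIFEST.tsv"), append = TRUE)
}

manifest_check <- function(outdir, file) {
  mf <- file.path(outdir, "MANIFEST.tsv")
  if (!file.exists(mf) || !file.exists(file)) return(invisible(TRUE))
  lines <- utils::read.delim(mf, header = FALSE, stringsAsFactors = FALSE)
  rows <- lines[lines[[1]] == basename(file), , drop = FALSE]
  if (!nrow(rows)) return(invisible(TRUE))
  recorded <- rows[nrow(rows), 2L]
  if (!identical(recorded, tools::md5sum(file)[[1]]))
    stop("stale intermediate: ", basename(file),
         " does not match its manifest hash; rerun the producing stage")
  invisible(TRUE)
}

#' Run the screen pipeline
#'
#' Orchestrates simulate -> count -> test -> call (and optionally the
#' expression filter) from a single configuration. Each stage writes its
#' outputs under `paths$outdir` together with a manifest line (file, md5,
#' tool version, config hash, seed) and later stages verify the hashes of
#' the intermediates they consume, so partial runs never silently reuse
#' stale files. Reruns with the same config and seed are byte-identical.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]) or the
#'   path to one.
#' @param stages Character subset of `c("simulate", "count", "test", "call",
#'   "expression_filter")`, or `"all"` (simulate through call).
#' @return Invisibly, a list of the main in-memory results per stage.
#' @export
run_screen_pipeline <- function(config, stages = "all") {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- validate_pipeline_config(config)
  all_stages <- c("simulate", "count", "test", "call", "expression_filter")
  if (identical(stages, "all")) stages <- c("simulate", "count", "test", "call")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]   # enforce execution order

  paths <- config$paths
  outdir <- paths$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- if (!is.null(config$config_path))
    tools::md5sum(config$config_path)[[1]] else "in-memory"
  sim <- config$simulation %||% list()
  seed <- sim$seed
  if (length(intersect(stages, c("simulate"))) && is.null(seed))
    stop("simulation block must carry a seed")

  need_input <- function(p, what) {
    if (is.null(p) || !file.exists(p))
      stop("missing input for stage: ", what, " (", p %||% "unset", ")")
    p
  }
  out <- list()
  structure_args <- sim[intersect(names(sim),
    c("index_start", "index_len", "spacer", "read_len"))]
  rs <- do.call(read_structure, structure_args)

  if ("simulate" %in% stages) {
    library <- read_hairpin_library(need_input(paths$library, "simulate"))
    samples <- read_sample_sheet(need_input(paths$samples, "simulate"), library)
    cfg_fields <- intersect(names(sim), names(formals(sim_config)))
    scfg <- do.call(sim_config, sim[cfg_fields])
    pipeline_log("simulate: ", nrow(library), " hairpins, ",
                 nrow(samples), " samples", seed = seed)
    truth <- simulate_truth(library, samples, scfg, seed)
    cmat <- simulate_counts(truth, samples, seed + 1L)
    fq <- paths$fastq %||% file.path(outdir, "simulated.fastq.gz")
    emit_fastq(cmat, fq, rs, error_rate = scfg$error_rate, seed = seed + 2L)
    truth_path <- file.path(outdir, "truth.tsv")
    utils::write.table(truth$hairpins, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (f in c(fq, truth_path)) manifest_add(outdir, f, cfg_hash, seed)
    paths$fastq <- fq
    out$truth <- truth
    out$simulated_counts <- cmat
  }

  if ("count" %in% stages) {
    library <- read_hairpin_library(need_input(paths$library, "count"))
    samples <- read_sample_sheet(need_input(paths$samples, "count"), library)
    fq <- need_input(paths$fastq, "count")
    manifest_check(outdir, fq)
    pipeline_log("count: tallying ", basename(fq), seed = seed)
    counted <- count_reads(fq, library, samples, rs)
    counts_path <- paths$counts %||% file.path(outdir, "counts.tsv")
    write_counts(counted$counts, counts_path)
    manifest_add(outdir, counts_path, cfg_hash, seed)
    pipeline_log("count: ", counted$report$matched, "/",
                 counted$report$total_reads, " reads matched", seed = seed)
    paths$counts <- counts_path
    out$counts <- counted$counts
    out$counting_report <- counted$report
  }

  if ("test" %in% stages) {
    cmat <- out$counts
    if (is.null(cmat)) {
      library <- read_hairpin_library(need_input(paths$library, "test"))
      samples <- read_sample_sheet(need_input(paths$samples, "test"), library)
      cp <- need_input(paths$counts %||% file.path(outdir, "counts.tsv"),
                       "test")
      manifest_check(outdir, cp)
      cmat <- read_counts(cp, library, samples)
    }
    pipeline_log("test: exact NB test, FDR scope ", config$test$fdr_scope,
                 seed = seed)
    res <- screen_exact_test(cmat, fdr_scope = config$test$fdr_scope,
                             prior = config$test$prior)
    results_path <- paths$results %||% file.path(outdir, "results.tsv")
    utils::write.table(res, results_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest_add(outdir, results_path, cfg_hash, seed)
    paths$results <- results_path
    out$results <- res
  }

  if ("call" %in% stages) {
    res <- out$results
    if (is.null(res)) {
      rp <- need_input(paths$results %||% file.path(outdir, "results.tsv"),
                       "call")
      manifest_check(outdir, rp)
      res <- utils::read.delim(rp, stringsAsFactors = FALSE)
    }
    hits <- classify_hits(res, fdr_max = config$thresholds$fdr_max,
                          fold_min = config$thresholds$fold_min)
    calls_path <- file.path(outdir, "calls.tsv")
    utils::write.table(hits$calls, calls_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest_add(outdir, calls_path, cfg_hash, seed)
    pipeline_log("call: ", hits$summary$n_significant, " significant (",
                 hits$summary$n_enriched, " enriched, ",
                 hits$summary$n_depleted, " depleted, ",
                 hits$summary$n_unique_genes, " genes)", seed = seed)
    out$calls <- hits
  }

  if ("expression_filter" %in% stages) {
    ep <- need_input(paths$expression, "expression_filter")
    expr <- as.matrix(utils::read.delim(ep, row.names = 1L,
                                        check.names = FALSE))
    calls <- expressed_calls(expr, threshold = config$thresholds$cpm_min,
                             groups = config$expression$groups %||% NULL)
    hits <- out$calls
    hit_genes <- if (!is.null(hits)) {
      sig <- hits$calls$class != "not_significant"
      unique(hits$calls$gene[sig])
    } else config$expression$hit_genes
    xr <- cross_reference_hits(hit_genes, calls,
                               primary_pops = config$expression$primary_pops,
                               sphere_pop = config$expression$sphere_pop)
    pipeline_log("expression_filter: ", xr$primary, "/", xr$n_genes,
                 " hit genes expressed in primary populations", seed = seed)
    out$expression <- xr
  }
  invisible(out)
}
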