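# All simulator randomness flows through one seeded generator; the caller's
# RNG state is restored afterwards so simulation never perturbs a session.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(list = ".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  expr
}

BASES <- c("A", "C", "G", "T")

#' Simulation parameters for a synthetic pooled screen
#'
#' Bundles the knobs of the generative model used by [simulate_truth()] and
#' [simulate_counts()]. The defaults describe the screen this package models:
#' pools of ~90 hairpins sequenced to about a million reads per sample, a
#' tenth of hairpins carrying a real fitness effect of threefold enrichment
#' or depletion over the T2 to T14 culture window, negative binomial
#' overdispersion phi = 0.1, and (when enabled) a transduction bottleneck of
#' on average 77 sphere-forming founder cells per hairpin.
#'
#' @param hit_fraction Fraction of hairpins with a planted fold-change != 1,
#'   in `[0, 1]`.
#' @param fold_enriched,fold_depleted Fitness multipliers for planted hits;
#'   either a scalar or a length-2 range sampled log-uniformly.
#' @param phi Negative binomial dispersion (variance = mu + phi mu^2); 0 is
#'   Poisson.
#' @param mean_libsize Mean sequencing depth per sample (reads).
#' @param libsize_sdlog Log-normal spread of per-sample depths (0 = equal
#'   depths).
#' @param baseline_sdlog Log-normal spread of baseline hairpin abundances.
#' @param bottleneck_mean Mean of the Poisson founder-cell draw per hairpin,
#'   or `NULL` for no bottleneck.
#' @param error_rate Per-base substitution rate used by [emit_fastq()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(hit_fraction = 0.1, fold_enriched = 3,
                       fold_depleted = 1 / 3, phi = 0.1,
                       mean_libsize = 1e6, libsize_sdlog = 0.2,
                       baseline_sdlog = 0.5, bottleneck_mean = NULL,
                       error_rate = 0) {
  if (hit_fraction < 0 || hit_fraction > 1)
    stop("hit_fraction must be in [0, 1]")
  if (phi < 0) stop("dispersion phi must be non-negative")
  if (any(fold_enriched <= 0) || any(fold_depleted <= 0))
    stop("fold multipliers must be positive")
  if (mean_libsize < 0) stop("mean_libsize must be non-negative")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (!is.null(bottleneck_mean) && bottleneck_mean < 0)
    stop("bottleneck_mean must be non-negative")
  structure(list(hit_fraction = hit_fraction, fold_enriched = fold_enriched,
                 fold_depleted = fold_depleted, phi = phi,
                 mean_libsize = mean_libsize, libsize_sdlog = libsize_sdlog,
                 baseline_sdlog = baseline_sdlog,
                 bottleneck_mean = bottleneck_mean, error_rate = error_rate),
            class = "sim_config")
}

draw_fold <- function(spec, n) {
  if (length(spec) == 1L) rep(spec, n)
  else exp(stats::runif(n, log(min(spec)), log(max(spec))))
}

#' Draw the ground truth of a synthetic screen
#'
#' Generates, per pool, baseline hairpin proportions (log-normal, then
#' normalized), planted fitness fold-changes for a chosen fraction of
#' hairpins (half enriched, half depleted), optional Poisson founder-cell
#' counts modelling the transduction bottleneck, and per-sample library
#' sizes. The result is the complete generative state against which recovery
#' of the downstream analysis can be scored.
#'
#' @param library A validated hairpin library (see
#'   [validate_hairpin_library()]).
#' @param samples A validated sample sheet.
#' @param config A [sim_config()].
#' @param seed Integer seed; the same seed reproduces the truth exactly.
#' @return An object of class `screen_truth`: list with `hairpins` (library
#'   columns plus `baseline_prop`, `fold`, and `founders` when a bottleneck
#'   is simulated), `phi`, and `lib_sizes` (named by sample id).
#' @export
simulate_truth <- function(library, samples, config = sim_config(), seed = 1L) {
  library <- validate_hairpin_library(library)
  samples <- validate_sample_sheet(samples, library)
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(seed, {
    hp <- library
    hp$baseline_prop <- NA_real_
    hp$fold <- 1
    if (!is.null(config$bottleneck_mean)) hp$founders <- NA_integer_
    for (p in unique(hp$pool_id)) {
      rows <- which(hp$pool_id == p)
      n <- length(rows)
      w <- stats::rlnorm(n, meanlog = 0, sdlog = config$baseline_sdlog)
      if (!is.null(config$bottleneck_mean)) {
        founders <- stats::rpois(n, config$bottleneck_mean)
        hp$founders[rows] <- founders
        w <- w * founders          # hairpins missing the bottleneck drop out
      }
      if (sum(w) == 0) w <- rep(1, n)   # degenerate bottleneck: keep uniform
      hp$baseline_prop[rows] <- w / sum(w)
      n_hit <- round(config$hit_fraction * n)
      if (n_hit > 0) {
        hits <- sample(rows, n_hit)
        n_up <- ceiling(n_hit / 2)
        up <- hits[seq_len(n_up)]
        down <- setdiff(hits, up)
        hp$fold[up] <- draw_fold(config$fold_enriched, length(up))
        hp$fold[down] <- draw_fold(config$fold_depleted, length(down))
      }
    }
    lib_sizes <- if (config$mean_libsize == 0) rep(0, nrow(samples)) else
      round(stats::rlnorm(
        nrow(samples),
        meanlog = log(config$mean_libsize) - config$libsize_sdlog^2 / 2,
        sdlog = config$libsize_sdlog))
    names(lib_sizes) <- samples$sample_id
    structure(list(hairpins = hp, phi = config$phi, lib_sizes = lib_sizes),
              class = "screen_truth")
  })
}

#' @export
print.screen_truth <- function(x, ...) {
  cat(sprintf(
    "screen_truth: %d hairpins in %d pool(s); %d planted hit(s); phi = %g\n",
    nrow(x$hairpins), length(unique(x$hairpins$pool_id)),
    sum(x$hairpins$fold != 1), x$phi))
  invisible(x)
}

#' Simulate a hairpin count matrix from a ground truth
#'
#' T2 counts for hairpin h in sample s are negative binomial with mean
#' `lib_size_s * baseline_prop_h` and dispersion `phi` (Poisson when
#' `phi = 0`). For T14 samples the baseline proportions are multiplied by the
#' planted folds and renormalized within the pool before scaling by library
#' size — sequencing is compositional, so a fixed depth is shared out among
#' whatever survived selection. Hairpins outside a sample's pool get zero.
#'
#' @param truth A `screen_truth` from [simulate_truth()].
#' @param samples The sample sheet the truth was drawn for.
#' @param seed Integer seed.
#' @return A [count_matrix()] carrying the library and sample metadata.
#' @export
simulate_counts <- function(truth, samples, seed = 1L) {
  stopifnot(inherits(truth, "screen_truth"))
  samples <- validate_sample_sheet(samples)
  if (!all(samples$sample_id %in% names(truth$lib_sizes)))
    stop("samples and truth disagree on sample ids")
  hp <- truth$hairpins
  with_seed(seed, {
    mat <- matrix(0L, nrow = nrow(hp), ncol = nrow(samples))
    for (j in seq_len(nrow(samples))) {
      pool <- samples$pool_id[j]
      rows <- which(hp$pool_id == pool)
      if (!length(rows)) stop("sample pool ", pool, " absent from truth")
      props <- hp$baseline_prop[rows]
      if (samples$timepoint[j] == "T14") {
        props <- props * hp$fold[rows]
        props <- props / sum(props)
      }
      mu <- truth$lib_sizes[[samples$sample_id[j]]] * props
      y <- if (truth$phi == 0) stats::rpois(length(mu), mu)
           else stats::rnbinom(length(mu), mu = mu, size = 1 / truth$phi)
      mat[rows, j] <- as.integer(y)
    }
    count_matrix(mat, hp, samples)
  })
}

#' Emit synthetic FASTQ reads for a count matrix
#'
#' Writes exactly `count[h, s]` reads per cell, each laid out per the read
#' structure as index + spacer + hairpin antisense + random filler up to the
#' read length, with optional uniform per-base substitution errors. Qualities
#' are a constant 'I' (the counting step is quality-blind). Read ids are
#' running numbers and encode nothing about the originating cell.
#'
#' @param cm A [count_matrix()] whose `hairpins` carry `antisense` and whose
#'   `samples` carry `index_seq`.
#' @param path Output FASTQ path; a `.gz` suffix writes gzip.
#' @param structure A [read_structure()].
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed (filler bases and errors).
#' @return Invisibly, a list with `path` and `n_reads`.
#' @export
emit_fastq <- function(cm, path, structure = read_structure(),
                       error_rate = 0, seed = 1L) {
  stopifnot(inherits(cm, "count_matrix"), inherits(structure, "read_structure"))
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (is.null(cm$hairpins$antisense) || is.null(cm$samples$index_seq))
    stop("count matrix metadata must carry antisense and index_seq")
  check_structure_fits(structure, cm$hairpins)
  if (any(nchar(cm$samples$index_seq) != structure$index_len))
    stop("index_seq length does not match the read structure")

  cells <- which(cm$counts > 0L, arr.ind = TRUE)
  reps <- cm$counts[cells]
  h <- rep(cells[, 1L], reps)
  s <- rep(cells[, 2L], reps)
  n <- length(h)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (n == 0L) {
    writeLines(character(0), con)
    return(invisible(list(path = path, n_reads = 0L)))
  }

  with_seed(seed, {
    lead <- random_strings(n, structure$index_start)
    core <- paste0(lead, cm$samples$index_seq[s], structure$spacer,
                   cm$hairpins$antisense[h])
    tail_len <- structure$read_len - nchar(core)
    tails <- random_strings(n, max(tail_len))
    reads <- paste0(core, substr(tails, 1L, tail_len))
    if (error_rate > 0) reads <- mutate_reads(reads, error_rate)
    qual <- strrep("I", structure$read_len)
    rec <- rbind(sprintf("@read_%08d", seq_len(n)), reads, "+", qual)
    writeLines(as.vector(rec), con, sep = "\n")
  })
  invisible(list(path = path, n_reads = n))
}

# n random A/C/G/T strings of identical length len (len 0 -> "")
random_strings <- function(n, len) {
  if (len <= 0L) return(rep("", n))
  m <- matrix(sample(BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# uniform per-base substitution to one of the three other bases
mutate_reads <- function(reads, rate) {
  L <- nchar(reads[1L])
  n_err <- stats::rbinom(length(reads), L, rate)
  for (i in which(n_err > 0L)) {
    pos <- sample.int(L, n_err[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    old <- match(chars[pos], BASES)
    chars[pos] <- BASES[((old - 1L + sample.int(3L, n_err[i], replace = TRUE)) %% 4L) + 1L]
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}
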