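#' Classify screen results into enriched / depleted / unchanged hairpins
#'
#' Applies the screen's reporting rule: a hairpin is significant when its
#' false discovery rate is at or below `fdr_max` (inclusive); significant
#' hairpins are `enriched` when the linear fold-change `2^logFC` is strictly
#' greater than `fold_min`, `depleted` when strictly less than `1/fold_min`,
#' and `significant_only` otherwise. Everything else is `not_significant`.
#' Unique genes among significant hairpins are counted case-insensitively
#' (screen tables mix symbol capitalisations).
#'
#' @param results A data.frame with columns `logFC` and `FDR` (case-
#'   insensitive; `fdr` accepted), plus `gene` and a hairpin identifier
#'   (`hairpin_id` or `clone_id`) when available.
#' @param fdr_max Significance cutoff on the FDR, in (0, 1]; inclusive.
#' @param fold_min Linear fold-change cutoff, > 1; strict.
#' @return A list with `calls` (per-hairpin data.frame: ids, `class`,
#'   `fold_linear`) and `summary` (`n_significant`, `n_enriched`,
#'   `n_depleted`, `n_unique_genes`).
#' @examples
#' tab <- table1_hits()
#' classify_hits(tab)$summary
#' @export
classify_hits <- function(results, fdr_max = 0.01, fold_min = 1.5) {
  if (fold_min <= 1) stop("fold_min must be > 1")
  if (fdr_max <= 0 || fdr_max > 1) stop("fdr_max must be in (0, 1]")
  results <- as.data.frame(results)
  fdr_col <- names(results)[tolower(names(results)) == "fdr"][1L]
  if (is.na(fdr_col) || is.null(results$logFC))
    stop("results must carry logFC and FDR columns")
  id_col <- intersect(c("hairpin_id", "clone_id"), names(results))[1L]
  n <- nrow(results)
  if (n == 0) {
    return(list(
      calls = data.frame(hairpin_id = character(0), gene = character(0),
                         class = character(0), fold_linear = numeric(0)),
      summary = list(n_significant = 0L, n_enriched = 0L, n_depleted = 0L,
                     n_unique_genes = 0L)))
  }
  if (any(!is.finite(results$logFC)) || any(!is.finite(results[[fdr_col]])))
    stop("logFC and FDR must be finite")
  fold <- 2^results$logFC
  sig <- results[[fdr_col]] <= fdr_max
  class <- rep("not_significant", n)
  class[sig] <- "significant_only"
  class[sig & fold > fold_min] <- "enriched"
  class[sig & fold < 1 / fold_min] <- "depleted"
  calls <- data.frame(
    hairpin_id = if (!is.na(id_col)) as.character(results[[id_col]])
                 else as.character(seq_len(n)),
    gene = if (!is.null(results$gene)) as.character(results$gene)
           else NA_character_,
    class = factor(class, levels = c("enriched", "depleted",
                                     "significant_only", "not_significant")),
    fold_linear = fold, stringsAsFactors = FALSE)
  list(calls = calls,
       summary = list(
         n_significant = sum(sig),
         n_enriched = sum(class == "enriched"),
         n_depleted = sum(class == "depleted"),
         n_unique_genes = length(unique(toupper(calls$gene[sig])))))
}

#' Expected sphere-forming transduced cells per hairpin
#'
#' The screen's design arithmetic: of `n_cells` plated cells a fraction
#' `sphere_rate` forms spheres and a fraction `infection_rate` carries a
#' hairpin, and the hairpins are shared equally by a pool of `pool_size`
#' members, so each hairpin is expected to be interrogated in
#' `n_cells * sphere_rate * infection_rate / pool_size` sphere-forming cells.
#'
#' @param n_cells Number of cells plated.
#' @param sphere_rate Sphere-forming fraction, in `[0, 1]`.
#' @param infection_rate Transduction fraction, in `[0, 1]`.
#' @param pool_size Hairpins per pool (>= 1).
#' @return The expected representation (cells per hairpin).
#' @examples
#' expected_representation(2e6, 0.0085, 0.40, 88)  # 77.27
#' @export
expected_representation <- function(n_cells, sphere_rate, infection_rate,
                                    pool_size) {
  if (sphere_rate < 0 || sphere_rate > 1 || infection_rate < 0 ||
      infection_rate > 1)
    stop("rates must be in [0, 1]")
  if (pool_size < 1) stop("pool_size must be >= 1")
  if (n_cells < 0) stop("n_cells must be non-negative")
  n_cells * sphere_rate * infection_rate / pool_size
}

#' MDS quality control of screen samples
#'
#' Embeds samples in two dimensions from leading log-fold-change distances:
#' counts are offset by 0.5, converted to counts per million and logged; the
#' distance between two samples is the root mean square of the `top_k`
#' largest squared per-hairpin log2 differences for that pair; classical
#' (Torgerson) scaling then gives 2-D coordinates. Samples whose coordinate
#' on either axis deviates from the median by more than 5 median absolute
#' deviations are flagged — advisory only, the analyst decides on removal.
#'
#' @param counts A [count_matrix()] or plain matrix with >= 3 columns.
#' @param top_k Number of leading hairpins per pair (default 500, capped at
#'   the number of hairpins).
#' @param mad_mult Outlier threshold in MADs (default 5).
#' @return A list with `points` (samples x 2), `dist` (pairwise distance
#'   matrix), `outliers` (character vector of flagged sample ids).
#' @export
mds_qc <- function(counts, top_k = 500L, mad_mult = 5) {
  mat <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  n_s <- ncol(mat)
  if (n_s < 3L) stop("MDS QC needs at least 3 samples")
  aug <- mat + 0.5
  logcpm <- log2(sweep(aug, 2L, colSums(aug), `/`) * 1e6)
  k <- min(top_k, nrow(mat))
  d <- matrix(0, n_s, n_s, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n_s - 1L)) for (j in (i + 1L):n_s) {
    sq <- (logcpm[, i] - logcpm[, j])^2
    d[i, j] <- d[j, i] <- sqrt(mean(sort(sq, decreasing = TRUE)[seq_len(k)]))
  }
  pts <- stats::cmdscale(stats::as.dist(d), k = 2L)
  colnames(pts) <- c("dim1", "dim2")
  flagged <- rep(FALSE, n_s)
  for (ax in 1:2) {
    med <- stats::median(pts[, ax])
    s <- stats::mad(pts[, ax])
    if (s == 0) s <- .Machine$double.eps
    flagged <- flagged | abs(pts[, ax] - med) > mad_mult * s
  }
  ids <- if (!is.null(colnames(mat))) colnames(mat) else as.character(seq_len(n_s))
  list(points = pts, dist = d, outliers = ids[flagged])
}

#' Single-hit limiting-dilution frequency estimate
#'
#' Estimates the frequency of repopulating cells from a transplantation
#' table under the single-hit Poisson model: a graft of `dose` cells grows
#' out with probability `1 - exp(-f * dose)`. The frequency `f` maximizes
#' the binomial likelihood over doses; the 95% confidence interval inverts
#' the likelihood-ratio test at the chi-squared 1-df 0.95 quantile. The
#' estimate is reported in the conventional "1 cell in N" form (N = 1/f).
#'
#' @param assay A data.frame with columns `dose` (cells transplanted, > 0),
#'   `n` (number of transplants) and `positive` (outgrowths, `0 <= positive
#'   <= n`).
#' @return A list with `f` (per-cell frequency), `frequency` (N = 1/f, the
#'   "1 in N" number), `ci_f` (95% CI on f), `ci_frequency` (on N, lower =
#'   most frequent), and `loglik`.
#' @examples
#' limiting_dilution_frequency(data.frame(dose = 100, n = 10, positive = 5))
#' @export
limiting_dilution_frequency <- function(assay) {
  assay <- as.data.frame(assay)
  if (!all(c("dose", "n", "positive") %in% names(assay)))
    stop("assay needs columns dose, n, positive")
  d <- as.numeric(assay$dose)
  n <- as.numeric(assay$n)
  pos <- as.numeric(assay$positive)
  if (any(d <= 0) || any(n < 1) || any(pos < 0) || any(pos > n))
    stop("require dose > 0 and 0 <= positive <= n")
  ll <- function(f) {
    p <- -expm1(-f * d)            # 1 - exp(-f d), accurately for small f d
    sum(pos * log(p) + (n - pos) * (-f * d))
  }
  crit <- stats::qchisq(0.95, df = 1) / 2
  if (all(pos == n))
    stop("every transplant positive at every dose: frequency unbounded above")
  if (all(pos == 0)) {
    # boundary: no outgrowths at all; MLE f = 0, upper limit from the LRT
    f_up <- crit / sum(n * d)
    return(list(f = 0, frequency = Inf, ci_f = c(0, f_up),
                ci_frequency = c(1 / f_up, Inf), loglik = 0))
  }
  t_lo <- log(1e-9 / max(d))
  t_hi <- log(50 / min(d))
  opt <- stats::optimize(function(t) -ll(exp(t)), c(t_lo, t_hi), tol = 1e-10)
  f_hat <- exp(opt$minimum)
  # polish to full precision on the score (the optimizer's golden-section
  # step leaves ~1e-7 relative slack)
  score <- function(f) sum(pos * d * exp(-f * d) / -expm1(-f * d) -
                             (n - pos) * d)
  br <- c(f_hat / 2, f_hat * 2)
  if (score(br[1]) > 0 && score(br[2]) < 0) {
    f_hat <- stats::uniroot(score, br, tol = f_hat * 1e-12)$root
  }
  ll_hat <- ll(f_hat)
  target <- function(t) ll(exp(t)) - (ll_hat - crit)
  lo <- if (target(t_lo) > 0) 0 else
    exp(stats::uniroot(target, c(t_lo, log(f_hat)), tol = 1e-12)$root)
  t_top <- log(1e4 / min(d))
  hi <- if (target(t_top) > 0) Inf else
    exp(stats::uniroot(target, c(log(f_hat), t_top), tol = 1e-12)$root)
  list(f = f_hat, frequency = 1 / f_hat, ci_f = c(lo, hi),
       ci_frequency = c(1 / hi, if (lo > 0) 1 / lo else Inf),
       loglik = ll_hat)
}

#' The packaged screen hit table
#'
#' The 80 shRNA clones reported as significant (FDR <= 0.01) in the original
#' mammosphere screen, shipped verbatim as an input fixture: vendor clone id,
#' target gene symbol, log2 fold-change (T14 vs T2), average log2 CPM,
#' p-value and FDR.
#'
#' @return A data.frame with 80 rows and columns `clone_id`, `gene`,
#'   `logFC`, `logCPM`, `PValue`, `FDR`.
#' @export
table1_hits <- function() {
  path <- system.file("extdata", "table1_screen_hits.tsv",
                      package = "poolscreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
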