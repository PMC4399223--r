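#' Counts per million
#'
#' Library-size normalization of a gene-count matrix. In linear mode each
#' column is scaled to sum to one million. In log mode a prior count is
#' added on the library-size-adjusted scale before taking log2: with
#' per-sample prior `pc_s = prior * libsize_s / mean(libsize)`, the value is
#' `log2((count + pc_s) / (libsize_s + 2 pc_s) * 1e6)`, which keeps zeros
#' finite and comparable across depths.
#'
#' @param counts Non-negative matrix, genes x samples.
#' @param log Return log2 CPM?
#' @param prior Prior count for log mode (default 0.25 per observation).
#' @param lib_sizes Optional library sizes (default: column sums, which must
#'   all be positive).
#' @return A matrix of the same shape.
#' @export
cpm <- function(counts, log = FALSE, prior = 0.25, lib_sizes = NULL) {
  mat <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(mat)
  if (any(lib_sizes <= 0))
    stop("zero column sum: CPM undefined for sample(s) ",
         paste(which(lib_sizes <= 0), collapse = ", "))
  if (!log) return(sweep(mat, 2L, lib_sizes, `/`) * 1e6)
  pc <- prior * lib_sizes / mean(lib_sizes)
  log2(sweep(sweep(mat, 2L, pc, `+`), 2L, lib_sizes + 2 * pc, `/`) * 1e6)
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization. For each sample a
#' weighted mean of gene-wise log2 ratios (M) against a reference column is
#' taken after discarding the most extreme 30% of M values and 5% of average
#' log intensities (A), weighting each gene by the inverse of its asymptotic
#' binomial variance. The reference is the column whose upper-quartile
#' (depth-normalized) is closest to the mean upper-quartile, unless given.
#' Factors are rescaled to multiply to 1.
#'
#' @param counts Non-negative matrix with >= 2 columns; no column may be all
#'   zero.
#' @param ref Reference column index, or `NULL` for automatic choice.
#' @param logratio_trim,sum_trim Trim fractions for M and A (defaults 0.3 and
#'   0.05).
#' @return Numeric vector of per-sample factors (product 1), named by column.
#' @export
tmm_factors <- function(counts, ref = NULL, logratio_trim = 0.3,
                        sum_trim = 0.05) {
  mat <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (ncol(mat) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(mat)
  if (any(lib == 0)) stop("column(s) with all zeros: ",
                          paste(which(lib == 0), collapse = ", "))
  if (is.null(ref)) {
    uq <- apply(sweep(mat, 2L, lib, `/`), 2L, stats::quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  }
  f <- vapply(seq_len(ncol(mat)), function(s)
    tmm_pair(mat[, s], mat[, ref], lib[s], lib[ref],
             logratio_trim, sum_trim), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(mat)
  f
}

# one-sample-versus-reference trimmed weighted mean of M values
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  f <- 2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  if (!is.finite(f)) 1 else f
}

#' Expressed-gene calls from average CPM
#'
#' A gene is called expressed in a population when its average linear CPM
#' over that population's replicates is strictly greater than the threshold
#' (0.5 by default).
#'
#' @param expr Linear-CPM matrix, genes x samples.
#' @param threshold CPM cutoff (strict `>`); must be non-negative.
#' @param groups Optional population label per column; columns sharing a
#'   label are averaged before thresholding. `NULL` treats each column as
#'   its own population.
#' @return Logical matrix, genes x populations.
#' @export
expressed_calls <- function(expr, threshold = 0.5, groups = NULL) {
  if (threshold < 0) stop("threshold must be non-negative")
  mat <- as.matrix(expr)
  if (!is.null(groups)) {
    if (length(groups) != ncol(mat)) stop("groups must label every column")
    pops <- unique(as.character(groups))
    avg <- do.call(cbind, lapply(pops, function(p)
      rowMeans(mat[, groups == p, drop = FALSE])))
    dimnames(avg) <- list(rownames(mat), pops)
    mat <- avg
  }
  mat > threshold
}

#' Cross-reference screen hit genes against expression calls
#'
#' Partitions the genes targeted by screen hits by where they are expressed:
#' in at least one primary epithelial population (and, of those, also in the
#' sphere-cultured population), only in the sphere population, or nowhere.
#' Genes expressed nowhere point to likely shRNA off-target effects. Gene
#' matching is case-insensitive. Hit genes absent from the calls table raise
#' an error naming them — they are never dropped silently.
#'
#' @param hit_genes Character vector of gene symbols (duplicates collapse).
#' @param calls Logical gene x population matrix from [expressed_calls()].
#' @param primary_pops Population labels counted as primary.
#' @param sphere_pop The sphere-culture population label.
#' @return A list of counts: `n_genes`, `primary` (>= 1 primary population;
#'   includes the next), `primary_and_sphere`, `sphere_only`, `nowhere`,
#'   plus `percent` (of `n_genes`) for each category.
#'   `primary + sphere_only + nowhere = n_genes`.
#' @export
cross_reference_hits <- function(hit_genes, calls, primary_pops, sphere_pop) {
  pops <- colnames(calls)
  unknown <- setdiff(c(primary_pops, sphere_pop), pops)
  if (length(unknown))
    stop("unknown population label(s): ", paste(unknown, collapse = ", "))
  genes <- unique(toupper(hit_genes))
  m <- match(genes, toupper(rownames(calls)))
  if (anyNA(m))
    stop("hit gene(s) absent from the expression table: ",
         paste(genes[is.na(m)], collapse = ", "))
  prim <- rowSums(calls[m, primary_pops, drop = FALSE]) > 0
  sph <- calls[m, sphere_pop]
  n <- length(genes)
  res <- list(n_genes = n,
              primary = sum(prim),
              primary_and_sphere = sum(prim & sph),
              sphere_only = sum(!prim & sph),
              nowhere = sum(!prim & !sph))
  res$percent <- vapply(res[c("primary", "primary_and_sphere",
                              "sphere_only", "nowhere")],
                        function(x) 100 * x / n, numeric(1))
  res
}

#' Collapse probe-level expression to gene level
#'
#' Cross-platform comparisons need one row per gene: for each gene the probe
#' with the highest mean expression across samples is taken as
#' representative; exact ties break to the lexicographically smallest probe
#' id.
#'
#' @param probes Numeric matrix, probes x samples, with probe ids as
#'   rownames.
#' @param probe2gene Character vector mapping each probe (names) to one gene.
#' @return Gene-level matrix (genes x samples) with attribute
#'   `"representative_probe"` naming the chosen probe per gene.
#' @export
collapse_probes <- function(probes, probe2gene) {
  mat <- as.matrix(probes)
  if (is.null(rownames(mat))) stop("probe matrix needs probe ids as rownames")
  gene <- unname(probe2gene[rownames(mat)])
  if (anyNA(gene))
    stop("probe(s) without gene mapping: ",
         paste(rownames(mat)[is.na(gene)], collapse = ", "))
  means <- rowMeans(mat)
  ord <- order(gene, -means, rownames(mat), method = "radix")
  first <- ord[!duplicated(gene[ord])]
  out <- mat[first, , drop = FALSE]
  reps <- rownames(mat)[first]
  rownames(out) <- gene[first]
  attr(out, "representative_probe") <- stats::setNames(reps, gene[first])
  out
}
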