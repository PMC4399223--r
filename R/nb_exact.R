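#' Equalize library sizes by linear scaling
#'
#' The conditional tests downstream assume every sample was sequenced to the
#' same depth. This step scales each column of the count matrix to a common
#' library size — the geometric mean of the observed column sums — producing
#' a matrix of non-negative real "pseudo-counts" whose columns all sum to the
#' common size. Columns that are entirely zero are left at zero and excluded
#' from the geometric mean.
#'
#' @param counts A [count_matrix()] or a plain non-negative matrix.
#' @return A list with `pseudo` (real matrix, same dimnames) and
#'   `common_libsize`.
#' @export
equalize_libsizes <- function(counts) {
  mat <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  cs <- colSums(mat)
  if (all(cs == 0)) stop("all-zero count matrix: library sizes undefined")
  common <- exp(mean(log(cs[cs > 0])))
  scale <- ifelse(cs > 0, common / cs, 0)
  pseudo <- sweep(mat, 2L, scale, `*`)
  list(pseudo = pseudo, common_libsize = common)
}

# Conditional log-likelihood of one hairpin's within-group counts given their
# group sum, under iid NB(mu, phi) within the group: y | sum ~ negative
# hypergeometric (Dirichlet-multinomial with equal shapes r = 1/phi), which
# is free of mu. Groups of size 1 carry no information and contribute 0.
cond_loglik_group <- function(y, r) {
  n <- length(y)
  if (n < 2L) return(0)
  z <- sum(y)
  sum(lgamma(y + r)) - n * lgamma(r) - sum(lgamma(y + 1)) -
    (lgamma(z + n * r) - lgamma(n * r) - lgamma(z + 1))
}

#' Estimate a common NB dispersion by conditional maximum likelihood
#'
#' One dispersion phi is assumed to apply to every hairpin. For each hairpin
#' the probability of its within-group counts conditional on the group sum —
#' which does not depend on the unknown mean — is summed in the log over all
#' hairpins, and phi maximizes that conditional log-likelihood over
#' `[1e-8, 20]`. Pseudo-counts (see [equalize_libsizes()]) are rounded to
#' integers before evaluation.
#'
#' @param pseudo Depth-equalized matrix (hairpins x samples).
#' @param groups Group label per column (e.g. `"T2"`/`"T14"`); at least one
#'   group needs two or more samples, otherwise the dispersion is not
#'   estimable.
#' @param interval Search interval for phi.
#' @param tol Optimizer tolerance.
#' @return A list of class `dispersion_estimate`: `phi`, `loglik_at_phi`,
#'   `n_hairpins_used` (hairpins with any nonzero count).
#' @export
common_dispersion <- function(pseudo, groups, interval = c(1e-8, 20),
                              tol = 1e-8) {
  pseudo <- as.matrix(pseudo)
  groups <- as.character(groups)
  if (length(groups) != ncol(pseudo))
    stop("groups must label every column")
  sizes <- table(groups)
  if (!any(sizes >= 2L))
    stop("dispersion not estimable: no group with >= 2 samples")
  y <- round(pseudo)
  by_group <- lapply(split(seq_along(groups), groups), function(j)
    y[, j, drop = FALSE])
  # vectorized sum over hairpins of cond_loglik_group()
  negll <- function(phi) {
    r <- 1 / phi
    total <- 0
    for (g in by_group) {
      ng <- ncol(g)
      if (ng < 2L) next
      z <- rowSums(g)
      total <- total + sum(lgamma(g + r)) - length(g) * lgamma(r) -
        sum(lgamma(g + 1)) -
        sum(lgamma(z + ng * r)) + nrow(g) * lgamma(ng * r) + sum(lgamma(z + 1))
    }
    -total
  }
  opt <- stats::optimize(negll, interval = interval, tol = tol)
  structure(list(phi = opt$minimum, loglik_at_phi = -opt$objective,
                 n_hairpins_used = sum(rowSums(y) > 0)),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf("common dispersion phi = %.6g (BCV %.3f), %d hairpins used\n",
              x$phi, sqrt(x$phi), x$n_hairpins_used))
  invisible(x)
}

# Log-pmf of the null conditional distribution of the T2 aggregate A given
# S = A + B, for group sums A ~ NB(n1 mu, phi/n1), B ~ NB(n2 mu, phi/n2):
# with sizes r1 = n1/phi, r2 = n2/phi the mean parameter cancels and
# P(A = a | S) is negative hypergeometric; phi = 0 is Binomial(S, n1/(n1+n2)).
cond_null_logpmf <- function(S, n1, n2, phi) {
  a <- 0:S
  if (phi == 0) return(stats::dbinom(a, S, n1 / (n1 + n2), log = TRUE))
  r1 <- n1 / phi
  r2 <- n2 / phi
  lp <- lgamma(a + r1) - lgamma(a + 1) - lgamma(r1) +
    lgamma(S - a + r2) - lgamma(S - a + 1) - lgamma(r2) -
    (lgamma(S + r1 + r2) - lgamma(S + 1) - lgamma(r1 + r2))
  lp - log(sum(exp(lp - max(lp)))) - max(lp)  # renormalize in log space
}

#' Exact two-group test for negative binomial counts
#'
#' For each hairpin the depth-equalized counts are aggregated to group sums
#' A (first group, n1 samples) and B (second group, n2 samples), rounded to
#' integers. Under the null of no abundance change, the conditional
#' distribution of A given S = A + B is free of the unknown mean; the
#' two-sided p-value sums the probability of every split of S no more likely
#' than the observed one (minimum-likelihood convention, ties included).
#' With phi = 0 the conditional law is Binomial(S, n1/(n1+n2)). Unequal
#' replicate numbers are handled by the group-level NB parameters
#' (mean n_g mu, dispersion phi/n_g).
#'
#' @param pseudo Depth-equalized matrix (see [equalize_libsizes()]).
#' @param groups Length-`ncol` labels with exactly two distinct values; the
#'   *second* level (reference ordering: `"T2"` before `"T14"` when both
#'   present, otherwise sorted unique order) is the numerator of the
#'   fold-change. Fold-changes are reported as second group over first.
#' @param phi Common dispersion (>= 0).
#' @param prior Prior count c added to each group mean in the fold-change,
#'   `logFC = log2((B/n2 + c) / (A/n1 + c))`; keeps logFC finite at zero.
#' @param lib_size Common library size for logCPM (defaults to the mean
#'   column sum of `pseudo`); `logCPM = log2(1e6 (S + 2c) / (lib_size (n1+n2)))`.
#' @param max_total Largest group total S enumerated directly (log-space over
#'   `0..S`); larger totals error with a request to downsample.
#' @return A data.frame with one row per hairpin: `logFC`, `logCPM`,
#'   `PValue`. Hairpins with S = 0 get p = 1 and logFC = 0 by convention.
#' @export
exact_test <- function(pseudo, groups, phi, prior = 0.5, lib_size = NULL,
                       max_total = 1e6) {
  pseudo <- as.matrix(pseudo)
  groups <- as.character(groups)
  if (phi < 0) stop("dispersion phi must be non-negative")
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required")
  if (all(c("T2", "T14") %in% lev)) lev <- c("T2", "T14") else lev <- sort(lev)
  g1 <- groups == lev[1L]
  g2 <- groups == lev[2L]
  n1 <- sum(g1)
  n2 <- sum(g2)
  if (is.null(lib_size)) lib_size <- mean(colSums(pseudo))

  A <- round(rowSums(pseudo[, g1, drop = FALSE]))
  B <- round(rowSums(pseudo[, g2, drop = FALSE]))
  S <- A + B
  if (any(S > max_total))
    stop("group total ", max(S), " exceeds the enumeration cap (",
         format(max_total, scientific = FALSE),
         "); downsample the counts before testing")

  pval <- rep(1, length(S))
  # p-values share the enumeration across hairpins with equal S
  for (Sv in unique(S[S > 0])) {
    lp <- cond_null_logpmf(Sv, n1, n2, phi)
    pr <- exp(lp)
    rows <- which(S == Sv)
    obs <- pr[A[rows] + 1L]
    pval[rows] <- vapply(obs, function(po)
      min(1, sum(pr[pr <= po * (1 + 1e-10)])), numeric(1))
  }
  logFC <- log2((B / n2 + prior) / (A / n1 + prior))
  logFC[S == 0] <- 0
  logCPM <- log2((S + 2 * prior) / (lib_size * (n1 + n2)) * 1e6)
  data.frame(logFC = logFC, logCPM = logCPM, PValue = pval,
             row.names = rownames(pseudo))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment of a vector of p-values; the output order matches the
#' input order, every adjusted value is at least its p-value and at most 1,
#' and adjustment preserves the ordering of the inputs.
#'
#' @param pvalues Numeric vector with all values in (0, 1].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the exact-test screen analysis per pool
#'
#' The screen contrasts T14 against T2 within each hairpin pool: for every
#' pool the relevant samples are depth-equalized, a common dispersion is
#' estimated by conditional maximum likelihood, the exact NB test is applied
#' hairpin-by-hairpin, and false discovery rates are computed — within each
#' pool by default (each pool is its own experiment), or globally across all
#' hairpins via `fdr_scope = "global"`.
#'
#' @param cm A [count_matrix()] whose samples carry `pool_id` and `timepoint`.
#' @param fdr_scope `"per_pool"` (default) or `"global"`.
#' @param prior Prior count for fold-changes (see [exact_test()]).
#' @param phi Optional fixed dispersion; when `NULL` (default) it is
#'   estimated per pool.
#' @return A data.frame (one row per hairpin): `hairpin_id`, `gene`,
#'   `pool_id`, `logFC`, `logCPM`, `PValue`, `FDR`; the per-pool dispersion
#'   estimates are attached as attribute `"dispersion"`.
#' @export
screen_exact_test <- function(cm, fdr_scope = c("per_pool", "global"),
                              prior = 0.5, phi = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  fdr_scope <- match.arg(fdr_scope)
  if (is.null(cm$samples$timepoint) || is.null(cm$samples$pool_id))
    stop("sample metadata must carry timepoint and pool_id")
  out <- NULL
  disp <- list()
  for (p in unique(cm$hairpins$pool_id)) {
    rows <- cm$hairpins$pool_id == p
    cols <- cm$samples$pool_id == p
    if (!any(cols)) next
    sub <- cm$counts[rows, cols, drop = FALSE]
    groups <- cm$samples$timepoint[cols]
    eq <- equalize_libsizes(sub)
    phi_p <- if (is.null(phi))
      common_dispersion(eq$pseudo, groups)$phi else phi
    res <- exact_test(eq$pseudo, groups, phi_p, prior = prior,
                      lib_size = eq$common_libsize)
    disp[[p]] <- phi_p
    res <- cbind(data.frame(hairpin_id = cm$hairpins$hairpin_id[rows],
                            gene = cm$hairpins$gene[rows],
                            pool_id = p, stringsAsFactors = FALSE),
                 res)
    res$FDR <- if (fdr_scope == "per_pool") bh_fdr(res$PValue) else NA_real_
    out <- rbind(out, res)
  }
  if (is.null(out)) stop("no sample matches any library pool")
  if (fdr_scope == "global") out$FDR <- bh_fdr(out$PValue)
  rownames(out) <- NULL
  attr(out, "dispersion") <- disp
  out
}
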