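# Deterministic fixtures, built in code.

# base-4 encoding of an integer as an A/C/G/T string of fixed length
int2dna <- function(i, len) {
  vapply(i, function(x) {
    digits <- integer(len)
    for (k in len:1) {
      digits[k] <- x %% 4
      x <- x %/% 4
    }
    paste(c("A", "C", "G", "T")[digits + 1], collapse = "")
  }, character(1))
}

make_library <- function(n_pools = 1, n = 8, len = 20) {
  total <- n_pools * n
  data.frame(hairpin_id = sprintf("hp%04d", seq_len(total)),
             gene = sprintf("Gene%04d", seq_len(total)),
             antisense = int2dna(seq_len(total), len),
             pool_id = rep(sprintf("pool%d", seq_len(n_pools)), each = n),
             stringsAsFactors = FALSE)
}

make_samples <- function(n_pools = 1, reps = 2) {
  per <- 2L * reps
  total <- n_pools * per
  data.frame(sample_id = sprintf("s%02d", seq_len(total)),
             index_seq = int2dna(seq_len(total), 5),
             pool_id = rep(sprintf("pool%d", seq_len(n_pools)), each = per),
             timepoint = rep(rep(c("T2", "T14"), each = reps), n_pools),
             replicate = rep(seq_len(reps), 2L * n_pools),
             stringsAsFactors = FALSE)
}

# hand-built ground truth (bypasses the random draw) for targeted simulations
make_truth <- function(library, samples, baseline_prop, fold, phi, lib_sizes) {
  hp <- library
  hp$baseline_prop <- baseline_prop
  hp$fold <- fold
  structure(list(hairpins = hp, phi = phi,
                 lib_sizes = stats::setNames(lib_sizes, samples$sample_id)),
            class = "screen_truth")
}

# Independent enumeration oracle for the conditional exact test: the null
# conditional law of A given S is computed from raw NB (or Poisson) pmf
# products at an arbitrary mean, then the minimum-likelihood two-sided
# p-value is summed directly.
oracle_exact_pvalue <- function(A, S, n1, n2, phi, mu = 10) {
  a <- 0:S
  pr <- if (phi == 0) {
    stats::dpois(a, n1 * mu) * stats::dpois(S - a, n2 * mu)
  } else {
    stats::dnbinom(a, size = n1 / phi, mu = n1 * mu) *
      stats::dnbinom(S - a, size = n2 / phi, mu = n2 * mu)
  }
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[A + 1] * (1 + 1e-10)]))
}

# pseudo-count matrix whose group sums are exactly (A, S - A) for each row
pseudo_for_splits <- function(A, S, n1, n2) {
  cbind(matrix(rep(A / n1, n1), ncol = n1),
        matrix(rep((S - A) / n2, n2), ncol = n2))
}
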