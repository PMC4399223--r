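#' Tally perfect index-hairpin matches from FASTQ reads
#'
#' Converts raw amplicon reads into the hairpin-by-sample count matrix. A
#' read increments cell (h, s) iff the substring at the index span equals
#' sample s's index exactly and the substring at the hairpin span equals
#' hairpin h's antisense exactly; matching is positional and quality-blind,
#' with no mismatch tolerance. Hairpin identity is resolved within the
#' matched sample's pool (antisense sequences are unique per pool, not
#' necessarily across pools). Reads failing either match are tallied in the
#' counting report; reads too short for the spans simply fail to match.
#'
#' @param fastq Path to a FASTQ file (`.gz` accepted transparently).
#' @param library A validated hairpin library.
#' @param samples A validated sample sheet.
#' @param structure A [read_structure()].
#' @param chunk_size Number of reads parsed per chunk (memory knob).
#' @return A list with `counts` (a [count_matrix()]) and `report` (totals:
#'   `total_reads`, `matched`, `index_only`, `hairpin_only`, `unmatched`;
#'   the four categories partition the total).
#' @section Ambiguity guard: within the lookup set of each pool no antisense
#'   may be a prefix of another — with variable 19-22 nt hairpins at a fixed
#'   offset a prefix collision would let one read match two hairpins. Such
#'   libraries are rejected up front.
#' @examples
#' \donttest{
#' lib <- data.frame(hairpin_id = c("h1", "h2"), gene = c("G1", "G2"),
#'                   antisense = c(strrep("A", 19), strrep("C", 19)),
#'                   pool_id = "p1")
#' sam <- data.frame(sample_id = "s1", index_seq = "ACGTA", pool_id = "p1",
#'                   timepoint = "T2", replicate = 1)
#' cm <- count_matrix(matrix(5:6, ncol = 1), lib, sam)
#' fq <- tempfile(fileext = ".fastq")
#' emit_fastq(cm, fq, read_structure(spacer = "", read_len = 30), seed = 7)
#' res <- count_reads(fq, lib, sam, read_structure(spacer = "", read_len = 30))
#' res$report
#' }
#' @export
count_reads <- function(fastq, library, samples, structure = read_structure(),
                        chunk_size = 100000L) {
  library <- validate_hairpin_library(library)
  samples <- validate_sample_sheet(samples, library)
  stopifnot(inherits(structure, "read_structure"))
  check_structure_fits(structure, library)
  check_pool_ambiguity(library, samples)

  n_h <- nrow(library)
  n_s <- nrow(samples)
  counts <- matrix(0, nrow = n_h, ncol = n_s)
  report <- c(total_reads = 0, matched = 0, index_only = 0,
              hairpin_only = 0, unmatched = 0)

  pools <- split(seq_len(n_h), library$pool_id)
  sample_pool <- samples$pool_id
  lens <- sort(unique(nchar(library$antisense)))
  is0 <- structure$index_start
  il <- structure$index_len
  hs <- structure$hairpin_start

  con <- if (grepl("\\.gz$", fastq)) gzfile(fastq, "rt") else file(fastq, "rt")
  on.exit(close(con))
  record_no <- 0L
  repeat {
    lines <- readLines(con, n = chunk_size * 4L)
    if (!length(lines)) break
    if (length(lines) %% 4L != 0L)
      stop("truncated FASTQ record at record ",
           record_no + length(lines) %/% 4L + 1L)
    m <- matrix(lines, nrow = 4L)
    bad <- !startsWith(m[1L, ], "@") | !startsWith(m[3L, ], "+") |
      nchar(m[2L, ]) != nchar(m[4L, ])
    if (any(bad))
      stop("malformed FASTQ record ", record_no + which(bad)[1L])
    seqs <- m[2L, ]
    nr <- length(seqs)
    record_no <- record_no + nr
    report["total_reads"] <- report["total_reads"] + nr

    s_idx <- match(substr(seqs, is0 + 1L, is0 + il), samples$index_seq)
    # hairpin span matches anything in the whole library? (for the report)
    any_hp <- rep(FALSE, nr)
    for (L in lens)
      any_hp <- any_hp |
        substr(seqs, hs + 1L, hs + L) %in% library$antisense[nchar(library$antisense) == L]

    h_idx <- rep(NA_integer_, nr)
    with_sample <- which(!is.na(s_idx))
    for (p in names(pools)) {
      prows <- pools[[p]]
      in_p <- with_sample[sample_pool[s_idx[with_sample]] == p]
      if (!length(in_p)) next
      for (L in intersect(lens, unique(nchar(library$antisense[prows])))) {
        cand <- prows[nchar(library$antisense[prows]) == L]
        hit <- match(substr(seqs[in_p], hs + 1L, hs + L),
                     library$antisense[cand])
        found <- !is.na(hit)
        h_idx[in_p[found]] <- cand[hit[found]]
      }
    }

    ok <- !is.na(s_idx) & !is.na(h_idx)
    if (any(ok)) {
      cell <- (s_idx[ok] - 1L) * n_h + h_idx[ok]
      tal <- tabulate(cell, nbins = n_h * n_s)
      counts <- counts + matrix(tal, nrow = n_h)
    }
    report["matched"] <- report["matched"] + sum(ok)
    report["index_only"] <- report["index_only"] + sum(!is.na(s_idx) & is.na(h_idx))
    report["hairpin_only"] <- report["hairpin_only"] + sum(is.na(s_idx) & any_hp)
    report["unmatched"] <- report["unmatched"] + sum(is.na(s_idx) & !any_hp)
  }
  list(counts = count_matrix(counts, library, samples),
       report = as.list(report))
}

# reject pools where one antisense is a proper prefix of another: a long
# hairpin's read would also perfect-match the short hairpin at the same offset
check_pool_ambiguity <- function(library, samples) {
  for (p in unique(library$pool_id)) {
    seqs <- sort(library$antisense[library$pool_id == p])
    if (length(seqs) < 2L) next
    pre <- startsWith(seqs[-1L], seqs[-length(seqs)])
    if (any(pre))
      stop("ambiguous pool ", p, ": antisense '", seqs[which(pre)[1L]],
           "' is a prefix of another hairpin's antisense")
  }
  invisible(TRUE)
}
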