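# hand-rolled FASTQ writer for constructing adversarial inputs
write_fastq <- function(seqs, path, qual = NULL) {
  if (is.null(qual)) qual <- strrep("I", nchar(seqs))
  rec <- rbind(sprintf("@r%d", seq_along(seqs)), seqs, "+", qual)
  writeLines(as.vector(rec), path)
  path
}

test_that("empty FASTQ gives an all-zero matrix and report", {
  lib <- make_library(n = 3)
  sam <- make_samples(reps = 1)
  fq <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), fq)
  got <- count_reads(fq, lib, sam, read_structure(spacer = "", read_len = 26))
  expect_true(all(got$counts$counts == 0L))
  expect_equal(got$report$total_reads, 0)
  expect_equal(got$report$matched, 0)
})

test_that("hand-constructed reads are tallied per an independent string oracle", {
  lib <- data.frame(hairpin_id = c("hA", "hB"), gene = c("G1", "G2"),
                    antisense = c(int2dna(7, 19), int2dna(9, 19)),
                    pool_id = "pool1", stringsAsFactors = FALSE)
  sam <- data.frame(sample_id = c("s1", "s2"),
                    index_seq = c("AACCA", "GGTTG"), pool_id = "pool1",
                    timepoint = c("T2", "T14"), replicate = 1L,
                    stringsAsFactors = FALSE)
  rs <- read_structure(spacer = "", read_len = 24)
  reads <- c(rep(paste0("AACCA", lib$antisense[1]), 3),
             rep(paste0("AACCA", lib$antisense[2]), 2),
             rep(paste0("GGTTG", lib$antisense[1]), 5))
  # independent oracle: per-read substring comparison
  oracle <- matrix(0L, 2, 2)
  for (r in reads) {
    s <- match(substr(r, 1, 5), sam$index_seq)
    h <- match(substr(r, 6, 24), lib$antisense)
    if (!is.na(s) && !is.na(h)) oracle[h, s] <- oracle[h, s] + 1L
  }
  fq <- write_fastq(reads, withr::local_tempfile(fileext = ".fastq"))
  got <- count_reads(fq, lib, sam, rs)
  expect_equal(unname(got$counts$counts), oracle)
  expect_equal(oracle, matrix(c(3L, 2L, 5L, 0L), 2))
  expect_equal(got$report$matched, 10)

  # one substitution inside the hairpin span: not counted, index still seen
  mut <- paste0("AACCA", sub("A", "T", lib$antisense[1]))
  fq2 <- write_fastq(c(reads[1], mut), withr::local_tempfile(fileext = ".fastq"))
  got2 <- count_reads(fq2, lib, sam, rs)
  expect_equal(sum(got2$counts$counts), 1)
  expect_equal(got2$report$index_only, 1)
  expect_equal(got2$report$hairpin_only, 0)
})

test_that("matrix total equals matched reads and order does not matter", {
  lib <- make_library(n_pools = 2, n = 5)
  sam <- make_samples(n_pools = 2, reps = 1)
  rs <- read_structure(spacer = "AC", read_len = 30)
  tr <- simulate_truth(lib, sam, sim_config(mean_libsize = 300), seed = 2)
  cm <- simulate_counts(tr, sam, seed = 3)
  fq <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(cm, fq, rs, seed = 4)
  lines <- readLines(fq)
  rec <- matrix(lines, nrow = 4)
  set.seed(9)
  shuf <- rec[, sample.int(ncol(rec))]
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(as.vector(shuf), fq2)
  a <- count_reads(fq, lib, sam, rs)
  b <- count_reads(fq2, lib, sam, rs)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_equal(sum(a$counts$counts), a$report$matched)

  # appending one perfectly matching read increments exactly one cell
  extra <- paste0(sam$index_seq[3], "AC", lib$antisense[7])
  extra <- paste0(extra, strrep("A", 30 - nchar(extra)))
  fq3 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c(lines, "@extra", extra, "+", strrep("I", 30)), fq3)
  c3 <- count_reads(fq3, lib, sam, rs)
  delta <- c3$counts$counts - a$counts$counts
  expect_equal(sum(delta), 1L)
  expect_equal(delta[7, 3], 1L)
})

test_that("short reads fail to match and malformed records are hard errors", {
  lib <- make_library(n = 2)
  sam <- make_samples(reps = 1)
  rs <- read_structure(spacer = "", read_len = 25)
  fq <- write_fastq(c("ACGT", paste0(sam$index_seq[1], lib$antisense[1])),
                    withr::local_tempfile(fileext = ".fastq"))
  got <- count_reads(fq, lib, sam, rs)
  expect_equal(got$report$unmatched, 1)
  expect_equal(got$report$matched, 1)

  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), bad)   # qual length mismatch
  expect_error(count_reads(bad, lib, sam, rs), "record 1")
  trunc <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+"), trunc)
  expect_error(count_reads(trunc, lib, sam, rs), "truncated")
})

test_that("prefix-ambiguous pools are rejected; cross-pool duplicates are not", {
  lib <- data.frame(hairpin_id = c("h1", "h2"),
                    gene = c("G1", "G2"),
                    antisense = c(int2dna(3, 19), paste0(int2dna(3, 19), "ACG")),
                    pool_id = "pool1", stringsAsFactors = FALSE)
  sam <- make_samples(reps = 1)
  expect_error(count_reads(tempfile(), lib, sam,
                           read_structure(spacer = "", read_len = 30)),
               "prefix")
  # same antisense in two different pools is legal: the index decides
  lib2 <- data.frame(hairpin_id = c("h1", "h2"), gene = c("G1", "G2"),
                     antisense = int2dna(c(3, 3), 19),
                     pool_id = c("pool1", "pool2"), stringsAsFactors = FALSE)
  sam2 <- make_samples(n_pools = 2, reps = 1)[c(1, 3), ]
  fq <- write_fastq(paste0(sam2$index_seq, int2dna(3, 19)),
                    withr::local_tempfile(fileext = ".fastq"))
  got <- count_reads(fq, lib2, sam2, read_structure(spacer = "", read_len = 24))
  expect_equal(unname(got$counts$counts), diag(2) * 1L)
})

test_that("gzip FASTQ is read transparently", {
  lib <- make_library(n = 2)
  sam <- make_samples(reps = 1)
  rs <- read_structure(read_len = 46)
  cm <- count_matrix(matrix(3L, 2, 2), lib, sam)
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  emit_fastq(cm, fq, rs, seed = 1)
  got <- count_reads(fq, lib, sam, rs)
  expect_identical(got$counts$counts, cm$counts)
})

test_that("count matrix TSV round-trips and rejects corrupt cells", {
  lib <- make_library(n_pools = 2, n = 4)
  sam <- make_samples(n_pools = 2, reps = 1)
  set.seed(5)
  cm <- count_matrix(matrix(rpois(16, 20), 8, 4), lib, sam)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cm, path)
  back <- read_counts(path, lib, sam)
  expect_identical(back$counts, cm$counts)
  expect_identical(back$hairpins$pool_id, cm$hairpins$pool_id)

  # 0-row matrix: header-only file, empty on the way back
  empty <- count_matrix(matrix(0L, 0, 4), lib[0, ], sam)
  p0 <- withr::local_tempfile(fileext = ".tsv")
  write_counts(empty, p0)
  expect_length(readLines(p0), 1)
  expect_equal(nrow(read_counts(p0)$counts), 0)

  tab <- utils::read.delim(path, check.names = FALSE)
  tab[2, 4] <- -3
  pbad <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, pbad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_counts(pbad), "hairpin 'hp0002'")
  tab[2, 4] <- 2.5
  utils::write.table(tab, pbad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_counts(pbad), "non-negative-integer")
})

test_that("metadata validation guards the count matrix container", {
  lib <- make_library(n = 3)
  sam <- make_samples(reps = 1)
  expect_error(count_matrix(matrix(-1, 3, 2), lib, sam), "non-negative")
  expect_error(count_matrix(matrix(0.5, 3, 2), lib, sam), "integer")
  expect_error(count_matrix(matrix(0L, 2, 2), lib, sam), "metadata has")
  lib_dup <- lib; lib_dup$antisense[2] <- lib_dup$antisense[1]
  expect_error(validate_hairpin_library(lib_dup), "duplicated antisense")
  sam_dup <- sam; sam_dup$index_seq[2] <- sam_dup$index_seq[1]
  expect_error(validate_sample_sheet(sam_dup), "unique")
})
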