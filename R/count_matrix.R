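#' Construct a hairpin-by-sample count matrix
#'
#' The central container of the pipeline: a non-negative integer matrix of
#' read counts (rows = hairpins, columns = samples) together with the hairpin
#' library rows and sample sheet rows that describe its dimensions.
#'
#' @param counts Integer matrix, hairpins in rows, samples in columns.
#' @param hairpins Hairpin metadata data.frame; must contain `hairpin_id` and
#'   `gene` (usually a validated hairpin library), one row per matrix row.
#' @param samples Sample metadata data.frame; must contain `sample_id`, one
#'   row per matrix column.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `hairpins`, `samples`. Dimnames of `counts` are set from the metadata.
#' @export
count_matrix <- function(counts, hairpins, samples) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  hairpins <- as.data.frame(hairpins, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(hairpins$hairpin_id) || is.null(samples$sample_id))
    stop("metadata must carry hairpin_id / sample_id columns")
  if (nrow(hairpins) != nrow(counts))
    stop("hairpin metadata has ", nrow(hairpins), " rows but counts has ",
         nrow(counts))
  if (nrow(samples) != ncol(counts))
    stop("sample metadata has ", nrow(samples), " rows but counts has ",
         ncol(counts), " columns")
  if (anyDuplicated(hairpins$hairpin_id)) stop("duplicated hairpin_id")
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample_id")
  dimnames(counts) <- list(hairpins$hairpin_id, samples$sample_id)
  structure(list(counts = counts, hairpins = hairpins, samples = samples),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d hairpins x %d samples, %s reads total\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ",")))
  if (!is.null(x$hairpins$pool_id))
    cat("pools:", paste(unique(x$hairpins$pool_id), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write a count matrix to a tab-separated file
#'
#' Layout: columns `hairpin_id`, `gene`, then one column per sample (header =
#' sample ids). The file round-trips losslessly through [read_counts()].
#'
#' @param cm A `count_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  gene <- if (!is.null(cm$hairpins$gene)) cm$hairpins$gene else
    rep("", nrow(cm$counts))
  df <- data.frame(hairpin_id = cm$hairpins$hairpin_id, gene = gene,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(cm$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_counts()]
#'
#' @param path Path to the TSV file.
#' @param library,samples Optional hairpin library / sample sheet; when given,
#'   their metadata (pool ids, timepoints, ...) is re-attached by id and the
#'   file must be consistent with them.
#' @return A `count_matrix`. Cells that are negative or non-integer raise an
#'   error naming the hairpin row and sample column.
#' @export
read_counts <- function(path, library = NULL, samples = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (!all(c("hairpin_id", "gene") %in% names(df)))
    stop("count file must start with hairpin_id and gene columns")
  sample_ids <- setdiff(names(df), c("hairpin_id", "gene"))
  mat <- matrix(0L, nrow = nrow(df), ncol = length(sample_ids),
                dimnames = list(df$hairpin_id, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(df[[sample_ids[j]]]))
    bad <- is.na(v) | v < 0 | v != round(v)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("non-negative-integer cell at hairpin '", df$hairpin_id[i],
           "', sample '", sample_ids[j], "': ", df[[sample_ids[j]]][i])
    }
    mat[, j] <- as.integer(v)
  }
  hairpins <- data.frame(hairpin_id = df$hairpin_id, gene = df$gene,
                         stringsAsFactors = FALSE)
  if (!is.null(library)) {
    m <- match(hairpins$hairpin_id, library$hairpin_id)
    if (anyNA(m))
      stop("count file contains hairpins absent from the library: ",
           paste(hairpins$hairpin_id[is.na(m)], collapse = ", "))
    hairpins <- library[m, , drop = FALSE]
    rownames(hairpins) <- NULL
  }
  smeta <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    m <- match(sample_ids, samples$sample_id)
    if (anyNA(m))
      stop("count file contains samples absent from the sample sheet: ",
           paste(sample_ids[is.na(m)], collapse = ", "))
    smeta <- samples[m, , drop = FALSE]
    rownames(smeta) <- NULL
  }
  count_matrix(mat, hairpins, smeta)
}
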