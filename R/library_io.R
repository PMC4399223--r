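#' Validate a hairpin library table
#'
#' A hairpin library describes the members of a pooled shRNA library: one row
#' per hairpin with its identifier, target gene symbol, mature antisense
#' sequence (the 19-22 nt stretch that is read on the sequencer) and the pool
#' it was screened in.
#'
#' @param library A data.frame with columns `hairpin_id`, `gene`, `antisense`
#'   and `pool_id`.
#' @return The validated data.frame (invisibly usable), with character columns.
#' @details Antisense sequences must be non-empty strings over A/C/G/T of
#'   length 19-22 and unique within each pool; `hairpin_id` must be globally
#'   unique and `gene` non-empty. Violations raise an error naming the
#'   offending rows.
#' @export
validate_hairpin_library <- function(library) {
  required <- c("hairpin_id", "gene", "antisense", "pool_id")
  missing <- setdiff(required, names(library))
  if (length(missing))
    stop("hairpin library is missing column(s): ", paste(missing, collapse = ", "))
  library <- as.data.frame(library, stringsAsFactors = FALSE)
  for (col in required) library[[col]] <- as.character(library[[col]])
  if (anyDuplicated(library$hairpin_id))
    stop("duplicated hairpin_id: ",
         paste(unique(library$hairpin_id[duplicated(library$hairpin_id)]), collapse = ", "))
  if (any(!nzchar(library$gene)))
    stop("empty gene symbol at row(s): ",
         paste(which(!nzchar(library$gene)), collapse = ", "))
  bad_seq <- !grepl("^[ACGT]+$", library$antisense) |
    nchar(library$antisense) < 19L | nchar(library$antisense) > 22L
  if (any(bad_seq))
    stop("antisense must be a 19-22 nt A/C/G/T string; bad row(s): ",
         paste(which(bad_seq), collapse = ", "))
  for (p in unique(library$pool_id)) {
    seqs <- library$antisense[library$pool_id == p]
    if (anyDuplicated(seqs))
      stop("duplicated antisense sequence within pool ", p)
  }
  library
}

#' Validate a sample sheet
#'
#' The sample sheet links each sequenced sample to its 5-bp multiplexing
#' index, the hairpin pool it carries, the timepoint (T2, shortly after
#' transduction; T14, after selection in culture) and a replicate number.
#'
#' @param samples A data.frame with columns `sample_id`, `index_seq`,
#'   `pool_id`, `timepoint` and `replicate`.
#' @param library Optional hairpin library; when given, every `pool_id` in the
#'   sheet must exist in the library.
#' @param index_len Required index length (default 5).
#' @return The validated data.frame.
#' @export
validate_sample_sheet <- function(samples, library = NULL, index_len = 5L) {
  required <- c("sample_id", "index_seq", "pool_id", "timepoint", "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  for (col in c("sample_id", "index_seq", "pool_id", "timepoint"))
    samples[[col]] <- as.character(samples[[col]])
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample sheet")
  if (anyDuplicated(samples$index_seq))
    stop("index sequences must be unique within a sequencing run; duplicated: ",
         paste(unique(samples$index_seq[duplicated(samples$index_seq)]), collapse = ", "))
  bad_idx <- !grepl("^[ACGT]+$", samples$index_seq) | nchar(samples$index_seq) != index_len
  if (any(bad_idx))
    stop("index_seq must be a ", index_len, " nt A/C/G/T string; bad row(s): ",
         paste(which(bad_idx), collapse = ", "))
  if (any(!samples$timepoint %in% c("T2", "T14")))
    stop("timepoint must be 'T2' or 'T14'")
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1L))
    stop("replicate must be a positive integer")
  if (!is.null(library)) {
    unknown <- setdiff(samples$pool_id, library$pool_id)
    if (length(unknown))
      stop("sample sheet references pool(s) absent from the library: ",
           paste(unknown, collapse = ", "))
  }
  samples
}

#' Read a hairpin library from a tab-separated file
#'
#' Expects a header with columns `hairpin_id`, `gene`, `antisense`, `pool_id`.
#' @param path Path to the TSV file.
#' @return A validated hairpin library data.frame.
#' @export
read_hairpin_library <- function(path) {
  validate_hairpin_library(
    utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character"))
}

#' Read a sample sheet from a tab-separated file
#'
#' Expects a header with columns `sample_id`, `index_seq`, `pool_id`,
#' `timepoint`, `replicate`.
#' @param path Path to the TSV file.
#' @param library Optional hairpin library for pool cross-checking.
#' @return A validated sample sheet data.frame.
#' @export
read_sample_sheet <- function(path, library = NULL) {
  validate_sample_sheet(utils::read.delim(path, stringsAsFactors = FALSE), library)
}

#' Describe the layout of an amplicon read
#'
#' The screen's sequencing reads have a fixed layout imposed by the PCR
#' primers: a short sample index at a fixed offset, a constant spacer (the
#' common primer region), then the hairpin antisense sequence, then whatever
#' vector sequence fills the read. Matching is positional, so the layout is
#' declared once and shared by the simulator and the counter. The default
#' spacer is the 20-nt common region of the indexed reverse primer; the
#' sequencer-facing orientation of the original run is not knowable from the
#' library alone, so every offset here is configurable.
#'
#' @param index_start 0-based offset of the sample index (default 0).
#' @param index_len Index length in nt (default 5).
#' @param spacer Constant sequence between index and hairpin (may be `""`).
#' @param read_len Total read length in nt.
#' @return An object of class `read_structure` with fields `index_start`,
#'   `index_len`, `spacer`, `hairpin_start` (derived) and `read_len`.
#' @examples
#' read_structure()                      # 5 + 20 + hairpin, 50 nt reads
#' read_structure(spacer = "", read_len = 27)  # index abuts the hairpin
#' @export
read_structure <- function(index_start = 0L, index_len = 5L,
                           spacer = "GTAGCCCCTTGAATTCCGAG", read_len = 50L) {
  index_start <- as.integer(index_start)
  index_len <- as.integer(index_len)
  read_len <- as.integer(read_len)
  if (index_start < 0L || index_len < 1L)
    stop("index_start must be >= 0 and index_len >= 1")
  if (!identical(spacer, "") && !grepl("^[ACGT]+$", spacer))
    stop("spacer must be an A/C/G/T string (possibly empty)")
  hairpin_start <- index_start + index_len + nchar(spacer)
  if (index_start + index_len > hairpin_start)
    stop("index span overlaps the hairpin span")
  if (hairpin_start >= read_len)
    stop("read_len leaves no room for the hairpin")
  structure(
    list(index_start = index_start, index_len = index_len, spacer = spacer,
         hairpin_start = as.integer(hairpin_start), read_len = read_len),
    class = "read_structure")
}

#' @export
print.read_structure <- function(x, ...) {
  cat(sprintf("Amplicon read layout (%d nt): index @%d-%d | spacer %s | hairpin @%d+\n",
              x$read_len, x$index_start, x$index_start + x$index_len - 1L,
              if (nzchar(x$spacer)) paste0(nchar(x$spacer), " nt") else "none",
              x$hairpin_start))
  invisible(x)
}

# check that a library fits the layout: hairpin must end within the read
check_structure_fits <- function(structure, library) {
  max_len <- max(nchar(library$antisense))
  if (structure$hairpin_start + max_len > structure$read_len)
    stop("hairpin of length ", max_len, " does not fit in a ",
         structure$read_len, " nt read at offset ", structure$hairpin_start)
  invisible(TRUE)
}
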