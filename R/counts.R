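#' Batch read-count matrix
#'
#' One batch of samples sequenced together: an integer matrix of read counts
#' with one row per sample and one column per target of a [target_grid()].
#' Exome (ES) batches default to 32 samples, targeted-exome (TsoE) batches
#' to 8; smaller or larger batches are accepted only with
#' `allow_any_size = TRUE` since the calling model depends on batch context.
#'
#' @param counts integer matrix, samples x targets, non-negative.
#' @param sample_ids character vector of row identifiers.
#' @param library_kind "ES" or "TsoE".
#' @param allow_any_size skip the batch-size check.
#' @return a `count_matrix` object.
#' @export
count_matrix <- function(counts, sample_ids = rownames(counts),
                         library_kind = c("ES", "TsoE"),
                         allow_any_size = FALSE) {
  library_kind <- match.arg(library_kind)
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%02d", seq_len(nrow(counts)))
  }
  if (length(sample_ids) != nrow(counts)) {
    stop("sample_ids length must equal the number of rows", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1L, ]
    stop(sprintf("counts must be non-negative integers (offending cell: sample %s, target column %d)",
                 sample_ids[bad[1L]], bad[2L]), call. = FALSE)
  }
  expected <- batch_size_default(library_kind)
  if (!allow_any_size && nrow(counts) != expected) {
    stop(sprintf("a %s batch has %d samples by default, got %d (use allow_any_size = TRUE to override)",
                 library_kind, expected, nrow(counts)), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- sample_ids
  structure(list(counts = counts, sample_ids = sample_ids,
                 library_kind = library_kind),
            class = "count_matrix")
}

#' Default batch size per library kind
#' @param library_kind "ES" or "TsoE".
#' @return integer batch size (32 for ES, 8 for TsoE).
#' @export
batch_size_default <- function(library_kind = c("ES", "TsoE")) {
  switch(match.arg(library_kind), ES = 32L, TsoE = 8L)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix (%s): %d samples x %d targets, total %.3g reads\n",
              x$library_kind, nrow(x$counts), ncol(x$counts),
              sum(as.numeric(x$counts))))
  invisible(x)
}

#' Read a per-sample per-target count matrix from TSV
#'
#' The first column holds sample identifiers; the header row holds target
#' identifiers (one column per target, in grid order).
#'
#' @param path TSV path.
#' @param library_kind "ES" or "TsoE".
#' @param allow_any_size skip the batch-size check.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, library_kind = c("ES", "TsoE"),
                              allow_any_size = TRUE) {
  library_kind <- match.arg(library_kind)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (file.size(path) == 0L) stop(sprintf("%s is empty", path), call. = FALSE)
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop(sprintf("%s: expected a sample column plus >=1 target column", path),
         call. = FALSE)
  }
  ids <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(apply(m, 2L, as.numeric))
  num <- matrix(num, nrow = nrow(m), dimnames = dimnames(m))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("%s: cell (sample %s, target %s) is not a non-negative integer: %s",
                 path, ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]],
                 m[bad[1L, 1L], bad[1L, 2L]]), call. = FALSE)
  }
  count_matrix(num, ids, library_kind, allow_any_size = allow_any_size)
}

#' Write a count matrix to TSV
#' @param matrix a [count_matrix()].
#' @param path output path.
#' @return `path`, invisibly. `read_count_matrix(write_count_matrix(m))` is
#'   the identity on counts and sample ids.
#' @export
write_count_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "count_matrix"))
  df <- data.frame(sample = matrix$sample_ids, matrix$counts,
                   check.names = FALSE)
  colnames(df) <- c("sample", colnames(matrix$counts) %||%
                      sprintf("T%05d", seq_len(ncol(matrix$counts))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count reads per capture target from an indexed alignment file
#'
#' A read is assigned to the unique target containing its leftmost aligned
#' base (0-based, half-open intervals), a fast proportional-signal rule.
#' Reads flagged unmapped, secondary, or duplicate are excluded, as are
#' reads below `min_mapq`.
#'
#' @param alignments path to a coordinate-sorted, indexed BAM file (index
#'   `.bai` alongside). SAM text must be converted/indexed first, e.g. with
#'   [Rsamtools::asBam()].
#' @param grid a [target_grid()].
#' @param min_mapq minimum mapping quality (default 20).
#' @return integer vector of counts, one per grid target (grid order).
#' @export
count_reads <- function(alignments, grid, min_mapq = 20L) {
  stopifnot(inherits(grid, "target_grid"))
  if (!file.exists(alignments)) {
    stop(sprintf("no such file: %s", alignments), call. = FALSE)
  }
  idx <- paste0(alignments, ".bai")
  if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", alignments))) {
    stop(sprintf("%s has no index; sort and index it first (e.g. Rsamtools::indexBam)",
                 alignments), call. = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(alignments)[[1L]]$targets
  bam_chroms <- names(hdr)
  grid_chroms <- unique(grid$chrom)
  mapped <- normalize_chroms(grid_chroms, bam_chroms)
  unmatched <- grid_chroms[!(mapped %in% bam_chroms)]
  if (length(unmatched) > 0L) {
    stop(sprintf("chromosome name mismatch between grid and %s: %s not found (alignment file has: %s)",
                 alignments, paste(unmatched, collapse = ", "),
                 paste(utils::head(bam_chroms, 5L), collapse = ", ")),
         call. = FALSE)
  }
  chrom_map <- setNames(mapped, grid_chroms)

  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   what = c("rname", "pos", "mapq"))
  res <- Rsamtools::scanBam(alignments, param = param)[[1L]]
  keep <- !is.na(res$pos) & !is.na(res$mapq) & res$mapq >= min_mapq
  # SAM pos is 1-based leftmost; convert to the internal 0-based convention
  start0 <- res$pos[keep] - 1L
  rname <- as.character(res$rname[keep])

  counts <- integer(nrow(grid))
  for (gc in grid_chroms) {
    sel_grid <- grid$chrom == gc
    sel_reads <- rname == chrom_map[[gc]]
    if (!any(sel_reads)) next
    ir_t <- as_iranges0(grid$start[sel_grid], grid$end[sel_grid])
    ir_r <- IRanges::IRanges(start = start0[sel_reads] + 1L, width = 1L)
    hits <- IRanges::findOverlaps(ir_r, ir_t)
    tab <- tabulate(S4Vectors::subjectHits(hits), nbins = sum(sel_grid))
    counts[sel_grid] <- tab
  }
  counts
}
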