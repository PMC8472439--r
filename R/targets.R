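#' Capture-target grid
#'
#' The target grid is the coordinate lattice for all depth arithmetic: an
#' ordered table of capture targets with one dense ordinal index
#' (`target_id`, 0-based) per chromosome. All coordinates are 0-based
#' half-open, so the size of an interval is simply `end - start`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer genomic coordinates, 0-based half-open.
#' @param gene optional gene symbols ("" when unknown).
#' @param exon_index optional 1-based exon index within `gene` (NA when
#'   unknown).
#' @return a `target_grid`: a data.frame with columns `chrom`, `start`,
#'   `end`, `gene`, `exon_index`, `target_id`, sorted by
#'   (chrom, start, end) with `target_id` dense 0..n-1 per chromosome.
#' @examples
#' g <- target_grid(c("chr1", "chr1"), c(100, 500), c(200, 650))
#' g$target_id
#' @export
target_grid <- function(chrom, start, end, gene = NULL, exon_index = NULL) {
  n <- length(chrom)
  gene <- gene %||% rep("", n)
  exon_index <- exon_index %||% rep(NA_integer_, n)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    gene = as.character(gene),
    exon_index = as.integer(exon_index),
    stringsAsFactors = FALSE
  )
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)[1L]
    stop(sprintf("target %s:%g-%g has end <= start", df$chrom[bad],
                 df$start[bad], df$end[bad]), call. = FALSE)
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  dup <- duplicated(df[, c("chrom", "start", "end", "gene")])
  df <- df[!dup, , drop = FALSE]
  df$target_id <- stats::ave(df$start, df$chrom,
                             FUN = function(x) seq_along(x) - 1L)
  df$target_id <- as.integer(df$target_id)
  rownames(df) <- NULL
  class(df) <- c("target_grid", "data.frame")
  df
}

#' Read capture targets from a BED file
#'
#' BED columns 1-3 are chromosome, start, end (0-based half-open, as in the
#' BED standard); optional columns 4 and 5 are interpreted as gene symbol
#' and 1-based exon index. Overlapping intervals are kept as distinct
#' targets; sorting and dense per-chromosome indexing are enforced.
#'
#' @param path path to a BED file (plain text, no header).
#' @return a [target_grid()].
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) stop(sprintf("%s: no target lines", path), call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop_parse(path, which(nf < 3L)[1L], "expected at least 3 tab-separated columns")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop_parse(path, which(is.na(start) | is.na(end))[1L],
               "non-numeric start/end coordinate")
  }
  bad <- which(end <= start)
  if (length(bad) > 0L) {
    stop_parse(path, bad[1L], sprintf("end (%g) <= start (%g)",
                                      end[bad[1L]], start[bad[1L]]))
  }
  gene <- ifelse(nf >= 4L, vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else "", ""), "")
  exon <- ifelse(nf >= 5L,
                 suppressWarnings(as.integer(vapply(fields, function(f)
                   if (length(f) >= 5L) f[[5L]] else NA_character_, ""))),
                 NA_integer_)
  target_grid(chrom, start, end, gene, exon)
}

#' Write a target grid to BED
#' @param grid a [target_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_targets <- function(grid, path) {
  stopifnot(inherits(grid, "target_grid"))
  df <- data.frame(grid$chrom, format(grid$start, scientific = FALSE, trim = TRUE),
                   format(grid$end, scientific = FALSE, trim = TRUE),
                   grid$gene,
                   ifelse(is.na(grid$exon_index), ".", grid$exon_index))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @export
print.target_grid <- function(x, ...) {
  cat(sprintf("target_grid: %d targets on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  NextMethod()
}

# GRanges view of a grid (1-based closed, for overlap queries)
grid_granges <- function(grid) {
  gr <- as_granges0(grid$chrom, grid$start, grid$end)
  S4Vectors::mcols(gr)$target_id <- grid$target_id
  gr
}
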