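#' @importFrom stats cor dnbinom median rbinom rlnorm rnbinom runif setNames
#' @importFrom utils read.delim write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize chromosome names to a reference vocabulary
#'
#' Strips or adds the "chr" prefix so that `chroms` matches the naming style
#' of `reference`. Used once per file read; a mixed file errors downstream
#' when names still disagree.
#'
#' @param chroms character vector of chromosome names to normalize.
#' @param reference character vector whose naming style ("chr1" vs "1") wins.
#' @return character vector, same length as `chroms`.
#' @keywords internal
normalize_chroms <- function(chroms, reference) {
  ref_has_prefix <- any(grepl("^chr", reference))
  has_prefix <- grepl("^chr", chroms)
  if (ref_has_prefix) {
    chroms[!has_prefix] <- paste0("chr", chroms[!has_prefix])
  } else {
    chroms[has_prefix] <- sub("^chr", "", chroms[has_prefix])
  }
  chroms
}

# 0-based half-open [start, end) -> IRanges (1-based closed)
as_iranges0 <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

# GRanges from 0-based half-open columns
as_granges0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(seqnames = chrom, ranges = as_iranges0(start, end))
}

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}
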