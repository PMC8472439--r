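#' Write CNV calls to TSV or VCF
#'
#' TSV output writes the call/annotation columns as-is (stable, documented
#' column set; 0-based half-open coordinates). VCF output follows VCF 4.2
#' structural-variant conventions: 1-based POS, `SVTYPE=DEL` for losses and
#' `SVTYPE=DUP` for gains, `END`, `CN` (copy number) and `MOSAIC` (percent
#' mosaic fraction, when estimated) in INFO.
#'
#' @param calls a `cnv_calls` or `annotated_cnvs` data.frame.
#' @param path output path.
#' @param format "TSV" or "VCF".
#' @return `path`, invisibly. An empty call list produces a valid
#'   header-only file.
#' @export
write_calls <- function(calls, path, format = c("TSV", "VCF")) {
  if (length(format) == 1L && !format %in% c("TSV", "VCF")) {
    stop(sprintf("unknown call output format: %s", format), call. = FALSE)
  }
  format <- match.arg(format)
  if (format == "TSV") {
    out <- as.data.frame(calls)
    attr(out, "gene_tables") <- NULL
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cnvbatch",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##ALT=<ID=DUP,Description=\"Duplication\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=CN,Number=1,Type=Integer,Description=\"Copy number\">",
    "##INFO=<ID=NTARGETS,Number=1,Type=Integer,Description=\"Capture targets spanned\">",
    "##INFO=<ID=QUAL10,Number=1,Type=Float,Description=\"log10 Bayes factor vs diploid\">",
    "##INFO=<ID=MOSAIC,Number=1,Type=Float,Description=\"Estimated mosaic fraction, percent\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- header
  if (nrow(calls) > 0L) {
    for (i in seq_len(nrow(calls))) {
      x <- calls[i, ]
      svtype <- if (x$type == "loss") "DEL" else "DUP"
      info <- sprintf("SVTYPE=%s;END=%d;CN=%d;NTARGETS=%d;QUAL10=%.2f",
                      svtype, as.integer(x$end), x$copy_number,
                      x$n_targets, x$quality)
      if (!is.na(x$mosaic_fraction)) {
        info <- sprintf("%s;MOSAIC=%.1f", info, 100 * x$mosaic_fraction)
      }
      # VCF is 1-based: POS = internal 0-based start + 1
      lines <- c(lines, sprintf("%s\t%d\t%s\tN\t<%s>\t%.1f\tPASS\t%s",
                                x$chrom, as.integer(x$start) + 1L,
                                sprintf("%s_cnv%d", x$sample, i), svtype,
                                x$quality, info))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV call table written by [write_calls()]
#' @param path TSV path.
#' @return a `cnv_calls` (or annotated) data.frame.
#' @export
read_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample", "chrom", "start", "end", "type",
                      "copy_number"), path)
  class(df) <- c("cnv_calls", "data.frame")
  df
}
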