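#' Read the annotation side-tables used after CNV calling
#'
#' Loads cytogenetic bands, the gene/exon model, microarray and MLPA probe
#' sets, clinical gene panels, CNV frequency tables (an in-house database of
#' previous batches and population structural-variant tables), and per-gene
#' dosage annotations. Every table is optional except the cytobands and gene
#' model arguments may also be omitted: a missing optional table yields an
#' empty set and a warning, so the pipeline still runs with reduced
#' annotation.
#'
#' File dialects:
#' \describe{
#'   \item{cytobands}{UCSC cytoBand.txt: chrom, start, end, band, stain
#'     (tab-separated, no header, 0-based half-open).}
#'   \item{gene_model}{refFlat-style: geneName, name, chrom, strand,
#'     txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds
#'     (exon starts/ends comma-separated, 0-based half-open).}
#'   \item{probes}{BED (chrom, start, end) per probe set.}
#'   \item{panels}{TSV with header columns `panel`, `gene`.}
#'   \item{frequency tables}{TSV with header chrom, start, end, type
#'     (gain/loss), freq in [0,1].}
#'   \item{gene_dosage}{TSV with header gene, hi_score, ts_score, domino,
#'     disease_flag, pseudogene_flag. HI/TS scores use the ClinGen
#'     vocabulary {0,1,2,3,30,40}; DOMINO lies in [0,1].}
#' }
#'
#' @param cytobands,gene_model,probes_180k,probes_1m,probes_mlpa,panels,inhouse_db,popsv_db,gene_dosage
#'   file paths, or NULL for "not provided".
#' @return an `annotation_tables` list with elements `cytobands` (data.frame),
#'   `gene_model` (list of per-gene exon tables), `probe_sets` (named list of
#'   GRanges), `panels` (named list of character vectors), `inhouse_db`,
#'   `popsv_db` (data.frames), `gene_dosage` (data.frame keyed by gene).
#' @export
read_annotation_tables <- function(cytobands = NULL, gene_model = NULL,
                                   probes_180k = NULL, probes_1m = NULL,
                                   probes_mlpa = NULL, panels = NULL,
                                   inhouse_db = NULL, popsv_db = NULL,
                                   gene_dosage = NULL) {
  opt <- function(path, reader, what, empty) {
    if (is.null(path)) return(empty)
    if (!file.exists(path)) {
      warning(sprintf("%s table %s not found; using empty set", what, path),
              call. = FALSE)
      return(empty)
    }
    reader(path)
  }
  empty_freq <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), type = character(),
                           freq = numeric(), stringsAsFactors = FALSE)
  structure(list(
    cytobands = opt(cytobands, read_cytobands, "cytoband",
                    data.frame(chrom = character(), start = numeric(),
                               end = numeric(), band = character(),
                               stain = character(), stringsAsFactors = FALSE)),
    gene_model = opt(gene_model, read_refflat, "gene model", list()),
    probe_sets = list(
      aCGH180K = opt(probes_180k, read_probe_bed, "aCGH 180K probe",
                     GenomicRanges::GRanges()),
      aCGH1M = opt(probes_1m, read_probe_bed, "aCGH 1M probe",
                   GenomicRanges::GRanges()),
      MLPA = opt(probes_mlpa, read_probe_bed, "MLPA probe",
                 GenomicRanges::GRanges())
    ),
    panels = opt(panels, read_panels, "panel", list()),
    inhouse_db = opt(inhouse_db, read_freq_table, "in-house frequency", empty_freq),
    popsv_db = opt(popsv_db, read_freq_table, "population-SV frequency", empty_freq),
    gene_dosage = opt(gene_dosage, read_gene_dosage, "gene dosage",
                      data.frame(gene = character(), hi_score = numeric(),
                                 ts_score = numeric(), domino = numeric(),
                                 disease_flag = logical(),
                                 pseudogene_flag = logical(),
                                 stringsAsFactors = FALSE))
  ), class = "annotation_tables")
}

#' Read a UCSC-style cytoband table
#' @param path cytoBand.txt-dialect file (no header).
#' @return data.frame with chrom, start, end, band, stain; bands on one
#'   chromosome must not overlap.
#' @export
read_cytobands <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) {
    stop(sprintf("%s: cytoband table needs >=4 columns (chrom,start,end,band)",
                 path), call. = FALSE)
  }
  names(df)[1:4] <- c("chrom", "start", "end", "band")
  df$stain <- if (ncol(df) >= 5L) as.character(df[[5L]]) else ""
  df <- df[, c("chrom", "start", "end", "band", "stain")]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop(sprintf("%s: overlapping band intervals on %s", path, ch),
           call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' Read a refFlat-style gene model
#' @param path refFlat-dialect file (no header).
#' @return named list: per gene, a data.frame of exons with chrom, start,
#'   end (0-based half-open), exon_index (1-based, in transcription order
#'   on the + strand sense of coordinates).
#' @export
read_refflat <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 11L) {
    stop(sprintf("%s: refFlat-style table needs 11 columns", path),
         call. = FALSE)
  }
  names(df) <- c("geneName", "name", "chrom", "strand", "txStart", "txEnd",
                 "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  out <- list()
  for (i in seq_len(nrow(df))) {
    starts <- as.numeric(strsplit(df$exonStarts[i], ",")[[1L]])
    ends <- as.numeric(strsplit(df$exonEnds[i], ",")[[1L]])
    if (length(starts) != length(ends) || length(starts) != df$exonCount[i]) {
      stop(sprintf("%s: gene %s: exon list lengths disagree with exonCount",
                   path, df$geneName[i]), call. = FALSE)
    }
    g <- df$geneName[i]
    ex <- data.frame(chrom = df$chrom[i], start = starts, end = ends,
                     exon_index = seq_along(starts), strand = df$strand[i],
                     stringsAsFactors = FALSE)
    # keep the transcript with the most exons when a gene repeats
    if (is.null(out[[g]]) || nrow(ex) > nrow(out[[g]])) out[[g]] <- ex
  }
  out
}

read_probe_bed <- function(path) {
  grid <- read_targets(path)
  as_granges0(grid$chrom, grid$start, grid$end)
}

#' Read gene panels
#' @param path TSV with header columns `panel` and `gene`.
#' @return named list of character gene vectors, one per panel.
#' @export
read_panels <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("panel", "gene"), path)
  split(df$gene, df$panel)
}

#' Read a CNV frequency table
#' @param path TSV with header chrom, start, end, type, freq.
#' @return data.frame; frequencies validated to lie in [0,1].
#' @export
read_freq_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("chrom", "start", "end", "type", "freq"), path)
  if (any(!df$type %in% c("gain", "loss"))) {
    stop(sprintf("%s: type must be 'gain' or 'loss'", path), call. = FALSE)
  }
  if (any(df$freq < 0 | df$freq > 1)) {
    stop(sprintf("%s: frequency outside [0,1]", path), call. = FALSE)
  }
  df
}

#' Read per-gene dosage annotations
#'
#' HI (haploinsufficiency) and TS (triplosensitivity) scores follow the
#' ClinGen vocabulary: 0 (no evidence), 1, 2, 3 (sufficient evidence),
#' 30 (autosomal recessive), 40 (dosage sensitivity unlikely). DOMINO is a
#' probability of dominant-acting deleterious variants, in [0,1].
#'
#' @param path TSV with header gene, hi_score, ts_score, domino,
#'   disease_flag, pseudogene_flag.
#' @return validated data.frame.
#' @export
read_gene_dosage <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("gene", "hi_score", "ts_score", "domino",
                      "disease_flag", "pseudogene_flag"), path)
  vocab <- c(0, 1, 2, 3, 30, 40)
  for (col in c("hi_score", "ts_score")) {
    vals <- df[[col]][!is.na(df[[col]])]
    if (any(!vals %in% vocab)) {
      stop(sprintf("%s: %s value outside ClinGen vocabulary {0,1,2,3,30,40}: %s",
                   path, col, paste(setdiff(vals, vocab), collapse = ",")),
           call. = FALSE)
    }
  }
  dom <- df$domino[!is.na(df$domino)]
  if (any(dom < 0 | dom > 1)) {
    stop(sprintf("%s: DOMINO score outside [0,1]: %s", path,
                 paste(dom[dom < 0 | dom > 1], collapse = ",")), call. = FALSE)
  }
  df$disease_flag <- as.logical(df$disease_flag)
  df$pseudogene_flag <- as.logical(df$pseudogene_flag)
  df
}
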