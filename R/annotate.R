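#' Merge fragmented calls separated by short target gaps
#'
#' Low coverage in a few targets can split one event into fragments. Calls
#' from one sample on one chromosome with the same type (gain/loss) and the
#' same copy number are merged when fewer than 3 library targets lie
#' between them (strictly less than `max_gap_targets`). Merging is applied
#' to a fixpoint and is independent of input order. The merged call takes
#' the maximum quality and the count-weighted (by n_targets) mean ratio of
#' its parts.
#'
#' @param calls a `cnv_calls` data.frame for one sample.
#' @param grid the [target_grid()] the calls were made on (used only for
#'   validation; gaps are computed from target ids).
#' @param max_gap_targets merge when intervening targets < this (default 3).
#' @return merged `cnv_calls` data.frame.
#' @export
merge_calls <- function(calls, grid = NULL, max_gap_targets = 3L) {
  if (nrow(calls) == 0L) return(calls)
  if (length(unique(calls$sample)) > 1L) {
    stop("merge_calls expects calls from a single sample", call. = FALSE)
  }
  ord <- order(calls$chrom, calls$first_target)
  calls <- calls[ord, , drop = FALSE]
  # overlapping calls of different ploidy indicate an upstream bug
  for (ch in unique(calls$chrom)) {
    sub <- calls[calls$chrom == ch, , drop = FALSE]
    if (nrow(sub) > 1L) {
      overlap <- sub$first_target[-1L] <= sub$last_target[-nrow(sub)]
      differ <- sub$copy_number[-1L] != sub$copy_number[-nrow(sub)]
      if (any(overlap & differ)) {
        stop(sprintf("overlapping calls of different ploidy on %s", ch),
             call. = FALSE)
      }
    }
  }
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < nrow(calls)) {
      a <- calls[i, ]; b <- calls[i + 1L, ]
      gap <- b$first_target - a$last_target - 1L
      if (a$chrom == b$chrom && a$type == b$type &&
          a$copy_number == b$copy_number && gap < max_gap_targets) {
        w <- c(a$n_targets, b$n_targets)
        calls$last_target[i] <- b$last_target
        calls$end[i] <- max(a$end, b$end)
        calls$start[i] <- min(a$start, b$start)
        calls$first_target[i] <- min(a$first_target, b$first_target)
        calls$n_targets[i] <- a$n_targets + b$n_targets
        calls$quality[i] <- max(a$quality, b$quality)
        calls$mean_ratio[i] <- sum(w * c(a$mean_ratio, b$mean_ratio)) / sum(w)
        calls <- calls[-(i + 1L), , drop = FALSE]
        merged_any <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged_any) break
  }
  rownames(calls) <- NULL
  calls
}

#' Cytogenetic band span of a CNV
#'
#' Formats the ISCN-like band span: chromosome name without the "chr"
#' prefix, the first overlapped band, and the last overlapped band when it
#' differs (e.g. "22q13.31q13.33"; a CNV within one band prints one band).
#'
#' @param cnv a list/row with `chrom`, `start`, `end` (0-based half-open).
#' @param cytobands cytoband data.frame from [read_cytobands()].
#' @return band span string.
#' @export
cytoband_span <- function(cnv, cytobands) {
  chrom_variants <- c(cnv$chrom, sub("^chr", "", cnv$chrom),
                      paste0("chr", cnv$chrom))
  bands <- cytobands[cytobands$chrom %in% chrom_variants, , drop = FALSE]
  if (nrow(bands) == 0L) {
    stop(sprintf("no cytobands loaded for chromosome %s", cnv$chrom),
         call. = FALSE)
  }
  hit <- bands$start < cnv$end & bands$end > cnv$start
  if (!any(hit)) {
    stop(sprintf("CNV %s:%g-%g lies outside cytoband coverage", cnv$chrom,
                 cnv$start, cnv$end), call. = FALSE)
  }
  bands <- bands[hit, , drop = FALSE]
  bands <- bands[order(bands$start), , drop = FALSE]
  chrom_label <- sub("^chr", "", cnv$chrom)
  first <- bands$band[1L]; last <- bands$band[nrow(bands)]
  if (first == last) paste0(chrom_label, first)
  else paste0(chrom_label, first, last)
}

#' Genes and exon counts overlapped by a CNV
#'
#' @param cnv a list/row with `chrom`, `start`, `end`.
#' @param gene_model named list from [read_refflat()].
#' @return data.frame with one row per overlapped gene: `gene`, `n_exons`
#'   (exons intersecting the CNV), `whole_gene` (all exons intersect),
#'   `intronic_only` (gene body overlapped but no exon). Genes whose
#'   transcript span does not touch the CNV are omitted.
#' @export
gene_overlap <- function(cnv, gene_model) {
  rows <- list()
  for (g in names(gene_model)) {
    ex <- gene_model[[g]]
    chrom_match <- ex$chrom[1L] %in% c(cnv$chrom, sub("^chr", "", cnv$chrom),
                                       paste0("chr", cnv$chrom))
    if (!chrom_match) next
    span_start <- min(ex$start); span_end <- max(ex$end)
    if (span_end <= cnv$start || span_start >= cnv$end) next
    hit <- ex$start < cnv$end & ex$end > cnv$start
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, n_exons = sum(hit), whole_gene = all(hit),
      intronic_only = !any(hit), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(gene = character(), n_exons = integer(),
                      whole_gene = logical(), intronic_only = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Probe counts and detectability under conventional assays
#'
#' Counts the probes of each assay whose intervals intersect the CNV. A
#' deviation is considered significant with at least 3 consecutive probes
#' on arrayCGH platforms and at least 2 on MLPA, so detectability flags use
#' those minima.
#'
#' @param cnv a list/row with `chrom`, `start`, `end`.
#' @param probe_sets named list of GRanges: `aCGH180K`, `aCGH1M`, `MLPA`
#'   (missing/empty sets give count 0 and flag FALSE).
#' @return list with `counts` (named integer vector) and `detectable`
#'   (named logical vector).
#' @export
probe_detectability <- function(cnv, probe_sets) {
  min_probes <- c(aCGH180K = 3L, aCGH1M = 3L, MLPA = 2L)
  counts <- vapply(names(min_probes), function(nm) {
    gr <- probe_sets[[nm]]
    if (is.null(gr) || length(gr) == 0L) return(0L)
    chroms <- as.character(GenomicRanges::seqnames(gr))
    variants <- c(cnv$chrom, sub("^chr", "", cnv$chrom),
                  paste0("chr", cnv$chrom))
    sel <- chroms %in% variants
    if (!any(sel)) return(0L)
    starts0 <- GenomicRanges::start(gr)[sel] - 1L
    ends0 <- GenomicRanges::end(gr)[sel]
    sum(starts0 < cnv$end & ends0 > cnv$start)
  }, integer(1))
  list(counts = counts, detectable = counts >= min_probes)
}

#' Target distance to the chromosome termini
#'
#' Number of library targets strictly before the CNV's first target (pTer
#' side) and strictly after its last target (qTer side) on the chromosome.
#' Proximity to a terminus can signal a larger structural rearrangement.
#'
#' @param cnv a list/row with `chrom`, `first_target`, `last_target`.
#' @param grid the [target_grid()].
#' @param terminal_max flag the CNV as terminal when either distance is at
#'   most this many targets (default 10).
#' @return list with `pter_targets`, `qter_targets`, `terminal`.
#' @export
terminal_distance <- function(cnv, grid, terminal_max = 10L) {
  n_chrom <- sum(grid$chrom == cnv$chrom)
  if (n_chrom == 0L) {
    stop(sprintf("grid has no targets on %s", cnv$chrom), call. = FALSE)
  }
  pter <- cnv$first_target
  qter <- n_chrom - 1L - cnv$last_target
  list(pter_targets = as.integer(pter), qter_targets = as.integer(qter),
       terminal = pter <= terminal_max || qter <= terminal_max)
}

# reciprocal overlap of [s1,e1) and [s2,e2): both fractions must clear the
# threshold for a match
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

#' Batch and database frequency of a CNV
#'
#' A record matches when it has the same type (gain/loss) and reciprocal
#' overlap at least `ro_threshold` (both ways). The batch frequency is the
#' fraction of batch samples carrying a matching call; the database
#' frequency is the maximum frequency among matching records of the
#' in-house and population tables.
#'
#' @param cnv a call row (`chrom`, `start`, `end`, `type`).
#' @param batch_calls `cnv_calls` for every sample of the batch.
#' @param batch_size number of samples in the batch.
#' @param inhouse_db,popsv_db frequency data.frames (chrom, start, end,
#'   type, freq).
#' @param ro_threshold reciprocal-overlap threshold (default 0.5).
#' @return list with `batch_freq` and `db_freq`, both in [0,1].
#' @export
frequency_annotate <- function(cnv, batch_calls, batch_size,
                               inhouse_db = NULL, popsv_db = NULL,
                               ro_threshold = 0.5) {
  match_rows <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(logical(0))
    same <- df$chrom == cnv$chrom & df$type == cnv$type
    ro <- reciprocal_overlap(cnv$start, cnv$end, df$start, df$end)
    same & ro >= ro_threshold
  }
  batch_freq <- 0
  if (!is.null(batch_calls) && nrow(batch_calls) > 0L) {
    m <- match_rows(batch_calls)
    batch_freq <- length(unique(batch_calls$sample[m])) / batch_size
  }
  db_freq <- 0
  for (db in list(inhouse_db, popsv_db)) {
    m <- match_rows(db)
    if (any(m)) db_freq <- max(db_freq, db$freq[m])
  }
  list(batch_freq = batch_freq, db_freq = db_freq)
}

#' Size class of a CNV
#'
#' Sizes use the 0-based half-open convention (size = end - start). CNVs
#' larger than 400 kb — the cut-off used in prenatal microarray testing —
#' are "large"; CNVs under 5 kb span only one or a few exons
#' ("exon_level"); the remainder are "gene_size".
#'
#' @param cnv a list/row with `start` and `end`, or a numeric size.
#' @param large_min,exon_max class boundaries in bp (defaults 400000, 5000).
#' @return one of "large", "gene_size", "exon_level".
#' @export
size_class <- function(cnv, large_min = 400000, exon_max = 5000) {
  size <- if (is.numeric(cnv) && length(cnv) == 1L) cnv else cnv$end - cnv$start
  if (size > large_min) "large"
  else if (size < exon_max) "exon_level"
  else "gene_size"
}

#' Annotate a table of CNV calls
#'
#' Runs [merge_calls()] and then attaches every annotation layer:
#' cytogenetic band span, gene/exon overlap, probe detectability, terminal
#' target distances, batch and database frequencies, size class, and gene
#' dosage summaries (maximum HI score among lost genes / maximum TS score
#' among gained genes, disease and pseudogene flags).
#'
#' @param calls `cnv_calls` for one sample.
#' @param grid the [target_grid()].
#' @param tables an [read_annotation_tables()] result.
#' @param batch_calls calls for the whole batch (for batch frequency); NULL
#'   to skip.
#' @param batch_size batch sample count (defaults to the batch-call sample
#'   count, or 1).
#' @param ro_threshold reciprocal-overlap threshold for frequency matching.
#' @param merge merge fragmented calls first (default TRUE).
#' @return an `annotated_cnvs` data.frame: the call columns plus `size`,
#'   `size_class`, `cytoband`, `genes` (comma-separated "gene(n_exons)"
#'   text), `n_genes`, `any_whole_gene`, probe counts/flags, terminal
#'   distances, `batch_freq`, `db_freq`, `max_hi`, `max_ts`,
#'   `any_disease_gene`, `any_pseudogene`. The per-gene detail tables are
#'   kept in `attr(x, "gene_tables")`.
#' @export
annotate_calls <- function(calls, grid, tables, batch_calls = NULL,
                           batch_size = NULL, ro_threshold = 0.5,
                           merge = TRUE) {
  if (merge) calls <- merge_calls(calls, grid)
  n <- nrow(calls)
  ann <- calls
  ann$size <- ann$end - ann$start
  cols <- list(size_class = character(n), cytoband = character(n),
               genes = character(n), n_genes = integer(n),
               any_whole_gene = logical(n),
               probes_180k = integer(n), probes_1m = integer(n),
               probes_mlpa = integer(n),
               detectable_180k = logical(n), detectable_1m = logical(n),
               detectable_mlpa = logical(n),
               pter_targets = integer(n), qter_targets = integer(n),
               terminal = logical(n),
               batch_freq = numeric(n), db_freq = numeric(n),
               max_hi = numeric(n), max_ts = numeric(n),
               any_disease_gene = logical(n), any_pseudogene = logical(n))
  for (nm in names(cols)) ann[[nm]] <- cols[[nm]]
  if (is.null(batch_size)) {
    batch_size <- if (!is.null(batch_calls) && nrow(batch_calls) > 0L) {
      length(unique(batch_calls$sample))
    } else 1L
  }
  gene_tables <- vector("list", n)
  dosage <- tables$gene_dosage
  for (i in seq_len(n)) {
    cnv <- calls[i, ]
    ann$size_class[i] <- size_class(cnv)
    ann$cytoband[i] <- if (nrow(tables$cytobands) > 0L) {
      cytoband_span(cnv, tables$cytobands)
    } else NA_character_
    gt <- gene_overlap(cnv, tables$gene_model)
    gene_tables[[i]] <- gt
    coding <- gt[gt$n_exons > 0L, , drop = FALSE]
    ann$genes[i] <- paste(sprintf("%s(%d)", gt$gene, gt$n_exons),
                          collapse = ",")
    ann$n_genes[i] <- nrow(coding)
    ann$any_whole_gene[i] <- any(gt$whole_gene)
    pd <- probe_detectability(cnv, tables$probe_sets)
    ann$probes_180k[i] <- pd$counts[["aCGH180K"]]
    ann$probes_1m[i] <- pd$counts[["aCGH1M"]]
    ann$probes_mlpa[i] <- pd$counts[["MLPA"]]
    ann$detectable_180k[i] <- pd$detectable[["aCGH180K"]]
    ann$detectable_1m[i] <- pd$detectable[["aCGH1M"]]
    ann$detectable_mlpa[i] <- pd$detectable[["MLPA"]]
    td <- terminal_distance(cnv, grid)
    ann$pter_targets[i] <- td$pter_targets
    ann$qter_targets[i] <- td$qter_targets
    ann$terminal[i] <- td$terminal
    fr <- frequency_annotate(cnv, batch_calls, batch_size,
                             tables$inhouse_db, tables$popsv_db,
                             ro_threshold)
    ann$batch_freq[i] <- fr$batch_freq
    ann$db_freq[i] <- fr$db_freq
    if (nrow(coding) > 0L && nrow(dosage) > 0L) {
      d <- dosage[dosage$gene %in% coding$gene, , drop = FALSE]
      # ClinGen 30/40 are categorical codes, not evidence levels 0-3
      ev <- function(x) { x <- x[!is.na(x) & x <= 3]; if (length(x)) max(x) else 0 }
      ann$max_hi[i] <- ev(d$hi_score)
      ann$max_ts[i] <- ev(d$ts_score)
      ann$any_disease_gene[i] <- any(d$disease_flag, na.rm = TRUE)
      ann$any_pseudogene[i] <- any(d$pseudogene_flag, na.rm = TRUE)
    }
  }
  attr(ann, "gene_tables") <- gene_tables
  class(ann) <- c("annotated_cnvs", class(calls))
  ann
}
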