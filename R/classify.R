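#' Flag CNVs overlapping a clinical gene panel
#'
#' Diagnostic analysis is restricted to genes of the requested panel(s): a
#' CNV is in-panel when at least one overlapped gene with coding (exon)
#' overlap belongs to the panel. In `panel` mode out-of-panel CNVs are
#' dropped from the report; in `genome_wide` mode all CNVs are kept with
#' the flag set, so findings outside the original panel are not passed
#' over.
#'
#' @param cnvs an `annotated_cnvs` table (from [annotate_calls()]).
#' @param panel character vector of panel gene symbols.
#' @param mode "panel" (drop out-of-panel) or "genome_wide" (keep all).
#' @return the table with an `in_panel` column, filtered per `mode`.
#' @export
panel_filter <- function(cnvs, panel, mode = c("panel", "genome_wide")) {
  mode <- match.arg(mode)
  if (mode == "panel" && length(panel) == 0L) {
    stop("panel mode requires a non-empty gene panel", call. = FALSE)
  }
  gene_tables <- attr(cnvs, "gene_tables")
  in_panel <- vapply(seq_len(nrow(cnvs)), function(i) {
    gt <- gene_tables[[i]]
    any(gt$gene %in% panel & gt$n_exons >= 1L)
  }, logical(1))
  cnvs$in_panel <- in_panel
  if (mode == "panel") {
    keep <- which(in_panel)
    gene_tables <- gene_tables[keep]
    cnvs <- cnvs[keep, , drop = FALSE]
    attr(cnvs, "gene_tables") <- gene_tables
  }
  cnvs
}

#' Classify an annotated CNV
#'
#' A transparent five-rule cascade over the evidence classes used in
#' diagnostic CNV review — rarity, phenotype-matched dosage-sensitive
#' genes, and known pathogenic regions:
#' \describe{
#'   \item{R0}{batch or database frequency above `rarity_max` ->
#'     benign (polymorphic, seen in the control population).}
#'   \item{R1}{same-type reciprocal overlap with a known pathogenic region
#'     -> pathogenic.}
#'   \item{R2}{loss over a haploinsufficiency-3 gene (or gain over a
#'     triplosensitivity-3 gene) that is in the phenotype gene set ->
#'     pathogenic.}
#'   \item{R3}{loss/gain over a disease-associated phenotype gene without
#'     dosage-3 support -> likely_pathogenic.}
#'   \item{R4}{rare and gene-impacting but no phenotype match -> VUS.}
#' }
#' Anything else (rare but impacting no coding gene) is likely_benign.
#' Every fired rule is recorded so the classification is reproducible from
#' its evidence list.
#'
#' @param cnv one row of an `annotated_cnvs` table (with its per-gene table
#'   passed as `gene_table`, or taken from the parent attribute by
#'   [classify_calls()]).
#' @param gene_table per-gene overlap data.frame for this CNV.
#' @param gene_dosage dosage data.frame (NULL/empty skips R2/R3 with a
#'   warning, never silently upgrading).
#' @param rarity_max frequency above which a CNV is considered polymorphic
#'   (default 0.01).
#' @param phenotype_genes genes associated with the patient's phenotype.
#' @param known_regions data.frame (chrom, start, end, type) of regions
#'   harbouring similar reported pathogenic CNVs.
#' @param ro_threshold reciprocal overlap required for a known-region match.
#' @return list with `classification` and `evidence` (character vector of
#'   fired rules).
#' @export
classify_cnv <- function(cnv, gene_table, gene_dosage = NULL,
                         rarity_max = 0.01, phenotype_genes = character(),
                         known_regions = NULL, ro_threshold = 0.5) {
  evidence <- character()
  if (max(cnv$batch_freq, cnv$db_freq) > rarity_max) {
    return(list(classification = "benign",
                evidence = sprintf("R0: frequency %.3g exceeds %.3g (polymorphic, seen in the control population)",
                                   max(cnv$batch_freq, cnv$db_freq), rarity_max)))
  }
  evidence <- c(evidence, sprintf("rare: batch %.3g, database %.3g <= %.3g",
                                  cnv$batch_freq, cnv$db_freq, rarity_max))
  if (!is.null(known_regions) && nrow(known_regions) > 0L) {
    same <- known_regions$chrom == cnv$chrom & known_regions$type == cnv$type
    ro <- reciprocal_overlap(cnv$start, cnv$end, known_regions$start,
                             known_regions$end)
    if (any(same & ro >= ro_threshold)) {
      return(list(classification = "pathogenic",
                  evidence = c(evidence, "R1: matches a known pathogenic CNV region")))
    }
  }
  coding <- gene_table[gene_table$n_exons >= 1L, , drop = FALSE]
  pheno <- coding[coding$gene %in% phenotype_genes, , drop = FALSE]
  have_dosage <- !is.null(gene_dosage) && nrow(gene_dosage) > 0L
  if (!have_dosage && nrow(pheno) > 0L) {
    warning("no gene dosage table: dosage rule (R2) skipped", call. = FALSE)
  }
  if (have_dosage && nrow(pheno) > 0L) {
    d <- gene_dosage[gene_dosage$gene %in% pheno$gene, , drop = FALSE]
    score <- if (cnv$type == "loss") d$hi_score else d$ts_score
    hit <- !is.na(score) & score == 3
    if (any(hit)) {
      return(list(classification = "pathogenic",
                  evidence = c(evidence,
                               sprintf("R2: %s of dosage-sensitive phenotype gene(s) %s (score 3)",
                                       cnv$type, paste(d$gene[hit], collapse = ",")))))
    }
    disease <- !is.na(d$disease_flag) & d$disease_flag
    if (any(disease)) {
      return(list(classification = "likely_pathogenic",
                  evidence = c(evidence,
                               sprintf("R3: %s of disease-associated phenotype gene(s) %s without dosage-3 support",
                                       cnv$type, paste(d$gene[disease], collapse = ",")))))
    }
  }
  if (nrow(pheno) > 0L) {
    # phenotype-matched genes but no dosage table to grade them
    return(list(classification = "likely_pathogenic",
                evidence = c(evidence,
                             sprintf("R3: %s of phenotype gene(s) %s",
                                     cnv$type, paste(pheno$gene, collapse = ",")))))
  }
  if (nrow(coding) > 0L) {
    return(list(classification = "VUS",
                evidence = c(evidence,
                             "R4: rare and gene-impacting but does not match the phenotype")))
  }
  list(classification = "likely_benign",
       evidence = c(evidence, "no coding gene impacted"))
}

#' Classify every CNV of an annotated table
#'
#' @param cnvs an `annotated_cnvs` table (optionally after
#'   [panel_filter()]).
#' @param gene_dosage dosage data.frame.
#' @inheritParams classify_cnv
#' @return the table with `classification` and `evidence` (collapsed with
#'   "; ") columns appended.
#' @export
classify_calls <- function(cnvs, gene_dosage = NULL, rarity_max = 0.01,
                           phenotype_genes = character(),
                           known_regions = NULL, ro_threshold = 0.5) {
  gene_tables <- attr(cnvs, "gene_tables")
  n <- nrow(cnvs)
  cnvs$classification <- character(n)
  cnvs$evidence <- character(n)
  for (i in seq_len(n)) {
    res <- classify_cnv(cnvs[i, ], gene_tables[[i]], gene_dosage,
                        rarity_max, phenotype_genes, known_regions,
                        ro_threshold)
    cnvs$classification[i] <- res$classification
    cnvs$evidence[i] <- paste(res$evidence, collapse = "; ")
  }
  attr(cnvs, "gene_tables") <- gene_tables
  cnvs
}
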