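# Bundled study fixtures: the 18 diagnostic CNVs, the 3 missed cases, the
# 450-patient cohort marginals, the 24 microarray-VUS records, and toy
# annotation tables (cytobands, gene models, probe sets, panels, dosage,
# known regions, frequency databases) rich enough for the 18 CNVs to
# annotate and classify end to end. Everything is generated in code; the
# cohort rows are privacy-equivalent synthetic stand-ins consistent with
# the published per-category marginals, not real patients.

seqs <- function(from, by, n) from + by * (0:(n - 1L))

fixture_chrom_lengths <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr7 = 159138663,
    chr9 = 141213431, chr10 = 135534747, chr13 = 115169878,
    chr14 = 107349540, chr15 = 102531392, chr17 = 81195210,
    chr22 = 51304566, chrX = 155270560)
}

#' The 18 diagnostic CNVs of the bundled study fixture
#'
#' One primary CNV per case plus the two secondary events of cases 7 and
#' 13 (`primary = FALSE`). Coordinates are GRCh37, 0-based half-open, so
#' `end - start` is the CNV size; the printed size string is stored
#' alongside (case 3's printed ">4.4 Kb" is inconsistent with its
#' coordinates and is flagged via `size_consistent`).
#'
#' @return data.frame with case, phase, category, library, chrom, start,
#'   end, copy_number, size_printed, size_consistent, gene, exons,
#'   validation, primary columns.
#' @export
fixture_table1 <- function() {
  df <- data.frame(
    case = c(1:18, 7L, 13L),
    phase = c(rep(2L, 11L), rep(3L, 7L), 2L, 3L),
    category = c("NDD", "NDD", "blood_immune", "NDD", "renal", "NDD",
                 "neurodegeneration", "NDD", "neurodegeneration", "NDD",
                 "NDD", "hearing_loss", "neurodegeneration", "hearing_loss",
                 "metabolic", "NDD", "neurodegeneration", "NDD",
                 "neurodegeneration", "neurodegeneration"),
    library = c(rep("ES", 11L), "TsoE", "ES", "TsoE", "TsoE", "TsoE",
                "TsoE", "ES", "ES", "ES"),
    chrom = c("chr22", "chr15", "chr13", "chr14", "chrX", "chr2", "chr10",
              "chr22", "chr7", "chr17", "chr1", "chr15", "chr9", "chr3",
              "chrX", "chrX", "chr2", "chr15", "chr10", "chr9"),
    start = c(44489809, 23609491, 103298645, 99640489, 107224311,
              237028837, 125769666, 18834446, 92818581, 1082962,
              146461120, 43892159, 79827886, 69928286, 21958944,
              99551276, 32352018, 22742397, 133747956, 80018153),
    end = c(51220722, 28632839, 103301836, 106236323, 107979574,
            242815426, 128860040, 21414817, 94540820, 1657828,
            147416212, 43901532, 79828230, 69988332, 22151741,
            99663595, 32353548, 28772634, 135379033, 80018237),
    copy_number = c(1L, 3L, 0L, 3L, 0L, 1L, 3L, 1L, 1L, 3L, 3L, 1L, 1L,
                    1L, 1L, 1L, 1L, 4L, 1L, 1L),
    size_printed = c(">6.7 Mb", ">5 Mb", ">4.4 Kb", ">7 Mb", ">755 kb",
                     ">5 Mb", ">7 Mb", ">2.5 Mb", ">1.7 Mb", ">574 Kb",
                     ">955 Kb", ">9.4 Kb", ">344 bp", ">60 Kb", ">192 Kb",
                     ">112 Kb", ">1.53 Kb", ">6 Mb", "", ">84 bp"),
    gene = c("", "", "TPP2", "", "COL4A5", "", "", "", "SGCE", "", "",
             "STRC", "VPS13A", "MITF", "PHEX", "PCDH19", "SPAST", "",
             "", "VPS13A"),
    exons = c("", "", "20-22", "", "", "", "", "", "", "", "", "16-28",
              "8-9", "1-3", "whole", "whole", "8-9", "", "", "69"),
    validation = c("aCGH180k", "aCGH180k", "WGS", "aCGH180k", "aCGH180k",
                   "aCGH180k", "aCGH180k", "aCGH180k", "aCGH180k",
                   "aCGH180k", "aCGH180k", "MLPA", "Sanger", "aCGH1M",
                   "aCGH180k", "MLPA", "MLPA", "aCGH180k", "aCGH180k",
                   "Sanger"),
    primary = c(rep(TRUE, 18L), FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  df$size_consistent <- df$case != 3L
  df
}

#' The 3 pathogenic CNVs missed by the sequencing pipeline
#' @return data.frame with case, category, gene, acgh coordinates and the
#'   reason each CNV was missed.
#' @export
fixture_table2 <- function() {
  data.frame(
    case = 19:21, phase = 2L, category = "NDD", library = "ES",
    ngs_chrom = c("", "chr13", "chr14"),
    ngs_start = c(NA, 35615071, 105814831),
    ngs_end = c(NA, 35697711, 106370569),
    acgh_chrom = c("chr17", "chr13", "chr14"),
    acgh_start = c(2433963, 35522735, 105807673),
    acgh_end = c(2548152, 35696113, 107278770),
    copy_number = 1L,
    gene = c("PAFAH1B1", "NBEA", "PACS2"),
    reason = c("low_coverage_first_exons", "gene_not_in_panel",
               "gene_not_in_panel"),
    stringsAsFactors = FALSE
  )
}

fixture_cytobands <- function() {
  band <- function(chrom, start, end, name) {
    data.frame(chrom = chrom, start = start, end = end, band = name,
               stain = "gneg", stringsAsFactors = FALSE)
  }
  L <- fixture_chrom_lengths()
  rbind(
    band("chr1", c(0, 28e6, 121.5e6, 142.6e6, 147.5e6, 150.3e6),
         c(28e6, 121.5e6, 142.6e6, 147.5e6, 150.3e6, L[["chr1"]]),
         c("p36.3", "p22", "q12", "q21.1", "q21.2", "q22")),
    band("chr2", c(0, 30e6, 36.6e6, 93.3e6, 236.4e6, 239.5e6),
         c(30e6, 36.6e6, 93.3e6, 236.4e6, 239.5e6, L[["chr2"]]),
         c("p25", "p22.3", "p21", "q21", "q37.2", "q37.3")),
    band("chr3", c(0, 69.7e6, 74.1e6, 90.5e6),
         c(69.7e6, 74.1e6, 90.5e6, L[["chr3"]]),
         c("p14", "p13", "p12", "q21")),
    band("chr7", c(0, 60e6, 92.2e6, 93.8e6, 98e6),
         c(60e6, 92.2e6, 93.8e6, 98e6, L[["chr7"]]),
         c("p21", "q11", "q21.2", "q21.3", "q22")),
    band("chr9", c(0, 49e6, 79e6, 81e6),
         c(49e6, 79e6, 81e6, L[["chr9"]]),
         c("p11", "q11", "q21.2", "q22")),
    band("chr10", c(0, 40e6, 125.7e6, 128.7e6, 130.6e6),
         c(40e6, 125.7e6, 128.7e6, 130.6e6, L[["chr10"]]),
         c("p11", "q21", "q26.13", "q26.2", "q26.3")),
    band("chr13", c(0, 19e6, 100e6, 105e6),
         c(19e6, 100e6, 105e6, L[["chr13"]]),
         c("p11", "q21", "q33.1", "q34")),
    band("chr14", c(0, 19.1e6, 100.4e6, 102.6e6, 104e6),
         c(19.1e6, 100.4e6, 102.6e6, 104e6, L[["chr14"]]),
         c("p11", "q31", "q32.2", "q32.31", "q32.33")),
    band("chr15", c(0, 20e6, 25.5e6, 27.2e6, 30e6, 42e6, 45e6),
         c(20e6, 25.5e6, 27.2e6, 30e6, 42e6, 45e6, L[["chr15"]]),
         c("p11", "q11.2", "q12", "q13.1", "q14", "q15.3", "q21")),
    band("chr17", c(0, 2.5e6, 3.3e6, 24e6),
         c(2.5e6, 3.3e6, 24e6, L[["chr17"]]),
         c("p13.3", "p13.2", "p11", "q21")),
    band("chr22", c(0, 14.7e6, 17.9e6, 22.2e6, 35.2e6, 44.2e6, 48.1e6,
                    49.8e6),
         c(14.7e6, 17.9e6, 22.2e6, 35.2e6, 44.2e6, 48.1e6, 49.8e6,
           L[["chr22"]]),
         c("p11", "q11.1", "q11.21", "q12", "q13.1", "q13.31", "q13.32",
           "q13.33")),
    band("chrX", c(0, 10.6e6, 16.8e6, 21.9e6, 24.3e6, 37.6e6, 60.6e6,
                   99.1e6, 103e6, 108.7e6),
         c(10.6e6, 16.8e6, 21.9e6, 24.3e6, 37.6e6, 60.6e6, 99.1e6, 103e6,
           108.7e6, L[["chrX"]]),
         c("p22.3", "p22.2", "p22.12", "p22.11", "p21", "p11", "q21",
           "q22.1", "q22.3", "q23"))
  )
}

fixture_genes <- function() {
  mk <- function(chrom, starts, ends = starts + 150) {
    data.frame(chrom = chrom, start = starts, end = ends,
               exon_index = seq_along(starts), strand = "+",
               stringsAsFactors = FALSE)
  }
  vps_starts <- c(seqs(79792000, 5000, 7), 79827900, 79828100,
                  seqs(79830000, 3000, 59), 80018160, 80020000)
  vps_ends <- vps_starts + 150
  vps_ends[8L] <- 79827990; vps_ends[9L] <- 79828200; vps_ends[69L] <- 80018230
  list(
    SHANK3 = mk("chr22", seqs(50674000, 6000, 10), seqs(50674000, 6000, 10) + 200),
    TPP2 = mk("chr13", c(seqs(103279000, 1030, 19), 103298700, 103299700,
                         103300700, 103302000, 103303000, 103304000)),
    VPS13A = mk("chr9", vps_starts, vps_ends),
    STRC = mk("chr15", c(seqs(43880000, 700, 15), seqs(43892200, 700, 13))),
    MITF = mk("chr3", c(69928400, 69950000, 69980000, seqs(69990000, 1000, 6))),
    PHEX = mk("chrX", seqs(21960000, 8000, 22)),
    PCDH19 = mk("chrX", seqs(99560000, 15000, 6)),
    SPAST = mk("chr2", c(seqs(32288000, 8000, 7), 32352100, 32353200,
                         seqs(32356000, 2000, 8))),
    SGCE = mk("chr7", seqs(94214000, 2000, 12)),
    COL4A5 = mk("chrX", seqs(107683000, 5000, 20)),
    HDAC4 = mk("chr2", seqs(239969000, 3000, 10)),
    TBX1 = mk("chr22", seqs(19744000, 1500, 8)),
    PAFAH1B1 = mk("chr17", seqs(2440000, 10000, 11)),
    NBEA = mk("chr13", seqs(35616000, 8000, 10)),
    PACS2 = mk("chr14", seqs(105830000, 10000, 5))
  )
}

write_refflat <- function(genes, path) {
  rows <- vapply(names(genes), function(g) {
    ex <- genes[[g]]
    paste(g, paste0("NM_", g), ex$chrom[1L], ex$strand[1L],
          min(ex$start), max(ex$end), min(ex$start), max(ex$end),
          nrow(ex), paste0(paste(ex$start, collapse = ","), ","),
          paste0(paste(ex$end, collapse = ","), ","), sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Build the fixture capture-target grid
#'
#' Targets are the union of every fixture gene exon and a backbone of one
#' 150 bp target per megabase on each fixture chromosome, so that terminal
#' target distances and probe/merging arithmetic behave like a (sparse)
#' exome design.
#'
#' @return a [target_grid()].
#' @export
fixture_grid <- function() {
  genes <- fixture_genes()
  ex <- do.call(rbind, lapply(names(genes), function(g) {
    data.frame(chrom = genes[[g]]$chrom, start = genes[[g]]$start,
               end = genes[[g]]$end, gene = g,
               exon_index = genes[[g]]$exon_index, stringsAsFactors = FALSE)
  }))
  L <- fixture_chrom_lengths()
  bb <- do.call(rbind, lapply(names(L), function(ch) {
    starts <- seq(500000, L[[ch]] - 200, by = 1000000)
    data.frame(chrom = ch, start = starts, end = starts + 150, gene = "",
               exon_index = NA_integer_, stringsAsFactors = FALSE)
  }))
  all <- rbind(ex, bb)
  target_grid(all$chrom, all$start, all$end, all$gene, all$exon_index)
}

fixture_probes <- function() {
  t1 <- fixture_table1()
  # 180K probes tile every case region (+/-50 kb) at the platform's 13 kb
  # median spacing; small CNVs naturally trap fewer than 3 probes
  tile <- function(rows, spacing, margin) {
    do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      starts <- seq(r$start - margin + spacing / 2, r$end + margin,
                    by = spacing)
      data.frame(chrom = r$chrom, start = round(starts),
                 end = round(starts) + 60, stringsAsFactors = FALSE)
    }))
  }
  p180 <- tile(t1, 13000, 50000)
  # 1M probes (2.6 kb spacing) around the gene-size and small cases;
  # the STRC region is excluded: its pseudogene leaves one usable probe
  small <- t1[t1$primary & t1$case %in% c(3, 13, 14, 15, 16, 17), ]
  p1m <- tile(small, 2600, 20000)
  strc <- t1[t1$case == 12 & t1$primary, ]
  p1m <- rbind(p1m, data.frame(chrom = strc$chrom,
                               start = strc$start + 2000,
                               end = strc$start + 2060))
  genes <- fixture_genes()
  mlpa_at <- function(g, idx) {
    ex <- genes[[g]]
    data.frame(chrom = ex$chrom[1L], start = ex$start[idx] + 20,
               end = ex$start[idx] + 80, stringsAsFactors = FALSE)
  }
  mlpa <- rbind(mlpa_at("STRC", c(18L, 24L)),
                mlpa_at("PCDH19", 1:6),
                mlpa_at("SPAST", c(8L, 9L)))
  list(aCGH180K = p180, aCGH1M = p1m, MLPA = mlpa)
}

fixture_panels <- function() {
  list(NDD = c("SHANK3", "HDAC4", "TBX1", "PCDH19", "PAFAH1B1"),
       hearing_loss = c("STRC", "MITF"),
       neurodegeneration = c("SGCE", "VPS13A", "SPAST"),
       renal = "COL4A5", metabolic = "PHEX", blood_immune = "TPP2")
}

fixture_dosage <- function() {
  genes <- c("SHANK3", "TPP2", "VPS13A", "STRC", "MITF", "PHEX", "PCDH19",
             "SPAST", "SGCE", "COL4A5", "HDAC4", "TBX1", "PAFAH1B1",
             "NBEA", "PACS2")
  data.frame(gene = genes, hi_score = 3, ts_score = 0,
             domino = 0.9, disease_flag = TRUE,
             pseudogene_flag = genes == "STRC", stringsAsFactors = FALSE)
}

fixture_known_regions <- function() {
  data.frame(
    chrom = c("chr15", "chr14", "chr10", "chr17", "chr1"),
    start = c(23000000, 99600000, 125700000, 1000000, 146400000),
    end = c(28600000, 106300000, 128900000, 1700000, 147500000),
    type = "gain",
    name = c("15q11q13 duplication", "14q32 distal duplication",
             "10q26 duplication", "17p13.3 microduplication",
             "1q21.1 microduplication"),
    stringsAsFactors = FALSE
  )
}

fixture_freq_dbs <- function() {
  list(
    inhouse = data.frame(chrom = "chr22", start = 24000000, end = 24050000,
                         type = "loss", freq = 0.25, stringsAsFactors = FALSE),
    popsv = data.frame(chrom = "chr1", start = 10000000, end = 10100000,
                       type = "gain", freq = 0.12, stringsAsFactors = FALSE)
  )
}

#' Synthetic 450-patient cohort consistent with the study marginals
#'
#' Patient-level rows are synthesized so that every per-category patient
#' count and positive count, the overall 162/450 positives, the 18
#' CNV-diagnosed patients (one of them positive for both an SNV and a CNV),
#' the 55/3 SNV/CNV VUS split, and the 87/15/18 microarray-timing counts
#' hold exactly. The 18 CNV-diagnosed patients carry the disease
#' categories of the corresponding fixture cases, three of them with two
#' categories (which is what reconciles 21 per-category CNV positives with
#' 18 patients).
#'
#' @return cohort data.frame (patient_id, categories as comma-separated
#'   text, outcome, acgh_status).
#' @export
fixture_cohort <- function() {
  rows <- list()
  add <- function(cats, outcome, acgh = "none", n = 1L) {
    for (k in seq_len(n)) {
      rows[[length(rows) + 1L]] <<- list(cats = cats, outcome = outcome,
                                         acgh = acgh)
    }
  }
  # the 18 CNV-diagnosed patients (fixture cases 1-18); cases 3, 4, 5 are
  # dual-category per their clinical descriptions
  t1 <- fixture_table1()
  t1 <- t1[t1$primary, ]
  dual <- list(`3` = c("blood_immune", "NDD"), `4` = c("NDD", "renal"),
               `5` = c("renal", "NDD"))
  for (i in seq_len(nrow(t1))) {
    cats <- dual[[as.character(t1$case[i])]] %||% t1$category[i]
    outcome <- if (t1$case[i] == 12L) "positive_both" else "positive_cnv"
    acgh <- if (i <= 15L) "validation" else "none"
    add(cats, outcome, acgh)
  }
  # SNV-diagnosed patients, single category
  snv_pos <- c(NDD = 77L, neurodegeneration = 13L, renal = 12L, heart = 13L,
               connective = 6L, vision = 12L, hearing_loss = 4L,
               metabolic = 2L, neuromuscular = 4L, mitochondrial = 1L)
  for (cat in names(snv_pos)) add(cat, "positive_snv", n = snv_pos[[cat]])
  # non-positive patients: 11 triples and 20 doubles absorb the extra
  # category slots, the rest are singles
  add(c("NDD", "neurodegeneration", "renal"), "negative", n = 11L)
  add(c("NDD", "diverse"), "negative", n = 20L)
  singles <- c(NDD = 108L, neurodegeneration = 35L, renal = 15L, heart = 22L,
               connective = 14L, vision = 7L, hearing_loss = 11L,
               neuromuscular = 10L, mitochondrial = 11L, blood_immune = 10L,
               metabolic = 7L, pulmonary_fibrosis = 7L)
  vus_left <- list(cnv = 3L, snv = 55L)
  for (cat in names(singles)) {
    for (k in seq_len(singles[[cat]])) {
      outcome <- if (vus_left$cnv > 0L) { vus_left$cnv <- vus_left$cnv - 1L; "vus_cnv" }
      else if (vus_left$snv > 0L) { vus_left$snv <- vus_left$snv - 1L; "vus_snv" }
      else "negative"
      add(cat, outcome)
    }
  }
  df <- data.frame(
    patient_id = sprintf("P%03d", seq_along(rows)),
    categories = vapply(rows, function(r) paste(r$cats, collapse = ","), ""),
    outcome = vapply(rows, function(r) r$outcome, ""),
    acgh_status = vapply(rows, function(r) r$acgh, ""),
    stringsAsFactors = FALSE
  )
  # microarray timing: 15 validations already set on CNV patients; 87
  # before-NGS and 18 after-NGS assigned to the later (non-positive) rows
  none_idx <- which(df$acgh_status == "none")
  neg_idx <- none_idx[df$outcome[none_idx] == "negative"]
  df$acgh_status[utils::tail(neg_idx, 18L)] <- "after_ngs"
  still_none <- which(df$acgh_status == "none")
  df$acgh_status[utils::head(still_none, 87L)] <- "before_ngs"
  df
}

#' The 24 microarray-VUS CNV records
#'
#' 20 fall in regions with capture targets (one of them a polymorphic
#' duplication seen in the batch and the control population), 4 in regions
#' without any target; the sequencing pipeline therefore re-detects 19.
#'
#' @return data.frame with patient_id, has_ngs_targets,
#'   polymorphic_in_batch, acgh_timing.
#' @export
fixture_acgh_vus <- function() {
  data.frame(
    patient_id = sprintf("A%02d", 1:24),
    has_ngs_targets = c(rep(TRUE, 20L), rep(FALSE, 4L)),
    polymorphic_in_batch = c(rep(FALSE, 19L), TRUE, rep(FALSE, 4L)),
    acgh_timing = c(rep("before_ngs", 22L), rep("after_ngs", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Turn fixture CNV coordinate rows into a call table
#'
#' Maps genomic intervals onto a grid (first/last overlapping target) and
#' fills the call columns the downstream stages expect: type from copy
#' number, depth ratio at the constitutive value c/2, a quality well above
#' threshold.
#'
#' @param regions data.frame with chrom, start, end, copy_number and
#'   optionally sample.
#' @param grid a [target_grid()].
#' @return a `cnv_calls` data.frame.
#' @export
calls_from_regions <- function(regions, grid) {
  out <- empty_calls()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    sel <- grid$chrom == r$chrom & grid$start < r$end & grid$end > r$start
    if (!any(sel)) {
      stop(sprintf("region %s:%g-%g overlaps no grid target", r$chrom,
                   r$start, r$end), call. = FALSE)
    }
    ids <- grid$target_id[sel]
    out <- rbind(out, data.frame(
      sample = if ("sample" %in% names(regions)) r$sample else sprintf("case%02d", i),
      chrom = r$chrom, first_target = min(ids), last_target = max(ids),
      start = r$start, end = r$end,
      type = if (r$copy_number < 2L) "loss" else "gain",
      copy_number = as.integer(r$copy_number), n_targets = sum(sel),
      mean_ratio = max(r$copy_number, 0.02) / 2, quality = 50,
      mosaic_fraction = NA_real_, stringsAsFactors = FALSE))
  }
  class(out) <- c("cnv_calls", "data.frame")
  out
}

#' Write every bundled fixture to a directory
#'
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
make_paper_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  tsv <- function(df, f) {
    write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
    p(f)
  }
  bed <- function(df, f) {
    write.table(data.frame(df$chrom,
                           format(df$start, scientific = FALSE, trim = TRUE),
                           format(df$end, scientific = FALSE, trim = TRUE)),
                p(f), sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    p(f)
  }
  probes <- fixture_probes()
  bands <- fixture_cytobands()
  write.table(data.frame(bands$chrom,
                         format(bands$start, scientific = FALSE, trim = TRUE),
                         format(bands$end, scientific = FALSE, trim = TRUE),
                         bands$band, bands$stain),
              p("cytobands.txt"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  panels <- fixture_panels()
  panel_df <- data.frame(panel = rep(names(panels), lengths(panels)),
                         gene = unlist(panels), row.names = NULL,
                         stringsAsFactors = FALSE)
  dbs <- fixture_freq_dbs()
  paths <- c(
    table1_cnvs = tsv(fixture_table1(), "table1_cnvs.tsv"),
    table2_missed = tsv(fixture_table2(), "table2_missed.tsv"),
    cohort = tsv(fixture_cohort(), "cohort.tsv"),
    acgh_vus = tsv(fixture_acgh_vus(), "acgh_vus.tsv"),
    cytobands = p("cytobands.txt"),
    genes = write_refflat(fixture_genes(), p("genes_refflat.txt")),
    targets = write_targets(fixture_grid(), p("targets.bed")),
    probes_180k = bed(probes$aCGH180K, "probes_acgh180k.bed"),
    probes_1m = bed(probes$aCGH1M, "probes_acgh1m.bed"),
    probes_mlpa = bed(probes$MLPA, "probes_mlpa.bed"),
    panels = tsv(panel_df, "panels.tsv"),
    gene_dosage = tsv(fixture_dosage(), "gene_dosage.tsv"),
    known_regions = tsv(fixture_known_regions(), "known_regions.tsv"),
    inhouse_db = tsv(dbs$inhouse, "inhouse_db.tsv"),
    popsv_db = tsv(dbs$popsv, "popsv_db.tsv")
  )
  invisible(paths)
}
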