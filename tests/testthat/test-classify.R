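annotated_one <- function(batch_freq = 0, db_freq = 0, type = "loss",
                          chrom = "chr1", start = 10000, end = 20000,
                          genes = data.frame(gene = "G1", n_exons = 3L,
                                             whole_gene = FALSE,
                                             intronic_only = FALSE)) {
  cnv <- one_call(chrom = chrom, start = start, end = end,
                  copy_number = if (type == "loss") 1L else 3L)
  cnv$type <- type
  cnv$batch_freq <- batch_freq
  cnv$db_freq <- db_freq
  attr(cnv, "gene_tables") <- list(genes)
  class(cnv) <- c("annotated_cnvs", class(cnv))
  cnv
}

dosage3 <- data.frame(gene = "G1", hi_score = 3, ts_score = 3, domino = 0.9,
                      disease_flag = TRUE, pseudogene_flag = FALSE)

test_that("the rule cascade orders rarity, known regions, dosage, phenotype", {
  # R0: common variant is benign regardless of gene content
  common <- annotated_one(db_freq = 0.2)
  r0 <- classify_cnv(common, attr(common, "gene_tables")[[1]], dosage3,
                     phenotype_genes = "G1")
  expect_equal(r0$classification, "benign")
  expect_match(r0$evidence[1], "polymorphic")
  # R1: known pathogenic region
  rare <- annotated_one(type = "gain")
  kr <- data.frame(chrom = "chr1", start = 9000, end = 21000, type = "gain")
  r1 <- classify_cnv(rare, attr(rare, "gene_tables")[[1]], dosage3,
                     known_regions = kr)
  expect_equal(r1$classification, "pathogenic")
  # R2: dosage-sensitive phenotype gene
  loss <- annotated_one()
  r2 <- classify_cnv(loss, attr(loss, "gene_tables")[[1]], dosage3,
                     phenotype_genes = "G1")
  expect_equal(r2$classification, "pathogenic")
  expect_true(any(grepl("R2", r2$evidence)))
  # R3: disease gene without dosage-3 support
  weak <- data.frame(gene = "G1", hi_score = 1, ts_score = 0, domino = 0.5,
                     disease_flag = TRUE, pseudogene_flag = FALSE)
  r3 <- classify_cnv(loss, attr(loss, "gene_tables")[[1]], weak,
                     phenotype_genes = "G1")
  expect_equal(r3$classification, "likely_pathogenic")
  # R4: rare, gene-impacting, no phenotype match
  r4 <- classify_cnv(loss, attr(loss, "gene_tables")[[1]], dosage3,
                     phenotype_genes = "OTHER")
  expect_equal(r4$classification, "VUS")
  # no coding impact at all
  none <- annotated_one(genes = data.frame(gene = character(),
                                           n_exons = integer(),
                                           whole_gene = logical(),
                                           intronic_only = logical()))
  r5 <- classify_cnv(none, attr(none, "gene_tables")[[1]], dosage3)
  expect_equal(r5$classification, "likely_benign")
  # missing dosage table warns rather than silently upgrading
  expect_warning(
    rw <- classify_cnv(loss, attr(loss, "gene_tables")[[1]], NULL,
                       phenotype_genes = "G1"),
    "dosage")
  expect_equal(rw$classification, "likely_pathogenic")
})

test_that("classification is monotone in rarity and phenotype gene sets", {
  ranks <- c(benign = 1, likely_benign = 2, VUS = 3, likely_pathogenic = 4,
             pathogenic = 5)
  gt <- data.frame(gene = "G1", n_exons = 2L, whole_gene = FALSE,
                   intronic_only = FALSE)
  for (freq in c(0.2, 0.009, 0.001, 0)) {
    lower <- annotated_one(db_freq = freq)
    cls_small <- classify_cnv(annotated_one(db_freq = 0), gt, dosage3,
                              phenotype_genes = "G1")$classification
    cls_this <- classify_cnv(lower, gt, dosage3,
                             phenotype_genes = "G1")$classification
    expect_gte(ranks[[cls_small]], ranks[[cls_this]])
  }
  without <- classify_cnv(annotated_one(), gt, dosage3,
                          phenotype_genes = character())$classification
  with_gene <- classify_cnv(annotated_one(), gt, dosage3,
                            phenotype_genes = "G1")$classification
  expect_gte(ranks[[with_gene]], ranks[[without]])
})

test_that("panel filtering keeps in-panel CNVs and respects genome-wide mode", {
  fb <- fixture_bundle()
  t2 <- fixture_table2()
  nbea <- t2[t2$gene == "NBEA", ]
  calls <- calls_from_regions(data.frame(chrom = nbea$ngs_chrom,
                                         start = nbea$ngs_start,
                                         end = nbea$ngs_end,
                                         copy_number = 1L), fb$grid)
  ann <- annotate_calls(calls, fb$grid, fb$tables, merge = FALSE)
  ndd_panel <- fb$tables$panels$NDD  # the original panel lacked NBEA
  expect_false("NBEA" %in% ndd_panel)
  dropped <- panel_filter(ann, ndd_panel, "panel")
  expect_equal(nrow(dropped), 0)
  kept <- panel_filter(ann, ndd_panel, "genome_wide")
  expect_equal(nrow(kept), 1)
  expect_false(kept$in_panel)
  # opened to all coding genes, the CNV classifies from its dosage evidence
  cls <- classify_calls(kept, fb$tables$gene_dosage,
                        phenotype_genes = c(ndd_panel, "NBEA"))
  expect_equal(cls$classification, "pathogenic")
  expect_error(panel_filter(ann, character(), "panel"), "non-empty")
})

test_that("intronic-only overlap of a panel gene does not count as in-panel", {
  fb <- fixture_bundle()
  # a strictly intronic PHEX interval (between exons 2 and 3, no target)
  intronic <- one_call(chrom = "chrX", start = 21970000, end = 21975000,
                       copy_number = 1L, first_target = 20L,
                       last_target = 20L)
  ann <- annotate_calls(intronic, fb$grid, fb$tables, merge = FALSE)
  out <- panel_filter(ann, "PHEX", "genome_wide")
  expect_false(out$in_panel)
})

test_that("the 18 fixture CNVs all classify as (likely) pathogenic", {
  fb <- fixture_bundle()
  t1 <- fixture_table1()
  t1 <- t1[t1$primary, ]
  t1$sample <- sprintf("case%02d", t1$case)
  calls <- calls_from_regions(t1, fb$grid)
  ann <- annotate_calls(calls, fb$grid, fb$tables, merge = FALSE)
  kr <- read.delim(fb$paths[["known_regions"]], stringsAsFactors = FALSE)
  panels <- fb$tables$panels
  cls <- vapply(seq_len(nrow(ann)), function(i) {
    classify_cnv(ann[i, ], attr(ann, "gene_tables")[[i]],
                 fb$tables$gene_dosage, rarity_max = 0.01,
                 phenotype_genes = panels[[t1$category[i]]],
                 known_regions = kr)$classification
  }, character(1))
  expect_true(all(cls %in% c("pathogenic", "likely_pathogenic")))
  # evidence reproduces the classification (audit property)
  res <- classify_cnv(ann[1, ], attr(ann, "gene_tables")[[1]],
                      fb$tables$gene_dosage, rarity_max = 0.01,
                      phenotype_genes = panels$NDD, known_regions = kr)
  expect_true(any(grepl("R2", res$evidence)))
  expect_true(any(grepl("rare", res$evidence)))
})
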