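grid20 <- tiny_grid(20)

call_on_targets <- function(first, last, copy_number = 1L, grid = grid20,
                            sample = "S01") {
  one_call(chrom = grid$chrom[1], start = grid$start[grid$target_id == first],
           end = grid$end[grid$target_id == last], copy_number = copy_number,
           first_target = first, last_target = last, sample = sample)
}

test_that("calls merge below the 3-target gap and with matching type and ploidy", {
  near <- rbind(call_on_targets(0, 2), call_on_targets(5, 7))   # gap 2
  merged <- merge_calls(near, grid20)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$first_target, 0L)
  expect_equal(merged$last_target, 7L)
  expect_equal(merged$n_targets, 6L)

  apart <- rbind(call_on_targets(0, 2), call_on_targets(6, 8))  # gap 3
  expect_equal(nrow(merge_calls(apart, grid20)), 2)

  mixed <- rbind(call_on_targets(0, 2, 1L), call_on_targets(4, 6, 3L))
  expect_equal(nrow(merge_calls(mixed, grid20)), 2)
  ploidy <- rbind(call_on_targets(0, 2, 0L), call_on_targets(4, 6, 1L))
  expect_equal(nrow(merge_calls(ploidy, grid20)), 2)
})

test_that("merging is idempotent, order-invariant, and chains to a fixpoint", {
  three <- rbind(call_on_targets(0, 1), call_on_targets(4, 5),
                 call_on_targets(8, 9))
  once <- merge_calls(three, grid20)
  expect_equal(nrow(once), 1)
  expect_equal(once$last_target, 9L)
  expect_equal(merge_calls(once, grid20), once)
  shuffled <- merge_calls(three[c(3, 1, 2), ], grid20)
  expect_equal(shuffled, once)
  # merged quality is the max, ratio the n_targets-weighted mean
  a <- call_on_targets(0, 1); a$quality <- 5; a$mean_ratio <- 0.4
  b <- call_on_targets(4, 7); b$quality <- 9; b$mean_ratio <- 0.55
  m <- merge_calls(rbind(a, b), grid20)
  expect_equal(m$quality, 9)
  expect_equal(m$mean_ratio, (2 * 0.4 + 4 * 0.55) / 6)
  # overlapping fragments of different ploidy are an upstream bug
  bad <- rbind(call_on_targets(0, 5, 1L), call_on_targets(3, 8, 0L))
  expect_error(merge_calls(bad, grid20), "ploidy")
})

test_that("cytoband spans render first and last band, single band collapses", {
  fb <- fixture_bundle()
  bands <- fb$tables$cytobands
  span <- cytoband_span(list(chrom = "chr22", start = 44489809,
                             end = 51220722), bands)
  expect_equal(span, "22q13.31q13.33")
  expect_equal(cytoband_span(list(chrom = "chr3", start = 69928286,
                                  end = 69988332), bands), "3p13")
  # a CNV exactly matching one band's interval reports that band
  expect_equal(cytoband_span(list(chrom = "chr22", start = 48.1e6,
                                  end = 49.8e6), bands), "22q13.32")
  expect_error(cytoband_span(list(chrom = "chrM", start = 0, end = 100),
                             bands), "cytoband")
})

test_that("gene overlap counts exons, flags whole genes and intronic-only hits", {
  fb <- fixture_bundle()
  gm <- fb$tables$gene_model
  vps <- gene_overlap(list(chrom = "chr9", start = 79827886, end = 79828230), gm)
  expect_equal(vps$gene, "VPS13A")
  expect_equal(vps$n_exons, 2L)
  expect_false(vps$whole_gene)
  pcdh <- gene_overlap(list(chrom = "chrX", start = 99551276, end = 99663595), gm)
  expect_true(pcdh$whole_gene[pcdh$gene == "PCDH19"])
  # strictly intronic interval: inside the gene body, touching no exon
  intr <- gene_overlap(list(chrom = "chrX", start = 21970000, end = 21975000), gm)
  expect_equal(intr$n_exons, 0L)
  expect_true(intr$intronic_only)
})

test_that("probe detectability uses the 3-probe aCGH and 2-probe MLPA minima", {
  mk_probes <- function(n, start = 1000, by = 500) {
    starts <- start + by * (seq_len(n) - 1)
    GenomicRanges::GRanges(rep("chr1", n),
                           IRanges::IRanges(starts + 1, starts + 60))
  }
  cnv <- list(chrom = "chr1", start = 900, end = 3000)
  for (n in 0:4) {
    sets <- list(aCGH180K = mk_probes(n), aCGH1M = mk_probes(n),
                 MLPA = mk_probes(n))
    pd <- probe_detectability(cnv, sets)
    expect_equal(unname(pd$counts[["aCGH180K"]]), n)
    expect_equal(unname(pd$detectable[["aCGH180K"]]), n >= 3)
    expect_equal(unname(pd$detectable[["aCGH1M"]]), n >= 3)
    expect_equal(unname(pd$detectable[["MLPA"]]), n >= 2)
  }
  # monotone: adding probes never loses detectability
  pd2 <- probe_detectability(cnv, list(aCGH180K = mk_probes(3)))
  pd3 <- probe_detectability(cnv, list(aCGH180K = mk_probes(6)))
  expect_true(pd3$detectable[["aCGH180K"]] >= pd2$detectable[["aCGH180K"]])
  # empty set: count 0, not detectable
  pd0 <- probe_detectability(cnv, list())
  expect_equal(sum(pd0$counts), 0)
  expect_false(any(pd0$detectable))
})

test_that("terminal distances count flanking targets and flag termini", {
  grid <- tiny_grid(100)
  mid <- terminal_distance(list(chrom = "chr1", first_target = 40L,
                                last_target = 49L), grid)
  expect_equal(mid$pter_targets, 40L)
  expect_equal(mid$qter_targets, 50L)
  expect_false(mid$terminal)
  last <- terminal_distance(list(chrom = "chr1", first_target = 99L,
                                 last_target = 99L), grid)
  expect_equal(last$qter_targets, 0L)
  expect_true(last$terminal)
  first <- terminal_distance(list(chrom = "chr1", first_target = 0L,
                                  last_target = 3L), grid)
  expect_equal(first$pter_targets, 0L)
  expect_true(first$terminal)
})

test_that("frequency matching needs same type and 50% reciprocal overlap", {
  cnv <- list(chrom = "chr1", start = 10000, end = 20000, type = "loss")
  batch <- rbind(one_call(start = 10000, end = 20000, sample = "S02"),
                 one_call(start = 10500, end = 19500, sample = "S07"))
  fr <- frequency_annotate(cnv, batch, batch_size = 32)
  expect_equal(fr$batch_freq, 2 / 32)
  # exact-coordinate population record
  pop <- data.frame(chrom = "chr1", start = 10000, end = 20000,
                    type = "loss", freq = 0.12)
  expect_equal(frequency_annotate(cnv, NULL, 32, popsv_db = pop)$db_freq, 0.12)
  # 30% reciprocal overlap is no match (independent arithmetic: 3kb shared
  # of 10kb each)
  pop30 <- data.frame(chrom = "chr1", start = 17000, end = 27000,
                      type = "loss", freq = 0.4)
  expect_equal(frequency_annotate(cnv, NULL, 32, popsv_db = pop30)$db_freq, 0)
  # type mismatch never matches
  gaindb <- data.frame(chrom = "chr1", start = 10000, end = 20000,
                       type = "gain", freq = 0.4)
  expect_equal(frequency_annotate(cnv, NULL, 32, popsv_db = gaindb)$db_freq, 0)
})

test_that("size classes split at 5 kb and 400 kb", {
  expect_equal(size_class(6730913), "large")
  expect_equal(size_class(1530), "exon_level")
  expect_equal(size_class(9373), "gene_size")
  expect_equal(size_class(400000), "gene_size")   # boundary: strictly larger
  expect_equal(size_class(5000), "gene_size")     # boundary: strictly smaller
  expect_equal(size_class(list(start = 100, end = 500100)), "large")
})

test_that("cytoband span is invariant under call merging", {
  fb <- fixture_bundle()
  grid <- fb$grid
  chr22 <- grid[grid$chrom == "chr22", ]
  a <- one_call(chrom = "chr22", start = chr22$start[chr22$target_id == 30],
                end = chr22$end[chr22$target_id == 32],
                first_target = 30L, last_target = 32L)
  b <- one_call(chrom = "chr22", start = chr22$start[chr22$target_id == 34],
                end = chr22$end[chr22$target_id == 36],
                first_target = 34L, last_target = 36L)
  merged <- merge_calls(rbind(a, b), grid)
  span_parts <- cytoband_span(list(chrom = "chr22", start = a$start,
                                   end = b$end), fb$tables$cytobands)
  expect_equal(cytoband_span(merged, fb$tables$cytobands), span_parts)
})
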