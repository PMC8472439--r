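# shared builders for tests: tiny grids, hand-made batches, SAM fixtures

tiny_grid <- function(n = 10L, chrom = "chr1", start0 = 100, step = 1000,
                      width = 150) {
  starts <- start0 + step * (seq_len(n) - 1L)
  target_grid(rep(chrom, n), starts, starts + width)
}

# batch where every sample is Poisson around a shared target profile
flat_batch <- function(n_samples = 8L, n_targets = 20L, depth = 100,
                       seed = 1L) {
  set.seed(seed)
  profile <- rep(depth, n_targets)
  counts <- t(vapply(seq_len(n_samples),
                     function(i) rpois(n_targets, profile),
                     numeric(n_targets)))
  count_matrix(counts, sprintf("S%02d", seq_len(n_samples)),
               library_kind = "TsoE", allow_any_size = TRUE)
}

# a small coordinate-sorted indexed BAM built from explicit read positions
# (1-based), mapq and flag; returns the BAM path
make_test_bam <- function(reads, chrom = "chr1", chrom_len = 1000000L,
                          dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "reads.sam")
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  reads <- reads[order(reads$pos), , drop = FALSE]
  body <- sprintf("r%03d\t%d\t%s\t%d\t%d\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
                  seq_len(nrow(reads)),
                  if (is.null(reads$flag)) rep(0L, nrow(reads)) else reads$flag,
                  chrom, reads$pos, reads$mapq)
  writeLines(c(header, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

# one-row call list for annotation helpers
one_call <- function(chrom = "chr1", start = 1000, end = 2000,
                     copy_number = 1L, first_target = 0L, last_target = 0L,
                     sample = "S01", quality = 10, mean_ratio = 0.5) {
  df <- data.frame(sample = sample, chrom = chrom,
                   first_target = as.integer(first_target),
                   last_target = as.integer(last_target),
                   start = start, end = end,
                   type = if (copy_number < 2) "loss" else "gain",
                   copy_number = as.integer(copy_number),
                   n_targets = last_target - first_target + 1L,
                   mean_ratio = mean_ratio, quality = quality,
                   mosaic_fraction = NA_real_, stringsAsFactors = FALSE)
  class(df) <- c("cnv_calls", "data.frame")
  df
}

# fixture bundle shared by annotate/classify/acceptance tests
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "cnvbatch-fixtures")
      paths <- make_paper_fixtures(dir)
      tables <- read_annotation_tables(
        cytobands = paths[["cytobands"]], gene_model = paths[["genes"]],
        probes_180k = paths[["probes_180k"]], probes_1m = paths[["probes_1m"]],
        probes_mlpa = paths[["probes_mlpa"]], panels = paths[["panels"]],
        inhouse_db = paths[["inhouse_db"]], popsv_db = paths[["popsv_db"]],
        gene_dosage = paths[["gene_dosage"]])
      cache <<- list(paths = paths, tables = tables, grid = fixture_grid())
    }
    cache
  }
})
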