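#' Specification of a simulated sequencing batch
#'
#' Describes a batch the way the calling model sees one: a target grid, a
#' per-target mean depth, multiplicative lognormal sample and target
#' effects (library size and capture efficiency), negative-binomial
#' overdispersion, and a list of spiked CNVs with known truth.
#'
#' @param n_samples batch size (default 32, the exome batch size).
#' @param n_targets targets on the simulated grid.
#' @param n_chroms chromosomes the targets are spread over.
#' @param mean_depth expected reads per target for an average sample.
#' @param sample_sd,target_sd lognormal sd of the sample and target
#'   effects.
#' @param rho negative-binomial overdispersion: Var = mu + rho * mu^2.
#' @param spikes data.frame with columns sample (index or id), chrom,
#'   first_target, last_target (0-based per-chromosome target ids),
#'   copy_number (0,1,3,4), mosaic_fraction (in (0,1]); NULL for none.
#' @param library_kind "ES" or "TsoE".
#' @param seed mandatory integer seed.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_samples = 32L, n_targets = 500L, n_chroms = 2L,
                     mean_depth = 200, sample_sd = 0.2, target_sd = 0.5,
                     rho = 0.01, spikes = NULL,
                     library_kind = c("ES", "TsoE"), seed) {
  if (missing(seed)) stop("sim_spec requires an explicit seed", call. = FALSE)
  library_kind <- match.arg(library_kind)
  stopifnot(n_samples >= 2L, n_targets >= 1L, mean_depth > 0,
            sample_sd >= 0, target_sd >= 0, rho >= 0)
  if (!is.null(spikes)) {
    check_columns(spikes, c("sample", "chrom", "first_target", "last_target",
                            "copy_number", "mosaic_fraction"), "spike table")
    if (any(!spikes$copy_number %in% c(0L, 1L, 3L, 4L))) {
      stop("spike copy_number must be one of 0, 1, 3, 4", call. = FALSE)
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_targets = as.integer(n_targets),
                 n_chroms = as.integer(n_chroms),
                 mean_depth = mean_depth, sample_sd = sample_sd,
                 target_sd = target_sd, rho = rho, spikes = spikes,
                 library_kind = library_kind, seed = as.integer(seed)),
            class = "sim_spec")
}

# grid of equal-size targets over n_chroms synthetic chromosomes
sim_grid <- function(spec) {
  per <- ceiling(spec$n_targets / spec$n_chroms)
  chrom <- rep(sprintf("chrS%d", seq_len(spec$n_chroms)), each = per)[seq_len(spec$n_targets)]
  idx <- unlist(lapply(table(factor(chrom, levels = unique(chrom))), seq_len))
  start <- 1000 * (idx - 1L)
  target_grid(chrom, start, start + 150)
}

#' Simulate a batch of per-target read counts with known CNV truth
#'
#' Counts are negative-binomial (gamma-mixed Poisson) with mean
#' depth x sample_effect x target_effect, deliberately a different noise
#' family from the caller's beta-binomial fraction model. A spiked CNV of
#' copy number c at mosaic fraction f multiplies the mean by
#' 1 + f (c - 2) / 2.
#'
#' @param spec a [sim_spec()].
#' @return list with `grid` (a [target_grid()]), `batch` (a
#'   [count_matrix()]) and `truth` (BED-like data.frame of spikes with
#'   genomic coordinates and expected multiplier).
#' @export
simulate_batch <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  grid <- sim_grid(spec)
  n <- spec$n_samples
  Tn <- nrow(grid)
  sample_eff <- rlnorm(n, 0, spec$sample_sd)
  target_eff <- rlnorm(Tn, 0, spec$target_sd)
  mu <- spec$mean_depth * outer(sample_eff, target_eff)
  sample_ids <- sprintf("S%02d", seq_len(n))

  truth <- data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      first_target = integer(), last_target = integer(),
                      copy_number = integer(), mosaic_fraction = numeric(),
                      multiplier = numeric(), type = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(spec$spikes)) {
    for (i in seq_len(nrow(spec$spikes))) {
      sp <- spec$spikes[i, ]
      s_idx <- if (is.numeric(sp$sample)) as.integer(sp$sample)
               else match(sp$sample, sample_ids)
      sel <- grid$chrom == sp$chrom & grid$target_id >= sp$first_target &
        grid$target_id <= sp$last_target
      if (!any(sel) || is.na(s_idx) || s_idx < 1L || s_idx > n) {
        stop(sprintf("spike %d lies outside the simulated grid or batch", i),
             call. = FALSE)
      }
      mult <- 1 + sp$mosaic_fraction * (sp$copy_number - 2) / 2
      mu[s_idx, sel] <- mu[s_idx, sel] * mult
      truth <- rbind(truth, data.frame(
        sample = sample_ids[s_idx], chrom = sp$chrom,
        start = min(grid$start[sel]), end = max(grid$end[sel]),
        first_target = sp$first_target, last_target = sp$last_target,
        copy_number = sp$copy_number,
        mosaic_fraction = sp$mosaic_fraction, multiplier = mult,
        type = if (sp$copy_number < 2L) "loss" else "gain",
        stringsAsFactors = FALSE))
    }
  }
  # NB with Var = mu + rho mu^2  <=>  size = 1/rho
  counts <- if (spec$rho > 0) {
    matrix(rnbinom(n * Tn, size = 1 / spec$rho, mu = mu), n, Tn)
  } else {
    matrix(stats::rpois(n * Tn, mu), n, Tn)
  }
  colnames(counts) <- sprintf("%s:%d-%d", grid$chrom,
                              as.integer(grid$start), as.integer(grid$end))
  batch <- count_matrix(counts, sample_ids, spec$library_kind,
                        allow_any_size = TRUE)
  list(grid = grid, batch = batch, truth = truth)
}
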