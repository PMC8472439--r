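#' Beta-binomial log probability mass
#'
#' Parameterised by mean `p` and intra-class correlation `rho`; shape
#' parameters are a = p(1-rho)/rho, b = (1-p)(1-rho)/rho. As rho -> 0 the
#' distribution tends to the binomial.
#'
#' @param x successes, 0..n.
#' @param n trials.
#' @param p mean success fraction, in (0,1).
#' @param rho overdispersion (intra-class correlation), in (0,1).
#' @return log pmf value(s).
#' @keywords internal
betabinom_lpmf <- function(x, n, p, rho) {
  a <- p * (1 - rho) / rho
  b <- (1 - p) * (1 - rho) / rho
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}

#' Expected observed-read fraction under a copy state
#'
#' With `N_s` total test-sample reads and `N_r` total reference reads, a
#' target with copy number `c` in the test sample is expected to contribute
#' a fraction p_c = (c/2 * N_s) / (c/2 * N_s + N_r) of the combined
#' (test + reference) reads at that target. For a homozygous deletion
#' (c = 0) the multiplier is floored at `eps` so the fraction stays
#' positive (residual mismapping keeps real data off zero).
#'
#' @param c integer copy number (0..4), possibly vectorised.
#' @param N_s,N_r positive read totals for the test sample and the
#'   aggregated reference.
#' @param eps floor for the c = 0 multiplier (default 0.01).
#' @return expected fraction(s), strictly increasing in `c`.
#' @examples
#' expected_fraction(2, 1e6, 1e6)  # 0.5
#' expected_fraction(1, 1e6, 1e6)  # 1/3
#' @export
expected_fraction <- function(c, N_s, N_r, eps = 0.01) {
  stopifnot(N_s > 0, N_r > 0)
  mult <- ifelse(c == 0, eps, c / 2)
  (mult * N_s) / (mult * N_s + N_r)
}

#' Per-target log-likelihood of an observed count under a copy state
#'
#' Beta-binomial log pmf of observing `o_t` test-sample reads out of
#' `o_t + r_t` combined reads when the expected test fraction is `p_c`.
#' Targets with no reads at all carry no information and return 0.
#'
#' @param o_t observed test-sample count(s), >= 0.
#' @param r_t aggregated reference count(s), >= 0.
#' @param p_c expected fraction under the copy state, in (0,1).
#' @param rho overdispersion, in (0,1).
#' @return log-likelihood value(s); 0 where o_t + r_t = 0.
#' @export
target_loglik <- function(o_t, r_t, p_c, rho) {
  stopifnot(all(o_t >= 0), all(r_t >= 0), all(p_c > 0 & p_c < 1),
            rho > 0, rho < 1)
  n <- o_t + r_t
  ll <- betabinom_lpmf(o_t, n, p_c, rho)
  ll[n == 0] <- 0
  ll
}

#' Method-of-moments overdispersion estimate
#'
#' Under the diploid model every target's observed fraction
#' f_t = o_t/(o_t + r_t) has mean p = N_s/(N_s + N_r) and variance
#' p(1-p)/n_t * (1 + (n_t - 1) rho). Solving the averaged moment equation
#' for rho gives the estimate; it is clamped to [1e-6, 0.5].
#'
#' @param o,r per-target test and reference count vectors.
#' @return rho estimate in [1e-6, 0.5].
#' @keywords internal
estimate_rho <- function(o, r) {
  n <- o + r
  keep <- n > 0
  o <- o[keep]; n <- n[keep]
  p <- sum(o) / sum(n)
  f <- o / n
  z <- (f - p)^2
  num <- mean(z - p * (1 - p) / n)
  den <- mean(p * (1 - p) * (n - 1) / n)
  rho <- if (den > 0) num / den else 0
  min(max(rho, 1e-6), 0.5)
}

# expected variance of the aggregate observed fraction, used by the greedy
# reference builder: smaller is a more informative reference
reference_score <- function(o, r) {
  rho <- estimate_rho(o, r)
  n <- o + r
  keep <- n > 0
  n <- n[keep]
  p <- sum(o[keep]) / sum(n)
  mean(p * (1 - p) * (1 + (n - 1) * rho) / n)
}

#' Build a reference model for one test sample from its batch
#'
#' Other batch samples are ranked by Pearson correlation of their count
#' profiles with the test sample; candidates are added greedily in rank
#' order while the expected beta-binomial variance of the aggregate
#' observed fraction keeps decreasing (up to `max_refs`). The
#' overdispersion rho of the final aggregate is estimated by the method of
#' moments.
#'
#' @param test sample identifier (must be a row of `batch`).
#' @param batch a [count_matrix()] with at least 2 samples.
#' @param max_refs maximum reference samples to aggregate (default 10).
#' @return a `reference_model` list: `test_sample`, `reference_ids`,
#'   `o` (test counts), `r` (summed reference counts), `N_s`, `N_r`, `rho`.
#' @export
select_reference <- function(test, batch, max_refs = 10L) {
  stopifnot(inherits(batch, "count_matrix"))
  if (nrow(batch$counts) < 2L) {
    stop("reference set requires a batch of at least 2 samples", call. = FALSE)
  }
  if (!test %in% batch$sample_ids) {
    stop(sprintf("sample %s is not in the batch", test), call. = FALSE)
  }
  o <- as.numeric(batch$counts[test, ])
  if (sum(o) == 0) {
    stop(sprintf("test sample %s has zero total reads", test), call. = FALSE)
  }
  others <- setdiff(batch$sample_ids, test)
  cors <- vapply(others, function(s) {
    x <- as.numeric(batch$counts[s, ])
    if (stats::sd(x) == 0 || stats::sd(o) == 0) return(-Inf)
    cor(o, x)
  }, numeric(1))
  ranked <- others[order(cors, decreasing = TRUE)]

  chosen <- ranked[1L]
  r <- as.numeric(batch$counts[chosen, ])
  best <- reference_score(o, r)
  for (s in ranked[-1L]) {
    if (length(chosen) >= max_refs) break
    r_try <- r + as.numeric(batch$counts[s, ])
    sc <- reference_score(o, r_try)
    if (sc < best) {
      chosen <- c(chosen, s)
      r <- r_try
      best <- sc
    } else break
  }
  structure(list(test_sample = test, reference_ids = chosen,
                 o = o, r = r, N_s = sum(o), N_r = sum(r),
                 rho = estimate_rho(o, r)),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("reference_model for %s: %d reference sample(s), N_s=%.3g, N_r=%.3g, rho=%.2g\n",
              x$test_sample, length(x$reference_ids), x$N_s, x$N_r, x$rho))
  invisible(x)
}

# copy states considered by the segmenter; the most extreme event seen in
# diagnostic practice here is a quadruplication
COPY_STATES <- 0:4
DIPLOID_STATE <- 2L

#' Viterbi decoding of copy states along one chromosome
#'
#' Maximises total emission log-likelihood minus a penalty of
#' `log(transition_prob)` for every entry into a non-diploid state (state
#' changes into the diploid state are free: the prior is "stay diploid").
#' Ties are broken toward the state closest to diploid.
#'
#' @param emission matrix of per-state log-likelihoods, states x targets
#'   (rows ordered as `states`).
#' @param states integer copy numbers labelling the rows.
#' @param transition_prob penalty probability per entry into a non-diploid
#'   state (default 1e-4).
#' @return integer vector of decoded copy numbers, one per target.
#' @export
viterbi_states <- function(emission, states = COPY_STATES,
                           transition_prob = 1e-4) {
  stopifnot(nrow(emission) == length(states))
  S <- length(states)
  Tn <- ncol(emission)
  log_t <- log(transition_prob)
  entry_pen <- ifelse(states == DIPLOID_STATE, 0, log_t)
  # tie-break: prefer |c - 2| small; add an infinitesimal bias is avoided,
  # instead resolve argmax deterministically by distance from diploid
  pref <- order(abs(states - DIPLOID_STATE), states)

  score <- matrix(-Inf, S, Tn)
  back <- matrix(0L, S, Tn)
  score[, 1L] <- emission[, 1L] + entry_pen
  if (Tn > 1L) {
    for (t in 2:Tn) {
      for (j in seq_len(S)) {
        # transition into j: free if staying or entering diploid, else penalty
        cand <- score[, t - 1L] +
          ifelse(seq_len(S) == j | states[j] == DIPLOID_STATE, 0, log_t)
        # deterministic argmax with diploid-proximal preference
        best <- pref[which.max(cand[pref])]
        score[j, t] <- cand[best] + emission[j, t]
        back[j, t] <- best
      }
    }
  }
  path <- integer(Tn)
  path[Tn] <- pref[which.max(score[pref, Tn])]
  if (Tn > 1L) {
    for (t in (Tn - 1L):1L) path[t] <- back[path[t + 1L], t + 1L]
  }
  states[path]
}

#' Call copy-number segments for one test sample
#'
#' For every chromosome of the grid, per-target log-likelihoods under copy
#' states 0..4 are computed from the beta-binomial observed-fraction model
#' and decoded with [viterbi_states()]. Maximal runs of non-diploid states
#' become candidate calls; each call's quality is the log10 likelihood
#' ratio of its decoded states against the all-diploid path over the same
#' targets, and calls below `call_threshold` are suppressed.
#'
#' @param ref_model a [select_reference()] result.
#' @param grid the [target_grid()] the batch was counted on.
#' @param transition_prob Viterbi entry penalty (default 1e-4).
#' @param call_threshold minimum quality, log10 Bayes factor vs diploid
#'   (default 3).
#' @param rho override the model's estimated overdispersion (optional).
#' @return a `cnv_calls` data.frame: sample, chrom, first_target,
#'   last_target, start, end, type, copy_number, n_targets, mean_ratio,
#'   quality, mosaic_fraction (NA until [estimate_mosaic()] is applied).
#' @export
call_segments <- function(ref_model, grid, transition_prob = 1e-4,
                          call_threshold = 3, rho = NULL) {
  stopifnot(inherits(ref_model, "reference_model"),
            inherits(grid, "target_grid"))
  if (length(ref_model$o) != nrow(grid)) {
    stop("reference model and grid disagree on the number of targets",
         call. = FALSE)
  }
  rho <- rho %||% ref_model$rho
  p_states <- expected_fraction(COPY_STATES, ref_model$N_s, ref_model$N_r)

  out <- list()
  for (ch in unique(grid$chrom)) {
    sel <- grid$chrom == ch
    o <- ref_model$o[sel]; r <- ref_model$r[sel]
    emission <- vapply(p_states, function(p) target_loglik(o, r, p, rho),
                       numeric(sum(sel)))
    emission <- t(emission)  # states x targets
    path <- viterbi_states(emission, COPY_STATES, transition_prob)

    runs <- rle(path != DIPLOID_STATE)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      idx <- starts[k]:ends[k]
      seg_states <- path[idx]
      tab <- table(seg_states)
      cn <- as.integer(names(tab)[which.max(tab)])
      diploid_row <- which(COPY_STATES == DIPLOID_STATE)
      state_rows <- match(seg_states, COPY_STATES)
      ll_path <- sum(emission[cbind(state_rows, idx)])
      ll_dip <- sum(emission[diploid_row, idx])
      quality <- (ll_path - ll_dip) / log(10)
      if (quality < call_threshold) next
      # observed / expected-diploid depth ratio over the segment; the diploid
      # expectation of o_t is r_t scaled by the ratio of library totals
      e_dip <- r[idx] * ref_model$N_s / ref_model$N_r
      mean_ratio <- if (sum(e_dip) > 0) sum(o[idx]) / sum(e_dip) else NA_real_
      gstart <- grid$start[sel][idx[1L]]
      gend <- grid$end[sel][idx[length(idx)]]
      out[[length(out) + 1L]] <- data.frame(
        sample = ref_model$test_sample, chrom = ch,
        first_target = grid$target_id[sel][idx[1L]],
        last_target = grid$target_id[sel][idx[length(idx)]],
        start = gstart, end = gend,
        type = if (cn < 2L) "loss" else "gain",
        copy_number = cn, n_targets = length(idx),
        mean_ratio = mean_ratio, quality = quality,
        mosaic_fraction = NA_real_, stringsAsFactors = FALSE
      )
    }
  }
  calls <- if (length(out) > 0L) do.call(rbind, out) else empty_calls()
  class(calls) <- c("cnv_calls", "data.frame")
  calls
}

empty_calls <- function() {
  data.frame(sample = character(), chrom = character(),
             first_target = integer(), last_target = integer(),
             start = numeric(), end = numeric(), type = character(),
             copy_number = integer(), n_targets = integer(),
             mean_ratio = numeric(), quality = numeric(),
             mosaic_fraction = numeric(), stringsAsFactors = FALSE)
}

#' Estimate the mosaic cell fraction of a single-copy event
#'
#' A duplication present in a fraction f of cells shifts the segment depth
#' ratio to 1 + f/2; a heterozygous deletion to 1 - f/2. Inverting gives
#' f = 2(r - 1) for copy number 3 and f = 2(1 - r) for copy number 1,
#' clamped to [0,1]. The mapping is ambiguous for copy numbers 0 and 4, so
#' those are not estimated. Fractions >= `constitutive_min` are reported as
#' constitutive (no mosaic annotation in the output writers).
#'
#' @param call one row of a `cnv_calls` data.frame (or a list with
#'   `copy_number` and `mean_ratio`).
#' @param constitutive_min fraction at or above which the event is treated
#'   as constitutive (default 0.95).
#' @return list with `fraction` in [0,1], `constitutive` flag, and
#'   `supported` flag (FALSE for copy numbers 0 and 4, where `fraction` is
#'   NA).
#' @examples
#' estimate_mosaic(list(copy_number = 3, mean_ratio = 1.29))$fraction  # 0.58
#' @export
estimate_mosaic <- function(call, constitutive_min = 0.95) {
  cn <- call$copy_number
  r <- call$mean_ratio
  if (!cn %in% c(1L, 3L)) {
    return(list(fraction = NA_real_, constitutive = NA, supported = FALSE))
  }
  f <- if (cn == 3L) 2 * (r - 1) else 2 * (1 - r)
  f <- min(max(f, 0), 1)
  list(fraction = f, constitutive = f >= constitutive_min, supported = TRUE)
}

#' Annotate mosaic fractions on a call table
#'
#' Applies [estimate_mosaic()] to every single-copy call; constitutive
#' events (fraction >= `constitutive_min`) and unsupported copy numbers
#' keep `mosaic_fraction = NA`.
#'
#' @param calls a `cnv_calls` data.frame.
#' @param constitutive_min see [estimate_mosaic()].
#' @return the call table with `mosaic_fraction` filled in.
#' @export
add_mosaic_fractions <- function(calls, constitutive_min = 0.95) {
  if (nrow(calls) == 0L) return(calls)
  for (i in seq_len(nrow(calls))) {
    m <- estimate_mosaic(calls[i, ], constitutive_min)
    calls$mosaic_fraction[i] <-
      if (isTRUE(m$supported) && !isTRUE(m$constitutive)) m$fraction else NA_real_
  }
  calls
}
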