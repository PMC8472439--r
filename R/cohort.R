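#' Cohort disease-category vocabulary
#' @export
COHORT_CATEGORIES <- c("NDD", "neurodegeneration", "renal", "heart",
                       "connective", "vision", "hearing_loss", "metabolic",
                       "neuromuscular", "blood_immune", "mitochondrial",
                       "pulmonary_fibrosis", "diverse")

#' Cohort outcome vocabulary
#' @export
COHORT_OUTCOMES <- c("positive_snv", "positive_cnv", "positive_both",
                     "vus_snv", "vus_cnv", "negative")

#' Read a cohort record table
#'
#' One row per patient: `patient_id`, `categories` (comma-separated
#' disease-category labels, at least one), `outcome` (one of
#' [COHORT_OUTCOMES]), `acgh_status` (before_ngs, validation, after_ngs,
#' none).
#'
#' @param path TSV path.
#' @return validated data.frame with a `categories` list-column.
#' @export
read_cohort <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("patient_id", "categories", "outcome", "acgh_status"),
                path)
  df$categories <- strsplit(df$categories, ",", fixed = TRUE)
  if (any(lengths(df$categories) == 0L)) {
    stop(sprintf("%s: every patient needs at least one category", path),
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(unlist(df$categories)), COHORT_CATEGORIES)
  if (length(bad_cat) > 0L) {
    stop(sprintf("%s: unknown categories: %s", path,
                 paste(bad_cat, collapse = ", ")), call. = FALSE)
  }
  if (any(!df$outcome %in% COHORT_OUTCOMES)) {
    stop(sprintf("%s: unknown outcome values", path), call. = FALSE)
  }
  df
}

is_positive <- function(outcome) {
  outcome %in% c("positive_snv", "positive_cnv", "positive_both")
}

#' Diagnostic-yield report for a cohort
#'
#' Overall positive rate (patients with a diagnostic SNV and/or CNV over
#' all patients) and per-category rates, where a multi-category patient
#' counts in the denominator (and numerator) of each of its categories.
#' Percentages are rounded to one decimal place but the underlying integer
#' counts are returned alongside.
#'
#' @param records cohort data.frame from [read_cohort()].
#' @return list with `n`, `n_positive`, `overall_rate` (percent, 1 dp),
#'   `n_vus`, `n_negative`, and `per_category` (data.frame: category, n,
#'   n_positive, rate).
#' @export
yield_report <- function(records) {
  if (nrow(records) == 0L) stop("empty cohort", call. = FALSE)
  n <- nrow(records)
  pos <- is_positive(records$outcome)
  per <- lapply(COHORT_CATEGORIES, function(cat) {
    in_cat <- vapply(records$categories, function(x) cat %in% x, logical(1))
    data.frame(category = cat, n = sum(in_cat),
               n_positive = sum(in_cat & pos),
               rate = if (sum(in_cat) > 0) round(100 * sum(in_cat & pos) / sum(in_cat), 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  per <- per[per$n > 0L, , drop = FALSE]
  per <- per[order(-per$rate, -per$n), , drop = FALSE]
  rownames(per) <- NULL
  list(n = n, n_positive = sum(pos),
       overall_rate = round(100 * sum(pos) / n, 1),
       n_vus = sum(records$outcome %in% c("vus_snv", "vus_cnv")),
       n_negative = sum(records$outcome == "negative"),
       per_category = per)
}

#' Contribution of the CNV pipeline to the diagnostic yield
#'
#' Counts patients whose diagnosis required the CNV pipeline (outcome
#' positive_cnv or positive_both) and the corresponding fraction of the
#' cohort.
#'
#' @param records cohort data.frame.
#' @return list with `n_cnv_diagnosed` and `fraction` (percent, 1 dp).
#' @export
cnv_yield_delta <- function(records) {
  cnv <- records$outcome %in% c("positive_cnv", "positive_both")
  list(n_cnv_diagnosed = sum(cnv),
       fraction = if (nrow(records) > 0) round(100 * sum(cnv) / nrow(records), 1) else 0)
}

#' Size-class breakdown of diagnostic CNVs
#'
#' @param sizes numeric CNV sizes in bp, or a data.frame with a
#'   `size_class` column.
#' @return data.frame: size_class, n, percent (1 dp; zero rows give 0).
#' @export
size_class_summary <- function(sizes) {
  classes <- c("large", "gene_size", "exon_level")
  cls <- if (is.data.frame(sizes)) sizes$size_class
         else vapply(sizes, size_class, character(1))
  n <- vapply(classes, function(k) sum(cls == k), integer(1))
  total <- sum(n)
  data.frame(size_class = classes, n = n,
             percent = if (total > 0) round(100 * n / total, 1) else rep(0, 3),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Concordance of microarray VUS findings with the sequencing pipeline
#'
#' For CNVs reported as VUS by arrayCGH, the sequencing pipeline detects
#' those that fall in regions with capture targets and are not polymorphic
#' in the batch; the undetected remainder is partitioned by reason.
#'
#' @param records data.frame with logical columns `has_ngs_targets` and
#'   `polymorphic_in_batch`.
#' @return list with `n`, `n_detected`, `n_no_targets`, `n_polymorphic`,
#'   and a per-record `reason` vector ("detected", "no_targets",
#'   "polymorphic").
#' @export
acgh_concordance <- function(records) {
  check_columns(records, c("has_ngs_targets", "polymorphic_in_batch"),
                "aCGH VUS record table")
  has_t <- as.logical(records$has_ngs_targets)
  poly <- as.logical(records$polymorphic_in_batch)
  reason <- ifelse(!has_t, "no_targets",
                   ifelse(poly, "polymorphic", "detected"))
  list(n = nrow(records), n_detected = sum(reason == "detected"),
       n_no_targets = sum(reason == "no_targets"),
       n_polymorphic = sum(reason == "polymorphic"), reason = reason)
}

#' Render a cohort report as text
#' @param records cohort data.frame.
#' @param sizes optional size input for [size_class_summary()].
#' @return character vector of report lines.
#' @export
render_cohort_report <- function(records, sizes = NULL) {
  y <- yield_report(records)
  d <- cnv_yield_delta(records)
  lines <- c(
    sprintf("Cohort: %d patients", y$n),
    sprintf("Positive diagnoses: %d (%.1f%%)", y$n_positive, y$overall_rate),
    sprintf("CNV-diagnosed patients: %d (%.1f%% of cohort)",
            d$n_cnv_diagnosed, d$fraction),
    sprintf("VUS: %d; negative: %d", y$n_vus, y$n_negative),
    "",
    "Per-category diagnostic yield:",
    sprintf("  %-20s %4d/%-4d %.1f%%", y$per_category$category,
            y$per_category$n_positive, y$per_category$n,
            y$per_category$rate)
  )
  if (!is.null(sizes)) {
    s <- size_class_summary(sizes)
    lines <- c(lines, "", "Size classes of diagnostic CNVs:",
               sprintf("  %-12s %3d (%.1f%%)", s$size_class, s$n, s$percent))
  }
  lines
}
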