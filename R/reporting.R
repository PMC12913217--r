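# Cross-assay derived statistics: luciferase refold capacity, fold-changes
# versus a control condition, and two-group tests, with round-tripping CSV
# helpers for tidy result tables.

#' Protein refold capacity
#'
#' The fraction of luciferase activity recovered after heat shock:
#' `activity_recovered / activity_nonshocked`, computed within genotype so
#' baseline translation differences between genotypes do not bias the
#' comparison. Values above 1 (over-recovery) are allowed with a warning.
#'
#' @param activity_recovered luminescence after heat shock and recovery
#'   (>= 0); vectorized.
#' @param activity_nonshocked luminescence of matched non-shocked samples
#'   (> 0).
#' @return numeric vector of refold capacities.
#' @examples
#' refold_capacity(0.6, 1.0)  # 60% recovery
#' @export
refold_capacity <- function(activity_recovered, activity_nonshocked) {
  if (any(activity_nonshocked <= 0))
    stop_nq("division_by_zero", "non-shocked activity must be positive")
  if (any(activity_recovered < 0))
    stop_nq("invalid_spec", "recovered activity must be non-negative")
  rc <- activity_recovered / activity_nonshocked
  if (any(rc > 1))
    warning("refold capacity above 1 (recovered activity exceeds non-shocked)")
  rc
}

#' Fold-change of each value against the control-condition mean
#'
#' Within each assay, divides every value by the mean of the control
#' condition's values, so control rows average to a fold-change of 1.
#'
#' @param table data.frame with columns `sample_id`, `condition`, `value`
#'   and optionally `assay` (a single implicit assay otherwise).
#' @param control label of the control condition.
#' @return the input with a `fold_change` column appended.
#' @export
fold_change_vs_control <- function(table, control) {
  stopifnot(is.data.frame(table),
            all(c("sample_id", "condition", "value") %in% names(table)))
  if (!"assay" %in% names(table)) table$assay <- "assay"
  table$fold_change <- NA_real_
  for (a in unique(table$assay)) {
    sel <- table$assay == a
    ctrl <- table$value[sel & table$condition == control]
    if (!length(ctrl))
      stop_nq("missing_control",
              sprintf("no '%s' rows for assay '%s'", control, a))
    m <- mean(ctrl)
    if (!is.finite(m) || m <= 0)
      stop_nq("non_positive_control_mean",
              sprintf("control mean for assay '%s' is not positive", a))
    table$fold_change[sel] <- table$value[sel] / m
  }
  table
}

#' Two-group comparison
#'
#' `kind = "rank"` runs a two-sided Mann-Whitney (Wilcoxon rank-sum) test,
#' the default for heavy-tailed per-cell image metrics; `kind = "t"` runs a
#' Welch t-test for per-sample assay values.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2).
#' @param kind `"rank"` or `"t"`.
#' @return list: `p_value`, `kind`, and a `groups` data.frame with `n`,
#'   `mean`, `median` per group.
#' @export
group_test <- function(values_a, values_b, kind = c("rank", "t")) {
  kind <- match.arg(kind)
  if (length(values_a) < 2 || length(values_b) < 2)
    stop_nq("too_few_values", "each group needs at least 2 values")
  p <- if (kind == "rank")
    suppressWarnings(stats::wilcox.test(values_a, values_b)$p.value)
  else
    stats::t.test(values_a, values_b)$p.value
  list(
    p_value = p,
    kind = kind,
    groups = data.frame(
      group = c("a", "b"),
      n = c(length(values_a), length(values_b)),
      mean = c(mean(values_a), mean(values_b)),
      median = c(stats::median(values_a), stats::median(values_b))
    )
  )
}

#' Benjamini-Hochberg adjustment for batch reports
#'
#' @param p_values numeric vector of per-comparison p-values.
#' @return adjusted p-values (FDR).
#' @export
adjust_fdr <- function(p_values) stats::p.adjust(p_values, method = "BH")

#' Write / read a tidy measurement table
#'
#' Plain CSV with a header; [read_measures()] restores what
#' [write_measures()] wrote (numeric, logical and character columns
#' round-trip exactly).
#'
#' @param measures data.frame to write.
#' @param path CSV path.
#' @return `path` invisibly (write) / the data.frame (read).
#' @export
write_measures <- function(measures, path) {
  utils::write.csv(measures, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_measures
#' @export
read_measures <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
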