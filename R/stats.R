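#' Mann-Whitney U test tuned for small replicate counts
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison. With
#' `n_x + n_y <= 16` and no ties the p-value is exact (full enumeration of
#' rank arrangements, as implemented by the null distribution of the rank
#' statistic); larger or tied samples fall back to the normal
#' approximation with tie and continuity corrections. Two completely
#' overlapping samples (all values tied across both groups) carry no
#' evidence either way and return p = 1.
#'
#' @param x,y Numeric vectors of replicate values; both non-empty.
#' @return A list with `u_statistic` (the U count for `x`, in
#'   `[0, n_x * n_y]`) and `p_value`.
#' @export
mann_whitney_exact <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && (length(x) + length(y)) <= 16L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  p <- wt$p.value
  if (!is.finite(p)) p <- 1 # zero-variance tie case: no evidence
  list(u_statistic = unname(wt$statistic), p_value = min(p, 1))
}

significance_marker <- function(p, vs_reference) {
  if (vs_reference) {
    if (p < 0.01) "##" else if (p < 0.05) "#" else "ns"
  } else {
    if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
  }
}

#' Compare every variant against a reference and against each other
#'
#' For each metric in a tidy metrics table, runs [mann_whitney_exact()]
#' for every non-reference variant against the reference (annotated with
#' hash markers: `#` p < 0.05, `##` p < 0.01) and for every pair of
#' non-reference variants (star markers: `*` p < 0.05, `**` p < 0.01).
#' Raw per-comparison p-values are reported; an optional Holm adjustment
#' adds a `p_holm` column (computed per metric) without changing the
#' markers.
#'
#' @param metrics_table Tidy `data.frame` with at least the columns
#'   `variant`, `replicate`, `metric`, `value` (see
#'   [heme_conformation()]).
#' @param reference Variant label of the reference group (default
#'   `"WT"`); must be present.
#' @param holm Add Holm-adjusted p-values?
#' @return A `data.frame` with one row per comparison: `metric`,
#'   `group_a`, `group_b`, `n_a`, `n_b`, `u_statistic`, `p_value`,
#'   `marker` (and `p_holm` if requested).
#' @export
compare_all <- function(metrics_table, reference = "WT", holm = FALSE) {
  stopifnot(is.data.frame(metrics_table),
            all(c("variant", "metric", "value") %in% names(metrics_table)))
  variants <- unique(metrics_table$variant)
  if (!reference %in% variants) {
    stop(sprintf("reference variant '%s' not present", reference), call. = FALSE)
  }
  others <- setdiff(variants, reference)
  if (length(others) == 0L) stop("need at least 2 variants", call. = FALSE)

  rows <- list()
  for (metric in unique(metrics_table$metric)) {
    sub <- metrics_table[metrics_table$metric == metric, , drop = FALSE]
    vals <- split(sub$value, sub$variant)
    pairs <- c(
      lapply(others, function(v) c(v, reference)),
      if (length(others) >= 2L) utils::combn(others, 2L, simplify = FALSE)
    )
    for (pr in pairs) {
      a <- vals[[pr[1]]]; b <- vals[[pr[2]]]
      if (is.null(a) || is.null(b) || length(a) < 2L || length(b) < 2L) {
        stop(sprintf("metric '%s': need >= 2 replicates for '%s' and '%s'",
                     metric, pr[1], pr[2]), call. = FALSE)
      }
      mw <- mann_whitney_exact(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, group_a = pr[1], group_b = pr[2],
        n_a = length(a), n_b = length(b),
        u_statistic = mw$u_statistic, p_value = mw$p_value,
        marker = significance_marker(mw$p_value, pr[2] == reference),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (holm) {
    res$p_holm <- NA_real_
    for (metric in unique(res$metric)) {
      sel <- res$metric == metric
      res$p_holm[sel] <- stats::p.adjust(res$p_value[sel], method = "holm")
    }
  }
  res
}

#' Per-variant means and standard errors of each metric
#'
#' @param metrics_table Tidy metrics `data.frame` (columns `variant`,
#'   `metric`, `value`, ...).
#' @return A `data.frame` with one row per (variant, metric): `mean`,
#'   `sem` (sample SD / sqrt(n); `NA` when n = 1) and `n`.
#' @export
summarize_metrics <- function(metrics_table) {
  stopifnot(is.data.frame(metrics_table),
            all(c("variant", "metric", "value") %in% names(metrics_table)))
  agg <- split(metrics_table,
               list(metrics_table$variant, metrics_table$metric), drop = TRUE)
  rows <- lapply(agg, function(g) {
    n <- nrow(g)
    data.frame(
      variant = g$variant[1], metric = g$metric[1],
      mean = mean(g$value),
      sem = if (n > 1L) stats::sd(g$value) / sqrt(n) else NA_real_,
      n = n, stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$metric, res$variant), , drop = FALSE]
  rownames(res) <- NULL
  res
}
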