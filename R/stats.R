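# Group-level statistics: mean +/- SEM summaries, Student's t comparisons,
# and drug-response normalization, matching common practice in contractility
# studies (>= 5 independent experiments, * p < 0.05, ** p < 0.01).

#' Mean and standard error of a group
#'
#' @param values Numeric vector of per-experiment summary values (n >= 1).
#' @param label Optional group label.
#' @return A `group_sample` list: `label`, `values`, `n`, `mean`, `sem`
#'   (NA with `sem_defined = FALSE` when n = 1; SEM uses the n-1 sd).
#' @examples
#' summarize_group(c(2, 4)) # mean 3, SEM 1
#' @export
summarize_group <- function(values, label = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values))) {
    pb_stop("`values` must be a non-empty finite numeric vector",
            "pillarbeat_invalid_parameter")
  }
  n <- length(values)
  structure(list(
    label = label, values = values, n = n, mean = mean(values),
    sem = if (n >= 2) sd(values) / sqrt(n) else NA_real_,
    sem_defined = n >= 2
  ), class = "group_sample")
}

#' @export
print.group_sample <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.3g (mean +/- SEM, n = %d)\n",
              if (is.null(x$label)) "group" else x$label,
              x$mean, x$sem, x$n))
  invisible(x)
}

significance_tier <- function(p) {
  if (is.na(p)) NA_character_
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "NS"
}

#' Compare two groups with Student's t-test
#'
#' Two-sided t-test, pooled-variance (classical Student) by default with
#' Welch available, plus the percent difference of means and a significance
#' tier (* p < 0.05, ** p < 0.01, NS otherwise). Degenerate inputs with
#' zero pooled variance give p = 1 for equal means and an infinite-t flag
#' otherwise.
#'
#' @param a,b [summarize_group()] results or plain numeric vectors
#'   (n >= 2 each).
#' @param paired Paired test (requires equal n).
#' @param welch Use the Welch (unequal-variance) test instead of pooled.
#' @return A `group_comparison` list: group means/SEMs/n,
#'   `percent_difference` (of b relative to a), `t`, `df`, `p`, `tier`,
#'   `infinite_t`.
#' @export
compare_groups <- function(a, b, paired = FALSE, welch = FALSE) {
  if (!inherits(a, "group_sample")) a <- summarize_group(a)
  if (!inherits(b, "group_sample")) b <- summarize_group(b)
  if (a$n < 2 || b$n < 2) {
    pb_stop("each group needs n >= 2 for a t-test",
            "pillarbeat_insufficient_data")
  }
  pooled_sd <- if (paired) sd(b$values - a$values)
               else sqrt((sum((a$values - a$mean)^2) +
                          sum((b$values - b$mean)^2)) /
                         (a$n + b$n - 2))
  if (pooled_sd == 0) {
    equal <- isTRUE(all.equal(a$mean, b$mean))
    tt <- list(statistic = if (equal) 0 else Inf,
               parameter = a$n + b$n - 2,
               p.value = if (equal) 1 else 0)
    inf_t <- !equal
  } else {
    ht <- t.test(b$values, a$values, paired = paired,
                 var.equal = !welch && !paired)
    tt <- list(statistic = unname(ht$statistic),
               parameter = unname(ht$parameter),
               p.value = ht$p.value)
    inf_t <- FALSE
  }
  structure(list(
    labels = c(a$label, b$label),
    means = c(a = a$mean, b = b$mean),
    sems = c(a = a$sem, b = b$sem),
    n = c(a = a$n, b = b$n),
    percent_difference = 100 * (b$mean - a$mean) / a$mean,
    t = tt$statistic, df = tt$parameter, p = tt$p.value,
    tier = significance_tier(tt$p.value),
    infinite_t = inf_t,
    paired = paired, welch = welch
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("Group comparison: %.4g +/- %.3g (n=%d) vs %.4g +/- %.3g ",
           "(n=%d)\n  difference %+.1f%%, t = %.3g (df %.3g), ",
           "p = %.3g [%s]\n"),
    x$means["a"], x$sems["a"], x$n["a"], x$means["b"], x$sems["b"],
    x$n["b"], x$percent_difference, x$t, x$df, x$p, x$tier))
  invisible(x)
}

#' Normalized drug response (percent decrease)
#'
#' Per experiment, `100 * (pre - post) / pre`; positive means the drug
#' decreased the contraction metric. The per-experiment percentages are then
#' summarized as mean +/- SEM. The percentage is invariant to rescaling
#' both values of an experiment by any positive constant.
#'
#' @param pre,post Paired per-experiment values before and after treatment
#'   (equal length; `pre` all positive).
#' @return A `group_sample` of percent decreases (plus field
#'   `percent_decrease` with the per-experiment values).
#' @examples
#' normalize_drug_response(0.1202, 0.0615) # ~48.8% decrease
#' @export
normalize_drug_response <- function(pre, post) {
  if (length(pre) != length(post)) {
    pb_stop("pre and post must be paired (equal length)",
            "pillarbeat_invalid_parameter")
  }
  bad <- which(pre <= 0)
  if (length(bad)) {
    pb_stop(sprintf("non-positive pre-treatment baseline in experiment %d",
                    bad[1]), "pillarbeat_invalid_parameter")
  }
  pct <- 100 * (pre - post) / pre
  out <- summarize_group(pct, label = "percent decrease")
  out$percent_decrease <- pct
  out
}

#' Summarize a tidy experiment table by group
#'
#' Pivots a tidy per-experiment table (columns `experiment_id, condition,
#' day, metric, value`) into per-(condition, day) mean/SEM/n rows — the
#' day-by-day aggregation behind bar-chart style summaries. Cells with
#' n < 2 are reported with an undefined SEM.
#'
#' @param table A data.frame with at least `condition`, `value` and the
#'   columns named in `by`; if a `metric` column exists it is filtered to
#'   `metric`.
#' @param metric Metric name to keep (ignored without a `metric` column).
#' @param by Grouping columns.
#' @return A data.frame with one row per group: `by` columns plus `n`,
#'   `mean`, `sem`.
#' @export
summarize_table <- function(table, metric = NULL,
                            by = c("condition", "day")) {
  if (!is.null(metric) && "metric" %in% names(table)) {
    table <- table[table$metric == metric, ]
  }
  if (nrow(table) == 0L) {
    pb_stop("no rows to summarize", "pillarbeat_insufficient_data")
  }
  by <- intersect(by, names(table))
  key <- interaction(table[by], drop = TRUE, lex.order = TRUE)
  parts <- lapply(split(table, key), function(g) {
    s <- summarize_group(g$value)
    cbind(g[1, by, drop = FALSE],
          data.frame(n = s$n, mean = s$mean, sem = s$sem))
  })
  out <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  out[do.call(order, out[by]), , drop = FALSE]
}
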