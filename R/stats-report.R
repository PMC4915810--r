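#' Two-tailed Wilcoxon rank-sum test (unpaired)
#'
#' Exact null distribution when `n1 * n2 <= 400` and the pooled sample is
#' tie-free, otherwise the normal approximation with tie and continuity
#' corrections. Degenerate input (all values identical across both
#' groups) returns p = 1 with a flag.
#'
#' @param x,y unpaired samples.
#' @return a `comparison_result` list: `test`, `statistic` (W), `p_value`,
#'   `n1`, `n2`, `direction` (sign of median(x) - median(y)), `exact`,
#'   `flag`.
#' @export
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) validation_error("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1)
    return(structure(list(test = "rank_sum", statistic = n1 * n2 / 2,
                          p_value = 1, n1 = n1, n2 = n2, direction = 0,
                          exact = FALSE, flag = "degenerate"),
                     class = "comparison_result"))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (n1 * n2 <= 400) && !ties
  w <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                           correct = TRUE))
  structure(list(test = "rank_sum", statistic = unname(w$statistic),
                 p_value = w$p.value, n1 = n1, n2 = n2,
                 direction = sign(stats::median(x) - stats::median(y)),
                 exact = exact, flag = NULL),
            class = "comparison_result")
}

#' Two-tailed Wilcoxon signed-rank test (paired)
#'
#' Zero differences are dropped (as in the classical test). Exact null
#' distribution when at most 25 non-zero differences remain and their
#' magnitudes are tie-free, otherwise the normal approximation with
#' corrections. All-zero differences return p = 1 with a flag.
#'
#' @param x,y paired samples of equal length.
#' @return a `comparison_result` list (statistic is V).
#' @export
signed_rank_test <- function(x, y) {
  if (length(x) != length(y))
    validation_error("paired samples must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(structure(list(test = "signed_rank", statistic = 0,
                          p_value = 1, n1 = length(x), n2 = length(y),
                          direction = 0, exact = FALSE,
                          flag = "degenerate"),
                     class = "comparison_result"))
  if (n < 2) validation_error("need >= 2 non-zero paired differences")
  ties <- anyDuplicated(abs(d)) > 0
  exact <- n <= 25 && !ties
  w <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                           exact = exact, correct = TRUE))
  structure(list(test = "signed_rank", statistic = unname(w$statistic),
                 p_value = w$p.value, n1 = length(x), n2 = length(y),
                 direction = sign(stats::median(d)), exact = exact,
                 flag = NULL),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s%s> statistic %.1f, p = %.4g (n = %d/%d)\n",
              x$test, if (x$exact) ", exact" else "", x$statistic,
              x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Tukey box-plot summary statistics
#'
#' Median, 1st/3rd quartiles (linear interpolation, quantile type 7) and
#' Tukey whiskers: the most extreme data points within 1.5 interquartile
#' ranges of the quartiles.
#'
#' @param values numeric vector (n >= 1).
#' @return a `box_stats` list: `median`, `q1`, `q3`, `whisker_lo`,
#'   `whisker_hi`, `n`.
#' @export
box_stats <- function(values) {
  if (length(values) < 1) validation_error("need at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_lo = min(values[values >= q[1] - 1.5 * iqr]),
                 whisker_hi = max(values[values <= q[3] + 1.5 * iqr]),
                 n = length(values)),
            class = "box_stats")
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf("<box_stats> n=%d [%.3g | %.3g (%.3g) %.3g | %.3g]\n",
              x$n, x$whisker_lo, x$q1, x$median, x$q3, x$whisker_hi))
  invisible(x)
}

# descriptive summary of one group of values
describe_group <- function(values) {
  b <- box_stats(values)
  c(n = length(values), mean = mean(values),
    sem = if (length(values) > 1) stats::sd(values) / sqrt(length(values))
          else NA_real_,
    median = b$median, q1 = b$q1, q3 = b$q3,
    whisker_lo = b$whisker_lo, whisker_hi = b$whisker_hi)
}

#' Cross-group report of per-cell metrics
#'
#' Builds the standard comparison tables for a cohort of cells: for every
#' metric, descriptive statistics per group x projection target, unpaired
#' projection comparisons (S2-p vs M1-p within each training group) and
#' training-group comparisons (good performer vs naive within each
#' projection target), at cell level and — when `mouse_id` is present —
#' at mouse level (cells averaged within mouse first). Raw p-values are
#' reported without multiple-testing correction, as is conventional for
#' this design.
#'
#' @param cell_metrics data frame with columns `cell_id`, `mouse_id`,
#'   `group` (`"good_performer"`/`"naive"`), `projection`
#'   (`"S2-p"`/`"M1-p"`) and one column per numeric metric.
#' @param metrics character vector of metric column names; default: all
#'   numeric columns not named above.
#' @return a `vm_report` list: `descriptives` (data frame), `comparisons`
#'   (data frame with test results), `note`.
#' @export
build_report <- function(cell_metrics, metrics = NULL) {
  if (nrow(cell_metrics) == 0) validation_error("empty cohort")
  id_cols <- c("cell_id", "mouse_id", "group", "projection")
  if (is.null(metrics)) {
    metrics <- setdiff(names(cell_metrics)[vapply(cell_metrics, is.numeric,
                                                  logical(1))], id_cols)
  }
  desc <- list(); comp <- list()
  levels_df <- list(cell = cell_metrics)
  if ("mouse_id" %in% names(cell_metrics)) {
    agg <- stats::aggregate(cell_metrics[metrics],
                            by = cell_metrics[c("mouse_id", "group",
                                                "projection")], FUN = mean)
    levels_df$mouse <- agg
  }
  for (lev in names(levels_df)) {
    df <- levels_df[[lev]]
    for (m in metrics) {
      for (g in unique(df$group)) {
        for (p in unique(df$projection)) {
          v <- df[[m]][df$group == g & df$projection == p]
          v <- v[!is.na(v)]
          if (length(v) == 0) next
          desc[[length(desc) + 1]] <- data.frame(
            level = lev, metric = m, group = g, projection = p,
            t(describe_group(v)))
        }
        x <- df[[m]][df$group == g & df$projection == "S2-p"]
        y <- df[[m]][df$group == g & df$projection == "M1-p"]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) && length(y)) {
          r <- rank_sum_test(x, y)
          comp[[length(comp) + 1]] <- data.frame(
            level = lev, metric = m, comparison = "S2-p vs M1-p",
            stratum = g, n1 = r$n1, n2 = r$n2,
            statistic = r$statistic, p_value = r$p_value)
        }
      }
      for (p in unique(df$projection)) {
        x <- df[[m]][df$projection == p & df$group == "good_performer"]
        y <- df[[m]][df$projection == p & df$group == "naive"]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (length(x) && length(y)) {
          r <- rank_sum_test(x, y)
          comp[[length(comp) + 1]] <- data.frame(
            level = lev, metric = m,
            comparison = "good_performer vs naive", stratum = p,
            n1 = r$n1, n2 = r$n2, statistic = r$statistic,
            p_value = r$p_value)
        }
      }
    }
  }
  structure(list(descriptives = do.call(rbind, desc),
                 comparisons = if (length(comp)) do.call(rbind, comp)
                               else NULL,
                 note = paste("Raw p-values; two-tailed Wilcoxon tests;",
                              "no multiple-testing correction.")),
            class = "vm_report")
}

#' @export
print.vm_report <- function(x, ...) {
  cat("<vm_report>\n")
  if (!is.null(x$comparisons)) {
    cat(sprintf("  %d comparisons over %d descriptive rows\n",
                nrow(x$comparisons), nrow(x$descriptives)))
  }
  cat(" ", x$note, "\n")
  invisible(x)
}
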