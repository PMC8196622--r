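#' Compare a metric across experimental groups
#'
#' Two groups: two-sided Mann-Whitney U (Wilcoxon rank-sum). More than two:
#' one-way ANOVA with Tukey's post hoc comparisons; pairwise Mann-Whitney
#' is also available for >2 groups by request. Group summaries are reported
#' in the "median (Q1; Q3)" style.
#'
#' @param samples_by_group named list of numeric vectors, one per group,
#'   each with at least 3 values.
#' @param test "auto" (Mann-Whitney for 2 groups, ANOVA + Tukey otherwise),
#'   "mann-whitney" (pairwise for >2 groups) or "anova".
#' @param metric optional metric name carried into the result.
#' @return object of class \code{"ca_group_comparison"}: list with
#'   \code{metric}, \code{test}, \code{summaries} (named "median (Q1; Q3)"
#'   strings), \code{comparisons} (data.frame: group_a, group_b, statistic,
#'   p_value) and the raw \code{samples}.
#' @export
#' @examples
#' compare_groups(list(sham = c(5, 6, 7, 8), hypoxia = c(1, 2, 2, 3)))
compare_groups <- function(samples_by_group,
                           test = c("auto", "mann-whitney", "anova"),
                           metric = NULL) {
  test <- match.arg(test)
  g <- samples_by_group
  if (is.null(names(g)) || any(names(g) == ""))
    stop("groups must be named", call. = FALSE)
  if (length(g) < 2)
    stop("need at least 2 groups", call. = FALSE)
  sizes <- vapply(g, function(v) sum(is.finite(v)), integer(1))
  if (any(sizes < 3))
    stop("every group needs at least 3 finite samples (",
         paste(names(g)[sizes < 3], collapse = ", "), " too small)",
         call. = FALSE)
  g <- lapply(g, function(v) v[is.finite(v)])
  if (test == "auto") test <- if (length(g) == 2) "mann-whitney" else "anova"

  summaries <- vapply(g, format_median_iqr, character(1))

  if (test == "mann-whitney") {
    combos <- utils::combn(names(g), 2)
    rows <- apply(combos, 2, function(pr) {
      wt <- suppressWarnings(stats::wilcox.test(g[[pr[1]]], g[[pr[2]]],
                                                alternative = "two.sided"))
      data.frame(group_a = pr[1], group_b = pr[2],
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value, stringsAsFactors = FALSE)
    })
    comparisons <- do.call(rbind, rows)
  } else {
    values <- unlist(g, use.names = FALSE)
    grp <- factor(rep(names(g), lengths(g)), levels = names(g))
    fit <- stats::aov(values ~ grp)
    tk <- stats::TukeyHSD(fit)$grp
    nm <- strsplit(rownames(tk), "-", fixed = TRUE)
    comparisons <- data.frame(
      group_a = vapply(nm, `[`, character(1), 1),
      group_b = vapply(nm, `[`, character(1), 2),
      statistic = tk[, "diff"],
      p_value = tk[, "p adj"],
      stringsAsFactors = FALSE)
    rownames(comparisons) <- NULL
  }
  structure(list(metric = metric, test = test, summaries = summaries,
                 comparisons = comparisons, samples = g),
            class = "ca_group_comparison")
}

#' Format a sample as "median (Q1; Q3)"
#' @param x numeric vector.
#' @param digits significant digits.
#' @return character scalar, e.g. \code{"3 (2; 4)"}.
#' @export
format_median_iqr <- function(x, digits = 4) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  fmt <- function(v) format(signif(v, digits), trim = TRUE)
  sprintf("%s (%s; %s)", fmt(q[2]), fmt(q[1]), fmt(q[3]))
}

#' @export
print.ca_group_comparison <- function(x, ...) {
  cat("group comparison", if (!is.null(x$metric))
    paste0(" of ", x$metric), " [", x$test, "]\n", sep = "")
  for (nm in names(x$summaries))
    cat(sprintf("  %-20s %s\n", nm, x$summaries[[nm]]))
  for (r in seq_len(nrow(x$comparisons)))
    cat(sprintf("  %s vs %s: statistic = %.4g, p = %.4g\n",
                x$comparisons$group_a[r], x$comparisons$group_b[r],
                x$comparisons$statistic[r], x$comparisons$p_value[r]))
  invisible(x)
}
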