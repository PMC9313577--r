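#' Spearman rank correlation of a value against age
#'
#' Spearman's rho on midranks (average ranks for ties), with a two-sided
#' asymptotic p-value (t approximation, the convention recorded in the
#' result). This is the trend statistic used for all age relationships;
#' no regression line is fitted.
#'
#' @param age,value numeric vectors of equal length, \eqn{n \ge 3}.
#' @param grouping optional character tag (tissue/compartment/subset)
#'   carried into the result.
#' @return a \code{trend_result}: \code{rho}, \code{p_value}, \code{n},
#'   \code{grouping}, \code{method}.
#' @examples
#' spearman_trend(1:6, c(10, 9, 7, 6, 4, 2))  # rho = -1
#' @export
spearman_trend <- function(age, value, grouping = NA_character_) {
  age <- as.numeric(age); value <- as.numeric(value)
  if (length(age) != length(value))
    stop("age and value must have equal length", call. = FALSE)
  keep <- is.finite(age) & is.finite(value)
  age <- age[keep]; value <- value[keep]
  n <- length(age)
  if (n < 3L)
    stop("at least 3 complete pairs required for a Spearman trend",
         call. = FALSE)
  if (length(unique(age)) < 2L || length(unique(value)) < 2L)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(age, value, method = "spearman", exact = FALSE,
                    alternative = "two.sided"))
  structure(list(grouping = grouping, rho = unname(ct$estimate),
                 p_value = ct$p.value, n = n,
                 method = "Spearman (midranks, asymptotic two-sided p)"),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat("Spearman trend", if (!is.na(x$grouping)) paste0("[", x$grouping, "]"),
      sprintf(": rho = %.4f, p = %.4g, n = %d\n", x$rho, x$p_value, x$n))
  invisible(x)
}

#' Kruskal-Wallis comparison across groups
#'
#' Rank-based comparison of two or more groups (typically tissues), with tie
#' correction and a chi-square approximation on \eqn{g - 1} degrees of
#' freedom.
#'
#' @param groups named or unnamed list of numeric vectors, each non-empty.
#' @return a \code{group_comparison_result}: \code{H}, \code{p_value},
#'   \code{df}, \code{group_sizes}, \code{groups} (labels), \code{method}.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least two groups required", call. = FALSE)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0L)) stop("every group must be non-empty", call. = FALSE)
  vals <- unlist(groups, use.names = FALSE)
  if (length(vals) < 3L) stop("total n must be at least 3", call. = FALSE)
  if (length(unique(vals)) == 1L)
    stop("all values identical across groups: H is degenerate", call. = FALSE)
  g <- factor(rep(seq_along(groups), times = sizes))
  kt <- stats::kruskal.test(vals, g)
  structure(list(groups = names(groups) %||% as.character(seq_along(groups)),
                 H = unname(kt$statistic), p_value = kt$p.value,
                 df = unname(kt$parameter), group_sizes = sizes,
                 method = "Kruskal-Wallis (tie-corrected, chi-square approx.)"),
            class = "group_comparison_result")
}

#' @export
print.group_comparison_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g (n = %s)\n",
              x$H, x$df, x$p_value,
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Median and interquartile range
#'
#' Aggregate summaries are reported as median and IQR because subset
#' frequencies are non-normally distributed. Percentiles use linear
#' interpolation (quantile type 7, the convention recorded in the result).
#'
#' @param values numeric vector, \eqn{n \ge 1}.
#' @return named numeric vector \code{c(median, q1, q3)} with attribute
#'   \code{method}.
#' @examples
#' median_iqr(c(1, 2, 3, 4))  # median 2.5
#' @export
median_iqr <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) == 0L)
    stop("median/IQR undefined for empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  structure(c(median = q[1], q1 = q[2], q3 = q[3]),
            method = "quantile type 7 (linear interpolation)")
}

#' Age-trend table over a cohort
#'
#' Runs \code{\link{spearman_trend}} of subset frequency against donor age
#' for every (tissue, compartment, subset) stratum of a cohort table.
#' Strata with fewer than 3 donors or a constant frequency are skipped.
#'
#' @param cohort a \code{cohort_table} from \code{\link{cohort_frequencies}}.
#' @param adjust apply Benjamini-Hochberg correction to the p-values
#'   (off by default: each trend is reported at its nominal p).
#' @return data.frame with one row per stratum: \code{tissue},
#'   \code{compartment}, \code{subset}, \code{rho}, \code{p_value}, \code{n}.
#' @export
cohort_age_trends <- function(cohort, adjust = FALSE) {
  stopifnot(is.data.frame(cohort))
  need <- c("tissue", "compartment", "subset", "age_years", "frequency")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  strata <- unique(cohort[c("tissue", "compartment", "subset")])
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    s <- strata[i, ]
    sel <- cohort$tissue == s$tissue & cohort$compartment == s$compartment &
      cohort$subset == s$subset
    tr <- tryCatch(
      spearman_trend(cohort$age_years[sel], cohort$frequency[sel],
                     grouping = paste(s$tissue, s$compartment, s$subset,
                                      sep = "/")),
      error = function(e) NULL)
    if (!is.null(tr))
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = s$tissue, compartment = s$compartment, subset = s$subset,
        rho = tr$rho, p_value = tr$p_value, n = tr$n,
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no stratum had enough data for a trend",
                          call. = FALSE)
  out <- do.call(rbind, rows)
  if (isTRUE(adjust)) out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  rownames(out) <- NULL
  out
}
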