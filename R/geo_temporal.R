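#' Positive-sentiment proportions by city or local hour
#'
#' @param results a [classify_corpus()] tibble carrying the grouping column
#'   (`city`, or `local_hour_bin` after [localize_timestamps()]).
#' @param grouping `"city"` or `"hour"`.
#' @return list with `table` (tibble: `group`, `n_positive`, `n_total`,
#'   `percent_positive`, one row per observed group, sorted by group) and
#'   `median_percent` across groups.
#' @export
proportion_by_group <- function(results, grouping = c("city", "hour")) {
  grouping <- match.arg(grouping)
  col <- if (grouping == "city") "city" else "local_hour_bin"
  g <- results[[col]]
  if (is.null(g) || anyNA(g)) {
    stop("every result must carry the grouping attribute '", col, "'")
  }
  pos <- results$hybrid_polarity == "positive"
  n_total <- tapply(pos, g, length)
  n_pos <- tapply(pos, g, sum)
  groups <- names(n_total)
  if (grouping == "hour") {
    ord <- order(as.integer(groups))
  } else {
    ord <- order(groups)
  }
  tab <- tibble::tibble(
    group = groups[ord],
    n_positive = as.integer(n_pos[ord]),
    n_total = as.integer(n_total[ord]),
    percent_positive = 100 * as.numeric(n_pos[ord]) / as.numeric(n_total[ord])
  )
  list(table = tab, median_percent = stats::median(tab$percent_positive))
}

#' Chi-square test of homogeneity of positive proportions
#'
#' Pearson chi-square on the k x 2 (positive, negative) contingency table,
#' `df = k - 1`, two-sided p from the chi-square distribution, without
#' continuity correction. A warning is attached when any expected cell count
#' falls below 1.
#'
#' @param table a `proportion_by_group()$table` tibble (columns `n_positive`,
#'   `n_total`).
#' @return list: `statistic`, `df`, `p`, `warning` (NULL or a message).
#' @export
homogeneity_test <- function(table) {
  stopifnot(all(c("n_positive", "n_total") %in% names(table)))
  if (nrow(table) < 2L) stop("need at least 2 groups")
  if (any(table$n_total <= 0)) stop("all groups must have n_total > 0")
  mat <- cbind(positive = table$n_positive,
               negative = table$n_total - table$n_positive)
  expected <- outer(rowSums(mat), colSums(mat)) / sum(mat)
  warn <- NULL
  if (any(expected < 1)) {
    warn <- "expected cell count < 1; chi-square approximation is unreliable"
    warning(warn)
  }
  ht <- suppressWarnings(stats::chisq.test(mat, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), warning = warn)
}

#' Spearman rank correlation between a city covariate and sentiment
#'
#' Spearman's rho with average ranks for ties; the two-sided p-value uses the
#' t approximation with `n - 2` degrees of freedom.
#'
#' @param x city covariate vector (e.g. percent uninsured).
#' @param y percent-positive vector, same city order.
#' @return list of class `correlation_result`: `rho`, `p`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("need at least 4 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("rho is undefined for a constant vector")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  structure(list(rho = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' Correlate city-level covariates with percent-positive sentiment
#'
#' Convenience wrapper running [spearman_correlation()] for every numeric
#' covariate column against the cities' percent positive.
#'
#' @param city_table a `proportion_by_group(results, "city")$table` tibble.
#' @param covariates data frame with a `city` column plus numeric covariate
#'   columns (the documented schema: population, density, median_age,
#'   pct_hs_grad, pct_bachelors, median_income, pct_below_poverty,
#'   pct_uninsured, sep_avg_high_temp, sep_precip_days, latitude, longitude).
#' @return tibble: `variable`, `rho`, `p`, `n`, sorted by `|rho|` descending.
#' @export
correlate_covariates <- function(city_table, covariates) {
  stopifnot("city" %in% names(covariates))
  merged <- merge(data.frame(city = city_table$group,
                             percent_positive = city_table$percent_positive),
                  covariates, by = "city")
  vars <- setdiff(names(covariates), c("city", "utc_offset"))
  vars <- vars[vapply(merged[vars], is.numeric, logical(1))]
  rows <- lapply(vars, function(v) {
    res <- spearman_correlation(merged[[v]], merged$percent_positive)
    tibble::tibble(variable = v, rho = res$rho, p = res$p, n = res$n)
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$rho)), ]
}
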