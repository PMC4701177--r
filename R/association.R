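#' Spearman rank correlation with tie handling
#'
#' rho is the Pearson correlation of midranks (average ranks for ties). The
#' p-value uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`;
#' for n <= 10 without ties the exact permutation distribution (AS 89) is
#' used instead.
#'
#' @param x,y numeric vectors of equal length >= 4; pairs with `NA` dropped
#' @return list with `rho`, `p.value`, `n`, `method`
#' @export
spearman_correlation <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4)
    stop_msrs("need >= 4 complete pairs", class = "msrs_insufficient_data")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_msrs("correlation undefined for constant input", class = "msrs_degenerate_error")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !has_ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    method <- "exact"
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p.value = p, n = n, method = method)
}

#' Group means with standard errors
#'
#' Summarizes per-monkey scores by a demographic grouping (dominance rank
#' thirds or sex). Monkeys lacking a demographics record are reported under
#' `"unmatched"`.
#'
#' @param scores named numeric vector from [per_monkey_scores()]
#' @param demo an `msrs_demographics`
#' @param by grouping variable: `"rank"` or `"sex"`
#' @return data frame with `level`, `mean`, `sem`, `n`
#' @export
group_summary <- function(scores, demo, by = c("rank", "sex")) {
  by <- match.arg(by)
  ids <- as.integer(names(scores))
  grp <- as.character(demo[[by]][match(ids, demo$monkey_id)])
  grp[is.na(grp)] <- "unmatched"
  levels_seen <- unique(grp)
  out <- do.call(rbind, lapply(levels_seen, function(g) {
    v <- scores[grp == g]
    data.frame(level = g, mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  }))
  order_pref <- c("low", "middle", "high", "female", "male", "unknown", "unmatched")
  out <- out[order(match(out$level, order_pref, nomatch = 99L)), ]
  rownames(out) <- NULL
  out
}

#' Demographic association report
#'
#' Spearman correlation of per-monkey scores with age, plus group summaries
#' by rank and sex.
#'
#' @inheritParams group_summary
#' @return list of class `msrs_association`
#' @export
association_report <- function(scores, demo) {
  ids <- as.integer(names(scores))
  age <- demo$age_years[match(ids, demo$monkey_id)]
  sp <- spearman_correlation(age, as.numeric(scores))
  structure(list(spearman_rho = sp$rho, spearman_p = sp$p.value,
                 spearman_n = sp$n, spearman_method = sp$method,
                 by_rank = group_summary(scores, demo, "rank"),
                 by_sex = group_summary(scores, demo, "sex")),
            class = "msrs_association")
}

#' @export
print.msrs_association <- function(x, ...) {
  cat(sprintf("<msrs_association> age Spearman rho = %.3f (p = %.3g, n = %d)\n",
              x$spearman_rho, x$spearman_p, x$spearman_n))
  invisible(x)
}
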