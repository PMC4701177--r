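#' Score a single item response
#'
#' Responses are on a 1..4 ordinal scale. Normally-keyed items score
#' `response - 1`; reverse-keyed items score `4 - response`, so that higher
#' scores always indicate greater social impairment. A complete 36-item
#' survey therefore totals between 0 and 108.
#'
#' @param response integer vector in 1..4 (`NA` allowed, passed through)
#' @param reverse_keyed logical vector (recycled)
#' @return integer scores in 0..3
#' @examples
#' score_item(1, FALSE)  # 0
#' score_item(4, TRUE)   # 0
#' @export
score_item <- function(response, reverse_keyed) {
  bad <- !is.na(response) & !(response %in% 1:4)
  if (any(bad))
    stop_msrs("response out of range 1..4: ", paste(utils::head(response[bad], 5), collapse = ", "),
              class = "msrs_domain_error")
  n <- max(length(response), length(reverse_keyed))
  r <- rep_len(as.integer(response), n)
  rev <- rep_len(as.logical(reverse_keyed), n)
  out <- r - 1L
  out[rev] <- 4L - r[rev]
  out
}

#' Per-survey item-score matrix
#'
#' One row per survey (rater x monkey pair), one column per item, values are
#' reverse-keyed scores 0..3 with `NA` for skipped answers.
#'
#' @param table an `msrs_survey`
#' @param raters optional rater id subset
#' @param monkeys optional monkey id subset
#' @return list with `scores` (matrix), `rater_id`, `monkey_id`
#' @export
item_score_matrix <- function(table, raters = NULL, monkeys = NULL) {
  q <- table$questionnaire
  r <- table$responses
  if (!is.null(raters)) r <- r[r$rater_id %in% raters, ]
  if (!is.null(monkeys)) r <- r[r$monkey_id %in% monkeys, ]
  keys <- unique(r[c("rater_id", "monkey_id")])
  rownames(keys) <- NULL
  m <- matrix(NA_integer_, nrow(keys), n_items(q),
              dimnames = list(NULL, sprintf("item_%02d", q$item_id)))
  rev <- q$reverse_keyed[match(r$item_id, q$item_id)]
  sc <- score_item(r$response, rev)
  idx <- match(paste(r$rater_id, r$monkey_id), paste(keys$rater_id, keys$monkey_id))
  m[cbind(idx, match(r$item_id, q$item_id))] <- sc
  list(scores = m, rater_id = keys$rater_id, monkey_id = keys$monkey_id)
}

#' Total score of a scored survey
#'
#' @param scores numeric vector of item scores (0..3, `NA` = skipped)
#' @param missing_policy `"strict"` returns `NA` when any item is missing;
#'   `"prorate"` rescales the mean of answered items to the full item count
#'   and rounds half-up.
#' @param n_total total number of items on the form (defaults to
#'   `length(scores)`)
#' @return integer total or `NA`
#' @export
total_score <- function(scores, missing_policy = c("strict", "prorate"),
                        n_total = length(scores)) {
  missing_policy <- match.arg(missing_policy)
  n_ans <- sum(!is.na(scores))
  if (n_ans == 0) return(NA_integer_)
  if (missing_policy == "strict") {
    if (n_ans < n_total) return(NA_integer_)
    return(as.integer(sum(scores)))
  }
  as.integer(floor(n_total * mean(scores, na.rm = TRUE) + 0.5))
}

#' Score every survey in a table
#'
#' @inheritParams item_score_matrix
#' @param missing_policy see [total_score()]
#' @return data frame with `rater_id`, `monkey_id`, `n_answered`, `total`
#' @export
score_surveys <- function(table, missing_policy = c("strict", "prorate")) {
  missing_policy <- match.arg(missing_policy)
  ism <- item_score_matrix(table)
  totals <- apply(ism$scores, 1, total_score, missing_policy = missing_policy,
                  n_total = ncol(ism$scores))
  data.frame(rater_id = ism$rater_id, monkey_id = ism$monkey_id,
             n_answered = rowSums(!is.na(ism$scores)),
             total = as.integer(totals))
}

#' Collapse survey totals to one score per monkey
#'
#' Monkeys rated by several raters contribute several surveys; the
#' distributional analysis operates on one value per monkey.
#'
#' @inheritParams score_surveys
#' @param aggregation how to collapse multiple surveys per monkey
#' @return named numeric vector, names are monkey ids
#' @export
per_monkey_scores <- function(table, aggregation = c("mean", "median", "first"),
                              missing_policy = c("prorate", "strict")) {
  aggregation <- match.arg(aggregation)
  missing_policy <- match.arg(missing_policy)
  sc <- score_surveys(table, missing_policy)
  sc <- sc[!is.na(sc$total), ]
  if (nrow(sc) == 0) return(stats::setNames(numeric(0), character(0)))
  f <- switch(aggregation, mean = mean, median = stats::median,
              first = function(x) x[[1]])
  agg <- tapply(sc$total, sc$monkey_id, f)
  stats::setNames(as.numeric(agg), names(agg))
}

#' Sample skewness
#'
#' @param x numeric vector
#' @param type `"g1"` is the biased moment estimator `m3 / m2^(3/2)` (the
#'   common statistics-toolbox default); `"G1"` applies the small-sample
#'   bias correction `g1 * sqrt(n(n-1))/(n-2)`.
#' @return skewness estimate (`NaN` for constant input)
#' @export
skewness <- function(x, type = c("g1", "G1")) {
  type <- match.arg(type)
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  if (type == "G1") g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g1
}

#' Distribution summary with outlier detection
#'
#' Mean, SD (n-1 denominator), skewness, a Lilliefors normality test, and
#' the k-SD outlier rule: scores strictly greater than `mean + outlier_k * sd`
#' are flagged.
#'
#' @param scores named numeric vector (names = monkey ids) or plain vector
#' @param outlier_k SD multiplier for the upper outlier threshold
#' @param n_mc Monte-Carlo replicates for the Lilliefors p-value
#' @param seed RNG seed for the Monte-Carlo null
#' @param skew_type see [skewness()]
#' @return list of class `msrs_distribution`
#' @export
distribution_summary <- function(scores, outlier_k = 2, n_mc = 10000,
                                 seed = NULL, skew_type = "g1") {
  x <- scores[!is.na(scores)]
  if (length(x) < 4)
    stop_msrs("need at least 4 scores, got ", length(x),
              class = "msrs_insufficient_data")
  mu <- mean(x)
  s <- stats::sd(x)
  thr <- mu + outlier_k * s
  out_idx <- which(x > thr)
  if (s > 0) {
    lt <- lilliefors_test(x, n_mc = n_mc, seed = seed)
    skew <- skewness(x, skew_type)
  } else {
    lt <- list(statistic = NA_real_, p.value = NA_real_)
    skew <- NaN
  }
  structure(list(
    n = length(x), mean = mu, sd = s, skewness = skew,
    ks_stat = lt$statistic, ks_p = lt$p.value,
    outlier_threshold = thr,
    outlier_ids = if (!is.null(names(x))) names(x)[out_idx] else out_idx,
    outlier_scores = unname(x[out_idx]),
    outlier_k = outlier_k
  ), class = "msrs_distribution")
}

#' @export
print.msrs_distribution <- function(x, ...) {
  cat(sprintf("<msrs_distribution> n=%d mean=%.2f sd=%.2f skew=%.2f KS=%.3f p=%.3g outliers=%d (> %.2f)\n",
              x$n, x$mean, x$sd, x$skewness, x$ks_stat, x$ks_p,
              length(x$outlier_ids), x$outlier_threshold))
  invisible(x)
}
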