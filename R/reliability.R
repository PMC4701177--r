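#' Two-way average-measures intraclass correlation
#'
#' Computes the two-way mixed, average-measures ICC from the classical
#' subjects x raters ANOVA decomposition. With `MSR` the between-subject
#' mean square, `MSC` the between-rater mean square and `MSE` the residual:
#'
#' * `consistency` (McGraw-Wong C-k): `(MSR - MSE) / MSR` — insensitive to
#'   per-rater additive offsets;
#' * `absolute` (McGraw-Wong A-k): `(MSR - MSE) / (MSR + (MSC - MSE)/n)` —
#'   penalizes rater mean differences.
#'
#' @param m numeric matrix, subjects in rows, raters in columns, complete
#'   cases only (rows with `NA` are dropped with a message).
#' @param variant `"consistency"` (default) or `"absolute"`
#' @return ICC value (<= 1, possibly negative)
#' @export
icc_twoway <- function(m, variant = c("consistency", "absolute")) {
  variant <- match.arg(variant)
  m <- as.matrix(m)
  keep <- stats::complete.cases(m)
  if (!all(keep)) {
    message(sum(!keep), " incomplete row(s) dropped from ICC matrix")
    m <- m[keep, , drop = FALSE]
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2)
    stop_msrs("ICC needs >= 2 subjects and >= 2 raters (got ", n, " x ", k, ")",
              class = "msrs_domain_error")
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - gm)^2)
  ss_cols <- n * sum((col_m - gm)^2)
  ss_tot <- sum((m - gm)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr == 0 && mse == 0)
    stop_msrs("ICC undefined: zero between-subject and error variance",
              class = "msrs_degenerate_error")
  switch(variant,
         consistency = (msr - mse) / msr,
         absolute = (msr - mse) / (msr + (msc - mse) / n))
}

#' Pairwise inter-rater ICCs over shared monkeys
#'
#' In sparse multi-rater designs most rater pairs never rate the same
#' animals; an ICC is computed for every pair sharing at least `min_shared`
#' monkeys. With `scores = "totals"` the two columns are the raters'
#' per-survey total scores over the shared monkeys (so each pair's ICC rests
#' on as few as `min_shared` rows and can be wildly negative when those few
#' monkeys happen to have similar totals); with `scores = "items"` the rows
#' are the concatenated (monkey, item) scores, which is far more stable on
#' small shared sets and matches the reading of rater reliability "on the
#' 36-item survey".
#'
#' @param table an `msrs_survey`
#' @param min_shared minimum number of shared monkeys for a pair to qualify
#' @param variant passed to [icc_twoway()]
#' @param scores rating unit for each pair's matrix: `"totals"` or `"items"`
#' @param raters optional rater id subset (e.g. the sparse main sample,
#'   excluding a complete follow-up block)
#' @param missing_policy passed to [score_surveys()]; prorated totals keep
#'   surveys with skipped items usable
#' @return list of class `msrs_pairwise_icc`: `pairs` (data frame with
#'   `rater_a`, `rater_b`, `n_shared`, `icc`), `mean_icc`,
#'   `n_possible_pairs` = choose(n_raters, 2), `variant`
#' @export
pairwise_icc <- function(table, min_shared = 3,
                         variant = c("consistency", "absolute"),
                         scores = c("totals", "items"),
                         raters = NULL,
                         missing_policy = c("prorate", "strict")) {
  variant <- match.arg(variant)
  scores <- match.arg(scores)
  sc <- score_surveys(table, match.arg(missing_policy))
  sc <- sc[!is.na(sc$total), ]
  if (!is.null(raters)) sc <- sc[sc$rater_id %in% raters, ]
  ism <- if (scores == "items") item_score_matrix(table) else NULL
  pair_matrix <- function(a, b, shared) {
    if (scores == "totals") {
      ta <- sc$total[match(paste(a, shared), paste(sc$rater_id, sc$monkey_id))]
      tb <- sc$total[match(paste(b, shared), paste(sc$rater_id, sc$monkey_id))]
      return(cbind(ta, tb))
    }
    rows_a <- match(paste(a, shared), paste(ism$rater_id, ism$monkey_id))
    rows_b <- match(paste(b, shared), paste(ism$rater_id, ism$monkey_id))
    m <- cbind(as.vector(t(ism$scores[rows_a, , drop = FALSE])),
               as.vector(t(ism$scores[rows_b, , drop = FALSE])))
    m[stats::complete.cases(m), , drop = FALSE]
  }
  raters <- sort(unique(sc$rater_id))
  n_possible <- choose(length(raters), 2)
  rows <- list()
  if (length(raters) >= 2) {
    cmb <- utils::combn(raters, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      shared <- intersect(sc$monkey_id[sc$rater_id == a],
                          sc$monkey_id[sc$rater_id == b])
      if (length(shared) >= min_shared) {
        m <- pair_matrix(a, b, shared)
        icc <- tryCatch(icc_twoway(m, variant), msrs_degenerate_error = function(e) NA_real_)
        rows[[length(rows) + 1]] <- data.frame(
          rater_a = a, rater_b = b, n_shared = length(shared), icc = icc)
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(rater_a = integer(), rater_b = integer(),
               n_shared = integer(), icc = numeric())
  if (nrow(pairs) == 0) warning("no rater pair shares >= ", min_shared, " monkeys")
  structure(list(pairs = pairs,
                 mean_icc = if (nrow(pairs)) mean(pairs$icc, na.rm = TRUE) else NA_real_,
                 n_possible_pairs = n_possible,
                 n_qualifying_pairs = nrow(pairs),
                 min_shared = min_shared, variant = variant, scores = scores),
            class = "msrs_pairwise_icc")
}

#' @export
print.msrs_pairwise_icc <- function(x, ...) {
  cat(sprintf("<msrs_pairwise_icc> %d of %d possible pairs qualify (>= %d shared); mean ICC = %.3f [%s]\n",
              x$n_qualifying_pairs, x$n_possible_pairs, x$min_shared,
              x$mean_icc, x$variant))
  invisible(x)
}

#' Cronbach's alpha
#'
#' `alpha = k/(k-1) * (1 - sum(column variances) / var(row sums))` for a
#' cases x measurements matrix. Here the "measurements" are raters scoring
#' one item and the cases are monkeys, so alpha measures rater agreement on
#' that item; it is negative when raters are anti-correlated.
#'
#' @param m numeric matrix, cases in rows, measurements (raters) in columns
#' @return alpha, or `NA` with attribute `zero_variance = TRUE` when the
#'   total score has no variance
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2)
    stop_msrs("alpha needs >= 2 measurement columns", class = "msrs_domain_error")
  if (nrow(m) < 2)
    stop_msrs("alpha needs >= 2 cases", class = "msrs_domain_error")
  v_tot <- stats::var(rowSums(m))
  if (v_tot == 0)
    return(structure(NA_real_, zero_variance = TRUE))
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / v_tot)
}

#' Per-item reliability over a complete rater block
#'
#' For a block of raters who all rated the same monkeys (e.g. a 4-rater x
#' 16-monkey follow-up set), computes Cronbach's alpha per item with raters
#' as the parallel measurements. Items whose scores never vary are flagged
#' `ZERO_VARIANCE`; the retained set is items with positive alpha *and*
#' nonzero variance — the set passed on to factor analysis.
#'
#' @param table an `msrs_survey`
#' @param block_raters rater ids forming the complete block
#' @return list of class `msrs_item_reliability`: `item_alphas` (named
#'   numeric, `NA` for zero-variance), `zero_variance_items`,
#'   `negative_alpha_items`, `retained_items`
#' @export
item_reliability <- function(table, block_raters) {
  r <- table$responses
  if (!all(block_raters %in% r$rater_id))
    stop_msrs("block rater(s) absent from table: ",
              paste(setdiff(block_raters, r$rater_id), collapse = ", "),
              class = "msrs_lookup_error")
  q <- table$questionnaire
  ism <- item_score_matrix(table, raters = block_raters)
  monkeys <- sort(unique(ism$monkey_id))
  alphas <- stats::setNames(rep(NA_real_, n_items(q)), q$item_id)
  zero_var <- logical(n_items(q))
  for (ii in seq_len(n_items(q))) {
    # monkeys x raters matrix for this item; complete cases per item
    m <- matrix(NA_real_, length(monkeys), length(block_raters))
    for (jj in seq_along(block_raters)) {
      sel <- ism$rater_id == block_raters[jj]
      m[match(ism$monkey_id[sel], monkeys), jj] <- ism$scores[sel, ii]
    }
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 2 || all(m == m[1])) { zero_var[ii] <- TRUE; next }
    a <- cronbach_alpha(m)
    if (isTRUE(attr(a, "zero_variance"))) zero_var[ii] <- TRUE else alphas[ii] <- a
  }
  retained <- q$item_id[!zero_var & !is.na(alphas) & alphas > 0]
  structure(list(item_alphas = alphas,
                 zero_variance_items = q$item_id[zero_var],
                 negative_alpha_items = q$item_id[!zero_var & !is.na(alphas) & alphas <= 0],
                 retained_items = retained,
                 block_raters = block_raters),
            class = "msrs_item_reliability")
}

#' @export
print.msrs_item_reliability <- function(x, ...) {
  cat(sprintf("<msrs_item_reliability> %d retained / %d negative-alpha / %d zero-variance items\n",
              length(x$retained_items), length(x$negative_alpha_items),
              length(x$zero_variance_items)))
  invisible(x)
}

#' Full reliability report
#'
#' Combines the pairwise inter-rater ICCs over the sparse sample with the
#' per-item alpha analysis over a complete rater block, and, when the block
#' is present, the all-rater average-measures ICC for the block.
#'
#' @inheritParams pairwise_icc
#' @param block_raters rater ids of the complete block (`NULL` to skip the
#'   item-level analysis)
#' @return list of class `msrs_reliability`
#' @export
reliability_report <- function(table, block_raters = NULL, min_shared = 3,
                               variant = c("consistency", "absolute")) {
  variant <- match.arg(variant)
  pw <- pairwise_icc(table, min_shared = min_shared, variant = variant)
  item_rel <- NULL
  block_icc <- NA_real_
  if (!is.null(block_raters)) {
    item_rel <- item_reliability(table, block_raters)
    sc <- score_surveys(table, "prorate")
    sc <- sc[sc$rater_id %in% block_raters & !is.na(sc$total), ]
    wide <- stats::reshape(sc[c("monkey_id", "rater_id", "total")],
                           idvar = "monkey_id", timevar = "rater_id",
                           direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    if (nrow(m) >= 2 && ncol(m) >= 2)
      block_icc <- icc_twoway(m, variant)
  }
  structure(list(pairwise = pw, block_icc = block_icc, item_reliability = item_rel,
                 variant = variant),
            class = "msrs_reliability")
}
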