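#' Run the full validation pipeline
#'
#' Executes the analysis stages in the validation order: score surveys,
#' per-monkey distribution with outlier detection, pairwise inter-rater
#' ICCs, per-item alpha over the complete block, item filtering
#' (drop zero-variance and non-positive-alpha items), eigenvalue bootstrap
#' retention, ML + varimax factor analysis with bootstrapped loadings, and
#' demographic associations. One master seed drives every stochastic stage
#' through stage-derived substreams, so stages can be re-run in isolation.
#'
#' @param table an `msrs_survey` (or path to a long-format CSV)
#' @param demographics an `msrs_demographics` (or path)
#' @param block_raters rater ids of the complete block used for item-level
#'   reliability (`NULL` disables the item filter and factor analysis runs
#'   on all non-constant items)
#' @param seed master seed
#' @param n_boot bootstrap replicates for eigenvalue retention and loadings
#' @param aggregation per-monkey collapse rule for the distribution stage
#' @param outlier_k SD multiplier for outlier flagging
#' @param min_shared minimum shared monkeys per rater pair
#' @param icc_variant `"consistency"` or `"absolute"`
#' @param k_override force the number of factors (default: bootstrap
#'   retention count, minimum 1)
#' @return list of class `msrs_report` with each stage's output and a
#'   config/provenance echo
#' @export
run_pipeline <- function(table, demographics, block_raters = NULL,
                         seed = 1L, n_boot = 1000,
                         aggregation = "mean", outlier_k = 2,
                         min_shared = 3, icc_variant = "consistency",
                         k_override = NULL) {
  if (is.character(table)) table <- read_survey(table)
  if (is.character(demographics)) demographics <- read_demographics(demographics)
  config <- list(seed = seed, n_boot = n_boot, aggregation = aggregation,
                 outlier_k = outlier_k, min_shared = min_shared,
                 icc_variant = icc_variant, block_raters = block_raters,
                 k_override = k_override)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_msrs("pipeline stage '", name, "' failed: ", conditionMessage(e),
                class = "msrs_pipeline_error")
    })
  }

  scores <- stage("scoring", per_monkey_scores(table, aggregation))
  dist <- stage("distribution",
                distribution_summary(scores, outlier_k = outlier_k,
                                     n_mc = max(n_boot, 1000),
                                     seed = derive_seed(seed, "lilliefors")))
  rel <- stage("reliability",
               reliability_report(table, block_raters = block_raters,
                                  min_shared = min_shared, variant = icc_variant))

  q <- table$questionnaire
  if (!is.null(rel$item_reliability)) {
    retained <- rel$item_reliability$retained_items
  } else {
    ism_all <- item_score_matrix(table)
    ok <- apply(ism_all$scores, 2, function(v) stats::sd(v, na.rm = TRUE) > 0)
    retained <- q$item_id[ok]
  }
  if (length(retained) < 3)
    stop_msrs("pipeline stage 'item_filter' failed: fewer than 3 retained items",
              class = "msrs_pipeline_error")

  # factor analysis runs on survey-level raw item scores of retained items;
  # surveys with any skipped retained item are dropped (complete cases)
  ism <- item_score_matrix(table)
  cols <- match(retained, q$item_id)
  xm <- ism$scores[, cols, drop = FALSE]
  xm <- xm[stats::complete.cases(xm), , drop = FALSE]
  eig <- stage("eigen_retention",
               bootstrap_eigen_retention(xm, n_boot = n_boot,
                                         seed = derive_seed(seed, "eigen")))
  k <- k_override %||% max(eig$n_retained, 1L)
  efa <- stage("factor_analysis",
               bootstrap_loadings(xm, k, n_boot = n_boot,
                                  seed = derive_seed(seed, "loadings")))
  assoc <- stage("association", association_report(scores, demographics))

  structure(list(config = config,
                 n_surveys = n_surveys(table),
                 n_monkeys = length(unique(table$responses$monkey_id)),
                 n_raters = length(unique(table$responses$rater_id)),
                 distribution = dist,
                 reliability = rel,
                 retained_items = retained,
                 eigen = eig,
                 efa = efa,
                 association = assoc,
                 provenance = list(seed = seed,
                                   package_version = as.character(utils::packageVersion("msrs")),
                                   r_version = R.version.string,
                                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "msrs_report")
}

#' @export
print.msrs_report <- function(x, ...) {
  cat("== mSRS validation report ==\n")
  cat(sprintf("%d surveys / %d monkeys / %d raters\n",
              x$n_surveys, x$n_monkeys, x$n_raters))
  print(x$distribution)
  print(x$reliability$pairwise)
  if (!is.null(x$reliability$item_reliability)) print(x$reliability$item_reliability)
  cat(sprintf("retained items: %s\n", paste(x$retained_items, collapse = ", ")))
  print(x$eigen)
  print(x$efa)
  print(x$association)
  invisible(x)
}

report_to_list <- function(x) {
  strip <- function(v) if (is.matrix(v)) apply(v, 2, as.numeric, simplify = FALSE) else v
  list(
    config = x$config,
    counts = list(n_surveys = x$n_surveys, n_monkeys = x$n_monkeys,
                  n_raters = x$n_raters),
    distribution = unclass(x$distribution),
    pairwise_icc = list(pairs = x$reliability$pairwise$pairs,
                        mean_icc = x$reliability$pairwise$mean_icc,
                        n_possible_pairs = x$reliability$pairwise$n_possible_pairs,
                        variant = x$reliability$pairwise$variant),
    block_icc = x$reliability$block_icc,
    item_reliability = if (is.null(x$reliability$item_reliability)) NULL else
      unclass(x$reliability$item_reliability),
    retained_items = x$retained_items,
    eigen = unclass(x$eigen),
    efa = list(loadings = x$efa$solution$loadings,
               uniquenesses = x$efa$solution$uniquenesses,
               var_explained = x$efa$solution$var_explained,
               boot_median = x$efa$boot_median,
               boot_lower = x$efa$boot_lower,
               boot_upper = x$efa$boot_upper,
               significant = x$efa$significant,
               n_boot = x$efa$n_boot, n_failed = x$efa$n_failed,
               alignment = x$efa$alignment),
    association = unclass(x$association),
    provenance = x$provenance)
}

#' Write a pipeline report to JSON (plus a short text summary)
#'
#' @param report an `msrs_report`
#' @param dir output directory (created if needed)
#' @return paths of the written files, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report_to_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", matrix = "rowmajor")
  txt_path <- file.path(dir, "summary.txt")
  writeLines(utils::capture.output(print(report)), txt_path)
  invisible(c(json = json_path, summary = txt_path))
}
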