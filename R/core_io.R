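#' Construct a survey table
#'
#' A survey table holds long-format responses — one row per
#' (rater, monkey, item) — together with the questionnaire they answer.
#' A *survey* is the set of rows sharing one (rater, monkey) pair. Skipped
#' answers are kept as `NA` responses; they are never imputed at this layer.
#'
#' String rater/monkey ids are accepted and mapped to anonymized integers;
#' the lookup is kept in `attr(x, "id_maps")` so it can be persisted.
#'
#' @param responses data frame with columns `rater_id`, `monkey_id`,
#'   `item_id`, `response` (integer 1..4 or `NA`).
#' @param questionnaire an [msrs_questionnaire()]; defaults to the packaged
#'   36-item definition.
#' @param check if `TRUE` (default), out-of-range responses and unknown item
#'   ids raise an error naming the offending row; set `FALSE` to admit dirty
#'   data for inspection with [validate_survey()].
#' @return An object of class `msrs_survey`.
#' @export
msrs_survey <- function(responses, questionnaire = default_questionnaire(),
                        check = TRUE) {
  stopifnot(is.data.frame(responses))
  need <- c("rater_id", "monkey_id", "item_id", "response")
  miss <- setdiff(need, names(responses))
  if (length(miss))
    stop_msrs("survey table is missing column(s): ", paste(miss, collapse = ", "),
              class = "msrs_schema_error")
  responses <- as.data.frame(responses)[need]
  id_maps <- list()
  for (col in c("rater_id", "monkey_id")) {
    v <- responses[[col]]
    if (is.character(v) || is.factor(v)) {
      lev <- unique(as.character(v))
      id_maps[[col]] <- stats::setNames(seq_along(lev), lev)
      responses[[col]] <- unname(id_maps[[col]][as.character(v)])
    }
    responses[[col]] <- as.integer(responses[[col]])
  }
  responses$item_id <- as.integer(responses$item_id)
  suppressWarnings(responses$response <- as.integer(responses$response))
  if (check) {
    bad <- which(!is.na(responses$response) &
                   !(responses$response %in% 1:4))
    if (length(bad))
      stop_msrs("response outside {1..4, blank} at row(s): ",
                paste(utils::head(bad, 5), collapse = ", "),
                class = "msrs_validation_error")
    unknown <- which(!(responses$item_id %in% questionnaire$item_id))
    if (length(unknown))
      stop_msrs("item_id not in questionnaire at row(s): ",
                paste(utils::head(unknown, 5), collapse = ", "),
                class = "msrs_validation_error")
  }
  rownames(responses) <- NULL
  structure(list(responses = responses, questionnaire = questionnaire),
            id_maps = id_maps, class = "msrs_survey")
}

#' @export
print.msrs_survey <- function(x, ...) {
  r <- x$responses
  cat(sprintf("<msrs_survey> %d responses | %d surveys | %d monkeys | %d raters | %d items\n",
              nrow(r), nrow(unique(r[c("rater_id", "monkey_id")])),
              length(unique(r$monkey_id)), length(unique(r$rater_id)),
              n_items(x$questionnaire)))
  invisible(x)
}

#' Number of distinct surveys (rater x monkey pairs)
#' @param table an `msrs_survey`
#' @export
n_surveys <- function(table) nrow(unique(table$responses[c("rater_id", "monkey_id")]))

guess_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", xlsx = "xlsx",
         stop_msrs("cannot infer format from extension '", ext, "'",
                   class = "msrs_io_error"))
}

read_table_any <- function(path, format) {
  if (!file.exists(path))
    stop_msrs("file not found: ", path, class = "msrs_io_error")
  switch(format,
    csv  = utils::read.csv(path, stringsAsFactors = FALSE),
    tsv  = utils::read.delim(path, stringsAsFactors = FALSE),
    xlsx = as.data.frame(readxl::read_xlsx(path)),
    stop_msrs("unsupported format: ", format, class = "msrs_io_error"))
}

wide_item_cols <- function(questionnaire, column_map = NULL) {
  if (!is.null(column_map)) {
    stopifnot(length(column_map) == n_items(questionnaire))
    return(column_map)
  }
  sprintf("item_%02d", questionnaire$item_id)
}

#' Read a survey table from disk
#'
#' Long layout expects columns `rater_id`, `monkey_id`, `item_id`,
#' `response`; wide layout expects one row per survey with `rater_id`,
#' `monkey_id` and one column per item (`item_01`..`item_36` by default, or
#' the names supplied in `column_map`). Blank cells are skipped answers and
#' come back as `NA`.
#'
#' @inheritParams msrs_survey
#' @param path file path (CSV, TSV, or XLSX).
#' @param format `"auto"` infers from the extension.
#' @param layout `"long"` or `"wide"`.
#' @param column_map optional character vector naming the wide item columns
#'   in item order, for files that deviate from `item_01..item_NN`.
#' @return An `msrs_survey`.
#' @export
read_survey <- function(path, format = c("auto", "csv", "tsv", "xlsx"),
                        layout = c("long", "wide"),
                        questionnaire = default_questionnaire(),
                        column_map = NULL) {
  format <- guess_format(path, match.arg(format))
  layout <- match.arg(layout)
  df <- read_table_any(path, format)
  if (layout == "wide") df <- wide_to_long(df, questionnaire, column_map)
  msrs_survey(df, questionnaire)
}

wide_to_long <- function(df, questionnaire, column_map = NULL) {
  cols <- wide_item_cols(questionnaire, column_map)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_msrs("wide layout missing item column(s): ", paste(utils::head(miss, 3), collapse = ", "),
              class = "msrs_schema_error")
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    data.frame(rater_id = df$rater_id[i], monkey_id = df$monkey_id[i],
               item_id = questionnaire$item_id,
               response = suppressWarnings(as.integer(unlist(df[i, cols]))))
  }))
  rownames(out) <- NULL
  out
}

long_to_wide <- function(table) {
  q <- table$questionnaire
  r <- table$responses
  keys <- unique(r[c("rater_id", "monkey_id")])
  cols <- wide_item_cols(q)
  m <- matrix(NA_integer_, nrow(keys), n_items(q), dimnames = list(NULL, cols))
  idx <- match(paste(r$rater_id, r$monkey_id), paste(keys$rater_id, keys$monkey_id))
  m[cbind(idx, match(r$item_id, q$item_id))] <- r$response
  cbind(keys, as.data.frame(m))
}

#' Write a survey table to disk
#'
#' @param table an `msrs_survey`
#' @param path output path
#' @param format `"csv"` or `"tsv"` (no xlsx writer is available offline)
#' @param layout `"long"` or `"wide"`
#' @export
write_survey <- function(table, path, format = c("csv", "tsv"),
                         layout = c("long", "wide")) {
  format <- match.arg(format)
  layout <- match.arg(layout)
  df <- if (layout == "long") table$responses else long_to_wide(table)
  write_delim_any(df, path, format)
  invisible(path)
}

write_delim_any <- function(df, path, format) {
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, qmethod = "double",
                     na = "")
}

#' Read a demographics table
#'
#' Requires columns `monkey_id`, `age_years` (or `age`), `sex`, `rank`;
#' `housing` is optional free text. Rank levels are lower-cased and must be
#' one of low/middle/high/unknown (missing rank becomes `"unknown"`).
#'
#' @param path file path
#' @param format file format, `"auto"` infers from extension
#' @return data frame of class `msrs_demographics`
#' @export
read_demographics <- function(path, format = c("auto", "csv", "tsv", "xlsx")) {
  format <- guess_format(path, match.arg(format))
  df <- read_table_any(path, format)
  if (nrow(df) == 0) {
    warning("demographics file is empty")
    df <- data.frame(monkey_id = integer(), age_years = numeric(),
                     sex = character(), rank = character(), housing = character())
    class(df) <- c("msrs_demographics", "data.frame")
    return(df)
  }
  msrs_demographics(df)
}

#' Construct/validate a demographics table
#' @param df data frame with `monkey_id`, `age_years`/`age`, `sex`, `rank`
#'   and optionally `housing`.
#' @export
msrs_demographics <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"age_years" %in% names(df) && "age" %in% names(df))
    names(df)[names(df) == "age"] <- "age_years"
  need <- c("monkey_id", "age_years", "sex", "rank")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_msrs("demographics missing column(s): ", paste(miss, collapse = ", "),
              class = "msrs_schema_error")
  if (!"housing" %in% names(df)) df$housing <- NA_character_
  df <- as.data.frame(df)[c(need, "housing")]
  df$monkey_id <- as.integer(df$monkey_id)
  df$age_years <- as.numeric(df$age_years)
  df$sex <- tolower(as.character(df$sex))
  df$rank <- tolower(as.character(df$rank))
  df$rank[is.na(df$rank) | df$rank == ""] <- "unknown"
  bad_rank <- setdiff(unique(df$rank), c("low", "middle", "high", "unknown"))
  if (length(bad_rank))
    stop_msrs("unknown rank level(s): ", paste(bad_rank, collapse = ", "),
              class = "msrs_schema_error")
  bad_sex <- setdiff(unique(df$sex), c("female", "male"))
  if (length(bad_sex))
    stop_msrs("sex must be female/male, got: ", paste(bad_sex, collapse = ", "),
              class = "msrs_schema_error")
  if (any(!is.na(df$age_years) & df$age_years <= 0))
    stop_msrs("age_years must be positive", class = "msrs_schema_error")
  rownames(df) <- NULL
  class(df) <- c("msrs_demographics", "data.frame")
  df
}

#' Write demographics to disk
#' @inheritParams write_survey
#' @param demo an `msrs_demographics`
#' @export
write_demographics <- function(demo, path, format = c("csv", "tsv")) {
  write_delim_any(as.data.frame(demo), path, match.arg(format))
  invisible(path)
}

#' Validate a survey table (and optionally demographics) without modifying it
#'
#' All problems are *reported*, never thrown: out-of-range responses,
#' duplicate (rater, monkey, item) keys, per-item missing rates, and monkeys
#' lacking a demographics record.
#'
#' @param table an `msrs_survey` (possibly built with `check = FALSE`)
#' @param demo optional `msrs_demographics`
#' @return list of class `msrs_validation` with counts and violation tables
#' @export
validate_survey <- function(table, demo = NULL) {
  r <- table$responses
  q <- table$questionnaire
  out_of_range <- r[!is.na(r$response) & !(r$response %in% 1:4), , drop = FALSE]
  key <- paste(r$rater_id, r$monkey_id, r$item_id)
  duplicate_keys <- r[duplicated(key), , drop = FALSE]
  denom <- nrow(unique(r[c("rater_id", "monkey_id")]))
  missing_rate <- vapply(q$item_id, function(i) {
    rows <- r[r$item_id == i, ]
    n_miss <- sum(is.na(rows$response)) + (denom - nrow(rows))
    if (denom == 0) 0 else n_miss / denom
  }, numeric(1))
  names(missing_rate) <- q$item_id
  unmatched <- integer()
  if (!is.null(demo)) unmatched <- setdiff(unique(r$monkey_id), demo$monkey_id)
  structure(list(
    n_surveys = denom,
    n_monkeys = length(unique(r$monkey_id)),
    n_raters = length(unique(r$rater_id)),
    out_of_range = out_of_range,
    missing_rate = missing_rate,
    duplicate_keys = duplicate_keys,
    unmatched_monkeys = unmatched,
    n_violations = nrow(out_of_range) + nrow(duplicate_keys) + length(unmatched)
  ), class = "msrs_validation")
}

#' @export
print.msrs_validation <- function(x, ...) {
  cat(sprintf("<msrs_validation> %d surveys / %d monkeys / %d raters; %d violation(s)\n",
              x$n_surveys, x$n_monkeys, x$n_raters, x$n_violations))
  invisible(x)
}
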