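#' Construct a questionnaire definition
#'
#' A questionnaire is an ordered set of items, each with an integer id, its
#' text, and a flag marking reverse-keyed wording (items phrased so that a
#' high raw response indicates *low* impairment; their scores are flipped
#' before summing).
#'
#' @param items data frame with columns `item_id` (integer), `text`
#'   (character) and `reverse_keyed` (logical).
#' @return An object of class `msrs_questionnaire` (a validated data frame).
#' @examples
#' q <- msrs_questionnaire(data.frame(
#'   item_id = 1:3, text = c("a", "b", "c"),
#'   reverse_keyed = c(FALSE, TRUE, FALSE)))
#' n_items(q)
#' @export
msrs_questionnaire <- function(items) {
  stopifnot(is.data.frame(items))
  need <- c("item_id", "text", "reverse_keyed")
  miss <- setdiff(need, names(items))
  if (length(miss))
    stop_msrs("questionnaire is missing column(s): ", paste(miss, collapse = ", "),
              class = "msrs_schema_error")
  items <- items[need]
  items$item_id <- as.integer(items$item_id)
  items$reverse_keyed <- as.logical(items$reverse_keyed)
  if (nrow(items) < 1)
    stop_msrs("questionnaire must contain at least one item", class = "msrs_schema_error")
  if (anyDuplicated(items$item_id) || !identical(sort(items$item_id), seq_len(nrow(items))))
    stop_msrs("item_ids must be unique and contiguous 1..n", class = "msrs_schema_error")
  if (anyNA(items$reverse_keyed))
    stop_msrs("reverse_keyed flags must be TRUE/FALSE", class = "msrs_schema_error")
  items <- items[order(items$item_id), ]
  rownames(items) <- NULL
  class(items) <- c("msrs_questionnaire", "data.frame")
  items
}

#' The packaged 36-item questionnaire (synthetic stand-in)
#'
#' Loads the canonical 36-item questionnaire definition shipped with the
#' package. The published instrument's item list and reverse-key flags live in
#' a supplementary questionnaire file that is not redistributed here, so this
#' definition is a *synthetic stand-in*: item texts paraphrase the published
#' example items where those are quoted in the literature and the reverse-key
#' set is a plausible invention. Treat it as data: analyses parameterize on
#' whatever questionnaire they are given.
#'
#' @return An `msrs_questionnaire` with 36 items.
#' @export
default_questionnaire <- function() {
  path <- system.file("extdata", "msrs_questionnaire_synthetic.csv", package = "msrs")
  items <- utils::read.csv(path, stringsAsFactors = FALSE)
  msrs_questionnaire(items)
}

#' @export
print.msrs_questionnaire <- function(x, ...) {
  cat(sprintf("<msrs_questionnaire> %d items (%d reverse-keyed)\n",
              nrow(x), sum(x$reverse_keyed)))
  invisible(x)
}

#' Number of items in a questionnaire
#' @param q an `msrs_questionnaire`
#' @return integer count
#' @export
n_items <- function(q) nrow(q)

#' Reverse-keyed item ids
#' @param q an `msrs_questionnaire`
#' @return integer vector of item ids with the reverse-key flag set
#' @export
reverse_keyed_items <- function(q) q$item_id[q$reverse_keyed]
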