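# Data model and I/O for the instrument: item bank, Likert response matrix,
# screener responses and derived binary outcomes.

#' Suicide Crisis Syndrome criterion labels
#'
#' The five SCS symptom criteria used throughout the package: `A` entrapment,
#' `B1` affective disturbance, `B2` loss of cognitive control, `B3`
#' hyperarousal, `B4` social withdrawal.
#'
#' @return character vector of the five criterion tokens, in canonical order.
#' @export
scs_criteria <- function() c("A", "B1", "B2", "B3", "B4")

#' Long names of the SCS criteria
#' @return named character vector mapping token to descriptive name.
#' @export
scs_criterion_names <- function() {
  c(A  = "Entrapment",
    B1 = "Affective Disturbance",
    B2 = "Loss of Cognitive Control",
    B3 = "Hyperarousal",
    B4 = "Social Withdrawal")
}

#' Construct an item bank
#'
#' An item bank describes the instrument: one row per item with a unique id,
#' display text, SCS criterion label and a reverse-coding flag. Each of the
#' five criteria should be represented by at least one item; a bank that does
#' not cover all five is accepted with a warning and carries
#' `attr(bank, "criterion_coverage") == FALSE`.
#'
#' @param items data.frame with columns `item_id`, `text`, `criterion`
#'   (one of [scs_criteria()]) and `reverse_coded` (logical or 0/1).
#' @param version free-form version string.
#' @return an `item_bank` object (a validated data.frame).
#' @export
item_bank <- function(items, version = "unversioned") {
  stop_if(!is.data.frame(items), "`items` must be a data.frame")
  req <- c("item_id", "text", "criterion", "reverse_coded")
  missing_cols <- setdiff(req, names(items))
  stop_if(length(missing_cols) > 0,
          paste0("item bank is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  items <- items[, req]
  items$item_id <- as.character(items$item_id)
  items$text <- as.character(items$text)
  items$criterion <- as.character(items$criterion)
  items$reverse_coded <- as.logical(items$reverse_coded)

  stop_if(any(!nzchar(items$item_id)) || anyNA(items$item_id),
          "item ids must be nonempty")
  dup <- items$item_id[duplicated(items$item_id)]
  stop_if(length(dup) > 0,
          paste0("duplicate item id(s) in bank: ",
                 paste(unique(dup), collapse = ", ")))
  bad <- setdiff(unique(items$criterion), scs_criteria())
  stop_if(length(bad) > 0,
          paste0("unknown criterion label(s): ", paste(bad, collapse = ", "),
                 " (expected ", paste(scs_criteria(), collapse = ", "), ")"))
  stop_if(anyNA(items$reverse_coded), "reverse_coded must be TRUE/FALSE")

  covered <- scs_criteria() %in% items$criterion
  coverage <- all(covered)
  if (!coverage) {
    warning("item bank does not cover all five SCS criteria (missing: ",
            paste(scs_criteria()[!covered], collapse = ", "), ")",
            call. = FALSE)
  }
  rownames(items) <- NULL
  structure(items,
            version = version,
            criterion_coverage = coverage,
            class = c("item_bank", "data.frame"))
}

#' Read an item bank from a delimited file
#'
#' Expects a header `item_id,text,criterion,reverse_coded` with criterion
#' tokens exactly `A,B1,B2,B3,B4`. File order is preserved.
#'
#' @param path path to a CSV (or TSV, with `sep = "\t"`) file.
#' @param sep field separator.
#' @return an [item_bank()].
#' @export
load_item_bank <- function(path, sep = ",") {
  stop_if(!file.exists(path), paste0("item bank file not found: ", path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if ("reverse_coded" %in% names(raw)) {
    raw$reverse_coded <- raw$reverse_coded %in% c("TRUE", "True", "true", "1")
  }
  item_bank(raw, version = basename(path))
}

#' Write an item bank to CSV
#' @param bank an [item_bank()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  utils::write.csv(as.data.frame(bank), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.item_bank <- function(x, ...) {
  tab <- table(factor(x$criterion, levels = scs_criteria()))
  cat(sprintf("<item_bank> %d items (version: %s)\n", nrow(x),
              attr(x, "version")))
  cat("  per criterion:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  cat("  reverse-coded:", sum(x$reverse_coded), "item(s)\n")
  invisible(x)
}

#' Construct a Likert response matrix
#'
#' Responses are integers on the 0--4 Likert scale, one row per respondent and
#' one column per item. The object records whether reverse coding has already
#' been applied (severity scale) so that [apply_reverse_coding()] cannot be
#' applied twice.
#'
#' @param values integer matrix, entries in `0:4`.
#' @param respondent_ids optional character vector of row ids.
#' @param item_ids optional character vector of column ids (defaults to
#'   `colnames(values)`).
#' @param reverse_applied logical; `TRUE` if flagged items are already on the
#'   severity scale.
#' @return a `response_matrix` object.
#' @export
response_matrix <- function(values, respondent_ids = NULL, item_ids = NULL,
                            reverse_applied = FALSE) {
  values <- as.matrix(values)
  item_ids <- item_ids %||% colnames(values)
  stop_if(is.null(item_ids), "item ids are required (set colnames or item_ids)")
  stop_if(length(item_ids) != ncol(values),
          "item_ids length does not match number of columns")
  respondent_ids <- respondent_ids %||% rownames(values) %||%
    paste0("R", seq_len(nrow(values)))
  stop_if(length(respondent_ids) != nrow(values),
          "respondent_ids length does not match number of rows")
  stop_if(anyNA(values), "response matrix contains missing values; filter with complete_cases() first")
  stop_if(!all(values %in% 0:4),
          "responses must be integers on the 0-4 Likert scale")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(as.character(respondent_ids),
                           as.character(item_ids))
  structure(values, reverse_applied = isTRUE(reverse_applied),
            class = c("response_matrix", "matrix", "array"))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d respondents x %d items (Likert 0-4)%s\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "reverse_applied"))) ", severity-coded" else ""))
  invisible(x)
}

#' Drop respondents with missing responses (complete-case filtering)
#'
#' Complete-case deletion at the respondent level; the number of dropped rows
#' is reported via `message()` and stored as `attr(, "n_dropped")`.
#'
#' @param values a matrix possibly containing `NA`s.
#' @param item_ids,respondent_ids see [response_matrix()].
#' @return a [response_matrix()] of the complete rows.
#' @export
complete_cases <- function(values, respondent_ids = NULL, item_ids = NULL) {
  values <- as.matrix(values)
  respondent_ids <- respondent_ids %||% rownames(values) %||%
    paste0("R", seq_len(nrow(values)))
  keep <- stats::complete.cases(values)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("complete_cases: dropped %d of %d respondents with missing responses",
                    n_dropped, length(keep)))
  }
  out <- response_matrix(values[keep, , drop = FALSE],
                         respondent_ids = respondent_ids[keep],
                         item_ids = item_ids)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read a response matrix from CSV
#'
#' First column is the respondent id; remaining column names are item ids.
#' Rows with missing entries are dropped (complete-case) with a message.
#'
#' @param path CSV path.
#' @return a [response_matrix()].
#' @export
read_response_matrix <- function(path) {
  stop_if(!file.exists(path), paste0("response file not found: ", path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if(ncol(raw) < 2, "response file needs an id column plus item columns")
  ids <- as.character(raw[[1L]])
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  complete_cases(vals, respondent_ids = ids, item_ids = colnames(vals))
}

#' Write a response matrix to CSV
#' @param rm a [response_matrix()].
#' @param path output path.
#' @param id_col name for the respondent id column.
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(rm, path, id_col = "respondent_id") {
  stopifnot(inherits(rm, "response_matrix"))
  df <- data.frame(rownames(rm), unclass(rm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply reverse coding to flagged items
#'
#' Maps responses of items flagged `reverse_coded` in the bank through
#' `x -> 4 - x` so that higher scores always indicate greater severity.
#' The transformation is an involution on the flagged columns, but the
#' response matrix records that it has been applied and a second application
#' is an error (it would silently undo the first).
#'
#' @param responses a [response_matrix()].
#' @param bank an [item_bank()] containing all response columns.
#' @return a severity-coded [response_matrix()].
#' @export
apply_reverse_coding <- function(responses, bank) {
  stopifnot(inherits(responses, "response_matrix"), inherits(bank, "item_bank"))
  stop_if(isTRUE(attr(responses, "reverse_applied")),
          "reverse coding has already been applied to this response matrix")
  unknown <- setdiff(colnames(responses), bank$item_id)
  stop_if(length(unknown) > 0,
          paste0("response columns absent from bank: ",
                 paste(unknown, collapse = ", ")))
  flagged <- bank$item_id[bank$reverse_coded]
  cols <- intersect(colnames(responses), flagged)
  vals <- unclass(responses)
  if (length(cols) > 0) vals[, cols] <- 4L - vals[, cols]
  response_matrix(vals, reverse_applied = TRUE)
}

#' Construct screener responses (C-SSRS style)
#'
#' A 9-item yes/no screener per respondent: items 1--5 grade suicidal
#' ideation severity, item 6 asks about preparatory behavior, items 7--9
#' cover aborted/interrupted/actual attempts.
#'
#' @param values n x 9 matrix with entries in `{0, 1}`.
#' @param respondent_ids optional row ids.
#' @return a `cssrs_responses` object.
#' @export
cssrs_responses <- function(values, respondent_ids = NULL) {
  values <- as.matrix(values)
  stop_if(ncol(values) != 9L, "screener must have exactly 9 item columns")
  stop_if(anyNA(values) || !all(values %in% c(0, 1)),
          "screener entries must be 0 or 1")
  respondent_ids <- respondent_ids %||% rownames(values) %||%
    paste0("R", seq_len(nrow(values)))
  storage.mode(values) <- "integer"
  dimnames(values) <- list(as.character(respondent_ids),
                           paste0("item", 1:9))
  structure(values, class = c("cssrs_responses", "matrix", "array"))
}

#' Read screener responses from CSV
#' @param path CSV path; first column respondent id, then 9 binary item columns.
#' @return a [cssrs_responses()].
#' @export
read_cssrs_responses <- function(path) {
  stop_if(!file.exists(path), paste0("screener file not found: ", path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cssrs_responses(as.matrix(raw[, -1L, drop = FALSE]),
                  respondent_ids = as.character(raw[[1L]]))
}

#' Construct outcome labels
#'
#' @param si binary vector: any suicidal ideation.
#' @param si_p binary vector: ideation with preparatory behavior.
#' @param respondent_ids optional ids.
#' @return an `outcome_labels` object with prevalence fields.
#' @export
outcome_labels <- function(si, si_p, respondent_ids = NULL) {
  stop_if(!is_binary(si) || !is_binary(si_p), "outcomes must be binary 0/1")
  stop_if(length(si) != length(si_p), "si and si_p must have equal length")
  stop_if(length(si) < 1, "at least one respondent is required")
  structure(list(si = as.integer(si),
                 si_p = as.integer(si_p),
                 prevalence_si = mean(si),
                 prevalence_si_p = mean(si_p),
                 respondent_ids = respondent_ids %||%
                   paste0("R", seq_along(si))),
            class = "outcome_labels")
}

#' @export
print.outcome_labels <- function(x, ...) {
  cat(sprintf("<outcome_labels> n=%d  SI: %d cases (%.2f%%)  SI-P: %d cases (%.2f%%)\n",
              length(x$si), sum(x$si), 100 * x$prevalence_si,
              sum(x$si_p), 100 * x$prevalence_si_p))
  invisible(x)
}

#' Derive SI and SI-P outcomes from screener responses
#'
#' SI is positive when any of screener items 1--5 is endorsed; SI-P is
#' positive when item 6 (preparatory behavior) is endorsed.
#'
#' @param screener a [cssrs_responses()].
#' @return an [outcome_labels()].
#' @export
derive_outcomes <- function(screener) {
  stopifnot(inherits(screener, "cssrs_responses"))
  stop_if(nrow(screener) < 1, "screener has no respondents")
  si <- as.integer(rowSums(screener[, 1:5, drop = FALSE]) > 0)
  si_p <- as.integer(screener[, 6L])
  outcome_labels(si, si_p, respondent_ids = rownames(screener))
}
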