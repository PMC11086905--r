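# Default 61-item bank and the 8-item reference short form.
#
# Item ids and criterion labels follow the published instrument's sparse
# numbering (ids are opaque tokens, never array indices). The display texts
# are short synthetic paraphrases written for this package: the full original
# instrument text is proprietary and is not redistributed here.

known_items <- function() {
  # id, criterion, reverse flag, paraphrased text
  data.frame(
    item_id = c("SCI-1", "SCI-2", "SCI-3", "SCI-4", "SCI-5", "SCI-7",
                "SCI-8", "SCI-11", "SCI-12", "SCI-13", "SCI-14", "SCI-24",
                "SCI-26", "SCI-30", "SCI-34", "SCI-35", "SCI-37", "SCI-38",
                "SCI-41", "SCI-45", "SCI-47", "SCI-48", "SCI-51", "SCI-54",
                "SCI-57", "SCI-59", "SCI-60", "SCI-61", "SCI-72", "SCI-74"),
    criterion = c("B3", "B2", "B2", "A", "B1", "B1",
                  "B2", "B2", "A", "A", "B2", "B2",
                  "B2", "A", "B2", "A", "B1", "B1",
                  "B1", "B2", "B2", "B1", "B1", "B1",
                  "B1", "B3", "B3", "B3", "B3", "B4"),
    reverse_coded = FALSE,
    text = c(
      "Woke from sleep tired and unrefreshed",
      "Mind crowded by unwanted thoughts",
      "Head full of many thoughts",
      "Felt there was no exit",
      "Sudden waves of negative emotion",
      "Inner pain too great to bear",
      "Could not switch off thinking",
      "Hard to stop worrying",
      "Felt hopeless",
      "Felt there was no way out",
      "Trouble thinking or concentrating from too many thoughts",
      "Thoughts were racing",
      "Looping thoughts that would not stop",
      "Felt trapped with no good options",
      "Ideas turning over and over in the mind",
      "Felt doomed",
      "Emotional pain colored everything",
      "Inner pain that had to be stopped",
      "Emotional pain felt unbearable",
      "Pressure in the head from overthinking",
      "Headache from too many thoughts",
      "Urge to escape the pain was hard to control",
      "Intense negative feelings directed at oneself",
      "Dissatisfied or bored with everything",
      "Enjoyed being with family or close friends",
      "So restless could not sit still",
      "Wanted to crawl out of own skin",
      "Stirred up inside to the point of screaming",
      "Easily annoyed or irritated",
      "Did not open up to family or friends"
    ),
    stringsAsFactors = FALSE
  )
}

filler_items <- function() {
  # synthetic filler items to bring the bank to its 61-item size; numbering
  # stays sparse like the real instrument
  fill <- list(
    A  = c(6, 9, 17, 22, 29, 36, 44),
    B1 = c(10, 16, 21, 28, 33, 40, 46),
    B2 = c(15, 20, 27, 32, 39),
    B3 = c(18, 23, 31, 42, 49),
    B4 = c(50, 52, 53, 55, 56, 58, 62)
  )
  long <- scs_criterion_names()
  do.call(rbind, lapply(names(fill), function(cr) {
    data.frame(item_id = paste0("SCI-", fill[[cr]]),
               criterion = cr,
               reverse_coded = FALSE,
               text = sprintf("%s domain item (synthetic filler)", long[[cr]]),
               stringsAsFactors = FALSE)
  }))
}

#' Default 61-item bank
#'
#' The instrument modelled throughout the package: 61 items on a 0--4 Likert
#' scale covering the five SCS criteria, with sparse item numbering and one
#' reverse-coded item (SCI-57, the enjoyment-of-company item, whose raw
#' endorsement indicates *less* severity). Item texts are synthetic
#' paraphrases, not the proprietary instrument wording.
#'
#' @return an [item_bank()] of 61 items.
#' @export
default_item_bank <- function() {
  items <- rbind(known_items(), filler_items())
  num <- as.integer(sub("^SCI-", "", items$item_id))
  items <- items[order(num), ]
  items$reverse_coded <- items$item_id == "SCI-57"
  item_bank(items[, c("item_id", "text", "criterion", "reverse_coded")],
            version = "sci2-synthetic-1.0")
}

#' Reference short form (8 items)
#'
#' The comparator short form used when judging rankings by criterion
#' distribution: four loss-of-cognitive-control items, two entrapment items
#' and two affective-disturbance items (criterion multiset
#' `{B2 x4, A x2, B1 x2}`), with no hyperarousal or social-withdrawal items.
#'
#' @param bank bank supplying criterion labels (default [default_item_bank()]).
#' @return a `reference_short_form` object.
#' @export
default_reference_short_form <- function(bank = default_item_bank()) {
  reference_short_form(c("SCI-2", "SCI-8", "SCI-26", "SCI-47",
                         "SCI-4", "SCI-30", "SCI-5", "SCI-37"), bank)
}

#' Construct a reference short form
#' @param item_ids ordered item ids, all present in `bank`.
#' @param bank an [item_bank()].
#' @return a `reference_short_form` object (bank subset, list ordering kept).
#' @export
reference_short_form <- function(item_ids, bank) {
  stopifnot(inherits(bank, "item_bank"))
  item_ids <- as.character(item_ids)
  unknown <- setdiff(item_ids, bank$item_id)
  stop_if(length(unknown) > 0,
          paste0("reference items absent from bank: ",
                 paste(unknown, collapse = ", ")))
  sub <- as.data.frame(bank)[match(item_ids, bank$item_id), ]
  rownames(sub) <- NULL
  structure(list(item_ids = item_ids, items = sub),
            class = "reference_short_form")
}

#' @export
print.reference_short_form <- function(x, ...) {
  cat(sprintf("<reference_short_form> %d items: %s\n",
              length(x$item_ids), paste(x$item_ids, collapse = ", ")))
  invisible(x)
}
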