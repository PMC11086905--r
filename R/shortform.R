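# Short-form construction: criterion-distribution comparison of rankings to
# a reference form, and quota-constrained assembly with cross-outcome
# fallback.

#' Criterion distribution of an item list
#'
#' Proportion of the listed items falling under each of the five SCS
#' criteria; criteria with no items are reported as 0.
#'
#' @param item_ids nonempty character vector of bank item ids.
#' @param bank an [item_bank()].
#' @return named numeric vector over [scs_criteria()], summing to 1.
#' @export
criterion_distribution <- function(item_ids, bank) {
  stopifnot(inherits(bank, "item_bank"))
  stop_if(length(item_ids) == 0, "item list is empty")
  unknown <- setdiff(item_ids, bank$item_id)
  stop_if(length(unknown) > 0,
          paste0("unknown item id(s): ", paste(unknown, collapse = ", ")))
  crit <- bank$criterion[match(item_ids, bank$item_id)]
  tab <- table(factor(crit, levels = scs_criteria()))
  stats::setNames(as.numeric(tab) / length(item_ids), scs_criteria())
}

#' Compare a ranking's top items to a reference short form
#'
#' Compares the criterion distribution of the ranking's `top_n` items with
#' that of the reference form. Similarity is `1 - 0.5 * L1` distance between
#' the two proportion vectors: 1 iff the distributions are equal, 0 iff they
#' are disjoint, and symmetric in its arguments. The default `top_n = 10`
#' reflects the point past which SFI typically drops below half its starting
#' value.
#'
#' @param ranking a `ranking_table`.
#' @param reference a [reference_short_form()].
#' @param bank the [item_bank()].
#' @param top_n how many top-ranked items to consider (default 10).
#' @return an `overlap_report`: `ranking_proportions`,
#'   `reference_proportions`, `similarity`, `top_n`, `top_items`.
#' @export
compare_rankings <- function(ranking, reference, bank, top_n = 10L) {
  stopifnot(inherits(ranking, "ranking_table"),
            inherits(reference, "reference_short_form"),
            inherits(bank, "item_bank"))
  stop_if(top_n > nrow(ranking),
          sprintf("top_n = %d exceeds the ranking's %d items", top_n,
                  nrow(ranking)))
  top_items <- ranking$item_id[seq_len(top_n)]
  pr <- criterion_distribution(top_items, bank)
  pf <- criterion_distribution(reference$item_ids, bank)
  structure(list(ranking_proportions = pr, reference_proportions = pf,
                 similarity = 1 - 0.5 * sum(abs(pr - pf)),
                 top_n = as.integer(top_n), top_items = top_items,
                 outcome_label = attr(ranking, "outcome_label")),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> top-%d of %s ranking vs reference form: similarity %.3f\n",
              x$top_n, x$outcome_label %||% "?", x$similarity))
  tab <- rbind(ranking = x$ranking_proportions,
               reference = x$reference_proportions)
  print(round(tab, 3))
  invisible(x)
}

#' Assemble a short form by per-criterion quotas
#'
#' For each criterion, takes its quota of highest-ranked items of that
#' criterion from the primary ranking; when the primary ranking cannot fill
#' the quota, the remainder comes from the fallback ranking (the
#' cross-outcome fallback rule). Every pick records its source ranking and
#' source rank. A criterion unsatisfiable from both rankings is an error.
#'
#' @param primary a `ranking_table` (the seeding ranking).
#' @param fallback optional second `ranking_table`.
#' @param bank the [item_bank()].
#' @param quotas named integer vector over criteria; default
#'   `c(A = 2, B1 = 2, B2 = 2, B3 = 2, B4 = 1)` (nine items).
#' @return a `short_form`: data.frame `selected` with
#'   `item_id, criterion, source, source_rank`, plus the quota map.
#' @export
assemble_short_form <- function(primary, fallback = NULL, bank,
                                quotas = c(A = 2L, B1 = 2L, B2 = 2L,
                                           B3 = 2L, B4 = 1L)) {
  stopifnot(inherits(primary, "ranking_table"), inherits(bank, "item_bank"))
  stop_if(!all(names(quotas) %in% scs_criteria()),
          "quota names must be SCS criterion tokens")
  missing_q <- setdiff(scs_criteria(), names(quotas))
  if (length(missing_q) > 0) {
    quotas <- c(quotas, stats::setNames(rep(0L, length(missing_q)), missing_q))
  }
  quotas <- quotas[scs_criteria()]
  stop_if(any(quotas < 0), "quotas must be nonnegative")

  pick_rows <- list()
  for (cr in scs_criteria()) {
    need <- quotas[[cr]]
    if (need == 0) next
    prim <- primary[primary$criterion == cr, , drop = FALSE]
    take <- utils::head(prim[prim$sfi > 0 | is.na(prim$sfi), , drop = FALSE], need)
    got <- nrow(take)
    if (got > 0) {
      pick_rows[[length(pick_rows) + 1L]] <-
        data.frame(item_id = take$item_id, criterion = cr,
                   source = attr(primary, "outcome_label") %||% "primary",
                   source_rank = take$rank, stringsAsFactors = FALSE)
    }
    if (got < need) {
      remainder <- need - got
      if (is.null(fallback)) {
        stop(sprintf("criterion %s: only %d of %d item(s) available and no fallback ranking",
                     cr, got, need), call. = FALSE)
      }
      fb <- fallback[fallback$criterion == cr &
                       !(fallback$item_id %in% take$item_id), , drop = FALSE]
      fb <- utils::head(fb[fb$sfi > 0 | is.na(fb$sfi), , drop = FALSE], remainder)
      if (nrow(fb) < remainder) {
        stop(sprintf("criterion %s: quota %d unsatisfiable from primary and fallback rankings",
                     cr, need), call. = FALSE)
      }
      pick_rows[[length(pick_rows) + 1L]] <-
        data.frame(item_id = fb$item_id, criterion = cr,
                   source = attr(fallback, "outcome_label") %||% "fallback",
                   source_rank = fb$rank, stringsAsFactors = FALSE)
    }
  }
  selected <- if (length(pick_rows) > 0) do.call(rbind, pick_rows)
              else data.frame(item_id = character(0), criterion = character(0),
                              source = character(0), source_rank = integer(0),
                              stringsAsFactors = FALSE)
  rownames(selected) <- NULL
  structure(list(selected = selected, per_criterion_quota = quotas),
            class = "short_form")
}

#' @export
print.short_form <- function(x, ...) {
  cat(sprintf("<short_form> %d items (quotas: %s)\n", nrow(x$selected),
              paste(sprintf("%s=%d", names(x$per_criterion_quota),
                            x$per_criterion_quota), collapse = " ")))
  if (nrow(x$selected) > 0) print.data.frame(x$selected, row.names = FALSE)
  invisible(x)
}

#' Render a short form as CSV or Markdown
#'
#' Emits a listing grouped by criterion with the source ranking, source rank
#' and item text.
#'
#' @param sf a [assemble_short_form()] result.
#' @param bank the [item_bank()] (supplies item texts).
#' @param format `"csv"` or `"markdown"`.
#' @param path optional output file.
#' @return character vector of lines, invisibly if written to `path`.
#' @export
render_short_form <- function(sf, bank, format = c("csv", "markdown"),
                              path = NULL) {
  stopifnot(inherits(sf, "short_form"), inherits(bank, "item_bank"))
  format <- match.arg(format)
  sel <- sf$selected
  long <- scs_criterion_names()
  df <- data.frame(criterion = sel$criterion,
                   criterion_name = unname(long[sel$criterion]),
                   source = sel$source,
                   source_rank = sel$source_rank,
                   item_id = sel$item_id,
                   text = bank$text[match(sel$item_id, bank$item_id)],
                   stringsAsFactors = FALSE)
  df <- df[order(match(df$criterion, scs_criteria()), df$source_rank), ,
           drop = FALSE]
  lines <- if (format == "csv") {
    c("criterion,criterion_name,source,source_rank,item_id,text",
      if (nrow(df) > 0)
        sprintf("%s,%s,%s,%d,%s,\"%s\"", df$criterion, df$criterion_name,
                df$source, df$source_rank, df$item_id, df$text))
  } else {
    c("| Criterion | Source | Rank | Item | Text |",
      "|---|---|---|---|---|",
      if (nrow(df) > 0)
        sprintf("| %s. %s | %s | %d | %s | %s |", df$criterion,
                df$criterion_name, df$source, df$source_rank, df$item_id,
                df$text))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse a short form back from its CSV rendering
#' @param path CSV produced by [render_short_form()].
#' @return a `short_form` (quotas recovered from the criterion counts).
#' @export
read_short_form <- function(path) {
  stop_if(!file.exists(path), paste0("short form file not found: ", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  selected <- data.frame(item_id = raw$item_id, criterion = raw$criterion,
                         source = raw$source, source_rank = raw$source_rank,
                         stringsAsFactors = FALSE)
  tab <- table(factor(selected$criterion, levels = scs_criteria()))
  structure(list(selected = selected,
                 per_criterion_quota = stats::setNames(as.integer(tab),
                                                       scs_criteria())),
            class = "short_form")
}
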