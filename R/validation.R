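#' Wrap relation candidates as manual-validation records
#'
#' Mirrors the curation workflow in which each mined candidate is reviewed
#' and marked `TRUE`, `FALSE` or `NOT_SURE`; `NOT_SURE` records go to a
#' second reviewer. All records start `UNREVIEWED`.
#'
#' @param candidates A `cyp_relations` data frame.
#' @return Data frame of class `cyp_validation`: the candidate columns plus
#'   `state`, `reviewer`, `comment`.
#' @export
as_validation_records <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  res <- candidates
  res$state <- rep("UNREVIEWED", nrow(res))
  res$reviewer <- rep("", nrow(res))
  res$comment <- rep("", nrow(res))
  class(res) <- c("cyp_validation", "data.frame")
  res
}

.validation_states <- c("UNREVIEWED", "TRUE", "FALSE", "NOT_SURE")

#' Record a review decision
#'
#' Enforces the curation state machine: `UNREVIEWED` may move to `TRUE`,
#' `FALSE` or `NOT_SURE`; `NOT_SURE` may move to `TRUE` or `FALSE` (the
#' second reviewer's decision); `TRUE` and `FALSE` are final.
#'
#' @param records A `cyp_validation` data frame.
#' @param index Row index (or logical vector) of the record(s) to update.
#' @param state Target state.
#' @param reviewer,comment Metadata stored on the record.
#' @return The updated records.
#' @export
set_validation_state <- function(records, index, state,
                                 reviewer = "", comment = "") {
  stopifnot(inherits(records, "cyp_validation"))
  state <- match.arg(state, .validation_states)
  for (i in seq_len(nrow(records))[index]) {
    from <- records$state[i]
    ok <- (from == "UNREVIEWED" && state %in% c("TRUE", "FALSE", "NOT_SURE")) ||
      (from == "NOT_SURE" && state %in% c("TRUE", "FALSE"))
    if (!ok)
      stop_cypscope("invalid validation transition ", from, " -> ", state,
                    " (row ", i, ")")
    records$state[i] <- state
    records$reviewer[i] <- reviewer
    records$comment[i] <- comment
  }
  records
}

.export_cols <- c("doc_id", "cyp", "ethnicity", "frequency", "effect",
                  "score", "state", "comment")

#' Export validated relation records to TSV
#'
#' Writes columns `doc_id`, `cyp`, `ethnicity`, `frequency`, `effect`,
#' `score`, `state`, `comment`. By default every record must be resolved
#' (`TRUE` or `FALSE`); pass `allow_unresolved = TRUE` to also export
#' `UNREVIEWED` / `NOT_SURE` records.
#'
#' @param records A `cyp_validation` data frame.
#' @param path Output file.
#' @param allow_unresolved Permit unresolved states (default FALSE).
#' @return `path`, invisibly.
#' @seealso [read_validation_records()] for the lossless reader.
#' @export
export_records <- function(records, path, allow_unresolved = FALSE) {
  stopifnot(inherits(records, "cyp_validation"))
  unresolved <- which(!records$state %in% c("TRUE", "FALSE"))
  if (length(unresolved) && !allow_unresolved)
    stop_cypscope("unresolved validation records at row(s): ",
                  paste(unresolved, collapse = ", "),
                  " (states ", paste(unique(records$state[unresolved]),
                                     collapse = ", "),
                  "); use allow_unresolved = TRUE to export anyway")
  write_tsv(records[, .export_cols, drop = FALSE], path)
}

#' Read exported validation records
#'
#' @param path TSV written by [export_records()].
#' @return Data frame with the exported columns; `frequency` and `score`
#'   numeric.
#' @export
read_validation_records <- function(path) {
  x <- read_tsv_strict(path, .export_cols)
  x$frequency <- as.numeric(x$frequency)
  x$score <- as.numeric(x$score)
  x$effect[!nzchar(x$effect)] <- NA_character_
  x
}
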