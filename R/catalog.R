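#' Load a star-allele frequency catalog
#'
#' Reads a TSV catalog with one row per star allele: columns `cyp`,
#' `allele`, `aa_changes` (semicolon-joined), `activity`, `test_drug`,
#' `source_ids` (semicolon-joined), followed by one frequency column per
#' ethnicity (percent, 0-100). Frequency cells may be plain numbers or
#' genotype-class breakdowns such as `"19.0% *1/*2 1.6% *2/*2"`; for the
#' latter the first percentage (the heterozygous carrier class) is taken as
#' the scalar allele frequency and the verbatim cell is preserved in a
#' `<ethnicity>_raw` column. Activity strings are mapped onto a fixed set of
#' classes distinguishing enzyme-level from expression/transcription-level
#' effects: `INCREASE`, `DECREASE`, `NO_ENZYME`, `NONFUNCTIONAL`,
#' `HIGHER_INDUCIBILITY`, `INCREASE_TRANSCRIPTION`, `DECREASE_EXPRESSION`.
#'
#' The catalog shipped with the package (`table1_caucasian.tsv`, see
#' [cypscope_catalog()]) transcribes a published curation of the 34 star
#' alleles polymorphic in Caucasians; known discrepancies between that
#' source's narrative and its tables are listed in the packaged
#' `ERRATA.md`.
#'
#' @param path Path to the catalog TSV.
#' @return A data frame of class `cyp_catalog` with parsed numeric
#'   frequency columns, raw-cell columns, and an `ethnicities` attribute.
#' @export
load_catalog <- function(path) {
  meta_cols <- c("cyp", "allele", "aa_changes", "activity", "test_drug",
                 "source_ids")
  x <- read_tsv_strict(path, meta_cols)
  eths <- setdiff(names(x), c(meta_cols, grep("_raw$", names(x), value = TRUE)))
  if (!length(eths))
    stop_cypscope("catalog has no ethnicity frequency columns")
  key <- paste(x$cyp, x$allele)
  if (anyDuplicated(key))
    stop_cypscope("duplicate (cyp, allele) rows: ",
                  paste(unique(key[duplicated(key)]), collapse = ", "))
  out <- x[, meta_cols, drop = FALSE]
  out$cyp <- canonical_cyp(out$cyp)
  out$activity_raw <- x$activity
  out$activity <- vapply(x$activity, map_activity, "", USE.NAMES = FALSE)
  for (e in eths) {
    raw <- x[[e]]
    out[[e]] <- vapply(seq_along(raw), function(i) {
      parse_frequency_cell(raw[i], row = paste0(x$cyp[i], x$allele[i]))
    }, numeric(1))
    out[[paste0(e, "_raw")]] <- raw
  }
  attr(out, "ethnicities") <- eths
  class(out) <- c("cyp_catalog", "data.frame")
  out
}

# first percentage in the cell is the scalar frequency; plain numbers are
# percentages without the sign
parse_frequency_cell <- function(cell, row = "?") {
  cell <- trimws(cell)
  if (!nzchar(cell)) return(NA_real_)
  if (grepl("^\\d+(\\.\\d+)?$", cell)) {
    v <- as.numeric(cell)
  } else {
    m <- regmatches(cell, regexpr("\\d+(\\.\\d+)?(?=\\s*%)", cell, perl = TRUE))
    if (!length(m))
      stop_cypscope("unparseable frequency cell for ", row, ": ",
                    deparse(cell))
    v <- as.numeric(m)
  }
  if (is.na(v) || v < 0 || v > 100)
    stop_cypscope("frequency out of [0, 100] for ", row, ": ", cell)
  v
}

.activity_map <- c(
  "increase" = "INCREASE",
  "increased" = "INCREASE",
  "decrease" = "DECREASE",
  "decreased" = "DECREASE",
  "no enzyme" = "NO_ENZYME",
  "nonfunctional" = "NONFUNCTIONAL",
  "higher inducibility" = "HIGHER_INDUCIBILITY",
  "increase (transcription)" = "INCREASE_TRANSCRIPTION",
  "increased (transcription)" = "INCREASE_TRANSCRIPTION",
  "decrease (expression)" = "DECREASE_EXPRESSION",
  "decreased (expression)" = "DECREASE_EXPRESSION")

map_activity <- function(s) {
  key <- tolower(trimws(s))
  if (toupper(key) %in% unname(.activity_map)) return(toupper(key))
  v <- .activity_map[key]
  if (is.na(v))
    stop_cypscope("unknown enzyme-activity class: ", deparse(s))
  unname(v)
}

#' The packaged Caucasian star-allele catalog
#'
#' Convenience loader for the shipped 34-allele Caucasian catalog.
#'
#' @return A `cyp_catalog` data frame (34 records).
#' @export
cypscope_catalog <- function() {
  load_catalog(system.file("extdata", "table1_caucasian.tsv",
                           package = "cypscope", mustWork = TRUE))
}

#' Export a catalog back to TSV
#'
#' Writes the same schema [load_catalog()] reads, emitting the verbatim raw
#' frequency cells so that load/export round-trips losslessly.
#'
#' @param records A `cyp_catalog`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_catalog <- function(records, path) {
  stopifnot(inherits(records, "cyp_catalog"))
  eths <- attr(records, "ethnicities")
  out <- records[, c("cyp", "allele", "aa_changes"), drop = FALSE]
  out$activity <- records$activity_raw
  out$test_drug <- records$test_drug
  out$source_ids <- records$source_ids
  for (e in eths) out[[e]] <- records[[paste0(e, "_raw")]]
  write_tsv(out, path)
}

#' Keep pharmacogenetic polymorphisms (frequency at or above a threshold)
#'
#' A variant allele carried at a frequency of at least one percent in a
#' population is by convention a pharmacogenetic polymorphism; the default
#' threshold implements that rule.
#'
#' @param records A `cyp_catalog`.
#' @param threshold_percent Frequency threshold in percent, in (0, 100\].
#' @param ethnicity Which frequency column to filter on.
#' @return The filtered `cyp_catalog`. Records with no frequency for the
#'   requested ethnicity are dropped with a warning.
#' @export
filter_polymorphic <- function(records, threshold_percent = 1.0,
                               ethnicity = "Caucasian") {
  stopifnot(inherits(records, "cyp_catalog"))
  if (!is.numeric(threshold_percent) || threshold_percent <= 0 ||
      threshold_percent > 100)
    stop_cypscope("threshold_percent must lie in (0, 100]")
  eths <- attr(records, "ethnicities")
  if (!ethnicity %in% eths)
    stop_cypscope("unknown ethnicity ", deparse(ethnicity),
                  "; catalog has: ", paste(eths, collapse = ", "))
  f <- records[[ethnicity]]
  if (anyNA(f)) {
    warning(sum(is.na(f)), " record(s) without a ", ethnicity,
            " frequency dropped", call. = FALSE)
  }
  out <- records[!is.na(f) & f >= threshold_percent, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ethnicities") <- eths
  class(out) <- class(records)
  out
}

#' Summarize a star-allele catalog
#'
#' @param records A non-empty `cyp_catalog`.
#' @param ethnicity Frequency column used for the ranking.
#' @return A list of class `cyp_catalog_summary` with `n_alleles`,
#'   `per_cyp_counts` (named, sorted by CYP id), `max_frequency`
#'   (`cyp`, `allele`, `percent`) and `ranked_alleles` (a data frame sorted
#'   by descending frequency, ties broken by (cyp, allele)).
#' @export
catalog_summary <- function(records, ethnicity = "Caucasian") {
  stopifnot(inherits(records, "cyp_catalog"))
  if (!nrow(records)) stop_cypscope("cannot summarize an empty catalog")
  eths <- attr(records, "ethnicities")
  if (!ethnicity %in% eths)
    stop_cypscope("unknown ethnicity ", deparse(ethnicity),
                  "; catalog has: ", paste(eths, collapse = ", "))
  counts <- table(records$cyp)
  per_cyp <- as.integer(counts)
  names(per_cyp) <- names(counts)
  per_cyp <- per_cyp[order(names(per_cyp))]
  f <- records[[ethnicity]]
  ord <- order(-ifelse(is.na(f), -Inf, f), records$cyp, records$allele)
  ranked <- records[ord, c("cyp", "allele", ethnicity), drop = FALSE]
  names(ranked)[3] <- "percent"
  rownames(ranked) <- NULL
  structure(list(
    n_alleles = nrow(records),
    per_cyp_counts = per_cyp,
    max_frequency = list(cyp = ranked$cyp[1], allele = ranked$allele[1],
                         percent = ranked$percent[1]),
    ranked_alleles = ranked,
    ethnicity = ethnicity), class = "cyp_catalog_summary")
}

#' @export
print.cyp_catalog_summary <- function(x, ...) {
  cat("Star-allele catalog summary (", x$ethnicity, ")\n", sep = "")
  cat("  alleles: ", x$n_alleles, " across ", length(x$per_cyp_counts),
      " CYPs\n", sep = "")
  cat("  most frequent: CYP", x$max_frequency$cyp, x$max_frequency$allele,
      " at ", x$max_frequency$percent, "%\n", sep = "")
  invisible(x)
}

#' Look up one star allele
#'
#' @param records A `cyp_catalog`.
#' @param cyp Canonical CYP id (case-insensitive).
#' @param allele Star-allele name; the `*` prefix is optional (`"4"` is
#'   `"*4"`).
#' @return The matching one-row `cyp_catalog`.
#' @export
lookup_allele <- function(records, cyp, allele) {
  stopifnot(inherits(records, "cyp_catalog"))
  cyp <- canonical_cyp(cyp)
  allele <- as.character(allele)
  if (!startsWith(allele, "*")) allele <- paste0("*", allele)
  hit <- records$cyp == cyp & tolower(records$allele) == tolower(allele)
  if (!any(hit)) {
    same_cyp <- records$allele[records$cyp == cyp]
    if (length(same_cyp))
      stop_cypscope("allele ", allele, " not found for CYP", cyp,
                    "; known alleles: ", paste(same_cyp, collapse = ", "))
    stop_cypscope("CYP", cyp, " not in catalog; known CYPs: ",
                  paste(sort(unique(records$cyp)), collapse = ", "))
  }
  out <- records[hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ethnicities") <- attr(records, "ethnicities")
  class(out) <- class(records)
  out
}

#' Percent and cumulative coverage of a count table
#'
#' Generic summarizer for "top k keys account for X% of the total" style
#' statements over any per-key count table (e.g. drug-metabolism reactions
#' per CYP).
#'
#' @param counts Named non-negative numeric vector with a positive total.
#' @return Data frame with `key`, `count`, `percent`,
#'   `cumulative_percent`, sorted by descending count (ties broken by key).
#' @examples
#' coverage_stats(c(a = 3, b = 1))
#' @export
coverage_stats <- function(counts) {
  if (is.table(counts)) counts <- stats::setNames(as.numeric(counts), names(counts))
  if (!is.numeric(counts) || is.null(names(counts)) || !all(nzchar(names(counts))))
    stop_cypscope("counts must be a named numeric vector")
  if (any(counts < 0)) stop_cypscope("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop_cypscope("counts sum to zero; nothing to rank")
  ord <- order(-counts, names(counts))
  out <- data.frame(key = names(counts)[ord], count = unname(counts[ord]),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$count / total
  out$cumulative_percent <- cumsum(out$percent)
  out
}
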