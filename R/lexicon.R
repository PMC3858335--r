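#' Read an entity lexicon
#'
#' A lexicon lists the surface forms used for dictionary-based entity
#' recognition in abstracts, one row per (class, surface) pair. Recognized
#' entity classes are `CYP`, `ETHNICITY`, `FREQUENCY`, `EFFECT` and
#' `NEGATION`. `FREQUENCY` and most `CYP` mentions are additionally found by
#' pattern rules (see [detect_mentions()]), so lexicons typically carry
#' ethnicity, effect, negation and CYP-synonym entries.
#'
#' @param path Path to a TSV file with columns `entity_class`,
#'   `surface_form`, `canonical_id`.
#' @return A data frame of class `cyp_lexicon`.
#' @seealso [default_lexicon()]
#' @export
read_lexicon <- function(path) {
  x <- read_tsv_strict(path, c("entity_class", "surface_form", "canonical_id"))
  validate_lexicon(x)
}

#' Default lexicon shipped with the package
#'
#' Ethnicity terms (Caucasian/European, Asian, African, Hispanic and
#' variants), effect terms (increase/decrease/metabolizer phenotypes),
#' negation cues, and a handful of non-systematic CYP synonyms such as
#' "debrisoquine hydroxylase" (CYP2D6).
#'
#' @return A `cyp_lexicon` data frame.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon_default.tsv",
                           package = "cypscope", mustWork = TRUE))
}

validate_lexicon <- function(x) {
  stopifnot(is.data.frame(x))
  classes <- c("CYP", "ETHNICITY", "FREQUENCY", "EFFECT", "NEGATION")
  bad <- setdiff(unique(x$entity_class), classes)
  if (length(bad))
    stop_cypscope("unknown entity class(es): ", paste(bad, collapse = ", "))
  if (any(!nzchar(trimws(x$surface_form))))
    stop_cypscope("lexicon contains empty surface forms")
  key <- paste(x$entity_class, tolower(x$surface_form))
  if (anyDuplicated(key))
    stop_cypscope("duplicated (entity_class, surface_form) pairs: ",
                  paste(unique(key[duplicated(key)]), collapse = "; "))
  cyp <- x$canonical_id[x$entity_class == "CYP"]
  bad_ids <- cyp[!is_cyp_id(cyp)]
  if (length(bad_ids))
    stop_cypscope("CYP canonical_id not of family-letter-subfamily form: ",
                  paste(bad_ids, collapse = ", "))
  x$surface_form <- trimws(x$surface_form)
  class(x) <- c("cyp_lexicon", "data.frame")
  x
}
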