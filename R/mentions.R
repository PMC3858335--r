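#' Detect entity mentions in tokenized text
#'
#' Combines case-insensitive dictionary matching against a [read_lexicon()]
#' lexicon (longest match wins; matched spans do not overlap) with two
#' pattern rules that no finite dictionary covers:
#'
#' * `FREQUENCY`: a numeric token ending in `%`, or a number followed by the
#'   word "percent". The numeric value is parsed onto the 0-100 scale;
#'   values outside \[0, 100\] are discarded with a warning. Spelled-out
#'   numbers are not parsed.
#' * `CYP`: a `CYPnXm` token (optionally carrying a star-allele suffix,
#'   e.g. `CYP2C19*2`), or the word `CYP` followed by a bare code token
#'   such as `2C19`. The canonical id is the code without the `CYP` prefix
#'   or allele suffix.
#'
#' @param tokens A `cyp_tokens` data frame from [tokenize()].
#' @param lexicon A `cyp_lexicon` data frame; default [default_lexicon()].
#' @return Data frame of class `cyp_mentions` with columns `entity_class`,
#'   `canonical_id`, `token_start` (0-based), `sentence`, `surface`, `value`
#'   (percent, `NA` except for `FREQUENCY`), sorted by `token_start`.
#' @export
detect_mentions <- function(tokens, lexicon = default_lexicon()) {
  stopifnot(is.data.frame(tokens))
  if (!inherits(lexicon, "cyp_lexicon")) lexicon <- validate_lexicon(lexicon)
  empty <- data.frame(entity_class = character(0), canonical_id = character(0),
                      token_start = integer(0), sentence = integer(0),
                      surface = character(0), value = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("cyp_mentions", "data.frame")
  if (nrow(tokens) == 0L) return(empty)

  tok <- tokens$token
  low <- tolower(tok)
  n <- length(tok)
  out <- list()
  add <- function(class, id, start, surface, value = NA_real_) {
    out[[length(out) + 1L]] <<- data.frame(
      entity_class = class, canonical_id = id,
      token_start = tokens$position[start],
      sentence = tokens$sentence[start],
      surface = surface, value = value, stringsAsFactors = FALSE)
  }

  # dictionary pass: surfaces tokenized with the same tokenizer, matched as
  # token n-grams, longest first, non-overlapping
  surf_tokens <- lapply(tolower(lexicon$surface_form),
                        function(s) tokenize(s)$token)
  surf_len <- lengths(surf_tokens)
  dict <- split(seq_len(nrow(lexicon)),
                vapply(surf_tokens, paste, "", collapse = " "))
  max_len <- max(c(1L, surf_len))
  i <- 1L
  while (i <= n) {
    hit_len <- 0L
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      key <- paste(low[i:(i + len - 1L)], collapse = " ")
      idx <- dict[[key]]
      if (!is.null(idx)) {
        for (j in idx)
          add(lexicon$entity_class[j], lexicon$canonical_id[j], i,
              paste(tok[i:(i + len - 1L)], collapse = " "))
        hit_len <- len
        break
      }
    }
    i <- i + max(1L, hit_len)
  }

  # pattern pass: frequencies
  pct <- grepl("^\\d+(\\.\\d+)?%$", tok)
  num <- grepl("^\\d+(\\.\\d+)?$", tok)
  for (i in seq_len(n)) {
    val <- NA_real_
    surface <- tok[i]
    if (pct[i]) {
      val <- as.numeric(sub("%$", "", tok[i]))
    } else if (num[i] && i < n && low[i + 1L] == "percent") {
      val <- as.numeric(tok[i])
      surface <- paste(tok[i], tok[i + 1L])
    }
    if (!is.na(val)) {
      if (val < 0 || val > 100) {
        warning("discarding out-of-range frequency mention: ", surface,
                call. = FALSE)
      } else {
        add("FREQUENCY", "percent", i, surface, val)
      }
    }
  }

  # pattern pass: CYP gene symbols (with or without star-allele suffix)
  cyp_pat <- paste0("^[Cc][Yy][Pp]\\s?([0-9]{1,2}[A-Za-z][0-9]{0,2})",
                    "(\\*[\\w/]+(\\*[\\w/]+)*)?$")
  for (i in seq_len(n)) {
    if (grepl(cyp_pat, tok[i], perl = TRUE)) {
      add("CYP", canonical_cyp(sub(cyp_pat, "\\1", tok[i], perl = TRUE)),
          i, tok[i])
    } else if (low[i] == "cyp" && i < n && is_cyp_id(sub("\\*.*$", "", tok[i + 1L]))) {
      add("CYP", canonical_cyp(sub("\\*.*$", "", tok[i + 1L])), i,
          paste(tok[i], tok[i + 1L]))
    }
  }

  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- unique(res)
  res <- res[order(res$token_start, res$entity_class), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("cyp_mentions", "data.frame")
  res
}
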