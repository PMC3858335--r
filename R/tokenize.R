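#' Tokenize abstract text with sentence indices
#'
#' Splits text into word-level tokens while keeping domain units intact:
#' star alleles (`CYP2D6*4`), rsIDs (`rs1065852`) and percentages
#' (`81.3%`) each remain single tokens. Sentence indices are 0-based and
#' non-decreasing; a sentence terminator (`.`, `!`, `?`) is emitted as its
#' own token and closes its sentence. Token positions are 0-based over the
#' whole input, so token-distance rules can subtract them directly.
#'
#' @param text Character vector; each element is a text segment (e.g. title
#'   then abstract). Segment boundaries always start a new sentence; token
#'   positions run on across segments.
#' @return A data frame of class `cyp_tokens` with columns `token`,
#'   `position` (0-based) and `sentence` (0-based). Empty text gives zero
#'   rows.
#' @examples
#' tokenize("CYP2D6*4 is frequent.")
#' tokenize("A. B.")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text))
  # alternation order matters: star-allele unit, percentage, number, word,
  # then any single non-space character (punctuation)
  pat <- paste0(
    "\\w+(?:\\*[\\w/]+)+",              # CYP2D6*4, 2D6*4, 3A5*3k/*10
    "|\\*\\w+",                         # bare star allele *4
    "|[0-9]{1,2}[A-Za-z][0-9]{1,2}\\b", # bare gene code 2D6, 3A43, 11B1
    "|\\d+(?:\\.\\d+)?%",               # 81.3%
    "|\\d+(?:\\.\\d+)?",                # 81.3
    "|[A-Za-z][A-Za-z0-9'-]*",          # words incl. CYP2D6, rs1065852
    "|\\S")
  toks <- character(0)
  sent <- integer(0)
  s <- 0L
  for (seg in text) {
    if (is.na(seg) || !nzchar(seg)) next
    m <- gregexpr(pat, seg, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    tt <- regmatches(seg, list(m))[[1]]
    ss <- integer(length(tt))
    for (i in seq_along(tt)) {
      ss[i] <- s
      if (tt[i] %in% c(".", "!", "?")) s <- s + 1L
    }
    toks <- c(toks, tt)
    sent <- c(sent, ss)
    # a segment boundary closes the sentence even without a terminator
    if (length(ss) && ss[length(ss)] == s) s <- s + 1L
  }
  out <- data.frame(token = toks,
                    position = seq_along(toks) - 1L,
                    sentence = sent,
                    stringsAsFactors = FALSE)
  class(out) <- c("cyp_tokens", "data.frame")
  out
}
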