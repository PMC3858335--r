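#' Scoring parameters for relation extraction
#'
#' The distance rule gives a candidate a score of exactly 100 when the
#' CYP-to-ethnicity token distance is at most `d_ce_max` (default 7) and the
#' frequency-to-CYP distance is at most `d_fc_max` (default 6) and the
#' candidate is not negated. Beyond the thresholds the score decays linearly
#' by `decay_weight` points per excess token in each dimension, floored at
#' 0; negated candidates are multiplied by `negation_factor`. Scores are
#' always clamped to \[0, 100\].
#'
#' @param d_ce_max,d_fc_max Distance thresholds (tokens).
#' @param decay_weight Points lost per excess token, per dimension.
#' @param negation_factor Multiplier applied to negated candidates.
#' @param min_score Candidates scoring below this are dropped by
#'   [extract_relations()]. The manually curated set in the original survey
#'   corresponds to `min_score = 100`; the default 0 returns everything.
#' @param cross_sentence Also pair mentions across adjacent sentences.
#' @param cross_sentence_cap Score ceiling for cross-sentence candidates.
#' @return A list of class `cyp_scoring_params`.
#' @export
scoring_params <- function(d_ce_max = 7L, d_fc_max = 6L, decay_weight = 10,
                           negation_factor = 0.5, min_score = 0,
                           cross_sentence = FALSE, cross_sentence_cap = 90) {
  stopifnot(d_ce_max >= 0, d_fc_max >= 0, decay_weight >= 0,
            negation_factor >= 0, negation_factor <= 1,
            min_score >= 0, min_score <= 100)
  structure(list(d_ce_max = d_ce_max, d_fc_max = d_fc_max,
                 decay_weight = decay_weight,
                 negation_factor = negation_factor, min_score = min_score,
                 cross_sentence = cross_sentence,
                 cross_sentence_cap = cross_sentence_cap),
            class = "cyp_scoring_params")
}

#' Score a relation candidate by the token-distance rule
#'
#' @param d_ce Token distance between the CYP and the ethnicity mention
#'   (non-negative; vectorized).
#' @param d_fc Token distance between the frequency and the CYP mention.
#' @param negated Logical; whether a negation cue separates the closest
#'   mention pair.
#' @param params A [scoring_params()] list.
#' @return Numeric score(s) in \[0, 100\]. A candidate within both
#'   thresholds and not negated scores exactly 100.
#' @examples
#' score_relation(7, 6)         # 100
#' score_relation(9, 6)         # 80
#' score_relation(7, 6, TRUE)   # 50
#' @export
score_relation <- function(d_ce, d_fc, negated = FALSE,
                           params = scoring_params()) {
  if (any(d_ce < 0) || any(d_fc < 0))
    stop_cypscope("token distances must be non-negative")
  n <- max(length(d_ce), length(d_fc), length(negated))
  d_ce <- rep_len(d_ce, n); d_fc <- rep_len(d_fc, n)
  negated <- rep_len(as.logical(negated), n)
  base <- 100 - params$decay_weight * pmax(0, d_ce - params$d_ce_max) -
    params$decay_weight * pmax(0, d_fc - params$d_fc_max)
  score <- pmax(0, base)
  score[negated] <- score[negated] * params$negation_factor
  pmin(100, pmax(0, score))
}

#' Build the literature query string for one CYP
#'
#' Reproduces the four-clause conjunctive query template used to retrieve
#' abstracts about a CYP's population allele frequencies: a wildcarded CYP
#' clause, an OR-expansion of population synonyms, an OR-expansion of
#' effect synonyms, and a fixed `frequenc*` clause, each searched over
#' Abstract and Title fields.
#'
#' @param cyp_canonical Canonical CYP id, e.g. `"2C19"`.
#' @param population_terms,effect_terms Non-empty character vectors of
#'   synonyms to OR-expand.
#' @return The query string (deterministic).
#' @examples
#' build_query("2C19", "population", "effect")
#' @export
build_query <- function(cyp_canonical, population_terms, effect_terms) {
  if (length(cyp_canonical) != 1L || !is_cyp_id(cyp_canonical))
    stop_cypscope("malformed CYP id: ", deparse(cyp_canonical),
                  " (expected family-letter-subfamily, e.g. \"2C19\")")
  if (!length(population_terms) || !length(effect_terms))
    stop_cypscope("empty synonym list: both population_terms and ",
                  "effect_terms must contain at least one term")
  clause <- function(terms) {
    paste0("(", paste(vapply(terms, function(t)
      paste0("Abstract: ", t, " OR Title: ", t), ""), collapse = " OR "), ")")
  }
  cyp <- paste0("CYP", canonical_cyp(cyp_canonical), "*")
  paste0("(Abstract: ", cyp, " OR Title: ", cyp, ") AND ",
         clause(population_terms), " AND ", clause(effect_terms),
         " AND (Abstract: frequenc* OR Title: frequenc*)")
}

#' Extract scored (CYP, ethnicity, frequency) relation candidates
#'
#' Enumerates all triples of CYP, ethnicity and frequency mentions that
#' share a sentence (or adjacent sentences when
#' `params$cross_sentence = TRUE`, capped at `cross_sentence_cap`),
#' attaches the nearest effect mention in the window, marks candidates
#' whose closest mention pair is separated by a negation cue, scores each
#' with [score_relation()], and returns candidates at or above
#' `params$min_score` sorted by descending score (ties by CYP then
#' ethnicity position).
#'
#' @param document A list or one-row data frame with `doc_id`, `title`,
#'   `abstract`.
#' @param lexicon A `cyp_lexicon`.
#' @param params A [scoring_params()] list.
#' @return Data frame of class `cyp_relations`: `doc_id`, `cyp`,
#'   `ethnicity`, `frequency`, `effect`, `cyp_start`, `ethnicity_start`,
#'   `frequency_start`, `d_ce`, `d_fc`, `negated`, `score`.
#' @export
extract_relations <- function(document, lexicon = default_lexicon(),
                              params = scoring_params()) {
  doc_id <- as.character(document$doc_id %||% document[["doc_id"]])
  if (!length(doc_id) || !nzchar(doc_id))
    stop_cypscope("document must carry a non-empty doc_id")
  tokens <- tokenize(c(as.character(document$title %||% ""),
                       as.character(document$abstract %||% "")))
  mentions <- detect_mentions(tokens, lexicon)
  relations_from_mentions(doc_id, mentions, params)
}

relations_from_mentions <- function(doc_id, mentions, params) {
  empty <- data.frame(doc_id = character(0), cyp = character(0),
                      ethnicity = character(0), frequency = numeric(0),
                      effect = character(0), cyp_start = integer(0),
                      ethnicity_start = integer(0),
                      frequency_start = integer(0), d_ce = integer(0),
                      d_fc = integer(0), negated = logical(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("cyp_relations", "data.frame")
  cyps <- mentions[mentions$entity_class == "CYP", , drop = FALSE]
  eths <- mentions[mentions$entity_class == "ETHNICITY", , drop = FALSE]
  freqs <- mentions[mentions$entity_class == "FREQUENCY", , drop = FALSE]
  negs <- mentions[mentions$entity_class == "NEGATION", , drop = FALSE]
  effs <- mentions[mentions$entity_class == "EFFECT", , drop = FALSE]
  if (!nrow(cyps) || !nrow(eths) || !nrow(freqs)) return(empty)

  sentences <- sort(unique(mentions$sentence))
  windows <- lapply(sentences, function(s) c(s, s))
  if (isTRUE(params$cross_sentence))
    windows <- c(windows, lapply(sentences, function(s) c(s, s + 1L)))

  rows <- list()
  for (w in windows) {
    in_w <- function(m) m[m$sentence >= w[1] & m$sentence <= w[2], , drop = FALSE]
    cw <- in_w(cyps); ew <- in_w(eths); fw <- in_w(freqs)
    if (!nrow(cw) || !nrow(ew) || !nrow(fw)) next
    nw <- in_w(negs); xw <- in_w(effs)
    cross <- w[1] != w[2]
    for (ci in seq_len(nrow(cw))) for (ei in seq_len(nrow(ew)))
      for (fi in seq_len(nrow(fw))) {
        cpos <- cw$token_start[ci]; epos <- ew$token_start[ei]
        fpos <- fw$token_start[fi]
        if (cross && length(unique(c(cw$sentence[ci], ew$sentence[ei],
                                     fw$sentence[fi]))) == 1L)
          next  # same-sentence triples are handled by their own window
        d_ce <- abs(cpos - epos)
        d_fc <- abs(fpos - cpos)
        # negation: a cue strictly between the closest of the two pairs
        pair <- if (d_ce <= d_fc) sort(c(cpos, epos)) else sort(c(cpos, fpos))
        negated <- nrow(nw) > 0 &&
          any(nw$token_start > pair[1] & nw$token_start < pair[2])
        score <- score_relation(d_ce, d_fc, negated, params)
        if (cross) score <- min(score, params$cross_sentence_cap)
        effect <- NA_character_
        if (nrow(xw)) {
          k <- which.min(abs(xw$token_start - cpos))
          effect <- xw$canonical_id[k]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          doc_id = doc_id, cyp = cw$canonical_id[ci],
          ethnicity = ew$canonical_id[ei], frequency = fw$value[fi],
          effect = effect, cyp_start = cpos, ethnicity_start = epos,
          frequency_start = fpos, d_ce = d_ce, d_fc = d_fc,
          negated = negated, score = score, stringsAsFactors = FALSE)
      }
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  # the same positional triple can fall into overlapping cross windows
  key <- paste(res$cyp_start, res$ethnicity_start, res$frequency_start)
  res <- res[order(key, -res$score), , drop = FALSE]
  res <- res[!duplicated(paste(res$cyp_start, res$ethnicity_start,
                               res$frequency_start)), , drop = FALSE]
  res <- res[res$score >= params$min_score, , drop = FALSE]
  res <- res[order(-res$score, res$cyp_start, res$ethnicity_start), ,
             drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("cyp_relations", "data.frame")
  res
}

#' Mine a whole corpus for relation candidates
#'
#' @param corpus Data frame with columns `doc_id`, `title`, `abstract`
#'   (see [read_corpus()]).
#' @param lexicon,params Passed to [extract_relations()].
#' @param dedup Collapse duplicate relations per document (default TRUE).
#' @return A `cyp_relations` data frame over all documents.
#' @export
mine_corpus <- function(corpus, lexicon = default_lexicon(),
                        params = scoring_params(), dedup = TRUE) {
  stopifnot(is.data.frame(corpus), all(c("doc_id", "abstract") %in% names(corpus)))
  if (anyDuplicated(corpus$doc_id))
    stop_cypscope("doc_id must be unique within a corpus")
  out <- lapply(seq_len(nrow(corpus)), function(i)
    extract_relations(corpus[i, , drop = FALSE], lexicon, params))
  res <- do.call(rbind, out)
  if (isTRUE(dedup)) res <- deduplicate(res)
  rownames(res) <- NULL
  res
}

#' Remove duplicate relation candidates
#'
#' Keeps one candidate per (doc_id, CYP, ethnicity, frequency value) key,
#' retaining the highest-scoring one. Idempotent.
#'
#' @param candidates A `cyp_relations` data frame.
#' @return The deduplicated `cyp_relations` data frame.
#' @export
deduplicate <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  if (!nrow(candidates)) return(candidates)
  key <- paste(candidates$doc_id, candidates$cyp, candidates$ethnicity,
               candidates$frequency, sep = "\r")
  ord <- order(key, -candidates$score)
  res <- candidates[ord, , drop = FALSE]
  res <- res[!duplicated(key[ord]), , drop = FALSE]
  res <- res[order(-res$score, res$doc_id, res$cyp_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read a corpus of abstracts
#'
#' Accepts either a UTF-8 TSV with columns `doc_id`, `title`, `abstract`,
#' or a directory of plain-text files named `<doc_id>.txt` (file content
#' becomes the abstract; title empty).
#'
#' @param path TSV file or directory.
#' @return Data frame with `doc_id`, `title`, `abstract`.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
    if (!length(files)) stop_cypscope("no .txt files under ", path)
    data.frame(
      doc_id = sub("\\.txt$", "", basename(files)),
      title = "",
      abstract = vapply(files, function(f)
        paste(readLines(f, warn = FALSE), collapse = " "), ""),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    read_tsv_strict(path, c("doc_id", "title", "abstract"))
  }
}
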