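#' Read a probes-by-tissues intensity matrix
#'
#' @param path TSV whose first column is `probe_id` and remaining columns
#'   are tissue intensities (non-negative, finite).
#' @return Numeric matrix, probes in rows, tissues in columns.
#' @export
read_expression_matrix <- function(path) {
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1] != "probe_id")
    stop_cypscope("first column must be probe_id")
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x$probe_id
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m)) || any(m < 0))
    stop_cypscope("intensities must be finite and non-negative")
  m
}

#' Read a probe-to-gene map
#'
#' @param path TSV with columns `probe_id`, `gene`.
#' @return Data frame with one gene per probe.
#' @export
read_probe_map <- function(path) {
  x <- read_tsv_strict(path, c("probe_id", "gene"))
  if (anyDuplicated(x$probe_id))
    stop_cypscope("each probe must map to exactly one gene")
  x$gene <- canonical_cyp(x$gene)
  x
}

#' Aggregate probe intensities to gene level
#'
#' Per-gene value in each tissue is the arithmetic mean of the gene's
#' probes' intensities on the provided scale (no log transform).
#' Probes without a map entry are excluded with a warning.
#'
#' @param matrix Probe-by-tissue numeric matrix (see
#'   [read_expression_matrix()]).
#' @param map Probe map data frame (see [read_probe_map()]).
#' @return Gene-by-tissue numeric matrix, genes sorted by name.
#' @export
aggregate_probes <- function(matrix, map) {
  stopifnot(is.matrix(matrix), is.data.frame(map),
            all(c("probe_id", "gene") %in% names(map)))
  mapped <- intersect(rownames(matrix), map$probe_id)
  unmapped <- setdiff(rownames(matrix), map$probe_id)
  if (length(unmapped))
    warning(length(unmapped), " unmapped probe(s) excluded: ",
            paste(utils::head(unmapped, 5), collapse = ", "),
            if (length(unmapped) > 5) ", ...", call. = FALSE)
  if (!length(mapped)) stop_cypscope("no probes could be mapped to genes")
  gene <- map$gene[match(mapped, map$probe_id)]
  sums <- rowsum(matrix[mapped, , drop = FALSE], group = gene)
  counts <- as.integer(table(gene)[rownames(sums)])
  out <- sums / counts
  out[order(rownames(out)), , drop = FALSE]
}

#' Per-gene relative expression (z-scores) across tissues
#'
#' For each gene, relative expression in a tissue is the intensity minus
#' the gene's mean intensity over the baseline tissues, divided by the
#' gene's standard deviation over the baseline (denominator n - 1). The
#' default baseline is all tissues; pass `exclude` (e.g. `"liver"`) to
#' compute the baseline statistics without dominant tissues while still
#' scoring them.
#'
#' @param gene_matrix Gene-by-tissue matrix (see [aggregate_probes()]).
#' @param baseline Character vector of tissue (column) names forming the
#'   baseline; default all columns.
#' @param exclude Tissues removed from the baseline (still z-scored).
#' @return List of class `cyp_relexp`: `z` (gene-by-tissue matrix),
#'   `baseline_stats` (data frame `gene`, `mean`, `sd`, `degenerate`), and
#'   `baseline` (tissue names used). Zero-variance genes get an all-zero z
#'   row and `degenerate = TRUE`.
#' @export
relative_expression <- function(gene_matrix, baseline = NULL,
                                exclude = NULL) {
  stopifnot(is.matrix(gene_matrix))
  tissues <- colnames(gene_matrix)
  baseline <- baseline %||% tissues
  bad <- setdiff(c(baseline, exclude), tissues)
  if (length(bad))
    stop_cypscope("unknown tissue(s): ", paste(bad, collapse = ", "))
  baseline <- setdiff(baseline, exclude)
  if (length(baseline) < 2L)
    stop_cypscope("baseline must contain at least two tissues")
  b <- gene_matrix[, baseline, drop = FALSE]
  mu <- rowMeans(b)
  sd <- apply(b, 1, stats::sd)
  degenerate <- sd == 0
  z <- (gene_matrix - mu) / ifelse(degenerate, 1, sd)
  z[degenerate, ] <- 0
  structure(list(
    z = z,
    baseline_stats = data.frame(gene = rownames(gene_matrix), mean = mu,
                                sd = sd, degenerate = degenerate,
                                row.names = NULL, stringsAsFactors = FALSE),
    baseline = baseline), class = "cyp_relexp")
}

#' Fold-threshold body-map calls
#'
#' For each (gene, tissue), the fold is the tissue intensity divided by the
#' mean intensity of that gene over all other tissues. A call is emitted
#' `UP` when fold is at least `fold_threshold` and `DOWN` when fold is at
#' most `1 / fold_threshold`. Cells whose other-tissue mean is zero are
#' suppressed with a warning.
#'
#' @param gene_matrix Gene-by-tissue matrix.
#' @param fold_threshold Fold-change threshold, must exceed 1. The survey
#'   used 2 for the body map table and 3 for the highlighted organ figure;
#'   both are valid choices here.
#' @return Data frame of class `cyp_bodymap`: `gene`, `tissue`, `fold`,
#'   `direction`, `threshold_used`.
#' @export
body_map_calls <- function(gene_matrix, fold_threshold = 2.0) {
  stopifnot(is.matrix(gene_matrix))
  if (!is.numeric(fold_threshold) || fold_threshold <= 1)
    stop_cypscope("fold_threshold must exceed 1")
  k <- ncol(gene_matrix)
  if (k < 2L) stop_cypscope("need at least two tissues")
  others_mean <- (rowSums(gene_matrix) - gene_matrix) / (k - 1)
  suppressed <- others_mean <= 0
  if (any(suppressed))
    warning(sum(suppressed),
            " cell(s) with zero mean over other tissues suppressed",
            call. = FALSE)
  fold <- ifelse(suppressed, NA_real_, gene_matrix / others_mean)
  up <- !is.na(fold) & fold >= fold_threshold
  down <- !is.na(fold) & fold <= 1 / fold_threshold
  idx <- which(up | down, arr.ind = TRUE)
  out <- data.frame(
    gene = rownames(gene_matrix)[idx[, 1]],
    tissue = colnames(gene_matrix)[idx[, 2]],
    fold = fold[idx],
    direction = ifelse(up[idx], "UP", "DOWN"),
    threshold_used = rep(fold_threshold, nrow(idx)),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cyp_bodymap", "data.frame")
  out
}

#' Export relative-expression z-scores as a long table
#'
#' @param relexp A `cyp_relexp` from [relative_expression()].
#' @param path Output TSV path; columns `gene`, `tissue`, `z`,
#'   `degenerate`.
#' @return `path`, invisibly.
#' @seealso [read_heatmap_table()]
#' @export
export_heatmap_table <- function(relexp, path) {
  stopifnot(inherits(relexp, "cyp_relexp"))
  z <- relexp$z
  deg <- relexp$baseline_stats$degenerate[match(rownames(z),
                                                relexp$baseline_stats$gene)]
  out <- data.frame(
    gene = rep(rownames(z), times = ncol(z)),
    tissue = rep(colnames(z), each = nrow(z)),
    z = as.vector(z),
    degenerate = rep(deg, times = ncol(z)),
    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Read a long-format z-score table back
#'
#' @param path TSV written by [export_heatmap_table()].
#' @return Data frame with `gene`, `tissue`, `z` (numeric), `degenerate`
#'   (logical).
#' @export
read_heatmap_table <- function(path) {
  x <- read_tsv_strict(path, c("gene", "tissue", "z", "degenerate"))
  x$z <- as.numeric(x$z)
  x$degenerate <- as.logical(x$degenerate)
  x
}
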