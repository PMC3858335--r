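#' Read annotated variants and genotypes from a VCF
#'
#' Thin wrapper around `VariantAnnotation::readVcf()`. Multi-allelic sites
#' are split into one record per alternate allele; gene, consequence class,
#' amino-acid change, cDNA change and damaging call are read from a
#' pipe-delimited annotation INFO key
#' (`GENE|CONSEQUENCE|AA|CDNA|DAMAGING`, one entry per alternate allele).
#' Consequence classes are never computed, only consumed; strings outside
#' `NON_SYNONYMOUS`, `SYNONYMOUS`, `SPLICE`, `FRAMESHIFT`, `OTHER` map to
#' `OTHER` with a warning. Phasing is ignored (`0|1` equals `0/1`).
#'
#' @param vcf_path Path to a VCF (plain or bgzipped) with GT genotypes.
#' @param info_key Name of the annotation INFO field (default
#'   `"CSQ_CLASS"`).
#' @return A list with `variants` (data frame: `chrom`, `pos`, `ref`,
#'   `alt`, `alt_index`, `rsid`, `gene`, `consequence`, `aa_change`,
#'   `cdna_change`, `damaging_call`, sorted by chrom, pos, alt) and
#'   `genotypes` (character matrix of original GT strings, one row per
#'   split variant record, columns = samples).
#' @export
read_variants <- function(vcf_path, info_key = "CSQ_CLASS") {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt))
    stop_cypscope("VCF has no GT genotype field: ", vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  alt <- as(alt, "CharacterList")
  info <- VariantAnnotation::info(vcf)
  ann <- NULL
  if (info_key %in% colnames(info)) {
    ann <- info[[info_key]]
    if (!methods::is(ann, "List")) ann <- as.list(as.character(ann))
  } else {
    warning("INFO key ", info_key, " absent; gene/consequence set to NA/OTHER",
            call. = FALSE)
  }
  rows <- list()
  gt_rows <- integer(0)
  for (i in seq_along(rr)) {
    alts <- alt[[i]]
    anns <- if (is.null(ann)) character(0) else as.character(ann[[i]])
    for (j in seq_along(alts)) {
      a <- if (length(anns) >= j) anns[[j]]
           else if (length(anns) == 1L) anns[[1L]]
           else NA_character_
      f <- parse_annotation(a)
      ref <- as.character(rr$REF[i])
      if (identical(ref, alts[[j]]))
        stop_cypscope("ref equals alt at record ", i)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(rr)[i]),
        pos = BiocGenerics::start(rr)[i],
        ref = ref, alt = alts[[j]], alt_index = j,
        rsid = if (!is.na(names(rr)[i]) && grepl("^rs", names(rr)[i]))
          names(rr)[i] else NA_character_,
        gene = f$gene, consequence = f$consequence, aa_change = f$aa,
        cdna_change = f$cdna, damaging_call = f$damaging,
        stringsAsFactors = FALSE)
      gt_rows <- c(gt_rows, i)
    }
  }
  variants <- do.call(rbind, rows)
  genotypes <- gt[gt_rows, , drop = FALSE]
  ord <- order(variants$chrom, variants$pos, variants$alt)
  variants <- variants[ord, , drop = FALSE]
  genotypes <- genotypes[ord, , drop = FALSE]
  rownames(variants) <- NULL
  rownames(genotypes) <- NULL
  list(variants = variants, genotypes = genotypes)
}

.consequence_classes <- c("NON_SYNONYMOUS", "SYNONYMOUS", "SPLICE",
                          "FRAMESHIFT", "OTHER")

parse_annotation <- function(a) {
  if (is.na(a) || !nzchar(a))
    return(list(gene = NA_character_, consequence = "OTHER",
                aa = NA_character_, cdna = NA_character_,
                damaging = NA_character_))
  f <- strsplit(a, "|", fixed = TRUE)[[1]]
  f <- c(f, rep(NA_character_, max(0, 5 - length(f))))
  f[!nzchar(f) | f == "."] <- NA_character_
  csq <- toupper(f[2])
  if (is.na(csq)) csq <- "OTHER"
  if (!csq %in% .consequence_classes) {
    warning("unknown consequence ", csq, " mapped to OTHER", call. = FALSE)
    csq <- "OTHER"
  }
  dmg <- toupper(f[5])
  if (!is.na(dmg) &&
      !dmg %in% c("BENIGN", "POSSIBLY_DAMAGING", "PROBABLY_DAMAGING"))
    dmg <- NA_character_
  list(gene = if (is.na(f[1])) NA_character_ else canonical_cyp(f[1]),
       consequence = csq, aa = f[3], cdna = f[4], damaging = dmg)
}

#' Compute cohort allele frequencies from diploid genotypes
#'
#' Standard AC/AN semantics: for each (split) variant record, `ac` counts
#' the alternate allele among called genotypes, `an` is twice the number of
#' called samples (missing genotypes are excluded from the denominator),
#' and `frequency_percent = 100 * ac / an`. Records with `an = 0` are
#' excluded with a warning.
#'
#' @param variants,genotypes As returned by [read_variants()].
#' @return Data frame of class `cyp_freq`: the variant columns plus `ac`,
#'   `an`, `frequency_percent`.
#' @export
allele_frequencies <- function(variants, genotypes) {
  stopifnot(is.data.frame(variants), is.matrix(genotypes),
            nrow(variants) == nrow(genotypes))
  n <- nrow(variants)
  ac <- integer(n); an <- integer(n)
  alt_index <- variants$alt_index
  if (is.null(alt_index)) alt_index <- rep(1L, n)
  alt_index[is.na(alt_index)] <- 1L
  for (i in seq_len(n)) {
    # a sample is called only if no allele is missing
    per <- strsplit(genotypes[i, ], "[/|]")
    called <- vapply(per, function(g) length(g) > 0 && !any(g == "."), TRUE)
    alleles <- unlist(per[called], use.names = FALSE)
    an[i] <- length(alleles)
    ac[i] <- sum(alleles == as.character(alt_index[i]))
  }
  keep <- an > 0L
  if (any(!keep))
    warning(sum(!keep), " variant(s) with no called genotypes excluded",
            call. = FALSE)
  out <- variants[keep, , drop = FALSE]
  out$ac <- ac[keep]
  out$an <- an[keep]
  out$frequency_percent <- 100 * out$ac / out$an
  rownames(out) <- NULL
  class(out) <- c("cyp_freq", "data.frame")
  out
}

#' Load a pre-computed SNP frequency table
#'
#' Reads a TSV of per-SNP global allele frequencies (columns `cyp`, `rsid`,
#' `cdna_change`, `aa_change`, `global_frequency_percent`) into the same
#' `cyp_freq` shape that [allele_frequencies()] produces. All rows in such
#' tables are non-synonymous coding SNPs by construction, so `consequence`
#' is set to `NON_SYNONYMOUS`; positional keys and AC/AN are `NA`. The
#' packaged `table2_1000g.tsv` (see [cypscope_snp_table()]) is the shipped
#' instance: 72 SNPs in 24 CYPs from a 1,092-genome cohort.
#'
#' @param path TSV path.
#' @return A `cyp_freq` data frame.
#' @export
load_frequency_table <- function(path) {
  x <- read_tsv_strict(path, c("cyp", "rsid", "cdna_change", "aa_change",
                               "global_frequency_percent"))
  out <- data.frame(
    chrom = NA_character_, pos = NA_integer_, ref = NA_character_,
    alt = NA_character_, alt_index = NA_integer_,
    rsid = x$rsid, gene = canonical_cyp(x$cyp),
    consequence = "NON_SYNONYMOUS", aa_change = x$aa_change,
    cdna_change = x$cdna_change, damaging_call = NA_character_,
    ac = NA_integer_, an = NA_integer_,
    frequency_percent = as.numeric(x$global_frequency_percent),
    stringsAsFactors = FALSE)
  if (anyNA(out$frequency_percent) || any(out$frequency_percent < 0) ||
      any(out$frequency_percent > 100))
    stop_cypscope("global_frequency_percent must be numeric in [0, 100]")
  class(out) <- c("cyp_freq", "data.frame")
  out
}

#' The packaged cohort SNP frequency table
#'
#' @return A `cyp_freq` data frame of the shipped 72-SNP table.
#' @export
cypscope_snp_table <- function() {
  load_frequency_table(system.file("extdata", "table2_1000g.tsv",
                                   package = "cypscope", mustWork = TRUE))
}

#' Keep common non-synonymous variants
#'
#' The survey rule: frequency analysis focuses on non-synonymous coding
#' SNPs at a prevalence of one percent or higher, regardless of ethnicity.
#'
#' @param results A `cyp_freq` data frame.
#' @param threshold_percent Frequency threshold in percent, in (0, 100\].
#' @return The filtered `cyp_freq`.
#' @export
filter_nonsyn_common <- function(results, threshold_percent = 1.0) {
  stopifnot(inherits(results, "cyp_freq"))
  if (!is.numeric(threshold_percent) || threshold_percent <= 0 ||
      threshold_percent > 100)
    stop_cypscope("threshold_percent must lie in (0, 100]")
  out <- results[results$consequence == "NON_SYNONYMOUS" &
                   results$frequency_percent >= threshold_percent, ,
                 drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(results)
  out
}

#' Per-gene variant counts and top variant
#'
#' @param results A non-empty `cyp_freq`.
#' @return Data frame with one row per gene: `gene`, `n_variants`,
#'   `top_rsid`, `top_frequency_percent` (per-gene maximum; frequency ties
#'   broken by rsid), sorted by gene.
#' @export
summarize_by_gene <- function(results) {
  stopifnot(inherits(results, "cyp_freq"))
  if (!nrow(results)) stop_cypscope("no variants to summarize")
  sp <- split(seq_len(nrow(results)), results$gene)
  out <- do.call(rbind, lapply(names(sp), function(g) {
    idx <- sp[[g]]
    ord <- idx[order(-results$frequency_percent[idx], results$rsid[idx])]
    data.frame(gene = g, n_variants = length(idx),
               top_rsid = results$rsid[ord[1]],
               top_frequency_percent = results$frequency_percent[ord[1]],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read star-allele defining-variant definitions
#'
#' @param path TSV with columns `cyp`, `allele`, `defining_variants`
#'   (semicolon-joined keys; each key is either `pos:ref:alt` or an rsID).
#' @return Data frame of class `cyp_star_defs` with a list-column `keys`.
#' @export
read_star_definitions <- function(path) {
  x <- read_tsv_strict(path, c("cyp", "allele", "defining_variants"))
  x$cyp <- canonical_cyp(x$cyp)
  x$keys <- lapply(strsplit(x$defining_variants, ";", fixed = TRUE), trimws)
  if (any(lengths(x$keys) == 0L))
    stop_cypscope("star-allele definitions must list at least one variant")
  class(x) <- c("cyp_star_defs", "data.frame")
  x
}

variant_keys <- function(results) {
  pos_key <- ifelse(is.na(results$pos), NA_character_,
                    paste(results$pos, results$ref, results$alt, sep = ":"))
  list(pos = pos_key, rsid = results$rsid)
}

#' Call star alleles present in a cohort
#'
#' An allele is `PRESENT` when every defining variant survives
#' [filter_nonsyn_common()] at the given threshold, `PARTIAL` when some do,
#' and `ABSENT` otherwise (including when the gene is absent from the
#' results, which is noted).
#'
#' @param results A `cyp_freq`.
#' @param definitions A `cyp_star_defs` from [read_star_definitions()].
#' @param threshold_percent Threshold passed to [filter_nonsyn_common()].
#' @return Data frame: `cyp`, `allele`, `status`, `n_defined`, `n_passing`,
#'   `note`.
#' @export
call_star_alleles <- function(results, definitions, threshold_percent = 1.0) {
  stopifnot(inherits(results, "cyp_freq"), inherits(definitions, "cyp_star_defs"))
  passing <- filter_nonsyn_common(results, threshold_percent)
  pk <- variant_keys(passing)
  out <- do.call(rbind, lapply(seq_len(nrow(definitions)), function(i) {
    keys <- definitions$keys[[i]]
    hit <- vapply(keys, function(k) {
      if (grepl("^rs", k)) k %in% stats::na.omit(pk$rsid)
      else k %in% stats::na.omit(pk$pos)
    }, TRUE)
    note <- ""
    if (!definitions$cyp[i] %in% results$gene)
      note <- "gene absent from results"
    status <- if (all(hit)) "PRESENT" else if (any(hit)) "PARTIAL" else "ABSENT"
    data.frame(cyp = definitions$cyp[i], allele = definitions$allele[i],
               status = status, n_defined = length(keys),
               n_passing = sum(hit), note = note, stringsAsFactors = FALSE)
  }))
  out %||% data.frame(cyp = character(0), allele = character(0),
                      status = character(0), n_defined = integer(0),
                      n_passing = integer(0), note = character(0))
}

#' Partition variants into nomenclature-known and novel
#'
#' A variant is `KNOWN` when its positional key (`pos:ref:alt`) or rsID
#' occurs among any star-allele definition's defining variants, otherwise
#' `NOVEL`. The partition is exhaustive and disjoint.
#'
#' @param results A `cyp_freq`.
#' @param catalog A `cyp_star_defs`.
#' @return `results` with an added logical column `novel`.
#' @export
flag_novel <- function(results, catalog) {
  stopifnot(inherits(results, "cyp_freq"))
  keys <- if (nrow(catalog)) unique(unlist(catalog$keys)) else character(0)
  vk <- variant_keys(results)
  known <- (!is.na(vk$pos) & vk$pos %in% keys) |
    (!is.na(vk$rsid) & vk$rsid %in% keys)
  results$novel <- !known
  results
}

#' Export a frequency table to TSV
#'
#' Mirrors the survey's published column layout (CYP, ID, Mutation, Amino
#' acid, Global frequency (%)) plus `ac`, `an` and the novel flag when
#' present.
#'
#' @param results A `cyp_freq` (optionally after [flag_novel()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_frequency_table <- function(results, path) {
  stopifnot(inherits(results, "cyp_freq"))
  out <- data.frame(cyp = results$gene, rsid = results$rsid,
                    cdna_change = results$cdna_change,
                    aa_change = results$aa_change,
                    global_frequency_percent = results$frequency_percent,
                    ac = results$ac, an = results$an,
                    stringsAsFactors = FALSE)
  if (!is.null(results$novel)) out$novel <- results$novel
  write_tsv(out, path)
}
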