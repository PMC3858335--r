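# Synthetic inputs with ground-truth ledgers. These stand in for the real
# upstream resources (literature abstracts, a 1,000-genome diploid cohort,
# a multi-tissue microarray series), reproducing the statistical structure
# each pipeline stage assumes -- not their linguistic or biological realism.

new_truth <- function(kind, entries, seed) {
  structure(list(kind = kind, entries = entries, seed = seed),
            class = "cyp_truth")
}

#' @export
print.cyp_truth <- function(x, ...) {
  cat("Synthetic ground truth (", x$kind, "), seed ", x$seed, ": ",
      nrow(x$entries), " planted entr", if (nrow(x$entries) == 1) "y" else "ies",
      "\n", sep = "")
  invisible(x)
}

# filler vocabulary deliberately disjoint from the default lexicon so token
# distances are exact and decoy-free
.filler_words <- c(
  "the", "a", "of", "in", "this", "study", "genotype", "genotypes",
  "sample", "samples", "analysis", "allele", "alleles", "variant",
  "variants", "observed", "reported", "among", "subjects", "patients",
  "cohort", "data", "was", "were", "within", "across", "carriers",
  "distribution", "assessed", "measured", "estimated", "frequency",
  "prevalence", "genotyped", "screened", "enrolled", "tested")

#' Generate a synthetic abstract corpus with planted relations
#'
#' Each planted document contains exactly one in-window
#' (CYP, ethnicity, frequency, effect) tuple at the requested token
#' distances, embedded in filler sentences built from a fixed vocabulary
#' (so distances are exact). A fraction `decoy_rate` of the remaining
#' documents are decoys carrying a full triple at distances
#' `threshold + 6` in both dimensions (outside the score-100 window);
#' the rest mention a CYP only.
#'
#' @param n_docs Number of documents.
#' @param n_planted Number of planted documents (at most `n_docs`).
#' @param distance_spec List with `d_ce` (CYP-ethnicity distance, default
#'   7) and `d_fc` (frequency-CYP distance, default 6) for planted tuples.
#' @param decoy_rate Fraction of non-planted documents that are decoys.
#' @param seed Integer seed; the same seed reproduces the corpus and
#'   ledger byte-identically.
#' @param sentence_budget Maximum tokens in a generated sentence; distances
#'   that cannot fit raise an error.
#' @return List with `corpus` (data frame `doc_id`, `title`, `abstract`)
#'   and `truth` (a `cyp_truth` whose `entries` ledger has one row per
#'   planted tuple: `doc_id`, `cyp`, `ethnicity`, `frequency`, `effect`,
#'   `d_ce`, `d_fc`).
#' @export
gen_abstracts <- function(n_docs = 200, n_planted = 100,
                          distance_spec = list(d_ce = 7L, d_fc = 6L),
                          decoy_rate = 0.5, seed = 1,
                          sentence_budget = 60L) {
  stopifnot(n_planted <= n_docs, n_docs >= 0,
            decoy_rate >= 0, decoy_rate <= 1)
  d_ce <- as.integer(distance_spec$d_ce %||% 7L)
  d_fc <- as.integer(distance_spec$d_fc %||% 6L)
  if (d_ce < 1L || d_fc < 1L)
    stop_cypscope("planted distances must be at least 1")
  if (d_ce + d_fc + 8L > sentence_budget)
    stop_cypscope("distance_spec exceeds the sentence length budget (",
                  sentence_budget, " tokens)")
  cyp_pool <- c("2D6", "2C19", "2C9", "1A2", "2A6", "2B6", "3A4", "3A5")
  eth_pool <- c(Caucasians = "Caucasian", Europeans = "Caucasian",
                Asians = "Asian", Africans = "African")
  eff_pool <- c(decreased = "decrease", increased = "increase")
  with_rng_seed(seed, {
    fill <- function(k) sample(.filler_words, k, replace = TRUE)
    filler_sentence <- function() paste(c(fill(sample(4:9, 1)), "."),
                                        collapse = " ")
    triple_sentence <- function(dce, dfc, with_effect = TRUE) {
      cyp <- sample(cyp_pool, 1)
      eth_surface <- sample(names(eth_pool), 1)
      eff_surface <- sample(names(eff_pool), 1)
      freq <- round(stats::runif(1, 0.5, 60), 1)
      toks <- c(fill(2), eth_surface, fill(dce - 1L), paste0("CYP", cyp),
                fill(dfc - 1L), sprintf("%.1f%%", freq))
      if (with_effect) toks <- c(toks, fill(1), eff_surface)
      toks <- c(toks, fill(1), ".")
      list(text = paste(toks, collapse = " "), cyp = cyp,
           ethnicity = unname(eth_pool[eth_surface]), frequency = freq,
           effect = unname(eff_pool[eff_surface]))
    }
    n_rest <- n_docs - n_planted
    n_decoy <- floor(decoy_rate * n_rest)
    roles <- c(rep("planted", n_planted), rep("decoy", n_decoy),
               rep("background", n_rest - n_decoy))
    docs <- vector("list", n_docs)
    ledger <- list()
    for (i in seq_len(n_docs)) {
      doc_id <- sprintf("SYN%05d", i)
      role <- roles[i]
      body <- c(filler_sentence())
      if (role == "planted") {
        tr <- triple_sentence(d_ce, d_fc)
        body <- c(body, tr$text, filler_sentence())
        ledger[[length(ledger) + 1L]] <- data.frame(
          doc_id = doc_id, cyp = tr$cyp, ethnicity = tr$ethnicity,
          frequency = tr$frequency, effect = tr$effect,
          d_ce = d_ce, d_fc = d_fc, stringsAsFactors = FALSE)
      } else if (role == "decoy") {
        tr <- triple_sentence(d_ce + 6L, d_fc + 6L, with_effect = FALSE)
        body <- c(body, tr$text)
      } else {
        body <- c(body,
                  paste(c(fill(3), paste0("CYP", sample(cyp_pool, 1)),
                          fill(2), "."), collapse = " "))
      }
      docs[[i]] <- data.frame(doc_id = doc_id,
                              title = paste("Synthetic record", i),
                              abstract = paste(body, collapse = " "),
                              stringsAsFactors = FALSE)
    }
    corpus <- do.call(rbind, docs) %||%
      data.frame(doc_id = character(0), title = character(0),
                 abstract = character(0))
    entries <- do.call(rbind, ledger) %||%
      data.frame(doc_id = character(0), cyp = character(0),
                 ethnicity = character(0), frequency = numeric(0),
                 effect = character(0), d_ce = integer(0),
                 d_fc = integer(0))
    list(corpus = corpus, truth = new_truth("RELATIONS", entries, seed))
  })
}

#' Generate a synthetic diploid VCF with known allele frequencies
#'
#' Genotypes are drawn under Hardy-Weinberg equilibrium: each sample
#' receives two independent Bernoulli(`true_freq`) alleles. The annotation
#' INFO key carries `GENE|CONSEQUENCE|AA|CDNA` per variant, matching what
#' [read_variants()] consumes. The ledger records the planted frequencies.
#'
#' @param n_samples Number of diploid samples.
#' @param variant_spec Data frame with columns `gene`, `consequence`,
#'   `true_freq` (allele frequency in \[0, 1\]) and optional `rsid`,
#'   `aa_change`.
#' @param seed Integer seed (byte-identical reruns).
#' @param path Output VCF path (plain text).
#' @param info_key Name of the annotation INFO field.
#' @return List with `path` and `truth` (ledger columns: `gene`, `rsid`,
#'   `chrom`, `pos`, `ref`, `alt`, `consequence`, `true_freq`,
#'   `true_freq_percent`).
#' @export
gen_vcf <- function(n_samples, variant_spec, seed = 1,
                    path = tempfile(fileext = ".vcf"),
                    info_key = "CSQ_CLASS") {
  stopifnot(is.data.frame(variant_spec),
            all(c("gene", "consequence", "true_freq") %in% names(variant_spec)),
            n_samples >= 1)
  if (any(variant_spec$true_freq < 0 | variant_spec$true_freq > 1))
    stop_cypscope("true_freq must lie in [0, 1]")
  nv <- nrow(variant_spec)
  rsid <- variant_spec$rsid %||% sprintf("rs%07d", seq_len(nv) * 101L)
  aa <- variant_spec$aa_change %||% rep("", nv)
  refs <- rep(c("A", "C", "G", "T"), length.out = nv)
  alts <- rep(c("G", "T", "A", "C"), length.out = nv)
  pos <- 10000L + 500L * seq_len(nv)
  with_rng_seed(seed, {
    gts <- matrix("", nrow = nv, ncol = n_samples)
    for (i in seq_len(nv)) {
      a1 <- stats::rbinom(n_samples, 1L, variant_spec$true_freq[i])
      a2 <- stats::rbinom(n_samples, 1L, variant_spec$true_freq[i])
      gts[i, ] <- paste0(a1, "/", a2)
    }
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=cypscope-synthetic",
      "##contig=<ID=chrS>",
      paste0("##INFO=<ID=", info_key, ",Number=A,Type=String,",
             "Description=\"GENE|CONSEQUENCE|AA|CDNA annotation\">"),
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", sprintf("S%04d", seq_len(n_samples))),
            collapse = "\t"))
    body <- vapply(seq_len(nv), function(i) {
      ann <- paste(variant_spec$gene[i],
                   toupper(variant_spec$consequence[i]), aa[i],
                   paste0(pos[i], refs[i], ">", alts[i]), sep = "|")
      paste(c("chrS", pos[i], rsid[i], refs[i], alts[i], ".", "PASS",
              paste0(info_key, "=", ann), "GT", gts[i, ]), collapse = "\t")
    }, "")
    writeLines(c(header, body), path)
    entries <- data.frame(
      gene = canonical_cyp(variant_spec$gene), rsid = rsid, chrom = "chrS",
      pos = pos, ref = refs, alt = alts,
      consequence = toupper(variant_spec$consequence),
      true_freq = variant_spec$true_freq,
      true_freq_percent = 100 * variant_spec$true_freq,
      stringsAsFactors = FALSE)
    list(path = path, truth = new_truth("GENOTYPES", entries, seed))
  })
}

# 40 CYP isoforms typically measured on the array used as the default shape
.cyp_gene_pool <- c(
  "1A1", "1A2", "1B1", "2A6", "2A7", "2A13", "2B6", "2C8", "2C9", "2C18",
  "2C19", "2D6", "2E1", "2F1", "2J2", "2R1", "2S1", "2U1", "2W1", "3A4",
  "3A5", "3A7", "3A43", "4A11", "4A22", "4B1", "4F2", "4F3", "4F8",
  "4F11", "4F12", "4V2", "5A1", "7A1", "8A1", "8B1", "11A1", "11B1",
  "11B2", "19A1")

#' Generate a synthetic probe-by-tissue expression matrix
#'
#' Background intensities are log-normal around `base_intensity`
#' (multiplicative noise of standard deviation `noise_sd` on the log
#' scale -- the usual microarray intensity model). Each gene carries 1-3
#' probes; planted (gene, tissue, fold) cells have every probe of that
#' gene multiplied by `fold` in that tissue. Defaults emulate the original
#' survey's shape: 84 probe sets, 40 CYP isoforms, 65 tissue regions (with
#' `liver` first, so the separate-liver baseline option is exercisable).
#'
#' @param n_genes Number of genes (at most 40 default gene names are
#'   available; more get generic names).
#' @param tissues Either the number of tissues or a character vector of
#'   tissue names.
#' @param planted Data frame with columns `gene`, `tissue`, `fold`
#'   (fold > 0), or NULL for none.
#' @param noise_sd Log-scale standard deviation of the background.
#' @param n_probes Total probe count (at least `n_genes`, at most
#'   3 * `n_genes`).
#' @param base_intensity Median background intensity.
#' @param seed Integer seed (byte-identical reruns).
#' @return List with `matrix` (probe-by-tissue), `probe_map` (data frame
#'   `probe_id`, `gene`) and `truth` (ledger of planted triples).
#' @export
gen_expression <- function(n_genes = 40, tissues = 65, planted = NULL,
                           noise_sd = 0.25, n_probes = 84,
                           base_intensity = 100, seed = 1) {
  stopifnot(n_genes >= 1, n_probes >= n_genes, n_probes <= 3 * n_genes,
            noise_sd >= 0, base_intensity > 0)
  if (is.numeric(tissues) && length(tissues) == 1L) {
    stopifnot(tissues >= 2)
    tissues <- c("liver", sprintf("tissue_%02d", seq_len(tissues - 1L)))
  }
  genes <- if (n_genes <= length(.cyp_gene_pool)) .cyp_gene_pool[seq_len(n_genes)]
           else c(.cyp_gene_pool,
                  sprintf("51Z%d", seq_len(n_genes - length(.cyp_gene_pool))))
  if (is.null(planted))
    planted <- data.frame(gene = character(0), tissue = character(0),
                          fold = numeric(0))
  stopifnot(all(c("gene", "tissue", "fold") %in% names(planted)))
  planted$gene <- canonical_cyp(planted$gene)
  if (any(!planted$gene %in% genes))
    stop_cypscope("planted gene(s) outside the matrix: ",
                  paste(setdiff(planted$gene, genes), collapse = ", "))
  if (any(!planted$tissue %in% tissues))
    stop_cypscope("planted tissue(s) outside the matrix: ",
                  paste(setdiff(planted$tissue, tissues), collapse = ", "))
  if (any(planted$fold <= 0)) stop_cypscope("planted fold must be positive")
  with_rng_seed(seed, {
    # every gene gets one probe; spare probes spread at random, max 3 each
    probe_gene <- genes
    spare <- n_probes - n_genes
    capacity <- rep(2L, n_genes)
    while (spare > 0L) {
      g <- sample(which(capacity > 0L), 1L)
      probe_gene <- c(probe_gene, genes[g])
      capacity[g] <- capacity[g] - 1L
      spare <- spare - 1L
    }
    probe_gene <- sort(probe_gene)
    probe_id <- paste0("cyp", tolower(probe_gene), "_",
                       stats::ave(seq_along(probe_gene), probe_gene,
                                  FUN = seq_along), "_at")
    m <- matrix(
      stats::rlnorm(length(probe_id) * length(tissues),
                    meanlog = log(base_intensity), sdlog = noise_sd),
      nrow = length(probe_id), ncol = length(tissues),
      dimnames = list(probe_id, tissues))
    for (r in seq_len(nrow(planted))) {
      pr <- probe_gene == planted$gene[r]
      m[pr, planted$tissue[r]] <- m[pr, planted$tissue[r]] * planted$fold[r]
    }
    list(matrix = m,
         probe_map = data.frame(probe_id = probe_id, gene = probe_gene,
                                stringsAsFactors = FALSE),
         truth = new_truth("EXPRESSION", planted, seed))
  })
}
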