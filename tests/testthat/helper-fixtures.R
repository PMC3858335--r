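# fixtures built in code; no binary files

mini_catalog_tsv <- function(rows = NULL) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  header <- "cyp\tallele\taa_changes\tactivity\ttest_drug\tsource_ids\tCaucasian"
  rows <- rows %||% c(
    "2D6\t*4\tP34S;S486T\tdecrease\tDextromethorphan\t9012401\t20.7",
    "3A5\t*3C\tSplicing defect\tdecrease\tSirolimus\t17162466\t81.3",
    "2C9\t*2\tR144C\tdecrease\tWarfarin\t15284536\t19.0% *1/*2 1.6% *2/*2")
  writeLines(c(header, rows), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal VCF writer for hand-constructed genotype fixtures
write_mini_vcf <- function(records, samples, info_key = "CSQ_CLASS") {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrS>",
    paste0("##INFO=<ID=", info_key, ",Number=A,Type=String,",
           "Description=\"GENE|CONSEQUENCE|AA|CDNA\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

one_doc <- function(abstract, doc_id = "D1", title = "") {
  list(doc_id = doc_id, title = title, abstract = abstract)
}
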