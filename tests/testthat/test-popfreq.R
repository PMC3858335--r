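# population allele frequencies: VCF reading, AC/AN computation, the
# non-synonymous 1% filter, star-allele calling, novel flagging

test_that("read_variants + allele_frequencies count alleles by hand-checkable rules", {
  # 3 samples, GTs 0/0 0/1 1/1 -> ac 3, an 6
  p <- write_mini_vcf(
    paste(c("chrS", "100", "rs1", "A", "G", ".", "PASS",
            "CSQ_CLASS=2D6|NON_SYNONYMOUS|P34S|100A>G", "GT",
            "0/0", "0/1", "1/1"), collapse = "\t"),
    samples = c("s1", "s2", "s3"))
  vv <- read_variants(p)
  fr <- allele_frequencies(vv$variants, vv$genotypes)
  expect_identical(fr$ac, 3L)
  expect_identical(fr$an, 6L)
  expect_equal(fr$frequency_percent, 50)
  expect_identical(fr$gene, "2D6")
  expect_identical(fr$consequence, "NON_SYNONYMOUS")

  # missing genotypes leave the denominator; phased == unphased
  p2 <- write_mini_vcf(
    paste(c("chrS", "100", "rs1", "A", "G", ".", "PASS",
            "CSQ_CLASS=2D6|NON_SYNONYMOUS||", "GT",
            "./.", "0|1", "1/1"), collapse = "\t"),
    samples = c("s1", "s2", "s3"))
  vv2 <- read_variants(p2)
  fr2 <- allele_frequencies(vv2$variants, vv2$genotypes)
  expect_identical(fr2$an, 4L)
  expect_identical(fr2$ac, 3L)

  # all-missing site is excluded with a warning
  p3 <- write_mini_vcf(
    paste(c("chrS", "100", "rs1", "A", "G", ".", "PASS",
            "CSQ_CLASS=2D6|NON_SYNONYMOUS||", "GT",
            "./.", "./."), collapse = "\t"),
    samples = c("s1", "s2"))
  vv3 <- read_variants(p3)
  expect_warning(fr3 <- allele_frequencies(vv3$variants, vv3$genotypes),
                 "no called genotypes")
  expect_identical(nrow(fr3), 0L)
})

test_that("multi-allelic sites split into per-alt records", {
  p <- write_mini_vcf(
    paste(c("chrS", "200", "rs9", "A", "G,T", ".", "PASS",
            "CSQ_CLASS=2C9|NON_SYNONYMOUS|R144C|430A>G,2C9|SYNONYMOUS||",
            "GT", "0/1", "1/2", "2/2"), collapse = "\t"),
    samples = c("s1", "s2", "s3"))
  vv <- read_variants(p)
  expect_identical(nrow(vv$variants), 2L)
  expect_identical(sort(vv$variants$alt), c("G", "T"))
  fr <- allele_frequencies(vv$variants, vv$genotypes)
  expect_identical(fr$ac[fr$alt == "G"], 2L)   # alleles "1"
  expect_identical(fr$ac[fr$alt == "T"], 3L)   # alleles "2"
  expect_identical(fr$an, c(6L, 6L))
  expect_identical(fr$consequence[fr$alt == "G"], "NON_SYNONYMOUS")
  expect_identical(fr$consequence[fr$alt == "T"], "SYNONYMOUS")
})

test_that("unknown consequence maps to OTHER with a warning", {
  p <- write_mini_vcf(
    paste(c("chrS", "100", "rs1", "A", "G", ".", "PASS",
            "CSQ_CLASS=2D6|weird_class||", "GT", "0/1"),
          collapse = "\t"),
    samples = "s1")
  expect_warning(vv <- read_variants(p), "unknown consequence")
  expect_identical(vv$variants$consequence, "OTHER")
})

test_that("filter_nonsyn_common keeps common non-synonymous variants only", {
  t2 <- cypscope_snp_table()
  f <- filter_nonsyn_common(t2, 1.0)
  expect_identical(nrow(f), 72L)
  expect_identical(length(unique(f$gene)), 24L)

  syn <- t2[1, ]
  syn$consequence <- "SYNONYMOUS"
  syn$frequency_percent <- 50
  rare <- t2[2, ]
  rare$frequency_percent <- 0.5
  mixed <- rbind(f, syn, rare)
  class(mixed) <- class(t2)
  expect_identical(nrow(filter_nonsyn_common(mixed, 1.0)), 72L)

  # anti-monotone in threshold (property)
  sizes <- vapply(c(0.5, 1, 2, 5, 10, 30),
                  function(t) nrow(filter_nonsyn_common(t2, t)), 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("summarize_by_gene reports per-gene counts and maxima", {
  f <- filter_nonsyn_common(cypscope_snp_table(), 1.0)
  s <- summarize_by_gene(f)
  expect_identical(nrow(s), 24L)
  expect_identical(sum(s$n_variants), 72L)
  top <- s[which.max(s$top_frequency_percent), ]
  expect_identical(top$gene, "4F11")
  expect_identical(top$top_rsid, "rs1060463")
  expect_equal(top$top_frequency_percent, 49.5)

  one <- f[f$rsid == "rs5031016", ]
  class(one) <- class(f)
  s1 <- summarize_by_gene(one)
  expect_identical(s1$top_rsid, "rs5031016")
  expect_error(summarize_by_gene(f[0, ]), "no variants")
})

test_that("call_star_alleles reports PRESENT / PARTIAL / ABSENT", {
  t2 <- cypscope_snp_table()
  defs <- read_star_definitions(system.file(
    "extdata", "star_definitions_2a6.tsv", package = "cypscope"))
  calls <- call_star_alleles(t2, defs, 1.0)
  expect_identical(calls$status, "PRESENT")  # rs5031016 at 5.1%
  expect_identical(calls$allele, "*36")

  # empty definitions -> empty report
  empty <- defs[0, ]
  class(empty) <- class(defs)
  expect_identical(nrow(call_star_alleles(t2, empty)), 0L)

  # one defining variant below threshold -> PARTIAL
  dpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cyp\tallele\tdefining_variants",
               "2A6\t*XX\trs5031016;rs0000000"), dpath)
  d2 <- read_star_definitions(dpath)
  expect_identical(call_star_alleles(t2, d2)$status, "PARTIAL")

  # gene absent from results -> ABSENT with note
  writeLines(c("cyp\tallele\tdefining_variants", "9Z9\t*1\trs0000001"), dpath)
  d3 <- read_star_definitions(dpath)
  c3 <- call_star_alleles(t2, d3)
  expect_identical(c3$status, "ABSENT")
  expect_match(c3$note, "absent")
})

test_that("flag_novel partitions exhaustively and disjointly", {
  t2 <- cypscope_snp_table()
  defs <- read_star_definitions(system.file(
    "extdata", "star_definitions_2a6.tsv", package = "cypscope"))
  flagged <- flag_novel(t2, defs)
  expect_identical(sum(!flagged$novel), 1L)  # only rs5031016 is known
  expect_identical(flagged$rsid[!flagged$novel], "rs5031016")
  expect_identical(sum(flagged$novel) + sum(!flagged$novel), nrow(t2))

  all_novel <- flag_novel(t2, defs[0, ])
  expect_true(all(all_novel$novel))
})

test_that("frequency table export mirrors the published columns and re-reads", {
  f <- flag_novel(cypscope_snp_table(),
                  read_star_definitions(system.file(
                    "extdata", "star_definitions_2a6.tsv",
                    package = "cypscope")))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_frequency_table(f, path)
  back <- utils::read.delim(path)
  expect_identical(nrow(back), 72L)
  expect_true(all(c("cyp", "rsid", "global_frequency_percent", "novel")
                  %in% names(back)))
  expect_equal(back$global_frequency_percent, f$frequency_percent)
})

test_that("frequency is invariant under sample order and ref/alt swap (property)", {
  spec <- data.frame(gene = "2D6", consequence = "NON_SYNONYMOUS",
                     true_freq = 0.3)
  g <- gen_vcf(50, spec, seed = 11)
  vv <- read_variants(g$path)
  fr <- allele_frequencies(vv$variants, vv$genotypes)
  perm <- sample(ncol(vv$genotypes))
  fr_perm <- allele_frequencies(vv$variants,
                                vv$genotypes[, perm, drop = FALSE])
  expect_equal(fr_perm$frequency_percent, fr$frequency_percent)

  # swapping ref/alt labels complements the frequency
  swapped <- vv$genotypes
  swapped[] <- vapply(vv$genotypes, function(g)
    chartr("01", "10", g), "")
  fr_swap <- allele_frequencies(vv$variants, swapped)
  expect_equal(fr_swap$frequency_percent, 100 - fr$frequency_percent)
})
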