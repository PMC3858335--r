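# Known discrepancies in the packaged catalog fixtures

The star-allele catalog (`table1_caucasian.tsv`) and the cohort SNP table
(`table2_1000g.tsv`) transcribe a published curation verbatim. The source's
narrative and its printed tables disagree in a few cells. Where they
conflict, the fixtures follow the tables; the conflicts are recorded here
and are NOT silently corrected.

1. CYP2A6*1B Caucasian frequency: narrative says 30.0%, table says 32.6%.
   Fixture: 32.6.
2. CYP2A6*2 Caucasian frequency: narrative says 8.0%, table says 2.3%.
   Fixture: 2.3.
3. CYP2C9*2 Caucasian frequency: narrative says 16.0%; the table cell is a
   genotype breakdown "19.0% *1/*2 1.6% *2/*2 1.8 % *2/*3". Fixture keeps
   the verbatim cell; the loader takes the first percentage (19.0, the
   *1/*2 carrier class) as the scalar frequency.
4. CYP2D6 allele count: narrative says 11 alleles with known impact, the
   table prints 10 rows; a 2D6*2A allele (32.4%) appears only in the
   narrative and is therefore absent from the fixture.
5. CYP4A11 top SNP: narrative cites rs112743 (42.6%), the SNP table lists
   rs1126743 for 4A11 at 42.6% (probable typo). Fixture: rs1126743.
6. `table2_1000g.tsv` reproduces duplicate rows as printed (rs28399499
   appears twice under 2A6 with distinct amino-acid changes; rs11572103
   appears twice under 2C8 with identical annotations).
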