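# toy VCF: 10 data lines = 4 carried SNVs + 2 indels + 1 multi-allelic
# (hom-ref) + 3 hom-ref SNVs
toy_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS",
    "1\t100\trs1\tA\tG\t100\tPASS\tAF=0.2\tGT\t0|1",
    "1\t200\trs2\tC\tT\t100\tPASS\tAF=0.1\tGT\t1|1",
    "1\t300\trs3\tG\tGA\t100\tPASS\tAF=0.1\tGT\t0|1",
    "1\t400\trs4\tTTG\tT\t100\tPASS\tAF=0.1\tGT\t1|0",
    "1\t500\trs5\tG\tA,C\t100\tPASS\tAF=0.1,0.1\tGT\t0|0",
    "1\t600\trs6\tT\tC\t100\tPASS\tAF=0.3\tGT\t0|0",
    "1\t700\trs7\tA\tC\t100\tPASS\tAF=0.3\tGT\t0|0",
    "1\t800\trs8\tG\tT\t100\tPASS\tAF=0.3\tGT\t0|0",
    "1\t900\trs9\tT\tA\t100\tPASS\tAF=0.05\tGT\t1|0",
    "1\t950\trs10\tC\tG\t100\tPASS\tAF=0.5\tGT\t0|1"), path)
  path
}

test_that("read_vcf keeps only carried biallelic SNVs and accounts for every line", {
  path <- toy_vcf(tempfile(fileext = ".vcf"))
  snps <- read_vcf(path, "S")
  expect_equal(nrow(snps), 4L)
  expect_equal(snps$id, c("rs1", "rs2", "rs9", "rs10"))
  expect_equal(snps$pos, c(100L, 200L, 900L, 950L))
  expect_equal(snps$ref[1], "A")
  expect_equal(snps$alt[1], "G")
  expect_equal(snps$zygosity, c("het", "hom", "het", "het"))
  expect_equal(snps$allele_freq[1], 0.2)
  # rows emitting records + skipped rows == data lines
  sk <- attr(snps, "skipped")
  expect_equal(length(unique(snps$pos)) + sum(sk), attr(snps, "n_records_input"))
  expect_equal(attr(snps, "n_records_input"), 10L)
})

test_that("read_vcf names available samples when the requested one is missing", {
  path <- toy_vcf(tempfile(fileext = ".vcf"))
  expect_error(read_vcf(path, "HG0"), "available.*S")
})

test_that("pre-miRNA TSV round-trips every field exactly", {
  mirs <- list(
    premirna("mirA", "chr1", 101, 180, "+",
             sequence = paste(rep("ACGU", 20), collapse = ""),
             mature_spans = data.frame(arm = c("5p", "3p"),
                                       start = c(3L, 50L), end = c(24L, 71L))),
    premirna("mirB", "chr2", 500, 559, "-",
             sequence = paste(rep("GUCA", 15), collapse = "")))
  path <- tempfile(fileext = ".tsv")
  write_premirnas(mirs, path)
  back <- read_premirnas(path)
  expect_equal(length(back), 2L)
  for (nm in c("mirA", "mirB")) {
    a <- mirs[[match(nm, vapply(mirs, `[[`, "", "name"))]]
    b <- back[[nm]]
    expect_equal(a[c("name", "chrom", "start", "end", "strand", "sequence")],
                 b[c("name", "chrom", "start", "end", "strand", "sequence")])
    expect_equal(a$mature_spans, b$mature_spans)
  }
})

test_that("FASTA sequences are transcribed and length-checked against spans", {
  fa <- tempfile(fileext = ".fa")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(">mirX", paste(rep("ACGT", 20), collapse = "")), fa)
  writeLines("mirX\tchr1\t101\t180\t+\t\t", tsv)
  mirs <- read_premirnas(tsv, fa)
  expect_equal(nchar(mirs$mirX$sequence), 80L)
  expect_false(grepl("T", mirs$mirX$sequence))
  expect_true(grepl("U", mirs$mirX$sequence))
  # span/sequence length mismatch is an error naming the hairpin
  writeLines("mirX\tchr1\t101\t150\t+\t\t", tsv)
  expect_error(read_premirnas(tsv, fa), "mirX")
})

test_that("GFF3 hairpins gain strand and within-hairpin mature spans", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    paste0("chr9\t.\tmiRNA_primary_transcript\t1001\t1080\t.\t-\t.\t",
           "ID=MI999;Name=syn-mir-minus"),
    paste0("chr9\t.\tmiRNA\t1055\t1076\t.\t-\t.\t",
           "ID=MIMAT1;Name=syn-mir-minus-5p;Derives_from=MI999")), gff)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">syn-mir-minus", strrep("ACGU", 20)), fa)
  mirs <- read_premirnas(gff, fa)
  m <- mirs[["syn-mir-minus"]]
  expect_equal(m$strand, "-")
  # minus strand: hairpin index 0 sits at genomic end
  expect_equal(m$mature_spans$start, 1080L - 1076L)
  expect_equal(m$mature_spans$end, 1080L - 1055L)
  expect_equal(m$mature_spans$arm, "5p")
})

test_that("read_reads collapses identical sequences and honours _xN headers", {
  fq <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII",
               "@r2", "ACGTACGT", "+", "IIIIIIII",
               "@r3", "ACGTACGT", "+", "IIIIIIII",
               "@r4", "TTTTCCCC", "+", "IIIIIIII"), fq)
  rs <- read_reads(fq)
  expect_equal(nrow(rs), 2L)
  expect_equal(rs$count[rs$sequence == "ACGTACGT"], 3L)

  fa <- tempfile(fileext = ".fa")
  writeLines(c(">seq1_x24", "AAACCCGGG", ">seq2_x3", "GGGTTTAAA"), fa)
  rs <- read_reads(fa)
  expect_equal(rs$count[rs$sequence == "AAACCCGGG"], 24L)

  # 100 reads over 7 distinct sequences
  set.seed(5)
  pool <- vapply(1:7, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""), character(1))
  picks <- sample(pool, 100, replace = TRUE)
  fq2 <- tempfile(fileext = ".fq")
  writeLines(unlist(lapply(seq_along(picks), function(i)
    c(sprintf("@x%d", i), picks[i], "+", strrep("I", 20)))), fq2)
  rs <- read_reads(fq2)
  expect_equal(nrow(rs), length(unique(picks)))
  expect_equal(sum(rs$count), 100L)

  empty <- tempfile(fileext = ".fq")
  file.create(empty)
  expect_warning(rs0 <- read_reads(empty), "no reads")
  expect_equal(nrow(rs0), 0L)
})
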