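rand_seq <- function(n) paste(sample(RNA_BASES <- c("A","C","G","U"), n, TRUE),
                              collapse = "")

test_that("spacer arithmetic reproduces the worked strand examples", {
  # minus-strand hairpin spanning 33484781-33484789, SNP at 33484783:
  # spacer 2, placed counting from the back of the sequence
  sq <- "AGUCACCGA"                      # index 6 (= 8 - 2) must match ref C
  mir <- premirna("mir-trans", "18", 33484781, 33484789, "-", sequence = sq)
  m <- map_snp(snp_row("18", 33484783, ref = "G", alt = "A"), mir)
  expect_equal(m$spacer, 2L)
  expect_equal(m$hairpin_index, 6L)
  # VCF ref G becomes hairpin C; VCF alt A becomes hairpin U
  expect_equal(m$ref_base, "C")
  expect_equal(m$alt_base, "U")

  # plus strand: index equals the spacer
  set.seed(1)
  sqp <- rand_seq(80)
  sqp <- set_char_at(sqp, 2L, "A")
  mirp <- premirna("mir-plus", "20", 1001, 1080, "+", sequence = sqp)
  mp <- map_snp(snp_row("20", 1003, ref = "A", alt = "G"), mirp)
  expect_equal(mp$spacer, 2L)
  expect_equal(mp$hairpin_index, 2L)
  expect_equal(mp$ref_base, "A")

  # minus strand, spacer 76: placed 76 from the 3' end
  sqm <- rand_seq(87)
  sqm <- set_char_at(sqm, 87L - 1L - 76L, "G")
  mirm <- premirna("mir-far", "5", 5001, 5087, "-", sequence = sqm)
  mm <- map_snp(snp_row("5", 5001 + 76, ref = "C", alt = "T"), mirm)
  expect_equal(mm$spacer, 76L)
  expect_equal(mm$hairpin_index, 87L - 1L - 76L)

  # outside the span
  expect_null(map_snp(snp_row("18", 33484790), mir))
})

test_that("reference mismatches are errors in strict mode, drops otherwise", {
  mir <- premirna("mirZ", "1", 100, 139, "+",
                  sequence = paste(rep("ACGU", 10), collapse = ""))
  bad <- snp_row("1", 100, ref = "G", alt = "T")   # hairpin has A at index 0
  expect_error(map_snp(bad, mir), "mirZ.*index 0.*expected G")
  expect_warning(expect_null(map_snp(bad, mir, strict = FALSE)),
                 "reference mismatch")
})

test_that("map_all groups overlaps and matches the brute-force oracle", {
  # 5 SNPs, 3 inside 2 hairpins
  m1 <- premirna("h1", "c1", 100, 179, "+", sequence = strrep("A", 80))
  m2 <- premirna("h2", "c1", 300, 379, "-", sequence = strrep("U", 80))
  snps <- do.call(rbind, list(
    snp_row("c1", 110, "s1", ref = "A", alt = "G"),
    snp_row("c1", 150, "s2", ref = "A", alt = "C"),
    snp_row("c1", 310, "s3", ref = "A", alt = "G"),  # minus: A -> hairpin U
    snp_row("c1", 250, "s4", ref = "A", alt = "G"),
    snp_row("c2", 110, "s5", ref = "A", alt = "G")))
  mapped <- map_all(snps, list(h1 = m1, h2 = m2))
  expect_equal(nrow(mapped), 3L)
  expect_equal(sort(unique(mapped$premirna_name)), c("h1", "h2"))

  # random instances against the O(n*m) double loop
  set.seed(42)
  mirs <- lapply(1:20, function(i) {
    st <- sample(1:5000, 1)
    len <- sample(60:110, 1)
    premirna(sprintf("r%02d", i), sample(c("cA", "cB"), 1), st, st + len - 1,
             sample(c("+", "-"), 1), sequence = strrep("A", len))
  })
  names(mirs) <- vapply(mirs, `[[`, "", "name")
  snps <- do.call(rbind, lapply(1:100, function(i)
    snp_row(sample(c("cA", "cB"), 1), sample(1:5200, 1), sprintf("q%03d", i),
            ref = "A", alt = "G")))
  want <- oracle_map(snps, mirs)
  # minus-strand hairpins of all-A sequence reject complemented ref T->U...
  # use non-complementing mode so the oracle (pure arithmetic) applies
  got2 <- suppressWarnings(map_all(snps, mirs, complement_minus = FALSE,
                                   strict = FALSE))
  expect_equal(got2$premirna_name, want$premirna_name)
  expect_equal(got2$snp_id, want$snp_id)
  expect_equal(got2$spacer, want$spacer)
  expect_equal(got2$hairpin_index, want$hairpin_index)
})

test_that("strand round-trip maps the same SNP to the mirrored index", {
  set.seed(7)
  for (rep in 1:1000) {
    len <- sample(60:110, 1)
    sq <- rand_seq(len)
    strand <- sample(c("+", "-"), 1)
    start <- sample(1:10000, 1)
    idx <- sample(0:(len - 1), 1)
    mir <- premirna("m", "c", start, start + len - 1, strand, sequence = sq)
    pos <- if (strand == "+") start + idx else (start + len - 1) - idx
    ref_vcf <- if (strand == "+") to_dna(char_at(sq, idx)) else
      to_dna(complement_rna(char_at(sq, idx)))
    alt_vcf <- setdiff(c("A", "C", "G", "T"), ref_vcf)[1]
    m1 <- map_snp(snp_row("c", pos, ref = ref_vcf, alt = alt_vcf), mir)
    # reverse-complement the hairpin, flip the strand: same genomic SNP
    mir2 <- premirna("m", "c", start, start + len - 1,
                     if (strand == "+") "-" else "+",
                     sequence = revcomp_rna(sq))
    m2 <- map_snp(snp_row("c", pos, ref = ref_vcf, alt = alt_vcf), mir2)
    expect_equal(m2$hairpin_index, len - 1 - m1$hairpin_index)
    expect_equal(m2$ref_base, complement_rna(m1$ref_base))
    expect_equal(m2$alt_base, complement_rna(m1$alt_base))
  }
})

test_that("substituting then remapping with swapped alleles restores the sequence", {
  set.seed(8)
  for (rep in 1:50) {
    len <- 80
    sq <- rand_seq(len)
    strand <- sample(c("+", "-"), 1)
    mir <- premirna("m", "c", 1000, 1000 + len - 1, strand, sequence = sq)
    idx <- sample(0:(len - 1), 1)
    pos <- if (strand == "+") 1000 + idx else mir$end - idx
    hb <- char_at(sq, idx)
    ref_vcf <- if (strand == "+") to_dna(hb) else to_dna(complement_rna(hb))
    alt_vcf <- setdiff(c("A", "C", "G", "T"), ref_vcf)[1]
    m1 <- map_snp(snp_row("c", pos, ref = ref_vcf, alt = alt_vcf), mir)
    sub_seq <- set_char_at(sq, m1$hairpin_index, m1$alt_base)
    mir_sub <- premirna("m", "c", 1000, 1000 + len - 1, strand,
                        sequence = sub_seq)
    m2 <- map_snp(snp_row("c", pos, ref = alt_vcf, alt = ref_vcf), mir_sub)
    restored <- set_char_at(sub_seq, m2$hairpin_index, m2$alt_base)
    expect_identical(restored, sq)
  }
})
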