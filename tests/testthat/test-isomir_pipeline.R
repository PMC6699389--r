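test_that("region annotation follows loop > seed > mature > stem precedence", {
  sh <- shared_fixture()
  nm <- names(sh$hairpins$mirs)[1]
  mir <- sh$hairpins$mirs[[nm]]
  tr <- sh$hairpins$truth[sh$hairpins$truth$name == nm, ]
  fd <- fold(mir$sequence, backend = "internal")
  reg_at <- function(idx) {
    row <- data.frame(hairpin_index = idx)
    annotate_region(row, mir, fd)
  }
  expect_equal(reg_at(tr$loop_start + 1L), "terminal loop")
  expect_equal(reg_at(tr$p5_5 + 1L), "seed")       # mature position 2
  expect_equal(reg_at(tr$p5_5 + 7L), "seed")       # mature position 8
  expect_equal(reg_at(tr$p5_5 + 8L), "mature")     # mature position 9
  expect_equal(reg_at(tr$p5_5), "mature")          # mature position 1
  expect_equal(reg_at(0L), "stem")
})

test_that("region histogram of planted SNPs matches generator ground truth", {
  spec <- fixture_spec(seed = 555L, n_hairpins = 25L)
  hp <- make_hairpins(spec)
  vc <- make_vcf(spec, hp)
  expect_gte(nrow(vc$truth), 15L)
  tmp <- tempfile(fileext = ".vcf"); writeLines(vc$vcf_lines, tmp)
  snps <- read_vcf(tmp, spec$sample_id)
  mapped <- map_all(snps, hp$mirs)
  mapped <- annotate_regions(mapped, hp$mirs)
  # oracle: recompute regions from the generator's truth table alone
  want <- vapply(seq_len(nrow(mapped)), function(i) {
    tr <- hp$truth[hp$truth$name == mapped$premirna_name[i], ]
    idx <- mapped$hairpin_index[i]
    if (idx >= tr$loop_start && idx <= tr$loop_end) return("terminal loop")
    for (arm in list(c(tr$p5_5, tr$p5_3), c(tr$p3_5, tr$p3_3))) {
      if (idx >= arm[1] && idx <= arm[2]) {
        rel <- idx - arm[1] + 1L
        return(if (rel >= 2 && rel <= 8) "seed" else "mature")
      }
    }
    "stem"
  }, character(1))
  expect_equal(table(factor(mapped$region, levels = unique(c(want, mapped$region)))),
               table(factor(want, levels = unique(c(want, mapped$region)))))
  # total over regions equals the number of mapped SNPs
  expect_equal(sum(table(mapped$region)), nrow(mapped))
})

test_that("a mature-region SNP yields an isomiR call carrying it as functional", {
  sh <- shared_fixture()
  nm <- names(sh$test_mirs)[1]
  mir <- sh$test_mirs[[nm]]
  tr <- sh$hairpins$truth[sh$hairpins$truth$name == nm, ]
  idx <- tr$p5_5 + 10L                       # middle of the 5p mature
  ref_b <- char_at(mir$sequence, idx)
  alt_b <- setdiff(c("A", "C", "G", "U"), ref_b)[1]
  mapped <- data.frame(premirna_name = nm, snp_id = "rsT", chrom = mir$chrom,
                       pos = 0L, strand = mir$strand, spacer = idx,
                       hairpin_index = idx, ref_base = ref_b, alt_base = alt_b,
                       zygosity = "het", region = NA, stringsAsFactors = FALSE)
  variants <- build_variants(mir, mapped)
  calls <- call_isomirs(sh$model, mir, variants)
  iso <- calls[calls$classification == "isomiR", ]
  expect_gte(nrow(iso), 1L)
  expect_true(all(iso$functional_snps == "rsT"))
  # at least one isomiR sequence carries the substituted base
  expect_true(any(vapply(iso$sequence, function(s)
    grepl(s, set_char_at(mir$sequence, idx, alt_b), fixed = TRUE),
    logical(1))))
  # functional SNPs always a subset of the SNPs mapped to the hairpin
  snp_sets <- strsplit(iso$functional_snps, "+", fixed = TRUE)
  expect_true(all(unlist(snp_sets) %in% mapped$snp_id))
})

test_that("variants reproducing canonical candidates are canonical-match", {
  sh <- shared_fixture()
  nm <- names(sh$test_mirs)[2]
  mir <- sh$test_mirs[[nm]]
  fd <- fold(mir$sequence, backend = "internal")
  # substitute far outside every candidate mature window: terminal loop
  idx <- fd$loop_span[1L] + 1L
  ref_b <- char_at(mir$sequence, idx)
  alt_b <- setdiff(c("A", "C"), ref_b)[1]  # keep the loop unpairable
  mapped <- data.frame(premirna_name = nm, snp_id = "rsL", chrom = mir$chrom,
                       pos = 0L, strand = mir$strand, spacer = idx,
                       hairpin_index = idx, ref_base = ref_b, alt_base = alt_b,
                       zygosity = "het", region = NA, stringsAsFactors = FALSE)
  calls <- call_isomirs(sh$model, mir, build_variants(mir, mapped))
  expect_true(all(calls$classification == "canonical-match"))
  expect_true(all(calls$functional_snps == ""))
})

test_that("read validation equals the naive substring oracle", {
  sh <- shared_fixture()
  set.seed(99)
  # 1000-read fixture: canonical matures, variants, noise
  pool <- character(0)
  for (nm in names(sh$test_mirs)[1:10]) {
    tr <- sh$hairpins$truth[sh$hairpins$truth$name == nm, ]
    m5 <- to_dna(subseq0(sh$test_mirs[[nm]]$sequence, tr$p5_5, tr$p5_3))
    pool <- c(pool, m5, substr(m5, 2, 22), paste0("AC", m5))
  }
  pool <- c(pool, vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 22, TRUE), collapse = ""), character(1)))
  picks <- sample(pool, 1000, replace = TRUE)
  agg <- table(picks)
  reads <- data.frame(sequence = names(agg), count = as.integer(agg),
                      stringsAsFactors = FALSE)
  expect_equal(sum(reads$count), 1000L)
  targets <- unique(c(pool[1:12], "TTTTTTTTTTTTTTTTTTTTTT"))
  calls <- data.frame(premirna_name = "x", label = "x", applied_snps = "s",
                      site_kind = "P5_5", position = 0L,
                      sequence = transcribe(targets),
                      classification = "isomiR", functional_snps = "s",
                      stringsAsFactors = FALSE)
  got <- validate_reads(calls, reads)
  for (t in targets) {
    expect_equal(got$read_count[got$sequence == t],
                 oracle_read_count(t, reads))
  }
  # absent sequence: zero and unsupported
  expect_equal(got$read_count[got$sequence == "TTTTTTTTTTTTTTTTTTTTTT"], 0L)
  expect_false(got$supported[got$sequence == "TTTTTTTTTTTTTTTTTTTTTT"])
  # collapsed counts are respected
  one <- data.frame(sequence = paste0("GG", targets[1], "GG"), count = 24L,
                    stringsAsFactors = FALSE)
  v <- validate_reads(calls[1, ], one)
  expect_equal(v$read_count[v$sequence == targets[1]], 24L)
})

test_that("the pipeline runs end to end, handles empty input and is reproducible", {
  sh <- shared_fixture()
  spec <- fixture_spec(seed = 777L, n_hairpins = 12L)
  dir <- file.path(tempdir(), "pipe_fix")
  bundle <- write_fixture_bundle(spec, dir)
  out1 <- file.path(tempdir(), "pipe_out1")
  res <- run_pipeline(file.path(dir, "sample.vcf"), spec$sample_id,
                      bundle$hairpins$mirs, sh$model,
                      reads_path = file.path(dir, "reads.fq"), outdir = out1)
  expect_equal(nrow(res$mapped), nrow(bundle$vcf$truth))
  expect_equal(sort(unique(res$mapped$snp_id)),
               sort(unique(bundle$vcf$truth$snp_id)))
  expect_true(file.exists(file.path(out1, "mapped_snps.tsv")))
  expect_equal(nrow(res$summary), 4L)

  # rerun: byte-identical reports
  out2 <- file.path(tempdir(), "pipe_out2")
  run_pipeline(file.path(dir, "sample.vcf"), spec$sample_id,
               bundle$hairpins$mirs, sh$model,
               reads_path = file.path(dir, "reads.fq"), outdir = out2)
  for (f in c("mapped_snps.tsv", "variants.fa", "isomir_calls.tsv",
              "isomirs_validated.tsv", "site_summary.tsv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }

  # empty VCF: empty reports, no error
  empty_vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      spec$sample_id)), empty_vcf)
  out3 <- file.path(tempdir(), "pipe_out3")
  res0 <- run_pipeline(empty_vcf, spec$sample_id, bundle$hairpins$mirs,
                       sh$model, reads_path = NULL, outdir = out3)
  expect_equal(nrow(res0$mapped), 0L)
  expect_equal(nrow(res0$calls), 0L)
})
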