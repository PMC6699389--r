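# Deterministic synthetic datasets: hairpins with planted processing-site
# determinants, matching coordinate tables, per-sample VCFs and small-RNA
# read sets, so every pipeline stage is testable without downloads.
#
# Hairpin geometry: [5' arm = pre | mature(22) | post] [loop] [3' arm =
# reverse complement of the 5' arm]. The planted, learnable determinants are
# a paired U at the mature 5' start preceded by G, and strand mismatches at
# fixed offsets (start-3 and end+2); background mismatch noise elsewhere
# emulates imperfect stems. The 3p mature span carries the canonical 2-nt
# 3' overhang relative to the 5p span's pairing partners.

#' Specification of a synthetic fixture set
#'
#' @param seed RNG seed (drives every downstream generator deterministically)
#' @param n_hairpins number of hairpins
#' @param stem_len arm length in nt (hairpin length = 2*stem_len + loop_len)
#' @param loop_len terminal loop length
#' @param mature_len planted mature length
#' @param snp_dist probabilities of 0,1,2,... SNPs per hairpin
#' @param n_noise_reads random background reads in the read set
#' @param spike_frac fraction of mature-region SNPs receiving a spiked
#'   isomiR read set
#' @param mismatch_rate per-position probability of a background strand
#'   mismatch outside the protected site neighbourhoods
#' @param sample_id sample column name used in generated VCFs
#' @return object of class `FixtureSpec`
#' @export
fixture_spec <- function(seed = 1L, n_hairpins = 30L, stem_len = 45L,
                         loop_len = 8L, mature_len = 22L,
                         snp_dist = c(0.3, 0.4, 0.2, 0.1),
                         n_noise_reads = 50L, spike_frac = 0.9,
                         mismatch_rate = 0.04, sample_id = "S1") {
  stopifnot(n_hairpins >= 1L, loop_len >= 4L,
            mature_len <= stem_len - 8L, abs(sum(snp_dist) - 1) < 1e-9)
  structure(list(seed = as.integer(seed), n_hairpins = as.integer(n_hairpins),
                 stem_len = as.integer(stem_len),
                 loop_len = as.integer(loop_len),
                 mature_len = as.integer(mature_len), snp_dist = snp_dist,
                 n_noise_reads = as.integer(n_noise_reads),
                 spike_frac = spike_frac, mismatch_rate = mismatch_rate,
                 sample_id = sample_id),
            class = "FixtureSpec")
}

# bases that can pair with b (including the GU wobble)
pairs_with <- function(b) switch(b, A = "U", U = c("A", "G"),
                                 G = c("C", "U"), C = "G")

#' Generate annotated synthetic hairpins with planted processing sites
#'
#' @param spec a [fixture_spec()]
#' @return list with `mirs` (named list of annotated [premirna()] objects,
#'   both genomic strands represented) and `truth` (data.frame of planted
#'   site positions, 0-based: `p5_5`, `p5_3`, `p3_5`, `p3_3`, `loop_start`,
#'   `loop_end`)
#' @export
make_hairpins <- function(spec) {
  set.seed(spec$seed)
  arm <- spec$stem_len; loop_len <- spec$loop_len; ml <- spec$mature_len
  L <- 2L * arm + loop_len
  mirs <- list(); truth <- list()
  cursor <- 1000L
  for (h in seq_len(spec$n_hairpins)) {
    pre5_range <- 4:(arm - ml - 4L)
    pre5 <- pre5_range[sample.int(length(pre5_range), 1L)]
    p5s <- pre5; p5e <- pre5 + ml - 1L
    arm5 <- sample(RNA_BASES, arm, replace = TRUE)
    # G/C clamp on the three loop-adjacent stem positions: with an all-A
    # loop this makes loop-invading base pairs impossible, so the planted
    # terminal loop is also the folded one
    arm5[(arm - 2L):arm] <- sample(c("C", "G"), 3L, replace = TRUE)
    arm5[p5s + 1L] <- "U"
    arm5[p5s] <- "G"                       # 0-based p5s-1
    # planted mismatch offsets; the Dicer-side one is dropped when it would
    # fall into the loop-adjacent clamp, where it could license an
    # equal-score shifted fold that moves the terminal loop
    m1 <- p5s - 3L; m2 <- p5e + 2L
    mm <- c(m1, if (m2 <= arm - 4L) m2)
    arm5[mm + 1L] <- "C"
    arm3 <- rev(chartr("ACGU", "UGCA", arm5))
    # hairpin index of arm5 position i pairs with L-1-i; arm3 local index
    # of hairpin position j is j - arm - loop_len
    mismatch_at <- function(i0) {
      j_local <- (L - 1L - i0) - arm - loop_len
      arm3[j_local + 1L] <<- "A"           # C..A: unpairable planted mismatch
    }
    for (m in mm) mismatch_at(m)
    protected <- c((p5s - 4L):(p5s + 2L), (p5e - 2L):(p5e + 3L),
                   (arm - 3L):(arm - 1L))
    for (i0 in setdiff(0:(arm - 1L), protected)) {
      if (runif(1) < spec$mismatch_rate) {
        b <- arm5[i0 + 1L]
        bad <- setdiff(RNA_BASES, pairs_with(b))
        j_local <- (L - 1L - i0) - arm - loop_len
        arm3[j_local + 1L] <- sample(bad, 1L)
      }
    }
    loop <- rep("A", loop_len)
    sq <- paste(c(arm5, loop, arm3), collapse = "")
    p3_3 <- L + 1L - p5s; p3_5 <- L + 1L - p5e
    name <- sprintf("syn-mir-%03d", h)
    chrom <- sprintf("chrS%d", 1L + (h - 1L) %/% 10L)
    if (h %% 10L == 1L) cursor <- 1000L
    start <- cursor; end <- start + L - 1L
    cursor <- end + 51L
    strand <- sample(c("+", "-"), 1L)
    mirs[[name]] <- premirna(
      name, chrom, start, end, strand, sequence = sq,
      mature_spans = data.frame(arm = c("5p", "3p"),
                                start = c(p5s, p3_5), end = c(p5e, p3_3),
                                stringsAsFactors = FALSE))
    truth[[name]] <- data.frame(
      name = name, chrom = chrom, start = start, end = end, strand = strand,
      length = L, p5_5 = p5s, p5_3 = p5e, p3_5 = p3_5, p3_3 = p3_3,
      loop_start = arm, loop_end = arm + loop_len - 1L,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(mirs = mirs, truth = truth)
}

#' Generate a per-sample VCF with SNVs planted in and around the hairpins
#'
#' Each hairpin receives 0-3 SNVs (per `spec$snp_dist`); when present, the
#' first lands uniformly inside the 5p mature span so downstream isomiR
#' recovery is exercised, the rest land uniformly elsewhere on the hairpin.
#' Decoy records (intergenic SNVs, indels, a multi-allelic site, hom-ref
#' lines) exercise the reader's filters.
#'
#' @param spec a [fixture_spec()]
#' @param hairpins [make_hairpins()] output
#' @param path optional file to write the VCF to
#' @return list with `vcf_lines` (character vector), `truth` (data.frame:
#'   `snp_id`, `premirna_name`, `hairpin_index`, `ref_base`, `alt_base`
#'   (hairpin RNA alphabet), `in_5p_mature`, `chrom`, `pos`), and `path`
#' @export
make_vcf <- function(spec, hairpins, path = NULL) {
  set.seed(spec$seed + 1L)
  truth <- list(); recs <- list()
  k <- 0L
  for (nm in names(hairpins$mirs)) {
    mir <- hairpins$mirs[[nm]]
    tr <- hairpins$truth[hairpins$truth$name == nm, ]
    n_snp <- sample(seq_along(spec$snp_dist) - 1L, 1L, prob = spec$snp_dist)
    if (!n_snp) next
    idx_mature <- sample(tr$p5_5:tr$p5_3, 1L)
    idx_rest <- if (n_snp > 1L)
      sample(setdiff(0:(tr$length - 1L), idx_mature), n_snp - 1L)
    else integer(0)
    for (idx in c(idx_mature, idx_rest)) {
      k <- k + 1L
      ref_b <- char_at(mir$sequence, idx)
      alt_b <- sample(setdiff(RNA_BASES, ref_b), 1L)
      if (mir$strand == "+") {
        pos <- mir$start + idx
        ref_d <- to_dna(ref_b); alt_d <- to_dna(alt_b)
      } else {
        pos <- mir$end - idx
        ref_d <- to_dna(complement_rna(ref_b))
        alt_d <- to_dna(complement_rna(alt_b))
      }
      gt <- sample(c("0|1", "1|0", "1|1"), 1L)
      id <- sprintf("snpS%04d", k)
      truth[[k]] <- data.frame(
        snp_id = id, premirna_name = nm, hairpin_index = idx,
        ref_base = ref_b, alt_base = alt_b,
        in_5p_mature = idx >= tr$p5_5 & idx <= tr$p5_3,
        chrom = mir$chrom, pos = pos, stringsAsFactors = FALSE)
      recs[[length(recs) + 1L]] <- data.frame(
        chrom = mir$chrom, pos = pos, id = id, ref = ref_d, alt = alt_d,
        info = sprintf("AF=%.4f", round(runif(1, 0.01, 0.5), 4)), gt = gt,
        stringsAsFactors = FALSE)
    }
  }
  # decoys: intergenic SNVs, indels, one multi-allelic, hom-ref lines
  chroms <- unique(hairpins$truth$chrom)
  decoy <- function(chrom, pos, ref, alt, gt)
    data.frame(chrom = chrom, pos = pos, id = ".", ref = ref, alt = alt,
               info = "AF=0.1000", gt = gt, stringsAsFactors = FALSE)
  for (ch in chroms) {
    recs[[length(recs) + 1L]] <- decoy(ch, 10L, "A", "G", "0|1")
    recs[[length(recs) + 1L]] <- decoy(ch, 20L, "C", "CAT", "0|1")   # insertion
    recs[[length(recs) + 1L]] <- decoy(ch, 30L, "TGA", "T", "1|1")   # deletion
    recs[[length(recs) + 1L]] <- decoy(ch, 40L, "G", "A,C", "0|0")   # multi-allelic, hom-ref
    recs[[length(recs) + 1L]] <- decoy(ch, 50L, "T", "C", "0|0")     # hom-ref
  }
  recs <- do.call(rbind, recs)
  recs <- recs[order(recs$chrom, recs$pos), , drop = FALSE]
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    spec$sample_id),
             sprintf("%s\t%d\t%s\t%s\t%s\t100\tPASS\t%s\tGT\t%s",
                     recs$chrom, recs$pos, recs$id, recs$ref, recs$alt,
                     recs$info, recs$gt))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(snp_id = character(), premirna_name = character(),
               hairpin_index = integer(), ref_base = character(),
               alt_base = character(), in_5p_mature = logical(),
               chrom = character(), pos = integer(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  if (!is.null(path)) writeLines(lines, path)
  list(vcf_lines = lines, truth = truth, path = path)
}

#' Generate a small-RNA read set with spiked isomiRs
#'
#' Canonical 5p and 3p matures of every hairpin are sampled at moderate
#' depth; for a `spike_frac` fraction of the 5p-mature SNPs from
#' [make_vcf()], the SNP-substituted mature sequence is spiked in at a known
#' count; random 22-mers provide background noise.
#'
#' @param spec a [fixture_spec()]
#' @param hairpins [make_hairpins()] output
#' @param snp_truth `truth` from [make_vcf()]
#' @param path optional FASTQ file to write (reads expanded by count)
#' @return list with `reads` (data.frame `sequence` (DNA), `count`),
#'   `spikes` (data.frame `snp_id`, `premirna_name`, `sequence`, `count`)
#'   and `path`
#' @export
make_reads <- function(spec, hairpins, snp_truth, path = NULL) {
  set.seed(spec$seed + 2L)
  reads <- list(); spikes <- list()
  for (nm in names(hairpins$mirs)) {
    mir <- hairpins$mirs[[nm]]
    tr <- hairpins$truth[hairpins$truth$name == nm, ]
    m5 <- to_dna(subseq0(mir$sequence, tr$p5_5, tr$p5_3))
    m3 <- to_dna(subseq0(mir$sequence, tr$p3_5, tr$p3_3))
    reads[[length(reads) + 1L]] <- data.frame(
      sequence = c(m5, m3), count = c(20L + rpois(1L, 10L), 8L + rpois(1L, 4L)),
      stringsAsFactors = FALSE)
  }
  st <- snp_truth[snp_truth$in_5p_mature, , drop = FALSE]
  for (i in seq_len(nrow(st))) {
    if (runif(1) > spec$spike_frac) next
    nm <- st$premirna_name[i]
    mir <- hairpins$mirs[[nm]]
    tr <- hairpins$truth[hairpins$truth$name == nm, ]
    var_seq <- set_char_at(mir$sequence, st$hairpin_index[i], st$alt_base[i])
    spike <- to_dna(subseq0(var_seq, tr$p5_5, tr$p5_3))
    cnt <- 5L + rpois(1L, 10L)
    spikes[[length(spikes) + 1L]] <- data.frame(
      snp_id = st$snp_id[i], premirna_name = nm, sequence = spike,
      count = cnt, stringsAsFactors = FALSE)
    reads[[length(reads) + 1L]] <- data.frame(sequence = spike, count = cnt,
                                              stringsAsFactors = FALSE)
  }
  if (spec$n_noise_reads > 0L) {
    noise <- vapply(seq_len(spec$n_noise_reads), function(i)
      paste(sample(c("A", "C", "G", "T"), 22L, replace = TRUE), collapse = ""),
      character(1))
    reads[[length(reads) + 1L]] <- data.frame(sequence = noise, count = 1L,
                                              stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, reads)
  agg <- tapply(reads$count, reads$sequence, sum)
  reads <- data.frame(sequence = names(agg), count = as.integer(agg),
                      stringsAsFactors = FALSE)
  reads <- reads[order(-reads$count, reads$sequence), , drop = FALSE]
  rownames(reads) <- NULL
  spikes <- if (length(spikes)) do.call(rbind, spikes) else
    data.frame(snp_id = character(), premirna_name = character(),
               sequence = character(), count = integer(),
               stringsAsFactors = FALSE)
  rownames(spikes) <- NULL
  if (!is.null(path)) {
    con <- file(path, "w")
    n <- 0L
    for (i in seq_len(nrow(reads))) {
      for (r in seq_len(reads$count[i])) {
        n <- n + 1L
        writeLines(c(sprintf("@read%06d", n), reads$sequence[i], "+",
                     strrep("I", nchar(reads$sequence[i]))), con)
      }
    }
    close(con)
  }
  list(reads = reads, spikes = spikes, path = path)
}

#' Write a complete fixture bundle to a directory
#'
#' Emits `premirnas.tsv` (package TSV dialect), `hairpins.fa`,
#' `site_truth.tsv`, `sample.vcf`, `snp_truth.tsv`, `reads.fq` and
#' `spikes.tsv`. Fixed seeds give byte-identical output on rerun.
#'
#' @param spec a [fixture_spec()]
#' @param dir output directory
#' @return invisible list with the generated objects and file paths
#' @export
write_fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hp <- make_hairpins(spec)
  vc <- make_vcf(spec, hp, path = file.path(dir, "sample.vcf"))
  rd <- make_reads(spec, hp, vc$truth, path = file.path(dir, "reads.fq"))
  write_premirnas(hp$mirs, file.path(dir, "premirnas.tsv"))
  write_fasta(setNames(vapply(hp$mirs, `[[`, "", "sequence"),
                       names(hp$mirs)), file.path(dir, "hairpins.fa"))
  write_report(hp$truth, file.path(dir, "site_truth.tsv"))
  write_report(vc$truth, file.path(dir, "snp_truth.tsv"))
  write_report(rd$spikes, file.path(dir, "spikes.tsv"))
  invisible(list(hairpins = hp, vcf = vc, reads = rd, dir = dir))
}
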