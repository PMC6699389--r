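# Independent oracles kept deliberately naive: they re-derive expected
# results by direct enumeration, never through the code paths they check.

# brute-force interval mapping: double loop over every (snp, hairpin) pair
oracle_map <- function(snps, mirs) {
  out <- list()
  for (i in seq_len(nrow(snps))) {
    for (m in mirs) {
      if (snps$chrom[i] != m$chrom) next
      if (snps$pos[i] < m$start || snps$pos[i] > m$end) next
      d <- snps$pos[i] - m$start
      idx <- if (m$strand == "+") d else (m$end - m$start) - d
      out[[length(out) + 1L]] <- data.frame(
        premirna_name = m$name, snp_id = snps$id[i], pos = snps$pos[i],
        spacer = d, hairpin_index = idx, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  o <- do.call(rbind, out)
  o[order(o$premirna_name, o$hairpin_index, o$snp_id), , drop = FALSE]
}

# brute-force subset substitution: every non-empty subset, sequences built
# character-by-character
oracle_variant_seqs <- function(sequence, idx0, alt) {
  n <- length(idx0)
  seqs <- character(0)
  for (mask in 1:(2^n - 1)) {
    chars <- strsplit(sequence, "")[[1]]
    for (j in seq_len(n)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L)
        chars[idx0[j] + 1L] <- alt[j]
    }
    seqs <- c(seqs, paste(chars, collapse = ""))
  }
  sort(unique(seqs))
}

# naive per-read substring scan at every offset
oracle_read_count <- function(pattern, reads) {
  total <- 0L
  np <- nchar(pattern)
  for (i in seq_len(nrow(reads))) {
    r <- reads$sequence[i]
    hit <- FALSE
    if (nchar(r) >= np) {
      for (s in 1:(nchar(r) - np + 1L)) {
        if (substr(r, s, s + np - 1L) == pattern) { hit <- TRUE; break }
      }
    }
    if (hit) total <- total + reads$count[i]
  }
  total
}

# a perfect-stem hairpin around a given 22-nt mature: mature + inert all-A
# loop + reverse complement; the default mature ends in CC so no loop-
# invading pair can compete with the stem
perfect_hairpin <- function(mature = "UGAGGUAGUAGGUUGUAUAGCC",
                            loop = "AAAAAAAA") {
  paste0(mature, loop, revcomp_rna(mature))
}

# one-row SNP record in read_vcf shape
snp_row <- function(chrom, pos, id = "rsX", ref = "A", alt = "G",
                    zygosity = "het") {
  data.frame(chrom = chrom, pos = pos, id = id, ref = ref, alt = alt,
             genotype = "0|1", zygosity = zygosity, allele_freq = NA_real_,
             stringsAsFactors = FALSE)
}
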