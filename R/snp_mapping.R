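# Placing SNPs inside pre-miRNA hairpins.
#
# The spacer count d = POS - start is taken from the genomic START coordinate
# on both strands. On the plus strand the hairpin is read front-to-back, so
# the 0-based hairpin index equals d; on the minus strand the hairpin runs
# antiparallel to the reference, so the position is found counting d from the
# back: index = (end - start) - d, and the VCF (plus-strand) alleles are
# complemented onto the hairpin strand.

#' Map one SNP into one pre-miRNA hairpin
#'
#' @param snp one-row data.frame as produced by [read_vcf()] (columns
#'   `chrom`, `pos`, `id`, `ref`, `alt`, optionally `zygosity`)
#' @param mir a [premirna()] with sequence attached
#' @param complement_minus complement alleles onto the hairpin strand for
#'   minus-strand hairpins (default `TRUE`; `FALSE` keeps the literal VCF
#'   alleles, transcribed only)
#' @param strict error (rather than warn and return `NULL`) when the hairpin
#'   base at the mapped index does not match the expected reference allele —
#'   the signature of a stale annotation or wrong genome build
#' @return one-row data.frame (`premirna_name`, `snp_id`, `chrom`, `pos`,
#'   `strand`, `spacer`, `hairpin_index`, `ref_base`, `alt_base`,
#'   `zygosity`, `region`) or `NULL` when the SNP lies outside the hairpin
#' @export
map_snp <- function(snp, mir, complement_minus = TRUE, strict = TRUE) {
  if (snp$chrom != mir$chrom) return(NULL)
  if (snp$pos < mir$start || snp$pos > mir$end) return(NULL)
  if (is.null(mir$sequence)) stop("hairpin '", mir$name, "' has no sequence")
  spacer <- snp$pos - mir$start
  L <- premirna_length(mir)
  if (mir$strand == "+") {
    idx <- spacer
    ref_b <- transcribe(snp$ref)
    alt_b <- transcribe(snp$alt)
  } else {
    idx <- (mir$end - mir$start) - spacer
    if (complement_minus) {
      ref_b <- complement_rna(transcribe(snp$ref))
      alt_b <- complement_rna(transcribe(snp$alt))
    } else {
      ref_b <- transcribe(snp$ref)
      alt_b <- transcribe(snp$alt)
    }
  }
  observed <- char_at(mir$sequence, idx)
  if (observed != ref_b) {
    msg <- sprintf(
      "reference mismatch in '%s' at hairpin index %d: expected %s, sequence has %s",
      mir$name, idx, ref_b, observed)
    if (strict) stop(msg) else {
      warning(msg)
      return(NULL)
    }
  }
  data.frame(premirna_name = mir$name, snp_id = snp$id, chrom = snp$chrom,
             pos = snp$pos, strand = mir$strand, spacer = spacer,
             hairpin_index = idx, ref_base = ref_b, alt_base = alt_b,
             zygosity = if ("zygosity" %in% names(snp)) snp$zygosity else NA_character_,
             region = NA_character_, stringsAsFactors = FALSE)
}

#' Map all SNPs into all pre-miRNAs by genomic overlap
#'
#' Interval overlap is computed with GenomicRanges; every (SNP, hairpin)
#' overlap contributes one mapped record, so a SNP inside two overlapping
#' hairpins appears twice.
#'
#' @param snps data.frame of SNP records ([read_vcf()] output)
#' @param mirs list of [premirna()] objects
#' @inheritParams map_snp
#' @return data.frame of mapped SNPs ordered by `premirna_name` then
#'   `hairpin_index`; zero rows when nothing overlaps. With `strict = FALSE`
#'   reference-mismatching records are dropped with a warning.
#' @export
map_all <- function(snps, mirs, complement_minus = TRUE, strict = FALSE) {
  empty <- data.frame(premirna_name = character(), snp_id = character(),
                      chrom = character(), pos = integer(), strand = character(),
                      spacer = integer(), hairpin_index = integer(),
                      ref_base = character(), alt_base = character(),
                      zygosity = character(), region = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(snps) || !length(mirs)) return(empty)
  mir_gr <- GenomicRanges::GRanges(
    seqnames = vapply(mirs, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(start = vapply(mirs, `[[`, 0L, "start"),
                              end = vapply(mirs, `[[`, 0L, "end")))
  snp_gr <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(snp_gr, mir_gr, ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  rows <- mapply(function(si, mi) {
    map_snp(snps[si, , drop = FALSE], mirs[[mi]],
            complement_minus = complement_minus, strict = strict)
  }, S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits),
  SIMPLIFY = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out <- out[order(out$premirna_name, out$hairpin_index, out$snp_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  vmsg(sprintf("map_all: %d mapped SNP(s) across %d hairpin(s)",
               nrow(out), length(unique(out$premirna_name))))
  out
}
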