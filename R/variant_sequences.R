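# Combinatorial construction of SNP-substituted precursor sequences: every
# non-empty subset of the SNPs mapped to a hairpin yields one variant, giving
# sum_{k=1..n} C(n,k) = 2^n - 1 variants for n SNPs.

#' Number of variant precursors for n mapped SNPs
#'
#' All non-empty SNP subsets are enumerated, so a hairpin carrying `n` SNPs
#' yields `2^n - 1` SNP-substituted sequences (0 for `n = 0`).
#'
#' @param n_snps number of SNPs mapped to one hairpin
#' @param cap refuse above this many SNPs (combinatorial guard, default 12,
#'   i.e. at most 4095 variants per hairpin)
#' @return integer count
#' @export
count_variants <- function(n_snps, cap = 12L) {
  stopifnot(length(n_snps) == 1L, n_snps >= 0L, n_snps == floor(n_snps))
  if (n_snps > cap)
    stop(n_snps, " SNPs on one hairpin exceeds cap ", cap,
         "; raise `cap` to enumerate 2^n - 1 subsets anyway")
  as.integer(2^n_snps - 1)
}

#' Build all SNP-substituted precursor sequences for one hairpin
#'
#' Enumerates every non-empty subset of the mapped SNPs and writes each
#' subset's alternate bases into the canonical hairpin sequence. Subsets are
#' ordered by size, then lexicographically by the joined SNP ids; within a
#' subset SNP ids are ordered by hairpin index. Labels take the form
#' `name|rs1+rs7` so downstream isomiR calls are traceable to SNP
#' combinations.
#'
#' @param mir a [premirna()] with sequence
#' @param mapped mapped SNPs for this hairpin ([map_all()] rows); hairpin
#'   indices must be distinct
#' @param cap per-hairpin SNP cap, see [count_variants()]
#' @return data.frame with columns `premirna_name`, `label`, `applied_snps`
#'   (SNP ids joined with `+`), `n_snps`, `sequence`
#' @export
build_variants <- function(mir, mapped, cap = 12L) {
  empty <- data.frame(premirna_name = character(), label = character(),
                      applied_snps = character(), n_snps = integer(),
                      sequence = character(), stringsAsFactors = FALSE)
  if (is.null(mapped) || !nrow(mapped)) return(empty)
  if (!all(mapped$premirna_name == mir$name))
    stop("mapped SNPs do not all belong to hairpin '", mir$name, "'")
  if (anyDuplicated(mapped$hairpin_index))
    stop("conflicting SNPs at one hairpin index in '", mir$name, "': ",
         paste(mapped$snp_id[duplicated(mapped$hairpin_index) |
                               duplicated(mapped$hairpin_index, fromLast = TRUE)],
               collapse = ", "))
  n <- nrow(mapped)
  n_total <- count_variants(n, cap = cap)
  mapped <- mapped[order(mapped$hairpin_index), , drop = FALSE]
  subsets <- unlist(lapply(seq_len(n), function(k)
    combn(seq_len(n), k, simplify = FALSE)), recursive = FALSE)
  sig <- vapply(subsets, function(s) paste(mapped$snp_id[s], collapse = "+"),
                character(1))
  sizes <- lengths(subsets)
  ord <- order(sizes, sig)
  subsets <- subsets[ord]; sig <- sig[ord]; sizes <- sizes[ord]
  seqs <- vapply(subsets, function(s) {
    sq <- mir$sequence
    for (j in s) sq <- set_char_at(sq, mapped$hairpin_index[j],
                                   mapped$alt_base[j])
    sq
  }, character(1))
  out <- data.frame(premirna_name = mir$name,
                    label = paste0(mir$name, "|", sig),
                    applied_snps = sig, n_snps = sizes, sequence = seqs,
                    stringsAsFactors = FALSE)
  stopifnot(nrow(out) == n_total)
  out
}

#' Build variant precursors for every hairpin with mapped SNPs
#' @param mirs named list of [premirna()] objects
#' @param mapped [map_all()] output
#' @param cap per-hairpin SNP cap
#' @return data.frame of variants across hairpins (see [build_variants()])
#' @export
build_all_variants <- function(mirs, mapped, cap = 12L) {
  pieces <- lapply(split(mapped, mapped$premirna_name), function(mp) {
    build_variants(mirs[[mp$premirna_name[1L]]], mp, cap = cap)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    return(build_variants(premirna("x", "c", 1, 1, "+", "A"), NULL))
  rownames(out) <- NULL
  out
}
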