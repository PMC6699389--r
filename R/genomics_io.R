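# Readers/writers for the external formats the pipeline touches.
# Conventions: genomic coordinates are 1-based inclusive (VCF/GFF);
# all within-hairpin indices (mature spans, SNP positions on the hairpin)
# are 0-based. Hairpin sequences are held in the RNA alphabet.

#' Construct a pre-miRNA hairpin record
#'
#' A `PreMiRNA` bundles a hairpin's identifier, genomic span, strand,
#' transcribed sequence (RNA alphabet, 5'->3' of the hairpin itself) and any
#' annotated mature spans given as 0-based inclusive within-hairpin indices.
#'
#' @param name hairpin identifier
#' @param chrom chromosome label
#' @param start,end 1-based inclusive genomic span
#' @param strand `"+"` or `"-"`
#' @param sequence hairpin sequence; DNA input is transcribed to RNA
#' @param mature_spans `NULL` or a data.frame with columns `arm`
#'   (`"5p"`/`"3p"`), `start`, `end` (0-based inclusive hairpin indices)
#' @return an object of class `PreMiRNA`
#' @export
premirna <- function(name, chrom, start, end, strand,
                     sequence = NULL, mature_spans = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (end < start) stop("PreMiRNA '", name, "': end < start")
  if (!strand %in% c("+", "-")) stop("PreMiRNA '", name, "': strand must be + or -")
  if (!is.null(sequence)) {
    sequence <- transcribe(sequence)
    if (!is_rna_seq(sequence))
      stop("PreMiRNA '", name, "': sequence has non-ACGU characters")
    if (nchar(sequence) != end - start + 1L)
      stop("PreMiRNA '", name, "': sequence length ", nchar(sequence),
           " != span length ", end - start + 1L)
  }
  if (is.null(mature_spans)) {
    mature_spans <- data.frame(arm = character(), start = integer(),
                               end = integer(), stringsAsFactors = FALSE)
  } else {
    mature_spans <- as.data.frame(mature_spans, stringsAsFactors = FALSE)
    stopifnot(all(c("arm", "start", "end") %in% names(mature_spans)))
    mature_spans$start <- as.integer(mature_spans$start)
    mature_spans$end <- as.integer(mature_spans$end)
    L <- end - start + 1L
    if (nrow(mature_spans) &&
        (any(mature_spans$start < 0L) || any(mature_spans$end >= L) ||
         any(mature_spans$end < mature_spans$start)))
      stop("PreMiRNA '", name, "': mature span outside [0, ", L - 1L, "]")
  }
  structure(list(name = name, chrom = as.character(chrom), start = start,
                 end = end, strand = strand, sequence = sequence,
                 mature_spans = mature_spans),
            class = "PreMiRNA")
}

#' @export
print.PreMiRNA <- function(x, ...) {
  cat(sprintf("PreMiRNA %s  %s:%d-%d(%s)  length %s\n", x$name, x$chrom,
              x$start, x$end, x$strand,
              if (is.null(x$sequence)) "NA" else nchar(x$sequence)))
  if (nrow(x$mature_spans))
    cat("  mature:", paste(sprintf("%s[%d-%d]", x$mature_spans$arm,
                                   x$mature_spans$start, x$mature_spans$end),
                           collapse = " "), "\n")
  invisible(x)
}

premirna_length <- function(mir) mir$end - mir$start + 1L

mature_span <- function(mir, arm) {
  sp <- mir$mature_spans
  sp <- sp[sp$arm == arm, , drop = FALSE]
  if (!nrow(sp)) return(NULL)
  c(start = sp$start[1L], end = sp$end[1L])
}

#' Read per-sample SNPs from a VCF file
#'
#' Parses a VCF 4.x file and returns the biallelic single-nucleotide
#' substitutions for which `sample_id` carries at least one alternate allele.
#' Indel alleles are skipped; multi-allelic rows contribute one record per
#' carried single-nucleotide alternate allele. Skip counts by category are
#' attached so that rows emitting records plus skipped rows equal the number
#' of data lines.
#'
#' @param path VCF file (plain or bgzipped)
#' @param sample_id sample column to extract genotypes from
#' @return data.frame with columns `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt`, `genotype` (GT string), `zygosity` (`"het"`/`"hom"`),
#'   `allele_freq` (NA when absent); attributes `skipped` (named integer
#'   vector) and `n_records_input` (data-line count)
#' @export
read_vcf <- function(path, sample_id) {
  hdr <- VariantAnnotation::scanVcfHeader(path)
  avail <- VariantAnnotation::samples(hdr)
  if (!sample_id %in% avail)
    stop("sample '", sample_id, "' not in VCF; available: ",
         paste(avail, collapse = ", "))
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  n <- nrow(vcf)
  skipped <- c(no_alt_carried = 0L, indel = 0L, missing_gt = 0L)
  empty <- data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character(),
                      genotype = character(), zygosity = character(),
                      allele_freq = numeric(), stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(empty, "skipped") <- skipped
    attr(empty, "n_records_input") <- 0L
    return(empty)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chroms <- as.character(GenomicRanges::seqnames(rr))
  poss <- GenomicRanges::start(rr)
  ids <- names(rr) %||% rep(NA_character_, n)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  alts <- lapply(seq_len(n), function(i) as.character(alts[[i]]))
  gts <- VariantAnnotation::geno(vcf)$GT[, sample_id]
  afs <- tryCatch(VariantAnnotation::info(vcf)$AF, error = function(e) NULL)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gt <- gts[i]
    if (is.na(gt) || gt %in% c(".", "./.", ".|.")) {
      skipped["missing_gt"] <- skipped["missing_gt"] + 1L
      next
    }
    alleles <- suppressWarnings(as.integer(strsplit(gt, "[/|]")[[1]]))
    carried <- unique(alleles[!is.na(alleles) & alleles > 0L])
    if (!length(carried)) {
      skipped["no_alt_carried"] <- skipped["no_alt_carried"] + 1L
      next
    }
    alt_i <- alts[[i]]
    carried <- carried[carried <= length(alt_i)]
    snv <- carried[nchar(refs[i]) == 1L & nchar(alt_i[carried]) == 1L &
                     alt_i[carried] %in% c("A", "C", "G", "T") &
                     alt_i[carried] != refs[i]]
    if (!length(snv) || !refs[i] %in% c("A", "C", "G", "T")) {
      skipped["indel"] <- skipped["indel"] + 1L
      next
    }
    af <- NA_real_
    if (!is.null(afs)) {
      afv <- unlist(afs[i])
      if (length(afv)) af <- afv[min(snv[1L], length(afv))]
    }
    hom <- length(alleles) >= 2L && all(!is.na(alleles)) &&
      length(unique(alleles)) == 1L
    rows[[i]] <- data.frame(
      chrom = chroms[i], pos = poss[i],
      id = if (is.na(ids[i]) || ids[i] == ".") sprintf("%s:%d", chroms[i], poss[i]) else ids[i],
      ref = refs[i], alt = alt_i[snv],
      genotype = gt, zygosity = if (hom) "hom" else "het",
      allele_freq = af, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  vmsg(sprintf("read_vcf: %d record(s) from %d line(s); skipped: %s",
               nrow(out), n,
               paste(names(skipped), skipped, sep = "=", collapse = ", ")))
  attr(out, "skipped") <- skipped
  attr(out, "n_records_input") <- n
  out
}

# ---- pre-miRNA annotation ---------------------------------------------------

encode_spans <- function(sp) {
  if (!nrow(sp)) return("")
  paste(sprintf("%s:%d-%d", sp$arm, sp$start, sp$end), collapse = ";")
}

decode_spans <- function(x) {
  if (is.na(x) || !nzchar(x))
    return(data.frame(arm = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(5p|3p):(\\d+)-(\\d+)$", parts))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed mature-span field: ", x)
  data.frame(arm = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Read pre-miRNA annotation (coordinates + hairpin sequences)
#'
#' Accepts either the package's 6/7-column TSV dialect (`name`, `chrom`,
#' `start`, `end`, `strand`, `sequence`, optional `mature_spans`, with a
#' commented header line) or a miRBase-style GFF3
#' (`miRNA_primary_transcript` rows plus `miRNA` rows linked by
#' `Derives_from`). Sequences may alternatively (or additionally) come from a
#' hairpin FASTA keyed by the same identifiers; DNA is transcribed to RNA.
#' Hairpins that end up without a sequence are dropped with a warning.
#'
#' @param coords_path TSV or GFF3 annotation file
#' @param fasta_path optional hairpin FASTA
#' @param format `"auto"` (by extension), `"tsv"` or `"gff3"`
#' @return named list of [premirna()] objects
#' @export
read_premirnas <- function(coords_path, fasta_path = NULL,
                           format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?(\\.gz)?$", coords_path)) "gff3" else "tsv"
  seqs <- NULL
  if (!is.null(fasta_path)) {
    fa <- Biostrings::readBStringSet(fasta_path)
    seqs <- transcribe(as.character(fa))
    names(seqs) <- sub("\\s.*$", "", names(fa))
  }
  if (format == "tsv") {
    tab <- read.delim(coords_path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE,
                      colClasses = "character")
    if (!ncol(tab) %in% c(6L, 7L))
      stop("pre-miRNA TSV must have 6 or 7 columns, got ", ncol(tab))
    names(tab) <- c("name", "chrom", "start", "end", "strand", "sequence",
                    "mature_spans")[seq_len(ncol(tab))]
    if (is.null(tab$mature_spans)) tab$mature_spans <- ""
    mirs <- lapply(seq_len(nrow(tab)), function(i) {
      sq <- tab$sequence[i]
      if ((is.na(sq) || !nzchar(sq)) && !is.null(seqs))
        sq <- unname(seqs[tab$name[i]])
      if (is.null(sq) || is.na(sq) || !nzchar(sq)) sq <- NULL
      premirna(tab$name[i], tab$chrom[i], tab$start[i], tab$end[i],
               tab$strand[i], sequence = sq,
               mature_spans = decode_spans(tab$mature_spans[i]))
    })
  } else {
    gr <- rtracklayer::import(coords_path)
    md <- S4Vectors::mcols(gr)
    type <- as.character(md$type)
    get_name <- function(i) {
      nm <- md$Name[i] %||% NA_character_
      if (is.na(nm)) nm <- md$ID[i]
      as.character(nm)
    }
    hp_idx <- which(type == "miRNA_primary_transcript")
    if (!length(hp_idx)) stop("GFF3 has no miRNA_primary_transcript records")
    ids <- as.character(md$ID[hp_idx])
    mirs <- lapply(seq_along(hp_idx), function(k) {
      i <- hp_idx[k]
      nm <- get_name(i)
      h_start <- GenomicRanges::start(gr)[i]
      h_end <- GenomicRanges::end(gr)[i]
      h_strand <- as.character(GenomicRanges::strand(gr))[i]
      sq <- if (!is.null(seqs)) unname(seqs[nm]) else NULL
      if (!is.null(sq) && is.na(sq)) sq <- NULL
      mat_idx <- which(type == "miRNA" &
                         as.character(md$Derives_from %||%
                                        rep(NA_character_, length(gr))) == ids[k])
      spans <- NULL
      if (length(mat_idx)) {
        L <- h_end - h_start + 1L
        spans <- do.call(rbind, lapply(mat_idx, function(j) {
          ms <- GenomicRanges::start(gr)[j]; me <- GenomicRanges::end(gr)[j]
          if (h_strand == "+") {
            s0 <- ms - h_start; e0 <- me - h_start
          } else {
            s0 <- h_end - me; e0 <- h_end - ms
          }
          mat_name <- get_name(j)
          arm <- if (grepl("-5p$", mat_name)) "5p"
            else if (grepl("-3p$", mat_name)) "3p"
            else if ((s0 + e0) / 2 < (L - 1) / 2) "5p" else "3p"
          data.frame(arm = arm, start = s0, end = e0, stringsAsFactors = FALSE)
        }))
      }
      premirna(nm, as.character(GenomicRanges::seqnames(gr))[i],
               h_start, h_end, h_strand, sequence = sq, mature_spans = spans)
    })
  }
  names(mirs) <- vapply(mirs, `[[`, "", "name")
  no_seq <- vapply(mirs, function(m) is.null(m$sequence), logical(1))
  if (any(no_seq)) {
    warning("dropping ", sum(no_seq), " hairpin(s) with no sequence: ",
            paste(names(mirs)[no_seq], collapse = ", "))
    mirs <- mirs[!no_seq]
  }
  mirs
}

#' Write pre-miRNAs to the package TSV dialect
#'
#' Seven tab-separated columns (`name`, `chrom`, `start`, `end`, `strand`,
#' `sequence`, `mature_spans`) under a commented header line. Re-reading with
#' [read_premirnas()] reproduces all fields exactly.
#'
#' @param mirs list of [premirna()] objects
#' @param path output file
#' @export
write_premirnas <- function(mirs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# name\tchrom\tstart\tend\tstrand\tsequence\tmature_spans", con)
  for (m in mirs) {
    writeLines(paste(m$name, m$chrom, m$start, m$end, m$strand,
                     m$sequence %||% "", encode_spans(m$mature_spans),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write hairpin (or variant) sequences to FASTA
#' @param seqs named character vector of sequences
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(setNames(as.character(seqs), names(seqs))), path)
  invisible(path)
}

#' Read small-RNA reads into a collapsed read set
#'
#' Accepts FASTQ or FASTA (plain or gzipped). FASTA headers in the collapsed
#' dialect `id_xN` contribute `N` copies. Identical sequences are merged with
#' summed counts; sequences are uppercased and kept in the DNA alphabet.
#'
#' @param path reads file
#' @param format `"auto"` (by extension), `"fastq"` or `"fasta"`
#' @return data.frame with columns `sequence`, `count`, sorted by count
#'   (decreasing); empty with a warning when the file holds no reads
#' @export
read_reads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  empty <- data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE)
  ss <- tryCatch(Biostrings::readBStringSet(path, format = format),
                 error = function(e) NULL)
  if (is.null(ss) || length(ss) == 0L) {
    warning("no reads in ", path)
    return(empty)
  }
  seqs <- toupper(as.character(ss))
  counts <- rep(1L, length(seqs))
  m <- regmatches(names(ss), regexec("_x(\\d+)\\s*$", names(ss)))
  has_n <- vapply(m, length, integer(1)) == 2L
  counts[has_n] <- as.integer(vapply(m[has_n], `[`, "", 2L))
  agg <- tapply(counts, seqs, sum)
  out <- data.frame(sequence = names(agg), count = as.integer(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}
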