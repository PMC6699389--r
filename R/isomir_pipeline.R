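# End-to-end orchestration: region annotation of mapped SNPs, isomiR calling
# by canonical-vs-variant candidate comparison, exact read validation, and
# TSV reports.

#' Annotate the hairpin region of a mapped SNP
#'
#' Terminal-loop indices map to `"terminal loop"`; indices inside an
#' annotated mature span map to `"seed"` at mature-relative positions 2-8
#' (1-based within the mature) and `"mature"` elsewhere in the span; all
#' other indices are `"stem"`.
#'
#' @param mapped one mapped-SNP row ([map_all()] output)
#' @param mir the corresponding [premirna()]
#' @param fold its [fold()] result
#' @return one of `"seed"`, `"mature"`, `"terminal loop"`, `"stem"`
#' @export
annotate_region <- function(mapped, mir, fold) {
  idx <- mapped$hairpin_index
  if (idx >= fold$loop_span[1L] && idx <= fold$loop_span[2L])
    return("terminal loop")
  sp <- mir$mature_spans
  for (k in seq_len(nrow(sp))) {
    if (idx >= sp$start[k] && idx <= sp$end[k]) {
      rel <- idx - sp$start[k] + 1L       # 1-based within the mature
      return(if (rel >= 2L && rel <= 8L) "seed" else "mature")
    }
  }
  "stem"
}

#' Annotate regions for a whole mapped-SNP table
#' @param mapped [map_all()] output
#' @param mirs named list of hairpins
#' @param backend folding backend
#' @return `mapped` with the `region` column filled
#' @export
annotate_regions <- function(mapped, mirs, backend = "internal") {
  if (!nrow(mapped)) return(mapped)
  folds <- lapply(mirs[unique(mapped$premirna_name)], function(m)
    tryCatch(fold(m$sequence, backend = backend), error = function(e) NULL))
  for (i in seq_len(nrow(mapped))) {
    nm <- mapped$premirna_name[i]
    fd <- folds[[nm]]
    mapped$region[i] <- if (is.null(fd)) NA_character_
      else annotate_region(mapped[i, ], mirs[[nm]], fd)
  }
  mapped
}

#' Call isomiRs for one hairpin's variant precursors
#'
#' The canonical candidate set per site is the set of mature sequences
#' induced by the top-five positions on the canonical hairpin. Each variant
#' precursor is folded and scored the same way; every induced mature
#' sequence absent from the canonical set for its site is called an isomiR,
#' carrying the variant's SNP ids as functional SNPs. Variants that no
#' longer fold into a hairpin are recorded as fold-disrupted and excluded.
#'
#' @param model trained [train_matpred()] model
#' @param mir canonical hairpin
#' @param variants [build_variants()] rows for this hairpin
#' @param compare `"sequence"` (default; an induced mature is canonical only
#'   if its sequence is in the canonical set) or `"position"` (only the cut
#'   position is compared)
#' @param backend folding backend
#' @return data.frame of calls (`premirna_name`, `label`, `applied_snps`,
#'   `site_kind`, `position`, `sequence`, `classification`,
#'   `functional_snps`) with attribute `fold_disrupted` (labels of dropped
#'   variants)
#' @export
call_isomirs <- function(model, mir, variants, compare = c("sequence", "position"),
                         backend = NULL) {
  compare <- match.arg(compare)
  backend <- backend %||% model$config$backend %||% "internal"
  mat_len <- model$config$mat_len %||% MATURE_LEN
  empty <- data.frame(premirna_name = character(), label = character(),
                      applied_snps = character(), site_kind = character(),
                      position = integer(), sequence = character(),
                      classification = character(),
                      functional_snps = character(), stringsAsFactors = FALSE)
  canon_fold <- fold(mir$sequence, backend = backend)
  canon_pred <- predict_sites(model, canon_fold)
  canon_set <- lapply(SITE_KINDS, function(sk) {
    p <- canon_pred[[sk]]$position
    list(positions = p,
         sequences = vapply(p, function(x)
           induced_mature(mir$sequence, sk, x, mat_len), character(1)))
  })
  names(canon_set) <- SITE_KINDS
  rows <- list()
  disrupted <- character(0)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    vf <- tryCatch(fold(v$sequence, backend = backend),
                   error = function(e) NULL)
    if (is.null(vf)) { disrupted <- c(disrupted, v$label); next }
    vp <- predict_sites(model, vf)
    for (sk in SITE_KINDS) {
      cand <- vp[[sk]]
      for (j in seq_len(nrow(cand))) {
        sq <- induced_mature(v$sequence, sk, cand$position[j], mat_len)
        is_canon <- if (compare == "sequence")
          sq %in% canon_set[[sk]]$sequences
        else cand$position[j] %in% canon_set[[sk]]$positions
        rows[[length(rows) + 1L]] <- data.frame(
          premirna_name = mir$name, label = v$label,
          applied_snps = v$applied_snps, site_kind = sk,
          position = cand$position[j], sequence = sq,
          classification = if (is_canon) "canonical-match" else "isomiR",
          functional_snps = if (is_canon) "" else v$applied_snps,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "fold_disrupted") <- disrupted
  out
}

#' Per-site summary of isomiR-producing hairpins and SNPs
#'
#' For each site kind, counts the distinct hairpins and distinct SNP ids
#' appearing among isomiR calls.
#'
#' @param calls [call_isomirs()] output (possibly concatenated)
#' @return data.frame with columns `site_kind`, `n_premirnas`, `n_snps`
#' @export
summarize_site_alterations <- function(calls) {
  iso <- calls[calls$classification == "isomiR", , drop = FALSE]
  do.call(rbind, lapply(SITE_KINDS, function(sk) {
    s <- iso[iso$site_kind == sk, , drop = FALSE]
    snps <- unique(unlist(strsplit(s$functional_snps, "+", fixed = TRUE)))
    data.frame(site_kind = sk, n_premirnas = length(unique(s$premirna_name)),
               n_snps = length(snps[nzchar(snps)]), stringsAsFactors = FALSE)
  }))
}

#' Validate isomiR calls against small-RNA reads
#'
#' Counts, for each distinct isomiR sequence, the reads (weighted by
#' collapse count) containing it as an exact substring after U/T
#' normalization to the DNA alphabet.
#'
#' @param calls [call_isomirs()] output
#' @param reads [read_reads()] output
#' @param threshold minimum weighted count for `supported` (default 1)
#' @return data.frame with columns `sequence` (DNA alphabet), `read_count`,
#'   `supported`, sorted by count decreasing
#' @export
validate_reads <- function(calls, reads, threshold = 1L) {
  iso <- unique(to_dna(calls$sequence[calls$classification == "isomiR"]))
  if (!length(iso))
    return(data.frame(sequence = character(), read_count = integer(),
                      supported = logical(), stringsAsFactors = FALSE))
  read_seq <- to_dna(toupper(reads$sequence))
  counts <- vapply(iso, function(s) {
    if (!nrow(reads)) return(0L)
    hit <- grepl(s, read_seq, fixed = TRUE)
    as.integer(sum(reads$count[hit]))
  }, integer(1))
  out <- data.frame(sequence = iso, read_count = counts,
                    supported = counts >= threshold, stringsAsFactors = FALSE)
  out <- out[order(-out$read_count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

write_report <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  invisible(path)
}

#' Run the full SNP-to-isomiR pipeline
#'
#' extract SNPs -> map into hairpins -> enumerate variant precursors ->
#' predict processing sites -> call isomiRs -> validate against reads, then
#' write TSV reports (`mapped_snps.tsv` with region annotation,
#' `variants.fa`, `isomir_calls.tsv`, `isomirs_validated.tsv`,
#' `site_summary.tsv`). Reports carry no timestamps, so reruns with the same
#' inputs and model are byte-identical.
#'
#' @param vcf_path per-sample VCF
#' @param sample sample id in the VCF
#' @param mirs named list of [premirna()] objects (or a TSV/GFF3 path)
#' @param model trained model ([train_matpred()] or [load_model()])
#' @param reads_path small-RNA reads (FASTQ/FASTA), or `NULL` to skip
#'   validation
#' @param outdir output directory (created if needed)
#' @param backend folding backend
#' @return invisible list with `mapped`, `variants`, `calls`, `validated`,
#'   `summary`, `fold_disrupted`
#' @export
run_pipeline <- function(vcf_path, sample, mirs, model, reads_path = NULL,
                         outdir = ".", backend = NULL) {
  backend <- backend %||% model$config$backend %||% "internal"
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.character(mirs)) mirs <- stage("read-mirs", read_premirnas(mirs))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  snps <- stage("extract-snps", read_vcf(vcf_path, sample))
  mapped <- stage("map-snps", map_all(snps, mirs))
  mapped <- stage("annotate-regions", annotate_regions(mapped, mirs, backend))
  variants <- stage("build-variants", build_all_variants(mirs, mapped))
  calls_list <- list(); disrupted <- character(0)
  if (nrow(variants)) {
    for (nm in unique(variants$premirna_name)) {
      v <- variants[variants$premirna_name == nm, , drop = FALSE]
      cl <- stage(paste0("call-isomirs:", nm),
                  call_isomirs(model, mirs[[nm]], v, backend = backend))
      disrupted <- c(disrupted, attr(cl, "fold_disrupted"))
      calls_list[[nm]] <- cl
    }
  }
  calls <- do.call(rbind, calls_list)
  if (is.null(calls))
    calls <- data.frame(premirna_name = character(), label = character(),
                        applied_snps = character(), site_kind = character(),
                        position = integer(), sequence = character(),
                        classification = character(),
                        functional_snps = character(), stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  validated <- data.frame(sequence = character(), read_count = integer(),
                          supported = logical(), stringsAsFactors = FALSE)
  if (!is.null(reads_path)) {
    reads <- stage("read-reads",
                   suppressWarnings(read_reads(reads_path)))
    validated <- stage("validate-reads", validate_reads(calls, reads))
  }
  summ <- summarize_site_alterations(calls)

  write_report(mapped, file.path(outdir, "mapped_snps.tsv"))
  write_fasta(setNames(variants$sequence, variants$label),
              file.path(outdir, "variants.fa"))
  iso <- calls[calls$classification == "isomiR", , drop = FALSE]
  iso_tab <- data.frame(site = iso$site_kind, premirna = iso$premirna_name,
                        sequence = to_dna(iso$sequence),
                        functional_snps = iso$functional_snps,
                        stringsAsFactors = FALSE)
  iso_tab <- unique(iso_tab)
  iso_tab$read_count <- if (nrow(validated))
    validated$read_count[match(iso_tab$sequence, validated$sequence)]
  else rep(NA_integer_, nrow(iso_tab))
  write_report(iso_tab, file.path(outdir, "isomir_calls.tsv"))
  write_report(validated, file.path(outdir, "isomirs_validated.tsv"))
  write_report(summ, file.path(outdir, "site_summary.tsv"))
  invisible(list(mapped = mapped, variants = variants, calls = calls,
                 validated = validated, summary = summ,
                 fold_disrupted = unique(disrupted)))
}
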