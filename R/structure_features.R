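# Secondary structure and the 115-dimensional processing-site feature set.
#
# Folding is pluggable behind one contract (sequence -> dot-bracket + energy):
# the "vienna" backend shells out to RNAfold, the "internal" backend is a
# weighted base-pair-maximization dynamic program (min hairpin loop 3,
# GC/AU/GU = -3/-2/-1) compiled with Rcpp. "auto" picks vienna when an
# RNAfold binary is on the PATH, otherwise internal.

#' Fold an RNA sequence into a hairpin structure
#'
#' @param sequence RNA (or DNA; transcribed) string, length >= `min_length`
#' @param backend `"auto"`, `"vienna"` (RNAfold) or `"internal"`
#' @param min_length refuse shorter sequences (default 40, the lower end of
#'   plausible pre-miRNA hairpins; relax for toy structures)
#' @return object of class `HairpinFold`: `sequence`, `dot_bracket`,
#'   `mfe_total` (kcal/mol; for the internal backend the negated pair-weight
#'   sum on the same ordering), `pair_table` (integer vector of 0-based
#'   partner indices, `NA` = unpaired) and `loop_span` (0-based inclusive
#'   bounds of the terminal loop of the longest stem)
#' @export
fold <- function(sequence, backend = c("auto", "vienna", "internal"),
                 min_length = 40L) {
  backend <- match.arg(backend)
  sequence <- transcribe(sequence)
  if (!is_rna_seq(sequence)) stop("sequence has non-ACGU characters")
  if (nchar(sequence) < min_length)
    stop("hairpin folding needs length >= ", min_length, ", got ",
         nchar(sequence))
  if (backend == "auto")
    backend <- if (nzchar(Sys.which("RNAfold"))) "vienna" else "internal"
  if (backend == "vienna") {
    res <- rnafold_backend(sequence)
  } else {
    r <- .nussinov_fold(sequence)
    res <- list(dot_bracket = r$structure, mfe = r$energy)
  }
  pt <- pair_table_from_db(res$dot_bracket)
  if (all(is.na(pt))) stop("not hairpin-like: '", substr(sequence, 1, 20),
                           "...' folds with no base pairs")
  loop <- terminal_loop(pt)
  structure(list(sequence = sequence, dot_bracket = res$dot_bracket,
                 mfe_total = res$mfe, pair_table = pt, loop_span = loop),
            class = "HairpinFold")
}

#' @export
print.HairpinFold <- function(x, ...) {
  cat("HairpinFold length", nchar(x$sequence), " MFE", x$mfe_total,
      " loop", paste(x$loop_span, collapse = "-"), "\n")
  cat(" ", x$sequence, "\n ", x$dot_bracket, "\n")
  invisible(x)
}

rnafold_backend <- function(sequence) {
  out <- system2("RNAfold", args = c("--noPS"), input = sequence,
                 stdout = TRUE, stderr = FALSE)
  if (length(out) < 2L) stop("RNAfold produced no structure")
  line <- out[2L]
  db <- sub("\\s.*$", "", line)
  mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
  list(dot_bracket = db, mfe = mfe)
}

# dot-bracket -> 0-based partner indices (NA = unpaired)
pair_table_from_db <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j - 1L
      pt[j] <- i - 1L
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  pt
}

# terminal loop of the longest stem: among maximal unpaired runs directly
# enclosed by a pair (hairpin loops), take the one whose enclosing helix
# stacks deepest; ties go to the 5'-most loop. 0-based inclusive bounds.
terminal_loop <- function(pt) {
  n <- length(pt)
  best <- NULL; best_stem <- -1L
  for (i in seq_len(n)) {
    j1 <- pt[i]                       # 0-based partner of position i-1
    if (is.na(j1)) next
    i0 <- i - 1L
    if (j1 <= i0) next
    inner <- if (j1 - i0 >= 2L) (i0 + 1L):(j1 - 1L) else integer(0)
    if (length(inner) == 0L || any(!is.na(pt[inner + 1L]))) next
    stem <- 1L
    while (i0 - stem >= 0L && j1 + stem <= n - 1L &&
           !is.na(pt[i0 - stem + 1L]) && pt[i0 - stem + 1L] == j1 + stem)
      stem <- stem + 1L
    if (stem > best_stem) {
      best_stem <- stem
      best <- c(i0 + 1L, j1 - 1L)
    }
  }
  if (is.null(best)) stop("not hairpin-like: no hairpin loop found")
  best
}

# MFE of a subsequence under the internal energy model (used for the
# flank-window MFE features regardless of the hairpin-folding backend:
# thousands of windows are scored per training run).
window_mfe <- function(sequence, from0, to0) {
  s <- subseq0(sequence, from0, to0)
  if (nchar(s) < 5L) return(0)
  .nussinov_energy(s)
}

# ---- duplex -----------------------------------------------------------------

DUPLEX_NCOL <- 25L

#' Build the miRNA:miRNA* duplex alignment for a candidate 5'-arm mature
#'
#' The top row holds the candidate mature (5'->3'); the bottom row holds its
#' 3'-arm partners read 3'->5', with `-` inserted opposite bulges on either
#' strand so paired bases share a column. The star strand's characteristic
#' 2-nt 3' overhang (the two star nucleotides beyond the partner of the
#' mature 5' end) occupies leading columns opposite gaps when those
#' nucleotides exist. Rows are padded with `-` on the right (or truncated)
#' to exactly 25 columns.
#'
#' @param fold a [fold()] result
#' @param p5_start 0-based index of the candidate mature 5' start
#' @param length mature window length (default 22)
#' @return object of class `DuplexAlignment`: `mature_row`, `star_row`
#'   (25-character strings), `paired` (logical per column), `mature_col`
#'   (1-based column of each mature position, `NA` once truncated)
#' @export
build_duplex <- function(fold, p5_start, length = 22L) {
  pt <- fold$pair_table
  loop_start <- fold$loop_span[1L]
  if (p5_start < 0L) stop("p5_start must be >= 0")
  if (p5_start + length > loop_start)
    stop("mature window [", p5_start, ",", p5_start + length - 1L,
         "] overlaps the terminal loop starting at ", loop_start)
  seqc <- strsplit(fold$sequence, "", fixed = TRUE)[[1]]
  n <- nchar(fold$sequence)
  idx <- p5_start:(p5_start + length - 1L)
  partners <- pt[idx + 1L]
  top <- character(0); bottom <- character(0); paired <- logical(0)
  mature_col <- rep(NA_integer_, length)
  first_paired <- which(!is.na(partners))[1L]
  if (!is.na(first_paired)) {
    j_anchor <- partners[first_paired]
    # 2-nt 3' overhang of the star strand, 3'-most first
    for (oh in c(j_anchor + 2L, j_anchor + 1L)) {
      if (oh <= n - 1L && oh > fold$loop_span[2L]) {
        top <- c(top, "-"); bottom <- c(bottom, seqc[oh + 1L])
        paired <- c(paired, FALSE)
      }
    }
    j_cur <- j_anchor
  } else {
    j_cur <- NA_integer_
  }
  for (k in seq_along(idx)) {
    p <- partners[k]
    if (!is.na(p)) {
      if (!is.na(j_cur)) {
        while (j_cur > p) {           # star-side bulge: gap in mature row
          top <- c(top, "-"); bottom <- c(bottom, seqc[j_cur + 1L])
          paired <- c(paired, FALSE)
          j_cur <- j_cur - 1L
        }
      }
      mature_col[k] <- length(top) + 1L
      top <- c(top, seqc[idx[k] + 1L]); bottom <- c(bottom, seqc[p + 1L])
      paired <- c(paired, TRUE)
      j_cur <- p - 1L
    } else {                          # mature-side bulge or mismatch
      mature_col[k] <- length(top) + 1L
      top <- c(top, seqc[idx[k] + 1L]); bottom <- c(bottom, "-")
      paired <- c(paired, FALSE)
    }
  }
  nc <- length(top)
  if (nc < DUPLEX_NCOL) {
    pad <- DUPLEX_NCOL - nc
    top <- c(top, rep("-", pad)); bottom <- c(bottom, rep("-", pad))
    paired <- c(paired, rep(FALSE, pad))
  } else if (nc > DUPLEX_NCOL) {
    top <- top[seq_len(DUPLEX_NCOL)]; bottom <- bottom[seq_len(DUPLEX_NCOL)]
    paired <- paired[seq_len(DUPLEX_NCOL)]
    mature_col[!is.na(mature_col) & mature_col > DUPLEX_NCOL] <- NA_integer_
  }
  structure(list(mature_row = paste(top, collapse = ""),
                 star_row = paste(bottom, collapse = ""),
                 paired = paired, mature_col = mature_col),
            class = "DuplexAlignment")
}

#' @export
print.DuplexAlignment <- function(x, ...) {
  cat("5' ", x$mature_row, "\n   ",
      paste(ifelse(x$paired, "|", " "), collapse = ""), "\n3' ",
      x$star_row, "\n", sep = "")
  invisible(x)
}

# ---- feature extraction -----------------------------------------------------

STRUCT_ALPHABET <- c("AM", "CM", "GM", "UM", "AN", "CN", "GN", "UN", "-N")
PAIR_ALPHABET <- c("AA", "AC", "AG", "AU", "CA", "CC", "CG", "CU",
                   "GA", "GC", "GG", "GU", "UA", "UC", "UG", "UU",
                   "A-", "C-", "G-", "U-", "-A", "-C", "-G", "-U", "--")

struct_code <- function(base, is_paired) {
  sym <- ifelse(base == "-", "-N", paste0(base, ifelse(is_paired, "M", "N")))
  match(sym, STRUCT_ALPHABET) / length(STRUCT_ALPHABET)
}

pair_code <- function(top, bottom) {
  sym <- paste0(top, bottom)
  match(sym, PAIR_ALPHABET) / length(PAIR_ALPHABET)
}

#' Names of the 115 processing-site features, in extraction order
#' @return character vector of length 115
#' @export
feature_names <- function() {
  c("MFE1_duplex", "MFE_9nt", "MFE_5nt", "MFE_3nt", "MFE_plus3nt",
    paste0("duplex_struct_mat_", 1:25), paste0("duplex_struct_star_", 1:25),
    paste0("flank9_self_", 1:9), paste0("flank9_partner_", 1:9),
    paste0("flank3_self_", 1:3), paste0("flank3_partner_", 1:3),
    paste0("duplex_pair_", 1:25),
    "gaps_3_8", "gaps_9_12", "gaps_m2_p2",
    "first_nt_type", "first_nt_paired",
    "mature_freq_A", "mature_freq_C", "mature_freq_G", "mature_freq_U",
    "mature_freq_gap",
    "dist_drosha_loop")
}

# per-hairpin-position structural-specificity codes (self base + its partner)
position_codes <- function(fold, pos0) {
  n <- nchar(fold$sequence)
  self <- numeric(length(pos0)); partner <- numeric(length(pos0))
  for (k in seq_along(pos0)) {
    p <- pos0[k]
    if (p < 0L || p > n - 1L) {
      self[k] <- struct_code("-", FALSE)
      partner[k] <- struct_code("-", FALSE)
    } else {
      q <- fold$pair_table[p + 1L]
      if (is.na(q)) {
        self[k] <- struct_code(char_at(fold$sequence, p), FALSE)
        partner[k] <- struct_code("-", FALSE)
      } else {
        self[k] <- struct_code(char_at(fold$sequence, p), TRUE)
        partner[k] <- struct_code(char_at(fold$sequence, q), TRUE)
      }
    }
  }
  c(self, partner)
}

#' Extract the 115-dimensional feature vector for a candidate site
#'
#' Features, in fixed order: 5 minimum-free-energy values (duplex MFE and
#' refolds of the windows starting 9/5/3 nt left and 3 nt right of the
#' 5'-arm Drosha site, through the 5'-arm Dicer site); 50 per-column
#' structural-specificity codes of the 25-column duplex (mature then star
#' strand); 18 codes for the 9-nt flank left of the Drosha site and 6 for
#' the 3-nt flank right of the Dicer site (position base + partner base);
#' 25 per-column pairing codes; 3 gap counts in duplex windows 3-8 nt and
#' 9-12 nt right of the Drosha column and -2..+2 around it; 7 mature-row
#' features (first-nucleotide type, first-nucleotide-paired indicator,
#' frequencies of A/C/G/U/- in the gapped mature row); and the distance
#' from the Drosha site to the terminal-loop start. Categorical codes are
#' fixed integers scaled to [0,1]; windows running off the sequence are
#' coded as gap/padding.
#'
#' @param fold a [fold()] result
#' @param p5_start,p5_end 0-based inclusive 5'-arm mature window
#' @param p3_start,p3_end optional 0-based 3'-arm mature window (recorded
#'   for provenance; features are computed in the 5'-arm frame)
#' @return named numeric vector of length 115
#' @export
extract_features <- function(fold, p5_start, p5_end,
                             p3_start = NULL, p3_end = NULL) {
  mat_len <- p5_end - p5_start + 1L
  dup <- build_duplex(fold, p5_start, length = mat_len)
  top <- strsplit(dup$mature_row, "", fixed = TRUE)[[1]]
  bottom <- strsplit(dup$star_row, "", fixed = TRUE)[[1]]

  mfe1 <- duplex_mfe(top, bottom, dup$paired)
  mfes <- c(mfe1,
            window_mfe(fold$sequence, p5_start - 9L, p5_end),
            window_mfe(fold$sequence, p5_start - 5L, p5_end),
            window_mfe(fold$sequence, p5_start - 3L, p5_end),
            window_mfe(fold$sequence, p5_start + 3L, p5_end))

  ss_dup <- c(struct_code(top, dup$paired), struct_code(bottom, dup$paired))
  ss_flank9 <- position_codes(fold, (p5_start - 9L):(p5_start - 1L))
  ss_flank3 <- position_codes(fold, (p5_end + 1L):(p5_end + 3L))
  pairs <- pair_code(top, bottom)

  c0 <- dup$mature_col[1L]
  if (is.na(c0)) c0 <- 1L
  gap_in <- function(lo, hi) {
    cols <- max(lo, 1L):min(hi, DUPLEX_NCOL)
    if (!length(cols) || lo > DUPLEX_NCOL)
      return(0)
    (sum(top[cols] == "-") + sum(bottom[cols] == "-")) / (2 * length(cols))
  }
  gaps <- c(gap_in(c0 + 3L, c0 + 8L), gap_in(c0 + 9L, c0 + 12L),
            gap_in(c0 - 2L, c0 + 2L))

  first_base <- char_at(fold$sequence, p5_start)
  # gap frequency is taken within the mature alignment extent (first..last
  # mature base column) so neither the star 3' overhang nor right padding
  # counts as a mature-row gap
  mat_cols <- which(top != "-")
  gap_extent <- if (length(mat_cols) >= 2L)
    sum(top[min(mat_cols):max(mat_cols)] == "-") else 0L
  mature7 <- c(match(first_base, RNA_BASES) / 4,
               as.numeric(!is.na(fold$pair_table[p5_start + 1L])),
               sum(top == "A") / DUPLEX_NCOL, sum(top == "C") / DUPLEX_NCOL,
               sum(top == "G") / DUPLEX_NCOL, sum(top == "U") / DUPLEX_NCOL,
               gap_extent / DUPLEX_NCOL)

  dist_feat <- (fold$loop_span[1L] - p5_start) / 100

  v <- c(mfes, ss_dup, ss_flank9, ss_flank3, pairs, gaps, mature7, dist_feat)
  names(v) <- feature_names()
  stopifnot(length(v) == 115L, !anyNA(v))
  v
}

# duplex MFE under the internal pair-weight model
duplex_mfe <- function(top, bottom, paired) {
  if (!any(paired)) return(0)
  w <- vapply(which(paired), function(i) {
    ab <- paste0(sort(c(top[i], bottom[i])), collapse = "")
    switch(ab, "CG" = 3, "AU" = 2, "GU" = 1, 0)
  }, numeric(1))
  -sum(w)
}
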