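# Per-site processing-site classifiers. Four binary soft-margin SVMs (one
# per site kind P5_5/P5_3/P3_5/P3_3) are trained on the 115-feature vectors
# of annotated sites (positives, offset 0) versus windows shifted by every
# nonzero offset within a range (negatives), mirroring the 22-nt-window /
# 2-nt-overhang training-set geometry. Candidate positions are ranked by
# decision score and the top five retained.

MATURE_LEN <- 22L
N_CANDIDATES <- 5L
MODEL_VERSION <- 1L

# 3'-arm <-> 5'-arm frame correspondence through the pair table with the
# canonical 2-nt 3' overhang: P3_3 = partner(P5_5) + 2, P3_5 = partner(P5_3)
# + 2. Unpaired lookups fall back to the nearest paired neighbour within 3
# nt (antiparallel adjustment). Returns c(p5_start, p5_end) or NULL.
p5_frame <- function(fold, site_kind, pos, mat_len = MATURE_LEN) {
  pt <- fold$pair_table
  n <- length(pt)
  partner_near <- function(x) {
    for (d in c(0L, 1L, -1L, 2L, -2L, 3L, -3L)) {
      xi <- x + d
      if (xi >= 0L && xi <= n - 1L && !is.na(pt[xi + 1L]))
        return(pt[xi + 1L] + d)       # antiparallel: partner falls as x rises
    }
    NA_integer_
  }
  win <- switch(site_kind,
    P5_5 = c(pos, pos + mat_len - 1L),
    P5_3 = c(pos - mat_len + 1L, pos),
    P3_5 = { e <- partner_near(pos - 2L); c(e - mat_len + 1L, e) },
    P3_3 = { s <- partner_near(pos - 2L); c(s, s + mat_len - 1L) },
    stop("unknown site kind: ", site_kind))
  if (anyNA(win)) return(NULL)
  if (win[1L] < 0L || win[2L] >= fold$loop_span[1L]) return(NULL)
  win
}

# annotated position of a site kind from the hairpin's mature spans; the 3p
# span is derived from the 5p span through the overhang rule when missing
annotated_site <- function(mir, fold, site_kind) {
  sp5 <- mature_span(mir, "5p")
  sp3 <- mature_span(mir, "3p")
  if (is.null(sp3) && !is.null(sp5) && site_kind %in% c("P3_5", "P3_3")) {
    pt <- fold$pair_table
    p33 <- if (!is.na(pt[sp5["start"] + 1L])) pt[sp5["start"] + 1L] + 2L else NA_integer_
    p35 <- if (!is.na(pt[sp5["end"] + 1L])) pt[sp5["end"] + 1L] + 2L else NA_integer_
    if (anyNA(c(p33, p35))) return(NA_integer_)
    sp3 <- c(start = p35, end = p33)
  }
  out <- switch(site_kind,
    P5_5 = if (is.null(sp5)) NA_integer_ else unname(sp5["start"]),
    P5_3 = if (is.null(sp5)) NA_integer_ else unname(sp5["end"]),
    P3_5 = if (is.null(sp3)) NA_integer_ else unname(sp3["start"]),
    P3_3 = if (is.null(sp3)) NA_integer_ else unname(sp3["end"]))
  as.integer(out)
}

# admissible candidate positions for a site kind on a folded hairpin
admissible_positions <- function(fold, site_kind, mat_len = MATURE_LEN) {
  loop_start <- fold$loop_span[1L]
  loop_end <- fold$loop_span[2L]
  n <- length(fold$pair_table)
  cand <- switch(site_kind,
    P5_5 = if (loop_start >= mat_len) 0L:(loop_start - mat_len) else integer(0),
    P5_3 = if (loop_start >= mat_len) (mat_len - 1L):(loop_start - 1L) else integer(0),
    P3_5 = if (n - loop_end - 1L >= mat_len) (loop_end + 1L):(n - mat_len) else integer(0),
    P3_3 = if (n - loop_end - 1L >= mat_len) (loop_end + mat_len):(n - 1L) else integer(0))
  cand[vapply(cand, function(p) !is.null(p5_frame(fold, site_kind, p, mat_len)),
              logical(1))]
}

#' Build the training set for one processing-site classifier
#'
#' For every annotated hairpin: one positive example at the annotated site
#' (offset 0) and one negative per nonzero offset within
#' `offset_range` whose 22-nt window stays inside the arm. 5'-arm site
#' windows anchor directly on the annotation; 3'-arm windows are carried to
#' the 5'-arm frame through the pair table and the 2-nt overhang
#' correspondence before feature extraction.
#'
#' @param mirs list of annotated [premirna()] objects
#' @param site_kind one of `SITE_KINDS`
#' @param offset_range negatives at offsets `-offset_range..offset_range`
#'   (excluding 0)
#' @param mat_len mature window length used in training-set geometry
#' @param backend folding backend, see [fold()]
#' @return list with `features` (matrix, one row per example), `label`
#'   (logical, `TRUE` = positive), `offset` (integer), `premirna_name`;
#'   hairpins too short for any window are skipped with a warning
#' @export
build_training_set <- function(mirs, site_kind, offset_range = 15L,
                               mat_len = MATURE_LEN,
                               backend = "internal") {
  rows <- list(); labs <- logical(0); offs <- integer(0); nms <- character(0)
  skipped <- character(0)
  for (mir in mirs) {
    fd <- tryCatch(fold(mir$sequence, backend = backend),
                   error = function(e) NULL)
    if (is.null(fd)) { skipped <- c(skipped, mir$name); next }
    pos0 <- annotated_site(mir, fd, site_kind)
    if (is.na(pos0)) { skipped <- c(skipped, mir$name); next }
    added <- 0L
    for (o in (-offset_range):offset_range) {
      win <- p5_frame(fd, site_kind, pos0 + o, mat_len)
      if (is.null(win)) next
      fv <- tryCatch(extract_features(fd, win[1L], win[2L]),
                     error = function(e) NULL)
      if (is.null(fv)) next
      rows[[length(rows) + 1L]] <- fv
      labs <- c(labs, o == 0L)
      offs <- c(offs, o)
      nms <- c(nms, mir$name)
      added <- added + 1L
    }
    if (!added) skipped <- c(skipped, mir$name)
  }
  if (length(skipped))
    warning("no ", site_kind, " training windows for: ",
            paste(unique(skipped), collapse = ", "))
  list(features = do.call(rbind, rows), label = labs, offset = offs,
       premirna_name = nms)
}

#' Train the four processing-site classifiers
#'
#' Fits one soft-margin RBF support vector machine per site kind on
#' standardized features, with class weights balancing the ~1:30
#' positive:negative ratio. Deterministic given the seed.
#'
#' @param mirs annotated hairpins (>= 20)
#' @param config list overriding defaults: `seed` (1), `offset_range` (15),
#'   `cost` (10), `gamma` (1/115), `mat_len` (22), `backend` (`"internal"`)
#' @return object of class `MatpredModel` with per-site fits, scaling
#'   statistics and training metadata
#' @export
train_matpred <- function(mirs, config = list()) {
  cfg <- modifyList(list(seed = 1L, offset_range = 15L, cost = 10,
                         gamma = 1 / 115, mat_len = MATURE_LEN,
                         backend = "internal"), config)
  if (length(mirs) < 20L)
    stop("need >= 20 annotated hairpins for training, got ", length(mirs))
  sites <- list()
  n_total <- 0L
  for (sk in SITE_KINDS) {
    ts <- build_training_set(mirs, sk, offset_range = cfg$offset_range,
                             mat_len = cfg$mat_len, backend = cfg$backend)
    if (is.null(ts$features) || length(unique(ts$label)) < 2L)
      stop("single-class training set for ", sk)
    X <- ts$features
    center <- colMeans(X)
    scale_ <- apply(X, 2L, stats::sd)
    scale_[scale_ < 1e-9] <- 1
    Xs <- scale(X, center = center, scale = scale_)
    y <- factor(ts$label, levels = c(FALSE, TRUE))
    wts <- c("FALSE" = 1, "TRUE" = sum(!ts$label) / max(sum(ts$label), 1L))
    set.seed(cfg$seed)
    fit <- e1071::svm(x = Xs, y = y, kernel = "radial", cost = cfg$cost,
                      gamma = cfg$gamma, class.weights = wts, scale = FALSE)
    dv <- attr(stats::predict(fit, Xs, decision.values = TRUE),
               "decision.values")[, 1L]
    flip <- if (mean(dv[ts$label]) >= mean(dv[!ts$label])) 1 else -1
    sites[[sk]] <- list(fit = fit, center = center, scale = scale_,
                        flip = flip, n_examples = nrow(X),
                        n_positive = sum(ts$label))
    n_total <- n_total + nrow(X)
  }
  structure(list(version = MODEL_VERSION, sites = sites, config = cfg,
                 metadata = list(seed = cfg$seed, n_examples = n_total,
                                 n_hairpins = length(mirs),
                                 date = as.character(Sys.Date()))),
            class = "MatpredModel")
}

#' @export
print.MatpredModel <- function(x, ...) {
  cat("MatpredModel v", x$version, ": ", x$metadata$n_examples,
      " examples from ", x$metadata$n_hairpins, " hairpins (seed ",
      x$metadata$seed, ")\n", sep = "")
  invisible(x)
}

#' Save / load a trained model
#' @param model a `MatpredModel`
#' @param path file path
#' @return `load_model` returns the model; `save_model` the path, invisibly
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "MatpredModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "MatpredModel") || model$version != MODEL_VERSION)
    stop("not a compatible model file: ", path)
  model
}

score_positions <- function(model, fd, site_kind, positions,
                            mat_len = MATURE_LEN) {
  if (!length(positions)) return(numeric(0))
  X <- do.call(rbind, lapply(positions, function(p) {
    win <- p5_frame(fd, site_kind, p, mat_len)
    extract_features(fd, win[1L], win[2L])
  }))
  if (!is.null(model$score_fun))   # pluggable scorer (null models, testing)
    return(model$score_fun(site_kind, positions, X))
  ms <- model$sites[[site_kind]]
  Xs <- scale(X, center = ms$center, scale = ms$scale)
  dv <- attr(stats::predict(ms$fit, Xs, decision.values = TRUE),
             "decision.values")[, 1L]
  ms$flip * dv
}

#' Predict the four processing sites of a hairpin
#'
#' Scores every admissible position for each site kind and returns the top
#' five candidates per site, highest decision score first; ties break toward
#' the 5'-most position.
#'
#' @param model a trained `MatpredModel` (or one carrying a `score_fun`
#'   override: `function(site_kind, positions, features)` returning scores)
#' @param sequence hairpin sequence, or a pre-computed [fold()] object
#' @param backend folding backend when `sequence` is a string
#' @return named list (one entry per site kind) of data.frames with columns
#'   `position` (0-based) and `score`, at most five rows, scores
#'   non-increasing
#' @export
predict_sites <- function(model, sequence, backend = NULL) {
  backend <- backend %||% model$config$backend %||% "internal"
  fd <- if (inherits(sequence, "HairpinFold")) sequence
    else fold(sequence, backend = backend)
  mat_len <- model$config$mat_len %||% MATURE_LEN
  out <- lapply(SITE_KINDS, function(sk) {
    pos <- admissible_positions(fd, sk, mat_len)
    if (!length(pos))
      return(data.frame(position = integer(), score = numeric()))
    sc <- score_positions(model, fd, sk, pos, mat_len)
    ord <- order(-sc, pos)
    k <- head(ord, N_CANDIDATES)
    data.frame(position = pos[k], score = sc[k])
  })
  names(out) <- SITE_KINDS
  out
}

#' Mature sequence induced by a site candidate
#'
#' Start-type sites (P5_5, P3_5) extend `mat_len` nucleotides rightward from
#' the candidate position; end-type sites (P5_3, P3_3) extend leftward.
#' Windows are clipped at the sequence bounds.
#'
#' @param sequence hairpin sequence (RNA)
#' @param site_kind one of `SITE_KINDS`
#' @param position 0-based candidate position
#' @param mat_len mature length (default 22)
#' @return character mature sequence
#' @export
induced_mature <- function(sequence, site_kind, position,
                           mat_len = MATURE_LEN) {
  if (site_kind %in% c("P5_5", "P3_5"))
    subseq0(sequence, position, position + mat_len - 1L)
  else
    subseq0(sequence, position - mat_len + 1L, position)
}

#' Evaluate position-deviation accuracy on annotated test hairpins
#'
#' For each site kind, the fraction of test hairpins whose rank-1 candidate
#' lies within `tolerance_nt` of the annotated position.
#'
#' @param model trained model
#' @param test_mirs annotated hairpins disjoint from training
#' @param tolerance_nt allowed absolute deviation (default 5)
#' @return named numeric vector of per-site accuracies
#' @export
evaluate_matpred <- function(model, test_mirs, tolerance_nt = 5L) {
  if (!length(test_mirs)) stop("empty test set")
  backend <- model$config$backend %||% "internal"
  hits <- setNames(rep(0L, 4L), SITE_KINDS)
  tots <- setNames(rep(0L, 4L), SITE_KINDS)
  for (mir in test_mirs) {
    fd <- tryCatch(fold(mir$sequence, backend = backend),
                   error = function(e) NULL)
    if (is.null(fd)) next
    preds <- predict_sites(model, fd)
    for (sk in SITE_KINDS) {
      truth <- annotated_site(mir, fd, sk)
      if (is.na(truth) || !nrow(preds[[sk]])) next
      tots[sk] <- tots[sk] + 1L
      if (abs(preds[[sk]]$position[1L] - truth) <= tolerance_nt)
        hits[sk] <- hits[sk] + 1L
    }
  }
  if (any(tots == 0L)) stop("no evaluable hairpins for some site kind")
  hits / tots
}
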