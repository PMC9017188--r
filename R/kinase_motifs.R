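# Position-specific log-odds models of kinase sequence specificity, window
# extraction, scoring, and kinase-class assignment.

#' Construct a kinase motif model
#'
#' A kinase motif model is a position-specific log2-odds matrix over the 20
#' canonical residues at positions `-w..+w` around the phospho-acceptor
#' (position 0), plus the set of acceptor residues the kinase can
#' phosphorylate and a logistic calibration that converts a raw log-odds
#' score into a match probability. The center row of the matrix must be all
#' zeros (acceptor preference is expressed through `acceptors` /
#' `acceptor_weights`, not the matrix), and the padding symbol `"_"`
#' contributes 0 at every position: a truncated window is uninformative, not
#' penalized.
#'
#' @param name kinase name, e.g. `"CK2"`.
#' @param kinase_class one of `"acidophilic"`, `"basophilic"`,
#'   `"pro_directed"`, `"tyrosine"`.
#' @param acceptors subset of `c("S","T","Y")`.
#' @param logodds numeric matrix with `2*w + 1` rows (named `-w..w`) and 20
#'   columns (named by residue); log2 odds versus background. A row of zeros
#'   means the position is unconstrained.
#' @param w window half-width; default 7 (15-mer windows).
#' @param match_midpoint,match_slope logistic calibration for
#'   [match_probability()]. The default midpoint is half the maximum
#'   attainable positive score; the default slope 3 keeps the background
#'   (zero-score) match probability below 0.1%, so non-substrates acquire
#'   essentially no back-phosphorylation.
#' @param acceptor_weights optional named weights over `acceptors` used when
#'   sampling consensus windows (e.g. a pT preference); defaults to uniform.
#' @return an object of class `kinase_motif_model`.
#' @seealso [default_kinase_models()], [motif_score()], [match_probability()]
#' @export
kinase_motif_model <- function(name, kinase_class, acceptors, logodds, w = 7L,
                               match_midpoint = NULL, match_slope = 3,
                               acceptor_weights = NULL) {
  kinase_class <- match.arg(kinase_class,
                            c("acidophilic", "basophilic", "pro_directed", "tyrosine"))
  if (!all(acceptors %in% ACCEPTOR_RESIDUES) || length(acceptors) < 1L)
    stop_input("acceptors must be a non-empty subset of S/T/Y")
  w <- as.integer(w)
  L <- 2L * w + 1L
  if (!is.matrix(logodds) || nrow(logodds) != L || ncol(logodds) != 20L)
    stop_input("logodds must be a ", L, " x 20 matrix")
  rownames(logodds) <- as.character(seq(-w, w))
  colnames(logodds) <- AA_ALPHABET
  if (any(logodds[w + 1L, ] != 0))
    stop_input("the center row of logodds must be all zeros")
  if (any(!is.finite(logodds)))
    stop_input("logodds entries must be finite")
  if (is.null(match_midpoint))
    match_midpoint <- sum(apply(pmax(logodds, 0), 1L, max)) / 2
  if (!is.finite(match_midpoint) || !is.finite(match_slope))
    stop_input("match calibration parameters must be finite")
  if (is.null(acceptor_weights)) {
    acceptor_weights <- stats::setNames(rep(1, length(acceptors)), acceptors)
  } else {
    if (!all(names(acceptor_weights) %in% acceptors))
      stop_input("acceptor_weights must be named by acceptors")
    acceptor_weights <- acceptor_weights[acceptors]
    acceptor_weights[is.na(acceptor_weights)] <- 0
    names(acceptor_weights) <- acceptors
  }
  structure(
    list(name = name, kinase_class = kinase_class,
         acceptors = sort(unique(acceptors)), w = w, logodds = logodds,
         match_midpoint = match_midpoint, match_slope = match_slope,
         acceptor_weights = acceptor_weights / sum(acceptor_weights)),
    class = "kinase_motif_model")
}

#' @export
print.kinase_motif_model <- function(x, ...) {
  cat(sprintf("<kinase_motif_model> %s (%s), acceptors %s, w=%d, midpoint=%.2f\n",
              x$name, x$kinase_class, paste(x$acceptors, collapse = "/"),
              x$w, x$match_midpoint))
  invisible(x)
}

# Build a log-odds matrix from a sparse description:
# entries is a list of list(pos = <int>, res = <chr vector>, value = <num>).
build_logodds <- function(w, entries) {
  L <- 2L * w + 1L
  m <- matrix(0, L, 20L, dimnames = list(as.character(seq(-w, w)), AA_ALPHABET))
  for (e in entries) m[as.character(e$pos), e$res] <- e$value
  m
}

#' Default kinase motif models
#'
#' Shipped models for the eight kinases used in the motif-centric boosting
#' design: CK2 (acidophilic), PKA (basophilic), ERK2 / JNK1 / p38a / CDK1
#' (Pro-directed), and SRC / EGFR (tyrosine). The matrices encode textbook
#' consensus preferences with invented calibration magnitudes (+2 strong,
#' +1 to +1.5 weak); they are a transparent position-weight-matrix stand-in
#' for learned kinase-specificity scores, and users may replace any matrix
#' (see [read_motif_models()]).
#'
#' * CK2: D/E at +1..+3, strongest at +3.
#' * PKA: R (and weaker K) at -3 and -2.
#' * ERK2: P at +1, P at -2.
#' * JNK1: P at +1 only.
#' * p38a: P at +1 with a mild pT acceptor preference.
#' * CDK1: P at +1 plus K/R at +3.
#' * SRC: acidic context N-terminal of pY (E at -3, D at -2), I/V at -1.
#' * EGFR: acidic context flanking pY (E at -1, D/E at +1..+2).
#'
#' @param w window half-width (default 7).
#' @return named list of [kinase_motif_model] objects.
#' @export
default_kinase_models <- function(w = 7L) {
  mk <- function(name, class, acc, entries, acc_w = NULL)
    kinase_motif_model(name, class, acc, build_logodds(w, entries), w = w,
                       acceptor_weights = acc_w)
  models <- list(
    mk("CK2", "acidophilic", c("S", "T"), list(
      list(pos = 1, res = c("D", "E"), value = 1.5),
      list(pos = 2, res = c("D", "E"), value = 1.5),
      list(pos = 3, res = c("D", "E"), value = 2))),
    mk("PKA", "basophilic", c("S", "T"), list(
      list(pos = -3, res = "R", value = 2),
      list(pos = -3, res = "K", value = 1),
      list(pos = -2, res = "R", value = 2),
      list(pos = -2, res = "K", value = 1))),
    mk("ERK2", "pro_directed", c("S", "T"), list(
      list(pos = 1, res = "P", value = 2),
      list(pos = -2, res = "P", value = 1.5))),
    mk("JNK1", "pro_directed", c("S", "T"), list(
      list(pos = 1, res = "P", value = 2))),
    mk("p38a", "pro_directed", c("S", "T"), list(
      list(pos = 1, res = "P", value = 2),
      list(pos = 2, res = c("D", "E"), value = 0.5)),
      acc_w = c(S = 0.3, T = 0.7)),
    mk("CDK1", "pro_directed", c("S", "T"), list(
      list(pos = 1, res = "P", value = 2),
      list(pos = 3, res = c("K", "R"), value = 1.5))),
    mk("SRC", "tyrosine", "Y", list(
      list(pos = -3, res = "E", value = 1.5),
      list(pos = -2, res = "D", value = 1.5),
      list(pos = -1, res = c("I", "V"), value = 1))),
    mk("EGFR", "tyrosine", "Y", list(
      list(pos = -1, res = "E", value = 1.5),
      list(pos = 1, res = c("D", "E"), value = 1.5),
      list(pos = 2, res = c("D", "E"), value = 1))))
  stats::setNames(models, vapply(models, `[[`, "", "name"))
}

#' Extract a fixed-width sequence window around a phosphosite
#'
#' Returns the `2*w + 1` residue context centered on `position` (1-based).
#' Positions outside the sequence are filled with the padding symbol `"_"`,
#' so padding only ever appears in maximal runs at the two ends.
#'
#' @param sequence protein or peptide amino-acid string.
#' @param position 1-based position of the phospho-acceptor.
#' @param w half-width (default 7).
#' @return character scalar of length `2*w + 1`.
#' @export
extract_window <- function(sequence, position, w = 7L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (position < 1L || position > n)
    stop_input("position out of bounds")
  if (!chars[position] %in% ACCEPTOR_RESIDUES)
    stop_input("invalid site: residue at position ", position, " is '",
               chars[position], "', not S/T/Y")
  idx <- (position - w):(position + w)
  out <- rep(PAD_SYMBOL, length(idx))
  ok <- idx >= 1L & idx <= n
  out[ok] <- chars[idx[ok]]
  paste(out, collapse = "")
}

#' Score sequence windows against a kinase motif model
#'
#' The score is the sum over non-center positions of the model's log2-odds
#' entry for the observed residue; padding contributes 0. Windows whose
#' center residue is outside the model's acceptor set receive `-Inf` (the
#' kinase cannot phosphorylate them at all).
#'
#' @param windows character vector of windows of width `2*model$w + 1`.
#' @param model a [kinase_motif_model].
#' @return numeric vector of log2-odds scores.
#' @export
motif_score <- function(windows, model) {
  M <- window_matrix(windows)
  L <- 2L * model$w + 1L
  if (ncol(M) != L)
    stop_input("window length ", ncol(M), " does not match model width ", L)
  if (!all(M %in% c(AA_ALPHABET, PAD_SYMBOL)))
    stop_input("windows contain characters outside the residue alphabet")
  score <- numeric(nrow(M))
  center <- model$w + 1L
  for (j in seq_len(L)) {
    if (j == center) next
    r <- M[, j]
    nz <- r != PAD_SYMBOL
    if (any(nz)) score[nz] <- score[nz] + model$logodds[j, r[nz]]
  }
  score[!(M[, center] %in% model$acceptors)] <- -Inf
  score
}

#' Convert a motif score to a match probability
#'
#' Logistic calibration `plogis((score - midpoint) * slope)`; monotone
#' increasing in the score, with the `-Inf` acceptor-gated sentinel mapping
#' to exactly 0. Used by the simulator as the per-site propensity of in
#' vitro back-phosphorylation.
#'
#' @param score numeric vector of log2-odds scores (may contain `-Inf`).
#' @param model a [kinase_motif_model].
#' @return probabilities in `[0, 1]`.
#' @export
match_probability <- function(score, model) {
  p <- stats::plogis((score - model$match_midpoint) * model$match_slope)
  p[is.infinite(score) & score < 0] <- 0
  p
}

#' Assign each window to its best-matching kinase
#'
#' Scores every window against every model, keeps models whose acceptor set
#' contains the center residue and whose score strictly exceeds `floor`,
#' and returns the argmax; ties are broken by model list order. Windows with
#' no qualifying model get `NA` (class `"none"`).
#'
#' @param windows character vector of sequence windows.
#' @param models list of [kinase_motif_model] objects (equal widths).
#' @param floor minimum qualifying score (strict); default 0.
#' @return data.frame with columns `kinase`, `kinase_class`, `score`.
#' @export
assign_kinase_class <- function(windows, models, floor = 0) {
  if (length(models) < 1L) stop_input("at least one model is required")
  S <- vapply(models, function(m) motif_score(windows, m), numeric(length(windows)))
  S <- matrix(S, nrow = length(windows))
  qual <- is.finite(S) & S > floor
  S[!qual] <- -Inf
  best <- max.col(S, ties.method = "first")
  any_qual <- rowSums(qual) > 0L
  nm <- vapply(models, `[[`, "", "name")
  cls <- vapply(models, `[[`, "", "kinase_class")
  data.frame(
    kinase = ifelse(any_qual, nm[best], NA_character_),
    kinase_class = ifelse(any_qual, cls[best], "none"),
    score = ifelse(any_qual, S[cbind(seq_along(windows), best)], NA_real_),
    stringsAsFactors = FALSE)
}

#' Per-position residue probabilities implied by a motif model
#'
#' `p(residue | position)` proportional to `background * 2^(gamma * logodds)`.
#' The sharpening exponent `gamma` controls how peaked consensus sampling is
#' around the model's preferred residues (`gamma = 1` is the literal
#' odds-weighted background; the generator default 4 yields windows that are
#' reliably recognized by their own model). The center row gives the
#' acceptor-residue weights.
#'
#' @param model a [kinase_motif_model].
#' @param gamma sharpening exponent (default 4).
#' @param background named residue composition (default near-uniform human
#'   proteome composition).
#' @return `(2*w+1) x 20` row-stochastic matrix.
#' @export
motif_probability_matrix <- function(model, gamma = 4, background = HUMAN_AA_FREQ) {
  background <- background[AA_ALPHABET]
  P <- sweep(2^(gamma * model$logodds), 2L, background, `*`)
  P <- P / rowSums(P)
  center <- model$w + 1L
  P[center, ] <- 0
  P[center, names(model$acceptor_weights)] <- model$acceptor_weights
  P
}

#' Sample consensus windows from a motif model
#'
#' Draws each position independently from [motif_probability_matrix()];
#' the center residue is drawn from the model's acceptor weights. Used to
#' plant known kinase substrates in synthetic experiments.
#'
#' @inheritParams motif_probability_matrix
#' @param n number of windows.
#' @param seed integer seed.
#' @return character vector of `n` windows.
#' @export
sample_motif_windows <- function(model, n, seed, gamma = 4,
                                 background = HUMAN_AA_FREQ) {
  P <- motif_probability_matrix(model, gamma = gamma, background = background)
  withr::with_seed(seed, {
    M <- apply(P, 1L, function(p) sample(AA_ALPHABET, n, replace = TRUE, prob = p))
    M <- matrix(M, nrow = n)
    apply(M, 1L, paste, collapse = "")
  })
}

#' Sample background (non-consensus) windows
#'
#' Flanking residues are drawn i.i.d. from `background`; the center residue
#' is drawn from `center_weights` (default the pS:pT:pY = 90:10:0.05
#' phosphosite composition).
#'
#' @param n number of windows.
#' @param seed integer seed.
#' @param w half-width.
#' @param background named residue composition.
#' @param center_weights named weights over S/T/Y.
#' @return character vector of windows.
#' @export
sample_background_windows <- function(n, seed, w = 7L,
                                      background = HUMAN_AA_FREQ,
                                      center_weights = c(S = 90, T = 10, Y = 0.05)) {
  withr::with_seed(seed, {
    L <- 2L * w + 1L
    M <- matrix(sample(AA_ALPHABET, n * L, replace = TRUE,
                       prob = background[AA_ALPHABET]), nrow = n)
    M[, w + 1L] <- sample(names(center_weights), n, replace = TRUE,
                          prob = center_weights / sum(center_weights))
    apply(M, 1L, paste, collapse = "")
  })
}

#' Write motif models to a JSON file
#'
#' Sparse representation: only non-zero log-odds entries are stored.
#'
#' @param models list of [kinase_motif_model] objects.
#' @param path output path.
#' @export
write_motif_models <- function(models, path) {
  ser <- lapply(models, function(m) {
    nz <- which(m$logodds != 0, arr.ind = TRUE)
    list(name = m$name, kinase_class = m$kinase_class,
         acceptors = as.list(m$acceptors), w = m$w,
         match_midpoint = m$match_midpoint, match_slope = m$match_slope,
         acceptor_weights = as.list(m$acceptor_weights),
         logodds = lapply(seq_len(nrow(nz)), function(i) list(
           position = as.integer(rownames(m$logodds)[nz[i, 1L]]),
           residue = colnames(m$logodds)[nz[i, 2L]],
           value = m$logodds[nz[i, 1L], nz[i, 2L]])))
  })
  jsonlite::write_json(unname(ser), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read motif models from a JSON file
#'
#' @param path JSON file written by [write_motif_models()] (or hand-authored
#'   in the same sparse format).
#' @return named list of [kinase_motif_model] objects.
#' @export
read_motif_models <- function(path) {
  raw <- jsonlite::read_json(path)
  models <- lapply(raw, function(m) {
    entries <- lapply(m$logodds, function(e)
      list(pos = e$position, res = e$residue, value = e$value))
    kinase_motif_model(
      name = m$name, kinase_class = m$kinase_class,
      acceptors = unlist(m$acceptors),
      logodds = build_logodds(as.integer(m$w), entries), w = as.integer(m$w),
      match_midpoint = m$match_midpoint, match_slope = m$match_slope,
      acceptor_weights = unlist(m$acceptor_weights))
  })
  stats::setNames(models, vapply(models, `[[`, "", "name"))
}
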