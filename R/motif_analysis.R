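# Residue-frequency and enrichment analysis of phosphosite windows: logo
# matrices, kinase-class composition, pS/pT/pY content.

#' Position-specific residue frequency matrix
#'
#' Counts residues per window position, excluding padding, and normalizes
#' each position over its observed residues (so every position with at
#' least one non-padding observation has frequencies summing to 1). The
#' counts matrix and number of windows are carried alongside — this is the
#' matrix behind a sequence logo.
#'
#' @param windows character vector of equal-width sequence windows.
#' @return object of class `frequency_matrix`: list with `counts`, `freq`
#'   (`(2w+1) x 20` matrices, rows named `-w..w`), and `n_windows`.
#' @export
frequency_matrix <- function(windows) {
  if (!length(windows)) stop_input("no windows supplied")
  M <- window_matrix(windows)
  L <- ncol(M)
  w <- (L - 1L) %/% 2L
  counts <- t(vapply(seq_len(L), function(j)
    table(factor(M[, j], levels = AA_ALPHABET)), numeric(20L)))
  dimnames(counts) <- list(as.character(seq(-w, w)), AA_ALPHABET)
  tot <- rowSums(counts)
  freq <- counts / ifelse(tot > 0, tot, 1)
  structure(list(counts = counts, freq = freq, n_windows = length(windows)),
            class = "frequency_matrix")
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat(sprintf("<frequency_matrix> %d windows, width %d\n",
              x$n_windows, nrow(x$freq)))
  invisible(x)
}

#' Log2-odds enrichment matrix (foreground vs background)
#'
#' `log2((fg + pc) / (bg + pc))` per cell, with a pseudocount guarding
#' against empty cells; identical foreground and background give an all-zero
#' matrix. Suitable for enrichment-logo export.
#'
#' @param foreground a [frequency_matrix()].
#' @param background a [frequency_matrix()], or a named residue composition
#'   vector recycled across positions.
#' @param pseudocount pseudo-frequency (default 0.01).
#' @return numeric log2-odds matrix, positions x residues.
#' @export
enrichment_matrix <- function(foreground, background, pseudocount = 0.01) {
  fg <- foreground$freq
  bg <- if (inherits(background, "frequency_matrix")) {
    background$freq
  } else {
    matrix(background[colnames(fg)], nrow(fg), ncol(fg), byrow = TRUE,
           dimnames = dimnames(fg))
  }
  if (!identical(dim(fg), dim(bg)))
    stop_input("foreground and background widths differ")
  log2((fg + pseudocount) / (bg + pseudocount))
}

#' pS/pT/pY content of a site set
#'
#' @param residues character vector of phosphosite residues (S/T/Y), or a
#'   data.frame with a `residue` column.
#' @return named fractions over S, T, Y summing to 1.
#' @export
residue_content <- function(residues) {
  if (is.data.frame(residues)) residues <- residues$residue
  if (!all(residues %in% ACCEPTOR_RESIDUES))
    stop_input("residues must be S, T, or Y")
  tab <- table(factor(residues, levels = ACCEPTOR_RESIDUES))
  as.vector(tab / sum(tab)) -> f
  stats::setNames(f, ACCEPTOR_RESIDUES)
}

#' Kinase-class composition of a site set
#'
#' Assigns each window to its best-matching kinase and tallies counts per
#' kinase and per kinase class, reporting unassigned sites separately.
#'
#' @param windows character vector of sequence windows (may be empty).
#' @param models named list of [kinase_motif_model] objects.
#' @param floor score floor passed to [assign_kinase_class()].
#' @return list with `by_kinase` and `by_class` named count vectors
#'   (including `"unassigned"` / `"none"`).
#' @export
class_composition <- function(windows, models, floor = 0) {
  kin_names <- vapply(models, `[[`, "", "name")
  classes <- unique(vapply(models, `[[`, "", "kinase_class"))
  if (!length(windows)) {
    return(list(
      by_kinase = stats::setNames(rep(0L, length(kin_names) + 1L),
                                  c(kin_names, "unassigned")),
      by_class = stats::setNames(rep(0L, length(classes) + 1L),
                                 c(classes, "none"))))
  }
  asg <- assign_kinase_class(windows, models, floor = floor)
  by_kin <- table(factor(ifelse(is.na(asg$kinase), "unassigned", asg$kinase),
                         levels = c(kin_names, "unassigned")))
  by_cls <- table(factor(asg$kinase_class, levels = c(classes, "none")))
  list(by_kinase = stats::setNames(as.integer(by_kin), names(by_kin)),
       by_class = stats::setNames(as.integer(by_cls), names(by_cls)))
}

#' Write a position x residue matrix as TSV
#'
#' @param m matrix (e.g. `freq` of a [frequency_matrix()] or an
#'   [enrichment_matrix()]).
#' @param path output path.
#' @export
write_position_matrix <- function(m, path) {
  df <- data.frame(position = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
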