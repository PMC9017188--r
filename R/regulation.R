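# Inhibitor-response classification (group A/B logic) and channel-ratio
# phosphorylation-stoichiometry estimation.

#' Site key string
#'
#' Canonical `protein|position|residue` key used to match sites across
#' tables and kinases.
#' @param table data.frame with `protein_id`, `position`, `residue`.
#' @export
site_key <- function(table) {
  paste(table$protein_id, table$position, table$residue, sep = "|")
}

#' Log2-transform (and optionally median-center) reporter intensities
#'
#' Zero or missing intensities become `NA`; `median_center` additionally
#' subtracts each intensity column's median so that channel loading
#' differences are removed. The default is `"none"`, matching the minimal
#' published processing (plain log2).
#'
#' @param table site quantification table.
#' @param method `"none"` or `"median_center"`.
#' @return the table with `intensity_*` columns on the log2 scale.
#' @export
log2_transform_normalize <- function(table, method = c("none", "median_center")) {
  method <- match.arg(method)
  cols <- grep("^intensity_", names(table), value = TRUE)
  for (cl in cols) {
    v <- table[[cl]]
    v[!is.na(v) & v <= 0] <- NA
    v <- log2(v)
    table[[cl]] <- v
  }
  if (method == "median_center")
    for (cl in cols)
      table[[cl]] <- table[[cl]] - stats::median(table[[cl]], na.rm = TRUE)
  attr(table, "log2") <- TRUE
  table
}

# Vectorized equal-variance two-sample t-test over matrix rows.
# Degenerate rows (pooled variance 0) are resolved explicitly: equal means
# give t = 0, p = 1; unequal means give t = +/-Inf, p = 0.
row_t_test <- function(X1, X2) {
  n1 <- rowSums(!is.na(X1)); n2 <- rowSums(!is.na(X2))
  m1 <- rowMeans(X1, na.rm = TRUE); m2 <- rowMeans(X2, na.rm = TRUE)
  v1 <- apply(X1, 1L, stats::var, na.rm = TRUE)
  v2 <- apply(X2, 1L, stats::var, na.rm = TRUE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  est <- m1 - m2
  t <- est / se
  p <- 2 * stats::pt(-abs(t), df)
  zero_var <- !is.na(sp2) & sp2 == 0
  t[zero_var & est == 0] <- 0
  p[zero_var & est == 0] <- 1
  t[zero_var & est != 0] <- sign(est[zero_var & est != 0]) * Inf
  p[zero_var & est != 0] <- 0
  undefined <- n1 < 2L | n2 < 2L
  t[undefined] <- NA; p[undefined] <- NA
  list(ratio = est, t = t, p = p, df = df, undefined = undefined)
}

#' Two-sample ratio test on log2 observations
#'
#' Equal-variance two-sided Student t-test (the Perseus default); the ratio
#' is `mean(group1) - mean(group2)` on the log2 scale. Fewer than two
#' observations in a group gives an undefined result rather than an error;
#' zero-variance groups are handled without division errors.
#'
#' @param group1,group2 numeric vectors of log2 observations.
#' @param var_equal use the pooled-variance test (default TRUE); FALSE gives
#'   the Welch variant.
#' @return list with `ratio`, `t`, `p`, `df`, `undefined`.
#' @export
ratio_test <- function(group1, group2, var_equal = TRUE) {
  g1 <- group1[!is.na(group1)]; g2 <- group2[!is.na(group2)]
  if (length(g1) < 2L || length(g2) < 2L)
    return(list(ratio = NA_real_, t = NA_real_, p = NA_real_,
                df = NA_real_, undefined = TRUE))
  if (var_equal || (stats::var(g1) == 0 && stats::var(g2) == 0)) {
    r <- row_t_test(matrix(c(g1, rep(NA, 0)), 1L),
                    matrix(g2, 1L))
    return(list(ratio = r$ratio, t = r$t, p = r$p, df = r$df, undefined = FALSE))
  }
  tt <- stats::t.test(g1, g2, var.equal = FALSE)
  list(ratio = mean(g1) - mean(g2), t = unname(tt$statistic),
       p = tt$p.value, df = unname(tt$parameter), undefined = FALSE)
}

#' Dual TMT-ratio tests for every site
#'
#' Computes, per site, the treatment contrast (treated vs control channels)
#' and the motif contrast (boost vs treated channels) on log2 intensities,
#' pooling duplicate channels across the supplied replicate-injection
#' tables as observations. Tables are matched by site key; a site
#' contributes the observations it has.
#'
#' @param tables a site table or list of site tables (replicate injections).
#' @param design a [channel_design()].
#' @param control,treated condition names for the treatment contrast.
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @param log2 log2-transform intensities first (set FALSE if the tables are
#'   already on the log2 scale).
#' @param normalize normalization method for [log2_transform_normalize()].
#' @return data.frame with site keys, `log2_ratio_treatment`, `p_treatment`,
#'   `log2_ratio_motif`, `p_motif`, observation counts, and BH-adjusted
#'   `q_treatment` / `q_motif`.
#' @export
regulation_test <- function(tables, design, control, treated,
                            var_equal = TRUE, log2 = TRUE,
                            normalize = "none") {
  if (is.data.frame(tables)) tables <- list(tables)
  if (log2)
    tables <- lapply(tables, log2_transform_normalize, method = normalize)
  keys <- unique(unlist(lapply(tables, site_key)))
  ctrl_ch <- channels_for_condition(design, control)
  trt_ch <- channels_for_condition(design, treated)
  bst_ch <- boost_channels(design)
  gather <- function(channels) {
    cols <- paste0("intensity_", channels)
    do.call(cbind, lapply(tables, function(tb) {
      m <- matrix(NA_real_, length(keys), length(cols))
      idx <- match(site_key(tb), keys)
      m[idx, ] <- as.matrix(tb[, cols, drop = FALSE])
      m
    }))
  }
  Xc <- gather(ctrl_ch); Xt <- gather(trt_ch); Xb <- gather(bst_ch)
  if (!var_equal) {
    res_t <- lapply(seq_along(keys), function(i)
      ratio_test(Xt[i, ], Xc[i, ], var_equal = FALSE))
    res_m <- lapply(seq_along(keys), function(i)
      ratio_test(Xb[i, ], Xt[i, ], var_equal = FALSE))
    tr <- list(ratio = vapply(res_t, `[[`, 0, "ratio"),
               p = vapply(res_t, `[[`, 0, "p"))
    mo <- list(ratio = vapply(res_m, `[[`, 0, "ratio"),
               p = vapply(res_m, `[[`, 0, "p"))
  } else {
    tr <- row_t_test(Xt, Xc)
    mo <- row_t_test(Xb, Xt)
  }
  parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  data.frame(
    protein_id = parts[, 1L], position = as.integer(parts[, 2L]),
    residue = parts[, 3L],
    log2_ratio_treatment = tr$ratio, p_treatment = tr$p,
    log2_ratio_motif = mo$ratio, p_motif = mo$p,
    n_treatment_obs = rowSums(!is.na(Xt)) + rowSums(!is.na(Xc)),
    n_motif_obs = rowSums(!is.na(Xb)) + rowSums(!is.na(Xt)),
    q_treatment = stats::p.adjust(tr$p, "BH"),
    q_motif = stats::p.adjust(mo$p, "BH"),
    stringsAsFactors = FALSE)
}

#' Classify sites by inhibitor response and motif boosting
#'
#' Direction: `down` iff `p_treatment < alpha` and the treatment log2 ratio
#' is below `-min_abs_log2_ratio` (`up` symmetric), else `unchanged`.
#' Group B (inferred direct substrates): down sites whose motif contrast is
#' significant (`p_motif < alpha`) with a positive motif ratio; group A:
#' down but not B. The default `min_abs_log2_ratio = 0` applies a
#' significance-only rule (no fold-change cutoff), and raw p-values are used
#' by default; q-value columns are available for stricter workflows.
#'
#' @param results data.frame from [regulation_test()].
#' @param alpha significance level (default 0.05).
#' @param min_abs_log2_ratio minimum absolute treatment log2 ratio.
#' @param use_q classify on BH q-values instead of raw p-values.
#' @return `results` with `direction` (`up`/`down`/`unchanged`) and `group`
#'   (`A`/`B`/`none`) columns.
#' @export
classify_sites <- function(results, alpha = 0.05, min_abs_log2_ratio = 0,
                           use_q = FALSE) {
  pt <- if (use_q) results$q_treatment else results$p_treatment
  pm <- if (use_q) results$q_motif else results$p_motif
  sig_t <- !is.na(pt) & pt < alpha
  down <- sig_t & results$log2_ratio_treatment < -min_abs_log2_ratio
  up <- sig_t & results$log2_ratio_treatment > min_abs_log2_ratio
  results$direction <- ifelse(down, "down", ifelse(up, "up", "unchanged"))
  sig_m <- !is.na(pm) & pm < alpha & results$log2_ratio_motif > 0
  results$group <- ifelse(down & sig_m, "B", ifelse(down, "A", "none"))
  results
}

#' Estimate per-site phosphorylation stoichiometry
#'
#' Stoichiometry is the ratio of the endogenous-channel signal to the
#' motif-centric boost-channel signal, under the assumption of complete in
#' vitro conversion. Within each duplicate set the endogenous channel of
#' `endo_condition` is divided by that preparation's boost channel (falling
#' back to the mean of all boost channels if the set contains none); the
#' per-site estimate is the median over replicate pairs. Values above 1 are
#' clipped to 1 and flagged; a site with no usable boost signal is flagged
#' undefined.
#'
#' @param table site quantification table (linear intensities).
#' @param design a [channel_design()].
#' @param endo_condition condition whose endogenous stoichiometry is wanted.
#' @return data.frame with site keys, `condition`, `stoichiometry`,
#'   `n_replicates`, `clipped`, `undefined`.
#' @export
estimate_stoichiometry <- function(table, design, endo_condition) {
  endo_ch <- channels_for_condition(design, endo_condition)
  bst_ch <- boost_channels(design)
  ratios <- vapply(design$duplicate_sets, function(set) {
    e <- intersect(set, endo_ch)
    b <- intersect(set, bst_ch)
    if (!length(b)) b <- bst_ch
    if (!length(e)) return(rep(NA_real_, nrow(table)))
    en <- rowMeans(intensity_columns(table, e), na.rm = TRUE)
    bo <- rowMeans(intensity_columns(table, b), na.rm = TRUE)
    ifelse(!is.na(bo) & bo > 0 & !is.na(en), en / bo, NA_real_)
  }, numeric(nrow(table)))
  ratios <- matrix(ratios, nrow = nrow(table))
  est <- apply(ratios, 1L, stats::median, na.rm = TRUE)
  n_rep <- as.integer(rowSums(!is.na(ratios)))
  undefined <- n_rep == 0L
  clipped <- !is.na(est) & est > 1
  est[clipped] <- 1
  est[undefined] <- NA_real_
  data.frame(protein_id = table$protein_id, position = table$position,
             residue = table$residue, condition = endo_condition,
             stoichiometry = est, n_replicates = n_rep,
             clipped = clipped, undefined = undefined,
             stringsAsFactors = FALSE)
}

#' Cumulative stoichiometry curve
#'
#' Sorts defined stoichiometry values in ascending order and reports the
#' cumulative fraction percent at each value (`rank / n * 100`, ties sharing
#' the higher rank), the representation used to compare stoichiometry
#' distributions between conditions.
#'
#' @param estimates numeric stoichiometries, or the data.frame from
#'   [estimate_stoichiometry()].
#' @return data.frame with `stoichiometry` and `cumulative_fraction`
#'   (percent), non-decreasing in both columns; empty for empty input.
#' @export
cumulative_stoichiometry_curve <- function(estimates) {
  v <- if (is.data.frame(estimates)) estimates$stoichiometry else estimates
  v <- v[!is.na(v)]
  if (!length(v))
    return(data.frame(stoichiometry = numeric(0), cumulative_fraction = numeric(0)))
  v <- sort(v)
  cf <- rank(v, ties.method = "max") / length(v) * 100
  unique(data.frame(stoichiometry = v, cumulative_fraction = cf))
}

#' Overlap of site sets across kinases
#'
#' Exact pairwise intersection counts for Venn/upset-style summaries.
#'
#' @param site_sets named list of site-key character vectors.
#' @return list with `sizes`, `pairwise` (intersection-count matrix with set
#'   sizes on the diagonal), and `union` (total distinct sites).
#' @export
overlap_analysis <- function(site_sets) {
  site_sets <- lapply(site_sets, unique)
  k <- length(site_sets)
  m <- matrix(0L, k, k, dimnames = list(names(site_sets), names(site_sets)))
  for (i in seq_len(k)) for (j in seq_len(k))
    m[i, j] <- length(intersect(site_sets[[i]], site_sets[[j]]))
  list(sizes = vapply(site_sets, length, 0L), pairwise = m,
       union = length(unique(unlist(site_sets))))
}
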