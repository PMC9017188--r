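# Seeded synthetic motif-centric TMT experiments: proteome, tryptic digestion,
# ground-truth phosphorylation, in vitro back-phosphorylation, and
# ion-budget-limited reporter-ion acquisition.

#' Generate a random proteome
#'
#' Protein sequences are drawn i.i.d. from `composition`; lengths are
#' Poisson around `length_mean` with a floor of 30 residues. The K/R
#' frequency of the composition controls tryptic peptide lengths downstream.
#'
#' @param n_proteins number of proteins (>= 1).
#' @param length_mean mean protein length in residues.
#' @param composition named residue frequency vector over the 20 canonical
#'   residues, summing to 1 (tolerance 1e-6).
#' @param seed integer seed; output is byte-identical for a fixed seed.
#' @return data.frame with columns `id`, `sequence`.
#' @export
generate_proteome <- function(n_proteins, length_mean = 300,
                              composition = HUMAN_AA_FREQ, seed = 1L) {
  if (!is_count(n_proteins)) stop_input("n_proteins must be a positive integer")
  composition <- composition[AA_ALPHABET]
  if (any(is.na(composition)) || abs(sum(composition) - 1) > 1e-6)
    stop_input("composition must cover the 20 residues and sum to 1 (tolerance 1e-6)")
  withr::with_seed(seed, {
    lens <- pmax(30L, stats::rpois(n_proteins, length_mean))
    seqs <- vapply(lens, function(L)
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = composition),
            collapse = ""), "")
  })
  data.frame(id = sprintf("PROT%05d", seq_len(n_proteins)),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Tryptic in silico digestion
#'
#' Cleaves C-terminal to K or R; cleavage is suppressed when the following
#' residue is P (the common search-engine convention) unless
#' `kp_suppression = FALSE`. Emits every product with `0..max_missed`
#' missed cleavages, with 1-based inclusive coordinates.
#'
#' @param sequence amino-acid string (one protein).
#' @param max_missed maximum missed cleavages (default 2).
#' @param kp_suppression suppress cleavage before proline (default TRUE).
#' @param protein_id optional identifier carried into the output.
#' @return data.frame with columns `protein_id`, `start`, `end`, `sequence`,
#'   `missed_cleavages`.
#' @export
digest <- function(sequence, max_missed = 2L, kp_suppression = TRUE,
                   protein_id = NA_character_) {
  if (!nzchar(sequence)) stop_input("cannot digest an empty sequence")
  if (max_missed < 0L) stop_input("max_missed must be >= 0")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts < n]
  if (kp_suppression && length(cuts))
    cuts <- cuts[chars[cuts + 1L] != "P"]
  ends <- c(cuts, n)
  starts <- c(1L, cuts + 1L)
  k <- length(ends)
  out <- list()
  for (m in 0:min(max_missed, k - 1L)) {
    i <- seq_len(k - m)
    out[[m + 1L]] <- data.frame(
      protein_id = protein_id, start = starts[i], end = ends[i + m],
      missed_cleavages = m, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$sequence <- substring(sequence, res$start, res$end)
  res[order(res$missed_cleavages, res$start),
      c("protein_id", "start", "end", "sequence", "missed_cleavages")]
}

#' Digest every protein in a proteome
#'
#' @param proteome data.frame from [generate_proteome()] (columns `id`,
#'   `sequence`).
#' @inheritParams digest
#' @return row-bound digests of all proteins.
#' @export
digest_proteome <- function(proteome, max_missed = 2L, kp_suppression = TRUE) {
  do.call(rbind, lapply(seq_len(nrow(proteome)), function(i)
    digest(proteome$sequence[i], max_missed, kp_suppression, proteome$id[i])))
}

#' Enumerate candidate phosphosites with protein and peptide context
#'
#' Lists every S/T/Y position in the proteome together with its
#' protein-context window and its peptide-truncated window (residues outside
#' the fully cleaved tryptic peptide replaced by padding). The peptide
#' window is what a peptide-level in vitro kinase reaction "sees".
#'
#' @param proteome data.frame with `id`, `sequence`.
#' @param w window half-width.
#' @param kp_suppression passed to the zero-missed-cleavage digestion used
#'   for peptide context.
#' @return data.frame with `protein_id`, `position`, `residue`, `window`,
#'   `peptide_window`, `peptide_start`, `peptide_end`.
#' @export
phosphosite_universe <- function(proteome, w = 7L, kp_suppression = TRUE) {
  out <- lapply(seq_len(nrow(proteome)), function(i) {
    seqc <- proteome$sequence[i]
    chars <- strsplit(seqc, "", fixed = TRUE)[[1]]
    pos <- which(chars %in% ACCEPTOR_RESIDUES)
    if (!length(pos)) return(NULL)
    pep <- digest(seqc, max_missed = 0L, kp_suppression = kp_suppression)
    pidx <- findInterval(pos, pep$start)
    data.frame(
      protein_id = proteome$id[i], position = pos, residue = chars[pos],
      window = vapply(pos, function(p) extract_window(seqc, p, w), ""),
      peptide_window = vapply(seq_along(pos), function(j) {
        k <- pidx[j]
        extract_window(pep$sequence[k], pos[j] - pep$start[k] + 1L, w)
      }, ""),
      peptide_start = pep$start[pidx], peptide_end = pep$end[pidx],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Sample an endogenous phosphosite set from a site universe
#'
#' Draws `n_sites` sites whose residue composition targets the configured
#' pS:pT:pY ratio (default 90:10:0.05, the classical phosphoproteome
#' composition). If a residue class is exhausted the shortfall is filled
#' from the remaining sites.
#'
#' @param universe data.frame from [phosphosite_universe()].
#' @param n_sites number of phosphosites to draw.
#' @param residue_weights named weights over S/T/Y.
#' @param seed integer seed.
#' @return subset of `universe` rows.
#' @export
sample_phosphosites <- function(universe, n_sites,
                                residue_weights = c(S = 90, T = 10, Y = 0.05),
                                seed = 1L) {
  if (n_sites > nrow(universe)) stop_input("n_sites exceeds the site universe")
  withr::with_seed(seed, {
    want <- sample(names(residue_weights), n_sites, replace = TRUE,
                   prob = residue_weights / sum(residue_weights))
    idx <- integer(0)
    for (r in names(residue_weights)) {
      avail <- setdiff(which(universe$residue == r), idx)
      take <- min(sum(want == r), length(avail))
      if (take > 0L) idx <- c(idx, sample(avail, take))
    }
    short <- n_sites - length(idx)
    if (short > 0L)
      idx <- c(idx, sample(setdiff(seq_len(nrow(universe)), idx), short))
  })
  universe[sort(idx), , drop = FALSE]
}

#' Build a synthetic site table directly from motif models
#'
#' Convenience generator used when the full proteome-digestion path is not
#' needed: `n` sites with fabricated site keys, where a configurable number
#' of windows per kinase is planted from that kinase's consensus
#' distribution and the remainder is background. `peptide_window` equals
#' `window` (no truncation) unless edited afterwards.
#'
#' @param n total number of sites.
#' @param models named list of [kinase_motif_model] objects (needed when
#'   `planted` is non-empty).
#' @param planted named integer vector, kinase name -> number of planted
#'   consensus windows.
#' @param residue_weights center-residue weights for background windows.
#' @param seed integer seed.
#' @param w half-width.
#' @param gamma consensus sharpening passed to [sample_motif_windows()].
#' @return data.frame shaped like [phosphosite_universe()] output.
#' @export
synthetic_site_table <- function(n, models = NULL, planted = integer(0),
                                 residue_weights = c(S = 90, T = 10, Y = 0.05),
                                 seed = 1L, w = 7L, gamma = 4) {
  n_planted <- sum(planted)
  if (n_planted > n) stop_input("planted sites exceed n")
  windows <- character(0)
  for (k in names(planted)) {
    if (is.null(models[[k]])) stop_input("no model named ", k)
    windows <- c(windows, sample_motif_windows(models[[k]], planted[[k]],
                                               seed = derive_seed(seed, match(k, names(planted))),
                                               gamma = gamma))
  }
  if (n > n_planted)
    windows <- c(windows, sample_background_windows(
      n - n_planted, seed = derive_seed(seed, 1000L), w = w,
      center_weights = residue_weights))
  data.frame(
    protein_id = sprintf("SYN%05d", seq_len(n)), position = w + 1L,
    residue = substring(windows, w + 1L, w + 1L),
    window = windows, peptide_window = windows,
    peptide_start = 1L, peptide_end = 2L * w + 1L,
    stringsAsFactors = FALSE)
}

default_stoichiometry_priors <- function() {
  list(acidophilic = c(2, 8), basophilic = c(1.5, 12),
       pro_directed = c(1.5, 12), tyrosine = c(1, 40), none = c(1.2, 15))
}

#' Assign ground-truth phosphorylation state to a site set
#'
#' Each site is classified by its best motif match ([assign_kinase_class()]);
#' its true endogenous stoichiometry is drawn from a per-class Beta prior
#' whose defaults (acidophilic Beta(2,8), Pro-directed/basophilic
#' Beta(1.5,12), tyrosine Beta(1,40), unassigned Beta(1.2,15)) reproduce the
#' observed ordering acidophilic > Pro-directed > tyrosine. A site is a
#' direct substrate of a kinase when its protein-context window reaches a
#' match probability of at least `substrate_match_min` under that kinase's
#' model. When an `inhibited_kinase` is given, direct substrates of that
#' kinase have their stoichiometry multiplied by `inhibitor_effect` in the
#' `treated_condition`.
#'
#' @param sites data.frame with at least `protein_id`, `position`, `residue`,
#'   `window` (and optionally `peptide_window`).
#' @param models named list of [kinase_motif_model] objects.
#' @param conditions condition names (columns `stoich_<condition>` are
#'   emitted); default `c("control", "treated")`.
#' @param priors named list of Beta(a, b) parameter pairs per kinase class.
#' @param inhibited_kinase name of the kinase perturbed in the treated
#'   condition, or `NULL` for no perturbation.
#' @param inhibitor_effect multiplicative stoichiometry factor for direct
#'   substrates of the inhibited kinase under treatment (default 0.5).
#' @param treated_condition which condition the inhibitor acts on.
#' @param substrate_match_min match-probability threshold for the
#'   direct-substrate flag (default 0.5, the logistic midpoint).
#' @param class_floor score floor for class assignment.
#' @param seed integer seed.
#' @return the input data.frame augmented with `kinase_class`, `kinase`,
#'   `direct_substrate_of` (comma-separated), `inhibitor_effect`, and one
#'   `stoich_<condition>` column per condition.
#' @export
assign_ground_truth <- function(sites, models,
                                conditions = c("control", "treated"),
                                priors = default_stoichiometry_priors(),
                                inhibited_kinase = NULL,
                                inhibitor_effect = 0.5,
                                treated_condition = "treated",
                                substrate_match_min = 0.5,
                                class_floor = 0, seed = 1L) {
  if (!all(sites$residue %in% ACCEPTOR_RESIDUES))
    stop_input("all site residues must be S, T, or Y")
  if (!is.null(inhibited_kinase)) {
    if (!treated_condition %in% conditions)
      stop_input("unknown condition '", treated_condition, "'")
    if (!inhibited_kinase %in% names(models))
      stop_input("unknown kinase '", inhibited_kinase, "'")
  }
  cls <- assign_kinase_class(sites$window, models, floor = class_floor)
  truth <- cbind(sites, cls)
  # direct-substrate flags: match probability at/above the logistic midpoint
  subst <- vapply(models, function(m)
    match_probability(motif_score(sites$window, m), m) >= substrate_match_min,
    logical(nrow(sites)))
  subst <- matrix(subst, nrow = nrow(sites))
  truth$direct_substrate_of <- apply(subst, 1L, function(z)
    paste(names(models)[z], collapse = ","))
  withr::with_seed(seed, {
    ab <- priors[truth$kinase_class]
    base <- vapply(seq_len(nrow(truth)), function(i)
      stats::rbeta(1L, ab[[i]][1L], ab[[i]][2L]), 0)
  })
  eff <- rep(1, nrow(truth))
  if (!is.null(inhibited_kinase)) {
    hit <- vapply(strsplit(truth$direct_substrate_of, ",", fixed = TRUE),
                  function(z) inhibited_kinase %in% z, TRUE)
    eff[hit] <- inhibitor_effect
  }
  truth$inhibitor_effect <- eff
  for (cond in conditions) {
    s <- base
    if (!is.null(inhibited_kinase) && cond == treated_condition) s <- s * eff
    truth[[paste0("stoich_", cond)]] <- pmin(1, pmax(0, s))
  }
  attr(truth, "conditions") <- conditions
  truth
}

#' Simulate an in vitro kinase (back-phosphorylation) reaction
#'
#' The fraction of the previously unphosphorylated peptide pool converted by
#' the reaction is `efficiency * match_probability(score) * (1 - true
#' stoichiometry)`, so the total phospho fraction in the motif channel
#' (endogenous + back) can never exceed 1. At `level = "peptide"` the motif
#' is scored on the peptide-truncated window: basophilic motifs whose
#' required K/R lies N-terminal of the tryptic peptide boundary score at
#' background, which is why basophilic reactions must be run at the protein
#' level. Sites whose residue is outside the kinase's acceptor set return 0.
#'
#' @param truth data.frame with `window` and `peptide_window` columns plus a
#'   `stoichiometry` vector (see `stoichiometry` argument).
#' @param model the kinase used for the reaction.
#' @param efficiency reaction efficiency in `[0, 1]` (the paper's analysis
#'   assumes 1).
#' @param level `"peptide"` or `"protein"`: which sequence context the
#'   kinase sees.
#' @param stoichiometry numeric vector of true stoichiometries of the
#'   substrate pool (defaults to 0, a fully unphosphorylated pool).
#' @return numeric vector of back-phosphorylated fractions in `[0, 1]`.
#' @export
simulate_kinase_reaction <- function(truth, model, efficiency = 1,
                                     level = c("peptide", "protein"),
                                     stoichiometry = 0) {
  level <- match.arg(level)
  if (efficiency < 0 || efficiency > 1)
    stop_input("efficiency must be in [0, 1]")
  win <- if (level == "peptide") {
    truth$peptide_window %||% truth$window
  } else truth$window
  p <- match_probability(motif_score(win, model), model)
  efficiency * p * (1 - stoichiometry)
}

#' Acquisition parameters for the simulated TMT experiment
#'
#' Defaults are calibrated so that the paper's filter thresholds are
#' meaningful on synthetic data: with 25 loading units per channel a typical
#' detected site has log2 summed sample intensity around 41-45, the noise
#' floor sits near 2^35, and the summed-abundance MS1 detection threshold is
#' 2^43. The ion budget default 5e4 is the reporter-scan AGC target.
#'
#' @param ms1_detection_threshold summed-abundance detection threshold.
#' @param id_probability_slope slope of the logistic identification model in
#'   log2 summed abundance (midpoint at the detection threshold).
#' @param ion_budget expected reporter ions per MS3 scan; `Inf` disables
#'   counting noise.
#' @param noise_floor_log2_mean,noise_floor_log2_sd lognormal (log2 scale)
#'   additive noise floor; mean `-Inf` disables it.
#' @param intensity_scale abundance units per unit (stoichiometry x loading).
#' @param localization_above_cutoff fraction of sites drawn with
#'   localization probability above `localization_cutoff`.
#' @param localization_cutoff class-1 localization cutoff (default 0.75).
#' @param phospho_specificity probability a record is flagged as a true
#'   phosphopeptide (enrichment specificity; default 0.91).
#' @param multiplicative_cv optional lognormal multiplicative measurement
#'   error (coefficient of variation; default 0).
#' @param oracle if TRUE, reported intensities equal true abundances exactly
#'   (no counting noise, no noise floor, no identification loss).
#' @param seed integer seed used for every stochastic draw in
#'   [simulate_tmt_experiment()].
#' @return a list of class `acquisition_params`.
#' @export
acquisition_params <- function(ms1_detection_threshold = 2^43,
                               id_probability_slope = 1,
                               ion_budget = 5e4,
                               noise_floor_log2_mean = 35,
                               noise_floor_log2_sd = 1,
                               intensity_scale = 2^40,
                               localization_above_cutoff = 0.9,
                               localization_cutoff = 0.75,
                               phospho_specificity = 0.91,
                               multiplicative_cv = 0,
                               oracle = FALSE,
                               seed = 1L) {
  if (ion_budget <= 0) stop_input("ion_budget must be > 0")
  if (ms1_detection_threshold < 0) stop_input("ms1_detection_threshold must be >= 0")
  structure(list(
    ms1_detection_threshold = ms1_detection_threshold,
    id_probability_slope = id_probability_slope, ion_budget = ion_budget,
    noise_floor_log2_mean = noise_floor_log2_mean,
    noise_floor_log2_sd = noise_floor_log2_sd,
    intensity_scale = intensity_scale,
    localization_above_cutoff = localization_above_cutoff,
    localization_cutoff = localization_cutoff,
    phospho_specificity = phospho_specificity,
    multiplicative_cv = multiplicative_cv,
    oracle = oracle, seed = as.integer(seed)), class = "acquisition_params")
}

#' Simulate a motif-centric TMT experiment
#'
#' For every ground-truth site: (i) the true per-channel abundance is
#' `intensity_scale x loading x phospho fraction`, where the fraction is the
#' endogenous stoichiometry of the channel's condition for sample channels
#' and stoichiometry + back-phosphorylated fraction (capped at 1) for boost
#' channels; (ii) the site is detected when the summed abundance over all
#' channels exceeds the MS1 threshold, and then identified with logistic
#' probability increasing in log2 summed abundance; (iii) reporter counts
#' are sampled per channel as independent Poissons with rates
#' `ion_budget x channel share` (jointly identical to a Poisson-total
#' multinomial), rescaled back to abundance units, and channels with at
#' least one sampled ion receive an additive lognormal noise floor — a
#' channel that sampled zero ions is recorded as 0 = missing; (iv) the
#' localization probability and phosphopeptide flag are drawn independently.
#' Identical seeds give identical tables.
#'
#' @param truth data.frame from [assign_ground_truth()].
#' @param design a [channel_design()].
#' @param amounts named loading amounts per channel (all channels present,
#'   non-negative).
#' @param acq an [acquisition_params()] object.
#' @param boost_model kinase model used for the in vitro reaction feeding the
#'   boost channels.
#' @param efficiency in vitro reaction efficiency.
#' @param level `"peptide"` or `"protein"` reaction level.
#' @param boost_source_condition condition whose endogenous stoichiometry the
#'   boost material carries (default: the design's last sample condition,
#'   mirroring boost peptides made from the treated pool).
#' @param force_match_probability optional override of the motif match
#'   probability (e.g. 1 for the idealized complete-conversion reaction).
#' @param keep_all keep undetected/unidentified rows with `detected` /
#'   `identified` flag columns (default FALSE: only identified records, as
#'   in real search output).
#' @param return_counts attach the raw reporter count matrix of identified
#'   records as attribute `"reporter_counts"`.
#' @return a site quantification table: site key columns, `window`,
#'   `localization_prob`, `is_phosphopeptide`, one `intensity_<channel>`
#'   column per channel, plus attributes `design` and `conditions`.
#' @export
simulate_tmt_experiment <- function(truth, design, amounts, acq = acquisition_params(),
                                    boost_model, efficiency = 1,
                                    level = c("peptide", "protein"),
                                    boost_source_condition = NULL,
                                    force_match_probability = NULL,
                                    keep_all = FALSE, return_counts = FALSE) {
  level <- match.arg(level)
  stopifnot(inherits(design, "channel_design"))
  chans <- design$channels
  if (!setequal(names(amounts), chans))
    stop_input("amounts must be named by exactly the design channels")
  amounts <- amounts[chans]
  if (any(amounts < 0)) stop_input("loading amounts must be non-negative")
  conds <- design$condition
  sample_ch <- chans[!is.na(conds)]
  boost_ch <- chans[is.na(conds)]
  boost_source_condition <- boost_source_condition %||%
    conds[!is.na(conds)][length(sample_ch)]
  src_col <- paste0("stoich_", boost_source_condition)
  if (!src_col %in% names(truth))
    stop_input("truth lacks column ", src_col)

  n <- nrow(truth)
  src <- truth[[src_col]]
  if (is.null(force_match_probability)) {
    back <- simulate_kinase_reaction(truth, boost_model, efficiency, level,
                                     stoichiometry = src)
  } else {
    back <- efficiency * force_match_probability * (1 - src)
  }
  frac <- matrix(0, n, length(chans), dimnames = list(NULL, chans))
  for (ch in sample_ch)
    frac[, ch] <- truth[[paste0("stoich_", conds[ch])]]
  for (ch in boost_ch)
    frac[, ch] <- pmin(1, src + back)
  A <- sweep(frac, 2L, amounts, `*`) * acq$intensity_scale
  total <- rowSums(A)
  detected <- total > acq$ms1_detection_threshold

  withr::with_seed(acq$seed, {
    if (acq$oracle) {
      identified <- detected
      intens <- A
    } else {
      p_id <- stats::plogis(acq$id_probability_slope *
                              (log2(pmax(total, .Machine$double.xmin)) -
                                 log2(acq$ms1_detection_threshold)))
      identified <- detected & stats::runif(n) < p_id
      share <- A / pmax(total, .Machine$double.xmin)
      if (is.infinite(acq$ion_budget)) {
        intens <- A
        observed <- intens > 0
      } else {
        counts <- matrix(stats::rpois(n * length(chans), acq$ion_budget * share),
                         n, length(chans), dimnames = list(NULL, chans))
        observed <- counts > 0
        intens <- counts * (total / acq$ion_budget)
      }
      if (acq$multiplicative_cv > 0) {
        sdlog <- sqrt(log(1 + acq$multiplicative_cv^2))
        noise <- matrix(stats::rlnorm(n * length(chans), -sdlog^2 / 2, sdlog),
                        n, length(chans))
        intens <- intens * noise
      }
      if (is.finite(acq$noise_floor_log2_mean)) {
        floor_i <- matrix(2^stats::rnorm(n * length(chans),
                                         acq$noise_floor_log2_mean,
                                         acq$noise_floor_log2_sd),
                          n, length(chans))
        intens <- ifelse(observed, intens + floor_i, 0)
      } else {
        intens <- ifelse(observed, intens, 0)
      }
    }
    hi <- stats::runif(n) < acq$localization_above_cutoff
    loc <- ifelse(hi,
                  stats::runif(n, acq$localization_cutoff, 1),
                  stats::runif(n, 0, acq$localization_cutoff))
    is_phos <- stats::runif(n) < acq$phospho_specificity
  })

  out <- data.frame(protein_id = truth$protein_id, position = truth$position,
                    residue = truth$residue, window = truth$window,
                    localization_prob = loc, is_phosphopeptide = is_phos,
                    stringsAsFactors = FALSE)
  colnames(intens) <- paste0("intensity_", chans)
  out <- cbind(out, as.data.frame(intens))
  if (keep_all) {
    out$detected <- detected
    out$identified <- identified
    keep <- rep(TRUE, n)
  } else {
    keep <- identified
  }
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "design") <- design
  attr(res, "conditions") <- unique(conds[!is.na(conds)])
  if (return_counts && !acq$oracle && !is.infinite(acq$ion_budget))
    attr(res, "reporter_counts") <- counts[keep, , drop = FALSE]
  res
}
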