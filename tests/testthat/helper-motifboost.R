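# Shared fixtures, all built in code.

# 15-mer window with the given center residue and uniform flank.
flat_window <- function(center = "S", flank = "A", w = 7L) {
  paste0(strrep(flank, w), center, strrep(flank, w))
}

# Boost-titration design: four sample channels of one condition plus one
# boost channel (the carrier-amount experiment layout).
titration_design <- function() {
  channel_design(
    channels = c("126", "127", "128", "129", "131"),
    condition = c("HeLa", "HeLa", "HeLa", "HeLa", NA),
    duplicate_sets = list(p1 = c("126", "127"), p2 = c("128", "129")))
}

# Randomized site quantification records spanning the filter thresholds,
# with zero (missing) and NA cells mixed in.
random_site_records <- function(n, design, seed) {
  withr::with_seed(seed, {
    ch <- design$channels
    k <- length(ch)
    m <- matrix(2^stats::runif(n * k, 30, 46), n, k)
    m[matrix(stats::runif(n * k) < 0.25, n, k)] <- 0
    m[matrix(stats::runif(n * k) < 0.05, n, k)] <- NA
    colnames(m) <- paste0("intensity_", ch)
    df <- data.frame(
      protein_id = sprintf("P%05d", seq_len(n)), position = 10L,
      residue = "S", window = flat_window(),
      localization_prob = stats::runif(n),
      is_phosphopeptide = stats::runif(n) < 0.91,
      stringsAsFactors = FALSE)
    cbind(df, as.data.frame(m))
  })
}

# Equal loading amounts for every channel of a design.
equal_amounts <- function(design, amount = 25) {
  stats::setNames(rep(amount, length(design$channels)), design$channels)
}

# Quiet acquisition settings: no counting noise, no noise floor, everything
# above threshold identified; optional multiplicative measurement error.
quiet_acq <- function(seed, cv = 0, threshold = 0) {
  acquisition_params(ms1_detection_threshold = threshold, ion_budget = Inf,
                     noise_floor_log2_mean = -Inf, multiplicative_cv = cv,
                     seed = seed)
}
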