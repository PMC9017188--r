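# Channel design, the acceptance-criteria filters, and summary metrics on
# site quantification tables.

#' Describe a TMT channel design
#'
#' Maps channel labels to roles: a sample channel carries one condition's
#' endogenous peptides, a boost channel (condition `NA`) carries the
#' motif-centric back-phosphorylated material. `duplicate_sets` partitions
#' the channels into preparation replicates; every sample channel must
#' appear in exactly one set. Channel labels are strings and are never
#' parsed as numbers.
#'
#' @param channels ordered channel labels, e.g. `c("126", ..., "131")`.
#' @param condition character vector (same length/order as `channels`) of
#'   condition names, `NA` for boost channels.
#' @param duplicate_sets named list of channel-label vectors partitioning
#'   the sample channels into replicate groups (boost channels may be
#'   included in their preparation's set).
#' @param denominator_channels optional sample channels used as the boost
#'   ratio denominator (default: all sample channels).
#' @return object of class `channel_design`.
#' @export
channel_design <- function(channels, condition, duplicate_sets = NULL,
                           denominator_channels = NULL) {
  channels <- as.character(channels)
  if (length(condition) != length(channels))
    stop_input("condition must have one entry per channel")
  condition <- stats::setNames(as.character(condition), channels)
  sample_ch <- channels[!is.na(condition)]
  boost_ch <- channels[is.na(condition)]
  if (length(boost_ch) < 1L) stop_input("at least one boost channel is required")
  if (length(sample_ch) < 2L) stop_input("at least two sample channels are required")
  if (is.null(duplicate_sets)) duplicate_sets <- list(all = sample_ch)
  covered <- unlist(duplicate_sets, use.names = FALSE)
  if (!setequal(intersect(covered, sample_ch), sample_ch) ||
      anyDuplicated(covered))
    stop_input("duplicate_sets must cover every sample channel exactly once")
  if (!all(covered %in% channels))
    stop_input("duplicate_sets refer to unknown channels")
  denominator_channels <- denominator_channels %||% sample_ch
  if (!all(denominator_channels %in% sample_ch))
    stop_input("denominator_channels must be sample channels")
  structure(list(channels = channels, condition = condition,
                 duplicate_sets = duplicate_sets,
                 denominator_channels = denominator_channels),
            class = "channel_design")
}

#' @export
print.channel_design <- function(x, ...) {
  role <- ifelse(is.na(x$condition), "boost", x$condition)
  cat("<channel_design>\n")
  cat(paste0("  ", x$channels, ": ", role, collapse = "\n"), "\n")
  invisible(x)
}

#' Sample channels of a design
#' @param design a [channel_design()].
#' @export
sample_channels <- function(design) design$channels[!is.na(design$condition)]

#' Boost channels of a design
#' @param design a [channel_design()].
#' @export
boost_channels <- function(design) design$channels[is.na(design$condition)]

#' Channels assigned to a condition
#' @param design a [channel_design()].
#' @param condition a condition name.
#' @export
channels_for_condition <- function(design, condition) {
  ch <- design$channels[!is.na(design$condition) & design$condition == condition]
  if (!length(ch)) stop_input("no channels for condition '", condition, "'")
  ch
}

#' The 6-plex CK2 inhibitor design
#'
#' DMSO in 126/129, CK2-inhibitor in 127/130, CK2 motif-centric boost in
#' 128/131, duplicate preparations (126-128) and (129-131).
#' @export
ck2_design <- function() {
  channel_design(
    channels = as.character(126:131),
    condition = c("DMSO", "CKi", NA, "DMSO", "CKi", NA),
    duplicate_sets = list(prep1 = as.character(126:128),
                          prep2 = as.character(129:131)))
}

intensity_columns <- function(table, channels) {
  cols <- paste0("intensity_", channels)
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop_input("table lacks intensity columns for channels: ",
               paste(sub("^intensity_", "", miss), collapse = ", "))
  as.matrix(table[, cols, drop = FALSE])
}

#' Boost ratio of each record
#'
#' Mean boost-channel intensity divided by the mean intensity of the
#' designated denominator sample channels (all sample channels unless the
#' design names specific ones, as in the pY design where the ratio is the
#' 131 signal over the average of 127 and 129). Undefined (NA, not an
#' error) when the denominator mean is 0.
#'
#' @param table site quantification table with `intensity_<channel>` columns.
#' @param design a [channel_design()].
#' @return numeric vector, `NA` where undefined.
#' @export
boost_ratio <- function(table, design) {
  num <- rowMeans(intensity_columns(table, boost_channels(design)))
  den <- rowMeans(intensity_columns(table, design$denominator_channels))
  ifelse(den > 0, num / den, NA_real_)
}

#' Count channels with a valid (positive) intensity
#'
#' Missing intensities are encoded as 0 (or NA); both are invalid.
#'
#' @param table site quantification table.
#' @param channels channel labels to count over.
#' @return integer vector of valid-channel counts.
#' @export
count_valid_channels <- function(table, channels) {
  if (!length(channels)) return(integer(nrow(table)))
  m <- intensity_columns(table, channels)
  as.integer(rowSums(!is.na(m) & m > 0))
}

#' Acceptance-criteria thresholds
#'
#' The three published criteria plus the class-1 localization filter: boost
#' ratio strictly less than `boost_ratio_max` (default 100), log2 of the
#' summed sample-channel intensity strictly greater than
#' `log2_total_sample_intensity_min` (default 40), and at least
#' `min_valid_channels` valid reporter values — within at least one
#' duplicate set when `require_valid_in_one_duplicate_set` (the multi-kinase
#' rule), otherwise across all sample channels (the quantifiable-site
#' definition). All inequalities are strict, matching the published wording.
#'
#' @param boost_ratio_max maximum boost ratio (strict).
#' @param log2_total_sample_intensity_min log2 intensity floor (strict).
#' @param min_valid_channels minimum valid reporter channels.
#' @param require_valid_in_one_duplicate_set apply the per-duplicate-set rule.
#' @param class1_min_localization class-1 localization cutoff (strict).
#' @param apply_class1 include the localization filter in the overall pass.
#' @return object of class `filter_criteria`.
#' @export
filter_criteria <- function(boost_ratio_max = 100,
                            log2_total_sample_intensity_min = 40,
                            min_valid_channels = 2L,
                            require_valid_in_one_duplicate_set = TRUE,
                            class1_min_localization = 0.75,
                            apply_class1 = TRUE) {
  if (boost_ratio_max <= 0 || log2_total_sample_intensity_min <= 0 ||
      min_valid_channels <= 0 || class1_min_localization <= 0)
    stop_input("all thresholds must be positive")
  structure(list(boost_ratio_max = boost_ratio_max,
                 log2_total_sample_intensity_min = log2_total_sample_intensity_min,
                 min_valid_channels = as.integer(min_valid_channels),
                 require_valid_in_one_duplicate_set = isTRUE(require_valid_in_one_duplicate_set),
                 class1_min_localization = class1_min_localization,
                 apply_class1 = isTRUE(apply_class1)),
            class = "filter_criteria")
}

#' Apply the acceptance criteria to a site table
#'
#' Adds independent, auditable pass/fail flags per criterion and an overall
#' flag. A record passes overall iff (a) its boost ratio is defined and
#' strictly below the maximum, (b) the log2 summed sample intensity strictly
#' exceeds the floor, (c) the valid-channel rule holds, and (d) — when
#' class-1 filtering is requested — the localization probability strictly
#' exceeds the cutoff.
#'
#' @param table site quantification table.
#' @param design a [channel_design()].
#' @param criteria a [filter_criteria()].
#' @return `table` with columns `boost_ratio`, `pass_boost_ratio`,
#'   `pass_intensity`, `pass_valid_channels`, `pass_localization`,
#'   `pass_all`.
#' @export
apply_acceptance_criteria <- function(table, design, criteria = filter_criteria()) {
  stopifnot(inherits(design, "channel_design"))
  samp <- intensity_columns(table, sample_channels(design))
  br <- boost_ratio(table, design)
  pass_br <- !is.na(br) & br < criteria$boost_ratio_max
  total <- rowSums(samp, na.rm = TRUE)
  pass_int <- log2(pmax(total, .Machine$double.xmin)) >
    criteria$log2_total_sample_intensity_min
  if (criteria$require_valid_in_one_duplicate_set) {
    per_set <- vapply(design$duplicate_sets, function(set)
      count_valid_channels(table, intersect(set, sample_channels(design))),
      integer(nrow(table)))
    per_set <- matrix(per_set, nrow = nrow(table))
    pass_valid <- rowSums(per_set >= criteria$min_valid_channels) > 0L
  } else {
    pass_valid <- count_valid_channels(table, sample_channels(design)) >=
      criteria$min_valid_channels
  }
  pass_loc <- if (criteria$apply_class1) {
    !is.na(table$localization_prob) &
      table$localization_prob > criteria$class1_min_localization
  } else rep(TRUE, nrow(table))
  table$boost_ratio <- br
  table$pass_boost_ratio <- pass_br
  table$pass_intensity <- pass_int
  table$pass_valid_channels <- pass_valid
  table$pass_localization <- pass_loc
  table$pass_all <- pass_br & pass_int & pass_valid & pass_loc
  table
}

#' Attrition counts per acceptance criterion
#'
#' @param filtered output of [apply_acceptance_criteria()].
#' @return data.frame of per-criterion pass counts plus input and overall.
#' @export
attrition_summary <- function(filtered) {
  data.frame(
    stage = c("input", "boost_ratio", "intensity", "valid_channels",
              "localization", "all"),
    passing = c(nrow(filtered), sum(filtered$pass_boost_ratio),
                sum(filtered$pass_intensity), sum(filtered$pass_valid_channels),
                sum(filtered$pass_localization), sum(filtered$pass_all)))
}

#' Phosphopeptide enrichment specificity
#'
#' Fraction of records flagged as phosphopeptides (the published benchmark
#' reports 91% for IMAC enrichment).
#'
#' @param table site table with an `is_phosphopeptide` column.
#' @return fraction in `[0, 1]`, or `NA` for an empty table.
#' @export
enrichment_specificity <- function(table) {
  if (nrow(table) == 0L) return(NA_real_)
  mean(table$is_phosphopeptide)
}

#' Locate the signal/noise notch in a log2 intensity distribution
#'
#' Estimates a kernel density (Gaussian kernel, Silverman's `nrd0`
#' bandwidth), finds the interior local maxima, and returns the position of
#' the deepest local minimum between the two tallest modes — the "notch"
#' that separates the reporter-noise population from genuine signal. For a
#' unimodal density there is no notch and `NA` is returned.
#'
#' @param log2_intensities numeric sample (>= 100 values recommended).
#' @param bw bandwidth specification passed to [stats::density()].
#' @param n_grid density grid size.
#' @return the threshold (log2 units), or `NA_real_` when unimodal.
#' @export
intensity_notch_threshold <- function(log2_intensities, bw = "nrd0", n_grid = 512L) {
  x <- log2_intensities[is.finite(log2_intensities)]
  if (length(x) < 2L) return(NA_real_)
  d <- stats::density(x, bw = bw, n = n_grid)
  y <- d$y
  i <- 2:(length(y) - 1L)
  maxima <- i[y[i] > y[i - 1L] & y[i] >= y[i + 1L]]
  if (length(maxima) < 2L) return(NA_real_)
  top2 <- maxima[order(y[maxima], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- i[i > lo & i < hi & y[i] < y[i - 1L] & y[i] <= y[i + 1L]]
  if (!length(between)) return(NA_real_)
  d$x[between[which.min(y[between])]]
}
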