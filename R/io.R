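# Table formats, FASTA, configuration, and manifests.

SITE_TABLE_HEADER <- "# motifboost site table v1"
TRUTH_TABLE_HEADER <- "# motifboost ground truth v1"

#' Write a site quantification table
#'
#' Tab-separated with a versioned header comment; intensities in linear
#' abundance units, missing encoded as 0.
#'
#' @param table site quantification table.
#' @param path output path.
#' @export
write_site_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SITE_TABLE_HEADER, con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Convert named columns of a character data.frame to numeric, reporting the
# first malformed cell with its row and column.
convert_numeric <- function(df, cols, path) {
  for (cl in cols) {
    raw <- df[[cl]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw) & raw != "" & toupper(raw) != "NA")
    if (length(bad))
      stop_input("non-numeric value '", raw[bad[1L]], "' in column '", cl,
                 "', row ", bad[1L], " of ", path)
    df[[cl]] <- v
  }
  df
}

#' Read a site quantification table
#'
#' Reads the native tab-separated dialect, or — given a `column_map` — a
#' subset of MaxQuant "Phospho (STY)Sites" columns (see
#' [maxquant_column_map()]). Zero intensities are kept as 0 and treated as
#' missing by the filters; malformed numeric cells are reported with their
#' row and column.
#'
#' @param path input path.
#' @param column_map optional mapping, as built by [maxquant_column_map()];
#'   `NULL` reads the native dialect.
#' @return a site quantification table.
#' @export
read_site_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    required <- c(column_map$protein_id, column_map$position,
                  column_map$residue, column_map$window,
                  column_map$localization_prob, names(column_map$intensities))
    miss <- setdiff(required, names(df))
    if (length(miss))
      stop_input("missing required column(s): ", paste(miss, collapse = ", "),
                 "; available: ", paste(names(df), collapse = ", "))
    out <- data.frame(protein_id = df[[column_map$protein_id]],
                      position = df[[column_map$position]],
                      residue = df[[column_map$residue]],
                      window = df[[column_map$window]],
                      localization_prob = df[[column_map$localization_prob]],
                      stringsAsFactors = FALSE)
    for (cn in names(column_map$intensities))
      out[[paste0("intensity_", column_map$intensities[[cn]])]] <- df[[cn]]
    df <- out
  }
  req <- c("protein_id", "position", "residue", "window", "localization_prob")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_input("missing required column(s): ", paste(miss, collapse = ", "))
  num_cols <- c("position", "localization_prob",
                grep("^intensity_", names(df), value = TRUE))
  df <- convert_numeric(df, num_cols, path)
  df$position <- as.integer(df$position)
  if ("is_phosphopeptide" %in% names(df))
    df$is_phosphopeptide <- as.logical(df$is_phosphopeptide)
  df
}

#' Column mapping for MaxQuant-style site tables
#'
#' Maps the documented subset of MaxQuant "Phospho (STY)Sites" columns
#' (`Protein`, `Position`, `Amino acid`, `Sequence window`,
#' `Localization prob`, `Reporter intensity 0..k-1`) onto the native
#' dialect, with reporter columns assigned to `channels` in order.
#'
#' @param channels channel labels in reporter-column order.
#' @return a column map for [read_site_table()].
#' @export
maxquant_column_map <- function(channels) {
  list(protein_id = "Protein", position = "Position", residue = "Amino acid",
       window = "Sequence window", localization_prob = "Localization prob",
       intensities = stats::setNames(as.character(channels),
                                     paste("Reporter intensity",
                                           seq_along(channels) - 1L)))
}

#' Write / read a ground-truth table
#'
#' @param truth data.frame from [assign_ground_truth()].
#' @param path file path.
#' @export
write_truth_table <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(TRUTH_TABLE_HEADER, con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  df
}

#' Write a proteome to FASTA
#'
#' @param proteome data.frame with `id`, `sequence`.
#' @param path output path.
#' @export
write_proteome_fasta <- function(proteome, path) {
  ss <- Biostrings::AAStringSet(stats::setNames(proteome$sequence, proteome$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a proteome from FASTA
#'
#' @param path FASTA path.
#' @return data.frame with `id`, `sequence`.
#' @export
read_proteome_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  data.frame(id = names(ss), sequence = as.character(ss),
             stringsAsFactors = FALSE, row.names = NULL)
}

RUN_CONFIG_KEYS <- c("seed", "design", "acquisition", "criteria",
                     "simulation", "analysis")

#' Assemble a run configuration
#'
#' A run configuration collects everything [run_pipeline()] needs: the
#' channel design, acquisition parameters, filter criteria, simulation
#' parameters, and analysis parameters. Unknown keys are rejected, and the
#' configuration round-trips through JSON unchanged.
#'
#' @param seed master integer seed for the whole run.
#' @param design a [channel_design()].
#' @param acquisition an [acquisition_params()].
#' @param criteria a [filter_criteria()].
#' @param simulation list: `n_sites`, `planted` (named counts), `amounts`
#'   (named per channel), `efficiency`, `level`, `boost_kinase`,
#'   `inhibited_kinase`, `inhibitor_effect`, `residue_weights`.
#' @param analysis list: `control`, `treated`, `alpha`, `normalize`,
#'   `endo_condition`.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, design = ck2_design(),
                       acquisition = acquisition_params(),
                       criteria = filter_criteria(),
                       simulation = list(), analysis = list()) {
  sim_defaults <- list(n_sites = 2000L, planted = c(CK2 = 200L),
                       amounts = NULL, efficiency = 1, level = "peptide",
                       boost_kinase = "CK2", inhibited_kinase = "CK2",
                       inhibitor_effect = 0.5,
                       residue_weights = c(S = 90, T = 10, Y = 0.05))
  ana_defaults <- list(control = "DMSO", treated = "CKi", alpha = 0.05,
                       normalize = "none", endo_condition = "DMSO")
  bad <- setdiff(names(simulation), names(sim_defaults))
  if (length(bad)) stop_input("unknown simulation key(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(analysis), names(ana_defaults))
  if (length(bad)) stop_input("unknown analysis key(s): ", paste(bad, collapse = ", "))
  simulation <- utils::modifyList(sim_defaults, simulation)
  analysis <- utils::modifyList(ana_defaults, analysis)
  if (is.null(simulation$amounts))
    simulation$amounts <- stats::setNames(rep(25, length(design$channels)),
                                          design$channels)
  structure(list(seed = as.integer(seed), design = design,
                 acquisition = acquisition, criteria = criteria,
                 simulation = simulation, analysis = analysis),
            class = "run_config")
}

#' Write / read a run configuration (JSON)
#'
#' @param config a [run_config()].
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  ser <- list(
    seed = config$seed,
    design = list(channels = as.list(config$design$channels),
                  condition = as.list(config$design$condition),
                  duplicate_sets = lapply(config$design$duplicate_sets, as.list),
                  denominator_channels = as.list(config$design$denominator_channels)),
    acquisition = unclass(config$acquisition),
    criteria = unclass(config$criteria),
    simulation = config$simulation,
    analysis = config$analysis)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path)
  bad <- setdiff(names(raw), RUN_CONFIG_KEYS)
  if (length(bad))
    stop_input("unknown config key(s): ", paste(bad, collapse = ", "))
  des <- raw$design
  cond <- unlist(lapply(des$condition, function(x) if (is.null(x)) NA_character_ else x))
  design <- channel_design(
    channels = unlist(des$channels), condition = cond,
    duplicate_sets = lapply(des$duplicate_sets, unlist),
    denominator_channels = unlist(des$denominator_channels))
  acq <- do.call(acquisition_params, raw$acquisition[
    setdiff(names(raw$acquisition), character(0))])
  crit <- do.call(filter_criteria, raw$criteria)
  sim <- raw$simulation
  sim$planted <- unlist(sim$planted)
  sim$amounts <- unlist(sim$amounts)
  sim$residue_weights <- unlist(sim$residue_weights)
  if (!is.null(sim$n_sites)) sim$n_sites <- as.integer(sim$n_sites)
  if (!is.null(sim$planted)) storage.mode(sim$planted) <- "integer"
  run_config(seed = raw$seed, design = design, acquisition = acq,
             criteria = crit, simulation = sim,
             analysis = lapply(raw$analysis, function(x) x))
}

#' Run manifest
#'
#' @param config a [run_config()].
#' @param counts named record counts per stage.
#' @return manifest list (version, config hash, seed, counts, timestamp).
#' @keywords internal
build_manifest <- function(config, counts) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  list(package = "motifboost",
       version = as.character(utils::packageVersion("motifboost")),
       seed = config$seed,
       config_hash = fnv1a_hash(readLines(tmp)),
       record_counts = as.list(counts),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
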