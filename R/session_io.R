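SCHEMA_VERSION <- "1.0"
REQUIRED_TABLES <- c("blocks", "trials", "units", "spikes", "waveforms")
OPTIONAL_TABLES <- c("pe_events", "unit_labels", "difference_scores",
                     "score_summaries", "anova_results")
TIME_COLS <- c("trial_light_on", "odor_on", "odor_off", "well_entry",
               "drop_1", "drop_2", "drop_3", "reaction_time", "time")

#' Validate a session object
#'
#' Checks referential integrity (every spike's unit exists, every trial's
#' block exists), spike-time ordering and range, and the presence of the
#' required tables. Errors list the offending rows.
#'
#' @param session A `vta_session`.
#' @return The session, invisibly.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "vta_session"))
  for (tb in REQUIRED_TABLES)
    if (is.null(session[[tb]])) stop("missing table: ", tb, call. = FALSE)
  if (is.null(session$meta$schema_version))
    stop("missing schema version", call. = FALSE)
  bad <- which(!(session$spikes$unit_id %in% session$units$unit_id))
  if (length(bad))
    stop("spikes reference unknown unit_id at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  bad <- which(!(session$trials$block_id %in% session$blocks$block_id))
  if (length(bad))
    stop("trials reference unknown block_id at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  bad <- which(!(session$waveforms$unit_id %in% session$units$unit_id))
  if (length(bad))
    stop("waveforms reference unknown unit_id at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  if (nrow(session$spikes) && any(session$spikes$time < 0))
    stop("negative spike times", call. = FALSE)
  invisible(session)
}

round_times <- function(df) {
  for (cc in intersect(TIME_COLS, names(df)))
    df[[cc]] <- round(df[[cc]], 6)
  if ("voltage" %in% names(df)) df$voltage <- round(df$voltage, 6)
  df
}

#' Write a session bundle
#'
#' Serializes a session to a directory of plain-text tables (comma-separated,
#' header row, UTF-8) plus a `metadata.json` carrying the schema version,
#' seeds, preset and configuration snapshot. Times are written as float
#' seconds from session start with 6 decimal places; spike rows are sorted by
#' unit then time. Output bytes are deterministic given the session.
#'
#' @param session A `vta_session`.
#' @param path Bundle directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(session$meta,
                       file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  sp <- session$spikes
  if (nrow(sp)) sp <- sp[order(sp$unit_id, sp$time), , drop = FALSE]
  tabs <- c(REQUIRED_TABLES, intersect(OPTIONAL_TABLES, names(session)))
  for (tb in tabs) {
    df <- if (tb == "spikes") sp else as.data.frame(session[[tb]])
    utils::write.csv(round_times(df), file.path(path, paste0(tb, ".csv")),
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a session bundle
#'
#' Reads and validates a bundle written by [write_session()]. An unsupported
#' schema version, a missing required table, or a referential-integrity
#' failure raises a structured error; unknown extra columns are preserved
#' with a warning.
#'
#' @param path Bundle directory.
#' @return A `vta_session`.
#' @export
read_session <- function(path) {
  mfile <- file.path(path, "metadata.json")
  if (!file.exists(mfile)) stop("missing table: metadata.json", call. = FALSE)
  meta <- jsonlite::read_json(mfile, simplifyVector = TRUE)
  if (is.null(meta$schema_version) ||
      !identical(as.character(meta$schema_version), SCHEMA_VERSION))
    stop("unsupported schema version: ",
         if (is.null(meta$schema_version)) "<absent>" else meta$schema_version,
         " (supported: ", SCHEMA_VERSION, ")", call. = FALSE)
  known_cols <- list(
    blocks = c("block_id", "shift_type", "length", "left_flavor",
               "left_drops", "right_flavor", "right_drops"),
    trials = c("trial_id", "block_id", "odor", "chosen_well", "correct",
               "reaction_time", "rewarded", "outcome_flavor", "outcome_drops",
               TIME_COLS),
    units = c("unit_id", "ground_truth_class", "reward_modulated",
              "baseline_rate", "gain_scale"),
    spikes = c("unit_id", "time"),
    waveforms = c("unit_id", "sample_index", "voltage")
  )
  out <- list(meta = meta)
  for (tb in REQUIRED_TABLES) {
    f <- file.path(path, paste0(tb, ".csv"))
    if (!file.exists(f)) stop("missing table: ", tb, call. = FALSE)
    df <- utils::read.csv(f, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    extra <- setdiff(names(df), known_cols[[tb]])
    if (length(extra))
      warning("table ", tb, " has unknown column(s) ",
              paste(extra, collapse = ", "), "; preserved", call. = FALSE)
    out[[tb]] <- df
  }
  for (tb in OPTIONAL_TABLES) {
    f <- file.path(path, paste0(tb, ".csv"))
    if (file.exists(f))
      out[[tb]] <- utils::read.csv(f, stringsAsFactors = FALSE,
                                   fileEncoding = "UTF-8")
  }
  if (nrow(out$spikes))
    out$spikes <- out$spikes[order(out$spikes$unit_id, out$spikes$time), ,
                             drop = FALSE]
  rownames(out$spikes) <- NULL
  session <- structure(out, class = "vta_session")
  validate_session(session)
  session
}

#' @export
print.vta_session <- function(x, ...) {
  cat("<vta_session> preset:", x$meta$preset %||% "?",
      "| blocks:", nrow(x$blocks),
      "| trials:", nrow(x$trials),
      "| units:", nrow(x$units),
      "| spikes:", nrow(x$spikes), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
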