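#' Write a session or epoch set to the native container
#'
#' The native container is a serialized R object (RDS): a single hierarchical
#' binary file holding the signal tensor, sampling rate, event table, grid
#' and montage, with a format tag so [read_session()] can validate it.
#' Round-trips are bit-exact. EDF is supported for raw ingestion only
#' ([read_edf()]) because it carries no epoch or paradigm semantics.
#'
#' @param x a [speller_session()] or [epoch_set()].
#' @param path output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_session <- function(x, path) {
  check_that(inherits(x, "speller_session") || inherits(x, "epoch_set"),
             "x must be a speller_session or epoch_set")
  obj <- list(format = "plcvrfe-session", version = 1L, payload = x)
  saveRDS(obj, path)
  invisible(path)
}

#' Read a speller session from disk
#'
#' Dispatches on file content: the package's native container (see
#' [write_session()]) is read back directly; an EDF file plus an event table
#' is assembled into a [speller_session()]. Extra channels in an EDF are
#' kept in file order.
#'
#' @param path native container (`.rds`) or EDF file.
#' @param event_table for EDF input: delimited text with columns
#'   `onset` (seconds), `code`, `is_target`, `block`, `repetition`.
#' @param target_characters for EDF input: one intended character per block
#'   (defaults to placeholder `"?"` entries when unknown).
#' @return a [speller_session()] or [epoch_set()] (native container only).
#' @export
read_session <- function(path, event_table = NULL, target_characters = NULL) {
  check_that(file.exists(path), "no such file: %s", path)
  if (is_edf_file(path)) {
    check_that(!is.null(event_table), "EDF input requires an event_table")
    edf <- read_edf(path)
    ev <- read_event_table(event_table)
    ev <- validate_events(ev, duration_s = ncol(edf$signals) / edf$fs)
    n_blocks <- length(unique(ev$block))
    if (is.null(target_characters)) target_characters <- rep("?", n_blocks)
    return(speller_session(edf$signals, edf$fs, ev, edf$montage, target_characters))
  }
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("'%s' is neither an EDF file nor a native container", path),
         call. = FALSE))
  check_that(is.list(obj) && identical(obj$format, "plcvrfe-session"),
             "'%s' is not a plcvrfe session container", path)
  obj$payload
}

#' Read a stimulus event table from delimited text
#'
#' @param path tab- or comma-delimited text with a header row and columns
#'   `onset`, `code`, `is_target`, `block`, `repetition`.
#' @return a validated event data frame.
#' @export
read_event_table <- function(path) {
  check_that(file.exists(path), "no such file: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  ev <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_events(ev)
}

#' Write a stimulus event table
#'
#' @param events event data frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  events <- validate_events(events)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a channel rank list
#'
#' Delimited text with columns `rank` (1 = most important), `label` and
#' optionally `weight`; parseable back with [read_rank_list()].
#'
#' @param ranks character vector of channel labels, best-ranked first; must
#'   be a permutation (no duplicates).
#' @param path output TSV path.
#' @param weights optional numeric per-channel scores, same order as `ranks`.
#' @return `path`, invisibly.
#' @export
write_rank_list <- function(ranks, path, weights = NULL) {
  check_that(!anyDuplicated(ranks), "duplicate labels in rank list: %s",
             paste(unique(ranks[duplicated(ranks)]), collapse = ", "))
  df <- data.frame(rank = seq_along(ranks), label = ranks,
                   stringsAsFactors = FALSE)
  if (!is.null(weights)) {
    check_that(length(weights) == length(ranks),
               "weights length must match ranks")
    df$weight <- weights
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a channel rank list written by [write_rank_list()]
#'
#' @param path TSV path.
#' @return data frame with columns `rank`, `label` and optionally `weight`,
#'   ordered by rank.
#' @export
read_rank_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  check_that(all(c("rank", "label") %in% names(df)),
             "rank list must have columns rank, label")
  df <- df[order(df$rank), , drop = FALSE]
  check_that(!anyDuplicated(df$label), "duplicate labels in rank list file")
  rownames(df) <- NULL
  df
}

#' Export a pair metric series to TSV
#'
#' @param series a `pair_metric_series` from [plv()], [pcv()], [plcv()],
#'   [itc()] or [te()].
#' @param path output TSV path (columns `time`, `value`).
#' @return `path`, invisibly.
#' @export
write_pair_metric <- function(series, path) {
  check_that(inherits(series, "pair_metric_series"),
             "series must be a pair_metric_series")
  utils::write.table(as.data.frame(series), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
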