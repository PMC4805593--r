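#' Write a trial set to CSV with a JSON sidecar
#'
#' The CSV carries the column contract of the producing module (go/no-go,
#' cued, 2afc or learning trials); the sidecar records the parameter
#' fingerprint, base seed, trial-set kind and artifact version, which is
#' enough metadata to regenerate the file.  Dialect: comma-separated,
#' UTF-8, header row, `.` decimal, empty field = missing (an absent RT is
#' an empty field, never 0).
#'
#' @param ts A `bg_trials` data frame.
#' @param path Destination CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @seealso [read_trials()] reconstructs an equal trial set.
#' @export
write_trials <- function(ts, path) {
  stopifnot(inherits(ts, "bg_trials"))
  df <- as.data.frame(ts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "",
                   fileEncoding = "UTF-8")
  sidecar <- list(
    artifact = "bgcompete",
    version = as.character(utils::packageVersion("bgcompete")),
    kind = attr(ts, "kind"),
    params_fingerprint = attr(ts, "params_fingerprint"),
    base_seed = attr(ts, "base_seed"),
    n = nrow(df),
    columns = names(df)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a trial set written by [write_trials()]
#'
#' @param path CSV path (the `<path>.json` sidecar must exist alongside).
#' @return A `bg_trials` data frame field-wise equal to the one written.
#' @export
read_trials <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path))
    stop("missing sidecar: ", sidecar_path)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0L && length(meta$columns))
    df <- df[, meta$columns, drop = FALSE]
  # restore types the CSV round trip loses on empty/NA-only columns
  if ("rt_ms" %in% names(df)) df$rt_ms <- as.numeric(df$rt_ms)
  for (col in intersect(c("crossed", "valid", "correct", "timeout"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  for (col in intersect(c("trial", "reward"), names(df)))
    df[[col]] <- as.integer(df[[col]])
  if ("seed" %in% names(df)) df$seed <- as.integer(df$seed)
  if ("condition" %in% names(df)) df$condition <- as.character(df$condition)
  new_bg_trials(df,
                params_fingerprint = meta$params_fingerprint,
                base_seed = as.integer(meta$base_seed),
                kind = meta$kind)
}

#' Export a trajectory as TSV with a JSON sidecar
#'
#' Columns `time_ms`, `d_rate`, `i_rate`; the sidecar records seed and
#' parameter fingerprint.
#'
#' @param traj A [simulate_channel()] trajectory.
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "bg_trajectory"))
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(list(artifact = "bgcompete",
                            version = as.character(
                              utils::packageVersion("bgcompete")),
                            seed = traj$seed,
                            params_fingerprint = traj$params_fingerprint),
                       paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

bg_log <- function(level, msg, threshold = "info") {
  ranks <- c(debug = 1, info = 2, warning = 3)
  if (ranks[[level]] >= ranks[[threshold]])
    message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", msg)
  invisible(NULL)
}
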