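#' Read and write spectra-series containers
#'
#' A series is persisted as a per-colony directory holding three plain-text
#' parts mirroring a hierarchical array layout:
#' \describe{
#'   \item{meta.json}{colony id, cadence, and the frequency-grid attributes
#'     (\code{f0}, \code{df}, \code{n_bins}).}
#'   \item{frames.csv}{one row per frame: ISO-8601 time and quality flag.}
#'   \item{amplitudes.csv}{the amplitude matrix, one comma-separated row per
#'     frame, written at full double precision (\code{\%.17g}) so that a
#'     write/read round trip is bit-identical.}
#' }
#' Missing frames keep their row (quality \code{missing}, amplitudes
#' \code{NA}); rows that are strictly zero on ingest are converted to
#' missing, matching how power-cut records appear in field exports.
#'
#' @param series a \code{spectra_series}.
#' @param path directory to create/read.
#' @return \code{read_series} returns a \code{spectra_series};
#'   \code{write_series} returns \code{path} invisibly.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "spectra_series"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(colony_id = series$colony_id, cadence = series$cadence,
               grid = list(f0 = series$grid$f0, df = series$grid$df,
                           n_bins = series$grid$n_bins),
               n_frames = length(series$times))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  frames <- data.frame(time = format(series$times, "%Y-%m-%dT%H:%M:%S"),
                       quality = series$quality)
  utils::write.csv(frames, file.path(path, "frames.csv"), row.names = FALSE)
  amp <- series$amplitudes
  lines <- vapply(seq_len(nrow(amp)), function(i)
    paste(sprintf("%.17g", amp[i, ]), collapse = ","), character(1))
  writeLines(lines, file.path(path, "amplitudes.csv"))
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  for (part in c("meta.json", "frames.csv", "amplitudes.csv"))
    if (!file.exists(file.path(path, part)))
      stop("not a series container: missing ", part, " in ", path)
  meta <- tryCatch(jsonlite::read_json(file.path(path, "meta.json")),
                   error = function(e)
                     stop("malformed meta.json in ", path, ": ",
                          conditionMessage(e)))
  for (field in c("colony_id", "cadence", "grid"))
    if (is.null(meta[[field]]))
      stop("malformed meta.json in ", path, ": missing '", field, "'")
  grid <- freq_grid(meta$grid$f0, meta$grid$df, meta$grid$n_bins)
  frames <- utils::read.csv(file.path(path, "frames.csv"),
                            stringsAsFactors = FALSE)
  if (nrow(frames) == 0L) stop("empty frames.csv in ", path)
  if (!all(c("time", "quality") %in% names(frames)))
    stop("malformed frames.csv in ", path, ": need 'time' and 'quality'")
  times <- as.POSIXct(frames$time, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(times)) {
    bad <- which(is.na(times))[1]
    stop("malformed frames.csv in ", path, ": unparseable time at row ", bad)
  }
  lines <- readLines(file.path(path, "amplitudes.csv"))
  if (length(lines) != nrow(frames))
    stop("amplitudes.csv in ", path, " has ", length(lines),
         " rows but frames.csv has ", nrow(frames))
  amp <- matrix(NA_real_, nrow = length(lines), ncol = grid$n_bins)
  for (i in seq_along(lines)) {
    vals <- suppressWarnings(as.numeric(strsplit(lines[i], ",",
                                                 fixed = TRUE)[[1]]))
    if (length(vals) != grid$n_bins)
      stop("malformed amplitudes.csv in ", path, ": row ", i, " has ",
           length(vals), " values, expected ", grid$n_bins)
    amp[i, ] <- vals
  }
  quality <- frames$quality
  # zero-filled power-cut records become explicit missing frames
  zero <- quality == "ok" &
    apply(amp, 1L, function(r) all(!is.na(r)) && all(r == 0))
  quality[zero] <- "missing"
  amp[quality == "missing", ] <- NA_real_
  spectra_series(meta$colony_id, times, grid, amp, quality,
                 cadence = meta$cadence)
}

#' Read and write colony event logs
#'
#' Event logs are stored as CSV with columns \code{time} (ISO-8601),
#' \code{kind} and \code{note}.
#'
#' @param log an \code{event_log}.
#' @param path CSV file path.
#' @return \code{read_event_log} returns an \code{event_log};
#'   \code{write_event_log} returns \code{path} invisibly.
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  out <- data.frame(time = format(log$time, "%Y-%m-%dT%H:%M:%S"),
                    kind = log$kind, note = log$note)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "kind") %in% names(df)))
    stop("malformed event log ", path, ": need 'time' and 'kind' columns")
  times <- as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(times))
    stop("malformed event log ", path, ": unparseable time at row ",
         which(is.na(times))[1])
  event_log(times, df$kind, if (is.null(df$note)) "" else df$note)
}
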