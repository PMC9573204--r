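# Session storage: wide CSV (one row per frame, one column per channel) plus
# a JSON metadata sidecar. Plain text keeps desk-scale recordings diffable.

#' Write a session to disk
#'
#' Writes `<path>.csv` (frame table, full double precision) and
#' `<path>.json` (task, subject metadata, sampling rate, segment lengths).
#'
#' @param session a `glove_session`
#' @param path file path without extension
#' @return `path`, invisibly
#' @export
write_session <- function(session, path) {
  validate_session(session)
  data.table::fwrite(session$frames, paste0(path, ".csv"))
  meta <- list(format = "spastiglove-session/1",
               task = session$task,
               sample_rate_hz = session$sample_rate_hz,
               stationary_frames = session$stationary_frames,
               warmup_frames = session$warmup_frames,
               subject = unclass(session$meta))
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session from disk
#'
#' @param path file path without extension, as given to [write_session()]
#' @return a validated `glove_session`
#' @export
read_session <- function(path) {
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  if (!file.exists(csv)) stop("missing frame table: ", csv)
  if (!file.exists(js)) stop("missing metadata sidecar: ", js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  if (!identical(meta$format, "spastiglove-session/1"))
    stop("unrecognised session format tag: ", meta$format)
  frames <- as.data.frame(data.table::fread(csv))
  sm <- subject_meta(meta$subject$subject_id, meta$subject$group,
                     meta$subject$mas_score, meta$subject$affected_side)
  new_session(frames, task = meta$task, meta = sm,
              sample_rate_hz = meta$sample_rate_hz,
              stationary_frames = meta$stationary_frames,
              warmup_frames = meta$warmup_frames)
}

#' Frame-timing report
#'
#' Sessions are nominally sampled every 20 ms; this reports how far the
#' recorded timestamps deviate, so jittery streams are flagged rather than
#' silently accepted.
#' @param session a `glove_session`
#' @return list with `nominal_dt`, `max_abs_dev` (seconds) and `ok`
#'   (deviation within `tol`)
#' @param tol tolerance in seconds
#' @export
timing_report <- function(session, tol = 1e-6) {
  tt <- session$frames$t
  nominal <- 1 / session$sample_rate_hz
  dev <- if (length(tt) > 1) max(abs(diff(tt) - nominal)) else 0
  list(nominal_dt = nominal, max_abs_dev = dev, ok = dev <= tol)
}
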