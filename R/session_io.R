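#' Write a session recording to a plain-text container
#'
#' One directory per session: `meta.json` (frame_rate_hz, day_index,
#' plane_id, n_neurons, n_frames), `traces.csv` (neurons x frames, no
#' header), `events.csv` (onset_frame, stimulus_id), `locomotion.csv`
#' (one 0/1 per frame) and `roi_stats.csv` (neuron_id, compactness,
#' skewness). The round trip through [read_session()] is lossless up to
#' numeric text precision (15 significant digits).
#'
#' @param session a `session_recording`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(frame_rate_hz = session$frame_rate_hz,
               day_index = session$day_index,
               plane_id = session$plane_id,
               n_neurons = nrow(session$traces),
               n_frames = ncol(session$traces))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(format(session$traces, digits = 15, trim = TRUE,
                            scientific = TRUE),
                     file.path(path, "traces.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.csv(session$events, file.path(path, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(locomotion = as.integer(session$locomotion_mask)),
                   file.path(path, "locomotion.csv"), row.names = FALSE)
  utils::write.csv(session$roi_stats, file.path(path, "roi_stats.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read and validate a session container
#'
#' Schema violations fail before any computation, naming the offending
#' dataset: missing files, a non-numeric or non-positive frame rate,
#' trace/mask length disagreements, or events whose onset frames fall
#' outside the trace.
#'
#' @param path session directory written by [write_session()].
#' @return a `session_recording`.
#' @export
read_session <- function(path) {
  need <- c("meta.json", "traces.csv", "events.csv", "locomotion.csv",
            "roi_stats.csv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("session container ", path, " is missing: ",
         paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!is.numeric(meta$frame_rate_hz) || length(meta$frame_rate_hz) != 1 ||
      meta$frame_rate_hz <= 0)
    stop("schema error in ", path, "/meta.json: frame_rate_hz must be a ",
         "positive number")
  traces <- as.matrix(utils::read.csv(file.path(path, "traces.csv"),
                                      header = FALSE))
  dimnames(traces) <- NULL
  storage.mode(traces) <- "double"
  if (!all(is.finite(traces)))
    stop("schema error in ", path, "/traces.csv: non-finite values")
  events <- utils::read.csv(file.path(path, "events.csv"))
  if (!all(c("onset_frame", "stimulus_id") %in% names(events)))
    stop("schema error in ", path, "/events.csv: need onset_frame, ",
         "stimulus_id")
  if (any(events$onset_frame < 1) || any(events$onset_frame > ncol(traces)))
    stop("validation error in ", path, "/events.csv: onset frames outside ",
         "1..", ncol(traces))
  loco <- utils::read.csv(file.path(path, "locomotion.csv"))$locomotion
  if (length(loco) != ncol(traces))
    stop("schema error in ", path, "/locomotion.csv: length ", length(loco),
         " != n_frames ", ncol(traces))
  roi_stats <- utils::read.csv(file.path(path, "roi_stats.csv"))
  structure(list(traces = traces, frame_rate_hz = meta$frame_rate_hz,
                 events = events, locomotion_mask = as.logical(loco),
                 day_index = meta$day_index, plane_id = meta$plane_id,
                 roi_stats = roi_stats),
            class = "session_recording")
}
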