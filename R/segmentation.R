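#' Segment extraction parameters
#'
#' Thresholds defining a return-loop segment: the trajectory must come back
#' within `slack_radius` of its start, last between `min_duration` and
#' `max_duration`, and cover at least `min_length` of path.  The duration
#' and length thresholds filter out both day-long outings and trivially
#' short loops produced by localisation noise or standing still.
#'
#' @param slack_radius Endpoint slack in metres (default 10).
#' @param min_duration Minimum duration in seconds (default 60).
#' @param max_duration Maximum duration in seconds (default 1200).
#' @param min_length Minimum path length in metres (default 100).
#' @return A list of class `mm_segment_params`.
#' @export
segment_params <- function(slack_radius = 10, min_duration = 60,
                           max_duration = 1200, min_length = 100) {
  stopifnot(slack_radius > 0, min_duration > 0, min_length > 0,
            min_duration < max_duration)
  structure(list(slack_radius = slack_radius, min_duration = min_duration,
                 max_duration = max_duration, min_length = min_length),
            class = "mm_segment_params")
}

cumulative_path_length <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(0)
  c(0, cumsum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)))
}

#' Candidate return endpoints for a segment start
#'
#' All sample indices `j > start_index` in the same recording bout whose
#' planar distance to the start sample is at most `slack_radius`, in
#' ascending order.  The result is defined purely by the distance
#' predicate; any spatial index used to find them is an implementation
#' detail.
#'
#' @param trace A projected trace.
#' @param start_index 1-based sample index of the candidate start.
#' @param params A [segment_params()] object.
#' @param bouts Optional bout table from [split_bouts()]; computed with the
#'   default gap threshold when missing.
#' @return Integer vector of candidate end indices.
#' @export
candidate_endpoints <- function(trace, start_index, params = segment_params(),
                                bouts = NULL) {
  if (is.null(trace$xy)) stop("trace must be projected first")
  if (is.null(bouts)) bouts <- split_bouts(trace)
  row <- which(bouts$start <= start_index & start_index < bouts$end)
  if (length(row) != 1) stop("start_index not inside any bout")
  lo <- start_index + 1L
  hi <- bouts$end[row] - 1L
  if (lo > hi) return(integer(0))
  idx <- lo:hi
  d2 <- (trace$xy[idx, 1] - trace$xy[start_index, 1])^2 +
    (trace$xy[idx, 2] - trace$xy[start_index, 2])^2
  idx[d2 <= params$slack_radius^2]
}

#' Extract non-overlapping return-loop segments
#'
#' Scans each recording bout left to right.  At candidate start `i` the
#' admissible endpoints are the later in-bout samples within
#' `slack_radius` of the start whose duration lies in the
#' `[min_duration, max_duration]` window and whose path length (sum of
#' the constituent linear pieces) reaches `min_length`; if any exist the
#' segment maximising path length (ties broken towards the later
#' endpoint) is emitted and the scan resumes just after its end,
#' otherwise the start advances by one sample.  Segments therefore never
#' overlap in time and never span recording gaps.
#'
#' @inheritParams candidate_endpoints
#' @param companionship_labels Optional per-sample labels from
#'   [label_companionship()]; each segment inherits the majority label.
#' @return A data frame with one row per segment: `participant_id`,
#'   `segment_id`, `start_idx`, `end_idx` (inclusive 1-based sample
#'   indices), `start_time`, `end_time`, `duration_s`, `path_length_m`,
#'   `companionship`.
#' @export
extract_segments <- function(trace, params = segment_params(), bouts = NULL,
                             companionship_labels = NULL) {
  if (is.null(trace$xy)) stop("trace must be projected first")
  if (is.null(bouts)) bouts <- split_bouts(trace)
  res <- list()
  for (b in seq_len(nrow(bouts))) {
    idx <- bouts$start[b]:(bouts$end[b] - 1L)
    if (length(idx) < 2) next
    xy <- trace$xy[idx, , drop = FALSE]
    tm <- trace$samples$time[idx]
    cum <- cumulative_path_length(xy)
    m <- greedy_segments_cpp(xy[, 1], xy[, 2], tm, cum,
                             params$slack_radius, params$min_duration,
                             params$max_duration, params$min_length)
    if (nrow(m) > 0) {
      res[[length(res) + 1L]] <- data.frame(
        start_idx = idx[m[, 1]], end_idx = idx[m[, 2]],
        duration_s = tm[m[, 2]] - tm[m[, 1]],
        path_length_m = cum[m[, 2]] - cum[m[, 1]])
    }
  }
  if (length(res) == 0) {
    return(data.frame(participant_id = character(0), segment_id = character(0),
                      start_idx = integer(0), end_idx = integer(0),
                      start_time = numeric(0), end_time = numeric(0),
                      duration_s = numeric(0), path_length_m = numeric(0),
                      companionship = character(0)))
  }
  segs <- do.call(rbind, res)
  comp <- rep("unknown", nrow(segs))
  if (!is.null(companionship_labels)) {
    comp <- vapply(seq_len(nrow(segs)), function(k) {
      segment_companionship(
        companionship_labels[segs$start_idx[k]:segs$end_idx[k]])
    }, character(1))
  }
  data.frame(participant_id = trace$participant_id,
             segment_id = sprintf("%s_s%03d", trace$participant_id,
                                  seq_len(nrow(segs))),
             start_idx = segs$start_idx, end_idx = segs$end_idx,
             start_time = trace$samples$time[segs$start_idx],
             end_time = trace$samples$time[segs$end_idx],
             duration_s = segs$duration_s,
             path_length_m = segs$path_length_m,
             companionship = comp,
             stringsAsFactors = FALSE)
}

#' Write a segment table in the export dialect
#'
#' @param segments Segment table from [extract_segments()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- data.frame(participant_id = segments$participant_id,
                    segment_id = segments$segment_id,
                    start_time = format_iso8601(segments$start_time),
                    end_time = format_iso8601(segments$end_time),
                    duration_s = segments$duration_s,
                    path_length_m = sprintf("%.3f", segments$path_length_m),
                    companionship = segments$companionship)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
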