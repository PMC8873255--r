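#' Construct a GPS trace object
#'
#' A trace holds the ordered, timestamped outdoor GPS samples of one
#' participant, together with the group label and (after
#' [project_to_plane()]) planar metric coordinates.
#'
#' @param participant_id Character scalar identifier.
#' @param group Either `"control"` or `"patient"`.
#' @param samples A data frame with numeric columns `time` (seconds since
#'   epoch, UTC), `lat`, `lon` (degrees WGS84) and optional `speed`
#'   (m/s) and `accuracy` (percent).
#' @param sampling_interval Nominal sampling interval in seconds (3 or 5 for
#'   the tracker configurations emulated here; any positive value accepted).
#' @return An object of class `mm_trace`.
#' @export
new_trace <- function(participant_id, group, samples, sampling_interval = 3) {
  group <- match.arg(group, c("control", "patient"))
  stopifnot(is.data.frame(samples), all(c("time", "lat", "lon") %in% names(samples)))
  if (nrow(samples) > 0) {
    if (any(!is.finite(samples$time))) stop("non-finite timestamps")
    if (any(samples$lat < -90 | samples$lat > 90, na.rm = TRUE))
      stop("latitude out of [-90, 90]")
    if (any(samples$lon < -180 | samples$lon > 180, na.rm = TRUE))
      stop("longitude out of [-180, 180]")
    if (is.unsorted(samples$time, strictly = TRUE)) {
      samples <- samples[order(samples$time), , drop = FALSE]
      dup <- duplicated(samples$time)
      if (any(dup)) samples <- samples[!dup, , drop = FALSE]
      rownames(samples) <- NULL
    }
  }
  structure(list(participant_id = as.character(participant_id),
                 group = group,
                 samples = samples,
                 sampling_interval = sampling_interval,
                 xy = NULL,
                 origin = NULL),
            class = "mm_trace")
}

#' @export
print.mm_trace <- function(x, ...) {
  cat(sprintf("<mm_trace> participant %s (%s): %d samples, %.2g h span%s\n",
              x$participant_id, x$group, nrow(x$samples),
              if (nrow(x$samples) > 1) diff(range(x$samples$time)) / 3600 else 0,
              if (is.null(x$xy)) "" else ", projected"))
  invisible(x)
}

parse_iso8601 <- function(s) {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  as.numeric(t)
}

format_iso8601 <- function(time) {
  format(as.POSIXct(time, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Read a GPS trace file
#'
#' Reads a point-track file in either the package CSV dialect (header
#' `participant_id,timestamp_iso8601,lat,lon,speed_mps,accuracy_pct`, the
#' last two columns optional/empty) or GPX 1.1 (`trkpt` elements with
#' `lat`/`lon` attributes and a `time` child).  Samples are returned sorted
#' by time with exact duplicate timestamps collapsed to the first occurrence
#' (the number of dropped rows is reported via `message()`).
#'
#' @inheritParams new_trace
#' @param path Path to the track file.
#' @return An [new_trace()] object.
#' @export
read_trace <- function(path, participant_id, group) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("<\\?xml|<gpx", first)) {
    samples <- read_gpx_samples(path)
  } else {
    samples <- read_csv_samples(path)
  }
  if (nrow(samples) == 0) stop("empty trace file: ", path)
  ord <- order(samples$time)
  samples <- samples[ord, , drop = FALSE]
  dup <- duplicated(samples$time)
  if (any(dup)) {
    message(sprintf("read_trace: dropped %d duplicate-timestamp rows from %s",
                    sum(dup), path))
    samples <- samples[!dup, , drop = FALSE]
  }
  rownames(samples) <- NULL
  new_trace(participant_id, group, samples)
}

read_csv_samples <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) stop("empty trace file: ", path)
  need <- c("timestamp_iso8601", "lat", "lon")
  if (!all(need %in% names(raw)))
    stop("trace CSV must have columns ", paste(need, collapse = ", "))
  time <- parse_iso8601(raw$timestamp_iso8601)
  lat <- suppressWarnings(as.numeric(raw$lat))
  lon <- suppressWarnings(as.numeric(raw$lon))
  bad <- which(!is.finite(time) | !is.finite(lat) | !is.finite(lon) |
                 lat < -90 | lat > 90 | lon < -180 | lon > 180)
  if (length(bad) > 0)
    stop(sprintf("unparseable or out-of-range row at line %d of %s",
                 bad[1] + 1L, path))  # +1 for the header line
  num_or_na <- function(col) {
    if (is.null(col)) return(rep(NA_real_, length(time)))
    v <- suppressWarnings(as.numeric(col))
    v
  }
  data.frame(time = time, lat = lat, lon = lon,
             speed = num_or_na(raw$speed_mps),
             accuracy = num_or_na(raw$accuracy_pct))
}

read_gpx_samples <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  pts <- xml2::xml_find_all(doc, ".//g:trkpt", ns)
  if (length(pts) == 0) pts <- xml2::xml_find_all(doc, ".//trkpt")
  if (length(pts) == 0) stop("no trkpt elements in ", path)
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  tnode <- vapply(pts, function(p) {
    tn <- xml2::xml_find_first(p, ".//g:time", ns)
    if (inherits(tn, "xml_missing")) tn <- xml2::xml_find_first(p, ".//time")
    xml2::xml_text(tn)
  }, character(1))
  time <- parse_iso8601(sub("Z$", "", tnode))
  bad <- which(!is.finite(time) | !is.finite(lat) | !is.finite(lon))
  if (length(bad) > 0)
    stop("unparseable trkpt #", bad[1], " in ", path)
  data.frame(time = time, lat = lat, lon = lon,
             speed = NA_real_, accuracy = NA_real_)
}

#' Write a trace in the package CSV dialect
#'
#' @param trace An [new_trace()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  s <- trace$samples
  df <- data.frame(
    participant_id = trace$participant_id,
    timestamp_iso8601 = format_iso8601(s$time),
    lat = sprintf("%.10f", s$lat),
    lon = sprintf("%.10f", s$lon),
    speed_mps = ifelse(is.na(s$speed), "", sprintf("%.3f", s$speed)),
    accuracy_pct = ifelse(is.na(s$accuracy), "", sprintf("%.1f", s$accuracy)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Project a trace onto a local metric plane
#'
#' Fills `trace$xy` with planar coordinates in metres from a local azimuthal
#' equirectangular projection centred on the participant's median (lat, lon):
#' `x = R cos(lat0) dlon`, `y = R dlat` with angles in radians and
#' `R = 6371008.8` m (mean Earth radius).  Over the city-scale spans
#' expected (tens of km) planar Euclidean distance agrees with geodesic
#' distance to better than 0.1 percent.
#'
#' @param trace An [new_trace()] object with at least one sample.
#' @param origin Optional `c(lat, lon)` projection centre; defaults to the
#'   per-participant median position.
#' @return The trace with `xy` (n x 2 matrix, metres) and `origin` filled.
#' @export
project_to_plane <- function(trace, origin = NULL) {
  s <- trace$samples
  if (nrow(s) < 1) stop("cannot project an empty trace")
  R <- 6371008.8
  if (is.null(origin))
    origin <- c(stats::median(s$lat), stats::median(s$lon))
  lat0 <- origin[1] * pi / 180
  x <- R * cos(lat0) * (s$lon - origin[2]) * pi / 180
  y <- R * (s$lat - origin[1]) * pi / 180
  trace$xy <- cbind(x = x, y = y)
  trace$origin <- origin
  trace
}

#' Split a trace into contiguous recording bouts
#'
#' The tracker is worn only when the participant leaves the house, so traces
#' contain long recording gaps.  A bout is a maximal run of consecutive
#' samples whose inter-sample time gaps are all at most `gap_threshold`.
#'
#' @param trace A projected trace.
#' @param gap_threshold Maximum within-bout gap in seconds (default 60).
#' @return A data frame with columns `start`, `end` giving half-open 1-based
#'   sample index ranges `[start, end)`; together the bouts partition the
#'   samples.
#' @export
split_bouts <- function(trace, gap_threshold = 60) {
  n <- nrow(trace$samples)
  if (n == 0) return(data.frame(start = integer(0), end = integer(0)))
  if (n == 1) return(data.frame(start = 1L, end = 2L))
  gaps <- diff(trace$samples$time)
  brk <- which(gaps > gap_threshold)
  start <- c(1L, brk + 1L)
  end <- c(brk, n) + 1L
  data.frame(start = start, end = end)
}

#' Read the participant metadata file
#'
#' @param path CSV with header `participant_id,group`.
#' @return A data frame with character `participant_id` and `group`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("participant_id", "group") %in% names(df)))
    stop("metadata must have columns participant_id, group")
  bad <- setdiff(unique(df$group), c("control", "patient"))
  if (length(bad) > 0) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df
}

#' Read the outing companionship annotations file
#'
#' @param path CSV with header
#'   `participant_id,start_iso8601,end_iso8601,companionship`.
#' @return A data frame with `participant_id`, numeric `start`, `end`
#'   (seconds since epoch; half-open intervals) and `companionship`
#'   (`"alone"` or `"accompanied"`).
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("participant_id", "start_iso8601", "end_iso8601", "companionship")
  if (!all(need %in% names(df)))
    stop("annotations must have columns ", paste(need, collapse = ", "))
  out <- data.frame(participant_id = df$participant_id,
                    start = parse_iso8601(df$start_iso8601),
                    end = parse_iso8601(df$end_iso8601),
                    companionship = df$companionship,
                    stringsAsFactors = FALSE)
  bad <- setdiff(unique(out$companionship), c("alone", "accompanied"))
  if (length(bad) > 0)
    stop("unknown companionship label(s): ", paste(bad, collapse = ", "))
  out
}

#' Label each sample with navigation-diary companionship
#'
#' Assigns `"alone"` or `"accompanied"` to every sample whose timestamp
#' falls inside an annotated outing interval `[start, end)`, and
#' `"unknown"` elsewhere.  Segments later inherit the majority label of
#' their samples (see [segment_companionship()]).
#'
#' @param trace An [new_trace()] object.
#' @param annotations Data frame as returned by [read_annotations()]
#'   (possibly covering several participants; only rows matching the trace's
#'   participant are used).
#' @return Character vector, one label per sample.
#' @export
label_companionship <- function(trace, annotations) {
  n <- nrow(trace$samples)
  lab <- rep("unknown", n)
  if (is.null(annotations) || nrow(annotations) == 0) return(lab)
  ann <- annotations[annotations$participant_id == trace$participant_id, ,
                     drop = FALSE]
  tm <- trace$samples$time
  for (k in seq_len(nrow(ann))) {
    inside <- tm >= ann$start[k] & tm < ann$end[k]
    lab[inside] <- ann$companionship[k]
  }
  lab
}

#' Majority companionship label for a sample span
#'
#' A span is labelled by the majority of its alone/accompanied samples;
#' it is `"unknown"` when more than half of its samples are unlabelled.
#'
#' @param labels Per-sample labels for the span (from
#'   [label_companionship()]).
#' @return One of `"alone"`, `"accompanied"`, `"unknown"`.
#' @export
segment_companionship <- function(labels) {
  n <- length(labels)
  if (n == 0) return("unknown")
  if (sum(labels == "unknown") > n / 2) return("unknown")
  known <- labels[labels != "unknown"]
  if (sum(known == "alone") >= sum(known == "accompanied")) "alone" else "accompanied"
}
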