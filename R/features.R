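#' Prepare a participant's trace for feature extraction
#'
#' Projects the trace, splits it into recording bouts, labels samples with
#' diary companionship and extracts the return-loop segments.
#'
#' @param trace An [new_trace()] object.
#' @param annotations Optional annotations data frame
#'   ([read_annotations()]).
#' @param seg_params A [segment_params()] object.
#' @param gap_threshold Bout-splitting gap in seconds (default 60).
#' @return A list with the projected `trace`, `bouts`, per-sample `labels`
#'   and the `segments` table.
#' @export
prepare_participant <- function(trace, annotations = NULL,
                                seg_params = segment_params(),
                                gap_threshold = 60) {
  trace <- project_to_plane(trace)
  bouts <- split_bouts(trace, gap_threshold)
  labels <- label_companionship(trace, annotations)
  segments <- extract_segments(trace, seg_params, bouts, labels)
  list(trace = trace, bouts = bouts, labels = labels, segments = segments)
}

#' Spatiotemporal features for a set of segments
#'
#' Computes, for the given segment subset of one participant, the
#' participant-level segment entropy and the per-segment features:
#' similarity fraction, distance from home, segment complexity, total
#' turning angle, radius of gyration and stop durations/counts.
#'
#' @param prep Output of [prepare_participant()].
#' @param segments Segment subset to use (default: all extracted
#'   segments).
#' @param grid A [grid_spec()].
#' @param jaccard_threshold Similarity threshold (default 0.5).
#' @param complexity_threshold Turning-angle threshold in degrees
#'   (default 120).
#' @param static_radius,min_stop_duration Stop-detection parameters
#'   (defaults 10 m, 60 s).
#' @param tz Timezone for the home-estimation calendar days.
#' @return `NULL` (with a message) if the subset is empty; otherwise a
#'   list with `entropy`, `home`, a per-segment data frame `seg`
#'   (`segment_id`, `companionship`, `similarity`, `distance_from_home`,
#'   `complexity`, `total_turning_angle`, `radius_of_gyration`,
#'   `n_stops`) and the list `stop_durations`.
#' @export
participant_features <- function(prep, segments = prep$segments,
                                 grid = grid_spec(),
                                 jaccard_threshold = 0.5,
                                 complexity_threshold = 120,
                                 static_radius = 10,
                                 min_stop_duration = 60,
                                 tz = "UTC") {
  if (is.null(segments) || nrow(segments) == 0) {
    message("participant ", prep$trace$participant_id,
            " has no segments in this subset; excluded")
    return(NULL)
  }
  trace <- prep$trace
  seqs <- segment_cell_sequences(trace, segments, grid)
  entropy <- segment_entropy(seqs)
  simfrac <- if (nrow(segments) >= 2) {
    as.numeric(segment_similarity_fractions(seqs, jaccard_threshold))
  } else rep(NA_real_, nrow(segments))
  home <- estimate_home(trace, tz)
  dist_home <- distance_from_home(trace, segments, home)
  n <- nrow(segments)
  complexity <- integer(n); tta <- numeric(n); rog <- numeric(n)
  n_stops <- integer(n); stop_durations <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- segments$start_idx[k]:segments$end_idx[k]
    xy <- trace$xy[idx, , drop = FALSE]
    ang <- turning_angles(xy)
    complexity[k] <- segment_complexity(ang, complexity_threshold)
    tta[k] <- total_turning_angle(ang)
    rog[k] <- radius_of_gyration(xy)
    st <- detect_stops(xy, trace$samples$time[idx], static_radius,
                       min_stop_duration)
    n_stops[k] <- st$count
    stop_durations[[k]] <- st$durations
  }
  list(entropy = entropy, home = home,
       seg = data.frame(segment_id = segments$segment_id,
                        companionship = segments$companionship,
                        similarity = simfrac,
                        distance_from_home = dist_home,
                        complexity = complexity,
                        total_turning_angle = tta,
                        radius_of_gyration = rog,
                        n_stops = n_stops,
                        stringsAsFactors = FALSE),
       stop_durations = stop_durations)
}

#' Assemble the classifier feature container for one participant
#'
#' Bundles scalar features and the raw value vectors behind the histogram
#' features into the shape consumed by [loo_classify()].
#'
#' @param pf Output of [participant_features()].
#' @param graph_tab Optional [centralities()] table of the participant's
#'   mobility graph; adds `node_count` and the three centrality value
#'   vectors.
#' @param node_count Node count of the graph (required with `graph_tab`).
#' @return A list with `scalars` (named numeric) and `values` (named list
#'   of numeric vectors).
#' @export
assemble_feature_values <- function(pf, graph_tab = NULL, node_count = NULL) {
  values <- list(
    segment_similarity = pf$seg$similarity[!is.na(pf$seg$similarity)],
    distance_from_home = pf$seg$distance_from_home,
    stop_durations = unlist(pf$stop_durations),
    complexity = as.numeric(pf$seg$complexity),
    total_turning_angle = pf$seg$total_turning_angle,
    radius_of_gyration = pf$seg$radius_of_gyration)
  scalars <- c(entropy = pf$entropy)
  if (!is.null(graph_tab)) {
    values$closeness <- graph_tab$closeness
    values$betweenness <- graph_tab$betweenness
    values$degree_centrality <- graph_tab$degree_centrality
    scalars <- c(scalars, node_count = as.numeric(node_count))
  }
  list(scalars = scalars, values = values)
}
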