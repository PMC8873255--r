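#' Grid specification for mobility-domain features
#'
#' Location resolution is coarsened by laying a square grid over the plane
#' and replacing each point by the index of the cell containing it.  Cells
#' are half-open (`[k*cell, (k+1)*cell)` per axis, floor convention), so a
#' point exactly on a boundary belongs to the higher-index cell.
#'
#' @param cell_size Cell edge in metres (default 100).
#' @param origin Planar `c(x, y)` anchoring cell (0, 0); defaults to the
#'   participant's projection origin `(0, 0)`.
#' @return A list of class `mm_grid`.
#' @export
grid_spec <- function(cell_size = 100, origin = c(0, 0)) {
  stopifnot(cell_size > 0)
  structure(list(cell_size = cell_size, origin = origin), class = "mm_grid")
}

#' Rasterize points to grid-cell indices
#'
#' @param xy An n x 2 matrix of planar coordinates in metres.
#' @param grid A [grid_spec()].
#' @return Data frame with integer columns `row`, `col` (one per point) and
#'   a character `cell` key `"row:col"`.
#' @export
rasterize <- function(xy, grid = grid_spec()) {
  col <- floor((xy[, 1] - grid$origin[1]) / grid$cell_size)
  row <- floor((xy[, 2] - grid$origin[2]) / grid$cell_size)
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = paste(row, col, sep = ":"), stringsAsFactors = FALSE)
}

#' Cell sequences for every segment of a participant
#'
#' @param trace A projected trace.
#' @param segments Segment table from [extract_segments()].
#' @param grid A [grid_spec()].
#' @return A named list (by `segment_id`); each element is the ordered
#'   character vector of cell keys, one per sample.
#' @export
segment_cell_sequences <- function(trace, segments, grid = grid_spec()) {
  cells <- rasterize(trace$xy, grid)$cell
  out <- lapply(seq_len(nrow(segments)), function(k)
    cells[segments$start_idx[k]:segments$end_idx[k]])
  names(out) <- segments$segment_id
  out
}

#' Segment entropy of a participant
#'
#' Pools per-sample cell visit counts over all the participant's segments,
#' normalises them to a probability mass over the visited cells (cells with
#' zero counts are not part of the support), and returns the Shannon
#' entropy \eqn{H = -\sum_c P(c) \log P(c)} in natural-log units.  Low
#' entropy means movement concentrated on few locations; the maximum
#' \eqn{\ln k} is attained for uniform visits over \eqn{k} cells.
#'
#' @param cell_sequences List of per-segment cell vectors from
#'   [segment_cell_sequences()].
#' @param per_crossing If `TRUE`, count each run of consecutive identical
#'   cells once instead of once per sample (default `FALSE`: every sample
#'   contributes one count, making the mass dwell-weighted).
#' @return Entropy in nats.
#' @export
segment_entropy <- function(cell_sequences, per_crossing = FALSE) {
  if (length(cell_sequences) == 0) stop("no cell sequences")
  pooled <- unlist(lapply(cell_sequences, function(cs) {
    if (per_crossing) cs[c(TRUE, cs[-1] != cs[-length(cs)])] else cs
  }), use.names = FALSE)
  if (length(pooled) == 0) stop("empty visit pool")
  p <- table(pooled) / length(pooled)
  -sum(p * log(p))
}

#' Jaccard similarity of two cell sets
#'
#' \eqn{|A \cap B| / |A \cup B|}.
#'
#' @param a,b Character vectors of cell keys (duplicates ignored).
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  stopifnot(length(a) > 0, length(b) > 0)
  length(intersect(a, b)) / length(union(a, b))
}

#' Per-segment similarity fractions
#'
#' Two segments are similar when the Jaccard similarity of their cell sets
#' exceeds `threshold`.  For each segment the feature is the fraction of
#' the participant's other segments similar to it (self-pairs excluded).
#'
#' @param cell_sequences List of per-segment cell vectors.
#' @param threshold Jaccard similarity threshold (default 0.5, strict).
#' @return Numeric vector of fractions, one per segment, named by segment.
#'   `NULL` (with a message) when the participant has fewer than two
#'   segments, for which the feature is undefined.
#' @export
segment_similarity_fractions <- function(cell_sequences, threshold = 0.5) {
  n <- length(cell_sequences)
  if (n < 2) {
    message("segment similarity undefined for a participant with < 2 segments; skipped")
    return(NULL)
  }
  sets <- lapply(cell_sequences, unique)
  sim <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sim[i, j] <- sim[j, i] <- jaccard(sets[[i]], sets[[j]]) > threshold
    }
  }
  out <- rowSums(sim) / (n - 1)
  names(out) <- names(cell_sequences)
  out
}

#' Estimate the home location of a participant
#'
#' The data contain no declared home address, so home is estimated as the
#' centroid of the daily first and last recorded positions: for each
#' calendar day with data, take the first and the last sample's planar
#' coordinates, then average all such points.
#'
#' @param trace A projected trace.
#' @param tz Timezone used to resolve calendar days (default `"UTC"`).
#' @return Numeric `c(x, y)` in metres.
#' @export
estimate_home <- function(trace, tz = "UTC") {
  if (nrow(trace$samples) == 0) stop("empty trace")
  day <- format(as.POSIXct(trace$samples$time, origin = "1970-01-01",
                           tz = tz), "%Y-%m-%d", tz = tz)
  pts <- do.call(rbind, lapply(split(seq_along(day), day), function(idx) {
    rbind(trace$xy[idx[1], ], trace$xy[idx[length(idx)], ])
  }))
  c(mean(pts[, 1]), mean(pts[, 2]))
}

#' Distance from home of each segment
#'
#' Euclidean distance between the estimated home and the centroid of the
#' segment's samples.
#'
#' @param trace A projected trace.
#' @param segments Segment table.
#' @param home `c(x, y)` from [estimate_home()].
#' @return Numeric vector of distances in metres, one per segment.
#' @export
distance_from_home <- function(trace, segments, home) {
  vapply(seq_len(nrow(segments)), function(k) {
    idx <- segments$start_idx[k]:segments$end_idx[k]
    cx <- mean(trace$xy[idx, 1]); cy <- mean(trace$xy[idx, 2])
    sqrt((cx - home[1])^2 + (cy - home[2])^2)
  }, numeric(1))
}
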