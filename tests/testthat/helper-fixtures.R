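# Build an mm_trace directly from planar coordinates (metres) and times.
# The lat/lon fields are back-projected from the planar coordinates so the
# object is fully consistent with the package's projection.
planar_trace <- function(xy, time = seq_len(nrow(xy)) * 3, id = "T001",
                         group = "control") {
  R <- 6371008.8
  lat0 <- 52; lon0 <- 0
  lat <- lat0 + xy[, 2] / R * 180 / pi
  lon <- lon0 + xy[, 1] / (R * cos(lat0 * pi / 180)) * 180 / pi
  tr <- new_trace(id, group, data.frame(time = time, lat = lat, lon = lon,
                                        speed = NA_real_,
                                        accuracy = NA_real_))
  project_to_plane(tr, origin = c(lat0, lon0))
}

# random-walk trace with occasional returns toward the origin, producing a
# mixture of loops and open wandering; used for oracle-equivalence tests
random_walk_trace <- function(n, seed, step_sd = 8, return_prob = 0.02,
                              gap_prob = 0) {
  set.seed(seed)
  xy <- matrix(0, n, 2)
  for (i in 2:n) {
    if (runif(1) < return_prob && i > 12) {
      back <- i - sample.int(min(i - 2, 200), 1)
      xy[i, ] <- xy[back, ] + rnorm(2, 0, 3)
    } else {
      xy[i, ] <- xy[i - 1, ] + rnorm(2, 0, step_sd)
    }
  }
  dt <- rep(3, n - 1)
  if (gap_prob > 0) dt[runif(n - 1) < gap_prob] <- 7200
  planar_trace(xy, time = cumsum(c(0, dt)))
}

# one shared small synthetic cohort per test session (generation is cheap
# but not free); memoised in the helper environment
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_cohort(
      cohort_config(n_controls = 5, n_patients = 5, days = 5,
                    master_seed = 424242))
  }
  .fixture_env$small
}

# trace visiting cells (x-index sequence) with given dwell seconds per cell
cell_trace <- function(cells_x, dwell_s, interval = 10) {
  xs <- c(); ts <- c(); t <- 0
  for (k in seq_along(cells_x)) {
    n <- max(1, round(dwell_s[k] / interval))
    xs <- c(xs, rep(cells_x[k] * 100 + 50, n))
    ts <- c(ts, t + seq_len(n) * interval)
    t <- ts[length(ts)]
  }
  planar_trace(cbind(xs, 50), time = ts)
}
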