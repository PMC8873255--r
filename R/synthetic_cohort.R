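#' Configuration of the synthetic GPS cohort generator
#'
#' The generator emulates the structure the analysis assumes in the study
#' population it stands in for: home-anchored round trips to a personal
#' set of destinations with Zipf-biased revisit probabilities and
#' persistent route variants; group contrasts in destination count,
#' destination distance and route reuse (patients: fewer, closer, more
#' reused); for patients a fraction of accompanied outings whose routes
#' carry more waypoints, sharper zigzag turns and extra mid-route pauses;
#' dwell pauses at destinations; two nominal sampling rates; and
#' autocorrelated Gaussian GPS noise.
#'
#' @param n_controls,n_patients Group sizes (defaults 18 and 15).
#' @param days Tracking period in days (default 14).
#' @param interval_prob_3s Probability that a participant's tracker samples
#'   every 3 s rather than 5 s, per group (defaults 13/18 controls, 8/15
#'   patients, the mix of the two tracker firmware generations emulated).
#' @param base_date UTC date on which tracking starts.
#' @param home_spacing Metres between participants' homes (default 5000).
#' @param gps_noise_sd Marginal positional noise sd in metres (default 5).
#' @param noise_ar_rho Lag-one autocorrelation of the noise process
#'   (default 0.85; 0 gives i.i.d. noise).
#' @param n_destinations Mean number of personal destinations, named
#'   `control`/`patient` (defaults 10 and 4).
#' @param dest_scale Mean destination distance from home in metres
#'   (defaults 2500 and 650).
#' @param route_reuse Probability that an outing replays an existing route
#'   variant to its destination instead of creating a new one (defaults
#'   0.3 and 0.75).
#' @param zipf_exponent Exponent of the destination revisit weights
#'   (default 1).
#' @param accompanied_fraction Fraction of patient outings made
#'   accompanied (default 0.5; controls always move alone).
#' @param accompanied_turn_multiplier Strength of the zigzag/arc
#'   decoration of accompanied routes (default 2.5; 0 disables it, making
#'   accompanied geometry identical to alone).
#' @param accompanied_extra_pauses Extra mid-route pauses on accompanied
#'   outings (default 2).
#' @param speed_range Uniform range of per-outing travel speed in m/s
#'   (default 2-6, mixing walking with faster transport).
#' @param outings_per_day Integer range of outings per day (default 1-4).
#' @param dest_dwell_range Dwell at the destination in seconds (default
#'   60-600).
#' @param pause_prob_alone Probability of one mid-route pause on an alone
#'   outing (default 0.3).
#' @param pause_duration_range Pause length in seconds (default 90-240).
#' @param waypoint_lateral_frac Lateral waypoint spread as a fraction of
#'   the destination distance (default 0.08).
#' @param waypoints_per_km Waypoint density of base routes (default 3).
#' @param master_seed Integer master seed.
#' @return A list of class `mm_cohort_config`.
#' @export
cohort_config <- function(n_controls = 18, n_patients = 15, days = 14,
                          interval_prob_3s = c(control = 13 / 18,
                                               patient = 8 / 15),
                          base_date = "2019-06-01",
                          home_spacing = 5000,
                          gps_noise_sd = 5, noise_ar_rho = 0.85,
                          n_destinations = c(control = 10, patient = 4),
                          dest_scale = c(control = 2500, patient = 650),
                          route_reuse = c(control = 0.3, patient = 0.75),
                          zipf_exponent = 1,
                          accompanied_fraction = 0.5,
                          accompanied_turn_multiplier = 2.5,
                          accompanied_extra_pauses = 2,
                          speed_range = c(2.5, 4.5),
                          outings_per_day = c(1, 4),
                          dest_dwell_range = c(60, 600),
                          pause_prob_alone = 0.3,
                          pause_duration_range = c(90, 240),
                          waypoint_lateral_frac = 0.08,
                          waypoints_per_km = 3,
                          master_seed = 1) {
  stopifnot(n_controls >= 0, n_patients >= 0, days > 0,
            gps_noise_sd >= 0, noise_ar_rho >= 0, noise_ar_rho < 1,
            accompanied_fraction >= 0, accompanied_fraction <= 1)
  structure(as.list(environment()), class = "mm_cohort_config")
}

#' Null-effect configuration
#'
#' The same generator with every group-contrast parameter set equal across
#' groups and the accompanied decoration disabled, so the two groups (and
#' alone/accompanied outings) are statistically identical.  Used for
#' calibration: downstream group tests should then be null.
#'
#' @param master_seed Integer master seed.
#' @param ... Overrides passed to [cohort_config()].
#' @return A `mm_cohort_config`.
#' @export
null_cohort_config <- function(master_seed = 1, ...) {
  args <- utils::modifyList(
    list(n_destinations = c(control = 10, patient = 10),
         dest_scale = c(control = 2500, patient = 2500),
         route_reuse = c(control = 0.65, patient = 0.65),
         interval_prob_3s = c(control = 0.65, patient = 0.65),
         accompanied_fraction = 0,
         accompanied_turn_multiplier = 0,
         accompanied_extra_pauses = 0,
         master_seed = master_seed),
    list(...))
  do.call(cohort_config, args)
}

# base piecewise-linear route from home (0,0) to dest, gentle waypoints
make_base_route <- function(dest, lateral_sd, waypoints_per_km) {
  d <- sqrt(sum(dest^2))
  nw <- max(1L, round(waypoints_per_km * d / 1000))
  fr <- seq_len(nw) / (nw + 1)
  u <- dest / d                       # unit along
  v <- c(-u[2], u[1])                 # unit lateral
  off <- stats::rnorm(nw, 0, lateral_sd)
  pts <- cbind(fr * dest[1] + off * v[1], fr * dest[2] + off * v[2])
  rbind(c(0, 0), pts, dest)
}

# shift the interior of a polyline laterally (tapered to zero at the
# endpoints): the return leg of an outing runs on the other side of the
# street, so outbound and return only come within endpoint-slack range of
# each other near home and near the destination
offset_path <- function(pts, offset) {
  n <- nrow(pts)
  if (n < 3 || offset == 0) return(pts)
  out <- pts
  for (i in 2:(n - 1)) {
    d <- pts[i + 1, ] - pts[i - 1, ]
    nd <- sqrt(sum(d^2))
    if (nd < 1e-9) next
    out[i, ] <- pts[i, ] + offset * c(-d[2], d[1]) / nd
  }
  out
}

# add interpolated vertices so decorations can attach anywhere along a route
densify_path <- function(pts, step = 100) {
  out <- pts[1, , drop = FALSE]
  for (e in seq_len(nrow(pts) - 1)) {
    a <- pts[e, ]; b <- pts[e + 1, ]
    len <- sqrt(sum((b - a)^2))
    if (len > 2 * step) {
      fr <- seq(step, len - step / 2, by = step) / len
      out <- rbind(out, cbind(a[1] + fr * (b[1] - a[1]),
                              a[2] + fr * (b[2] - a[2])))
    }
    out <- rbind(out, b)
  }
  out
}

# replace each sufficiently long edge by a semicircular "scallop": the
# meandering of an accompanied stroll.  Interior arc turns are many small
# same-signed angles whose sines accumulate (with a CCW side bias the
# signed turning sum drifts positive), while the near-reversal junctions
# between consecutive scallops are sharp enough to count as complexity
# but contribute ~sin(180) = 0 to the turning sum.  No scallop closes a
# loop, so the decoration creates no spurious return segments.
scallop_path <- function(pts, min_edge = 60, ccw_prob = 0.8, prob = 1) {
  out <- pts[1, , drop = FALSE]
  for (e in seq_len(nrow(pts) - 1)) {
    a <- pts[e, ]; b <- pts[e + 1, ]
    len <- sqrt(sum((b - a)^2))
    if (len >= min_edge && stats::runif(1) < prob) {
      side <- if (stats::runif(1) < ccw_prob) 1 else -1
      centre <- (a + b) / 2
      phi0 <- atan2(a[2] - centre[2], a[1] - centre[1])
      phi <- phi0 + side * seq(pi / 8, pi * 7 / 8, length.out = 7)
      arc <- cbind(centre[1] + len / 2 * cos(phi),
                   centre[2] + len / 2 * sin(phi))
      out <- rbind(out, arc)
    }
    out <- rbind(out, b)
  }
  out
}

ar1_noise <- function(n, sd, rho) {
  if (sd == 0 || n == 0) return(matrix(0, n, 2))
  innov_sd <- sd * sqrt(1 - rho^2)
  cbind(as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), rho,
                                 method = "recursive",
                                 init = stats::rnorm(1, 0, sd))),
        as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), rho,
                                 method = "recursive",
                                 init = stats::rnorm(1, 0, sd))))
}

# timestamped vertex schedule -> sampled positions at the tracker interval;
# within stationary windows (destination dwell, pauses) the tracker repeats
# its cached fix, as consumer GPS units do when not moving
sample_schedule <- function(vt, vx, vy, interval, noise_sd, rho,
                            stationary = NULL) {
  ts <- seq(vt[1], vt[length(vt)], by = interval)
  x <- stats::approx(vt, vx, ts)$y
  y <- stats::approx(vt, vy, ts)$y
  xy <- cbind(x, y) + ar1_noise(length(ts), noise_sd, rho)
  if (!is.null(stationary) && nrow(stationary) > 0) {
    for (k in seq_len(nrow(stationary))) {
      idx <- which(ts >= stationary[k, 1] & ts <= stationary[k, 2])
      if (length(idx) > 1)
        xy[idx, ] <- matrix(xy[idx[1], ], length(idx), 2, byrow = TRUE)
    }
  }
  list(time = ts, xy = xy)
}

# one outing: home -> destination (dwell) -> home, with optional pauses
# and accompanied decoration; returns sampled points and the end time
build_outing <- function(config, route, speed, t0, interval, accompanied) {
  m <- config$accompanied_turn_multiplier
  decorate <- function(p) {
    if (!accompanied || m <= 0) return(p)
    p <- densify_path(p, step = 100)
    scallop_path(p, prob = min(1, 0.4 * m))
  }
  out_pts <- decorate(route)
  side <- if (stats::runif(1) < 0.5) 1 else -1
  back_pts <- offset_path(route[rev(seq_len(nrow(route))), , drop = FALSE],
                          side * stats::runif(1, 15, 30))
  back_pts <- decorate(back_pts)
  # accompanied outings also stroll around the destination itself
  wander <- NULL
  if (accompanied && m > 0) {
    dest <- route[nrow(route), ]
    for (e in seq_len(max(1L, round(m)))) {
      th <- stats::runif(1, 0, 2 * pi)
      r <- stats::runif(1, 30, 60)
      wander <- rbind(wander, dest + r * c(cos(th), sin(th)), dest)
    }
  }
  n_pause <- if (accompanied) {
    config$accompanied_extra_pauses +
      stats::rbinom(1, 1, config$pause_prob_alone)
  } else stats::rbinom(1, 1, config$pause_prob_alone)
  pts <- rbind(out_pts, wander, back_pts[-1, , drop = FALSE])
  dwell_at <- nrow(out_pts)           # destination vertex (dwell, then wander)
  seglen <- sqrt(rowSums(diff(pts)^2))
  vt <- t0 + c(0, cumsum(seglen / speed))
  # destination dwell: hold the dest vertex for a while
  dwell <- stats::runif(1, config$dest_dwell_range[1],
                        config$dest_dwell_range[2])
  nv <- length(vt)
  vt2 <- c(vt[1:dwell_at], vt[dwell_at] + dwell,
           vt[(dwell_at + 1):nv] + dwell)
  vx <- c(pts[1:dwell_at, 1], pts[dwell_at, 1], pts[(dwell_at + 1):nv, 1])
  vy <- c(pts[1:dwell_at, 2], pts[dwell_at, 2], pts[(dwell_at + 1):nv, 2])
  # mid-route pauses at random vertices (not home, not the dwell pair)
  if (n_pause > 0) {
    cand <- setdiff(seq_along(vt2), c(1, dwell_at, dwell_at + 1, length(vt2)))
    cand <- cand[cand > 1]
    np <- min(n_pause, length(cand))
    if (np > 0) {
      at <- sort(sample(cand, np))
      for (j in rev(at)) {
        pd <- stats::runif(1, config$pause_duration_range[1],
                           config$pause_duration_range[2])
        vt2 <- c(vt2[1:j], vt2[j] + pd, vt2[(j + 1):length(vt2)] + pd)
        vx <- c(vx[1:j], vx[j], vx[(j + 1):length(vx)])
        vy <- c(vy[1:j], vy[j], vy[(j + 1):length(vy)])
      }
    }
  }
  # stationary windows = plateaus of duplicated vertices (dwell, pauses)
  plat <- which(diff(vx) == 0 & diff(vy) == 0 & diff(vt2) > 0)
  stationary <- cbind(vt2[plat], vt2[plat + 1])
  smp <- sample_schedule(vt2, vx, vy, interval, config$gps_noise_sd,
                         config$noise_ar_rho, stationary)
  list(time = smp$time, xy = smp$xy, t_end = vt2[length(vt2)])
}

#' Generate one synthetic participant
#'
#' Draws the participant's destination set (group-scaled distances,
#' Zipf-weighted revisit probabilities), simulates 1-4 home-anchored
#' round-trip outings per day over the tracking period with persistent,
#' possibly reused route variants, dwell pauses at destinations and (for
#' patients) accompanied outings with decorated routes, then samples
#' positions at the tracker interval, perturbs them with autocorrelated
#' Gaussian noise and converts them to latitude/longitude around the
#' participant's home.
#'
#' @param config A [cohort_config()].
#' @param group `"control"` or `"patient"`.
#' @param seed Integer seed for this participant.
#' @param index Participant index (used for the identifier and home
#'   placement).
#' @return A list with `trace` ([new_trace()]), `annotations` (data frame
#'   of outing intervals with companionship) and `ground_truth` (home,
#'   destinations, per-outing destination/route/companionship).
#' @export
generate_participant <- function(config, group, seed, index = 1) {
  set.seed(seed)
  pid <- sprintf("%s%03d", if (group == "control") "C" else "P", index)
  R <- 6371008.8
  lat0 <- 52 + ((index - 1) %% 6) * config$home_spacing / 111000
  lon0 <- 0.1 + ((index - 1) %/% 6) * config$home_spacing /
    (111000 * cos(52 * pi / 180))
  # tracker firmware is allocated in batches, not per-participant at
  # random: interleave the two sampling intervals deterministically so a
  # group's realized 3 s / 5 s mix matches its configured share
  p3 <- config$interval_prob_3s[[group]]
  interval <- if ((index * p3) %% 1 >= (1 - p3)) 3 else 5
  # destination count at the group value and distances on a fixed quantile
  # profile of the distance law: participants of a group share the same
  # destination-distance spectrum (at random bearings), so group contrasts
  # come from the group parameters rather than participant-lottery noise
  n_dest <- max(2L, round(config$n_destinations[[group]]))
  ddist <- pmax(200, config$dest_scale[[group]] *
                  stats::qgamma((seq_len(n_dest) - 0.5) / n_dest,
                                shape = 3, rate = 3))
  # decouple distance from revisit rank with a fixed permutation shared by
  # all participants (keeps the visit-weighted distance spectrum identical
  # within a group)
  ddist <- ddist[order(sin(seq_len(n_dest) * 12.9898))]
  # bearings spread around the compass with jitter, so distinct
  # destinations do not share an approach corridor
  dang <- (seq_len(n_dest) - 1) * 2 * pi / n_dest +
    stats::runif(n_dest, 0, 1.2 * pi / n_dest)
  dests <- cbind(ddist * cos(dang), ddist * sin(dang))
  zipf <- (1 / seq_len(n_dest)^config$zipf_exponent)
  zipf <- zipf / sum(zipf)
  variants <- rep(list(list()), n_dest)
  variant_use <- rep(list(numeric(0)), n_dest)
  dest_visits <- rep(0, n_dest)
  base_epoch <- as.numeric(as.POSIXct(paste(config$base_date, "00:00:00"),
                                      tz = "UTC"))
  times <- numeric(0); xs <- numeric(0); ys <- numeric(0)
  ann <- list(); gt_out <- list()
  for (day in seq_len(config$days)) {
    day_start <- base_epoch + (day - 1) * 86400
    t <- day_start + 8 * 3600 + stats::runif(1, 0, 3600)
    # routine alternation around the midpoint of the configured range,
    # with an occasional extra or skipped outing: outing volume is a
    # household habit with modest day-to-day variation
    mid <- mean(config$outings_per_day)
    n_out <- if (day %% 2 == 1) floor(mid) else ceiling(mid)
    if (stats::runif(1) < 0.2) n_out <- n_out + sample(c(-1L, 1L), 1)
    n_out <- min(max(n_out, config$outings_per_day[1]),
                 config$outings_per_day[2])
    for (o in seq_len(n_out)) {
      if (t > day_start + 20 * 3600) break
      # routinized visit schedule: destinations are visited in proportion
      # to their Zipf weights by a largest-deficit rule, reflecting the
      # habitual weekly structure of real visit sequences
      dest_k <- which.max(zipf - dest_visits / max(1, sum(dest_visits)))
      dest_visits[dest_k] <- dest_visits[dest_k] + 1
      # replay an existing variant with probability route_reuse; the pool
      # of variants per destination is capped so that long-run variant
      # counts are comparable across participants of a group
      v_max <- max(1L, round((1 - config$route_reuse[[group]]) * 6))
      reuse <- length(variants[[dest_k]]) > 0 &&
        (stats::runif(1) < config$route_reuse[[group]] ||
           length(variants[[dest_k]]) >= v_max)
      if (reuse) {
        # replay the least-recently-favoured variant so that variant usage
        # rotates evenly (habitual alternation between known routes)
        vid <- which.min(variant_use[[dest_k]][seq_along(variants[[dest_k]])])
      } else {
        d <- sqrt(sum(dests[dest_k, ]^2))
        variants[[dest_k]][[length(variants[[dest_k]]) + 1]] <-
          make_base_route(dests[dest_k, ],
                          config$waypoint_lateral_frac * d,
                          config$waypoints_per_km)
        variant_use[[dest_k]] <- c(variant_use[[dest_k]], 0)
        vid <- length(variants[[dest_k]])
      }
      variant_use[[dest_k]][vid] <- variant_use[[dest_k]][vid] + 1
      route <- variants[[dest_k]][[vid]]
      accompanied <- group == "patient" &&
        stats::runif(1) < config$accompanied_fraction
      speed <- stats::runif(1, config$speed_range[1], config$speed_range[2])
      # accompanied outings proceed at strolling pace with the carer
      if (accompanied && config$accompanied_turn_multiplier > 0)
        speed <- max(1, 0.5 * speed)
      outing <- build_outing(config, route, speed, t, interval, accompanied)
      times <- c(times, outing$time)
      xs <- c(xs, outing$xy[, 1]); ys <- c(ys, outing$xy[, 2])
      comp <- if (accompanied) "accompanied" else "alone"
      ann[[length(ann) + 1]] <- data.frame(
        participant_id = pid, start = outing$time[1],
        end = outing$time[length(outing$time)] + interval,
        companionship = comp, stringsAsFactors = FALSE)
      gt_out[[length(gt_out) + 1]] <- data.frame(
        day = day, destination = dest_k, route_variant = vid,
        companionship = comp, start = outing$time[1], end = outing$t_end)
      t <- outing$t_end + stats::runif(1, 1800, 7200)
    }
  }
  lat <- lat0 + ys / R * 180 / pi
  lon <- lon0 + xs / (R * cos(lat0 * pi / 180)) * 180 / pi
  samples <- data.frame(time = times, lat = lat, lon = lon,
                        speed = NA_real_, accuracy = NA_real_)
  trace <- new_trace(pid, group, samples, sampling_interval = interval)
  list(trace = trace,
       annotations = do.call(rbind, ann),
       ground_truth = list(participant_id = pid, group = group,
                           home = c(lat0, lon0), destinations = dests,
                           outings = do.call(rbind, gt_out)))
}

#' Generate a full synthetic cohort
#'
#' Deterministic given `config$master_seed`: participant seeds are drawn
#' once from the master seed, so each participant's trace is reproducible.
#'
#' @param config A [cohort_config()].
#' @return A list of class `mm_cohort` with `traces` (named list),
#'   `metadata` (participant/group data frame), `annotations` (pooled
#'   outing intervals) and `ground_truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$master_seed)
  n <- config$n_controls + config$n_patients
  seeds <- sample.int(2147483646, n)
  groups <- c(rep("control", config$n_controls),
              rep("patient", config$n_patients))
  traces <- list(); ann <- list(); gt <- list()
  for (i in seq_len(n)) {
    idx <- if (groups[i] == "control") i else i - config$n_controls
    p <- generate_participant(config, groups[i], seeds[i], idx)
    traces[[p$trace$participant_id]] <- p$trace
    ann[[i]] <- p$annotations
    gt[[p$trace$participant_id]] <- p$ground_truth
  }
  structure(list(traces = traces,
                 metadata = data.frame(
                   participant_id = names(traces),
                   group = groups, stringsAsFactors = FALSE),
                 annotations = do.call(rbind, ann),
                 ground_truth = gt,
                 config = config),
            class = "mm_cohort")
}

#' Write a synthetic cohort to disk in the exchange dialects
#'
#' Writes one trace CSV per participant plus `metadata.csv` and
#' `annotations.csv`, all readable back through the trace I/O functions.
#'
#' @param cohort A `mm_cohort` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in cohort$traces)
    write_trace(tr, file.path(dir, paste0(tr$participant_id, ".csv")))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  ann <- cohort$annotations
  out <- data.frame(participant_id = ann$participant_id,
                    start_iso8601 = format_iso8601(ann$start),
                    end_iso8601 = format_iso8601(ann$end),
                    companionship = ann$companionship)
  utils::write.csv(out, file.path(dir, "annotations.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
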