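write_lines <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

csv_header <- "participant_id,timestamp_iso8601,lat,lon,speed_mps,accuracy_pct"

test_that("read_trace parses well-formed CSV and sorts by time", {
  p <- write_lines(c(csv_header,
                     "P1,2019-06-01T10:00:06,52.0002,0.0002,,",
                     "P1,2019-06-01T10:00:00,52.0000,0.0000,1.2,90",
                     "P1,2019-06-01T10:00:03,52.0001,0.0001,,"))
  tr <- read_trace(p, "P1", "control")
  expect_s3_class(tr, "mm_trace")
  expect_equal(nrow(tr$samples), 3)
  expect_false(is.unsorted(tr$samples$time, strictly = TRUE))
  expect_equal(tr$samples$lat, c(52.0000, 52.0001, 52.0002))
  expect_equal(tr$samples$speed[1], 1.2)
})

test_that("malformed rows raise an error naming the line", {
  p <- write_lines(c(csv_header,
                     "P1,2019-06-01T10:00:00,52.0,0.0,,",
                     "P1,2019-06-01T10:00:03,91.2,0.0,,"))
  expect_error(read_trace(p, "P1", "control"), "line 3")
  expect_error(read_trace(write_lines(csv_header), "P1", "control"), "empty")
})

test_that("duplicate timestamps collapse to the first occurrence", {
  p <- write_lines(c(csv_header,
                     "P1,2019-06-01T10:00:00,52.0000,0.0000,,",
                     "P1,2019-06-01T10:00:00,52.5000,0.5000,,",
                     "P1,2019-06-01T10:00:03,52.0001,0.0001,,"))
  expect_message(tr <- read_trace(p, "P1", "control"), "1 duplicate")
  expect_equal(nrow(tr$samples), 2)
  expect_equal(tr$samples$lat[1], 52.0000)
})

test_that("GPX 1.1 track files are accepted", {
  p <- write_lines(c(
    "<?xml version='1.0'?>",
    "<gpx version='1.1' xmlns='http://www.topografix.com/GPX/1/1'><trk><trkseg>",
    "<trkpt lat='52.0' lon='0.1'><time>2019-06-01T10:00:00Z</time></trkpt>",
    "<trkpt lat='52.001' lon='0.1'><time>2019-06-01T10:00:05Z</time></trkpt>",
    "</trkseg></trk></gpx>"), ext = ".gpx")
  tr <- read_trace(p, "P1", "patient")
  expect_equal(nrow(tr$samples), 2)
  expect_equal(tr$samples$lat, c(52.0, 52.001))
})

test_that("write_trace round-trips timestamps and coordinates", {
  co <- small_cohort()
  tr <- co$traces[[1]]
  p <- tempfile(fileext = ".csv")
  write_trace(tr, p)
  back <- read_trace(p, tr$participant_id, tr$group)
  expect_equal(back$samples$time, round(tr$samples$time))
  expect_true(max(abs(back$samples$lat - tr$samples$lat)) < 1e-9)
  expect_true(max(abs(back$samples$lon - tr$samples$lon)) < 1e-9)
})

test_that("projection is centred and metric", {
  tr <- new_trace("P1", "control",
                  data.frame(time = c(0, 3), lat = c(52, 52.001),
                             lon = c(0.5, 0.5)))
  tr <- project_to_plane(tr, origin = c(52, 0.5))
  expect_equal(unname(tr$xy[1, ]), c(0, 0))
  d <- sqrt(sum((tr$xy[2, ] - tr$xy[1, ])^2))
  expect_equal(d, 111.19, tolerance = 1e-3)
})

test_that("planar distances agree with haversine within 0.1% over 50 km", {
  skip_if_not_installed("geosphere")
  set.seed(7)
  # a city-scale cloud: narrow in latitude (the projection fixes the
  # east-west metre scale at the median latitude), pair distances up to
  # ~50 km east-west
  lat <- 52 + runif(1000, -0.02, 0.02)
  lon <- 0.3 + runif(1000, -0.35, 0.35)
  tr <- new_trace("P1", "control",
                  data.frame(time = seq_along(lat), lat = lat, lon = lon))
  tr <- project_to_plane(tr)
  i <- sample(1000, 500); j <- sample(1000, 500)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  planar <- sqrt((tr$xy[i, 1] - tr$xy[j, 1])^2 + (tr$xy[i, 2] - tr$xy[j, 2])^2)
  geo <- geosphere::distHaversine(cbind(lon[i], lat[i]), cbind(lon[j], lat[j]),
                                  r = 6371008.8)   # same sphere as the projection
  expect_true(all(abs(planar - geo) / geo < 1e-3))
})

test_that("bout splitting partitions the samples at long gaps", {
  tr <- planar_trace(matrix(0, 100, 2), time = seq(0, by = 3, length.out = 100))
  b <- split_bouts(tr, 60)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end), c(1, 101))

  tm <- c(seq(0, by = 3, length.out = 50), seq(7500, by = 3, length.out = 50))
  tr2 <- planar_trace(matrix(0, 100, 2), time = tm)
  b2 <- split_bouts(tr2, 60)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$end[1], 51)

  tr3 <- planar_trace(matrix(0, 1, 2), time = 0)
  expect_equal(split_bouts(tr3, 60), data.frame(start = 1L, end = 2L))

  # partition property: every index in exactly one bout
  tr4 <- random_walk_trace(300, seed = 11, gap_prob = 0.02)
  b4 <- split_bouts(tr4, 60)
  covered <- unlist(mapply(function(s, e) s:(e - 1), b4$start, b4$end))
  expect_equal(sort(covered), 1:300)
  expect_equal(anyDuplicated(covered), 0)
})

test_that("companionship labelling follows interval containment and majority", {
  tr <- planar_trace(matrix(0, 10, 2), time = 0:9 * 3, id = "P1")
  ann <- data.frame(participant_id = "P1", start = 0, end = 100,
                    companionship = "alone")
  expect_equal(unique(label_companionship(tr, ann)), "alone")
  expect_equal(unique(label_companionship(tr, NULL)), "unknown")

  # 60% alone, 40% accompanied -> majority alone
  labs <- c(rep("alone", 6), rep("accompanied", 4))
  expect_equal(segment_companionship(labs), "alone")
  # >50% unlabelled -> unknown
  expect_equal(segment_companionship(c(rep("unknown", 6), rep("alone", 4))),
               "unknown")
  expect_equal(segment_companionship(character(0)), "unknown")
})

test_that("trace validation rejects out-of-range coordinates", {
  expect_error(new_trace("P", "control",
                         data.frame(time = 1, lat = 95, lon = 0)), "latitude")
  expect_error(new_trace("P", "control",
                         data.frame(time = 1, lat = 0, lon = 200)), "longitude")
  expect_error(new_trace("P", "oops", data.frame(time = 1, lat = 0, lon = 0)))
})
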