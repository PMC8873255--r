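# a square loop of given perimeter walked in the given time, returning to
# the start exactly
square_loop <- function(perimeter, duration, n = 40, jitter = 0) {
  side <- perimeter / 4
  s <- seq(0, 1, length.out = n / 4 + 1)[-1]
  pts <- rbind(c(0, 0),
               cbind(side * s, 0),
               cbind(side, side * s),
               cbind(side - side * s, side),
               cbind(0, side - side * s))
  if (jitter > 0) pts <- pts + matrix(rnorm(2 * nrow(pts), 0, jitter),
                                      ncol = 2)
  planar_trace(pts, time = seq(0, duration, length.out = nrow(pts)))
}

test_that("candidate endpoints are defined by the distance predicate", {
  tr <- planar_trace(matrix(0, 20, 2), time = 0:19 * 3)
  expect_equal(candidate_endpoints(tr, 1), 2:20)

  line <- planar_trace(cbind(0:19 * 12, 0), time = 0:19 * 3)  # 4 m/s outbound
  expect_length(candidate_endpoints(line, 1), 0)

  out_back <- planar_trace(cbind(c(0:10, 9:0) * 20, 0), time = 0:20 * 10)
  cand <- candidate_endpoints(out_back, 1)
  expect_true(21 %in% cand)    # exact return to start
  # brute-force check of the predicate
  d <- sqrt(rowSums((out_back$xy - matrix(out_back$xy[1, ], 21, 2,
                                          byrow = TRUE))^2))
  expect_equal(cand, which(d <= 10 & seq_len(21) > 1))
})

test_that("a valid loop is extracted and the stated filters apply", {
  tr <- square_loop(400, 300)       # 400 m in 5 min
  segs <- extract_segments(tr)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_idx, 1)
  expect_equal(segs$end_idx, nrow(tr$samples))
  expect_gte(segs$path_length_m, 100)

  expect_equal(nrow(extract_segments(square_loop(400, 1500))), 0)  # 25 min
  expect_equal(nrow(extract_segments(square_loop(50, 120))), 0)    # 50 m
})

test_that("the longer of two loops from one start is chosen", {
  # figure-eight: small loop (idx 1..21) then large loop (idx 1..61);
  # both start and end within slack of the origin
  small <- square_loop(200, 100)$xy
  big <- square_loop(600, 200)$xy * c(1, -1)
  xy <- rbind(small, big[-1, ])
  tr <- planar_trace(xy, time = seq(0, 700, length.out = nrow(xy)))
  segs <- extract_segments(tr)
  expect_equal(segs$start_idx[1], 1)
  expect_equal(segs$end_idx[1], nrow(xy))   # maximum path length wins
  oracle <- oracle_segments(tr)
  expect_equal(cbind(segs$start_idx, segs$end_idx), unname(oracle))
})

test_that("extraction equals the quadratic brute-force reference on random traces", {
  for (s in 1:50) {
    tr <- random_walk_trace(n = 200 + (s %% 5) * 200, seed = 1000 + s,
                            return_prob = 0.05, gap_prob = 0.005)
    segs <- extract_segments(tr)
    oracle <- oracle_segments(tr)
    got <- if (nrow(segs) == 0) NULL else cbind(segs$start_idx, segs$end_idx)
    expect_equal(got, unname(oracle), info = paste("seed", 1000 + s))
  }
})

test_that("segments never overlap and satisfy every filter", {
  params <- segment_params()
  for (s in 1:10) {
    tr <- random_walk_trace(800, seed = 2000 + s, return_prob = 0.05)
    segs <- extract_segments(tr, params)
    if (nrow(segs) < 1) next
    spans <- mapply(function(a, b) a:b, segs$start_idx, segs$end_idx)
    expect_equal(anyDuplicated(unlist(spans)), 0)
    for (k in seq_len(nrow(segs))) {
      i <- segs$start_idx[k]; j <- segs$end_idx[k]
      expect_lte(sqrt(sum((tr$xy[i, ] - tr$xy[j, ])^2)), params$slack_radius)
      expect_gte(segs$duration_s[k], params$min_duration)
      expect_lte(segs$duration_s[k], params$max_duration)
      expect_gte(segs$path_length_m[k], params$min_length)
    }
  }
})

test_that("halving the length threshold never reduces the segment count", {
  for (s in 1:5) {
    tr <- random_walk_trace(600, seed = 3000 + s, return_prob = 0.05)
    n_full <- nrow(extract_segments(tr, segment_params(min_length = 100)))
    n_half <- nrow(extract_segments(tr, segment_params(min_length = 50)))
    expect_gte(n_half, n_full)
  }
})

test_that("segments never span recording gaps", {
  # two complete loops separated by a 2 h recording gap
  one <- square_loop(400, 300)
  xy <- rbind(one$xy, one$xy)
  n1 <- nrow(one$xy)
  tm <- c(one$samples$time, one$samples$time + 300 + 7200)
  tr2 <- planar_trace(xy, time = tm)
  segs <- extract_segments(tr2)
  bouts <- split_bouts(tr2)
  expect_equal(nrow(bouts), 2)
  expect_equal(nrow(segs), 2)       # one loop per bout, none across the gap
  for (k in seq_len(nrow(segs))) {
    b <- which(bouts$start <= segs$start_idx[k] & segs$start_idx[k] < bouts$end)
    expect_true(segs$end_idx[k] < bouts$end[b])
  }
})
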