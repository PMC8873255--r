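rot <- function(xy, deg) {
  th <- deg * pi / 180
  xy %*% t(matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE))
}

test_that("first-order turning angles match elementary geometry", {
  line <- cbind(0:5 * 10, 0)
  expect_equal(turning_angles(line)$theta1, rep(0, 4))

  left <- rbind(c(0, 0), c(10, 0), c(10, 10))        # 90 degree left turn
  expect_equal(turning_angles(left)$theta1, 90)

  right <- rbind(c(0, 0), c(10, 0), c(10, -10))      # clockwise -> 270
  expect_equal(turning_angles(right)$theta1, 270)

  back <- rbind(c(0, 0), c(10, 0), c(0, 0))          # exact reversal
  expect_equal(turning_angles(back)$theta1, 180)
})

test_that("duplicate points are merged before angle computation", {
  withdup <- rbind(c(0, 0), c(10, 0), c(10, 0), c(10, 10))
  expect_equal(turning_angles(withdup)$theta1, 90)
  allsame <- matrix(1, 5, 2)
  expect_length(turning_angles(allsame)$theta1, 0)
})

test_that("complexity counts averaged angles above the threshold", {
  line <- cbind(0:9 * 10, 0)
  expect_equal(segment_complexity(turning_angles(line)), 0)

  # 6-point hairpin: out along +x, back along -x; at the tip both the
  # first- and second-order angles are 180
  hair <- rbind(c(0, 0), c(10, 0), c(20, 0), c(10, 0), c(0, 0), c(-10, 0))
  expect_equal(segment_complexity(turning_angles(hair)), 1)

  # direction-reversal invariance on random paths
  set.seed(21)
  for (r in 1:100) {
    xy <- apply(matrix(rnorm(40, 0, 10), ncol = 2), 2, cumsum)
    fwd <- segment_complexity(turning_angles(xy))
    rev_ <- segment_complexity(turning_angles(xy[nrow(xy):1, ]))
    expect_equal(fwd, rev_)
  }
})

test_that("total turning angle sums sines with sign", {
  line <- cbind(0:9 * 10, 0)
  expect_equal(total_turning_angle(turning_angles(line)), 0)

  # square spiral: every turn is a 90 degree counterclockwise turn
  for (m in c(3, 6, 10)) {
    dirs <- rbind(c(10, 0), c(0, 10), c(-10, 0), c(0, -10))
    steps <- dirs[(0:m) %% 4 + 1, ]
    xy <- rbind(c(0, 0), apply(steps, 2, cumsum))
    expect_equal(total_turning_angle(turning_angles(xy)), m, tolerance = 1e-9)
  }

  # one left and one right turn cancel
  z <- rbind(c(0, 0), c(10, 0), c(10, 10), c(20, 10))
  expect_equal(total_turning_angle(turning_angles(z)), 0, tolerance = 1e-12)
})

test_that("shape features respect rotation/reflection symmetries and bounds", {
  set.seed(31)
  for (r in 1:20) {
    xy <- apply(matrix(rnorm(30, 0, 10), ncol = 2), 2, cumsum)
    n <- nrow(xy)
    ang <- turning_angles(xy)
    rxy <- rot(xy, runif(1, 0, 360))
    rang <- turning_angles(rxy)
    expect_equal(segment_complexity(rang), segment_complexity(ang))
    expect_equal(total_turning_angle(rang), total_turning_angle(ang),
                 tolerance = 1e-8)
    expect_equal(radius_of_gyration(rxy), radius_of_gyration(xy),
                 tolerance = 1e-8)
    # reflection negates the signed turning sum
    expect_equal(total_turning_angle(turning_angles(xy %*% diag(c(1, -1)))),
                 -total_turning_angle(ang), tolerance = 1e-8)
    # |sum of sines| bounded by the number of angles
    expect_lte(abs(total_turning_angle(ang)), n - 2)
  }
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(5, 7, 2)), 0)
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  circ <- cbind(40 * cos(th), 40 * sin(th)) + 7
  expect_equal(radius_of_gyration(circ), 40, tolerance = 1e-9)
  two <- rbind(c(-30, 0), c(30, 0))
  expect_equal(radius_of_gyration(two), 30)
})

test_that("stop detection follows the anchored-window rule", {
  # moving, then static for 120 s, then moving again
  xy <- rbind(cbind(0:9 * 20, 0),
              matrix(rep(c(200, 0), 40), ncol = 2, byrow = TRUE),
              cbind(200 + 1:10 * 20, 0))
  tm <- seq_len(nrow(xy)) * 3
  st <- detect_stops(xy, tm)
  expect_equal(st$count, 1)
  expect_gte(st$durations[1], 117)

  moving <- cbind(seq_len(50) * 12, 0)          # 4 m/s throughout
  expect_equal(detect_stops(moving, seq_len(50) * 3)$count, 0)

  # 30 s of standstill is below the one-minute rule
  xy2 <- rbind(cbind(0:9 * 20, 0), matrix(rep(c(200, 0), 10), ncol = 2,
                                          byrow = TRUE))
  expect_equal(detect_stops(xy2, seq_len(nrow(xy2)) * 3)$count, 0)
})

test_that("stop detection equals the all-windows oracle on random segments", {
  set.seed(41)
  for (r in 1:100) {
    n <- sample(30:300, 1)
    # mixture of movement and pauses
    step <- matrix(rnorm(2 * n, 0, 6), ncol = 2)
    pause <- runif(n) < 0.25
    step[pause, ] <- step[pause, , drop = FALSE] * 0.05
    xy <- apply(step, 2, cumsum)
    tm <- cumsum(c(0, rep(3, n - 1)))
    got <- detect_stops(xy, tm)
    want <- oracle_stops(xy, tm)
    expect_equal(got$durations, as.numeric(want$durations))
    expect_equal(got$count, want$count)
  }
})
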