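test_that("interpolar fraction counts cross-pole crosslink engagement", {
  p <- tiny_params()
  st <- make_fixture("frozen_antiparallel_pair", p, seed = 1)
  expect_equal(interpolar_fraction(st), 0)  # all crosslinkers free

  # hand-built 28-MT state with exactly 7 engaged MTs
  st <- initialize_spindle(p, seed = 2)
  # 4 crosslinks engaging MT pairs (1,15), (2,16), (3,17), (4,15): MTs
  # 1,2,3,4,15,16,17 are engaged -> 7 of 28
  pairs <- list(c(1, 15), c(2, 16), c(3, 17), c(4, 15))
  for (i in seq_along(pairs)) {
    st$xl$state[i] <- 2L
    st$xl$mt0[i] <- pairs[[i]][1]
    st$xl$mt1[i] <- pairs[[i]][2]
    st$xl$geom[i, c("x0", "x1")] <- 0.05
  }
  expect_equal(interpolar_fraction(st), 7 / 28)

  # same-pole crosslinks never count
  st2 <- initialize_spindle(p, seed = 2)
  st2$xl$state[1] <- 2L
  st2$xl$mt0[1] <- 1L
  st2$xl$mt1[1] <- 2L
  expect_equal(interpolar_fraction(st2), 0)

  # full engagement
  st3 <- initialize_spindle(p, seed = 2)
  for (i in 1:14) {
    st3$xl$state[i] <- 2L
    st3$xl$mt0[i] <- i
    st3$xl$mt1[i] <- i + 14L
    st3$xl$geom[i, c("x0", "x1")] <- 0.05
  }
  expect_equal(interpolar_fraction(st3), 1)
  expect_equal(interpolar_fraction(st3, method = "length"), 1)

  # rotation invariance: rotating every coordinate leaves IF unchanged
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- st
  rot$mt$geom[, 1:3] <- st$mt$geom[, 1:3] %*% t(Rz)
  rot$mt$geom[, 4:6] <- st$mt$geom[, 4:6] %*% t(Rz)
  expect_equal(interpolar_fraction(rot), interpolar_fraction(st))
})

test_that("bipolarity classifier implements the sustained-threshold rule", {
  fi <- 1
  # plateau from 300 s to the end of a 600 s run
  s <- make_fixture("engineered_if_series", plateau = 0.5, start = 300)
  cls <- classify_success(s$if_series, fi)
  expect_true(cls$success)
  expect_equal(cls$start_time, 300)

  # one 10 s dip inside the epoch is tolerated
  s <- make_fixture("engineered_if_series", plateau = 0.5, start = 300,
                    dips = list(c(at = 400, length = 10)))
  cls <- classify_success(s$if_series, fi)
  expect_true(cls$success)
  expect_equal(cls$start_time, 300)

  # a 13 s dip is not
  s <- make_fixture("engineered_if_series", plateau = 0.5, start = 300,
                    dips = list(c(at = 400, length = 13)))
  cls <- classify_success(s$if_series, fi)
  # the epoch restarts after the long dip: still succeeds from 413 s
  expect_true(cls$success)
  expect_equal(cls$start_time, 413)

  # a 13 s dip too close to the end: the post-dip epoch is < 2 min
  s <- make_fixture("engineered_if_series", plateau = 0.5, start = 300,
                    dips = list(c(at = 500, length = 13)))
  expect_false(classify_success(s$if_series, fi)$success)

  # multiple short dips are each tolerated
  s <- make_fixture("engineered_if_series", plateau = 0.5, start = 300,
                    dips = list(c(at = 350, length = 8),
                                c(at = 450, length = 11)))
  expect_true(classify_success(s$if_series, fi)$success)

  # never crosses the threshold
  s <- make_fixture("engineered_if_series", plateau = 0.19, start = 0)
  expect_false(classify_success(s$if_series, fi)$success)

  # crosses only in the last 60 s: duration < 2 min
  s <- make_fixture("engineered_if_series", plateau = 0.5, start = 540)
  expect_false(classify_success(s$if_series, fi)$success)

  # invariant to prepending sub-threshold history
  s <- make_fixture("engineered_if_series", plateau = 0.5, start = 300)
  pre <- c(rep(0, 100), s$if_series)
  cls <- classify_success(pre, fi)
  expect_true(cls$success)
  expect_equal(cls$start_time, 400)

  # raising the threshold above the maximum turns success into failure
  expect_false(classify_success(s$if_series, fi, threshold = 1.01)$success)

  expect_error(classify_success(rep(0.5, 50), fi), "too short")
})

test_that("late-time separation is the mean over the final window", {
  traj <- data.frame(time = 0:600, separation = rep(2, 601))
  expect_equal(late_time_separation(traj), 2)

  # linear ramp from 1 to 2 um over the last 30 s: mean is the midpoint
  sep <- c(rep(1, 570), seq(1, 2, length.out = 31))
  traj <- data.frame(time = 0:600, separation = sep)
  expect_equal(late_time_separation(traj), 1.5, tolerance = 1e-12)
})

test_that("scan aggregation counts successes and flags empty sets", {
  samples <- list(
    structure(list(id = 1, values = c(number = 10, growth_speed = 0.1)),
              class = "parameter_sample"),
    structure(list(id = 2, values = c(number = 20, growth_speed = 0.2)),
              class = "parameter_sample"))
  runs <- data.frame(
    sample_id = rep(1:2, each = 12),
    replicate = rep(1:12, 2),
    success = c(rep(c(TRUE, FALSE), 6), rep(FALSE, 12)),
    late_separation = runif(24, 1, 2),
    mean_mt_length = runif(24, 0.5, 1))
  agg <- aggregate_scan(list(samples = samples, runs = runs))
  expect_equal(agg$per_sample$success_fraction, c(0.5, 0))
  expect_true(is.na(agg$per_sample$mean_separation[2]))
  expect_equal(agg$overall_success_pct, 25)
  expect_named(agg$marginals, c("number", "growth_speed"))
})
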