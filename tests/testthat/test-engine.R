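test_that("side-by-side initialization meets its contract", {
  p <- tiny_params()
  st <- initialize_spindle(p, seed = 42)
  expect_equal(nrow(st$mt$geom), 2 * p$geometry$sites_per_spb)
  expect_true(all(st$mt$geom[, "length"] == p$geometry$initial_mt_length))
  R <- p$geometry$envelope_diameter / 2
  sep <- sqrt(sum((st$spb[[1]]$u * R - st$spb[[2]]$u * R)^2))
  expect_lte(sep, 2 * p$geometry$spb_diameter)
  expect_equal(sep, p$geometry$spb_diameter, tolerance = 1e-9)
  # orientations unit, crosslinkers all free inside the envelope
  nn <- sqrt(rowSums(st$mt$geom[, 4:6]^2))
  expect_lt(max(abs(nn - 1)), 1e-9)
  expect_true(all(st$xl$state == 0))
  expect_true(all(sqrt(rowSums(st$xl$geom[, 1:3]^2)) <= R))

  # bitwise determinism
  expect_identical(st, initialize_spindle(p, seed = 42))
  expect_false(identical(st, initialize_spindle(p, seed = 43)))

  expect_error(initialize_spindle(
    spindle_params(geometry = list(spb_diameter = 5, envelope_diameter = 3)),
    seed = 1), "envelope")
})

test_that("runs are reproducible and frames are on the recording grid", {
  p <- fast_reference(total_time = 30, frame_interval = 2)
  r1 <- run_simulation(p, seed = 7)
  r2 <- run_simulation(p, seed = 7)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$final_state, r2$final_state)
  expect_equal(r1$trajectory$time, seq(0, 30, by = 2))
  r3 <- run_simulation(p, seed = 8)
  expect_false(identical(r1$trajectory$separation, r3$trajectory$separation))
})

test_that("null model shows no sustained bipolarity signal", {
  # no crosslinkers, no wall force: SPB separation performs a bounded random
  # walk and the interpolar fraction stays identically zero
  p <- spindle_params(
    crosslinkers = list(number = 0),
    wall_force = list(asymptotic_force = 0),
    control = fast_control(total_time = 150))
  r <- run_simulation(p, seed = 3)
  expect_true(all(r$trajectory$interpolar_fraction == 0))
  R <- p$geometry$envelope_diameter
  expect_true(all(r$trajectory$separation <= R))
})

test_that("parameter scans schedule the requested runs deterministically", {
  rg <- sampling_ranges()
  base <- fast_reference(total_time = 10)  # smoke-scale runs (unclassified)
  sc <- run_parameter_scan(rg, n_sets = 2, replicates = 3, seed = 5,
                           base = base)
  expect_equal(nrow(sc$runs), 6)
  expect_equal(sort(unique(sc$runs$sample_id)), 1:2)
  expect_length(sc$samples, 2)
  sc2 <- run_parameter_scan(rg, n_sets = 2, replicates = 3, seed = 5,
                            base = base)
  expect_identical(sc$runs, sc2$runs)

  # knockout scan pins all factors at one
  k <- run_parameter_scan(rg, n_sets = 2, replicates = 1, seed = 5,
                          stabilization_enabled = FALSE, base = base)
  for (s in k$samples)
    expect_true(all(s$values[c("growth_factor", "shrink_factor",
                               "catastrophe_factor", "rescue_factor")] == 1))

  # checkpoint + resume reproduces the uninterrupted scan
  pf <- tempfile(fileext = ".jsonl")
  sc3 <- run_parameter_scan(rg, n_sets = 2, replicates = 3, seed = 5,
                            base = base, progress_file = pf)
  expect_true(file.exists(pf))
  sc4 <- run_parameter_scan(rg, n_sets = 2, replicates = 3, seed = 5,
                            base = base, progress_file = pf, resume = TRUE)
  expect_equal(sc4$runs$success, sc3$runs$success)
  expect_equal(sc4$runs$late_separation, sc3$runs$late_separation)
})

test_that("single-parameter sweeps hold everything else at reference", {
  vals <- seq(0, 14.8, length.out = 24)  # the wall-force sweep grid
  expect_length(vals, 24)
  expect_equal(diff(range(diff(vals))), 0)

  base <- fast_reference(total_time = 10)
  sw <- run_single_parameter_sweep("asymptotic_force", c(0, 7), replicates = 2,
                                   seed = 2, base = base)
  expect_equal(nrow(sw$runs), 4)
  expect_equal(sw$summary$value, c(0, 7))

  # degenerate single-value sweep equals a replicate batch
  sw1 <- run_single_parameter_sweep("number", 150, replicates = 2, seed = 2,
                                    base = base)
  expect_equal(nrow(sw1$runs), 2)

  expect_error(run_single_parameter_sweep("no_such_knob", 1, 1),
               "usage error")
})

test_that("run outputs can be archived and reproduce their configuration", {
  p <- fast_reference(total_time = 10)
  r <- run_simulation(p, seed = 12)
  d <- tempfile()
  save_run(r, d)
  expect_true(file.exists(file.path(d, "trajectory.csv")))
  expect_true(file.exists(file.path(d, "summary.json")))
  q <- load_config(file.path(d, "config.yaml"))
  expect_equal(q$crosslinkers, p$crosslinkers, tolerance = 1e-9)
  tr <- utils::read.csv(file.path(d, "trajectory.csv"))
  expect_equal(nrow(tr), nrow(r$trajectory))
})
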