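test_that("centroids follow the weighted-mean closed forms", {
  co <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(mass_weighted_centroid(co, 1:2, c(1, 1)), c(1, 0, 0))
  co2 <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(mass_weighted_centroid(co2, 1:2, c(1, 3)), c(3, 0, 0))
  expect_equal(mass_weighted_centroid(co2, 2, c(1, 3)), c(4, 0, 0))
  expect_error(mass_weighted_centroid(co, integer(0), c(1, 1)), "empty")
})

test_that("the least-squares slope matches exact lines and the textbook formula", {
  expect_equal(ols_slope(c(0, 1, 2), c(10, 9, 8)), -1)
  expect_identical(ols_slope(c(0, 1, 2), c(7, 7, 7)), 0)
  set.seed(31)
  t <- sort(runif(200, 0, 50))
  d <- 20 - 0.1 * t + rnorm(200)
  expect_equal(ols_slope(t, d), oracle_slope(t, d), tolerance = 1e-10)
  expect_error(ols_slope(1, 2), ">= 2")
  expect_error(ols_slope(c(2, 2, 2), c(1, 2, 3)), "zero variance")
})

test_that("window decisions follow the sign of the slope", {
  sys <- tiny_stub_system()
  ecfg <- engine_config(dielectric = 1)
  scfg <- supervision_config(seed = 1)
  st <- sim_state(sys, seed = 1)

  dec <- stub_engine_from_distance(function(t) 12 - 0.1 * t)
  out <- supervised_window(sys, st, ecfg, scfg, engine = dec)
  expect_equal(out$record$decision, "accepted")
  expect_lt(out$record$slope, 0)
  expect_equal(out$state$time, scfg$window_length)

  cst <- stub_engine_from_distance(function(t) 7)
  out2 <- supervised_window(sys, st, ecfg, scfg, engine = cst,
                            retry_seed = 5)
  expect_equal(out2$record$decision, "retried")
  expect_identical(out2$record$slope, 0)  # zero slope counts as a failure
  # a rejected window returns the start coordinates and clock with
  # freshly drawn velocities
  expect_identical(out2$state$coords, st$coords)
  expect_equal(out2$state$time, st$time)
  expect_false(identical(out2$state$velocities, st$velocities))
})

test_that("a never-improving run terminates after the configured failures", {
  sys <- tiny_stub_system()
  ecfg <- engine_config(dielectric = 1)
  scfg <- supervision_config(seed = 2)
  st <- sim_state(sys, seed = 2)
  res <- run_sumd(sys, st, ecfg, scfg,
                  engine = stub_engine_from_distance(function(t) 12))
  expect_equal(res$status, "unbound_terminated")
  expect_equal(nrow(res$windows), 30)
  expect_true(all(res$windows$decision == "retried"))
  expect_equal(max(res$windows$consecutive_failures_after), 30)
  expect_null(res$trajectory)
  expect_true(is.na(res$first_binding_time))
  # retried windows never advance the accepted clock
  expect_true(all(res$windows$start_time == 0))
  expect_equal(res$total_simulated_time, 30 * scfg$window_length)
})

test_that("phases switch exactly at the binding threshold", {
  sys <- tiny_stub_system()
  ecfg <- engine_config(dielectric = 1)
  scfg <- supervision_config(seed = 3, production_length = 10)
  st <- sim_state(sys, seed = 3)
  # distance falls 1 A per 10 ps window from 12, then plateaus at 1
  res <- run_sumd(sys, st, ecfg, scfg,
                  engine = stub_engine_from_distance(
                    function(t) max(12 - 0.1 * t, 1)))
  expect_equal(res$status, "bound")
  w <- res$windows
  sup <- w[w$phase == "supervised", ]
  # windows end at 11, 10, ..., 5, 4; the window ending at 4 (the first
  # strictly below 5) is the 8th and the last supervised one
  expect_equal(nrow(sup), 8)
  expect_equal(sup$end_distance, seq(11, 4), tolerance = 1e-12)
  expect_equal(sum(w$phase == "unsupervised_check"),
               scfg$n_unsupervised_checks)
  expect_equal(sum(w$phase == "production"), 1)
  # exact time accounting: every attempted window counts
  expect_equal(res$total_simulated_time,
               8 * scfg$window_length +
                 scfg$n_unsupervised_checks *
                 scfg$unsupervised_window_length +
                 scfg$production_length)
  # first crossing is inside window 8 (between 70 and 80 ps)
  expect_true(res$first_binding_time > 70 && res$first_binding_time <= 80)
})

test_that("window decisions equal the independent slope oracle on random series", {
  sys <- tiny_stub_system()
  ecfg <- engine_config(dielectric = 1)
  scfg <- supervision_config(seed = 4)
  st <- sim_state(sys, seed = 4)
  set.seed(77)
  agree <- 0L
  n_series <- 200
  for (i in seq_len(n_series)) {
    d <- runif(scfg$n_distance_samples, 2, 40)
    eng <- stub_engine_from_series(list(d))
    out <- supervised_window(sys, st, ecfg, scfg, engine = eng,
                             retry_seed = i)
    ds <- out$record$distance_series
    expected <- if (oracle_slope(ds$time_ps, ds$distance_A) < 0)
      "accepted" else "retried"
    agree <- agree + as.integer(out$record$decision == expected)
  }
  expect_equal(agree, n_series)
})

test_that("failure bookkeeping and time accounting hold on random runs", {
  sys <- tiny_stub_system()
  ecfg <- engine_config(dielectric = 1)
  set.seed(55)
  for (rep in 1:5) {
    scfg <- supervision_config(seed = rep, max_consecutive_failures = 6,
                               n_unsupervised_checks = 3,
                               production_length = 0, time_budget = 3500)
    # random-walk distance sequence bouncing above/below the threshold
    n_wins <- 400
    series <- lapply(seq_len(n_wins), function(i)
      pmax(runif(1, 1, 15) + cumsum(rnorm(20, 0, 0.3)), 0.5))
    st <- sim_state(sys, seed = rep)
    res <- run_sumd(sys, st, ecfg, scfg,
                    engine = stub_engine_from_series(series))
    w <- res$windows
    expect_true(res$status %in% c("bound", "unbound_terminated",
                                  "budget_exhausted"))
    expect_true(all(w$consecutive_failures_after <=
                      scfg$max_consecutive_failures))
    # the counter resets to zero on every accepted window
    acc <- which(w$decision == "accepted" & w$phase == "supervised")
    expect_true(all(w$consecutive_failures_after[acc] == 0))
    # exact time accounting over all attempted windows
    expect_equal(res$total_simulated_time,
                 sum(ifelse(w$phase == "supervised", scfg$window_length,
                            scfg$unsupervised_window_length)))
    # accepted trajectory clock is strictly increasing
    if (!is.null(res$trajectory))
      expect_true(all(diff(res$trajectory$times) > 0))
  }
})

test_that("a ligand already inside the threshold is rejected upfront", {
  sys <- tiny_stub_system(ligand_x = 2)
  st <- sim_state(sys, seed = 1)
  expect_error(run_sumd(sys, st, engine_config(dielectric = 1),
                        supervision_config()),
               "already within")
})

test_that("supervised runs are reproducible given the same seeds", {
  sys <- build_funnel_system(scenario_config(seed = 1))
  ecfg <- default_funnel_engine_config(sys)
  scfg <- supervision_config(seed = 9, time_budget = 60,
                             production_length = 0)
  st <- sim_state(sys, seed = 9)
  a <- run_sumd(sys, st, ecfg, scfg)
  b <- run_sumd(sys, st, ecfg, scfg)
  expect_identical(a$windows, b$windows)
  expect_identical(a$final_state$coords, b$final_state$coords)
})
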