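p333 <- construct_params("333")

test_that("ctmc_equilibrium solves the stationary distribution", {
  # full symmetry: all states equivalent
  eq <- ctmc_equilibrium(setNames(rep(2, 6), gqfret:::gq_rate_labels()))
  expect_equal(unname(eq), rep(1 / 3, 3), tolerance = 1e-12)

  # reducible-but-unique case from the folding cycle with no exits to UF:
  # analytic stationary = (P 0.5, AP 0.5, UF 0), cross-checked by the
  # independent exponential-race oracle
  rates <- c(P_AP = 1, P_U = 0, AP_P = 1, AP_U = 0, U_P = 1, U_AP = 1)
  eq <- ctmc_equilibrium(rates)
  expect_equal(unname(eq), c(0.5, 0.5, 0), tolerance = 1e-12)
  set.seed(31)
  occ <- oracle_ctmc_occupancy(rates, total_time = 5000, start = "P")
  expect_equal(unname(eq), unname(occ), tolerance = 0.03)

  # time-rescaling invariance
  expect_equal(ctmc_equilibrium(p333$rates), ctmc_equilibrium(10 * p333$rates),
               tolerance = 1e-12)

  # no unique stationary distribution -> error naming the states
  expect_error(ctmc_equilibrium(setNames(rep(0, 6), gqfret:::gq_rate_labels())),
               "no unique stationary")
  expect_error(ctmc_equilibrium(c(P_AP = 0, P_U = 0, AP_P = 0, AP_U = 0,
                                  U_P = 1, U_AP = 1)),
               "P.*AP|AP.*P")
})

test_that("simulate_trajectory respects the kinetic model", {
  # absorbing start state: constant path at the parallel FRET level
  frozen <- p333
  frozen$rates[] <- 0
  tr <- simulate_trajectory(frozen, duration = 30, dt = 0.1, seed = 5,
                            start_state = "P", bleach_rate = 0)
  expect_true(all(tr$truth$frame_states == "P"))
  fret <- tr$acceptor / (tr$acceptor + tr$donor)
  expect_equal(mean(fret), 0.55, tolerance = 0.02)

  # mean dwell of P with exit rates 0.1 + 0.1 is 5 s
  two_exit <- frozen
  two_exit$rates[c("P_AP", "P_U")] <- 0.1
  set.seed(17)
  dwells <- replicate(400, {
    path <- gqfret:::gillespie_path(two_exit$rates, 1e5, "P")
    path$durations[1]
  })
  expect_equal(mean(dwells), 5, tolerance = 3 * 5 / sqrt(400))

  # determinism: identical (params, seed) -> byte-identical traces
  a <- simulate_trajectory(p333, 20, dt = 0.1, seed = 99)
  b <- simulate_trajectory(p333, 20, dt = 0.1, seed = 99)
  expect_identical(a, b)

  expect_error(simulate_trajectory(p333, duration = 0.05, dt = 0.1), "duration")
})

test_that("long-run occupancy matches the stationary distribution", {
  eq <- ctmc_equilibrium(p333$rates)
  set.seed(23)
  tr <- simulate_trajectory(p333, duration = 4000, dt = 0.1, seed = NULL,
                            bleach_rate = 0)
  occ <- prop.table(table(factor(tr$truth$frame_states, levels = c("P", "AP", "UF"))))
  # CLT error for a Markov chain: use a generous 3x iid binomial scale
  for (s in c("P", "AP", "UF")) {
    tol <- 3 * sqrt(eq[s] * (1 - eq[s]) / 400)  # ~400 effective dwells
    expect_lt(abs(occ[s] - eq[s]), max(tol, 0.05))
  }
})

test_that("simulated dwell times are exponential with the generator's exit rates", {
  # long traces: completed dwells in a window much shorter than ~100x the
  # mean dwell carry a detectable right-censoring selection bias
  set.seed(41)
  traces <- simulate_population(p333, 25, frames_per_molecule = 4800,
                                mode = "dynamic", bleach_rate = 0)
  dw <- truth_dwells(traces)
  done <- dw[!dw$censored, ]
  exit_rates <- c(P = sum(p333$rates[c("P_AP", "P_U")]),
                  AP = sum(p333$rates[c("AP_P", "AP_U")]),
                  UF = sum(p333$rates[c("U_P", "U_AP")]))
  for (s in names(exit_rates)) {
    d <- done$duration[done$state == s]
    expect_gt(length(d), 200)
    ks <- suppressWarnings(stats::ks.test(d, "pexp", rate = exit_rates[s]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("snapshot populations draw states from the registry fractions", {
  pure <- p333
  pure$fractions <- c(P = 1, AP = 0, UF = 0)
  snap <- simulate_snapshot_fret(pure, 100, seed = 3)
  expect_true(all(snap$state == "P"))

  half <- p333
  half$fractions <- c(P = 0.5, AP = 0.5, UF = 0)
  snap <- simulate_snapshot_fret(half, 10000, seed = 4)
  n_p <- sum(snap$state == "P")
  expect_lt(abs(n_p - 5000), 3 * sqrt(10000 * 0.25))

  # trace-based snapshot mode: states frozen per molecule
  traces <- simulate_population(half, 50, frames_per_molecule = 20, seed = 5,
                                mode = "snapshot", bleach_rate = 0)
  per_mol_states <- vapply(traces, function(tr) {
    length(unique(tr$truth$frame_states))
  }, integer(1))
  expect_true(all(per_mol_states == 1L))
})

test_that("flow experiments fold with the configured latency and first state", {
  p133 <- construct_params("133")
  set.seed(7)
  lat <- replicate(1000, {
    simulate_flow_experiment(p133, pre_frames = 5, duration = 10,
                             dt = 0.1)$truth$latency
  })
  expect_equal(mean(lat), 1 / p133$initial_folding_rate,
               tolerance = 3 / sqrt(1000))

  tr <- simulate_flow_experiment(p133, pre_frames = 50, duration = 30,
                                 dt = 0.1, seed = 11)
  expect_identical(tr$flow_onset_frame, 51L)
  post_fold <- tr$truth$states[tr$truth$states != "UF"]
  expect_identical(post_fold[1], "P")

  p433 <- construct_params("433")
  tr <- simulate_flow_experiment(p433, pre_frames = 50, duration = 30,
                                 dt = 0.1, seed = 12)
  post_fold <- tr$truth$states[tr$truth$states != "UF"]
  expect_identical(post_fold[1], "AP")

  no_rate <- p133
  no_rate$initial_folding_rate <- NA_real_
  expect_error(simulate_flow_experiment(no_rate, 10, 10, 0.1),
               "initial_folding_rate")
})

test_that("quench curves follow the Hill equation", {
  qp <- quench_curve_params(vmax = 80, k = 0.5, n = 1.5, noise_sd = 0,
                            concentrations = c(0, 0.5, 1e6))
  curve <- simulate_quench_curve(qp)
  expect_equal(curve$quench[curve$concentration == 0], 0)
  expect_equal(curve$quench[curve$concentration == 0.5], 40)       # Vmax/2 at k
  expect_equal(curve$quench[curve$concentration == 1e6], 80, tolerance = 1e-6)

  expect_error(quench_curve_params(vmax = 0), "vmax")
  expect_error(quench_curve_params(k = -1), "Kd")
  expect_error(quench_curve_params(concentrations = c(-1, 1)), "non-negative")
})
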