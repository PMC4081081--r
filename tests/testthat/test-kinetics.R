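p333 <- construct_params("333")
centers <- p333$centers

test_that("state assignment thresholds at center midpoints", {
  fs <- function(v) compute_fret(1000 * (1 - v), 1000 * v)
  path <- assign_states(fs(rep(0.55, 10)), centers)
  expect_true(all(path$states == "P"))

  stepped <- c(rep(0.25, 5), rep(0.55, 5), rep(0.75, 5))
  path <- assign_states(fs(stepped), centers)
  expect_identical(rle(path$states)$values, c("UF", "P", "AP"))

  expect_error(assign_states(fs(rep(0.5, 5)), c(UF = 0.5, P = 0.3, AP = 0.7)),
               "ordered")

  # same-flank noise spikes (up to min_dwell frames) are merged away
  spiky <- c(rep(0.55, 8), 0.75, rep(0.55, 8))
  path <- assign_states(fs(spiky), centers, min_dwell = 2L)
  expect_true(all(path$states == "P"))
  spiky2 <- c(rep(0.55, 8), 0.75, 0.75, rep(0.55, 8))
  path <- assign_states(fs(spiky2), centers, min_dwell = 2L)
  expect_true(all(path$states == "P"))

  # a short sojourn between two *different* states is a real transit and
  # its transitions are preserved
  transit <- c(rep(0.25, 8), 0.55, rep(0.75, 8))
  path <- assign_states(fs(transit), centers, min_dwell = 2L)
  expect_identical(rle(path$states)$values, c("UF", "P", "AP"))

  # invalid frames are preserved and act as boundaries
  v <- rep(0.55, 10)
  fsr <- fs(v)
  fsr$fret[4] <- NA
  path <- assign_states(fsr, centers)
  expect_identical(path$states[4], "invalid")
})

test_that("frame-level state accuracy is >= 95% at noise sd 0.05", {
  set.seed(71)
  traces <- simulate_population(p333, 60, frames_per_molecule = 400,
                                mode = "dynamic", bleach_rate = 0)
  acc <- vapply(traces, function(tr) {
    path <- assign_states(select_window(tr), centers)
    mean(path$states == tr$truth$frame_states)
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("dwell collection censors flanks and labels transitions", {
  path <- structure(list(id = "m", dt = 0.1,
                         states = c(rep("UF", 5), rep("P", 10), rep("AP", 5))),
                    class = "gq_state_path")
  dw <- collect_dwells(path)
  done <- dw[!dw$censored, ]
  expect_identical(nrow(done), 1L)
  expect_identical(done$state, "P")
  expect_equal(done$duration, 1.0)
  expect_identical(done$transition, "P_AP")
  expect_identical(sum(dw$censored), 2L)

  single <- structure(list(id = "m", dt = 0.1, states = rep("P", 30)),
                      class = "gq_state_path")
  expect_identical(nrow(collect_dwells(single)[!collect_dwells(single)$censored, ]),
                   0L)

  # mean of simulated completed dwells matches 1/exit rate
  frozen <- p333
  frozen$rates[] <- 0
  frozen$rates[c("P_AP", "P_U")] <- 0.15   # exit 0.3 from P
  frozen$rates[c("AP_P", "U_P")] <- 2      # quick return to P
  set.seed(72)
  traces <- simulate_population(frozen, 40, frames_per_molecule = 800,
                                mode = "dynamic", bleach_rate = 0)
  dw <- truth_dwells(traces)
  d <- dw$duration[!dw$censored & dw$state == "P"]
  expect_gt(length(d), 500)
  expect_lt(abs(mean(d) - 1 / 0.3), 3 * (1 / 0.3) / sqrt(length(d)))
})

test_that("rate estimation splits exit rates by transition counts", {
  dw <- data.frame(molecule = "m", state = "P",
                   duration = rep(2.0, 40),
                   transition = rep(c("P_AP", "P_U"), 20),
                   censored = FALSE, stringsAsFactors = FALSE)
  est <- estimate_rates(dw, dt = 0)   # continuous dwells: no correction
  r <- est$rates
  expect_equal(r$rate[r$transition == "P_AP"], 0.25)
  expect_equal(r$rate[r$transition == "P_U"], 0.25)
  expect_identical(r$n[r$transition == "P_AP"], 20L)

  # below the minimum dwell count the rate is missing, with its count
  dw4 <- dw[1:8, ]
  dw4$transition <- c(rep("P_AP", 5), rep("P_U", 3))
  est <- estimate_rates(dw4, dt = 0)
  expect_true(is.na(est$rates$rate[est$rates$transition == "P_U"]))
  expect_identical(est$rates$n[est$rates$transition == "P_U"], 3L)
  expect_false(is.na(est$rates$rate[est$rates$transition == "P_AP"]))
})

test_that("six-rate recovery on dynamic traces is within +/-15%", {
  set.seed(73)
  traces <- simulate_population(p333, 200, frames_per_molecule = 600,
                                mode = "dynamic", bleach_rate = 0)
  paths <- lapply(traces, function(tr) assign_states(select_window(tr), centers))
  est <- estimate_rates(collect_dwells(paths), dt = 0.1)
  r <- est$rates
  for (lab in r$transition) {
    got <- r$rate[r$transition == lab]
    expect_false(is.na(got), info = lab)
    expect_lt(abs(got / p333$rates[[lab]] - 1), 0.15, label = lab)
  }
  # most exchange rates for this registry sit in the 0.1-0.2 1/s band
  folded <- r$rate[r$transition %in% c("P_AP", "P_U", "AP_P", "AP_U")]
  expect_true(all(folded > 0.05 & folded < 0.3))

  # equilibrium of the *estimated* rates matches the generator occupancy
  est_rates <- setNames(r$rate, r$transition)
  eq_est <- ctmc_equilibrium(est_rates)
  eq_true <- ctmc_equilibrium(p333$rates)
  expect_lt(max(abs(eq_est - eq_true)), 0.05)
})

test_that("truncation-corrected rate estimation is unbiased over replicates", {
  sym <- p333
  sym$rates[] <- 0.075    # every state exits at 0.15 1/s
  truth_exit <- 0.15
  n_rep <- 50L
  est_corr <- numeric(n_rep)
  est_raw <- numeric(n_rep)
  set.seed(74)
  # traces must be much longer than the mean dwell (6.7 s): dwells that
  # complete inside a short window are a selection-biased short sample
  for (r in seq_len(n_rep)) {
    traces <- simulate_population(sym, 3, frames_per_molecule = 10000,
                                  mode = "dynamic", bleach_rate = 0,
                                  noise_scale = 0, noise_floor = 0)
    paths <- lapply(traces, function(tr) assign_states(select_window(tr), centers))
    dw <- collect_dwells(paths)
    done <- dw[!dw$censored & dw$state == "P", ]
    surv <- done$duration[done$duration > 0.25]
    est_corr[r] <- 1 / (mean(surv) - 0.25)   # (min_frames - 1/2) dt
    est_raw[r] <- 1 / mean(surv)             # correction off
  }
  expect_lt(abs(mean(est_corr) / truth_exit - 1), 0.05)
  # without the correction the surviving-dwell mean is inflated by the
  # truncation point c, leaving a measurable low bias ~ c * rate^2 on the
  # rate; the corrected/uncorrected gap equals c / (m (m - c)) ~ c rate^2
  shift <- mean(est_corr - est_raw)
  c_trunc <- 0.25
  expect_gt(shift, 0)
  expect_lt(abs(shift - c_trunc * truth_exit^2) / (c_trunc * truth_exit^2), 0.5)
  # and the corrected estimator agrees with estimate_rates() end to end
  traces <- simulate_population(sym, 10, frames_per_molecule = 10000,
                                mode = "dynamic", bleach_rate = 0,
                                noise_scale = 0, noise_floor = 0)
  paths <- lapply(traces, function(tr) assign_states(select_window(tr), centers))
  est <- estimate_rates(collect_dwells(paths), dt = 0.1)
  exit_p <- sum(est$rates$rate[est$rates$transition %in% c("P_AP", "P_U")])
  expect_lt(abs(exit_p / truth_exit - 1), 0.25)
})

test_that("flank censoring leaves dwell distributions exponential", {
  # traces must be long relative to the mean dwell: dwells that complete
  # inside a short window are a right-censoring-biased (short) sample
  set.seed(75)
  traces <- simulate_population(p333, 25, frames_per_molecule = 4800,
                                mode = "dynamic", bleach_rate = 0)
  dw <- truth_dwells(traces)
  done <- dw[!dw$censored, ]
  exit <- c(P = sum(p333$rates[c("P_AP", "P_U")]),
            AP = sum(p333$rates[c("AP_P", "AP_U")]),
            UF = sum(p333$rates[c("U_P", "U_AP")]))
  for (s in names(exit)) {
    d <- done$duration[done$state == s]
    expect_gt(length(d), 500)
    ks <- suppressWarnings(stats::ks.test(d, "pexp", rate = exit[[s]]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("flow onset detection uses manifest or change point", {
  tr <- simulate_flow_experiment(construct_params("133"), pre_frames = 49,
                                 duration = 30, dt = 0.1, seed = 76)
  expect_identical(detect_flow_onset(tr), 50L)

  # change-point fallback on a synthetic FRET jump at frame 80
  set.seed(77)
  v <- c(rep(0.25, 79), rep(0.6, 121)) + rnorm(200, 0, 0.04)
  jump <- gqfret:::new_gq_trace("m", 0.1, 1000 * (1 - v), 1000 * v)
  expect_lte(abs(detect_flow_onset(jump) - 80L), 2L)

  flat <- gqfret:::new_gq_trace("m", 0.1,
                                1000 * (1 - (0.3 + rnorm(200, 0, 0.04))),
                                1000 * (0.3 + rnorm(200, 0, 0.04)))
  expect_error(detect_flow_onset(flat), "no flow onset")
})

test_that("initial folding rate recovers the generator latency scale", {
  p133 <- construct_params("133")
  set.seed(78)
  traces <- lapply(1:200, function(i) {
    simulate_flow_experiment(p133, pre_frames = 50, duration = 25, dt = 0.1,
                             id = paste0("m", i))
  })
  fr <- initial_folding_rate(traces, p133)
  expect_lt(abs(fr$rate / p133$initial_folding_rate - 1), 0.15)
  expect_gt(fr$n_folded, 150)
  expect_identical(names(which.max(fr$first_state_tally)), "P")

  # 433 folds first into the antiparallel state in > 90% of molecules
  p433 <- construct_params("433")
  set.seed(79)
  traces <- lapply(1:120, function(i) {
    simulate_flow_experiment(p433, pre_frames = 30, duration = 25, dt = 0.1,
                             id = paste0("m", i))
  })
  fr <- initial_folding_rate(traces, p433)
  tally <- fr$first_state_tally
  expect_gt(tally[["AP"]] / sum(tally), 0.9)
})
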