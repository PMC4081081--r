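# Independent oracles used to cross-check the analysis implementations.
# These deliberately re-derive quantities by brute force / enumeration and
# share no code with the package internals they validate.

# --- long-run occupancy of a 3-state CTMC by naive exponential-race
# simulation (independent of the package's Gillespie path sampler)
oracle_ctmc_occupancy <- function(rates, total_time = 20000, start = "P") {
  labs <- c("P_AP", "P_U", "AP_P", "AP_U", "U_P", "U_AP")
  stopifnot(setequal(names(rates), labs))
  exits <- list(
    UF = list(to = c("P", "AP"), r = c(rates[["U_P"]], rates[["U_AP"]])),
    P  = list(to = c("AP", "UF"), r = c(rates[["P_AP"]], rates[["P_U"]])),
    AP = list(to = c("P", "UF"), r = c(rates[["AP_P"]], rates[["AP_U"]]))
  )
  occ <- c(UF = 0, P = 0, AP = 0)
  s <- start
  t_now <- 0
  while (t_now < total_time) {
    ex <- exits[[s]]
    times <- ifelse(ex$r > 0, stats::rexp(2L, pmax(ex$r, 1e-300)), Inf)
    dwell <- min(times)
    if (!is.finite(dwell)) {
      occ[s] <- occ[s] + (total_time - t_now)
      break
    }
    dwell <- min(dwell, total_time - t_now)
    occ[s] <- occ[s] + dwell
    s <- ex$to[which.min(times)]
    t_now <- t_now + dwell
  }
  occ <- occ / sum(occ)
  c(P = unname(occ["P"]), AP = unname(occ["AP"]), UF = unname(occ["UF"]))
}

# --- exhaustive grid search for a 2-component Gaussian mixture fit to a
# binned histogram under the same chi-square (1/(counts+1)) weighting the
# package fit uses.  For each candidate component pair the weighted
# objective is quadratic in the mixing weight, so the grid minimum over w
# is found analytically and snapped to the w grid.
oracle_grid_mixture2 <- function(hist,
                                 mean1_grid = seq(0.40, 0.64, by = 0.01),
                                 mean2_grid = seq(0.62, 0.88, by = 0.01),
                                 sd_grid = seq(0.030, 0.075, by = 0.0025),
                                 w_step = 0.02) {
  mids <- hist$mids
  y <- hist$density
  wt <- 1 / (hist$counts + 1)
  nbw <- hist$n_molecules * hist$bin_width
  sqw <- sqrt(wt)

  cand <- function(mean_grid) {
    g <- expand.grid(mean = mean_grid, sd = sd_grid)
    D <- t(vapply(seq_len(nrow(g)), function(i) {
      stats::dnorm(mids, g$mean[i], g$sd[i]) * sqw
    }, numeric(length(mids))))
    list(par = g, D = D)
  }
  c1 <- cand(mean1_grid)
  c2 <- cand(mean2_grid)
  Y <- y * sqw
  G12 <- c1$D %*% t(c2$D)                       # cross Gram matrix
  n1 <- rowSums(c1$D^2)
  n2 <- rowSums(c2$D^2)
  yd1 <- drop(c1$D %*% Y)
  yd2 <- drop(c2$D %*% Y)
  yy <- sum(Y^2)
  w_grid <- seq(w_step, 1 - w_step, by = w_step)

  best <- list(chi2 = Inf)
  for (j in seq_len(nrow(c2$par))) {
    # model = d2 + w (d1 - d2); coefficients of the quadratic in w
    A <- yy - 2 * yd2[j] + n2[j]                 # |Y - d2|^2
    B <- yd1 - yd2[j] - G12[, j] + n2[j]         # (Y - d2) . (d1 - d2)
    C <- n1 - 2 * G12[, j] + n2[j]               # |d1 - d2|^2
    w_star <- pmin(max(w_grid), pmax(min(w_grid), B / C))
    w_snap <- round(w_star / w_step) * w_step
    chi2 <- (A - 2 * w_snap * B + w_snap^2 * C) * nbw^2
    i <- which.min(chi2)
    if (chi2[i] < best$chi2) {
      best <- list(chi2 = chi2[i], mean1 = c1$par$mean[i], sd1 = c1$par$sd[i],
                   mean2 = c2$par$mean[j], sd2 = c2$par$sd[j],
                   w1 = w_snap[i])
    }
  }
  best
}

# grid resolutions of the oracle, for agreement tolerances
oracle_grid_res <- list(mean = 0.01, w = 0.02)
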