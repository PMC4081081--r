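#' Ligand quenching, Hill fits, EMSA fractions and conformation correlation
#'
#' Porphyrin ligands (NMM/NMP) bind the parallel GQ conformation and
#' quench the nearby Cy3 dye; percent quenching is the complement of the
#' normalised fluorescence, 100 (1 - F/F0).  Dose-response curves are
#' fitted with the Hill model `y = Vmax x^n / (x^n + k^n)` (k is the
#' apparent Kd) and with a double-exponential saturation model; protein
#' (G4R1) binding is quantified as the EMSA shifted-band fraction.
#'
#' @name binding
NULL

#' Percent quenching from fluorescence readings
#'
#' `q(x) = 100 (1 - F(x)/F0)`, clipped to \[0, 100\] with a warning when
#' readings fall outside.
#'
#' @param fluorescence readings at each concentration (a.u.).
#' @param f0 reading at zero ligand, > 0.
#' @return percent quench series.
#' @export
percent_quenching <- function(fluorescence, f0) {
  if (!(length(f0) == 1L && f0 > 0)) stopf("F0 must be a single positive value")
  q <- 100 * (1 - fluorescence / f0)
  if (any(q < 0 | q > 100)) {
    warnf("%d quenching value(s) outside [0, 100]; clipped", sum(q < 0 | q > 100))
    q <- pmin(100, pmax(0, q))
  }
  q
}

#' Subtract the non-GQ background (T25) quenching signal
#'
#' Pointwise difference of two percent-quench curves, floored at 0.
#' Mismatched concentration grids are reconciled by linear interpolation
#' of the background onto the signal grid (with a warning); disjoint
#' grids are an error.
#'
#' @param quench data frame (`concentration`, `quench`) for the construct.
#' @param background data frame (`concentration`, `quench`) for T25.
#' @return data frame (`concentration`, `quench`) of corrected values.
#' @export
subtract_background <- function(quench, background) {
  stopifnot(all(c("concentration", "quench") %in% names(quench)),
            all(c("concentration", "quench") %in% names(background)))
  xq <- quench$concentration
  xb <- background$concentration
  if (length(xq) == length(xb) && all(abs(xq - xb) < 1e-12)) {
    bg <- background$quench
  } else {
    if (min(xq) > max(xb) || max(xq) < min(xb)) {
      stopf("background and signal concentration grids are disjoint")
    }
    warnf("concentration grids differ; background interpolated linearly")
    bg <- stats::approx(xb, background$quench, xout = xq, rule = 2)$y
  }
  data.frame(concentration = xq, quench = pmax(0, quench$quench - bg))
}

#' Fit the Hill equation to a quenching curve
#'
#' Nonlinear least squares of `y = Vmax x^n / (x^n + k^n)` with
#' deterministic multi-start: k over a log grid spanning the observed
#' concentration range, n in \{0.5, 1, 2\}; bounds Vmax in (0, 120\],
#' n in \[0.2, 6\], k > 0.
#'
#' @param curve data frame with `concentration` (uM) and `quench` (%);
#'   needs >= 5 points spanning at least one decade of positive
#'   concentration.
#' @return object of class `gq_hill_fit`: `vmax`, `k` (Kd, uM), `n`,
#'   `rss`, `converged`.  Non-convergence yields a flagged fit.
#' @export
fit_hill <- function(curve) {
  stopifnot(all(c("concentration", "quench") %in% names(curve)))
  x <- curve$concentration
  y <- curve$quench
  if (length(x) < 5L) stopf("need >= 5 points for a Hill fit")
  xp <- x[x > 0]
  if (max(xp) / min(xp) < 10) {
    stopf("concentrations must span at least one decade")
  }
  obj <- function(theta) {
    vmax <- theta[1]; k <- exp(theta[2]); n <- theta[3]
    sum((y - hill_curve(x, vmax, k, n))^2)
  }
  k_grid <- exp(seq(log(min(xp)), log(max(xp)), length.out = 7))
  n_grid <- c(0.5, 1, 2)
  lower <- c(1e-3, log(min(xp) / 100), 0.2)
  upper <- c(120, log(max(xp) * 100), 6)
  best <- NULL
  any_converged <- FALSE
  for (k0 in k_grid) for (n0 in n_grid) {
    theta0 <- c(min(max(y), 119), log(k0), n0)
    fit <- tryCatch(
      stats::optim(theta0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0L) any_converged <- TRUE
    if (is.null(best) || fit$value < best$value - 1e-15) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(vmax = NA_real_, k = NA_real_, n = NA_real_,
                          rss = NA_real_, converged = FALSE),
                     class = "gq_hill_fit"))
  }
  structure(list(vmax = best$par[1], k = exp(best$par[2]), n = best$par[3],
                 rss = best$value, converged = any_converged),
            class = "gq_hill_fit")
}

#' @export
print.gq_hill_fit <- function(x, ...) {
  cat(sprintf("<gq_hill_fit> Vmax=%.3g%%, Kd=%.3g uM, n=%.3g (rss %.3g)%s\n",
              x$vmax, x$k, x$n, x$rss,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Double-exponential saturation level of a quenching curve
#'
#' Fits `q(x) = A1 (1 - exp(-x/c1)) + A2 (1 - exp(-x/c2))` and reports
#' the saturation `A1 + A2`; when the fit fails the maximum observed
#' quench is returned with a fallback flag.
#'
#' @param curve data frame with `concentration` and `quench` (>= 6 points).
#' @return object of class `gq_saturation_fit`: `saturation` (%), `a1`,
#'   `a2`, `c1`, `c2`, `rss`, `fallback`.
#' @export
fit_saturation <- function(curve) {
  stopifnot(all(c("concentration", "quench") %in% names(curve)))
  x <- curve$concentration
  y <- curve$quench
  if (length(x) < 6L) stopf("need >= 6 points for a saturation fit")
  xp <- x[x > 0]
  if (!length(xp)) xp <- 1

  # the model is linear in (A1, A2) given the scales (c1, c2): scan a log
  # grid of scale pairs with an exact non-negative 2-variable solve, then
  # polish the best candidate with a full 4-parameter optimisation
  nn_solve <- function(u1, u2) {
    fitAB <- function(U) {
      a <- tryCatch(unname(qr.solve(U, y)), error = function(e) NULL)
      if (is.null(a)) return(NULL)
      a
    }
    a <- fitAB(cbind(u1, u2))
    if (is.null(a)) return(NULL)
    if (any(a < 0)) {  # clamp the negative amplitude, refit the other
      a1 <- max(0, sum(u1 * y) / sum(u1 * u1))
      a2 <- max(0, sum(u2 * y) / sum(u2 * u2))
      cand <- list(c(a1, 0), c(0, a2))
      rss <- vapply(cand, function(ab) sum((y - ab[1] * u1 - ab[2] * u2)^2),
                    numeric(1))
      a <- cand[[which.min(rss)]]
    }
    a
  }
  scales <- exp(seq(log(min(xp) / 10), log(max(x) * 10), length.out = 25))
  best <- NULL
  for (i in seq_along(scales)) for (j in i:length(scales)) {
    u1 <- 1 - exp(-x / scales[i])
    u2 <- 1 - exp(-x / scales[j])
    a <- nn_solve(u1, u2)
    if (is.null(a)) next
    rss <- sum((y - a[1] * u1 - a[2] * u2)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(a1 = a[1], a2 = a[2], c1 = scales[i], c2 = scales[j],
                   rss = rss)
    }
  }
  if (!is.null(best)) {
    obj <- function(theta) {
      sum((y - (theta[1] * (1 - exp(-x / exp(theta[3]))) +
                  theta[2] * (1 - exp(-x / exp(theta[4])))))^2)
    }
    polish <- tryCatch(
      stats::optim(c(best$a1, best$a2, log(best$c1), log(best$c2)), obj,
                   method = "L-BFGS-B",
                   lower = c(0, 0, log(min(xp) / 1000), log(min(xp) / 1000)),
                   upper = c(120, 120, log(max(x) * 1000), log(max(x) * 1000)),
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$rss) {
      best <- list(a1 = polish$par[1], a2 = polish$par[2],
                   c1 = exp(polish$par[3]), c2 = exp(polish$par[4]),
                   rss = polish$value)
    }
  }
  if (is.null(best)) {
    return(structure(list(saturation = max(y), a1 = NA_real_, a2 = NA_real_,
                          c1 = NA_real_, c2 = NA_real_, rss = NA_real_,
                          fallback = TRUE),
                     class = "gq_saturation_fit"))
  }
  structure(list(saturation = best$a1 + best$a2, a1 = best$a1, a2 = best$a2,
                 c1 = best$c1, c2 = best$c2, rss = best$rss,
                 fallback = FALSE),
            class = "gq_saturation_fit")
}

#' @export
print.gq_saturation_fit <- function(x, ...) {
  cat(sprintf("<gq_saturation_fit> saturation %.3g%%%s\n", x$saturation,
              if (x$fallback) " [fallback: max observed]" else ""))
  invisible(x)
}

#' EMSA bound fraction
#'
#' `100 * shifted / (shifted + unshifted)` from gel band areas.
#'
#' @param shifted_area area of the protein-bound (shifted) band, >= 0.
#' @param unshifted_area area of the free-DNA band, >= 0.
#' @return percent bound.
#' @export
emsa_bound_fraction <- function(shifted_area, unshifted_area) {
  if (any(shifted_area < 0) || any(unshifted_area < 0)) {
    stopf("band areas must be non-negative")
  }
  total <- shifted_area + unshifted_area
  if (any(total == 0)) stopf("shifted and unshifted areas are both zero")
  100 * shifted_area / total
}

#' Correlate a binding readout with the parallel-conformer percentage
#'
#' @param percent_parallel per-construct parallel percentages.
#' @param response matched binding readout (max quench, Kd, % bound...).
#' @return list with `pearson`, `spearman`, `n`; constant inputs yield
#'   `NA` coefficients with a message.
#' @export
correlate_with_parallel <- function(percent_parallel, response) {
  ok <- !is.na(percent_parallel) & !is.na(response)
  x <- percent_parallel[ok]; y <- response[ok]
  if (length(x) < 3L) stopf("need >= 3 constructs with both quantities")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("constant input: correlation undefined")
    return(list(pearson = NA_real_, spearman = NA_real_, n = length(x)))
  }
  list(pearson = stats::cor(x, y, method = "pearson"),
       spearman = stats::cor(x, y, method = "spearman"),
       n = length(x))
}
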