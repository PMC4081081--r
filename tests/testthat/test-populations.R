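p233 <- construct_params("233")
p333 <- construct_params("333")

test_that("histograms bin FRET values deterministically", {
  h <- build_histogram(c(0.01, 0.03, 0.03), bin_width = 0.02)
  expect_identical(h$counts[1:2], c(1L, 2L))
  expect_identical(h$n_molecules, 3L)
  expect_equal(sum(h$density) * h$bin_width, 1)

  expect_error(build_histogram(numeric(0)), "no FRET values")
  expect_error(build_histogram(c(0.5, 1.5)), "outside")

  # density-weighted mean recovers the location of a pure Gaussian
  set.seed(61)
  v <- rnorm(1e4, 0.55, 0.05)
  h <- build_histogram(v)
  m <- sum(h$mids * h$density) * h$bin_width
  expect_equal(m, 0.55, tolerance = 0.002)
})

test_that("single-component fits recover mean and sd", {
  set.seed(62)
  v <- rnorm(5000, 0.55, 0.05)
  fit <- fit_gaussian_mixture(build_histogram(v), k = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$components$mean - 0.55), 0.005)
  expect_lt(abs(fit$components$sd - 0.05), 0.05 * 0.10)   # sd within 10%
  expect_equal(sum(fit$components$weight), 1, tolerance = 1e-6)
})

test_that("two-component fits agree with the exhaustive grid-search oracle", {
  # the spec case: 0.55/0.75, sd 0.05, weights 0.7/0.3, n = 5000
  set.seed(63)
  comp <- sample(c(1, 2), 5000, replace = TRUE, prob = c(0.7, 0.3))
  v <- rnorm(5000, c(0.55, 0.75)[comp], 0.05)
  h <- build_histogram(v)
  fit <- fit_gaussian_mixture(h, k = 2)
  expect_equal(fit$components$weight[1], 0.7, tolerance = 0.03)
  oracle <- oracle_grid_mixture2(h)
  expect_lte(fit$chi2, oracle$chi2 + 1e-8)
  expect_lt(abs(fit$components$mean[1] - oracle$mean1),
            oracle_grid_res$mean / 2 + 0.007)
  expect_lt(abs(fit$components$mean[2] - oracle$mean2),
            oracle_grid_res$mean / 2 + 0.007)
  expect_lt(abs(fit$components$weight[1] - oracle$w1),
            oracle_grid_res$w / 2 + 0.02)

  # 20 random small instances
  set.seed(64)
  for (i in 1:20) {
    m1 <- runif(1, 0.45, 0.58); m2 <- runif(1, 0.68, 0.85)
    s <- runif(1, 0.04, 0.06); w <- runif(1, 0.25, 0.75)
    comp <- sample(c(1, 2), 4000, replace = TRUE, prob = c(w, 1 - w))
    v <- rnorm(4000, c(m1, m2)[comp], s)
    h <- build_histogram(v)
    fit <- fit_gaussian_mixture(h, k = 2)
    oracle <- oracle_grid_mixture2(h)
    expect_lte(fit$chi2, oracle$chi2 + 1e-8)
    expect_lt(abs(fit$components$mean[1] - oracle$mean1),
              oracle_grid_res$mean / 2 + 0.007)
    expect_lt(abs(fit$components$weight[1] - oracle$w1),
              oracle_grid_res$w / 2 + 0.02)
  }
})

test_that("component-count selection follows the RSS-improvement rule", {
  set.seed(65)
  one <- build_histogram(rnorm(4000, 0.55, 0.05))
  expect_identical(as.integer(select_component_count(one)), 1L)

  comp <- sample(c(1, 2), 4000, replace = TRUE, prob = c(0.6, 0.4))
  two <- build_histogram(rnorm(4000, c(0.55, 0.75)[comp], 0.05))
  expect_identical(as.integer(select_component_count(two)), 2L)

  p433 <- construct_params("433")
  three <- build_histogram(simulate_snapshot_fret(p433, 4000, seed = 66)$fret)
  expect_identical(as.integer(select_component_count(three)), 3L)
})

test_that("components are labelled by nearest expected center", {
  # single cMyc-style component at the parallel level
  fit1 <- structure(list(components = data.frame(mean = 0.55, sd = 0.05,
                                                 weight = 1),
                         rss = 0, k = 1L, converged = TRUE,
                         n_molecules = 100L, bin_width = 0.02),
                    class = "gq_mixture_fit")
  pf <- label_components(fit1, construct_params("cMyc"))
  expect_equal(unname(pf$fractions["P"]), 1)

  # 333-style mixture: 0.55 (0.56) + 0.75 (0.44)
  fit2 <- structure(list(components = data.frame(mean = c(0.55, 0.75),
                                                 sd = c(0.05, 0.05),
                                                 weight = c(0.56, 0.44)),
                         rss = 0, k = 2L, converged = TRUE,
                         n_molecules = 100L, bin_width = 0.02),
                    class = "gq_mixture_fit")
  pf <- label_components(fit2, p333)
  expect_equal(unname(pf$fractions["P"]), 0.56)
  expect_equal(unname(pf$fractions["AP"]), 0.44)

  # an AAA-style 0.40 component is unfolded
  fit3 <- fit1
  fit3$components$mean <- 0.40
  pf <- label_components(fit3, construct_params("AAA"))
  expect_equal(unname(pf$fractions["UF"]), 1)

  # components outside every tolerance window fold into UF with a warning
  fit4 <- fit1
  fit4$components$mean <- 0.05
  expect_warning(pf <- label_components(fit4, p333), "folded into UF")
  expect_equal(unname(pf$fractions["UF"]), 1)

  # fractions always sum to 1
  expect_equal(sum(pf$fractions), 1, tolerance = 1e-9)
})

test_that("fractions are stable under bin-width halving", {
  snap <- simulate_snapshot_fret(p333, 4000, seed = 67)
  f1 <- quantify_populations(snap$fret, p333, k = 2, bin_width = 0.02)
  f2 <- quantify_populations(snap$fret, p333, k = 2, bin_width = 0.01)
  expect_lt(max(abs(f1$fractions - f2$fractions)), 0.02)
})

test_that("snapshot population recovery is unbiased over replicates", {
  constructs <- c("233", "333", "TTA", "TAA")
  n_rep <- 50L
  for (cname in constructs) {
    p <- construct_params(cname)
    k <- sum(p$fractions > 0)
    rec <- vapply(seq_len(n_rep), function(r) {
      snap <- simulate_snapshot_fret(p, 3000, seed = 7000 + 100 * match(cname, constructs) + r)
      fit <- suppressWarnings(quantify_populations(snap$fret, p, k = k))
      unname(fit$fractions["P"])
    }, numeric(1))
    expect_lt(abs(mean(rec) - p$fractions[["P"]]), 0.03)
  }
})
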