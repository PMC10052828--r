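test_that("rescaling to the unit interval is monotone, scale-free, zero-preserving", {
  v <- c(0, 0.5, 3, 12)
  r <- rescale_to_unit(v)
  expect_equal(max(r$values), 1 / (1 + 1e-6))
  expect_identical(r$values[1], 0)
  expect_equal(rescale_to_unit(7 * v)$values, r$values)
  expect_null(rescale_to_unit(c(0, 0, 0)))
  expect_error(rescale_to_unit(c(-1, 2)), "non-negative")
})

test_that("minimum-KS beta fitting recovers shapes and dominates the uniform", {
  set.seed(101)
  errs <- replicate(5, {
    x <- rbeta(2000, 2, 5)
    f <- fit_beta_ks(x)
    c(abs(f$alpha - 2) / 2, abs(f$beta_ - 5) / 5)
  })
  expect_lte(median(errs), 0.15)

  x <- rbeta(2000, 3, 3)
  f <- fit_beta_ks(x)
  expect_lte(abs(f$alpha - f$beta_) / (f$alpha + f$beta_), 0.1)

  # optimizer dominance over the explicitly evaluated uniform candidate
  xs <- sort(x); n <- length(xs); i <- seq_len(n)
  ks_unif <- max(i / n - xs, xs - (i - 1) / n)  # Beta(1,1) CDF is identity
  expect_lte(f$ks_distance, ks_unif)

  expect_warning(expect_null(fit_beta_ks(runif(10))), "skipped")
})

test_that("KS fit agrees with independent maximum goodness-of-fit estimation", {
  set.seed(7)
  x <- rbeta(1500, 2, 4)
  mine <- fit_beta_ks(x)
  ref <- fitdistrplus::fitdist(x, "beta", method = "mge", gof = "KS",
                               start = list(shape1 = 1, shape2 = 1))
  expect_equal(mine$alpha, unname(ref$estimate["shape1"]), tolerance = 0.1)
  expect_equal(mine$beta_, unname(ref$estimate["shape2"]), tolerance = 0.1)
})

test_that("dropout iteration attributes uniformly-missing zeros to dropout", {
  set.seed(13)
  for (s in 1:5) {
    x <- rbeta(2000, 2, 2)
    x[sample(2000, 600)] <- 0
    f <- fit_hurdle(x)
    expect_gte(f$pr_dropout, 0.9)
    expect_equal(f$zero_fraction, 0.3)
    # shapes estimated on the nonzero part, unharmed by dropout
    expect_lt(abs(f$alpha - 2) / 2, 0.25)
  }
})

test_that("hurdle fit without zeros reduces to the beta fit", {
  set.seed(19)
  x <- rbeta(600, 2, 5)
  fh <- fit_hurdle(x)
  fb <- fit_beta_ks(x)
  expect_identical(fh$alpha, fb$alpha)
  expect_identical(fh$beta_, fb$beta_)
  expect_identical(fh$pi0, 0)
  expect_warning(expect_null(fit_hurdle(rep(0, 50))), "zero")
})

test_that("grid optimality is certified by exhaustive re-evaluation", {
  set.seed(23)
  x <- rbeta(500, 2, 3); x[sample(500, 100)] <- 0
  f <- fit_hurdle(x, dropout_grid_step = 0.1)
  nz <- sort(x[x > 0]); n0 <- sum(x == 0)
  ks_at <- vapply(seq(0, 1, by = 0.1), function(d) {
    m0 <- round(n0 * (1 - d))
    p <- c(rep(0, m0), pbeta(nz, f$alpha, f$beta_))
    m <- length(p); i <- seq_len(m)
    max(i / m - p, p - (i - 1) / m)
  }, numeric(1))
  expect_lte(f$ks_distance, min(ks_at) + 1e-12)
})

test_that("model CDF carries the true-zero point mass", {
  set.seed(29)
  x <- rbeta(300, 2, 2); x[1:100] <- 0
  f <- fit_hurdle(x, dropout_grid_step = 0.5)
  expect_equal(hurdle_cdf(f, 0), f$pi0)
  expect_equal(hurdle_cdf(f, 1), 1)
  expect_identical(hurdle_cdf(f, -0.1), 0)
})

test_that("expected value matches the closed form and is monotone in alpha", {
  f <- function(a, b, pi0 = 0) structure(list(alpha = a, beta_ = b, pi0 = pi0),
                                         class = "beta_hurdle_fit")
  expect_equal(expected_value(f(3, 3)), 0.5)
  expect_equal(expected_value(f(1, 3)), 0.25)
  # printed form 1/(1 + beta/alpha) == alpha/(alpha+beta)
  set.seed(31)
  for (i in 1:20) {
    a <- runif(1, 0.01, 50); b <- runif(1, 0.01, 50)
    expect_equal(expected_value(f(a, b)), a / (a + b))
  }
  expect_gt(expected_value(f(2.5, 4)), expected_value(f(2, 4)))
  # mixture mode with all zeros attributed to dropout equals the default
  expect_equal(expected_value(f(2, 4, pi0 = 0), mode = "mixture"),
               expected_value(f(2, 4)))
  expect_equal(expected_value(f(2, 4, pi0 = 0.5), mode = "mixture"), 0.5 / 3)
})

test_that("contribution shares follow E*N and sum to one", {
  e <- rbind(g1 = c(beta = 0.4, alpha = 0.1))
  tb <- contribution_table(e, c(beta = 100, alpha = 200))
  expect_equal(unname(tb$q["g1", ]), c(2 / 3, 1 / 3))
  # doubling every N leaves Q unchanged
  tb2 <- contribution_table(e, c(beta = 200, alpha = 400))
  expect_equal(tb$q, tb2$q)
  # single cell type: Q = 1 for every expressed gene
  tb3 <- contribution_table(rbind(g1 = c(beta = 0.2)), c(beta = 10))
  expect_equal(unname(tb3$q["g1", ]), 1)
  # all-zero rows flagged undefined, not silently zeroed
  tb4 <- contribution_table(rbind(g1 = c(beta = 0, alpha = 0)),
                            c(beta = 1, alpha = 1))
  expect_true(tb4$undefined["g1"])
  expect_true(all(is.na(tb4$q["g1", ])))
  expect_error(contribution_table(e, c(beta = -1, alpha = 1)), "non-negative")
})

test_that("specific-gene calls require the threshold in every cohort", {
  mk <- function(q) {
    e <- rbind(g1 = c(beta = q, alpha = 1 - q))
    contribution_table(e, c(beta = 1, alpha = 1))
  }
  tabs <- lapply(rep(0.85, 6), mk); names(tabs) <- paste0("c", 1:6)
  expect_true(call_specific_genes(tabs, "beta")$called)
  tabs$c6 <- mk(0.79)
  expect_false(call_specific_genes(tabs, "beta")$called)
  # vacuous threshold calls every defined gene
  expect_true(call_specific_genes(tabs, "beta", tau = 0)$called)
  expect_error(call_specific_genes(tabs, "pp-cell"), "absent")
})

test_that("Cullen-Frey moments locate known distributions", {
  set.seed(37)
  u <- runif(50000)
  cf <- cullen_frey_diagnostic(u, n_boot = 50)
  expect_lt(cf$skewness_sq, 0.01)
  expect_lt(abs(cf$kurtosis - 1.8), 0.1)  # uniform kurtosis 9/5
  g <- rnorm(50000)
  expect_lt(abs(cullen_frey_diagnostic(g, n_boot = 10)$kurtosis - 3), 0.15)
  # bootstrap cloud surrounds the point estimate
  cfb <- cullen_frey_diagnostic(runif(500), n_boot = 200, seed = 1)
  expect_gt(mean(cfb$boot$kurtosis), min(cfb$boot$kurtosis))
  expect_lte(abs(median(cfb$boot$kurtosis) - cfb$kurtosis), 0.25)
  expect_error(cullen_frey_diagnostic(rep(1, 20)), "constant")
  # independent cross-check against the reference diagnostic implementation
  x <- rbeta(2000, 2, 5)
  ref <- fitdistrplus::descdist(x, graph = FALSE)
  cfx <- cullen_frey_diagnostic(x, n_boot = 10)
  expect_equal(cfx$skewness_sq, unname(ref$skewness)^2, tolerance = 0.01)
  expect_equal(cfx$kurtosis, unname(ref$kurtosis), tolerance = 0.02)
})

test_that("end-to-end attribution recovers planted beta-specific genes", {
  st <- simulate_islet_study(n_genes = 20, n_specific = 5,
                             cell_types = c("beta", "alpha", "delta"),
                             n_cells_per_type = 150,
                             cohort_ids = c("A", "B"), seed = 4)
  ae <- generate_cells(st$specs, st$cohorts, seed = 4)
  fits <- fit_cell_type_models(ae$matrix, ae$cell_meta,
                               dropout_grid_step = 0.05)
  tabs <- contributions_from_fits(fits)
  for (tb in tabs) {
    sums <- rowSums(tb$q)
    expect_true(all(abs(sums[!tb$undefined] - 1) < 1e-9))
  }
  calls <- call_specific_genes(tabs, "beta")
  called <- calls$gene_id[calls$called]
  truth <- st$truth$specific_genes
  sens <- length(intersect(called, truth)) / length(truth)
  spec <- 1 - length(setdiff(called, truth)) / (20 - length(truth))
  expect_gte(sens, 0.8)
  expect_gte(spec, 0.9)
})
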