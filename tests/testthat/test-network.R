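test_that("TMM normalization handles depth, identity, and composition bias", {
  set.seed(1)
  mu <- rexp(2000, 1 / 100)
  A <- rpois(2000, mu)
  counts <- rbind(A = A, A2 = A)
  f <- attr(normalize_bulk(counts), "norm_factors")
  expect_equal(unname(f), c(1, 1))
  # doubled depth is absorbed by the library size, factors stay 1
  f2 <- attr(normalize_bulk(rbind(A = A, B = 2L * A)), "norm_factors")
  expect_equal(unname(f2), c(1, 1))
  # planted 5% of genes 8-fold up in B (non-DE genes drawn independently at
  # equal expectation): B's effective library is inflated, so its scaling
  # factor drops below 1 and non-DE genes re-equalize
  B <- rpois(2000, mu)
  up <- sample(2000, 100)
  B[up] <- rpois(100, mu[up] * 8)
  nb <- normalize_bulk(rbind(A = A, B = B))
  f3 <- attr(nb, "norm_factors")
  expect_lt(f3[["B"]], 1)
  keep <- setdiff(which(A > 20), up)
  expect_lt(median(abs(nb["B", keep] - nb["A", keep])), 0.2)
  expect_error(normalize_bulk(rbind(A = A, Z = 0 * A)), "zero total")
})

test_that("inverse normal transform matches the Blom formula and is rank-based", {
  x <- c(3, 1, 4, 1.5, 9)
  m <- cbind(g = x, h = exp(x), const = 1)
  expect_warning(z <- inverse_normal_transform(m), "constant")
  expect_equal(z[, "g"], qnorm((rank(x) - 3 / 8) / 5.25), ignore_attr = TRUE)
  expect_equal(z[, "g"], z[, "h"])      # monotone-transform invariance
  expect_true(all(z[, "const"] == 0))
  z2 <- inverse_normal_transform(cbind(a = c(1, 2, 3)))
  expect_equal(z2[1], -z2[3])           # symmetry about zero
  expect_lt(abs(mean(z[, "g"])), 1e-12)
})

test_that("biweight midcorrelation is exact on affine pairs, near Pearson otherwise", {
  set.seed(2)
  x <- rnorm(50)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, 3 - 2 * x), -1)
  expect_equal(bicor(x, 1 + 0.5 * x), 1)
  z <- rnorm(200)
  y <- 0.8 * z + sqrt(1 - 0.64) * rnorm(200)
  expect_lt(abs(bicor(z, y) - cor(z, y)), 0.1)
  expect_error(bicor(x[1:3], x[1:3]), "4 samples")
  expect_warning(bicor(c(0, 0, 0, 0, 0, 1), rnorm(6)), "MAD")
  # matrix form agrees with the pairwise form
  m <- matrix(rnorm(40), 10, 4)
  bm <- bicor(m)
  expect_equal(bm[1, 2], bicor(m[, 1], m[, 2]))
  expect_equal(bm, t(bm))
})

test_that("soft-threshold selection finds a scale-free power on heavy-tailed networks", {
  # planted degree hierarchy: cor_ij = sqrt(c_i c_j) with power-law c
  set.seed(3)
  n <- 150
  cvec <- (seq_len(n) / n)^3
  cm <- sqrt(outer(cvec, cvec))
  diag(cm) <- 1
  st <- pick_soft_threshold(cm, powers = 1:12)
  r2 <- st$fit_table$r_squared[st$fit_table$power == st$power]
  expect_gte(r2, 0.9)
  # increasing power never increases an off-diagonal adjacency
  a2 <- adjacency_matrix(cm, 2); a3 <- adjacency_matrix(cm, 3)
  expect_true(all(a3 <= a2 + 1e-15))
  expect_error(pick_soft_threshold(cm, powers = 0:3), "powers > 0")
})

test_that("topological overlap matches brute-force evaluation and its closed cases", {
  for (s in 1:3) {
    a <- random_adjacency(10, seed = s)
    expect_lt(max(abs(tom_matrix(a) - tom_brute(a))), 1e-12)
  }
  # two genes joined by a unit edge, isolated otherwise
  a <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(tom_matrix(a)[1, 2], 1)
  # no direct edge, no shared neighbor
  b <- diag(0, 3); b[1, 2] <- b[2, 1] <- 1  # gene 3 isolated
  expect_equal(tom_matrix(b)[1, 3], 0)
  tm <- tom_matrix(random_adjacency(20, seed = 9))
  expect_true(all(tm >= 0 & tm <= 1))
  expect_lt(max(abs(tm - t(tm))), 1e-12)
  expect_error(tom_matrix(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("module detection recovers planted blocks and leaves noise unassigned", {
  sim <- simulate_coexpression(n_samples = 40, n_genes = 40, n_modules = 2,
                               module_size = 20, within_cor = 0.9,
                               trait_effect = 0, seed = 11)
  tom <- tom_matrix(adjacency_matrix(suppressWarnings(bicor(sim$expr)), 6))
  lab <- detect_modules(tom)
  expect_equal(ari(lab, sim$truth$modules), 1)

  # i.i.d. noise: most genes unassigned, aggregated over seeds
  frac <- vapply(1:20, function(s) {
    set.seed(s)
    e <- matrix(rnorm(32 * 60), 32, 60,
                dimnames = list(NULL, paste0("g", 1:60)))
    tom <- tom_matrix(adjacency_matrix(suppressWarnings(bicor(e)), 8))
    mean(detect_modules(tom) == "unassigned")
  }, numeric(1))
  expect_gte(mean(frac >= 0.9), 0.9)

  # permuting gene order permutes labels consistently
  p <- sample(ncol(sim$expr))
  labp <- detect_modules(tom_matrix(adjacency_matrix(
    suppressWarnings(bicor(sim$expr[, p])), 6)))
  expect_equal(ari(labp[colnames(sim$expr)], lab), 1)
})

test_that("eigengenes summarize modules up to sign and scale", {
  set.seed(12)
  z <- rnorm(30)
  expr <- sapply(1:6, function(i) z + rnorm(30, sd = 0.3))
  colnames(expr) <- paste0("g", 1:6)
  lab <- setNames(rep("M1", 6), colnames(expr))
  eg <- eigengene(expr, lab)
  expect_gte(abs(cor(eg[, "M1"], z)), sqrt(0.7))  # PC1 captures the factor
  expect_equal(sd(eg[, "M1"]), 1)
  # identical genes: eigengene is the shared profile
  expr2 <- matrix(rep(z, 4), 30, 4, dimnames = list(NULL, paste0("g", 1:4)))
  eg2 <- eigengene(expr2, setNames(rep("M1", 4), colnames(expr2)))
  expect_equal(abs(cor(eg2[, 1], z)), 1)
  expect_gt(cor(eg2[, 1], z), 0)  # sign aligned with the mean profile
  # flipping every gene flips nothing after alignment
  eg3 <- eigengene(-expr2, setNames(rep("M1", 4), colnames(expr2)))
  expect_equal(abs(cor(eg3[, 1], eg2[, 1])), 1)
})

test_that("module-trait correlation flags the planted link and controls the null", {
  sim <- simulate_coexpression(seed = 13)
  tom <- tom_matrix(adjacency_matrix(suppressWarnings(bicor(
    inverse_normal_transform(sim$expr))), 8))
  lab <- detect_modules(tom)
  eg <- eigengene(sim$expr, lab)
  mt <- module_trait(eg, sim$phenotypes)
  linked <- names(which.max(vapply(setdiff(unique(lab), "unassigned"),
    function(m) sum(names(lab)[lab == m] %in%
                      names(which(sim$truth$modules == "M1"))), numeric(1))))
  expect_true(mt$significant[mt$module == linked & mt$trait == "trait_1"])
  # exact dependence and antisymmetry
  ph <- data.frame(t1 = eg[, 1], t2 = -eg[, 1])
  mt2 <- module_trait(eg[, 1, drop = FALSE], ph)
  expect_equal(mt2$r, c(1, -1))
  expect_lt(mt2$p_value[1], 1e-12)
  # null: false-positive pairs at q < 0.05 stay near the nominal budget
  fp <- vapply(1:20, function(s) {
    set.seed(s)
    egn <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("M", 1:6)))
    phn <- as.data.frame(matrix(rnorm(20 * 4), 20, 4))
    sum(module_trait(egn, phn)$significant)
  }, numeric(1))
  expect_lte(mean(fp), 0.05 * 24 + 3 * sd(fp) / sqrt(20) + 0.05)
})

test_that("module membership tracks trait association in a linked module", {
  sim <- simulate_coexpression(seed = 14)
  lab <- sim$truth$modules
  eg <- eigengene(sim$expr, lab[lab != "none"])
  mm <- module_membership(sim$expr, eg, sim$phenotypes[-1])
  expect_true(all(abs(mm$kme) <= 1))
  members <- names(lab)[lab == "M1"]
  expect_gt(min(abs(mm$kme[members, "M1"])), 0.6)
  rs <- cor(abs(mm$kme[, "M1"]), abs(mm$gene_trait[, "trait_1"]),
            method = "spearman")
  expect_gt(rs, 0.5)
})

test_that("intramodular connectivity matches closed forms and brute force", {
  # module of m genes with all adjacencies a: k_within = (m-1) * a
  m <- 5; aval <- 0.3
  a <- matrix(aval, m, m); diag(a) <- 0
  dimnames(a) <- list(paste0("g", 1:m), paste0("g", 1:m))
  lab <- setNames(rep("M1", m), rownames(a))
  expect_equal(k_within(a, lab)$k_within, rep((m - 1) * aval, m))
  # singleton module
  lab2 <- setNames(c("M1", "M1", "M1", "M1", "M2"), rownames(a))
  expect_equal(k_within(a, lab2)$k_within[5], 0)
  # brute force on a hand-built 5-gene adjacency with mixed labels
  a2 <- random_adjacency(5, seed = 21)
  dimnames(a2) <- dimnames(a)
  lab3 <- setNames(c("M1", "M1", "M2", "M2", "M2"), rownames(a2))
  kw <- k_within(a2, lab3)$k_within
  brute <- vapply(1:5, function(i) {
    s <- 0
    for (j in 1:5) if (j != i && lab3[j] == lab3[i]) s <- s + a2[i, j]
    s
  }, numeric(1))
  expect_equal(kw, brute)
})

test_that("differential connectivity follows its definition and conventions", {
  expect_equal(kdiff(10, 0), 1)
  expect_equal(kdiff(3, 1), 0.5)
  expect_true(is.na(kdiff(0, 0)))
  set.seed(22)
  ka <- runif(50); kb <- runif(50)
  expect_equal(kdiff(ka, kb), -kdiff(kb, ka))

  # planted: genes correlated in cohort A only are flagged
  n <- 8
  za <- rnorm(n)
  ea <- sapply(1:12, function(i)
    if (i <= 6) sqrt(0.9) * za + sqrt(0.1) * rnorm(n) else rnorm(n))
  eb <- sapply(1:12, function(i) rnorm(n))
  colnames(ea) <- colnames(eb) <- paste0("g", 1:12)
  lab <- setNames(rep("M1", 12), paste0("g", 1:12))
  dc <- differential_connectivity(ea, eb, lab, power = 6)
  expect_gte(mean(dc$flagged[1:6]), 0.9)
  ok <- !dc$undefined
  expect_true(all(dc$k_diff[ok] >= -1 & dc$k_diff[ok] <= 1))
  # flag convention is strict: |kdiff| <= 0.5 is never flagged
  expect_identical(dc$flagged, ok & abs(dc$k_diff) > 0.5)
  # swapping the cohorts negates every kdiff
  dc_rev <- differential_connectivity(eb, ea, lab, power = 6)
  expect_equal(dc$k_diff, -dc_rev$k_diff)
  expect_error(differential_connectivity(ea[1:3, ], eb, lab), "4 samples")
})
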