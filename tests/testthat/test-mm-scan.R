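test_that("genotype codings follow the four gene-action maps and their algebra", {
  d <- c(0, 1, 2)
  expect_equal(code_genotype(d, "additive"), c(0, 1, 2))
  expect_equal(code_genotype(d, "dominance"), c(0, 1, 1))
  expect_equal(code_genotype(d, "recessive"), c(0, 0, 1))
  expect_equal(code_genotype(d, "overdominance"), c(0, 1, 0))
  expect_error(code_genotype(c(0, 3), "additive"), "0, 1 or 2")
  # identities over every dosage vector of length 6
  grid <- as.matrix(expand.grid(rep(list(0:2), 6)))
  for (i in seq_len(nrow(grid))) {
    v <- grid[i, ]
    expect_identical(code_genotype(v, "additive"),
                     code_genotype(v, "dominance") +
                       code_genotype(v, "recessive"))
    expect_identical(code_genotype(v, "overdominance"),
                     code_genotype(v, "dominance") -
                       code_genotype(v, "recessive"))
  }
})

test_that("null model with G = I matches the closed-form OLS analysis", {
  set.seed(101)
  n <- 80
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(0.5, 0.3)) + rnorm(n)
  fit <- fit_null_model(y, diag(n), X = X)
  ols <- lm.fit(X, y)
  # with G = I only the total variance is identified
  expect_equal(fit$var_u + fit$var_e,
               sum(ols$residuals^2) / (n - 2), tolerance = 1e-6)
  expect_equal(unname(fit$fixed_estimates), unname(ols$coefficients),
               tolerance = 1e-6)
  expect_equal(fit$residuals, unname(ols$residuals), tolerance = 1e-6)
})

test_that("null model recovers variance components on heritable data", {
  set.seed(102)
  g <- simulate_genotypes(sim_config(300, 1500, seed = 103))
  G <- as.matrix(compute_G(g))
  ev <- eigen(G, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  h2s <- replicate(15, {
    u <- drop(L %*% rnorm(300)) * sqrt(0.4)
    y <- u + rnorm(300, 0, sqrt(0.6))
    f <- fit_null_model(y, G)
    f$var_u / (f$var_u + f$var_e)
  })
  expect_lt(abs(mean(h2s) - 0.4), 0.1)
})

test_that("estimated variance ratio collapses when data are non-heritable", {
  set.seed(104)
  g <- simulate_genotypes(sim_config(300, 1500, seed = 105))
  G <- as.matrix(compute_G(g))
  ratios <- replicate(40, {
    y <- rnorm(300)
    f <- fit_null_model(y, G)
    f$var_u / (f$var_u + f$var_e)
  })
  # REML h2 under the null piles up at the zero boundary; the sampling sd of
  # h2-hat at n = 300 is ~0.1, so individual replicates can stray upward
  expect_lt(median(ratios), 0.02)
  expect_lt(mean(ratios), 0.15)
})

test_that("null-model estimates are invariant to permutation and scale", {
  set.seed(106)
  g <- simulate_genotypes(sim_config(100, 500, seed = 107))
  G <- as.matrix(compute_G(g))
  y <- rnorm(100) + 0.5
  f <- fit_null_model(y, G)
  perm <- sample(100)
  fp <- fit_null_model(y[perm], G[perm, perm])
  expect_equal(fp$var_u, f$var_u, tolerance = 1e-4)
  expect_equal(fp$var_e, f$var_e, tolerance = 1e-4)
  fs <- fit_null_model(3 * y, G)
  expect_equal(fs$var_u / fs$var_e, f$var_u / f$var_e, tolerance = 1e-4)
  expect_equal(fs$var_u + fs$var_e, 9 * (f$var_u + f$var_e), tolerance = 1e-4)
})

test_that("V0 is reconstructible from the stored components", {
  set.seed(108)
  g <- simulate_genotypes(sim_config(60, 400, seed = 109))
  G <- as.matrix(compute_G(g))
  y <- rnorm(60)
  f <- fit_null_model(y, G)
  expect_lt(max(abs(f$V0 - (f$var_u * G + f$var_e * diag(60)))), 1e-8)
  expect_lt(max(abs(f$V0 %*% f$V0_inv - diag(60))), 1e-6)
  expect_true(f$var_u >= 0 && f$var_e >= 0)
})

test_that("two-step z equals the exact per-SNP GLS Wald oracle at fixed V0", {
  set.seed(110)
  cfg <- sim_config(100, 200, h2_liability = 0.3, seed = 111)
  g <- simulate_genotypes(cfg)
  tr <- simulate_binary_trait(g, cfg)
  G <- as.matrix(compute_G(g))
  fit <- fit_null_model(tr$phenotype$score, G)
  for (mode in c("additive", "recessive")) {
    scan <- scan_snps(fit, g, modes = mode)
    keep <- !scan$skipped
    z_oracle <- vapply(which(keep), function(j) {
      oracle_gls_wald(tr$phenotype$score, fit$X,
                      code_genotype(g$dosages[, j], mode), fit$V0)
    }, numeric(1))
    expect_equal(scan$z[keep], z_oracle, tolerance = 1e-8)
  }
})

test_that("constant coded columns are flagged, not errors", {
  d <- cbind(a = c(0, 1, 2, 1, 0, 2), b = c(1, 1, 1, 1, 1, 1),
             c = c(0, 1, 0, 1, 0, 1))
  g <- toy_genotypes(d)
  fit <- fit_null_model(rnorm(6), diag(6))
  scan <- scan_snps(fit, g, modes = "recessive")
  # SNP b is constant; SNP c has no dosage-2 carriers so codes to constant 0
  expect_true(all(scan$skipped[2:3]))
  expect_true(all(is.na(scan$z[2:3])))
  expect_false(scan$skipped[1])
  expect_true(all(scan$p[1] > 0 & scan$p[1] <= 1))
})

test_that("scan p-values are calibrated under a permuted-phenotype null", {
  set.seed(112)
  n <- 200
  g <- simulate_genotypes(sim_config(n, 3000, seed = 113))
  y <- sample(rep(0:1, each = n / 2))       # shuffled scores, G = I path
  fit <- fit_null_model(y, diag(n))
  scan <- scan_snps(fit, g, modes = "additive")
  frac <- mean(scan$p[!scan$skipped] <= 0.05)
  m <- sum(!scan$skipped)
  expect_lt(abs(frac - 0.05), 1.96 * sqrt(0.05 * 0.95 / m))
})

test_that("p-values are uniform under a polygenic null with a real G", {
  cfg <- sim_config(300, 2000, h2_liability = 0, seed = 3001)
  g <- simulate_genotypes(cfg)
  tr <- simulate_binary_trait(g, cfg)
  fit <- fit_null_model(tr$phenotype$score, as.matrix(compute_G(g)))
  scan <- scan_snps(fit, g, modes = "additive")
  ks <- suppressWarnings(ks.test(scan$p[!scan$skipped], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("allele flips map the codings into each other as expected", {
  set.seed(114)
  cfg <- sim_config(120, 150, h2_liability = 0.2, seed = 115)
  g <- simulate_genotypes(cfg)
  tr <- simulate_binary_trait(g, cfg)
  fit <- fit_null_model(tr$phenotype$score, as.matrix(compute_G(g)))
  flip <- genotype_matrix(2 - g$dosages, g$map)
  s_add <- scan_snps(fit, g, modes = "additive")
  f_add <- scan_snps(fit, flip, modes = "additive")
  keep <- !s_add$skipped & !f_add$skipped
  expect_equal(f_add$z[keep], -s_add$z[keep], tolerance = 1e-8)
  s_rec <- scan_snps(fit, g, modes = "recessive")
  f_dom <- scan_snps(fit, flip, modes = "dominance")
  keep <- !s_rec$skipped & !f_dom$skipped
  # recessive for one allele is dominance for the other (sign aside)
  expect_equal(abs(f_dom$z[keep]), abs(s_rec$z[keep]), tolerance = 1e-8)
  expect_equal(f_dom$p[keep], s_rec$p[keep], tolerance = 1e-8)
})

test_that("a recessive QTL is detected best by the recessive coding", {
  set.seed(116)
  wins <- replicate(25, {
    seed <- sample.int(1e6, 1)
    cfg <- sim_config(400, 150, maf_range = c(0.25, 0.35),
                      qtl = data.frame(snp = 75, mode = "recessive",
                                       effect = 1.2),
                      h2_liability = 0.4, prevalence_or_split = 0.5,
                      seed = seed)
    g <- simulate_genotypes(cfg)
    tr <- simulate_binary_trait(g, cfg)
    fit <- fit_null_model(tr$phenotype$score, as.matrix(compute_G(g)))
    scan <- scan_snps(fit, subset_snps(g, 75),
                      modes = c("additive", "recessive"))
    scan$p[scan$coding == "recessive"] < scan$p[scan$coding == "additive"]
  })
  expect_gt(mean(wins), 0.5)
})

test_that("genomic inflation behaves like a median-chi-square diagnostic", {
  set.seed(117)
  n <- 300
  g <- simulate_genotypes(sim_config(n, 2000, seed = 118))
  fit <- fit_null_model(rnorm(n), diag(n))
  scan <- scan_snps(fit, g, modes = "additive")
  gi <- genomic_inflation(scan)
  expect_lt(abs(gi$lambda - 1), 0.1)
  # doubling every z quadruples lambda (median scaling)
  scan2 <- scan
  scan2$z <- scan$z * 2
  gi2 <- genomic_inflation(scan2)
  expect_equal(gi2$lambda, 4 * gi$lambda, tolerance = 1e-10)
  # expected Q-Q quantiles equal the rank/(n+1) rule computed directly
  m <- nrow(gi$qq)
  expect_equal(gi$qq$expected, -log10(seq_len(m) / (m + 1)))
  expect_equal(gi$qq$observed,
               sort(-log10(scan$p[!scan$skipped]), decreasing = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
})
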