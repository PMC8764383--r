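test_that("simulated genotypes follow the configured allele-frequency model", {
  # symmetric frequencies: mean dosage per SNP ~ 1
  g <- simulate_genotypes(sim_config(2000, 50, maf_range = c(0.5, 0.5),
                                     seed = 11))
  expect_true(all(abs(colMeans(g$dosages) - 1) < 0.1))

  # determinism under a fixed seed
  cfg <- sim_config(100, 200, n_chromosomes = 3, seed = 42)
  expect_identical(simulate_genotypes(cfg)$dosages,
                   simulate_genotypes(cfg)$dosages)

  # empirical MAF distribution against its Monte-Carlo sampling distribution:
  # with p ~ U(0.05, 0.5) and n = 500, the 1st percentile of empirical MAF
  # computed by direct simulation bounds what the generator may produce
  set.seed(7)
  mc <- replicate(20000, {
    p <- runif(1, 0.05, 0.5)
    f <- mean(rbinom(500, 2, p)) / 2
    min(f, 1 - f)
  })
  lo <- quantile(mc, 0.0005)
  g2 <- simulate_genotypes(sim_config(500, 1000, maf_range = c(0.05, 0.5),
                                      seed = 3))
  maf <- pmin(g2$allele_freq, 1 - g2$allele_freq)
  expect_true(all(maf > 0))            # all polymorphic
  expect_gte(min(maf), lo)             # within the sampling distribution
})

test_that("invalid simulator configurations are rejected", {
  expect_error(sim_config(10, 5, maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(10, 5, maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(10, 5, h2_liability = 1.2), "h2_liability")
  expect_error(sim_config(10, 5, qtl = data.frame(snp = c(1, 1),
                                                  mode = "additive",
                                                  effect = 1)), "distinct")
  expect_error(sim_config(10, 5, qtl = data.frame(snp = 9, mode = "additive",
                                                  effect = 1)), "range")
})

test_that("marker maps are valid and positions increase within chromosomes", {
  g <- simulate_genotypes(sim_config(20, 300, n_chromosomes = 5,
                                     chrom_length_bp = 1e6, seed = 5))
  expect_equal(length(unique(g$map$chrom)), 5)
  for (ch in unique(g$map$chrom))
    expect_true(all(diff(g$map$pos[g$map$chrom == ch]) > 0))
  expect_equal(unname(g$allele_freq), unname(colMeans(g$dosages) / 2))
})

test_that("pedigree simulation yields topologically ordered acyclic pedigrees", {
  ped0 <- simulate_pedigree(10, n_generations = 0, seed = 1)
  expect_true(all(is.na(ped0$sire)) && all(is.na(ped0$dam)))

  ped <- simulate_pedigree(12, n_generations = 3, seed = 2)
  pos <- seq_len(nrow(ped))
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  expect_true(all(si[!is.na(si)] < pos[!is.na(si)]))
  expect_true(all(di[!is.na(di)] < pos[!is.na(di)]))
  # acyclicity by upward traversal from every individual
  for (i in seq_len(nrow(ped))) {
    seen <- character(0)
    frontier <- ped$id[i]
    while (length(frontier) > 0) {
      j <- match(frontier, ped$id)
      parents <- na.omit(c(ped$sire[j], ped$dam[j]))
      expect_false(ped$id[i] %in% parents)
      frontier <- setdiff(parents, seen)
      seen <- c(seen, frontier)
    }
  }
  # parent-offspring pairs identifiable in a minimal pedigree
  ped2 <- simulate_pedigree(2, n_generations = 1, offspring_per_mating = 1,
                            seed = 3)
  off <- ped2[ped2$generation == 1, ]
  expect_equal(nrow(off), 1)
  expect_true(off$sire %in% ped2$id && off$dam %in% ped2$id)
})

test_that("binary-trait liability respects h2 and the case-fraction target", {
  # null heritability: phenotype independent of genotype
  cfg0 <- sim_config(400, 100, h2_liability = 0, seed = 21)
  g0 <- simulate_genotypes(cfg0)
  tr0 <- simulate_binary_trait(g0, cfg0)
  expect_equal(tr0$genetic_values, numeric(400))

  # split 0.5 at n = 1000: case fraction inside the 95% binomial interval
  cfg <- sim_config(1000, 200, h2_liability = 0.3, prevalence_or_split = 0.5,
                    seed = 22)
  tr <- simulate_binary_trait(simulate_genotypes(cfg), cfg)
  expect_lt(abs(mean(tr$phenotype$score) - 0.5), 1.96 * sqrt(0.25 / 1000))

  # a strong purely recessive QTL enriches dosage-2 carriers among cases
  cfgr <- sim_config(800, 100, maf_range = c(0.4, 0.5), h2_liability = 0.5,
                     qtl = data.frame(snp = 10, mode = "recessive",
                                      effect = 2), seed = 23)
  gr <- simulate_genotypes(cfgr)
  trr <- simulate_binary_trait(gr, cfgr)
  carrier <- gr$dosages[, 10] == 2
  enrich_high <- mean(carrier[trr$phenotype$score == 1])
  enrich_low <- mean(carrier[trr$phenotype$score == 0])
  expect_gt(enrich_high, enrich_low)
  expect_equal(trr$qtl$snp_id, "snp00010")
})

test_that("liability variance decomposition matches the configured components", {
  cfg <- health_sim_config(n_cows = 3000, max_lactation = 3,
                           n_herd_year_seasons = 300, var_hys = 0.3,
                           var_additive = 0.4, var_pe = 0.2,
                           incidence_target = 0.1, seed = 31)
  ped <- simulate_pedigree(3200, n_generations = 2, offspring_per_mating = 3,
                           seed = 31)
  sim <- simulate_health_records(ped, cfg)
  expect_lt(abs(var(sim$truth$hys) - 0.3), 0.1)
  expect_lt(abs(var(sim$truth$pe) - 0.2), 0.03)
  # gene-dropped breeding values: founders have variance var_additive
  founders <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
  expect_lt(abs(var(sim$truth$u[founders]) - 0.4), 0.05)
})

test_that("health records reproduce the target incidence and determinism", {
  # null structure: i.i.d. Bernoulli(incidence)
  cfg0 <- health_sim_config(n_cows = 4000, max_lactation = 3,
                            var_hys = 0, var_additive = 0, var_pe = 0,
                            incidence_target = 0.1, seed = 41)
  ped <- simulate_pedigree(4200, n_generations = 1, offspring_per_mating = 2,
                           seed = 41)
  sim0 <- simulate_health_records(ped, cfg0)
  n <- nrow(sim0$records)
  inc <- incidence(sim0$records)
  expect_lt(abs(inc$percent / 100 - 0.1), 3 * sqrt(0.1 * 0.9 / n))

  # displaced-abomasum scale: 27,408 records at 1.8% incidence
  cfg_da <- health_sim_config(n_cows = 13401, max_lactation = 3,
                              n_herd_year_seasons = 100,
                              incidence_target = 0.018, seed = 42)
  ped_da <- simulate_pedigree(14000, n_generations = 1,
                              offspring_per_mating = 2, seed = 42)
  sim_da <- simulate_health_records(ped_da, cfg_da)
  n_da <- nrow(sim_da$records)
  exp_cases <- n_da * 0.018
  # bound widened beyond the i.i.d. binomial SD: records of the same cow
  # share u, pe and hys, which inflates the variance of the case count
  got <- incidence(sim_da$records)$cases
  expect_lt(abs(got - exp_cases), 6 * sqrt(n_da * 0.018 * 0.982))

  # determinism
  sim_rep <- simulate_health_records(ped_da, cfg_da)
  expect_identical(sim_da$records, sim_rep$records)
})

test_that("half-sib genomic resemblance exceeds unrelated pairs in A", {
  ped <- simulate_pedigree(20, n_generations = 1, offspring_per_mating = 3,
                           seed = 51)
  A <- as.matrix(compute_A(ped))
  off <- ped[!is.na(ped$sire), ]
  same_sire <- outer(off$sire, off$sire, "==") &
    outer(off$dam, off$dam, "!=")
  unrel <- outer(off$sire, off$sire, "!=") & outer(off$dam, off$dam, "!=")
  sub <- A[off$id, off$id]
  diag(same_sire) <- diag(unrel) <- FALSE
  expect_gt(mean(sub[same_sire]), mean(sub[unrel]))
})
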