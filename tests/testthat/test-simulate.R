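test_that("genotypes follow Hardy-Weinberg proportions", {
  cfg <- sim_config(n_samples = 10000, n_variants = 3,
                    maf_range = c(0.5, 0.5), seed = 71)
  G <- simulate_genotypes(cfg)
  freqs <- table(factor(G$dosages[, 1], levels = 0:2)) / 10000
  expect_equal(as.numeric(freqs), c(0.25, 0.5, 0.25), tolerance = 0.03)
  # observed allele frequency within 3 standard errors of the target
  cfg2 <- sim_config(n_samples = 10000, n_variants = 2,
                     maf_range = c(0.2, 0.2), seed = 72)
  G2 <- simulate_genotypes(cfg2)
  se <- sqrt(0.2 * 0.8 / (2 * 10000))
  for (j in 1:2) {
    expect_lt(abs(mean(G2$dosages[, j]) / 2 - 0.2), 3 * se)
  }
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_samples = 100, n_variants = 20, n_causal = 5,
                    h2_liability = 0.4, prevalence = 0.2, seed = 73)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$G$dosages, b$G$dosages)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$truth, b$truth)
  cfg2 <- cfg; cfg2$seed <- 74L
  expect_false(identical(simulate_cohort(cfg2)$G$dosages, a$G$dosages))
})

test_that("the empirical-quantile rule gives an exact case count", {
  cfg <- sim_config(n_samples = 5000, n_variants = 10, n_causal = 2,
                    h2_liability = 0.3, prevalence = 0.1, seed = 75)
  sim <- simulate_cohort(cfg)
  expect_equal(sum(sim$pheno$y == 1), ceiling(0.1 * 5000))
  # prevalence that does not divide n exactly
  cfg2 <- sim_config(n_samples = 333, n_variants = 5, prevalence = 0.25,
                     seed = 76)
  sim2 <- simulate_cohort(cfg2)
  expect_equal(sum(sim2$pheno$y == 1), ceiling(0.25 * 333))
})

test_that("zero heritability yields chance-level prediction", {
  cfg <- sim_config(n_samples = 3000, n_variants = 50, n_causal = 10,
                    h2_liability = 0, prevalence = 0.3, seed = 77)
  sim <- simulate_cohort(cfg)
  score <- rowSums(sim$G$dosages)  # any genotype-derived score
  expect_lt(abs(auc(score, sim$pheno$y) - 0.5), 0.035)  # ~3 SE at this n
})

test_that("the recessive encoding leaves heterozygotes at baseline", {
  cfg <- sim_config(n_samples = 6000, n_variants = 1, maf_range = c(0.4, 0.5),
                    n_causal = 1, h2_liability = 0.5, dominance_fraction = 1,
                    mode_weights = c(recessive = 1), prevalence = 0.3,
                    seed = 78)
  sim <- simulate_cohort(cfg)
  expect_equal(sim$truth$mode, "recessive")
  g <- sim$G$dosages[, sim$truth$index]
  m0 <- mean(sim$liability[g == 0])
  m1 <- mean(sim$liability[g == 1])
  m2 <- mean(sim$liability[g == 2])
  expect_lt(abs(m1 - m0), 0.1)  # ~3 SE of the group-mean difference
  expect_gt(abs(m2 - m0), 3 * abs(m1 - m0))
})

test_that("mode allocation matches the configured composition exactly", {
  cfg <- recovery_cfg(seed = 79)
  sim <- simulate_cohort(cfg)
  tab <- table(sim$truth$mode)
  expect_equal(unname(tab["recessive"]), 3L, ignore_attr = TRUE)
  expect_equal(unname(tab["dominant"]), 2L, ignore_attr = TRUE)
  expect_equal(unname(tab["additive"]), 5L, ignore_attr = TRUE)
  # overshoot modes carry the stated effect signs
  cfg2 <- sim_config(n_samples = 200, n_variants = 40, n_causal = 8,
                     h2_liability = 0.5, dominance_fraction = 1,
                     mode_weights = c(overdominant = 0.5, overrecessive = 0.5),
                     prevalence = 0.3, seed = 80)
  sim2 <- simulate_cohort(cfg2)
  expect_true(all(sim2$truth$beta[sim2$truth$mode == "overdominant"] >= 0))
  expect_true(all(sim2$truth$beta[sim2$truth$mode == "overrecessive"] <= 0))
})

test_that("fixtures round-trip through the PLINK writer", {
  cfg <- sim_config(n_samples = 30, n_variants = 7, n_causal = 2,
                    h2_liability = 0.4, prevalence = 0.4, seed = 81)
  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim$G, sim$pheno, dir, "mini")
  G2 <- read_bed(paths["bed"], flip_to_minor = FALSE)
  expect_equal(G2$dosages, sim$G$dosages, ignore_attr = TRUE)
  ph2 <- read_pheno_table(paths["pheno"])
  expect_equal(ph2$y, sim$pheno$y)
  expect_equal(length(readLines(paths["fam"])), 30L)
  expect_equal(file.size(paths["bed"]), ceiling(30 / 4) * 7 + 3)
})

test_that("non-additive models beat additive ones only under dominance", {
  # strongly recessive architecture: the non-additive fit wins most seeds
  wins <- 0L
  gaps_add <- numeric(0)
  for (seed in 1:5) {
    cfgR <- sim_config(n_samples = 1000, n_variants = 100, n_causal = 6,
                       h2_liability = 0.5, dominance_fraction = 1,
                       mode_weights = c(recessive = 1), prevalence = 0.3,
                       seed = seed)
    simR <- simulate_cohort(cfgR)
    r2n <- holdout_r2(simR, "nonadditive", iterations = 100L, seed = seed)
    r2a <- holdout_r2(simR, "additive", iterations = 100L, seed = seed)
    if (r2n > r2a) wins <- wins + 1L

    # the additive-architecture comparison needs enough samples for the
    # per-kind validation estimates to resolve a 0.01 difference
    cfgA <- sim_config(n_samples = 2000, n_variants = 200, n_causal = 10,
                       h2_liability = 0.5, dominance_fraction = 0,
                       prevalence = 0.3, seed = seed)
    simA <- simulate_cohort(cfgA)
    gaps_add <- c(gaps_add,
                  holdout_r2(simA, "nonadditive", iterations = 100L,
                             seed = seed) -
                    holdout_r2(simA, "additive", iterations = 100L,
                               seed = seed))
  }
  expect_gte(wins, 4)
  # purely additive architecture: the two kinds are nearly interchangeable
  expect_lt(median(abs(gaps_add)), 0.01)
})

test_that("model sparsity grows with polygenicity", {
  n_sel <- vapply(c(4L, 40L, 160L), function(nc) {
    cfg <- sim_config(n_samples = 1000, n_variants = 250, n_causal = nc,
                      h2_liability = 0.5, prevalence = 0.3, seed = 82)
    sim <- simulate_cohort(cfg)
    fit <- boost_fit(sim$G, sim$pheno,
                     boost_params(gamma = 0.1, iterations = 150),
                     "nonadditive")
    length(unique(fit$learners$variant_index))
  }, numeric(1))
  expect_gt(cor(n_sel, c(4, 40, 160), method = "spearman"), 0)
})
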