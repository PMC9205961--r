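test_that("identical seeds give bit-identical panels", {
  cfg <- simulationConfig(seed = 7, n_snps = 150)
  a <- simulatePanel(cfg)
  b <- simulatePanel(cfg)
  expect_identical(genotypes(a$genotypes), genotypes(b$genotypes))
  expect_identical(a$truth, b$truth)
  expect_identical(as.character(a$mtdna$sequences),
                   as.character(b$mtdna$sequences))
  expect_identical(a$traits, b$traits)
})

test_that("config validation rejects bad specs", {
  expect_error(flat_config(1, 100, 10, F = 0), "F must lie")
  hs <- data.frame(parent_a = "A", parent_b = "nosuch", generation = "F1",
                   n = 1, maternal_parent = "A")
  expect_error(flat_config(1, 100, 10, 0.1, npop = 2, hybrid_specs = hs),
               "unknown population")
  expect_error(
    simulationConfig(mtdna = list(length = 100, haplogroup_core_distance = 0,
                                  within_group_mutation_rate = 1)),
    "core distance")
})

test_that("near-zero drift gives near-zero differentiation", {
  cfg <- flat_config(5, 1500, 60, F = 0.001, npop = 2, missing_rate = 0)
  sim <- simulateGenotypes(cfg)
  fst <- phiSt(sim$genotypes, sim$truth$population)
  expect_lt(fst$phi_st[1], 0.01)
})

test_that("drift F = 0.10 yields FST near the realized-frequency oracle", {
  # two populations with F tuned so the Hudson expectation is ~0.10
  cfg <- flat_config(11, 2000, 50, F = 0.10, npop = 2, missing_rate = 0)
  sim <- simulateGenotypes(cfg)
  g <- genotypes(sim$genotypes)
  grp <- sim$truth$population
  est <- phiSt(sim$genotypes, grp)$phi_st[1]
  # oracle: Hudson estimator computed directly from realized sample
  # frequencies, independent of the pairwise-difference implementation
  p1 <- colMeans(g[grp == "A", ]) / 2
  p2 <- colMeans(g[grp == "B", ]) / 2
  oracle <- fst_from_freqs(p1, p2, 100, 100)
  expect_lt(abs(est - oracle), 0.02)
  expect_lt(abs(est - 0.10), 0.04)
})

test_that("allele frequencies pool to the population mixture as n grows", {
  cfg <- flat_config(3, 300, 400, F = 0.2, npop = 2, missing_rate = 0)
  sim <- simulateGenotypes(cfg)
  pooled <- colMeans(genotypes(sim$genotypes)) / 2
  mix <- rowMeans(sim$pop_freqs)
  expect_lt(mean(abs(pooled - mix)), 0.03)
})

test_that("sibling pairs show elevated genotype correlation", {
  ss <- data.frame(population = "A", n_groups = 10, group_size = 2)
  cfg <- flat_config(13, 1000, 40, F = 0.2, npop = 1, sibling_specs = ss,
                     missing_rate = 0)
  sim <- simulateGenotypes(cfg)
  g <- genotypes(sim$genotypes)
  tr <- sim$truth
  sib_cor <- vapply(unique(na.omit(tr$sibling_group)), function(sg) {
    idx <- which(tr$sibling_group == sg)
    cor(g[idx[1], ], g[idx[2], ])
  }, numeric(1))
  unrel <- which(is.na(tr$sibling_group))
  set.seed(1)
  bg_cor <- replicate(40, {
    p <- sample(unrel, 2)
    cor(g[p[1], ], g[p[2], ])
  })
  # full sibs share half their genome: expected correlation is the
  # unrelated baseline plus half the remaining gap (pedigree expectation)
  bg <- mean(bg_cor)
  expect_gt(mean(sib_cor), bg + 0.1)
  expect_lt(abs(mean(sib_cor) - (bg + 0.5 * (1 - bg))), 0.12)
})

test_that("mtDNA: zero mutation rate collapses lineages onto their cores", {
  cfg <- flat_config(2, 50, 5, 0.2, npop = 2,
                     mtdna = list(length = 200, haplogroup_core_distance = 10,
                                  within_group_mutation_rate = 0))
  cfg$pop_specs$p_owa <- c(0, 1)
  sim <- simulateGenotypes(cfg)
  mt <- simulateMtdna(cfg, sim$truth)
  for (i in seq_len(nrow(sim$truth))) {
    core <- as.character(mt$cores[[sim$truth$haplogroup[i]]])
    expect_identical(as.character(mt$sequences[[i]]), core)
  }
})

test_that("hybrids inherit the maternal lineage's haplogroup", {
  hs <- data.frame(parent_a = "MEDU_north", parent_b = "game_farm",
                   generation = "F1", n = 8, maternal_parent = "game_farm")
  cfg <- simulationConfig(seed = 21, n_snps = 60, hybrid_specs = hs,
                          sibling_specs = defaultSiblingSpecs()[0, ])
  sim <- simulateGenotypes(cfg)
  f1 <- sim$truth$class == "F1"
  # game-farm (domestic) mothers all carry Old World A haplotypes
  expect_true(all(sim$truth$haplogroup[f1] == "OW-A"))
  mt <- simulateMtdna(cfg, sim$truth)
  hg <- assignHaplogroup(mt$sequences[f1], mt$cores)
  expect_true(all(hg == "OW-A"))
})

test_that("haplotype collapsing recovers at least the two cores", {
  panel <- default_panel()
  haps <- collapseHaplotypes(panel$mtdna$sequences)
  # exact-sequence dedupe oracle
  oracle <- length(unique(toupper(as.character(panel$mtdna$sequences))))
  expect_identical(length(unique(haps$table$haplotype)), oracle)
  expect_gte(oracle, 2)
})

test_that("variant expression hits its configured rate in immature males", {
  cfg <- flat_config(31, 10, 1, 0.2, npop = 1)
  n <- 1000
  truth <- data.frame(sample_id = sprintf("x%04d", 1:n), class = "A",
                      population = "A", sibling_group = NA,
                      sex = "M", age = "immature", site = "A:site_1",
                      haplogroup = "NW-B", cohort = "MI",
                      stringsAsFactors = FALSE)
  tr <- simulateTraits(cfg, truth)
  sch <- loadTraitSchema()
  ps <- scorePlumage(tr, sch)$PS
  frac_expressing <- mean(ps > 0)
  expect_lt(abs(frac_expressing - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  # and the PS <= 4 calibration holds marginally
  expect_lt(abs(mean(ps <= 4) - 0.97), 3 * sqrt(0.03 * 0.97 / n))
})

test_that("variant_expression_prob = 0 gives all-null Mexican duck records", {
  cfg <- flat_config(32, 10, 1, 0.2, npop = 1,
                     trait_model = list(variant_expression_prob = 0,
                                        ps_le4_frac = 0.97,
                                        mallard_max_prob = 0.98,
                                        hybrid_parent_mix = 0.5))
  truth <- data.frame(sample_id = sprintf("x%03d", 1:200), class = "A",
                      population = "A", sibling_group = NA,
                      sex = "M", age = "immature", site = "A:site_1",
                      haplogroup = "NW-B", cohort = "MI",
                      stringsAsFactors = FALSE)
  ps <- scorePlumage(simulateTraits(cfg, truth), loadTraitSchema())$PS
  expect_true(all(ps <= 1))
})

test_that("adult male mallards mostly score the cohort maximum", {
  ps_spec <- data.frame(name = "wild_mallard", n_samples = 1, F = 0.2,
                        p_owa = 0.3, is_mallard_type = TRUE)
  cfg <- simulationConfig(seed = 33, n_snps = 10, pop_specs = ps_spec,
                          hybrid_specs = defaultHybridSpecs()[0, ],
                          sibling_specs = defaultSiblingSpecs()[0, ])
  truth <- data.frame(sample_id = sprintf("m%03d", 1:300),
                      class = "wild_mallard", population = "wild_mallard",
                      sibling_group = NA, sex = "M", age = "adult",
                      site = "wild_mallard:site_1", haplogroup = "NW-B",
                      cohort = "MA", stringsAsFactors = FALSE)
  sch <- loadTraitSchema()
  ps <- scorePlumage(simulateTraits(cfg, truth, sch), sch)$PS
  # independent schema walker for the cohort maximum
  raw <- read.csv(system.file("extdata", "trait_schema.csv",
                              package = "vetkey"))
  pl <- raw[raw$kind == "plumage" & grepl("MA", raw$cohorts), ]
  mx <- sum(tapply(pl$score, pl$trait, max))
  expect_identical(mx, 21L)
  expect_gt(mean(ps == mx), 0.5)
  expect_true(all(ps <= mx))
})
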