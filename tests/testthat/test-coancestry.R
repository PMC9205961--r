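test_that("a cloned sample is its clone's closest relative", {
  sim <- simulateGenotypes(flat_config(41, 300, 15, 0.2, npop = 2))
  g <- genotypes(sim$genotypes)
  g <- rbind(g, clone = g[1, ])
  rownames(g) <- c(rownames(g)[-nrow(g)], "clone")
  cm <- coancestryMatrix(genotypeMatrix(g))
  C <- coancestry(cm)
  off <- C[1, -1]
  expect_equal(unname(which.max(off)), which(names(off) == "clone"))
  expect_gt(C[1, "clone"], max(off[names(off) != "clone"]))
})

test_that("C is symmetric, diagonal-maximal and permutation-equivariant", {
  sim <- simulateGenotypes(flat_config(43, 250, 12, 0.3, npop = 2,
                                       missing_rate = 0.05))
  cm <- coancestryMatrix(sim$genotypes)
  C <- coancestry(cm)
  expect_equal(C, t(C))
  expect_true(all(diag(C) >= apply(C - diag(diag(C)), 1, max)))

  set.seed(2)
  perm <- sample(nSamples(sim$genotypes))
  cm2 <- coancestryMatrix(sim$genotypes[perm, ])
  expect_equal(coancestry(cm2), C[perm, perm])
})

test_that("group means are consistent with direct averaging of C", {
  sim <- simulateGenotypes(flat_config(44, 200, 10, 0.3, npop = 2))
  grp <- sim$truth$population
  cm <- coancestryMatrix(sim$genotypes, groups = grp)
  C <- coancestry(cm)
  direct_ab <- mean(C[grp == "A", grp == "B"])
  expect_equal(unname(groupMeans(cm)["A", "B"]), direct_ab)
  blockA <- C[grp == "A", grp == "A"]
  expect_equal(unname(groupMeans(cm)["A", "A"]),
               mean(blockA[upper.tri(blockA)]))
})

test_that("panmictic halves of one population are indistinguishable", {
  sim <- simulateGenotypes(flat_config(45, 1200, 40, 0.2, npop = 1,
                                       missing_rate = 0))
  grp <- rep(c("half1", "half2"), each = 20)
  cm <- coancestryMatrix(sim$genotypes, groups = grp)
  gm <- groupMeans(cm)
  expect_lt(abs(gm["half1", "half1"] - gm["half1", "half2"]), 0.005)
  expect_lt(abs(gm["half2", "half2"] - gm["half1", "half2"]), 0.005)
})

test_that("private rare alleles never increase coancestry with others", {
  sim <- simulateGenotypes(flat_config(46, 150, 10, 0.3, npop = 1,
                                       missing_rate = 0))
  g <- genotypes(sim$genotypes)
  C0 <- coancestry(coancestryMatrix(genotypeMatrix(g)))
  extra <- matrix(0L, nrow(g), 20)
  extra[1, ] <- 1L   # sample 1 gains 20 private rare alleles
  g2 <- cbind(g, extra)
  rownames(g2) <- rownames(g)
  C1 <- coancestry(coancestryMatrix(genotypeMatrix(g2)))
  expect_true(all(C1[1, -1] <= C0[1, -1] + 1e-12))
})

test_that("full sibs stand out from the within-population distribution", {
  hits <- vapply(1:5, function(r) {
    ss <- data.frame(population = "A", n_groups = 1, group_size = 2)
    sim <- simulateGenotypes(flat_config(500 + r, 600, 30, 0.2, npop = 1,
                                         sibling_specs = ss,
                                         missing_rate = 0))
    cm <- coancestryMatrix(sim$genotypes)
    C <- coancestry(cm)
    tr <- sim$truth
    sib_idx <- which(!is.na(tr$sibling_group))
    unrel <- which(is.na(tr$sibling_group))
    vals <- C[unrel, unrel][upper.tri(C[unrel, unrel])]
    C[sib_idx[1], sib_idx[2]] > mean(vals) + 3 * sd(vals)
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("sibling detection recovers simulated groups and flags evidence", {
  ss <- data.frame(population = c("A", "B"), n_groups = c(2, 1),
                   group_size = c(2, 3))
  cfg <- flat_config(47, 1000, 35, c(0.05, 0.08), npop = 2,
                     sibling_specs = ss, missing_rate = 0.02)
  sim <- simulateGenotypes(cfg)
  mt <- simulateMtdna(cfg, sim$truth)
  names(mt$sequences) <- sim$truth$sample_id
  haps <- collapseHaplotypes(mt$sequences)
  cm <- coancestryMatrix(sim$genotypes, groups = sim$truth$population)
  sibs <- detectSiblings(cm, data.frame(sample_id = sim$truth$sample_id,
                                        site = sim$truth$site),
                         haplotypes = haps$table)
  found <- siblingGroups(sibs)
  truth_groups <- split(sim$truth$sample_id, sim$truth$sibling_group)
  for (tg in truth_groups) {
    match_found <- any(vapply(found, function(f) all(tg %in% f), logical(1)))
    expect_true(match_found)
  }
  expect_identical(anyDuplicated(unlist(found)), 0L)
  # groups of true siblings share site and haplotype, hence confirmed
  ev <- sibs@evidence
  for (i in seq_along(found))
    if (all(found[[i]] %in% unlist(truth_groups)))
      expect_true(ev$confirmed[i])
})

test_that("a sibling pair split across sites is retained but unconfirmed", {
  ss <- data.frame(population = "A", n_groups = 1, group_size = 2)
  cfg <- flat_config(48, 800, 25, 0.1, npop = 1, sibling_specs = ss)
  sim <- simulateGenotypes(cfg)
  meta <- data.frame(sample_id = sim$truth$sample_id, site = sim$truth$site)
  sib_ids <- sim$truth$sample_id[!is.na(sim$truth$sibling_group)]
  meta$site[meta$sample_id == sib_ids[2]] <- "elsewhere"
  cm <- coancestryMatrix(sim$genotypes, groups = sim$truth$population)
  sibs <- detectSiblings(cm, meta)
  hit <- vapply(siblingGroups(sibs), function(f) all(sib_ids %in% f),
                logical(1))
  expect_true(any(hit))
  expect_false(sibs@evidence$confirmed[which(hit)])
  expect_true(is.na(sibs@evidence$same_haplotype[which(hit)]))
})

test_that("dropping to representatives removes sum(size - 1) samples", {
  # 12 groups totaling 29 samples (7 pairs + 5 trios) -> 17 removed
  ids <- sprintf("s%03d", 1:40)
  sizes <- c(rep(2, 7), rep(3, 5))
  groups <- split(ids[1:29], rep(seq_along(sizes), sizes))
  ev <- data.frame(group = sprintf("g%02d", 1:12),
                   mean_coancestry = 0.9, same_site = TRUE,
                   same_haplotype = TRUE, confirmed = TRUE,
                   representative = vapply(groups, min, character(1)))
  sibs <- new("SiblingGroups", groups = unname(groups), evidence = ev)
  m <- matrix(0:1, nrow = 40, ncol = 10)
  rownames(m) <- ids
  gm <- genotypeMatrix(m)
  out <- dropToRepresentatives(gm, sibs)
  expect_identical(nSamples(gm) - nSamples(out), 17L)

  # one trio -> 2 removed; no groups -> identity
  trio <- new("SiblingGroups", groups = list(ids[1:3]),
              evidence = ev[1, , drop = FALSE])
  expect_identical(nSamples(gm) - nSamples(dropToRepresentatives(gm, trio)),
                   2L)
  none <- new("SiblingGroups", groups = list(),
              evidence = ev[0, , drop = FALSE])
  expect_identical(sampleIds(dropToRepresentatives(gm, none)),
                   sampleIds(gm))
})
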