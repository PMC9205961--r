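sch <- loadTraitSchema()

test_that("the packaged schema carries the full trait transcription", {
  tab <- traitTable(sch)
  expect_identical(sum(tab$kind == "plumage"), 16L)
  expect_identical(sum(tab$kind %in% c("structural", "mass")), 7L)
  expect_identical(tab$max_score[tab$trait == "percent_green_head"], 3L)
  expect_identical(tab$max_score[tab$trait == "central_tail_curl"], 2L)
  expect_identical(nrow(traitLevels(sch, "rump_pattern")), 3L)
  # female cohorts never score the male-only traits
  expect_false("percent_green_head" %in% applicableTraits(sch, "FA"))
  expect_true("percent_green_head" %in% applicableTraits(sch, "MI"))
})

test_that("schemas with gapped or single-level ordinals are rejected", {
  tmp <- tempfile(fileext = ".csv")
  raw <- read.csv(system.file("extdata", "trait_schema.csv",
                              package = "vetkey"))
  bad <- raw
  bad$score[bad$trait == "rump_pattern" & bad$score == 1] <- 5
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(loadTraitSchema(tmp), "consecutive")

  bad2 <- raw[!(raw$trait == "speculum_color" & raw$score == 1), ]
  write.csv(bad2, tmp, row.names = FALSE)
  expect_error(loadTraitSchema(tmp), ">= 2 levels")
})

test_that("plumage scores sum applicable ordinals per cohort", {
  # all-null adult female
  rec <- data.frame(sample_id = "f", cohort = "FA")
  for (tr in applicableTraits(sch, "FA")) rec[[tr]] <- 0L
  expect_identical(scorePlumage(rec, sch)$PS, 0L)

  # adult male at every maximum: PS 21
  tab <- traitTable(sch)
  rec2 <- data.frame(sample_id = "m", cohort = "MA")
  for (tr in applicableTraits(sch, "MA"))
    rec2[[tr]] <- tab$max_score[tab$trait == tr]
  expect_identical(scorePlumage(rec2, sch)$PS, 21L)
  expect_identical(cohortMaxScore(sch, "MA"), 21L)

  # green-head 1 + tail curl 1 + rump 1, all else null: PS 3
  rec3 <- data.frame(sample_id = "m2", cohort = "MA",
                     percent_green_head = 1L, central_tail_curl = 1L,
                     rump_pattern = 1L)
  sc3 <- scorePlumage(rec3, sch)
  expect_identical(sc3$PS, 3L)
  # unsupplied traits count as missing and contribute 0
  expect_identical(sc3$n_missing,
                   length(applicableTraits(sch, "MA")) - 3L)

  expect_error(scorePlumage(
    data.frame(sample_id = "x", cohort = "MA", rump_pattern = 7L), sch),
    "rump_pattern")
  expect_error(scorePlumage(
    data.frame(sample_id = "x", cohort = "ZZ", rump_pattern = 1L), sch),
    "cohort")
})

test_that("PS is monotone in any single trait level", {
  base <- data.frame(sample_id = "m", cohort = "MA",
                     percent_green_head = 0L, rump_pattern = 1L,
                     central_tail_curl = 0L)
  ps0 <- scorePlumage(base, sch)$PS
  for (tr in c("percent_green_head", "rump_pattern", "central_tail_curl")) {
    up <- base
    up[[tr]] <- up[[tr]] + 1L
    expect_gt(scorePlumage(up, sch)$PS, ps0 - 1L)
    expect_gte(scorePlumage(up, sch)$PS, ps0)
  }
})

test_that("plumage PCA separates classes and handles degenerate input", {
  panel <- default_panel()
  truth <- panel$truth
  sel <- truth$class %in% c("MEDU_north", "wild_mallard") &
    truth$cohort == "MA"
  rec <- panel$traits[sel, ]
  pca <- plumagePCA(rec, sch)
  side <- truth$class[sel]
  a <- pca$scores[side == "MEDU_north", 1]
  b <- pca$scores[side == "wild_mallard", 1]
  expect_true(min(a) > max(b) || min(b) > max(a))

  same <- rec[rep(1, 5), ]
  expect_true(all(plumagePCA(same, sch)$explained_variance_fraction == 0))
  expect_error(plumagePCA(rec[1, ], sch), "at least 2")
  rec_na <- rec
  rec_na$flank_pattern <- NA_integer_
  expect_warning(plumagePCA(rec_na, sch), "all-missing")
})

test_that("structural ANOVA is calibrated under the null and powered
           under a shift", {
  set.seed(8)
  n <- 60
  rec <- data.frame(sample_id = sprintf("s%02d", 1:n), cohort = "MA",
                    mass = rnorm(n, 1000, 50),
                    tarsus_length = rnorm(n, 43, 1),
                    bill_length = rep(52, n))   # constant -> undefined F
  labels <- rep(c("mexican_duck", "mallard", "hybrid"), each = n / 3)
  null_out <- structuralTests(rec, labels, sch)
  an <- null_out$anova
  expect_false(any(an$significant[!an$undefined]))
  expect_true(an$undefined[an$trait == "bill_length"])

  rec$mass[labels == "mallard"] <- rec$mass[labels == "mallard"] + 200
  shift <- structuralTests(rec, labels, sch)$anova
  expect_true(shift$significant[shift$trait == "mass"])
})

test_that("diagnostic-trait selection finds a perfectly separating trait", {
  set.seed(10)
  n <- 40
  rec <- data.frame(sample_id = sprintf("s%02d", 1:n), cohort = "MA")
  labels <- rep(c("mexican_duck", "mallard"), each = n / 2)
  rec$speculum_color <- ifelse(labels == "mallard", 1L, 0L)
  rec$flank_pattern <- sample(0:1, n, replace = TRUE)   # noise
  rec$breast_pattern <- sample(0:1, n, replace = TRUE)  # noise
  out <- selectDiagnosticTraits(rec, labels, "MA", sch)
  expect_identical(out$traits, "speculum_color")
  expect_identical(out$loo_accuracy, 1)
  expect_identical(out$ranking$trait[1], "speculum_color")
})

test_that("selection is stable under appended pure-noise traits", {
  panel <- default_panel()
  truth <- panel$truth
  key_class <- ifelse(truth$class %in% c("F1", "BC1"), "hybrid",
                      ifelse(truth$class %in% c("wild_mallard", "game_farm",
                                                "khaki_campbell"),
                             "mallard", "mexican_duck"))
  sel <- truth$cohort == "MA"
  rec <- panel$traits[sel, ]
  base <- selectDiagnosticTraits(rec, key_class[sel], "MA", sch)
  stable <- vapply(1:5, function(r) {
    set.seed(700 + r)
    noisy <- rec
    for (tr in c("flank_pattern", "breast_pattern"))
      noisy[[tr]] <- sample(0:1, nrow(noisy), replace = TRUE)
    # replacing two traits with noise must not pull noise into the subset
    out <- selectDiagnosticTraits(noisy, key_class[sel], "MA", sch)
    !any(c("flank_pattern", "breast_pattern") %in% out$traits)
  }, logical(1))
  expect_gte(sum(stable), 4)
  # selected traits only ever come from the cohort's diagnostic-flagged set
  tab <- traitTable(sch)
  flagged <- tab$trait[tab$diag_MA]
  expect_true(all(base$traits %in% flagged))
})

test_that("keys calibrate, merge overlapping classes, and classify", {
  # disjoint synthetic ranges -> three-class key
  scores <- data.frame(sample_id = sprintf("s%02d", 1:30), cohort = "MA",
                       PS = c(rep(0:4, 4), 6:9, 13:18),
                       traits_used = 16, n_missing = 0)
  labels <- c(rep("mexican_duck", 20), rep("hybrid", 4), rep("mallard", 6))
  key <- buildKey(scores, labels, "MA", sch)
  iv <- keyIntervals(key)
  expect_identical(iv$class, c("mexican_duck", "hybrid", "mallard"))
  expect_identical(iv$upper[iv$class == "mexican_duck"], 4L)
  expect_identical(iv$upper[iv$class == "hybrid"], 9L)

  expect_identical(
    classifyPlumage(data.frame(cohort = "MA", PS = c(0L, 4L, 5L, 10L)), key),
    c("mexican_duck", "mexican_duck", "hybrid", "mallard"))
  expect_error(classifyPlumage(data.frame(cohort = "FI", PS = 1L), key),
               "cohort mismatch")

  # overlapping hybrid/mallard ranges -> merged class
  labels2 <- c(rep("mexican_duck", 20), rep("hybrid", 4), rep("mallard", 6))
  scores2 <- scores
  scores2$PS <- c(rep(0:4, 4), 8:11, 9:14)
  key2 <- buildKey(scores2, labels2, "MA", sch)
  expect_identical(keyIntervals(key2)$class,
                   c("mexican_duck", "hybrid/mallard"))
  expect_true(key2@calibration$merged)

  # missing reference class is flagged, not fatal
  expect_message(
    key3 <- buildKey(scores[1:20, ], labels[1:20], "MA", sch),
    "absent")
  expect_identical(keyIntervals(key3)$class,
                   c("mexican_duck", "hybrid/mallard"))
})

test_that("classification never moves toward Mexican duck as PS rises", {
  scores <- data.frame(sample_id = sprintf("s%02d", 1:30), cohort = "MA",
                       PS = c(rep(0:4, 4), 6:9, 13:18),
                       traits_used = 16, n_missing = 0)
  labels <- c(rep("mexican_duck", 20), rep("hybrid", 4), rep("mallard", 6))
  key <- buildKey(scores, labels, "MA", sch)
  rank <- c(mexican_duck = 1, hybrid = 2, "hybrid/mallard" = 2.5,
            mallard = 3)
  cls <- classifyPlumage(data.frame(cohort = "MA", PS = 0:21), key)
  expect_true(all(diff(rank[cls]) >= 0))
})

test_that("rebuilding a key from its own classifications is idempotent", {
  scores <- data.frame(sample_id = sprintf("s%02d", 1:30), cohort = "MA",
                       PS = c(rep(0:4, 4), 6:9, 13:18),
                       traits_used = 16, n_missing = 0)
  labels <- c(rep("mexican_duck", 20), rep("hybrid", 4), rep("mallard", 6))
  key <- buildKey(scores, labels, "MA", sch)
  relabeled <- classifyPlumage(scores, key)
  key2 <- buildKey(scores, relabeled, "MA", sch)
  expect_identical(keyIntervals(key2), keyIntervals(key))
})

test_that("key evaluation reports accuracy and a permutation baseline", {
  preds <- data.frame(sample_id = sprintf("s%02d", 1:40),
                      cohort = rep(c("MA", "FA"), each = 20),
                      class = rep(c("mexican_duck", "mallard"), 20))
  truth <- data.frame(sample_id = preds$sample_id, class = preds$class)
  perfect <- evaluateKey(preds, truth)
  expect_true(all(perfect$accuracy$accuracy == 1))

  set.seed(11)
  shuffled <- truth
  shuffled$class <- sample(shuffled$class)
  base <- evaluateKey(preds, shuffled)
  expect_lt(abs(base$overall - 0.5), 0.25)
  # merged key class matches either genetic label
  m <- evaluateKey(data.frame(sample_id = "a", cohort = "MA",
                              class = "hybrid/mallard"),
                   data.frame(sample_id = "a", class = "hybrid"))
  expect_identical(m$overall, 1)
  expect_error(evaluateKey(preds, data.frame(sample_id = "zz",
                                             class = "mallard")),
               "overlapping")
})

test_that("historical reassessment recovers the generator's truth table", {
  # all-null records reclassify as Mexican duck regardless of original label
  keyset <- local({
    scores <- data.frame(sample_id = sprintf("s%02d", 1:30), cohort = "MA",
                         PS = c(rep(0:4, 4), 6:9, 13:18),
                         traits_used = 16, n_missing = 0)
    labels <- c(rep("mexican_duck", 20), rep("hybrid", 4),
                rep("mallard", 6))
    list(MA = buildKey(scores, labels, "MA", sch))
  })
  rec <- data.frame(sample_id = c("h1", "h2"), cohort = "MA")
  for (tr in applicableTraits(sch, "MA")) rec[[tr]] <- 0L
  out <- reassessSpecimens(rec, c("hybrid", "mexican_duck"), keyset, sch)
  expect_true(all(out$per_specimen$key_class == "mexican_duck"))
  expect_identical(out$per_specimen$changed, c(TRUE, FALSE))

  # empty input gives an empty report
  empty <- reassessSpecimens(rec[0, ], character(0), keyset, sch)
  expect_identical(nrow(empty$per_specimen), 0L)

  # cohort without a key is skipped with a message
  rec2 <- rbind(rec, rec[1, ])
  rec2$cohort[3] <- "FI"
  rec2$sample_id[3] <- "h3"
  expect_message(out2 <- reassessSpecimens(rec2, c("hybrid", "mexican_duck",
                                                   "hybrid"), keyset, sch),
                 "skipping")
  expect_identical(nrow(out2$per_specimen), 2L)

  # synthetic "historical" panel: key classes equal the generator truth
  panel <- default_panel()
  truth <- panel$truth
  key_class <- ifelse(truth$class %in% c("F1", "BC1"), "hybrid",
                      ifelse(truth$class %in% c("wild_mallard", "game_farm",
                                                "khaki_campbell"),
                             "mallard", "mexican_duck"))
  scores <- scorePlumage(panel$traits, sch)
  keys <- lapply(setNames(c("MI", "MA", "FI", "FA"),
                          c("MI", "MA", "FI", "FA")), function(coh) {
    s <- scores$cohort == coh
    buildKey(scores[s, ], key_class[s], coh, sch)
  })
  orig <- sample(c("mexican_duck", "hybrid"), nrow(panel$traits),
                 replace = TRUE)   # deliberately unreliable originals
  rep_out <- reassessSpecimens(panel$traits, orig, keys, sch)
  per <- rep_out$per_specimen
  truth_cls <- key_class[match(per$sample_id, truth$sample_id)]
  merged_ok <- per$key_class == truth_cls |
    (per$key_class == "hybrid/mallard" & truth_cls %in% c("hybrid",
                                                          "mallard"))
  expect_gt(mean(merged_ok), 0.95)
})
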