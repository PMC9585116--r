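test_that("blank filtering implements the two-fold rule per cell", {
  samples <- tiny_samples()
  feats <- dplyr::bind_rows(
    feature_long("F1", 300, 5, list(P1_M = 10000, P2_M = 9999, B1_WB = 5000)),
    feature_long("F2", 310, 6, list(P1_M = 100, P2_M = 50, B1_WB = 0)),
    feature_long("F3", 320, 7, list(P1_M = 4000, P2_M = 3000, B1_WB = 5000))
  )
  out <- filter_blank_features(feats, samples, ratio = 2)
  ab <- function(f, s) out$abundance[out$feature_id == f & out$sample_id == s][1]
  expect_equal(ab("F1", "P1_M"), 10000)  # exactly two-fold qualifies
  expect_equal(ab("F1", "P2_M"), 0)      # 9999 < 2 x 5000
  expect_equal(ab("F2", "P1_M"), 100)    # zero blank signal: untouched
  expect_false("F3" %in% out$feature_id) # all cells fail -> feature dropped
  expect_equal(attr(out, "n_dropped"), 1)

  no_blank <- samples[samples$matrix != "water_blank", ]
  expect_error(filter_blank_features(feats, no_blank),
               class = "expo_validation_error", regexp = "1")
})

test_that("raising the blank ratio only zeroes more cells", {
  samples <- tiny_samples()
  set.seed(42)
  feats <- dplyr::bind_rows(lapply(1:20, function(i) {
    feature_long(sprintf("F%02d", i), 200 + i, i / 2,
                 list(P1_M = runif(1, 0, 2e4), P2_M = runif(1, 0, 2e4),
                      B1_WB = runif(1, 0, 8e3)))
  }))
  zeroed <- vapply(c(1.5, 2, 3, 5), function(r) {
    out <- filter_blank_features(feats, samples, ratio = r)
    attr(out, "n_zeroed")
  }, numeric(1))
  expect_true(all(diff(zeroed) >= 0))
})

test_that("replicate averaging keeps doubly-observed cells and drops singletons", {
  f <- tibble::tibble(
    feature_id = "F1", neutral_mass = 300, rt = 1, mode = "positive",
    batch = 1L,
    sample_id = rep(c("S1", "S2", "S3"), each = 2),
    replicate = rep(1:2, 3),
    abundance = c(4000, 6000, 7000, 0, 5000, 5000)
  )
  out <- average_replicates(f)
  expect_equal(out$abundance[out$sample_id == "S1"], 5000)
  expect_equal(out$abundance[out$sample_id == "S2"], 0)  # singleton filtered
  expect_equal(out$abundance[out$sample_id == "S3"], 5000)

  f3 <- dplyr::bind_rows(f, tibble::tibble(
    feature_id = "F1", neutral_mass = 300, rt = 1, mode = "positive",
    batch = 1L, sample_id = "S1", replicate = 3L, abundance = 1))
  expect_error(average_replicates(f3), class = "expo_validation_error")
})

test_that("formula matching minimises ppm error and applies the score cut", {
  db <- tibble::tibble(formula = c("A", "B"),
                       monoisotopic_mass = c(300, 300.01))
  f <- tibble::tibble(
    feature_id = c("F1", "F2", "F3"),
    neutral_mass = c(300.0000, 300.0060, 300.0104))
  m <- match_formulas(f, db, ppm_tol = 5, score_threshold = 0)
  expect_equal(m$formula[m$feature_id == "F1"], "A")
  expect_equal(m$ppm_error[m$feature_id == "F1"], 0)
  expect_equal(m$match_score[m$feature_id == "F1"], 100)
  # 300.0060 is 20 ppm from A and ~13 ppm from B: outside the 5 ppm window
  expect_false("F2" %in% m$feature_id)
  # F3 sits between the two formulas; assigned to the nearer (B)
  expect_equal(m$formula[m$feature_id == "F3"], "B")
  expect_equal(attr(m, "n_unmatched"), 1)

  # default score threshold 70 corresponds to |ppm| <= 1.5 at tol 5
  f2 <- tibble::tibble(feature_id = c("G1", "G2"),
                       neutral_mass = 300 * (1 + c(1.4e-6, 1.6e-6)))
  m2 <- match_formulas(f2, db, ppm_tol = 5, score_threshold = 70)
  expect_true("G1" %in% m2$feature_id)
  expect_false("G2" %in% m2$feature_id)
  expect_error(match_formulas(f, db[0, ]), class = "expo_argument_error")
})

test_that("detection calling uses the inclusive 5000 boundary", {
  ab <- tibble::tibble(chemical = "c", sample_id = c("a", "b", "d"),
                       abundance = c(5000, 4999, 0))
  det <- call_detections(ab)
  expect_equal(det$detected, c(TRUE, FALSE, FALSE))
  expect_error(call_detections(tibble::tibble(abundance = -1)),
               class = "expo_validation_error")
})

test_that("duplicate grouping applies both windows and transitive closure", {
  base <- 400
  feat <- tibble::tibble(
    feature_id = c("A", "B", "C", "D", "E"),
    formula = "X",
    neutral_mass = c(base,
                     base * (1 + 10e-6),   # 10 ppm from A
                     base * (1 + 20e-6),   # 10 ppm from B, 20 ppm from A
                     base * (1 + 10e-6),   # duplicate mass of B...
                     base),
    rt = c(1.0, 1.3, 1.1, 1.9, 2.6),       # ...but RT 0.6 from B
    batch = 1L, ppm_error = 0
  )
  g <- find_duplicate_groups(feat, scope = "within_batch")
  p <- partition_of(g)
  # A-B and B-C match, A-C does not: transitively one group; D beyond RT
  # window of B; E isolated
  expect_equal(p, list(c("A", "B", "C"), "D", "E"))
})

test_that("duplicate windows are inclusive at exactly 15 ppm and 0.5 min", {
  base <- 300
  at <- tibble::tibble(
    feature_id = c("P", "Q"), formula = "X",
    neutral_mass = c(base, base * (1 + 15e-6)),
    rt = c(1.0, 1.5), batch = 1L, ppm_error = 0)
  expect_equal(max(find_duplicate_groups(at)$group_id), 1L)
  beyond_ppm <- at; beyond_ppm$neutral_mass[2] <- base * (1 + 15.01e-6)
  expect_equal(max(find_duplicate_groups(beyond_ppm)$group_id), 2L)
  beyond_rt <- at; beyond_rt$rt[2] <- 1.51
  expect_equal(max(find_duplicate_groups(beyond_rt)$group_id), 2L)
})

test_that("duplicate groups equal an independent BFS oracle on random instances", {
  for (s in 1:40) {
    feat <- random_feature_instance(sample(2:120, 1), seed = s)
    got <- partition_of(find_duplicate_groups(feat, scope = "across_batch"))
    want <- bfs_components(feat$feature_id, pairwise_match_matrix(feat))
    expect_equal(got, want)
  }
})

test_that("collapse keeps the highest-DF member with a deterministic tie rule", {
  feat <- tibble::tibble(
    feature_id = c("A", "B", "C"), formula = "X",
    neutral_mass = c(500, 500.0001, 500.0002), rt = 1, batch = 1L,
    ppm_error = c(2, 1, 1))
  groups <- tibble::tibble(feature_id = c("A", "B", "C"), group_id = 1L)
  freqs <- tibble::tibble(feature_id = c("A", "B", "C"),
                          detection_frequency = c(0.8, 0.5, 0.5))
  kept <- collapse_duplicates(feat, groups, freqs)
  expect_equal(kept$feature_id, "A")
  expect_equal(nrow(attr(kept, "removed")), 2)

  # tie on DF -> smaller |ppm_error|; tie again -> smaller id
  freqs2 <- tibble::tibble(feature_id = c("A", "B", "C"),
                           detection_frequency = 0.5)
  expect_equal(collapse_duplicates(feat, groups, freqs2)$feature_id, "B")
  feat$ppm_error <- 1
  expect_equal(collapse_duplicates(feat, groups, freqs2)$feature_id, "A")

  # singleton group retains itself
  g1 <- tibble::tibble(feature_id = "A", group_id = 1L)
  expect_equal(collapse_duplicates(feat[1, ], g1, freqs)$feature_id, "A")
})

test_that("retained set is invariant to input order and collapsing is idempotent", {
  feat <- random_feature_instance(80, seed = 99)
  freqs <- tibble::tibble(feature_id = feat$feature_id,
                          detection_frequency = withr::with_seed(
                            99, round(runif(80), 2)))
  run <- function(f) {
    g <- find_duplicate_groups(f, scope = "within_batch")
    sort(collapse_duplicates(f, g, freqs)$feature_id)
  }
  kept <- run(feat)
  for (s in 1:5) {
    perm <- withr::with_seed(s, feat[sample.int(nrow(feat)), ])
    expect_equal(run(perm), kept)
  }
  # idempotence: a second pass removes nothing
  once <- collapse_duplicates(feat,
                              find_duplicate_groups(feat, scope = "within_batch"),
                              freqs)
  twice <- collapse_duplicates(once,
                               find_duplicate_groups(once, scope = "within_batch"),
                               freqs)
  expect_setequal(twice$feature_id, once$feature_id)
  expect_equal(nrow(attr(twice, "removed")), 0)
})

test_that("mode merging collapses cross-mode duplicates and passes exclusives", {
  feat <- tibble::tibble(
    feature_id = c("pos1", "neg1", "pos2"),
    formula = c("X", "X", "Y"),
    neutral_mass = c(400, 400.0004, 500),
    rt = c(1, 1.2, 3), batch = 1L,
    mode = c("positive", "negative", "positive"),
    ppm_error = c(0.5, 1, 0))
  freqs <- tibble::tibble(feature_id = c("pos1", "neg1", "pos2"),
                          detection_frequency = c(0.9, 0.4, 0.2))
  out <- merge_modes(feat, freqs)
  expect_setequal(out$feature_id, c("pos1", "pos2"))
  # an empty table passes through unchanged
  expect_equal(nrow(merge_modes(feat[0, ], freqs)), 0)
})

test_that("cross-batch harmonization chains batches and keeps exclusives", {
  feat <- tibble::tibble(
    feature_id = c("A1", "A2", "A3", "B1"),
    formula = c("X", "X", "X", "Y"),
    neutral_mass = c(600, 600 * (1 + 10e-6), 600 * (1 + 20e-6), 700),
    rt = c(1.0, 1.3, 1.6, 2),
    batch = c(1L, 2L, 3L, 2L),
    ppm_error = 0)
  ab <- tibble::tibble(
    feature_id = c("A1", "A2", "A3", "B1"),
    sample_id = c("s1", "s2", "s3", "s2"),
    abundance = c(1e4, 2e4, 3e4, 5e3))
  freqs <- tibble::tibble(feature_id = feat$feature_id,
                          detection_frequency = c(0.5, 0.6, 0.7, 0.2))
  h <- harmonize_batches(feat, ab, freqs)
  expect_equal(nrow(h$chemicals), 2)
  spanning <- h$chemicals[h$chemicals$formula == "X", ]
  expect_equal(spanning$n_batches, 3)  # A1-A2, A2-A3 chained transitively
  expect_equal(h$chemicals$n_batches[h$chemicals$formula == "Y"], 1)
  expect_true(all(table(h$provenance$chemical[h$provenance$chemical ==
                                                spanning$chemical]) == 3))

  # drop_unreplicated removes the batch-exclusive chemical
  h2 <- harmonize_batches(feat, ab, freqs, drop_unreplicated = TRUE)
  expect_equal(nrow(h2$chemicals), 1)

  # two same-batch members in one component -> warning, one kept per batch
  feat3 <- feat
  feat3$batch <- c(1L, 1L, 2L, 2L)
  expect_warning(h3 <- harmonize_batches(feat3, ab, freqs),
                 "same-batch")
  expect_equal(nrow(h3$provenance[h3$provenance$chemical ==
                                    h3$chemicals$chemical[1], ]), 2)
})

test_that("the full feature pipeline recovers the known chemical count", {
  db <- generate_chemical_db(30, 2, seed = 21)
  cohort <- generate_cohort(8, seed = 21)
  truth <- make_ground_truth(db, n_differential = 3, seed = 21)
  gen <- generate_feature_tables(
    db, cohort, truth, seed = 21,
    duplicate_fraction = 0, blank_fail_fraction = 0, both_modes_fraction = 0,
    mass_sd_ppm = 0.3, mass_max_ppm = 1, mass_rep_ppm = 0.05,
    rt_jitter_within = 0.02, rt_jitter_between = 0.05,
    replicate_dropout = 0)
  res <- run_feature_pipeline(gen$features, gen$samples, db)
  # dedup-clean input with tight jitter: one harmonized chemical per formula
  expect_equal(nrow(res$harmonized$chemicals), 30)
  expect_equal(res$report$n_duplicates_removed_within_batch, 0)
  expect_true(all(res$detections$abundance >= 0))
  # each harmonized chemical spans exactly the batches in which the generator
  # placed its features
  prov <- res$harmonized$provenance
  prov$true <- gen$feature_truth$true_chemical[
    match(prov$feature_id, gen$feature_truth$feature_id)]
  got_span <- prov |>
    dplyr::group_by(true) |>
    dplyr::summarise(batches = list(sort(unique(batch))))
  want_span <- gen$feature_truth |>
    dplyr::group_by(true_chemical) |>
    dplyr::summarise(batches = list(sort(unique(batch))))
  expect_equal(got_span$batches,
               want_span$batches[match(got_span$true,
                                       want_span$true_chemical)])
})

test_that("injected duplicates are found with perfect precision and recall", {
  db <- generate_chemical_db(25, 2, seed = 31)
  cohort <- generate_cohort(6, seed = 31)
  truth <- make_ground_truth(db, n_differential = 0, seed = 31)
  gen <- generate_feature_tables(
    db, cohort, truth, seed = 31,
    duplicate_fraction = 1, both_modes_fraction = 0, blank_fail_fraction = 0,
    mass_sd_ppm = 0.3, mass_max_ppm = 1, mass_rep_ppm = 0.05,
    rt_jitter_within = 0.02, rt_jitter_between = 0.05)
  feat <- dplyr::distinct(gen$features, feature_id, .keep_all = TRUE)
  feat <- dplyr::inner_join(feat, gen$feature_truth,
                            by = c("feature_id", "batch", "mode"))
  feat$formula <- truth$chemicals$formula[
    match(feat$true_chemical, truth$chemicals$chemical)]
  feat$ppm_error <- 0
  got <- partition_of(find_duplicate_groups(feat, scope = "within_batch"))
  want <- unname(split(feat$feature_id,
                       paste(feat$true_chemical, feat$batch)))
  want <- lapply(want, sort)
  want <- want[order(vapply(want, `[`, character(1), 1))]
  expect_equal(got, want)
})
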