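test_that("propensity model recovers null and known covariate effects", {
  # null association: coefficients near zero, scores near the base rate
  cohort <- withr::with_seed(1, tibble::tibble(
    participant_id = sprintf("P%04d", 1:400),
    city = rep(c("Fresno", "SanFrancisco"), each = 200),
    age_cat = sample(c("<30", "30+"), 400, TRUE),
    race_eth = sample(c("A", "B"), 400, TRUE),
    education = sample(c("lo", "hi"), 400, TRUE),
    marital = sample(c("m", "n"), 400, TRUE)))
  fit <- estimate_propensity(cohort)
  expect_true(fit$converged)
  expect_true(all(abs(fit$coefficients[-1]) < 0.5))
  expect_equal(mean(fit$scores$score), 0.5, tolerance = 0.02)

  # a binary covariate with true log-odds 1.0 is recovered at n = 2000
  big <- withr::with_seed(2, {
    x <- sample(c("low", "high"), 4000, TRUE)
    eta <- ifelse(x == "low", 1, 0)  # "low" is the non-reference level
    tibble::tibble(
      participant_id = sprintf("P%04d", 1:4000),
      city = ifelse(runif(4000) < plogis(-0.5 + eta), "Fresno", "SanFrancisco"),
      age_cat = x, race_eth = "A", education = "lo", marital = "m")
  })
  fit2 <- estimate_propensity(big, covariates = "age_cat")
  expect_equal(unname(fit2$coefficients["age_catlow"]), 1.0, tolerance = 0.2)

  # agrees with the standard IRLS fit (independent route)
  glm_fit <- glm(I(city == "Fresno") ~ age_cat, family = binomial, data = big)
  expect_equal(unname(fit2$coefficients), unname(coef(glm_fit)),
               tolerance = 1e-4)

  # deterministic given data; both cities required
  expect_identical(estimate_propensity(big, covariates = "age_cat")$coefficients,
                   fit2$coefficients)
  expect_error(estimate_propensity(big[big$city == "Fresno", ],
                                   covariates = "age_cat"),
               class = "expo_argument_error")
  expect_s3_class(tidy(fit2), "tbl_df")
  expect_equal(glance(fit2)$n, 4000)
})

test_that("nearest-neighbour matching is 1:1 without replacement", {
  cohort <- dplyr::bind_rows(
    generate_cohort(75, seed = 5)[1:75, ],           # Fresno rows
    generate_cohort(100, seed = 6)[101:200, ])       # SanFrancisco rows
  fit <- estimate_propensity(cohort)
  m <- match_nearest_neighbor(fit)
  expect_equal(nrow(m), 75)
  expect_true(!anyDuplicated(m$sf_id))
  expect_true(!anyDuplicated(m$fresno_id))
  expect_identical(match_nearest_neighbor(fit), m)

  # identical score distributions: every pair at distance ~0
  flat <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:40),
    city = rep(c("Fresno", "SanFrancisco"), 20),
    age_cat = "a", race_eth = "b", education = "c", marital = "d")
  fitf <- estimate_propensity(flat)
  mf <- match_nearest_neighbor(fitf)
  expect_equal(nrow(mf), 20)
  expect_true(all(mf$distance < 1e-12))
})

test_that("matching improves covariate balance on a confounded cohort", {
  cohort <- generate_cohort(75, seed = 7)
  fit <- estimate_propensity(cohort)
  m <- match_nearest_neighbor(fit)
  bal <- covariate_balance(cohort, m)
  expect_true(all(bal$smd_after <= bal$smd_before))
})

test_that("log transform substitutes zeros with 0.1", {
  expect_equal(log_transform(c(0, 1, exp(1))), c(log(0.1), 0, 1))
  expect_error(log_transform(-1), class = "expo_validation_error")
  m <- matrix(c(0, 4), 1)
  expect_equal(log_transform(m), matrix(c(log(0.1), log(4)), 1))
})

test_that("batch correction removes injected location and scale effects", {
  G <- 50; n <- 200  # batch sizes comparable to a real instrument batch
  batch <- rep(1:2, each = n / 2)
  sim <- withr::with_seed(11, {
    mu <- runif(G, 5, 10)
    y <- matrix(rnorm(G * n, mu, 0.5), G, n)
    y[, batch == 2] <- y[, batch == 2] + 1.0          # additive shift
    y[, batch == 2] <- (y[, batch == 2] - mu) * sqrt(2) + mu  # variance x2
    y
  })
  corr <- correct_batch_effects(sim, batch)
  diffs <- abs(rowMeans(corr[, batch == 1]) - rowMeans(corr[, batch == 2]))
  expect_lt(mean(diffs), 0.05)
  v1 <- apply(corr[, batch == 1], 1, var)
  v2 <- apply(corr[, batch == 2], 1, var)
  expect_equal(mean(v2) / mean(v1), 1, tolerance = 0.1)

  # single batch passes through unchanged
  expect_equal(correct_batch_effects(sim, rep(1, n)), sim)
})

test_that("batch correction matches the reference empirical-Bayes implementation", {
  G <- 40; n <- 30
  batch <- rep(1:3, each = 10)
  x <- rep(c(0, 1), length.out = n)
  y <- withr::with_seed(12, {
    mu <- runif(G, 4, 9)
    out <- matrix(rnorm(G * n, mu, 1), G, n)
    out[, batch == 2] <- out[, batch == 2] + 0.8
    out + outer(runif(G, 0, 0.5), x)
  })
  design <- data.frame(x = factor(x))
  mine <- correct_batch_effects(y, batch, design = design)
  ref <- sva::ComBat(dat = y, batch = batch,
                     mod = stats::model.matrix(~ x, data = design))
  expect_equal(unname(mine[, ]), unname(ref), tolerance = 1e-3)
})

test_that("confounded covariates are dropped with a warning", {
  G <- 10; n <- 20
  batch <- rep(1:2, each = 10)
  y <- withr::with_seed(13, matrix(rnorm(G * n, 6, 1), G, n))
  confounded <- data.frame(z = factor(batch))  # identical to batch
  expect_warning(out <- correct_batch_effects(y, batch, design = confounded),
                 "confounded")
  expect_equal(dim(out), dim(y))
})

test_that("Fisher exact p matches hand-derived and reference values", {
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(3, 3, 3, 3), 1)
  expect_equal(fisher_exact_2x2(0, 0, 3, 3), 1)  # zero margin convention
  expect_error(fisher_exact_2x2(-1, 0, 0, 0), class = "expo_validation_error")
  expect_error(fisher_exact_2x2(1.5, 0, 0, 0), class = "expo_validation_error")
  # agreement with the standard implementation on random tables
  for (s in 1:25) {
    cells <- withr::with_seed(s, rpois(4, 8))
    got <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])
    want <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("differential detection flags injected city effects", {
  cohort <- generate_cohort(75, seed = 20)
  fit <- estimate_propensity(cohort)
  matched <- match_nearest_neighbor(fit)
  sim <- simulate_detections(cohort, n_chemicals = 30, n_differential = 6,
                             seed = 20)
  det <- sim$detections
  det$sample_id <- paste0(det$participant_id, "_M")
  det$abundance <- ifelse(det$detected, 1e5, 0)
  samples <- tibble::tibble(
    sample_id = paste0(cohort$participant_id, "_M"),
    participant_id = cohort$participant_id,
    matrix = "maternal", batch = 1L)
  res <- differential_detection(call_detections(det), samples, matched)
  truth <- sim$truth
  flagged_true <- res$differential[match(truth$chemical[truth$differential],
                                         res$chemical)]
  expect_true(all(flagged_true))
  null_rate <- mean(res$differential[match(truth$chemical[!truth$differential],
                                           res$chemical)])
  expect_lt(null_rate, 0.25)
  expect_true(all(res$fisher_p >= 0 & res$fisher_p <= 1))

  # chemical detected everywhere is not differential
  allone <- res[res$chemical == res$chemical[1], ]
  det2 <- det; det2$detected <- TRUE; det2$abundance <- 1e5
  res2 <- differential_detection(call_detections(det2), samples, matched)
  expect_true(all(res2$fisher_p == 1))
  expect_false(any(res2$differential))
  expect_s3_class(glance(res), "tbl_df")
})

test_that("Fisher p is symmetric in city and detection-row swaps", {
  for (s in 1:10) {
    cells <- withr::with_seed(100 + s, rpois(4, 6))
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    expect_equal(fisher_exact_2x2(a, b, c, d), fisher_exact_2x2(b, a, d, c))
    expect_equal(fisher_exact_2x2(a, b, c, d), fisher_exact_2x2(c, d, a, b))
  }
})

test_that("paired correlation recovers a known latent coupling", {
  expect_equal(paired_correlation(1:10, 1:10), 1)
  expect_equal(paired_correlation(1:10, -(1:10)), -1)
  # shared latent factor with loading sqrt(0.7) gives correlation 0.7
  sim <- withr::with_seed(30, {
    latent <- rnorm(5000)
    list(a = sqrt(0.7) * latent + sqrt(0.3) * rnorm(5000),
         b = sqrt(0.7) * latent + sqrt(0.3) * rnorm(5000))
  })
  expect_equal(paired_correlation(sim$a, sim$b), 0.7, tolerance = 0.05)
  expect_error(paired_correlation(1:2, 1:2), class = "expo_argument_error")
  expect_error(paired_correlation(rep(1, 5), 1:5),
               class = "expo_degenerate_error")
})

test_that("PCA batch check orders pre- and post-correction structure", {
  G <- 40; n <- 40
  batch <- rep(1:2, each = 20)
  y <- withr::with_seed(31, matrix(rnorm(G * n, 6, 1), G, n))
  y[, batch == 2] <- y[, batch == 2] + 2
  pre <- batch_mixing_check(y, batch)
  post <- batch_mixing_check(correct_batch_effects(y, batch), batch)
  expect_gt(pre$r_squared_batch[1], post$r_squared_batch[1])

  expect_true(all(batch_mixing_check(y, rep(1, n))$r_squared_batch == 0))
  perm <- withr::with_seed(32, sample(batch))
  expect_lt(batch_mixing_check(y, perm)$r_squared_batch[1], 0.3)
  expect_error(batch_mixing_check(y[, 1, drop = FALSE], 1, n_components = 2),
               class = "expo_argument_error")
})
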