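# Independent oracles and small fixture builders shared across tests.

# Exhaustive hypergeometric enumeration oracle for the two-sided Fisher test,
# written from first principles with choose() (independent of dhyper).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Breadth-first-search connected components over an explicit pairwise match
# matrix; returns a canonical partition (list of sorted id vectors, sorted by
# first element).
bfs_components <- function(ids, match_matrix) {
  n <- length(ids)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      nbrs <- which(match_matrix[v, ] & !seen)
      seen[nbrs] <- TRUE
      queue <- c(queue, nbrs)
    }
    comps[[length(comps) + 1L]] <- sort(ids[members])
  }
  comps[order(vapply(comps, `[`, character(1), 1))]
}

# Canonicalise a feature_id -> group_id tibble into the same partition shape.
partition_of <- function(groups) {
  comps <- unname(split(groups$feature_id, groups$group_id))
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, `[`, character(1), 1))]
}

# Pairwise duplicate predicate, restated independently for oracle use.
pairwise_match_matrix <- function(feat, ppm_tol = 15, rt_tol = 0.5) {
  same_formula <- outer(feat$formula, feat$formula, `==`)
  dmass <- abs(outer(feat$neutral_mass, feat$neutral_mass, `-`))
  denom <- outer(feat$neutral_mass, feat$neutral_mass, pmin)
  dppm <- dmass / denom * 1e6
  drt <- abs(outer(feat$rt, feat$rt, `-`))
  m <- same_formula & dppm <= ppm_tol * (1 + 1e-9) & drt <= rt_tol + 1e-9
  diag(m) <- FALSE
  m
}

# Random matched-feature instance designed to produce collision clusters.
random_feature_instance <- function(n_features, n_formulas = 5, seed = 1) {
  withr::with_seed(seed, {
    formulas <- sprintf("FRM%02d", seq_len(n_formulas))
    base_mass <- stats::runif(n_formulas, 150, 900)
    f_idx <- sample.int(n_formulas, n_features, replace = TRUE)
    tibble::tibble(
      feature_id = sprintf("R%04d", seq_len(n_features)),
      formula = formulas[f_idx],
      neutral_mass = base_mass[f_idx] *
        (1 + stats::rnorm(n_features, 0, 12) * 1e-6),
      rt = stats::runif(n_features, 0, 3),
      batch = sample(1:3, n_features, replace = TRUE),
      ppm_error = stats::rnorm(n_features, 0, 1)
    )
  })
}

# Hand-built chemical database with known scaling extremes.
tiny_db <- function() {
  tibble::tibble(
    formula = c("C10H10O2", "C10H10O2", "C10H10O2", "C12H8N2", "C20H30O5"),
    monoisotopic_mass = c(162.068, 162.068, 162.068, 180.069, 350.209),
    isomer = c("alpha", "beta", "gamma", "delta", "omega"),
    pubmed_count = c(10, 0, 5, 2, 1),
    pubchem_count = c(100, 0, 50, 20, 10),
    production_volume = c(1000, 0, 500, 200, 100),
    categories = c("pesticide", "", "cosmetic/fragrance;pesticide",
                   "pharmaceutical", "PAH")
  )
}

# Minimal samples + long feature table (with replicates) for blank-filter and
# averaging tests.
tiny_samples <- function() {
  tibble::tibble(
    sample_id = c("P1_M", "P2_M", "B1_WB"),
    participant_id = c("P1", "P2", NA),
    matrix = c("maternal", "maternal", "water_blank"),
    batch = 1L
  )
}

feature_long <- function(feature_id, mass, rt, abund_by_sample, batch = 1L,
                         mode = "positive") {
  rows <- lapply(names(abund_by_sample), function(s) {
    tibble::tibble(
      feature_id = feature_id, neutral_mass = mass, rt = rt, mode = mode,
      batch = batch, sample_id = s, replicate = 1:2,
      abundance = rep(abund_by_sample[[s]], length.out = 2)
    )
  })
  dplyr::bind_rows(rows)
}
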