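# Cohort statistics: propensity-score matching of the two cities, log
# transformation, empirical-Bayes location/scale batch correction, Fisher's
# exact differential detection, abundance ratios, paired maternal-cord
# correlation, and a PCA check of batch mixing.

#' Estimate the propensity of living in Fresno from matching covariates
#'
#' Fits a main-effects logistic regression of the Fresno indicator on
#' indicator-coded categorical covariates by iteratively reweighted least
#' squares with a small ridge penalty (default 1e-6, intercept unpenalised)
#' so that quasi-separable cohorts still yield finite scores.
#'
#' @param cohort Cohort tibble with a `city` column containing both cities.
#' @param covariates Character vector of covariate column names.
#' @param ridge Ridge penalty on non-intercept coefficients.
#' @param tol Convergence tolerance on the max absolute score gradient.
#' @param max_iter IRLS iteration cap.
#' @return Object of class `expo_propensity`: coefficients, per-participant
#'   scores, convergence info.
#' @export
estimate_propensity <- function(cohort,
                                covariates = c("age_cat", "race_eth",
                                               "education", "marital"),
                                ridge = 1e-6, tol = 1e-8, max_iter = 100) {
  assert_columns(cohort, c("participant_id", "city", covariates), "cohort")
  if (dplyr::n_distinct(cohort$city) < 2) {
    expo_abort("Cohort must contain participants from both cities.",
               class = "expo_argument_error")
  }
  y <- as.numeric(cohort$city == "Fresno")
  # covariates observed at a single level carry no information and would
  # break the indicator expansion
  usable <- covariates[vapply(covariates,
                              function(v) dplyr::n_distinct(cohort[[v]]) > 1,
                              logical(1))]
  fml <- if (length(usable)) {
    stats::as.formula(paste("~", paste(usable, collapse = " + ")))
  } else {
    ~1
  }
  X <- stats::model.matrix(fml, data = cohort)
  beta <- rep(0, ncol(X))
  pen <- c(0, rep(ridge, ncol(X) - 1))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    H <- crossprod(X, X * w) + diag(pen, ncol(X))
    beta <- beta + solve(H, grad)
  }
  scores <- stats::plogis(drop(X %*% beta))
  out <- list(
    coefficients = stats::setNames(beta, colnames(X)),
    scores = tibble::tibble(participant_id = cohort$participant_id,
                            city = cohort$city, score = scores),
    covariates = covariates,
    converged = converged, n_iter = iter, ridge = ridge,
    n = nrow(cohort)
  )
  class(out) <- "expo_propensity"
  out
}

#' @export
print.expo_propensity <- function(x, ...) {
  cat(sprintf("Propensity model (%d participants, %d coefficients, %s)\n",
              x$n, length(x$coefficients),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.expo_propensity <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.expo_propensity <- function(x, ...) {
  tibble::tibble(n = x$n, n_terms = length(x$coefficients),
                 converged = x$converged, n_iter = x$n_iter)
}

#' 1:1 nearest-neighbour matching without replacement on propensity scores
#'
#' Fresno participants are processed in descending propensity order; each
#' takes the still-unmatched San Francisco participant with the smallest
#' absolute score difference (ties broken by smaller participant id). The
#' procedure is deterministic, so repeated runs reproduce the same pairs.
#'
#' @param model `expo_propensity` fit covering the participants to match.
#' @param participants Optional character vector restricting matching to a
#'   subset (e.g. participants with a cord sample).
#' @return Tibble of matched pairs: `pair_id`, `fresno_id`, `sf_id`,
#'   `score_fresno`, `score_sf`, `distance`.
#' @export
match_nearest_neighbor <- function(model, participants = NULL) {
  sc <- model$scores
  if (!is.null(participants)) sc <- sc[sc$participant_id %in% participants, ]
  fres <- sc[sc$city == "Fresno", ]
  sf <- sc[sc$city != "Fresno", ]
  if (nrow(fres) == 0 || nrow(sf) == 0) {
    expo_abort("Both cities must be present for matching.",
               class = "expo_argument_error")
  }
  fres <- fres[order(-fres$score, fres$participant_id), ]
  sf <- sf[order(sf$participant_id), ]
  available <- rep(TRUE, nrow(sf))
  n_pairs <- min(nrow(fres), nrow(sf))
  out <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    d <- abs(sf$score - fres$score[i])
    d[!available] <- Inf
    j <- which.min(d)  # ties: first in id order, since sf is id-sorted
    available[j] <- FALSE
    out[[i]] <- tibble::tibble(
      fresno_id = fres$participant_id[i], sf_id = sf$participant_id[j],
      score_fresno = fres$score[i], score_sf = sf$score[j],
      distance = abs(fres$score[i] - sf$score[j]))
  }
  res <- dplyr::bind_rows(out)
  res$pair_id <- seq_len(nrow(res))
  res[, c("pair_id", "fresno_id", "sf_id", "score_fresno", "score_sf",
          "distance")]
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences of each covariate's level indicators between
#' cities, aggregated per covariate as the mean absolute SMD over levels.
#'
#' @param cohort Cohort tibble.
#' @param matched Matched pairs from [match_nearest_neighbor()].
#' @param covariates Covariate columns.
#' @return Tibble `covariate`, `smd_before`, `smd_after`.
#' @export
covariate_balance <- function(cohort, matched,
                              covariates = c("age_cat", "race_eth",
                                             "education", "marital")) {
  smd_set <- function(data) {
    vapply(covariates, function(cov) {
      levs <- unique(cohort[[cov]])
      smds <- vapply(levs, function(l) {
        p1 <- mean(data[[cov]][data$city == "Fresno"] == l)
        p2 <- mean(data[[cov]][data$city != "Fresno"] == l)
        v <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
        if (v == 0) 0 else abs(p1 - p2) / sqrt(v)
      }, numeric(1))
      mean(smds)
    }, numeric(1))
  }
  ids <- c(matched$fresno_id, matched$sf_id)
  tibble::tibble(
    covariate = covariates,
    smd_before = unname(smd_set(cohort)),
    smd_after = unname(smd_set(cohort[cohort$participant_id %in% ids, ]))
  )
}

#' Natural-log transform with zero substitution
#'
#' Abundances of exactly 0 are replaced by `zero_sub` (0.1 by default) before
#' taking the natural log, preserving the zero boundary.
#'
#' @param x Non-negative numeric vector or matrix.
#' @param zero_sub Substitution value for zeros.
#' @return `log(x)` with zeros substituted.
#' @export
log_transform <- function(x, zero_sub = 0.1) {
  if (any(x < 0, na.rm = TRUE)) {
    expo_abort("Abundances must be non-negative.", class = "expo_validation_error")
  }
  x[x == 0] <- zero_sub
  log(x)
}

#' Empirical-Bayes location/scale batch-effect correction
#'
#' Re-implementation of the parametric empirical-Bayes batch adjustment used
#' for omics batch correction: per-chemical abundances are standardised after
#' fitting covariate effects, per-batch additive and multiplicative batch
#' parameters are estimated, shrunk towards across-chemical parametric priors
#' (normal location, inverse-gamma scale, moment-matched), and the data are
#' adjusted and the covariate effects restored. A single batch is returned
#' unchanged. Covariate columns perfectly confounded with batch are dropped
#' with a warning.
#'
#' @param log_abund Numeric matrix, chemicals in rows, samples in columns, on
#'   the log scale.
#' @param batch Batch label per column.
#' @param design Optional covariate data frame (one row per column of
#'   `log_abund`) or model matrix whose effects are preserved.
#' @param conv Convergence tolerance of the empirical-Bayes iteration.
#' @return Corrected matrix of the same dimensions; attribute `batch_params`
#'   holds the shrunken per-batch location/scale estimates.
#' @export
correct_batch_effects <- function(log_abund, batch, design = NULL, conv = 1e-6) {
  stopifnot(is.matrix(log_abund))
  batch <- factor(batch)
  if (length(batch) != ncol(log_abund)) {
    expo_abort("`batch` must have one label per sample column.",
               class = "expo_validation_error")
  }
  if (nlevels(batch) < 2) return(log_abund)
  n_array <- ncol(log_abund)
  batchmod <- stats::model.matrix(~ -1 + batch)
  n_batches <- table(batch)

  covmod <- NULL
  if (!is.null(design)) {
    covmod <- if (is.matrix(design)) design else
      stats::model.matrix(~ ., data = as.data.frame(design))
    # drop intercept (absorbed by batch indicators) and columns confounded
    # with batch
    keep <- apply(covmod, 2, function(col) stats::sd(col) > 0)
    covmod <- covmod[, keep, drop = FALSE]
    if (ncol(covmod)) {
      base_rank <- qr(batchmod)$rank
      ok <- logical(ncol(covmod))
      acc <- batchmod
      for (j in seq_len(ncol(covmod))) {
        cand <- cbind(acc, covmod[, j])
        if (qr(cand)$rank > qr(acc)$rank) { ok[j] <- TRUE; acc <- cand }
      }
      if (any(!ok)) {
        warning(sprintf(
          "Dropping covariate column(s) confounded with batch: %s.",
          paste(colnames(covmod)[!ok], collapse = ", ")))
      }
      covmod <- covmod[, ok, drop = FALSE]
    }
    if (ncol(covmod) == 0) covmod <- NULL
  }
  design_full <- cbind(batchmod, covmod)

  # chemicals with (near-)constant values across all samples carry no batch
  # information; they pass through unchanged
  row_var <- apply(log_abund, 1, stats::var)
  informative <- which(row_var > 1e-10)
  if (length(informative) < nrow(log_abund)) {
    out_full <- log_abund
    if (length(informative) >= 2) {
      out_full[informative, ] <- correct_batch_effects(
        log_abund[informative, , drop = FALSE], batch, design, conv)
    }
    return(out_full)
  }

  B_hat <- solve(crossprod(design_full), crossprod(design_full, t(log_abund)))
  grand_mean <- drop(crossprod(as.numeric(n_batches) / n_array,
                               B_hat[seq_len(nlevels(batch)), , drop = FALSE]))
  resid <- log_abund - t(design_full %*% B_hat)
  var_pooled <- rowMeans(resid^2)
  var_pooled[var_pooled == 0] <- .Machine$double.eps

  stand_mean <- outer(grand_mean, rep(1, n_array))
  if (!is.null(covmod)) {
    nb <- nlevels(batch)
    stand_mean <- stand_mean +
      t(covmod %*% B_hat[(nb + 1):nrow(B_hat), , drop = FALSE])
  }
  s_data <- (log_abund - stand_mean) / sqrt(var_pooled)

  gamma_star <- delta_star <- matrix(NA_real_, nlevels(batch), nrow(log_abund))
  for (b in seq_len(nlevels(batch))) {
    idx <- which(batch == levels(batch)[b])
    sd_b <- s_data[, idx, drop = FALSE]
    g_hat <- rowMeans(sd_b)
    d_hat <- apply(sd_b, 1, stats::var)
    d_hat[is.na(d_hat) | d_hat == 0] <- .Machine$double.eps
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    n_b <- length(idx)
    if (!is.finite(t2) || t2 <= 0 || !is.finite(s2) || s2 <= 0) {
      # degenerate across-chemical spread: no basis for shrinkage
      gamma_star[b, ] <- g_hat
      delta_star[b, ] <- d_hat
      next
    }
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    g_new <- g_hat; d_new <- d_hat
    change <- 1
    iter <- 0L
    while (change > conv && iter < 200L) {
      iter <- iter + 1L
      g_old <- g_new; d_old <- d_new
      g_new <- (n_b * t2 * g_hat + d_old * g_bar) / (n_b * t2 + d_old)
      ss <- rowSums((sd_b - g_new)^2)
      d_new <- (b_prior + 0.5 * ss) / (n_b / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / (abs(d_old) + 1e-12))
    }
    gamma_star[b, ] <- g_new
    delta_star[b, ] <- d_new
  }
  bayes <- s_data
  for (b in seq_len(nlevels(batch))) {
    idx <- which(batch == levels(batch)[b])
    bayes[, idx] <- (s_data[, idx, drop = FALSE] - gamma_star[b, ]) /
      sqrt(delta_star[b, ])
  }
  out <- bayes * sqrt(var_pooled) + stand_mean
  dimnames(out) <- dimnames(log_abund)
  attr(out, "batch_params") <- list(gamma = gamma_star, delta = delta_star,
                                    batches = levels(batch))
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Probability-mass method: the two-sided p-value is the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's (with a small relative slack for
#' floating point). A table with any zero margin returns p = 1.
#'
#' @param a,b,c,d Cell counts of the table `[[a, b], [c, d]]` (rows =
#'   detected/not, columns = city).
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    expo_abort("Cell counts must be non-negative integers.",
               class = "expo_validation_error")
  }
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Per-chemical differential detection between cities
#'
#' For each chemical, detections in the matched participants are tabulated as
#' a detected/not x city 2x2 table and compared with the two-sided Fisher's
#' exact test; a chemical is flagged differential when p < `alpha` (no
#' multiplicity correction by default, optionally Benjamini-Hochberg). The
#' abundance ratio is the ratio of the cities' mean natural-scale abundances.
#'
#' @param detections Long tibble (`chemical`, `sample_id`, `abundance`,
#'   `detected`), abundances on the natural scale after any correction.
#' @param samples Sample table mapping `sample_id` to `participant_id` and
#'   `matrix`.
#' @param matched Matched pairs from [match_nearest_neighbor()].
#' @param matrix Which specimen type to analyse.
#' @param alpha Significance level.
#' @param fdr Apply Benjamini-Hochberg adjustment before flagging.
#' @param ratio_from Optional alternative long abundance table (`chemical`,
#'   `sample_id`, `abundance`) from which the abundance ratio is computed
#'   (e.g. raw pre-correction abundances); detections themselves are always
#'   taken from `detections`.
#' @return Tibble of class `expo_differential`: `chemical`, `df_fresno`,
#'   `df_sf`, `fisher_p`, `abundance_ratio`, `differential`, `direction`.
#' @export
differential_detection <- function(detections, samples, matched,
                                   matrix = c("maternal", "cord"),
                                   alpha = 0.05, fdr = FALSE,
                                   ratio_from = NULL) {
  matrix <- match.arg(matrix)
  assert_columns(detections, c("chemical", "sample_id", "abundance", "detected"),
                 "detections")
  ids <- c(matched$fresno_id, matched$sf_id)
  smp <- samples[samples$matrix == matrix &
                   samples$participant_id %in% ids, ]
  city <- ifelse(smp$participant_id %in% matched$fresno_id, "Fresno", "SanFrancisco")
  det <- detections[detections$sample_id %in% smp$sample_id, ]
  det$city <- city[match(det$sample_id, smp$sample_id)]
  res <- det |>
    dplyr::group_by(.data$chemical) |>
    dplyr::summarise(
      n_f = sum(.data$city == "Fresno"),
      n_s = sum(.data$city != "Fresno"),
      det_f = sum(.data$detected & .data$city == "Fresno"),
      det_s = sum(.data$detected & .data$city != "Fresno"),
      mean_ab_f = mean(.data$abundance[.data$city == "Fresno"]),
      mean_ab_s = mean(.data$abundance[.data$city != "Fresno"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      df_fresno = .data$det_f / .data$n_f,
      df_sf = .data$det_s / .data$n_s,
      fisher_p = purrr::pmap_dbl(
        list(.data$det_f, .data$det_s, .data$n_f - .data$det_f,
             .data$n_s - .data$det_s),
        function(a, b, c, d) fisher_exact_2x2(a, b, c, d)),
      abundance_ratio = dplyr::if_else(.data$mean_ab_s > 0,
                                       .data$mean_ab_f / .data$mean_ab_s,
                                       NA_real_)
    )
  if (!is.null(ratio_from)) {
    alt <- ratio_from[ratio_from$sample_id %in% smp$sample_id, ]
    alt$city <- city[match(alt$sample_id, smp$sample_id)]
    rr <- alt |>
      dplyr::group_by(.data$chemical) |>
      dplyr::summarise(
        mean_f = mean(.data$abundance[.data$city == "Fresno"]),
        mean_s = mean(.data$abundance[.data$city != "Fresno"]),
        .groups = "drop")
    res$abundance_ratio <- dplyr::if_else(
      rr$mean_s[match(res$chemical, rr$chemical)] > 0,
      rr$mean_f[match(res$chemical, rr$chemical)] /
        rr$mean_s[match(res$chemical, rr$chemical)],
      NA_real_)
  }
  p_flag <- if (fdr) stats::p.adjust(res$fisher_p, method = "BH") else res$fisher_p
  res$differential <- p_flag < alpha
  res$direction <- dplyr::case_when(
    res$df_fresno > res$df_sf ~ "higher_in_fresno",
    res$df_fresno < res$df_sf ~ "higher_in_sf",
    TRUE ~ "equal"
  )
  out <- res[, c("chemical", "df_fresno", "df_sf", "fisher_p",
                 "abundance_ratio", "differential", "direction")]
  class(out) <- c("expo_differential", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "matrix") <- matrix
  out
}

#' @export
tidy.expo_differential <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.expo_differential <- function(x, ...) {
  tibble::tibble(
    n_chemicals = nrow(x),
    n_differential = sum(x$differential),
    n_higher_fresno = sum(x$differential & x$direction == "higher_in_fresno"),
    n_higher_sf = sum(x$differential & x$direction == "higher_in_sf"),
    median_ratio_differential = stats::median(
      x$abundance_ratio[x$differential], na.rm = TRUE),
    alpha = attr(x, "alpha")
  )
}

#' Pearson correlation of paired maternal and cord log abundances
#'
#' @param maternal,cord Paired numeric vectors (log abundances), length >= 3.
#' @return Pearson correlation coefficient.
#' @export
paired_correlation <- function(maternal, cord) {
  if (length(maternal) != length(cord) || length(maternal) < 3) {
    expo_abort("Paired vectors of equal length >= 3 are required.",
               class = "expo_argument_error")
  }
  if (stats::sd(maternal) == 0 || stats::sd(cord) == 0) {
    expo_abort("Correlation undefined: zero variance input.",
               class = "expo_degenerate_error")
  }
  stats::cor(maternal, cord)
}

#' How much batch structure remains in the top principal components
#'
#' Principal components of the sample x chemical matrix are computed and, for
#' each of the top components, the R-squared of a regression of the component
#' scores on the batch factor is reported. Comparing before and after
#' correction shows whether batch effects were sufficiently removed.
#'
#' @param log_abund Chemicals x samples log-abundance matrix.
#' @param batch Batch label per sample column.
#' @param n_components Number of leading components to assess.
#' @return Tibble `component`, `var_explained`, `r_squared_batch`.
#' @export
batch_mixing_check <- function(log_abund, batch, n_components = 2) {
  if (ncol(log_abund) < n_components) {
    expo_abort("Fewer samples than requested components.",
               class = "expo_argument_error")
  }
  batch <- factor(batch)
  keep <- apply(log_abund, 1, stats::sd) > 0
  pc <- stats::prcomp(t(log_abund[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  r2 <- vapply(seq_len(k), function(i) {
    if (nlevels(batch) < 2) return(0)
    fit <- stats::lm(pc$x[, i] ~ batch)
    summary(fit)$r.squared
  }, numeric(1))
  tibble::tibble(component = seq_len(k), var_explained = ve[seq_len(k)],
                 r_squared_batch = r2)
}
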