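# Cross-platform comparison: silicone-wristband concentrations vs serum
# suspect screening (formula + detection-frequency-rank matching), and
# Spearman correlations of chemical counts with tract-level pollution and
# pesticide percentiles.

#' Normalise a wristband amount to ng per g silicone per week
#'
#' @param raw_ng Total nanograms extracted from the wristband.
#' @param silicone_g Wristband mass in grams of silicone.
#' @param days_worn Days the wristband was worn.
#' @return `raw_ng / silicone_g / (days_worn / 7)`, vectorised.
#' @export
normalize_wristband <- function(raw_ng, silicone_g, days_worn) {
  if (any(silicone_g <= 0) || any(days_worn <= 0)) {
    expo_abort("`silicone_g` and `days_worn` must be positive.",
               class = "expo_argument_error")
  }
  if (any(raw_ng < 0)) {
    expo_abort("`raw_ng` must be non-negative.", class = "expo_argument_error")
  }
  raw_ng / silicone_g / (days_worn / 7)
}

#' Wristband detection frequency per chemical
#'
#' The wristband report floor is 0, so a chemical counts as detected in a
#' wearer when its concentration is positive.
#'
#' @param wristband Wristband tibble (`participant_id`, `chemical`,
#'   `concentration`, plus `formula`, `in_serum_db`, `categories` carried
#'   through).
#' @return One row per chemical with `detection_frequency`.
#' @export
wristband_detection_frequency <- function(wristband) {
  assert_columns(wristband, c("participant_id", "chemical", "concentration"),
                 "wristband")
  carry <- intersect(c("formula", "in_serum_db", "categories"), names(wristband))
  wristband |>
    dplyr::group_by(.data$chemical) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(carry), dplyr::first),
      detection_frequency = mean(.data$concentration > 0),
      mean_concentration = mean(.data$concentration[.data$concentration > 0]),
      .groups = "drop"
    )
}

#' Match wristband chemicals to serum suspect chemicals by formula and rank
#'
#' Wristband chemicals whose formula is absent from the serum database are
#' excluded (not amenable to the serum screen). Within each shared formula,
#' chemicals are sorted by descending detection frequency in each source and
#' paired positionally; the unpaired remainder is reported unmatched.
#'
#' @param wristband_df Per-chemical wristband table with `chemical`,
#'   `formula`, `detection_frequency` (see
#'   [wristband_detection_frequency()]).
#' @param serum_df Per-chemical serum table with `chemical`, `formula`,
#'   `detection_frequency`.
#' @param serum_db Serum chemical database (defines which formulas are
#'   amenable).
#' @return Tibble of matches (`formula`, `wristband_chemical`,
#'   `serum_chemical`, the two detection frequencies, `rank`); attributes
#'   `excluded` (wristband chemicals outside the serum database, with reason)
#'   and `unmatched` (leftover chemicals on either side).
#' @export
match_wristband_to_serum <- function(wristband_df, serum_df, serum_db) {
  assert_columns(wristband_df, c("chemical", "formula", "detection_frequency"),
                 "wristband_df")
  assert_columns(serum_df, c("chemical", "formula", "detection_frequency"),
                 "serum_df")
  in_db <- wristband_df$formula %in% unique(serum_db$formula)
  excluded <- wristband_df[!in_db, c("chemical", "formula")]
  if (nrow(excluded)) excluded$reason <- "formula not in serum database"
  wb <- wristband_df[in_db, ]
  wb_ranked <- wb |>
    dplyr::group_by(.data$formula) |>
    dplyr::arrange(dplyr::desc(.data$detection_frequency), .data$chemical,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  serum_ranked <- serum_df |>
    dplyr::group_by(.data$formula) |>
    dplyr::arrange(dplyr::desc(.data$detection_frequency), .data$chemical,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  matches <- dplyr::inner_join(
    wb_ranked[, c("formula", "rank", "chemical", "detection_frequency")],
    serum_ranked[, c("formula", "rank", "chemical", "detection_frequency")],
    by = c("formula", "rank"), suffix = c("_wristband", "_serum")
  ) |>
    dplyr::rename(wristband_chemical = "chemical_wristband",
                  serum_chemical = "chemical_serum",
                  df_wristband = "detection_frequency_wristband",
                  df_serum = "detection_frequency_serum")
  unmatched_wb <- dplyr::anti_join(wb_ranked, matches,
                                   by = c("formula", "rank"))
  unmatched_serum <- dplyr::anti_join(serum_ranked, matches,
                                      by = c("formula", "rank"))
  attr(matches, "excluded") <- excluded
  attr(matches, "unmatched") <- list(
    wristband = unmatched_wb[, c("chemical", "formula")],
    serum = unmatched_serum[, c("chemical", "formula")])
  matches
}

#' Spearman rank correlation with midrank ties
#'
#' Rank correlation of two paired vectors. For n <= 8 the two-sided p-value
#' is exact, by enumeration of all permutations of one rank vector; for
#' larger n it uses the large-sample t approximation with n - 2 degrees of
#' freedom.
#'
#' @param x,y Paired numeric vectors of length >= 3.
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    expo_abort("Paired vectors of equal length >= 3 are required.",
               class = "expo_argument_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    expo_abort("Spearman correlation undefined for a constant vector.",
               class = "expo_degenerate_error")
  }
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- permutations_of(n)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

# all permutations of 1..n as rows (n <= 8 keeps this small)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Per-participant count of detected chemicals carrying a source category
#'
#' @param detections Long detection tibble (`chemical`, `sample_id`,
#'   `detected`).
#' @param samples Sample table mapping samples to participants; restricted to
#'   one matrix by the caller or via `matrix`.
#' @param annotations Annotation tibble (`chemical`, `categories`
#'   semicolon-separated).
#' @param category One of [chemical_categories()], or `"all"`.
#' @param matrix Specimen type to count in.
#' @return Tibble `participant_id`, `count`.
#' @export
count_chemicals_by_category <- function(detections, samples, annotations,
                                        category = "all",
                                        matrix = "maternal") {
  valid <- c("all", chemical_categories())
  if (!category %in% valid) {
    expo_abort(sprintf("Unknown category '%s'. Valid: %s.", category,
                       paste(valid, collapse = ", ")),
               class = "expo_argument_error")
  }
  smp <- samples[samples$matrix == matrix & !is.na(samples$participant_id), ]
  keep_chem <- if (category == "all") unique(annotations$chemical) else {
    annotations$chemical[
      vapply(strsplit(annotations$categories %||% "", ";", fixed = TRUE),
             function(cc) category %in% cc, logical(1))]
  }
  det <- detections[detections$sample_id %in% smp$sample_id &
                      detections$chemical %in% keep_chem & detections$detected, ]
  det$participant_id <- smp$participant_id[match(det$sample_id, smp$sample_id)]
  counts <- det |>
    dplyr::count(.data$participant_id, name = "count")
  tibble::tibble(participant_id = smp$participant_id) |>
    dplyr::distinct() |>
    dplyr::left_join(counts, by = "participant_id") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' Correlate per-participant chemical counts with tract percentiles
#'
#' Spearman correlation between chemical counts and a CalEnviroScreen-style
#' tract percentile, computed per city.
#'
#' @param counts Tibble `participant_id`, `count`.
#' @param cohort Cohort tibble carrying the percentile column and `city`.
#' @param percentile Column name of the percentile to use.
#' @return Tibble `city`, `rho`, `p_value`, `n`; a city whose percentile is
#'   constant is reported with `NA` and a warning.
#' @export
correlate_geo <- function(counts, cohort,
                          percentile = c("pesticide_pctile",
                                         "pollution_burden_pctile")) {
  percentile <- match.arg(percentile)
  df <- dplyr::inner_join(counts, cohort, by = "participant_id")
  if (nrow(df) < 3) {
    expo_abort("At least 3 participants with both values are required.",
               class = "expo_argument_error")
  }
  df |>
    dplyr::group_by(.data$city) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 3) {
        expo_abort(sprintf("City %s has fewer than 3 participants.", key$city),
                   class = "expo_argument_error")
      }
      res <- tryCatch(
        spearman_rho(g[[percentile]], g$count),
        expo_degenerate_error = function(e) {
          warning(sprintf("Constant input in city %s; correlation undefined.",
                          key$city))
          tibble::tibble(rho = NA_real_, p_value = NA_real_, n = nrow(g))
        })
      res
    }) |>
    dplyr::ungroup()
}
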