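# Feature pipeline: raw per-batch, per-mode feature tables -> harmonized
# chemical x sample table. Blank filtering, replicate averaging, formula
# matching by mass accuracy, duplicate collapsing within and across batches
# and modes.

#' Zero out feature abundances not exceeding the water-blank signal
#'
#' The water blank is the procedural blank: a study-sample cell is kept only
#' if its abundance is at least `ratio` times the mean water-blank abundance
#' of that feature in the same batch (exactly `ratio`-fold qualifies).
#' Cells failing the rule are set to 0; features whose study-sample cells are
#' then all 0 are dropped. A feature with zero blank signal is never filtered.
#'
#' @param features Long feature tibble (`feature_id`, `batch`, `sample_id`,
#'   `abundance`, optionally `replicate`).
#' @param samples Sample table (`sample_id`, `matrix`, `batch`).
#' @param ratio Blank ratio threshold (default 2).
#' @return Filtered feature tibble, with attributes `n_dropped` (features
#'   removed entirely) and `n_zeroed` (cells zeroed).
#' @export
filter_blank_features <- function(features, samples, ratio = 2) {
  assert_positive(ratio, "ratio")
  assert_columns(features, c("feature_id", "batch", "sample_id", "abundance"),
                 "features")
  assert_columns(samples, c("sample_id", "matrix", "batch"), "samples")
  batches <- unique(features$batch)
  wb <- samples[samples$matrix == "water_blank", ]
  no_blank <- setdiff(batches, wb$batch)
  if (length(no_blank)) {
    expo_abort(sprintf("Batch(es) without a water blank: %s.",
                       paste(sort(no_blank), collapse = ", ")),
               class = "expo_validation_error")
  }
  kind <- samples$matrix[match(features$sample_id, samples$sample_id)]
  blank_mean <- features |>
    dplyr::filter(kind[dplyr::row_number()] == "water_blank") |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(blank_abund = mean(.data$abundance), .groups = "drop")
  is_study <- kind %in% c("maternal", "cord")
  bm <- blank_mean$blank_abund[match(features$feature_id, blank_mean$feature_id)]
  bm[is.na(bm)] <- 0
  fail <- is_study & bm > 0 & features$abundance < ratio * bm
  out <- features
  out$abundance[fail] <- 0
  study_sum <- tapply(out$abundance * is_study, out$feature_id, sum)
  keep_ids <- names(study_sum)[study_sum > 0]
  dropped <- length(unique(out$feature_id)) - length(keep_ids)
  res <- out[out$feature_id %in% keep_ids, ]
  attr(res, "n_dropped") <- dropped
  attr(res, "n_zeroed") <- sum(fail)
  res
}

#' Average technical replicates, filtering singleton extractions
#'
#' Abundance becomes the mean of the two technical replicates when a
#' (feature, sample) cell was observed (abundance > 0) in both; cells observed
#' in only one replicate are treated as not reliably extracted and set to 0.
#'
#' @param features Long feature tibble with a `replicate` column (values 1, 2).
#' @return Tibble with one row per (feature, sample); `replicate` dropped.
#' @export
average_replicates <- function(features) {
  assert_columns(features, c("feature_id", "sample_id", "replicate", "abundance"),
                 "features")
  n_rep <- features |>
    dplyr::count(.data$feature_id, .data$sample_id, name = "n")
  if (any(n_rep$n > 2)) {
    expo_abort("More than two replicates found for some (feature, sample) cells.",
               class = "expo_validation_error")
  }
  keys <- setdiff(names(features), c("replicate", "abundance"))
  features |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      abundance = if (sum(.data$abundance > 0) == 2) mean(.data$abundance) else 0,
      .groups = "drop"
    )
}

#' Match features to molecular formulas by mass accuracy
#'
#' Each feature is assigned the database formula minimising the absolute ppm
#' error (formula mass in the denominator) among those within `ppm_tol`. A
#' match score on the 0--100 scale is computed from mass accuracy alone,
#' `score = 100 * (1 - |ppm| / ppm_tol)`, and matches scoring below
#' `score_threshold` are discarded (the default 70 corresponds to
#' |ppm| <= 1.5 at the 5 ppm tolerance).
#'
#' @param features Feature-level tibble with `feature_id`, `neutral_mass`
#'   (one row per feature, or long format from which distinct features are
#'   taken).
#' @param db Chemical database (`formula`, `monoisotopic_mass`).
#' @param ppm_tol Matching tolerance in ppm.
#' @param score_threshold Minimum match score retained.
#' @return Tibble of matched features: feature columns plus `formula`,
#'   `formula_mass`, `ppm_error`, `match_score`; attribute `n_unmatched`
#'   counts features without an acceptable match.
#' @export
match_formulas <- function(features, db, ppm_tol = 5, score_threshold = 70) {
  assert_positive(ppm_tol, "ppm_tol")
  assert_columns(features, c("feature_id", "neutral_mass"), "features")
  assert_columns(db, c("formula", "monoisotopic_mass"), "db")
  if (nrow(db) == 0) expo_abort("`db` is empty.", class = "expo_argument_error")
  feat <- dplyr::distinct(features, .data$feature_id, .keep_all = TRUE)
  fmass <- db[!duplicated(db$formula), c("formula", "monoisotopic_mass")]
  ord <- order(fmass$monoisotopic_mass)
  fm <- fmass$monoisotopic_mass[ord]
  ff <- fmass$formula[ord]
  # nearest formula mass via sorted lookup
  idx <- findInterval(feat$neutral_mass, fm, all.inside = FALSE)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(fm))
  d_lo <- abs(feat$neutral_mass - fm[lo])
  d_hi <- abs(feat$neutral_mass - fm[hi])
  best <- ifelse(d_hi < d_lo, hi, lo)
  out <- feat
  out$formula <- ff[best]
  out$formula_mass <- fm[best]
  out$ppm_error <- ppm_error(out$neutral_mass, out$formula_mass)
  out$match_score <- 100 * (1 - abs(out$ppm_error) / ppm_tol)
  ok <- abs(out$ppm_error) <= ppm_tol & out$match_score >= score_threshold
  res <- out[ok, ]
  attr(res, "n_unmatched") <- sum(!ok)
  res
}

#' Call detections from an abundance table
#'
#' A chemical (or feature) is detected in a sample when its abundance meets or
#' exceeds the detection threshold (>= 5000 by default, inclusive).
#'
#' @param abundances Long tibble with an `abundance` column.
#' @param threshold Detection limit.
#' @return The input with a logical `detected` column appended.
#' @export
call_detections <- function(abundances, threshold = 5000) {
  assert_columns(abundances, "abundance", "abundances")
  if (any(abundances$abundance < 0, na.rm = TRUE)) {
    expo_abort("Negative abundances are not allowed.",
               class = "expo_validation_error")
  }
  abundances$detected <- abundances$abundance >= threshold
  abundances
}

#' Per-feature detection frequency
#'
#' Fraction of study samples (of that feature's batch, unless `samples` spans
#' one batch) in which the feature is detected.
#'
#' @param detections Output of [call_detections()] at feature level.
#' @param samples Sample table used to restrict to study samples
#'   (maternal/cord) and supply per-batch denominators.
#' @return Tibble `feature_id`, `detection_frequency`.
#' @export
feature_detection_frequency <- function(detections, samples) {
  study_ids <- samples$sample_id[samples$matrix %in% c("maternal", "cord")]
  denom <- samples |>
    dplyr::filter(.data$matrix %in% c("maternal", "cord")) |>
    dplyr::count(.data$batch, name = "n_samples")
  det <- detections[detections$sample_id %in% study_ids, ]
  det |>
    dplyr::group_by(.data$feature_id, .data$batch) |>
    dplyr::summarise(n_det = sum(.data$detected), .groups = "drop") |>
    dplyr::left_join(denom, by = "batch") |>
    dplyr::mutate(detection_frequency = .data$n_det / .data$n_samples) |>
    dplyr::select("feature_id", "detection_frequency")
}

#' Group duplicate features by mass and retention time
#'
#' Two formula-matched features are duplicates when they share a formula and
#' their experimental masses agree within `ppm_tol` (relative to the smaller
#' mass) and their retention times within `rt_tol` minutes, both boundaries
#' inclusive. Features that share a duplicate in common but are not duplicates
#' themselves belong to the same group: groups are the connected components of
#' the pairwise relation.
#'
#' @param matched Matched-feature tibble (`feature_id`, `formula`,
#'   `neutral_mass`, `rt`, `batch`).
#' @param ppm_tol,rt_tol Duplicate windows (15 ppm, 0.5 min).
#' @param scope `"within_batch"` restricts pairs to the same batch;
#'   `"across_batch"` compares all features.
#' @return Tibble `feature_id`, `group_id`; singleton groups included.
#' @export
find_duplicate_groups <- function(matched, ppm_tol = 15, rt_tol = 0.5,
                                  scope = c("within_batch", "across_batch")) {
  scope <- match.arg(scope)
  assert_columns(matched, c("feature_id", "formula", "neutral_mass", "rt"),
                 "matched")
  if (scope == "within_batch") assert_columns(matched, "batch", "matched")
  n <- nrow(matched)
  if (n == 0) {
    return(tibble::tibble(feature_id = character(0), group_id = integer(0)))
  }
  edges <- duplicate_edges(matched, ppm_tol, rt_tol, scope)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  comp <- igraph::components(g)$membership
  tibble::tibble(feature_id = matched$feature_id, group_id = as.integer(comp))
}

# pairwise duplicate relation, blocked by formula for efficiency
duplicate_edges <- function(matched, ppm_tol, rt_tol, scope) {
  out <- list()
  idx_by_formula <- split(seq_len(nrow(matched)), matched$formula)
  for (ids in idx_by_formula) {
    m <- length(ids)
    if (m < 2) next
    pairs <- utils::combn(ids, 2)
    i <- pairs[1, ]; j <- pairs[2, ]
    # inclusive boundaries (a pair at exactly 15 ppm / 0.5 min is a
    # duplicate); tiny epsilon guards against floating-point representation
    ok <- ppm_between(matched$neutral_mass[i], matched$neutral_mass[j]) <=
      ppm_tol * (1 + 1e-9) &
      abs(matched$rt[i] - matched$rt[j]) <= rt_tol + 1e-9
    if (scope == "within_batch") ok <- ok & matched$batch[i] == matched$batch[j]
    if (any(ok)) out[[length(out) + 1L]] <- data.frame(i = i[ok], j = j[ok])
  }
  if (length(out)) dplyr::bind_rows(out) else data.frame(i = integer(0), j = integer(0))
}

#' Collapse duplicate groups, retaining the highest-detection-frequency member
#'
#' Ties on detection frequency are broken by smaller absolute ppm error, then
#' lexicographically smallest feature id, making the retained set invariant to
#' input order.
#'
#' @param matched Matched features (must carry `ppm_error`).
#' @param groups Output of [find_duplicate_groups()].
#' @param freqs Per-feature detection frequencies
#'   (`feature_id`, `detection_frequency`).
#' @return Retained rows of `matched`, with `group_id` and
#'   `detection_frequency` columns; attribute `removed` holds the discarded
#'   members with their retained counterpart.
#' @export
collapse_duplicates <- function(matched, groups, freqs) {
  assert_columns(matched, c("feature_id", "ppm_error"), "matched")
  matched <- matched[, setdiff(names(matched),
                               c("group_id", "detection_frequency"))]
  x <- matched |>
    dplyr::inner_join(groups, by = "feature_id") |>
    dplyr::left_join(freqs, by = "feature_id") |>
    dplyr::mutate(detection_frequency =
                    dplyr::coalesce(.data$detection_frequency, 0))
  x <- x[order(-x$detection_frequency, abs(x$ppm_error), x$feature_id), ]
  retained <- x[!duplicated(x$group_id), ]
  removed <- x[duplicated(x$group_id), ]
  removed$retained_id <- retained$feature_id[match(removed$group_id,
                                                   retained$group_id)]
  retained <- retained[order(retained$feature_id), ]
  attr(retained, "removed") <- removed
  retained
}

#' Merge positive- and negative-mode suspect chemicals within batches
#'
#' Concatenates per-mode matched feature tables and collapses cross-mode
#' duplicates within each batch under the usual 15 ppm / 0.5 min windows.
#'
#' @param matched Matched features from both modes (column `mode` present).
#' @param freqs Per-feature detection frequencies.
#' @param ppm_tol,rt_tol Duplicate windows.
#' @return Retained features (see [collapse_duplicates()]).
#' @export
merge_modes <- function(matched, freqs, ppm_tol = 15, rt_tol = 0.5) {
  if (nrow(matched) == 0) return(matched)
  groups <- find_duplicate_groups(matched, ppm_tol, rt_tol, scope = "within_batch")
  collapse_duplicates(matched, groups, freqs)
}

#' Harmonize deduplicated per-batch tables into one chemical list
#'
#' Re-applies the duplicate criterion across batches; connected components of
#' the cross-batch relation (including chains: a shared match joins features
#' that do not match each other directly) become single harmonized chemicals.
#' A component containing two features from one batch signals an upstream
#' dedup miss: a warning is raised and the higher-detection-frequency member
#' represents that batch. Each harmonized chemical's per-sample abundances are
#' contributed by its batch-specific member features.
#'
#' @param retained Deduplicated matched features across all batches.
#' @param abundances Long feature x sample abundance table
#'   (replicate-averaged).
#' @param freqs Per-feature detection frequencies.
#' @param ppm_tol,rt_tol Duplicate windows.
#' @param drop_unreplicated Drop harmonized chemicals observed in a single
#'   batch only (off by default).
#' @return List of class `expo_harmonized`: `chemicals` (chemical id, formula,
#'   consensus mass/RT, member feature ids), `abundances` (chemical,
#'   sample_id, abundance), `provenance` (chemical, batch, feature_id).
#' @export
harmonize_batches <- function(retained, abundances, freqs,
                              ppm_tol = 15, rt_tol = 0.5,
                              drop_unreplicated = FALSE) {
  retained <- retained[, setdiff(names(retained),
                                 c("group_id", "detection_frequency"))]
  groups <- find_duplicate_groups(retained, ppm_tol, rt_tol, scope = "across_batch")
  x <- retained |>
    dplyr::inner_join(groups, by = "feature_id") |>
    dplyr::left_join(freqs, by = "feature_id") |>
    dplyr::mutate(detection_frequency =
                    dplyr::coalesce(.data$detection_frequency, 0))
  conflicts <- x |>
    dplyr::count(.data$group_id, .data$batch) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflicts)) {
    warning(sprintf(
      "%d cross-batch component(s) contain multiple same-batch features; keeping the higher detection-frequency member per batch.",
      nrow(conflicts)))
    x <- x[order(-x$detection_frequency, abs(x$ppm_error), x$feature_id), ]
    x <- x[!duplicated(x[, c("group_id", "batch")]), ]
  }
  if (drop_unreplicated) {
    multi <- x |>
      dplyr::group_by(.data$group_id) |>
      dplyr::summarise(nb = dplyr::n_distinct(.data$batch), .groups = "drop")
    x <- x[x$group_id %in% multi$group_id[multi$nb > 1], ]
  }
  chem_ids <- x |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      formula = .data$formula[1],
      neutral_mass = stats::median(.data$neutral_mass),
      rt = stats::median(.data$rt),
      n_batches = dplyr::n_distinct(.data$batch),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$formula, .data$rt) |>
    dplyr::mutate(chemical = sprintf("CHEM%04d", dplyr::row_number()))
  x$chemical <- chem_ids$chemical[match(x$group_id, chem_ids$group_id)]
  ab <- abundances |>
    dplyr::inner_join(x[, c("feature_id", "chemical")], by = "feature_id") |>
    dplyr::group_by(.data$chemical, .data$sample_id) |>
    dplyr::summarise(abundance = max(.data$abundance), .groups = "drop")
  out <- list(
    chemicals = chem_ids[, c("chemical", "formula", "neutral_mass", "rt",
                             "n_batches")],
    abundances = ab,
    provenance = tibble::as_tibble(x[, c("chemical", "batch", "feature_id")])
  )
  class(out) <- "expo_harmonized"
  out
}

#' @export
print.expo_harmonized <- function(x, ...) {
  cat(sprintf("Harmonized suspect table: %d chemicals, %d abundance cells\n",
              nrow(x$chemicals), nrow(x$abundances)))
  invisible(x)
}

#' Run the full feature pipeline
#'
#' Blank filtering, replicate averaging, formula matching, within-batch
#' cross-mode duplicate collapsing, and cross-batch harmonization, in that
#' order.
#'
#' @param features Raw long feature table (with replicates).
#' @param samples Sample table.
#' @param db Chemical database.
#' @param blank_ratio,detection_threshold,ppm_tol_match,score_threshold,ppm_tol_dup,rt_tol_dup
#'   Pipeline thresholds (defaults: 2, 5000, 5 ppm, 70, 15 ppm, 0.5 min).
#' @param drop_unreplicated_across_batches Drop chemicals seen in one batch
#'   only (default `FALSE`).
#' @return List: `harmonized` (`expo_harmonized`), `detections` (long tibble
#'   chemical x study sample with `detected`), `report` (counts per stage).
#' @export
run_feature_pipeline <- function(features, samples, db,
                                 blank_ratio = 2, detection_threshold = 5000,
                                 ppm_tol_match = 5, score_threshold = 70,
                                 ppm_tol_dup = 15, rt_tol_dup = 0.5,
                                 drop_unreplicated_across_batches = FALSE) {
  filtered <- filter_blank_features(features, samples, ratio = blank_ratio)
  averaged <- average_replicates(filtered)
  matched <- match_formulas(averaged, db, ppm_tol = ppm_tol_match,
                            score_threshold = score_threshold)
  feat_level <- dplyr::distinct(matched, .data$feature_id, .keep_all = TRUE)
  det_feat <- call_detections(
    averaged[averaged$feature_id %in% feat_level$feature_id, ],
    threshold = detection_threshold)
  freqs <- feature_detection_frequency(det_feat, samples)

  deduped <- feat_level |>
    dplyr::group_split(.data$batch) |>
    purrr::map(~ merge_modes(.x, freqs, ppm_tol_dup, rt_tol_dup))
  removed_by_batch <- purrr::map(deduped, ~ attr(.x, "removed"))
  retained <- dplyr::bind_rows(deduped)

  harmonized <- harmonize_batches(
    retained,
    averaged[, c("feature_id", "sample_id", "abundance")],
    freqs, ppm_tol_dup, rt_tol_dup,
    drop_unreplicated = drop_unreplicated_across_batches)

  study_ids <- samples$sample_id[samples$matrix %in% c("maternal", "cord")]
  ab_full <- tidyr::crossing(chemical = harmonized$chemicals$chemical,
                             sample_id = study_ids) |>
    dplyr::left_join(harmonized$abundances, by = c("chemical", "sample_id")) |>
    dplyr::mutate(abundance = dplyr::coalesce(.data$abundance, 0))
  detections <- call_detections(ab_full, threshold = detection_threshold)

  removed_counts <- purrr::map_int(removed_by_batch,
                                   ~ if (is.null(.x)) 0L else nrow(.x))
  report <- list(
    n_features_raw = dplyr::n_distinct(features$feature_id),
    n_features_after_blank = dplyr::n_distinct(filtered$feature_id),
    n_cells_zeroed_by_blank = attr(filtered, "n_zeroed"),
    n_features_matched = nrow(feat_level),
    n_features_unmatched = attr(matched, "n_unmatched"),
    n_duplicates_removed_within_batch = sum(removed_counts),
    duplicates_removed_by_batch = stats::setNames(
      as.list(removed_counts),
      purrr::map_chr(deduped, ~ as.character(.x$batch[1] %||% NA))),
    n_chemicals_harmonized = nrow(harmonized$chemicals)
  )
  list(harmonized = harmonized, detections = detections, report = report)
}
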