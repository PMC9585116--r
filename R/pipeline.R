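# End-to-end orchestration: generate -> features -> analyze -> compare, with
# one validated configuration object and a reproducibility manifest.

#' Build (and validate) a pipeline configuration
#'
#' All screening thresholds are surfaced as named keys with their standard
#' defaults: blank ratio 2, detection limit 5000, duplicate windows 15 ppm and
#' 0.5 min, formula-match tolerance 5 ppm with score threshold 70, and zero
#' substitution 0.1 before log transformation.
#'
#' @param ... Overrides of the default keys (see the function body or the
#'   methods vignette for the full list). Nested values such as `batch_plan`
#'   and `batch_shift` may be given as named lists.
#' @param yaml Optional path to a YAML file of overrides; explicit `...`
#'   arguments win over YAML values.
#' @return Validated config list of class `expo_config`.
#' @export
pipeline_config <- function(..., yaml = NULL) {
  defaults <- list(
    seed = 1L,
    n_formulas = 250L, max_isomers = 6L,
    n_per_city = 75L,
    n_differential = 20L, df_fresno = 0.9, df_sf = 0.3,
    batch_shift = c(`1` = 0.5, `2` = -0.3, `3` = 0),
    pesticide_coupling = 1.0,
    duplicate_fraction = 0.1, blank_fail_fraction = 0.1,
    blank_ratio = 2, detection_threshold = 5000,
    ppm_tol_match = 5, score_threshold = 70,
    ppm_tol_dup = 15, rt_tol_dup = 0.5,
    zero_sub = 0.1, alpha = 0.05, fdr = FALSE,
    ratio_abundances = "corrected",
    drop_unreplicated_across_batches = FALSE,
    n_wristband = 26L, wristband_chemicals = 81L,
    wristband_overlap = 56 / 81,
    matrices = c("maternal", "cord"),
    covariates = c("age_cat", "race_eth", "education", "marital"),
    n_matching_repeats = 3L
  )
  overrides <- list(...)
  if (!is.null(yaml)) {
    from_yaml <- yaml::read_yaml(yaml)
    for (k in names(from_yaml)) {
      if (!k %in% names(overrides)) overrides[[k]] <- from_yaml[[k]]
    }
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    expo_abort(sprintf("Unknown config key(s): %s.",
                       paste(unknown, collapse = ", ")),
               class = "expo_config_error")
  }
  cfg <- utils::modifyList(defaults, overrides)
  if (is.list(cfg$batch_shift)) cfg$batch_shift <- unlist(cfg$batch_shift)
  problems <- character(0)
  for (k in c("blank_ratio", "detection_threshold", "ppm_tol_match",
              "ppm_tol_dup", "rt_tol_dup", "zero_sub")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0) {
      problems <- c(problems, sprintf("`%s` must be positive", k))
    }
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    problems <- c(problems, "`alpha` must be in (0, 1)")
  }
  if (length(problems)) {
    expo_abort(paste0("Invalid configuration:\n",
                      paste("-", problems, collapse = "\n")),
               class = "expo_config_error")
  }
  structure(cfg, class = "expo_config")
}

#' Run the full screening pipeline
#'
#' Executes the four stages in order -- synthetic-data generation, feature
#' pipeline, cohort analysis (per specimen matrix), and external comparisons
#' -- writing every intermediate table and a run manifest to `outdir`.
#' Re-running with the same config and seed reproduces identical outputs.
#'
#' @param config `expo_config` from [pipeline_config()].
#' @param outdir Output directory.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory results of every stage plus
#'   the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("expo_run_"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "expo_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- as.integer(config$seed)

  # --- stage 1: generate ---------------------------------------------------
  say("[generate] chemical database, cohort, feature tables, wristbands")
  db <- generate_chemical_db(config$n_formulas, config$max_isomers, seed = seed)
  cohort <- generate_cohort(config$n_per_city, seed = seed + 1L)
  truth <- make_ground_truth(db, n_differential = config$n_differential,
                             df_fresno = config$df_fresno, df_sf = config$df_sf,
                             batch_shift = config$batch_shift,
                             pesticide_coupling = config$pesticide_coupling,
                             seed = seed + 2L)
  generated <- generate_feature_tables(
    db, cohort, truth, seed = seed + 3L,
    duplicate_fraction = config$duplicate_fraction,
    blank_fail_fraction = config$blank_fail_fraction)
  wb_wearers <- cohort$participant_id[cohort$city == "Fresno"][
    seq_len(min(config$n_wristband, sum(cohort$city == "Fresno")))]
  wristband <- generate_wristband_data(
    db, wb_wearers, seed = seed + 4L,
    n_chemicals = config$wristband_chemicals,
    overlap_fraction = config$wristband_overlap)
  write_pipeline_inputs(generated, cohort, db, wristband, truth, outdir)

  # --- stage 2: feature pipeline -------------------------------------------
  say("[features] blank filter, replicate averaging, formula match, dedup")
  fp <- run_feature_pipeline(
    generated$features, generated$samples, db,
    blank_ratio = config$blank_ratio,
    detection_threshold = config$detection_threshold,
    ppm_tol_match = config$ppm_tol_match,
    score_threshold = config$score_threshold,
    ppm_tol_dup = config$ppm_tol_dup, rt_tol_dup = config$rt_tol_dup,
    drop_unreplicated_across_batches = config$drop_unreplicated_across_batches)
  readr::write_csv(fp$harmonized$abundances, file.path(outdir, "harmonized.csv"))
  readr::write_csv(fp$detections, file.path(outdir, "detections.csv"))
  jsonlite::write_json(fp$report, file.path(outdir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)

  annotations <- annotate_chemicals(fp$harmonized$chemicals, db)
  readr::write_csv(annotations, file.path(outdir, "annotations.csv"))

  # --- stage 3: cohort analysis per matrix ---------------------------------
  model <- estimate_propensity(cohort, config$covariates)
  samples <- generated$samples
  analysis <- list()
  for (mx in config$matrices) {
    say("[analyze] matrix = %s", mx)
    with_sample <- unique(samples$participant_id[samples$matrix == mx])
    matched <- match_nearest_neighbor(model, participants = with_sample)
    ids <- c(matched$fresno_id, matched$sf_id)
    smp <- samples[samples$matrix == mx & samples$participant_id %in% ids, ]

    ab <- fp$harmonized$abundances[
      fp$harmonized$abundances$sample_id %in% smp$sample_id, ]
    full <- tidyr::crossing(chemical = fp$harmonized$chemicals$chemical,
                            sample_id = smp$sample_id) |>
      dplyr::left_join(ab, by = c("chemical", "sample_id")) |>
      dplyr::mutate(abundance = dplyr::coalesce(.data$abundance, 0))
    mat <- tidyr::pivot_wider(full, names_from = "sample_id",
                              values_from = "abundance")
    m <- as.matrix(mat[, -1]); rownames(m) <- mat$chemical
    logm <- log_transform(m, zero_sub = config$zero_sub)
    batch <- smp$batch[match(colnames(m), smp$sample_id)]
    covs <- cohort[match(smp$participant_id[match(colnames(m), smp$sample_id)],
                         cohort$participant_id), config$covariates]
    pca_before <- batch_mixing_check(logm, batch)
    corrected <- withCallingHandlers(
      correct_batch_effects(logm, batch, design = covs),
      warning = function(w) {
        say("[analyze] %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    pca_after <- batch_mixing_check(corrected, batch)

    nat <- exp(corrected)
    long <- tibble::as_tibble(nat, rownames = "chemical") |>
      tidyr::pivot_longer(-"chemical", names_to = "sample_id",
                          values_to = "abundance")
    det <- call_detections(long, threshold = config$detection_threshold)
    diff_res <- differential_detection(
      det, samples, matched, matrix = mx,
      alpha = config$alpha, fdr = config$fdr,
      ratio_from = if (identical(config$ratio_abundances, "raw")) full)
    diff_out <- dplyr::left_join(
      tidy(diff_res),
      annotations[, c("chemical", "formula", "isomer", "categories")],
      by = "chemical")
    readr::write_csv(matched, file.path(outdir, sprintf("matched_pairs_%s.csv", mx)))
    readr::write_csv(long, file.path(outdir, sprintf("corrected_%s.csv", mx)))
    readr::write_csv(diff_out,
                     file.path(outdir, sprintf("differential_results_%s.csv", mx)))
    analysis[[mx]] <- list(matched = matched, corrected = corrected,
                           detections = det, differential = diff_res,
                           differential_annotated = diff_out,
                           pca_before = pca_before, pca_after = pca_after,
                           balance = covariate_balance(cohort, matched,
                                                       config$covariates))
  }

  # repeat matching to confirm the differential set is stable (deterministic
  # matching makes this an identity check; reported as Jaccard similarity)
  jac <- vapply(seq_len(config$n_matching_repeats), function(r) {
    perm <- cohort[sample.int(nrow(cohort)), ]
    m2 <- estimate_propensity(perm, config$covariates)
    mt2 <- match_nearest_neighbor(
      m2, participants = unique(samples$participant_id[samples$matrix == "maternal"]))
    jaccard_similarity(
      paste(analysis$maternal$matched$fresno_id, analysis$maternal$matched$sf_id),
      paste(mt2$fresno_id, mt2$sf_id))
  }, numeric(1))

  # --- stage 4: external comparisons ---------------------------------------
  say("[compare] wristband cross-platform match, geographic correlations")
  wb_df <- wristband_detection_frequency(wristband)
  serum_det <- analysis$maternal$detections
  serum_df <- serum_det |>
    dplyr::group_by(.data$chemical) |>
    dplyr::summarise(detection_frequency = mean(.data$detected), .groups = "drop") |>
    dplyr::left_join(fp$harmonized$chemicals[, c("chemical", "formula")],
                     by = "chemical")
  xmatch <- match_wristband_to_serum(wb_df, serum_df, db)
  readr::write_csv(xmatch, file.path(outdir, "crossplatform_matches.csv"))

  pest_counts <- count_chemicals_by_category(
    fp$detections, samples,
    annotations[, c("chemical", "categories")], "pesticide", matrix = "maternal")
  all_counts <- count_chemicals_by_category(
    fp$detections, samples,
    annotations[, c("chemical", "categories")], "all", matrix = "maternal")
  geo <- dplyr::bind_rows(
    dplyr::mutate(correlate_geo(pest_counts, cohort, "pesticide_pctile"),
                  counts = "pesticide", percentile = "pesticide_pctile"),
    dplyr::mutate(correlate_geo(all_counts, cohort, "pollution_burden_pctile"),
                  counts = "all", percentile = "pollution_burden_pctile"))
  readr::write_csv(geo, file.path(outdir, "geo_correlations.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("exposcreen")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = seed,
    stages = list(
      generate = list(n_features = dplyr::n_distinct(generated$features$feature_id),
                      n_samples = nrow(generated$samples),
                      n_participants = nrow(cohort),
                      n_wristband_rows = nrow(wristband)),
      features = fp$report,
      analyze = lapply(analysis, function(a) list(
        n_pairs = nrow(a$matched),
        n_differential = sum(a$differential$differential))),
      compare = list(n_crossplatform_matches = nrow(xmatch),
                     geo = geo)
    ),
    matching_repeat_jaccard = jac
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(db = db, cohort = cohort, truth = truth, generated = generated,
                 feature_pipeline = fp, annotations = annotations,
                 propensity = model, analysis = analysis,
                 wristband = wristband, crossplatform = xmatch, geo = geo,
                 manifest = manifest, outdir = outdir))
}
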