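# Synthetic-data generators: every input the screening pipeline consumes can
# be produced here with known ground truth, emulating a two-city pregnancy
# cohort analysed by LC-QTOF/MS in per-city batches.

#' Source-category labels used in the chemical database
#'
#' @return Character vector of the recognised exposure-source labels.
#' @export
chemical_categories <- function() {
  c("pesticide", "cosmetic/fragrance", "pharmaceutical", "chemical-in-commerce",
    "personal-care", "PAH", "flame-retardant", "consumer-product")
}

#' Generate a synthetic suspect-screening chemical database
#'
#' Builds a database of molecular formulas (monoisotopic masses uniform on the
#' instrument scan range 100--1000 Da) each carrying one or more isomers.
#' Isomers carry literature-mention counts (PubMed, PubChem) and an annual
#' production volume drawn from heavy-tailed distributions, so that
#' evidence-based annotation scores discriminate between isomers, plus zero or
#' more exposure-source category labels.
#'
#' @param n_formulas Number of unique formulas (>= 1).
#' @param max_isomers Maximum isomers per formula (>= 1).
#' @param seed Integer seed; the same seed reproduces the database exactly.
#' @return A tibble with one row per isomer: `formula`, `monoisotopic_mass`,
#'   `isomer`, `pubmed_count`, `pubchem_count`, `production_volume`,
#'   `categories` (semicolon-separated, possibly empty).
#' @export
generate_chemical_db <- function(n_formulas, max_isomers = 8, seed = 1) {
  n_formulas <- assert_count(n_formulas, "n_formulas")
  max_isomers <- assert_count(max_isomers, "max_isomers")
  with_seed_(seed, {
    masses <- stats::runif(n_formulas, 100, 1000)
    formulas <- make_formula_strings(n_formulas)
    n_iso <- sample.int(max_isomers, n_formulas, replace = TRUE,
                        prob = 0.6^seq_len(max_isomers))
    db <- tibble::tibble(
      formula = rep(formulas, n_iso),
      monoisotopic_mass = rep(masses, n_iso)
    )
    k <- nrow(db)
    db$isomer <- paste0(db$formula, "-", unlist(lapply(n_iso, function(m) letters[seq_len(m)])))
    db$pubmed_count <- stats::rnbinom(k, size = 0.3, mu = 60)
    db$pubchem_count <- stats::rnbinom(k, size = 0.3, mu = 250)
    db$production_volume <- stats::rlnorm(k, meanlog = 8, sdlog = 2.2)
    cats <- chemical_categories()
    n_cat <- sample(0:3, k, replace = TRUE, prob = c(0.25, 0.45, 0.20, 0.10))
    db$categories <- vapply(n_cat, function(m) {
      paste(sort(sample(cats, m)), collapse = ";")
    }, character(1))
    db
  })
}

# Pseudo Hill-notation formula strings; uniqueness enforced by construction.
make_formula_strings <- function(n) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n && tries < 50L) {
    tries <- tries + 1L
    need <- n - length(out)
    c_n <- sample(6:30, need, replace = TRUE)
    h_n <- sample(4:40, need, replace = TRUE)
    n_n <- sample(0:4, need, replace = TRUE)
    o_n <- sample(0:8, need, replace = TRUE)
    f <- paste0("C", c_n, "H", h_n,
                ifelse(n_n > 0, paste0("N", n_n), ""),
                ifelse(o_n > 0, paste0("O", o_n), ""))
    out <- unique(c(out, f))
  }
  if (length(out) < n) {
    out <- c(out, paste0(out[1], "X", seq_len(n - length(out))))
  }
  out[seq_len(n)]
}

#' Default city-specific covariate configuration
#'
#' The defaults emulate the demographic contrast between the two study cities:
#' the Central Valley city skews younger, more Latina, with lower educational
#' attainment, and with far higher agricultural-pesticide tract percentiles
#' than the coastal city.
#'
#' @return A named list with one entry per covariate (levels plus per-city
#'   sampling probabilities) and Beta parameters for the two tract percentiles.
#' @export
default_covariate_config <- function() {
  list(
    age_cat = list(levels = c("<30", "30-34", "35+"),
                   Fresno = c(0.60, 0.30, 0.10),
                   SanFrancisco = c(0.30, 0.40, 0.30)),
    race_eth = list(levels = c("Latina", "White", "Black", "Asian", "Other"),
                    Fresno = c(0.55, 0.20, 0.10, 0.10, 0.05),
                    SanFrancisco = c(0.25, 0.35, 0.10, 0.25, 0.05)),
    education = list(levels = c("<HS", "HS", "SomeCollege", "Bachelor+"),
                     Fresno = c(0.20, 0.35, 0.30, 0.15),
                     SanFrancisco = c(0.05, 0.15, 0.25, 0.55)),
    marital = list(levels = c("Married", "LivingTogether", "NeverMarried"),
                   Fresno = c(0.40, 0.30, 0.30),
                   SanFrancisco = c(0.60, 0.25, 0.15)),
    pesticide_pctile = list(Fresno = c(shape1 = 5, shape2 = 2),
                            SanFrancisco = c(shape1 = 1.2, shape2 = 8)),
    pollution_burden_pctile = list(Fresno = c(shape1 = 6, shape2 = 2.5),
                                   SanFrancisco = c(shape1 = 3, shape2 = 4))
  )
}

#' Generate a synthetic two-city cohort
#'
#' @param n_per_city Participants per city (>= 1).
#' @param covariate_config Per-city covariate distributions, see
#'   [default_covariate_config()].
#' @param seed Integer seed.
#' @return Tibble of participants: `participant_id`, `city`, the four matching
#'   covariates, and the two tract percentiles (0--100).
#' @export
generate_cohort <- function(n_per_city, covariate_config = default_covariate_config(),
                            seed = 1) {
  n_per_city <- assert_count(n_per_city, "n_per_city")
  validate_covariate_config(covariate_config)
  with_seed_(seed, {
    cities <- c("Fresno", "SanFrancisco")
    rows <- lapply(cities, function(city) {
      prefix <- if (city == "Fresno") "F" else "S"
      out <- tibble::tibble(
        participant_id = sprintf("%s%03d", prefix, seq_len(n_per_city)),
        city = city
      )
      for (cov in c("age_cat", "race_eth", "education", "marital")) {
        cfg <- covariate_config[[cov]]
        out[[cov]] <- sample(cfg$levels, n_per_city, replace = TRUE,
                             prob = cfg[[city]])
      }
      for (pct in c("pesticide_pctile", "pollution_burden_pctile")) {
        sh <- covariate_config[[pct]][[city]]
        out[[pct]] <- 100 * stats::rbeta(n_per_city, sh[[1]], sh[[2]])
      }
      out
    })
    dplyr::bind_rows(rows)
  })
}

validate_covariate_config <- function(config) {
  for (cov in c("age_cat", "race_eth", "education", "marital")) {
    cfg <- config[[cov]]
    if (is.null(cfg) || length(cfg$levels) == 0) {
      expo_abort(sprintf("covariate_config$%s has no levels.", cov),
                 class = "expo_config_error")
    }
    for (city in c("Fresno", "SanFrancisco")) {
      if (length(cfg[[city]]) != length(cfg$levels)) {
        expo_abort(sprintf(
          "covariate_config$%s: %s probabilities do not match levels.", cov, city),
          class = "expo_config_error")
      }
    }
  }
  invisible(config)
}

#' Construct the ground-truth object driving feature generation
#'
#' Selects `n_differential` isomers from the database as truly differentially
#' detected between cities (with per-city detection probabilities), fixes
#' per-batch additive log-abundance shifts, and a coefficient coupling a
#' participant's agricultural-pesticide tract percentile to the odds of
#' detecting pesticide-annotated chemicals.
#'
#' @param db Chemical database tibble.
#' @param n_differential Number of truly differential chemicals.
#' @param df_fresno,df_sf Per-city detection probabilities of differential
#'   chemicals.
#' @param base_df_range Range of the (city-invariant) detection probability of
#'   null chemicals.
#' @param batch_shift Named numeric vector of additive log-abundance offsets
#'   per batch.
#' @param pesticide_coupling Log-odds change in pesticide detection per 50
#'   percentile points of the pesticide tract score.
#' @param seed Integer seed.
#' @return A list of class `expo_truth`.
#' @export
make_ground_truth <- function(db, n_differential = 20, df_fresno = 0.9, df_sf = 0.3,
                              base_df_range = c(0.05, 0.95),
                              batch_shift = c(`1` = 0.5, `2` = -0.3, `3` = 0),
                              pesticide_coupling = 0, seed = 1) {
  assert_columns(db, c("formula", "isomer"), "db")
  with_seed_(seed, {
    # One candidate chemical per formula (the first isomer); distinct isomers
    # of one formula would co-elute only by coincidence, which the duplicate
    # injection machinery handles separately.
    chems <- db[!duplicated(db$formula), ]
    n_differential <- min(n_differential, nrow(chems))
    diff_idx <- sample.int(nrow(chems), n_differential)
    differential <- tibble::tibble(
      chemical = chems$isomer[diff_idx],
      p_fresno = df_fresno,
      p_sf = df_sf
    )
    base <- stats::runif(nrow(chems), base_df_range[1], base_df_range[2])
    truth <- list(
      chemicals = tibble::tibble(chemical = chems$isomer, formula = chems$formula,
                                 base_df = base),
      differential = differential,
      batch_shift = batch_shift,
      pesticide_coupling = pesticide_coupling
    )
    class(truth) <- "expo_truth"
    truth
  })
}

#' Default batch plan
#'
#' The coastal city's samples are split over two batches, the Central Valley
#' city is analysed in its own single batch, mirroring the three-batch design
#' the pipeline must harmonise.
#' @return Named list city -> integer batch ids.
#' @export
default_batch_plan <- function() {
  list(Fresno = 3L, SanFrancisco = c(1L, 2L))
}

#' Generate per-batch, per-mode LC-QTOF feature tables with ground truth
#'
#' Every truly present chemical spawns, in each batch where at least one of
#' its carriers was analysed, one feature per ionization mode it is amenable
#' to. Feature neutral masses deviate from the formula mass by truncated
#' Gaussian noise (SD `mass_sd_ppm`, truncated at `mass_max_ppm`), retention
#' times jitter around a chemical-specific value, per-batch additive log
#' shifts are applied, water-blank signal is injected for a configurable
#' fraction of features (so they fail the two-fold blank rule), a configurable
#' fraction of features is split into duplicate pairs within the 15 ppm /
#' 0.5 min windows, and every sample is measured in two technical replicates.
#'
#' @param db Chemical database from [generate_chemical_db()].
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param truth Ground truth from [make_ground_truth()].
#' @param batch_plan Named list city -> batch ids, see [default_batch_plan()].
#' @param seed Integer seed.
#' @param cord_fraction Probability a participant also contributes a cord
#'   serum sample.
#' @param both_modes_fraction Fraction of chemicals ionising in both modes.
#' @param duplicate_fraction Fraction of chemical/batch features split into an
#'   injected duplicate pair.
#' @param blank_fail_fraction Fraction of chemicals whose water-blank signal
#'   is comparable to sample signal (they should be removed by blank
#'   filtering).
#' @param mass_sd_ppm,mass_max_ppm Mass-error model (Gaussian SD, truncation)
#'   for the chemical-specific systematic error.
#' @param mass_rep_ppm SD of the small additional between-batch mass jitter
#'   (continuous reference-mass recalibration keeps between-run mass
#'   reproducibility far tighter than absolute accuracy).
#' @param rt_jitter_within,rt_jitter_between RT jitter SD in minutes within
#'   and between batches.
#' @param absent_meanlog,absent_sdlog Log-abundance distribution of the
#'   sub-threshold signal left in samples where a chemical is absent.
#' @param absent_zero_prob Probability an absent cell is a hard zero (feature
#'   not extracted) rather than low signal.
#' @param abund_meanlog_range Range of per-chemical mean log abundance.
#' @param participant_sd,residual_sd Log-abundance SD of the shared
#'   participant effect (couples maternal and cord levels) and of the
#'   sample-level residual.
#' @param replicate_cv Log-scale SD between technical replicates.
#' @param replicate_dropout Probability a (feature, sample) cell is observed
#'   in only one of the two replicates.
#' @return List with `features` (long tibble: `feature_id`, `neutral_mass`,
#'   `rt`, `mode`, `batch`, `sample_id`, `replicate`, `abundance`),
#'   `samples`, and `feature_truth` (feature -> true chemical).
#' @export
generate_feature_tables <- function(db, cohort, truth,
                                    batch_plan = default_batch_plan(), seed = 1,
                                    cord_fraction = 64 / 75,
                                    both_modes_fraction = 0.2,
                                    duplicate_fraction = 0.1,
                                    blank_fail_fraction = 0.1,
                                    mass_sd_ppm = 2, mass_max_ppm = 5,
                                    mass_rep_ppm = 0.3,
                                    rt_jitter_within = 0.1, rt_jitter_between = 0.2,
                                    abund_meanlog_range = log(c(1e5, 3e6)),
                                    participant_sd = 0.5, residual_sd = 0.33,
                                    absent_meanlog = log(500), absent_sdlog = 1,
                                    absent_zero_prob = 0.3,
                                    replicate_cv = 0.05, replicate_dropout = 0.02) {
  assert_columns(cohort, c("participant_id", "city", "pesticide_pctile"), "cohort")
  missing_city <- setdiff(unique(cohort$city), names(batch_plan))
  if (length(missing_city)) {
    expo_abort(sprintf("batch_plan assigns no batch to city: %s.",
                       paste(missing_city, collapse = ", ")),
               class = "expo_config_error")
  }
  with_seed_(seed, {
    samples <- build_sample_table(cohort, batch_plan, cord_fraction)
    chems <- truth$chemicals
    k <- nrow(chems)
    chem <- tibble::tibble(
      chemical = chems$chemical,
      formula = chems$formula,
      base_df = chems$base_df,
      mass = db$monoisotopic_mass[match(chems$formula, db$formula)],
      rt = stats::runif(k, 0.2, 19),
      meanlog = stats::runif(k, abund_meanlog_range[1], abund_meanlog_range[2]),
      both_modes = stats::runif(k) < both_modes_fraction,
      primary_mode = sample(c("positive", "negative"), k, replace = TRUE,
                            prob = c(0.6, 0.4)),
      blank_fail = stats::runif(k) < blank_fail_fraction,
      is_pesticide = grepl("pesticide",
                           db$categories[match(chems$chemical, db$isomer)], fixed = TRUE),
      # systematic mass error per chemical; batches add only small
      # recalibration jitter on top (see build_feature_rows)
      ppm_err = rppm(k, mass_sd_ppm, mass_max_ppm)
    )
    di <- match(chem$chemical, truth$differential$chemical)

    # Per-participant presence (shared by that participant's maternal and cord
    # samples so paired sera correlate), city-dependent for differential
    # chemicals, pesticide-percentile-coupled for pesticides.
    presence <- matrix(FALSE, k, nrow(cohort),
                       dimnames = list(chem$chemical, cohort$participant_id))
    p_base <- matrix(chem$base_df, k, nrow(cohort))
    is_f <- cohort$city == "Fresno"
    if (any(!is.na(di))) {
      dd <- which(!is.na(di))
      p_base[dd, is_f] <- truth$differential$p_fresno[di[dd]]
      p_base[dd, !is_f] <- truth$differential$p_sf[di[dd]]
    }
    if (truth$pesticide_coupling != 0) {
      pest <- which(chem$is_pesticide)
      if (length(pest)) {
        shift <- truth$pesticide_coupling * (cohort$pesticide_pctile - 50) / 50
        lo <- stats::qlogis(pmin(pmax(p_base[pest, , drop = FALSE], 1e-6), 1 - 1e-6))
        p_base[pest, ] <- stats::plogis(sweep(lo, 2, shift, `+`))
      }
    }
    presence[] <- stats::runif(k * nrow(cohort)) < p_base
    part_effect <- matrix(stats::rnorm(k * nrow(cohort), 0, participant_sd),
                          k, nrow(cohort), dimnames = dimnames(presence))

    feats <- build_feature_rows(chem, samples, presence, part_effect, truth,
                                mass_rep_ppm,
                                rt_jitter_within, rt_jitter_between,
                                duplicate_fraction, residual_sd,
                                absent_meanlog, absent_sdlog, absent_zero_prob,
                                replicate_cv, replicate_dropout)
    list(features = feats$features, samples = samples,
         feature_truth = feats$feature_truth)
  })
}

build_sample_table <- function(cohort, batch_plan, cord_fraction) {
  per_part <- lapply(seq_len(nrow(cohort)), function(i) {
    city <- cohort$city[i]
    batches <- batch_plan[[city]]
    batch <- if (length(batches) > 1) sample(batches, 1) else batches
    pid <- cohort$participant_id[i]
    rows <- tibble::tibble(
      sample_id = paste0(pid, "_M"),
      participant_id = pid, matrix = "maternal", batch = as.integer(batch)
    )
    if (stats::runif(1) < cord_fraction) {
      rows <- dplyr::bind_rows(rows, tibble::tibble(
        sample_id = paste0(pid, "_C"),
        participant_id = pid, matrix = "cord", batch = as.integer(batch)
      ))
    }
    rows
  })
  study <- dplyr::bind_rows(per_part)
  blanks <- dplyr::bind_rows(lapply(sort(unique(study$batch)), function(b) {
    tibble::tibble(
      sample_id = sprintf("B%d_%s", b, c("WB", "MB", "MS")),
      participant_id = NA_character_,
      matrix = c("water_blank", "matrix_blank", "matrix_spike"),
      batch = b
    )
  }))
  dplyr::bind_rows(study, blanks)
}

# truncated-at-max Gaussian ppm error
rppm <- function(n, sd, max_ppm) {
  x <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(x) > max_ppm)) x[bad] <- stats::rnorm(sum(bad), 0, sd)
  x
}

build_feature_rows <- function(chem, samples, presence, part_effect, truth,
                               mass_rep_ppm,
                               rt_jitter_within, rt_jitter_between,
                               duplicate_fraction, residual_sd,
                               absent_meanlog, absent_sdlog, absent_zero_prob,
                               replicate_cv, replicate_dropout) {
  batches <- sort(unique(samples$batch))
  study <- samples[samples$matrix %in% c("maternal", "cord"), ]
  feat_meta <- list(); abund_rows <- list(); fid <- 0L
  for (b in batches) {
    sb <- study[study$batch == b, ]
    wb_id <- samples$sample_id[samples$matrix == "water_blank" & samples$batch == b]
    mb_ids <- samples$sample_id[samples$matrix %in% c("matrix_blank", "matrix_spike") &
                                  samples$batch == b]
    shift <- truth$batch_shift[as.character(b)]
    if (is.na(shift) || is.null(shift)) shift <- 0
    pres_b <- presence[, sb$participant_id, drop = FALSE]
    active <- which(rowSums(pres_b) > 0)
    for (ci in active) {
      modes <- if (chem$both_modes[ci]) c("positive", "negative") else chem$primary_mode[ci]
      # sample-level log abundance shared across the chemical's features
      base_log <- chem$meanlog[ci] + part_effect[ci, sb$participant_id] +
        stats::rnorm(nrow(sb), 0, residual_sd) + shift
      # absent chemicals leave low sub-threshold signal in most samples
      # (integrated noise / trace carry-over); a fraction is a hard zero
      # (feature not extracted at all in that sample)
      low_log <- absent_meanlog + stats::rnorm(nrow(sb), 0, absent_sdlog) + shift
      low_ab <- ifelse(stats::runif(nrow(sb)) < absent_zero_prob, 0, exp(low_log))
      sample_ab <- ifelse(pres_b[ci, ], exp(base_log), low_ab)
      split <- stats::runif(1) < duplicate_fraction
      for (mode in modes) {
        n_copies <- if (split) 2L else 1L
        mass0 <- chem$mass[ci] *
          (1 + (chem$ppm_err[ci] + rppm(1, mass_rep_ppm, 3 * mass_rep_ppm)) * 1e-6)
        rt0 <- chem$rt[ci] + stats::rnorm(1, 0, rt_jitter_between)
        for (copy in seq_len(n_copies)) {
          fid <- fid + 1L
          id <- sprintf("FT%06d", fid)
          if (copy == 1L) {
            mass <- mass0; rt <- rt0; ab <- sample_ab * if (split) 0.7 else 1
          } else {
            # injected duplicate: within 15 ppm and 0.5 min of the original,
            # lower abundance so the original keeps the higher detection
            # frequency
            mass <- mass0 * (1 + sample(c(-1, 1), 1) * stats::runif(1, 2, 10) * 1e-6)
            rt <- rt0 + sample(c(-1, 1), 1) * stats::runif(1, 0.05, 0.3)
            ab <- sample_ab * 0.3
          }
          blank_ab <- if (chem$blank_fail[ci]) exp(chem$meanlog[ci] + shift) else 0
          mb_ab <- if (chem$blank_fail[ci]) blank_ab * 0.5 else 0
          feat_meta[[fid]] <- tibble::tibble(
            feature_id = id, neutral_mass = mass, rt = max(rt, 0),
            mode = mode, batch = b, true_chemical = chem$chemical[ci]
          )
          abund_rows[[fid]] <- make_replicates(
            id, c(sb$sample_id, wb_id, mb_ids),
            c(ab, blank_ab, rep(mb_ab, length(mb_ids))),
            replicate_cv, replicate_dropout)
        }
      }
    }
  }
  meta <- dplyr::bind_rows(feat_meta)
  ab <- dplyr::bind_rows(abund_rows)
  features <- dplyr::inner_join(meta[, c("feature_id", "neutral_mass", "rt",
                                         "mode", "batch")],
                                ab, by = "feature_id")
  list(features = tibble::as_tibble(features),
       feature_truth = meta[, c("feature_id", "batch", "mode", "true_chemical")])
}

make_replicates <- function(feature_id, sample_ids, abund, cv, dropout) {
  abund <- unname(abund)
  n <- length(sample_ids)
  r1 <- abund * exp(stats::rnorm(n, 0, cv))
  r2 <- abund * exp(stats::rnorm(n, 0, cv))
  drop_mask <- stats::runif(n) < dropout & abund > 0
  which_rep <- stats::runif(n) < 0.5
  r1[drop_mask & which_rep] <- 0
  r2[drop_mask & !which_rep] <- 0
  r1[abund == 0] <- 0
  r2[abund == 0] <- 0
  tibble::tibble(
    feature_id = feature_id,
    sample_id = rep(sample_ids, 2),
    replicate = rep(1:2, each = n),
    abundance = c(r1, r2)
  )
}

#' Generate synthetic silicone-wristband screening results
#'
#' Emulates a targeted wristband screen for a subset of participants:
#' concentrations are reported in ng per g silicone per week of wear, wear
#' time averages 35 days, and a configurable fraction of the wristband panel
#' overlaps the serum suspect database (the remainder, like PCBs, is not
#' amenable to the serum screen).
#'
#' @param db Serum chemical database.
#' @param participants Character vector of participant ids wearing wristbands.
#' @param seed Integer seed.
#' @param n_chemicals Size of the wristband panel actually detected.
#' @param overlap_fraction Fraction of panel chemicals present in the serum
#'   database.
#' @param mean_days Average days worn.
#' @return Tibble: `participant_id`, `chemical`, `formula`, `in_serum_db`,
#'   `categories`, `raw_ng`, `silicone_g`, `days_worn`, `concentration`
#'   (ng/g/week).
#' @export
generate_wristband_data <- function(db, participants, seed = 1,
                                    n_chemicals = 81, overlap_fraction = 56 / 81,
                                    mean_days = 35) {
  if (length(participants) == 0) {
    expo_abort("`participants` must be non-empty.", class = "expo_argument_error")
  }
  with_seed_(seed, {
    n_in <- round(n_chemicals * overlap_fraction)
    n_out <- n_chemicals - n_in
    iso <- db[sample.int(nrow(db), min(n_in, nrow(db))), ]
    panel <- tibble::tibble(
      chemical = iso$isomer, formula = iso$formula,
      in_serum_db = TRUE, categories = iso$categories
    )
    if (n_out > 0) {
      cl <- tibble::tibble(
        chemical = sprintf("PCB-like-%02d", seq_len(n_out)),
        formula = sprintf("C12H%dCl%d", sample(3:6, n_out, TRUE), sample(4:8, n_out, TRUE)),
        in_serum_db = FALSE,
        categories = sample(c("chemical-in-commerce", "flame-retardant"), n_out, TRUE)
      )
      panel <- dplyr::bind_rows(panel, cl)
    }
    panel$detect_p <- stats::rbeta(nrow(panel), 0.9, 1.6)
    panel$meanlog <- stats::runif(nrow(panel), log(2), log(200))
    wear <- tibble::tibble(
      participant_id = participants,
      days_worn = pmax(stats::rnorm(length(participants), mean_days, 6), 7),
      silicone_g = pmax(stats::rnorm(length(participants), 4.5, 0.25), 3)
    )
    out <- tidyr::crossing(wear, panel)
    detected <- stats::runif(nrow(out)) < out$detect_p
    out$raw_ng <- ifelse(
      detected,
      exp(out$meanlog + stats::rnorm(nrow(out), 0, 0.8)) * out$silicone_g *
        out$days_worn / 7,
      0)
    out$concentration <- ifelse(
      out$raw_ng > 0,
      normalize_wristband(out$raw_ng, out$silicone_g, out$days_worn),
      0)
    out[, c("participant_id", "chemical", "formula", "in_serum_db", "categories",
            "raw_ng", "silicone_g", "days_worn", "concentration")]
  })
}

#' Simulate a detection matrix directly from detection probabilities
#'
#' Bypasses the mass-spectrometric feature layer: each chemical is detected in
#' each participant's sample as an independent Bernoulli draw with a
#' city-dependent probability for differential chemicals and a shared
#' probability for null chemicals. Useful for calibration and power studies of
#' the differential-detection stage in isolation.
#'
#' @param cohort Cohort tibble (`participant_id`, `city`).
#' @param n_chemicals Total chemicals simulated.
#' @param n_differential Number of truly differential chemicals.
#' @param df_fresno,df_sf Differential chemicals' detection probabilities.
#' @param base_df Detection probability of null chemicals (recycled).
#' @param seed Integer seed.
#' @return List: `detections` (long tibble `chemical`, `participant_id`,
#'   `detected`), `truth` (tibble `chemical`, `differential`).
#' @export
simulate_detections <- function(cohort, n_chemicals = 100, n_differential = 20,
                                df_fresno = 0.9, df_sf = 0.3, base_df = 0.5,
                                seed = 1) {
  with_seed_(seed, {
    chems <- sprintf("SIM%04d", seq_len(n_chemicals))
    is_diff <- seq_len(n_chemicals) <= n_differential
    base <- rep_len(base_df, n_chemicals)
    grid <- tidyr::crossing(chemical = chems,
                            participant_id = cohort$participant_id)
    ci <- match(grid$chemical, chems)
    fres <- cohort$city[match(grid$participant_id, cohort$participant_id)] == "Fresno"
    p <- ifelse(is_diff[ci], ifelse(fres, df_fresno, df_sf), base[ci])
    grid$detected <- stats::runif(nrow(grid)) < p
    list(detections = grid,
         truth = tibble::tibble(chemical = chems, differential = is_diff))
  })
}
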