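# Isomer annotation: pick the most probable chemical structure for a
# formula-level suspect from a blind prior and min-max scaled evidence
# (literature mentions and production volume), and assign isomers to multiple
# co-formula differential chemicals by detection-frequency rank.

#' Blind probability of an isomer given its formula
#'
#' With no evidence, each of a formula's k isomers is equally likely: 1/k.
#'
#' @param formula Formula string present in `db`.
#' @param db Chemical database (one row per isomer).
#' @return `1 / k`.
#' @export
blind_probability <- function(formula, db) {
  k <- sum(db$formula == formula)
  if (k == 0) {
    expo_abort(sprintf("Formula '%s' not found in database.", formula),
               class = "expo_lookup_error")
  }
  1 / k
}

#' Evidence scores for every isomer in the database
#'
#' PubMed mentions, PubChem mentions, and production volume are each min-max
#' scaled to 0--1 across the whole database (a constant column scales to 0;
#' missing values are treated as 0 before scaling), then combined as a
#' weighted mean.
#'
#' @param db Chemical database.
#' @param weights Positive weights for (pubmed, pubchem, volume); default
#'   equal.
#' @return `db` with `evidence_score` (and the three scaled columns) appended.
#' @export
evidence_scores <- function(db, weights = c(1, 1, 1)) {
  assert_columns(db, c("isomer", "pubmed_count", "pubchem_count",
                       "production_volume"), "db")
  if (length(weights) != 3 || any(weights < 0) || sum(weights) == 0) {
    expo_abort("`weights` must be three non-negative values, not all zero.",
               class = "expo_argument_error")
  }
  scale01 <- function(x) {
    x[is.na(x)] <- 0
    rng <- range(x)
    if (rng[1] == rng[2]) return(rep(0, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  out <- db
  out$scaled_pubmed <- scale01(db$pubmed_count)
  out$scaled_pubchem <- scale01(db$pubchem_count)
  out$scaled_volume <- scale01(db$production_volume)
  w <- weights / sum(weights)
  out$evidence_score <- w[1] * out$scaled_pubmed + w[2] * out$scaled_pubchem +
    w[3] * out$scaled_volume
  out
}

#' Evidence score for a single isomer
#'
#' @param isomer Isomer name.
#' @inheritParams evidence_scores
#' @return Scalar evidence score in 0--1.
#' @export
evidence_score <- function(isomer, db, weights = c(1, 1, 1)) {
  scored <- evidence_scores(db, weights)
  i <- match(isomer, scored$isomer)
  if (is.na(i)) {
    expo_abort(sprintf("Isomer '%s' not found in database.", isomer),
               class = "expo_lookup_error")
  }
  scored$evidence_score[i]
}

#' Score and rank a formula's isomers
#'
#' Final score is the average of the blind probability (1/k) and the evidence
#' score; isomers are ranked by descending final score, ties broken by isomer
#' name.
#'
#' @inheritParams blind_probability
#' @param weights Evidence metric weights.
#' @return Tibble: `isomer`, `blind_probability`, `evidence_score`,
#'   `final_score`, `rank`, `categories`.
#' @export
score_isomers <- function(formula, db, weights = c(1, 1, 1)) {
  scored <- evidence_scores(db, weights)
  rows <- scored[scored$formula == formula, ]
  if (nrow(rows) == 0) {
    expo_abort(sprintf("Formula '%s' not found in database.", formula),
               class = "expo_lookup_error")
  }
  k <- nrow(rows)
  out <- tibble::tibble(
    formula = formula,
    isomer = rows$isomer,
    blind_probability = 1 / k,
    evidence_score = rows$evidence_score,
    final_score = (1 / k + rows$evidence_score) / 2,
    categories = if ("categories" %in% names(rows)) rows$categories else ""
  )
  out <- out[order(-out$final_score, out$isomer), ]
  out$rank <- seq_len(k)
  out
}

#' Annotate harmonized chemicals with their most probable isomer
#'
#' @param chemicals Tibble with `chemical` and `formula` columns.
#' @param db Chemical database.
#' @param weights Evidence metric weights.
#' @return `chemicals` joined with the rank-1 isomer, its scores and
#'   categories.
#' @export
annotate_chemicals <- function(chemicals, db, weights = c(1, 1, 1)) {
  assert_columns(chemicals, c("chemical", "formula"), "chemicals")
  scored <- evidence_scores(db, weights)
  top <- scored |>
    dplyr::group_by(.data$formula) |>
    dplyr::mutate(blind_probability = 1 / dplyr::n(),
                  final_score = (.data$blind_probability + .data$evidence_score) / 2) |>
    dplyr::arrange(dplyr::desc(.data$final_score), .data$isomer,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("formula", "isomer", "blind_probability", "evidence_score",
                  "final_score", "categories")
  dplyr::left_join(chemicals, top, by = "formula")
}

#' Assign isomers to multiple differential chemicals of one formula by rank
#'
#' The most probable isomer is assigned to the chemical with the highest
#' detection frequency, the second most probable to the second highest, and
#' so on. There must be at least as many isomers as chemicals.
#'
#' @param formula Shared formula.
#' @param chemicals Tibble with `chemical` and `detection_frequency` columns,
#'   all sharing `formula`.
#' @param db Chemical database.
#' @param weights Evidence metric weights.
#' @return Tibble `chemical`, `detection_frequency`, `isomer`, `final_score`,
#'   `rank`.
#' @export
assign_isomers_by_rank <- function(formula, chemicals, db, weights = c(1, 1, 1)) {
  assert_columns(chemicals, c("chemical", "detection_frequency"), "chemicals")
  iso <- score_isomers(formula, db, weights)
  if (nrow(chemicals) > nrow(iso)) {
    expo_abort(sprintf(
      "Formula '%s' has %d isomers but %d chemicals to annotate.",
      formula, nrow(iso), nrow(chemicals)),
      class = "expo_annotation_error")
  }
  ch <- chemicals[order(-chemicals$detection_frequency, chemicals$chemical), ]
  tibble::tibble(
    chemical = ch$chemical,
    detection_frequency = ch$detection_frequency,
    isomer = iso$isomer[seq_len(nrow(ch))],
    final_score = iso$final_score[seq_len(nrow(ch))],
    rank = iso$rank[seq_len(nrow(ch))]
  )
}
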