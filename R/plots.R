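# ggplot2 views of the main result types.

#' Histogram of per-participant detected chemical counts by city
#'
#' @param detections Long detection tibble (`chemical`, `sample_id`,
#'   `detected`).
#' @param samples Sample table.
#' @param cohort Cohort tibble (for city labels).
#' @param matrix Specimen type.
#' @return A ggplot object.
#' @export
plot_detection_counts <- function(detections, samples, cohort,
                                  matrix = "maternal") {
  smp <- samples[samples$matrix == matrix & !is.na(samples$participant_id), ]
  counts <- detections[detections$sample_id %in% smp$sample_id &
                         detections$detected, ] |>
    dplyr::count(.data$sample_id, name = "n_detected")
  counts$participant_id <- smp$participant_id[match(counts$sample_id,
                                                    smp$sample_id)]
  counts$city <- cohort$city[match(counts$participant_id,
                                   cohort$participant_id)]
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$n_detected, fill = .data$city)) +
    ggplot2::geom_histogram(bins = 25, alpha = 0.6, position = "identity") +
    ggplot2::labs(x = sprintf("Suspect chemicals detected (%s serum)", matrix),
                  y = "Participants", fill = "City") +
    ggplot2::theme_minimal()
}

#' Dot plot of differentially detected chemicals by source category
#'
#' One point per (chemical, category); point size encodes the
#' Fresno / San Francisco abundance ratio, colour the direction.
#'
#' @param object `expo_differential` result joined with annotation
#'   (`isomer`, `categories` columns), e.g. the `differential_annotated`
#'   element of a [run_pipeline()] stage.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expo_differential <- function(object, ...) {
  x <- tibble::as_tibble(unclass(object))
  if (!"categories" %in% names(x)) x$categories <- ""
  d <- x[x$differential, ]
  d <- tidyr::separate_rows(d, "categories", sep = ";")
  d$categories[is.na(d$categories) | d$categories == ""] <- "uncategorised"
  label <- if ("isomer" %in% names(d)) d$isomer else d$chemical
  d$label <- dplyr::coalesce(label, d$chemical)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$df_fresno - .data$df_sf,
                                  y = .data$label,
                                  size = .data$abundance_ratio,
                                  colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.8, position = ggplot2::position_jitter(height = 0.1)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$categories),
                        scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "Detection-frequency difference (Fresno - San Francisco)",
                  y = NULL, size = "Abundance ratio", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Batch structure in principal components, before vs after correction
#'
#' @param before,after Outputs of [batch_mixing_check()] on the uncorrected
#'   and corrected matrices.
#' @return A ggplot object comparing per-component batch R-squared.
#' @export
plot_batch_pca <- function(before, after) {
  d <- dplyr::bind_rows(
    dplyr::mutate(before, stage = "before correction"),
    dplyr::mutate(after, stage = "after correction"))
  d$stage <- factor(d$stage, levels = c("before correction", "after correction"))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$component),
                                  y = .data$r_squared_batch,
                                  fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Principal component", y = expression(R^2 ~ "of batch"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
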