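#' Correlate regional brain activity with a per-subject covariate
#'
#' Across-subject Pearson correlation of each region-of-interest (ROI)
#' value with a behavioral or autonomic covariate (e.g. the norepinephrine
#' change score, or entropy), with two-sided p-values; ROIs below the
#' significance threshold are flagged with their sign. This is the
#' ROI-level analogue of a voxelwise covariate correlation map.
#'
#' @param roi Long ROI table with columns `subject_id`, `roi`, `value`
#'   (one value per subject per ROI).
#' @param covariate Either a data frame with columns `subject_id` and
#'   `value`, or a vector named by subject.
#' @param alpha Flagging threshold on the uncorrected two-sided p-value
#'   (default 0.001).
#' @return A tibble with columns `roi`, `r`, `p`, `sign` (+1/-1) and
#'   `flagged`.
#' @export
roi_covariate_correlation <- function(roi, covariate, alpha = 0.001) {
  stopifnot(is.data.frame(roi),
            all(c("subject_id", "roi", "value") %in% names(roi)))
  if (is.data.frame(covariate)) {
    cov_vec <- setNames(covariate$value, covariate$subject_id)
  } else {
    cov_vec <- covariate
    if (is.null(names(cov_vec))) abort("covariate vector must be named by subject")
  }
  subjects <- unique(as.character(roi$subject_id))
  if (!setequal(subjects, names(cov_vec))) {
    abort("subjects in the ROI table and the covariate do not match")
  }
  roi %>%
    group_by(.data$roi) %>%
    summarise(
      r = cor(.data$value[match(names(cov_vec),
                                as.character(.data$subject_id))], cov_vec),
      n = dplyr::n(), .groups = "drop") %>%
    mutate(
      p = 2 * pt(abs(.data$r) * sqrt(.data$n - 2) /
                   sqrt(pmax(1 - .data$r^2, .Machine$double.eps)),
                 df = .data$n - 2, lower.tail = FALSE),
      sign = sign(.data$r),
      flagged = .data$p < alpha
    ) %>%
    select("roi", "r", "p", "sign", "flagged")
}

#' Seed-based ROI connectivity
#'
#' Across-subject Pearson correlation of one seed ROI's values with every
#' other ROI — the ROI-level analogue of a seed-based connectivity map
#' (e.g. seeding the right anterior insula after it shows the strongest
#' entropy correlation).
#'
#' @inheritParams roi_covariate_correlation
#' @param seed_label Name of the seed ROI (must be present in `roi$roi`).
#' @return A tibble with columns `roi`, `r`, `p` and `flagged`, excluding
#'   the seed itself unless `include_seed = TRUE`.
#' @param include_seed Keep the seed's self-correlation row (r = 1)?
#'   Default `FALSE`.
#' @export
seed_connectivity <- function(roi, seed_label, alpha = 0.001,
                              include_seed = FALSE) {
  stopifnot(is.data.frame(roi),
            all(c("subject_id", "roi", "value") %in% names(roi)))
  if (!seed_label %in% roi$roi) {
    abort(sprintf("unknown seed ROI '%s'", seed_label))
  }
  seed <- roi %>% filter(.data$roi == seed_label)
  cov_df <- tibble(subject_id = seed$subject_id, value = seed$value)
  out <- roi_covariate_correlation(roi, cov_df, alpha = alpha) %>%
    select("roi", "r", "p", "flagged")
  if (!include_seed) out <- out %>% filter(.data$roi != seed_label)
  out
}
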