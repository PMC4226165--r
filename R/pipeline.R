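#' Run the full analysis pipeline
#'
#' Orchestrates simulate/synthesize -> behavioral scoring -> HRV features
#' -> change scores -> linkage statistics, and writes report tables plus a
#' machine-readable run manifest. Inputs are either a synthetic-cohort
#' configuration (default) or a list of CSV paths
#' (`list(trials =, panels =, beats =, roi =)`; `beats` and `roi`
#' optional). Identical configuration and seed yield identical numeric
#' outputs.
#'
#' Report files written to `out_dir`: `behavioral_indices.csv` (per
#' subject x condition x block), `behavioral_summary.csv` (condition
#' means/SEs), `autonomic_changes.csv`, `correlations_<condition>.csv`,
#' `regression_<condition>.csv` (stepwise trace and final model),
#' `anova_behavior.csv`, `anova_autonomic.csv`, `roi_flags_<condition>.csv`,
#' `seed_connectivity_<condition>.csv` (when ROI data are present) and
#' `manifest.json`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed governing synthesis.
#' @param cohort A [cohort_config()] used when `inputs` is `NULL`.
#' @param inputs Optional named list of CSV paths.
#' @param c Entropy smoothing constant.
#' @param rate HRV resampling rate (Hz).
#' @param p_enter,p_remove Stepwise thresholds.
#' @param alpha ROI flagging threshold.
#' @param entropy_covariate Use measured entropy as a second ROI covariate
#'   (default `TRUE`).
#' @return Invisibly, a named list with every computed table and fitted
#'   object.
#' @export
run_full <- function(out_dir, seed = 1, cohort = cohort_config(),
                     inputs = NULL, c = 1, rate = 4,
                     p_enter = 0.05, p_remove = 0.10, alpha = 0.001,
                     entropy_covariate = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(inputs)) {
    coh <- sample_cohort(cohort, seed = seed)
    trials <- coh$trials
    panels <- coh$panels
    beats <- coh$beats
    roi <- coh$roi
  } else {
    if (is.null(inputs$trials) || is.null(inputs$panels)) {
      abort("`inputs` must name at least trials and panels CSVs")
    }
    trials <- read_trials(inputs$trials)
    panels <- read_panels(inputs$panels)
    beats <- if (!is.null(inputs$beats)) read_beats(inputs$beats) else NULL
    roi <- if (!is.null(inputs$roi)) read_roi(inputs$roi) else NULL
  }

  # ---- behavioral indices (Table-1-style layout) -------------------------
  indices <- score_trials(trials, c = c)
  summary_tbl <- indices %>%
    tidyr::pivot_longer(c("response_bias", "reward_acquisition", "entropy"),
                        names_to = "index") %>%
    group_by(.data$condition, .data$index) %>%
    summarise(mean = mean(.data$value),
              se = sd(.data$value) / sqrt(dplyr::n()), .groups = "drop")

  # ---- HRV features merged into the panels (when beats are present) ------
  if (!is.null(beats)) {
    hrv <- hrv_table(beats, rate = rate)
    hrv_long <- hrv %>%
      select("subject_id", "condition", "block", "period",
             "lf_hf_ratio", "hf_pct") %>%
      rename(lf_hf = "lf_hf_ratio") %>%
      tidyr::pivot_longer(c("lf_hf", "hf_pct"), names_to = "variable")
    panels <- panels %>%
      dplyr::anti_join(distinct(hrv_long, .data$variable),
                       by = "variable") %>%
      dplyr::bind_rows(hrv_long)
  } else {
    hrv <- NULL
  }

  # ---- change scores and per-condition linkage ---------------------------
  changes <- change_scores(panels)
  conds <- sort(unique(indices$condition))
  link <- purrr::map(setNames(conds, conds), function(cd) {
    beh <- condition_summary(trials %>% filter(.data$condition == cd), c = c)
    wide <- changes %>%
      filter(.data$condition == cd) %>%
      select("subject_id", "variable", "delta") %>%
      tidyr::pivot_wider(names_from = "variable", values_from = "delta") %>%
      left_join(beh %>% select("subject_id", "response_bias",
                               "reward_acquisition", "entropy"),
                by = "subject_id")
    cm <- pearson_matrix(wide)
    sw <- stepwise_regression(
      wide, "entropy",
      predictors = intersect(
        c("mbp", "hr", "tpr", "epinephrine", "norepinephrine",
          "lf_hf", "hf_pct"), names(wide)),
      p_enter = p_enter, p_remove = p_remove)
    out <- list(data = wide, cormat = cm, stepwise = sw)
    if (!is.null(roi)) {
      roi_cd <- roi %>% filter(.data$condition == cd)
      cov_ne <- wide %>% select("subject_id", value = "norepinephrine")
      flags_ne <- roi_covariate_correlation(roi_cd, cov_ne, alpha = alpha) %>%
        mutate(covariate = "norepinephrine", .before = 1)
      flags <- flags_ne
      if (entropy_covariate) {
        cov_h <- wide %>% select("subject_id", value = "entropy")
        flags_h <- roi_covariate_correlation(roi_cd, cov_h, alpha = alpha) %>%
          mutate(covariate = "entropy", .before = 1)
        flags <- dplyr::bind_rows(flags, flags_h)
        best <- flags_h %>% arrange(.data$p) %>% head(1)
        out$seed_roi <- best$roi
        out$connectivity <- seed_connectivity(roi_cd, best$roi, alpha = alpha)
      }
      out$roi_flags <- flags
    }
    out
  })

  # ---- repeated-measures ANOVAs ------------------------------------------
  anova_beh <- purrr::map(
    setNames(c("response_bias", "reward_acquisition", "entropy"),
             c("response_bias", "reward_acquisition", "entropy")),
    function(v) {
      if (length(conds) < 2) return(NULL)
      tidy(rm_anova(indices, dv = v, within = c("condition", "block"))) %>%
        mutate(dv = v, .before = 1)
    })
  anova_beh <- dplyr::bind_rows(anova_beh)
  anova_aut <- if (length(conds) >= 2) {
    purrr::map(unique(panels$variable), function(v) {
      d <- panels %>% filter(.data$variable == v)
      tidy(rm_anova(d, dv = "value",
                    within = c("condition", "period", "block"))) %>%
        mutate(dv = v, .before = 1)
    }) %>% dplyr::bind_rows()
  } else NULL

  # ---- write report ------------------------------------------------------
  params <- list(seed = seed, c = c, rate = rate, p_enter = p_enter,
                 p_remove = p_remove, alpha = alpha,
                 source = if (is.null(inputs)) "synthetic" else "csv",
                 package_version = as.character(
                   utils::packageVersion("explorentropy")))
  manifest <- c(params, list(hash = rlang::hash(list(params, cohort)),
                             n_trials = nrow(trials),
                             n_panel_rows = nrow(panels)))
  wr <- function(x, name) {
    readr::write_csv(
      x %>% mutate(manifest_hash = manifest$hash),
      file.path(out_dir, name), na = "")
  }
  wr(indices, "behavioral_indices.csv")
  wr(summary_tbl, "behavioral_summary.csv")
  wr(changes, "autonomic_changes.csv")
  if (nrow(anova_beh)) wr(anova_beh, "anova_behavior.csv")
  if (!is.null(anova_aut)) wr(anova_aut, "anova_autonomic.csv")
  for (cd in conds) {
    wr(tidy(link[[cd]]$cormat), sprintf("correlations_%s.csv", cd))
    wr(dplyr::bind_rows(
      link[[cd]]$stepwise$trace %>% mutate(part = "trace"),
      tidy(link[[cd]]$stepwise) %>%
        rename(variable = "term", p_value = "p.value") %>%
        select("variable", "p_value", "estimate", "std_estimate") %>%
        mutate(part = "final")),
      sprintf("regression_%s.csv", cd))
    if (!is.null(link[[cd]]$roi_flags)) {
      wr(link[[cd]]$roi_flags, sprintf("roi_flags_%s.csv", cd))
      wr(link[[cd]]$connectivity,
         sprintf("seed_connectivity_%s.csv", cd))
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(trials = trials, panels = panels, beats = beats, roi = roi,
                 indices = indices, summary = summary_tbl, hrv = hrv,
                 changes = changes, link = link, anova_behavior = anova_beh,
                 anova_autonomic = anova_aut, manifest = manifest))
}
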