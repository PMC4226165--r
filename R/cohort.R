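#' Invert the asymptotic entropy of a symmetric Stay/Shift policy
#'
#' Finds the symmetric outcome-conditioned policy whose asymptotic
#' normalized entropy ([expected_entropy()]) equals a target value:
#' `p_stay_gain = p`, `p_stay_loss = 1 - p` with `p >= 0.5` and binary
#' entropy `h(p) = theta`, obtained by monotone root-finding. At
#' `theta = 1` the policy is uniform (`p = 0.5`); as `theta -> 0` it
#' approaches deterministic Win-Stay/Lose-Shift.
#'
#' @param theta Target normalized entropy in (0, 1].
#' @return Named numeric vector `c(p_stay_gain, p_stay_loss)`.
#' @examples
#' invert_expected_entropy(1)        # c(0.5, 0.5)
#' invert_expected_entropy(0.9183)   # p_stay_gain ~ 2/3
#' @export
invert_expected_entropy <- function(theta) {
  stopifnot(length(theta) == 1)
  if (!is.finite(theta) || theta <= 0 || theta > 1) {
    abort("`theta` must lie in (0, 1]")
  }
  if (theta == 1) {
    return(c(p_stay_gain = 0.5, p_stay_loss = 0.5))
  }
  p <- uniroot(function(p) binary_entropy(p) - theta,
               lower = 0.5, upper = 1 - 1e-15, tol = 1e-13)$root
  c(p_stay_gain = p, p_stay_loss = 1 - p)
}

#' Default ROI loading structure of the synthetic cohort
#'
#' Loadings of each region of interest on the standardized measured
#' entropy (`b_entropy`), the standardized norepinephrine change
#' (`b_ne`), and a shared "salience network" factor (`b_network`) that
#' induces seed connectivity between the right anterior insula and the
#' rostral ACC; residual variance tops each ROI up to unit variance. In
#' the contingent condition the parahippocampal gyrus, rostral ACC and
#' right posterior insula load negatively on the norepinephrine change and
#' the right anterior insula (and superior temporal gyrus) negatively on
#' entropy; in the random condition bilateral DLPFC and the right inferior
#' parietal lobule load positively on entropy. All other regions are
#' unloaded null controls. Default magnitudes give each flagged ROI a
#' population correlation of about 0.86 with its covariate, sized so that
#' the p < 0.001 flag (n = 16) fires in well over 80% of cohorts.
#'
#' @return A tibble with columns `roi`, `condition`, `b_entropy`, `b_ne`,
#'   `b_network`.
#' @export
default_roi_structure <- function() {
  dplyr::bind_rows(
    tibble(roi = "parahippocampal_gyrus_L", condition = "contingent",
           b_entropy = 0, b_ne = -0.86, b_network = 0),
    tibble(roi = "posterior_insula_R", condition = "contingent",
           b_entropy = 0, b_ne = -0.86, b_network = 0),
    tibble(roi = "rostral_acc_L", condition = "contingent",
           b_entropy = -0.395, b_ne = -0.611, b_network = 0.408),
    tibble(roi = "anterior_insula_R", condition = "contingent",
           b_entropy = -0.86, b_ne = 0, b_network = 0.510),
    tibble(roi = "superior_temporal_gyrus_R", condition = "contingent",
           b_entropy = -0.86, b_ne = 0, b_network = 0),
    tibble(roi = "dlpfc_R", condition = "random",
           b_entropy = 0.86, b_ne = 0, b_network = 0),
    tibble(roi = "dlpfc_L", condition = "random",
           b_entropy = 0.86, b_ne = 0, b_network = 0),
    tibble(roi = "inferior_parietal_lobule_R", condition = "random",
           b_entropy = 0.86, b_ne = 0, b_network = 0)
  )
}

# regions present in every generated ROI table (loaded or null)
.roi_regions <- c(
  "parahippocampal_gyrus_L", "posterior_insula_R", "rostral_acc_L",
  "anterior_insula_R", "superior_temporal_gyrus_R", "dlpfc_R", "dlpfc_L",
  "inferior_parietal_lobule_R", "thalamus_R", "putamen_R",
  "globus_pallidus_L", "cerebellum_R", "postcentral_gyrus_R")

#' Configure the synthetic cohort generator
#'
#' Fixes the study conditions the generator emulates: 16 subjects, two
#' reward conditions of 3 blocks x 40 trials each, condition-level entropy
#' means of 0.64 (contingent) and 0.74 (random) with a between-subject SD
#' of 0.24 (the printed standard error 0.06 times sqrt(16)), an
#' entropy-norepinephrine coupling of 0.63 in the contingent condition
#' only, norepinephrine change scores centered at +3.04 pg/ml (contingent)
#' and -11.15 pg/ml (random), and high-frequency HRV percentages larger in
#' the random than the contingent condition.
#'
#' @param n_subjects Number of subjects (default 16).
#' @param trials_per_block,blocks Task dimensions (defaults 40 and 3).
#' @param entropy_mean Named vector of condition-level entropy means.
#' @param entropy_sd Between-subject entropy SD (default 0.24).
#' @param rho_entropy_ne Named vector of target entropy-NE correlations.
#' @param ne_delta_mean Named vector of mean NE change scores (pg/ml).
#' @param ne_delta_sd Between-subject SD of the NE change score (pg/ml).
#' @param hf_pct_target List per condition of named `c(baseline, task)`
#'   high-frequency percentage targets.
#' @param roi_structure Loading table as in [default_roi_structure()].
#' @param baseline_duration_s,task_duration_s HRV recording lengths.
#' @return A list of class `expl_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 16, trials_per_block = 40, blocks = 3,
                          entropy_mean = c(contingent = 0.64, random = 0.74),
                          entropy_sd = 0.24,
                          rho_entropy_ne = c(contingent = 0.63, random = 0),
                          ne_delta_mean = c(contingent = 3.04,
                                            random = -11.15),
                          ne_delta_sd = 20,
                          hf_pct_target = list(
                            contingent = c(baseline = 51, task = 53),
                            random = c(baseline = 52, task = 58)),
                          roi_structure = default_roi_structure(),
                          baseline_duration_s = 120,
                          task_duration_s = 240) {
  stopifnot(n_subjects >= 4, all(abs(rho_entropy_ne) < 1),
            all(entropy_mean > 0 & entropy_mean < 1), entropy_sd > 0)
  structure(list(
    n_subjects = n_subjects, trials_per_block = trials_per_block,
    blocks = blocks, entropy_mean = entropy_mean, entropy_sd = entropy_sd,
    rho_entropy_ne = rho_entropy_ne, ne_delta_mean = ne_delta_mean,
    ne_delta_sd = ne_delta_sd, hf_pct_target = hf_pct_target,
    roi_structure = roi_structure,
    baseline_duration_s = baseline_duration_s,
    task_duration_s = task_duration_s
  ), class = "expl_cohort_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a complete synthetic cohort
#'
#' Draws a latent exploration tendency per subject, maps it to a target
#' entropy, inverts the entropy to a symmetric outcome-conditioned policy
#' (see [invert_expected_entropy()]), simulates the task, and generates
#' autonomic panels, interbeat-interval series, and ROI tables whose
#' correlation structure follows the configuration. The norepinephrine
#' change score couples to the subject's *realized* standardized measured
#' entropy with the configured correlation (so the configured rho is the
#' population correlation of the measured data); ROI values are linear
#' combinations of the standardized measured entropy, the standardized NE
#' change, and a shared network factor, plus unit-variance-completing
#' noise, rescaled to arbitrary normalized rCBF units (50 +/- 5).
#'
#' The latent truth (z, target entropy, policy parameters, realized
#' entropy, NE change) is returned alongside the observables for
#' parameter-recovery tests.
#'
#' @param config An [cohort_config()] object.
#' @param seed Integer master seed; all randomness derives from it.
#' @param conditions Conditions to generate (default both).
#' @param include_beats Generate interbeat-interval series? (Default
#'   `TRUE`; switch off for large simulation studies that do not use the
#'   HRV pipeline.)
#' @param include_roi Generate the ROI table? (Default `TRUE`.)
#' @return An object of class `expl_cohort`: a list with tibbles `trials`,
#'   `panels`, `beats` (or `NULL`), `roi` (or `NULL`), `latent`, plus the
#'   config and seed.
#' @examples
#' coh <- sample_cohort(cohort_config(n_subjects = 6), seed = 1,
#'                      conditions = "contingent", include_beats = FALSE)
#' coh$latent
#' @export
sample_cohort <- function(config = cohort_config(), seed,
                          conditions = c("contingent", "random"),
                          include_beats = TRUE, include_roi = TRUE) {
  stopifnot(inherits(config, "expl_cohort_config"))
  conditions <- match.arg(conditions, c("contingent", "random"),
                          several.ok = TRUE)
  set.seed(as.integer(seed))
  n <- config$n_subjects
  subjects <- sprintf("S%02d", seq_len(n))
  panel_vars <- tibble(
    variable = c("mbp", "hr", "tpr", "epinephrine"),
    base_mean = c(79, 65, 0.78, 38),
    base_sd = c(7, 8, 0.20, 18),
    delta_mean = c(3, 1.5, 0.02, 9),
    delta_sd = c(3, 2, 0.05, 15),
    block_sd = c(1.5, 1, 0.02, 6)
  )

  all_trials <- list()
  all_panels <- list()
  all_beats <- list()
  all_roi <- list()
  all_latent <- list()

  for (cond in conditions) {
    rho <- unname(config$rho_entropy_ne[[cond]])
    # --- master-stream draws, fixed order ---------------------------------
    z <- rnorm(n)
    trial_seeds <- sample.int(.Machine$integer.max - 1L, n)
    eps_ne <- rnorm(n)
    ne_base <- rnorm(n, 207, 60)
    ne_base_jit <- matrix(rnorm(n * config$blocks, 0, 4), n)
    ne_task_jit <- matrix(rnorm(n * config$blocks, 0, 4), n)
    pv_base <- matrix(rnorm(n * nrow(panel_vars)), n)
    pv_delta <- matrix(rnorm(n * nrow(panel_vars)), n)
    pv_jit <- array(rnorm(n * nrow(panel_vars) * config$blocks * 2),
                    c(n, nrow(panel_vars), config$blocks, 2))
    hf_base <- clamp(matrix(rnorm(n * config$blocks,
                                  config$hf_pct_target[[cond]][["baseline"]],
                                  6), n), 15, 85)
    hf_task <- clamp(matrix(rnorm(n * config$blocks,
                                  config$hf_pct_target[[cond]][["task"]],
                                  6), n), 15, 85)
    total_pow <- matrix(exp(rnorm(n * config$blocks * 2,
                                  log(1100), 0.25)), n)
    beat_seeds <- array(sample.int(.Machine$integer.max - 1L,
                                   n * config$blocks * 2),
                        c(n, config$blocks, 2))
    f_net <- rnorm(n)
    roi_eps <- matrix(rnorm(n * length(.roi_regions)), n,
                      dimnames = list(NULL, .roi_regions))

    # --- behavior ---------------------------------------------------------
    theta <- clamp(config$entropy_mean[[cond]] + config$entropy_sd * z,
                   0.05, 0.995)
    cfg <- task_config(cond, trials_per_block = config$trials_per_block,
                       blocks = config$blocks)
    ntr <- config$trials_per_block
    nb <- config$blocks
    ch_all <- integer(n * nb * ntr)
    out_all <- integer(n * nb * ntr)
    side_all <- character(n * nb * ntr)
    ent_hat <- numeric(n)
    for (i in seq_len(n)) {
      ps <- invert_expected_entropy(theta[i])
      ag <- agent_outcome_conditioned(ps[["p_stay_gain"]],
                                      ps[["p_stay_loss"]])
      set.seed(trial_seeds[i]) # same stream as run_session(ag, cfg, seed)
      hsum <- 0
      for (b in seq_len(nb)) {
        sim <- simulate_block(ag, cfg)
        at <- (i - 1) * nb * ntr + (b - 1) * ntr + seq_len(ntr)
        ch_all[at] <- sim$choice
        out_all[at] <- sim$outcome
        side_all[at] <- sim$side
        hsum <- hsum + block_entropy_int(sim$choice, sim$outcome)
      }
      ent_hat[i] <- hsum / nb
    }
    all_trials[[length(all_trials) + 1]] <- tibble(
      subject_id = rep(subjects, each = nb * ntr),
      condition = cond,
      block = rep(rep(seq_len(nb) - 1L, each = ntr), n),
      trial = rep(seq_len(ntr) - 1L, n * nb),
      choice = c("none", .choices)[ch_all + 1L],
      outcome = .outcomes[2L - out_all],
      side_adv = side_all)
    s_std <- as.numeric(scale(ent_hat))

    # --- norepinephrine change coupled to realized entropy ----------------
    ne_delta <- config$ne_delta_mean[[cond]] + config$ne_delta_sd *
      (rho * s_std + sqrt(1 - rho^2) * eps_ne)
    d_std <- as.numeric(scale(ne_delta))

    # --- autonomic panels -------------------------------------------------
    # each variable as an n x blocks baseline matrix + task matrix; long
    # format assembled once per condition
    nb <- config$blocks
    pv_list <- list()
    # norepinephrine: task block jitter centered within subject so the
    # measured change score equals ne_delta exactly
    ne_base_mat <- ne_base + ne_base_jit
    eta <- ne_task_jit - rowMeans(ne_task_jit)
    pv_list[["norepinephrine"]] <-
      list(base = ne_base_mat, task = ne_base_mat + ne_delta + eta)
    for (v in seq_len(nrow(panel_vars))) {
      pv <- panel_vars[v, ]
      base_lvl <- pv$base_mean + pv$base_sd * pv_base[, v]
      delta <- pv$delta_mean + pv$delta_sd * pv_delta[, v]
      pv_list[[pv$variable]] <- list(
        base = base_lvl + pv$block_sd * pv_jit[, v, , 1],
        task = base_lvl + delta + pv$block_sd * pv_jit[, v, , 2])
    }
    pv_list[["hf_pct"]] <- list(base = hf_base, task = hf_task)
    pv_list[["lf_hf"]] <- list(base = (100 - hf_base) / hf_base,
                               task = (100 - hf_task) / hf_task)
    hr_mat <- pv_list[["hr"]]
    all_panels[[length(all_panels) + 1]] <- tibble(
      subject_id = rep(rep(subjects, times = nb), times = 2 * length(pv_list)),
      condition = cond,
      block = rep(rep(seq_len(nb) - 1L, each = n),
                  times = 2 * length(pv_list)),
      period = rep(rep(c("baseline", "task"), each = n * nb),
                   times = length(pv_list)),
      variable = rep(names(pv_list), each = 2 * n * nb),
      value = unlist(lapply(pv_list, function(m)
        c(as.vector(m$base), as.vector(m$task))), use.names = FALSE))

    # --- interbeat-interval series ---------------------------------------
    if (include_beats) {
      for (i in seq_len(n)) {
        for (b in seq_len(config$blocks)) {
          for (pidx in 1:2) {
            period <- c("baseline", "task")[pidx]
            hf_pct <- if (pidx == 1) hf_base[i, b] else hf_task[i, b]
            tp <- total_pow[i, (b - 1) * 2 + pidx]
            hr_val <- if (pidx == 1) hr_mat$base[i, b] else hr_mat$task[i, b]
            dur <- if (pidx == 1) config$baseline_duration_s else
              config$task_duration_s
            set.seed(beat_seeds[i, b, pidx])
            bt <- synth_beat_series(
              dur, lf_power = tp * (1 - hf_pct / 100),
              hf_power = tp * hf_pct / 100,
              mean_ibi_ms = 60000 / hr_val, noise_sd = 2)
            all_beats[[length(all_beats) + 1]] <- tibble(
              subject_id = subjects[i], condition = cond, block = b - 1L,
              period = period, beat_time_s = bt)
          }
        }
      }
    }

    # --- ROI table --------------------------------------------------------
    if (include_roi) {
      loads <- config$roi_structure %>% filter(.data$condition == cond)
      for (rg in .roi_regions) {
        ld <- loads %>% filter(.data$roi == rg)
        bs <- if (nrow(ld)) ld$b_entropy else 0
        bd <- if (nrow(ld)) ld$b_ne else 0
        bw <- if (nrow(ld)) ld$b_network else 0
        sys_var <- bs^2 + bd^2 + 2 * bs * bd * rho + bw^2
        resid <- sqrt(max(0, 1 - sys_var))
        val <- bs * s_std + bd * d_std + bw * f_net + resid * roi_eps[, rg]
        all_roi[[length(all_roi) + 1]] <- tibble(
          subject_id = subjects, condition = cond, roi = rg,
          value = 50 + 5 * val)
      }
    }

    all_latent[[length(all_latent) + 1]] <- tibble(
      subject_id = subjects, condition = cond, z = z, theta = theta,
      p_stay_gain = vapply(theta, function(t)
        invert_expected_entropy(t)[["p_stay_gain"]], numeric(1)),
      entropy_measured = ent_hat, ne_delta = ne_delta)
  }

  structure(list(
    trials = dplyr::bind_rows(all_trials) %>%
      select("subject_id", dplyr::everything()),
    panels = dplyr::bind_rows(all_panels),
    beats = if (include_beats) dplyr::bind_rows(all_beats) else NULL,
    roi = if (include_roi) dplyr::bind_rows(all_roi) else NULL,
    latent = dplyr::bind_rows(all_latent),
    config = config, seed = seed
  ), class = "expl_cohort")
}

#' @export
print.expl_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic cohort: %d subjects, conditions: %s, seed %s>\n",
    x$config$n_subjects,
    paste(unique(x$latent$condition), collapse = ", "),
    format(x$seed)))
  cat(sprintf("  trials: %d rows; panels: %d rows; beats: %s; roi: %s\n",
              nrow(x$trials), nrow(x$panels),
              if (is.null(x$beats)) "none" else paste(nrow(x$beats), "rows"),
              if (is.null(x$roi)) "none" else paste(nrow(x$roi), "rows")))
  invisible(x)
}
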