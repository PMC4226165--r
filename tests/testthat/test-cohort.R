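test_that("entropy inversion round-trips through the closed form", {
  expect_equal(invert_expected_entropy(1),
               c(p_stay_gain = 0.5, p_stay_loss = 0.5))
  expect_equal(invert_expected_entropy(0.9182958)[["p_stay_gain"]], 2 / 3,
               tolerance = 1e-6)
  set.seed(9)
  for (theta in runif(100, 0.01, 1)) {
    ps <- invert_expected_entropy(theta)
    ag <- agent_outcome_conditioned(ps[["p_stay_gain"]],
                                    ps[["p_stay_loss"]])
    expect_lt(abs(expected_entropy(ag) - theta), 1e-9)
    expect_gte(ps[["p_stay_gain"]], 0.5)
    expect_equal(ps[["p_stay_loss"]], 1 - ps[["p_stay_gain"]])
  }
  expect_error(invert_expected_entropy(0), "\\(0, 1\\]")
  expect_error(invert_expected_entropy(1.2), "\\(0, 1\\]")
})

test_that("cohorts are deterministic in the master seed", {
  cfg <- cohort_config(n_subjects = 6)
  a <- sample_cohort(cfg, seed = 77, conditions = "contingent",
                     include_beats = FALSE)
  b <- sample_cohort(cfg, seed = 77, conditions = "contingent",
                     include_beats = FALSE)
  expect_identical(a$trials, b$trials)
  expect_identical(a$panels, b$panels)
  expect_identical(a$roi, b$roi)
  d <- sample_cohort(cfg, seed = 78, conditions = "contingent",
                     include_beats = FALSE)
  expect_false(identical(a$trials, d$trials))
})

test_that("the generated change score equals the stored latent NE delta", {
  coh <- sample_cohort(cohort_config(n_subjects = 8), seed = 5,
                       include_beats = FALSE)
  ch <- change_scores(dplyr::filter(coh$panels,
                                    variable == "norepinephrine"))
  merged <- dplyr::left_join(ch, coh$latent,
                             by = c("subject_id", "condition"))
  expect_equal(merged$delta, merged$ne_delta, tolerance = 1e-9)
})

test_that("measured entropy tracks the latent target", {
  # long blocks make the block statistic converge onto theta
  thetas <- c(0.3, 0.5, 0.7, 0.85, 0.95)
  hhat <- vapply(seq_along(thetas), function(i) {
    ps <- invert_expected_entropy(thetas[i])
    tr <- run_session(agent_outcome_conditioned(ps[[1]], ps[[2]]),
                      task_config("contingent", trials_per_block = 10000,
                                  blocks = 1), seed = 100 + i)
    entropy(tr)
  }, numeric(1))
  slope <- coef(lm(hhat ~ thetas))[["thetas"]]
  expect_lt(abs(slope - 1), 0.1)
  expect_lt(max(abs(hhat - thetas)), 0.03)
})

test_that("a maximally exploratory subject gets the uniform policy", {
  ps <- invert_expected_entropy(1)
  expect_equal(unname(ps), c(0.5, 0.5))
  tr <- run_session(agent_outcome_conditioned(0.5, 0.5),
                    task_config("contingent", trials_per_block = 20000,
                                blocks = 1), seed = 55)
  expect_equal(entropy(tr), 1, tolerance = 0.01)
})

test_that("cohort tables carry the documented schema and latent truth", {
  coh <- sample_cohort(cohort_config(n_subjects = 5), seed = 12)
  expect_setequal(names(coh$trials),
                  c("subject_id", "condition", "block", "trial", "choice",
                    "outcome", "side_adv"))
  expect_setequal(unique(coh$trials$condition), c("contingent", "random"))
  expect_equal(nrow(coh$trials), 5 * 2 * 3 * 40)
  expect_setequal(names(coh$panels),
                  c("subject_id", "condition", "block", "period",
                    "variable", "value"))
  expect_setequal(unique(coh$panels$variable),
                  c("mbp", "hr", "tpr", "epinephrine", "norepinephrine",
                    "hf_pct", "lf_hf"))
  expect_true(all(c("z", "theta", "p_stay_gain", "entropy_measured",
                    "ne_delta") %in% names(coh$latent)))
  expect_false(is.null(coh$beats))
  # beat series are valid strictly increasing recordings
  one <- dplyr::filter(coh$beats, subject_id == "S01",
                       condition == "contingent", block == 0,
                       period == "task")
  expect_true(all(diff(one$beat_time_s) > 0))
  expect_gt(max(one$beat_time_s), 200)
})

test_that("generated HRV content lands near the configured HF percentage", {
  coh <- sample_cohort(cohort_config(n_subjects = 4), seed = 21,
                       conditions = "random")
  bs <- dplyr::filter(coh$beats, subject_id == "S01", block == 0)
  est <- hrv_table(bs)
  pan <- dplyr::filter(coh$panels, subject_id == "S01", block == 0,
                       variable == "hf_pct")
  merged <- dplyr::left_join(est, pan,
                             by = c("subject_id", "condition", "block",
                                    "period"))
  expect_lt(max(abs(merged$hf_pct - merged$value)), 8)
})
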