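test_that("identical seeds yield identical logs", {
  cfg <- task_config("contingent")
  a <- agent_outcome_conditioned(0.7, 0.4, lapse = 0.05)
  expect_identical(run_session(a, cfg, seed = 42),
                   run_session(a, cfg, seed = 42))
  ctl <- task_config("control")
  expect_identical(control_session(ctl, seed = 9),
                   control_session(ctl, seed = 9))
  expect_false(identical(run_session(a, cfg, seed = 42),
                         run_session(a, cfg, seed = 43)))
})

test_that("outcome frequencies follow the configured contingencies", {
  # constant-advantageous agent under 70/30: gain fraction ~ 0.70
  trials <- run_session(agent_constant("adv"),
                        task_config("contingent", trials_per_block = 10000,
                                    blocks = 1), seed = 1)
  se <- sqrt(0.7 * 0.3 / 10000)
  expect_lt(abs(mean(trials$outcome == "gain") - 0.70), 3 * se)

  # any policy under 50/50: gain fraction ~ 0.50
  trials <- run_session(agent_wsls(), task_config("random",
                                                  trials_per_block = 10000,
                                                  blocks = 1), seed = 2)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(trials$outcome == "gain") - 0.50), 3 * se)

  # per-stimulus outcome distributions pass a goodness-of-fit check
  trials <- run_session(agent_outcome_conditioned(0.6, 0.4),
                        task_config("contingent", trials_per_block = 10000,
                                    blocks = 1), seed = 3)
  for (ch in c("adv", "disadv")) {
    p <- if (ch == "adv") 0.7 else 0.3
    sub <- trials[trials$choice == ch, ]
    gof <- stats::chisq.test(table(factor(sub$outcome,
                                          c("gain", "loss"))),
                             p = c(p, 1 - p))
    expect_gt(gof$p.value, 0.01)
  }
})

test_that("exact-count schedules deliver exact gain counts", {
  trials <- run_session(agent_constant("adv"),
                        task_config("contingent", trials_per_block = 40,
                                    blocks = 1,
                                    schedule_mode = "exact_count"),
                        seed = 5)
  expect_identical(sum(trials$outcome == "gain"), 28L) # 0.70 * 40
  trials <- run_session(agent_constant("disadv"),
                        task_config("contingent", trials_per_block = 40,
                                    blocks = 1,
                                    schedule_mode = "exact_count"),
                        seed = 5)
  expect_identical(sum(trials$outcome == "gain"), 12L)
})

test_that("control sessions are computer-driven and outcome-balanced", {
  cfg <- task_config("control", trials_per_block = 10000, blocks = 1)
  trials <- control_session(cfg, seed = 4)
  expect_equal(nrow(trials), 10000)
  expect_true(all(trials$choice != "none"))
  # uniform computer choice under 70/30: 0.5*0.7 + 0.5*0.3 = 0.5
  expect_lt(abs(mean(trials$outcome == "gain") - 0.5), 3 * sqrt(0.25 / 1e4))
  # block structure intact at default sizes
  small <- control_session(task_config("control"), seed = 4)
  expect_equal(unname(table(small$block)), rep(40L, 3), ignore_attr = TRUE)
  expect_error(control_session(task_config("contingent"), seed = 1),
               "control")
})

test_that("lapses produce timeout losses and are skipped by the agent", {
  trials <- run_session(agent_outcome_conditioned(0.9, 0.1, lapse = 0.2),
                        task_config("contingent", trials_per_block = 2000,
                                    blocks = 1), seed = 6)
  lapsed <- trials$choice == "none"
  expect_gt(mean(lapsed), 0.1)
  expect_true(all(trials$outcome[lapsed] == "loss"))
})

test_that("relabeling the advantageous stimulus leaves Stay/Shift statistics unchanged", {
  trials <- run_session(agent_outcome_conditioned(0.7, 0.3),
                        task_config("contingent", trials_per_block = 200,
                                    blocks = 1), seed = 8)
  swapped <- trials
  swapped$choice <- c(adv = "disadv", disadv = "adv",
                      none = "none")[trials$choice]
  expect_identical(count_transitions(trials)$num,
                   count_transitions(swapped)$num)
  expect_equal(entropy(trials), entropy(swapped))
})

test_that("invalid configurations are rejected", {
  expect_error(task_config("contingent", p_gain_adv = 0.8,
                           p_gain_dis = 0.3), "p_gain_adv \\+ p_gain_dis")
  expect_error(task_config("random", p_gain_adv = 0.7, p_gain_dis = 0.3),
               "0.5")
  expect_error(task_config("contingent", trials_per_block = 1),
               "trials_per_block")
  expect_error(task_config("bernoulli"), "arg")
})
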