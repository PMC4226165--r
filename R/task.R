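#' Configure the two-option stochastic decision-making task
#'
#' Builds the task description used by [run_session()] and
#' [control_session()]. The `"contingent"` preset links the advantageous
#' stimulus with gain at probability 0.70 (loss 0.30) and the disadvantageous
#' stimulus with the reversed probabilities; the `"random"` preset links both
#' stimuli with gain at 0.50. In the `"control"` condition the computer makes
#' the choice on every trial. Each gain or loss is worth `stake` JPY and a
#' timeout counts as a loss.
#'
#' `schedule_mode = "bernoulli"` draws each outcome i.i.d. at choice time
#' with the chosen stimulus's gain probability; `"exact_count"` pre-permutes,
#' per stimulus and block, a schedule containing exactly
#' `round(p * trials_per_block)` gains, consumed in order as that stimulus is
#' chosen.
#'
#' @param condition `"contingent"`, `"random"` or `"control"`.
#' @param p_gain_adv,p_gain_dis Gain probabilities of the two stimuli;
#'   defaults follow the condition preset (control uses the 70/30 mapping
#'   unless overridden).
#' @param trials_per_block Trials per block (>= 2; default 40).
#' @param blocks Number of blocks (default 3).
#' @param stake Money at stake per trial, JPY (default 100).
#' @param timeout_is_loss Logical; a missed response loses the stake
#'   (default `TRUE`).
#' @param schedule_mode `"bernoulli"` or `"exact_count"`.
#' @return A list of class `expl_task_config`.
#' @examples
#' task_config("contingent")
#' task_config("random", blocks = 1, trials_per_block = 100)
#' @export
task_config <- function(condition = c("contingent", "random", "control"),
                        p_gain_adv = NULL, p_gain_dis = NULL,
                        trials_per_block = 40, blocks = 3, stake = 100,
                        timeout_is_loss = TRUE,
                        schedule_mode = c("bernoulli", "exact_count")) {
  condition <- match.arg(condition)
  schedule_mode <- match.arg(schedule_mode)
  defaults <- switch(condition,
    contingent = c(0.70, 0.30),
    random = c(0.50, 0.50),
    control = c(0.70, 0.30)
  )
  p_gain_adv <- p_gain_adv %||% defaults[[1]]
  p_gain_dis <- p_gain_dis %||% defaults[[2]]
  if (p_gain_adv < 0 || p_gain_adv > 1 || p_gain_dis < 0 || p_gain_dis > 1) {
    abort("gain probabilities must lie in [0, 1]")
  }
  if (condition == "contingent" &&
      abs(p_gain_adv + p_gain_dis - 1) > 1e-12) {
    abort("contingent condition requires p_gain_adv + p_gain_dis = 1")
  }
  if (condition == "random" &&
      (p_gain_adv != 0.5 || p_gain_dis != 0.5)) {
    abort("random condition requires both gain probabilities equal to 0.5")
  }
  if (trials_per_block < 2) {
    abort("`trials_per_block` must be >= 2 (entropy needs a transition)")
  }
  if (blocks < 1) abort("`blocks` must be >= 1")
  structure(list(condition = condition, p_gain_adv = p_gain_adv,
                 p_gain_dis = p_gain_dis, trials_per_block = trials_per_block,
                 blocks = blocks, stake = stake,
                 timeout_is_loss = timeout_is_loss,
                 schedule_mode = schedule_mode),
            class = "expl_task_config")
}

#' @export
print.expl_task_config <- function(x, ...) {
  cat(sprintf(
    "<task %s: P(gain|adv)=%.2f P(gain|dis)=%.2f, %d blocks x %d trials, %s>\n",
    x$condition, x$p_gain_adv, x$p_gain_dis, x$blocks, x$trials_per_block,
    x$schedule_mode))
  invisible(x)
}

# exact-count outcome schedule for one stimulus: 1 = gain, 0 = loss
make_exact_schedule <- function(p, n) {
  gains <- round(p * n)
  sample(c(rep(1L, gains), rep(0L, n - gains)))
}

# Core per-block simulator. Choices coded 1 = adv, 2 = disadv, 0 = none.
# `agent` may be NULL (control condition: uniform computer choice, no lapse).
simulate_block <- function(agent, config) {
  n <- config$trials_per_block
  p_gain <- c(config$p_gain_adv, config$p_gain_dis)
  choice <- integer(n)
  outcome <- integer(n) # 1 = gain, 0 = loss
  side <- sample(c("L", "R"), n, replace = TRUE)

  exact <- config$schedule_mode == "exact_count"
  if (exact) {
    sched <- list(make_exact_schedule(p_gain[[1]], n),
                  make_exact_schedule(p_gain[[2]], n))
    used <- c(0L, 0L)
  }
  draw_outcome <- function(ch) {
    if (exact) {
      used[[ch]] <<- used[[ch]] + 1L
      sched[[ch]][[used[[ch]]]]
    } else {
      as.integer(runif(1) < p_gain[[ch]])
    }
  }

  if (is.null(agent)) { # control: computer picks uniformly, never times out
    choice <- sample(1:2, n, replace = TRUE)
    for (t in seq_len(n)) outcome[[t]] <- draw_outcome(choice[[t]])
  } else {
    kind <- agent$kind
    pp <- agent$params
    lapse <- agent$lapse
    st <- agent_init_state(agent)
    const_stim <- if (kind == "constant" && !is.null(pp$stimulus)) {
      match(pp$stimulus, .choices)
    } else NULL
    prev_ch <- 0L
    prev_out <- NA_integer_
    for (t in seq_len(n)) {
      if (lapse > 0 && runif(1) < lapse) {
        choice[[t]] <- 0L
        outcome[[t]] <- 0L # timeout is a loss
        prev_ch <- 0L
        next
      }
      ch <- if (kind == "biased_random") {
        if (runif(1) < pp$p_adv) 1L else 2L
      } else if (kind == "constant") {
        if (is.null(const_stim)) const_stim <- sample(1:2, 1)
        const_stim
      } else if (kind == "q_softmax") {
        pr_adv <- 1 / (1 + exp(-pp$beta * (st$q[[1]] - st$q[[2]])))
        if (runif(1) < pr_adv) 1L else 2L
      } else if (prev_ch == 0L) { # first trial / after timeout
        sample(1:2, 1)
      } else if (kind == "wsls") {
        rule <- if (prev_out == 1L) prev_ch else 3L - prev_ch
        if (runif(1) < pp$p_execute) rule else 3L - rule
      } else { # outcome_conditioned
        ps <- if (prev_out == 1L) pp$p_stay_gain else pp$p_stay_loss
        if (runif(1) < ps) prev_ch else 3L - prev_ch
      }
      out <- draw_outcome(ch)
      if (kind == "q_softmax") {
        r <- if (out == 1L) 1 else -1
        st$q[[ch]] <- st$q[[ch]] + pp$alpha * (r - st$q[[ch]])
      }
      choice[[t]] <- ch
      outcome[[t]] <- out
      prev_ch <- ch
      prev_out <- out
    }
  }
  list(choice = choice, outcome = outcome, side = side)
}

block_to_tibble <- function(sim, block_index) {
  tibble(
    block = block_index,
    trial = seq_along(sim$choice) - 1L,
    choice = c("none", .choices)[sim$choice + 1L],
    outcome = .outcomes[2L - sim$outcome],
    side_adv = sim$side
  )
}

#' Simulate a session of the decision-making task
#'
#' Runs `config$blocks` blocks of `config$trials_per_block` trials with the
#' given agent. Outcomes are drawn per chosen stimulus with that stimulus's
#' gain probability (or consumed from a pre-permuted exact-count schedule;
#' see [task_config()]). The screen side of the advantageous stimulus is
#' randomized independently each trial. Identical `(agent, config, seed)`
#' triples yield identical logs.
#'
#' @param agent An [agents] object (or a spec string for [parse_agent()]).
#' @param config An `expl_task_config`.
#' @param seed Integer seed.
#' @return A tibble with columns `block`, `trial` (both 0-based), `choice`
#'   (`"adv"`, `"disadv"`, `"none"`), `outcome` (`"gain"`, `"loss"`) and
#'   `side_adv` (`"L"`, `"R"`), plus a `condition` column.
#' @examples
#' trials <- run_session(agent_wsls(), task_config("contingent"), seed = 1)
#' dplyr::count(trials, outcome)
#' @export
run_session <- function(agent, config, seed) {
  if (is.character(agent)) agent <- parse_agent(agent)
  stopifnot(inherits(agent, "expl_agent"),
            inherits(config, "expl_task_config"))
  if (config$condition == "control") {
    abort("use control_session() for the control condition")
  }
  set.seed(as.integer(seed))
  out <- purrr::map(seq_len(config$blocks) - 1L, function(b) {
    block_to_tibble(simulate_block(agent, config), b)
  })
  dplyr::bind_rows(out) %>%
    mutate(condition = config$condition, .before = 1)
}

#' Simulate a control-condition session
#'
#' Same trial structure and logging as [run_session()], but the computer
#' makes a uniform random choice on every trial (participants only execute
#' it), so no trial ever times out and the policy is outcome-independent.
#'
#' @param config An `expl_task_config` with `condition = "control"`.
#' @param seed Integer seed.
#' @return A trial tibble as in [run_session()].
#' @export
control_session <- function(config, seed) {
  stopifnot(inherits(config, "expl_task_config"))
  if (config$condition != "control") {
    abort("control_session() requires condition = 'control'")
  }
  set.seed(as.integer(seed))
  out <- purrr::map(seq_len(config$blocks) - 1L, function(b) {
    block_to_tibble(simulate_block(NULL, config), b)
  })
  dplyr::bind_rows(out) %>%
    mutate(condition = "control", .before = 1)
}
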