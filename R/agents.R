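#' Generative choice policies for the two-option task
#'
#' Constructors for the behavioral policies used to exercise the entropy
#' statistic and to build synthetic cohorts. All agents choose between the
#' `"adv"` (advantageous) and `"disadv"` (disadvantageous) stimulus; an
#' optional lapse probability produces `"none"` (timeout) trials.
#'
#' * `agent_constant()` picks a stimulus on the first trial (uniformly, unless
#'   `stimulus` is given) and repeats it forever, regardless of outcome.
#' * `agent_biased_random()` chooses the advantageous stimulus with fixed
#'   probability `p_adv`, independently across trials.
#' * `agent_wsls()` is Win-Stay/Lose-Shift: after a gain it repeats the
#'   previous choice, after a loss it switches, each rule executed with
#'   probability `p_execute` (the opposite action otherwise).
#' * `agent_outcome_conditioned()` stays with probability `p_stay_gain` after
#'   a gain and `p_stay_loss` after a loss.
#' * `agent_q_softmax()` is a two-armed Rescorla-Wagner learner
#'   (`Q <- Q + alpha * (r - Q)`, rewards coded +1/-1, action values start at
#'   0) with softmax choice of sharpness `beta` (the "inverse temperature").
#'
#' On the first trial of a session (and on the trial after a timeout) no
#' previous choice/outcome is available and every agent chooses uniformly,
#' except `q_softmax`, which always chooses by softmax over its current
#' action values.
#'
#' @param stimulus Optional fixed stimulus (`"adv"` or `"disadv"`) for the
#'   constant agent; default `NULL` picks uniformly on the first trial.
#' @param p_adv Probability of choosing the advantageous stimulus.
#' @param p_execute Probability of executing the Win-Stay/Lose-Shift rule.
#' @param p_stay_gain,p_stay_loss Stay probabilities after a gain / a loss.
#' @param alpha Learning rate in (0, 1].
#' @param beta Inverse temperature, >= 0.
#' @param lapse Probability of a timeout (`"none"` choice) on any trial.
#' @return An object of class `expl_agent`.
#' @examples
#' a <- agent_wsls(p_execute = 1)
#' act(a, prev_choice = "adv", prev_outcome = "gain")$choice  # "adv"
#' expected_entropy(agent_outcome_conditioned(0.5, 0.5))      # 1
#' @name agents
NULL

new_agent <- function(kind, params, lapse) {
  probs <- unlist(params[names(params) != "beta"])
  probs <- probs[vapply(probs, is.numeric, logical(1))]
  if (kind != "q_softmax" && length(probs) &&
      any(probs < 0 | probs > 1)) {
    abort("agent probability parameters must lie in [0, 1]")
  }
  if (lapse < 0 || lapse > 1) abort("`lapse` must lie in [0, 1]")
  structure(list(kind = kind, params = params, lapse = lapse),
            class = "expl_agent")
}

#' @rdname agents
#' @export
agent_constant <- function(stimulus = NULL, lapse = 0) {
  if (!is.null(stimulus)) stimulus <- match.arg(stimulus, .choices)
  new_agent("constant", list(stimulus = stimulus), lapse)
}

#' @rdname agents
#' @export
agent_biased_random <- function(p_adv = 0.5, lapse = 0) {
  new_agent("biased_random", list(p_adv = p_adv), lapse)
}

#' @rdname agents
#' @export
agent_wsls <- function(p_execute = 1, lapse = 0) {
  new_agent("wsls", list(p_execute = p_execute), lapse)
}

#' @rdname agents
#' @export
agent_outcome_conditioned <- function(p_stay_gain, p_stay_loss, lapse = 0) {
  new_agent("outcome_conditioned",
            list(p_stay_gain = p_stay_gain, p_stay_loss = p_stay_loss), lapse)
}

#' @rdname agents
#' @export
agent_q_softmax <- function(alpha = 0.3, beta = 5, lapse = 0) {
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1]")
  if (beta < 0) abort("`beta` must be >= 0")
  new_agent("q_softmax", list(alpha = alpha, beta = beta), lapse)
}

#' @export
print.expl_agent <- function(x, ...) {
  ps <- paste(names(x$params), unlist(x$params) %||% "?", sep = "=",
              collapse = ", ")
  cat(sprintf("<expl_agent %s(%s) lapse=%g>\n", x$kind, ps, x$lapse))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse an agent specification string
#'
#' Turns a compact textual spec such as `"wsls:p_execute=0.9"`,
#' `"ocond:psg=0.8,psl=0.3"`, `"qsoftmax:alpha=0.3,beta=5"`,
#' `"brand:p_adv=0.7"` or `"constant"` into an [agents] object. Useful for
#' scripted runs and run manifests.
#'
#' @param spec Character scalar.
#' @return An `expl_agent`.
#' @export
parse_agent <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1)
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  kind <- parts[[1]]
  kv <- list()
  if (length(parts) > 1) {
    for (tok in strsplit(parts[[2]], ",", fixed = TRUE)[[1]]) {
      eq <- strsplit(tok, "=", fixed = TRUE)[[1]]
      kv[[eq[[1]]]] <- as.numeric(eq[[2]])
    }
  }
  lapse <- kv[["lapse"]] %||% 0
  switch(kind,
    constant = agent_constant(lapse = lapse),
    brand = ,
    biased_random = agent_biased_random(kv[["p_adv"]] %||% 0.5, lapse),
    wsls = agent_wsls(kv[["p_execute"]] %||% 1, lapse),
    ocond = ,
    outcome_conditioned = agent_outcome_conditioned(
      kv[["psg"]] %||% kv[["p_stay_gain"]],
      kv[["psl"]] %||% kv[["p_stay_loss"]], lapse),
    qsoftmax = ,
    q_softmax = agent_q_softmax(kv[["alpha"]] %||% 0.3,
                                kv[["beta"]] %||% 5, lapse),
    abort(sprintf("unknown agent kind '%s'", kind))
  )
}

# fresh per-session mutable state for an agent
agent_init_state <- function(agent) {
  switch(agent$kind,
    q_softmax = list(q = c(adv = 0, disadv = 0)),
    constant = list(stimulus = agent$params$stimulus),
    list()
  )
}

#' Draw one choice from an agent
#'
#' Single-step interface to the policies in [agents]. Uses R's global random
#' number stream; call `set.seed()` for reproducibility. `prev_choice` and
#' `prev_outcome` are `NULL` (or `"none"`) on the first trial and after a
#' timeout.
#'
#' @param agent An `expl_agent`.
#' @param prev_choice Previous choice (`"adv"`, `"disadv"`, `"none"` or
#'   `NULL`).
#' @param prev_outcome Previous outcome (`"gain"`, `"loss"` or `NULL`).
#' @param state Agent state as returned by a previous `act()` call; `NULL`
#'   initializes a fresh state.
#' @return A list with elements `choice` and `state`.
#' @export
act <- function(agent, prev_choice = NULL, prev_outcome = NULL, state = NULL) {
  stopifnot(inherits(agent, "expl_agent"))
  if (is.null(state)) state <- agent_init_state(agent)
  if (!is.null(prev_choice) && identical(prev_choice, "none")) {
    prev_choice <- NULL
    prev_outcome <- NULL
  }
  if (agent$lapse > 0 && runif(1) < agent$lapse) {
    return(list(choice = "none", state = state))
  }
  choice <- agent_choose(agent, state, prev_choice, prev_outcome)
  if (agent$kind == "constant" && is.null(state$stimulus)) {
    state$stimulus <- choice
  }
  list(choice = choice, state = state)
}

agent_choose <- function(agent, state, prev_choice, prev_outcome) {
  p <- agent$params
  other <- function(ch) if (ch == "adv") "disadv" else "adv"
  switch(agent$kind,
    constant = {
      if (!is.null(state$stimulus)) state$stimulus
      else sample(.choices, 1)
    },
    biased_random = if (runif(1) < p$p_adv) "adv" else "disadv",
    wsls = {
      if (is.null(prev_choice)) sample(.choices, 1)
      else {
        rule <- if (prev_outcome == "gain") prev_choice else other(prev_choice)
        if (runif(1) < p$p_execute) rule else other(rule)
      }
    },
    outcome_conditioned = {
      if (is.null(prev_choice)) sample(.choices, 1)
      else {
        ps <- if (prev_outcome == "gain") p$p_stay_gain else p$p_stay_loss
        if (runif(1) < ps) prev_choice else other(prev_choice)
      }
    },
    q_softmax = {
      pr <- softmax2(p$beta * state$q)
      if (runif(1) < pr[["adv"]]) "adv" else "disadv"
    },
    abort(sprintf("unknown agent kind '%s'", agent$kind))
  )
}

softmax2 <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# learning update after an observed (choice, outcome); no-op except q_softmax
agent_update <- function(agent, state, choice, outcome) {
  if (agent$kind == "q_softmax" && choice != "none") {
    r <- if (outcome == "gain") 1 else -1
    a <- agent$params$alpha
    state$q[[choice]] <- state$q[[choice]] + a * (r - state$q[[choice]])
  }
  state
}

#' Binary Shannon entropy (bits)
#'
#' `h(p) = -p log2 p - (1 - p) log2(1 - p)`, with the `0 log 0 = 0`
#' convention.
#'
#' @param p Probability vector.
#' @return Entropy in bits, same length as `p`.
#' @export
binary_entropy <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Asymptotic normalized entropy of a stationary policy
#'
#' Closed-form value that the block-estimated conditional entropy
#' ([entropy]) converges to as the number of trials grows: the mean of the
#' binary entropies of the stay probability after a gain and after a loss.
#' Available for agents with stationary conditional stay probabilities
#' (`constant`, `biased_random`, `wsls`, `outcome_conditioned`); the
#' Q-learning softmax agent has no stationary closed form and raises an
#' error (estimate by simulation instead).
#'
#' @param agent An `expl_agent`.
#' @return Normalized entropy in `[0, 1]`.
#' @export
expected_entropy <- function(agent) {
  stopifnot(inherits(agent, "expl_agent"))
  p <- agent$params
  switch(agent$kind,
    constant = 0,
    wsls = {
      # stay prob = p_execute after gain, 1 - p_execute after loss
      (binary_entropy(p$p_execute) + binary_entropy(1 - p$p_execute)) / 2
    },
    outcome_conditioned =
      (binary_entropy(p$p_stay_gain) + binary_entropy(p$p_stay_loss)) / 2,
    biased_random = {
      # i.i.d. choice: P(stay) = p^2 + (1-p)^2 in both states
      q <- p$p_adv^2 + (1 - p$p_adv)^2
      binary_entropy(q)
    },
    q_softmax = abort(
      "expected_entropy() has no closed form for q_softmax agents; estimate by simulation"),
    abort(sprintf("unknown agent kind '%s'", agent$kind))
  )
}
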