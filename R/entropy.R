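#' Count Stay/Shift transitions conditioned on the previous outcome
#'
#' Tabulates, over one ordered block of trials, how often the choice on
#' trial *t* repeated (`Stay`) or switched from (`Shift`) the choice on
#' trial *t - 1*, split by the outcome of trial *t - 1* (the state:
#' `gain` or `loss`). Stay/Shift is defined by stimulus identity, never by
#' screen side. A transition contributes only when both of its trials were
#' responded to: timeout (`"none"`) trials break the chain, dropping both
#' the transition into and out of them. The first trial of a block
#' contributes no transition.
#'
#' @param trials A data frame of ordered trials for a single block, with
#'   columns `choice` (`"adv"`/`"disadv"`/`"none"`) and `outcome`
#'   (`"gain"`/`"loss"`).
#' @param c Smoothing constant carried into [conditional_policy()]
#'   (default 1).
#' @return An object of class `stay_shift_counts`: a 2 x 2 integer matrix
#'   `num` (rows `stay`/`shift`, columns `gain`/`loss`) with the smoothing
#'   constant and transition count attached.
#' @examples
#' tr <- tibble::tibble(
#'   choice  = c("adv", "adv", "disadv", "disadv", "adv"),
#'   outcome = c("gain", "loss", "loss", "gain", "gain")
#' )
#' count_transitions(tr)
#' @export
count_transitions <- function(trials, c = 1) {
  stopifnot(is.data.frame(trials), c >= 0)
  num <- matrix(0L, 2, 2, dimnames = list(c("stay", "shift"),
                                          c("gain", "loss")))
  ch <- as.character(trials$choice)
  out <- as.character(trials$outcome)
  n <- length(ch)
  if (n >= 2) {
    prev <- ch[-n]
    curr <- ch[-1]
    valid <- prev != "none" & curr != "none"
    if (any(valid)) {
      stay <- prev[valid] == curr[valid]
      state <- out[-n][valid]
      num["stay", "gain"] <- sum(stay & state == "gain")
      num["shift", "gain"] <- sum(!stay & state == "gain")
      num["stay", "loss"] <- sum(stay & state == "loss")
      num["shift", "loss"] <- sum(!stay & state == "loss")
    }
  }
  structure(list(num = num, c = c, n_transitions = sum(num)),
            class = "stay_shift_counts")
}

#' @export
print.stay_shift_counts <- function(x, ...) {
  cat(sprintf("<stay_shift_counts: %d transitions, c = %g>\n",
              x$n_transitions, x$c))
  print(x$num)
  invisible(x)
}

#' Smoothed conditional Stay/Shift policy
#'
#' Converts transition counts into the smoothed conditional probabilities
#' `P(a | S) = (Num(a | S) + c) / sum_k (Num(k | S) + c)` for action
#' `a` in `{Stay, Shift}` and state `S` in `{gain, loss}`. The constant `c`
#' (fixed to 1 by default) stabilizes the estimate; with no observed
#' transitions and `c = 1` every entry is 0.5.
#'
#' @param counts A `stay_shift_counts` object.
#' @return An object of class `conditional_policy`: a 2 x 2 matrix of
#'   probabilities whose columns each sum to 1.
#' @examples
#' conditional_policy(count_transitions(
#'   tibble::tibble(choice = c("adv", "adv"), outcome = c("gain", "gain"))))
#' @export
conditional_policy <- function(counts) {
  stopifnot(inherits(counts, "stay_shift_counts"))
  sm <- counts$num + counts$c
  tot <- colSums(sm)
  if (any(tot == 0)) {
    abort(sprintf(
      "undefined conditional probability: no transitions in state '%s' and c = 0",
      colnames(counts$num)[tot == 0][1]))
  }
  p <- sweep(sm, 2, tot, "/")
  structure(p, class = c("conditional_policy", class(p)))
}

#' Normalized conditional entropy of a Stay/Shift policy
#'
#' The exploration statistic: `H = -(1/N) * sum_S sum_a P(a|S) log2 P(a|S)`
#' with `N` the number of states (2: previous gain, previous loss).
#' Division by `N` standardizes `H` to `[0, 1]`: fixed strategies (constant
#' choice, perfect Win-Stay/Lose-Shift) approach 0 (never reaching it when
#' `c > 0`), while choice that ignores the previous outcome approaches 1.
#'
#' `entropy()` is generic: it accepts a `conditional_policy`, a
#' `stay_shift_counts` (smoothed first), or a trial data frame for a single
#' block (counted, smoothed with constant `c`, then scored).
#'
#' @param x A `conditional_policy`, `stay_shift_counts`, or trial data
#'   frame.
#' @param ... Passed between methods; the data-frame method takes `c`
#'   (smoothing, default 1).
#' @param n_states Number of conditioning states (default 2).
#' @return Normalized entropy in `(0, 1]` for interior policies.
#' @examples
#' counts <- count_transitions(tibble::tibble(
#'   choice = c("adv", "disadv", "adv"), outcome = c("gain", "loss", "gain")))
#' entropy(counts)
#' @export
entropy <- function(x, ...) UseMethod("entropy")

#' @rdname entropy
#' @export
entropy.conditional_policy <- function(x, n_states = 2, ...) {
  p <- unclass(x)
  terms <- ifelse(p == 0, 0, -p * log2(p))
  sum(terms) / n_states
}

#' @rdname entropy
#' @export
entropy.stay_shift_counts <- function(x, n_states = 2, ...) {
  entropy(conditional_policy(x), n_states = n_states)
}

#' @rdname entropy
#' @export
entropy.data.frame <- function(x, c = 1, n_states = 2, ...) {
  entropy(count_transitions(x, c = c), n_states = n_states)
}

# lean scalar path used by scoring loops: choice/outcome character vectors
block_entropy <- function(choice, outcome, c = 1) {
  n <- length(choice)
  if (n < 2) return(entropy_from_counts(0, 0, 0, 0, c))
  prev <- choice[-n]
  curr <- choice[-1]
  valid <- prev != "none" & curr != "none"
  stay <- prev == curr & valid
  gain <- outcome[-n] == "gain"
  entropy_from_counts(sum(stay & gain), sum(valid & !stay & gain),
                      sum(stay & !gain & valid),
                      sum(valid & !stay & !gain), c)
}

# integer-coded variant (choice 1 = adv, 2 = disadv, 0 = none;
# outcome 1 = gain, 0 = loss) used by the cohort generator
block_entropy_int <- function(choice, outcome, c = 1) {
  n <- length(choice)
  if (n < 2) return(entropy_from_counts(0, 0, 0, 0, c))
  prev <- choice[-n]
  curr <- choice[-1]
  valid <- prev != 0L & curr != 0L
  stay <- prev == curr & valid
  gain <- outcome[-n] == 1L
  entropy_from_counts(sum(stay & gain), sum(valid & !stay & gain),
                      sum(stay & !gain), sum(valid & !stay & !gain), c)
}

entropy_from_counts <- function(sg, fg, sl, fl, c = 1) {
  h2 <- function(a, b) {
    p <- (a + c) / (a + b + 2 * c)
    q <- 1 - p
    (if (p > 0) -p * log2(p) else 0) + (if (q > 0) -q * log2(q) else 0)
  }
  (h2(sg, fg) + h2(sl, fl)) / 2
}

#' Behavioral indices of one block
#'
#' Computes the three per-block indices: response bias (fraction of
#' responded trials on which the advantageous stimulus was chosen), reward
#' acquisition (fraction of *all* trials yielding a gain, timeouts counting
#' as losses), and the normalized conditional [entropy] of Stay/Shift
#' behavior.
#'
#' @param trials Trial data frame for a single block (columns `choice`,
#'   `outcome`).
#' @param c Entropy smoothing constant (default 1).
#' @return A one-row tibble with `response_bias`, `reward_acquisition`,
#'   `entropy`, `n_trials` and `n_responded`.
#' @export
behavioral_indices <- function(trials, c = 1) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1)
  ch <- as.character(trials$choice)
  out <- as.character(trials$outcome)
  responded <- ch != "none"
  if (!any(responded)) abort("response bias undefined: no responded trials")
  tibble(
    response_bias = sum(ch == "adv") / sum(responded),
    reward_acquisition = mean(out == "gain"),
    entropy = block_entropy(ch, out, c = c),
    n_trials = length(ch),
    n_responded = sum(responded)
  )
}

#' Score a trial log into per-block behavioral indices
#'
#' Applies [behavioral_indices()] within each block of a (possibly
#' multi-subject, multi-condition) trial log. Grouping columns are any of
#' `subject_id`, `condition`, `block` that are present; transitions never
#' cross block boundaries.
#'
#' @param trials Trial tibble as produced by [run_session()] or
#'   [read_trials()].
#' @param c Entropy smoothing constant (default 1).
#' @return A tibble with one row per group and the index columns of
#'   [behavioral_indices()].
#' @examples
#' run_session(agent_outcome_conditioned(0.8, 0.3),
#'             task_config("contingent"), seed = 1) |>
#'   score_trials()
#' @export
score_trials <- function(trials, c = 1) {
  stopifnot(is.data.frame(trials))
  keys <- intersect(c("subject_id", "condition", "block"), names(trials))
  if (length(keys) == 0) return(behavioral_indices(trials, c = c))
  trials %>%
    group_by(across(all_of(keys))) %>%
    summarise(
      response_bias = sum(.data$choice == "adv") /
        sum(.data$choice != "none"),
      reward_acquisition = mean(.data$outcome == "gain"),
      entropy = block_entropy(.data$choice, .data$outcome, c = c),
      n_trials = dplyr::n(),
      n_responded = sum(.data$choice != "none"),
      .groups = "drop")
}

#' Condition-level summary of behavioral indices
#'
#' Aggregates per-block indices to one row per subject and condition.
#' `aggregate = "mean_blocks"` (default) computes indices per block and
#' averages them with an unweighted mean; `"pooled"` pools Stay/Shift
#' transition counts across blocks (still never counting a transition
#' across a block boundary) before the entropy is taken, and pools trials
#' for bias and reward.
#'
#' @param trials Trial tibble covering one or more blocks.
#' @param c Entropy smoothing constant (default 1).
#' @param aggregate `"mean_blocks"` or `"pooled"`.
#' @return A tibble with one row per subject x condition.
#' @export
condition_summary <- function(trials, c = 1,
                              aggregate = c("mean_blocks", "pooled")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(trials))
  keys <- intersect(c("subject_id", "condition"), names(trials))
  if (aggregate == "mean_blocks") {
    score_trials(trials, c = c) %>%
      group_by(across(all_of(keys))) %>%
      summarise(across(c("response_bias", "reward_acquisition", "entropy"),
                       mean),
                n_blocks = dplyr::n(), .groups = "drop")
  } else {
    grouper <- if (length(keys)) {
      trials %>% group_by(across(all_of(keys)))
    } else trials %>% group_by()
    grouper %>%
      dplyr::group_modify(function(d, k) {
        blocks <- if ("block" %in% names(d)) split(d, d$block) else list(d)
        num <- Reduce(`+`, lapply(blocks,
                                  function(b) count_transitions(b, c = c)$num))
        counts <- structure(list(num = num, c = c, n_transitions = sum(num)),
                            class = "stay_shift_counts")
        ch <- as.character(d$choice)
        tibble(
          response_bias = sum(ch == "adv") / sum(ch != "none"),
          reward_acquisition = mean(d$outcome == "gain"),
          entropy = entropy(counts),
          n_blocks = length(blocks)
        )
      }) %>%
      ungroup()
  }
}
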