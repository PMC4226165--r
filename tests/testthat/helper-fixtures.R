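# shared fixture builders (all data generated in code)

make_trials <- function(choices, outcomes, block = 0L) {
  tibble::tibble(
    condition = "contingent",
    block = block,
    trial = seq_along(choices) - 1L,
    choice = choices,
    outcome = outcomes,
    side_adv = rep_len(c("L", "R"), length(choices))
  )
}

# independent brute-force evaluation of the normalized conditional entropy
# from raw Stay/Shift counts: enumerates the four P log2 P terms directly
brute_force_entropy <- function(stay_gain, shift_gain, stay_loss,
                                shift_loss, c = 1) {
  total <- 0
  for (state in list(c(stay_gain, shift_gain), c(stay_loss, shift_loss))) {
    denom <- state[1] + c + state[2] + c
    for (a in 1:2) {
      p <- (state[a] + c) / denom
      if (p > 0) total <- total - p * log2(p)
    }
  }
  total / 2
}

counts_object <- function(stay_gain, shift_gain, stay_loss, shift_loss,
                          c = 1) {
  num <- matrix(as.integer(c(stay_gain, shift_gain, stay_loss, shift_loss)),
                2, 2, dimnames = list(c("stay", "shift"), c("gain", "loss")))
  structure(list(num = num, c = c, n_transitions = sum(num)),
            class = "stay_shift_counts")
}

# long panel table for a single subject/condition from per-block vectors
make_panel <- function(baseline, task, variable = "norepinephrine",
                       subject_id = "S01", condition = "contingent") {
  nb <- length(baseline)
  tibble::tibble(
    subject_id = subject_id, condition = condition,
    block = rep(seq_len(nb) - 1L, 2),
    period = rep(c("baseline", "task"), each = nb),
    variable = variable, value = c(baseline, task)
  )
}

# balanced within-subject dataset for ANOVA oracle comparisons
make_rm_data <- function(n_subjects, levels, seed, effect_size = 0.5) {
  set.seed(seed)
  grid <- expand.grid(lapply(levels, function(l) paste0("l", seq_len(l))),
                      stringsAsFactors = FALSE)
  names(grid) <- paste0("f", seq_along(levels))
  out <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    g <- grid
    g$subject_id <- sprintf("S%02d", i)
    g$value <- rnorm(nrow(grid)) + effect_size * as.numeric(factor(g$f1)) +
      rnorm(1)
    g
  }))
  tibble::as_tibble(out)
}
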