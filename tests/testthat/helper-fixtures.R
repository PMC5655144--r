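# Small designs and hand-built records shared across tests.

tiny_config <- function() {
  session_config(n_groups = 2, approval_probs = c(0.8, 0.2),
                 feedback_trials_per_group = 10, no_feedback_per_group = 2,
                 n_blocks = 1,
                 probe_gaps = c(3, 3, 2, 2, 3, 3, 2, 2, 2, 2))
}

# A minimal schedule data frame: one group, given outcomes, single probe
# after the last trial (modelable).
micro_schedule <- function(outcomes, probe_last = TRUE,
                           approval_probs = 0.8) {
  n <- length(outcomes)
  out <- data.frame(trial_index = seq_len(n), group_id = 1L,
                    outcome = outcomes,
                    probe_after = c(rep(FALSE, n - 1), probe_last),
                    probe_modelable = c(rep(FALSE, n - 1), probe_last),
                    stringsAsFactors = FALSE)
  attr(out, "approval_probs") <- approval_probs
  out
}

# A hand-built behavioural record (data frame with record semantics).
hand_record <- function(outcomes, choices, ratings_at, ratings,
                        group_id = 1L, missed = NULL,
                        approval_probs = c(0.85, 0.70, 0.30, 0.15)) {
  n <- length(outcomes)
  if (length(group_id) == 1L) group_id <- rep(group_id, n)
  rec <- data.frame(trial_index = seq_len(n), block = 1L,
                    group_id = group_id, choice = choices,
                    outcome = outcomes,
                    missed = if (is.null(missed)) rep(FALSE, n) else missed,
                    probe_after = seq_len(n) %in% ratings_at,
                    probe_modelable = seq_len(n) %in% ratings_at,
                    probe_rating = NA_real_,
                    stringsAsFactors = FALSE)
  rec$probe_rating[ratings_at] <- ratings
  structure(rec, class = c("esteem_record", "data.frame"),
            approval_probs = approval_probs)
}

default_params <- function(...) agent_params(...)
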