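#' Design parameters for a social-evaluation session
#'
#' Builds the configuration object consumed by [build_session()]. The default
#' design has 184 trials: four rater groups with approval probabilities
#' 0.85/0.70/0.30/0.15, 40 feedback trials plus 6 no-feedback trials per
#' group, three blocks, and 78 self-esteem probes placed after inter-probe
#' gaps of 2 or 3 trials (fifty 2s and twenty-eight 3s, so the gaps tile the
#' whole session: 2*50 + 3*28 = 184).
#'
#' @param n_groups Number of rater groups.
#' @param approval_probs Probability of approval per group, strictly
#'   decreasing in group id. `approval_probs * feedback_trials_per_group`
#'   must be integer-valued.
#' @param feedback_trials_per_group Trials per group on which feedback
#'   (approval or disapproval) is revealed.
#' @param no_feedback_per_group Trials per group on which no feedback is
#'   shown (outcome `"none"`).
#' @param n_blocks Number of blocks; trials are split into near-equal
#'   consecutive blocks (remainder trials go to the earliest blocks).
#' @param probe_gaps Integer vector of inter-probe gaps; must sum to the
#'   total number of trials. One probe follows the trial at each cumulative
#'   gap position.
#' @param max_run Maximum number of consecutive trials showing the same
#'   group's color cue.
#' @param max_recurrence_gap Each occurrence of a color must come at most
#'   this many trials after its previous occurrence; the clock is anchored
#'   at the session start, so every color must also first appear within
#'   this many trials.
#' @param max_attempts Cap on constrained-sampling restarts before
#'   [build_session()] gives up with an error.
#' @param colors Color labels, one per group.
#' @return A list of class `"esteem_session_config"`.
#' @seealso [build_session()], [validate_session()]
#' @export
session_config <- function(n_groups = 4,
                           approval_probs = c(0.85, 0.70, 0.30, 0.15),
                           feedback_trials_per_group = 40,
                           no_feedback_per_group = 6,
                           n_blocks = 3,
                           probe_gaps = c(rep(2L, 50), rep(3L, 28)),
                           max_run = 2,
                           max_recurrence_gap = 7,
                           max_attempts = 10000,
                           colors = c("blue", "green", "yellow", "red")) {
  stopifnot(n_groups >= 1, length(approval_probs) == n_groups,
            all(approval_probs >= 0 & approval_probs <= 1),
            feedback_trials_per_group >= 0, no_feedback_per_group >= 0,
            n_blocks >= 1, max_run >= 1, max_recurrence_gap >= 1)
  if (n_groups > 1 && any(diff(approval_probs) >= 0))
    stop("approval_probs must be strictly decreasing in group id")
  n_approve <- approval_probs * feedback_trials_per_group
  if (any(abs(n_approve - round(n_approve)) > 1e-9))
    stop("approval_probs * feedback_trials_per_group must be integers")
  n_trials <- n_groups * (feedback_trials_per_group + no_feedback_per_group)
  if (length(probe_gaps) && sum(probe_gaps) != n_trials)
    stop("probe_gaps must sum to the total number of trials (",
         n_trials, "), got ", sum(probe_gaps))
  if (length(colors) < n_groups)
    colors <- paste0("color", seq_len(n_groups))
  structure(list(
    n_groups = as.integer(n_groups),
    approval_probs = approval_probs,
    feedback_trials_per_group = as.integer(feedback_trials_per_group),
    no_feedback_per_group = as.integer(no_feedback_per_group),
    n_blocks = as.integer(n_blocks),
    probe_gaps = as.integer(probe_gaps),
    max_run = as.integer(max_run),
    max_recurrence_gap = as.integer(max_recurrence_gap),
    max_attempts = as.integer(max_attempts),
    colors = colors[seq_len(n_groups)],
    n_trials = as.integer(n_trials)
  ), class = "esteem_session_config")
}

# Near-equal consecutive block sizes (remainder to the earliest blocks).
block_sizes <- function(n_trials, n_blocks) {
  base <- n_trials %/% n_blocks
  sizes <- rep(base, n_blocks)
  extra <- n_trials - base * n_blocks
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

# Constrained sequential sampling of the group/color sequence: at each
# position a group is drawn among those with trials remaining, subject to the
# run-length cap; a color whose recurrence deadline falls on the current
# position is forced. The recurrence clock is anchored at the session start
# (virtual occurrence at trial 0), so every color must also first appear
# within the cap. Dead ends (two colors due at once, no legal pick, or an
# unavoidable run violation) trigger a restart, up to `max_attempts`.
draw_group_sequence <- function(counts, max_run, max_gap, max_attempts) {
  n <- sum(counts)
  K <- length(counts)
  if (K == 1L) {
    if (max_run < n) stop(constraint_error("run-length",
      "a single group cannot satisfy the run-length constraint"))
    return(rep(1L, n))
  }
  for (attempt in seq_len(max_attempts)) {
    rem <- counts
    last <- rep(0L, K)
    run_grp <- 0L
    run_len <- 0L
    out <- integer(n)
    ok <- TRUE
    for (pos in seq_len(n)) {
      due <- which((pos - last) >= max_gap & rem > 0L)
      if (length(due) > 1L) { ok <- FALSE; break }
      allowed <- which(rem > 0L)
      if (run_len >= max_run) allowed <- setdiff(allowed, run_grp)
      if (length(due) == 1L) {
        if (!(due %in% allowed)) { ok <- FALSE; break }
        pick <- due
      } else if (!length(allowed)) {
        ok <- FALSE; break
      } else if (length(allowed) == 1L) {
        pick <- allowed
      } else {
        # weight by remaining count, boosted when a color nears its deadline
        slack <- last[allowed] + max_gap - pos
        w <- rem[allowed] * ifelse(slack <= 2, 5, 1)
        pick <- allowed[sample.int(length(allowed), 1L, prob = w)]
      }
      out[pos] <- pick
      rem[pick] <- rem[pick] - 1L
      last[pick] <- pos
      if (pick == run_grp) run_len <- run_len + 1L
      else { run_grp <- pick; run_len <- 1L }
    }
    if (ok) return(out)
  }
  stop(constraint_error("sequence",
    sprintf("no group sequence satisfying run <= %d and recurrence gap <= %d found in %d attempts",
            max_run, max_gap, max_attempts)))
}

constraint_error <- function(constraint, message) {
  structure(class = c("esteem_constraint_error", "error", "condition"),
            list(message = paste0("constraint infeasible [", constraint, "]: ",
                                  message),
                 call = NULL, constraint = constraint))
}

#' Generate a session of the social-evaluation task
#'
#' Produces a full trial schedule satisfying the design constraints: exact
#' per-group approval counts (`approval_prob * feedback_trials_per_group`
#' approvals per group), no color cue more than `max_run` times in a row,
#' every recurrence of a color at most `max_recurrence_gap` trials after its
#' previous occurrence, unique raters balanced by sex, and self-esteem probes
#' at the configured inter-probe gaps. Output is deterministic given
#' `(config, seed)`.
#'
#' Probes are additionally flagged as "modelable": the session's first probe
#' is excluded, as is the first remaining probe of every block, leaving 74 of
#' the default 78 probes available for model fitting.
#'
#' @param config An `"esteem_session_config"`, see [session_config()].
#' @param seed Integer seed.
#' @return An object of class `"esteem_session"`: a list with `trials` (a
#'   data frame with one row per trial), `probe_positions`, `config`, `seed`.
#' @examples
#' s <- build_session(session_config(), seed = 1)
#' table(s$trials$scheduled_outcome)
#' @export
build_session <- function(config = session_config(), seed = 1L) {
  stopifnot(inherits(config, "esteem_session_config"))
  n <- config$n_trials
  K <- config$n_groups
  per_group <- config$feedback_trials_per_group + config$no_feedback_per_group
  set.seed(as.integer(seed))

  grp <- draw_group_sequence(rep(per_group, K), config$max_run,
                             config$max_recurrence_gap, config$max_attempts)

  # scheduled outcomes: exact counts per group, order shuffled within group
  outcome <- character(n)
  for (k in seq_len(K)) {
    n_app <- as.integer(round(config$approval_probs[k] *
                                config$feedback_trials_per_group))
    pool <- c(rep("approve", n_app),
              rep("disapprove", config$feedback_trials_per_group - n_app),
              rep("none", config$no_feedback_per_group))
    outcome[grp == k] <- sample(pool)
  }

  # unique raters, sex balanced within each group (and hence overall)
  rater_id <- sprintf("rater_%03d", sample.int(n))
  rater_sex <- character(n)
  for (k in seq_len(K)) {
    half <- per_group %/% 2
    sexes <- c(rep("female", half), rep("male", per_group - half))
    rater_sex[grp == k] <- sample(sexes)
  }

  sizes <- block_sizes(n, config$n_blocks)
  block <- rep(seq_len(config$n_blocks), times = sizes)

  probe_positions <- cumsum(sample(config$probe_gaps))
  probe_after <- seq_len(n) %in% probe_positions
  modelable <- flag_modelable_probes(probe_positions, block)
  probe_modelable <- logical(n)
  probe_modelable[probe_positions] <- modelable

  trials <- data.frame(
    trial_index = seq_len(n),
    block = block,
    rater_id = rater_id,
    rater_sex = rater_sex,
    group_id = grp,
    color = config$colors[grp],
    scheduled_outcome = outcome,
    probe_after = probe_after,
    probe_modelable = probe_modelable,
    stringsAsFactors = FALSE
  )
  structure(list(trials = trials,
                 probe_positions = as.integer(probe_positions),
                 config = config, seed = as.integer(seed)),
            class = "esteem_session")
}

# Modelable-probe rule: drop the session's very first probe, then the first
# remaining probe of each block (block 1's being the session's second probe).
# With 3 blocks this removes 4 probes: 78 -> 74 under the default design.
flag_modelable_probes <- function(probe_positions, block) {
  m <- rep(TRUE, length(probe_positions))
  if (!length(probe_positions)) return(m)
  m[1] <- FALSE
  pb <- block[probe_positions]
  for (b in unique(block)) {
    cand <- which(pb == b & m)
    if (length(cand)) m[cand[1]] <- FALSE
  }
  m
}

#' @export
print.esteem_session <- function(x, ...) {
  tr <- x$trials
  cat("Social-evaluation task session (seed ", x$seed, ")\n", sep = "")
  cat("  trials: ", nrow(tr), " in ", x$config$n_blocks, " blocks; groups: ",
      x$config$n_groups, "\n", sep = "")
  tab <- table(tr$scheduled_outcome)
  cat("  outcomes:", paste(names(tab), as.integer(tab), sep = "=",
                           collapse = ", "), "\n")
  cat("  probes: ", length(x$probe_positions), " (",
      sum(tr$probe_modelable), " modelable)\n", sep = "")
  invisible(x)
}

#' Validate a task session against its design constraints
#'
#' Never raises on bad content: each constraint is checked and reported with
#' a pass/fail flag, so hand-built (or corrupted) sessions can be diagnosed.
#'
#' @param session An `"esteem_session"` (the `trials` data frame is what is
#'   actually inspected, so partially hand-built sessions validate too).
#' @return A list of class `"esteem_session_validation"` with per-constraint
#'   results, summary counts, and an overall `pass` flag.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "esteem_session"))
  tr <- session$trials
  cfg <- session$config
  if (nrow(tr) == 0) stop("empty session")
  checks <- list()

  n_app <- sum(tr$scheduled_outcome == "approve")
  n_dis <- sum(tr$scheduled_outcome == "disapprove")
  n_none <- sum(tr$scheduled_outcome == "none")
  exp_app <- sum(round(cfg$approval_probs * cfg$feedback_trials_per_group))
  exp_fb <- cfg$n_groups * cfg$feedback_trials_per_group
  checks$outcome_counts <- (n_app == exp_app &&
                            n_dis == exp_fb - exp_app &&
                            n_none == cfg$n_groups * cfg$no_feedback_per_group)

  appr_frac <- vapply(seq_len(cfg$n_groups), function(k) {
    fb <- tr$scheduled_outcome != "none" & tr$group_id == k
    if (!any(fb)) return(NA_real_)
    mean(tr$scheduled_outcome[fb] == "approve")
  }, numeric(1))
  checks$group_approval_fractions <-
    all(abs(appr_frac - cfg$approval_probs) < 1e-9, na.rm = TRUE)

  runs <- rle(tr$color)
  max_run_len <- max(runs$lengths)
  checks$color_run_length <- max_run_len <= cfg$max_run

  # recurrence clock anchored at the session start: the first occurrence of
  # each color counts as a gap from virtual trial 0
  gaps <- unlist(lapply(split(tr$trial_index, tr$color), function(ix)
    diff(c(0L, sort(ix)))))
  max_gap <- if (length(gaps)) max(gaps) else 0
  checks$color_recurrence_gap <- max_gap <= cfg$max_recurrence_gap

  checks$unique_raters <- !anyDuplicated(tr$rater_id)

  probe_pos <- tr$trial_index[tr$probe_after]
  probe_gap <- diff(c(0L, probe_pos))
  checks$probe_count <- length(probe_pos) == length(cfg$probe_gaps)
  checks$probe_gaps <- identical(sort(as.integer(probe_gap)),
                                 sort(cfg$probe_gaps))

  structure(list(
    checks = checks,
    pass = all(unlist(checks)),
    n_approve = n_app, n_disapprove = n_dis, n_none = n_none,
    group_approval_fractions = appr_frac,
    max_color_run = max_run_len,
    max_recurrence_gap = max_gap,
    probe_gap_table = table(probe_gap),
    n_probes = length(probe_pos),
    n_modelable = sum(tr$probe_modelable)
  ), class = "esteem_session_validation")
}

#' @export
print.esteem_session_validation <- function(x, ...) {
  cat("Session validation:", if (x$pass) "PASS" else "FAIL", "\n")
  for (nm in names(x$checks))
    cat(sprintf("  %-26s %s\n", nm, if (x$checks[[nm]]) "ok" else "VIOLATED"))
  cat("  outcomes: approve=", x$n_approve, " disapprove=", x$n_disapprove,
      " none=", x$n_none, "\n", sep = "")
  cat("  max color run ", x$max_color_run, ", max recurrence gap ",
      x$max_recurrence_gap, ", probes ", x$n_probes, " (", x$n_modelable,
      " modelable)\n", sep = "")
  invisible(x)
}

#' Read and write sessions as TSV
#'
#' One row per trial with columns trial_index, block, rater_id, rater_sex,
#' group_id, color, scheduled_outcome, probe_after, probe_modelable.
#'
#' @param session An `"esteem_session"`.
#' @param path File path.
#' @param config,seed Optionally attached when reading, so a round-tripped
#'   session can be re-validated against its design.
#' @return `read_session()` returns an `"esteem_session"`; `write_session()`
#'   returns `path` invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "esteem_session"))
  utils::write.table(session$trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path, config = session_config(), seed = NA_integer_) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  required <- c("trial_index", "block", "rater_id", "rater_sex", "group_id",
                "color", "scheduled_outcome", "probe_after", "probe_modelable")
  missing_cols <- setdiff(required, names(tr))
  if (length(missing_cols))
    stop("session table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tr$probe_after <- as.logical(tr$probe_after)
  tr$probe_modelable <- as.logical(tr$probe_modelable)
  structure(list(trials = tr,
                 probe_positions = tr$trial_index[tr$probe_after],
                 config = config, seed = as.integer(seed)),
            class = "esteem_session")
}
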