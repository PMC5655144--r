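#' The six-model family of self-esteem dynamics
#'
#' All models share an exponential-kernel account of state self-esteem: at a
#' probe following trial t the deterministic prediction is
#' \deqn{w_0 + w_1 \sum_{j \le t} \gamma^{t-j} SPE_j}
#' where the social approval prediction error is \eqn{SPE_j = SF_j - ESV_j}
#' (feedback coded +1 approval, -1 disapproval, 0 none) and \eqn{ESV} is the
#' expected social value of the cued rater group, updated on feedback trials
#' by Rescorla-Wagner learning \eqn{ESV \leftarrow ESV + \eta\, SPE}. Choices
#' follow a biased softmax with temperature. The variants are:
#'
#' * `M1` — learning with response bias (9 free parameters)
#' * `M2` — learning without bias (8)
#' * `M3` — no learning, initial expectations fixed at the true approval
#'   probabilities rescaled to the feedback coding, 2p - 1 (6)
#' * `M4` — `M1` plus a separate expectation kernel weighted by `w2` (10)
#' * `M5` — no learning, free initial expectations, fitted to ratings only (6)
#' * `M6` — outcome valence only: the kernel runs over raw feedback
#'   \eqn{SF_j}, no expectations, fitted to ratings only (4)
#'
#' @param model_id One of `"M1" .. "M6"` (an existing spec passes through).
#' @return A list of class `"esteem_model"` describing the variant: which
#'   parameters are free, whether expectations are learned, whether the
#'   likelihood covers choices and ratings or ratings only, and `k`, the
#'   free-parameter count.
#' @export
model_spec <- function(model_id = c("M1", "M2", "M3", "M4", "M5", "M6")) {
  if (inherits(model_id, "esteem_model")) return(model_id)
  model_id <- match.arg(toupper(model_id[[1]]), c("M1", "M2", "M3", "M4",
                                                  "M5", "M6"))
  esteem_pars <- c("w0", "w1", "sigma", "gamma")
  choice_pars <- c("esv0", "temperature")
  init_pars <- c("esv1_init", "esv4_init")
  spec <- switch(model_id,
    M1 = list(learns = TRUE, has_bias = TRUE, has_expectation_term = FALSE,
              valence_only = FALSE, fit_target = "choices_and_ratings",
              free = c(esteem_pars, "eta", choice_pars, init_pars)),
    M2 = list(learns = TRUE, has_bias = FALSE, has_expectation_term = FALSE,
              valence_only = FALSE, fit_target = "choices_and_ratings",
              free = c(esteem_pars, "eta", "temperature", init_pars)),
    M3 = list(learns = FALSE, has_bias = TRUE, has_expectation_term = FALSE,
              valence_only = FALSE, fit_target = "choices_and_ratings",
              free = c(esteem_pars, choice_pars)),
    M4 = list(learns = TRUE, has_bias = TRUE, has_expectation_term = TRUE,
              valence_only = FALSE, fit_target = "choices_and_ratings",
              free = c(esteem_pars, "w2", "eta", choice_pars, init_pars)),
    M5 = list(learns = FALSE, has_bias = FALSE, has_expectation_term = FALSE,
              valence_only = FALSE, fit_target = "ratings_only",
              free = c(esteem_pars, init_pars)),
    M6 = list(learns = FALSE, has_bias = FALSE, has_expectation_term = FALSE,
              valence_only = TRUE, fit_target = "ratings_only",
              free = esteem_pars)
  )
  structure(c(list(model_id = model_id), spec, list(k = length(spec$free))),
            class = "esteem_model")
}

#' @export
print.esteem_model <- function(x, ...) {
  cat("Self-esteem model ", x$model_id, " (k = ", x$k, ", fit to ",
      gsub("_", " ", x$fit_target), ")\n", sep = "")
  cat("  free parameters:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

#' Agent parameters
#'
#' Bundles the parameters of the generative models. Self-esteem ratings live
#' on the unit interval (visual-analogue endpoints mapped to 0 and 1);
#' expected social values live on the feedback coding scale \eqn{[-1, 1]}.
#'
#' @param w0 Baseline self-esteem on the rating scale.
#' @param w1 Weight of the prediction-error kernel.
#' @param sigma Gaussian rating-noise SD (> 0).
#' @param eta Learning rate in \eqn{[0, 1]}.
#' @param esv0 Response bias added to the softmax drive.
#' @param temperature Decision temperature (> 0); smaller values make
#'   choices more deterministic in the expectation.
#' @param esv1_init,esv4_init Initial expected social value of the most and
#'   least approving group; the middle groups are spaced equally in between
#'   (see [initial_esvs()]).
#' @param gamma Forgetting factor in \eqn{[0, 1]}: per-trial exponential
#'   decay of past prediction errors in the self-esteem kernel.
#' @param w2 Weight of the separate expectation kernel; only meaningful for
#'   model M4 and rejected by other models.
#' @return A list of class `"esteem_params"`.
#' @export
agent_params <- function(w0 = 0.73, w1 = 0.04, sigma = 0.08, eta = 0.04,
                         esv0 = 0.42, temperature = 0.12,
                         esv1_init = 0.81, esv4_init = 0.47,
                         gamma = 0.66, w2 = NULL) {
  p <- list(w0 = w0, w1 = w1, sigma = sigma, eta = eta, esv0 = esv0,
            temperature = temperature, esv1_init = esv1_init,
            esv4_init = esv4_init, gamma = gamma, w2 = w2)
  check_params(p)
  structure(p, class = "esteem_params")
}

check_params <- function(p) {
  num <- p[!vapply(p, is.null, logical(1))]
  if (!all(vapply(num, function(x) is.numeric(x) && is.finite(x), logical(1))))
    stop("all supplied parameters must be finite numbers")
  if (p$eta < 0 || p$eta > 1) stop("eta must lie in [0, 1]")
  if (p$gamma < 0 || p$gamma > 1) stop("gamma must lie in [0, 1]")
  if (p$sigma <= 0) stop("sigma must be > 0")
  if (p$temperature <= 0) stop("temperature must be > 0")
  invisible(p)
}

#' Initial expected social values for the four groups
#'
#' The most and least approving groups carry free initial expectations; the
#' two middle groups are spaced equally in between:
#' \eqn{ESV_2 = ESV_1 - (ESV_1 - ESV_4)/3},
#' \eqn{ESV_3 = ESV_1 - 2(ESV_1 - ESV_4)/3}.
#'
#' @param esv1_init,esv4_init Initial expectations for groups 1 and 4.
#' @return Numeric 4-vector of initial expectations.
#' @examples
#' initial_esvs(0.85, 0.15)
#' @export
initial_esvs <- function(esv1_init, esv4_init) {
  stopifnot(is.finite(esv1_init), is.finite(esv4_init))
  d <- esv1_init - esv4_init
  c(esv1_init, esv1_init - d / 3, esv1_init - 2 * d / 3, esv4_init)
}

#' Social approval prediction error
#'
#' @param sf Social feedback coded +1 (approval), -1 (disapproval) or 0 (no
#'   feedback shown).
#' @param esv Expected social value of the cued group before the outcome.
#' @return `sf - esv`.
#' @export
compute_spe <- function(sf, esv) {
  stopifnot(all(is.finite(esv)))
  sf - esv
}

#' Rescorla-Wagner update of an expected social value
#'
#' @param esv Current expectation.
#' @param spe Prediction error on the trial.
#' @param eta Learning rate in \eqn{[0, 1]}.
#' @return `esv + eta * spe`.
#' @export
rw_update <- function(esv, spe, eta) {
  stopifnot(eta >= 0, eta <= 1)
  esv + eta * spe
}

#' Biased softmax probability of predicting approval
#'
#' \deqn{\pi_L = 1 / (1 + e^{-(ESV + ESV_0)/T})}
#' The probability is 0.5 exactly when the summed drive `esv + esv0` is zero,
#' regardless of temperature.
#'
#' @param esv Expected social value of the cued group.
#' @param esv0 Response bias.
#' @param temperature Decision temperature, strictly positive.
#' @return Probability in (0, 1), vectorised over `esv`.
#' @examples
#' choice_prob(0.3, -0.3, 0.12)  # 0.5 at the indifference point
#' @export
choice_prob <- function(esv, esv0, temperature) {
  if (!is.numeric(temperature) || any(temperature <= 0))
    stop("temperature must be > 0")
  stats::plogis((esv + esv0) / temperature)
}

#' Exponential-kernel sum (explicit reference form)
#'
#' Evaluates \eqn{S_t = \sum_{j=1}^{t} \gamma^{t-j} x_j} for every t by the
#' explicit sum. The model machinery uses the algebraically equivalent
#' recursion \eqn{S_t = \gamma S_{t-1} + x_t}; this explicit form is exported
#' so the two routes can be compared directly.
#'
#' @param x Numeric input sequence (prediction errors, or raw feedback for
#'   the valence-only model).
#' @param gamma Forgetting factor.
#' @param method `"recursive"` (default, used throughout the package) or
#'   `"sum"` (explicit evaluation).
#' @return Numeric vector of kernel states, same length as `x`.
#' @export
kernel_states <- function(x, gamma, method = c("recursive", "sum")) {
  method <- match.arg(method)
  if (!length(x)) return(numeric(0))
  if (method == "recursive")
    return(as.numeric(stats::filter(x, gamma, method = "recursive")))
  vapply(seq_along(x), function(t)
    sum(gamma ^ (t - seq_len(t)) * x[seq_len(t)]), numeric(1))
}

# Social feedback coding used throughout: +1 approve, -1 disapprove, 0 none.
sf_code <- function(outcome) {
  ifelse(outcome == "approve", 1, ifelse(outcome == "disapprove", -1, 0))
}

model_initial_esvs <- function(params, model, approval_probs) {
  if (identical(model$model_id, "M3")) {
    # true approval probabilities rescaled to the +/-1 feedback coding
    2 * approval_probs - 1
  } else if (model$valence_only) {
    rep(0, length(approval_probs))
  } else {
    iv <- initial_esvs(params$esv1_init, params$esv4_init)
    iv[seq_along(approval_probs)]
  }
}

check_model_params <- function(params, model) {
  if (!is.null(params$w2) && !model$has_expectation_term)
    stop("w2 supplied but model ", model$model_id,
         " has no separate expectation term")
  if (model$has_expectation_term && is.null(params$w2))
    stop("model ", model$model_id, " requires w2")
  invisible(params)
}

#' Forward pass: latent trace of a model over a trial schedule
#'
#' Computes per-trial expected social values (pre-update), prediction
#' errors, choice probabilities, kernel states and the per-probe
#' deterministic self-esteem prediction, for one model and parameter set.
#' Trials flagged missed are dropped entirely: they contribute no choice
#' probability, no prediction error to the kernel, and no learning update.
#'
#' @param schedule Data frame with columns `trial_index`, `group_id`,
#'   `outcome` (`"approve"`, `"disapprove"`, `"none"`), and logical
#'   `probe_after`, `probe_modelable`; an `"esteem_session"` or
#'   `"esteem_record"` may be passed instead.
#' @param params An `"esteem_params"`.
#' @param model An `"esteem_model"` or a model id string.
#' @param missed Optional logical vector marking missed trials (defaults to
#'   the schedule's `missed` column, else none).
#' @return A list of class `"esteem_trace"` with data frame `trials`
#'   (`trial_index`, `group_id`, `sf`, `esv`, `spe`, `p_like`,
#'   `kernel_spe`, `kernel_esv`, kept trials only) and data frame `probes`
#'   (`probe`, `trial_index`, `modelable`, `esteem_pred`).
#' @export
model_trace <- function(schedule, params, model = "M1", missed = NULL) {
  model <- model_spec(model)
  check_params(params)
  check_model_params(params, model)
  sched <- as_schedule(schedule)
  if (is.null(missed)) {
    missed <- if ("missed" %in% names(sched)) as.logical(sched$missed)
              else rep(FALSE, nrow(sched))
  }
  stopifnot(length(missed) == nrow(sched))
  probes_all <- which(sched$probe_after)
  if (!nrow(sched)) stop("empty schedule")

  keep <- !missed
  tr <- sched[keep, , drop = FALSE]
  n <- nrow(tr)
  if (!n) stop("all trials missed")
  K <- max(sched$group_id)
  probs <- attr(sched, "approval_probs")
  if (is.null(probs)) probs <- rep(NA_real_, K)
  init <- model_initial_esvs(params, model, probs)
  if (anyNA(init))
    stop("model M3 needs the session's approval probabilities in the schedule")

  sf <- sf_code(tr$outcome)
  esv <- numeric(n)
  eta <- if (model$learns) params$eta else 0
  for (k in seq_len(K)) {
    idx <- which(tr$group_id == k)
    if (!length(idx)) next
    upd <- idx[tr$outcome[idx] != "none"]
    if (eta > 0 && length(upd)) {
      post <- as.numeric(stats::filter(eta * sf[upd], 1 - eta,
                                       method = "recursive", init = init[k]))
      # expectation entering trial j is the value after the latest earlier
      # feedback trial of the same group (the update itself is post-outcome)
      n_before <- findInterval(idx - 1L, upd)
      esv[idx] <- c(init[k], post)[n_before + 1L]
    } else {
      esv[idx] <- init[k]
    }
  }

  spe <- compute_spe(sf, esv)
  kernel_in <- if (model$valence_only) sf else spe
  ks <- kernel_states(kernel_in, params$gamma)
  ke <- if (model$has_expectation_term) kernel_states(esv, params$gamma)
        else rep(NA_real_, n)

  p_like <- if (model$fit_target == "choices_and_ratings") {
    drive_bias <- if (model$has_bias) params$esv0 else 0
    choice_prob(esv, drive_bias, params$temperature)
  } else rep(0.5, n)

  # probes attach to the trial they follow; a probe after a missed trial
  # reads the kernel state of the latest kept trial before it
  state_at <- findInterval(probes_all, tr$trial_index)
  pred <- ifelse(state_at >= 1, params$w0 + params$w1 * ks[pmax(state_at, 1)],
                 params$w0)
  if (model$has_expectation_term)
    pred <- pred + ifelse(state_at >= 1,
                          params$w2 * ke[pmax(state_at, 1)], 0)

  trials <- data.frame(trial_index = tr$trial_index, group_id = tr$group_id,
                       sf = sf, esv = esv, spe = spe, p_like = p_like,
                       kernel_spe = ks, kernel_esv = ke)
  probes <- data.frame(probe = seq_along(probes_all),
                       trial_index = probes_all,
                       modelable = sched$probe_modelable[probes_all],
                       esteem_pred = pred)
  structure(list(trials = trials, probes = probes,
                 model_id = model$model_id, params = params),
            class = "esteem_trace")
}

# Normalise the accepted schedule inputs into one data frame.
as_schedule <- function(x) {
  if (inherits(x, "esteem_session")) {
    out <- data.frame(trial_index = x$trials$trial_index,
                      group_id = x$trials$group_id,
                      outcome = x$trials$scheduled_outcome,
                      probe_after = x$trials$probe_after,
                      probe_modelable = x$trials$probe_modelable,
                      stringsAsFactors = FALSE)
    attr(out, "approval_probs") <- x$config$approval_probs
    return(out)
  }
  if (inherits(x, "esteem_record")) return(as_schedule_record(x))
  stopifnot(is.data.frame(x))
  need <- c("trial_index", "group_id", "outcome", "probe_after",
            "probe_modelable")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("schedule is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  x
}

#' Per-probe model-predicted self-esteem
#'
#' Convenience accessor over [model_trace()]: returns the deterministic
#' self-esteem prediction at each probe (all probes, with the modelable flag
#' attached).
#'
#' @inheritParams model_trace
#' @return The trace's `probes` data frame.
#' @export
predict_self_esteem <- function(schedule, params, model = "M1",
                                missed = NULL) {
  model_trace(schedule, params, model, missed)$probes
}

#' Simulate an agent performing a session
#'
#' Choices are sampled from the biased-softmax probabilities, outcomes are
#' taken from the session schedule, expectations update by Rescorla-Wagner
#' learning on revealed-feedback trials, and probe ratings are the
#' deterministic kernel prediction plus Gaussian noise of SD `sigma`,
#' truncated to the rating scale \eqn{[0, 1]}. Ratings-only models (M5, M6)
#' carry no choice parameters; their simulated choices are unbiased coin
#' flips.
#'
#' @param session An `"esteem_session"`.
#' @param params An `"esteem_params"`.
#' @param model Model id or `"esteem_model"`.
#' @param seed Integer seed; fixed seed reproduces the record exactly.
#' @return A list with `record` (an `"esteem_record"` data frame: one row
#'   per trial with the choice, outcome, missed flag and probe rating) and
#'   `trace` (the `"esteem_trace"` used to generate it).
#' @export
simulate_agent <- function(session, params, model = "M1", seed = 1L) {
  stopifnot(inherits(session, "esteem_session"))
  model <- model_spec(model)
  trace <- model_trace(session, params, model)
  set.seed(as.integer(seed))
  n <- nrow(session$trials)
  liked <- stats::rbinom(n, 1L, trace$trials$p_like) == 1L
  pr <- trace$probes
  noise <- stats::rnorm(nrow(pr), 0, params$sigma)
  ratings <- pmin(1, pmax(0, pr$esteem_pred + noise))

  rec <- data.frame(
    trial_index = session$trials$trial_index,
    block = session$trials$block,
    group_id = session$trials$group_id,
    choice = ifelse(liked, "liked", "disliked"),
    outcome = session$trials$scheduled_outcome,
    missed = FALSE,
    probe_after = session$trials$probe_after,
    probe_modelable = session$trials$probe_modelable,
    probe_rating = NA_real_,
    stringsAsFactors = FALSE
  )
  rec$probe_rating[pr$trial_index] <- ratings
  rec <- structure(rec, class = c("esteem_record", "data.frame"),
                   approval_probs = session$config$approval_probs,
                   seed = as.integer(seed), model_id = model$model_id)
  list(record = rec, trace = trace)
}

as_schedule_record <- function(record) {
  out <- data.frame(trial_index = record$trial_index,
                    group_id = record$group_id,
                    outcome = record$outcome,
                    probe_after = record$probe_after,
                    probe_modelable = record$probe_modelable,
                    missed = record$missed,
                    stringsAsFactors = FALSE)
  attr(out, "approval_probs") <- attr(record, "approval_probs")
  out
}

#' @export
print.esteem_trace <- function(x, ...) {
  cat("Latent trace (", x$model_id, "): ", nrow(x$trials), " trials, ",
      nrow(x$probes), " probes (", sum(x$probes$modelable),
      " modelable)\n", sep = "")
  invisible(x)
}
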