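#' Generative specification for a synthetic cohort
#'
#' Per-parameter means and SDs default to the group-level estimates of the
#' winning model (baseline self-esteem 0.73 (0.16), SPE weight 0.04 (0.03),
#' rating-noise SD 0.08 (0.04), learning rate 0.04 (0.08), forgetting factor
#' 0.66 (0.35), response bias 0.42 (0.25), decision temperature 0.12 (0.35),
#' average initial approval beliefs 0.64 (0.24), range of initial approval
#' beliefs 0.34 (0.29)). Initial expectations are parameterised as their
#' average and range, matching how they are summarised and entered into the
#' symptom analysis; they are converted to the group-1/group-4 values when
#' agents are simulated.
#'
#' @param n_subjects Number of subjects.
#' @param means,sds Named numeric vectors over
#'   `w0, w1, sigma, eta, gamma, esv0, temperature, avg_init, range_init`;
#'   supplied entries override the defaults.
#' @param bounds Named list of length-2 truncation ranges; supplied entries
#'   override the defaults (`eta`, `gamma` in \[0,1\]; `sigma`,
#'   `temperature` in (0.005, 2\]; `w0` in \[0,1\]; `avg_init` in \[-1,1\];
#'   `range_init` in \[0,2\]; others mean +/- 4 SD).
#' @param coupling Named numeric vector: additive shift of each parameter's
#'   mean per unit of the latent vulnerability factor (default all zero).
#' @param seed Integer seed.
#' @return A list of class `"esteem_cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 40, means = NULL, sds = NULL,
                        bounds = NULL, coupling = NULL, seed = 1L) {
  m <- c(w0 = 0.73, w1 = 0.04, sigma = 0.08, eta = 0.04, gamma = 0.66,
         esv0 = 0.42, temperature = 0.12, avg_init = 0.64, range_init = 0.34)
  s <- c(w0 = 0.16, w1 = 0.03, sigma = 0.04, eta = 0.08, gamma = 0.35,
         esv0 = 0.25, temperature = 0.35, avg_init = 0.24, range_init = 0.29)
  if (!is.null(means)) m[names(means)] <- means
  if (!is.null(sds)) s[names(sds)] <- sds
  if (any(s < 0)) stop("sds must be >= 0")
  b <- list(w0 = c(0, 1), eta = c(0, 1), gamma = c(0, 1),
            sigma = c(0.005, 2), temperature = c(0.005, 2),
            avg_init = c(-1, 1), range_init = c(0, 2),
            w1 = m["w1"] + c(-4, 4) * s["w1"],
            esv0 = m["esv0"] + c(-4, 4) * s["esv0"])
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  for (nm in names(m))
    if (m[nm] < b[[nm]][1] || m[nm] > b[[nm]][2])
      stop("mean of ", nm, " lies outside its bounds")
  cpl <- stats::setNames(rep(0, length(m)), names(m))
  if (!is.null(coupling)) cpl[names(coupling)] <- coupling
  structure(list(n_subjects = as.integer(n_subjects), means = m, sds = s,
                 bounds = b, coupling = cpl, seed = as.integer(seed)),
            class = "esteem_cohort_spec")
}

#' Default vulnerability-to-parameter coupling
#'
#' Sign pattern for planted-vulnerability cohorts: higher vulnerability
#' lowers baseline self-esteem and average initial approval beliefs, and
#' raises the SPE weight and the range of initial beliefs. The scale
#' argument is in units of each parameter's generative SD.
#'
#' @param strength Coupling magnitude in SD units (1 shifts a parameter by
#'   one SD per unit vulnerability).
#' @param spec A cohort spec supplying the SDs.
#' @return Named coupling vector suitable for [cohort_spec()].
#' @export
vulnerability_coupling <- function(strength = 1, spec = cohort_spec()) {
  s <- spec$sds
  strength * c(w0 = -s[["w0"]], w1 = s[["w1"]],
               avg_init = -s[["avg_init"]], range_init = s[["range_init"]])
}

# Inverse-CDF draw from a truncated normal; `mean` may be a vector.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) {
    if (any(mean < lower | mean > upper))
      stop("degenerate draw outside bounds")
    return(rep_len(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (any(phi - plo <= 0)) stop("infeasible truncation bounds")
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

#' Draw a cohort of agent parameters around a latent vulnerability factor
#'
#' Each subject receives a standard-normal vulnerability score; every
#' parameter is then drawn from a truncated Gaussian centred at
#' `mean + coupling * vulnerability` with the spec's SD and bounds, the
#' draws being independent across parameters given vulnerability.
#'
#' @param spec An `"esteem_cohort_spec"`.
#' @return A list with `params` (data frame, one row per subject, columns
#'   `subject`, the nine generative parameters, plus derived `esv1_init`,
#'   `esv4_init` clipped to \[-1, 1\]) and `vulnerability` (numeric vector,
#'   the ground-truth latent scores).
#' @export
draw_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "esteem_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  vul <- stats::rnorm(n)
  cols <- lapply(names(spec$means), function(nm) {
    mu <- spec$means[[nm]] + spec$coupling[[nm]] * vul
    rtruncnorm(n, mu, spec$sds[[nm]], spec$bounds[[nm]][1],
               spec$bounds[[nm]][2])
  })
  names(cols) <- names(spec$means)
  df <- data.frame(subject = seq_len(n), cols)
  df$esv1_init <- pmin(1, pmax(-1, df$avg_init + df$range_init / 2))
  df$esv4_init <- pmin(1, pmax(-1, df$avg_init - df$range_init / 2))
  list(params = df, vulnerability = vul)
}

cohort_row_params <- function(row, model = "M1") {
  model <- model_spec(model)
  agent_params(w0 = row$w0, w1 = row$w1, sigma = row$sigma, eta = row$eta,
               esv0 = row$esv0, temperature = row$temperature,
               esv1_init = row$esv1_init, esv4_init = row$esv4_init,
               gamma = row$gamma,
               w2 = if (model$has_expectation_term) 0.02 else NULL)
}

#' Simulate behaviour for a cohort
#'
#' One task session and one behavioural record per subject, with distinct
#' per-subject sub-seeds derived deterministically from the master seed.
#'
#' @param params Data frame of per-subject parameters (as from
#'   [draw_cohort()]`$params`).
#' @param config Session design, see [session_config()].
#' @param model Generative model id.
#' @param seed Master seed for choice/rating noise.
#' @param session Optional fixed `"esteem_session"` shared by all subjects;
#'   by default each subject gets an independent session seed derived from
#'   `seed`.
#' @return List of `"esteem_record"` objects (traces attached as attribute
#'   `"traces"`).
#' @export
simulate_cohort <- function(params, config = session_config(), model = "M1",
                            seed = 1L, session = NULL) {
  recs <- vector("list", nrow(params))
  traces <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    ses <- if (is.null(session)) build_session(config,
                                               derive_seed(seed, 2L * i))
           else session
    sim <- simulate_agent(ses, cohort_row_params(params[i, ], model), model,
                          seed = derive_seed(seed, 2L * i + 1L))
    recs[[i]] <- sim$record
    traces[[i]] <- sim$trace
  }
  structure(recs, traces = traces)
}

#' Specification of the symptom-scale battery
#'
#' Eleven scales spanning self-evaluation (trait and state self-esteem,
#' self-perception, narcissism), interpersonal sensitivity (fear of negative
#' evaluation, rejection sensitivity) and symptoms (state/trait/social
#' anxiety and two depression inventories). Each scale loads on the latent
#' vulnerability factor with the stated sign — self-evaluation scales
#' negatively, sensitivity/anxiety/depression scales positively — plus
#' Gaussian residual noise. Defaults give each scale unit total variance so
#' the generated scores are already on a z-scale.
#'
#' @param loadings Named numeric vector over the 11 scales (overrides).
#' @param noise_sd Residual SDs; default `sqrt(1 - loading^2)`.
#' @return A list of class `"esteem_symptom_spec"`.
#' @export
symptom_spec <- function(loadings = NULL, noise_sd = NULL) {
  l <- c(trait_self_esteem = -0.8, state_self_esteem = -0.8,
         self_perception = -0.6, narcissism = -0.3,
         fear_negative_evaluation = 0.6, rejection_sensitivity = 0.6,
         state_anxiety = 0.7, trait_anxiety = 0.7, social_anxiety = 0.7,
         depression_bdi = 0.7, depression_second = 0.7)
  if (!is.null(loadings)) l[names(loadings)] <- loadings
  if (length(l) != 11) stop("exactly 11 symptom scales are required")
  ns <- sqrt(pmax(1 - l ^ 2, 0.05))
  if (!is.null(noise_sd)) ns[names(noise_sd)] <- noise_sd
  if (any(ns <= 0)) stop("noise_sd must be > 0")
  structure(list(scale_names = names(l), loadings = l, noise_sd = ns),
            class = "esteem_symptom_spec")
}

#' Generate symptom-scale scores from vulnerability
#'
#' `scale_ij = loading_j * vulnerability_i + N(0, noise_sd_j)`.
#'
#' @param vulnerability Per-subject latent scores.
#' @param spec An `"esteem_symptom_spec"`.
#' @param seed Integer seed.
#' @return Data frame, subjects x 11 scales.
#' @export
draw_symptoms <- function(vulnerability, spec = symptom_spec(), seed = 1L) {
  stopifnot(inherits(spec, "esteem_symptom_spec"))
  set.seed(as.integer(seed))
  n <- length(vulnerability)
  out <- vapply(seq_along(spec$loadings), function(j)
    spec$loadings[j] * vulnerability + stats::rnorm(n, 0, spec$noise_sd[j]),
    numeric(n))
  out <- as.data.frame(out)
  names(out) <- spec$scale_names
  out
}

#' Build a complete synthetic cohort dataset
#'
#' Parameters, behaviour and symptom scores in one call: the full study-like
#' object every downstream analysis consumes.
#'
#' @param n Number of subjects.
#' @param seed Master seed.
#' @param coupling Vulnerability-to-parameter coupling (default none).
#' @param spec Optional pre-built `"esteem_cohort_spec"` (overrides `n`,
#'   `coupling`, `seed` for the parameter draws).
#' @param symptoms An `"esteem_symptom_spec"`.
#' @param config Session design.
#' @param model Generative model id.
#' @param simulate_behavior Set `FALSE` to skip the (comparatively slow)
#'   behavioural simulation when only parameters/symptoms are needed.
#' @return A list of class `"esteem_cohort"` with `params`, `records`,
#'   `symptoms`, `vulnerability`, `spec`, `symptom_spec`.
#' @export
make_cohort <- function(n = 40, seed = 1L, coupling = NULL, spec = NULL,
                        symptoms = symptom_spec(), config = session_config(),
                        model = "M1", simulate_behavior = TRUE) {
  if (is.null(spec))
    spec <- cohort_spec(n_subjects = n, coupling = coupling, seed = seed)
  drawn <- draw_cohort(spec)
  recs <- if (simulate_behavior)
    simulate_cohort(drawn$params, config, model,
                    seed = derive_seed(spec$seed, 999L))
  else NULL
  sym <- draw_symptoms(drawn$vulnerability, symptoms,
                       seed = derive_seed(spec$seed, 555L))
  structure(list(params = drawn$params, records = recs, symptoms = sym,
                 vulnerability = drawn$vulnerability, spec = spec,
                 symptom_spec = symptoms, model_id = model),
            class = "esteem_cohort")
}

#' @export
print.esteem_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$params), " subjects (generative model ",
      x$model_id, ")\n", sep = "")
  cat("  behaviour: ", if (is.null(x$records)) "not simulated"
      else paste0(length(x$records), " records"), "\n", sep = "")
  cat("  symptoms: ", ncol(x$symptoms), " scales\n", sep = "")
  invisible(x)
}

#' Model-implied first canonical correlation of a planted cohort
#'
#' Under the shared-factor construction (parameters shifted by
#' `coupling * vulnerability` with residual SD `sds`; symptom scales
#' `loading * vulnerability` plus noise), the best linear read-out of
#' vulnerability from each block has correlation
#' \eqn{\rho = \sqrt{a/(1+a)}} with the factor, where `a` sums the squared
#' coupling-to-noise ratios of the block; the first canonical correlation
#' between the blocks is the product of the two read-out correlations.
#' Truncation of the parameter draws is ignored, so the value is exact only
#' when the coupled parameters' bounds are wide.
#'
#' @param spec An `"esteem_cohort_spec"`.
#' @param symptoms An `"esteem_symptom_spec"`.
#' @return Scalar: the implied first canonical correlation.
#' @export
planted_canonical_correlation <- function(spec, symptoms = symptom_spec()) {
  a <- sum((spec$coupling / spec$sds) ^ 2, na.rm = TRUE)
  b <- sum((symptoms$loadings / symptoms$noise_sd) ^ 2)
  sqrt(a / (1 + a)) * sqrt(b / (1 + b))
}
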