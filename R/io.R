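#' Read and write behavioural records
#'
#' TSV with one row per trial and columns `trial_index`, `block`,
#' `group_id`, `choice`, `outcome`, `missed`, `probe_after`,
#' `probe_modelable`, `probe_rating` (empty when no probe). Writing then
#' reading reproduces every field.
#'
#' @param record An `"esteem_record"`.
#' @param path File path.
#' @param approval_probs Group approval probabilities attached on read (used
#'   by model M3); defaults to the standard design.
#' @return `read_behavior()` returns an `"esteem_record"`;
#'   `write_behavior()` returns `path` invisibly.
#' @export
write_behavior <- function(record, path) {
  stopifnot(inherits(record, "esteem_record"))
  utils::write.table(as.data.frame(record), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path, approval_probs = c(0.85, 0.70, 0.30, 0.15)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  required <- c("trial_index", "block", "group_id", "choice", "outcome",
                "missed", "probe_after", "probe_modelable", "probe_rating")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("behaviour table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!df$outcome %in% c("approve", "disapprove", "none"))
  if (length(bad))
    stop("invalid outcome at row ", bad[1], ": '", df$outcome[bad[1]], "'")
  df$missed <- as.logical(df$missed)
  df$probe_after <- as.logical(df$probe_after)
  df$probe_modelable <- as.logical(df$probe_modelable)
  df$probe_rating <- as.numeric(df$probe_rating)
  structure(df, class = c("esteem_record", "data.frame"),
            approval_probs = approval_probs)
}

#' Read a run configuration (JSON or YAML)
#'
#' Recognised keys mirror [session_config()] (`n_groups`, `approval_probs`,
#' `feedback_trials_per_group`, `no_feedback_per_group`, `n_blocks`,
#' `probe_gaps`, `seed`) and an optional `params` block of agent parameters,
#' which is bounds-checked on load.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `config` (an `"esteem_session_config"`),
#'   `params` (an `"esteem_params"` or `NULL`) and `seed`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg_keys <- intersect(names(raw),
                        c("n_groups", "approval_probs",
                          "feedback_trials_per_group",
                          "no_feedback_per_group", "n_blocks", "probe_gaps",
                          "max_run", "max_recurrence_gap", "max_attempts"))
  config <- do.call(session_config, raw[cfg_keys])
  params <- NULL
  if (!is.null(raw$params)) params <- do.call(agent_params, raw$params)
  list(config = config, params = params,
       seed = if (is.null(raw$seed)) NA_integer_ else as.integer(raw$seed))
}

#' Serialise a fit result to JSON
#'
#' @param fit An `"esteem_fit"`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "esteem_fit"))
  out <- list(model = fit$model$model_id,
              params = as.list(coef(fit)),
              loglik = fit$loglik, k = fit$k, n = fit$n, bic = fit$bic,
              r2_esteem = fit$r2_esteem, r2_choice = fit$r2_choice,
              mse_esteem = fit$mse_esteem,
              n_restarts_converged = fit$n_restarts_converged,
              seed = fit$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
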