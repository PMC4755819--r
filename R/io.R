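# File interfaces: the canonical trial-table CSV (NA as empty field,
# 1-based trial indices) and JSON/YAML serialisation of environment, agent,
# and run configurations.

TRIAL_REQUIRED <- c("participant_id", "group", "condition", "trial",
                    "choice", "reward")

#' Write a trial table to CSV
#'
#' Canonical encoding: comma-separated, header row, `NA` as an empty field.
#'
#' @param trials A trial table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a trial-table CSV
#'
#' Checks the required columns (`participant_id`, `group`, `condition`,
#' `trial`, `choice`, `reward`), column types, and per-participant trial
#' contiguity; schema violations are reported with the offending column or
#' row.
#'
#' @param path CSV file.
#' @return A validated trial table.
#' @export
read_trial_table <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  validate_trial_table(trials)
}

#' @rdname read_trial_table
#' @param trials A data.frame to validate in place.
#' @export
validate_trial_table <- function(trials) {
  missing_cols <- setdiff(TRIAL_REQUIRED, names(trials))
  if (length(missing_cols))
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in c("trial", "choice", "reward")) {
    if (!is.numeric(trials[[col]]))
      stop("column '", col, "' must be numeric")
  }
  bad <- which(!trials$choice %in% c(0, 1))
  if (length(bad))
    stop("column 'choice' must be 0 or 1 (first bad row: ", bad[1], ")")
  for (pt in split(trials, trials$participant_id)) {
    tr <- sort(pt$trial)
    if (any(tr != seq_along(tr)))
      stop("participant ", pt$participant_id[1],
           ": trials are not contiguous 1..n")
  }
  trials
}

config_to_list <- function(x) {
  x <- unclass(x)
  lapply(x, function(v) if (inherits(v, c("lf_env_config", "lf_agent_config")))
    config_to_list(v) else v)
}

#' Serialise a configuration to JSON or YAML
#'
#' Works for [env_config()] and [agent_config()] objects; the format is
#' inferred from the file extension (`.json`, `.yaml`, `.yml`).
#'
#' @param config The configuration object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lst <- config_to_list(config)
  lst$.class <- class(config)[1]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(lst, path)
  else
    jsonlite::write_json(lst, path, auto_unbox = TRUE, null = "null",
                         digits = NA)
  invisible(path)
}

#' Read a configuration from JSON or YAML
#'
#' @param path File written by [write_config()] (or hand-authored with the
#'   same field names; a `.class` field of `lf_env_config` or
#'   `lf_agent_config` selects the constructor, defaulting to the field set
#'   that matches).
#' @return An [env_config()] or [agent_config()].
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- lst$.class
  lst$.class <- NULL
  if (is.null(cls))
    cls <- if ("kind" %in% names(lst)) "lf_agent_config" else "lf_env_config"
  lst <- lapply(lst, function(v) if (is.list(v) && length(v) == 0) NULL else v)
  switch(cls,
         lf_env_config = do.call(env_config, lst),
         lf_agent_config = do.call(agent_config, lst),
         stop("unknown config class: ", cls))
}
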