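.behavior_cols <- c("participant_id", "group", "age_years", "coherence_pct",
                    "direction", "choice", "rt_s", "is_catch", "trial_index")

#' Write / read a behavioural trial table
#'
#' Plain-CSV round trip for the tidy trial schema. Reading validates the
#' schema and value domains and reports offending lines; response times may
#' be ingested in milliseconds with an explicit unit flag (never guessed).
#'
#' @param dataset behavioural trial table.
#' @param path CSV path.
#' @export
write_behavior <- function(dataset, path) {
  miss <- setdiff(.behavior_cols, names(dataset))
  if (length(miss)) stop("dataset misses columns: ",
                         paste(miss, collapse = ", "))
  write.csv(dataset[.behavior_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @param rt_unit unit of the `rt_s` column in the file: `"s"` (default) or
#'   `"ms"` (converted on read).
#' @return `read_behavior` returns the validated trial table (with a
#'   derived `correct` column).
#' @export
read_behavior <- function(path, rt_unit = c("s", "ms")) {
  rt_unit <- match.arg(rt_unit)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(.behavior_cols, names(raw))
  if (length(miss)) stop("file misses columns: ", paste(miss, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("0-row behaviour file")
    out <- raw[.behavior_cols]
    out$rt_s <- numeric(0); out$age_years <- numeric(0)
    out$coherence_pct <- numeric(0); out$is_catch <- logical(0)
    out$trial_index <- integer(0); out$correct <- integer(0)
    return(out)
  }
  bad_line <- function(flag, what) {
    if (any(flag))
      stop("invalid ", what, " at line(s): ",
           paste(head(which(flag) + 1, 10), collapse = ", "))
  }
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad_line(!is.na(x) & x != "" & is.na(v), what)
    v
  }
  out <- data.frame(participant_id = raw$participant_id, group = raw$group,
                    age_years = num(raw$age_years, "age_years"),
                    coherence_pct = num(raw$coherence_pct, "coherence_pct"),
                    direction = raw$direction, choice = raw$choice,
                    rt_s = num(raw$rt_s, "rt_s (use --rt-unit for ms data; locale decimal commas are rejected)"),
                    is_catch = toupper(raw$is_catch) %in% c("TRUE", "1"),
                    trial_index = as.integer(num(raw$trial_index,
                                                 "trial_index")),
                    stringsAsFactors = FALSE)
  bad_line(!out$direction %in% c("up", "down"), "direction (must be up/down)")
  bad_line(!(out$choice %in% c("up", "down") | is.na(out$rt_s)),
           "choice (must be up/down)")
  if (rt_unit == "ms") out$rt_s <- out$rt_s / 1000
  out$correct <- as.integer(out$choice == out$direction)
  out
}

#' Read a YAML run configuration
#'
#' Thin wrapper merging a YAML file over [default_run_config()].
#'
#' @param path YAML file.
#' @return a run-config list (see [run_pipeline()]).
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  cfg[names(user)] <- user
  cfg
}
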