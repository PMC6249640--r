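# Schema validation shared by readers, fitters and the synthetic generator.
# CSV dialects are fixed: longitudinal = id,time,response,<covariates...>;
# survival = id,time,event; effects = id,b0,b1.

validate_survival <- function(data, require_id = FALSE) {
  if (!is.data.frame(data)) abort("Survival data must be a data frame.")
  missing_cols <- setdiff(c("time", "event"), names(data))
  if (length(missing_cols)) {
    abort(sprintf("Survival table is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  data <- as_tibble(data)
  if (!"id" %in% names(data)) {
    if (require_id) abort("Survival table is missing column: id.")
    data$id <- as.character(seq_len(nrow(data)))
  }
  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) {
    abort(sprintf("Duplicate subject id '%s' in survival table.",
                  data$id[anyDuplicated(data$id)]))
  }
  bad_t <- which(!is.finite(data$time) | data$time <= 0)
  if (length(bad_t)) {
    abort(sprintf("Survival time at row %d is not a positive number (%s).",
                  bad_t[1], format(data$time[bad_t[1]])))
  }
  bad_e <- which(!data$event %in% c(0, 1))
  if (length(bad_e)) {
    abort(sprintf("Event indicator at row %d must be 0 or 1 (got %s).",
                  bad_e[1], format(data$event[bad_e[1]])))
  }
  data[c("id", "time", "event")]
}

validate_effects <- function(effects) {
  if (!is.data.frame(effects)) abort("Effects must be a data frame.")
  missing_cols <- setdiff(c("id", "b0", "b1"), names(effects))
  if (length(missing_cols)) {
    abort(sprintf("Effects table is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  effects <- as_tibble(effects)
  effects$id <- as.character(effects$id)
  if (anyDuplicated(effects$id)) {
    abort(sprintf("Duplicate subject id '%s' in effects table.",
                  effects$id[anyDuplicated(effects$id)]))
  }
  bad <- which(!is.finite(effects$b0) | !is.finite(effects$b1))
  if (length(bad)) abort(sprintf("Non-finite random effect at row %d.", bad[1]))
  effects[c("id", "b0", "b1")]
}

validate_longitudinal <- function(data) {
  if (!is.data.frame(data)) abort("Longitudinal data must be a data frame.")
  missing_cols <- setdiff(c("id", "time", "response"), names(data))
  if (length(missing_cols)) {
    abort(sprintf("Longitudinal table is missing column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  data <- as_tibble(data)
  data$id <- as.character(data$id)
  bad_t <- which(!is.finite(data$time) | data$time < 0)
  if (length(bad_t)) {
    abort(sprintf("Longitudinal time at row %d is not a non-negative number (%s).",
                  bad_t[1], format(data$time[bad_t[1]])))
  }
  bad_y <- which(!is.finite(data$response))
  if (length(bad_y)) abort(sprintf("Missing or non-finite response at row %d.", bad_y[1]))
  data
}

#' Read the two-stage input tables
#'
#' CSV readers with schema validation. The longitudinal file must contain
#' `id`, `time`, `response` plus any fixed-effect covariate columns; the
#' survival file exactly `id`, `time`, `event`; the effects file exactly
#' `id`, `b0`, `b1`. Offending rows are reported by position.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @name two-stage-io
#' @export
read_longitudinal <- function(path) {
  validate_longitudinal(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname two-stage-io
#' @export
read_survival <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  extra <- setdiff(names(df), c("id", "time", "event"))
  if (length(extra)) {
    abort(sprintf("Unexpected column(s) in survival table: %s.",
                  paste(extra, collapse = ", ")))
  }
  validate_survival(df, require_id = TRUE)
}

#' @rdname two-stage-io
#' @export
read_effects <- function(path) {
  validate_effects(readr::read_csv(path, show_col_types = FALSE))
}
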