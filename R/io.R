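EVENT_LOG_SCHEMA_VERSION <- "1.0"

session_to_json <- function(row) {
  att <- row$attempts[[1]]
  jsonlite::toJSON(list(
    schema_version = EVENT_LOG_SCHEMA_VERSION,
    learner_id = row$learner_id,
    arm = row$arm,
    session_index = row$session_index,
    start = iso8601(row$start),
    end = iso8601(row$end),
    score = if (is.na(row$score)) NULL else row$score,
    completed = row$completed,
    attempts = att
  ), auto_unbox = TRUE, digits = NA, null = "null", na = "null")
}

#' Write an event log
#'
#' Serializes a session log either as JSONL (one session per line with
#' nested attempts, schema-versioned) or as a flattened RFC 4180 CSV with
#' one row per attempt and the session fields repeated. Timestamps are
#' written as ISO-8601 UTC.
#'
#' @param log A `trial_log` or sessions tibble.
#' @param path Output file path.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(log, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  sessions <- if (is.data.frame(log)) log else log$sessions
  if (format == "jsonl") {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(sessions))) {
      writeLines(session_to_json(sessions[i, ]), con)
    }
  } else {
    flat <- flatten_attempts(sessions)
    meta <- sessions[, c("learner_id", "session_index", "start", "end",
                         "score", "completed")]
    meta$start <- iso8601(meta$start)
    meta$end <- iso8601(meta$end)
    flat <- dplyr::left_join(flat, meta,
                             by = c("learner_id", "session_index"))
    flat$schema_version <- EVENT_LOG_SCHEMA_VERSION
    cols <- c("schema_version", "learner_id", "arm", "session_index",
              "start", "end", "score", "completed", "task_id",
              "attempt_index", "correct", "feedback_level", "p_next")
    write.csv(flat[, cols], path, row.names = FALSE, na = "")
  }
  invisible(path)
}

parse_session_line <- function(line) {
  rec <- jsonlite::fromJSON(line, simplifyDataFrame = TRUE)
  if (is.null(rec$schema_version)) stop("missing schema_version")
  if (!identical(as.character(rec$schema_version),
                 EVENT_LOG_SCHEMA_VERSION)) {
    stop(sprintf("schema version mismatch: got '%s', expected '%s'",
                 rec$schema_version, EVENT_LOG_SCHEMA_VERSION))
  }
  att <- tibble::as_tibble(rec$attempts)
  att$feedback_level <- as.integer(att$feedback_level)
  att$p_next <- as.numeric(att$p_next)
  tibble::tibble(
    learner_id = as.character(rec$learner_id),
    arm = as.character(rec$arm),
    session_index = as.integer(rec$session_index),
    start = parse_iso8601(rec$start),
    end = parse_iso8601(rec$end),
    score = if (is.null(rec$score)) NA_real_ else as.numeric(rec$score),
    completed = isTRUE(rec$completed),
    attempts = list(att)
  )
}

#' Read and validate an event log
#'
#' Parses a JSONL or flattened-CSV event log back into the in-memory
#' session representation. Malformed lines/rows are not fatal: they are
#' collected into a rejects table (with line numbers and reasons)
#' attached as the `"rejects"` attribute and returned alongside the valid
#' records. A schema version other than the supported one is an error.
#'
#' @param path Input file.
#' @param format `"jsonl"` or `"csv"`; guessed from the extension when
#'   missing.
#' @return A sessions tibble with attribute `"rejects"`.
#' @export
read_event_log <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read event log: ", path,
                               call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
              else "jsonl"
  }
  rejects <- tibble::tibble(line = integer(), reason = character())
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      if (!nzchar(trimws(lines[i]))) next
      rows[[i]] <- tryCatch(parse_session_line(lines[i]), error = function(e) {
        if (grepl("schema version mismatch", conditionMessage(e))) {
          stop(conditionMessage(e), call. = FALSE)
        }
        rejects[nrow(rejects) + 1L, ] <<-
          list(i, conditionMessage(e))
        NULL
      })
    }
    sessions <- dplyr::bind_rows(rows)
  } else {
    flat <- read.csv(path, stringsAsFactors = FALSE,
                     colClasses = c(schema_version = "character"))
    if (!"schema_version" %in% names(flat) ||
        !all(flat$schema_version == EVENT_LOG_SCHEMA_VERSION)) {
      stop("schema version mismatch in CSV event log", call. = FALSE)
    }
    key <- paste(flat$learner_id, flat$session_index, sep = "\r")
    rows <- lapply(unique(key), function(k) {
      g <- flat[key == k, , drop = FALSE]
      tibble::tibble(
        learner_id = as.character(g$learner_id[1]),
        arm = g$arm[1],
        session_index = as.integer(g$session_index[1]),
        start = parse_iso8601(g$start[1]),
        end = parse_iso8601(g$end[1]),
        score = if (is.na(g$score[1]) || g$score[1] == "") NA_real_
                else as.numeric(g$score[1]),
        completed = as.logical(g$completed[1]),
        attempts = list(tibble::tibble(
          task_id = g$task_id,
          attempt_index = as.integer(g$attempt_index),
          correct = as.integer(g$correct),
          feedback_level = suppressWarnings(as.integer(g$feedback_level)),
          p_next = suppressWarnings(as.numeric(g$p_next))
        ))
      )
    })
    sessions <- dplyr::bind_rows(rows)
  }
  val <- validate_event_log(sessions)
  rejects <- dplyr::bind_rows(rejects, val$rejects)
  out <- val$log
  attr(out, "rejects") <- rejects
  out
}

#' Validate a session log against the event-log schema
#'
#' Checks field presence and types, score bounds, arm vocabulary, and that
#' session start times are non-decreasing within each learner. Validation
#' is idempotent: validating an already-valid log changes nothing.
#'
#' @param sessions Sessions tibble.
#' @return A list with `log` (valid rows) and `rejects` (tibble of row
#'   numbers and reasons).
#' @export
validate_event_log <- function(sessions) {
  rejects <- tibble::tibble(line = integer(), reason = character())
  if (is.null(sessions) || nrow(sessions) == 0) {
    return(list(log = sessions, rejects = rejects))
  }
  bad <- function(i, why) {
    rejects[nrow(rejects) + 1L, ] <<- list(i, why)
  }
  keep <- rep(TRUE, nrow(sessions))
  for (i in seq_len(nrow(sessions))) {
    s <- sessions[i, ]
    why <- NULL
    if (is.na(s$learner_id) || !nzchar(s$learner_id)) {
      why <- "missing learner_id"
    } else if (!s$arm %in% c("control", "experiment")) {
      why <- "unknown arm"
    } else if (is.na(s$session_index) || s$session_index < 1) {
      why <- "invalid session_index"
    } else if (is.na(s$start) || is.na(s$end) || s$end < s$start) {
      why <- "invalid timestamps"
    } else if (!is.na(s$score) && (s$score < 0 || s$score > 100)) {
      why <- "score out of range"
    } else if (isTRUE(s$completed) && is.na(s$score)) {
      why <- "completed session without score"
    }
    if (!is.null(why)) {
      bad(i, why)
      keep[i] <- FALSE
    }
  }
  ok <- sessions[keep, , drop = FALSE]
  if (nrow(ok) > 1) {
    ord <- order(ok$learner_id, ok$session_index)
    okk <- ok[ord, ]
    drop_ids <- integer(0)
    for (i in 2:nrow(okk)) {
      if (okk$learner_id[i] == okk$learner_id[i - 1] &&
          okk$start[i] < okk$end[i - 1]) {
        bad(which(keep)[ord[i]], "timestamps out of order within learner")
        drop_ids <- c(drop_ids, ord[i])
      }
    }
    if (length(drop_ids)) ok <- ok[-drop_ids, , drop = FALSE]
  }
  list(log = ok, rejects = rejects)
}

#' Write or read a trial configuration as YAML
#'
#' @param config A [trial_config()].
#' @param path YAML file path.
#' @return `read_trial_config()` returns a [trial_config()];
#'   `write_trial_config()` returns `path` invisibly.
#' @export
write_trial_config <- function(config, path) {
  stopifnot(inherits(config, "trial_config"))
  x <- unclass(config)
  x$spacing_probs <- as.list(x$spacing_probs)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_trial_config
#' @export
read_trial_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(trial_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("configuration error: unknown keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(x$spacing_probs)) {
    x$spacing_probs <- unlist(x$spacing_probs)
  }
  do.call(trial_config, x)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a command: seed, a hash of the
#' configuration, package version, input/output paths and a timestamp.
#' One manifest is written per CLI invocation.
#'
#' @param dir Output directory.
#' @param config Configuration object (hashed).
#' @param seed Integer seed used.
#' @param inputs,outputs Character vectors of paths.
#' @param command Command name.
#' @return Path of the manifest, invisibly.
#' @export
write_run_manifest <- function(dir, config, seed, inputs = character(),
                               outputs = character(), command = "run") {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    command = command,
    package = "bktrial",
    package_version = as.character(packageVersion("bktrial")),
    seed = seed,
    config_hash = rlang::hash(config),
    inputs = inputs,
    outputs = outputs,
    created = iso8601(Sys.time())
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
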