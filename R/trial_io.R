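#' Trial metadata
#'
#' Identifies one quiet-standing trial within a study design of repeated
#' sessions and trials per subject.
#'
#' @param subject_id Opaque subject label.
#' @param group Group label: `"younger"`, `"older"` or `"unknown"`.
#' @param session Session number (>= 1).
#' @param trial Trial number within session (>= 1).
#' @param condition Visual condition: `"eyes_open"` or `"eyes_closed"`.
#' @return An object of class `trial_meta`.
#' @export
trial_meta <- function(subject_id = "unknown", group = "unknown",
                       session = 1L, trial = 1L, condition = "eyes_open") {
  group <- match.arg(group, c("younger", "older", "unknown"))
  condition <- match.arg(condition, c("eyes_open", "eyes_closed"))
  session <- as.integer(session); trial <- as.integer(trial)
  if (is.na(session) || session < 1L) stop("`session` must be >= 1")
  if (is.na(trial) || trial < 1L) stop("`trial` must be >= 1")
  structure(list(subject_id = as.character(subject_id), group = group,
                 session = session, trial = trial, condition = condition),
            class = "trial_meta")
}

#' @export
print.trial_meta <- function(x, ...) {
  cat(sprintf("<trial_meta> subject %s (%s), session %d, trial %d, %s\n",
              x$subject_id, x$group, x$session, x$trial, x$condition))
  invisible(x)
}

#' Write a force-plate trial to a delimited text file
#'
#' The on-disk format is self-describing plain text: `#`-prefixed header lines
#' carry metadata keys (subject, group, session, trial, condition, units),
#' followed by a comma-separated table with columns `time`, `cop_x`, `grf_x`
#' and, when present, `grf_z`. Values are written with 17 significant digits,
#' so a write/read round trip reproduces doubles bit-identically.
#'
#' @param s A [sway_series()].
#' @param meta A [trial_meta()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_trial()]
#' @export
write_trial <- function(s, meta = trial_meta(), path) {
  validate_sway_series(s)
  stopifnot(inherits(meta, "trial_meta"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# subject: %s", meta$subject_id),
    sprintf("# group: %s", meta$group),
    sprintf("# session: %d", meta$session),
    sprintf("# trial: %d", meta$trial),
    sprintf("# condition: %s", meta$condition),
    "# units: time=s, cop=mm, grf=N"), con)
  cols <- list(time = sway_times(s), cop_x = s$cop_x, grf_x = s$grf_x)
  if (!is.null(s$grf_z)) cols$grf_z <- s$grf_z
  writeLines(paste(names(cols), collapse = ","), con)
  body <- do.call(paste, c(lapply(cols, function(v) sprintf("%.17g", v)),
                           sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a force-plate trial from a delimited text file
#'
#' Accepts comma- or tab-delimited files in the layout produced by
#' [write_trial()]: optional `#` metadata header lines, a column header naming
#' at least `time`, `cop_x` and `grf_x` (a `grf_z` column is optional), then
#' numeric rows. The sampling rate is inferred from the median time step;
#' timestamps must be uniform to within 1e-6 s.
#'
#' @param path Path to a trial file.
#' @return A list with elements `series` ([sway_series()]) and `meta`
#'   ([trial_meta()]).
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- parse_meta_lines(meta_lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("trial file has no data rows")
  sep <- if (grepl("\t", body[1])) "\t" else ","
  header <- trimws(strsplit(body[1], sep, fixed = TRUE)[[1]])
  for (need in c("time", "cop_x", "grf_x"))
    if (!need %in% header) stop("missing channel: column '", need, "' not found")
  df <- utils::read.table(text = paste(body[-1], collapse = "\n"), sep = sep,
                          col.names = header, colClasses = "numeric")
  if (anyNA(df)) stop("non-numeric or missing cell in trial data")
  tt <- df$time
  dt <- diff(tt)
  if (any(dt <= 0)) stop("time column must be strictly increasing")
  if (max(abs(dt - stats::median(dt))) > 1e-6)
    stop("non-uniform sampling: timestamp jitter exceeds 1e-6 s")
  fs <- 1 / stats::median(dt)
  series <- sway_series(fs = fs, t0 = tt[1], cop_x = df$cop_x, grf_x = df$grf_x,
                        grf_z = if ("grf_z" %in% header) df$grf_z)
  list(series = series, meta = meta)
}

parse_meta_lines <- function(meta_lines) {
  kv <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- trimws(m[3])
  }
  trial_meta(
    subject_id = kv$subject %||% "unknown",
    group = kv$group %||% "unknown",
    session = as.integer(kv$session %||% 1L),
    trial = as.integer(kv$trial %||% 1L),
    condition = kv$condition %||% "eyes_open")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
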