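#' SVC dialect descriptor
#'
#' Describes the plain-text layout used for digitizer recordings: the first
#' line holds the sample count, every following line one whitespace-separated
#' sample. The column order is carried in the descriptor so corpora with
#' permuted columns can be read without code changes. Timestamps are integer
#' milliseconds; positions and the pressure/tilt channels are device units.
#'
#' @param columns character vector naming, in file order, the seven sample
#'   fields `x, y, t, on_surface, azimuth, altitude, pressure`.
#' @param timeUnit unit of the timestamp column; only "ms" is supported.
#' @return A list of class `svcDialect`.
#' @export
#' @examples
#' svcDialect()
svcDialect <- function(columns = c("x", "y", "t", "on_surface",
                                   "azimuth", "altitude", "pressure"),
                       timeUnit = "ms") {
  if (!setequal(columns, SAMPLE_COLUMNS) || length(columns) != 7L)
    stop("dialect columns must be a permutation of: ",
         paste(SAMPLE_COLUMNS, collapse = ", "), call. = FALSE)
  timeUnit <- match.arg(timeUnit, "ms")
  structure(list(columns = columns, timeUnit = timeUnit), class = "svcDialect")
}

#' Validate a task recording
#'
#' Reports semantic defects of a recording without throwing: non-monotone or
#' duplicated timestamps, non-binary contact flags, negative pressure, too
#' few samples, or the absence of any on-surface sample. An empty report
#' means the recording is usable by every downstream operation.
#'
#' @param rec a [TaskRecording-class] (possibly built with `check = FALSE`).
#' @return data.frame with columns `sample` (0-based index of the offending
#'   sample, NA for whole-recording defects), `rule`, `message`; zero rows if
#'   the recording is clean.
#' @export
#' @examples
#' rec <- TaskRecording("l", data.frame(
#'   t = c(0, 10), x = 0, y = 0, on_surface = 1,
#'   azimuth = 0, altitude = 0, pressure = 0))
#' validateRecording(rec)   # empty report
validateRecording <- function(rec) {
  stopifnot(is(rec, "TaskRecording"))
  s <- rec@samples
  viol <- list()
  add <- function(sample, rule, message)
    viol[[length(viol) + 1L]] <<- data.frame(sample = sample, rule = rule,
                                             message = message)
  if (nrow(s) < 2L)
    add(NA_integer_, "min_samples",
        sprintf("recording has %d sample(s), need >= 2", nrow(s)))
  if (nrow(s) >= 2L) {
    dt <- diff(s$t)
    for (i in which(dt == 0))
      add(i, "duplicate_timestamp",
          sprintf("duplicated timestamp %s at sample %d", format(s$t[i + 1L]), i))
    for (i in which(dt < 0))
      add(i, "non_monotone_time",
          sprintf("timestamp decreases at sample %d", i))
  }
  for (i in which(!s$on_surface %in% c(0, 1)))
    add(i - 1L, "contact_flag",
        sprintf("contact flag %s at sample %d not in {0,1}", format(s$on_surface[i]), i - 1L))
  for (i in which(s$pressure < 0))
    add(i - 1L, "negative_pressure",
        sprintf("negative pressure at sample %d", i - 1L))
  if (nrow(s) >= 1L && all(s$on_surface != 1))
    add(NA_integer_, "no_on_surface", "recording has no on-surface sample")
  if (length(viol)) do.call(rbind, viol)
  else data.frame(sample = integer(), rule = character(), message = character())
}

.fmtNum <- function(v) {
  # integers (even stored as doubles) print without decimal point, so
  # integer-valued fields round-trip bit-exactly
  ifelse(v == round(v) & abs(v) < 1e15,
         format(v, scientific = FALSE, trim = TRUE, nsmall = 0),
         format(v, scientific = FALSE, trim = TRUE, digits = 15))
}

#' Read an SVC-dialect recording
#'
#' Parses a plain-text digitizer file: first line = sample count, then one
#' line per sample with whitespace-separated numeric fields in the dialect's
#' column order. Sample order in the file is preserved.
#'
#' @param path file path or a `connection`.
#' @param taskId task identifier to attach to the recording.
#' @param dialect an [svcDialect()] descriptor.
#' @param check validate the recording after parsing (default `TRUE`).
#' @return A [TaskRecording-class].
#' @export
readRecording <- function(path, taskId = "task", dialect = svcDialect(),
                          check = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty input: no sample-count header", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n)) stop("parse error at line 1: header is not a sample count",
                     call. = FALSE)
  body <- lines[-1L]
  if (length(body) != n)
    stop(sprintf("header declares %d samples but file has %d data lines",
                 n, length(body)), call. = FALSE)
  if (n == 0L) stop("empty input: recording declares 0 samples", call. = FALSE)
  fields <- strsplit(trimws(body), "[[:space:]]+")
  nf <- lengths(fields)
  bad <- which(nf != 7L)
  if (length(bad))
    stop(sprintf("parse error at line %d: expected 7 columns, found %d",
                 bad[1L] + 1L, nf[bad[1L]]), call. = FALSE)
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    badRow <- ceiling(which(is.na(vals))[1L] / 7)
    stop(sprintf("parse error at line %d: non-numeric field", badRow + 1L),
         call. = FALSE)
  }
  m <- matrix(vals, ncol = 7L, byrow = TRUE,
              dimnames = list(NULL, dialect$columns))
  samples <- as.data.frame(m)[, SAMPLE_COLUMNS]
  TaskRecording(taskId, samples, check = check)
}

#' Write an SVC-dialect recording
#'
#' Serializes a recording so that [readRecording()] reproduces it exactly;
#' integer-valued fields are written without a decimal point and round-trip
#' bit-exactly.
#'
#' @param rec a valid [TaskRecording-class].
#' @param path file path or connection; if `NULL`, the lines are returned
#'   invisibly instead of written.
#' @param dialect an [svcDialect()] descriptor.
#' @return Invisibly, the character vector of file lines.
#' @export
writeRecording <- function(rec, path = NULL, dialect = svcDialect()) {
  stopifnot(is(rec, "TaskRecording"))
  report <- validateRecording(rec)
  if (nrow(report))
    stop("refusing to write invalid recording: ",
         paste(report$message, collapse = "; "), call. = FALSE)
  s <- rec@samples[, dialect$columns]
  cols <- lapply(s, .fmtNum)
  lines <- c(format(nrow(s)), do.call(paste, cols))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a session from a manifest
#'
#' A session manifest is a tab-separated file with columns `task_id` and
#' `file` (paths relative to the manifest's directory), one row per task.
#'
#' @param manifestPath path to the manifest file.
#' @param subjectId subject identifier for the resulting session.
#' @param dialect an [svcDialect()].
#' @param age,sex,handedness,label session metadata (see [Session()]).
#' @return A [Session-class].
#' @export
readSessionManifest <- function(manifestPath, subjectId = "subject",
                                dialect = svcDialect(), age = NA_integer_,
                                sex = "M", handedness = "R", label = "unknown") {
  man <- read.table(manifestPath, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("task_id", "file") %in% colnames(man)))
    stop("manifest must have columns 'task_id' and 'file'", call. = FALSE)
  base <- dirname(manifestPath)
  recs <- lapply(seq_len(nrow(man)), function(i)
    readRecording(file.path(base, man$file[i]), taskId = man$task_id[i],
                  dialect = dialect))
  names(recs) <- man$task_id
  Session(subjectId, recs, age = age, sex = sex, handedness = handedness,
          label = label)
}

#' Write a cohort of sessions as SVC files
#'
#' Writes one sub-directory per subject containing the task SVC files and a
#' `manifest.tsv`, plus a top-level `labels.tsv` with the demographics and
#' labels.
#'
#' @param sessions list of [Session-class].
#' @param dir output directory (created if missing).
#' @param dialect an [svcDialect()].
#' @return Invisibly, the path to `labels.tsv`.
#' @export
writeCohort <- function(sessions, dir, dialect = svcDialect()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- lapply(sessions, function(ses) {
    sdir <- file.path(dir, ses$subjectId)
    dir.create(sdir, showWarnings = FALSE)
    tasks <- names(ses$recordings)
    files <- paste0(tasks, ".svc")
    for (i in seq_along(tasks))
      writeRecording(ses$recordings[[i]], file.path(sdir, files[i]), dialect)
    write.table(data.frame(task_id = tasks, file = files),
                file.path(sdir, "manifest.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    data.frame(subject_id = ses$subjectId, age = ses$age, sex = ses$sex,
               handedness = ses$handedness, label = ses$label)
  })
  labPath <- file.path(dir, "labels.tsv")
  write.table(do.call(rbind, meta), labPath, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(labPath)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir cohort directory containing `labels.tsv` and per-subject
#'   sub-directories.
#' @param dialect an [svcDialect()].
#' @return List of [Session-class] objects.
#' @export
readCohort <- function(dir, dialect = svcDialect()) {
  lab <- read.table(file.path(dir, "labels.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
  lapply(seq_len(nrow(lab)), function(i)
    readSessionManifest(file.path(dir, lab$subject_id[i], "manifest.tsv"),
                        subjectId = lab$subject_id[i], dialect = dialect,
                        age = as.integer(lab$age[i]), sex = lab$sex[i],
                        handedness = lab$handedness[i], label = lab$label[i]))
}
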