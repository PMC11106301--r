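#' Construct an LFP trace
#'
#' An `lfp_trace` holds one animal's continuous single-channel voltage
#' samples together with its sampling rate and session metadata. Samples are
#' unitless ADC integers (or numeric values for in-memory synthetic traces);
#' no conversion to volts is ever attempted because the acquisition scaling
#' is not part of the stored files.
#'
#' @param samples numeric vector of ADC samples, ordered in time.
#' @param fs sampling rate in Hz (default 1024).
#' @param subject_id,cohort_id character identifiers.
#' @param condition `"group"` or `"single"`.
#' @param t0 session-relative start time in seconds.
#' @param bit_width ADC bit width used by the hexadecimal on-disk dialect.
#' @return an object of class `lfp_trace`.
#' @export
lfp_trace <- function(samples, fs = 1024, subject_id = "unknown",
                      cohort_id = "unknown", condition = c("group", "single"),
                      t0 = 0, bit_width = 16L) {
  condition <- match.arg(condition)
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("'samples' must be a non-empty numeric vector")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number")
  structure(
    list(samples = as.numeric(samples), fs = fs, subject_id = subject_id,
         cohort_id = cohort_id, condition = condition, t0 = t0,
         bit_width = as.integer(bit_width)),
    class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> subject %s (cohort %s, %s), %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$cohort_id, x$condition, length(x$samples),
              x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Duration of a trace in seconds
#' @param trace an `lfp_trace`.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$fs

.hex_width <- function(bit_width) {
  if (bit_width %% 4L != 0L || bit_width < 4L || bit_width > 32L)
    stop("'bit_width' must be a multiple of 4 between 4 and 32")
  bit_width %/% 4L
}

#' Read a hexadecimal space-delimited LFP file
#'
#' The wireless telemetry modules stream samples as fixed-width hexadecimal
#' tokens separated by whitespace (newlines included), one token per sample,
#' in 30-min file segments. Tokens are decoded as two's-complement signed
#' integers at the declared bit width.
#'
#' @param path file to read.
#' @param fs sampling rate in Hz.
#' @param bit_width token bit width; tokens must be exactly `bit_width/4`
#'   hex digits.
#' @param ... metadata passed to [lfp_trace()] (`subject_id`, `cohort_id`,
#'   `condition`, `t0`).
#' @return an [lfp_trace()].
#' @seealso [write_cbrain_hex()], [read_lfp()]
#' @export
read_cbrain_hex <- function(path, fs = 1024, bit_width = 16L, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  width <- .hex_width(bit_width)
  tokens <- scan(path, what = character(), quiet = TRUE)
  if (length(tokens) == 0L) stop("empty LFP file: ", path)
  bad <- grep(sprintf("^[0-9A-Fa-f]{%d}$", width), tokens, invert = TRUE)
  if (length(bad))
    stop(sprintf("malformed hex token '%s' at token index %d in %s",
                 tokens[bad[1L]], bad[1L], path))
  v <- strtoi(tokens, base = 16L)
  # two's complement: high range maps to negative values
  half <- 2^(bit_width - 1)
  v <- ifelse(v >= half, v - 2 * half, v)
  lfp_trace(v, fs = fs, bit_width = bit_width, ...)
}

#' Write a trace in the hexadecimal space-delimited dialect
#'
#' Inverse of [read_cbrain_hex()]: fixed-width uppercase hexadecimal,
#' two's-complement, whitespace-delimited. Round trips are bit exact for any
#' integer representable at the trace's bit width.
#'
#' @param trace an [lfp_trace()] with integer-valued samples.
#' @param path output file.
#' @param tokens_per_line tokens per output line.
#' @return `path`, invisibly.
#' @export
write_cbrain_hex <- function(trace, path, tokens_per_line = 32L) {
  bw <- trace$bit_width
  width <- .hex_width(bw)
  x <- trace$samples
  if (any(x != round(x)))
    stop("samples must be integer-valued for hexadecimal output")
  half <- 2^(bw - 1)
  if (any(x < -half | x > half - 1))
    stop(sprintf("sample out of %d-bit two's-complement range [%d, %d]",
                 bw, -half, half - 1))
  u <- ifelse(x < 0, x + 2 * half, x)
  tok <- sprintf(sprintf("%%0%dX", width), u)
  n <- length(tok)
  rows <- ceiling(n / tokens_per_line)
  idx <- rep(seq_len(rows), each = tokens_per_line)[seq_len(n)]
  lines <- vapply(split(tok, idx), paste, "", collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

#' Read an LFP segment file, dispatching on extension
#'
#' `.hex` files use the hexadecimal dialect ([read_cbrain_hex()]); `.txt`
#' files hold one signed decimal integer per line; `.i16` files are raw
#' little-endian int16. All decode to the same [lfp_trace()].
#'
#' @inheritParams read_cbrain_hex
#' @export
read_lfp <- function(path, fs = 1024, bit_width = 16L, ...) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("hex", "txt", "i16"))
    stop("unrecognised LFP file extension: .", ext)
  if (ext == "hex") return(read_cbrain_hex(path, fs, bit_width, ...))
  if (!file.exists(path)) stop("file not found: ", path)
  if (ext == "txt") {
    v <- scan(path, what = numeric(), quiet = TRUE)
    if (length(v) == 0L) stop("empty LFP file: ", path)
    return(lfp_trace(v, fs = fs, bit_width = bit_width, ...))
  }
  if (ext == "i16") {
    n <- file.size(path) %/% 2L
    if (n == 0L) stop("empty LFP file: ", path)
    v <- readBin(path, "integer", n = n, size = 2L, signed = TRUE,
                 endian = "little")
    return(lfp_trace(v, fs = fs, bit_width = bit_width, ...))
  }
  stop("unrecognised LFP file extension: .", ext)
}

#' Concatenate 30-min file segments into one continuous trace
#'
#' @param segments either a character vector of file paths (read with
#'   [read_lfp()]) or a list of [lfp_trace()] objects, in session order.
#' @param fs sampling rate passed to the reader when `segments` are paths.
#' @param ... further arguments to [read_lfp()].
#' @return a single [lfp_trace()] whose length is the sum of the segment
#'   lengths, in the given order.
#' @export
concatenate_segments <- function(segments, fs = 1024, ...) {
  if (length(segments) == 0L) stop("no segments to concatenate")
  if (is.character(segments))
    segments <- lapply(segments, read_lfp, fs = fs, ...)
  if (!all(vapply(segments, inherits, TRUE, "lfp_trace")))
    stop("'segments' must be file paths or lfp_trace objects")
  ids <- unique(vapply(segments, `[[`, "", "subject_id"))
  if (length(ids) > 1L)
    stop("segments belong to different subjects: ", paste(ids, collapse = ", "))
  fss <- unique(vapply(segments, `[[`, 0, "fs"))
  if (length(fss) > 1L) stop("segments have different sampling rates")
  out <- segments[[1L]]
  out$samples <- unlist(lapply(segments, `[[`, "samples"), use.names = FALSE)
  out
}

#' Session manifest
#'
#' Describes one recording session: cohort, condition, subjects and the
#' ordered LFP segment files of each subject.
#'
#' @param cohort_id character cohort label.
#' @param condition `"group"` or `"single"`.
#' @param subjects character vector of subject IDs (no duplicates).
#' @param files named list mapping each subject ID to an ordered character
#'   vector of segment file paths.
#' @param duration_s expected session length in seconds.
#' @param fs sampling rate in Hz.
#' @param bit_width ADC bit width of the hexadecimal files.
#' @param max_subjects upper bound on cohort size (4 animals per box in the
#'   default design).
#' @return an object of class `session_manifest`.
#' @export
session_manifest <- function(cohort_id, condition = c("group", "single"),
                             subjects, files = NULL, duration_s = 10800,
                             fs = 1024, bit_width = 16L, max_subjects = 4L) {
  condition <- match.arg(condition)
  subjects <- as.character(subjects)
  if (length(subjects) < 1L || length(subjects) > max_subjects)
    stop(sprintf("number of subjects must be between 1 and %d", max_subjects))
  if (anyDuplicated(subjects)) stop("duplicate subject IDs in manifest")
  if (!is.null(files)) {
    if (!setequal(names(files), subjects))
      stop("'files' must be named by exactly the manifest subjects")
    if (any(vapply(files, length, 0L) == 0L))
      stop("every subject needs at least one segment file")
    files <- files[subjects]
  }
  if (duration_s <= 0) stop("'duration_s' must be positive")
  structure(list(cohort_id = cohort_id, condition = condition,
                 subjects = subjects, files = files,
                 duration_s = duration_s, fs = fs,
                 bit_width = as.integer(bit_width)),
            class = "session_manifest")
}

#' @export
print.session_manifest <- function(x, ...) {
  cat(sprintf("<session_manifest> cohort %s (%s): %d subjects, %g s @ %g Hz\n",
              x$cohort_id, x$condition, length(x$subjects), x$duration_s, x$fs))
  invisible(x)
}

#' Read / write a session manifest (YAML or JSON by extension)
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return [session_manifest()].
#' @export
read_manifest <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
              yaml = , yml = yaml::read_yaml(path),
              json = jsonlite::read_json(path, simplifyVector = TRUE),
              stop("unrecognised manifest extension: .", ext))
  files <- m$files
  if (!is.null(files)) files <- lapply(files, as.character)
  session_manifest(m$cohort_id, m$condition, m$subjects, files,
                   duration_s = m$duration_s,
                   fs = if (is.null(m$fs)) 1024 else m$fs,
                   bit_width = if (is.null(m$bit_width)) 16L else m$bit_width)
}

#' @rdname read_manifest
#' @param manifest a [session_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  ext <- tolower(tools::file_ext(path))
  obj <- unclass(manifest)
  switch(ext,
         yaml = , yml = yaml::write_yaml(obj, path),
         json = jsonlite::write_json(obj, path, auto_unbox = TRUE,
                                     pretty = TRUE, null = "null"),
         stop("unrecognised manifest extension: .", ext))
  invisible(path)
}

## ---- behavioural annotations ----

.locomotive_states <- c("inactive", "active_still", "active")

#' Locomotive-state vocabulary
#'
#' Per-second annotation vocabulary: `inactive` (no movement),
#' `active_still` (head movement without displacement), `active` (the animal
#' changes its location).
#' @export
locomotive_states <- function() .locomotive_states

#' Build an annotation table
#'
#' One row per (subject, second). `second` is 1-based and must cover every
#' second of the session for every subject. `huddle_group_id` labels the
#' huddle episode a subject participates in at that second (`NA` when not in
#' trunk-to-trunk contact); it may only be non-missing in group condition.
#'
#' @param df data.frame with columns `subject_id`, `second`,
#'   `locomotive_state` and optionally `huddle_group_id`, `sleep`.
#' @param condition session condition the table belongs to.
#' @param duration_s session length in seconds; defaults to the maximum
#'   annotated second.
#' @return a `data.frame` of class `annotation_table`.
#' @export
annotation_table <- function(df, condition = c("group", "single"),
                             duration_s = NULL) {
  condition <- match.arg(condition)
  need <- c("subject_id", "second", "locomotive_state")
  if (!all(need %in% names(df)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$second <- as.integer(df$second)
  df$locomotive_state <- as.character(df$locomotive_state)
  bad <- setdiff(unique(df$locomotive_state), .locomotive_states)
  if (length(bad))
    stop("unknown locomotive state(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.locomotive_states, collapse = ", "), ")")
  if (is.null(df$huddle_group_id)) df$huddle_group_id <- NA_character_
  df$huddle_group_id[!is.na(df$huddle_group_id) & df$huddle_group_id == ""] <-
    NA_character_
  if (condition == "single" && any(!is.na(df$huddle_group_id)))
    stop("huddle labels are not allowed in single condition")
  if (is.null(duration_s)) duration_s <- max(df$second)
  # completeness: every second 1..duration_s for every subject
  for (s in unique(df$subject_id)) {
    have <- df$second[df$subject_id == s]
    gaps <- setdiff(seq_len(duration_s), have)
    if (length(gaps))
      stop(sprintf("annotation gaps for subject %s at second(s) %s", s,
                   paste(utils::head(gaps, 5L), collapse = ", ")))
    if (anyDuplicated(have))
      stop("duplicate annotated seconds for subject ", s)
  }
  df <- df[order(df$subject_id, df$second), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, condition = condition, duration_s = duration_s,
            class = c("annotation_table", "data.frame"))
}

#' Read per-second behavioural annotations
#'
#' Comma-delimited UTF-8 table with columns `subject_id`, `second`,
#' `locomotive_state`, `huddle_group_id` (empty = not huddled). The table
#' must contain one row per second per manifest subject with no gaps;
#' locomotive states outside the closed vocabulary are rejected.
#'
#' @param path CSV file.
#' @param manifest a [session_manifest()]; supplies condition, subject set
#'   and expected duration.
#' @return an [annotation_table()].
#' @export
read_annotations <- function(path, manifest) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(huddle_group_id = "character"))
  unknown <- setdiff(unique(as.character(df$subject_id)), manifest$subjects)
  if (length(unknown))
    stop("annotation subject(s) not in manifest: ",
         paste(unknown, collapse = ", "))
  missing_subj <- setdiff(manifest$subjects, unique(as.character(df$subject_id)))
  if (length(missing_subj))
    stop("no annotations for manifest subject(s): ",
         paste(missing_subj, collapse = ", "))
  annotation_table(df, condition = manifest$condition,
                   duration_s = floor(manifest$duration_s))
}

#' @rdname read_annotations
#' @param table an [annotation_table()].
#' @export
write_annotations <- function(table, path) {
  out <- as.data.frame(table)
  out$huddle_group_id[is.na(out$huddle_group_id)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
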