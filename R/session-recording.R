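#' Construct a session recording
#'
#' A `session_recording` holds one recording session of multi-channel sEMG:
#' the signal matrix, the per-sample stimulus (class) vector and the
#' per-sample repetition vector, together with the sampling rate and
#' subject/session identifiers. Stimulus value 0 marks rest; values 1-7 mark
#' the seven grasp classes. The stimulus vector plays the role of the
#' refined ("restimulus") label vector of multi-session grasp datasets: it
#' marks the true extent of each muscle activation.
#'
#' @param signal numeric matrix, samples x channels.
#' @param fs sampling rate in Hz (2000 for DB6-style data).
#' @param stimulus integer vector of per-sample class ids in 0..7.
#' @param repetition integer vector of per-sample repetition ids (>= 0;
#'   0 conventionally marks rest samples, as in the DB6 rerepetition vector).
#' @param session_id,subject_id integer identifiers.
#' @return an object of class `session_recording`.
#' @export
session_recording <- function(signal, fs, stimulus, repetition,
                              session_id = 1L, subject_id = 1L) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal) || nrow(signal) < 1L)
    stopf("signal must be a non-empty numeric matrix (samples x channels)")
  n <- nrow(signal)
  stimulus <- as.integer(stimulus)
  repetition <- as.integer(repetition)
  if (length(stimulus) != n || length(repetition) != n)
    stopf("stimulus and repetition must each have one entry per sample (%d)", n)
  if (anyNA(stimulus) || any(stimulus < 0L) || any(stimulus > 7L))
    stopf("stimulus values must lie in 0..7")
  if (anyNA(repetition) || any(repetition < 0L))
    stopf("repetition ids must be >= 0")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stopf("fs must be a positive sampling rate in Hz")
  structure(list(
    signal = signal, fs = as.numeric(fs),
    stimulus = stimulus, repetition = repetition,
    session_id = as.integer(session_id), subject_id = as.integer(subject_id)
  ), class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "session_recording: subject %d, session %d\n  %d samples x %d channels @ %g Hz (%.1f s)\n  classes present: %s\n",
    x$subject_id, x$session_id, nrow(x$signal), ncol(x$signal), x$fs,
    nrow(x$signal) / x$fs, paste(sort(unique(x$stimulus)), collapse = " ")))
  invisible(x)
}

#' Write / read a portable session container
#'
#' Stores the signal plus stimulus and repetition vectors as one
#' tab-separated table (`<prefix>.tsv`) and the metadata (sampling rate,
#' subject, session) as a YAML sidecar (`<prefix>.yaml`).
#'
#' @param recording a [session_recording()].
#' @param prefix path prefix; `.tsv` and `.yaml` are appended.
#' @return `write_session` returns the prefix invisibly; `read_session`
#'   returns the reconstructed [session_recording()].
#' @export
write_session <- function(recording, prefix) {
  stopifnot(inherits(recording, "session_recording"))
  tab <- data.table::as.data.table(recording$signal)
  data.table::setnames(tab, paste0("ch", seq_len(ncol(recording$signal))))
  tab[, `:=`(stimulus = recording$stimulus, repetition = recording$repetition)]
  data.table::fwrite(tab, paste0(prefix, ".tsv"), sep = "\t")
  yaml::write_yaml(list(
    fs = recording$fs, subject_id = recording$subject_id,
    session_id = recording$session_id,
    n_samples = nrow(recording$signal), n_channels = ncol(recording$signal)
  ), paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname write_session
#' @export
read_session <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  tab <- data.table::fread(paste0(prefix, ".tsv"), sep = "\t")
  chans <- grep("^ch[0-9]+$", names(tab), value = TRUE)
  session_recording(
    signal = as.matrix(tab[, chans, with = FALSE]),
    fs = meta$fs, stimulus = tab$stimulus, repetition = tab$repetition,
    session_id = meta$session_id, subject_id = meta$subject_id)
}

#' Read and write DB6-style MAT session files (classic Level-4 layout)
#'
#' Multi-session grasp datasets ship sessions as MATLAB files with fields
#' `emg` (samples x channels), `restimulus` and `rerepetition` (per-sample
#' vectors). These functions handle the classic MAT Level-4 binary layout
#' (2-D double matrices), which is sufficient for round-tripping that field
#' structure; the modern HDF5-based v7.3 layout is not supported.
#'
#' @param path path to a `.mat` file.
#' @param fs sampling rate to attach (the MAT layout does not carry it).
#' @param session_id,subject_id identifiers to attach.
#' @return `read_mat_session` returns a [session_recording()].
#' @export
read_mat_session <- function(path, fs = 2000, session_id = 1L, subject_id = 1L) {
  mats <- read_mat4(path)
  need <- c("emg", "restimulus", "rerepetition")
  miss <- setdiff(need, names(mats))
  if (length(miss))
    stopf("MAT file %s lacks field(s): %s", path, paste(miss, collapse = ", "))
  session_recording(
    signal = mats$emg, fs = fs,
    stimulus = as.vector(mats$restimulus),
    repetition = as.vector(mats$rerepetition),
    session_id = session_id, subject_id = subject_id)
}

#' @rdname read_mat_session
#' @param recording a [session_recording()] to store.
#' @export
write_mat_session <- function(recording, path) {
  stopifnot(inherits(recording, "session_recording"))
  write_mat4(path, list(
    emg = recording$signal,
    restimulus = matrix(as.numeric(recording$stimulus), ncol = 1L),
    rerepetition = matrix(as.numeric(recording$repetition), ncol = 1L)))
  invisible(path)
}

# --- minimal MAT Level-4 codec (little-endian double matrices only) ------

write_mat4 <- function(path, matrices) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (nm in names(matrices)) {
    m <- as.matrix(matrices[[nm]])
    storage.mode(m) <- "double"
    # header: type (0 = LE double, full), mrows, ncols, imagf, name length
    writeBin(as.integer(c(0L, nrow(m), ncol(m), 0L, nchar(nm) + 1L)),
             con, size = 4L, endian = "little")
    writeBin(c(charToRaw(nm), as.raw(0L)), con)
    writeBin(as.vector(m), con, size = 8L, endian = "little")
  }
  invisible(path)
}

read_mat4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  out <- list()
  repeat {
    hdr <- readBin(con, "integer", n = 5L, size = 4L, endian = "little")
    if (length(hdr) < 5L) break
    if (hdr[1] != 0L)
      stopf("unsupported MAT element (type code %d); only Level-4 LE double matrices are handled", hdr[1])
    raw_nm <- readBin(con, "raw", n = hdr[5])
    nm <- rawToChar(raw_nm[raw_nm != as.raw(0L)])
    vals <- readBin(con, "double", n = hdr[2] * hdr[3], size = 8L, endian = "little")
    out[[nm]] <- matrix(vals, nrow = hdr[2], ncol = hdr[3])
  }
  out
}
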