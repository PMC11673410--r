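#' Read an EEG recording from disk
#'
#' Supports the two biosignal standards EDF (16-bit) and BDF (24-bit,
#' BioSemi) for continuous recordings, plus a plain matrix exchange
#' format: a delimited text file (channels x samples, tab-separated) with
#' a JSON sidecar of the same basename carrying
#' `{channel_names, fs, label, subject_id, trial_id}`.
#'
#' EDF/BDF headers carry no attention label; if a JSON sidecar
#' (`<basename>.json`) is present next to the file its `label`,
#' `subject_id` and `trial_id` entries are used, otherwise the label is
#' `NA` and a note is added to the recording's warnings.
#'
#' Channel labels not resolvable against `montage` (for instance in-ear
#' electrodes) are never silently dropped at read time: the recording is
#' returned complete and each unknown label is reported in
#' `$warnings`.  Montage filtering happens later, in [build_dataset()].
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"edf"`, `"bdf"` or `"matrix"`.
#' @param montage montage used to vet channel labels
#'   (default [standard_montage()]).
#' @return An [eeg_recording()].
#' @seealso [write_matrix_recording()], [write_edf()], [write_bdf()]
#' @export
read_recording <- function(path, format = c("auto", "edf", "bdf", "matrix"),
                           montage = standard_montage()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", bdf = "bdf",
                     tsv = "matrix", txt = "matrix", csv = "matrix",
                     stop("cannot infer format from extension: .", ext))
  }
  rec <- switch(format,
                edf = .read_edf_bdf(path, bits = 16L),
                bdf = .read_edf_bdf(path, bits = 24L),
                matrix = .read_matrix_recording(path))
  unknown <- rec$channel_names[!montage_resolves(rec$channel_names, montage)]
  if (length(unknown))
    rec$warnings <- c(rec$warnings,
                      paste0("channel not in montage: ", unknown))
  rec
}

.sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

.read_matrix_recording <- function(path) {
  side <- .sidecar_path(path)
  if (!file.exists(side))
    stop("matrix format requires a JSON sidecar, not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  need <- c("channel_names", "fs")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("sidecar ", side, " missing required keys: ",
         paste(miss, collapse = ", "))
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  data <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(data) <- NULL
  eeg_recording(data, meta$channel_names, meta$fs,
                label = if (is.null(meta$label)) NA_character_ else meta$label,
                subject_id = if (is.null(meta$subject_id)) "S0" else meta$subject_id,
                trial_id = if (is.null(meta$trial_id)) "T0" else meta$trial_id)
}

#' Write a recording in the matrix + JSON exchange format
#'
#' Writes `<path>` as tab-separated channels x samples text and
#' `<basename>.json` with the metadata sidecar read back by
#' [read_recording()].
#'
#' @param rec an [eeg_recording()].
#' @param path output path for the data file (e.g. `"trial1.tsv"`).
#' @return `path`, invisibly.
#' @export
write_matrix_recording <- function(rec, path) {
  utils::write.table(rec$data, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(channel_names = rec$channel_names, fs = rec$fs,
               label = rec$label, subject_id = rec$subject_id,
               trial_id = rec$trial_id)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# ---- EDF / BDF ------------------------------------------------------------
# Minimal continuous-recording reader/writer for the two standards.
# EDF: 16-bit little-endian samples; BDF: 24-bit (BioSemi), first header
# byte 0xFF followed by "BIOSEMI".  One data record per second is used by
# the writer; the reader accepts any record duration.

.pad <- function(s, n) {
  s <- formatC(as.character(s), width = n, flag = "-")
  substr(s, 1L, n)  # header fields are fixed-width
}

.read_ascii <- function(con, n) {
  rawToChar(readBin(con, "raw", n))
}

.read_edf_bdf <- function(path, bits) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (bits == 24L) {
    if (magic[1] != as.raw(255) ||
        rawToChar(magic[2:8]) != "BIOSEMI")
      stop("not a BDF file (bad magic): ", path)
  } else {
    if (!grepl("^0", rawToChar(magic)))
      stop("not an EDF file (bad version field): ", path)
  }
  invisible(.read_ascii(con, 80L))            # patient id
  invisible(.read_ascii(con, 80L))            # recording id
  invisible(.read_ascii(con, 16L))            # start date + time
  invisible(.read_ascii(con, 8L))             # header bytes
  invisible(.read_ascii(con, 44L))            # reserved
  n_rec <- as.integer(.read_ascii(con, 8L))
  rec_dur <- as.numeric(.read_ascii(con, 8L))
  ns <- as.integer(.read_ascii(con, 4L))
  lab <- trimws(vapply(seq_len(ns), function(i) .read_ascii(con, 16L), ""))
  invisible(replicate(ns, .read_ascii(con, 80L)))   # transducer
  invisible(replicate(ns, .read_ascii(con, 8L)))    # physical dimension
  pmin <- as.numeric(vapply(seq_len(ns), function(i) .read_ascii(con, 8L), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) .read_ascii(con, 8L), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) .read_ascii(con, 8L), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) .read_ascii(con, 8L), ""))
  invisible(replicate(ns, .read_ascii(con, 80L)))   # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) .read_ascii(con, 8L), ""))
  invisible(replicate(ns, .read_ascii(con, 32L)))   # reserved
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported: ", path)
  fs <- spr[1] / rec_dur
  scale <- (pmax - pmin) / (dmax - dmin)
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <-
        if (bits == 16L) {
          readBin(con, "integer", n = spr[s], size = 2L, endian = "little",
                  signed = TRUE)
        } else {
          raw3 <- readBin(con, "raw", n = 3L * spr[s])
          b <- matrix(as.integer(raw3), nrow = 3L)
          v <- b[1, ] + b[2, ] * 256L + b[3, ] * 65536L
          v - ifelse(v >= 8388608, 16777216, 0)
        }
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        pmin[s] + (dig - dmin[s]) * scale[s]
    }
  }
  warnings <- character()
  side <- .sidecar_path(path)
  label <- NA_character_; subj <- "S0"; trial <- "T0"
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$label)) label <- meta$label
    if (!is.null(meta$subject_id)) subj <- meta$subject_id
    if (!is.null(meta$trial_id)) trial <- meta$trial_id
  } else {
    warnings <- "no JSON sidecar: attention label unknown (NA)"
  }
  eeg_recording(data, lab, fs, label = label, subject_id = subj,
                trial_id = trial, warnings = warnings)
}

.write_edf_bdf <- function(rec, path, bits) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF/BDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_samp <- ncol(rec$data)
  if (n_samp %% fs != 0L)
    stop("EDF/BDF writer requires a whole number of 1-second records; ",
         "got ", n_samp, " samples at ", fs, " Hz")
  n_rec <- n_samp %/% fs
  dig_lim <- if (bits == 16L) 32767 else 8388607
  pmax <- apply(abs(rec$data), 1, max)
  pmax <- ifelse(pmax <= 0, 1, pmax * 1.01)        # avoid zero range
  pmax <- ceiling(pmax * 100) / 100   # match the 2-decimal header fields
  con <- file(path, "wb")
  on.exit(close(con))
  if (bits == 24L) {
    writeBin(as.raw(255), con)
    writeChar("BIOSEMI", con, 7L, eos = NULL)
  } else {
    writeChar(.pad("0", 8L), con, 8L, eos = NULL)
  }
  writeChar(.pad(rec$subject_id, 80L), con, 80L, eos = NULL)
  writeChar(.pad(rec$trial_id, 80L), con, 80L, eos = NULL)
  writeChar("01.01.00", con, 8L, eos = NULL)
  writeChar("00.00.00", con, 8L, eos = NULL)
  writeChar(.pad(256L * (1L + ns), 8L), con, 8L, eos = NULL)
  writeChar(.pad(if (bits == 24L) "24BIT" else "", 44L), con, 44L, eos = NULL)
  writeChar(.pad(n_rec, 8L), con, 8L, eos = NULL)
  writeChar(.pad(1L, 8L), con, 8L, eos = NULL)
  writeChar(.pad(ns, 4L), con, 4L, eos = NULL)
  wfield <- function(vals, width)
    for (v in vals) writeChar(.pad(v, width), con, width, eos = NULL)
  wfield(rec$channel_names, 16L)
  wfield(rep("", ns), 80L)
  wfield(rep("uV", ns), 8L)
  wfield(sprintf("%.2f", -pmax), 8L)
  wfield(sprintf("%.2f", pmax), 8L)
  wfield(rep(-dig_lim - 1L, ns), 8L)
  wfield(rep(dig_lim, ns), 8L)
  wfield(rep("", ns), 80L)
  wfield(rep(fs, ns), 8L)
  wfield(rep("", ns), 32L)
  scale <- (2 * pmax) / (2 * dig_lim + 1)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((rec$data[s, idx] - (-pmax[s])) / scale[s]) - dig_lim - 1L
      dig <- pmin(pmax(dig, -dig_lim - 1L), dig_lim)
      if (bits == 16L) {
        writeBin(as.integer(dig), con, size = 2L, endian = "little")
      } else {
        v <- as.integer(dig)
        v <- ifelse(v < 0, v + 16777216L, v)
        b <- rbind(v %% 256L, (v %/% 256L) %% 256L, v %/% 65536L)
        writeBin(as.raw(b), con)
      }
    }
  }
  # sidecar so the label survives the round trip
  jsonlite::write_json(list(label = rec$label, subject_id = rec$subject_id,
                            trial_id = rec$trial_id),
                       .sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' Write a recording as EDF or BDF
#'
#' Minimal continuous-recording writers (one 1-second data record per
#' second, a common physical/digital scaling per channel).  Intended for
#' interchange and for generating test fixtures; amplitude resolution is
#' the standard's 16-bit (EDF) or 24-bit (BDF) quantization.  A JSON
#' sidecar carrying the attention label is written next to the file.
#'
#' @param rec an [eeg_recording()] whose sample count is a whole number
#'   of seconds.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) .write_edf_bdf(rec, path, 16L)

#' @rdname write_edf
#' @export
write_bdf <- function(rec, path) .write_edf_bdf(rec, path, 24L)
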