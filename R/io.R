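#' Read or write a recording
#'
#' Two on-disk formats are supported: a plain CSV (`time_s, eeg, emg`,
#' lossless) and 16-bit EDF (two signals labelled "EEG" and "EMG", 1-s data
#' records).  EDF round-trips are exact up to one quantization step of the
#' stored physical range.
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`; inferred from the extension when `NULL`.
#' @param schedule optional `light_schedule` to attach to the result.
#' @return `read_recording()` returns a `recording`.
#' @export
read_recording <- function(path, format = NULL, schedule = NULL) {
  format <- infer_format(path, format)
  if (format == "csv") {
    d <- utils::read.csv(path)
    need <- c("time_s", "eeg", "emg")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("recording CSV is missing column(s): ", paste(miss, collapse = ", "))
    fs <- round(1 / stats::median(diff(d$time_s)))
    new_recording(d$eeg, d$emg, fs = fs, t0 = d$time_s[1], schedule = schedule)
  } else {
    e <- read_edf(path)
    lab <- toupper(trimws(e$labels))
    for (ch in c("EEG", "EMG")) if (!ch %in% lab)
      stop("EDF file is missing required channel: ", ch)
    fs <- e$fs[match("EEG", lab)]
    if (length(unique(e$fs)) != 1)
      stop("inconsistent sampling rates across EDF channels")
    new_recording(e$signals[[match("EEG", lab)]],
                  e$signals[[match("EMG", lab)]], fs = fs, schedule = schedule)
  }
}

#' @rdname read_recording
#' @param rec a `recording`.
#' @export
write_recording <- function(rec, path, format = NULL) {
  stopifnot(inherits(rec, "recording"))
  format <- infer_format(path, format)
  if (format == "csv") {
    t_s <- rec$t0 + (seq_along(rec$eeg) - 1) / rec$fs
    utils::write.csv(data.frame(time_s = t_s, eeg = rec$eeg, emg = rec$emg),
                     path, row.names = FALSE)
  } else {
    write_edf(path, list(EEG = rec$eeg, EMG = rec$emg), fs = rec$fs)
  }
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) {
    format <- match.arg(tolower(format), c("csv", "edf"))
    return(format)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "edf")) ext else
    stop("cannot infer format from extension '", ext, "'; pass format=")
}

# ---- minimal EDF (16-bit, equal fs, 1-s records) -------------------------

pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")

# numeric -> at most 8 ASCII chars (EDF header field); returns the string
# actually written so quantization can use the same value
num8 <- function(x) {
  for (d in 7:1) {
    s <- sprintf("%.*g", d, x)
    if (nchar(s) <= 8) return(s)
  }
  stop("cannot represent ", x, " in 8 characters")
}

write_edf <- function(path, signals, fs) {
  ns <- length(signals)
  n <- unique(lengths(signals))
  if (length(n) != 1) stop("all channels must have equal length")
  spr <- fs                                   # samples per 1-s record
  n_rec <- floor(n / spr)
  if (n_rec < 1) stop("recording shorter than one EDF data record")
  phys_min <- vapply(signals, min, 0)
  phys_max <- vapply(signals, max, 0)
  flat <- phys_max - phys_min < 1e-12
  phys_max[flat] <- phys_min[flat] + 1
  # widen to the 8-char header representation, then use the written values
  # for quantization so the round-trip honours the advertised step
  pm_s <- vapply(phys_min - abs(phys_min) * 1e-3 - 1e-9, num8, "")
  px_s <- vapply(phys_max + abs(phys_max) * 1e-3 + 1e-9, num8, "")
  phys_min <- as.numeric(pm_s)
  phys_max <- as.numeric(px_s)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("synthetic mouse", 80), pad("circsleep recording", 80),
    pad("01.01.26", 8), pad("08.30.00", 8), pad(256 * (1 + ns), 8),
    pad("", 44), pad(n_rec, 8), pad(1, 8), pad(ns, 4),
    paste0(pad(names(signals), 16), collapse = ""),
    strrep(pad("synthetic", 80), ns),
    strrep(pad("uV", 8), ns),
    paste0(pad(sprintf("%.6g", phys_min), 8), collapse = ""),
    paste0(pad(sprintf("%.6g", phys_max), 8), collapse = ""),
    strrep(pad(-32768, 8), ns), strrep(pad(32767, 8), ns),
    strrep(pad("", 80), ns), strrep(pad(spr, 8), ns), strrep(pad("", 32), ns))
  writeChar(hdr, con, eos = NULL)
  scale <- (phys_max - phys_min) / (32767 - (-32768))
  dig <- lapply(seq_len(ns), function(j) {
    v <- round((signals[[j]] - phys_min[j]) / scale[j]) - 32768
    as.integer(pmin(32767, pmax(-32768, v)))
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (j in seq_len(ns)) writeBin(dig[[j]][idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                        # header bytes
  rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16); fld(80); fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80); spr <- as.integer(fld(8)); fld(32)
  sig <- lapply(seq_len(ns), function(j) numeric(n_rec * spr[j]))
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      v <- readBin(con, "integer", spr[j], size = 2, signed = TRUE,
                   endian = "little")
      sig[[j]][((r - 1) * spr[j] + 1):(r * spr[j])] <- v
    }
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- lapply(seq_len(ns), function(j)
    (sig[[j]] - dig_min[j]) * scale[j] + phys_min[j])
  list(labels = labels, signals = sig, fs = spr / rec_dur,
       phys_min = phys_min, phys_max = phys_max)
}

#' Read/write hypnogram and activity CSV
#'
#' Hypnogram CSV columns: `epoch_index` (0-based), `t_start_s`, `state`
#' (single letters W/N/R).  Activity CSV columns: `t_min`, `distance`.
#'
#' @param hyp a `hypnogram`; @param path file path.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  states <- c(WAKE = "W", NREM = "N", REM = "R")[unclass(hyp)]
  utils::write.csv(data.frame(epoch_index = seq_along(hyp) - 1,
                              t_start_s = (seq_along(hyp) - 1) * 4,
                              state = unname(states)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  d <- utils::read.csv(path)
  full <- c(W = "WAKE", N = "NREM", R = "REM")[as.character(d$state)]
  if (anyNA(full)) stop("hypnogram CSV contains states outside {W, N, R}")
  new_hypnogram(unname(full), provenance = "scored")
}

#' @rdname write_hypnogram
#' @param act an `activity_series`.
#' @export
write_activity <- function(act, path) {
  utils::write.csv(as.data.frame(act)[c("t_min", "distance")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_activity <- function(path) {
  d <- utils::read.csv(path)
  structure(data.frame(t_min = d$t_min, distance = d$distance),
            class = c("activity_series", "data.frame"))
}
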