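# Recording readers/writers: CSV with a JSON sidecar (debug-friendly), and
# a minimal EDF+ dialect (16-bit, one-second data records, annotations in
# an "EDF Annotations" signal). No installed R package reads EDF, so the
# format is implemented here with base readBin/writeBin.

pad_str <- function(s, n) {
  s <- substr(paste0(s, strrep(" ", n)), 1, n)
  s
}

fmt_edf_num <- function(x) {
  s <- formatC(x, format = "g", digits = 6)
  if (nchar(s) > 8) s <- formatC(x, format = "g", digits = 3)
  pad_str(s, 8)
}

# internal: write an EDF+ file from a plain matrix (channels x samples)
write_edf <- function(data, fs, labels, annotations, path) {
  nch <- nrow(data)
  n_rec <- ceiling(ncol(data) / fs)
  pad <- n_rec * fs - ncol(data)
  if (pad > 0) data <- cbind(data, matrix(0, nch, pad))

  pmin <- apply(data, 1, min); pmax <- apply(data, 1, max)
  flat <- pmax - pmin < 1e-12
  if (any(flat)) {
    warning("constant channel(s): physical range widened")
    pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  }
  dmin <- -32768; dmax <- 32767

  # annotation TALs (NUL-separated): record-start TAL per record; all class
  # annotations go into record 1
  ann_events <- sprintf("+%g\x15%g\x14%s\x14", annotations$start,
                        annotations$end - annotations$start,
                        annotations$class_id)
  rec_tal <- function(t) sprintf("+%g\x14\x14", t)
  ann0_raw <- unlist(lapply(c(rec_tal(0), ann_events),
                            function(p) c(charToRaw(p), as.raw(0))))
  ann_samples <- ceiling(max(length(ann0_raw), 40) / 2)

  ns <- nch + 1L
  header <- paste0(
    pad_str("0", 8), pad_str("X X X X", 80), pad_str("Startdate X X X X", 80),
    pad_str("01.01.20", 8), pad_str("00.00.00", 8),
    pad_str(as.character(256 * (ns + 1)), 8), pad_str("EDF+C", 44),
    pad_str(as.character(n_rec), 8), pad_str("1", 8), pad_str(as.character(ns), 4))
  sig_field <- function(vals, width) paste(vapply(vals, pad_str, "", n = width),
                                           collapse = "")
  header <- paste0(header,
    sig_field(c(labels, "EDF Annotations"), 16),
    sig_field(rep("", ns), 80),
    sig_field(c(rep("uV", nch), ""), 8),
    paste(c(vapply(pmin, fmt_edf_num, ""), fmt_edf_num(-1)), collapse = ""),
    paste(c(vapply(pmax, fmt_edf_num, ""), fmt_edf_num(1)), collapse = ""),
    sig_field(rep(as.character(dmin), ns), 8),
    sig_field(rep(as.character(dmax), ns), 8),
    sig_field(rep("", ns), 80),
    sig_field(as.character(c(rep(fs, nch), ann_samples)), 8),
    sig_field(rep("", ns), 32))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ci in seq_len(nch)) {
      dig <- as.integer(round((data[ci, idx] - pmin[ci]) * scale[ci] + dmin))
      writeBin(dig, con, size = 2, endian = "little")
    }
    tal_raw <- if (r == 1) ann0_raw
               else c(charToRaw(rec_tal(r - 1)), as.raw(0))
    writeBin(c(tal_raw, raw(2 * ann_samples - length(tal_raw))), con)
  }
  invisible(path)
}

# internal: read an EDF file written by write_edf (handles any EDF with one
# trailing annotations signal and equal per-signal rates)
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  rd(8 + 80 + 80 + 8 + 8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(width) vapply(seq_len(ns), function(i) trimws(rd(width)), "")
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8)); fld(80)
  spr <- as.integer(fld(8)); fld(32)
  stopifnot(hdr_bytes == 256 * (ns + 1))
  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  fs <- spr[sig_idx[1]] / rec_dur
  data <- matrix(0, length(sig_idx), n_rec * spr[sig_idx[1]])
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (si in seq_len(ns)) {
      if (is_ann[si]) {
        ann_raw <- c(ann_raw, readBin(con, "raw", 2 * spr[si]))
      } else {
        dig <- readBin(con, "integer", spr[si], size = 2, endian = "little")
        ci <- match(si, sig_idx)
        phys <- (dig - dmin[si]) * (pmax[si] - pmin[si]) / (dmax[si] - dmin[si]) +
          pmin[si]
        data[ci, ((r - 1) * spr[si] + 1):(r * spr[si])] <- phys
      }
    }
  }
  rownames(data) <- labels[sig_idx]
  # TALs are NUL-separated; only those with a duration field (\x15) are
  # class annotations, the rest are record-keeping timestamps
  keep <- which(ann_raw != as.raw(0))
  tals <- if (length(keep)) {
    grp <- cumsum(c(1, diff(keep) != 1))
    vapply(split(keep, grp), function(ii) rawToChar(ann_raw[ii]), "")
  } else character(0)
  ann <- data.frame(start = numeric(0), end = numeric(0),
                    class_id = character(0), stringsAsFactors = FALSE)
  for (t in tals) {
    if (!grepl("\x15", t)) next
    parts <- strsplit(t, "\x14")[[1]]
    od <- strsplit(parts[1], "\x15")[[1]]
    onset <- as.numeric(od[1]); dur <- as.numeric(od[2])
    lab <- if (length(parts) > 1) parts[2] else ""
    if (is.finite(onset) && is.finite(dur) && nzchar(lab))
      ann <- rbind(ann, data.frame(start = onset, end = onset + dur,
                                   class_id = lab, stringsAsFactors = FALSE))
  }
  list(data = data, fs = fs, labels = labels[sig_idx], annotations = ann)
}

#' Write a recording to disk
#'
#' `"csv"` writes one column per channel (header row = channel labels) plus
#' a JSON sidecar (`<path>.json`) holding the sampling rate, montage,
#' annotations and identifiers. `"edf"` writes a 16-bit EDF+ file with
#' physical ranges set from the data extrema and class annotations as EDF+
#' events; amplitudes round-trip within the 16-bit quantization step.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @param format `"csv"` or `"edf"` (default from the file extension).
#' @return the path, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") {
    write_edf(rec$data, rec$fs, rownames(rec$data), rec$annotations, path)
  } else {
    df <- as.data.frame(t(rec$data))
    names(df) <- rownames(rec$data)
    utils::write.csv(df, path, row.names = FALSE)
    sidecar <- list(fs = rec$fs,
                    montage = rec$montage[c("channel_labels", "reference_label",
                                            "ground_label")],
                    annotations = rec$annotations,
                    subject_id = rec$subject_id, trial_id = rec$trial_id)
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' Reads the formats produced by [write_recording()]. If `montage` is
#' given, the file's channel count and labels are validated against it.
#'
#' @param path file path (`.csv` expects `<path>.json` alongside).
#' @param format `"csv"`, `"edf"` or `"auto"` (extension).
#' @param montage optional [montage_spec()] to validate against.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           montage = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") {
    e <- read_edf(path)
    if (!is.null(montage)) {
      if (length(e$labels) != length(montage$channel_labels))
        stop(errorCondition(
          sprintf("file has %d channels but montage expects %d",
                  length(e$labels), length(montage$channel_labels)),
          class = c("mibmi_validation_error", "error")))
      if (!identical(e$labels, montage$channel_labels))
        stop(errorCondition("channel labels do not match montage",
                            class = c("mibmi_validation_error", "error")))
    } else montage <- montage_spec(e$labels)
    bad <- setdiff(e$annotations$class_id, mi_classes())
    if (length(bad))
      stop(errorCondition(paste("unknown class label(s):",
                                paste(bad, collapse = ", ")),
                          class = c("mibmi_validation_error", "error")))
    return(structure(list(data = e$data, fs = e$fs, montage = montage,
                          annotations = e$annotations,
                          subject_id = NA_integer_, trial_id = NA_integer_),
                     class = "eeg_recording"))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m2 <- montage_spec(unlist(side$montage$channel_labels),
                     side$montage$reference_label, side$montage$ground_label)
  if (!is.null(montage)) {
    if (!identical(m2$channel_labels, montage$channel_labels))
      stop(errorCondition("channel labels do not match montage",
                          class = c("mibmi_validation_error", "error")))
  }
  data <- t(as.matrix(df))
  rownames(data) <- names(df)
  structure(list(data = data, fs = side$fs, montage = m2,
                 annotations = as.data.frame(side$annotations),
                 subject_id = side$subject_id, trial_id = side$trial_id),
            class = "eeg_recording")
}
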