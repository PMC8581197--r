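# Minimal EDF+ (European Data Format) writer/reader for raw sessions.
# 16-bit samples, 1-s data records, events stored as EDF+ annotations
# (time-stamped annotation lists) in a dedicated "EDF Annotations" signal.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

#' Write a session to an EDF+ file
#'
#' Samples are quantized to 16-bit integers over a symmetric physical range
#' (max absolute value of the data), so round-tripping preserves values to
#' within one quantization step. Events are written as EDF+ annotations of
#' the form `condition/run` at their onset times; phase, subject and exact
#' sample count are kept in the header's recording field.
#'
#' @param session A `raw_session`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "raw_session"))
  data <- session$data
  n_ch <- nrow(data)
  fs <- session$sampling_rate
  if (fs != round(fs))
    stop_labeled("bad_argument", "EDF writer requires an integer sampling rate")
  n_rec <- ceiling(ncol(data) / fs)
  pad <- n_rec * fs - ncol(data)
  if (pad > 0) data <- cbind(data, matrix(0, n_ch, pad))

  # quantize against the physical range exactly as printed in the header
  pm <- as.numeric(sprintf("%.6g", max(abs(data), 1e-6)))
  dig_max <- 32767; dig_min <- -32768
  scale <- (2 * pm) / (dig_max - dig_min)
  dig <- matrix(as.integer(pmin(dig_max, pmax(dig_min,
    round((data + pm) / scale) + dig_min))), n_ch)

  # one annotation TAL per event, placed in the record containing its onset
  ann_by_rec <- vector("list", n_rec)
  for (i in seq_len(nrow(session$events))) {
    onset <- (session$events$onset[i] - 1) / fs
    rec <- min(n_rec, floor(onset) + 1L)
    tal <- sprintf("+%.6f\x15%g\x14%s/%d\x14",
                   onset, 4, session$events$condition[i],
                   session$events$run[i])
    ann_by_rec[[rec]] <- c(ann_by_rec[[rec]], tal)
  }
  ann_raw <- lapply(seq_len(n_rec), function(r) {
    ts <- sprintf("+%d\x14\x14", r - 1L)
    c(charToRaw(ts), as.raw(0),
      if (length(ann_by_rec[[r]])) charToRaw(paste0(ann_by_rec[[r]], collapse = "")),
      as.raw(0))
  })
  ann_samples <- max(16L, ceiling(max(vapply(ann_raw, length, 1L)) / 2))

  ns <- n_ch + 1L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, eos = NULL)
  wr("0", 8)
  wr(session$subject_id, 80)
  wr(sprintf("phase=%s ns=%d fs=%d", session$phase, ncol(session$data), fs), 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1L), 8)
  wr("EDF+C", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(ns, 4)
  labels <- c(session$channels, "EDF Annotations")
  for (lb in labels) wr(lb, 16)
  for (i in seq_len(ns)) wr("", 80)                 # transducer
  for (i in seq_len(ns)) wr(if (i <= n_ch) "uV" else "", 8)
  for (i in seq_len(ns)) wr(if (i <= n_ch) sprintf("%.6g", -pm) else "-1", 8)
  for (i in seq_len(ns)) wr(if (i <= n_ch) sprintf("%.6g", pm) else "1", 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr(if (i <= n_ch) "BP 4-30Hz possible" else "", 80)
  for (i in seq_len(ns)) wr(if (i <= n_ch) fs else ann_samples, 8)
  for (i in seq_len(ns)) wr("", 32)

  for (r in seq_len(n_rec)) {
    cols <- (r - 1L) * fs + seq_len(fs)
    for (ch in seq_len(n_ch))
      writeBin(dig[ch, cols], con, size = 2, endian = "little")
    buf <- raw(2 * ann_samples)
    a <- ann_raw[[r]]
    buf[seq_along(a)] <- a
    writeBin(buf, con)
  }
  invisible(path)
}

#' Read a session from an EDF+ file
#'
#' Restores the channel data, events (from the annotations signal), phase
#' and subject metadata written by [write_session()]. Channel coordinates
#' are re-attached from the built-in montage table where labels match.
#'
#' @param path EDF+ file path.
#' @return A `raw_session`.
#' @export
read_session <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    x <- readChar(con, width, useBytes = TRUE)
    if (nchar(x, type = "bytes") < width)
      stop_labeled("parse_error", "truncated EDF header near byte %d",
                   seek(con, where = NA))
    trimws(x)
  }
  rd(8)                                   # version
  subject_id <- rd(80)
  recording <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1)
    stop_labeled("parse_error", "bad signal count near byte 252")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  ann_i <- which(labels == "EDF Annotations")
  if (!length(ann_i))
    stop_labeled("missing_annotations",
                 "no 'EDF Annotations' signal in %s", path)
  ch_i <- setdiff(seq_len(ns), ann_i)

  meta <- regmatches(recording,
                     regexec("phase=(\\S+) ns=(\\d+) fs=(\\d+)", recording))[[1]]
  if (length(meta) != 4)
    stop_labeled("parse_error", "recording field lacks phase/ns/fs metadata")
  phase <- meta[2]; n_samples <- as.integer(meta[3]); fs <- as.numeric(meta[4])

  data <- matrix(0, length(ch_i), n_rec * spr[ch_i[1]])
  ann_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (si in seq_len(ns)) {
      if (si %in% ann_i) {
        ann_raw <- c(ann_raw, readBin(con, "raw", n = 2L * spr[si]))
      } else {
        vals <- readBin(con, "integer", n = spr[si], size = 2,
                        endian = "little", signed = TRUE)
        if (length(vals) < spr[si])
          stop_labeled("parse_error", "truncated data record %d", r)
        k <- match(si, ch_i)
        sc <- (pmax_[si] - pmin_[si]) / (dmax_[si] - dmin_[si])
        data[k, (r - 1L) * spr[si] + seq_len(spr[si])] <-
          pmin_[si] + (vals - dmin_[si]) * sc
      }
    }
  }
  data <- data[, seq_len(n_samples), drop = FALSE]
  rownames(data) <- labels[ch_i]

  # split the annotation byte stream into NUL-terminated TAL chunks
  nul <- ann_raw == as.raw(0)
  grp <- cumsum(nul) - as.integer(nul)
  chunks <- split(ann_raw[!nul], grp[!nul])
  tals <- vapply(chunks, rawToChar, "")
  ev <- regmatches(tals, regexec("\\+([0-9.]+)\x15[0-9.]+\x14(\\w+)/(\\d+)",
                                 tals))
  ev <- ev[vapply(ev, length, 1L) == 4]
  events <- if (length(ev)) data.frame(
    onset = as.integer(round(as.numeric(vapply(ev, `[`, "", 2)) * fs)) + 1L,
    condition = vapply(ev, `[`, "", 3),
    run = as.integer(vapply(ev, `[`, "", 4)),
    stringsAsFactors = FALSE)
  else data.frame(onset = integer(0), condition = character(0),
                  run = integer(0))
  rownames(events) <- NULL

  mon <- montage_1020()
  idx <- match(labels[ch_i], mon$label)
  coords <- as.matrix(mon[ifelse(is.na(idx), 1L, idx), c("x", "y", "z")])
  coords[is.na(idx), ] <- NA_real_
  rownames(coords) <- labels[ch_i]

  structure(list(data = data, events = events, phase = phase,
                 subject_id = subject_id, sampling_rate = fs,
                 channels = labels[ch_i], channel_coords = coords,
                 ground_truth = NULL),
            class = "raw_session")
}
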