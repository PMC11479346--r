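# Plain-text recording serialisation: one comma-separated file per channel
# (metadata line, column header, then time_s,value rows), an events file and
# a key=value metadata file. Chosen over a binary container so fixtures stay
# inspectable and diffable.

.fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.nan(x)] <- "NaN"
  out[is.na(x) & !is.nan(x)] <- "NA"
  out
}

#' Write a recording to a directory
#'
#' Serialises a [recording()] as plain comma-separated text: one file per
#' channel (`<name>.csv` with a `# channel=... sample_rate=... start_time=...`
#' metadata line), `events.csv`, and `metadata.txt`. Numeric values keep 12
#' significant digits, so a read/write round trip is lossless well beyond 9
#' digits; repeated writes are byte-identical.
#'
#' @param rec a validated `vims_recording`.
#' @param path directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("unwritable path: ", path, call. = FALSE)
  for (nm in names(rec$channels)) {
    ch <- rec$channels[[nm]]
    f <- file.path(path, paste0(nm, ".csv"))
    tm <- channel_times(ch)
    con <- file(f, open = "wb")
    writeLines(c(sprintf("# channel=%s sample_rate=%s start_time=%s",
                         ch$name, .fmt_num(ch$sample_rate),
                         .fmt_num(ch$start_time)),
                 "time_s,value",
                 paste(.fmt_num(tm), .fmt_num(ch$values), sep = ",")),
               con, sep = "\n")
    close(con)
  }
  ev <- file.path(path, "events.csv")
  lines <- "time_s,vims_level,drowsiness,fatigue"
  for (r in rec$reports) {
    lines <- c(lines, sprintf("%s,%d,%s,%s", .fmt_num(r$time_s),
                              r$vims_level,
                              ifelse(is.na(r$drowsiness), "NA", r$drowsiness),
                              ifelse(is.na(r$fatigue), "NA", r$fatigue)))
  }
  con <- file(ev, open = "wb"); writeLines(lines, con, sep = "\n"); close(con)
  meta <- file.path(path, "metadata.txt")
  con <- file(meta, open = "wb")
  writeLines(c(paste0("participant_id=", rec$participant_id),
               paste0("display_condition=", rec$display_condition),
               paste0("duration_s=", .fmt_num(rec$duration_s))),
             con, sep = "\n")
  close(con)
  invisible(path)
}

.parse_channel_header <- function(line, file) {
  m <- regmatches(line, regexec(
    "^# channel=(\\S+) sample_rate=(\\S+) start_time=(\\S+)$", line))[[1]]
  if (length(m) != 4L)
    stop("malformed channel header in ", file, call. = FALSE)
  list(name = m[2], sample_rate = as.numeric(m[3]),
       start_time = as.numeric(m[4]))
}

#' Read a recording from a directory
#'
#' Inverse of [write_recording()]. Channel sample rates declared in the file
#' headers are cross-checked against the median sample spacing; a
#' disagreement beyond 1% raises a `sample-rate mismatch` error. Validation
#' errors (`channel missing`, `events unordered`, `event out of range`) are
#' raised rather than returning a partial recording.
#'
#' @param path directory written by [write_recording()].
#' @return A validated `vims_recording`.
#' @export
read_recording <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  meta_file <- file.path(path, "metadata.txt")
  if (!file.exists(meta_file)) stop("metadata.txt missing", call. = FALSE)
  kv <- strsplit(readLines(meta_file), "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, character(1), 2),
                   vapply(kv, `[`, character(1), 1))
  channels <- list()
  for (nm in .REQUIRED_CHANNELS) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("channel missing: ", nm, call. = FALSE)
    hdr <- .parse_channel_header(readLines(f, n = 1L), f)
    dt <- data.table::fread(f, skip = 2L, header = FALSE,
                            col.names = c("time_s", "value"),
                            na.strings = c("NA"), showProgress = FALSE)
    vals <- as.numeric(dt$value)
    tms <- as.numeric(dt$time_s)
    if (length(tms) > 1L) {
      spacing <- median(diff(tms))
      implied <- 1 / spacing
      if (abs(implied - hdr$sample_rate) / hdr$sample_rate > 0.01)
        stop("sample-rate mismatch in channel '", nm, "': header says ",
             hdr$sample_rate, " Hz but samples imply ",
             signif(implied, 6), " Hz", call. = FALSE)
    }
    channels[[nm]] <- channel_signal(hdr$name, hdr$sample_rate, vals,
                                     start_time = hdr$start_time)
  }
  ev_file <- file.path(path, "events.csv")
  reports <- list()
  if (file.exists(ev_file)) {
    ev <- data.table::fread(ev_file, header = TRUE, na.strings = "NA",
                            showProgress = FALSE)
    if (nrow(ev) > 0) {
      reports <- lapply(seq_len(nrow(ev)), function(i)
        report_event(ev$time_s[i], ev$vims_level[i], ev$drowsiness[i],
                     ev$fatigue[i]))
    }
  }
  recording(meta[["participant_id"]], meta[["display_condition"]],
            channels, reports, as.numeric(meta[["duration_s"]]))
}
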