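# Plain-format persistence: recordings as a documented lossless binary
# (little-endian float64 with a JSON header), events and electrodes as
# TSV, ground truth as JSON.

#' Write a recording to disk
#'
#' Writes `<stem>.json` (header: sampling rate, dimensions, contact
#' table, byte order), `<stem>.f64` (the signal matrix, column-major
#' little-endian IEEE-754 doubles — lossless, so round trips are
#' bit-exact) and `<stem>_events.tsv` (columns `onset_s`, `condition`).
#'
#' @param recording an [ieeg_recording].
#' @param stem path stem (no extension).
#' @return invisibly, the paths written.
#' @export
write_recording <- function(recording, stem) {
  stopifnot(inherits(recording, "ieeg_recording"))
  header <- list(format = "ieegswitch-raw-v1", fs = recording$fs,
                 n_samples = nrow(recording$signal),
                 n_contacts = ncol(recording$signal),
                 byte_order = "little", dtype = "float64",
                 order = "column-major",
                 contacts = recording$contacts)
  paths <- c(json = paste0(stem, ".json"), bin = paste0(stem, ".f64"),
             events = paste0(stem, "_events.tsv"))
  jsonlite::write_json(header, paths["json"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  con <- file(paths["bin"], "wb")
  on.exit(close(con))
  writeBin(as.vector(recording$signal), con, size = 8, endian = "little")
  ev <- recording$events
  ev_out <- data.frame(onset_s = (ev$onset - 1) / recording$fs,
                       condition = ev$condition)
  utils::write.table(ev_out, paths["events"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}

#' Read a recording written by [write_recording()]
#'
#' @param stem path stem used when writing.
#' @return an [ieeg_recording].
#' @export
read_recording <- function(stem) {
  header <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  stopifnot(identical(header$format, "ieegswitch-raw-v1"))
  n <- header$n_samples * header$n_contacts
  con <- file(paste0(stem, ".f64"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  sig <- matrix(x, header$n_samples, header$n_contacts)
  ev <- utils::read.delim(paste0(stem, "_events.tsv"),
                          stringsAsFactors = FALSE)
  events <- data.frame(onset = as.integer(round(ev$onset_s * header$fs)) + 1L,
                       condition = ev$condition, stringsAsFactors = FALSE)
  ieeg_recording(sig, header$fs, as.data.frame(header$contacts), events)
}

#' Write electrode contacts to TSV
#'
#' @param contacts contact table (`name`, `x`, `y`, `z`, ...).
#' @param path output path.
#' @export
write_electrodes <- function(contacts, path) {
  utils::write.table(contacts[, c("name", "x", "y", "z")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
}

#' Write cohort ground truth to JSON
#'
#' @param ground_truth the `ground_truth` element of [generate_cohort()].
#' @param path output path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
}
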