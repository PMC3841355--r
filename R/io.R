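#' Write a raw recording to disk
#'
#' Writes the samples as gzip-compressed delimited text (columns `x_g`,
#' `y_g`, `z_g`) next to a YAML sidecar holding the metadata (`fs_hz`,
#' `start_time`, `location`, `participant_id`, `n_samples`). Files are
#' named `<participant_id>_<location>.csv.gz` / `.yml`.
#'
#' @param recording A [raw_recording()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the sidecar path.
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "raw_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, paste0(recording$participant_id, "_",
                                recording$location))
  con <- gzfile(paste0(stem, ".csv.gz"), "w")
  on.exit(close(con), add = TRUE)
  df <- as.data.frame(recording$samples)
  names(df) <- c("x_g", "y_g", "z_g")
  utils::write.csv(df, con, row.names = FALSE)
  yaml::write_yaml(list(fs_hz = recording$fs,
                        start_time = recording$start_time,
                        location = recording$location,
                        participant_id = recording$participant_id,
                        n_samples = nrow(recording$samples)),
                   paste0(stem, ".yml"))
  invisible(paste0(stem, ".yml"))
}

#' Read a raw recording written by [write_recording()]
#'
#' @param sidecar Path to the `.yml` sidecar (the `.csv.gz` must sit next
#'   to it with the same stem).
#' @return A [raw_recording()].
#' @export
read_recording <- function(sidecar) {
  meta <- yaml::read_yaml(sidecar)
  csv <- sub("\\.yml$", ".csv.gz", sidecar)
  df <- utils::read.csv(gzfile(csv))
  raw_recording(as.matrix(df), fs = meta$fs_hz, start_time = meta$start_time,
                location = meta$location, participant_id = meta$participant_id)
}

#' Write / read a cohort table
#'
#' Delimited text with a header row; missing values are empty fields.
#'
#' @param cohort Cohort table `data.frame`.
#' @param path File path.
#' @return `write_cohort`: invisibly, `path`; `read_cohort`: the cohort
#'   table.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  for (fl in c("completed_study", "completed_program_week12"))
    if (!is.null(out[[fl]])) out[[fl]] <- as.logical(out[[fl]])
  class(out) <- c("cohort_table", "data.frame")
  out
}
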