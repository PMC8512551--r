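# CSV readers/writers for the two recording types and the JSON manifest.
#
# Dialect: UTF-8, header row, '.' decimal separator; both LF and CRLF line
# endings parse identically.  Malformed numeric cells are rejected per file
# with their line numbers.

read_numeric_csv <- function(path, required, optional = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- list()
  for (cl in c(required, intersect(optional, names(raw)))) {
    v <- raw[[cl]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & !(v %in% c("", "NA", "NaN")))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value(s) in column '%s' at line(s) %s",
                   basename(path), cl,
                   paste(utils::head(bad + 1L, 5), collapse = ", ")),
           call. = FALSE)
    }
    out[[cl]] <- num
  }
  as.data.frame(out)
}

#' Read a TUG distance recording from CSV
#'
#' Expects columns `time_s` and `distance_m`.  `NA` cells are kept (they
#' are treated as dropout samples by [tug_preprocess()]).
#'
#' @param path CSV file path.
#' @param meta Optional identifier list attached to the signal.
#' @return A `tug_signal`.
#' @export
read_distance_csv <- function(path, meta = NULL) {
  df <- read_numeric_csv(path, c("time_s", "distance_m"))
  as_tug_signal(df, meta = meta)
}

#' Write a TUG distance recording to CSV
#'
#' @param signal A `tug_signal`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_distance_csv <- function(signal, path) {
  utils::write.csv(as.data.frame(signal)[c("time_s", "distance_m")], path,
                   row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TMG twitch trace from CSV
#'
#' Expects columns `time_ms` and `displacement_mm`; timestamps are relative
#' to the stimulus at t = 0.
#'
#' @param path CSV file path.
#' @param muscle Muscle label to attach (`"BF"`, `"GM"`, `"VL"`, `"VM"`).
#' @param meta Optional identifier list.
#' @return A `tmg_response`.
#' @export
read_tmg_csv <- function(path, muscle = NA_character_, meta = NULL) {
  df <- read_numeric_csv(path, c("time_ms", "displacement_mm"))
  if (anyNA(df$displacement_mm)) {
    stop(sprintf("%s: missing displacement values", basename(path)),
         call. = FALSE)
  }
  tmg_response(df$time_ms, df$displacement_mm, muscle = muscle, meta = meta)
}

#' Write a TMG twitch trace to CSV
#'
#' @param response A `tmg_response`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tmg_csv <- function(response, path) {
  utils::write.csv(as.data.frame(response)[c("time_ms", "displacement_mm")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a participant manifest
#'
#' The manifest links participants to their recordings:
#' ```json
#' {"participants": [{"id": "P01",
#'                    "tug": ["tug/p01_1.csv"],
#'                    "tmg": {"VM": ["tmg/p01_vm_1.csv", "tmg/p01_vm_2.csv"]}}]}
#' ```
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path JSON manifest path.
#' @return The manifest as a nested list, with a `root` attribute.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  mf <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(mf$participants)) {
    stop("manifest has no 'participants' entry", call. = FALSE)
  }
  attr(mf, "root") <- dirname(normalizePath(path))
  mf
}
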