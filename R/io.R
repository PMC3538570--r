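# TAC file format: delimited text, '#' comment lines, one header row
# (frame_end_time_s, blood_value, tissue_value), then one row per frame.
# Times are stored in seconds on disk and converted to minutes on read.

schema_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("ftkin_schema_error", "error")))
}

#' Read a blood/tissue TAC file
#'
#' Parses a delimited text file with columns `frame_end_time_s`,
#' `blood_value`, `tissue_value` (whitespace-, comma- or tab-separated; lines
#' starting with `#` are comments).  Times are converted from seconds to
#' minutes at this boundary.  At least four frames are required (four
#' unknown rates).
#'
#' @param path file path.
#' @return List with elements `blood` and `tissue` ([tac()] objects).
#' @seealso [write_tacs()]
#' @export
read_tacs <- function(path) {
  if (!file.exists(path)) schema_error("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^[[:space:]]*(#|$)", lines))
  if (length(keep) < 2) schema_error("no data rows in ", path)
  split_row <- function(s) strsplit(trimws(s), "[,\t ]+")[[1]]
  header <- tolower(split_row(lines[keep[1]]))
  want <- c("frame_end_time_s", "blood_value", "tissue_value")
  if (!all(want %in% header))
    schema_error("header must contain: ", paste(want, collapse = ", "))
  idx <- match(want, header)
  rows <- lapply(keep[-1], function(ln) {
    f <- suppressWarnings(as.numeric(split_row(lines[ln])))
    if (length(f) < max(idx) || any(!is.finite(f[idx])))
      schema_error("malformed row at line ", ln, " of ", path)
    f[idx]
  })
  m <- do.call(rbind, rows)
  if (nrow(m) < 4)
    schema_error("too few frames (", nrow(m), "); at least 4 required")
  if (any(diff(m[, 1]) <= 0))
    schema_error("frame-end times must be strictly increasing")
  list(blood = tac(m[, 1] / 60, m[, 2], kind = "blood"),
       tissue = tac(m[, 1] / 60, m[, 3], kind = "tissue"))
}

#' Write a blood/tissue TAC file
#'
#' Inverse of [read_tacs()]: writes full-precision decimal values with times
#' in seconds.
#'
#' @param path output file path.
#' @param blood,tissue [tac()] objects on a shared schedule.
#' @param comment optional comment line(s) written at the top.
#' @return `path`, invisibly.
#' @export
write_tacs <- function(path, blood, tissue, comment = NULL) {
  stopifnot(inherits(blood, "tac"), inherits(tissue, "tac"))
  if (length(blood) != length(tissue) ||
      max(abs(blood$times - tissue$times)) > 1e-12)
    stop("blood and tissue curves must share the frame schedule")
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("frame_end_time_s\tblood_value\ttissue_value", con)
  writeLines(sprintf("%.17g\t%.17g\t%.17g",
                     blood$times * 60, blood$values, tissue$values), con)
  invisible(path)
}
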