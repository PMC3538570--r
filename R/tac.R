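#' Time-activity curve
#'
#' A non-uniformly sampled time-activity curve (TAC).  `times` are frame-end
#' times in minutes and `values` the frame-integrated activities
#' (activity * min).  All package internals work in minutes; conversion from
#' seconds happens only at the file boundary ([read_tacs()] / [write_tacs()])
#' and in schedule construction.
#'
#' Noiseless curves are nonnegative; noisy curves may contain negative values
#' (no clipping is applied anywhere), so no sign constraint is enforced.
#'
#' @param times frame-end times (min), strictly increasing.
#' @param values frame-integrated activities, same length as `times`.
#' @param kind label, `"blood"` or `"tissue"`.
#' @return A list of class `"tac"` with elements `times`, `values`, `kind`.
#' @export
tac <- function(times, values, kind = c("tissue", "blood")) {
  kind <- match.arg(kind)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) < 1 || !all(is.finite(times)) || !all(is.finite(values)))
    stop("times and values must be finite and non-empty")
  if (any(diff(times) <= 0)) stop("frame-end times must be strictly increasing")
  structure(list(times = times, values = values, kind = kind), class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("Time-activity curve (%s): %d frames, %.3g to %.3g min\n",
              x$kind, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(time_min = x$times, value = x$values)
}

#' @export
length.tac <- function(x) length(x$times)
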