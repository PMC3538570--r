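#' Non-uniform acquisition schedule
#'
#' Frame-end times of a dynamic acquisition together with the integration
#' window.  Each recorded sample is the time integral of the curve over the
#' `window_s` seconds ending at the frame-end time (truncated at t = 0), so
#' for closely spaced early frames the integration windows overlap.
#'
#' `default_schedule()` is the simulation protocol used throughout:
#' 30 x 5 s, 20 x 10 s, 10 x 30 s, 10 x 60 s, 10 x 150 s and 3 x 300 s
#' (83 frames, last frame ending at 3650 s), each integrated over a 60 s
#' window.
#'
#' @param frame_ends_s frame-end times in seconds, strictly increasing.
#' @param window_s integration window in seconds (> 0).
#' @return A list of class `"sampling_schedule"` with `frame_ends_s`,
#'   `window_s` and their minute equivalents `frame_ends_min`, `window_min`.
#' @examples
#' default_schedule()
#' @export
sampling_schedule <- function(frame_ends_s, window_s = 60) {
  frame_ends_s <- as.numeric(frame_ends_s)
  if (any(diff(frame_ends_s) <= 0) || any(frame_ends_s <= 0))
    stop("frame-end times must be positive and strictly increasing")
  if (!is.finite(window_s) || window_s <= 0) stop("window_s must be > 0")
  structure(list(frame_ends_s = frame_ends_s, window_s = window_s,
                 frame_ends_min = frame_ends_s / 60,
                 window_min = window_s / 60),
            class = "sampling_schedule")
}

#' @rdname sampling_schedule
#' @export
default_schedule <- function(window_s = 60) {
  sampling_schedule(cumsum(c(rep(5, 30), rep(10, 20), rep(30, 10),
                             rep(60, 10), rep(150, 10), rep(300, 3))),
                    window_s = window_s)
}

#' Parse a run-length schedule string
#'
#' Converts a compact description such as `"30x5,20x10,10x30"` (count x
#' spacing in seconds) into a [sampling_schedule()].
#'
#' @param text run-length pairs `"<n>x<dt>"` separated by commas.
#' @param window_s integration window in seconds.
#' @return A [sampling_schedule()].
#' @export
parse_schedule <- function(text, window_s = 60) {
  parts <- strsplit(gsub("[[:space:]]", "", text), ",")[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)x([0-9.]+)$", parts))
  if (any(vapply(m, length, integer(1)) != 3))
    stop("cannot parse schedule string: ", text)
  dt <- unlist(lapply(m, function(g) rep(as.numeric(g[3]), as.integer(g[2]))))
  sampling_schedule(cumsum(dt), window_s = window_s)
}

#' @export
print.sampling_schedule <- function(x, ...) {
  cat(sprintf("Sampling schedule: %d frames to %g s, %g-s integration window\n",
              length(x$frame_ends_s), max(x$frame_ends_s), x$window_s))
  invisible(x)
}

#' Frame-integrate a continuous curve onto a schedule
#'
#' For each frame-end time t_i returns the integral of the curve over
#' [max(0, t_i - window), t_i].  Exponential-polynomial curves (the Feng
#' input, the closed-form tissue curve) are integrated analytically;
#' arbitrary functions by adaptive quadrature to relative error < 1e-8.
#'
#' @param curve a function of time in minutes (vectorised or not), or an
#'   internal exponential-polynomial object.
#' @param schedule a [sampling_schedule()].
#' @param kind label for the returned curve.
#' @return A [tac()] with frame-integrated values (activity * min).
#' @export
frame_integrate <- function(curve, schedule, kind = "tissue") {
  hi <- schedule$frame_ends_min
  lo <- pmax(0, hi - schedule$window_min)
  if (inherits(curve, "ep_terms")) {
    vals <- ep_integrate(curve, lo, hi)
  } else if (is.function(curve)) {
    vals <- mapply(function(l, h)
      stats::integrate(function(u) vapply(u, curve, numeric(1)),
                       l, h, rel.tol = 1e-9, abs.tol = 0,
                       subdivisions = 400L)$value,
      lo, hi)
  } else stop("curve must be a function or ep_terms object")
  tac(hi, vals, kind = kind)
}

#' Add count-statistics noise to a tissue curve
#'
#' Adds scaled Gaussian noise to a noiseless frame-integrated curve:
#' value_i + sigma_i z_i with z_i i.i.d. N(0, 1) and
#' sigma_i = alpha * sqrt(max(value_i, 0) * 2^(-t_i / T_half) / window_s),
#' the usual count-rate noise model with isotope decay.  `alpha = 0`
#' reproduces the input bit-exactly; negative noisy values are kept.
#' Deterministic given `seed` (the caller's RNG state is restored on exit).
#'
#' @param x a noiseless [tac()].
#' @param alpha noise scale, `>= 0`.
#' @param half_life isotope half-life (min).
#' @param window_s frame integration span in seconds (the count-normalising
#'   time in the variance model).
#' @param seed optional integer seed.
#' @return A [tac()] with noise added.
#' @export
add_noise <- function(x, alpha, half_life = 110, window_s = 60, seed = NULL) {
  stopifnot(inherits(x, "tac"))
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be >= 0")
  if (alpha == 0) return(x)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  sigma <- alpha * sqrt(pmax(x$values, 0) * 2^(-x$times / half_life) / window_s)
  tac(x$times, x$values + sigma * stats::rnorm(length(x$values)),
      kind = x$kind)
}

#' Simulate a blood/tissue dataset
#'
#' Generates the study dataset: the Feng blood input and the closed-form
#' two-tissue response to it, both frame-integrated on the acquisition
#' schedule; count-statistics noise (see [add_noise()]) is then added to the
#' tissue curve only (the blood input is treated as noiselessly known).
#'
#' @param truth ground-truth [rate_params()] (strictly positive).
#' @param input a [feng_params()] object.
#' @param schedule a [sampling_schedule()].
#' @param alpha tissue noise scale (0 = noiseless).
#' @param seed integer seed for the noise draw.
#' @param half_life isotope half-life (min) in the noise model.
#' @param noisy_blood if `TRUE`, also perturb the blood curve (for
#'   robustness studies; off in the standard protocol).
#' @return List of class `"tac_dataset"` with elements `blood` and `tissue`
#'   ([tac()] objects) and the generating settings as attributes.
#' @examples
#' ds <- generate_dataset(rate_params(0.4, 0.3, 0.2, 0.1), alpha = 0)
#' length(ds$tissue)
#' @export
generate_dataset <- function(truth, input = feng_params(),
                             schedule = default_schedule(), alpha = 0,
                             seed = NULL, half_life = 110,
                             noisy_blood = FALSE) {
  truth <- as_rate_params(truth)
  if (!is_physical(truth)) stop("ground-truth rates must be strictly positive")
  blood <- frame_integrate(feng_ep(input), schedule, kind = "blood")
  tissue <- frame_integrate(tissue_ep(truth, input), schedule, kind = "tissue")
  noisy_dataset(blood, tissue, schedule, alpha, seed, half_life, noisy_blood)
}

# split out so Monte-Carlo loops can reuse the noiseless curves
noisy_dataset <- function(blood, tissue, schedule, alpha, seed,
                          half_life = 110, noisy_blood = FALSE) {
  if (alpha > 0) {
    tissue <- add_noise(tissue, alpha, half_life = half_life,
                        window_s = schedule$window_s, seed = seed)
    if (noisy_blood)
      blood <- add_noise(blood, alpha, half_life = half_life,
                         window_s = schedule$window_s,
                         seed = if (is.null(seed)) NULL else seed + 500009L)
  }
  structure(list(blood = blood, tissue = tissue),
            class = "tac_dataset", schedule = schedule, alpha = alpha,
            seed = seed)
}

#' @export
print.tac_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d frames, alpha = %g\n",
              length(x$tissue), attr(x, "alpha")))
  invisible(x)
}
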