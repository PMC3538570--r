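#' Rate constants of the reversible two-tissue compartment model
#'
#' Bundles the four exchange rates of the standard reversible two-tissue
#' compartment model: `K1` (blood to free compartment), `k2` (free back to
#' blood), `k3` (free to bound) and `k4` (bound to free), all in min^-1.
#' Simulation ground truth must be strictly positive; estimator outputs are
#' unconstrained (negative estimates are meaningful diagnostics and are
#' preserved), so no sign check is applied here.  Use [is_physical()] to test
#' positivity.
#'
#' @param K1,k2,k3,k4 rate constants (min^-1), finite scalars.
#' @return A named numeric vector of class `"rate_params"`.
#' @examples
#' rate_params(0.4, 0.3, 0.2, 0.1)
#' @export
rate_params <- function(K1, k2, k3, k4) {
  x <- c(K1 = unname(K1), k2 = unname(k2), k3 = unname(k3), k4 = unname(k4))
  if (length(x) != 4 || !all(is.finite(x)))
    stop("rate_params requires four finite scalar rates")
  structure(x, class = "rate_params")
}

as_rate_params <- function(x) {
  if (inherits(x, "rate_params")) return(x)
  x <- as.numeric(x)
  rate_params(x[1], x[2], x[3], x[4])
}

#' @export
print.rate_params <- function(x, digits = 4, ...) {
  cat("Two-tissue compartment rates (min^-1)\n")
  print(round(unclass(x), digits))
  if (!is_physical(x)) cat("note: not all rates are positive\n")
  invisible(x)
}

#' Are all four rates strictly positive?
#'
#' @param params a [rate_params()] object.
#' @return Logical scalar.
#' @export
is_physical <- function(params) all(unclass(as_rate_params(params)) > 0)

#' Input-output ODE coefficients of the two-tissue model
#'
#' Eliminating the unobservable compartments from the state equations leaves a
#' single second-order ODE relating the tissue curve C(t) to the blood input
#' B(t):  C'' = x1 B' + x2 B + x3 C' + x4 C, with
#' x1 = K1, x2 = K1 (k3 + k4), x3 = -(k2 + k3 + k4), x4 = -k2 k4.
#'
#' @param params a [rate_params()] object (any real rates accepted).
#' @return Named numeric vector `c(x1, x2, x3, x4)` of class `"poly_coeffs"`.
#' @examples
#' rates_to_poly(rate_params(0.4, 0.3, 0.2, 0.1))
#' @export
rates_to_poly <- function(params) {
  p <- as_rate_params(params)
  structure(c(x1 = unname(p["K1"]),
              x2 = unname(p["K1"] * (p["k3"] + p["k4"])),
              x3 = unname(-(p["k2"] + p["k3"] + p["k4"])),
              x4 = unname(-p["k2"] * p["k4"])),
            class = "poly_coeffs")
}

#' System poles and convolution amplitudes
#'
#' The impulse response of the two-tissue model is bi-exponential,
#' h(t) = a1 exp(s1 t) + a2 exp(s2 t), where s1 >= s2 are the roots of
#' s^2 - x3 s - x4 = 0 and a_i = (x1 s_i + x2) / (s_i - s_j).  For strictly
#' positive rates both poles are real and negative and a1 + a2 = K1.
#'
#' @param coeffs a `"poly_coeffs"` vector from [rates_to_poly()].
#' @param tol discriminant tolerance below which the system is declared
#'   degenerate (repeated or complex poles).
#' @return List with elements `s1`, `s2`, `a1`, `a2` (class
#'   `"mode_decomposition"`).
#' @examples
#' poly_to_modes(rates_to_poly(rate_params(0.4, 0.3, 0.2, 0.1)))
#' @export
poly_to_modes <- function(coeffs, tol = 1e-12) {
  x <- as.numeric(coeffs)
  disc <- x[3]^2 + 4 * x[4]
  if (!is.finite(disc) || disc <= tol)
    stop("degenerate system: repeated or complex poles ",
         "(discriminant = ", format(disc), "); outside the reversible-model regime")
  if (x[1] == 0) stop("degenerate system: x1 = K1 = 0")
  r <- sqrt(disc)
  s1 <- (x[3] + r) / 2
  s2 <- (x[3] - r) / 2
  structure(list(s1 = s1, s2 = s2,
                 a1 = (x[1] * s1 + x[2]) / (s1 - s2),
                 a2 = (x[1] * s2 + x[2]) / (s2 - s1)),
            class = "mode_decomposition")
}

#' Frequency response of the two-tissue model
#'
#' H(iw) = K1 (iw + k3 + k4) / ((iw)^2 + (k2 + k3 + k4) iw + k2 k4), the
#' transfer function from blood input to tissue activity (no blood-volume
#' contamination).  At w = 0 this is the DC gain, i.e. the volume of
#' distribution K1 (k3 + k4) / (k2 k4).
#'
#' @param params a [rate_params()] object.
#' @param omega angular frequency (rad min^-1), vectorised.
#' @return Complex vector of `H(i omega)`.
#' @examples
#' Re(transfer_function(rate_params(0.4, 0.3, 0.2, 0.1), 0))  # VD = 4
#' @export
transfer_function <- function(params, omega) {
  p <- as_rate_params(params)
  iw <- 1i * omega
  den <- iw^2 + (p["k2"] + p["k3"] + p["k4"]) * iw + p["k2"] * p["k4"]
  if (any(Mod(den) == 0))
    stop("transfer function undefined: zero denominator (omega = 0 with k2*k4 = 0)")
  unname(p["K1"] * (iw + p["k3"] + p["k4"]) / den)
}

#' Macro-parameters of clinical interest
#'
#' Computes the volume of distribution VD = K1 (k3 + k4) / (k2 k4), the
#' binding-potential-type ratios K1 k3 / (k2 k4) and k3 / k4, and the net
#' uptake K1 k3 / (k2 + k3).
#'
#' @param params a [rate_params()] object.
#' @return Named numeric vector with elements `vd`, `bp`, `k3k4_ratio`,
#'   `net_uptake`.
#' @examples
#' macro_params(rate_params(0.4, 0.3, 0.2, 0.1))
#' @export
macro_params <- function(params) {
  p <- unclass(as_rate_params(params))
  if (p["k2"] * p["k4"] == 0)
    stop("macro-parameter undefined: k2*k4 = 0 (vd, bp)")
  if (p["k4"] == 0) stop("macro-parameter undefined: k4 = 0 (k3/k4)")
  if (p["k2"] + p["k3"] == 0)
    stop("macro-parameter undefined: k2 + k3 = 0 (net uptake)")
  c(vd = unname(p["K1"] * (p["k3"] + p["k4"]) / (p["k2"] * p["k4"])),
    bp = unname(p["K1"] * p["k3"] / (p["k2"] * p["k4"])),
    k3k4_ratio = unname(p["k3"] / p["k4"]),
    net_uptake = unname(p["K1"] * p["k3"] / (p["k2"] + p["k3"])))
}
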