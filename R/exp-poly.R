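# Exponential-polynomial algebra.
#
# Both the Feng arterial input and the bi-exponential convolution solution of
# the two-tissue compartment model are finite sums of terms
#     coef * t^pow * exp(rate * t),   pow in {0, 1, 2}.
# Representing curves this way lets the simulator evaluate frame integrals
# analytically instead of by quadrature, which keeps Monte-Carlo experiments
# cheap.  All rates and times are in minutes / min^-1.

ep_terms <- function(coef, rate, pow) {
  stopifnot(length(coef) == length(rate), length(rate) == length(pow),
            all(pow %in% 0:2))
  structure(list(coef = as.numeric(coef), rate = as.numeric(rate),
                 pow = as.integer(pow)), class = "ep_terms")
}

ep_combine <- function(...) {
  parts <- list(...)
  ep_terms(unlist(lapply(parts, `[[`, "coef")),
           unlist(lapply(parts, `[[`, "rate")),
           unlist(lapply(parts, `[[`, "pow")))
}

ep_scale <- function(ep, k) ep_terms(k * ep$coef, ep$rate, ep$pow)

# value at t (vectorised); zero for t < 0
ep_eval <- function(ep, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  if (any(pos)) {
    tp <- t[pos]
    acc <- numeric(length(tp))
    for (j in seq_along(ep$coef)) {
      acc <- acc + ep$coef[j] * tp^ep$pow[j] * exp(ep$rate[j] * tp)
    }
    out[pos] <- acc
  }
  out
}

# antiderivative of t^p * exp(a t) evaluated at t, with F(0) = 0
ep_term_antideriv <- function(a, p, t) {
  if (a == 0) return(t^(p + 1) / (p + 1))
  e <- exp(a * t)
  if (p == 0) return((e - 1) / a)
  if (p == 1) return(e * (t / a - 1 / a^2) + 1 / a^2)
  e * (t^2 / a - 2 * t / a^2 + 2 / a^3) - 2 / a^3
}

# integral of the curve over [lower, upper] (vectorised over frame pairs);
# the curve is taken to vanish for t < 0
ep_integrate <- function(ep, lower, upper) {
  lower <- pmax(lower, 0)
  acc <- numeric(length(upper))
  for (j in seq_along(ep$coef)) {
    acc <- acc + ep$coef[j] *
      (ep_term_antideriv(ep$rate[j], ep$pow[j], upper) -
         ep_term_antideriv(ep$rate[j], ep$pow[j], lower))
  }
  acc
}

# exact convolution  integral_0^t exp(s (t - tau)) * input(tau) dtau  for an
# exponential-polynomial input with pow <= 1.  Near-confluent terms
# (|s + rate| < tol) switch to the limiting t*exp(s t) / t^2*exp(s t) forms.
ep_convolve_exp <- function(s, input_ep, tol = 1e-10) {
  coef <- numeric(0); rate <- numeric(0); pow <- integer(0)
  add <- function(cf, rt, pw) {
    coef <<- c(coef, cf); rate <<- c(rate, rt); pow <<- c(pow, pw)
  }
  for (j in seq_along(input_ep$coef)) {
    cj <- input_ep$coef[j]; aj <- input_ep$rate[j]; pj <- input_ep$pow[j]
    mu <- s - aj   # input term is exp(aj t); lag kernel exp(s t)
    if (pj == 0L) {
      if (abs(mu) < tol) {
        add(cj, s, 1L)
      } else {
        add(cj / mu, s, 0L)
        add(-cj / mu, aj, 0L)
      }
    } else if (pj == 1L) {
      if (abs(mu) < tol) {
        add(cj / 2, s, 2L)
      } else {
        add(cj / mu^2, s, 0L)
        add(-cj / mu^2, aj, 0L)
        add(-cj / mu, aj, 1L)
      }
    } else {
      stop("ep_convolve_exp() supports polynomial degree <= 1 in the input")
    }
  }
  ep_terms(coef, rate, pow)
}
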