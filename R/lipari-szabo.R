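# Model-free spin relaxation: Lipari-Szabo spectral density and the
# standard 15N dipolar + CSA rate expressions.

# physical constants (SI)
.mu0 <- 4e-7 * pi
.hbar <- 1.054571817e-34
.gamma_h <- 2.6752218744e8   # rad/s/T
.gamma_n <- -2.7126180436e7  # rad/s/T
.r_nh <- 1.02e-10            # N-H bond length, m
.csa_n <- -160e-6            # 15N CSA (axially symmetric approximation)

#' Lipari-Szabo model-free spectral density
#'
#' `J(w) = (2/5) * (S2 tc / (1 + (w tc)^2) + (1 - S2) tau / (1 + (w tau)^2))`
#' with `1/tau = 1/tc + 1/te`.
#'
#' @param omega Angular frequency, rad/s (vectorized).
#' @param s2 Generalized order parameter in `[0, 1]`.
#' @param tau_c Overall rotational correlation time, s.
#' @param tau_e Effective internal correlation time, s (0 allowed).
#' @return Spectral density, s/rad.
#' @export
spectral_density <- function(omega, s2, tau_c, tau_e = 0) {
  if (s2 < 0 || s2 > 1) stop("`s2` must lie in [0, 1]", call. = FALSE)
  assert_num(tau_c, "tau_c", positive = TRUE, len = 1)
  if (tau_e < 0 || tau_e >= tau_c)
    stop("`tau_e` must satisfy 0 <= tau_e < tau_c", call. = FALSE)
  tau <- if (tau_e == 0) 0 else 1 / (1 / tau_c + 1 / tau_e)
  int <- if (tau == 0) 0 else (1 - s2) * tau / (1 + (omega * tau)^2)
  0.4 * (s2 * tau_c / (1 + (omega * tau_c)^2) + int)
}

#' Backbone amide 15N relaxation rates from the model-free parameters
#'
#' Standard dipolar (N-H, 1.02 Angstrom) plus axially symmetric 15N CSA
#' (-160 ppm) expressions evaluated on the Lipari-Szabo spectral density.
#'
#' @inheritParams spectral_density
#' @param field A [field_context] (the 1H frequency sets both Larmor
#'   frequencies; the `nucleus` element is ignored).
#' @return List with `r1`, `r2` (1/s) and `noe` (heteronuclear 1H-15N NOE).
#' @examples
#' f <- field_context(850, "15N")
#' lipari_szabo_rates(0.85, 10e-9, 50e-12, f)
#' @export
lipari_szabo_rates <- function(s2, tau_c, tau_e, field) {
  stopifnot(inherits(field, "field_context"))
  wh <- 2 * pi * field$h1_mhz * 1e6
  wn <- wh * abs(.gamma_n / .gamma_h)
  d <- .mu0 * .hbar * .gamma_h * abs(.gamma_n) / (4 * pi * .r_nh^3)
  c <- wn * .csa_n / sqrt(3)
  J <- function(w) spectral_density(w, s2, tau_c, tau_e)
  r1 <- d^2 / 4 * (J(wh - wn) + 3 * J(wn) + 6 * J(wh + wn)) + c^2 * J(wn)
  r2 <- d^2 / 8 * (4 * J(0) + J(wh - wn) + 3 * J(wn) + 6 * J(wh) +
                     6 * J(wh + wn)) +
    c^2 / 6 * (4 * J(0) + 3 * J(wn))
  noe <- 1 + d^2 / 4 * (.gamma_h / .gamma_n) * (6 * J(wh + wn) - J(wh - wn)) / r1
  list(r1 = r1, r2 = r2, noe = noe)
}
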