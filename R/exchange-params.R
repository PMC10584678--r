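#' Global two-site exchange parameters
#'
#' The two-site model interconverts a ground state (state 2, population
#' `1 - p1`) and an excited state (state 1, population `p1`) with microscopic
#' rate constants `k21` (2 to 1) and `k12` (1 to 2).  The global parameters
#' are the total exchange rate `k_ex = k21 + k12` and the excited-state
#' population `p1 = k21 / k_ex`; detailed balance `p1 * k12 = (1 - p1) * k21`
#' holds by construction.
#'
#' @param k_ex Total exchange rate constant, 1/s.
#' @param p1 Excited-state population, fraction in `[0, 1]`.  Values above
#'   0.5 are accepted but warned about, since the "excited" label then no
#'   longer designates the minor state.
#' @return An object of class `two_site_params` with fields `k_ex`, `p1`,
#'   `k21` and `k12`.
#' @examples
#' two_site_params(k_ex = 400, p1 = 0.1015)
#' @export
two_site_params <- function(k_ex, p1) {
  assert_num(k_ex, "k_ex", len = 1)
  assert_num(p1, "p1", len = 1)
  if (k_ex <= 0)
    stop_kexdyn("k_ex must be > 0 (both rates zero gives no exchange)",
                "kexdyn_degenerate_exchange")
  if (p1 < 0 || p1 > 1) stop("`p1` must lie in [0, 1]", call. = FALSE)
  if (p1 > 0.5)
    warning("p1 > 0.5: state 1 is no longer the minor ('excited') state",
            call. = FALSE)
  structure(
    list(k_ex = k_ex, p1 = p1, k21 = p1 * k_ex, k12 = (1 - p1) * k_ex),
    class = "two_site_params"
  )
}

#' Global parameters from microscopic rate constants
#'
#' @param k21 Ground-to-excited (2 to 1) rate constant, 1/s.
#' @param k12 Excited-to-ground (1 to 2) rate constant, 1/s.
#' @return A [two_site_params] object with `k_ex = k21 + k12` and
#'   `p1 = k21 / (k21 + k12)`.
#' @examples
#' equilibrium_from_rates(40.6, 359)   # k_ex ~ 399.6, p1 ~ 10.2%
#' @export
equilibrium_from_rates <- function(k21, k12) {
  assert_num(k21, "k21", len = 1)
  assert_num(k12, "k12", len = 1)
  if (k21 < 0 || k12 < 0) stop("rate constants must be >= 0", call. = FALSE)
  if (k21 + k12 <= 0)
    stop_kexdyn("both rate constants are zero: exchange is degenerate",
                "kexdyn_degenerate_exchange")
  two_site_params(k_ex = k21 + k12, p1 = k21 / (k21 + k12))
}

#' Microscopic rates from global parameters
#'
#' Inverse of [equilibrium_from_rates()]; round-trips to machine precision.
#'
#' @param params A [two_site_params] object.
#' @return Named numeric vector `c(k21 = , k12 = )`.
#' @export
rates_from_equilibrium <- function(params) {
  stopifnot(inherits(params, "two_site_params"))
  c(k21 = params$p1 * params$k_ex, k12 = (1 - params$p1) * params$k_ex)
}

#' @export
print.two_site_params <- function(x, ...) {
  cat(sprintf("<two_site_params> k_ex = %.4g /s, p1 = %.4g%% (k21 = %.4g, k12 = %.4g /s)\n",
              x$k_ex, 100 * x$p1, x$k21, x$k12))
  invisible(x)
}
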