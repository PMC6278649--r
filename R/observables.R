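#' Imino-proton exchange rate versus protein:DNA molar ratio
#'
#' Forward model for the observed exchange rate of a Z-form imino proton
#' during a titration obeying the half-stoichiometry regime
#' (\eqn{K_{BZ,1} = 1}, tight binding, \eqn{Z_t = \frac{1}{2}[P]_t}),
#' valid for \eqn{0 \le \chi \le 2}:
#' \deqn{k_{ex} = k_{ex,ZP_2} + \frac{k_{ex,ZP} - k_{ex,ZP_2}}{(1-\alpha)\chi}
#'   \left\{1 - \sqrt{1 - 4(1-\alpha)\left(\tfrac{\chi}{2} -
#'   \tfrac{\chi^2}{4}\right)}\right\}.}
#'
#' The implementation multiplies by the conjugate,
#' \eqn{1 - \sqrt{1-\epsilon} = \epsilon/(1 + \sqrt{1-\epsilon})}, so the
#' \eqn{(1-\alpha)\chi} prefactor cancels exactly:
#' \eqn{k_{ex} = k_{ex,ZP_2} + (k_{ex,ZP} - k_{ex,ZP_2})(2-\chi)/(1 +
#' \sqrt{1-\epsilon})}. This removes the removable singularities at
#' \eqn{\chi \to 0} (limit \eqn{k_{ex,ZP}}) and \eqn{\alpha \to 1} with no
#' loss of precision; at \eqn{\chi = 2} the model returns
#' \eqn{k_{ex,ZP_2}} exactly.
#'
#' Beyond \eqn{\chi = 2} the regime assumption breaks down and this
#' function refuses to extrapolate; use [kex_z_species()] with explicit
#' equilibrium constants instead.
#'
#' @param rates An [exchange_rates()] object; `kex_ZP` and `kex_ZP2` must
#'   be set.
#' @param alpha Ratio of dissociation constants, > 0.
#' @param chi Numeric vector of molar ratios in `[0, 2]`.
#' @return Exchange rates, 1/s (same length as `chi`).
#' @examples
#' r <- exchange_rates(kex_ZP = 10, kex_ZP2 = 1)
#' kex_vs_chi(r, alpha = 1.15e-2, chi = c(0.5, 1, 2))
#' @export
kex_vs_chi <- function(rates, alpha, chi) {
  stopifnot(inherits(rates, "exchange_rates"))
  check_rate_set(rates, c("kex_ZP", "kex_ZP2"))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop_bz("invalid_params", "alpha must be a single number > 0")
  if (!is.numeric(chi) || any(!is.finite(chi)))
    stop_bz("invalid_mixture", "chi must be finite")
  if (any(chi < 0 | chi > 2))
    stop_bz("regime", "kex_vs_chi is defined for chi in [0, 2] (Z_t = [P]_t/2 regime)")
  eps <- 4 * (1 - alpha) * (chi / 2 - chi^2 / 4)
  arg <- 1 - eps
  if (any(arg < -1e-12))
    stop_bz("numerical_domain", "square-root argument negative beyond tolerance")
  arg <- pmax(arg, 0)
  rates$kex_ZP2 + (rates$kex_ZP - rates$kex_ZP2) * (2 - chi) / (1 + sqrt(arg))
}

# shared bracket of the Z-fraction exchange models:
# s = 1 + (K-1) f,  d = 4 K (1-alpha) f (1-f),  bracket = s - sqrt(s^2 - d).
# Returned as d / (s + sqrt(s^2 - d)) for exactness at d -> 0.
# The discriminant satisfies s^2 - d = ((1-f) - K f)^2 + 4 K alpha f (1-f),
# hence is non-negative for all alpha >= 0, K >= 0, f in [0, 1]; a negative
# value can only be float noise and is clamped at -1e-12.
fz_bracket_den <- function(alpha, K_BZ1, f_Z) {
  s <- 1 + (K_BZ1 - 1) * f_Z
  d <- 4 * K_BZ1 * (1 - alpha) * f_Z * (1 - f_Z)
  disc <- s^2 - d
  if (any(disc < -1e-12))
    stop_bz("numerical_domain", "discriminant negative beyond tolerance")
  s + sqrt(pmax(disc, 0))
}

check_fz_params <- function(alpha, K_BZ1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop_bz("invalid_params", "alpha must be a single finite number >= 0")
  if (!is.numeric(K_BZ1) || length(K_BZ1) != 1L || !is.finite(K_BZ1) || K_BZ1 <= 0)
    stop_bz("invalid_params", "K_BZ1 must be a single finite number > 0")
}

check_rate_set <- function(rates, needed) {
  miss <- needed[vapply(needed, function(n) is.na(rates[[n]]), TRUE)]
  if (length(miss))
    stop_bz("invalid_rates", paste("required exchange rates are NA:",
                                   paste(miss, collapse = ", ")))
}

#' Exchange rate of a B-form imino proton versus Z-fraction
#'
#' Forward model for the observed exchange rate of an imino proton seen in
#' the B conformation, as a function of the relative Z-DNA population
#' \eqn{f_Z = Z_t/[N]_t} (used when the titration does not obey the
#' half-stoichiometry regime):
#' \deqn{k_{ex} = k_{ex,B} + \frac{k_{ex,BP} - k_{ex,B}}{2(1-\alpha)(1-f_Z)}
#'   \left\{1 + (K_{BZ,1}-1)f_Z - \sqrt{(1 + (K_{BZ,1}-1)f_Z)^2 -
#'   4K_{BZ,1}(1-\alpha)f_Z(1-f_Z)}\right\}.}
#'
#' Evaluated through the conjugate form (the brace equals
#' \eqn{d/(s + \sqrt{s^2-d})} with \eqn{s = 1+(K_{BZ,1}-1)f_Z},
#' \eqn{d = 4K_{BZ,1}(1-\alpha)f_Z(1-f_Z)}), which cancels the prefactor
#' exactly: \eqn{k_{ex} = k_{ex,B} + (k_{ex,BP}-k_{ex,B}) \cdot
#' 2K_{BZ,1}f_Z/(s + \sqrt{s^2-d})}. The removable point \eqn{f_Z = 0}
#' evaluates exactly to \eqn{k_{ex,B}}; \eqn{f_Z = 1} is outside the
#' domain (the B-form probe no longer exists).
#'
#' @param rates An [exchange_rates()] object; `kex_B` and `kex_BP` must be
#'   set.
#' @param alpha Ratio of dissociation constants, >= 0.
#' @param K_BZ1 Protein-bound B-to-Z equilibrium constant, > 0.
#' @param f_Z Numeric vector of Z-fractions in `[0, 1)`.
#' @return Exchange rates, 1/s.
#' @examples
#' r <- exchange_rates(kex_B = 2, kex_BP = 30)
#' kex_bform_vs_fz(r, alpha = 1.42, K_BZ1 = 0.4, f_Z = c(0.1, 0.5, 0.9))
#' @export
kex_bform_vs_fz <- function(rates, alpha, K_BZ1, f_Z) {
  stopifnot(inherits(rates, "exchange_rates"))
  check_rate_set(rates, c("kex_B", "kex_BP"))
  check_fz_params(alpha, K_BZ1)
  if (!is.numeric(f_Z) || any(!is.finite(f_Z)) || any(f_Z < 0))
    stop_bz("invalid_state", "f_Z must be finite and >= 0")
  if (any(f_Z >= 1))
    stop_bz("regime", "kex_bform_vs_fz requires f_Z < 1 (B-form probe must exist)")
  den <- fz_bracket_den(alpha, K_BZ1, f_Z)
  rates$kex_B + (rates$kex_BP - rates$kex_B) * 2 * K_BZ1 * f_Z / den
}

#' Exchange rate of a Z-form imino proton versus Z-fraction
#'
#' Forward model for the observed exchange rate of an imino proton seen in
#' the Z conformation, as a function of \eqn{f_Z} and for general
#' \eqn{K_{BZ,1}} (generalising [kex_vs_chi()], to which it reduces
#' exactly when \eqn{K_{BZ,1} = 1} and \eqn{f_Z = \chi/2}):
#' \deqn{k_{ex} = k_{ex,ZP_2} + \frac{k_{ex,ZP} - k_{ex,ZP_2}}
#'   {2K_{BZ,1}(1-\alpha)f_Z}\left\{1 + (K_{BZ,1}-1)f_Z -
#'   \sqrt{(1 + (K_{BZ,1}-1)f_Z)^2 - 4K_{BZ,1}(1-\alpha)f_Z(1-f_Z)}\right\}.}
#'
#' Conjugate form: \eqn{k_{ex} = k_{ex,ZP_2} + (k_{ex,ZP}-k_{ex,ZP_2})
#' \cdot 2(1-f_Z)/(s + \sqrt{s^2-d})}. The removable point
#' \eqn{f_Z \to 0} evaluates exactly to \eqn{k_{ex,ZP}}, and
#' \eqn{f_Z = 1} returns \eqn{k_{ex,ZP_2}} exactly.
#'
#' @inheritParams kex_bform_vs_fz
#' @param rates An [exchange_rates()] object; `kex_ZP` and `kex_ZP2` must
#'   be set.
#' @param f_Z Numeric vector of Z-fractions in `[0, 1]`.
#' @return Exchange rates, 1/s.
#' @examples
#' r <- exchange_rates(kex_ZP = 10, kex_ZP2 = 1)
#' kex_zform_vs_fz(r, alpha = 0.154, K_BZ1 = 1.02, f_Z = c(0.25, 0.5, 1))
#' @export
kex_zform_vs_fz <- function(rates, alpha, K_BZ1, f_Z) {
  stopifnot(inherits(rates, "exchange_rates"))
  check_rate_set(rates, c("kex_ZP", "kex_ZP2"))
  check_fz_params(alpha, K_BZ1)
  if (!is.numeric(f_Z) || any(!is.finite(f_Z)) || any(f_Z < 0 | f_Z > 1))
    stop_bz("invalid_state", "f_Z must lie in [0, 1]")
  den <- fz_bracket_den(alpha, K_BZ1, f_Z)
  rates$kex_ZP2 + (rates$kex_ZP - rates$kex_ZP2) * 2 * (1 - f_Z) / den
}

#' Species-weighted Z-form exchange rate from explicit equilibria
#'
#' Population-weighted average of the ZP and ZP2 limiting rates using
#' species concentrations from the equilibrium solver,
#' \eqn{k_{ex} = ([ZP]k_{ex,ZP} + [ZP_2]k_{ex,ZP_2})/([ZP]+[ZP_2])}.
#' This is the general-mechanism route for compositions outside the
#' regime of [kex_vs_chi()] (for example \eqn{\chi > 2}). In the
#' tight-binding, \eqn{K_{BZ,1}=1} regime it agrees with [kex_vs_chi()]
#' when the \eqn{\alpha} of that formula is matched to
#' \eqn{K_{d,BP}/K_{d,ZP_2}} (see the package vignette for why the
#' printed ratio convention inverts here).
#'
#' @param params A [bz_params()] object.
#' @param rates An [exchange_rates()] object with `kex_ZP`, `kex_ZP2` set.
#' @param mix A [bz_mixture()] object (must yield a nonzero Z population).
#' @return Exchange rate, 1/s.
#' @export
kex_z_species <- function(params, rates, mix) {
  stopifnot(inherits(rates, "exchange_rates"))
  check_rate_set(rates, c("kex_ZP", "kex_ZP2"))
  st <- equilibrium_state(params, mix)
  if (st$Z_total <= 0)
    stop_bz("invalid_state", "no Z-DNA population at this composition")
  (st$ZP * rates$kex_ZP + st$ZP2 * rates$kex_ZP2) / st$Z_total
}

#' Observed amide chemical-shift perturbation of one probe
#'
#' Population-weighted shift perturbation of a protein amide resonance in
#' fast exchange among free, B-bound and Z-bound states:
#' \deqn{\Delta\delta_{obs} = \frac{[BP]}{[P]_t}\Delta\delta_B +
#'   \frac{[ZP] + 2[ZP_2]}{[P]_t}\Delta\delta_Z.}
#' The ZP2 term carries the factor 2 because both protein molecules of the
#' ZP2 complex are Z-bound. Free protein contributes zero by construction
#' (shifts are referenced to the free form).
#'
#' @param state A `bz_species` object from [species_concentrations()] or
#'   [equilibrium_state()]; its `P_total` must be > 0.
#' @param shifts A [shift_pair()] with the limiting shift differences of
#'   the probe, ppm.
#' @return Observed shift perturbation, ppm.
#' @examples
#' p <- bz_params(Kd_BP = 0.028, Kd_ZP2 = 0.345, K_BZ1 = 0.87)
#' st <- equilibrium_state(p, bz_mixture(P_total = 25, N_total = 50))
#' delta_obs(st, shift_pair("probe1", delta_B = 0.10, delta_Z = 0.30))
#' @export
delta_obs <- function(state, shifts) {
  stopifnot(inherits(state, "bz_species"), inherits(shifts, "shift_pair"))
  if (state$P_total <= 0)
    stop_bz("undefined_observable",
            "delta_obs is a protein-observed quantity: P_total must be > 0")
  (state$BP / state$P_total) * shifts$delta_B +
    ((state$ZP + 2 * state$ZP2) / state$P_total) * shifts$delta_Z
}
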