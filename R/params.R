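#' Equilibrium constants of the four-state B-Z transition model
#'
#' Bundles the thermodynamic constants of the sequential mechanism
#' B \eqn{\rightleftharpoons} BP \eqn{\rightleftharpoons} ZP
#' \eqn{\rightleftharpoons} ZP\eqn{_2} by which a Z-DNA-binding protein (P)
#' converts a short B-form DNA duplex to the left-handed Z conformation:
#' the dissociation constant of the first binding event
#' (`Kd_BP`, \eqn{K_{d,BP} = [B][P]/[BP]}), the dissociation constant of the
#' second protein binding to the Z-form complex
#' (`Kd_ZP2`, \eqn{K_{d,ZP_2} = [ZP][P]/[ZP_2]}), and the dimensionless
#' protein-bound B-to-Z conformational equilibrium constant
#' (`K_BZ1`, \eqn{K_{BZ,1} = [ZP]/[BP]}).
#'
#' The ratio \eqn{\alpha = K_{d,ZP_2}/K_{d,BP}} is derived, never set
#' directly; it measures how much more weakly (\eqn{\alpha > 1}) or tightly
#' (\eqn{\alpha < 1}) the second protein binds relative to the first.
#'
#' All concentrations in this package are micromolar; convert nM or mM
#' values on input.
#'
#' @param Kd_BP Dissociation constant of the BP complex, uM. Must be > 0.
#' @param Kd_ZP2 Dissociation constant of the second binding step
#'   (ZP + P = ZP2), uM. Must be > 0.
#' @param K_BZ1 Equilibrium constant `[ZP]/[BP]`, dimensionless. Must be > 0;
#'   a value of exactly zero is rejected because the mass-balance cubic
#'   divides by it.
#' @return An object of class `bz_params`: a list with fields `Kd_BP`,
#'   `Kd_ZP2`, `K_BZ1` and the derived `alpha`.
#' @examples
#' # caZa_PKZ / d(TCGCGCG)2 at pH 6.0, 10 mM NaCl
#' bz_params(Kd_BP = 0.028, Kd_ZP2 = 0.345, K_BZ1 = 0.87)
#' @seealso [bz_mixture()], [species_concentrations()], [titration_curve()]
#' @export
bz_params <- function(Kd_BP, Kd_ZP2, K_BZ1) {
  for (nm in c("Kd_BP", "Kd_ZP2", "K_BZ1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_bz("invalid_params", sprintf("`%s` must be a single finite number", nm))
  }
  if (K_BZ1 == 0)
    stop_bz("degenerate_model",
            "K_BZ1 = 0 is a degenerate model: the mass-balance cubic divides by K_BZ1")
  if (Kd_BP <= 0 || Kd_ZP2 <= 0 || K_BZ1 < 0)
    stop_bz("invalid_params", "Kd_BP, Kd_ZP2 and K_BZ1 must all be positive")
  structure(
    list(Kd_BP = Kd_BP, Kd_ZP2 = Kd_ZP2, K_BZ1 = K_BZ1,
         alpha = Kd_ZP2 / Kd_BP),
    class = "bz_params"
  )
}

#' @export
print.bz_params <- function(x, ...) {
  cat("Four-state B-Z transition model constants (uM)\n")
  cat(sprintf("  Kd_BP  = %g uM\n  Kd_ZP2 = %g uM\n  K_BZ1  = %g\n  alpha  = %g  (Kd_ZP2/Kd_BP)\n",
              x$Kd_BP, x$Kd_ZP2, x$K_BZ1, x$alpha))
  invisible(x)
}

#' Mixture composition of a titration point
#'
#' Total protein and DNA duplex concentrations of one sample, with the
#' molar ratio \eqn{\chi = [P]_t/[N]_t} derived when `N_total > 0`.
#'
#' @param P_total Total ZBP concentration `[P]_t`, uM (>= 0).
#' @param N_total Total DNA duplex concentration `[N]_t`, uM (>= 0).
#' @return An object of class `bz_mixture` with fields `P_total`, `N_total`
#'   and `chi` (`NA` when `N_total == 0`).
#' @examples
#' bz_mixture(P_total = 50, N_total = 100)$chi  # 0.5
#' @export
bz_mixture <- function(P_total, N_total) {
  if (!is.numeric(P_total) || length(P_total) != 1L || !is.finite(P_total) || P_total < 0)
    stop_bz("invalid_mixture", "P_total must be a single finite number >= 0")
  if (!is.numeric(N_total) || length(N_total) != 1L || !is.finite(N_total) || N_total < 0)
    stop_bz("invalid_mixture", "N_total must be a single finite number >= 0")
  structure(
    list(P_total = P_total, N_total = N_total,
         chi = if (N_total > 0) P_total / N_total else NA_real_),
    class = "bz_mixture"
  )
}

#' @export
print.bz_mixture <- function(x, ...) {
  cat(sprintf("Mixture: [P]_t = %g uM, [N]_t = %g uM, chi = %s\n",
              x$P_total, x$N_total,
              if (is.na(x$chi)) "undefined" else format(x$chi)))
  invisible(x)
}

#' Limiting imino-proton exchange rate constants
#'
#' Hydrogen-exchange rate constants of a base-pair imino proton in each of
#' the four states of the mechanism. Exchange of imino protons with solvent
#' reports on base-pair opening and differs between the free duplex, the
#' B-form complex and the two Z-form complexes, which is what makes the
#' exchange titration an observable of the transition.
#'
#' Rates that do not apply to a given observable (for instance `kex_B` and
#' `kex_BP` for a probe that only exists in the Z conformation) may be left
#' `NA`.
#'
#' @param kex_B Exchange rate in free B-DNA, 1/s.
#' @param kex_BP Exchange rate in the BP complex, 1/s.
#' @param kex_ZP Exchange rate in the ZP complex, 1/s.
#' @param kex_ZP2 Exchange rate in the ZP2 complex, 1/s.
#' @return An object of class `exchange_rates`.
#' @examples
#' exchange_rates(kex_ZP = 10, kex_ZP2 = 1)
#' @export
exchange_rates <- function(kex_B = NA_real_, kex_BP = NA_real_,
                           kex_ZP = NA_real_, kex_ZP2 = NA_real_) {
  vals <- c(kex_B = kex_B, kex_BP = kex_BP, kex_ZP = kex_ZP, kex_ZP2 = kex_ZP2)
  if (!is.numeric(vals) || length(vals) != 4L)
    stop_bz("invalid_rates", "exchange rates must be single numeric values")
  bad <- !is.na(vals) & (vals < 0 | !is.finite(vals))
  if (any(bad))
    stop_bz("invalid_rates",
            paste("exchange rates must be finite and >= 0:", paste(names(vals)[bad], collapse = ", ")))
  structure(as.list(vals), class = "exchange_rates")
}

#' @export
print.exchange_rates <- function(x, ...) {
  cat("Limiting imino-proton exchange rates (1/s):\n")
  cat(sprintf("  kex_B = %s  kex_BP = %s  kex_ZP = %s  kex_ZP2 = %s\n",
              format(x$kex_B), format(x$kex_BP), format(x$kex_ZP), format(x$kex_ZP2)))
  invisible(x)
}

#' Limiting chemical-shift differences of one amide probe
#'
#' For one backbone amide 1H or 15N resonance of the protein, the
#' chemical-shift difference of the B-DNA-bound form (`delta_B`) and of the
#' Z-DNA-bound form (`delta_Z`) relative to the free protein, in ppm.
#' Shifts may be negative; they enter the observed perturbation as
#' population weights of the bound states.
#'
#' @param probe_id Label of the probe (e.g. `"G2-H"` or `"K56-N"`).
#' @param delta_B Shift difference of the B-bound form, ppm.
#' @param delta_Z Shift difference of the Z-bound form, ppm.
#' @return An object of class `shift_pair`.
#' @examples
#' shift_pair("W60-N", delta_B = 0.10, delta_Z = 0.30)
#' @export
shift_pair <- function(probe_id, delta_B, delta_Z) {
  if (!is.character(probe_id) || length(probe_id) != 1L || is.na(probe_id))
    stop_bz("invalid_shift_pair", "probe_id must be a single string")
  if (!is.numeric(delta_B) || length(delta_B) != 1L || !is.finite(delta_B) ||
      !is.numeric(delta_Z) || length(delta_Z) != 1L || !is.finite(delta_Z))
    stop_bz("invalid_shift_pair", "delta_B and delta_Z must be single finite numbers")
  structure(list(probe_id = probe_id, delta_B = delta_B, delta_Z = delta_Z),
            class = "shift_pair")
}

#' @export
print.shift_pair <- function(x, ...) {
  cat(sprintf("Probe %s: ddelta_B = %g ppm, ddelta_Z = %g ppm\n",
              x$probe_id, x$delta_B, x$delta_Z))
  invisible(x)
}

# classed condition helper: all package errors carry class
# c("bz_<what>", "bzfit_error", "error")
stop_bz <- function(what, msg, ...) {
  cnd <- structure(
    class = c(paste0("bz_", what), "bzfit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cnd)
}

warn_bz <- function(what, msg) {
  warning(structure(
    class = c(paste0("bz_", what), "bzfit_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
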