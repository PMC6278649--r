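#' Coefficients of the free-protein mass-balance cubic
#'
#' Combining the four-state equilibria with the DNA and protein mass
#' balances reduces the equilibrium problem to a single monic cubic in the
#' free protein concentration,
#' \deqn{[P]^3 + a[P]^2 + b[P] + c = 0,}
#' with
#' \deqn{a = 2[N]_t - [P]_t + (1 + 1/K_{BZ,1}) K_{d,ZP_2}}
#' \deqn{b = (1 + 1/K_{BZ,1}) K_{d,ZP_2} ([N]_t - [P]_t) + K_{d,BP}K_{d,ZP_2}/K_{BZ,1}}
#' \deqn{c = -K_{d,BP}K_{d,ZP_2}[P]_t / K_{BZ,1}.}
#'
#' When the trigonometric closed form applies (`a^2 - 3b >= 0` and the
#' arccos argument lies in `[-1, 1]` up to a `1e-9` clamp), the angle
#' \eqn{\theta = \arccos\{(-2a^3 + 9ab - 27c) / (2 (a^2-3b)^{3/2})\}}
#' is populated; otherwise `theta` is `NA` and the caller should use the
#' numeric solver.
#'
#' @param params A [bz_params()] object.
#' @param mix A [bz_mixture()] object.
#' @return An object of class `bz_cubic`: list with `a`, `b`, `c` (uM,
#'   uM^2, uM^3), the discriminant-like quantity `disc = a^2 - 3b`, the raw
#'   arccos argument `cos_arg`, and `theta` (radians, `NA` when the
#'   trigonometric form does not apply).
#' @examples
#' p <- bz_params(Kd_BP = 0.028, Kd_ZP2 = 0.345, K_BZ1 = 1)
#' cubic_coefficients(p, bz_mixture(5, 10))$a  # 2*10 - 5 + 2*0.345
#' @export
cubic_coefficients <- function(params, mix) {
  stopifnot(inherits(params, "bz_params"), inherits(mix, "bz_mixture"))
  if (params$K_BZ1 == 0)
    stop_bz("degenerate_model", "K_BZ1 = 0: cubic coefficients divide by K_BZ1")
  Nt <- mix$N_total; Pt <- mix$P_total
  a <- 2 * Nt - Pt + (1 + 1 / params$K_BZ1) * params$Kd_ZP2
  b <- (1 + 1 / params$K_BZ1) * params$Kd_ZP2 * (Nt - Pt) +
    params$Kd_BP * params$Kd_ZP2 / params$K_BZ1
  cc <- -params$Kd_BP * params$Kd_ZP2 * Pt / params$K_BZ1
  disc <- a^2 - 3 * b
  cos_arg <- NA_real_
  theta <- NA_real_
  if (disc > 0) {
    cos_arg <- (-2 * a^3 + 9 * a * b - 27 * cc) / (2 * disc^1.5)
    if (abs(cos_arg) <= 1 + 1e-9)
      theta <- acos(min(1, max(-1, cos_arg)))
  }
  structure(list(a = a, b = b, c = cc, disc = disc,
                 cos_arg = cos_arg, theta = theta),
            class = "bz_cubic")
}

#' Closed-form (trigonometric) root of the mass-balance cubic
#'
#' Evaluates the three trigonometric candidate roots
#' \eqn{-a/3 + (2/3)\sqrt{a^2-3b}\,\cos((\theta + 2\pi k)/3)}, `k = 0, 1, 2`,
#' polishes each with Newton iterations on the cubic (the raw trigonometric
#' expression loses precision by cancellation when the physical root is
#' much smaller than `[P]_t`), and keeps the roots falling inside
#' `[0, [P]_t]` up to a `1e-9` relative slack. Physical uniqueness is
#' guaranteed by the monotone protein mass balance, so exactly one root
#' must survive; ambiguity, an out-of-domain arccos argument, or
#' `a^2 - 3b < 0` (the one-real-root regime of the cubic) raise classed
#' conditions instructing the caller to use [solve_free_protein_numeric()].
#' [solve_free_protein()] does this fallback automatically.
#'
#' @param coeffs A `bz_cubic` object from [cubic_coefficients()].
#' @param mix The [bz_mixture()] the coefficients were computed for.
#' @return Free protein concentration `[P]` in uM.
#' @seealso [solve_free_protein()] for the automatic-fallback entry point.
#' @export
solve_free_protein_closed_form <- function(coeffs, mix) {
  stopifnot(inherits(coeffs, "bz_cubic"), inherits(mix, "bz_mixture"))
  Pt <- mix$P_total
  if (Pt == 0) return(0)
  if (coeffs$disc < -1e-12 * max(coeffs$a^2, 1))
    stop_bz("numerical_domain",
            "a^2 - 3b < 0: trigonometric form inapplicable, use the numeric solver")
  if (is.na(coeffs$theta))
    stop_bz("numerical_domain",
            "arccos argument outside [-1, 1]: use the numeric solver")
  disc <- max(coeffs$disc, 0)
  roots <- -coeffs$a / 3 +
    (2 / 3) * sqrt(disc) * cos((coeffs$theta + 2 * pi * c(0, 1, 2)) / 3)
  roots <- vapply(roots, polish_cubic_root, 0,
                  a = coeffs$a, b = coeffs$b, cc = coeffs$c)
  slack <- 1e-9 * max(1, Pt)
  inrange <- roots >= -slack & roots <= Pt + slack
  cand <- unique(signif(roots[inrange], 12))
  cand <- roots[inrange][match(cand, signif(roots[inrange], 12))]
  if (length(cand) == 0L)
    stop_bz("root_selection",
            "no trigonometric root in [0, [P]_t]; candidates: " %+%
              paste(format(roots), collapse = ", "),
            roots = roots)
  if (length(cand) > 1L)
    stop_bz("root_selection",
            "ambiguous root selection (multiple roots in [0, [P]_t]); candidates: " %+%
              paste(format(roots), collapse = ", "),
            roots = roots)
  root <- min(max(cand, 0), Pt)
  scale <- max(abs(root)^3, abs(coeffs$a * root^2), abs(coeffs$b * root),
               abs(coeffs$c), .Machine$double.xmin)
  resid <- ((root + coeffs$a) * root + coeffs$b) * root + coeffs$c
  if (abs(resid) > 1e-9 * scale)
    stop_bz("root_selection", "selected root fails the cubic residual check")
  root
}

# Newton refinement of a cubic root; restores the digits lost to
# cancellation in the trigonometric evaluation.
polish_cubic_root <- function(x, a, b, cc) {
  for (i in 1:12) {
    f <- ((x + a) * x + b) * x + cc
    fp <- (3 * x + 2 * a) * x + b
    if (fp == 0) break
    step <- f / fp
    xn <- x - step
    if (!is.finite(xn)) break
    x <- xn
    if (abs(step) <= 1e-15 * max(abs(x), .Machine$double.xmin)) break
  }
  x
}

`%+%` <- function(a, b) paste0(a, b)

#' Numeric (bracketing) solver for the free protein concentration
#'
#' Independent of the closed form: finds the unique `[P]` in `[0, [P]_t]`
#' where the protein mass-balance residual
#' \eqn{g([P]) = [P] + [BP] + [ZP] + 2[ZP_2] - [P]_t}
#' crosses zero, using Brent bracketing ([stats::uniroot()]) at absolute
#' tolerance `1e-12 * max(1, [P]_t)`. Because every bound-species
#' concentration is non-decreasing in `[P]`, `g` is strictly increasing and
#' the root is unique. When the root is far below `[P]_t` (tight binding)
#' the bracket is refined on a log-concentration scale so the result is
#' accurate in relative terms as well.
#'
#' @param params A [bz_params()] object.
#' @param mix A [bz_mixture()] object.
#' @return Free protein concentration `[P]` in uM.
#' @export
solve_free_protein_numeric <- function(params, mix) {
  stopifnot(inherits(params, "bz_params"), inherits(mix, "bz_mixture"))
  Pt <- mix$P_total; Nt <- mix$N_total
  if (Pt == 0) return(0)
  if (Nt == 0) return(Pt)
  g <- function(P) {
    s <- raw_species(params, Nt, P)
    P + s$BP + s$ZP + 2 * s$ZP2 - Pt
  }
  g0 <- g(0); g1 <- g(Pt)
  if (g0 > 0 || g1 < 0)
    stop_bz("internal_consistency",
            "mass-balance residual has no sign change in [0, [P]_t]")
  root <- stats::uniroot(g, c(0, Pt), f.lower = g0, f.upper = g1,
                         tol = 1e-12 * max(1, Pt))$root
  # log-scale refinement for tiny roots: the absolute tolerance above
  # cannot pin down [P] in relative terms when [P] << [P]_t (tight
  # binding), and may even return 0
  if (root < 1e-2 * Pt) {
    h <- function(u) g(exp(u))
    hi <- log(Pt)
    lo <- if (root > 0) log(root) - 3 else hi - 40
    while (h(lo) > 0 && lo > hi - 800) lo <- lo - 40
    if (h(lo) <= 0)
      root <- exp(stats::uniroot(h, c(lo, hi), tol = 1e-15)$root)
  }
  root
}

#' Solve the free protein concentration (closed form with fallback)
#'
#' Entry point combining both solvers: `"auto"` (default) tries the
#' trigonometric closed form and falls back to the bracketing solver when
#' the closed form raises a domain or root-selection condition.
#'
#' @param params A [bz_params()] object.
#' @param mix A [bz_mixture()] object.
#' @param method `"auto"`, `"closed_form"` or `"numeric"`.
#' @return Free protein concentration `[P]` in uM.
#' @examples
#' p <- bz_params(Kd_BP = 0.028, Kd_ZP2 = 0.345, K_BZ1 = 0.87)
#' solve_free_protein(p, bz_mixture(1, 1))
#' @export
solve_free_protein <- function(params, mix,
                               method = c("auto", "closed_form", "numeric")) {
  method <- match.arg(method)
  if (method == "numeric") return(solve_free_protein_numeric(params, mix))
  if (mix$P_total == 0) return(0)
  if (mix$N_total == 0) return(mix$P_total)
  cf <- function() solve_free_protein_closed_form(cubic_coefficients(params, mix), mix)
  if (method == "closed_form") return(cf())
  tryCatch(cf(), bzfit_error = function(e) solve_free_protein_numeric(params, mix))
}

# species partition at given free protein; shared denominator of the
# equilibrium expressions. Internal, unvalidated, vector-safe in P.
raw_species <- function(params, N_total, P) {
  Kbp <- params$Kd_BP; Kzp2 <- params$Kd_ZP2; K <- params$K_BZ1
  D <- Kbp * Kzp2 + (1 + K) * Kzp2 * P + K * P^2
  list(B = N_total * Kbp * Kzp2 / D,
       BP = N_total * Kzp2 * P / D,
       ZP = N_total * K * Kzp2 * P / D,
       ZP2 = N_total * K * P^2 / D)
}

#' Equilibrium species concentrations at a given free protein concentration
#'
#' Partitions the DNA among the four states by the shared-denominator
#' equilibrium expressions
#' \deqn{D = K_{d,BP}K_{d,ZP_2} + (1 + K_{BZ,1})K_{d,ZP_2}[P] + K_{BZ,1}[P]^2}
#' \deqn{[B] = [N]_t K_{d,BP}K_{d,ZP_2}/D, \quad [BP] = [N]_t K_{d,ZP_2}[P]/D,}
#' \deqn{[ZP] = [N]_t K_{BZ,1}K_{d,ZP_2}[P]/D, \quad [ZP_2] = [N]_t K_{BZ,1}[P]^2/D,}
#' and derives the total Z-DNA \eqn{Z_t = [ZP] + [ZP_2]} and both
#' Z-fraction conventions in use in the literature: `f_Z_dna`
#' (\eqn{Z_t/[N]_t}, the relative Z-DNA population) and `f_Z_protein`
#' (\eqn{Z_t/[P]_t}, the Z-DNA yield per added protein). All claims about
#' the DNA population (such as the half-stoichiometry relation
#' \eqn{Z_t = \frac12 [P]_t} under tight binding with \eqn{K_{BZ,1}=1})
#' use `f_Z_dna`.
#'
#' @param params A [bz_params()] object.
#' @param mix A [bz_mixture()] object.
#' @param P_free Free protein concentration, uM (usually from
#'   [solve_free_protein()]).
#' @return An object of class `bz_species`: list with `P_free`, `B`, `BP`,
#'   `ZP`, `ZP2`, `Z_total`, `f_Z_dna`, `f_Z_protein` and the totals
#'   `P_total`, `N_total`.
#' @examples
#' p <- bz_params(Kd_BP = 1e-4, Kd_ZP2 = 1e-6, K_BZ1 = 1)
#' m <- bz_mixture(P_total = 1, N_total = 1)
#' st <- species_concentrations(p, m, solve_free_protein(p, m))
#' st$f_Z_dna  # ~0.5: Z-DNA produced is half the added protein
#' @export
species_concentrations <- function(params, mix, P_free) {
  stopifnot(inherits(params, "bz_params"), inherits(mix, "bz_mixture"))
  if (!is.numeric(P_free) || length(P_free) != 1L || !is.finite(P_free) || P_free < 0)
    stop_bz("invalid_state", "P_free must be a single finite number >= 0")
  s <- raw_species(params, mix$N_total, P_free)
  Zt <- s$ZP + s$ZP2
  structure(
    list(P_free = P_free, B = s$B, BP = s$BP, ZP = s$ZP, ZP2 = s$ZP2,
         Z_total = Zt,
         f_Z_dna = if (mix$N_total > 0) Zt / mix$N_total else NA_real_,
         f_Z_protein = if (mix$P_total > 0) Zt / mix$P_total else NA_real_,
         P_total = mix$P_total, N_total = mix$N_total),
    class = "bz_species"
  )
}

#' @export
print.bz_species <- function(x, ...) {
  cat("Equilibrium species (uM):\n")
  cat(sprintf("  [P]free = %g  [B] = %g  [BP] = %g  [ZP] = %g  [ZP2] = %g\n",
              x$P_free, x$B, x$BP, x$ZP, x$ZP2))
  cat(sprintf("  Z_t = %g uM   f_Z (per DNA) = %s   f_Z (per protein) = %s\n",
              x$Z_total, format(x$f_Z_dna), format(x$f_Z_protein)))
  invisible(x)
}

#' Equilibrium state of a mixture
#'
#' Convenience wrapper: solve the free protein concentration and return the
#' full species state in one call.
#'
#' @inheritParams solve_free_protein
#' @return A `bz_species` object (see [species_concentrations()]).
#' @export
equilibrium_state <- function(params, mix, method = "auto") {
  species_concentrations(params, mix, solve_free_protein(params, mix, method))
}

#' Simulated titration: species along a protein:DNA ratio grid
#'
#' Computes the equilibrium state at each molar ratio
#' \eqn{\chi = [P]_t/[N]_t} with `[P]_t = chi * N_total`, reproducing the
#' familiar Z-fraction titration curves (`f_Z` versus protein:DNA ratio).
#' Under tight binding with \eqn{K_{BZ,1} = 1} the curve follows
#' `f_Z_dna = chi/2` up to saturation.
#'
#' @param params A [bz_params()] object.
#' @param N_total Total DNA duplex concentration, uM (> 0).
#' @param chi Numeric vector of molar ratios (>= 0).
#' @param method Root-finding method, see [solve_free_protein()].
#' @return A data frame with one row per ratio and columns `chi`,
#'   `P_total`, `N_total`, `P_free`, `B`, `BP`, `ZP`, `ZP2`, `Z_total`,
#'   `f_Z_dna`, `f_Z_protein`.
#' @examples
#' p <- bz_params(Kd_BP = 0.028, Kd_ZP2 = 0.345, K_BZ1 = 0.87)
#' tc <- titration_curve(p, N_total = 100, chi = seq(0, 2, 0.25))
#' tc[, c("chi", "f_Z_dna")]
#' @export
titration_curve <- function(params, N_total, chi, method = "auto") {
  stopifnot(inherits(params, "bz_params"))
  if (!is.numeric(N_total) || length(N_total) != 1L || N_total <= 0)
    stop_bz("invalid_mixture", "N_total must be a single number > 0")
  if (!is.numeric(chi) || any(!is.finite(chi)) || any(chi < 0))
    stop_bz("invalid_mixture", "chi must be finite and >= 0")
  rows <- lapply(chi, function(x) {
    st <- equilibrium_state(params, bz_mixture(x * N_total, N_total), method)
    data.frame(chi = x, P_total = st$P_total, N_total = st$N_total,
               P_free = st$P_free, B = st$B, BP = st$BP, ZP = st$ZP,
               ZP2 = st$ZP2, Z_total = st$Z_total, f_Z_dna = st$f_Z_dna,
               f_Z_protein = st$f_Z_protein)
  })
  do.call(rbind, rows)
}
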