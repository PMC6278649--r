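## Nonlinear least-squares estimation of the equilibrium constants from
## titration data. All positive constants are fitted on a log10 scale by
## default (bounds: Kd in [1e-4, 1e4] uM, K_BZ1 in [1e-3, 1e2], alpha in
## [1e-4, 1e3]); the limiting rates / per-probe shifts enter the models
## linearly and are profiled out by weighted linear least squares
## (variable projection), so the nonlinear search runs over at most three
## parameters.

BZ_BOUNDS <- list(
  alpha = c(1e-4, 1e3),
  K_BZ1 = c(1e-3, 1e2),
  Kd = c(1e-4, 1e4)
)

# deterministic Latin-hypercube starts in a log10 box; first start is the
# box centre so a run with n_starts = 1 is fully deterministic too
lhs_starts <- function(n_starts, lower, upper, seed = 1L) {
  k <- length(lower)
  centre <- (lower + upper) / 2
  if (n_starts <= 1L) return(matrix(centre, nrow = 1L))
  u <- withr::with_seed(seed, lhs::randomLHS(n_starts - 1L, k))
  rbind(centre, sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+"))
}

# weighted linear least squares, tolerant of rank deficiency
wls_coef <- function(X, y, w) {
  fit <- stats::lm.wfit(X, y, w^2)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  co
}

# numeric Jacobian of a residual function (central differences)
num_jacobian <- function(fn, par, eps = 1e-6) {
  r0 <- fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(abs(par[j]), 1)
    pp <- par; pp[j] <- par[j] + h
    pm <- par; pm[j] <- par[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

# covariance of the estimates from the weighted-residual Jacobian;
# scaled by the reduced chi-square as is conventional in curve fitting
fit_covariance <- function(resfun, par) {
  J <- num_jacobian(resfun, par)
  r <- resfun(par)
  n <- length(r); p <- length(par)
  sv <- svd(J)
  rank_ok <- length(sv$d) > 0 && sv$d[1] > 0 &&
    min(sv$d) / max(sv$d) > 1e-8
  s2 <- if (n > p) sum(r^2) / (n - p) else NA_real_
  cov <- if (rank_ok) {
    Vi <- sv$v %*% (t(sv$u) / sv$d)
    tcrossprod(Vi) * if (is.na(s2)) 1 else s2
  } else {
    matrix(NA_real_, p, p)
  }
  list(cov = cov, rank_ok = rank_ok, s2 = s2)
}

new_bz_fit <- function(model, estimates, se, objective, n_points, n_free,
                       converged, flags, residuals, multi_start = NULL,
                       probe_shifts = NULL, refit = NULL) {
  structure(
    list(model = model, estimates = estimates, se = se,
         objective = objective, n_points = n_points, n_free = n_free,
         converged = converged, flags = flags, residuals = residuals,
         multi_start = multi_start, probe_shifts = probe_shifts,
         refit = refit),
    class = "bz_fit"
  )
}

#' @export
print.bz_fit <- function(x, ...) {
  cat(sprintf("B-Z transition fit [%s]: %d points, %d free parameters\n",
              x$model, x$n_points, x$n_free))
  est <- data.frame(estimate = x$estimates,
                    se = x$se[names(x$estimates)])
  print(est)
  cat(sprintf("  weighted SSR = %g;  converged: %s%s\n", x$objective,
              x$converged,
              if (length(x$flags)) paste0("  flags: ", paste(x$flags, collapse = ", "))
              else ""))
  if (!is.null(x$probe_shifts)) {
    cat("  per-probe limiting shifts (ppm):\n")
    print(x$probe_shifts, row.names = FALSE)
  }
  invisible(x)
}

check_kind <- function(data, kind) {
  stopifnot(inherits(data, "titration_dataset"))
  if (data$observable_kind != kind)
    stop_bz("invalid_dataset",
            sprintf("expected a %s dataset, got %s", kind, data$observable_kind))
}

fit_weights <- function(sigma, n) {
  if (is.null(sigma) || all(is.na(sigma))) rep(1, n) else {
    s <- sigma
    s[is.na(s)] <- stats::median(s, na.rm = TRUE)
    1 / s
  }
}

#' Fit the molar-ratio exchange model to a titration dataset
#'
#' Estimates \eqn{\alpha} (and, unless supplied as fixed, the limiting
#' rates \eqn{k_{ex,ZP}}, \eqn{k_{ex,ZP_2}}) from exchange rates measured
#' versus the molar ratio \eqn{\chi \le 2}, by weighted least squares on
#' the [kex_vs_chi()] model. \eqn{\alpha} is searched on a log10 scale
#' (default) over `[1e-4, 1e3]`; the rates enter linearly and are profiled
#' out, so the search is one-dimensional (coarse bracket scan plus golden-
#' section refinement, deterministic).
#'
#' @param data A [titration_dataset()] of kind `"kex_vs_chi"` with point
#'   columns `chi` (in `(0, 2]`), `kex` and optional `sigma`.
#' @param fixed Optional [exchange_rates()]; when `kex_ZP` and `kex_ZP2`
#'   are set they are held fixed and only \eqn{\alpha} is estimated.
#' @param log_scale Fit \eqn{\alpha} as `log10(alpha)` (default `TRUE`).
#' @return A `bz_fit` object with fields `estimates` (named: `alpha`,
#'   `kex_ZP`, `kex_ZP2`), `se`, `objective` (weighted SSR), `residuals`,
#'   `converged` and `flags`.
#' @examples
#' r <- exchange_rates(kex_ZP = 10, kex_ZP2 = 1)
#' chi <- seq(0.2, 2, length.out = 12)
#' d <- titration_dataset("kex_vs_chi",
#'   data.frame(chi = chi, kex = kex_vs_chi(r, 1.15e-2, chi), sigma = NA))
#' fit_eq1(d)$estimates
#' @export
fit_eq1 <- function(data, fixed = NULL, log_scale = TRUE) {
  check_kind(data, "kex_vs_chi")
  pts <- data$points[!is.na(data$points$kex), , drop = FALSE]
  chi <- pts$chi; y <- pts$kex
  if (any(chi <= 0 | chi > 2))
    stop_bz("regime", "fit_eq1 requires chi in (0, 2]")
  wt <- fit_weights(pts$sigma, length(y))
  rates_fixed <- !is.null(fixed) && !is.na(fixed$kex_ZP) && !is.na(fixed$kex_ZP2)
  n_free <- 1L + if (rates_fixed) 0L else 2L

  basis <- function(alpha) {
    eps <- 4 * (1 - alpha) * (chi / 2 - chi^2 / 4)
    (2 - chi) / (1 + sqrt(pmax(1 - eps, 0)))
  }
  rates_for <- function(alpha) {
    if (rates_fixed) return(c(fixed$kex_ZP, fixed$kex_ZP2))
    w1 <- basis(alpha)
    wls_coef(cbind(w1, 1 - w1), y, wt)
  }
  profile_obj <- function(alpha) {
    k <- rates_for(alpha)
    w1 <- basis(alpha)
    sum(((y - (k[1] * w1 + k[2] * (1 - w1))) * wt)^2)
  }
  bounds <- BZ_BOUNDS$alpha
  sol <- optimise_1d(profile_obj, bounds, log_scale)
  alpha_hat <- sol$x
  k_hat <- rates_for(alpha_hat)

  resfun <- function(par) {
    a <- if (log_scale) 10^par[1] else par[1]
    k <- if (rates_fixed) c(fixed$kex_ZP, fixed$kex_ZP2) else par[2:3]
    w1 <- basis(a)
    (y - (k[1] * w1 + k[2] * (1 - w1))) * wt
  }
  par_full <- c(if (log_scale) log10(alpha_hat) else alpha_hat,
                if (rates_fixed) NULL else k_hat)
  finish_fit("kex_vs_chi", data, resfun, par_full, log_idx = if (log_scale) 1L else integer(),
             par_names = c("alpha", if (!rates_fixed) c("kex_ZP", "kex_ZP2")),
             n_points = length(y), n_free = n_free,
             fitted = {
               w1 <- basis(alpha_hat)
               k_hat[1] * w1 + k_hat[2] * (1 - w1)
             },
             obs = y, wt = wt, x = chi, x_name = "chi",
             refit = function(d) fit_eq1(d, fixed = fixed, log_scale = log_scale))
}

# deterministic 1-D minimisation: coarse log-spaced scan + optimize()
# inside the bracketing interval around the best grid point
optimise_1d <- function(fn, bounds, log_scale, n_grid = 41L) {
  if (log_scale) {
    tg <- seq(log10(bounds[1]), log10(bounds[2]), length.out = n_grid)
    vals <- vapply(tg, function(t) fn(10^t), 0)
    i <- which.min(vals)
    lo <- tg[max(1L, i - 1L)]; hi <- tg[min(n_grid, i + 1L)]
    o <- stats::optimize(function(t) fn(10^t), c(lo, hi), tol = 1e-12)
    list(x = 10^o$minimum, value = o$objective)
  } else {
    tg <- 10^seq(log10(bounds[1]), log10(bounds[2]), length.out = n_grid)
    vals <- vapply(tg, fn, 0)
    i <- which.min(vals)
    lo <- tg[max(1L, i - 1L)]; hi <- tg[min(n_grid, i + 1L)]
    o <- stats::optimize(fn, c(lo, hi), tol = 1e-12)
    list(x = o$minimum, value = o$objective)
  }
}

# shared tail of every fit: covariance, flags, result object
finish_fit <- function(model, data, resfun, par_full, log_idx, par_names,
                       n_points, n_free, fitted, obs, wt, x, x_name,
                       refit, multi_start = NULL, probe_shifts = NULL,
                       extra_flags = character()) {
  flags <- extra_flags
  if (n_points < n_free) {
    flags <- c(flags, "under_determined")
    warn_bz("under_determined",
            sprintf("%d points cannot determine %d parameters", n_points, n_free))
  }
  cv <- fit_covariance(resfun, par_full)
  if (!cv$rank_ok) flags <- c(flags, "rank_deficient")
  se_par <- if (all(is.na(cv$cov))) rep(NA_real_, length(par_full))
            else sqrt(pmax(diag(cv$cov), 0))
  # delta method back to the linear scale for log10-fitted parameters
  est <- par_full
  se <- se_par
  if (length(log_idx)) {
    est[log_idx] <- 10^par_full[log_idx]
    se[log_idx] <- est[log_idx] * log(10) * se_par[log_idx]
  }
  names(est) <- names(se) <- par_names
  resid_df <- data.frame(x = x, observed = obs, fitted = fitted,
                         residual = obs - fitted, weight = wt)
  names(resid_df)[1] <- x_name
  new_bz_fit(model, est, se, objective = sum(((obs - fitted) * wt)^2),
             n_points = n_points, n_free = n_free,
             converged = !("non_convergent" %in% flags),
             flags = unique(flags), residuals = resid_df,
             multi_start = multi_start, probe_shifts = probe_shifts,
             refit = refit)
}

# common machinery of the two f_Z exchange fits: nonlinear in
# (alpha, K_BZ1), linear in the two limiting rates
fit_fz_model <- function(data, kind, fixed, log_scale, n_starts) {
  check_kind(data, kind)
  pts <- data$points[!is.na(data$points$kex), , drop = FALSE]
  f <- pts$f_z; y <- pts$kex
  if (kind == "kex_bform" && any(f >= 1))
    stop_bz("regime", "B-form probe data require f_z < 1")
  if (any(f < 0 | f > 1))
    stop_bz("regime", "f_z must lie in [0, 1]")
  wt <- fit_weights(pts$sigma, length(y))
  rate_names <- if (kind == "kex_bform") c("kex_B", "kex_BP") else c("kex_ZP", "kex_ZP2")
  rates_fixed <- !is.null(fixed) && !any(is.na(unlist(fixed[rate_names])))
  n_free <- 2L + if (rates_fixed) 0L else 2L

  # weight of the "perturbed" state in the linear parameterisation
  basis <- function(alpha, K) {
    den <- fz_bracket_den(alpha, K, f)
    if (kind == "kex_bform") 2 * K * f / den else 2 * (1 - f) / den
  }
  # model: base*(1-w) + other*w  (bform: base kex_B, other kex_BP;
  #        zform: base kex_ZP2... written uniformly via X matrix)
  Xmat <- function(w) {
    if (kind == "kex_bform") cbind(1 - w, w) else cbind(w, 1 - w)
  }
  rates_for <- function(alpha, K) {
    if (rates_fixed) return(unlist(fixed[rate_names], use.names = FALSE))
    wls_coef(Xmat(basis(alpha, K)), y, wt)
  }
  model_y <- function(alpha, K, k) {
    drop(Xmat(basis(alpha, K)) %*% k)
  }
  profile_obj <- function(u) {
    a <- if (log_scale) 10^u[1] else u[1]
    K <- if (log_scale) 10^u[2] else u[2]
    v <- tryCatch({
      k <- rates_for(a, K)
      sum(((y - model_y(a, K, k)) * wt)^2)
    }, error = function(e) NA_real_)
    if (!is.finite(v)) 1e12 else v
  }
  lower <- c(BZ_BOUNDS$alpha[1], BZ_BOUNDS$K_BZ1[1])
  upper <- c(BZ_BOUNDS$alpha[2], BZ_BOUNDS$K_BZ1[2])
  ms <- multistart_optim(profile_obj, log10(lower), log10(upper),
                         n_starts, log_scale)
  alpha_hat <- ms$par[1]; K_hat <- ms$par[2]
  k_hat <- rates_for(alpha_hat, K_hat)

  resfun <- function(par) {
    a <- if (log_scale) 10^par[1] else par[1]
    K <- if (log_scale) 10^par[2] else par[2]
    k <- if (rates_fixed) unlist(fixed[rate_names], use.names = FALSE) else par[3:4]
    (y - model_y(a, K, k)) * wt
  }
  par_full <- c(if (log_scale) log10(c(alpha_hat, K_hat)) else c(alpha_hat, K_hat),
                if (rates_fixed) NULL else k_hat)
  extra <- if (!ms$converged) "non_convergent" else character()
  finish_fit(kind, data, resfun, par_full,
             log_idx = if (log_scale) 1:2 else integer(),
             par_names = c("alpha", "K_BZ1", if (!rates_fixed) rate_names),
             n_points = length(y), n_free = n_free,
             fitted = model_y(alpha_hat, K_hat, k_hat),
             obs = y, wt = wt, x = f, x_name = "f_z",
             refit = function(d) fit_fz_model(d, kind, fixed, log_scale, n_starts),
             multi_start = ms$table, extra_flags = extra)
}

# L-BFGS-B from deterministic Latin-hypercube starts (log10 box);
# returns the best solution on the scale requested by log_scale
multistart_optim <- function(obj, log_lower, log_upper, n_starts, log_scale) {
  starts <- lhs_starts(n_starts, log_lower, log_upper)
  best <- NULL
  tab <- data.frame()
  for (i in seq_len(nrow(starts))) {
    u0 <- if (log_scale) starts[i, ] else 10^starts[i, ]
    lo <- if (log_scale) log_lower else 10^log_lower
    hi <- if (log_scale) log_upper else 10^log_upper
    o <- tryCatch(
      stats::optim(u0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(o)) next
    tab <- rbind(tab, data.frame(start = i, objective = o$value,
                                 convergence = o$convergence))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop_bz("non_convergent", "all optimizer starts failed")
  # convergence is judged on the multistart solution; the polish below
  # may stall in the line search at machine precision without that
  # saying anything about convergence of the fit itself
  conv_ok <- best$convergence == 0
  # final polish from the best start at the tightest tolerance, so the
  # optimum is independent of the parameter scale used for the search
  pol <- tryCatch(
    stats::optim(best$par, obj, method = "L-BFGS-B",
                 lower = if (log_scale) log_lower else 10^log_lower,
                 upper = if (log_scale) log_upper else 10^log_upper,
                 control = list(maxit = 1000, factr = 1, pgtol = 0)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value) {
    best[c("par", "value")] <- pol[c("par", "value")]
    conv_ok <- conv_ok || pol$convergence == 0
  }
  # derivative-free polish: L-BFGS-B can stall in the numerically flat
  # basin of a near-zero SSR
  nm <- tryCatch(
    stats::optim(best$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-15)),
    error = function(e) NULL)
  if (!is.null(nm) && nm$value <= best$value) {
    best[c("par", "value")] <- nm[c("par", "value")]
    conv_ok <- conv_ok || nm$convergence == 0
  }
  par <- if (log_scale) 10^best$par else best$par
  list(par = par, value = best$value, converged = conv_ok, table = tab)
}

#' Fit the B-form-probe exchange model (Z-fraction parameterisation)
#'
#' Estimates \eqn{\alpha} and \eqn{K_{BZ,1}} (plus, unless fixed, the
#' limiting rates \eqn{k_{ex,B}}, \eqn{k_{ex,BP}}) from exchange rates of
#' a B-form imino proton observed versus the relative Z-DNA population,
#' using the [kex_bform_vs_fz()] model. The two constants are searched on
#' a log10 scale by L-BFGS-B from deterministic Latin-hypercube starts;
#' the rates are profiled out linearly.
#'
#' When the two limiting rates coincide the model carries no information
#' about the constants; the fit then reports a `rank_deficient` flag
#' rather than a spurious estimate.
#'
#' @param data A [titration_dataset()] of kind `"kex_bform"` with point
#'   columns `f_z` (in `[0, 1)`), `kex`, optional `sigma`.
#' @param fixed Optional [exchange_rates()] holding `kex_B`, `kex_BP`
#'   fixed.
#' @param log_scale Fit the constants as log10 values (default `TRUE`).
#' @param n_starts Number of multi-start points (default 8).
#' @return A `bz_fit` object (`estimates`: `alpha`, `K_BZ1`, `kex_B`,
#'   `kex_BP`).
#' @export
fit_eq2 <- function(data, fixed = NULL, log_scale = TRUE, n_starts = 8L) {
  fit_fz_model(data, "kex_bform", fixed, log_scale, n_starts)
}

#' Fit the Z-form-probe exchange model (Z-fraction parameterisation)
#'
#' Estimates \eqn{\alpha} and \eqn{K_{BZ,1}} (plus, unless fixed,
#' \eqn{k_{ex,ZP}}, \eqn{k_{ex,ZP_2}}) from exchange rates of a Z-form
#' imino proton observed versus the relative Z-DNA population, using the
#' [kex_zform_vs_fz()] model. Same optimiser layout as [fit_eq2()].
#'
#' @param data A [titration_dataset()] of kind `"kex_zform"` with point
#'   columns `f_z` (in `(0, 1]`), `kex`, optional `sigma`.
#' @inheritParams fit_eq2
#' @return A `bz_fit` object (`estimates`: `alpha`, `K_BZ1`, `kex_ZP`,
#'   `kex_ZP2`).
#' @examples
#' r <- exchange_rates(kex_ZP = 12, kex_ZP2 = 0.8)
#' fz <- seq(0.05, 1, length.out = 25)
#' d <- titration_dataset("kex_zform",
#'   data.frame(f_z = fz, kex = kex_zform_vs_fz(r, 0.154, 1.02, fz), sigma = NA))
#' fit_eq3(d)$estimates[c("alpha", "K_BZ1")]
#' @export
fit_eq3 <- function(data, fixed = NULL, log_scale = TRUE, n_starts = 8L) {
  fit_fz_model(data, "kex_zform", fixed, log_scale, n_starts)
}

#' Global fit of chemical-shift and Z-fraction titrations
#'
#' Joint weighted least-squares estimation of the three equilibrium
#' constants \eqn{K_{d,BP}}, \eqn{K_{d,ZP_2}} and \eqn{K_{BZ,1}} from all
#' amide-probe shift-perturbation curves and the Z-fraction data of a
#' titration across absolute compositions \eqn{([P]_t, [N]_t)}. For each
#' trial set of constants the equilibrium species are solved through the
#' mass-balance cubic; each probe's limiting shifts
#' (\eqn{\Delta\delta_B}, \eqn{\Delta\delta_Z}) enter the observed
#' perturbation linearly and are profiled out by weighted linear least
#' squares, so the nonlinear search runs over the three (log10) constants
#' only, from deterministic Latin-hypercube starts. This joint approach is
#' what turns shift titrations into *absolute* binding constants rather
#' than only their ratio \eqn{\alpha}.
#'
#' @param datasets A `titration_dataset` of kind `"shift_and_fz"`, or a
#'   list of them sharing one composition grid (they are merged and share
#'   the three constants; probes keep per-probe shifts).
#' @param config Optional list: `fz_denominator` (`"dna"`, the default, or
#'   `"protein"` for the per-protein Z-yield convention), `n_starts`
#'   (default 8), `log_scale` (default `TRUE`).
#' @return A `bz_fit` object. `estimates` holds `Kd_BP`, `Kd_ZP2`,
#'   `K_BZ1` and the derived `alpha`; `probe_shifts` is a data frame of
#'   per-probe limiting shifts.
#' @export
global_fit_shifts <- function(datasets, config = list()) {
  if (inherits(datasets, "titration_dataset")) datasets <- list(datasets)
  if (!length(datasets))
    stop_bz("invalid_dataset", "at least one shift_and_fz dataset is required")
  for (d in datasets) check_kind(d, "shift_and_fz")
  fzden <- match.arg(config$fz_denominator %||% "dna", c("dna", "protein"))
  n_starts <- config$n_starts %||% 8L
  log_scale <- config$log_scale %||% TRUE

  grids <- lapply(datasets, function(d)
    unique(d$points[order(d$points$N_total_uM, d$points$P_total_uM),
                    c("P_total_uM", "N_total_uM")]))
  if (length(datasets) > 1L) {
    for (g in grids[-1]) if (!isTRUE(all.equal(g, grids[[1]], check.attributes = FALSE)))
      stop_bz("invalid_dataset", "datasets have inconsistent composition grids")
  }
  pts <- do.call(rbind, lapply(datasets, function(d) d$points))

  shift_rows <- pts[!is.na(pts$probe_id) & !is.na(pts$ddelta_obs_ppm), , drop = FALSE]
  fz_rows <- if ("f_z" %in% names(pts))
    pts[is.na(pts$probe_id) & !is.na(pts$f_z), , drop = FALSE]
  else pts[0, , drop = FALSE]
  if (nrow(shift_rows) == 0L)
    stop_bz("empty_dataset", "no shift observations in the dataset")
  probes <- unique(shift_rows$probe_id)

  comps <- unique(rbind(shift_rows[, c("P_total_uM", "N_total_uM")],
                        if (nrow(fz_rows)) fz_rows[, c("P_total_uM", "N_total_uM")]))
  comp_key <- function(df) paste(signif(df$P_total_uM, 12), signif(df$N_total_uM, 12))
  comps$key <- comp_key(comps)
  shift_rows$ci <- match(comp_key(shift_rows), comps$key)
  if (nrow(fz_rows)) fz_rows$ci <- match(comp_key(fz_rows), comps$key)

  w_shift <- fit_weights(shift_rows$sigma_ppm, nrow(shift_rows))
  w_fz <- if (nrow(fz_rows)) fit_weights(fz_rows$f_z_sigma, nrow(fz_rows)) else numeric()

  # weight fractions of the bound states at every distinct composition
  state_basis <- function(p) {
    x1 <- x2 <- fz <- numeric(nrow(comps))
    for (i in seq_len(nrow(comps))) {
      mx <- bz_mixture(comps$P_total_uM[i], comps$N_total_uM[i])
      st <- equilibrium_state(p, mx)
      x1[i] <- if (mx$P_total > 0) st$BP / mx$P_total else 0
      x2[i] <- if (mx$P_total > 0) (st$ZP + 2 * st$ZP2) / mx$P_total else 0
      fz[i] <- if (fzden == "dna") st$f_Z_dna else st$f_Z_protein
    }
    list(x1 = x1, x2 = x2, fz = fz)
  }
  probe_solve <- function(sb) {
    co <- matrix(0, length(probes), 2,
                 dimnames = list(probes, c("delta_B", "delta_Z")))
    for (p in probes) {
      sel <- shift_rows$probe_id == p
      X <- cbind(sb$x1[shift_rows$ci[sel]], sb$x2[shift_rows$ci[sel]])
      co[p, ] <- wls_coef(X, shift_rows$ddelta_obs_ppm[sel], w_shift[sel])
    }
    co
  }
  resid_all <- function(sb, co) {
    fitted_sh <- sb$x1[shift_rows$ci] * co[shift_rows$probe_id, "delta_B"] +
      sb$x2[shift_rows$ci] * co[shift_rows$probe_id, "delta_Z"]
    r <- (shift_rows$ddelta_obs_ppm - fitted_sh) * w_shift
    if (nrow(fz_rows))
      r <- c(r, (fz_rows$f_z - sb$fz[fz_rows$ci]) * w_fz)
    r
  }
  obj <- function(u) {
    v <- tryCatch({
      p <- bz_params(10^u[1], 10^u[2], 10^u[3])
      sb <- state_basis(p)
      sum(resid_all(sb, probe_solve(sb))^2)
    }, error = function(e) NA_real_)
    if (!is.finite(v)) 1e12 else v
  }
  lower <- log10(c(BZ_BOUNDS$Kd[1], BZ_BOUNDS$Kd[1], BZ_BOUNDS$K_BZ1[1]))
  upper <- log10(c(BZ_BOUNDS$Kd[2], BZ_BOUNDS$Kd[2], BZ_BOUNDS$K_BZ1[2]))
  ms <- multistart_optim(obj, lower, upper, n_starts, log_scale = TRUE)
  p_hat <- bz_params(ms$par[1], ms$par[2], ms$par[3])
  sb_hat <- state_basis(p_hat)
  co_hat <- probe_solve(sb_hat)

  resfun <- function(par) {
    p <- bz_params(10^par[1], 10^par[2], 10^par[3])
    sb <- state_basis(p)
    co <- matrix(par[-(1:3)], ncol = 2, dimnames = dimnames(co_hat))
    resid_all(sb, co)
  }
  par_full <- c(log10(c(p_hat$Kd_BP, p_hat$Kd_ZP2, p_hat$K_BZ1)), as.vector(co_hat))
  n_free <- 3L + 2L * length(probes)
  n_points <- nrow(shift_rows) + nrow(fz_rows)

  fitted_sh <- sb_hat$x1[shift_rows$ci] * co_hat[shift_rows$probe_id, "delta_B"] +
    sb_hat$x2[shift_rows$ci] * co_hat[shift_rows$probe_id, "delta_Z"]
  obs <- c(shift_rows$ddelta_obs_ppm, if (nrow(fz_rows)) fz_rows$f_z)
  fitted <- c(fitted_sh, if (nrow(fz_rows)) sb_hat$fz[fz_rows$ci])
  wt <- c(w_shift, w_fz)
  xlab <- c(paste0("shift:", shift_rows$probe_id, "@", comp_key(shift_rows)),
            if (nrow(fz_rows)) paste0("f_z@", comp_key(fz_rows)))

  fit <- finish_fit(
    "shift_and_fz", datasets, resfun, par_full, log_idx = 1:3,
    par_names = c("Kd_BP", "Kd_ZP2", "K_BZ1",
                  paste0(rep(rownames(co_hat), 2), rep(c(":delta_B", ":delta_Z"),
                                                       each = length(probes)))),
    n_points = n_points, n_free = n_free, fitted = fitted, obs = obs,
    wt = wt, x = xlab, x_name = "observation",
    refit = function(d) global_fit_shifts(d, config),
    multi_start = ms$table,
    probe_shifts = data.frame(probe_id = rownames(co_hat),
                              delta_B = co_hat[, "delta_B"],
                              delta_Z = co_hat[, "delta_Z"]),
    extra_flags = if (!ms$converged) "non_convergent" else character()
  )
  # headline estimates first, with the derived ratio alongside
  keep <- c("Kd_BP", "Kd_ZP2", "K_BZ1")
  est <- c(fit$estimates[keep], alpha = unname(fit$estimates["Kd_ZP2"] / fit$estimates["Kd_BP"]))
  se <- c(fit$se[keep], alpha = NA_real_)
  fit$probe_se <- fit$se[setdiff(names(fit$se), keep)]
  fit$estimates <- est
  fit$se <- se
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Case-resampling bootstrap uncertainties for a fit
#'
#' Re-estimates the parameters of a converged fit on `n_boot`
#' case-resampled copies of the data and reports percentile intervals.
#' For exchange-rate datasets, points are resampled with replacement; for
#' shift/Z-fraction datasets, whole composition points are resampled
#' (cluster bootstrap), keeping each composition's probes together.
#' Replicates whose resample is degenerate (too few distinct abscissae, or
#' a failed refit) are skipped and counted. Deterministic under `seed`.
#'
#' @param fit A `bz_fit` object.
#' @param data The dataset (or list of datasets) that produced the fit.
#' @param n_boot Number of bootstrap replicates (>= 100 recommended).
#' @param seed Integer seed.
#' @return An object of class `bz_boot`: a list with `table` (per
#'   parameter: sd, 16/84 and 2.5/97.5 percentiles), `n_ok`, `n_skipped`,
#'   and the replicate estimates in `replicates`.
#' @export
bootstrap_uncertainty <- function(fit, data, n_boot = 200L, seed = 1L) {
  stopifnot(inherits(fit, "bz_fit"))
  if (!fit$converged)
    stop_bz("non_convergent", "bootstrap requires a converged fit")
  if (is.null(fit$refit))
    stop_bz("invalid_state", "fit object carries no refit closure")
  single <- inherits(data, "titration_dataset")
  ds1 <- if (single) data else data[[1]]

  # one shared index draw per replicate so a list of datasets keeps a
  # consistent resampled composition grid
  resample <- function(d, idx) {
    if (d$observable_kind == "shift_and_fz") {
      key <- paste(d$points$P_total_uM, d$points$N_total_uM)
      pick <- unique(key)[idx]
      pts <- do.call(rbind, lapply(pick, function(k) d$points[key == k, , drop = FALSE]))
    } else {
      pts <- d$points[idx, , drop = FALSE]
    }
    titration_dataset(d$observable_kind, pts, pH = d$pH,
                      salt_mM = d$salt_mM, sequence = d$sequence)
  }
  n_units <- if (ds1$observable_kind == "shift_and_fz")
    length(unique(paste(ds1$points$P_total_uM, ds1$points$N_total_uM)))
  else nrow(ds1$points)
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_units, n_units, replace = TRUE)
      est <- tryCatch({
        dnew <- if (single) resample(ds1, idx)
                else lapply(data, resample, idx = idx)
        x_col <- if (ds1$observable_kind == "shift_and_fz") NULL else
          (if (ds1$observable_kind == "kex_vs_chi") "chi" else "f_z")
        if (!is.null(x_col)) {
          dd <- if (single) dnew else dnew[[1]]
          if (length(unique(dd$points[[x_col]])) < 3L)
            stop("degenerate resample")
        }
        suppressWarnings(fit$refit(dnew))$estimates
      }, error = function(e) NULL)
      est
    })
  })
  ok <- !vapply(reps, is.null, TRUE)
  if (!any(ok))
    stop_bz("non_convergent", "every bootstrap replicate failed")
  mat <- do.call(rbind, reps[ok])
  mat <- mat[, intersect(colnames(mat), names(fit$estimates)), drop = FALSE]
  qs <- t(apply(mat, 2, stats::quantile,
                probs = c(0.025, 0.16, 0.84, 0.975), na.rm = TRUE))
  tab <- data.frame(parameter = colnames(mat),
                    estimate = fit$estimates[colnames(mat)],
                    sd = apply(mat, 2, stats::sd),
                    q2.5 = qs[, 1], q16 = qs[, 2], q84 = qs[, 3], q97.5 = qs[, 4])
  structure(list(table = tab, n_ok = sum(ok), n_skipped = sum(!ok),
                 replicates = mat),
            class = "bz_boot")
}

#' @export
print.bz_boot <- function(x, ...) {
  cat(sprintf("Bootstrap uncertainties: %d replicates (%d skipped)\n",
              x$n_ok, x$n_skipped))
  print(x$table, row.names = FALSE)
  invisible(x)
}
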