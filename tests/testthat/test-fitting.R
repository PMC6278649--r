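rZ <- exchange_rates(kex_ZP = 10, kex_ZP2 = 1)
rB <- exchange_rates(kex_B = 2, kex_BP = 30)

make_eq1_data <- function(alpha, noise_cv = 0, n = 12, seed = 1) {
  sp <- simulation_spec("kex_vs_chi",
    truth = list(alpha = alpha, rates = rZ),
    design = list(chi = seq(0.17, 2, length.out = n)),
    noise = list(kex_cv = noise_cv), seed = seed)
  simulate_dataset(sp)
}

test_that("noise-free molar-ratio data return the generating parameters", {
  d <- make_eq1_data(1.15e-2)
  f <- fit_eq1(d)
  expect_true(f$converged)
  expect_rel_equal(f$estimates["alpha"], 1.15e-2, 1e-6)
  expect_rel_equal(f$estimates["kex_ZP"], 10, 1e-6)
  expect_rel_equal(f$estimates["kex_ZP2"], 1, 1e-6)

  # with the limiting rates supplied as known constants
  ff <- fit_eq1(d, fixed = rZ)
  expect_rel_equal(ff$estimates["alpha"], 1.15e-2, 1e-6)
  expect_equal(f$n_free, 3L)
  expect_equal(ff$n_free, 1L)
})

test_that("molar-ratio fit agrees with an independent optimizer", {
  skip_if_not_installed("minpack.lm")
  d <- make_eq1_data(0.154)
  f <- fit_eq1(d)
  nls_fit <- minpack.lm::nlsLM(
    kex ~ kZP2 + (kZP - kZP2) / ((1 - a) * chi) *
      (1 - sqrt(1 - 4 * (1 - a) * (chi / 2 - chi^2 / 4))),
    data = d$points, start = list(a = 0.5, kZP = 5, kZP2 = 2),
    lower = c(1e-4, 0, 0), upper = c(10, 100, 100),
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14))
  expect_rel_equal(f$estimates["alpha"], coef(nls_fit)[["a"]], 1e-5)
})

test_that("fitting in log or linear parameter space gives the same optimum", {
  d <- make_eq1_data(0.154)
  f_log <- fit_eq1(d, log_scale = TRUE)
  f_lin <- fit_eq1(d, log_scale = FALSE)
  expect_rel_equal(f_log$estimates["alpha"], f_lin$estimates["alpha"], 1e-6)

  fz <- seq(0.05, 1, length.out = 25)
  d3 <- titration_dataset("kex_zform",
    data.frame(f_z = fz, kex = kex_zform_vs_fz(rZ, 0.154, 1.02, fz)))
  g_log <- fit_eq3(d3, log_scale = TRUE)
  g_lin <- fit_eq3(d3, log_scale = FALSE)
  expect_rel_equal(g_log$estimates[c("alpha", "K_BZ1")],
                   g_lin$estimates[c("alpha", "K_BZ1")], 1e-6)
})

test_that("noise-free Z-fraction data return alpha and K_BZ1 jointly", {
  fz <- seq(0.05, 1, length.out = 25)
  d3 <- titration_dataset("kex_zform",
    data.frame(f_z = fz, kex = kex_zform_vs_fz(rZ, 0.154, 1.02, fz)))
  f3 <- fit_eq3(d3)
  expect_rel_equal(f3$estimates["alpha"], 0.154, 1e-4)
  expect_rel_equal(f3$estimates["K_BZ1"], 1.02, 1e-4)

  fzb <- seq(0.04, 0.92, length.out = 25)
  d2 <- titration_dataset("kex_bform",
    data.frame(f_z = fzb, kex = kex_bform_vs_fz(rB, 1.42, 0.4, fzb)))
  f2 <- fit_eq2(d2)
  expect_rel_equal(f2$estimates["alpha"], 1.42, 1e-4)
  expect_rel_equal(f2$estimates["K_BZ1"], 0.4, 1e-4)
})

test_that("the objective is convex along K_BZ1 around the optimum", {
  fz <- seq(0.05, 1, length.out = 25)
  d3 <- titration_dataset("kex_zform",
    data.frame(f_z = fz, kex = kex_zform_vs_fz(rZ, 0.154, 1.02, fz)))
  # profile the SSR over a K grid with alpha at truth
  Kgrid <- seq(0.6, 1.6, by = 0.05)
  ssr <- vapply(Kgrid, function(K)
    sum((kex_zform_vs_fz(rZ, 0.154, K, fz) - d3$points$kex)^2), 0)
  i0 <- which.min(ssr)
  expect_equal(Kgrid[i0], 1.00, tolerance = 0.051)
  expect_true(all(diff(ssr[i0:length(ssr)]) > 0))
  expect_true(all(diff(ssr[1:i0]) < 0))
})

test_that("degenerate designs are flagged instead of silently fitted", {
  # equal limiting rates leave the constants without signal
  flatB <- exchange_rates(kex_B = 5, kex_BP = 5)
  fz <- seq(0.04, 0.92, length.out = 20)
  dflat <- titration_dataset("kex_bform",
    data.frame(f_z = fz, kex = kex_bform_vs_fz(flatB, 1.42, 0.4, fz)))
  fflat <- suppressWarnings(fit_eq2(dflat))
  expect_true("rank_deficient" %in% fflat$flags)

  # a single point cannot determine the parameters
  d1 <- titration_dataset("kex_zform", data.frame(f_z = 0.5, kex = 4))
  expect_warning(f1 <- fit_eq3(d1), class = "bz_under_determined")
  expect_true(any(c("under_determined", "rank_deficient") %in% f1$flags))
})

test_that("the alpha = 1 boundary is removable: curve affine in chi, still fittable", {
  # at alpha = 1 the square root collapses and the model reduces to the
  # straight line kex_ZP2 + (kex_ZP - kex_ZP2)(2 - chi)/2
  chi <- seq(0.2, 2, length.out = 12)
  y <- kex_vs_chi(rZ, 1, chi)
  expect_equal(y, 1 + (10 - 1) * (2 - chi) / 2, tolerance = 1e-12)
  # the fit still passes through the boundary smoothly
  f <- fit_eq1(make_eq1_data(1, noise_cv = 0))
  expect_rel_equal(f$estimates["alpha"], 1, 1e-4)
})

test_that("B-form-probe noisy titrations recover K_BZ1 at the calibrated accuracy", {
  rec2 <- recovery_study("kex_bform",
    truth = list(alpha = 1.42, K_BZ1 = 0.4, rates = rB),
    n_rep = 200, noise = list(kex_cv = 0.05), seed = 33,
    fit_args = list(n_starts = 4))
  err_K <- rec2$summary$median_rel_error[rec2$summary$parameter == "K_BZ1"]
  expect_lt(err_K, 0.15)
  expect_lt(rec2$n_failed, 10)
})

test_that("recovery error shrinks as the design grows", {
  med_err <- vapply(c(12, 24, 48), function(n) {
    rec <- recovery_study("kex_vs_chi",
      truth = list(alpha = 0.154, rates = rZ),
      n_rep = 30, noise = list(kex_cv = 0.05), seed = 20,
      design = list(chi = seq(0.17, 2, length.out = n)))
    rec$summary$median_rel_error[rec$summary$parameter == "alpha"]
  }, 0)
  expect_true(med_err[3] < med_err[1])
})

test_that("zero-noise global fit recovers the three constants", {
  truth <- pkz_truth(1)  # pH 6.0, 10 mM NaCl condition
  ds <- simulate_dataset(simulation_spec("shift_and_fz",
    truth = list(params = truth), seed = 2))
  f <- global_fit_shifts(ds)
  expect_true(f$converged)
  expect_rel_equal(f$estimates["Kd_BP"], truth$Kd_BP, 1e-3)
  expect_rel_equal(f$estimates["Kd_ZP2"], truth$Kd_ZP2, 1e-3)
  expect_rel_equal(f$estimates["K_BZ1"], truth$K_BZ1, 1e-3)
  # per-probe limiting shifts come back too
  probes <- attr(ds, "truth")$probes
  got <- f$probe_shifts[match(probes$probe_id, f$probe_shifts$probe_id), ]
  expect_rel_equal(got$delta_B, probes$delta_B, 1e-3)
  expect_rel_equal(got$delta_Z, probes$delta_Z, 1e-3)
})

test_that("dropping the Z-fraction data degrades the second binding constant", {
  truth <- pkz_truth(1)
  ds <- simulate_dataset(simulation_spec("shift_and_fz",
    truth = list(params = truth),
    noise = list(shift_sigma = 0.005, fz_sigma = 0.02), seed = 9))
  full <- global_fit_shifts(ds)
  no_fz <- ds
  no_fz$points <- ds$points[!is.na(ds$points$probe_id), , drop = FALSE]
  ablated <- global_fit_shifts(no_fz)
  # an NA standard error means the ablated design went rank-deficient,
  # i.e. precision degraded completely
  expect_true(is.na(ablated$se["Kd_ZP2"]) ||
                ablated$se["Kd_ZP2"] / full$se["Kd_ZP2"] > 1)
})

test_that("global fit validates composition-grid consistency across datasets", {
  truth <- pkz_truth(4)
  ds1 <- simulate_dataset(simulation_spec("shift_and_fz",
    truth = list(params = truth), seed = 2))
  ds2 <- simulate_dataset(simulation_spec("shift_and_fz",
    truth = list(params = truth), design = list(chi = c(0.4, 1.1, 1.9)),
    seed = 2))
  expect_error(global_fit_shifts(list(ds1, ds2)), class = "bz_invalid_dataset")
  # identical grids are accepted and fit jointly
  f <- global_fit_shifts(list(ds1, ds1), config = list(n_starts = 2))
  expect_rel_equal(f$estimates["K_BZ1"], truth$K_BZ1, 1e-3)
})

test_that("bootstrap intervals are deterministic and collapse on noise-free data", {
  d <- make_eq1_data(0.154, noise_cv = 0.05, seed = 5)
  f <- fit_eq1(d)
  b1 <- bootstrap_uncertainty(f, d, n_boot = 100, seed = 42)
  b2 <- bootstrap_uncertainty(f, d, n_boot = 100, seed = 42)
  expect_identical(b1$table, b2$table)
  expect_gt(b1$n_ok, 90)

  d0 <- make_eq1_data(0.154, noise_cv = 0)
  f0 <- fit_eq1(d0)
  b0 <- bootstrap_uncertainty(f0, d0, n_boot = 100, seed = 1)
  width <- b0$table[b0$table$parameter == "alpha", "q84"] -
    b0$table[b0$table$parameter == "alpha", "q16"]
  expect_lt(width, 1e-6 * f0$estimates["alpha"])
})

test_that("nominal 68% covariance intervals cover the truth at a plausible rate", {
  rec <- recovery_study("kex_vs_chi",
    truth = list(alpha = 0.154, rates = rZ),
    n_rep = 200, noise = list(kex_cv = 0.05),
    design = list(chi = seq(0.1, 2, length.out = 20)), seed = 77)
  cov <- rec$summary$coverage_68[rec$summary$parameter == "alpha"]
  expect_gte(cov, 0.58)
  expect_lte(cov, 0.78)
})
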