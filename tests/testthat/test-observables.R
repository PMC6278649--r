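rZ <- exchange_rates(kex_ZP = 10, kex_ZP2 = 1)
rB <- exchange_rates(kex_B = 2, kex_BP = 30)

test_that("molar-ratio exchange model matches the printed formula away from chi = 0", {
  for (alpha in c(1.15e-2, 0.154, 0.9, 1.5, 13.9)) {
    chi <- seq(0.05, 2, length.out = 40)
    expect_rel_equal(kex_vs_chi(rZ, alpha, chi),
                     naive_kex1(10, 1, alpha, chi), 1e-10)
  }
})

test_that("molar-ratio exchange model hits its limits exactly", {
  # full saturation: two proteins per duplex, only ZP2 remains
  expect_identical(kex_vs_chi(rZ, 0.7, 2), 1)
  # dilute-protein limit is the ZP rate (removable singularity)
  expect_identical(kex_vs_chi(rZ, 0.7, 0), 10)
  expect_equal(kex_vs_chi(rZ, 0.7, 1e-10), 10, tolerance = 1e-8)
  # outside the half-stoichiometry regime the model refuses
  expect_error(kex_vs_chi(rZ, 0.7, 2.5), class = "bz_regime")
  expect_error(kex_vs_chi(rZ, 0, 1), class = "bz_invalid_params")
})

test_that("Z-fraction exchange models match the printed formulas on interior points", {
  grid <- expand.grid(alpha = c(0.05, 0.154, 1.42, 13.9),
                      K = c(0.4, 1.02, 6.3))
  f <- seq(0.05, 0.95, length.out = 25)
  for (i in seq_len(nrow(grid))) {
    a <- grid$alpha[i]; K <- grid$K[i]
    expect_rel_equal(kex_bform_vs_fz(rB, a, K, f), naive_kex2(2, 30, a, K, f), 1e-9)
    expect_rel_equal(kex_zform_vs_fz(rZ, a, K, f), naive_kex3(10, 1, a, K, f), 1e-9)
  }
})

test_that("Z-fraction exchange models honour their boundary identities", {
  # discriminant zero point, evaluated by hand: K=1, alpha=0, f=1/2
  # gives brace 1 and k_ex = kex_B + (kex_BP - kex_B)
  expect_equal(kex_bform_vs_fz(rB, 0, 1, 0.5), 2 + (30 - 2))
  # full conversion leaves only ZP2
  expect_identical(kex_zform_vs_fz(rZ, 0.3, 1.7, 1), 1)
  # dilute limits
  expect_identical(kex_bform_vs_fz(rB, 0.3, 1.7, 0), 2)
  expect_identical(kex_zform_vs_fz(rZ, 0.3, 1.7, 0), 10)
  # equal limiting rates carry no conformational signal
  flat <- exchange_rates(kex_B = 5, kex_BP = 5, kex_ZP = 5, kex_ZP2 = 5)
  f <- seq(0, 0.9, 0.1)
  expect_equal(kex_bform_vs_fz(flat, 0.7, 2, f), rep(5, length(f)))
  expect_equal(kex_zform_vs_fz(flat, 0.7, 2, f), rep(5, length(f)))
  # f_Z = 1 has no B-form probe left
  expect_error(kex_bform_vs_fz(rB, 0.5, 1, 1), class = "bz_regime")
})

test_that("the molar-ratio model is the K_BZ1 = 1 slice of the Z-fraction model", {
  chi <- seq(0.05, 2, length.out = 30)
  for (alpha in c(1.15e-2, 0.5, 2)) {
    expect_rel_equal(kex_zform_vs_fz(rZ, alpha, 1, chi / 2),
                     kex_vs_chi(rZ, alpha, chi), 1e-12)
  }
})

test_that("population-weighted species route reproduces the molar-ratio model under tight binding", {
  # the formula's alpha plays the role of Kd_BP/Kd_ZP2 when matched to the
  # four-state species model (see vignette); deviation scales as sqrt(Kd/N)
  alpha <- 1.15e-2
  p <- bz_params(Kd_BP = alpha * 1e-14, Kd_ZP2 = 1e-14, K_BZ1 = 1)
  chi <- seq(0.05, 2, length.out = 25)
  kex_pop <- vapply(chi, function(x)
    kex_z_species(p, rZ, bz_mixture(x, 1)), 0)
  expect_rel_equal(kex_pop, kex_vs_chi(rZ, alpha, chi), 1e-6)
  # and both agree with the independent quadrature-closure oracle
  expect_rel_equal(weights_kex1(10, 1, alpha, chi),
                   kex_vs_chi(rZ, alpha, chi), 1e-9)
})

test_that("shift perturbation is the population-weighted average of the limiting shifts", {
  p <- bz_params(0.028, 0.345, 0.87)
  st <- equilibrium_state(p, bz_mixture(P_total = 25, N_total = 50))
  sp <- shift_pair("probe", delta_B = 0.10, delta_Z = 0.30)
  got <- delta_obs(st, sp)
  # independent recomputation through the numeric-root path
  stn <- species_concentrations(p, bz_mixture(25, 50),
                                solve_free_protein_numeric(p, bz_mixture(25, 50)))
  expect_equal(got, (stn$BP / 25) * 0.10 + ((stn$ZP + 2 * stn$ZP2) / 25) * 0.30,
               tolerance = 1e-9)
  # bounded by the convex hull of {0, delta_B, delta_Z}
  expect_lte(got, 0.30)
  expect_gte(got, 0)

  # no binding: all protein free, no perturbation
  weak <- bz_params(1e8, 1e8, 1)
  expect_equal(delta_obs(equilibrium_state(weak, bz_mixture(25, 50)), sp), 0,
               tolerance = 1e-6)
  # exactly two tight-binding proteins per duplex: all protein Z-bound
  # in ZP2 and the perturbation reaches delta_Z
  sat <- equilibrium_state(bz_params(1e-6, 1e-6, 1), bz_mixture(200, 100))
  expect_equal(delta_obs(sat, sp), 0.30, tolerance = 1e-3)
  expect_error(delta_obs(equilibrium_state(p, bz_mixture(0, 50)), sp),
               class = "bz_undefined_observable")
})

test_that("shift perturbation is invariant under joint concentration scaling", {
  sp <- shift_pair("probe", 0.2, -0.4)
  base <- delta_obs(equilibrium_state(bz_params(0.028, 0.345, 0.87),
                                      bz_mixture(25, 50)), sp)
  for (s in c(1e-2, 10, 1e3)) {
    scaled <- delta_obs(
      equilibrium_state(bz_params(0.028 * s, 0.345 * s, 0.87),
                        bz_mixture(25 * s, 50 * s)), sp)
    expect_equal(scaled, base, tolerance = 1e-8)
  }
})
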