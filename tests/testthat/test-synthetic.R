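test_that("zero-noise simulations equal the forward models exactly", {
  r <- exchange_rates(kex_ZP = 10, kex_ZP2 = 1)
  sp <- simulation_spec("kex_vs_chi", truth = list(alpha = 0.154, rates = r))
  ds <- simulate_dataset(sp)
  expect_identical(ds$points$kex, kex_vs_chi(r, 0.154, ds$points$chi))

  sp3 <- simulation_spec("kex_zform",
    truth = list(alpha = 0.154, K_BZ1 = 1.02, rates = r))
  ds3 <- simulate_dataset(sp3)
  expect_identical(ds3$points$kex,
                   kex_zform_vs_fz(r, 0.154, 1.02, ds3$points$f_z))

  truth <- pkz_truth(1)
  spg <- simulation_spec("shift_and_fz", truth = list(params = truth))
  dsg <- simulate_dataset(spg)
  fz_rows <- dsg$points[is.na(dsg$points$probe_id), ]
  for (i in seq_len(nrow(fz_rows))) {
    st <- equilibrium_state(truth, bz_mixture(fz_rows$P_total_uM[i],
                                              fz_rows$N_total_uM[i]))
    expect_equal(fz_rows$f_z[i], st$f_Z_dna)
  }
})

test_that("identical seeds give identical datasets, different seeds differ", {
  r <- exchange_rates(kex_ZP = 10, kex_ZP2 = 1)
  sp <- function(seed) simulation_spec("kex_vs_chi",
    truth = list(alpha = 0.154, rates = r),
    noise = list(kex_cv = 0.05), seed = seed)
  a <- simulate_dataset(sp(7)); b <- simulate_dataset(sp(7))
  expect_identical(a$points, b$points)
  expect_false(identical(a$points$kex, simulate_dataset(sp(8))$points$kex))
  # the generator does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_dataset(sp(7))); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated Z-fraction curves are monotone and saturate", {
  truth <- pkz_truth(4)  # pH 8.0, 10 mM condition
  ds <- simulate_dataset(simulation_spec("shift_and_fz",
    truth = list(params = truth),
    design = list(N_total = 100, chi = seq(0.25, 3, by = 0.25))))
  fz <- ds$points[is.na(ds$points$probe_id), ]
  fz <- fz[order(fz$P_total_uM), ]
  expect_true(all(diff(fz$f_z) >= -1e-12))
  expect_gt(max(fz$f_z), 0.95)
})

test_that("empirical noise matches the specification", {
  r <- exchange_rates(kex_ZP = 10, kex_ZP2 = 1)
  n <- 10000
  sp <- simulation_spec("kex_vs_chi",
    truth = list(alpha = 0.154, rates = r),
    design = list(chi = seq(2e-4, 2, length.out = n)),
    noise = list(kex_cv = 0.05), seed = 31)
  ds <- simulate_dataset(sp)
  mu <- kex_vs_chi(r, 0.154, ds$points$chi)
  factors <- ds$points$kex / mu
  expect_equal(sd(factors), 0.05, tolerance = 0.03)
  expect_equal(mean(factors), 1, tolerance = 0.002)

  truthp <- pkz_truth(1)
  spg <- simulation_spec("shift_and_fz",
    truth = list(params = truthp),
    design = list(N_total = 10, chi = seq(0.01, 2, length.out = 1250)),
    noise = list(shift_sigma = 0.005), seed = 32)
  dsg <- simulate_dataset(spg)
  sh <- dsg$points[!is.na(dsg$points$probe_id), ]
  mu_sh <- unlist(attr(dsg, "truth")$noisefree$shift_mu)
  expect_equal(sd(sh$ddelta_obs_ppm - mu_sh), 0.005, tolerance = 0.03 * 0.005 / 0.005)
})

test_that("noisy Z-fractions are clipped to the unit interval", {
  ds <- simulate_dataset(simulation_spec("shift_and_fz",
    truth = list(params = pkz_truth(1)),
    noise = list(fz_sigma = 0.3), seed = 5))
  fz <- ds$points$f_z[is.na(ds$points$probe_id)]
  expect_true(all(fz >= 0 & fz <= 1))
})

test_that("fixture suite is reproducible and covers every reference condition", {
  dir1 <- file.path(tempdir(), "fix1"); dir2 <- file.path(tempdir(), "fix2")
  unlink(c(dir1, dir2), recursive = TRUE)
  m1 <- make_fixture_suite(dir1, seed = 3)
  m2 <- make_fixture_suite(dir2, seed = 3)
  md5 <- function(m) vapply(m$datasets, `[[`, "", "md5")
  expect_identical(md5(m1), md5(m2))

  # six global-fit condition rows, three noise levels each
  kinds <- vapply(m1$datasets, `[[`, "", "observable_kind")
  expect_equal(sum(kinds == "shift_and_fz"), 6L * 3L)
  pkz_ids <- unique(sub("_(none|low|nominal)\\.csv$", "",
                        grep("^pkz", vapply(m1$datasets, `[[`, "", "file"), value = TRUE)))
  expect_equal(length(pkz_ids), 6L)
  # all four observable kinds are represented
  expect_setequal(unique(kinds),
                  c("kex_vs_chi", "kex_bform", "kex_zform", "shift_and_fz"))

  # fixtures round-trip through the CSV reader with zero value drift
  for (e in m1$datasets[c(1, 5, 13)]) {
    ds <- read_titration_csv(file.path(dir1, e$file),
                             observable_kind = e$observable_kind)
    raw <- utils::read.csv(file.path(dir1, e$file))
    if (e$observable_kind == "shift_and_fz") {
      expect_identical(ds$points$ddelta_obs_ppm, raw$ddelta_obs_ppm)
    } else {
      expect_identical(ds$points$kex, raw$kex)
    }
  }
  unlink(c(dir1, dir2), recursive = TRUE)
})
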