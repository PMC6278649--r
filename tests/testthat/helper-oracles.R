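# Independent oracles, coded directly from the printed model expressions
# and from first principles, deliberately NOT sharing code with the
# package internals.

# raw exchange-rate formulas, exactly as printed (numerically naive on
# purpose: the package's conjugate forms are checked against these away
# from the removable points)
naive_kex1 <- function(kex_ZP, kex_ZP2, alpha, chi) {
  kex_ZP2 + (kex_ZP - kex_ZP2) / ((1 - alpha) * chi) *
    (1 - sqrt(1 - 4 * (1 - alpha) * (chi / 2 - chi^2 / 4)))
}

naive_kex2 <- function(kex_B, kex_BP, alpha, K, f) {
  s <- 1 + (K - 1) * f
  kex_B + (kex_BP - kex_B) / (2 * (1 - alpha) * (1 - f)) *
    (s - sqrt(s^2 - 4 * K * (1 - alpha) * f * (1 - f)))
}

naive_kex3 <- function(kex_ZP, kex_ZP2, alpha, K, f) {
  s <- 1 + (K - 1) * f
  kex_ZP2 + (kex_ZP - kex_ZP2) / (2 * K * (1 - alpha) * f) *
    (s - sqrt(s^2 - 4 * K * (1 - alpha) * f * (1 - f)))
}

# population-weight route to the molar-ratio exchange model: solve the
# ZP fraction x of Z_t from the quadratic closure of the half-
# stoichiometry regime (K_BZ1 = 1, all protein bound, Z_t = chi/2 per
# unit DNA), then weight the limiting rates
weights_kex1 <- function(kex_ZP, kex_ZP2, alpha, chi) {
  q <- chi / 2 - chi^2 / 4
  x <- (1 - sqrt(1 - 4 * (1 - alpha) * q)) / (2 * (1 - alpha))
  w <- x / (chi / 2)
  kex_ZP * w + kex_ZP2 * (1 - w)
}

# bisection on the protein mass balance, from scratch (no uniroot, no
# package code): unique root of
#   g(P) = P + [BP] + [ZP] + 2[ZP2] - Pt
oracle_free_protein <- function(Kd_BP, Kd_ZP2, K_BZ1, N_total, P_total,
                                iters = 200) {
  if (P_total == 0) return(0)
  g <- function(P) {
    D <- Kd_BP * Kd_ZP2 + (1 + K_BZ1) * Kd_ZP2 * P + K_BZ1 * P^2
    BP <- N_total * Kd_ZP2 * P / D
    ZP <- N_total * K_BZ1 * Kd_ZP2 * P / D
    ZP2 <- N_total * K_BZ1 * P^2 / D
    P + BP + ZP + 2 * ZP2 - P_total
  }
  lo <- 0; hi <- P_total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo <= .Machine$double.eps * hi) break
  }
  (lo + hi) / 2
}

# reference truth sets used across tests
pkz_truth <- function(row = 1) {
  tab <- pkz_salt_constants()
  bz_params(tab$Kd_BP_uM[row], tab$Kd_ZP2_uM[row], tab$K_BZ1[row])
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol * pmax(abs(expected), .Machine$double.xmin)),
              label = sprintf("max rel dev %.3g <= %g",
                              max(abs(actual - expected) / pmax(abs(expected), .Machine$double.xmin)),
                              tol))
}
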