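# Integral engine against closed forms and independent constructions.

test_that("s-type integrals match closed-form Gaussian results", {
  a <- 0.7; b <- 1.3; R <- 1.234
  Na <- (2 * a / pi)^0.75; Nb <- (2 * b / pi)^0.75
  sh <- list(list(l = 0L, exps = a, coefs = Na, center = c(0, 0, 0)),
             list(l = 0L, exps = b, coefs = Nb, center = c(0, 0, R)))
  S <- sapt1dm:::cpp_one_electron(sh, 0L)
  p <- a + b; q <- a * b / p
  expect_equal(S[1, 2], Na * Nb * (pi / p)^1.5 * exp(-q * R^2), tolerance = 1e-14)
  Tk <- sapt1dm:::cpp_one_electron(sh, 1L)
  expect_equal(Tk[1, 2], Na * Nb * q * (3 - 2 * q * R^2) * (pi / p)^1.5 * exp(-q * R^2),
               tolerance = 1e-13)
  expect_equal(Tk[1, 1], 1.5 * a, tolerance = 1e-13)
  # nuclear attraction via the Boys function closed form
  z0 <- 0.9
  V <- sapt1dm:::cpp_nuclear(sh[1], matrix(c(0, 0, z0), 1, 3), 1.0)
  Tt <- 2 * a * z0^2
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  F0 <- sqrt(pi) / 2 * erf(sqrt(Tt)) / sqrt(Tt)
  expect_equal(V[1, 1], -Na^2 * (2 * pi / (2 * a)) * F0, tolerance = 1e-13)
  # (ss|ss) one-center
  g <- sapt1dm:::cpp_eri(sh[1], 0)
  expect_equal(g[1], Na^4 * 2 * pi^2.5 / ((2 * a)^2 * sqrt(4 * a)), tolerance = 1e-13)
})

test_that("p-function overlap matches the analytic s-p formula", {
  a <- 0.7; b <- 1.3; R <- 1.234
  Na <- (2 * a / pi)^0.75; Nb <- (2 * b / pi)^0.75
  sh <- list(list(l = 0L, exps = a, coefs = Na, center = c(0, 0, 0)),
             list(l = 1L, exps = b, coefs = Nb * 2 * sqrt(b), center = c(0, 0, R)))
  S <- sapt1dm:::cpp_one_electron(sh, 0L)
  p <- a + b; q <- a * b / p
  expect_equal(S[1, 4], Na * Nb * 2 * sqrt(b) * (pi / p)^1.5 * exp(-q * R^2) * (-a * R / p),
               tolerance = 1e-13)
  expect_equal(S[1, 2], 0); expect_equal(S[1, 3], 0)
})

test_that("MO transform equals an explicit four-loop AO contraction", {
  fx <- fx_h2h2_min()
  sys <- fx$sys; C <- fx$hfA$C
  g <- sapt1dm:::mo_eri(sys, C, C, C, C)
  gc <- sapt1dm:::mo_to_cart(sys, C)
  n <- sys$nao_cart
  pid0 <- function(i, j) { a <- max(i, j) - 1; b <- min(i, j) - 1; a * (a + 1) / 2 + b }
  G <- array(0, rep(n, 4))
  for (mu in 1:n) for (nu in 1:n) for (la in 1:n) for (si in 1:n) {
    ij <- pid0(mu, nu); kl <- pid0(la, si)
    G[mu, nu, la, si] <- sys$eri[(max(ij, kl) * (max(ij, kl) + 1) / 2 + min(ij, kl)) + 1]
  }
  i <- 1; j <- 2; k <- 3; l <- 4
  ref <- sum(G * outer(outer(gc[, i], gc[, j]), outer(gc[, k], gc[, l])))
  expect_equal(g[i, j, k, l], ref, tolerance = 1e-12)
  ref2 <- sum(G * outer(outer(gc[, 2], gc[, 2]), outer(gc[, 1], gc[, 3])))
  expect_equal(g[2, 2, 1, 3], ref2, tolerance = 1e-12)
})

test_that("energies are invariant under rigid rotation and translation", {
  geo1 <- dimer_geometry(c("H", "H", "He"),
                         rbind(c(-0.8, 0, 0), c(0.8, 0, 0), c(0, 0, 4)),
                         c("A", "A", "B"))
  # rotate by 30 degrees about y and translate
  th <- pi / 6
  Rm <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  xyz2 <- t(Rm %*% t(geo1$coords)) + matrix(rep(c(1.1, -0.4, 2.2), each = 3), 3)
  geo2 <- dimer_geometry(geo1$element, xyz2, geo1$monomer)
  s1 <- build_dimer_system(geo1, "aug-cc-pvdz")
  s2 <- build_dimer_system(geo2, "aug-cc-pvdz")
  e1 <- rhf(s1, "A")$E; e2 <- rhf(s2, "A")$E
  expect_equal(e1, e2, tolerance = 1e-9)
  a1 <- solve_monomer(s1, "A", method_spec("fci"))
  b1 <- solve_monomer(s1, "B", method_spec("fci"))
  a2 <- solve_monomer(s2, "A", method_spec("fci"))
  b2 <- solve_monomer(s2, "B", method_spec("fci"))
  d1 <- sapt_first_order(s1, a1, b1)
  d2 <- sapt_first_order(s2, a2, b2)
  expect_equal(d1$E_exch_S2, d2$E_exch_S2, tolerance = 1e-9)
  expect_equal(d1$E_exch_S4_incr, d2$E_exch_S4_incr, tolerance = 1e-9)
})

test_that("He RHF energy in the bundled aug-cc-pVTZ basis matches the known value", {
  geo <- dimer_geometry(c("He", "H"), rbind(c(0, 0, 0), c(0, 0, 500)), c("A", "B"))
  sys <- build_dimer_system(geo, "aug-cc-pvtz")
  expect_equal(rhf(sys, "A")$E, -2.86118, tolerance = 5e-5)
})
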