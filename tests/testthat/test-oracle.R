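test_that("exchange-operator sums reproduce the first-quantized antisymmetrizer", {
  # <1 + P> over determinant products equals the determinant of the
  # combined occupied-spinorbital overlap matrix
  geo <- dimer_geometry(c("H", "H", "H", "H"),
                        rbind(c(-0.7, 0, 0), c(0.7, 0, 0),
                              c(0, 0, 4.0), c(0, 0, 5.4)),
                        c("A", "A", "B", "B"))
  sys <- build_dimer_system(geo, "sto-3g")
  hfA <- rhf(sys, "A"); hfB <- rhf(sys, "B")
  n <- sys$nao
  CA <- hfA$C[, 1, drop = FALSE]; CB <- hfB$C[, 1, drop = FALSE]
  s <- as.numeric(t(CA) %*% sys$S %*% CB)
  tn <- interaction_tensors(sys, list(C = hfA$C, N = 2), list(C = hfB$C, N = 2))
  st <- product_state(list(c(1, 1 + n)), 1, list(c(1, 1 + n)), 1, n, n)
  bx <- brute_expectations(st, tn, k_max = 2)
  expect_equal(bx$P[1], -2 * s^2, tolerance = 1e-12)
  expect_equal(bx$P[2], s^4, tolerance = 1e-12)
  expect_equal(1 + sum(bx$P), (1 - s^2)^2, tolerance = 1e-12)
  # open-shell 3+2 case against the explicit 5x5 determinant
  SAB <- t(hfA$C[, 1:2]) %*% sys$S %*% CB
  M <- diag(5)
  M[1, 4] <- M[4, 1] <- SAB[1, 1]; M[2, 4] <- M[4, 2] <- SAB[2, 1]
  M[3, 5] <- M[5, 3] <- SAB[1, 1]
  stA <- product_state(list(c(1, 2, 1 + n)), 1, list(c(1, 1 + n)), 1, n, n)
  bxA <- brute_expectations(stA, tn, k_max = 2)
  expect_lt(abs(1 + sum(bxA$P) - det(M)), 1e-10)
})

test_that("applying more exchanges than electron pairs annihilates the state", {
  fx <- fx_h2h2_min()
  n <- fx$sys$nao
  st <- product_state(list(c(1, 1 + n)), 1, list(c(1, 1 + n)), 1, n, n)
  S_so <- matrix(0.05, 2 * n, 2 * n)
  p3 <- apply_P2k(st, 3, S_so)
  expect_length(p3$coef, 0)
})

test_that("the oracle refuses systems beyond its size cap", {
  expect_error(product_state(list(c(1, 7)), 1, list(c(1, 7)), 1, 6, 6),
               "spinorbitals")
})
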