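# Dense DM path against the determinant-space oracle, composition algebra,
# and the structural invariants of the overlap expansion.

test_that("one-electron monomers reproduce the closed-form single exchange", {
  geo <- dimer_geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.6)),
                        c("A", "B"))
  sys <- build_dimer_system(geo, "sto-3g")
  CA <- matrix(c(1, 0), 2, 1); CB <- matrix(c(0, 1), 2, 1)
  tn <- interaction_tensors(sys, list(C = CA, N = 1), list(C = CB, N = 1),
                            projected = TRUE)
  s <- tn$S[1, 1]
  st <- product_state(list(c(1)), 1, list(c(1)), 1, 1, 1)
  bx <- brute_expectations(st, tn, k_max = 1)
  expect_equal(bx$P[1], -s^2, tolerance = 1e-13)
  expect_equal(bx$VP[1], -s^2 * bx$V, tolerance = 1e-13)
  dA <- sapt1dm:::new_dms(1, 1, diag(c(1, 0)))
  dA$G2 <- array(0, rep(2, 4)); dA$G3 <- array(0, rep(2, 6))
  S_so <- sapt1dm:::so_overlap(tn$S)
  expect_equal(expectation_P2k(1, S_so, dA, dA), -s^2, tolerance = 1e-13)
  expect_equal(expectation_VP2k(1, tn, dA, dA), bx$VP[1], tolerance = 1e-13)
})

test_that("dense DM path equals the oracle on HF, FCI and geminal monomers", {
  fx <- fx_h2h2_min()
  sys <- fx$sys; n <- sys$nao
  orbA <- list(C = fx$hfA$C, N = 2); orbB <- list(C = fx$hfB$C, N = 2)
  tn <- interaction_tensors(sys, orbA, orbB)
  fA <- fci2(sys, "A", C = fx$hfA$C); fB <- fci2(sys, "B", C = fx$hfB$C)
  cases <- list(
    hf_hf   = list(dA = hf_rdms(1, n), dB = hf_rdms(1, n),
                   ciA = list(dets = list(c(1, 1 + n)), coef = 1),
                   ciB = list(dets = list(c(1, 1 + n)), coef = 1)),
    fci_fci = list(dA = gem2e_rdms(fA$gmats[[1]]), dB = gem2e_rdms(fB$gmats[[1]]),
                   ciA = gem_to_detci(fA$gmats[[1]]), ciB = gem_to_detci(fB$gmats[[1]])),
    fci_hf  = list(dA = gem2e_rdms(fA$gmats[[1]]), dB = hf_rdms(1, n),
                   ciA = gem_to_detci(fA$gmats[[1]]),
                   ciB = list(dets = list(c(1, 1 + n)), coef = 1)),
    gem_gem = local({
      gA <- random_gem(n, 21); gB <- random_gem(n, 22)
      list(dA = gem2e_rdms(gA), dB = gem2e_rdms(gB),
           ciA = gem_to_detci(gA), ciB = gem_to_detci(gB))
    }))
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    st <- product_state(cs$ciA$dets, cs$ciA$coef, cs$ciB$dets, cs$ciB$coef, n, n)
    bx <- brute_expectations(st, tn, k_max = 2)
    de <- dense_expectations(tn, cs$dA, cs$dB)
    expect_equal(de$V, bx$V, tolerance = 1e-10, label = paste(nm, "V"))
    expect_equal(de$P, bx$P[1:2], tolerance = 1e-10, label = paste(nm, "P"))
    expect_equal(de$VP, bx$VP[1:2], tolerance = 1e-10, label = paste(nm, "VP"))
  }
})

test_that("dense DM path equals the oracle for a four-electron monomer (3-RDM terms)", {
  fx <- fx_beto()
  sys <- fx$sys; nn <- sys$nao
  dA <- ci_rdms(fx$fsA$dets, fx$fsA$vectors[, 1], nn, kmax = 3)
  dB <- gem2e_rdms(fx$fB$gmats[[1]])
  tn <- interaction_tensors(sys, list(C = fx$hfA$C, N = 4),
                            list(C = fx$hfB$C, N = 2))
  st <- product_state(fx$fsA$dets, fx$fsA$vectors[, 1],
                      gem_to_detci(fx$fB$gmats[[1]])$dets,
                      gem_to_detci(fx$fB$gmats[[1]])$coef, nn, nn)
  bx <- brute_expectations(st, tn, k_max = 2)
  de <- dense_expectations(tn, dA, dB)
  expect_equal(de$V, bx$V, tolerance = 1e-10)
  expect_equal(de$P, bx$P[1:2], tolerance = 1e-10)
  expect_equal(de$VP, bx$VP[1:2], tolerance = 1e-10)
})

test_that("three-electron open-shell monomer matches the oracle", {
  fx <- fx_h2h2_min()
  sys <- fx$sys; n <- sys$nao
  # 3 electrons on A (2 alpha, 1 beta) via determinant FCI in 2 orbitals
  h <- t(fx$hfA$C) %*% sapt1dm:::monomer_hcore(sys, "A") %*% fx$hfA$C
  g <- sapt1dm:::mo_eri(sys, fx$hfA$C, fx$hfA$C, fx$hfA$C, fx$hfA$C)
  fs <- fci_small(h[1:3, 1:3], g[1:3, 1:3, 1:3, 1:3], 2, 1, nroots = 1)
  # embed in the n-orbital support
  emb <- function(d) c(d[d <= 3], d[d > 3] - 3 + n)
  detsA <- lapply(fs$dets, emb)
  dA <- ci_rdms(detsA, fs$vectors[, 1], n, kmax = 3)
  fB <- fci2(sys, "B", C = fx$hfB$C)
  dB <- gem2e_rdms(fB$gmats[[1]])
  tn <- interaction_tensors(sys, list(C = fx$hfA$C, N = 3),
                            list(C = fx$hfB$C, N = 2))
  ciB <- gem_to_detci(fB$gmats[[1]])
  st <- product_state(detsA, fs$vectors[, 1], ciB$dets, ciB$coef, n, n)
  bx <- brute_expectations(st, tn, k_max = 2)
  de <- dense_expectations(tn, dA, dB)
  expect_equal(de$V, bx$V, tolerance = 1e-10)
  expect_equal(de$P, bx$P[1:2], tolerance = 1e-10)
  expect_equal(de$VP, bx$VP[1:2], tolerance = 1e-10)
})

test_that("composition generator enumerates the expected term structures", {
  t1 <- generate_compositions(1)
  expect_length(t1, 2)
  expect_equal(vapply(t1, `[[`, 0, "sign"), c(1, -1))
  t2 <- generate_compositions(2)
  expect_length(t2, 4)
  expect_setequal(vapply(t2, `[[`, 0, "sign"), c(1, -1, -1, 1))
  # ordered-tuple multiplicity at n = 3: (1,2) and (2,1) both occur
  t3 <- generate_compositions(3)
  k12 <- Filter(function(tm) tm$s == 2 && setequal(tm$k_list, c(1, 2)), t3)
  expect_length(k12, 2)
})

test_that("general-order assembly matches the series expansion of the symmetrized ratio", {
  set.seed(4)
  V <- rnorm(1); P <- rnorm(3); VP0 <- rnorm(4)
  # formal series in x where <P_2k> carries x^k:
  # (V + sum_k VP_k x^k) / (1 + sum_k P_k x^k) ; E_n = coefficient of x^n
  num <- c(V, VP0[2:4])
  den <- c(1, P)
  series <- numeric(4)
  inv <- numeric(4); inv[1] <- 1
  for (n in 2:4) inv[n] <- -sum(den[2:n] * inv[(n - 1):1])
  for (n in 1:4) series[n] <- sum(num[1:n] * inv[n:1])
  expect_equal(exchange_order_general(1, c(V, VP0[2]), P[1]), series[2],
               tolerance = 1e-12)
  expect_equal(exchange_order_general(2, c(V, VP0[2:3]), P[1:2]), series[3],
               tolerance = 1e-12)
  expect_equal(exchange_order_general(3, c(V, VP0[2:4]), P[1:3]), series[4],
               tolerance = 1e-12)
  # explicit double-exchange formula with signs {+,-,-,+}
  expect_equal(exchange_order_general(2, c(V, VP0[2:3]), P[1:2]),
               VP0[3] - VP0[2] * P[1] - V * P[2] + V * P[1]^2, tolerance = 1e-12)
  expect_equal(exchange_order_general(1, c(V, VP0[2]), P[1]),
               VP0[2] - V * P[1], tolerance = 1e-12)
  expect_error(generate_compositions(0))
})

test_that("overlap scaling separates the exchange orders", {
  fx <- fx_h2h2_min()
  sys <- fx$sys; n <- sys$nao
  fA <- fci2(sys, "A", C = fx$hfA$C); fB <- fci2(sys, "B", C = fx$hfB$C)
  dA <- gem2e_rdms(fA$gmats[[1]]); dB <- gem2e_rdms(fB$gmats[[1]])
  tn <- interaction_tensors(sys, list(C = fx$hfA$C, N = 2),
                            list(C = fx$hfB$C, N = 2))
  S_so <- sapt1dm:::so_overlap(tn$S)
  P2 <- expectation_P2k(1, S_so, dA, dB)
  P4 <- expectation_P2k(2, S_so, dA, dB)
  for (lam in c(0.5, 0.25)) {
    expect_equal(expectation_P2k(1, lam * S_so, dA, dB), lam^2 * P2,
                 tolerance = 1e-12)
    expect_equal(expectation_P2k(2, lam * S_so, dA, dB), lam^4 * P4,
                 tolerance = 1e-12)
  }
})

test_that("exchange vanishes beyond the smaller electron count", {
  fx <- fx_h2h2_min()
  sys <- fx$sys; n <- sys$nao
  dA <- gem2e_rdms(random_gem(n, 31))
  S_so <- matrix(0.1, 2 * n, 2 * n)
  expect_equal(expectation_P2k(3, S_so, dA, dA), 0)
})

test_that("frozen-core correction obeys its algebraic identities", {
  expect_equal(frozen_core_correction(1.5, 2.0, 2.0), 1.5)
  expect_equal(frozen_core_correction(frozen_core_correction(1, 3, 2), 2, 3), 1)
})

test_that("the frozen-core correction recovers the all-electron exchange on a small model", {
  # compact all-s basis so the four-electron monomers are solvable by
  # determinant FCI: the corrected frozen-core single-exchange term must
  # land within 2% of the all-electron value (the raw frozen-core value
  # is off by ~25%)
  bas <- structure(list(name = "toy-be", elements = list(
    Be = list(list(l = 0L, exps = c(1293.4, 193.96, 41.938, 11.751, 3.6063, 1.1424),
                   coefs = c(.002, .015, .072, .237, .469, .356)),
              list(l = 0L, exps = 0.29, coefs = 1),
              list(l = 0L, exps = 0.10, coefs = 1)))), class = "basis_set")
  geom <- make_fixture("be_be", R = 4.6)
  sys <- build_dimer_system(geom, bas)
  hfA <- rhf(sys, "A"); hfB <- rhf(sys, "B")
  sol_ae <- function(mono, Chf) {
    h <- t(Chf) %*% sapt1dm:::monomer_hcore(sys, mono) %*% Chf
    g <- sapt1dm:::mo_eri(sys, Chf, Chf, Chf, Chf)
    fs <- fci_small(h, g, 2, 2, nroots = 1)
    ci_rdms(fs$dets, fs$vectors[, 1], ncol(Chf), kmax = 3)
  }
  aA <- sol_ae("A", hfA$C); aB <- sol_ae("B", hfB$C)
  tn <- interaction_tensors(sys, list(C = hfA$C, N = 4), list(C = hfB$C, N = 4))
  Sso <- sapt1dm:::so_overlap(tn$S)
  S2_ae <- expectation_VP2k(1, tn, aA, aB) -
    electrostatic_energy(tn, sapt1dm:::dms_spatial1(aA),
                         sapt1dm:::dms_spatial1(aB)) *
    expectation_P2k(1, Sso, aA, aB)
  ref <- frozen_core_reference(sys, frozen = 1L)
  expect_lt(abs(ref$corrected[["E_exch_S2"]] / S2_ae - 1), 0.02)
  expect_gt(abs(ref$fci_fc$E_exch_S2 / S2_ae - 1), 0.10)  # correction is doing real work
})

test_that("triple exchange on a three-electron-per-monomer toy matches the oracle", {
  bas <- structure(list(name = "li-toy", elements = list(
    Li = list(list(l = 0L, exps = c(16.1, 2.4, 0.6), coefs = c(.1, .4, .6)),
              list(l = 0L, exps = 0.12, coefs = 1),
              list(l = 0L, exps = 0.05, coefs = 1)))), class = "basis_set")
  geo <- dimer_geometry(c("Li", "Li"), rbind(c(0, 0, 0), c(0, 0, 6.0)),
                        c("A", "B"))
  sys <- build_dimer_system(geo, bas)
  own <- function(idx) {   # own-atom 3-orbital model space, orthonormalized
    P <- matrix(0, sys$nao, 3); P[cbind(idx, 1:3)] <- 1
    M <- t(P) %*% sys$S %*% P
    e <- eigen(M, symmetric = TRUE)
    P %*% e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  }
  CA <- own(1:3); CB <- own(4:6)
  sol <- function(mono, C) {
    h <- t(C) %*% sapt1dm:::monomer_hcore(sys, mono) %*% C
    g <- sapt1dm:::mo_eri(sys, C, C, C, C)
    fci_small(h, g, 2, 1, nroots = 1)
  }
  fsA <- sol("A", CA); fsB <- sol("B", CB)
  dA <- ci_rdms(fsA$dets, fsA$vectors[, 1], 3L, kmax = 3)
  dB <- ci_rdms(fsB$dets, fsB$vectors[, 1], 3L, kmax = 3)
  tn <- interaction_tensors(sys, list(C = CA, N = 3), list(C = CB, N = 3),
                            projected = TRUE)
  Sso <- sapt1dm:::so_overlap(tn$S)
  st <- product_state(fsA$dets, fsA$vectors[, 1], fsB$dets, fsB$vectors[, 1],
                      3L, 3L)
  bx <- brute_expectations(st, tn, k_max = 3)
  expect_lt(abs(expectation_P2k(3, Sso, dA, dB) - bx$P[3]), 1e-12)
  # the order-S^6 assembly from the generated compositions, with the
  # dense <P_6> and the oracle's <V P_6>, equals the all-oracle assembly
  V <- electrostatic_energy(tn, sapt1dm:::dms_spatial1(dA),
                            sapt1dm:::dms_spatial1(dB))
  E6 <- exchange_order_general(3, c(V, bx$VP),
                               c(bx$P[1], bx$P[2],
                                 expectation_P2k(3, Sso, dA, dB)))
  expect_equal(E6, exchange_order_general(3, c(bx$V, bx$VP), bx$P),
               tolerance = 1e-10)
})
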