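test_that("modified potential differs from the bare block by the stated closed form", {
  fx <- fx_h2h2_min()
  tn <- interaction_tensors(fx$sys, list(C = fx$hfA$C, N = 2),
                            list(C = fx$hfB$C, N = 2), keep_raw = TRUE)
  nA <- tn$nA; nB <- tn$nB
  dA <- diag(nA); dB <- diag(nB)
  resid <- tn$vtG - tn$vG -
    outer(dA, tn$vA_BB) / 2 - outer(tn$vB_AA, dB) / 2 -
    outer(dA, dB) * tn$V_AB / 4
  expect_lt(max(abs(resid)), 1e-14)
  residC <- tn$vtC - tn$vC -
    outer(tn$S, tn$vA_BA) / 2 - outer(tn$vB_AB, t(tn$S)) / 2 -
    outer(tn$S, t(tn$S)) * tn$V_AB / 4
  expect_lt(max(abs(residC)), 1e-14)
})

test_that("generalized blocks from direct integrals equal the overlap-projected build on complete supports", {
  fx <- fx_h2h2_min()
  orbA <- list(C = fx$hfA$C, N = 2); orbB <- list(C = fx$hfB$C, N = 2)
  tn <- interaction_tensors(fx$sys, orbA, orbB)
  tp <- interaction_tensors(fx$sys, orbA, orbB, projected = TRUE)
  expect_equal(tn$vtF, tp$vtF, tolerance = 1e-12)
  expect_equal(tn$vtD, tp$vtD, tolerance = 1e-12)
  expect_equal(tn$vtC, tp$vtC, tolerance = 1e-12)
})

test_that("intermolecular overlap vanishes at large separation", {
  geo <- dimer_geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1000)),
                        c("A", "B"))
  sys <- build_dimer_system(geo, "sto-3g")
  CA <- matrix(c(1, 0), 2, 1); CB <- matrix(c(0, 1), 2, 1)
  tn <- interaction_tensors(sys, list(C = CA, N = 1), list(C = CB, N = 1),
                            blocks = "G")
  expect_lt(max(abs(tn$S)), 1e-12)
})
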