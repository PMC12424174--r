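test_that("pair-basis singlet FCI agrees with determinant FCI", {
  fx <- fx_h2h2_min()
  f2 <- fci2(fx$sys, "A", C = fx$hfA$C, nroots = 2)
  h <- t(fx$hfA$C) %*% sapt1dm:::monomer_hcore(fx$sys, "A") %*% fx$hfA$C
  g <- sapt1dm:::mo_eri(fx$sys, fx$hfA$C, fx$hfA$C, fx$hfA$C, fx$hfA$C)
  fs <- fci_small(h, g, 1, 1, nroots = 4)
  singlets <- fs$energies + fx$sys$E_nn_A
  expect_equal(f2$energies[1], singlets[1], tolerance = 1e-9)
})

test_that("CAS(2,2) equals FCI when the active space is the full space", {
  geo <- dimer_geometry(c("H", "H", "H"),
                        rbind(c(-0.7, 0, 0), c(0.7, 0, 0), c(0, 0, 400)),
                        c("A", "A", "B"))
  sys <- build_dimer_system(geo, "sto-3g")
  f <- fci2(sys, "A")
  cas <- cas2_scf(sys, "A", ncas = 2)
  expect_equal(cas$energy, f$energies[1], tolerance = 1e-9)
})

test_that("CAS energies are variational between GVB and FCI", {
  geo <- dimer_geometry(c("H", "H", "H"),
                        rbind(c(-0.7, 0, 0), c(0.7, 0, 0), c(0, 0, 400)),
                        c("A", "A", "B"))
  sys <- build_dimer_system(geo, "aug-cc-pvdz")
  f <- fci2(sys, "A")
  c2 <- cas2_scf(sys, "A", ncas = 2)
  c4 <- cas2_scf(sys, "A", ncas = 4, C0 = c2$C)
  expect_lt(f$energies[1], c4$energy)
  expect_lt(c4$energy, c2$energy)
  expect_lt(c2$energy, rhf(sys, "A")$E)
})

test_that("mirror-odd root selection targets the open-shell singlet", {
  geo <- dimer_geometry(c("H", "H", "H"),
                        rbind(c(-1.22, 0, 0), c(1.22, 0, 0), c(0, 0, 400)),
                        c("A", "A", "B"))
  sys <- build_dimer_system(geo, "aug-cc-pvdz")
  U <- reflection_operator(sys, "x")
  f <- fci2(sys, "A", nroots = 6, symop = U)
  iu <- which(f$characters < -0.5)[1]
  expect_false(is.na(iu))
  cas <- cas2_scf(sys, "A", ncas = 2, symop = U, sym_char = -1)
  expect_lt(cas$character, -0.99)
  # a two-orbital open-shell singlet geminal has coefficients 1/sqrt(2)
  expect_equal(abs(cas$coef), rep(1 / sqrt(2), 2), tolerance = 1e-6)
  expect_gte(cas$energy, f$energies[iu] - 1e-10)
})
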