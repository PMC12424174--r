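# Factorized geminal evaluation against the dense DM path.

test_that("fast path equals the dense path on every structure type", {
  fx <- fx_h2h2_min()
  sys <- fx$sys; n <- sys$nao
  orb2 <- function(C, N) list(C = C, N = N)
  fA <- fci2(sys, "A", C = fx$hfA$C); fB <- fci2(sys, "B", C = fx$hfB$C)
  g2 <- random_gem(2, 7); g3 <- random_gem(2, 8)
  cases <- list(
    hf = list(tn = interaction_tensors(sys, orb2(fx$hfA$C, 2), orb2(fx$hfB$C, 2)),
              gsA = gem_struct(list(list(orbs = 1L, g = matrix(1, 1, 1))), n),
              gsB = gem_struct(list(list(orbs = 1L, g = matrix(1, 1, 1))), n),
              dA = hf_rdms(1, n), dB = hf_rdms(1, n)),
    fci = list(tn = interaction_tensors(sys, orb2(fx$hfA$C, 2), orb2(fx$hfB$C, 2)),
               gsA = gem_struct(list(list(orbs = seq_len(n), g = fA$gmats[[1]])), n),
               gsB = gem_struct(list(list(orbs = seq_len(n), g = fB$gmats[[1]])), n),
               dA = gem2e_rdms(fA$gmats[[1]]), dB = gem2e_rdms(fB$gmats[[1]])),
    core_gem = list(tn = interaction_tensors(sys, orb2(fx$hfA$C, 4), orb2(fx$hfB$C, 2)),
                    gsA = gem_struct(list(list(orbs = 1L, g = matrix(1, 1, 1)),
                                          list(orbs = c(2L, 3L), g = g2)), n),
                    gsB = gem_struct(list(list(orbs = seq_len(n), g = fB$gmats[[1]])), n),
                    dA = dms_combine(hf_rdms(1, n), gem2e_rdms(g2, n = n, orbs = c(2, 3))),
                    dB = gem2e_rdms(fB$gmats[[1]])),
    two_gem = list(tn = interaction_tensors(sys, orb2(fx$hfA$C, 4), orb2(fx$hfB$C, 4)),
                   gsA = gem_struct(list(list(orbs = c(1L, 2L), g = g2),
                                         list(orbs = c(3L, 4L), g = g3)), n),
                   gsB = gem_struct(list(list(orbs = 1L, g = matrix(1, 1, 1)),
                                         list(orbs = c(2L, 4L), g = g3)), n),
                   dA = dms_combine(gem2e_rdms(g2, n = n, orbs = c(1, 2)),
                                    gem2e_rdms(g3, n = n, orbs = c(3, 4))),
                   dB = dms_combine(hf_rdms(1, n),
                                    gem2e_rdms(g3, n = n, orbs = c(2, 4)))))
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    fp <- exchange_fastpath(cs$tn, cs$gsA, cs$gsB)
    de <- dense_expectations(cs$tn, cs$dA, cs$dB)
    expect_equal(fp$V, de$V, tolerance = 1e-10, label = paste(nm, "V"))
    expect_equal(fp$P, de$P, tolerance = 1e-9, label = paste(nm, "P"))
    expect_equal(fp$VP, de$VP, tolerance = 1e-9, label = paste(nm, "VP"))
  }
})

test_that("the GVB-PP limit with unit coefficients reproduces Hartree-Fock", {
  fx <- fx_h2h2_min()
  sys <- fx$sys; n <- sys$nao
  tn <- interaction_tensors(sys, list(C = fx$hfA$C, N = 2),
                            list(C = fx$hfB$C, N = 2))
  gs_hf <- gem_struct(list(list(orbs = 1L, g = matrix(1, 1, 1))), n)
  gs_gvb <- gem_struct(list(list(orbs = c(1L, 2L),
                                 g = diag(c(1, 0)))), n)  # c = (1, 0)
  f1 <- exchange_fastpath(tn, gs_hf, gs_hf)
  f2 <- exchange_fastpath(tn, gs_gvb, gs_gvb)
  expect_equal(f1$P, f2$P, tolerance = 1e-12)
  expect_equal(f1$VP, f2$VP, tolerance = 1e-12)
})

test_that("cost model scales no faster than the sixth power of the orbital count", {
  gs2 <- gem_struct(list(list(orbs = 1:2, g = diag(c(1, 0)))), 2L)
  gs4 <- gem_struct(list(list(orbs = 1:4, g = diag(c(1, 0, 0, 0)))), 4L)
  c2 <- cost_model(gs2, gs2)
  c4 <- cost_model(gs4, gs4)
  expect_lte(c4$flops / c2$flops, 2^6)
  expect_lte(c4$flops / c2$flops, 70)
  # the Hartree-Fock limit collapses to the occupied-orbital polynomial:
  # one doubly occupied orbital gives the minimal term count
  hf1 <- gem_struct(list(list(orbs = 1L, g = matrix(1, 1, 1))), 1L)
  expect_lte(cost_model(hf1, hf1)$nterms, c2$nterms)
})

test_that("structural invariants of gem_struct are enforced", {
  expect_error(gem_struct(list(list(orbs = 1:2, g = diag(2)),
                               list(orbs = 2:3, g = diag(2))), 3L), "overlap")
})
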