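# Shared small fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# minimal-basis H2...H2 (T-ish): 4 orbitals, full supports, oracle-friendly
fx_h2h2_min <- function() fx_get("h2h2", function() {
  geo <- dimer_geometry(c("H", "H", "H", "H"),
                        rbind(c(-0.7, 0, 0), c(0.7, 0, 0),
                              c(0, 0, 5.0), c(0, 0, 6.4)),
                        c("A", "A", "B", "B"))
  sys <- build_dimer_system(geo, "sto-3g")
  hfA <- rhf(sys, "A"); hfB <- rhf(sys, "B")
  list(geo = geo, sys = sys, hfA = hfA, hfB = hfB)
})

# tiny all-s two-center toy with a 4-electron monomer (nonzero 3-RDM)
fx_beto <- function() fx_get("beto", function() {
  bas <- structure(list(name = "toy", elements = list(
    Be = list(list(l = 0L, exps = c(30, 5.5, 1.2), coefs = c(.08, .35, .7)),
              list(l = 0L, exps = 0.25, coefs = 1),
              list(l = 0L, exps = 0.08, coefs = 1)),
    He = list(list(l = 0L, exps = c(6.36, 1.159), coefs = c(.2, .8)),
              list(l = 0L, exps = 0.31, coefs = 1)))), class = "basis_set")
  geo <- dimer_geometry(c("Be", "He"), rbind(c(0, 0, 0), c(0, 0, 4.5)),
                        c("A", "B"))
  sys <- build_dimer_system(geo, bas)
  hfA <- rhf(sys, "A"); hfB <- rhf(sys, "B")
  # 4-electron FCI on A, 2-electron FCI on B
  hA <- t(hfA$C) %*% sapt1dm:::monomer_hcore(sys, "A") %*% hfA$C
  gA <- sapt1dm:::mo_eri(sys, hfA$C, hfA$C, hfA$C, hfA$C)
  fsA <- fci_small(hA, gA, 2, 2, nroots = 1)
  fB <- fci2(sys, "B", C = hfB$C)
  list(geo = geo, sys = sys, hfA = hfA, hfB = hfB, fsA = fsA, fB = fB)
})

# geminal matrix -> determinant CI over 2n spinorbitals
gem_to_detci <- function(g) {
  n <- nrow(g); dets <- list(); coef <- numeric(0)
  for (p in 1:n) for (q in 1:n) if (abs(g[p, q]) > 1e-15) {
    dets[[length(dets) + 1L]] <- c(p, q + n)
    coef <- c(coef, g[p, q])
  }
  list(dets = dets, coef = coef)
}

random_gem <- function(n, seed) {
  set.seed(seed)
  g <- matrix(rnorm(n * n), n, n); g <- g + t(g)
  g / sqrt(sum(g^2))
}

# all five expectation values through the dense DM path
dense_expectations <- function(tn, dA, dB) {
  S_so <- sapt1dm:::so_overlap(tn$S)
  list(V = electrostatic_energy(tn, sapt1dm:::dms_spatial1(dA),
                                sapt1dm:::dms_spatial1(dB)),
       P = c(expectation_P2k(1, S_so, dA, dB), expectation_P2k(2, S_so, dA, dB)),
       VP = c(expectation_VP2k(1, tn, dA, dB), expectation_VP2k(2, tn, dA, dB)))
}
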