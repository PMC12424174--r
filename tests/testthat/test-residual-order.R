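test_that("the truncation residual decays as a sixth-order overlap quantity", {
  # along a radial scan the difference between the full symmetrized ratio
  # and E_elst + S^2 + S^4 must fall off at least 1.4x as fast (log slope)
  # as the S^4 increment itself
  Rs <- c(4.5, 5.5, 6.5, 7.5)
  res <- s4 <- numeric(length(Rs))
  for (i in seq_along(Rs)) {
    geo <- dimer_geometry(c("H", "H", "H", "H"),
                          rbind(c(-0.7, 0, 0), c(0.7, 0, 0),
                                c(0, 0, Rs[i] - 0.7), c(0, 0, Rs[i] + 0.7)),
                          c("A", "A", "B", "B"))
    sys <- build_dimer_system(geo, "sto-3g")
    hfA <- rhf(sys, "A"); hfB <- rhf(sys, "B")
    fA <- fci2(sys, "A", C = hfA$C); fB <- fci2(sys, "B", C = hfB$C)
    n <- sys$nao
    ciA <- gem_to_detci(fA$gmats[[1]]); ciB <- gem_to_detci(fB$gmats[[1]])
    tn <- interaction_tensors(sys, list(C = hfA$C, N = 2), list(C = hfB$C, N = 2))
    st <- product_state(ciA$dets, ciA$coef, ciB$dets, ciB$coef, n, n)
    bx <- brute_expectations(st, tn, k_max = 2)
    truncated <- bx$V + bx$E_exch_S2 + bx$E_exch_S4_incr
    res[i] <- abs(bx$E1_full - truncated)
    s4[i] <- abs(bx$E_exch_S4_incr)
  }
  slope <- function(y) stats::coef(stats::lm(log(y) ~ Rs))[2]
  expect_lte(slope(res), 1.4 * slope(s4))  # slopes are negative: steeper decay
})
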