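# RDM builders against the literal second-quantized string evaluation.

test_that("two-electron geminal RDMs equal the CI-string evaluation", {
  g <- random_gem(3, 1)
  dg <- gem2e_rdms(g, kmax = 3)
  ci <- gem_to_detci(g)
  dc <- ci_rdms(ci$dets, ci$coef, 3, kmax = 3)
  expect_equal(dg$G1, dc$G1, tolerance = 1e-12)
  expect_equal(dg$G2, dc$G2, tolerance = 1e-12)
  expect_equal(max(abs(dg$G3 - dc$G3)), 0, tolerance = 1e-12)
})

test_that("closed-shell determinant RDMs are Wick factorizations", {
  dh <- hf_rdms(c(1, 2), 3, kmax = 3)
  det <- list(c(1, 2, 4, 5))
  dc <- ci_rdms(det, 1, 3, kmax = 3)
  expect_equal(dh$G2, dc$G2, tolerance = 1e-13)
  expect_equal(dh$G3, dc$G3, tolerance = 1e-13)
  expect_equal(unname(dms_trace_errors(dh)), rep(0, 4), tolerance = 1e-10)
})

test_that("independent-subsystem combination reproduces the product-state RDMs", {
  g2 <- random_gem(2, 7)
  dcomb <- dms_combine(hf_rdms(1, 3), gem2e_rdms(g2, n = 3, orbs = c(2, 3)))
  # explicit CI for the core (x) geminal product
  dets <- list(); coef <- numeric(0)
  for (p in 2:3) for (q in 2:3) {
    occ <- integer(0); sgn <- 1
    for (o in rev(c(1, 4, p, q + 3))) {
      cr <- sapt1dm:::det_create(occ, o); occ <- cr$occ; sgn <- sgn * cr$sign
    }
    k <- sapt1dm:::det_key(occ)
    i <- if (length(dets)) which(vapply(dets, function(d) sapt1dm:::det_key(d) == k, TRUE)) else integer(0)
    if (length(i)) coef[i] <- coef[i] + sgn * g2[p - 1, q - 1]
    else { dets[[length(dets) + 1L]] <- occ; coef <- c(coef, sgn * g2[p - 1, q - 1]) }
  }
  dcc <- ci_rdms(dets, coef, 3, kmax = 3)
  expect_equal(dcomb$G2, dcc$G2, tolerance = 1e-12)
  expect_equal(dcomb$G3, dcc$G3, tolerance = 1e-12)
})

test_that("trace identities hold for every builder", {
  expect_equal(unname(dms_trace_errors(gem2e_rdms(random_gem(3, 2), kmax = 3))),
               rep(0, 4), tolerance = 1e-10)
  gm <- geminal_model(list(list(orbs = 1:2, coef = c(0.9, -sqrt(1 - 0.81))),
                           list(orbs = 3:4, coef = c(0.8, sqrt(1 - 0.64)))))
  da <- apsg_rdms(gm, n = 4, kmax = 3)
  tr <- dms_trace_errors(da)
  expect_equal(unname(tr), rep(0, 4), tolerance = 1e-10)  # G3 trace = 4*3*2
  # rank beyond electron count vanishes
  d2 <- gem2e_rdms(random_gem(2, 3), kmax = 3)
  expect_equal(max(abs(d2$G3)), 0)
})

test_that("frozen-core embedding adds determinant core blocks", {
  g2 <- random_gem(2, 11)
  dact <- gem2e_rdms(g2, n = 3, orbs = c(2, 3), kmax = 3)
  dfull <- frozen_core_embed_rdms(dact, core_orbs = 1L)
  expect_equal(dfull$N, 4)
  expect_equal(sum(diag(dfull$G1)), 4, tolerance = 1e-12)
  expect_equal(unname(dms_trace_errors(dfull)), rep(0, 4), tolerance = 1e-10)
  # empty core is the identity
  expect_identical(frozen_core_embed_rdms(dact, integer(0)), dact)
  # overlapping supports rejected
  expect_error(frozen_core_embed_rdms(dact, 2L), "overlap")
})

test_that("bit-level CI string kernel agrees with the plain-R reference", {
  g <- random_gem(2, 5)
  ci <- gem_to_detci(g)
  a <- ci_rdms(ci$dets, ci$coef, 2, kmax = 2)
  b <- sapt1dm:::.ci_rdms_r(ci$dets, ci$coef, 2, kmax = 2)
  expect_equal(a$G1, b$G1, tolerance = 1e-14)
  expect_equal(a$G2, b$G2, tolerance = 1e-14)
})
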