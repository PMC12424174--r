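test_that("XYZ reader handles units and monomer splits", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("3", "unit=bohr monomer_split=2", "H -0.7 0 0", "H 0.7 0 0",
               "He 0 0 4.5"), f)
  g <- read_xyz_dimer(f)
  expect_equal(g$monomer, c("A", "A", "B"))
  expect_equal(g$coords[3, 3], 4.5)
  writeLines(c("2", "", "H 0 0 0", "H 0 0 1.0"), f)
  g2 <- read_xyz_dimer(f)
  expect_equal(g2$coords[2, 3], 1.8897261254578281, tolerance = 1e-12)
})

test_that("geometry invariants are enforced", {
  expect_error(dimer_geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0)),
                              c("A", "B")), "coincide")
  expect_error(dimer_geometry(c("H", "Xx"), rbind(c(0, 0, 0), c(0, 0, 1)),
                              c("A", "B")), "unknown element")
  expect_error(dimer_geometry(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1)),
                              c("A", "A")), "at least one atom")
})

test_that("fixtures reproduce their defining distances", {
  g <- make_fixture("be_be")
  expect_equal(sqrt(sum((g$coords[1, ] - g$coords[2, ])^2)), 4.6)
  g2 <- make_fixture("he_h2_T_excited")
  expect_equal(sqrt(sum((g2$coords[1, ] - g2$coords[2, ])^2)), 2.44)
  g3 <- make_fixture("h2_h2_T", r_probe = 5.8)
  expect_equal(sqrt(sum((g3$coords[1, ] - g3$coords[2, ])^2)), 5.8)
  cenA <- colMeans(g3$coords[1:2, ]); cenB <- colMeans(g3$coords[3:4, ])
  expect_equal(sqrt(sum((cenA - cenB)^2)), 6.21)
})
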