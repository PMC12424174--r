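test_that("analysis utilities behave on synthetic tables", {
  x <- seq(1, 3, by = 0.25)
  expect_equal(analyze(x, sin(x), sin(x), what = "relative_error"),
               rep(0, length(x)))
  expect_equal(analyze(x, 1:9, 2 * (1:9), what = "recovery_fraction"),
               rep(50, 9))
  # zero crossing of a shifted sine recovered to high accuracy
  f <- function(x) sin(x - 2.2341)
  xr <- analyze(x, f(x), what = "zero_crossing")
  expect_equal(xr, 2.2341, tolerance = 1e-4)
  expect_error(analyze(x, exp(x), what = "zero_crossing"), "sign change")
})

test_that("scans are deterministic and honor the S2-only order", {
  methods <- list(hf = list(A = method_spec("hf"), B = method_spec("hf")))
  t1 <- run_scan("he_h2_T_ground", c(4.0, 5.0), "sto-3g", methods, order = "s2")
  t2 <- run_scan("he_h2_T_ground", c(4.0, 5.0), "sto-3g", methods, order = "s2")
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 2)
  expect_true(all(is.na(t1$E_exch_S4_incr)))
  expect_equal(t1$E_exch_S2, t1$VP2 - t1$E_elst * t1$P2, tolerance = 1e-14)
})

test_that("monomer swap leaves the decomposition unchanged", {
  geo <- make_fixture("he_h2_T_ground", R = 4.5)
  sys <- build_dimer_system(geo, "sto-3g")
  a <- solve_monomer(sys, "A", method_spec("fci"))
  b <- solve_monomer(sys, "B", method_spec("fci"))
  d1 <- sapt_first_order(sys, a, b)
  sys2 <- build_dimer_system(swap_monomers(geo), "sto-3g")
  a2 <- solve_monomer(sys2, "A", method_spec("fci"))
  b2 <- solve_monomer(sys2, "B", method_spec("fci"))
  d2 <- sapt_first_order(sys2, a2, b2)
  expect_equal(d1$E_elst, d2$E_elst, tolerance = 1e-10)
  expect_equal(d1$E_exch_S2, d2$E_exch_S2, tolerance = 1e-10)
  expect_equal(d1$E_exch_S4_incr, d2$E_exch_S4_incr, tolerance = 1e-10)
})

test_that("decompositions serialize to JSON and CSV", {
  d <- assemble_first_order(-1e-4, -1e-3, 2e-4, 1e-7, -8e-8)
  fj <- tempfile(fileext = ".json"); fc <- tempfile(fileext = ".csv")
  write_decomposition(d, fj, meta = list(system = "test"))
  write_decomposition(d, fc)
  j <- jsonlite::read_json(fj)
  expect_equal(j$E_exch_S2, d$E_exch_S2, tolerance = 1e-12)
  cc <- read.csv(fc)
  expect_equal(cc$hartree[cc$term == "E_elst"], -1e-4)
  expect_equal(cc$microhartree[cc$term == "E_elst"], -100)
})
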