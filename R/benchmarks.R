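# Reproduction drivers for the model-system benchmarks: each returns both
# the raw decompositions and the derived comparison statistics.

#' H2...H2 plateau benchmark: geminal-based exchange versus full CI
#'
#' T-shaped H2...H2 (centers 6.21 bohr apart, spectator bond 1.44) with the
#' probe bond stretched to `r_probe`; each monomer solved with FCI, GVB-PP
#' (one two-orbital geminal) and a four-orbital single-geminal CAS(2,4), and
#' the single- and double-exchange terms compared.
#'
#' @param basis Basis set name.
#' @param r_probe Probe H2 bond length (bohr).
#' @return List with per-method decompositions and signed percent errors
#'   of the geminal methods against FCI for the S^2 and proportional-S^4
#'   exchange terms.
#' @export
benchmark_h2h2_plateau <- function(basis = "aug-cc-pvtz", r_probe = 5.8) {
  geom <- make_fixture("h2_h2_T", r_probe = r_probe)
  sys <- build_dimer_system(geom, basis)
  stF <- list(A = solve_monomer(sys, "A", method_spec("fci")),
              B = solve_monomer(sys, "B", method_spec("fci")))
  decF <- sapt_first_order(sys, stF$A, stF$B)
  run <- function(spec) {
    a <- solve_monomer(sys, "A", spec, C0 = stF$A$C_full)
    b <- solve_monomer(sys, "B", spec, C0 = stF$B$C_full)
    sapt_first_order(sys, a, b)
  }
  decG <- run(method_spec("gvb"))
  dec4 <- run(method_spec("cas", ncas = 4))
  rel <- function(x, r) 100 * (x - r) / abs(r)
  list(fci = decF, gvb = decG, cas4 = dec4, nao = sys$nao,
       err_gvb_s2 = rel(decG$E_exch_S2, decF$E_exch_S2),
       err_gvb_s4 = rel(decG$E_exch_S4_incr, decF$E_exch_S4_incr),
       err_cas4_s2 = abs(rel(dec4$E_exch_S2, decF$E_exch_S2)),
       err_cas4_s4 = abs(rel(dec4$E_exch_S4_incr, decF$E_exch_S4_incr)))
}

#' He...H2 excited-state scan benchmark
#'
#' T-shaped He...H2 with the hydrogen molecule in its first excited
#' mirror-odd singlet (bond 2.44 bohr), scanned over He-to-midpoint
#' distances; monomers described by FCI, GVB-PP and CAS(2,4).  Locates the
#' sign changes of the single-exchange term and the largest percent
#' deviations of the double-exchange term from FCI.
#'
#' @param basis Basis set name.
#' @param grid He-to-bond-midpoint distances (bohr).
#' @param densify Extra points placed inside a sign-change bracket before
#'   interpolating the crossing.
#' @return List with the scan table, the FCI and GVB crossing distances,
#'   and the maximum percent deviations of GVB and CAS(2,4) from FCI for
#'   the proportional-S^4 term.
#' @export
benchmark_heh2_excited <- function(basis = "aug-cc-pvtz",
                                   grid = seq(4.0, 8.0, by = 0.2),
                                   densify = 2L) {
  methods <- list(
    fci = list(A = method_spec("fci", sym_plane = "x", sym_char = -1),
               B = method_spec("fci")),
    gvb = list(A = method_spec("gvb", sym_plane = "x", sym_char = -1),
               B = method_spec("gvb")),
    cas4 = list(A = method_spec("cas", ncas = 4, sym_plane = "x", sym_char = -1),
                B = method_spec("cas", ncas = 4)))
  tab <- run_scan("he_h2_T_excited", grid, basis, methods)
  crossing <- function(meth) {
    sub <- tab[tab$method == meth, ]
    x <- sub$coord; y <- sub$E_exch_S2
    sgn <- sign(y)
    br <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (!length(br)) stop("no sign change for ", meth)
    i <- br[1]
    if (densify > 0) {
      extra <- seq(x[i], x[i + 1], length.out = densify + 2L)
      extra <- extra[-c(1, length(extra))]
      t2 <- run_scan("he_h2_T_excited", extra, basis, methods[meth])
      x <- c(x, t2$coord); y <- c(y, t2$E_exch_S2)
      o <- order(x); x <- x[o]; y <- y[o]
    }
    analyze(x, y, what = "zero_crossing")
  }
  sub <- function(m) tab[tab$method == m, ]
  dev <- function(m)
    analyze(sub(m)$coord, sub(m)$E_exch_S4_incr, sub("fci")$E_exch_S4_incr,
            what = "max_abs_relative_deviation")
  list(table = tab,
       crossing_fci = crossing("fci"), crossing_gvb = crossing("gvb"),
       maxdev_gvb_s4 = dev("gvb"), maxdev_cas4_s4 = dev("cas4"))
}

#' Be...Be frozen-core benchmark
#'
#' Collinear Be...Be at `R`; the reference is frozen-core FCI (1s frozen,
#' two valence electrons correlated in the full remaining space) corrected
#' by the all-electron-minus-frozen-core Hartree-Fock difference, and the
#' approximation is CAS(2,4)SCF monomers (2s plus 2p active above the
#' optimized 1s core, full-support RDMs).
#'
#' @param basis Basis set name.
#' @param R Internuclear distance (bohr).
#' @return List with the reference pieces, the CAS decomposition, and the
#'   percent of the corrected reference recovered at the S^2 and
#'   proportional-S^4 levels.
#' @export
benchmark_bebe <- function(basis = "aug-cc-pvdz", R = 4.6) {
  geom <- make_fixture("be_be", R = R)
  sys <- build_dimer_system(geom, basis)
  ref <- frozen_core_reference(sys, frozen = 1L)
  sc <- method_spec("cas", ncas = 4, core = 1)
  stA <- solve_monomer(sys, "A", sc)
  stB <- solve_monomer(sys, "B", sc)
  dec <- sapt_first_order(sys, stA, stB)
  list(reference = ref, cas = dec, nao = sys$nao,
       recov_s2 = 100 * dec$E_exch_S2 / ref$corrected[["E_exch_S2"]],
       recov_s4 = 100 * dec$E_exch_S4_incr / ref$corrected[["E_exch_S4_incr"]])
}
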