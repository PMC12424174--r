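# Model-system fixtures, scan driver and analysis utilities.

#' Model dimer geometries
#'
#' Builds the package's benchmark geometries (coordinates in bohr):
#' \describe{
#'   \item{h2_h2_T}{T-shaped H2...H2: monomer A (the probe) lies along x
#'     with bond length `r_probe`, centered at the origin; monomer B (the
#'     spectator, bond 1.44) lies along the intermolecular z axis with its
#'     center `R` = 6.21 away.}
#'   \item{he_h2_T_ground / he_h2_T_excited}{T-shaped He...H2: H2 along x
#'     (bond 1.44 for the ground state, 2.44 for the excited-state
#'     fixture) centered at the origin as monomer A; He on the z axis at
#'     distance `R` from the bond midpoint as monomer B.}
#'   \item{be_be}{Collinear Be...Be at distance `R` (default 4.6).}
#' }
#'
#' @param name Fixture name.
#' @param r_probe Probe H2 bond length (h2_h2_T).
#' @param R Intermolecular distance (center-to-center / He-to-midpoint /
#'   Be-Be).
#' @return A [dimer_geometry()].
#' @export
make_fixture <- function(name = c("h2_h2_T", "he_h2_T_ground",
                                  "he_h2_T_excited", "be_be"),
                         r_probe = 1.44, R = NULL) {
  name <- match.arg(name)
  switch(name,
    h2_h2_T = {
      if (is.null(R)) R <- 6.21
      dimer_geometry(c("H", "H", "H", "H"),
                     rbind(c(-r_probe / 2, 0, 0), c(r_probe / 2, 0, 0),
                           c(0, 0, R - 0.72), c(0, 0, R + 0.72)),
                     c("A", "A", "B", "B"))
    },
    he_h2_T_ground = {
      if (is.null(R)) R <- 6.4
      dimer_geometry(c("H", "H", "He"),
                     rbind(c(-0.72, 0, 0), c(0.72, 0, 0), c(0, 0, R)),
                     c("A", "A", "B"))
    },
    he_h2_T_excited = {
      if (is.null(R)) R <- 4.43
      dimer_geometry(c("H", "H", "He"),
                     rbind(c(-1.22, 0, 0), c(1.22, 0, 0), c(0, 0, R)),
                     c("A", "A", "B"))
    },
    be_be = {
      if (is.null(R)) R <- 4.6
      dimer_geometry(c("Be", "Be"), rbind(c(0, 0, 0), c(0, 0, R)),
                     c("A", "B"))
    })
}

#' Scan the first-order decomposition over a distance grid
#'
#' Runs one or several monomer-method combinations over a grid of
#' geometries.  Within a point, full-CI natural orbitals seed the CAS
#' solvers of the same monomer and symmetry; across points, each solver is
#' warm-started from the previous geometry.  The run is deterministic:
#' identical inputs give identical tables.
#'
#' @param fixture Fixture name (see [make_fixture()]).
#' @param grid Strictly increasing values of the scanned coordinate
#'   (the fixture's `R`, or `r_probe` when `scan_coord = "r_probe"`).
#' @param basis Basis set name.
#' @param methods Named list of method pairs `list(A = method_spec, B =
#'   method_spec)`.
#' @param order `"s2"` or `"s4"`.
#' @param scan_coord Which fixture parameter the grid refers to.
#' @param verbose Print one line per point and method.
#' @return Data frame with one row per (point, method), energies in
#'   hartree.
#' @export
run_scan <- function(fixture, grid, basis, methods, order = "s4",
                     scan_coord = c("R", "r_probe"), verbose = FALSE) {
  scan_coord <- match.arg(scan_coord)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (inherits(methods[[1]], "method_spec"))
    methods <- list(method = list(A = methods[[1]], B = methods[[2]]))
  rows <- list()
  warm <- list()   # (method|monomer) -> previous full orbital set
  for (x in grid) {
    point <- tryCatch({
      geom <- if (scan_coord == "R") make_fixture(fixture, R = x)
      else make_fixture(fixture, r_probe = x)
      sys <- build_dimer_system(geom, basis)
      states <- list()
      # FCI methods first: their natural orbitals seed CAS of the same root
      ord <- order(vapply(methods, function(m) m$A$kind != "fci", TRUE))
      for (mi in ord) {
        mname <- names(methods)[mi]
        m <- methods[[mi]]
        st <- list()
        for (side in c("A", "B")) {
          key <- paste(mname, side)
          C0 <- warm[[key]]
          if (is.null(C0) && m[[side]]$kind == "cas") {
            # look for an FCI solution with the same symmetry targeting
            for (oth in names(states)) {
              so <- states[[oth]][[side]]
              if (!is.null(so) && so$spec$kind == "fci" &&
                  identical(so$spec$sym_char, m[[side]]$sym_char) &&
                  ncol(so$C) == ncol(so$C_full))
                C0 <- so$C   # full-space natural orbitals
            }
          }
          s <- solve_monomer(sys, side, m[[side]], C0 = C0)
          warm[[key]] <- s$C_full
          st[[side]] <- s
        }
        states[[mname]] <- st
        dec <- sapt_first_order(sys, st$A, st$B, order = order)
        rows[[length(rows) + 1L]] <- data.frame(
          coord = x, method = mname, E_elst = dec$E_elst,
          E_exch_S2 = dec$E_exch_S2, E_exch_S4_incr = dec$E_exch_S4_incr,
          E_exch_S4 = dec$E_exch_S4,
          P2 = dec$P2, VP2 = dec$VP2, P4 = dec$P4, VP4 = dec$VP4,
          E_A = st$A$energy, E_B = st$B$energy)
        if (verbose)
          message(sprintf("  %s = %.3f %-8s S2 = %.6e, S4 incr = %.6e",
                          scan_coord, x, mname,
                          dec$E_exch_S2, dec$E_exch_S4_incr))
      }
      TRUE
    }, error = function(e) {
      warning(sprintf("scan point %g failed: %s", x, conditionMessage(e)))
      FALSE
    })
  }
  if (!length(rows)) stop("all scan points failed")
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Comparison statistics between two scans
#'
#' @param x Numeric vector: grid coordinate.
#' @param approx,ref Numeric vectors of the approximate and reference
#'   quantity on the same grid.
#' @param what One of `"relative_error"` (signed percent, pointwise),
#'   `"recovery_fraction"` (approx/ref in percent, pointwise),
#'   `"max_abs_relative_deviation"` (percent, scalar), or
#'   `"zero_crossing"` (coordinate where `ref` changes sign, by monotone
#'   cubic interpolation between the bracketing points; `approx` ignored).
#' @return Numeric vector or scalar, per `what`.
#' @export
analyze <- function(x, approx, ref = NULL,
                    what = c("relative_error", "recovery_fraction",
                             "max_abs_relative_deviation", "zero_crossing")) {
  what <- match.arg(what)
  if (what == "zero_crossing") {
    y <- approx
    sgn <- sign(y)
    br <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (!length(br)) stop("no sign change bracketed on the grid")
    i <- br[1]
    lo <- max(1, i - 2); hi <- min(length(x), i + 3)
    f <- stats::splinefun(x[lo:hi], y[lo:hi], method = "monoH.FC")
    return(stats::uniroot(f, c(x[i], x[i + 1]), tol = 1e-10)$root)
  }
  if (is.null(ref)) stop("ref required")
  switch(what,
    relative_error = 100 * (approx - ref) / abs(ref),
    recovery_fraction = 100 * approx / ref,
    max_abs_relative_deviation = max(abs(100 * (approx - ref) / abs(ref))))
}

#' Frozen-core-corrected reference decomposition for an atom pair
#'
#' Computes the exchange terms with frozen-core FCI monomers and corrects
#' them with the all-electron-minus-frozen-core Hartree-Fock difference.
#'
#' @param sys A dimer system whose monomers have 2 valence electrons above
#'   a frozen core (e.g. Be with a 1s core).
#' @param frozen Number of frozen core orbitals per monomer.
#' @param order `"s4"` or `"s2"`.
#' @return List with the three decompositions (`fci_fc`, `hf`, `hf_fc`)
#'   and `corrected` (named vector: E_exch_S2, E_exch_S4_incr).
#' @export
frozen_core_reference <- function(sys, frozen = 1L, order = "s4") {
  sfc <- method_spec("fci", frozen = frozen)
  shf <- method_spec("hf")
  shffc <- method_spec("hf", frozen = frozen)
  stA <- solve_monomer(sys, "A", sfc); stB <- solve_monomer(sys, "B", sfc)
  dec_fc <- sapt_first_order(sys, stA, stB, order = order)
  hA <- solve_monomer(sys, "A", shf); hB <- solve_monomer(sys, "B", shf)
  dec_hf <- sapt_first_order(sys, hA, hB, order = order)
  fA <- solve_monomer(sys, "A", shffc); fB <- solve_monomer(sys, "B", shffc)
  dec_hffc <- sapt_first_order(sys, fA, fB, order = order)
  corr <- c(
    E_exch_S2 = frozen_core_correction(dec_fc$E_exch_S2, dec_hf$E_exch_S2,
                                       dec_hffc$E_exch_S2),
    E_exch_S4_incr = frozen_core_correction(dec_fc$E_exch_S4_incr,
                                            dec_hf$E_exch_S4_incr,
                                            dec_hffc$E_exch_S4_incr))
  list(fci_fc = dec_fc, hf = dec_hf, hf_fc = dec_hffc, corrected = corr)
}

#' Serialize a decomposition to JSON or CSV
#'
#' @param dec A `first_order_decomposition`.
#' @param path Output file; format from the extension (.json or .csv).
#' @param meta Optional named list of provenance fields (geometry, basis,
#'   method labels) stored alongside the energies.
#' @return The path, invisibly.
#' @export
write_decomposition <- function(dec, path, meta = list()) {
  vals <- list(E_elst = dec$E_elst, E_exch_S2 = dec$E_exch_S2,
               E_exch_S4_incr = dec$E_exch_S4_incr, E_exch_S4 = dec$E_exch_S4,
               P2 = dec$P2, VP2 = dec$VP2, P4 = dec$P4, VP4 = dec$VP4)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(c(meta, lapply(vals, identity),
                           list(unit = "hartree")),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(term = names(vals),
                     hartree = unlist(vals),
                     microhartree = unlist(vals) * 1e6)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
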