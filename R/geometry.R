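# Dimer geometries: construction, validation, XYZ input.

.BOHR_PER_ANGSTROM <- 1.8897261254578281

#' Construct a dimer geometry
#'
#' @param element Character vector of element symbols.
#' @param coords Numeric matrix (n x 3) of coordinates.
#' @param monomer Character vector of "A"/"B" labels, one per atom.
#' @param unit `"bohr"` (default) or `"angstrom"`; coordinates are stored in
#'   bohr.
#' @return A `dimer_geometry` object.
#' @export
dimer_geometry <- function(element, coords, monomer, unit = "bohr") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(nrow(coords) == length(element), ncol(coords) == 3,
            length(monomer) == length(element))
  monomer <- toupper(monomer)
  if (!all(monomer %in% c("A", "B")))
    stop("monomer labels must be 'A' or 'B'")
  if (!any(monomer == "A") || !any(monomer == "B"))
    stop("each monomer needs at least one atom")
  if (unit == "angstrom") coords <- coords * .BOHR_PER_ANGSTROM
  else if (unit != "bohr") stop("unit must be 'bohr' or 'angstrom'")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  if (any(d < 1e-6)) stop("two atoms coincide")
  if (!all(element %in% names(.elements)))
    stop("unknown element(s): ", paste(setdiff(element, names(.elements)),
                                       collapse = ", "))
  structure(list(element = element, coords = coords, monomer = monomer,
                 charge = unname(.elements[element])),
            class = "dimer_geometry")
}

#' @export
print.dimer_geometry <- function(x, ...) {
  cat("dimer geometry (bohr):\n")
  for (i in seq_along(x$element))
    cat(sprintf("  %-2s %s %12.6f %12.6f %12.6f\n", x$element[i], x$monomer[i],
                x$coords[i, 1], x$coords[i, 2], x$coords[i, 3]))
  invisible(x)
}

#' Read a dimer geometry from an XYZ file
#'
#' Standard XYZ layout; the comment line may carry `unit=bohr|angstrom`
#' (default angstrom, the XYZ convention) and `monomer_split=k`, meaning the
#' first k atoms belong to monomer A.  Without `monomer_split` the atoms are
#' split at half the list.
#'
#' @param path File path.
#' @return A `dimer_geometry` object.
#' @export
read_xyz_dimer <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nat <- as.integer(trimws(lines[1]))
  comment <- if (length(lines) >= 2) lines[2] else ""
  unit <- "angstrom"
  if (grepl("unit=bohr", comment)) unit <- "bohr"
  split <- if (grepl("monomer_split=", comment))
    as.integer(sub(".*monomer_split=(\\d+).*", "\\1", comment))
  else nat %/% 2L
  rows <- strsplit(trimws(lines[2 + seq_len(nat)]), "\\s+")
  element <- vapply(rows, `[`, "", 1)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  monomer <- rep(c("A", "B"), c(split, nat - split))
  dimer_geometry(element, coords, monomer, unit = unit)
}

#' Swap the monomer labels of a dimer geometry
#' @param geom A `dimer_geometry`.
#' @return The geometry with A and B interchanged.
#' @export
swap_monomers <- function(geom) {
  geom$monomer <- c(A = "B", B = "A")[geom$monomer]
  geom
}
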