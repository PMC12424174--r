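# Basis set handling: parse bundled basis files, build contracted Cartesian
# shells and the Cartesian -> real-spherical-harmonic transformation.

.elements <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
               F = 9, Ne = 10)

.l_codes <- c(S = 0L, P = 1L, D = 2L, F = 3L, G = 4L)

#' Load a Gaussian basis set by name
#'
#' Reads one of the basis set definitions bundled with the package
#' (`aug-cc-pvdz`, `aug-cc-pvtz`, `sto-3g`) or a user file in the same
#' format.  Returns, per element, a list of shells (angular momentum,
#' exponents, contraction coefficients referring to normalized primitives).
#'
#' @param name Basis set name (case-insensitive) or path to a basis file.
#' @return An object of class `basis_set`: named list of elements, each a
#'   list of shells with fields `l`, `exps`, `coefs`.
#' @export
load_basis <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "basis", paste0(tolower(name), ".dat"),
                package = "sapt1dm")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown basis set: ", name)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (lines[i] == "****") { i <- i + 1L; next }
    hdr <- strsplit(lines[i], "\\s+")[[1]]
    elem <- hdr[1]
    i <- i + 1L
    shells <- list()
    while (i <= n && lines[i] != "****") {
      sh <- strsplit(lines[i], "\\s+")[[1]]
      l <- .l_codes[[toupper(sh[1])]]
      nprim <- as.integer(sh[2])
      i <- i + 1L
      ex <- co <- numeric(nprim)
      for (k in seq_len(nprim)) {
        v <- as.numeric(strsplit(lines[i], "\\s+")[[1]])
        ex[k] <- v[1]; co[k] <- v[2]
        i <- i + 1L
      }
      shells[[length(shells) + 1L]] <- list(l = l, exps = ex, coefs = co)
    }
    out[[elem]] <- shells
  }
  structure(list(name = name, elements = out), class = "basis_set")
}

# Normalization of a primitive Cartesian Gaussian x^a y^b z^c exp(-al r^2)
.prim_norm <- function(al, l) {
  # axial component (l,0,0)
  (2 * al / pi)^0.75 * (4 * al)^(l / 2) / sqrt(.dfact(2 * l - 1))
}

.dfact <- function(k) if (k <= 0) 1 else prod(seq(k, 1, by = -2))

# Build the shell list (for the C++ engine) for a geometry.
# Returns list(shells=, ao_atom=, ao_l=, nsph_map=...) where shells carry
# coefficients scaled by primitive norms.
build_shells <- function(geom, basis) {
  shells <- list()
  meta <- list()
  for (ia in seq_along(geom$element)) {
    el <- geom$element[ia]
    bs <- basis$elements[[el]]
    if (is.null(bs)) stop("basis has no entry for element ", el)
    for (sh in bs) {
      co <- sh$coefs * vapply(sh$exps, .prim_norm, 0, l = sh$l)
      shells[[length(shells) + 1L]] <-
        list(l = sh$l, exps = sh$exps, coefs = co,
             center = as.numeric(geom$coords[ia, ]))
      meta[[length(meta) + 1L]] <- list(atom = ia, l = sh$l)
    }
  }
  list(shells = shells, meta = meta)
}

# Real solid harmonic coefficients in terms of Cartesian monomials for l<=2
# (rows: spherical components; columns: Cartesian components in the engine's
# lexicographic order).  Overall scale is irrelevant: spherical AOs are
# normalized numerically against the Cartesian overlap matrix.
.sph_coefs <- function(l) {
  if (l == 0) return(matrix(1, 1, 1))
  if (l == 1) return(diag(3))          # px, py, pz
  if (l == 2) {
    # cart order: xx, xy, xz, yy, yz, zz
    rbind(
      c(-0.5, 0, 0, -0.5, 0, 1),       # d_z2
      c(0, 0, 1, 0, 0, 0),             # d_xz
      c(0, 0, 0, 0, 1, 0),             # d_yz
      c(sqrt(3) / 2, 0, 0, -sqrt(3) / 2, 0, 0),  # d_x2-y2
      c(0, 1, 0, 0, 0, 0))             # d_xy
  } else stop("spherical transform implemented for l <= 2")
}

# Assemble the (nsph x ncart) block-diagonal transform for a shell list,
# normalized so that the resulting spherical AOs have unit self-overlap.
sph_transform <- function(shellinfo, S_cart) {
  blocks <- lapply(shellinfo$shells, function(sh) .sph_coefs(sh$l))
  ncart <- vapply(shellinfo$shells, function(sh) (sh$l + 1) * (sh$l + 2) / 2, 0)
  nsph <- vapply(blocks, nrow, 0L)
  Tm <- matrix(0, sum(nsph), sum(ncart))
  ro <- co <- 0L
  for (i in seq_along(blocks)) {
    Tm[ro + seq_len(nsph[i]), co + seq_len(ncart[i])] <- blocks[[i]]
    ro <- ro + nsph[i]; co <- co + ncart[i]
  }
  nrm <- sqrt(diag(Tm %*% S_cart %*% t(Tm)))
  Tm / nrm
}
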