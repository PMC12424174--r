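# Dimer system: AO integrals in the dimer-centered basis.
#
# Every monomer calculation uses the full dimer AO set (partner atoms act as
# ghost centers carrying basis functions but no charge), the dimer-centered
# basis (DCBS) convention.  All AO-level tensors are kept in the Cartesian
# primitive basis; orbitals live in the normalized real-spherical AO basis.

#' Build a dimer system in the dimer-centered basis
#'
#' Computes AO overlap, kinetic and per-monomer nuclear-attraction matrices,
#' the two-electron integrals (chemists' notation, 8-fold packed), the
#' Cartesian-to-spherical transform, and the intermonomer nuclear repulsion.
#'
#' @param geom A [dimer_geometry()].
#' @param basis Basis set name (resolved via [load_basis()]) or a
#'   `basis_set` object.
#' @param screen_tol Schwarz screening threshold for two-electron integrals.
#' @param lindep_tol Eigenvalue threshold below which AO-overlap directions
#'   are dropped by canonical orthogonalization (with a warning).
#' @return A `dimer_system` object.
#' @export
build_dimer_system <- function(geom, basis, screen_tol = 1e-12,
                               lindep_tol = 1e-8) {
  stopifnot(inherits(geom, "dimer_geometry"))
  bs <- if (inherits(basis, "basis_set")) basis else load_basis(basis)
  si <- build_shells(geom, bs)
  Sc <- cpp_one_electron(si$shells, 0L)
  Tc <- cpp_one_electron(si$shells, 1L)
  maskA <- geom$monomer == "A"
  VcA <- cpp_nuclear(si$shells, geom$coords[maskA, , drop = FALSE],
                     geom$charge[maskA])
  VcB <- cpp_nuclear(si$shells, geom$coords[!maskA, , drop = FALSE],
                     geom$charge[!maskA])
  Tsph <- sph_transform(si, Sc)
  S <- Tsph %*% Sc %*% t(Tsph)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  keep <- ev$values > lindep_tol
  if (!all(keep))
    warning(sprintf("AO basis near-linearly dependent: dropping %d of %d functions (smallest overlap eigenvalue %.2e)",
                    sum(!keep), length(keep), min(ev$values)))
  X <- ev$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(ev$values[keep]), sum(keep))
  eri <- cpp_eri(si$shells, screen_tol)
  # nuclear repulsion: within monomers and between them
  nn <- function(idx) {
    e <- 0
    idx <- which(idx)
    if (length(idx) < 2) return(0)
    for (i in idx) for (j in idx) if (j > i)
      e <- e + geom$charge[i] * geom$charge[j] /
        sqrt(sum((geom$coords[i, ] - geom$coords[j, ])^2))
    e
  }
  V_AB <- 0
  for (i in which(maskA)) for (j in which(!maskA))
    V_AB <- V_AB + geom$charge[i] * geom$charge[j] /
      sqrt(sum((geom$coords[i, ] - geom$coords[j, ])^2))
  structure(list(
    geom = geom, basis_name = bs$name, shellinfo = si,
    nao_cart = ncol(Sc), nao = nrow(S),
    Tsph = Tsph, S = S, X = X, Tkin = Tsph %*% Tc %*% t(Tsph),
    V_A = Tsph %*% VcA %*% t(Tsph), V_B = Tsph %*% VcB %*% t(Tsph),
    eri = eri, V_AB = V_AB, E_nn_A = nn(maskA), E_nn_B = nn(!maskA),
    nelec_A = sum(geom$charge[maskA]), nelec_B = sum(geom$charge[!maskA]),
    smin = min(ev$values), cache = new.env(parent = emptyenv())),
    class = "dimer_system")
}

#' @export
print.dimer_system <- function(x, ...) {
  cat(sprintf("dimer system: %d spherical AOs (%d Cartesian), basis %s\n",
              x$nao, x$nao_cart, x$basis_name))
  cat(sprintf("  N_A = %d, N_B = %d, V_AB = %.8f Eh, min overlap eigenvalue %.2e\n",
              x$nelec_A, x$nelec_B, x$V_AB, x$smin))
  invisible(x)
}

# monomer one-electron Hamiltonian (own nuclei only) in spherical AO basis
monomer_hcore <- function(sys, monomer) {
  sys$Tkin + if (monomer == "A") sys$V_A else sys$V_B
}

# transform MO coefficient matrix (spherical AO x norb) to Cartesian AO rows
mo_to_cart <- function(sys, C) t(sys$Tsph) %*% C

# general MO-basis two-electron tensor over four coefficient sets
# (chemists' order: T[i,j,k,l] = (ij|kl) with i,j from C1,C2 / k,l from C3,C4)
mo_eri <- function(sys, C1, C2, C3 = C1, C4 = C2) {
  c1 <- mo_to_cart(sys, C1); c2 <- mo_to_cart(sys, C2)
  c3 <- mo_to_cart(sys, C3); c4 <- mo_to_cart(sys, C4)
  if (is.null(sys$cache$G))
    sys$cache$G <- cpp_unpack_eri(sys$eri, sys$nao_cart)
  v <- cpp_transform_eri_g(sys$cache$G, sys$nao_cart, c1, c2, c3, c4)
  array(v, dim = c(ncol(C1), ncol(C2), ncol(C3), ncol(C4)))
}
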