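# Restricted Hartree-Fock for a monomer in the dimer-centered basis.

# eigen() sorts decreasing; chemistry wants ascending orbital energies
.eig_asc <- function(M) {
  eg <- eigen(M, symmetric = TRUE)
  o <- order(eg$values)
  list(values = eg$values[o], vectors = eg$vectors[, o, drop = FALSE])
}

# Fock build from AO (spherical) density using the Cartesian ERI store:
# J and K are formed in the Cartesian basis and transformed back.
.fock_jk <- function(sys, D_sph) {
  Dc <- t(sys$Tsph) %*% D_sph %*% sys$Tsph
  n <- sys$nao_cart
  JK <- cpp_jk(sys$eri, n, Dc)
  list(J = sys$Tsph %*% JK$J %*% t(sys$Tsph),
       K = sys$Tsph %*% JK$K %*% t(sys$Tsph))
}

#' Restricted Hartree-Fock solution for one monomer
#'
#' Solves the closed-shell SCF equations for monomer A or B in the full
#' dimer-centered basis (ghost functions on the partner monomer).
#'
#' @param sys A [build_dimer_system()] handle.
#' @param monomer `"A"` or `"B"`.
#' @param conv Convergence threshold on the DIIS error norm.
#' @param maxiter Maximum SCF iterations.
#' @param C0 Optional orbitals from a nearby geometry (warm start).
#' @return List with MO coefficients `C` (spherical AO basis), orbital
#'   energies, total energy, number of doubly occupied orbitals.
#' @export
rhf <- function(sys, monomer, conv = 1e-9, maxiter = 120, C0 = NULL) {
  key <- paste0("rhf_", monomer)
  if (!is.null(sys$cache) && !is.null(sys$cache[[key]]))
    return(sys$cache[[key]])
  h <- monomer_hcore(sys, monomer)
  nel <- if (monomer == "A") sys$nelec_A else sys$nelec_B
  if (nel %% 2L) stop("RHF requires an even electron count")
  nocc <- nel %/% 2L
  Enn <- if (monomer == "A") sys$E_nn_A else sys$E_nn_B
  X <- sys$X
  if (!is.null(C0)) {
    # warm start: occupied orbitals from a previous (nearby) geometry,
    # re-orthonormalized in the current metric
    Co <- C0[, seq_len(nocc), drop = FALSE]
    M <- t(Co) %*% sys$S %*% Co
    Co <- Co %*% solve(chol(M))
    D <- 2 * Co %*% t(Co)
  } else {
    Fo <- t(X) %*% h %*% X
    eg <- .eig_asc((Fo + t(Fo)) / 2)
    C <- X %*% eg$vectors
    D <- 2 * C[, seq_len(nocc), drop = FALSE] %*% t(C[, seq_len(nocc), drop = FALSE])
  }
  errs <- list(); focks <- list()
  E_old <- 0
  for (it in seq_len(maxiter)) {
    jk <- .fock_jk(sys, D)
    Fm <- h + jk$J - 0.5 * jk$K
    E <- 0.5 * sum(D * (h + Fm)) + Enn
    err <- Fm %*% D %*% sys$S - sys$S %*% D %*% Fm
    errs[[length(errs) + 1L]] <- err
    focks[[length(focks) + 1L]] <- Fm
    if (length(errs) > 8) { errs <- errs[-1]; focks <- focks[-1] }
    ne <- sqrt(sum(err^2))
    if (ne < conv && abs(E - E_old) < 1e-11) {
      Fo <- t(X) %*% Fm %*% X
      eg <- .eig_asc((Fo + t(Fo)) / 2)
      C <- X %*% eg$vectors
      out <- list(C = C, eps = eg$values, E = E, nocc = nocc,
                  monomer = monomer, niter = it)
      if (!is.null(sys$cache)) sys$cache[[key]] <- out
      return(out)
    }
    E_old <- E
    # DIIS extrapolation
    m <- length(errs)
    if (m > 1) {
      Bm <- matrix(0, m + 1, m + 1)
      for (i in seq_len(m)) for (j in seq_len(m))
        Bm[i, j] <- sum(errs[[i]] * errs[[j]])
      Bm[m + 1, seq_len(m)] <- Bm[seq_len(m), m + 1] <- -1
      rhs <- c(rep(0, m), -1)
      co <- tryCatch(solve(Bm, rhs)[seq_len(m)], error = function(e) NULL)
      if (!is.null(co)) {
        Fm <- Reduce(`+`, Map(`*`, focks, co))
      }
    }
    Fo <- t(X) %*% Fm %*% X
    eg <- .eig_asc((Fo + t(Fo)) / 2)
    C <- X %*% eg$vectors
    D <- 2 * C[, seq_len(nocc), drop = FALSE] %*% t(C[, seq_len(nocc), drop = FALSE])
  }
  stop("SCF did not converge for monomer ", monomer)
}
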