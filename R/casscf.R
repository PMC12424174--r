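# State-specific CAS(2,n)SCF: two active electrons in n orbitals above an
# optional closed-shell core, with orbital optimization by a two-step
# scheme (exact active CI + first-order orbital rotations with an
# approximate diagonal Hessian and backtracking line search).
#
# For a two-electron active space the CAS wave function is exactly one
# geminal (APSG with N_K = n), which is how GVB-PP (n = 2) monomer states
# are produced.

# effective one-electron Hamiltonian and energy of the closed-shell core
.core_embed <- function(h, Jc, Kc) h + 2 * Jc - Kc

# closed-shell J/K in MO basis from the AO ERI store for a given set of
# orbitals (columns of C); returns MO-basis matrices over Call columns.
.mo_jk <- function(sys, Call, Ccore) {
  Dc <- 2 * Ccore %*% t(Ccore)
  jk <- .fock_jk(sys, Dc)
  list(J = t(Call) %*% jk$J %*% Call / 2, K = t(Call) %*% jk$K %*% Call / 2)
}

#' State-specific CAS(2,n)SCF for a two-electron-active monomer
#'
#' @param sys A [build_dimer_system()] handle.
#' @param monomer `"A"` or `"B"`.
#' @param ncas Number of active orbitals.
#' @param core Number of doubly occupied core orbitals (kept closed but
#'   variationally optimized).
#' @param root Which CI root to follow (after symmetry filtering).
#' @param symop Optional AO reflection operator (see
#'   [reflection_operator()]); with `sym_char` selects roots whose mirror
#'   character matches (+1 or -1).
#' @param sym_char Target character under `symop`.
#' @param C0 Starting orbitals (default RHF).
#' @param maxiter,conv Orbital optimization control (gradient norm).
#' @return List with optimized orbitals `C` (active columns rotated to the
#'   natural orbitals of the geminal), `core`, `active` column indices,
#'   geminal coefficients `coef`, total `energy`, CI `character`, and the
#'   iteration count.
#' @export
cas2_scf <- function(sys, monomer, ncas, core = 0L, root = 1L, symop = NULL,
                     sym_char = NULL, C0 = NULL, maxiter = 400L, conv = 5e-7) {
  nel <- if (monomer == "A") sys$nelec_A else sys$nelec_B
  if (nel != 2L * core + 2L) stop("cas2_scf needs N = 2*core + 2 electrons")
  Enn <- if (monomer == "A") sys$E_nn_A else sys$E_nn_B
  hAO <- monomer_hcore(sys, monomer)
  if (is.null(C0)) {
    # natural-orbital starting guess: correlating orbitals of a CI in (a
    # window of) the virtual space, which puts the active set close to its
    # optimum and keeps the orbital optimization to a few iterations
    Chf <- rhf(sys, monomer)$C
    nmo_ <- ncol(Chf)
    if (core == 0L) {
      froot <- if (!is.null(sym_char)) {
        ff <- fci2(sys, monomer, C = Chf, nroots = 8L, symop = symop)
        sel <- which(abs(ff$characters - sym_char) < 0.5)
        if (!length(sel)) stop("no FCI root with requested character for the guess")
        ff$gmats[[sel[1]]]
      } else fci2(sys, monomer, C = Chf, nroots = 1L)$gmats[[1]]
      C0 <- Chf %*% gem_natural(froot)$U
    } else {
      win <- (core + 1L):min(nmo_, core + 20L)
      Cwin <- Chf[, win, drop = FALSE]
      h <- t(Cwin) %*% hAO %*% Cwin
      jkc <- .mo_jk(sys, Cwin, Chf[, seq_len(core), drop = FALSE])
      heff <- h + 2 * jkc$J - jkc$K
      gw <- mo_eri(sys, Cwin, Cwin, Cwin, Cwin)
      Hp <- cpp_fci2_hamiltonian(heff, as.numeric(gw), length(win))
      sol <- cpp_davidson(Hp, 1L, 1e-10, 200L)
      U <- gem_natural(pairvec_to_g(sol$vectors[, 1], length(win)))$U
      C0 <- Chf
      C0[, win] <- Cwin %*% U
    }
  }
  # tolerate starting orbitals from a nearby geometry
  C0 <- C0 %*% solve(chol(t(C0) %*% sys$S %*% C0))
  nmo <- ncol(C0)
  C <- C0
  icore <- seq_len(core)
  iact <- core + seq_len(ncas)
  iocc <- c(icore, iact)
  ia <- which(iocc %in% iact)
  g_prev <- NULL

  # one quarter transform per iteration serves the core embedding, the
  # active CI and the orbital gradient
  iterate <- function(C) {
    h <- t(C) %*% hAO %*% C
    Cocc <- C[, iocc, drop = FALSE]
    vmoc <- mo_eri(sys, C, Cocc, Cocc, Cocc)   # (m q | r s), q,r,s in occ
    # core embedding
    Ecore <- 0
    heff <- h[iact, iact]
    if (core > 0) {
      icp <- which(iocc %in% icore)
      Jc <- matrix(0, ncas, ncas); Kc <- matrix(0, ncas, ncas)
      for (c1 in icp) {
        Jc <- Jc + vmoc[iact, ia, c1, c1]
        Kc <- Kc + vmoc[iact, c1, ia, c1]
      }
      heff <- heff + 2 * Jc - Kc
      Ecore <- 2 * sum(diag(h)[icore])
      for (c1 in icp) for (c2 in icp)
        Ecore <- Ecore + 2 * vmoc[iocc[c1], c1, c2, c2] - vmoc[iocc[c1], c2, c1, c2]
    }
    gact <- array(vmoc[iact, ia, ia, ia], rep(ncas, 4))
    H <- cpp_fci2_hamiltonian(heff, as.numeric(gact), ncas)
    npair <- ncas * (ncas + 1) / 2
    nr <- min(npair, max(4L, root + 3L))
    sol <- cpp_davidson(H, as.integer(nr), 1e-11, 200L)
    gms <- lapply(seq_len(ncol(sol$vectors)), function(i)
      pairvec_to_g(sol$vectors[, i], ncas))
    chars <- rep(NA_real_, length(gms))
    if (!is.null(symop)) {
      Cact <- C[, iact, drop = FALSE]
      U <- t(Cact) %*% sys$S %*% symop %*% Cact
      chars <- vapply(gms, function(gm) sum(gm * (U %*% gm %*% t(U))), 0)
    }
    sel <- seq_along(gms)
    if (!is.null(sym_char))
      sel <- sel[!is.na(chars[sel]) & abs(chars[sel] - sym_char) < 0.5]
    if (!length(sel)) stop("no CI root with requested symmetry character")
    if (!is.null(g_prev)) {
      ov <- vapply(sel, function(i) abs(sum(gms[[i]] * g_prev)), 0)
      pick <- sel[which.max(ov)]
    } else pick <- sel[min(root, length(sel))]
    gmat <- gms[[pick]]
    E <- sol$values[pick] + Ecore + Enn
    # orbital gradient from the generalized Fock
    D <- matrix(0, nmo, nmo)
    if (core > 0) diag(D)[icore] <- 2
    D[iact, iact] <- 2 * gmat %*% t(gmat)
    nocc <- length(iocc)
    Do <- D[iocc, iocc]
    Gam <- array(outer(Do, Do), rep(nocc, 4)) -
      0.5 * aperm(array(outer(Do, Do), rep(nocc, 4)), c(1, 4, 3, 2))
    Dact <- 2 * gmat %*% t(gmat)
    Gact2 <- 2 * aperm(array(outer(gmat, gmat), rep(ncas, 4)), c(1, 3, 2, 4))
    wedge <- array(outer(Dact, Dact), rep(ncas, 4)) -
      0.5 * aperm(array(outer(Dact, Dact), rep(ncas, 4)), c(1, 4, 3, 2))
    Gam[ia, ia, ia, ia] <- Gam[ia, ia, ia, ia] + (Gact2 - wedge)
    Fg <- matrix(0, nmo, nmo)
    Fg[, iocc] <- h[, iocc, drop = FALSE] %*% D[iocc, iocc]
    Gm <- matrix(aperm(Gam, c(2, 3, 4, 1)), nocc^3, nocc)
    Vm <- matrix(vmoc, nmo, nocc^3)
    Fg[, iocc] <- Fg[, iocc] + Vm %*% Gm
    list(E = E, g = gmat, char = chars[pick], A = 2 * (Fg - t(Fg)))
  }

  mask <- matrix(FALSE, nmo, nmo)
  ivirt <- setdiff(seq_len(nmo), iocc)
  mask[icore, iact] <- TRUE; mask[icore, ivirt] <- TRUE; mask[iact, ivirt] <- TRUE
  mask <- mask | t(mask)
  Ktot <- matrix(0, nmo, nmo)
  Kprev <- Ktot
  hist_K <- list(); hist_g <- list()
  prec <- NULL
  E_prev <- Inf
  gnorm <- Inf
  scale <- 1
  nstall <- 0L
  for (it in seq_len(maxiter)) {
    ci <- iterate(C)
    if (ci$E > E_prev + 1e-9 && it > 1L) {
      # energy rose: halve the last step, damp future steps, drop history
      Ktot <- (Kprev + Ktot) / 2
      hist_K <- list(); hist_g <- list()
      scale <- max(scale / 2, 0.02)
      C <- C0 %*% .expm_skew(Ktot)
      C <- C %*% solve(chol(t(C) %*% sys$S %*% C))
      E_prev <- Inf
      next
    }
    stalled <- abs(ci$E - E_prev) < 1e-11
    E_prev <- ci$E
    g_prev <- ci$g
    A <- ci$A
    A[!mask] <- 0
    gnorm <- max(abs(A))
    nstall <- if (stalled) nstall + 1L else 0L
    if (gnorm < conv || (nstall >= 20L && gnorm < 1e-5)) {
      nat <- gem_natural(ci$g)
      sgn <- sign(nat$coef[1]); if (sgn == 0) sgn <- 1
      Cnat <- C
      Cnat[, iact] <- C[, iact, drop = FALSE] %*% nat$U
      coef <- sgn * nat$coef
      return(list(C = Cnat, core = icore, active = iact, coef = coef,
                  gmat = diag(coef, ncas, ncas), energy = ci$E,
                  character = ci$char, niter = it, monomer = monomer))
    }
    if (is.null(prec)) {
      # one-time diagonal Hessian estimate from a closed-shell-like Fock
      D <- matrix(0, nmo, nmo)
      if (core > 0) diag(D)[icore] <- 2
      D[iact, iact] <- 2 * ci$g %*% t(ci$g)
      jk <- .fock_jk(sys, C %*% D %*% t(C))
      fmo <- diag(t(C) %*% (hAO + jk$J - 0.5 * jk$K) %*% C)
      occd <- diag(D)
      prec <- outer(occd, occd, `-`) * outer(fmo, fmo, function(a, b) b - a)
      prec <- 2 * pmax(prec, 0.05)
    }
    step <- -A / prec * scale
    mx <- max(abs(step))
    if (mx > 0.3) step <- step * (0.3 / mx)
    if (it %% 40L == 0L) scale <- min(1, scale * 2)  # slow recovery
    Kprev <- Ktot
    Ktot <- Ktot + step
    hist_K[[length(hist_K) + 1L]] <- Ktot
    hist_g[[length(hist_g) + 1L]] <- A
    if (length(hist_K) > 8L) { hist_K <- hist_K[-1]; hist_g <- hist_g[-1] }
    m <- length(hist_K)
    if (m >= 3L) {
      B <- matrix(0, m + 1, m + 1)
      for (i in seq_len(m)) for (j in seq_len(m))
        B[i, j] <- sum(hist_g[[i]] * hist_g[[j]])
      B[m + 1, seq_len(m)] <- B[seq_len(m), m + 1] <- -1
      co <- tryCatch(solve(B, c(rep(0, m), -1))[seq_len(m)],
                     error = function(e) NULL)
      if (!is.null(co) && all(is.finite(co)) && max(abs(co)) < 20) {
        Ktot <- Reduce(`+`, Map(`*`, hist_K, co))
      }
    }
    C <- C0 %*% .expm_skew(Ktot)
    C <- C %*% solve(chol(t(C) %*% sys$S %*% C))
  }
  stop("CASSCF did not converge (gradient ", signif(gnorm, 3), ")")
}

# matrix exponential of a skew-symmetric matrix via eigen of iK (small nmo)
.expm_skew <- function(K) {
  # use the series via squaring for robustness
  nrm <- max(abs(K))
  if (nrm < 1e-14) return(diag(nrow(K)))
  s <- max(0L, ceiling(log2(nrm / 0.25)))
  Ks <- K / 2^s
  E <- diag(nrow(K))
  term <- diag(nrow(K))
  for (i in 1:12) {
    term <- term %*% Ks / i
    E <- E + term
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}
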