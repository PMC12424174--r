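# CI machinery.
#
# Spinorbital convention used throughout the package: for n spatial orbitals,
# spinorbitals 1..n are alpha and n+1..2n are beta; determinants are ordered
# occupation lists (ascending spinorbital index), i.e. |det> =
# a+_{o1} a+_{o2} ... |0> with o1 < o2 < ...  This fixes every phase.

# --- determinant primitives ------------------------------------------------

det_key <- function(occ) paste(occ, collapse = ",")

# apply annihilator a_p: returns list(occ=, sign=) or NULL
det_annihilate <- function(occ, p) {
  i <- match(p, occ)
  if (is.na(i)) return(NULL)
  list(occ = occ[-i], sign = if (i %% 2L) 1 else -1)  # (-1)^(i-1)
}

# apply creator a+_p
det_create <- function(occ, p) {
  if (p %in% occ) return(NULL)
  nbefore <- sum(occ < p)
  occ2 <- sort(c(occ, p))
  list(occ = occ2, sign = if (nbefore %% 2L) -1 else 1)
}

# enumerate determinants for (nalpha, nbeta) electrons in n spatial orbitals
enumerate_dets <- function(n, nalpha, nbeta) {
  av <- if (nalpha > 0) utils::combn(seq_len(n), nalpha, simplify = FALSE) else list(integer(0))
  bv <- if (nbeta > 0) utils::combn(seq_len(n), nbeta, simplify = FALSE) else list(integer(0))
  out <- vector("list", length(av) * length(bv))
  k <- 0L
  for (a in av) for (b in bv) {
    k <- k + 1L
    out[[k]] <- c(a, b + n)
  }
  out
}

# transition element <I| a+_p a_q |J> for single spinorbital pair
.det_tdm1 <- function(occI, occJ) {
  # returns sparse list of (p, q, sign) with <I|a+p aq|J>
  dI <- setdiff(occI, occJ); dJ <- setdiff(occJ, occI)
  if (length(dJ) > 1L) return(NULL)
  if (length(dJ) == 1L) {
    q <- dJ; p <- dI
    a1 <- det_annihilate(occJ, q)
    c1 <- det_create(a1$occ, p)
    if (is.null(c1) || det_key(c1$occ) != det_key(occI)) return(NULL)
    return(list(p = p, q = q, s = a1$sign * c1$sign))
  }
  NULL  # diagonal handled by caller
}

# --- generic dense FCI in a small orbital space -----------------------------

# h: spatial one-electron matrix (n x n); g: spatial ERI array (n,n,n,n)
# chemists' order (pq|rs).  Sz sector fixed by nalpha/nbeta.
#' Full CI in a small orbital space (determinant enumeration)
#'
#' Exact diagonalization over all determinants of a given Sz sector.  Used
#' for validation and for small active spaces; cost grows combinatorially.
#'
#' @param h One-electron integral matrix over n spatial orbitals.
#' @param g Two-electron integrals, array `(n,n,n,n)`, chemists' order.
#' @param nalpha,nbeta Electron counts per spin.
#' @param nroots Number of roots to return.
#' @return List with `energies`, `vectors` (columns = CI vectors), `dets`.
#' @export
fci_small <- function(h, g, nalpha, nbeta, nroots = 1L) {
  n <- nrow(h)
  dets <- enumerate_dets(n, nalpha, nbeta)
  nd <- length(dets)
  spat <- function(p) ifelse(p > n, p - n, p)
  spin <- function(p) ifelse(p > n, 2L, 1L)
  hso <- function(p, q) if (spin(p) == spin(q)) h[spat(p), spat(q)] else 0
  gso <- function(p, q, r, s) {
    # <pq||rs> antisymmetrized physicists = (pr|qs) - (ps|qr) with spin deltas
    t1 <- if (spin(p) == spin(r) && spin(q) == spin(s))
      g[spat(p), spat(r), spat(q), spat(s)] else 0
    t2 <- if (spin(p) == spin(s) && spin(q) == spin(r))
      g[spat(p), spat(s), spat(q), spat(r)] else 0
    t1 - t2
  }
  H <- matrix(0, nd, nd)
  for (I in seq_len(nd)) for (J in seq_len(I)) {
    oI <- dets[[I]]; oJ <- dets[[J]]
    dI <- setdiff(oI, oJ); dJ <- setdiff(oJ, oI)
    nex <- length(dJ)
    v <- 0
    if (nex == 0L) {
      v <- sum(vapply(oI, function(p) hso(p, p), 0))
      if (length(oI) > 1) {
        pr <- utils::combn(oI, 2)
        v <- v + sum(apply(pr, 2, function(x) gso(x[1], x[2], x[1], x[2])))
      }
    } else if (nex == 1L) {
      t <- .det_tdm1(oI, oJ)
      if (!is.null(t)) {
        v <- hso(t$p, t$q)
        for (m in intersect(oI, oJ)) v <- v + gso(t$p, m, t$q, m)
        v <- v * t$s
      }
    } else if (nex == 2L) {
      # double excitation: q1<q2 removed from J, p1<p2 added; the operator
      # string a+_{p1} a+_{p2} a_{q2} a_{q1} applies a+_{p2} first
      q12 <- sort(dJ); p12 <- sort(dI)
      a1 <- det_annihilate(oJ, q12[1]); a2 <- det_annihilate(a1$occ, q12[2])
      c1 <- det_create(a2$occ, p12[2]); c2 <- det_create(c1$occ, p12[1])
      s <- a1$sign * a2$sign * c1$sign * c2$sign
      v <- s * gso(p12[1], p12[2], q12[1], q12[2])
    }
    H[I, J] <- H[J, I] <- v
  }
  eg <- eigen(H, symmetric = TRUE)
  o <- order(eg$values)[seq_len(min(nroots, nd))]
  list(energies = eg$values[o],
       vectors = eg$vectors[, o, drop = FALSE],
       dets = dets, norb = n)
}

# --- two-electron singlet FCI over the full MO space ------------------------

# pair index helpers for p <= q (1-based)
.pair_list <- function(n) {
  P <- integer(0); Q <- integer(0)
  for (p in seq_len(n)) { P <- c(P, rep(p, n - p + 1L)); Q <- c(Q, p:n) }
  list(P = P, Q = Q)
}

# convert pair-basis CI vector to the symmetric geminal matrix g
pairvec_to_g <- function(v, n) {
  pl <- .pair_list(n)
  g <- matrix(0, n, n)
  for (i in seq_along(v)) {
    p <- pl$P[i]; q <- pl$Q[i]
    if (p == q) g[p, p] <- v[i] else g[p, q] <- g[q, p] <- v[i] / sqrt(2)
  }
  g
}

#' Singlet full CI for a two-electron monomer
#'
#' Diagonalizes the two-electron Hamiltonian in the basis of symmetrized
#' spatial orbital pairs (exact singlet FCI) over the supplied orthonormal
#' MO set, which by default spans the full dimer-centered basis.
#'
#' @param sys A [build_dimer_system()] handle.
#' @param monomer `"A"` or `"B"`.
#' @param C MO coefficients (spherical AO x norb), orthonormal; default RHF.
#' @param nroots Number of roots.
#' @param symop Optional AO-basis symmetry operation matrix (see
#'   [reflection_operator()]); characters are reported per root.
#' @return List with `energies`, `gmats` (list of symmetric geminal
#'   matrices in the MO basis), `characters`, `C`, `monomer`.
#' @export
fci2 <- function(sys, monomer, C = NULL, nroots = 1L, symop = NULL) {
  nel <- if (monomer == "A") sys$nelec_A else sys$nelec_B
  if (nel != 2L) stop("fci2 requires a two-electron monomer")
  if (is.null(C)) C <- rhf(sys, monomer)$C
  n <- ncol(C)
  h <- t(C) %*% monomer_hcore(sys, monomer) %*% C
  g <- mo_eri(sys, C, C, C, C)
  H <- cpp_fci2_hamiltonian(h, as.numeric(g), n)
  Enn <- if (monomer == "A") sys$E_nn_A else sys$E_nn_B
  sol <- cpp_davidson(H, as.integer(nroots), 1e-10, 200L)
  gm <- lapply(seq_len(ncol(sol$vectors)), function(i)
    pairvec_to_g(sol$vectors[, i], n))
  chars <- NULL
  if (!is.null(symop)) {
    U <- t(C) %*% sys$S %*% symop %*% C
    chars <- vapply(gm, function(gmat) sum(gmat * (U %*% gmat %*% t(U))), 0)
  }
  list(energies = as.numeric(sol$values) + Enn, gmats = gm,
       characters = chars, C = C, monomer = monomer, nelec = 2L)
}

#' Reflection symmetry operation in the AO basis
#'
#' Builds the AO-coefficient transformation of a reflection through a
#' coordinate plane, assuming the shell centers are symmetric under it
#' (signed permutation of AOs).  Supported planes: `"x"`, `"y"`, `"z"`
#' (normal axis).
#'
#' @param sys A dimer system.
#' @param plane Normal axis of the mirror plane.
#' @return Square matrix `U` acting on spherical-AO coefficient vectors.
#' @export
reflection_operator <- function(sys, plane = "x") {
  ax <- match(plane, c("x", "y", "z"))
  shells <- sys$shellinfo$shells
  # mirror-image shell index for every shell
  cen <- t(vapply(shells, function(s) s$center, numeric(3)))
  cen2 <- cen
  cen2[, ax] <- -cen2[, ax]
  lofsh <- vapply(shells, function(s) s$l, 0L)
  # spherical component counts and per-component reflection signs
  sph_sign <- function(l) {
    if (l == 0) return(1)
    if (l == 1) { s <- c(1, 1, 1); s[ax] <- -1; return(s) }
    if (l == 2) {
      # order: z2, xz, yz, x2-y2, xy
      switch(ax,
             c(1, -1, 1, 1, -1),   # x -> -x
             c(1, 1, -1, 1, -1),   # y -> -y
             c(1, -1, -1, 1, 1))   # z -> -z
    } else stop("reflection supported for l <= 2")
  }
  nsph <- ifelse(lofsh == 0, 1L, ifelse(lofsh == 1, 3L, 2L * lofsh + 1L))
  off <- cumsum(c(0L, nsph))
  U <- matrix(0, sys$nao, sys$nao)
  for (i in seq_along(shells)) {
    # find partner shell: same l, same exponents, mirrored center
    j <- which(vapply(seq_along(shells), function(j2) {
      lofsh[j2] == lofsh[i] &&
        length(shells[[j2]]$exps) == length(shells[[i]]$exps) &&
        all(abs(shells[[j2]]$exps - shells[[i]]$exps) < 1e-12) &&
        all(abs(shells[[j2]]$coefs - shells[[i]]$coefs) < 1e-12) &&
        sum(abs(cen[j2, ] - cen2[i, ])) < 1e-8
    }, TRUE))[1]
    if (is.na(j)) stop("geometry not symmetric under reflection ", plane)
    sg <- sph_sign(lofsh[i])
    for (k in seq_len(nsph[i]))
      U[off[j] + k, off[i] + k] <- sg[k]
  }
  U
}

# natural orbitals of a 2-electron geminal matrix: g = U diag(c) U^T
gem_natural <- function(gmat) {
  eg <- eigen((gmat + t(gmat)) / 2, symmetric = TRUE)
  o <- order(abs(eg$values), decreasing = TRUE)
  list(coef = eg$values[o], U = eg$vectors[, o, drop = FALSE])
}
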