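# Interaction tensors between two monomer orbital sets in the dimer basis.
#
# All blocks are in chemists' notation: v[p,q,r,s] = (pq|rs) where the first
# index pair is the electron-1 charge distribution.  In the operator
# language, v[p,q,r,s] couples the A-side transition p->q with the B-side
# transition r->s.  The modified potential vtilde absorbs the one-electron
# attraction and nuclear repulsion terms divided by electron counts, so the
# whole interaction operator takes a single two-index-pair form.
#
# Four index patterns are required by the exchange expressions:
#   G-block  [p,q,r,s]   p,q in A; r,s in B        (A A | B B)
#   F-block  [p,s1,r,s]  p in A; s1,r,s in B       (A B | B B)
#   D-block  [p,q,r,q1]  p,q,q1 in A; r in B       (A A | B A)
#   C-block  [p,s1,r,q1] p,q1 in A; s1,r in B      (A B | B A)
# The generalized blocks are built by direct AO transformation (never by
# contracting the G-block with truncated overlap sums, which would be exact
# only for a complete orbital set).

#' Interaction tensors for a monomer orbital pair
#'
#' @param sys A [build_dimer_system()] handle.
#' @param orbA,orbB Lists with fields `C` (spherical-AO coefficient matrix of
#'   the support orbitals, orthonormal within the monomer) and `N` (electron
#'   count entering the modified-potential denominators).  An optional
#'   `Dcore` (spherical-AO density of frozen-core electrons excluded from
#'   the support) folds the core Coulomb potential into the one-electron
#'   attraction terms and the frozen charge distributions into the
#'   internuclear term, so that index-range-restricted (frozen-core)
#'   calculations see electrostatically neutral partners.
#' @param blocks Which two-electron patterns to build (subset of
#'   `c("G","F","D","C")`).
#' @param projected If `FALSE` (default) the generalized F/D/C blocks are
#'   built as direct hybrid AO integrals, which is exact when the monomer
#'   orbital sets span the full dimer basis (the production situation: the
#'   resolution of identity behind the generalized modified potential is
#'   then exact, and restricting the remaining indices to the RDM support
#'   loses nothing because RDM elements outside it vanish).  With
#'   `projected = TRUE` they are instead assembled by contracting the
#'   primary block with the overlap over the support orbitals themselves,
#'   which is the consistent operator for a model whose single-particle
#'   basis *is* the truncated support (used when validating against the
#'   determinant-space oracle on reduced spaces).
#' @return An `interaction_tensors` object with overlap `S`, one-electron
#'   attraction blocks, nuclear term `V_AB`, raw blocks `vG`..`vC` and
#'   modified blocks `vtG`..`vtC`, all in hartree.
#' @export
interaction_tensors <- function(sys, orbA, orbB, blocks = c("G", "F", "D", "C"),
                                projected = FALSE, keep_raw = FALSE) {
  if (projected) return(.interaction_tensors_projected(sys, orbA, orbB))
  CA <- orbA$C; CB <- orbB$C
  NA_ <- orbA$N; NB_ <- orbB$N
  if (NA_ <= 0 || NB_ <= 0) stop("electron counts must be positive (vtilde)")
  nA <- ncol(CA); nB <- ncol(CB)
  S <- t(CA) %*% sys$S %*% CB
  # frozen-core screening: valence electrons interact with the partner
  # nucleus plus its frozen core density; the nuclear term becomes the full
  # electrostatic interaction of the two frozen (nucleus + core) systems
  VAop <- sys$V_A; VBop <- sys$V_B
  V_AB <- sys$V_AB
  if (!is.null(orbA$Dcore)) {
    JA <- .fock_jk(sys, orbA$Dcore)$J
    VAop <- VAop + JA
    V_AB <- V_AB + sum(orbA$Dcore * sys$V_B)
  }
  if (!is.null(orbB$Dcore)) {
    JB <- .fock_jk(sys, orbB$Dcore)$J
    VBop <- VBop + JB
    V_AB <- V_AB + sum(orbB$Dcore * sys$V_A)
    if (!is.null(orbA$Dcore)) V_AB <- V_AB + sum(orbA$Dcore * JB)
  }
  vA_BB <- t(CB) %*% VAop %*% CB   # attraction of B electrons to A side
  vB_AA <- t(CA) %*% VBop %*% CA
  vB_AB <- t(CA) %*% VBop %*% CB   # hybrid blocks for generalized vtilde
  vA_BA <- t(CB) %*% VAop %*% CA
  out <- list(S = S, vA_BB = vA_BB, vB_AA = vB_AA, vB_AB = vB_AB,
              vA_BA = vA_BA, V_AB = V_AB, N_A = NA_, N_B = NB_,
              nA = nA, nB = nB)
  dA <- diag(nA); dB <- diag(nB)
  raw <- list()
  if (setequal(blocks, c("G", "F", "D", "C"))) {
    # one AO sweep for all four patterns: second slot runs over A then B,
    # fourth over B then A
    CAB <- cbind(CA, CB); CBA <- cbind(CB, CA)
    big <- mo_eri(sys, CA, CAB, CB, CBA)
    iA2 <- seq_len(nA); iB2 <- nA + seq_len(nB)
    iB4 <- seq_len(nB); iA4 <- nB + seq_len(nA)
    raw$G <- big[, iA2, , iB4, drop = FALSE]
    raw$F <- big[, iB2, , iB4, drop = FALSE]
    raw$D <- big[, iA2, , iA4, drop = FALSE]
    raw$C <- big[, iB2, , iA4, drop = FALSE]
    rm(big)
    dim(raw$G) <- c(nA, nA, nB, nB)
    dim(raw$F) <- c(nA, nB, nB, nB)
    dim(raw$D) <- c(nA, nA, nB, nA)
    dim(raw$C) <- c(nA, nB, nB, nA)
  } else {
    if ("G" %in% blocks) raw$G <- mo_eri(sys, CA, CA, CB, CB)
    if ("F" %in% blocks) raw$F <- mo_eri(sys, CA, CB, CB, CB)
    if ("D" %in% blocks) raw$D <- mo_eri(sys, CA, CA, CB, CA)
    if ("C" %in% blocks) raw$C <- mo_eri(sys, CA, CB, CB, CA)
  }
  if (keep_raw) {
    out$vG <- raw$G; out$vF <- raw$F; out$vD <- raw$D; out$vC <- raw$C
  }
  if (!is.null(raw$G)) {
    out$vtG <- raw$G + outer(dA, vA_BB) / NA_ + outer(vB_AA, dB) / NB_ +
      outer(dA, dB) * (V_AB / (NA_ * NB_))
    raw$G <- NULL
  }
  if (!is.null(raw$F)) {
    out$vtF <- raw$F + outer(S, vA_BB) / NA_ + outer(vB_AB, dB) / NB_ +
      outer(S, dB) * (V_AB / (NA_ * NB_))
    raw$F <- NULL
  }
  if (!is.null(raw$D)) {
    out$vtD <- raw$D + outer(dA, vA_BA) / NA_ + outer(vB_AA, t(S)) / NB_ +
      outer(dA, t(S)) * (V_AB / (NA_ * NB_))
    raw$D <- NULL
  }
  if (!is.null(raw$C)) {
    out$vtC <- raw$C + outer(S, vA_BA) / NA_ + outer(vB_AB, t(S)) / NB_ +
      outer(S, t(S)) * (V_AB / (NA_ * NB_))
    raw$C <- NULL
  }
  class(out) <- "interaction_tensors"
  out
}

# support-projected variant: generalized blocks from the primary block by
# overlap contraction within the supports (model-consistent for truncated
# single-particle spaces; equals the direct build when the supports are
# complete in the dimer basis)
.interaction_tensors_projected <- function(sys, orbA, orbB) {
  out <- interaction_tensors(sys, orbA, orbB, blocks = "G", projected = FALSE)
  S <- out$S
  # one-electron hybrids projected the same way
  out$vB_AB <- out$vB_AA %*% S
  out$vA_BA <- out$vA_BB %*% t(S)
  vt <- out$vtG
  # vtF[p,s1,r,s] = sum_q vtG[p,q,r,s] S[q,s1]
  out$vtF <- aperm(tdot(vt, 2L, S, 1L), c(1L, 4L, 2L, 3L))
  # vtD[p,q,r,q1] = sum_s vtG[p,q,r,s] t(S)[s,q1] -> contract dim4 with S dim? S[q1,s]
  out$vtD <- tdot(vt, 4L, t(S), 1L)
  # vtC[p,s1,r,q1] = sum_{q,s} vtG[p,q,r,s] S[q,s1] t(S)[s,q1]
  tmp <- tdot(vt, 2L, S, 1L)            # [p,r,s,s1]
  out$vtC <- aperm(tdot(tmp, 3L, t(S), 1L), c(1L, 3L, 2L, 4L))
  out
}

#' @export
print.interaction_tensors <- function(x, ...) {
  cat(sprintf("interaction tensors: %d A-orbitals x %d B-orbitals (N_A=%g, N_B=%g), V_AB=%.8f\n",
              x$nA, x$nB, x$N_A, x$N_B, x$V_AB))
  invisible(x)
}

# expand a spatial 4-index block into the spinorbital block with spin
# deltas on each index pair: pattern gives for each of the 4 slots whether
# it is on the A side or B side (only used to size the spin blocks).
so_expand4 <- function(v, sideA = c(TRUE, TRUE, FALSE, FALSE)) {
  d <- dim(v)
  m <- 2L * d
  out <- array(0, m)
  i1 <- seq_len(d[1]); i2 <- seq_len(d[2]); i3 <- seq_len(d[3]); i4 <- seq_len(d[4])
  # slots pair as (1,2) electron-1 and (3,4) electron-2: same spin within pair
  for (s1 in 0:1) for (s2 in 0:1) {
    out[i1 + s1 * d[1], i2 + s1 * d[2], i3 + s2 * d[3], i4 + s2 * d[4]] <- v
  }
  out
}

# spinorbital overlap between supports (block diagonal in spin)
so_overlap <- function(S) {
  nA <- nrow(S); nB <- ncol(S)
  out <- matrix(0, 2 * nA, 2 * nB)
  out[seq_len(nA), seq_len(nB)] <- S
  out[nA + seq_len(nA), nB + seq_len(nB)] <- S
  out
}
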