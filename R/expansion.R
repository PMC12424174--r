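# Overlap expansion of the first-order energy from density matrices:
# Moszynski-type intermediates, the expectation values <V P_2k> and <P_2k>,
# and the assembly of the electrostatic and exchange terms.
#
# This is the dense ("general DM") path: spinorbital tensors over the
# monomer RDM supports.  The sign (-1)^k of the exchange operators lives in
# the expectation functions; the intermediates are sign-free.

# ---- tensor contraction helper --------------------------------------------

# contract dims `da` of A with dims `db` of B (matched in order); the result
# keeps A's free dims then B's free dims.
tdot <- function(A, da, B, db) {
  dA <- dim(A); dB <- dim(B)
  fa <- setdiff(seq_along(dA), da); fb <- setdiff(seq_along(dB), db)
  Ap <- aperm(A, c(fa, da)); Bp <- aperm(B, c(db, fb))
  dim(Ap) <- c(prod(dA[fa]), prod(dA[da]))
  dim(Bp) <- c(prod(dB[db]), prod(dB[fb]))
  out <- Ap %*% Bp
  newd <- c(dA[fa], dB[fb])
  if (length(newd) <= 1L) return(as.numeric(out))
  array(out, newd)
}

# ---- electrostatics --------------------------------------------------------

#' Electrostatic energy from monomer 1-RDMs
#'
#' The expectation value of the interaction operator over the product state:
#' full contraction of the modified potential with the spin-summed spatial
#' 1-RDMs of the monomers.
#'
#' @param tensors An [interaction_tensors()] object (G block required).
#' @param g1A,g1B Spin-summed spatial 1-RDMs over the supports.
#' @return Energy in hartree.
#' @export
electrostatic_energy <- function(tensors, g1A, g1B) {
  if (any(dim(tensors$vtG)[1:2] != dim(g1A)) ||
      any(dim(tensors$vtG)[3:4] != dim(g1B)))
    stop("1-RDM dimensions do not match the interaction tensors")
  as.numeric(tdot(tdot(tensors$vtG, c(1, 2), g1A, c(1, 2)), c(1, 2), g1B, c(1, 2)))
}

# ---- intermediates (Moszynski-type) ----------------------------------------

# All take spinorbital objects: S (2nA x 2nB), SBA = t(S), and dense RDMs.
# Layouts follow the vtilde blocks:
#   G[p,q,r,s], F[p,s1,r,s], D[p,q,r,q1], C[p,s1,r,q1].

#' Exchange intermediates for the density-matrix expansion
#'
#' Builds the four contraction intermediates of order k from the monomer
#' k- and (k+1)-body RDMs and the intermonomer overlap.  `which` selects
#' the tensor; prefactors (1/k!)^2, 1/(k!(k-1)!), (1/(k-1)!)^2 are included.
#'
#' @param k Exchange order (1 or 2).
#' @param S Spinorbital intermonomer overlap (A x B).
#' @param dmsA,dmsB Monomer `dms` objects (spinorbital, same supports as S).
#' @param which One of `"G"`, `"F"`, `"D"`, `"C"`.
#' @return Dense 4-index intermediate in the layout of the matching
#'   interaction block.
#' @export
exchange_intermediate <- function(k, S, dmsA, dmsB, which = c("G", "F", "D", "C")) {
  which <- match.arg(which)
  SBA <- t(S)
  need <- function(d, rank) {
    x <- if (rank == 1) d$G1 else if (rank == 2) d$G2 else d$G3
    if (is.null(x)) stop("missing RDM of rank ", rank)
    x
  }
  if (k == 1) {
    switch(which,
      G = {
        G2A <- need(dmsA, 2); G2B <- need(dmsB, 2)
        # X[p,q,s1] = sum_p1 G2A[p,p1,q,q1->] S[p1,s1]; done stepwise below
        X <- tdot(G2A, 2L, S, 1L)            # [p,q,q1,s1]
        Y <- tdot(G2B, 2L, SBA, 1L)          # [r,s,s1,q1]
        # G[p,q,r,s] = sum_{q1,s1} X[p,q,q1,s1] Y[r,s,s1,q1]
        G <- tdot(X, c(3L, 4L), Y, c(4L, 3L))  # [p,q,r,s]
        G
      },
      F = {
        G1A <- need(dmsA, 1); G2B <- need(dmsB, 2)
        # F[p,s1,r,s] = sum_{q1,r1} G1A[p,q1] SBA[r1,q1] G2B[r,r1,s,s1]
        X <- tdot(G1A, 2L, SBA, 2L)          # [p,r1]
        Fm <- tdot(X, 2L, G2B, 2L)           # [p, r,s,s1]
        aperm(Fm, c(1L, 4L, 2L, 3L))
      },
      D = {
        G2A <- need(dmsA, 2); G1B <- need(dmsB, 1)
        X <- tdot(G1B, 2L, S, 2L)            # [r,p1]
        Dm <- tdot(X, 2L, G2A, 2L)           # [r, p,q,q1]
        aperm(Dm, c(2L, 3L, 1L, 4L))
      },
      C = {
        G1A <- need(dmsA, 1); G1B <- need(dmsB, 1)
        # C[p,s1,r,q1] = G1A[p,q1] G1B[r,s1]
        aperm(array(outer(G1A, G1B), c(dim(G1A), dim(G1B))), c(1L, 4L, 3L, 2L))
      })
  } else if (k == 2) {
    switch(which,
      G = {
        G3A <- need(dmsA, 3); G3B <- need(dmsB, 3)
        # X[p,q,q1,q2,s1,s2] = sum_{p1,p2} G3A[p,p1,p2,q,q1,q2] S[p1,s1] S[p2,s2]
        X <- tdot(G3A, 2L, S, 1L)            # [p,p2,q,q1,q2,s1]
        X <- tdot(X, 2L, S, 1L)              # [p,q,q1,q2,s1,s2]
        Y <- tdot(G3B, 2L, SBA, 1L)          # [r,r2,s,s1,s2,q1]
        Y <- tdot(Y, 2L, SBA, 1L)            # [r,s,s1,s2,q1,q2]
        0.25 * tdot(X, c(3L, 4L, 5L, 6L), Y, c(5L, 6L, 3L, 4L))
      },
      F = {
        G2A <- need(dmsA, 2); G3B <- need(dmsB, 3)
        # F2[p,s1,r,s] = 1/2 sum S_BA[r1,q1] S[p2,s2] SBA[r2,q2]
        #                G2A[p,p2,q1,q2] G3B[r,r1,r2,s,s1,s2]
        X <- tdot(G2A, 2L, S, 1L)            # [p,q1,q2,s2]
        Y <- tdot(G3B, 2L, SBA, 1L)          # [r,r2,s,s1,s2,q1]
        Y <- tdot(Y, 2L, SBA, 1L)            # [r,s,s1,s2,q1,q2]
        0.5 * aperm(tdot(X, c(2L, 3L, 4L), Y, c(5L, 6L, 4L)), c(1L, 4L, 2L, 3L))
      },
      D = {
        G3A <- need(dmsA, 3); G2B <- need(dmsB, 2)
        X <- tdot(G3A, 2L, S, 1L)            # [p,p2,q,q1,q2,s1]
        X <- tdot(X, 2L, S, 1L)              # [p,q,q1,q2,s1,s2]
        Y <- tdot(G2B, 2L, SBA, 1L)          # [r,s1,s2,q2]
        0.5 * tdot(X, c(4L, 5L, 6L), Y, c(4L, 2L, 3L))  # [p,q,q1, r] -> layout
      },
      C = {
        G2A <- need(dmsA, 2); G2B <- need(dmsB, 2)
        X <- tdot(G2A, 2L, S, 1L)            # [p,q1,q2,s2]
        Y <- tdot(G2B, 2L, SBA, 1L)          # [r,s1,s2,q2]
        # C[p,s1,r,q1] = sum_{q2,s2} X[p,q1,q2,s2] Y[r,s1,s2,q2]
        aperm(tdot(X, c(3L, 4L), Y, c(4L, 3L)), c(1L, 4L, 3L, 2L))
      })
  } else stop("k must be 1 or 2")
}

# fix D2 layout: tdot above returns [p,q,q1,r]; reorder to [p,q,r,q1]
.fix_D2 <- function(D) aperm(D, c(1L, 2L, 4L, 3L))

# ---- expectation values ----------------------------------------------------

#' Expectation value of the k-pair exchange operator from k-RDMs
#'
#' @param k Number of exchanged electron pairs.
#' @param S Spinorbital intermonomer overlap over the supports.
#' @param dmsA,dmsB Monomer `dms` objects.
#' @return `<P_2k>` (dimensionless).
#' @export
expectation_P2k <- function(k, S, dmsA, dmsB) {
  if (k > min(dmsA$N, dmsB$N)) return(0)
  GA <- if (k == 1) dmsA$G1 else if (k == 2) dmsA$G2 else if (k == 3) dmsA$G3
  GB <- if (k == 1) dmsB$G1 else if (k == 2) dmsB$G2 else if (k == 3) dmsB$G3
  if (is.null(GA) || is.null(GB)) stop("missing RDM of rank ", k)
  SBA <- t(S)
  if (k == 1) {
    X <- tdot(GA, 1L, S, 1L)        # [q1, s1]
    Y <- tdot(GB, 1L, SBA, 1L)      # [s1, q1]
    return(-sum(X * t(Y)))
  }
  if (k == 2) {
    X <- tdot(GA, 1L, S, 1L)        # [p2,q1,q2,s1]
    X <- tdot(X, 1L, S, 1L)         # [q1,q2,s1,s2]
    Y <- tdot(GB, 1L, SBA, 1L)      # [r2,s1,s2,q1]
    Y <- tdot(Y, 1L, SBA, 1L)       # [s1,s2,q1,q2]
    return(0.25 * sum(X * aperm(Y, c(3L, 4L, 1L, 2L))))
  }
  if (k == 3) {
    X <- tdot(GA, 1L, S, 1L); X <- tdot(X, 1L, S, 1L); X <- tdot(X, 1L, S, 1L)
    # X[q1,q2,q3,s1,s2,s3]
    Y <- tdot(GB, 1L, SBA, 1L); Y <- tdot(Y, 1L, SBA, 1L); Y <- tdot(Y, 1L, SBA, 1L)
    # Y[s1,s2,s3,q1,q2,q3]
    return(-(1 / 36) * sum(X * aperm(Y, c(4L, 5L, 6L, 1L, 2L, 3L))))
  }
  stop("k must be 1..3 for the dense path")
}

#' Expectation value of V times the k-pair exchange operator
#'
#' Assembles `<V P_2k>` from the four intermediates and the matching
#' modified-potential blocks, including the (-1)^k sign.
#'
#' @param k Exchange order (1 or 2).
#' @param tensors [interaction_tensors()] with all four blocks.
#' @param dmsA,dmsB Monomer `dms` objects over the tensor supports.
#' @return Energy in hartree.
#' @export
expectation_VP2k <- function(k, tensors, dmsA, dmsB) {
  if (k > min(dmsA$N, dmsB$N)) return(0)
  S <- so_overlap(tensors$S)
  vtG <- so_expand4(tensors$vtG)
  vtF <- so_expand4(tensors$vtF)
  vtD <- so_expand4(tensors$vtD)
  vtC <- so_expand4(tensors$vtC)
  G <- exchange_intermediate(k, S, dmsA, dmsB, "G")
  Fm <- exchange_intermediate(k, S, dmsA, dmsB, "F")
  D <- exchange_intermediate(k, S, dmsA, dmsB, "D")
  if (k == 2) D <- .fix_D2(D)
  C <- exchange_intermediate(k, S, dmsA, dmsB, "C")
  (-1)^k * (sum(G * vtG) + sum(Fm * vtF) + sum(D * vtD) + sum(C * vtC))
}

# ---- composition generator and assembly ------------------------------------

#' Terms of the general-order exchange assembly
#'
#' Enumerates the signed products of expectation values whose sum gives the
#' exchange energy proportional to S^(2n): the leading `<V P_2n>` plus, for
#' each s >= 1 and each ordered tuple (k_1..k_s) of positive integers with
#' sum at most n, the term (-1)^s <V P_2(n - sum k)> prod_i <P_2k_i>, where
#' a residual of zero means the bare `<V>`.
#'
#' @param n Half the overlap order (n = 1 gives the S^2 terms).
#' @return List of terms: each has `s`, `k_list`, `residual`, `sign`.
#' @export
generate_compositions <- function(n) {
  if (n < 1) stop("n must be >= 1")
  terms <- list(list(s = 0L, k_list = integer(0), residual = n, sign = 1))
  # ordered tuples of positive integers with sum <= n
  tuples <- list(integer(0))
  for (s in seq_len(n)) {
    new <- list()
    for (tp in tuples) if (length(tp) == s - 1L) {
      left <- n - sum(tp)
      for (k in seq_len(left)) new[[length(new) + 1L]] <- c(tp, k)
    }
    tuples <- c(tuples, new)
  }
  for (tp in tuples) {
    s <- length(tp)
    if (s == 0L) next
    terms[[length(terms) + 1L]] <-
      list(s = s, k_list = tp, residual = n - sum(tp), sign = (-1)^s)
  }
  terms
}

#' General-order exchange energy from supplied expectation values
#'
#' @param n Half the overlap order.
#' @param VP Numeric vector: `VP[k+1]` = `<V P_2k>` for k = 0..n (so `VP[1]`
#'   is `<V>`).
#' @param P Numeric vector: `P[k]` = `<P_2k>` for k = 1..n.
#' @return The exchange energy term proportional to S^(2n).
#' @export
exchange_order_general <- function(n, VP, P) {
  if (length(VP) < n + 1 || (n >= 1 && length(P) < n))
    stop("missing expectation values up to order ", n)
  tot <- 0
  for (tm in generate_compositions(n)) {
    val <- tm$sign * VP[tm$residual + 1L]
    for (k in tm$k_list) val <- val * P[k]
    tot <- tot + val
  }
  tot
}

#' Assemble the first-order interaction energy decomposition
#'
#' @param Velst `<V>` (electrostatic energy).
#' @param P2,VP2 Single-exchange expectation values.
#' @param P4,VP4 Double-exchange expectation values (optional; S^2-only
#'   decompositions leave the S^4 fields NA).
#' @return A `first_order_decomposition` object with fields `E_elst`,
#'   `E_exch_S2`, `E_exch_S4_incr`, `E_exch_S4`, `E_int_S4` and the raw
#'   expectation values, all in hartree.
#' @export
assemble_first_order <- function(Velst, P2, VP2, P4 = NA_real_, VP4 = NA_real_) {
  E2 <- VP2 - Velst * P2
  E4 <- if (is.na(P4) || is.na(VP4)) NA_real_
  else VP4 - VP2 * P2 - Velst * P4 + Velst * P2^2
  structure(list(
    E_elst = Velst, P2 = P2, VP2 = VP2, P4 = P4, VP4 = VP4,
    E_exch_S2 = E2, E_exch_S4_incr = E4,
    E_exch_S4 = if (is.na(E4)) NA_real_ else E2 + E4,
    E_int_S4 = if (is.na(E4)) NA_real_ else Velst + E2 + E4),
    class = "first_order_decomposition")
}

#' @export
print.first_order_decomposition <- function(x, digits = 10, ...) {
  uh <- 1e6
  cat("first-order SRS decomposition (hartree / microhartree):\n")
  rows <- c(E_elst = x$E_elst, `E_exch(S2)` = x$E_exch_S2,
            `E_exch(prop S4)` = x$E_exch_S4_incr, `E_exch(S4)` = x$E_exch_S4,
            `E_int(1)(S4)` = x$E_int_S4)
  for (nm in names(rows))
    cat(sprintf("  %-16s %18.12f   %14.6f\n", nm, rows[[nm]], rows[[nm]] * uh))
  invisible(x)
}

#' Frozen-core correction for an exchange term
#'
#' Hybrid correction: the frozen-core value of a high-level method plus the
#' all-electron-minus-frozen-core difference at the Hartree-Fock level.
#'
#' @param E_fc High-level frozen-core value.
#' @param E_hf All-electron Hartree-Fock value of the same term.
#' @param E_hf_fc Frozen-core Hartree-Fock value.
#' @return Corrected estimate of the all-electron high-level value.
#' @export
frozen_core_correction <- function(E_fc, E_hf, E_hf_fc) E_fc + (E_hf - E_hf_fc)
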