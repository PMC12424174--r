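# k-body reduced density matrices (k <= 3), spinorbital representation.
#
# A `dms` object stores dense spinorbital tensors over a support of n
# spatial orbitals (spinorbitals 1..n alpha, n+1..2n beta):
#   G1[p, q]                = <a+_p a_q>
#   G2[p1, p2, q1, q2]      = <a+_p1 a+_p2 a_q2 a_q1>
#   G3[p1, p2, p3, q1, q2, q3] = <a+_p1 a+_p2 a+_p3 a_q3 a_q2 a_q1>
# i.e. the factorial-free normalization: tr G1 = N, "tr" G2 = N(N-1),
# "tr" G3 = N(N-1)(N-2).

new_dms <- function(n, N, G1, G2 = NULL, G3 = NULL, monomer = NA,
                    struct = NULL) {
  structure(list(n = n, m = 2L * n, N = N, G1 = G1, G2 = G2, G3 = G3,
                 monomer = monomer, struct = struct), class = "dms")
}

#' @export
print.dms <- function(x, ...) {
  cat(sprintf("density matrix set: %d electrons on %d spatial orbitals (ranks:%s)\n",
              x$N, x$n,
              paste(c(" 1", if (!is.null(x$G2)) " 2", if (!is.null(x$G3)) " 3"),
                    collapse = "")))
  invisible(x)
}

# spin-summed spatial 1-RDM (for electrostatics)
dms_spatial1 <- function(d) {
  n <- d$n
  d$G1[seq_len(n), seq_len(n), drop = FALSE] +
    d$G1[n + seq_len(n), n + seq_len(n), drop = FALSE]
}

# ---- trace identities ------------------------------------------------------

#' Check the trace and occupation invariants of a density-matrix set
#'
#' @param d A `dms` object.
#' @return Named vector of deviations: `tr1` (trace of the 1-RDM minus N),
#'   `tr2`, `tr3` likewise for N(N-1) and N(N-1)(N-2), and `occ_range`
#'   (how far the 1-RDM eigenvalues stray from [0, 1]).
#' @export
dms_trace_errors <- function(d) {
  m <- d$m; N <- d$N
  out <- c(tr1 = sum(diag(d$G1)) - N)
  if (!is.null(d$G2)) {
    tr2 <- 0
    for (p in seq_len(m)) for (q in seq_len(m)) tr2 <- tr2 + d$G2[p, q, p, q]
    out["tr2"] <- tr2 - N * (N - 1)
  }
  if (!is.null(d$G3)) {
    tr3 <- 0
    for (p in seq_len(m)) for (q in seq_len(m)) for (r in seq_len(m))
      tr3 <- tr3 + d$G3[p, q, r, p, q, r]
    out["tr3"] <- tr3 - N * (N - 1) * (N - 2)
  }
  ev <- eigen((d$G1 + t(d$G1)) / 2, symmetric = TRUE, only.values = TRUE)$values
  out["occ_range"] <- max(0, max(ev) - 1, -min(ev))
  out
}

# ---- Hartree-Fock (single determinant) -------------------------------------

#' RDMs of a closed-shell determinant
#'
#' The k-RDMs of a single determinant are antisymmetrized products of the
#' 1-RDM (Wick factorization): each element is the determinant of the k x k
#' matrix of 1-RDM elements.
#'
#' @param occ_spatial Indices (within the support) of doubly occupied
#'   spatial orbitals.
#' @param n Support size (number of spatial orbitals).
#' @param kmax Highest rank to build (1..3).
#' @return A `dms` object.
#' @export
hf_rdms <- function(occ_spatial, n, kmax = 3L) {
  m <- 2L * n
  occ_so <- c(occ_spatial, occ_spatial + n)
  g1 <- matrix(0, m, m)
  diag(g1)[occ_so] <- 1
  d <- new_dms(n, 2L * length(occ_spatial), g1,
               struct = list(groups = lapply(occ_spatial, function(o)
                 list(orbs = o, g = matrix(1, 1, 1)))))
  if (kmax >= 2) d$G2 <- .wedge11(g1, g1) / 2
  if (kmax >= 3) d$G3 <- .det3_rdm(g1)
  d
}

# third-order RDM of a determinant: 3x3 determinant of 1-RDM elements,
# expanded over the six permutations
.det3_rdm <- function(g1) {
  m <- nrow(g1)
  O <- array(outer(outer(g1, g1), g1), rep(m, 6))  # [p1,q?,p2,q?,p3,q?]
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  sgns <- c(1, -1, -1, 1, 1, -1)
  G3 <- array(0, rep(m, 6))
  for (i in seq_along(perms)) {
    sig <- perms[[i]]
    # O[p1, qs1, p2, qs2, p3, qs3] where factor j carries q_{sig[j]}
    # target [p1,p2,p3,q1,q2,q3]: source dims: p's at 1,3,5; q_{sig[j]} at 2j
    up <- c(1L, 3L, 5L)
    lo <- integer(3)
    for (j in 1:3) lo[sig[j]] <- 2L * j
    G3 <- G3 + sgns[i] * aperm(O, c(up, lo))
  }
  G3
}

# antisymmetrized product of two 1-RDMs (cross terms of independent
# subsystems); for ga == gb this gives 2x the determinant-factorized G2.
.wedge11 <- function(ga, gb) {
  m <- nrow(ga)
  o1 <- aperm(array(outer(ga, gb), c(m, m, m, m)), c(1, 3, 2, 4))  # ga[p1,q1] gb[p2,q2]
  o2 <- aperm(array(outer(gb, ga), c(m, m, m, m)), c(1, 3, 2, 4))
  x1 <- aperm(array(outer(ga, gb), c(m, m, m, m)), c(1, 3, 4, 2))  # ga[p1,q2] gb[p2,q1]
  x2 <- aperm(array(outer(gb, ga), c(m, m, m, m)), c(1, 3, 4, 2))
  o1 + o2 - x1 - x2
}

# antisymmetrized product of a 2-RDM with a 1-RDM (subsystem cross terms);
# for the G2, G1 of the same determinant gives 3x the factorized G3.
.wedge21 <- function(G2, g1) {
  m <- nrow(g1)
  G3 <- array(0, rep(m, 6))
  # base outer product: O[p1,p2,q1,q2,P,Q] = G2[p1,p2,q1,q2] g1[P,Q]
  O <- array(outer(G2, g1), c(m, m, m, m, m, m))
  # insert the 1-RDM index pair at upper position i and lower position j
  # with parity (-1)^(i+j); remaining indices keep their order.
  for (i in 1:3) for (j in 1:3) {
    sgn <- if ((i + j) %% 2L == 0L) 1 else -1
    up <- append(c(1L, 2L), 5L, after = i - 1L)     # positions of p1,p2,P
    lo <- append(c(3L, 4L), 6L, after = j - 1L)     # positions of q1,q2,Q
    G3 <- G3 + sgn * aperm(O, perm = c(up, lo))
  }
  G3
}

# ---- two-electron singlet geminal ------------------------------------------

# antisymmetric spinorbital pair amplitude of a 2-electron singlet with
# symmetric spatial matrix g: T[p alpha, q beta] = g[p,q],
# T[p beta, q alpha] = -g[q,p].
gem_pair_amplitude <- function(gmat, n = nrow(gmat), orbs = seq_len(nrow(gmat))) {
  m <- 2L * n
  Tm <- matrix(0, m, m)
  Tm[orbs, orbs + n] <- gmat
  Tm[orbs + n, orbs] <- -t(gmat)
  Tm
}

#' RDMs of a two-electron singlet (one geminal)
#'
#' For the state sum_pq g[p,q] a+_{p,alpha} a+_{q,beta} |0> (g symmetric,
#' normalized to sum(g^2) = 1): the 2-RDM is the rank-one outer product of
#' the antisymmetric pair amplitude, and the 3-RDM vanishes.
#'
#' @param gmat Symmetric spatial coefficient matrix over its orbitals.
#' @param n Support size; `orbs` indices of the geminal orbitals within it.
#' @param orbs Geminal orbital indices.
#' @param kmax Highest rank.
#' @return A `dms` object.
#' @export
gem2e_rdms <- function(gmat, n = nrow(gmat), orbs = seq_len(nrow(gmat)),
                       kmax = 3L) {
  m <- 2L * n
  P <- matrix(0, n, n)
  P[orbs, orbs] <- gmat %*% t(gmat)
  g1 <- matrix(0, m, m)
  g1[seq_len(n), seq_len(n)] <- P
  g1[n + seq_len(n), n + seq_len(n)] <- P
  d <- new_dms(n, 2L, g1,
               struct = list(groups = list(list(orbs = orbs, g = gmat))))
  if (kmax >= 2) {
    Tm <- gem_pair_amplitude(gmat, n, orbs)
    d$G2 <- aperm(array(outer(Tm, Tm), c(m, m, m, m)), c(1, 2, 3, 4))
    # outer(Tm, Tm)[p1,p2,q1,q2] = T[p1,p2] T[q1,q2] : already ordered
  }
  if (kmax >= 3) d$G3 <- array(0, rep(m, 6))
  d
}

# ---- generic determinant CI ------------------------------------------------

#' k-RDMs from a determinant CI expansion
#'
#' Direct evaluation of the k-body reduced density matrices by operating on
#' the CI expansion with explicit second-quantized strings.  Exact for any
#' state; cost is combinatorial, intended for small spaces.
#'
#' @param dets List of determinants (ascending spinorbital index vectors).
#' @param coef CI coefficients.
#' @param n Number of spatial orbitals in the support.
#' @param kmax Highest rank (1..3).
#' @param N Electron count (inferred from the determinants by default).
#' @return A `dms` object.
#' @export
ci_rdms <- function(dets, coef, n, kmax = 3L, N = length(dets[[1]])) {
  m <- 2L * n
  if (m > 30L) stop("ci_rdms limited to 30 spinorbitals")
  masks <- vapply(dets, function(o) sum(bitwShiftL(1L, o - 1L)), 0L)
  r <- cpp_ci_rdms(masks, coef, m, as.integer(kmax))
  d <- new_dms(n, N, r$G1)
  if (kmax >= 2) d$G2 <- array(r$G2, rep(m, 4))
  if (kmax >= 3) d$G3 <- array(r$G3, rep(m, 6))
  d
}

# plain-R reference implementation of the same strings (kept as an
# independent check of the bit-level kernel on tiny cases)
.ci_rdms_r <- function(dets, coef, n, kmax = 2L, N = length(dets[[1]])) {
  m <- 2L * n
  keep <- abs(coef) > 1e-14
  dets <- dets[keep]; coef <- coef[keep]
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(dets)) assign(det_key(dets[[i]]), i, envir = lookup)
  d <- new_dms(n, N, matrix(0, m, m))
  if (kmax >= 2) d$G2 <- array(0, rep(m, 4))
  if (kmax >= 3) d$G3 <- array(0, rep(m, 6))
  perms_of <- function(v) {
    if (length(v) == 1L) return(list(v))
    if (length(v) == 2L) return(list(v, v[2:1]))
    list(v[c(1,2,3)], v[c(1,3,2)], v[c(2,1,3)], v[c(2,3,1)], v[c(3,1,2)], v[c(3,2,1)])
  }
  for (k in seq_len(kmax)) {
    if (k > N) next
    for (J in seq_along(dets)) {
      oJ <- dets[[J]]; cJ <- coef[J]
      qsets <- utils::combn(oJ, k, simplify = FALSE)
      for (qs in qsets) for (qt in perms_of(qs)) {
        occ <- oJ; sgn <- 1; ok <- TRUE
        for (i in seq_len(k)) {
          a <- det_annihilate(occ, qt[i])
          if (is.null(a)) { ok <- FALSE; break }
          occ <- a$occ; sgn <- sgn * a$sign
        }
        if (!ok) next
        avail <- seq_len(m)
        psets <- utils::combn(setdiff(avail, occ), k, simplify = FALSE)
        for (ps in psets) for (pt in perms_of(ps)) {
          occ2 <- occ; s2 <- sgn; ok2 <- TRUE
          for (i in rev(seq_len(k))) {
            cr <- det_create(occ2, pt[i])
            if (is.null(cr)) { ok2 <- FALSE; break }
            occ2 <- cr$occ; s2 <- s2 * cr$sign
          }
          if (!ok2) next
          I <- get0(det_key(occ2), envir = lookup, ifnotfound = NULL)
          if (is.null(I)) next
          w <- coef[I] * cJ * s2
          if (w == 0) next
          if (k == 1L) d$G1[pt[1], qt[1]] <- d$G1[pt[1], qt[1]] + w
          else if (k == 2L) d$G2[pt[1], pt[2], qt[1], qt[2]] <-
              d$G2[pt[1], pt[2], qt[1], qt[2]] + w
          else d$G3[pt[1], pt[2], pt[3], qt[1], qt[2], qt[3]] <-
              d$G3[pt[1], pt[2], pt[3], qt[1], qt[2], qt[3]] + w
        }
      }
    }
  }
  d
}

# ---- combination of independent (disjoint-support) subsystems --------------

#' Combine RDM sets of two independent subsystems
#'
#' Both inputs must live on the same support with disjoint occupied orbital
#' blocks (strong orthogonality).  Produces the RDMs of the antisymmetrized
#' product state: wedge sums of the subsystem RDMs.
#'
#' @param d1,d2 `dms` objects on a common support.
#' @param kmax Highest rank for the result.
#' @return A `dms` object for the combined state.
#' @export
dms_combine <- function(d1, d2, kmax = 3L) {
  stopifnot(d1$n == d2$n)
  out <- new_dms(d1$n, d1$N + d2$N, d1$G1 + d2$G1,
                 struct = if (!is.null(d1$struct) && !is.null(d2$struct))
                   list(groups = c(d1$struct$groups, d2$struct$groups)))
  if (kmax >= 2) {
    G2 <- .wedge11(d1$G1, d2$G1)
    if (!is.null(d1$G2)) G2 <- G2 + d1$G2
    if (!is.null(d2$G2)) G2 <- G2 + d2$G2
    out$G2 <- G2
  }
  if (kmax >= 3) {
    m <- out$m
    G3 <- array(0, rep(m, 6))
    if (!is.null(d1$G3)) G3 <- G3 + d1$G3
    if (!is.null(d2$G3)) G3 <- G3 + d2$G3
    if (!is.null(d1$G2)) G3 <- G3 + .wedge21(d1$G2, d2$G1)
    if (!is.null(d2$G2)) G3 <- G3 + .wedge21(d2$G2, d1$G1)
    out$G3 <- G3
  }
  out
}

#' Embed frozen-core orbitals into active-space RDMs
#'
#' Builds full-support RDMs for a state in which the listed core orbitals
#' are doubly occupied in every determinant and the remaining electrons are
#' described by the supplied active-space RDMs.
#'
#' @param d_active `dms` over the full support with core blocks empty.
#' @param core_orbs Spatial indices of the doubly occupied core orbitals.
#' @param kmax Highest rank.
#' @return A `dms` for the full state (trace N_core + N_active).
#' @export
frozen_core_embed_rdms <- function(d_active, core_orbs, kmax = 3L) {
  if (length(core_orbs) == 0L) return(d_active)
  n <- d_active$n
  occ_active <- which(abs(diag(d_active$G1)[seq_len(n)]) > 1e-12)
  if (length(intersect(core_orbs, occ_active)))
    stop("core and active orbital supports overlap")
  core <- hf_rdms(core_orbs, n, kmax = kmax)
  dms_combine(core, d_active, kmax = kmax)
}

#' RDMs of an APSG / GVB-PP geminal product
#'
#' Spin-resolved k-RDMs (k <= 3) assembled from intra-geminal blocks and
#' antisymmetrized inter-geminal products of lower-rank RDMs.
#'
#' @param gem A [geminal_model()].
#' @param n Support size.
#' @param kmax Highest rank.
#' @return A `dms` object.
#' @export
apsg_rdms <- function(gem, n, kmax = 3L) {
  stopifnot(inherits(gem, "geminal_model"))
  parts <- lapply(gem$geminals, function(gk) {
    gm <- diag(gk$coef, length(gk$coef), length(gk$coef))
    gem2e_rdms(gm, n = n, orbs = gk$orbs, kmax = kmax)
  })
  Reduce(function(a, b) dms_combine(a, b, kmax = kmax), parts)
}
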