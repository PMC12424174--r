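# Exact determinant-space oracle.
#
# The zeroth-order state is a tensor product of monomer CI expansions over
# their own (disjoint) spinorbital sets; creation/annihilation operators of
# different monomers commute.  The k-pair exchange operator is applied
# literally as its second-quantized string: after bringing the string into
# application order, the creator part factorizes into "overlap-dressed"
# creators (one per annihilator of the partner monomer), so the operator is
# exact sparse algebra on determinant pairs.  This is the independent truth
# standard for the density-matrix contraction path on tiny systems.

.MAX_ORACLE_SO <- 20L

.occ_to_mask <- function(occ) sum(bitwShiftL(1L, occ - 1L))

#' Product state of two monomer CI expansions
#'
#' @param detsA,detsB Lists of determinants (ascending spinorbital indices,
#'   1..2 nA / 1..2 nB within each monomer).
#' @param coefA,coefB Normalized CI coefficients.
#' @param nA,nB Spatial orbital counts of the two supports.
#' @return A `product_state` object.
#' @export
product_state <- function(detsA, coefA, detsB, coefB, nA, nB) {
  if (abs(sqrt(sum(coefA^2)) - 1) > 1e-12 ||
      abs(sqrt(sum(coefB^2)) - 1) > 1e-12)
    stop("monomer CI vectors must be normalized")
  if (2L * (nA + nB) > .MAX_ORACLE_SO)
    stop("oracle limited to ", .MAX_ORACLE_SO,
         " spinorbitals total; use the density-matrix path")
  mA <- vapply(detsA, .occ_to_mask, 0L)
  mB <- vapply(detsB, .occ_to_mask, 0L)
  # collapse to the product expansion
  grid <- expand.grid(i = seq_along(mA), j = seq_along(mB))
  structure(list(maskA = mA[grid$i], maskB = mB[grid$j],
                 coef = coefA[grid$i] * coefB[grid$j],
                 nA = nA, nB = nB,
                 NA_ = length(detsA[[1]]), NB_ = length(detsB[[1]])),
            class = "product_state")
}

#' Apply the k-pair exchange operator to a product state
#'
#' Literal sparse application of the second-quantized exchange-operator
#' string, including the (-1)^k (1/k!)^2 prefactor.
#'
#' @param state A [product_state()].
#' @param k Number of exchanged pairs.
#' @param S_so Spinorbital intermonomer overlap over the supports.
#' @return A new `product_state` (unnormalized expansion).
#' @export
apply_P2k <- function(state, k, S_so) {
  if (k > min(state$NA_, state$NB_)) {
    return(structure(list(maskA = integer(0), maskB = integer(0),
                          coef = numeric(0), nA = state$nA, nB = state$nB,
                          NA_ = state$NA_, NB_ = state$NB_),
                     class = "product_state"))
  }
  if (k > 3L) stop("oracle implements k <= 3")
  r <- cpp_apply_P2k(state$maskA, state$maskB, state$coef, as.integer(k), S_so)
  structure(list(maskA = r$maskA, maskB = r$maskB, coef = r$coef,
                 nA = state$nA, nB = state$nB,
                 NA_ = state$NA_, NB_ = state$NB_),
            class = "product_state")
}

state_dot <- function(s1, s2)
  cpp_state_dot(s1$maskA, s1$maskB, s1$coef, s2$maskA, s2$maskB, s2$coef)

state_V_dot <- function(bra, vt_so, ket)
  cpp_state_V_dot(bra$maskA, bra$maskB, bra$coef,
                  ket$maskA, ket$maskB, ket$coef,
                  as.numeric(vt_so), dim(vt_so)[1], dim(vt_so)[3])

#' Brute-force expectation table for a product state
#'
#' Computes `<V>`, `<P_2k>` and `<V P_2k>` for k up to `k_max` by explicit
#' operator application, together with the assembled S^2 and S^4 exchange
#' energies and the full symmetrized ratio over all exchange orders.
#'
#' @param state A [product_state()].
#' @param tensors [interaction_tensors()] over the same supports (use
#'   `projected = TRUE` if the supports do not span the dimer basis).
#' @param k_max Highest exchange order to tabulate.
#' @return List with `V`, vectors `P` and `VP` (index k), `E_exch_S2`,
#'   `E_exch_S4_incr`, and `E1_full` = (<V> + <V P>)/(1 + <P>) over every
#'   order up to min(N_A, N_B) (capped at 3 exchanged pairs).
#' @export
brute_expectations <- function(state, tensors, k_max = 2L) {
  vt_so <- so_expand4(tensors$vtG)
  S_so <- so_overlap(tensors$S)
  mA <- 2L * state$nA; mB <- 2L * state$nB
  kful <- min(state$NA_, state$NB_, 3L)
  kk <- min(max(k_max, kful), 3L)
  P <- numeric(kk); VP <- numeric(kk)
  V <- cpp_state_V_dot(state$maskA, state$maskB, state$coef,
                       state$maskA, state$maskB, state$coef,
                       as.numeric(vt_so), mA, mB)
  for (k in seq_len(kk)) {
    if (k > min(state$NA_, state$NB_)) break
    Pk <- apply_P2k(state, k, S_so)
    P[k] <- state_dot(state, Pk)
    VP[k] <- cpp_state_V_dot(state$maskA, state$maskB, state$coef,
                             Pk$maskA, Pk$maskB, Pk$coef,
                             as.numeric(vt_so), mA, mB)
  }
  E2 <- VP[1] - V * P[1]
  E4 <- if (kk >= 2) VP[2] - VP[1] * P[1] - V * P[2] + V * P[1]^2 else NA_real_
  list(V = V, P = P, VP = VP,
       E_exch_S2 = E2, E_exch_S4_incr = E4,
       E1_full = (V + sum(VP[seq_len(kful)])) / (1 + sum(P[seq_len(kful)])))
}
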