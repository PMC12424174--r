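# Geminal models (APSG / GVB-PP) and the approximate CAS(n,n) -> GVB-PP
# mapping based on 2-RDM structure.

#' Construct a geminal model
#'
#' @param geminals List of geminals: each `list(orbs = <orbital indices>,
#'   coef = <expansion coefficients>)` with sum(coef^2) = 1; orbital sets
#'   must be pairwise disjoint (strong orthogonality / Arai theorem).
#' @return A `geminal_model` object.
#' @export
geminal_model <- function(geminals) {
  allorb <- unlist(lapply(geminals, `[[`, "orbs"))
  if (anyDuplicated(allorb)) stop("geminal orbital sets must be disjoint")
  for (g in geminals) {
    if (length(g$orbs) != length(g$coef))
      stop("orbital list and coefficients differ in length")
    if (abs(sum(g$coef^2) - 1) > 1e-10)
      stop("geminal coefficients must be normalized")
  }
  structure(list(geminals = geminals), class = "geminal_model")
}

#' @export
print.geminal_model <- function(x, ...) {
  cat(sprintf("geminal model: %d geminal(s)\n", length(x$geminals)))
  for (i in seq_along(x$geminals)) {
    g <- x$geminals[[i]]
    cat(sprintf("  K=%d  orbitals (%s)  c = (%s)\n", i,
                paste(g$orbs, collapse = ","),
                paste(sprintf("%.4f", g$coef), collapse = ", ")))
  }
  invisible(x)
}

# geminal model -> gem_struct over a support of n orbitals
gem_struct_from_model <- function(gm, n) {
  gem_struct(lapply(gm$geminals, function(g)
    list(orbs = g$orbs, g = diag(g$coef, length(g$coef), length(g$coef)))), n)
}

# spin-summed chemists' 2-RDM of a dms: Gam[u,v,x,y] =
# sum_{s,s'} <a+_{u s} a+_{x s'} a_{y s'} a_{v s}>  (pattern (uv|xy))
dms_spatial2_chem <- function(d) {
  n <- d$n
  G <- array(0, rep(n, 4))
  sp <- list(seq_len(n), n + seq_len(n))
  for (s1 in 1:2) for (s2 in 1:2) {
    blk <- d$G2[sp[[s1]], sp[[s2]], sp[[s1]], sp[[s2]], drop = FALSE]
    # blk[u, x, v, y] -> add to G[u,v,x,y]
    G <- G + aperm(array(blk, rep(n, 4)), c(1, 3, 2, 4))
  }
  G
}

#' Map a valence CAS(n,n) 2-RDM onto a GVB-PP geminal model
#'
#' Pairs each strongly occupied active orbital with exactly one weakly
#' occupied partner by comparing the CAS 2-RDM with the 2-RDM implied by
#' the GVB-PP (perfect-pairing) structure built from the CAS occupation
#' numbers.  The geminal coefficients are c = +/- sqrt(n_occ / 2); the sign
#' of the weak partner is taken from the corresponding pair-coupling 2-RDM
#' element (only products of coefficients are observable; the leading
#' coefficient is chosen positive).  All perfect matchings are scored
#' exhaustively and the minimum-score assignment returned.
#'
#' @param G2 Spin-summed chemists' 2-RDM over the active orbitals, element
#'   `[u,v,x,y]` = sum over spins of `<a+_u a+_x a_y a_v>`.
#' @param occ Occupation numbers of the active orbitals (0..2, summing to
#'   the electron count n).
#' @param threshold Per-element score above which the mapping is rejected
#'   (the CAS state is then not of GVB-PP type).
#' @param warn_threshold Per-element score above which a warning is issued.
#' @return A `geminal_model` with attributes `score` (root-mean-square
#'   deviation of the reconstructed 2-RDM over the compared elements) and
#'   `pairing`.
#' @export
map_cas_to_gvb <- function(G2, occ, threshold = 1e-1, warn_threshold = 1e-2) {
  nact <- length(occ)
  if (abs(sum(occ) - round(sum(occ))) > 1e-6)
    stop("occupation numbers must sum to an integer electron count")
  nel <- round(sum(occ))
  if (nel %% 2L) stop("odd electron count: no perfect pairing exists")
  npair <- nel %/% 2L
  if (nact == npair * 2L || TRUE) {
    strong <- order(occ, decreasing = TRUE)[seq_len(npair)]
    weak <- setdiff(order(occ, decreasing = TRUE), strong)
  }
  if (npair == 1L) {
    # CAS(2,n): one geminal holding every active orbital, no search
    ord <- order(occ, decreasing = TRUE)
    cf <- sqrt(pmax(occ[ord], 0) / 2)
    # signs from the pair-coupling elements against the leading orbital
    s1 <- ord[1]
    for (i in seq_along(ord)[-1]) {
      el <- G2[s1, ord[i], s1, ord[i]]
      if (el < 0) cf[i] <- -cf[i]
    }
    cf <- cf / sqrt(sum(cf^2))
    gm <- geminal_model(list(list(orbs = ord, coef = cf)))
    attr(gm, "score") <- .gvb_score(G2, gm, nact)
    attr(gm, "pairing") <- ord
    return(gm)
  }
  if (npair > 10L) stop("exhaustive pairing search limited to 10 pairs")
  if (length(weak) < npair) stop("not enough weakly occupied partners")
  # score a strong-weak pair by the pair-coupling element
  pair_score <- function(s, w) {
    cs <- sqrt(occ[s] / 2); cw <- sqrt(pmax(occ[w], 0) / 2)
    el <- G2[s, w, s, w]
    abs(abs(el) - 2 * cs * cw)
  }
  Smat <- outer(strong, weak, Vectorize(pair_score))
  # exhaustive over all injective assignments strong -> weak
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- NULL; best_score <- Inf
  for (p in perms(seq_along(weak))) {
    p <- p[seq_len(npair)]
    sc <- sum(Smat[cbind(seq_len(npair), p)])
    if (sc < best_score) { best_score <- sc; best <- p }
  }
  gems <- vector("list", npair)
  for (i in seq_len(npair)) {
    s <- strong[i]; w <- weak[best[i]]
    cs <- sqrt(occ[s] / 2); cw <- sqrt(pmax(occ[w], 0) / 2)
    if (G2[s, w, s, w] < 0) cw <- -cw
    cf <- c(cs, cw); cf <- cf / sqrt(sum(cf^2))
    gems[[i]] <- list(orbs = c(s, w), coef = cf)
  }
  # leftover weak orbitals (occupations ~ 0) are dropped from the model
  gm <- geminal_model(gems)
  score <- .gvb_score(G2, gm, nact)
  attr(gm, "score") <- score
  attr(gm, "pairing") <- vapply(gems, function(g) g$orbs[2], 0)
  if (score > threshold)
    stop(sprintf("no GVB-PP pairing fits this 2-RDM (best per-element score %.3g); best candidates: %s",
                 score, paste(attr(gm, "pairing"), collapse = ",")))
  if (score > warn_threshold)
    warning(sprintf("GVB-PP mapping is approximate for this state (score %.3g)", score))
  gm
}

# rms deviation between the CAS 2-RDM and the one reconstructed from the
# geminal model, over the active block
.gvb_score <- function(G2, gm, nact) {
  d <- apsg_rdms(gm, n = nact, kmax = 2L)
  G2m <- dms_spatial2_chem(d)
  sqrt(mean((G2 - G2m)^2))
}
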