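# Factorized (geminal) evaluation of the exchange expectation values.
#
# A strongly orthogonal product state (APSG/GVB-PP; Hartree-Fock and any
# two-electron singlet are special cases) is described by groups: each group
# carries two electrons on its own disjoint orbital set, with a symmetric
# coefficient matrix g (one doubly occupied orbital: g = 1).  Its k-RDMs
# factorize into per-group pieces:
#   gamma_j = g g^T per spin (one index pair), and
#   Gamma2_j = T_j (x) T_j with the antisymmetric pair amplitude T_j
# (two index pairs); the 3-RDM never has three indices on one group.
# Substituting this structure into the operator classes of the normal-
# ordered V P_2k expansion turns every term into a product of matrix chains
# threaded by intermonomer overlaps, contracted with one modified-potential
# block.  The 3-RDM is never formed; the term count grows with the square
# of the number of geminals and each term costs at most O(n^4), which keeps
# the double-exchange cost within the sixth power of the number of active
# geminal orbitals.

#' Structured geminal-product description of a monomer
#'
#' @param groups List of groups, each `list(orbs = <spatial indices in the
#'   support>, g = <symmetric coefficient matrix>)`; a doubly occupied
#'   orbital is `list(orbs = i, g = matrix(1, 1, 1))`.
#' @param n Support size (spatial orbitals).
#' @return A `gem_struct` object.
#' @export
gem_struct <- function(groups, n) {
  allorb <- unlist(lapply(groups, `[[`, "orbs"))
  if (anyDuplicated(allorb))
    stop("geminal orbital sets overlap (strong orthogonality violated)")
  for (g in groups) {
    nk <- length(g$orbs)
    if (!all(dim(g$g) == nk)) stop("coefficient matrix does not match orbital list")
  }
  structure(list(groups = groups, n = n, N = 2L * length(groups)),
            class = "gem_struct")
}

# per-group spinorbital matrices over the support
.group_mats <- function(gs) {
  n <- gs$n
  lapply(gs$groups, function(gr) {
    P <- gr$g %*% t(gr$g)
    gam <- matrix(0, 2 * n, 2 * n)
    gam[gr$orbs, gr$orbs] <- P
    gam[gr$orbs + n, gr$orbs + n] <- P
    list(gamma = gam, Tm = gem_pair_amplitude(gr$g, n, gr$orbs))
  })
}

# ---- slot/link tables for the operator classes -----------------------------

# Slots are labelled: A-up 0..k (0 = the vtilde slot where present), etc.
# The table builder returns, for a class and order k:
#   slots: data.frame(side, dir, id) and
#   links: list of (slot_i, slot_j) joined by the overlap, plus the vtilde
#   leg assignment (kappa/lambda/mu/nu -> slot).
.class_table <- function(class, k) {
  Aup <- function(i) paste0("Au", i); Alo <- function(i) paste0("Al", i)
  Bup <- function(i) paste0("Bu", i); Blo <- function(i) paste0("Bl", i)
  links <- list(); legs <- NULL
  if (class == "P") {
    aup <- vapply(seq_len(k), Aup, ""); alo <- vapply(seq_len(k), Alo, "")
    bup <- vapply(seq_len(k), Bup, ""); blo <- vapply(seq_len(k), Blo, "")
    for (i in seq_len(k)) {
      links[[length(links) + 1L]] <- c(Aup(i), Blo(i))
      links[[length(links) + 1L]] <- c(Bup(i), Alo(i))
    }
  } else if (class == "G") {
    aup <- vapply(0:k, Aup, ""); alo <- vapply(0:k, Alo, "")
    bup <- vapply(0:k, Bup, ""); blo <- vapply(0:k, Blo, "")
    for (i in seq_len(k)) {
      links[[length(links) + 1L]] <- c(Aup(i), Blo(i))
      links[[length(links) + 1L]] <- c(Bup(i), Alo(i))
    }
    legs <- c(kappa = Aup(0), lambda = Alo(0), mu = Bup(0), nu = Blo(0))
  } else if (class == "F") {
    aup <- vapply(c(0, seq_len(k)[-1]), Aup, "")       # p, p2..pk
    alo <- vapply(seq_len(k), Alo, "")                 # q1..qk
    bup <- vapply(0:k, Bup, ""); blo <- vapply(0:k, Blo, "")
    links[[1]] <- c(Bup(1), Alo(1))
    for (i in seq_len(k)[-1]) {
      links[[length(links) + 1L]] <- c(Aup(i), Blo(i))
      links[[length(links) + 1L]] <- c(Bup(i), Alo(i))
    }
    legs <- c(kappa = Aup(0), lambda = Blo(1), mu = Bup(0), nu = Blo(0))
  } else if (class == "D") {
    aup <- vapply(0:k, Aup, ""); alo <- vapply(0:k, Alo, "")
    bup <- vapply(c(0, seq_len(k)[-1]), Bup, "")       # r, r2..rk
    blo <- vapply(seq_len(k), Blo, "")                 # s1..sk
    links[[1]] <- c(Aup(1), Blo(1))
    for (i in seq_len(k)[-1]) {
      links[[length(links) + 1L]] <- c(Aup(i), Blo(i))
      links[[length(links) + 1L]] <- c(Bup(i), Alo(i))
    }
    legs <- c(kappa = Aup(0), lambda = Alo(0), mu = Bup(0), nu = Alo(1))
  } else if (class == "C") {
    aup <- vapply(c(0, seq_len(k)[-1]), Aup, "")
    alo <- vapply(seq_len(k), Alo, "")
    bup <- vapply(c(0, seq_len(k)[-1]), Bup, "")
    blo <- vapply(seq_len(k), Blo, "")
    for (i in seq_len(k)[-1]) {
      links[[length(links) + 1L]] <- c(Aup(i), Blo(i))
      links[[length(links) + 1L]] <- c(Bup(i), Alo(i))
    }
    legs <- c(kappa = Aup(0), lambda = Blo(1), mu = Bup(0), nu = Alo(1))
  }
  list(Aup = aup, Alo = alo, Bup = bup, Blo = blo, links = links, legs = legs)
}

# assignments of one side's slots to groups: list of (upmap, lomap, sign)
# where upmap/lomap are named integer vectors slot -> group index.
.side_assignments <- function(upslots, loslots, ngroups) {
  k <- length(upslots)
  if (k != length(loslots)) stop("internal: slot imbalance")
  out <- list()
  # distributions: m_j in 0..2, sum = k
  distribute <- function(j, left, acc) {
    if (j > ngroups) {
      if (left == 0L) return(list(acc))
      return(list())
    }
    res <- list()
    for (m in 0:min(2L, left))
      res <- c(res, distribute(j + 1L, left - m, c(acc, m)))
    res
  }
  dists <- distribute(1L, k, integer(0))
  # parity of the permutation taking slot order -> group-blocked order
  perm_parity <- function(assign_vec) {
    # assign_vec: group index per slot position; blocked order sorts stably
    o <- order(assign_vec)
    inv <- 0L
    for (i in seq_along(o)) for (j in seq_len(i - 1L))
      if (o[j] > o[i]) inv <- inv + 1L
    if (inv %% 2L) -1 else 1
  }
  choose_sets <- function(slots, dist) {
    # all ways to pick which slots go to which group (sets, slot order kept)
    res <- list(list(map = integer(0), used = integer(0)))
    maps <- list(stats::setNames(integer(0), character(0)))
    cur <- list(integer(length(slots)))
    # recursive: assign groups slotwise is easier: each slot gets a group,
    # respecting capacity dist
    res <- list()
    rec <- function(i, cap, asg) {
      if (i > length(slots)) { res[[length(res) + 1L]] <<- asg; return() }
      for (j in seq_along(cap)) if (cap[j] > 0L) {
        cap2 <- cap; cap2[j] <- cap2[j] - 1L
        asg2 <- asg; asg2[i] <- j
        rec(i + 1L, cap2, asg2)
      }
    }
    rec(1L, dist, integer(length(slots)))
    res
  }
  for (dist in dists) {
    ups <- choose_sets(upslots, dist)
    los <- choose_sets(loslots, dist)
    for (u in ups) for (l in los) {
      sgn <- perm_parity(u) * perm_parity(l)
      out[[length(out) + 1L]] <-
        list(up = stats::setNames(u, upslots), lo = stats::setNames(l, loslots),
             sign = sgn)
    }
  }
  out
}

# ---- chain walker ----------------------------------------------------------

# Given a full assignment for both sides, decompose the network into paths
# between vtilde legs and closed cycles; return end-matrices and the scalar
# cycle factor.  All matrices are spinorbital over the supports.
.walk_network <- function(tab, asgA, asgB, matsA, matsB, S_so) {
  SBA <- t(S_so)
  slots <- c(tab$Aup, tab$Alo, tab$Bup, tab$Blo)
  side <- function(s) substr(s, 1, 1)
  dir <- function(s) substr(s, 2, 2)
  # factor partner(s) of a slot and matrix retrieval
  grp_of <- function(s) {
    if (side(s) == "A") {
      if (dir(s) == "u") asgA$up[[s]] else asgA$lo[[s]]
    } else {
      if (dir(s) == "u") asgB$up[[s]] else asgB$lo[[s]]
    }
  }
  # factor edges: for each group on each side, its assigned up/lo slots
  fedge <- list()   # slot -> list(to = slot, mat = matrix) possibly via T
  add_fedges <- function(asg, mats, sd) {
    ups <- names(asg$up); los <- names(asg$lo)
    for (j in unique(c(asg$up, asg$lo))) {
      us <- ups[asg$up == j]; ls <- los[asg$lo == j]
      if (length(us) == 1L) {
        # gamma: up -> lo
        fedge[[us]] <<- list(to = ls, mat = mats[[j]]$gamma, tr = FALSE)
        fedge[[ls]] <<- list(to = us, mat = mats[[j]]$gamma, tr = TRUE)
      } else if (length(us) == 2L) {
        Tm <- mats[[j]]$Tm
        fedge[[us[1]]] <<- list(to = us[2], mat = Tm, tr = FALSE)
        fedge[[us[2]]] <<- list(to = us[1], mat = Tm, tr = TRUE)
        fedge[[ls[1]]] <<- list(to = ls[2], mat = Tm, tr = FALSE)
        fedge[[ls[2]]] <<- list(to = ls[1], mat = Tm, tr = TRUE)
      }
    }
  }
  add_fedges(asgA, matsA, "A")
  add_fedges(asgB, matsB, "B")
  # link edges
  ledge <- list()
  for (ln in tab$links) {
    a <- ln[1]; b <- ln[2]
    M <- if (side(a) == "A") S_so else SBA
    ledge[[a]] <- list(to = b, mat = M, tr = FALSE)
    ledge[[b]] <- list(to = a, mat = M, tr = TRUE)
  }
  legs <- tab$legs
  is_leg <- function(s) !is.null(legs) && s %in% legs
  visited <- character(0)
  paths <- list()
  cycfac <- 1
  # walk from each vtilde leg: factor edge first, then link, alternating
  if (!is.null(legs)) {
    for (lg in legs) {
      if (lg %in% visited) next
      cur <- lg
      M <- NULL
      visited <- c(visited, cur)
      repeat {
        fe <- fedge[[cur]]
        Mf <- if (fe$tr) t(fe$mat) else fe$mat
        M <- if (is.null(M)) Mf else M %*% Mf
        cur <- fe$to
        visited <- c(visited, cur)
        if (is_leg(cur)) break
        le <- ledge[[cur]]
        Ml <- if (le$tr) t(le$mat) else le$mat
        M <- M %*% Ml
        cur <- le$to
        visited <- c(visited, cur)
        if (is_leg(cur)) stop("internal: leg reached through a link")
      }
      paths[[length(paths) + 1L]] <- list(from = lg, to = cur, M = M)
    }
  }
  # remaining slots form closed cycles
  for (s0 in slots) {
    if (s0 %in% visited) next
    cur <- s0
    M <- NULL
    start <- s0
    repeat {
      fe <- fedge[[cur]]
      Mf <- if (fe$tr) t(fe$mat) else fe$mat
      M <- if (is.null(M)) Mf else M %*% Mf
      visited <- c(visited, cur)
      cur <- fe$to
      visited <- c(visited, cur)
      le <- ledge[[cur]]
      Ml <- if (le$tr) t(le$mat) else le$mat
      M <- M %*% Ml
      cur <- le$to
      if (cur == start) break
    }
    cycfac <- cycfac * sum(diag(M))
  }
  list(paths = paths, cycfac = cycfac)
}

# spin-summed contraction of a vtilde block with two end matrices
# vt: spatial array [kappa, lambda, mu, nu] with spin deltas within
# (kappa,lambda) and (mu,nu); X, Y spinorbital end matrices with known legs.
.vt_contract <- function(vt, cache, pathlist, legs, nA, nB) {
  stopifnot(length(pathlist) == 2L)
  legname <- function(s) names(legs)[match(s, legs)]
  ends <- lapply(pathlist, function(p) c(legname(p$from), legname(p$to)))
  # orient X to (kappa or lambda first)
  ord <- c("kappa", "lambda", "mu", "nu")
  Xi <- pathlist[[1]]; Yi <- pathlist[[2]]
  ex <- ends[[1]]; ey <- ends[[2]]
  # spin block extraction: legs kappa/lambda are electron-1 (spin sigma);
  # mu/nu electron-2 (spin tau)
  elec <- c(kappa = 1L, lambda = 1L, mu = 2L, nu = 2L)
  dims <- c(kappa = nA, lambda = dim(vt)[2], mu = nB, nu = dim(vt)[4])
  # note: lambda/nu dimensions depend on the block pattern
  blk <- function(M, rows_n, cols_n, rs, cs) {
    M[(rs - 1) * rows_n + seq_len(rows_n), (cs - 1) * cols_n + seq_len(cols_n),
      drop = FALSE]
  }
  pairing_same <- setequal(ex, c("kappa", "lambda"))
  if (pairing_same || setequal(ex, c("mu", "nu"))) {
    # J-type: X over (kappa,lambda), Y over (mu,nu) (or swapped)
    if (setequal(ex, c("mu", "nu"))) { tmp <- Xi; Xi <- Yi; Yi <- tmp; tmp <- ex; ex <- ey; ey <- tmp }
    Xm <- if (ex[1] == "kappa") Xi$M else t(Xi$M)
    Ym <- if (ey[1] == "mu") Yi$M else t(Yi$M)
    nk <- dims["kappa"]; nl <- dims["lambda"]
    nm <- dims["mu"]; nn <- dims["nu"]
    Xs <- blk(Xm, nk, nl, 1, 1) + blk(Xm, nk, nl, 2, 2)
    Ys <- blk(Ym, nm, nn, 1, 1) + blk(Ym, nm, nn, 2, 2)
    Vm <- matrix(vt, nk * nl, nm * nn)
    return(as.numeric(t(as.numeric(Xs)) %*% Vm %*% as.numeric(Ys)))
  }
  # cross pairings: need the permuted block and per-spin-combination sums
  if (setequal(ex, c("kappa", "mu")) || setequal(ex, c("lambda", "nu"))) {
    if (setequal(ex, c("lambda", "nu"))) { tmp <- Xi; Xi <- Yi; Yi <- tmp; tmp <- ex; ex <- ey; ey <- tmp }
    Xm <- if (ex[1] == "kappa") Xi$M else t(Xi$M)   # (kappa, mu)
    Ym <- if (ey[1] == "lambda") Yi$M else t(Yi$M)  # (lambda, nu)
    key <- "perm_kmln"
    if (is.null(cache[[key]])) cache[[key]] <- aperm(vt, c(1, 3, 2, 4))
    vp <- cache[[key]]
    nk <- dims["kappa"]; nm <- dims["mu"]; nl <- dims["lambda"]; nn <- dims["nu"]
    Vm <- matrix(vp, nk * nm, nl * nn)
    tot <- 0
    for (s1 in 1:2) for (s2 in 1:2) {
      Xb <- blk(Xm, nk, nm, s1, s2)
      Yb <- blk(Ym, nl, nn, s1, s2)
      tot <- tot + as.numeric(t(as.numeric(Xb)) %*% Vm %*% as.numeric(Yb))
    }
    return(tot)
  }
  # (kappa, nu) with (lambda, mu)
  if (setequal(ex, c("lambda", "mu"))) { tmp <- Xi; Xi <- Yi; Yi <- tmp; tmp <- ex; ex <- ey; ey <- tmp }
  Xm <- if (ex[1] == "kappa") Xi$M else t(Xi$M)   # (kappa, nu)
  Ym <- if (ey[1] == "lambda") Yi$M else t(Yi$M)  # (lambda, mu)
  key <- "perm_knlm"
  if (is.null(cache[[key]])) cache[[key]] <- aperm(vt, c(1, 4, 2, 3))
  vp <- cache[[key]]
  nk <- dims["kappa"]; nn <- dims["nu"]; nl <- dims["lambda"]; nm <- dims["mu"]
  Vm <- matrix(vp, nk * nn, nl * nm)
  tot <- 0
  for (s1 in 1:2) for (s2 in 1:2) {
    Xb <- blk(Xm, nk, nn, s1, s2)
    Yb <- blk(Ym, nl, nm, s1, s2)
    tot <- tot + as.numeric(t(as.numeric(Xb)) %*% Vm %*% as.numeric(Yb))
  }
  tot
}

# ---- driver ---------------------------------------------------------------

#' Exchange expectation values for geminal-product monomers (fast path)
#'
#' Evaluates `<P_2k>` and `<V P_2k>` (k = 1, 2) for two strongly orthogonal
#' geminal-product monomers by factorized contraction, without forming any
#' 3-RDM.  Numerically identical to the dense density-matrix path.
#'
#' @param tensors [interaction_tensors()] over the supports.
#' @param gsA,gsB [gem_struct()] monomer descriptions.
#' @param kmax Highest exchange order (1 or 2).
#' @return List with `V`, `P` (vector over k), `VP` (vector over k), and
#'   `nterms` (number of factorized terms evaluated, for the cost model).
#' @export
exchange_fastpath <- function(tensors, gsA, gsB, kmax = 2L) {
  nA <- tensors$nA; nB <- tensors$nB
  stopifnot(gsA$n == nA, gsB$n == nB)
  matsA <- .group_mats(gsA); matsB <- .group_mats(gsB)
  S_so <- so_overlap(tensors$S)
  cache <- new.env(parent = emptyenv())
  GA <- length(gsA$groups); GB <- length(gsB$groups)
  nterms <- 0L
  blocks <- list(G = tensors$vtG, F = tensors$vtF, D = tensors$vtD,
                 C = tensors$vtC)
  cache_env <- lapply(blocks, function(b) new.env(parent = emptyenv()))
  P <- numeric(kmax); VP <- numeric(kmax)
  for (k in seq_len(kmax)) {
    # <P_2k>
    tab <- .class_table("P", k)
    asA <- .side_assignments(tab$Aup, tab$Alo, GA)
    asB <- .side_assignments(tab$Bup, tab$Blo, GB)
    acc <- 0
    for (aA in asA) for (aB in asB) {
      w <- .walk_network(tab, aA, aB, matsA, matsB, S_so)
      nterms <- nterms + 1L
      acc <- acc + aA$sign * aB$sign * w$cycfac
    }
    P[k] <- (-1)^k / factorial(k)^2 * acc
    # <V P_2k>: the four operator classes
    pref <- c(G = 1 / factorial(k)^2,
              F = 1 / (factorial(k) * factorial(k - 1)),
              D = 1 / (factorial(k) * factorial(k - 1)),
              C = 1 / factorial(k - 1)^2)
    tot <- 0
    for (cl in c("G", "F", "D", "C")) {
      tab <- .class_table(cl, k)
      nAup <- length(tab$Aup)
      asA <- .side_assignments(tab$Aup, tab$Alo, GA)
      asB <- .side_assignments(tab$Bup, tab$Blo, GB)
      if (!length(asA) || !length(asB)) next
      acc <- 0
      for (aA in asA) for (aB in asB) {
        w <- .walk_network(tab, aA, aB, matsA, matsB, S_so)
        v <- .vt_contract(blocks[[cl]], cache_env[[cl]], w$paths, tab$legs,
                          nA, nB)
        nterms <- nterms + 1L
        acc <- acc + aA$sign * aB$sign * w$cycfac * v
      }
      tot <- tot + pref[[cl]] * acc
    }
    VP[k] <- (-1)^k * tot
  }
  g1A <- Reduce(`+`, lapply(matsA, `[[`, "gamma"))
  g1B <- Reduce(`+`, lapply(matsB, `[[`, "gamma"))
  sp <- function(M, n) M[seq_len(n), seq_len(n), drop = FALSE] +
    M[n + seq_len(n), n + seq_len(n), drop = FALSE]
  V <- electrostatic_energy(tensors, sp(g1A, nA), sp(g1B, nB))
  list(V = V, P = P, VP = VP, nterms = nterms)
}

#' Predicted cost of the fast path
#'
#' Leading-order operation count for the factorized double-exchange
#' evaluation: (number of factorized terms) x (cost of one block
#' contraction, fourth power of the support size) plus the chain algebra.
#'
#' @param gsA,gsB [gem_struct()] descriptions.
#' @return List with `nterms`, `flops` (leading order), and the support
#'   sizes.
#' @export
cost_model <- function(gsA, gsB) {
  GA <- length(gsA$groups); GB <- length(gsB$groups)
  count_side <- function(G, k) {
    # number of slot->group assignments for one side at order k
    tot <- 0L
    for (asg in .side_assignments(paste0("u", seq_len(k + 1)),
                                  paste0("l", seq_len(k + 1)),
                                  G)) tot <- tot + 1L
    tot
  }
  n4 <- (gsA$n * gsB$n)^2
  nt <- 0L
  for (k in 1:2) nt <- nt + count_side(GA, k - 1 + 1) * count_side(GB, k - 1 + 1)
  list(nterms = nt, flops = as.numeric(nt) * n4,
       nA = gsA$n, nB = gsB$n)
}
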